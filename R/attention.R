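# Self-attention gating and fusion. Raw omics features are gated by a
# per-feature sigmoid score (feature-level attention), embedded into a shared
# D-dimensional latent space, gated again by a per-subject scalar sigmoid
# score (omics-level attention), and the M gated latents are concatenated.

#' Build the attention/embedding networks for one configuration
#'
#' Layer sizes follow architecture strings (see
#' \code{\link{parse_layer_string}}): the feature-attention encoder
#' \code{f_i} maps \code{V_i -> V_i}, the omics embedding \code{emb_i} maps
#' \code{V_i -> D} (linear, ReLU, dropout), and the omics-attention encoder
#' \code{g_i} maps \code{D -> 1}. The latent dimension D is shared across
#' all omics layers.
#'
#' @param V integer vector of per-view input dimensions.
#' @param D shared latent dimension.
#' @param dropout dropout probability in the embedding stacks.
#' @param f_strings,emb_strings,g_strings optional explicit architecture
#'   strings per view; defaults are \code{"V-V"}, \code{"V-D-ReLU-DP"} and
#'   \code{"D-1"}.
#' @return list of class \code{attention_config} holding the per-view
#'   networks \code{f}, \code{emb}, \code{g} and the dims.
#' @export
attention_config <- function(V, D, dropout = 0.5, f_strings = NULL,
                             emb_strings = NULL, g_strings = NULL) {
  M <- length(V)
  if (is.null(f_strings)) f_strings <- paste0(V, "-", V)
  if (is.null(emb_strings)) emb_strings <- paste0(V, "-", D, "-ReLU-DP")
  if (is.null(g_strings)) g_strings <- rep(paste0(D, "-1"), M)
  f <- lapply(f_strings, parse_layer_string, dropout = dropout)
  emb <- lapply(emb_strings, parse_layer_string, dropout = dropout)
  g <- lapply(g_strings, parse_layer_string, dropout = dropout)
  for (i in seq_len(M)) {
    if (mlp_in_dim(f[[i]]) != V[i] || mlp_out_dim(f[[i]]) != V[i])
      stop("f must map V_i -> V_i for view ", i)
    if (mlp_in_dim(emb[[i]]) != V[i] || mlp_out_dim(emb[[i]]) != D)
      stop("emb must map V_i -> D for view ", i)
    if (mlp_in_dim(g[[i]]) != D || mlp_out_dim(g[[i]]) != 1L)
      stop("g must map D -> 1 for view ", i)
  }
  structure(list(f = f, emb = emb, g = g, V = as.integer(V),
                 D = as.integer(D), dropout = dropout),
            class = "attention_config")
}

#' Feature-level attention scores
#'
#' Passes the raw features through the feature-attention encoder and a
#' sigmoid, giving one score per feature per subject, strictly in (0, 1).
#'
#' @param x N x V feature matrix for one omics layer.
#' @param f_net the feature-attention network (maps V -> V).
#' @return N x V score matrix.
#' @export
feature_attention <- function(x, f_net) {
  x <- as.matrix(x)
  if (ncol(x) != mlp_in_dim(f_net))
    stop("shape error: ", ncol(x), " features but network expects ",
         mlp_in_dim(f_net))
  sigmoid(mlp_forward(f_net, x, training = FALSE)$out)
}

#' Embed gated features into the shared latent space
#'
#' Multiplies features elementwise by their attention scores and applies
#' the omics embedding stack (linear, ReLU, dropout). Dropout is active
#' only when \code{training = TRUE}.
#'
#' @param x N x V feature matrix.
#' @param fatt N x V feature-attention scores.
#' @param emb_net the embedding network (maps V -> D).
#' @param training logical; enables dropout.
#' @return N x D embedded matrix.
#' @export
embed_omics <- function(x, fatt, emb_net, training = FALSE) {
  x <- as.matrix(x); fatt <- as.matrix(fatt)
  if (!all(dim(x) == dim(fatt)))
    stop("shape error: x and fatt must have identical shapes")
  if (any(fatt < 0 | fatt > 1))
    warning("contract warning: fatt values outside [0, 1]; ",
            "scores should come from feature_attention()")
  mlp_forward(emb_net, x * fatt, training = training)$out
}

#' Omics-level attention score
#'
#' One scalar sigmoid score per subject for a whole omics block, computed
#' from the embedded features.
#'
#' @param x_hat N x D embedded matrix.
#' @param g_net the omics-attention network (maps D -> 1).
#' @return N x 1 score matrix, entries strictly in (0, 1).
#' @export
omics_attention <- function(x_hat, g_net) {
  x_hat <- as.matrix(x_hat)
  if (ncol(x_hat) != mlp_in_dim(g_net))
    stop("shape error: ", ncol(x_hat), " latent dims but network expects ",
         mlp_in_dim(g_net))
  sigmoid(mlp_forward(g_net, x_hat, training = FALSE)$out)
}

#' Apply the omics-level gate
#'
#' The per-subject scalar score is broadcast across all D latent
#' dimensions: \code{z = x_hat * matt}.
#'
#' @param x_hat N x D embedded matrix.
#' @param matt N x 1 (or length-N) gate scores.
#' @return N x D gated latent matrix.
#' @export
apply_omics_attention <- function(x_hat, matt) {
  x_hat <- as.matrix(x_hat)
  matt <- as.vector(matt)
  if (length(matt) != nrow(x_hat))
    stop("shape error: need one gate score per subject")
  x_hat * matt
}

#' Concatenate per-omics latents into the fused representation
#'
#' @param latents list of M matrices, all N x D, in fixed view order.
#' @return N x (M * D) matrix \code{[z_1, ..., z_M]}.
#' @export
fuse <- function(latents) {
  stopifnot(is.list(latents), length(latents) >= 1L)
  ns <- vapply(latents, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("shape error: latents disagree on subject count")
  do.call(cbind, latents)
}
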