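# Cross-omics latent completion. For every ordered view pair (i, k) a small
# encoder-decoder bridge h_ik maps view k's latent to a prediction of view
# i's latent. Bridges are fitted only on subjects observed in both views;
# at imputation time a missing latent is the mean of the bridge predictions
# from all observed source views.

#' Build the bank of cross-omics bridges
#'
#' Creates one encoder--decoder network per ordered pair (i, k), i != k —
#' M(M-1) bridges in total — each mapping the shared latent dimension D to
#' itself through a bottleneck stack (default
#' \code{"D-64-BN-ReLU-32-ReLU-64-BN-ReLU-D"}).
#'
#' @param M number of omics layers.
#' @param D shared latent dimension.
#' @param arch optional architecture string for every bridge.
#' @return list of class \code{bridge_bank}; element \code{nets} is a named
#'   list with keys \code{"i_k"} (predict view i from view k).
#' @export
bridge_bank <- function(M, D, arch = NULL) {
  stopifnot(M >= 2L)
  if (is.null(arch)) arch <- paste0(D, "-64-BN-ReLU-32-ReLU-64-BN-ReLU-", D)
  nets <- list()
  for (i in seq_len(M)) for (k in seq_len(M)) {
    if (i == k) next
    net <- parse_layer_string(arch)
    if (mlp_in_dim(net) != D || mlp_out_dim(net) != D)
      stop("bridge architecture must map D -> D")
    nets[[bridge_key(i, k)]] <- net
  }
  structure(list(nets = nets, M = as.integer(M), D = as.integer(D),
                 arch = arch), class = "bridge_bank")
}

bridge_key <- function(i, k) paste0(i, "_", k)

#' Predict one omics latent from another through a bridge
#'
#' @param z_k N x D latent matrix of the source view k.
#' @param bank a \code{\link{bridge_bank}}.
#' @param i target view index.
#' @param k source view index.
#' @param training logical; \code{FALSE} (default) uses batch-norm running
#'   statistics, making the map deterministic.
#' @return N x D predicted latent for view i.
#' @export
predict_latent <- function(z_k, bank, i, k, training = FALSE) {
  key <- bridge_key(i, k)
  if (is.null(bank$nets[[key]]))
    stop("lookup error: no bridge for pair (", i, ", ", k, ")")
  mlp_forward(bank$nets[[key]], as.matrix(z_k), training = training)$out
}

#' Squared-error reconstruction loss for one bridge
#'
#' Sum over subjects of the squared L2 distance between the predicted and
#' the observed latent.
#'
#' @param pred,target N x D matrices.
#' @return non-negative scalar.
#' @export
pair_reconstruction_loss <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!all(dim(pred) == dim(target)))
    stop("shape error: pred and target must have identical shapes")
  sum((pred - target)^2)
}

#' Total cross-omics reconstruction loss over all ordered pairs
#'
#' Sums \code{\link{pair_reconstruction_loss}} over every ordered pair
#' (i, k), i != k, restricted to subjects observed in BOTH views. With
#' M = 2 and a complete mask this reduces to the bi-view form
#' \code{L_co^{12} + L_co^{21}}.
#'
#' @param latents list of M latent matrices (N x D each).
#' @param bank a \code{\link{bridge_bank}}.
#' @param mask optional N x M availability matrix (default: all observed).
#' @param training passed to \code{\link{predict_latent}}.
#' @return non-negative scalar.
#' @export
total_reconstruction_loss <- function(latents, bank, mask = NULL,
                                      training = FALSE) {
  M <- length(latents)
  if (M < 2L) stop("value error: need at least 2 omics layers")
  N <- nrow(latents[[1]])
  if (is.null(mask)) mask <- matrix(TRUE, N, M)
  total <- 0
  for (i in seq_len(M)) for (k in seq_len(M)) {
    if (i == k) next
    both <- which(mask[, i] & mask[, k])
    if (!length(both)) next
    pred <- predict_latent(latents[[k]][both, , drop = FALSE], bank, i, k,
                           training = training)
    total <- total + pair_reconstruction_loss(
      pred, latents[[i]][both, , drop = FALSE])
  }
  total
}

#' Impute missing latents from observed views through trained bridges
#'
#' Observed latents pass through unchanged. A missing latent for view i of
#' subject j is replaced by the mean of \code{h_ik(z_k)} over all views k
#' observed for that subject; with one observed source the mean degenerates
#' to the single bridge prediction.
#'
#' @param latents list of M latent matrices (rows for unobserved subjects
#'   may contain placeholders; they are overwritten).
#' @param bank a \code{\link{bridge_bank}}.
#' @param mask N x M logical availability matrix.
#' @return list of M mask-complete latent matrices.
#' @export
impute_missing <- function(latents, bank, mask) {
  M <- length(latents)
  mask <- as.matrix(mask) != 0
  if (any(rowSums(mask) < 1L))
    stop("contract violation: subject with zero observed omics layers")
  out <- latents
  for (i in seq_len(M)) {
    miss <- which(!mask[, i])
    if (!length(miss)) next
    acc <- matrix(0, length(miss), ncol(latents[[i]]))
    cnt <- numeric(length(miss))
    for (k in seq_len(M)) {
      if (k == i) next
      have <- mask[miss, k]
      if (!any(have)) next
      rows <- miss[have]
      pred <- predict_latent(latents[[k]][rows, , drop = FALSE], bank, i, k)
      acc[have, ] <- acc[have, ] + pred
      cnt[have] <- cnt[have] + 1
    }
    out[[i]][miss, ] <- acc / cnt
  }
  out
}
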