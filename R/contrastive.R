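# Cross-view contrastive objective. Latent rows from two omics are mapped to
# probability vectors by row-softmax; their batch-averaged outer product is a
# D x D joint probability table P. The loss rewards high mutual information
# between the two views and (for alpha > 0) high marginal entropy per view:
#   L = - sum_{d,d'} P_dd' * ln( P_dd' / (P_d^(alpha+1) * P_d'^(alpha+1)) )

#' Contrastive-loss configuration
#'
#' @param alpha non-negative balance between cross-omics mutual information
#'   and per-omics marginal entropy; \code{alpha = 0} gives pure negative
#'   mutual information. Default 9, the value used by the dual-prediction
#'   contrastive loss this objective adopts.
#' @param epsilon positive numerical floor applied inside logarithms.
#' @return list of class \code{contrastive_config}.
#' @export
contrastive_config <- function(alpha = 9, epsilon = 1e-8) {
  if (alpha < 0) stop("value error: alpha must be >= 0")
  if (epsilon <= 0) stop("value error: epsilon must be > 0")
  structure(list(alpha = alpha, epsilon = epsilon),
            class = "contrastive_config")
}

#' Joint probability table of two latent blocks
#'
#' Rows of both blocks are first mapped to probability vectors by softmax;
#' P is the average over subjects of the outer products, then symmetrized
#' (\code{(P + t(P)) / 2}) and renormalized to sum exactly 1.
#'
#' @param Z_i,Z_k N x D latent matrices (same N; same D).
#' @return list of class \code{joint_distribution} with the D x D matrix
#'   \code{P} and marginals \code{P_d} (rows), \code{P_dp} (columns).
#' @export
joint_distribution <- function(Z_i, Z_k) {
  Z_i <- as.matrix(Z_i); Z_k <- as.matrix(Z_k)
  if (nrow(Z_i) == 0L) stop("value error: need at least one subject")
  if (nrow(Z_i) != nrow(Z_k))
    stop("shape error: latent blocks disagree on subject count")
  Qi <- softmax_rows(Z_i)
  Qk <- softmax_rows(Z_k)
  P <- crossprod(Qi, Qk) / nrow(Qi)
  P <- (P + t(P)) / 2
  P <- P / sum(P)
  structure(list(P = P, P_d = rowSums(P), P_dp = colSums(P)),
            class = "joint_distribution")
}

#' Contrastive loss of one joint table
#'
#' @param jd a \code{\link{joint_distribution}}, or a bare D x D joint
#'   probability matrix.
#' @param alpha non-negative entropy/MI balance.
#' @param epsilon log floor.
#' @return scalar loss; at \code{alpha = 0} it equals minus the mutual
#'   information of the table and is always <= 0.
#' @export
contrastive_pair_loss <- function(jd, alpha = 9, epsilon = 1e-8) {
  if (alpha < 0) stop("value error: alpha must be >= 0")
  P <- if (inherits(jd, "joint_distribution")) jd$P else as.matrix(jd)
  Pd <- rowSums(P)
  Pdp <- colSums(P)
  lP <- log(pmax(P, epsilon))
  lPd <- log(pmax(Pd, epsilon))
  lPdp <- log(pmax(Pdp, epsilon))
  inner <- lP - (alpha + 1) * outer(lPd, rep(1, length(Pdp))) -
    (alpha + 1) * outer(rep(1, length(Pd)), lPdp)
  -sum(P * inner)
}

# gradient of contrastive_pair_loss with respect to the raw latent rows.
# Returns dZ_i and dZ_k for the ordered pair, chaining through row-softmax,
# the outer-product average, symmetrization and renormalization.
contrastive_pair_grad <- function(Z_i, Z_k, alpha, epsilon = 1e-8) {
  n <- nrow(Z_i)
  Qi <- softmax_rows(Z_i)
  Qk <- softmax_rows(Z_k)
  P0 <- crossprod(Qi, Qk) / n
  S <- (P0 + t(P0)) / 2
  sig <- sum(S)
  P <- S / sig
  Pd <- rowSums(P)
  Pdp <- colSums(P)
  lP <- log(pmax(P, epsilon))
  lPd <- log(pmax(Pd, epsilon))
  lPdp <- log(pmax(Pdp, epsilon))
  # dL/dP~ : product rule over the entry itself and both marginals
  g <- -(lP + 1) + (alpha + 1) * outer(lPd + 1, rep(1, length(Pdp))) +
    (alpha + 1) * outer(rep(1, length(Pd)), lPdp + 1)
  # renormalization: P~ = S / sig
  dS <- (g - sum(g * P)) / sig
  # symmetrization: S = (P0 + t(P0)) / 2
  dP0 <- (dS + t(dS)) / 2
  # P0 = crossprod(Qi, Qk) / n
  dQi <- (Qk %*% t(dP0)) / n
  dQk <- (Qi %*% dP0) / n
  # row-softmax backward
  dZi <- (dQi - rowSums(dQi * Qi)) * Qi
  dZk <- (dQk - rowSums(dQk * Qk)) * Qk
  list(dZ_i = dZi, dZ_k = dZk)
}

#' Total contrastive loss over all ordered view pairs
#'
#' Sums \code{\link{contrastive_pair_loss}} over every ordered pair (i, k),
#' i != k, with the joint table built from subjects observed in BOTH views
#' only (imputed latents are excluded so the objective never rewards
#' self-consistency of the completion bridges). A single view gives 0; a
#' pair with no jointly observed subjects contributes 0 with a warning.
#'
#' @param latents list of M latent matrices (N x D each).
#' @param mask optional N x M availability matrix (default all observed).
#' @param cfg a \code{\link{contrastive_config}}.
#' @return scalar loss.
#' @export
contrastive_total <- function(latents, mask = NULL,
                              cfg = contrastive_config()) {
  M <- length(latents)
  if (M < 2L) return(0)
  N <- nrow(latents[[1]])
  if (is.null(mask)) mask <- matrix(TRUE, N, M)
  total <- 0
  for (i in seq_len(M)) for (k in seq_len(M)) {
    if (i == k) next
    both <- which(mask[, i] & mask[, k])
    if (!length(both)) {
      warning("no jointly observed subjects for view pair (", i, ", ", k,
              "); pair contributes 0")
      next
    }
    jd <- joint_distribution(latents[[i]][both, , drop = FALSE],
                             latents[[k]][both, , drop = FALSE])
    total <- total + contrastive_pair_loss(jd, cfg$alpha, cfg$epsilon)
  }
  total
}
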