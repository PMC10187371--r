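# Classification metrics and the experiment harnesses: missing-rate sweep,
# omics-combination ablation, and loss-component ablation.

#' Classification metrics for one prediction set
#'
#' Binary tasks (C = 2) report ACC, F1 on the positive class (class 1) and
#' AUC via the Mann-Whitney rank statistic (ties credited 0.5) on the
#' class-1 scores. Multiclass tasks report ACC, support-weighted mean
#' per-class F1 (WeightedF1) and unweighted mean (MacroF1). Per-class F1
#' with an empty precision/recall denominator is defined as 0.
#'
#' @param probs N x C probability matrix.
#' @param labels 0-based class indices.
#' @return list of class \code{metric_report}; binary fields are populated
#'   iff C = 2.
#' @export
compute_metrics <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  C <- ncol(probs)
  stopifnot(C >= 2L, length(labels) == nrow(probs))
  pred <- max.col(probs) - 1L
  acc <- mean(pred == labels)
  out <- list(ACC = acc, n_test = length(labels))
  if (C == 2L) {
    out$F1 <- f1_class(pred, labels, positive = 1L)
    if (length(unique(labels)) < 2L)
      stop("AUC undefined: only one class present in the labels")
    out$AUC <- rank_auc(probs[, 2L], labels)
  } else {
    f1s <- vapply(0:(C - 1L), function(cl) f1_class(pred, labels, cl), 0)
    support <- vapply(0:(C - 1L), function(cl) sum(labels == cl), 0)
    out$WeightedF1 <- sum(f1s * support) / sum(support)
    out$MacroF1 <- mean(f1s)
  }
  structure(out, class = "metric_report")
}

f1_class <- function(pred, labels, positive) {
  tp <- sum(pred == positive & labels == positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Mann-Whitney AUC of scores for the class-1 subjects, 0.5 credit for ties.
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels != 1L]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' @export
print.metric_report <- function(x, ...) {
  nm <- setdiff(names(x), "n_test")
  cat(paste(sprintf("%s = %.4f", nm, unlist(x[nm])), collapse = ", "),
      sprintf(" (n = %d)\n", x$n_test))
  invisible(x)
}

metrics_row <- function(mr) {
  if (!is.null(mr$F1))
    data.frame(ACC = mr$ACC, F1 = mr$F1, AUC = mr$AUC,
               WeightedF1 = NA_real_, MacroF1 = NA_real_, n_test = mr$n_test)
  else
    data.frame(ACC = mr$ACC, F1 = NA_real_, AUC = NA_real_,
               WeightedF1 = mr$WeightedF1, MacroF1 = mr$MacroF1,
               n_test = mr$n_test)
}

# seeds derived from a run seed, kept inside the 32-bit integer range
derive_seed <- function(seed, offset)
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)

# Train on sp$train and evaluate on sp$test, with fresh availability masks
# drawn at rate eta for both splits (mirroring evaluation on incomplete
# data); eta = 0 leaves the masks complete.
run_one <- function(sp, eta, seed, config_args, mask_test = TRUE) {
  train <- sp$train
  test <- sp$test
  if (eta > 0) {
    train <- set_mask(train, make_missing_mask(n_subjects(train),
                                               n_views(train), eta,
                                               seed = derive_seed(seed, 1)))
    if (mask_test)
      test <- set_mask(test, make_missing_mask(n_subjects(test),
                                               n_views(test), eta,
                                               seed = derive_seed(seed, 2)))
  }
  args <- c(list(V = vapply(train$views, ncol, 1L), C = train$C), config_args)
  model <- train_clclsa(train, do.call(clclsa_config, args), seed = seed)
  list(model = model,
       metrics = compute_metrics(predict(model, test), test$labels),
       train = train, test = test)
}

#' Missing-rate sweep
#'
#' For each missing rate eta and seed, masks the training and (by default)
#' test subjects at rate eta, trains a model and evaluates it, producing a
#' tidy table of metrics — the data behind a performance-vs-missing-rate
#' curve.
#'
#' @param ds an \code{\link{omics_dataset}} (complete; masks are drawn per
#'   run).
#' @param etas missing rates to evaluate, within \code{[0, 1)}.
#' @param seeds integer seeds; each (eta, seed) cell is one run.
#' @param train_fraction train split fraction.
#' @param mask_test also mask the test subjects at rate eta (default);
#'   \code{FALSE} evaluates on complete test data.
#' @param config_args list of extra \code{\link{clclsa_config}} arguments.
#' @return data frame with one row per (eta, seed).
#' @export
missing_rate_sweep <- function(ds, etas = seq(0.1, 0.8, by = 0.1),
                               seeds = 0L, train_fraction = 0.7,
                               mask_test = TRUE, config_args = list()) {
  if (any(etas < 0 | etas >= 1)) stop("value error: etas must lie in [0, 1)")
  rows <- list()
  for (eta in etas) for (s in seeds) {
    sp <- split_dataset(ds, train_fraction, seed = s, stratified = TRUE)
    res <- run_one(sp, eta, s, config_args, mask_test)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(eta = eta, seed = s), metrics_row(res$metrics))
  }
  do.call(rbind, rows)
}

#' Omics-combination ablation
#'
#' Trains and evaluates the model on subsets of the omics layers (e.g. all
#' three layers vs each pair) across missing rates. Two-view combinations
#' exercise the bi-view reconstruction loss; single-view combinations have
#' no bridges and lambda_co is forced to 0.
#'
#' @param ds an \code{\link{omics_dataset}}.
#' @param combos list of integer vectors of view indices; default all views
#'   plus every pair.
#' @param etas missing rates.
#' @param seeds integer seeds.
#' @param train_fraction train split fraction.
#' @param config_args extra \code{\link{clclsa_config}} arguments.
#' @return data frame with one row per (combo, eta, seed).
#' @export
omics_combination_ablation <- function(ds, combos = NULL, etas = 0,
                                       seeds = 0L, train_fraction = 0.7,
                                       config_args = list()) {
  M <- n_views(ds)
  if (is.null(combos)) {
    combos <- list(seq_len(M))
    if (M >= 3L)
      combos <- c(combos, utils::combn(M, 2L, simplify = FALSE))
  }
  rows <- list()
  for (ci in seq_along(combos)) {
    combo <- combos[[ci]]
    if (!length(combo)) stop("value error: empty omics combination")
    sub <- omics_dataset(ds$views[combo], ds$labels,
                         ds$mask[, combo, drop = FALSE],
                         ds$view_names[combo], ds$C)
    cargs <- config_args
    if (length(combo) == 1L) {
      if (!is.null(cargs$weights)) cargs$weights$lambda_co <- 0
      sub_etas <- 0  # a lone view cannot be dropped
    } else sub_etas <- etas
    for (eta in sub_etas) for (s in seeds) {
      sp <- split_dataset(sub, train_fraction, seed = s, stratified = TRUE)
      res <- run_one(sp, eta, s, cargs)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(combo = paste(ds$view_names[combo], collapse = "+"),
                         eta = eta, seed = s), metrics_row(res$metrics))
    }
  }
  do.call(rbind, rows)
}

#' Loss-component ablation
#'
#' Compares four configurations at a fixed missing rate, all with the
#' cross-omics bridges active (lambda_co fixed, default 0.1):
#' \describe{
#'   \item{plain}{no contrastive loss, no auxiliary loss, attention gates
#'     bypassed (scores fixed at 1);}
#'   \item{ctst}{contrastive loss only;}
#'   \item{aux}{attention gating + auxiliary confidence loss only;}
#'   \item{ctst+aux}{the full model.}
#' }
#'
#' @param ds an \code{\link{omics_dataset}}.
#' @param eta missing rate applied to train and test subjects.
#' @param seeds integer seeds; each config x seed is one run.
#' @param lambda_co fixed bridge-loss weight.
#' @param lambda_al,lambda_cl weights used when the component is active.
#' @param train_fraction train split fraction.
#' @param config_args extra \code{\link{clclsa_config}} arguments.
#' @param configs which of the four configurations to run (default all).
#' @return data frame with one row per (config, seed).
#' @export
component_ablation <- function(ds, eta = 0.3, seeds = 0L, lambda_co = 0.1,
                               lambda_al = 0.1, lambda_cl = 0.1,
                               train_fraction = 0.7, config_args = list(),
                               configs = c("plain", "ctst", "aux",
                                           "ctst+aux")) {
  if (lambda_co <= 0)
    stop("value error: the component ablation requires lambda_co > 0")
  configs <- match.arg(configs, several.ok = TRUE)
  all_configs <- list(
    plain = list(weights = loss_weights(0, lambda_co, 0),
                 use_attention = FALSE),
    ctst = list(weights = loss_weights(0, lambda_co, lambda_cl),
                use_attention = FALSE),
    aux = list(weights = loss_weights(lambda_al, lambda_co, 0),
               use_attention = TRUE),
    `ctst+aux` = list(weights = loss_weights(lambda_al, lambda_co, lambda_cl),
                      use_attention = TRUE))
  rows <- list()
  for (nm in configs) for (s in seeds) {
    sp <- split_dataset(ds, train_fraction, seed = s, stratified = TRUE)
    res <- run_one(sp, eta, s, c(all_configs[[nm]], config_args))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(config = nm, eta = eta, seed = s),
            metrics_row(res$metrics))
  }
  do.call(rbind, rows)
}
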