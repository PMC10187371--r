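# Small fixtures built in code; everything is seed-controlled.

tiny_ds <- function(N = 30, M = 3, C = 2, V = c(6, 5, 4), q = 3, delta = 2,
                    sigma_noise = 0.3, eta = 0, seed = 1) {
  simulate_omics(sim_config(N = N, M = M, C = C, V = V[seq_len(M)], q = q,
                            delta = delta, sigma_noise = sigma_noise,
                            eta = eta, seed = seed))
}

tiny_config <- function(V = c(6, 5, 4), C = 2, D = 4, epochs = 30,
                        weights = loss_weights(0.1, 0.1, 0.1), ...) {
  clclsa_config(V = V, C = C, D = D, epochs = epochs, weights = weights,
                bridge_arch = paste0(D, "-6-BN-ReLU-3-ReLU-6-BN-ReLU-", D),
                ...)
}

# random probability rows (softmax of gaussian logits)
random_probs <- function(n, C) {
  p <- matrix(stats::rexp(n * C), n, C)
  p / rowSums(p)
}

# independent brute-force contrastive loss: explicit double loop over the
# joint table, no vectorized shortcuts shared with the implementation
brute_contrastive <- function(P, alpha, eps = 1e-8) {
  D1 <- nrow(P); D2 <- ncol(P)
  Pd <- numeric(D1); Pdp <- numeric(D2)
  for (d in seq_len(D1)) for (dp in seq_len(D2)) {
    Pd[d] <- Pd[d] + P[d, dp]
    Pdp[dp] <- Pdp[dp] + P[d, dp]
  }
  total <- 0
  for (d in seq_len(D1)) for (dp in seq_len(D2)) {
    total <- total - P[d, dp] *
      (log(max(P[d, dp], eps)) - (alpha + 1) * log(max(Pd[d], eps)) -
         (alpha + 1) * log(max(Pdp[dp], eps)))
  }
  total
}

# brute-force joint table from two latent matrices
brute_joint <- function(Zi, Zk) {
  n <- nrow(Zi)
  soft <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  P <- matrix(0, ncol(Zi), ncol(Zk))
  for (j in seq_len(n))
    P <- P + outer(soft(Zi[j, ]), soft(Zk[j, ]))
  P <- P / n
  P <- (P + t(P)) / 2
  P / sum(P)
}

# brute-force metrics from confusion counts and pairwise AUC counting
brute_metrics <- function(probs, labels) {
  C <- ncol(probs)
  pred <- apply(probs, 1L, which.max) - 1L
  acc <- mean(pred == labels)
  per_class_f1 <- function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  if (C == 2L) {
    s <- probs[, 2L]
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (s[a] > s[b]) + 0.5 * (s[a] == s[b])
    list(ACC = acc, F1 = per_class_f1(1L),
         AUC = conc / (length(pos) * length(neg)))
  } else {
    f1s <- vapply(0:(C - 1L), per_class_f1, 0)
    supp <- vapply(0:(C - 1L), function(cl) sum(labels == cl), 0)
    list(ACC = acc, WeightedF1 = sum(f1s * supp) / sum(supp),
         MacroF1 = mean(f1s))
  }
}

# hash of every parameter in a set of networks (for touched/untouched checks)
params_digest <- function(nets) {
  vals <- unlist(lapply(nets, function(net) lapply(net, function(layer) {
    nm <- clclsa:::param_names(layer)
    if (length(nm)) lapply(nm, function(p) layer[[p]]) else NULL
  })))
  sum(vals * seq_along(vals) %% 97)
}
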