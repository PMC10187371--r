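# Model assembly, loss functions, the two-phase training loop, prediction
# and the lambda grid search.
#
# Total objective:  L = L_clf + lambda_al * L_al + lambda_co * L_co
#                       + lambda_cl * L_cl
# Each epoch runs two optimizer steps: (1) subjects with all omics layers
# update every component (classifiers, attention encoders, bridges,
# contrastive alignment); (2) subjects with missing layers have those
# latents completed through the trained bridges and contribute to the
# classification and auxiliary losses only.

#' Loss-component weights
#'
#' @param lambda_al,lambda_co,lambda_cl non-negative weights for the
#'   auxiliary, cross-omics reconstruction and contrastive losses.
#' @return list of class \code{loss_weights}.
#' @export
loss_weights <- function(lambda_al = 0.1, lambda_co = 0.1, lambda_cl = 0.1) {
  for (v in c(lambda_al, lambda_co, lambda_cl))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || !is.finite(v))
      stop("value error: lambda weights must be non-negative finite numbers")
  structure(list(lambda_al = lambda_al, lambda_co = lambda_co,
                 lambda_cl = lambda_cl), class = "loss_weights")
}

#' Summed cross-entropy classification loss
#'
#' \code{-sum_j ln p[j, y_j]} over subjects (a sum, not a mean), with the
#' probability floored at \code{epsilon} inside the log.
#'
#' @param probs N x C matrix of class probabilities (rows sum to 1).
#' @param labels 0-based class indices.
#' @param epsilon log floor.
#' @return non-negative scalar.
#' @export
classification_loss <- function(probs, labels, epsilon = 1e-8) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= ncol(probs)))
    stop("index error: label outside 0..C-1")
  if (length(labels) != nrow(probs))
    stop("shape error: one label per probability row required")
  -sum(log(pmax(probs[cbind(seq_along(labels), labels + 1L)], epsilon)))
}

#' Auxiliary confidence + classification loss
#'
#' For each omics layer i: \code{sum_j (matt_i[j] - conf_i[j])^2 +
#' CE(aux_probs_i, labels)}, summed over layers. \code{conf_i} is the
#' auxiliary classifier's confidence for subject j — by default its
#' true-class probability (TCP), alternatively its maximal softmax output —
#' treated as a constant (no gradient) in the squared term.
#'
#' @param matt list of per-omics gate score vectors/matrices (values in
#'   (0, 1), one per subject).
#' @param aux_probs list of per-omics N x C probability matrices.
#' @param labels 0-based class indices.
#' @param confidence \code{"tcp"} (true-class probability, default) or
#'   \code{"max"} (maximal softmax probability).
#' @param epsilon log floor for the cross-entropy term.
#' @return non-negative scalar.
#' @export
auxiliary_loss <- function(matt, aux_probs, labels, confidence = "tcp",
                           epsilon = 1e-8) {
  stopifnot(length(matt) == length(aux_probs))
  labels <- as.integer(labels)
  total <- 0
  for (i in seq_along(matt)) {
    m <- as.vector(matt[[i]])
    p <- as.matrix(aux_probs[[i]])
    if (length(m) != nrow(p) || length(m) != length(labels))
      stop("shape error: gates, probabilities and labels disagree on N")
    conf <- confidence_scores(p, labels, confidence)
    total <- total + sum((m - conf)^2) + classification_loss(p, labels, epsilon)
  }
  total
}

confidence_scores <- function(probs, labels, confidence) {
  switch(confidence,
         tcp = probs[cbind(seq_along(labels), labels + 1L)],
         max = apply(probs, 1L, max),
         stop("value error: confidence must be 'tcp' or 'max'"))
}

#' Combine loss components into the weighted total
#'
#' @param l_clf,l_al,l_co,l_cl scalar loss components.
#' @param weights a \code{\link{loss_weights}}.
#' @return list of class \code{loss_bundle} with all components and
#'   \code{total}.
#' @export
total_loss <- function(l_clf, l_al, l_co, l_cl, weights) {
  comp <- c(l_clf = l_clf, l_al = l_al, l_co = l_co, l_cl = l_cl)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad))
    stop("training divergence: non-finite loss component ", bad[1L])
  structure(list(l_clf = l_clf, l_al = l_al, l_co = l_co, l_cl = l_cl,
                 total = l_clf + weights$lambda_al * l_al +
                   weights$lambda_co * l_co + weights$lambda_cl * l_cl),
            class = "loss_bundle")
}

# ---- model assembly --------------------------------------------------------

#' Model configuration
#'
#' @param V integer vector of per-view feature dimensions.
#' @param C class count.
#' @param D shared latent dimension.
#' @param dropout dropout probability in the embedding stacks.
#' @param weights a \code{\link{loss_weights}}.
#' @param alpha contrastive entropy/MI balance (see
#'   \code{\link{contrastive_config}}).
#' @param epsilon numerical log floor.
#' @param lr initial Adam learning rate.
#' @param epochs maximum training epochs.
#' @param lr_decay_every,lr_decay_factor step learning-rate decay: the rate
#'   is multiplied by \code{lr_decay_factor} every \code{lr_decay_every}
#'   epochs.
#' @param use_attention if \code{FALSE}, both attention gates are bypassed
#'   (scores fixed at 1); used by the component ablation.
#' @param imputation \code{"bridge"} (cross-omics bridges, default) or
#'   \code{"zero"} (missing latents zero-filled; ablation baseline).
#' @param confidence confidence notion for the auxiliary squared term
#'   (\code{"tcp"} or \code{"max"}).
#' @param f_strings,emb_strings,g_strings,bridge_arch optional architecture
#'   strings (see \code{\link{parse_layer_string}}).
#' @return list of class \code{clclsa_config}.
#' @export
clclsa_config <- function(V, C, D = 64L, dropout = 0.5,
                          weights = loss_weights(), alpha = 9,
                          epsilon = 1e-8, lr = 1e-4, epochs = 2500L,
                          lr_decay_every = 500L, lr_decay_factor = 0.2,
                          use_attention = TRUE, imputation = "bridge",
                          confidence = "tcp", f_strings = NULL,
                          emb_strings = NULL, g_strings = NULL,
                          bridge_arch = NULL) {
  stopifnot(inherits(weights, "loss_weights"))
  imputation <- match.arg(imputation, c("bridge", "zero"))
  confidence <- match.arg(confidence, c("tcp", "max"))
  structure(list(V = as.integer(V), C = as.integer(C), D = as.integer(D),
                 M = length(V), dropout = dropout, weights = weights,
                 alpha = alpha, epsilon = epsilon, lr = lr,
                 epochs = as.integer(epochs),
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 use_attention = use_attention, imputation = imputation,
                 confidence = confidence, f_strings = f_strings,
                 emb_strings = emb_strings, g_strings = g_strings,
                 bridge_arch = bridge_arch),
            class = "clclsa_config")
}

build_model <- function(cfg, seed = 0L) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  att <- attention_config(cfg$V, cfg$D, cfg$dropout, cfg$f_strings,
                          cfg$emb_strings, cfg$g_strings)
  M <- cfg$M
  nets <- list()
  for (i in seq_len(M)) {
    nets[[paste0("f", i)]] <- att$f[[i]]
    nets[[paste0("emb", i)]] <- att$emb[[i]]
    nets[[paste0("g", i)]] <- att$g[[i]]
    nets[[paste0("aux", i)]] <- parse_layer_string(paste0(cfg$D, "-", cfg$C))
  }
  nets[["final"]] <- parse_layer_string(paste0(M * cfg$D, "-", cfg$C))
  if (M >= 2L) {
    bank <- bridge_bank(M, cfg$D, cfg$bridge_arch)
    for (key in names(bank$nets)) nets[[paste0("br_", key)]] <- bank$nets[[key]]
  }
  structure(list(cfg = cfg, nets = nets, seed = as.integer(seed),
                 history = NULL, adam = NULL, t = 0L),
            class = "clclsa_model")
}

model_bank <- function(model) {
  keys <- grep("^br_", names(model$nets), value = TRUE)
  nets <- model$nets[keys]
  names(nets) <- sub("^br_", "", keys)
  structure(list(nets = nets, M = model$cfg$M, D = model$cfg$D,
                 arch = model$cfg$bridge_arch), class = "bridge_bank")
}

#' @export
print.clclsa_model <- function(x, ...) {
  cfg <- x$cfg
  cat("clclsa_model: M =", cfg$M, "omics layers, D =", cfg$D,
      ", C =", cfg$C, "classes\n")
  cat("  lambda (al, co, cl): ", cfg$weights$lambda_al, ", ",
      cfg$weights$lambda_co, ", ", cfg$weights$lambda_cl,
      "; alpha = ", cfg$alpha, "\n", sep = "")
  if (!is.null(x$history))
    cat("  trained", nrow(x$history), "epochs; final total loss",
        format(utils::tail(x$history$total, 1), digits = 6), "\n")
  invisible(x)
}

# ---- forward pass ----------------------------------------------------------

# Forward of the attention/embedding stack for the views of one batch.
# Rows absent for a view (mask FALSE) are skipped; their latent rows are
# left at 0 to be imputed by the caller. Returns latents, gates, caches.
forward_views <- function(model, views, mask, training) {
  cfg <- model$cfg
  M <- cfg$M
  n <- nrow(views[[1]])
  st <- list(Z = vector("list", M), m = vector("list", M),
             Fatt = vector("list", M), Xhat = vector("list", M),
             obs = vector("list", M), caches = vector("list", M),
             nets = model$nets)
  for (i in seq_len(M)) {
    obs <- which(mask[, i])
    st$obs[[i]] <- obs
    Z <- matrix(0, n, cfg$D)
    m <- rep(1, n)
    ci <- list()
    if (length(obs)) {
      X <- views[[i]][obs, , drop = FALSE]
      if (cfg$use_attention) {
        fw_f <- mlp_forward(st$nets[[paste0("f", i)]], X, training)
        st$nets[[paste0("f", i)]] <- fw_f$net
        Fatt <- sigmoid(fw_f$out)
        G <- X * Fatt
      } else {
        fw_f <- NULL; Fatt <- NULL; G <- X
      }
      fw_e <- mlp_forward(st$nets[[paste0("emb", i)]], G, training)
      st$nets[[paste0("emb", i)]] <- fw_e$net
      Xhat <- fw_e$out
      if (cfg$use_attention) {
        fw_g <- mlp_forward(st$nets[[paste0("g", i)]], Xhat, training)
        st$nets[[paste0("g", i)]] <- fw_g$net
        mv <- as.vector(sigmoid(fw_g$out))
      } else {
        fw_g <- NULL; mv <- rep(1, length(obs))
      }
      Z[obs, ] <- Xhat * mv
      m[obs] <- mv
      ci <- list(X = X, fw_f = fw_f, Fatt = Fatt, fw_e = fw_e,
                 Xhat = Xhat, fw_g = fw_g, mv = mv)
      if (!is.null(Fatt)) st$Fatt[[i]] <- Fatt
      st$Xhat[[i]] <- Xhat
    }
    st$Z[[i]] <- Z
    st$m[[i]] <- m
    st$caches[[i]] <- ci
  }
  st
}

# Fill missing latent rows through the bridges (eval-mode batch norm) or
# with zeros; record the per-application caches for the backward pass.
forward_impute <- function(model, st, mask) {
  cfg <- model$cfg
  if (cfg$imputation == "zero" || cfg$M < 2L) {
    st$imp <- NULL
    return(st)
  }
  M <- cfg$M
  n <- nrow(mask)
  imp <- list()
  cnt <- matrix(0, n, M)
  for (i in seq_len(M)) {
    miss <- which(!mask[, i])
    if (!length(miss)) next
    acc <- matrix(0, length(miss), cfg$D)
    for (k in seq_len(M)) {
      if (k == i) next
      have <- mask[miss, k]
      if (!any(have)) next
      rows <- miss[have]
      key <- paste0("br_", bridge_key(i, k))
      fw <- mlp_forward(st$nets[[key]], st$Z[[k]][rows, , drop = FALSE],
                        training = FALSE)
      acc[have, ] <- acc[have, ] + fw$out
      cnt[rows, i] <- cnt[rows, i] + 1
      imp[[paste0(i, "_", k)]] <- list(i = i, k = k, rows = rows, fw = fw)
    }
    st$Z[[i]][miss, ] <- acc / cnt[miss, i]
  }
  st$imp <- imp
  st$imp_cnt <- cnt
  st
}

# Classifier heads on the fused latent.
forward_heads <- function(model, st, training) {
  fw_c <- mlp_forward(st$nets[["final"]], fuse(st$Z), training)
  st$nets[["final"]] <- fw_c$net
  st$fw_c <- fw_c
  st$probs <- softmax_rows(fw_c$out)
  st
}

# Full eval-mode forward: returns class probabilities plus the latent block.
model_forward <- function(model, views, mask, training = FALSE) {
  st <- forward_views(model, views, mask, training)
  st <- forward_impute(model, st, mask)
  forward_heads(model, st, training)
}

# ---- gradient computation --------------------------------------------------

# One training step's loss bundle and gradients. phase = "complete": all
# subjects have every view; full objective. phase = "incomplete": missing
# latents are imputed (eval-mode bridges, gradients flow end-to-end from the
# classification loss); only L_clf and L_al (observed views) apply.
model_grad <- function(model, views, labels, mask, phase) {
  cfg <- model$cfg
  w <- cfg$weights
  M <- cfg$M
  n <- length(labels)
  Y <- one_hot(labels, cfg$C)
  eps <- cfg$epsilon

  st <- forward_views(model, views, mask, training = TRUE)
  if (phase == "incomplete") st <- forward_impute(model, st, mask)
  st <- forward_heads(model, st, training = TRUE)

  grads <- stats::setNames(vector("list", length(st$nets)), names(st$nets))
  dZ <- lapply(seq_len(M), function(i) matrix(0, n, cfg$D))
  dm_sq <- vector("list", M)

  # classification loss and its gradient through the final head
  l_clf <- classification_loss(st$probs, labels, eps)
  dlogits <- st$probs - Y
  bw_c <- mlp_backward(st$nets[["final"]], st$fw_c$caches, dlogits)
  grads[["final"]] <- bw_c$grads
  for (i in seq_len(M))
    dZ[[i]] <- bw_c$dx[, ((i - 1L) * cfg$D + 1L):(i * cfg$D), drop = FALSE]

  # auxiliary heads: confidence-gate squared term + per-omics cross-entropy
  l_al <- 0
  if (w$lambda_al > 0) {
    for (i in seq_len(M)) {
      obs <- if (phase == "incomplete") st$obs[[i]] else seq_len(n)
      if (!length(obs)) next
      Zi <- st$Z[[i]][obs, , drop = FALSE]
      fw_a <- mlp_forward(st$nets[[paste0("aux", i)]], Zi, training = TRUE)
      st$nets[[paste0("aux", i)]] <- fw_a$net
      p_i <- softmax_rows(fw_a$out)
      lab_o <- labels[obs]
      conf <- confidence_scores(p_i, lab_o, cfg$confidence)  # detached
      mv <- st$m[[i]][obs]
      l_al <- l_al + sum((mv - conf)^2) +
        classification_loss(p_i, lab_o, eps)
      bw_a <- mlp_backward(st$nets[[paste0("aux", i)]], fw_a$caches,
                           w$lambda_al * (p_i - Y[obs, , drop = FALSE]))
      grads[[paste0("aux", i)]] <- acc_grads(grads[[paste0("aux", i)]],
                                             bw_a$grads)
      dZ[[i]][obs, ] <- dZ[[i]][obs, ] + bw_a$dx
      dsq <- rep(0, n)
      dsq[obs] <- w$lambda_al * 2 * (mv - conf)
      dm_sq[[i]] <- dsq
    }
  }

  # cross-omics reconstruction (complete phase only; targets detached)
  l_co <- 0
  if (phase == "complete" && w$lambda_co > 0 && M >= 2L) {
    for (i in seq_len(M)) for (k in seq_len(M)) {
      if (i == k) next
      key <- paste0("br_", bridge_key(i, k))
      fw_b <- mlp_forward(st$nets[[key]], st$Z[[k]], training = TRUE)
      st$nets[[key]] <- fw_b$net
      diffm <- fw_b$out - st$Z[[i]]
      l_co <- l_co + sum(diffm^2)
      bw_b <- mlp_backward(st$nets[[key]], fw_b$caches,
                           w$lambda_co * 2 * diffm)
      grads[[key]] <- acc_grads(grads[[key]], bw_b$grads)
      dZ[[k]] <- dZ[[k]] + bw_b$dx
    }
  }

  # contrastive alignment (complete phase only)
  l_cl <- 0
  if (phase == "complete" && w$lambda_cl > 0 && M >= 2L) {
    for (i in seq_len(M)) for (k in seq_len(M)) {
      if (i == k) next
      jd <- joint_distribution(st$Z[[i]], st$Z[[k]])
      l_cl <- l_cl + contrastive_pair_loss(jd, cfg$alpha, eps)
      cg <- contrastive_pair_grad(st$Z[[i]], st$Z[[k]], cfg$alpha, eps)
      dZ[[i]] <- dZ[[i]] + w$lambda_cl * cg$dZ_i
      dZ[[k]] <- dZ[[k]] + w$lambda_cl * cg$dZ_k
    }
  }

  # imputation backward: distribute missing-row gradients to the bridges
  # and onward into the observed source latents
  if (phase == "incomplete" && !is.null(st$imp)) {
    for (ap in st$imp) {
      key <- paste0("br_", bridge_key(ap$i, ap$k))
      dpred <- dZ[[ap$i]][ap$rows, , drop = FALSE] /
        st$imp_cnt[ap$rows, ap$i]
      bw_b <- mlp_backward(st$nets[[key]], ap$fw$caches, dpred)
      grads[[key]] <- acc_grads(grads[[key]], bw_b$grads)
      dZ[[ap$k]][ap$rows, ] <- dZ[[ap$k]][ap$rows, ] + bw_b$dx
    }
  }

  # backward through the gated embedding stacks, observed rows only
  for (i in seq_len(M)) {
    obs <- st$obs[[i]]
    if (!length(obs)) next
    ci <- st$caches[[i]]
    dZo <- dZ[[i]][obs, , drop = FALSE]
    dXhat <- dZo * ci$mv
    if (cfg$use_attention) {
      dm <- rowSums(dZo * ci$Xhat)
      if (!is.null(dm_sq[[i]])) dm <- dm + dm_sq[[i]][obs]
      dA <- dm * ci$mv * (1 - ci$mv)
      bw_g <- mlp_backward(st$nets[[paste0("g", i)]], ci$fw_g$caches,
                           matrix(dA, ncol = 1L))
      grads[[paste0("g", i)]] <- acc_grads(grads[[paste0("g", i)]],
                                           bw_g$grads)
      dXhat <- dXhat + bw_g$dx
    }
    bw_e <- mlp_backward(st$nets[[paste0("emb", i)]], ci$fw_e$caches, dXhat)
    grads[[paste0("emb", i)]] <- acc_grads(grads[[paste0("emb", i)]],
                                           bw_e$grads)
    if (cfg$use_attention) {
      dF <- bw_e$dx * ci$X
      dS <- dF * ci$Fatt * (1 - ci$Fatt)
      bw_f <- mlp_backward(st$nets[[paste0("f", i)]], ci$fw_f$caches, dS)
      grads[[paste0("f", i)]] <- acc_grads(grads[[paste0("f", i)]],
                                           bw_f$grads)
    }
  }

  bundle <- total_loss(l_clf, l_al, l_co, l_cl, w)
  list(bundle = bundle, grads = grads, nets = st$nets)
}

# ---- training --------------------------------------------------------------

#' Train a CLCLSA model
#'
#' Runs the two-phase full-batch regime for up to \code{epochs} epochs (see
#' the package vignette): complete subjects optimize the full objective
#' including the cross-omics bridges and the contrastive alignment;
#' incomplete subjects have their missing latents completed through the
#' bridges and contribute to the classification and auxiliary losses.
#' Optimization is Adam with a stepwise learning-rate decay. When the
#' training mask is complete, \code{lambda_co} is forced to 0 and the
#' bridges are never touched.
#'
#' @param ds a training \code{\link{omics_dataset}}.
#' @param config a \code{\link{clclsa_config}}; defaults are built from the
#'   dataset when \code{NULL}.
#' @param seed integer seed controlling initialization and dropout.
#' @param verbose print the loss bundle every 50 epochs.
#' @param ... passed to \code{\link{clclsa_config}} when \code{config} is
#'   \code{NULL}.
#' @return a \code{clclsa_model} with the per-epoch loss history in
#'   \code{$history}.
#' @export
train_clclsa <- function(ds, config = NULL, seed = 0L, verbose = FALSE, ...) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (n_subjects(ds) == 0L) stop("value error: empty training set")
  if (length(unique(ds$labels)) < ds$C)
    stop("value error: every class must be present in the training labels")
  if (is.null(config))
    config <- clclsa_config(V = vapply(ds$views, ncol, 1L), C = ds$C, ...)
  if (all(ds$mask)) config$weights$lambda_co <- 0

  model <- build_model(config, seed)
  model$adam <- adam_init(model$nets)
  rng <- local_rng(seed + 1L)
  on.exit(rng(), add = TRUE)

  complete <- which(rowSums(ds$mask) == config$M)
  incomplete <- setdiff(seq_len(n_subjects(ds)), complete)
  hist_rows <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr_t <- config$lr *
      config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
    bundle <- NULL
    if (length(complete)) {
      gv <- model_grad(model,
                       lapply(ds$views, function(v) v[complete, , drop = FALSE]),
                       ds$labels[complete],
                       ds$mask[complete, , drop = FALSE],
                       phase = "complete")
      model$nets <- gv$nets
      model$t <- model$t + 1L
      upd <- adam_step(model$nets, gv$grads, model$adam, lr_t, model$t)
      model$nets <- upd$nets
      model$adam <- upd$state
      bundle <- gv$bundle
    }
    if (length(incomplete)) {
      gv <- model_grad(model,
                       lapply(ds$views, function(v) v[incomplete, , drop = FALSE]),
                       ds$labels[incomplete],
                       ds$mask[incomplete, , drop = FALSE],
                       phase = "incomplete")
      model$nets <- gv$nets
      model$t <- model$t + 1L
      upd <- adam_step(model$nets, gv$grads, model$adam, lr_t, model$t)
      model$nets <- upd$nets
      model$adam <- upd$state
      if (is.null(bundle)) bundle <- gv$bundle
    }
    if (!is.finite(bundle$total))
      stop("training divergence at epoch ", epoch)
    hist_rows[[epoch]] <- data.frame(epoch = epoch, l_clf = bundle$l_clf,
                                     l_al = bundle$l_al, l_co = bundle$l_co,
                                     l_cl = bundle$l_cl, total = bundle$total)
    if (verbose && epoch %% 50L == 0L)
      message(sprintf("epoch %d: total %.4f (clf %.4f al %.4f co %.4f cl %.4f)",
                      epoch, bundle$total, bundle$l_clf, bundle$l_al,
                      bundle$l_co, bundle$l_cl))
  }
  model$history <- do.call(rbind, hist_rows)
  model
}

#' Predict class probabilities for a dataset
#'
#' Eval-mode forward pass: dropout off, batch norm on running statistics,
#' missing latents completed per the model's imputation mode. Rows sum
#' to 1.
#'
#' @param object a trained \code{clclsa_model}.
#' @param ds an \code{\link{omics_dataset}} with matching feature dims.
#' @param type \code{"prob"} (default) for the N x C probability matrix or
#'   \code{"class"} for 0-based hard labels.
#' @param ... unused.
#' @return probability matrix or label vector.
#' @export
predict.clclsa_model <- function(object, ds, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(ds, "omics_dataset"))
  Vd <- vapply(ds$views, ncol, 1L)
  if (!identical(Vd, object$cfg$V))
    stop("shape error: dataset feature dims ", paste(Vd, collapse = ","),
         " do not match model config ", paste(object$cfg$V, collapse = ","))
  st <- model_forward(object, ds$views, ds$mask, training = FALSE)
  if (type == "prob") st$probs else max.col(st$probs) - 1L
}

#' Gated latent representations of a dataset
#'
#' Returns the per-omics latent block: gated latents \code{Z} (missing rows
#' imputed when \code{impute = TRUE}), omics-level gates \code{matt} and
#' feature-level scores \code{fatt} (observed rows only).
#'
#' @param model a trained \code{clclsa_model}.
#' @param ds an \code{\link{omics_dataset}}.
#' @param impute complete missing latent rows through the bridges.
#' @return list with \code{Z}, \code{matt}, \code{fatt}.
#' @export
latent_block <- function(model, ds, impute = TRUE) {
  st <- forward_views(model, ds$views, ds$mask, training = FALSE)
  if (impute) st <- forward_impute(model, st, ds$mask)
  list(Z = st$Z, matt = st$m, fatt = st$Fatt)
}

#' Latent imputation error of the trained bridges vs a mean baseline
#'
#' On subjects of \code{ds_eval} observed in all views, each view's true
#' latent is hidden in turn and reconstructed (a) through the trained
#' cross-omics bridges (mean over source views) and (b) by the
#' per-dimension mean of the training latents. Reports the mean squared
#' error of both reconstructions.
#'
#' @param model a trained \code{clclsa_model}.
#' @param ds_train the training dataset (defines the mean baseline).
#' @param ds_eval the dataset to evaluate on.
#' @return named numeric vector \code{c(bridge = ..., mean = ...)}.
#' @export
latent_imputation_mse <- function(model, ds_train, ds_eval) {
  M <- model$cfg$M
  bank <- model_bank(model)
  lb_tr <- latent_block(model, ds_train, impute = FALSE)
  lb_ev <- latent_block(model, ds_eval, impute = FALSE)
  complete <- which(rowSums(ds_eval$mask) == M)
  if (!length(complete)) stop("value error: no complete subjects to evaluate")
  se_bridge <- 0; se_mean <- 0; n_terms <- 0
  for (i in seq_len(M)) {
    truth <- lb_ev$Z[[i]][complete, , drop = FALSE]
    acc <- matrix(0, length(complete), model$cfg$D)
    for (k in seq_len(M)) {
      if (k == i) next
      acc <- acc + predict_latent(lb_ev$Z[[k]][complete, , drop = FALSE],
                                  bank, i, k)
    }
    pred_bridge <- acc / (M - 1)
    obs_tr <- which(ds_train$mask[, i])
    mu <- colMeans(lb_tr$Z[[i]][obs_tr, , drop = FALSE])
    pred_mean <- matrix(mu, length(complete), model$cfg$D, byrow = TRUE)
    se_bridge <- se_bridge + sum((pred_bridge - truth)^2)
    se_mean <- se_mean + sum((pred_mean - truth)^2)
    n_terms <- n_terms + length(truth)
  }
  c(bridge = se_bridge / n_terms, mean = se_mean / n_terms)
}

# ---- grid search -----------------------------------------------------------

#' Exhaustive grid search over the loss weights
#'
#' Trains one model per (lambda_al, lambda_co, lambda_cl) triple and seed
#' on a train/validation split of \code{ds} and scores validation accuracy.
#' With a complete availability mask the lambda_co dimension collapses to
#' \{0\}. Ties in mean accuracy are broken by mean F1 (binary F1 or macro
#' F1) and then by the smaller lambda sum.
#'
#' @param ds an \code{\link{omics_dataset}}.
#' @param lambda_grid numeric vector of candidate values for each weight;
#'   default the canonical grid \code{c(0, 0.01, 0.02, 0.05, 0.1, 1)}.
#' @param seeds integer vector of training seeds per triple.
#' @param val_fraction fraction of \code{ds} held out for validation.
#' @param config_args list of extra arguments to
#'   \code{\link{clclsa_config}} (e.g. \code{epochs}).
#' @return list with \code{best} (a \code{\link{loss_weights}}) and
#'   \code{table} (one row per triple x seed with ACC and F1).
#' @export
grid_search <- function(ds, lambda_grid = c(0, 0.01, 0.02, 0.05, 0.1, 1),
                        seeds = 0L, val_fraction = 0.3,
                        config_args = list()) {
  if (!length(lambda_grid)) stop("value error: empty grid")
  sp <- split_dataset(ds, train_fraction = 1 - val_fraction,
                      seed = seeds[1L], stratified = TRUE)
  co_grid <- if (all(ds$mask)) 0 else lambda_grid
  combos <- expand.grid(lambda_al = lambda_grid, lambda_co = unique(co_grid),
                        lambda_cl = lambda_grid)
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    for (s in seeds) {
      args <- c(list(V = vapply(ds$views, ncol, 1L), C = ds$C,
                     weights = loss_weights(combos$lambda_al[r],
                                            combos$lambda_co[r],
                                            combos$lambda_cl[r])),
                config_args)
      model <- train_clclsa(sp$train, do.call(clclsa_config, args), seed = s)
      mr <- compute_metrics(predict(model, sp$test), sp$test$labels)
      f1 <- if (ds$C == 2L) mr$F1 else mr$MacroF1
      rows[[length(rows) + 1L]] <-
        cbind(combos[r, , drop = FALSE],
              data.frame(seed = s, ACC = mr$ACC, F1 = f1))
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(ACC, F1) ~ lambda_al + lambda_co + lambda_cl,
                          data = tab, FUN = mean)
  agg$lsum <- agg$lambda_al + agg$lambda_co + agg$lambda_cl
  best <- agg[order(-agg$ACC, -agg$F1, agg$lsum), ][1L, ]
  list(best = loss_weights(best$lambda_al, best$lambda_co, best$lambda_cl),
       table = tab)
}

# ---- serialization ---------------------------------------------------------

#' Save / load a trained model
#'
#' Models round-trip with bit-identical eval-mode predictions.
#'
#' @param model a \code{clclsa_model}.
#' @param path file path.
#' @return \code{load_clclsa} returns the model; \code{save_clclsa} its
#'   path, invisibly.
#' @export
save_clclsa <- function(model, path) {
  stopifnot(inherits(model, "clclsa_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_clclsa
#' @export
load_clclsa <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "clclsa_model"))
  model
}
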