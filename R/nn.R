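# Minimal feed-forward neural-network engine: linear / ReLU / dropout /
# batch-norm layers with manual reverse-mode gradients and an Adam optimizer.
# All model components (attention encoders, omics embeddings, cross-omics
# bridges, classifier heads) are stacks of these layers.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

one_hot <- function(labels, C) {
  # labels are 0-based class indices
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# ---- layers ----------------------------------------------------------------

nn_linear <- function(d_in, d_out) {
  # fan-in uniform init, U(-1/sqrt(d_in), 1/sqrt(d_in))
  bound <- 1 / sqrt(d_in)
  list(type = "linear",
       W = matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out),
       b = matrix(stats::runif(d_out, -bound, bound), 1, d_out))
}

nn_relu <- function() list(type = "relu")

nn_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p)
}

nn_batchnorm <- function(d, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, d), beta = rep(0, d),
       running_mean = rep(0, d), running_var = rep(1, d),
       momentum = momentum, eps = eps)
}

# ---- forward / backward ----------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    linear = {
      out <- x %*% layer$W + matrix(layer$b, nrow(x), ncol(layer$W), byrow = TRUE)
      list(out = out, cache = list(x = x), layer = layer)
    },
    relu = {
      list(out = pmax(x, 0), cache = list(pos = x > 0), layer = layer)
    },
    dropout = {
      if (training && layer$p > 0) {
        m <- matrix(stats::runif(length(x)) >= layer$p, nrow(x)) / (1 - layer$p)
        list(out = x * m, cache = list(mask = m), layer = layer)
      } else {
        list(out = x, cache = list(mask = NULL), layer = layer)
      }
    },
    batchnorm = {
      if (training && nrow(x) > 1L) {
        mu <- colMeans(x)
        v <- pmax(colMeans(x^2) - mu^2, 0)  # guard cancellation
        xc <- sweep(x, 2L, mu)
        inv <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2L, inv, `*`)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
        out <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
        list(out = out, cache = list(xhat = xhat, inv = inv, train_mode = TRUE),
             layer = layer)
      } else {
        inv <- 1 / sqrt(layer$running_var + layer$eps)
        xhat <- sweep(sweep(x, 2L, layer$running_mean), 2L, inv, `*`)
        out <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
        list(out = out, cache = list(xhat = xhat, inv = inv, train_mode = FALSE),
             layer = layer)
      }
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    linear = {
      list(dx = dout %*% t(layer$W),
           grads = list(W = crossprod(cache$x, dout),
                        b = matrix(colSums(dout), 1)))
    },
    relu = list(dx = dout * cache$pos, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    batchnorm = {
      xhat <- cache$xhat
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2L, layer$gamma, `*`)
      if (cache$train_mode) {
        n <- nrow(dout)
        dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
                      sweep(xhat, 2L, colMeans(dxhat * xhat), `*`),
                    2L, cache$inv, `*`)
      } else {
        dx <- sweep(dxhat, 2L, cache$inv, `*`)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    stop("unknown layer type: ", layer$type))
}

# A network is a plain list of layers. Forward returns the output plus the
# per-layer caches needed for the backward pass; batch-norm running statistics
# are updated in place on the returned network copy.
mlp_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (l in seq_along(net)) {
    fw <- layer_forward(net[[l]], x, training)
    x <- fw$out
    caches[[l]] <- fw$cache
    net[[l]] <- fw$layer  # carries updated running stats
  }
  list(out = x, caches = caches, net = net)
}

mlp_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (l in rev(seq_along(net))) {
    bw <- layer_backward(net[[l]], caches[[l]], dout)
    dout <- bw$dx
    # assigning NULL would delete the element and misalign the list
    if (!is.null(bw$grads)) grads[[l]] <- bw$grads
  }
  list(dx = dout, grads = grads)
}

mlp_in_dim <- function(net) {
  for (l in net) if (l$type == "linear") return(nrow(l$W))
  NA_integer_
}

mlp_out_dim <- function(net) {
  d <- NA_integer_
  for (l in net) if (l$type == "linear") d <- ncol(l$W)
  d
}

# ---- architecture strings --------------------------------------------------

#' Parse a layer-string architecture description
#'
#' Architectures are written as dash-separated tokens, e.g.
#' \code{"200-300-ReLU-DP"} (linear 200 to 300, ReLU, dropout) or
#' \code{"300-64-BN-ReLU-32-ReLU-64-BN-ReLU-300"} for an
#' encoder--decoder bridge. Numeric tokens are layer widths joined by linear
#' maps; \code{ReLU}, \code{DP} (dropout) and \code{BN} (batch
#' normalization) insert the corresponding layer after the preceding linear
#' output; a terminal \code{Softmax} token is accepted and ignored (softmax
#' is applied by the classifier heads).
#'
#' @param s architecture string.
#' @param dropout dropout probability used for \code{DP} tokens.
#' @return a network: a list of layer objects.
#' @examples
#' net <- parse_layer_string("4-3-ReLU-DP")
#' length(net)
#' @export
parse_layer_string <- function(s, dropout = 0.5) {
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  net <- list()
  prev <- NA_integer_
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      d <- as.integer(tk)
      if (!is.na(prev)) net[[length(net) + 1L]] <- nn_linear(prev, d)
      prev <- d
    } else if (toupper(tk) == "RELU") {
      net[[length(net) + 1L]] <- nn_relu()
    } else if (toupper(tk) == "DP") {
      net[[length(net) + 1L]] <- nn_dropout(dropout)
    } else if (toupper(tk) == "BN") {
      net[[length(net) + 1L]] <- nn_batchnorm(prev)
    } else if (toupper(tk) == "SOFTMAX") {
      # handled by the heads
    } else {
      stop("unknown token in layer string: ", tk)
    }
  }
  net
}

# ---- Adam ------------------------------------------------------------------

param_names <- function(layer) {
  switch(layer$type,
    linear = c("W", "b"),
    batchnorm = c("gamma", "beta"),
    character(0))
}

adam_init <- function(nets) {
  lapply(nets, function(net) lapply(net, function(layer) {
    nm <- param_names(layer)
    if (!length(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = layer[[p]] * 0, v = layer[[p]] * 0))
    names(st) <- nm
    st
  }))
}

# nets and grads share the same nested structure (net -> layer -> param).
adam_step <- function(nets, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (n in seq_along(nets)) {
    if (is.null(grads[[n]])) next
    for (l in seq_along(nets[[n]])) {
      g <- grads[[n]][[l]]
      if (is.null(g)) next
      for (p in names(g)) {
        st <- state[[n]][[l]][[p]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
        nets[[n]][[l]][[p]] <- nets[[n]][[l]][[p]] -
          lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
        state[[n]][[l]][[p]] <- st
      }
    }
  }
  list(nets = nets, state = state)
}

# elementwise accumulation of two grad structures (either may be NULL)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (l in seq_along(b)) {
    if (is.null(b[[l]])) next
    if (is.null(a[[l]])) { a[[l]] <- b[[l]]; next }
    for (p in names(b[[l]])) a[[l]][[p]] <- a[[l]][[p]] + b[[l]][[p]]
  }
  a
}

zero_grads_like <- function(net) {
  lapply(net, function(layer) {
    nm <- param_names(layer)
    if (!length(nm)) return(NULL)
    g <- lapply(nm, function(p) layer[[p]] * 0)
    names(g) <- nm
    g
  })
}
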