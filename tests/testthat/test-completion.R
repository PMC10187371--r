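# Cross-omics bridges: reconstruction losses, reduction identities, the
# imputation averaging rule, and the trained-bridge-vs-mean benchmark.

test_that("the bank holds M(M-1) ordered bridges of the right shape", {
  bank <- bridge_bank(3, 4, arch = "4-6-BN-ReLU-3-ReLU-6-BN-ReLU-4")
  expect_length(bank$nets, 6L)
  z <- matrix(rnorm(20), 5, 4)
  pred <- predict_latent(z, bank, i = 1, k = 2)
  expect_equal(dim(pred), c(5L, 4L))
  # eval-mode calls are deterministic
  expect_identical(pred, predict_latent(z, bank, 1, 2))
  expect_error(predict_latent(z, bank, 1, 1), "lookup error")
})

test_that("a toy bridge equals its layer-by-layer composition", {
  bank <- bridge_bank(2, 2, arch = "2-2-ReLU-2")
  net <- bank$nets[["1_2"]]
  W1 <- matrix(c(1, 0.5, -1, 2), 2, 2); b1 <- c(0, 0.1)
  W2 <- matrix(c(0.3, -0.2, 1, 0.4), 2, 2); b2 <- c(-0.1, 0.2)
  net[[1]]$W <- W1; net[[1]]$b <- matrix(b1, 1)
  net[[3]]$W <- W2; net[[3]]$b <- matrix(b2, 1)
  bank$nets[["1_2"]] <- net
  z <- matrix(c(1, -2, 0.5, 3), 2, 2)
  hand <- sweep(pmax(sweep(z %*% W1, 2, b1, `+`), 0) %*% W2, 2, b2, `+`)
  expect_equal(predict_latent(z, bank, 1, 2), hand, tolerance = 1e-12)
})

test_that("pair loss is the summed squared L2 distance", {
  expect_equal(pair_reconstruction_loss(matrix(c(1, 2), 1), matrix(0, 1, 2)), 5)
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(pair_reconstruction_loss(z, z), 0)
  expect_gte(pair_reconstruction_loss(matrix(rnorm(8), 2),
                                      matrix(rnorm(8), 2)), 0)
  expect_error(pair_reconstruction_loss(matrix(1, 2, 2), matrix(1, 3, 2)),
               "shape error")
})

test_that("the multi-view loss reduces to the bi-view form at M = 2", {
  set.seed(10)
  bank <- bridge_bank(2, 3, arch = "3-4-BN-ReLU-2-ReLU-4-BN-ReLU-3")
  latents <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  total <- total_reconstruction_loss(latents, bank)
  manual <- pair_reconstruction_loss(predict_latent(latents[[2]], bank, 1, 2),
                                     latents[[1]]) +
    pair_reconstruction_loss(predict_latent(latents[[1]], bank, 2, 1),
                             latents[[2]])
  expect_equal(total, manual, tolerance = 1e-10)
  expect_error(total_reconstruction_loss(latents[1], bank), "value error")
})

test_that("the total loss counts all ordered pairs and respects the mask", {
  set.seed(11)
  M <- 3; D <- 2
  bank <- bridge_bank(M, D, arch = "2-3-ReLU-2")
  latents <- lapply(1:M, function(i) matrix(rnorm(8), 4, D))
  # brute-force enumeration over ordered pairs
  brute <- 0
  for (i in 1:M) for (k in 1:M) if (i != k)
    brute <- brute + sum((predict_latent(latents[[k]], bank, i, k) -
                            latents[[i]])^2)
  expect_equal(total_reconstruction_loss(latents, bank), brute,
               tolerance = 1e-10)

  # masked subjects drop out of the pair terms
  mask <- matrix(TRUE, 4, M); mask[1, 2] <- FALSE
  brute_m <- 0
  for (i in 1:M) for (k in 1:M) {
    if (i == k) next
    rows <- which(mask[, i] & mask[, k])
    brute_m <- brute_m +
      sum((predict_latent(latents[[k]][rows, , drop = FALSE], bank, i, k) -
             latents[[i]][rows, , drop = FALSE])^2)
  }
  expect_equal(total_reconstruction_loss(latents, bank, mask), brute_m,
               tolerance = 1e-10)

  # permutation invariance in subject order
  perm <- c(3, 1, 4, 2)
  expect_equal(
    total_reconstruction_loss(lapply(latents, function(z) z[perm, ]), bank),
    total_reconstruction_loss(latents, bank), tolerance = 1e-9)
})

test_that("imputation averages bridge predictions and passes observed latents through", {
  # toy bridges returning constants: view 1 missing, sources give [1,1], [3,3]
  bank <- bridge_bank(3, 2, arch = "2-2")
  for (key in names(bank$nets)) {
    bank$nets[[key]][[1]]$W[] <- 0
    bank$nets[[key]][[1]]$b[] <- 0
  }
  bank$nets[["1_2"]][[1]]$b[] <- 1
  bank$nets[["1_3"]][[1]]$b[] <- 3
  latents <- list(matrix(0, 1, 2), matrix(5, 1, 2), matrix(7, 1, 2))
  mask <- matrix(c(FALSE, TRUE, TRUE), 1, 3)
  out <- impute_missing(latents, bank, mask)
  expect_equal(out[[1]], matrix(2, 1, 2))          # mean of [1,1] and [3,3]
  expect_identical(out[[2]], latents[[2]])          # observed: untouched
  expect_identical(out[[3]], latents[[3]])

  # single source degenerates to that bridge's prediction
  mask2 <- matrix(c(FALSE, TRUE, FALSE), 1, 3)
  out2 <- impute_missing(latents, bank, mask2)
  expect_equal(out2[[1]], matrix(1, 1, 2))

  # full mask: identity
  full <- matrix(TRUE, 1, 3)
  expect_identical(impute_missing(latents, bank, full), latents)

  expect_error(impute_missing(latents, bank, matrix(FALSE, 1, 3)),
               "contract violation")
})

test_that("trained bridges beat the per-dimension mean baseline on noiseless linked views", {
  # deterministic cross-view linear maps, zero noise: every view is an
  # exact image of the shared latent, so bridges have recoverable signal.
  # some subjects must be incomplete for the bridge loss to be active.
  mses <- NULL
  for (s in 1:5) {
    ds <- tiny_ds(N = 120, V = c(20, 20, 12), q = 4, sigma_noise = 0,
                  delta = 2, eta = 0.3, seed = s)
    sp <- split_dataset(ds, 0.7, seed = s)
    model <- train_clclsa(sp$train,
                          tiny_config(V = c(20, 20, 12), D = 8, epochs = 300,
                                      dropout = 0, lr = 1e-3),
                          seed = s)
    mses <- rbind(mses, latent_imputation_mse(model, sp$train, sp$test))
  }
  expect_lt(mean(mses[, "bridge"]), mean(mses[, "mean"]))
  expect_gte(sum(mses[, "bridge"] < mses[, "mean"]), 4)
})
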