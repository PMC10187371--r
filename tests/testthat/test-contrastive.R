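# The mutual-information contrastive objective: hand-derived values,
# brute-force oracles, and its symmetry/monotonicity properties.

test_that("the joint table matches the brute-force average of outer products", {
  # single subject, one-hot rows: a single outer product
  jd <- joint_distribution(matrix(c(10, -10), 1, 2), matrix(c(10, -10), 1, 2))
  expect_equal(jd$P, matrix(c(1, 0, 0, 0), 2, 2), tolerance = 1e-8)

  set.seed(20)
  for (rep in 1:20) {
    n <- sample(2:8, 1); D <- sample(2:5, 1)
    Zi <- matrix(rnorm(n * D), n, D)
    Zk <- matrix(rnorm(n * D), n, D)
    jd <- joint_distribution(Zi, Zk)
    expect_equal(jd$P, brute_joint(Zi, Zk), tolerance = 1e-12)
    expect_equal(sum(jd$P), 1, tolerance = 1e-12)
    expect_true(all(jd$P >= 0))
    expect_equal(jd$P_d, rowSums(jd$P))
  }
  expect_error(joint_distribution(matrix(0, 0, 2), matrix(0, 0, 2)),
               "value error")
})

test_that("hand-derived pair-loss values are reproduced", {
  ident <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  unif <- matrix(0.25, 2, 2)
  expect_equal(contrastive_pair_loss(ident, alpha = 0), -log(2),
               tolerance = 1e-10)
  expect_equal(contrastive_pair_loss(unif, alpha = 0), 0, tolerance = 1e-10)
  expect_equal(contrastive_pair_loss(ident, alpha = 1), -log(8),
               tolerance = 1e-10)
  expect_error(contrastive_pair_loss(ident, alpha = -1), "value error")
})

test_that("the pair loss matches an independent double-loop evaluation", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:6, 1); D <- sample(2:5, 1)
    Zi <- matrix(rnorm(n * D, sd = 2), n, D)
    Zk <- matrix(rnorm(n * D, sd = 2), n, D)
    jd <- joint_distribution(Zi, Zk)
    for (alpha in c(0, 1, 9)) {
      expect_equal(contrastive_pair_loss(jd, alpha),
                   brute_contrastive(jd$P, alpha), tolerance = 1e-10)
    }
  }
})

test_that("the loss is symmetric under swapping the two views", {
  set.seed(22)
  for (rep in 1:20) {
    Zi <- matrix(rnorm(12), 4, 3); Zk <- matrix(rnorm(12), 4, 3)
    l_ik <- contrastive_pair_loss(joint_distribution(Zi, Zk), alpha = 3)
    l_ki <- contrastive_pair_loss(joint_distribution(Zk, Zi), alpha = 3)
    expect_equal(l_ik, l_ki, tolerance = 1e-10)
  }
})

test_that("at alpha = 0 the loss is minus the mutual information, never positive", {
  set.seed(23)
  for (rep in 1:50) {
    jd <- joint_distribution(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
    expect_lte(contrastive_pair_loss(jd, alpha = 0), 1e-12)
  }
  # exactly zero iff the joint factorizes (independent uniform case)
  expect_equal(contrastive_pair_loss(matrix(1 / 9, 3, 3), alpha = 0), 0,
               tolerance = 1e-12)
})

test_that("the loss decreases in alpha for diagonal joints", {
  set.seed(24)
  for (rep in 1:20) {
    p <- rexp(4); p <- p / sum(p)
    P <- diag(p)
    losses <- vapply(c(0, 0.5, 1, 2, 5, 9),
                     function(a) contrastive_pair_loss(P, a), 0)
    expect_true(all(diff(losses) < 0))
  }
})

test_that("the total sums all ordered pairs on jointly observed subjects", {
  expect_equal(contrastive_total(list(matrix(rnorm(8), 4, 2))), 0)  # M = 1

  set.seed(25)
  latents <- lapply(1:3, function(i) matrix(rnorm(18), 6, 3))
  cfg <- contrastive_config(alpha = 2)
  brute <- 0
  for (i in 1:3) for (k in 1:3) if (i != k)
    brute <- brute +
      contrastive_pair_loss(joint_distribution(latents[[i]], latents[[k]]), 2)
  expect_equal(contrastive_total(latents, cfg = cfg), brute,
               tolerance = 1e-12)

  # M = 2 with a full mask: twice one direction, by transpose symmetry
  two <- latents[1:2]
  expect_equal(contrastive_total(two, cfg = cfg),
               2 * contrastive_pair_loss(joint_distribution(two[[1]],
                                                            two[[2]]), 2),
               tolerance = 1e-10)

  # only jointly observed subjects enter a pair's joint table
  mask <- matrix(TRUE, 6, 3); mask[1:2, 1] <- FALSE
  brute_m <- 0
  for (i in 1:3) for (k in 1:3) {
    if (i == k) next
    rows <- which(mask[, i] & mask[, k])
    brute_m <- brute_m + contrastive_pair_loss(
      joint_distribution(latents[[i]][rows, ], latents[[k]][rows, ]), 2)
  }
  expect_equal(contrastive_total(latents, mask, cfg), brute_m,
               tolerance = 1e-12)

  # pairs with no joint support contribute zero, one warning per direction
  mask2 <- matrix(TRUE, 6, 2)
  mask2[1:3, 1] <- FALSE; mask2[4:6, 2] <- FALSE
  w <- testthat::capture_warnings(
    val <- contrastive_total(list(latents[[1]], latents[[2]]), mask2, cfg))
  expect_length(w, 2L)
  expect_match(w, "no jointly observed", all = TRUE)
  expect_equal(val, 0)
})

test_that("the analytic latent gradient of the pair loss matches finite differences", {
  set.seed(26)
  Zi <- matrix(rnorm(12), 4, 3); Zk <- matrix(rnorm(12), 4, 3)
  g <- clclsa:::contrastive_pair_grad(Zi, Zk, alpha = 2)
  loss_of <- function(Zi, Zk)
    contrastive_pair_loss(joint_distribution(Zi, Zk), alpha = 2)
  h <- 1e-6
  for (ii in seq_len(12)) {
    Z2 <- Zi; Z2[ii] <- Z2[ii] + h
    Z3 <- Zi; Z3[ii] <- Z3[ii] - h
    expect_equal(g$dZ_i[ii], (loss_of(Z2, Zk) - loss_of(Z3, Zk)) / (2 * h),
                 tolerance = 1e-5)
    Z2 <- Zk; Z2[ii] <- Z2[ii] + h
    Z3 <- Zk; Z3[ii] <- Z3[ii] - h
    expect_equal(g$dZ_k[ii], (loss_of(Zi, Z2) - loss_of(Zi, Z3)) / (2 * h),
                 tolerance = 1e-5)
  }
})
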