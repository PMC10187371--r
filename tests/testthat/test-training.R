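# Loss functions, the loss bundle, the two-phase trainer, prediction and
# the grid search.

test_that("classification loss is the summed floored cross-entropy", {
  expect_equal(classification_loss(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                                   c(0, 1)), 0, tolerance = 1e-6)
  expect_equal(classification_loss(matrix(c(0.5, 0.5), 1), 0), log(2),
               tolerance = 1e-10)
  # sum over subjects, not mean
  p <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_equal(classification_loss(p, c(0, 0)), -log(0.8) - log(0.3),
               tolerance = 1e-12)
  expect_error(classification_loss(p, c(0, 5)), "index error")
})

test_that("auxiliary loss combines the confidence gap and per-omics cross-entropy", {
  # gates equal to confidence and one-hot-correct probabilities: zero loss
  p_hot <- matrix(c(1, 0), 1)
  expect_equal(auxiliary_loss(list(1), list(p_hot), 0), 0, tolerance = 1e-6)

  # gate 0.5 vs confidence 1.0 with a perfect CE term: (0.5 - 1)^2
  expect_equal(auxiliary_loss(list(0.5), list(p_hot), 0), 0.25,
               tolerance = 1e-6)

  # two omics layers: equals the brute-force sum over layers and subjects
  set.seed(30)
  labels <- c(0, 1, 1)
  matt <- list(runif(3), runif(3))
  probs <- list(random_probs(3, 2), random_probs(3, 2))
  brute <- 0
  for (i in 1:2) for (j in 1:3) {
    conf <- probs[[i]][j, labels[j] + 1]
    brute <- brute + (matt[[i]][j] - conf)^2 - log(probs[[i]][j, labels[j] + 1])
  }
  expect_equal(auxiliary_loss(matt, probs, labels), brute, tolerance = 1e-10)

  # max-softmax confidence variant
  p <- matrix(c(0.3, 0.7), 1)
  expect_equal(auxiliary_loss(list(0.7), list(p), 0, confidence = "max"),
               -log(0.3), tolerance = 1e-10)
  expect_error(auxiliary_loss(list(c(0.5, 0.5)), list(p_hot), 0),
               "shape error")
})

test_that("the loss bundle is the stated weighted sum", {
  w <- loss_weights(0.1, 0.05, 0.01)
  b <- total_loss(1, 2, 3, 4, w)
  expect_equal(b$total, 1 + 0.2 + 0.15 + 0.04, tolerance = 1e-12)
  expect_equal(b$total,
               b$l_clf + w$lambda_al * b$l_al + w$lambda_co * b$l_co +
                 w$lambda_cl * b$l_cl, tolerance = 1e-10)
  expect_error(total_loss(NaN, 0, 0, 0, w), "l_clf")
  expect_error(loss_weights(-0.1, 0, 0), "value error")
})

test_that("training is deterministic and decreases the loss", {
  ds <- tiny_ds(N = 40, eta = 0.3, seed = 6)
  m1 <- train_clclsa(ds, tiny_config(epochs = 40), seed = 2)
  m2 <- train_clclsa(ds, tiny_config(epochs = 40), seed = 2)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, ds), predict(m2, ds))
  expect_lt(tail(m1$history$total, 1), m1$history$total[1])
  # bundle invariant holds at every epoch
  w <- m1$cfg$weights
  expect_equal(m1$history$total,
               m1$history$l_clf + w$lambda_al * m1$history$l_al +
                 w$lambda_co * m1$history$l_co +
                 w$lambda_cl * m1$history$l_cl, tolerance = 1e-8)
})

test_that("with a complete mask the bridges are never touched and lambda_co is 0", {
  ds <- tiny_ds(N = 30, eta = 0, seed = 7)
  model <- train_clclsa(ds, tiny_config(epochs = 25), seed = 1)
  expect_equal(model$cfg$weights$lambda_co, 0)
  fresh <- clclsa:::build_model(model$cfg, seed = model$seed)
  bridge_names <- grep("^br_", names(model$nets), value = TRUE)
  expect_equal(params_digest(model$nets[bridge_names]),
               params_digest(fresh$nets[bridge_names]))
  # the rest of the model did train
  expect_false(isTRUE(all.equal(params_digest(model$nets["final"]),
                                params_digest(fresh$nets["final"]))))
})

test_that("prediction rows sum to one and complete subjects ignore the imputation path", {
  ds <- tiny_ds(N = 30, eta = 0.4, seed = 8)
  model <- train_clclsa(ds, tiny_config(epochs = 25), seed = 3)
  p <- predict(model, ds)
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-6)
  expect_true(all(p >= 0))

  complete <- which(rowSums(ds$mask) == 3)
  sub <- clclsa:::subset_dataset(ds, complete)
  p_bridge <- predict(model, sub)
  m_zero <- model; m_zero$cfg$imputation <- "zero"
  expect_equal(p_bridge, predict(m_zero, sub), tolerance = 1e-12)

  bad <- tiny_ds(N = 5, V = c(9, 9, 9))
  expect_error(predict(model, bad), "shape error")

  cls <- predict(model, ds, type = "class")
  expect_identical(cls, max.col(p) - 1L)
})

test_that("a one-subject forward pass equals the hand-composed pipeline", {
  ds <- tiny_ds(N = 8, C = 2, seed = 9)
  cfg <- tiny_config(dropout = 0, epochs = 1)
  model <- clclsa:::build_model(cfg, seed = 5)
  one <- clclsa:::subset_dataset(ds, 3L)
  p <- predict(model, one)

  # hand-composed: gate -> embed -> gate -> concatenate -> linear -> softmax
  zs <- list()
  for (i in 1:3) {
    x <- one$views[[i]]
    fatt <- feature_attention(x, model$nets[[paste0("f", i)]])
    xh <- embed_omics(x, fatt, model$nets[[paste0("emb", i)]])
    matt <- omics_attention(xh, model$nets[[paste0("g", i)]])
    zs[[i]] <- apply_omics_attention(xh, matt)
  }
  Z <- fuse(zs)
  fin <- model$nets[["final"]]
  logits <- Z %*% fin[[1]]$W + matrix(fin[[1]]$b, 1)
  expect_equal(as.vector(p), as.vector(exp(logits) / sum(exp(logits))),
               tolerance = 1e-10)
})

test_that("models survive a save/load round trip with identical predictions", {
  ds <- tiny_ds(N = 20, eta = 0.3, seed = 10)
  model <- train_clclsa(ds, tiny_config(epochs = 15), seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_clclsa(model, path)
  back <- load_clclsa(path)
  expect_identical(predict(back, ds), predict(model, ds))
})

test_that("grid search scores every combination and breaks ties sensibly", {
  ds <- tiny_ds(N = 40, eta = 0.3, seed = 11)
  res <- grid_search(ds, lambda_grid = c(0, 0.1), seeds = 0L,
                     config_args = list(D = 4L, epochs = 10L,
                                        bridge_arch = "4-6-BN-ReLU-3-ReLU-6-BN-ReLU-4"))
  expect_equal(nrow(res$table), 8L)  # 2^3 combinations x 1 seed
  expect_s3_class(res$best, "loss_weights")

  # complete data: the lambda_co dimension collapses to zero
  ds0 <- tiny_ds(N = 40, eta = 0, seed = 12)
  res0 <- grid_search(ds0, lambda_grid = c(0, 0.1), seeds = 0L,
                      config_args = list(D = 4L, epochs = 10L,
                                         bridge_arch = "4-6-BN-ReLU-3-ReLU-6-BN-ReLU-4"))
  expect_equal(nrow(res0$table), 4L)
  expect_true(all(res0$table$lambda_co == 0))
})

test_that("training rejects empty or label-deficient datasets", {
  ds <- tiny_ds(N = 20, C = 2, seed = 13)
  ds$labels[] <- 0L
  expect_error(train_clclsa(ds, tiny_config(epochs = 2)),
               "every class")
})
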