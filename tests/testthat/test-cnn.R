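test_that("network architecture has the documented shape", {
  cfg <- hpnet_config()
  expect_equal(cfg$depths, c(4, 16, 64))
  expect_equal(cfg$input, c(120, 180, 4))
  expect_error(hpnet_config(depths = c(8, 16, 32)), "compiled engine")
  # 180x120 through three pool stages -> 22x15, flatten 21120
  set.seed(2)
  x <- array(runif(120 * 180 * 4 * 4), c(120, 180, 4, 4))
  y <- matrix(runif(24), 4, 6)
  m <- hpnet_train(x, y, 1:3, 4, train = hpnet_train_config(epochs = 1,
                                                            batch = 2,
                                                            seed = 1))
  W <- m$weights$W
  expect_equal(dim(W[[1]]), c(4, 36))       # conv1a: 4 out, 4*9 in
  expect_equal(dim(W[[4]]), c(16, 144))     # conv2b
  expect_equal(dim(W[[6]]), c(64, 576))     # conv3b
  expect_equal(dim(W[[7]]), c(128, 22 * 15 * 64))
  expect_equal(dim(W[[8]]), c(6, 128))
})

test_that("label scaler maps train extremes to [0,1] and inverts exactly", {
  set.seed(4)
  labels <- matrix(rnorm(600), 100, 6)
  sc <- label_scaler(labels)
  scaled <- scale_labels(labels, sc)
  expect_equal(apply(scaled, 2, min), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(scaled, 2, max), rep(1, 6), tolerance = 1e-12)
  expect_equal(unscale_predictions(scaled, sc), labels, tolerance = 1e-12)
  # test labels transformed with a saved mapping may leave [0,1]
  outside <- scale_labels(matrix(10, 1, 6), sc)
  expect_true(all(outside > 1))
  expect_error(label_scaler(matrix(1, 5, 6)), "degenerate")
})

test_that("scaler isolation: refitting with test data changes the mapping", {
  set.seed(5)
  trainval <- matrix(rnorm(300), 50, 6)
  test <- matrix(rnorm(60, sd = 3), 10, 6)
  sc_good <- label_scaler(trainval)
  sc_leaky <- label_scaler(rbind(trainval, test))
  expect_false(isTRUE(all.equal(sc_good$min, sc_leaky$min)))
  # and the model carries its saved mapping into prediction
  x <- array(runif(120 * 180 * 4 * 6), c(120, 180, 4, 6))
  m <- hpnet_train(x, trainval[1:6, ], 1:4, 5:6,
                   train = hpnet_train_config(epochs = 1, batch = 4,
                                              seed = 2))
  p_scaled <- predict(m, x[, , , 1:2], unscale = FALSE)
  p_un <- predict(m, x[, , , 1:2])
  expect_equal(p_un, unscale_predictions(p_scaled, m$scaler),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("preprocessing scales, resizes and stacks four views", {
  z <- new_frame(matrix(0, 480, 720))
  stack <- preprocess_inputs(z, z, z, z)
  expect_equal(dim(stack), c(120, 180, 4))
  expect_true(all(stack == 0))
  w <- new_frame(matrix(255, 480, 720))
  stack2 <- preprocess_inputs(w, z, z, z)
  expect_true(all(abs(stack2[, , 1] - 1) < 1e-12))
  expect_true(all(stack2[, , 2:4] == 0))
  # resize preserves the mean of a smooth image within 1%
  img <- outer(seq(0, 200, length.out = 480),
               seq(0, 1, length.out = 720), function(a, b) a * (0.5 + b / 2))
  r <- resize_bilinear(img, 180, 120)
  expect_equal(mean(r), mean(img), tolerance = 0.01)
  small <- new_frame(matrix(1, 120, 180))
  expect_error(preprocess_inputs(w, z, z, small), "resolution")
})

test_that("training is seeded-deterministic with a recorded history", {
  set.seed(6)
  x <- array(runif(120 * 180 * 4 * 12), c(120, 180, 4, 12))
  y <- matrix(runif(72), 12, 6)
  run <- function() hpnet_train(x, y, 1:10, 11:12,
                                train = hpnet_train_config(epochs = 4,
                                                           batch = 5,
                                                           seed = 9))
  m1 <- run(); m2 <- run()
  expect_identical(m1$train_loss, m2$train_loss)
  expect_identical(m1$val_loss, m2$val_loss)
  expect_identical(m1$weights, m2$weights)
  expect_length(m1$train_loss, 4)
  expect_true(all(is.finite(m1$val_loss)))
  expect_error(hpnet_train(x, y, integer(0), 1:2), "empty split")
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  B <- 2
  x <- array(runif(120 * 180 * 4 * B), c(120, 180, 4, B))
  y <- matrix(runif(B * 6), B, 6)
  m <- hpnet_train(x, y, 1:B, 1:B,
                   train = hpnet_train_config(epochs = 1, batch = B,
                                              seed = 2),
                   scaler = label_scaler(y))
  w <- m$weights
  ys <- scale_labels(y, m$scaler)
  g <- moirepose:::.hp_cnn_grad(w, x, ys)
  eps <- 5e-4
  set.seed(12)
  for (li in c(1, 3, 5, 6, 7, 8)) {
    W <- w$W[[li]]
    for (r in 1:2) {
      i <- sample(nrow(W), 1); j <- sample(ncol(W), 1)
      wp <- w; wp$W[[li]][i, j] <- W[i, j] + eps
      wm <- w; wm$W[[li]][i, j] <- W[i, j] - eps
      num <- (moirepose:::.hp_cnn_grad(wp, x, ys)$loss -
                moirepose:::.hp_cnn_grad(wm, x, ys)$loss) / (2 * eps)
      ana <- g$dW[[li]][i, j]
      # single precision + ReLU kinks limit the attainable agreement
      expect_lt(abs(num - ana), 0.05 * max(abs(ana), 0.05))
    }
  }
})

test_that("the compact sample store matches the array pathway", {
  set.seed(10)
  n <- 6
  x <- array(runif(120 * 180 * 4 * n), c(120, 180, 4, n))
  y <- matrix(runif(n * 6), n, 6)
  store <- moirepose:::.hp_store_create(n)
  for (i in 1:n) moirepose:::.hp_store_set(store, i, x[, , , i])
  ds <- structure(list(store = store, n = n, labels = y),
                  class = "hp_dataset")
  cfg <- hpnet_train_config(epochs = 2, batch = 3, seed = 5)
  m_arr <- hpnet_train(x, y, 1:4, 5:6, train = cfg)
  m_ptr <- hpnet_train(ds, y, 1:4, 5:6, train = cfg)
  expect_equal(m_arr$train_loss, m_ptr$train_loss, tolerance = 1e-6)
  expect_equal(predict(m_arr, x), predict(m_ptr, ds), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("the network can overfit a tiny dataset (capacity sanity)", {
  # capacity probe of the architecture: regularisation off, so the
  # network must drive the fit through sheer expressiveness
  set.seed(7)
  x <- array(runif(120 * 180 * 4 * 10), c(120, 180, 4, 10))
  y <- matrix(runif(60), 10, 6)
  m <- hpnet_train(x, y, 1:10, 1:10,
                   config = hpnet_config(dropout = 0),
                   train = hpnet_train_config(epochs = 500, batch = 10,
                                              lr = 1e-3, seed = 3),
                   scaler = label_scaler(y))
  expect_lt(tail(m$train_loss, 1), 1e-3)
  # optimisation sanity: early loss is decreasing on average
  expect_lt(mean(m$train_loss[6:10]), mean(m$train_loss[1:5]))
})

test_that("evaluation reports per-DOF RMSE and their unweighted mean", {
  set.seed(8)
  x <- array(runif(120 * 180 * 4 * 8), c(120, 180, 4, 8))
  y <- matrix(rnorm(48), 8, 6)
  m <- hpnet_train(x, y, 1:6, 7:8,
                   train = hpnet_train_config(epochs = 1, batch = 4,
                                              seed = 4))
  pred <- predict(m, x)
  # a predictor that matches the labels exactly scores zero
  ev0 <- evaluate_hpnet(m, x, pred)
  expect_equal(unname(ev0$per_dof), rep(0, 6), tolerance = 1e-5)
  # a constant 0.1 offset in X only shows up in X and the average
  shifted <- pred
  shifted[, 1] <- shifted[, 1] - 0.1
  ev <- evaluate_hpnet(m, x, shifted)
  expect_equal(unname(ev$per_dof[1]), 0.1, tolerance = 1e-5)
  expect_lt(sum(ev$per_dof[2:6]), 1e-5)
  expect_equal(ev$average, 0.1 / 6, tolerance = 1e-5)
  expect_error(evaluate_hpnet(m, array(0, c(120, 180, 4, 0)),
                              matrix(0, 0, 6)), "empty")
})

test_that("split summary reports the distribution diagnostic", {
  labels <- matrix(rnorm(1200), 200, 6)
  s <- split_summary(labels, list(train = 1:140, val = 141:180,
                                  test = 181:200))
  expect_equal(nrow(s), 18)
  expect_setequal(unique(s$set), c("train", "val", "test"))
  expect_true(all(c("mean", "median", "sd", "min", "max") %in% names(s)))
})
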