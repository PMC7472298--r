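test_that("default architectures land near 100K parameters", {
  nb <- n_params(build_blstm())
  nc <- n_params(build_cnn())
  expect_gt(nb, 5e4); expect_lt(nb, 2e5)
  expect_gt(nc, 5e4); expect_lt(nc, 2e5)
})

test_that("forward passes have the contracted shapes and normalization", {
  mb <- build_blstm(blstm_spec(input_features = 7), seed = 2)
  X <- matrix(0, 7, 700)
  pr <- swingseg:::blstm_probs(mb$params, X, 5L, 32L, 5L)
  expect_identical(dim(pr), c(5L, 700L))
  expect_true(all(is.finite(pr)))
  expect_equal(colSums(pr), rep(1, 700), tolerance = 1e-9)
  mc <- build_cnn(cnn_spec(), seed = 2)
  s <- mc$spec
  y <- swingseg:::cnn_predict_one(mc$params, X, s$kernel1, s$filters1, s$pool1,
                                  s$kernel2, s$filters2, s$pool2, s$fc_units, 4L)
  expect_identical(length(y), 4L)
  expect_true(all(is.finite(y)))
})

test_that("initialization is deterministic given the seed", {
  expect_identical(build_blstm(seed = 7)$params, build_blstm(seed = 7)$params)
  expect_identical(build_cnn(seed = 7)$params, build_cnn(seed = 7)$params)
  expect_false(identical(build_cnn(seed = 7)$params, build_cnn(seed = 8)$params))
})

test_that("network gradients agree with finite differences", {
  set.seed(3)
  m <- build_blstm(blstm_spec(n_layers = 2, hidden_units = 4,
                              input_features = 3), seed = 5, n_time = 15)
  X <- array(rnorm(2 * 3 * 15), c(3, 15, 2))
  Y <- matrix(sample.int(5, 30, TRUE), 15, 2)
  storage.mode(Y) <- "integer"
  r <- swingseg:::blstm_batch_grad(m$params, X, Y, 2L, 4L, 5L)
  idx <- sample(length(m$params), 20)
  for (j in idx) {
    p1 <- m$params; p1[j] <- p1[j] + 1e-6
    p2 <- m$params; p2[j] <- p2[j] - 1e-6
    num <- (swingseg:::blstm_batch_loss(p1, X, Y, 2L, 4L, 5L) -
              swingseg:::blstm_batch_loss(p2, X, Y, 2L, 4L, 5L)) / 2e-6
    expect_equal(r$grad[j], num, tolerance = 1e-4)
  }
  mc <- build_cnn(cnn_spec(kernel1 = 5, filters1 = 3, pool1 = 2, kernel2 = 3,
                           filters2 = 4, pool2 = 2, fc_units = 6,
                           input_features = 3), seed = 7, n_time = 40)
  Xc <- array(rnorm(3 * 40 * 2), c(3, 40, 2))
  Yc <- matrix(runif(8), 4, 2)
  rc <- swingseg:::cnn_batch_grad(mc$params, Xc, Yc, 5L, 3L, 2L, 3L, 4L, 2L, 6L)
  for (j in sample(length(mc$params), 20)) {
    p1 <- mc$params; p1[j] <- p1[j] + 1e-6
    p2 <- mc$params; p2[j] <- p2[j] - 1e-6
    num <- (swingseg:::cnn_batch_loss(p1, Xc, Yc, 5L, 3L, 2L, 3L, 4L, 2L, 6L) -
              swingseg:::cnn_batch_loss(p2, Xc, Yc, 5L, 3L, 2L, 3L, 4L, 2L, 6L)) / 2e-6
    expect_equal(rc$grad[j], num, tolerance = 1e-4)
  }
})

make_tiny_windows <- function(n_subjects = 2, swings = 4, seed = 31) {
  swings <- simulate_dataset(n_subjects, swings, generator_config(),
                             placements = "wrist", seed = seed)
  make_swing_windows(swings, "wrist", "both", impact = "truth")
}

test_that("training reduces the loss and is reproducible", {
  w <- make_tiny_windows()
  tc <- train_config(learning_rate = 2e-3, batch_size = 4, max_epochs = 8,
                     patience = 8, seed = 5)
  m1 <- train_model(build_cnn(cnn_spec(), seed = 5), w, tc)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_model(build_cnn(cnn_spec(), seed = 5), w, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("validation stopping halts after `patience` flat epochs", {
  w <- make_tiny_windows()
  tc <- train_config(learning_rate = 0, batch_size = 4, max_epochs = 50,
                     patience = 5, seed = 5)
  m <- train_model(build_cnn(cnn_spec(), seed = 5), w, tc)
  # epoch 1 sets the best; epochs 2..6 are flat -> stop at epoch 6
  expect_identical(nrow(m$history), 6L)
})

test_that("sequence cleanup is the identity on monotone input and robust to glitches", {
  t <- window_t()
  clean <- phases_from_points(example_points(), t)
  expect_identical(unclass(clean_sequence(clean)), unclass(clean))
  codes <- unclass(clean)
  codes[400] <- 1L  # single glitch inside DS
  fixed <- clean_sequence(phase_sequence(codes))
  expect_identical(unclass(fixed), unclass(clean))
  noise <- phase_sequence(rep(c(1L, 5L), 350))
  expect_swingseg_error(clean_sequence(noise), "incomplete_phase_sequence")
})

test_that("prediction decoders invert the label encodings", {
  # feed ground-truth encodings through the same decode path the models use
  t <- window_t()
  set.seed(13)
  for (i in 1:20) {
    pts <- sort(runif(4, 0.08, 3.42))
    if (min(diff(pts)) < 0.08) next
    p <- dividing_points(pts[1], pts[2], pts[3], pts[4])
    seq_dec <- points_from_phases(clean_sequence(phases_from_points(p, t)), t)
    expect_lt(max(abs(unclass(seq_dec) - unclass(p))), 0.005 + 1e-9)
    frac <- (unclass(p) - t[1]) / 3.5
    cnn_dec <- t[1] + 3.5 * frac
    expect_lt(max(abs(cnn_dec - unclass(p))), 1e-9)
  }
})

test_that("an untrained model yields ordered points or a flagged error", {
  w <- make_tiny_windows()
  m <- build_cnn(cnn_spec(), seed = 1)
  t <- window_t(w$t0[1])
  res <- tryCatch(predict_points(m, w$inputs[1, , ], t),
                  swingseg_error = function(e) e)
  expect_true(inherits(res, "dividing_points") || inherits(res, "swingseg_error"))
  mb <- build_blstm(blstm_spec(), seed = 1)
  res_b <- tryCatch(predict_points(mb, w$inputs[1, , ], t),
                    swingseg_error = function(e) e)
  expect_true(inherits(res_b, "dividing_points") ||
                inherits(res_b, "swingseg_error"))
})

test_that("model checkpoints round trip with their configuration", {
  m <- build_cnn(cnn_spec(), seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  write_model(m, f)
  expect_identical(read_model(f), m)
})
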