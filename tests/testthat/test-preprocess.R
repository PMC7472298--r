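test_that("the zero-phase filter has unit DC gain and no phase delay", {
  fs <- 200
  x <- rep(2.5, 600)
  expect_equal(lowpass_zero_phase(x, fs), x, tolerance = 1e-7)
  t <- (0:599) / fs
  s <- sin(2 * pi * 1 * t)
  y <- lowpass_zero_phase(s, fs)
  cc <- ccf(y, s, lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("stopband attenuation matches the squared Butterworth response", {
  # |H|^2 at 5x cutoff for an order-10 design is (1 + 5^20)^-1 ~ 1e-14,
  # far below the 1e-3 bound asserted here
  fs <- 200
  t <- (0:799) / fs
  s <- sin(2 * pi * 50 * t)
  y <- lowpass_zero_phase(s, fs)
  # away from the edge-transient region the 50 Hz tone is annihilated
  expect_lt(max(abs(y[160:640])), 1e-3)
})

test_that("too-short signals are rejected", {
  expect_swingseg_error(lowpass_zero_phase(rnorm(25), 200), "filter_length_error")
})

test_that("jump-peak alignment recovers an injected clock offset", {
  imu <- spike_recording(spike_t = 1.0, spike_g = 4)
  off <- align_by_jump_peak(imu, reference_t_peak = 1.100, c(0, 2))
  expect_equal(off, 0.100, tolerance = 1e-9)
  # applying the offset and re-estimating gives zero within one sample
  imu2 <- imu
  imu2$t <- imu$t + off
  expect_lt(abs(align_by_jump_peak(imu2, 1.100, c(0.5, 2))), 0.005 + 1e-9)
})

test_that("a flat gravity-only recording has no jump peak", {
  imu <- spike_recording(spike_g = 0)
  expect_swingseg_error(align_by_jump_peak(imu, 1, c(0, 2)), "no_jump_peak")
})

test_that("the impact proxy takes the earliest of tied maxima", {
  t <- (0:999) / 200
  acc <- matrix(0, 3, 1000)
  acc[1, c(301, 601)] <- 10
  imu <- imu_recording(t, acc, matrix(0, 3, 1000), "wrist")
  expect_equal(find_impact_proxy(imu), t[301])
})

test_that("windows are exactly 3.5 s at the recording's rate", {
  fs <- 200
  t <- (0:1600) / fs
  imu <- imu_recording(t, matrix(0, 3, length(t)), matrix(0, 3, length(t)),
                       "wrist", fs)
  win <- cut_window(imu, 5.0)
  expect_identical(length(win$t), 700L)
  expect_equal(win$t[1], 2.5)
  expect_equal(win$t[700], 6.0 - 1 / fs)
  expect_swingseg_error(cut_window(imu, 1.0), "window_out_of_range")
  imu100 <- imu_recording(t[1:800] * 2, matrix(0, 3, 800), matrix(0, 3, 800),
                          "wrist", 100)
  expect_identical(length(cut_window(imu100, 4)$t), 350L)
})

test_that("per-feature normalization maps rows to [-1, 1]", {
  expect_equal(normalize_features(matrix(c(-2, 0, 2), 1)),
               matrix(c(-1, 0, 1), 1))
  expect_equal(normalize_features(matrix(5, 1, 3)), matrix(0, 1, 3))
  m <- matrix(rnorm(30), 3)
  nm <- normalize_features(m)
  expect_equal(unname(apply(nm, 1, min)), rep(-1, 3))
  expect_equal(unname(apply(nm, 1, max)), rep(1, 3))
})

test_that("assembled inputs have the documented shapes and time ramp", {
  sw <- sim_swing(2)
  imu <- filter_recording(sw$recordings$wrist)
  win <- cut_window(imu, sw$truth[["imp_s"]])
  both <- assemble_input(win, "both")
  expect_identical(dim(both), c(7L, 700L))
  expect_identical(dim(assemble_input(win, "acc")), c(4L, 700L))
  expect_identical(dim(assemble_input(win, "gyro")), c(4L, 700L))
  ramp <- both[1, ]
  expect_equal(ramp[1], -1)
  expect_equal(ramp[700], 1)
  expect_equal(diff(ramp), rep(2 / 699, 699), tolerance = 1e-9)
})

test_that("label encoding places impact at 5/7 of the window and round trips", {
  sw <- sim_swing(2)
  imu <- filter_recording(sw$recordings$wrist)
  win <- cut_window(imu, sw$truth[["imp_s"]])
  lab <- encode_labels(win, sw$truth)
  expect_equal(lab$cnn[3], 2.5 / 3.5, tolerance = 2e-3)
  expect_true(all(diff(lab$cnn) > 0) && all(lab$cnn > 0 & lab$cnn < 1))
  # decode both encodings back to times
  dec_seq <- points_from_phases(lab$blstm, win$t)
  expect_lt(max(abs(unclass(dec_seq) - unclass(sw$truth))), 0.005 + 1e-9)
  dec_cnn <- win$t[1] + 3.5 * lab$cnn
  expect_lt(max(abs(dec_cnn - unclass(sw$truth))), 0.005 + 1e-9)
  bad <- unclass(sw$truth) + c(0, 0, 0, 2)
  expect_swingseg_error(
    encode_labels(win, dividing_points(bad[1], bad[2], bad[3], bad[4])),
    "labels_out_of_window")
})

test_that("filtering commutes with windowing away from the edges", {
  sw <- sim_swing(6, quiet_config())
  raw <- sw$recordings$wrist
  imp <- sw$truth[["imp_s"]]
  a <- cut_window(filter_recording(raw), imp)
  b <- filter_recording(cut_window(raw, imp))
  inner <- 60:640
  expect_lt(max(abs(a$acc[, inner] - b$acc[, inner])), 1e-3)
})

test_that("window sets carry matched inputs, labels and subjects", {
  swings <- simulate_dataset(2, 2, generator_config(), placements = "wrist",
                             seed = 3)
  w <- make_swing_windows(swings, "wrist", "both", impact = "truth")
  expect_identical(dim(w$inputs), c(4L, 7L, 700L))
  expect_identical(dim(w$blstm), c(4L, 700L))
  expect_identical(dim(w$cnn), c(4L, 4L))
  expect_identical(w$subject, c("01", "01", "02", "02"))
  # augmented sets replicate swings with jitter
  set.seed(1)
  wa <- make_swing_windows(swings, "wrist", "both", impact = "truth",
                           jitter_s = 0.3, n_augment = 3)
  expect_identical(dim(wa$inputs)[1], 12L)
  expect_gt(sd(wa$cnn[1:3, 3]), 0)  # impact fraction varies across copies
  f <- withr::local_tempfile(fileext = ".rds")
  write_windows(wa, f)
  expect_identical(read_windows(f), wa)
})
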