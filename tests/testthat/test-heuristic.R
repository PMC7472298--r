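test_that("event detection matches analytic extrema and crossings", {
  t <- seq(0, 1, by = 0.002)
  r_zc <- indicator_rule("wrist", "BST", "gyro", "z", "zero_crossing",
                         window = c(0.2, 0.8), slope = "-")
  expect_equal(detect_event(sin(2 * pi * t), t, r_zc, 0), 0.5,
               tolerance = 1e-6)
  r_min <- indicator_rule("wrist", "ADD", "gyro", "y", "min",
                          window = c(0, 1))
  expect_equal(detect_event((t - 0.3)^2, t, r_min, 0), 0.3, tolerance = 1e-9)
  expect_swingseg_error(detect_event(rep(1, length(t)), t, r_zc, 0),
                        "event_not_found")
})

test_that("event detection is translation-equivariant", {
  t <- seq(0, 2, by = 0.005)
  x <- sin(2 * pi * t) + 0.3 * cos(5 * t)
  r <- indicator_rule("wrist", "BST", "gyro", "z", "zero_crossing",
                      window = c(-0.4, 0.4), slope = "either")
  base <- detect_event(x, t, r, 1.0)
  for (dt in c(0.25, 0.5, 1.0)) {
    expect_equal(detect_event(x, t + dt, r, 1.0 + dt), base + dt,
                 tolerance = 1e-9)
  }
})

test_that("norm channels cannot carry zero-crossing rules", {
  expect_swingseg_error(
    indicator_rule("wrist", "FIN", "gyro", "norm", "zero_crossing"),
    "config_error")
})

test_that("the shipped rules load and cover every placement and point", {
  for (pl in PLACEMENTS) {
    rules <- default_indicator_rules(pl)
    expect_named(rules, POINT_LEVELS)
  }
  for (m in c("acc", "gyro")) {
    expect_named(default_indicator_rules("wrist", m), POINT_LEVELS)
  }
  expect_swingseg_error(default_indicator_rules("head", "acc"), "config_error")
})

test_that("heuristic segmentation recovers noiseless truth at all placements", {
  cfg <- quiet_config()
  for (seed in 1:8) {
    sw <- sim_swing(seed, cfg)
    for (pl in PLACEMENTS) {
      est <- heuristic_segment(filter_recording(sw$recordings[[pl]]))
      expect_lt(max(abs(unclass(est) - unclass(sw$truth))), 0.010,
                label = sprintf("placement %s seed %d", pl, seed))
    }
  }
})

test_that("a destroyed indicator region names the failing point", {
  cfg <- quiet_config()
  sw <- sim_swing(4, cfg, placements = "wrist")
  imu <- sw$recordings$wrist
  # flatten omega_z around BST (with margin for filter smearing) so the
  # zero crossing disappears
  idx <- which(imu$t > sw$truth[["bst_s"]] - 0.9 &
                 imu$t < sw$truth[["imp_s"]] + 0.25)
  imu$gyro[3, idx] <- 5
  err <- tryCatch(heuristic_segment(filter_recording(imu)),
                  swingseg_error = function(e) conditionMessage(e))
  expect_match(err, "BST")
})

test_that("candidate ranking prefers the shipped rules over lagged decoys", {
  cfg <- generator_config()
  swings <- simulate_dataset(2, 4, cfg, placements = "wrist", seed = 13)
  rules <- default_indicator_rules("wrist")
  lagged <- lapply(rules, function(r) {
    indicator_rule(r$placement, r$point, r$source, r$channel, r$event,
                   window = r$window + 0.25, slope = r$slope)
  })
  ranked <- rank_indicator_candidates(c(rules, unname(lagged)), swings)
  sel <- attr(ranked, "selection")
  # the best rule per point must be one of the first four (shipped) rules
  expect_true(all(sel$candidate <= 4L))
})

test_that("ranking a single candidate and ties behave predictably", {
  cfg <- generator_config()
  swings <- simulate_dataset(2, 2, cfg, placements = "wrist", seed = 17)
  r <- default_indicator_rules("wrist")$IMP
  one <- rank_indicator_candidates(list(r), swings)
  expect_identical(nrow(one), 1L)
  expect_true(is.finite(one$mae_ms))
  two <- rank_indicator_candidates(list(r, r), swings)
  expect_equal(two$mae_ms[1], two$mae_ms[2])
  expect_identical(two$candidate, c(1L, 2L))  # stable order on ties
})

test_that("under noise the wrist top-of-swing beats the address indicator", {
  cfg <- generator_config()
  errs <- NULL
  for (k in 1:30) {
    sw <- sim_swing(700 + k, cfg, placements = "wrist")
    hs <- tryCatch(heuristic_segment(filter_recording(sw$recordings$wrist)),
                   swingseg_error = function(e) NULL)
    if (!is.null(hs)) errs <- rbind(errs, abs(unclass(hs) - unclass(sw$truth)))
  }
  expect_lt(mean(errs[, "bst_s"]), mean(errs[, "add_s"]))
})

test_that("heuristic error does not improve as sensor noise grows", {
  mae_at <- function(sd_g, sd_dps, seed0) {
    cfg <- generator_config(noise_acc_g = sd_g, noise_gyro_dps = sd_dps)
    e <- NULL
    for (k in 1:25) {
      sw <- sim_swing(seed0 + k, cfg, placements = "wrist")
      hs <- tryCatch(heuristic_segment(filter_recording(sw$recordings$wrist)),
                     swingseg_error = function(e) NULL)
      if (!is.null(hs)) e <- c(e, mean(abs(unclass(hs) - unclass(sw$truth))))
    }
    c(mean = mean(e), se = sd(e) / sqrt(length(e)))
  }
  lo <- mae_at(0, 0, 300)
  mid <- mae_at(0.05, 8, 300)
  hi <- mae_at(0.15, 24, 300)
  expect_gt(mid[["mean"]], lo[["mean"]] - 3 * mid[["se"]])
  expect_gt(hi[["mean"]], mid[["mean"]] - 3 * (hi[["se"]] + mid[["se"]]))
})
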