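test_that("subject-level MAE summary matches hand arithmetic", {
  m <- mae_by_point(c(10, -20, 0), c("A", "A", "B"))
  expect_equal(unname(m$per_subject), c(15, 0))
  expect_equal(m$grand_mean, 7.5)
  expect_equal(m$sd, sd(c(15, 0)))
  z <- mae_by_point(rep(0, 6), rep(c("A", "B"), 3))
  expect_equal(z$grand_mean, 0)
  expect_equal(z$sd, 0)
  # permuting swings within subjects changes nothing
  set.seed(2)
  e <- rnorm(20); s <- rep(c("A", "B"), each = 10)
  o <- c(sample(1:10), 10 + sample(1:10))
  expect_equal(mae_by_point(e, s)$grand_mean, mae_by_point(e[o], s[o])$grand_mean)
})

test_that("phase-length errors are percentages of the reference length", {
  truth <- dividing_points(0, 1.163, 1.480, 2.150)
  est <- dividing_points(0, 1.163, 1.496, 2.166)
  e <- phase_length_error_pct(est, truth)
  expect_equal(unname(e[["ds"]]), 100 * 0.016 / 0.317, tolerance = 1e-6)
  expect_equal(unname(phase_length_error_pct(truth, truth)), rep(0, 3))
  # scale invariance
  tr2 <- dividing_points(0, 2.326, 2.960, 4.300)
  es2 <- dividing_points(0, 2.326, 2.992, 4.332)
  expect_equal(phase_length_error_pct(es2, tr2), e, tolerance = 1e-9)
})

test_that("leave-one-subject-out folds test each subject exactly once", {
  swings <- simulate_dataset(3, 3, generator_config(), placements = "wrist",
                             seed = 19)
  rep <- loso_cv(swings, "heuristic", "wrist", "a+g")
  expect_identical(rep$n_subjects, 3L)
  per <- table(rep$errors$subject[rep$errors$point == "IMP"])
  expect_identical(unname(c(per)), rep(3L, 3))
})

test_that("the heuristic is invariant to the training folds", {
  cfg <- generator_config()
  d_small <- simulate_dataset(2, 2, cfg, placements = "wrist", seed = 23)
  d_big <- c(d_small, simulate_dataset(3, 2, cfg, placements = "wrist",
                                       seed = 29)[5:6])
  r1 <- loso_cv(d_small, "heuristic", "wrist", "a+g")
  r2 <- loso_cv(d_big, "heuristic", "wrist", "a+g")
  e1 <- r1$errors[r1$errors$subject == "01", "error_ms"]
  e2 <- r2$errors[r2$errors$subject == "01", "error_ms"]
  expect_identical(e1, e2)
})

test_that("modality arms use 4- and 7-feature inputs on matched folds", {
  swings <- simulate_dataset(2, 2, generator_config(), placements = "wrist",
                             seed = 37)
  wa <- make_swing_windows(swings, "wrist", "acc")
  wg <- make_swing_windows(swings, "wrist", "gyro")
  wb <- make_swing_windows(swings, "wrist", "both")
  expect_identical(dim(wa$inputs)[2], 4L)
  expect_identical(dim(wg$inputs)[2], 4L)
  expect_identical(dim(wb$inputs)[2], 7L)
  arms <- modality_ablation(swings, "heuristic", "wrist")
  expect_named(arms, c("a", "g", "a+g"))
  expect_false(is.null(arms[["a"]]))
  # head single-modality heuristic rule sets are not defined
  swings_h <- simulate_dataset(2, 2, generator_config(), placements = "head",
                               seed = 37)
  arms_h <- modality_ablation(swings_h, "heuristic", "head")
  expect_null(arms_h[["a"]])
  expect_false(is.null(arms_h[["a+g"]]))
})

test_that("paired significance flags shifts and rejects bad pairings", {
  set.seed(5)
  a <- runif(20, 10, 30)
  same <- paired_significance(a, a)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  shifted <- paired_significance(a, a + 25)
  expect_true(shifted$significant)
  expect_lt(shifted$p_value, 0.001)
  tt <- paired_significance(a, a + 25, test = "ttest")
  expect_true(tt$significant)
  expect_swingseg_error(paired_significance(a[1:3], a[1:3] + 1), "pairing_error")
  expect_swingseg_error(paired_significance(a, a[1:10]), "pairing_error")
})

test_that("rendered reports round trip numerically", {
  swings <- simulate_dataset(2, 2, generator_config(), placements = "wrist",
                             seed = 41)
  rep <- loso_cv(swings, "heuristic", "wrist", "a+g")
  d <- withr::local_tempdir()
  render_report(rep, d)
  back <- utils::read.csv(file.path(d, "summary.csv"))
  expect_identical(nrow(back), nrow(summary(rep)))
  expect_equal(back$grand_mean, summary(rep)$grand_mean, tolerance = 1e-9)
  expect_true(file.exists(file.path(d, "mae_ms.png")))
})

test_that("heuristic errors at the head and waist exceed the wrist", {
  swings <- simulate_dataset(4, 6, generator_config(), seed = 47)
  overall <- vapply(PLACEMENTS, function(pl) {
    rep <- loso_cv(swings, "heuristic", pl, "a+g")
    mean(vapply(POINT_LEVELS, function(p) mean(subject_mae(rep, p)), 0))
  }, 0)
  expect_gt(overall[["head"]], overall[["wrist"]])
  expect_gt(overall[["waist"]], overall[["wrist"]])
})
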