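test_that("zero random-effect SDs give unit multipliers and zero offsets", {
  cfg <- generator_config(subject_amp_sdlog = 0, subject_lag_sd = 0,
                          subject_dur_sdlog = 0)
  p <- sample_subject_profile(cfg, seed = 1)
  expect_identical(unname(p$acc_amp), rep(1, 3))
  expect_identical(unname(p$gyro_amp), rep(1, 3))
  expect_identical(unname(p$lag_offset), rep(0, 3))
  expect_identical(p$dur_mult, 1)
})

test_that("profiles and swings are deterministic given the seed", {
  cfg <- generator_config()
  expect_identical(sample_subject_profile(cfg, seed = 9),
                   sample_subject_profile(cfg, seed = 9))
  s1 <- sim_swing(5, cfg)
  s2 <- sim_swing(5, cfg)
  expect_identical(s1$recordings$wrist$acc, s2$recordings$wrist$acc)
  expect_identical(unclass(s1$truth), unclass(s2$truth))
})

test_that("lag-offset draws have the configured spread", {
  cfg <- generator_config(subject_lag_sd = 0.02)
  set.seed(4)
  draws <- replicate(1000, sample_subject_profile(cfg)$lag_offset[["wrist"]])
  expect_gt(sd(draws), 0.015)
  expect_lt(sd(draws), 0.025)
})

test_that("the reference labeler recovers the noiseless ground truth", {
  cfg <- quiet_config()
  for (seed in 1:10) {
    sw <- sim_swing(seed, cfg, placements = "wrist")
    lr <- label_reference(sw$track)
    expect_lt(max(abs(unclass(lr) - unclass(sw$truth))), 0.005)
  }
})

test_that("an over-range impact transient saturates at exactly 16 g", {
  cfg <- quiet_config(impact_amp_g = c(wrist = 30, head = 0.3, waist = 7))
  sw <- sim_swing(8, cfg, placements = "wrist")
  expect_identical(max(sw$recordings$wrist$acc), 16)
})

test_that("dataset simulation has the requested structure and is reproducible", {
  cfg <- generator_config()
  d <- simulate_dataset(3, 4, cfg, placements = "wrist", seed = 11)
  expect_length(d, 12L)
  expect_identical(length(unique(vapply(d, function(s) s$subject_id, ""))), 3L)
  expect_setequal(unique(vapply(d, function(s) s$club, "")),
                  c("driver", "iron7"))
  d2 <- simulate_dataset(3, 4, cfg, placements = "wrist", seed = 11)
  expect_identical(d[[5]]$recordings$wrist$gyro, d2[[5]]$recordings$wrist$gyro)
  # adding swings must not change earlier ones
  d3 <- simulate_dataset(3, 6, cfg, placements = "wrist", seed = 11)
  expect_identical(unclass(d[[2]]$truth), unclass(d3[[2]]$truth))
})

test_that("phase-duration statistics recover the configured values", {
  cfg <- generator_config()
  d <- simulate_dataset(25, 16, cfg, placements = "wrist", seed = 5)
  lens <- t(vapply(d, function(s) phase_lengths(s$truth), numeric(4)))
  n <- nrow(lens)
  # total spread combines the within-swing SD and the subject tempo effect
  tot_sd <- function(mu, sd) sqrt(sd^2 + (mu * cfg$subject_dur_sdlog)^2)
  for (spec in list(list(1, cfg$bs_mean, cfg$bs_sd),
                    list(2, cfg$ds_mean, cfg$ds_sd),
                    list(3, cfg$ft_mean, cfg$ft_sd))) {
    mu <- spec[[2]]; s_tot <- tot_sd(mu, spec[[3]])
    expect_lt(abs(mean(lens[, spec[[1]]]) - mu), 3.5 * s_tot / sqrt(n))
    expect_lt(abs(sd(lens[, spec[[1]]]) - s_tot), 0.25 * s_tot)
  }
})

test_that("large subject effects dominate the between-subject variance", {
  cfg <- generator_config(subject_dur_sdlog = 0.2)
  d <- simulate_dataset(20, 10, cfg, placements = "wrist", seed = 9)
  ds <- vapply(d, function(s) phase_lengths(s$truth)[["ds_s"]], 0)
  subj <- vapply(d, function(s) s$subject_id, "")
  subj_means <- tapply(ds, subj, mean)
  within_sd <- sqrt(mean(tapply(ds, subj, var)))
  expect_gt(sd(subj_means), within_sd / sqrt(10))
})

test_that("an unlabelable track is reported", {
  t <- seq(0, 4, by = 0.005)
  tr <- clubhead_track(t, ball_coord = -1 - t, speed = t * 10)
  expect_swingseg_error(label_reference(tr), "unlabelable_track")
})

test_that("labeling is robust to multiplicative speed noise", {
  cfg <- quiet_config()
  set.seed(21)
  worst <- 0
  for (k in 1:200) {
    sw <- sim_swing(k, cfg, placements = "wrist")
    tr <- sw$track
    tr$speed <- pmax(tr$speed * (1 + rnorm(length(tr$speed), 0, 0.01)), 0)
    lr <- label_reference(tr)
    worst <- max(worst, abs(unclass(lr) - unclass(sw$truth)))
  }
  expect_lt(worst, 0.02)
})

test_that("generator configs round trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  cfg <- generator_config(noise_acc_g = 0.02)
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("a full-scale cohort has the study's structure", {
  d <- simulate_dataset(20, 20, generator_config(), placements = "wrist",
                        seed = 2)
  expect_length(d, 400L)
  expect_identical(length(unique(vapply(d, function(s) s$subject_id, ""))), 20L)
  clubs <- table(vapply(d, function(s) s$club, ""))
  expect_identical(unname(c(clubs)), c(200L, 200L))
})
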