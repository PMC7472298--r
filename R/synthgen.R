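#' Synthetic swing generator configuration
#'
#' Parameters of the synthetic golf-swing kinematics generator. Phase
#' durations are drawn per swing from truncated normal distributions whose
#' defaults reproduce the reference phase-length statistics (backswing
#' 1.163 +/- 0.232 s, downswing 0.317 +/- 0.050 s, follow-through
#' 0.670 +/- 0.119 s when the within-swing SDs are combined with the
#' subject-level tempo effect). Body-segment motion follows a
#' proximal-to-distal sequence: the waist leads, the head follows and the
#' wrist trails (`lag_s`), with subject-specific amplitude, lag and tempo
#' random effects. Signals carry an impact acceleration transient, white
#' sensor noise and +/-16 g / +/-2000 dps saturation.
#'
#' @param sample_rate_hz sampling rate (Hz).
#' @param bs_mean,bs_sd,ds_mean,ds_sd,ft_mean,ft_sd within-subject phase
#'   duration means and SDs (s) for backswing, downswing, follow-through.
#' @param dur_bounds list of length-2 bounds (s) used to truncate each
#'   duration draw.
#' @param bf_pad_s,af_pad_s quiet padding before ADD and after FIN (s).
#'   The pre-ADD padding is sized so the 2.5 s pre-impact half-window never
#'   extends before the recording starts.
#' @param lag_s named proximal-to-distal segment lags (s); must be ordered
#'   waist <= head <= wrist.
#' @param acc_scale,gyro_scale named per-placement amplitude multipliers.
#' @param impact_amp_g named per-placement impact transient amplitude (g),
#'   before clipping.
#' @param impact_decay_s,impact_freq_hz impact transient decay constant (s)
#'   and ring frequency (Hz; kept below the 10 Hz analysis bandwidth so the
#'   transient survives low-pass filtering).
#' @param speed_peak_mps named clubhead speed peak at impact per club (m/s).
#' @param bs_speed_peak_mps clubhead speed peak during the backswing (m/s).
#' @param noise_acc_g,noise_gyro_dps white sensor-noise SDs.
#' @param subject_amp_sdlog SD of the log amplitude multipliers.
#' @param subject_lag_sd SD (s) of the additive per-placement lag offsets.
#' @param subject_dur_sdlog SD of the log tempo (duration) multiplier.
#' @param jump_amp_g,jump_time_s,jump_width_s pre-swing time-alignment jump
#'   spike: amplitude (g), centre time (s) and Gaussian width (s).
#' @param seed default seed used by [simulate_dataset()].
#' @return An object of class `generator_config` (a named list).
#' @export
generator_config <- function(sample_rate_hz = 200,
                             bs_mean = 1.163, bs_sd = 0.221,
                             ds_mean = 0.317, ds_sd = 0.046,
                             ft_mean = 0.670, ft_sd = 0.112,
                             dur_bounds = list(bs = c(0.1, 2.1),
                                               ds = c(0.1, 0.55),
                                               ft = c(0.1, 0.93)),
                             bf_pad_s = 2.3, af_pad_s = 0.8,
                             lag_s = c(waist = 0, head = 0.015, wrist = 0.030),
                             acc_scale = c(wrist = 1, head = 1, waist = 1),
                             gyro_scale = c(wrist = 1, head = 1, waist = 1),
                             impact_amp_g = c(wrist = 12, head = 0.3,
                                              waist = 7),
                             impact_decay_s = c(wrist = 0.05, head = 0.02,
                                                waist = 0.015),
                             impact_freq_hz = c(wrist = 8, head = 0,
                                                waist = 0),
                             speed_peak_mps = c(driver = 42, iron7 = 36),
                             bs_speed_peak_mps = 5,
                             noise_acc_g = 0.05, noise_gyro_dps = 8,
                             subject_amp_sdlog = 0.15,
                             subject_lag_sd = 0.015,
                             subject_dur_sdlog = 0.06,
                             jump_amp_g = c(wrist = 2.0, head = 0.5,
                                            waist = 0.9),
                             jump_time_s = 0.45, jump_width_s = 0.03,
                             seed = 1L) {
  cfg <- as.list(environment())
  sds <- c(cfg$bs_sd, cfg$ds_sd, cfg$ft_sd, cfg$noise_acc_g,
           cfg$noise_gyro_dps, cfg$subject_amp_sdlog, cfg$subject_lag_sd,
           cfg$subject_dur_sdlog)
  if (any(sds < 0)) swingseg_error("config_error", "SDs must be >= 0")
  if (any(vapply(cfg$dur_bounds, function(b) b[1] < 0.1 - 1e-12, TRUE))) {
    swingseg_error("config_error", "duration draws must be floored at 0.1 s")
  }
  l <- cfg$lag_s
  if (!(l[["waist"]] <= l[["head"]] && l[["head"]] <= l[["wrist"]])) {
    swingseg_error("config_error", "lags must be ordered waist <= head <= wrist")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> %g Hz; BS %.3f+/-%.3f, DS %.3f+/-%.3f,",
                     " FT %.3f+/-%.3f s; noise %.3g g / %.3g dps\n"),
              x$sample_rate_hz, x$bs_mean, x$bs_sd, x$ds_mean, x$ds_sd,
              x$ft_mean, x$ft_sd, x$noise_acc_g, x$noise_gyro_dps))
  invisible(x)
}

#' Read/write a generator configuration as YAML
#' @param path YAML file path.
#' @return [read_generator_config()] returns a `generator_config`.
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$dur_bounds <- lapply(x$dur_bounds, unlist)
  for (f in c("lag_s", "acc_scale", "gyro_scale", "impact_amp_g",
              "impact_decay_s", "impact_freq_hz", "jump_amp_g",
              "speed_peak_mps")) x[[f]] <- unlist(x[[f]])
  do.call(generator_config, x)
}

#' @rdname read_generator_config
#' @param config a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' Draw a subject profile
#'
#' Subject-level random effects: log-normal amplitude multipliers (median 1)
#' per placement and modality, normal additive lag offsets (mean 0) per
#' placement, and a log-normal tempo multiplier applied to the phase
#' duration means. Deterministic given the seed.
#'
#' @param config a [generator_config()].
#' @param subject_id identifier stored on the profile.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return An object of class `subject_profile`.
#' @export
sample_subject_profile <- function(config, subject_id = "S01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pls <- PLACEMENTS
  amp <- function() stats::setNames(
    exp(stats::rnorm(3, 0, config$subject_amp_sdlog)), pls)
  prof <- list(subject_id = as.character(subject_id),
               acc_amp = amp(), gyro_amp = amp(),
               lag_offset = stats::setNames(
                 stats::rnorm(3, 0, config$subject_lag_sd), pls),
               dur_mult = exp(stats::rnorm(1, 0, config$subject_dur_sdlog)),
               sway_phase = stats::runif(3, 0, 2 * pi))
  if (any(c(prof$acc_amp, prof$gyro_amp, prof$dur_mult) <= 0)) {
    swingseg_error("config_error", "amplitude multipliers must be positive")
  }
  structure(prof, class = "subject_profile")
}

# ---- signal primitives ------------------------------------------------------

# Gaussian bump, unit peak
.gb <- function(t, mu, s) exp(-((t - mu)^2) / (2 * s * s))

# envelope with an exact zero (value and slope) at tau; pins event times
.envmin <- function(t, tau, w) 1 - .gb(t, tau, w)

# localized zero crossing at tau with slope sign `sgn`
.zcp <- function(t, tau, w, span, sgn) sgn * tanh((t - tau) / w) * .gb(t, tau, span)

# one-sided decaying impact oscillation; `shape` "cos" jumps to full
# amplitude at onset (sharp proximal shock), "sin" rises from zero
# (attenuated distal shock)
.impact_osc <- function(t, imp, amp, decay, freq, shape) {
  x <- t - imp
  on <- as.numeric(x >= 0)
  if (shape == "alpha") {
    # rises from zero, peaks `amp` at x = decay; models the delayed,
    # attenuated shock reaching a distal segment
    return(amp * on * (pmax(x, 0) / decay) * exp(1 - pmax(x, 0) / decay))
  }
  ring <- if (shape == "cos") cos(2 * pi * freq * x) else sin(2 * pi * freq * x)
  amp * on * exp(-pmax(x, 0) / decay) * ring
}

# ---- per-placement channel templates ---------------------------------------

# Each channel is (sum of event primitives) + background * prod(envmin at
# each event time on that channel). Backgrounds therefore vanish with zero
# slope at event times, so extrema / zero crossings sit exactly on the
# ground-truth dividing points in the noiseless limit.
.simulate_placement <- function(placement, t, anch, cfg, prof) {
  add <- anch$add; bst <- anch$bst; imp <- anch$imp; fin <- anch$fin
  bs <- bst - add; ds <- imp - bst; ft <- fin - imp
  lag <- cfg$lag_s[[placement]] + prof$lag_offset[[placement]]
  m_g <- cfg$gyro_scale[[placement]] * prof$gyro_amp[[placement]]
  m_a <- cfg$acc_scale[[placement]] * prof$acc_amp[[placement]]
  mb <- (add + bst) / 2 + lag   # lagged mid-backswing
  md <- (bst + imp) / 2 + lag   # lagged mid-downswing
  mf <- (imp + fin) / 2 + lag   # lagged mid-follow-through
  wag <- add - 0.35 + lag       # pre-address waggle centre
  # three-channel sway with 120-degree spacing: the gyro-norm floor stays
  # flat (no collective zero crossings that would fake quiet-phase minima)
  ph0 <- prof$sway_phase[match(placement, PLACEMENTS)]
  sw <- function(k, a = 4) a * sin(2 * pi * 0.4 * t + ph0 + 2 * pi * (k - 1) / 3)
  G <- function(mu, s) .gb(t, mu, s)
  E <- function(tau, w) .envmin(t, tau, w)
  e_fin <- E(fin, 0.09)

  if (placement == "wrist") {
    gy <- (-18 * G(add, 0.22) - 600 * G(imp, 0.035) +
             (160 * G(mb, bs / 4) + 120 * G(mf, ft / 4) + sw(1, 6)) *
               E(add, 0.20) * E(imp, 0.05)) * e_fin
    gz <- (180 * .zcp(t, bst, 0.06, 0.45, -1) +
             (25 * G(wag, 0.15) + sw(2, 6)) * E(bst, 0.08)) * e_fin
    gx <- (90 * G(mb, bs / 4) - 350 * G(md, ds / 3) + 100 * G(mf, ft / 4) +
             35 * G(fin + 0.30, 0.15) + sw(3, 6)) * e_fin
    osc <- .impact_osc(t, imp, cfg$impact_amp_g[["wrist"]],
                       cfg$impact_decay_s[["wrist"]], cfg$impact_freq_hz[["wrist"]], "cos")
    ax <- (-1.2 * G(bst, 0.10) +
             (3.0 * G(md, ds / 3) + 1.5 * G(mf, ft / 4) +
                0.3 * G(fin + 0.25, 0.10) + 0.2 * G(wag, 0.15) +
                0.04 * sw(1)) * E(bst, 0.08)) * E(fin, 0.09) + osc
    ay <- (-0.35 * G(add, 0.18) +
             (2.0 * G(md, ds / 3) + 1.0 * G(mb, bs / 4) + 0.03 * sw(2)) *
               E(add, 0.10)) * E(fin, 0.09)
    az_motion <- 0 * t
  } else if (placement == "head") {
    e_add <- E(add, 0.07)
    gx <- (30 * G(wag, 0.15) + 50 * G(mb, bs / 3.5) - 120 * G(md, ds / 3) +
             40 * G(mf, ft / 3.5) + 12 * G(fin + 0.25, 0.10) + sw(1)) *
      e_add * e_fin
    gy <- (20 * G(wag + 0.05, 0.18) + 60 * G(mb, bs / 4) -
             100 * G(md, ds / 3) + 30 * G(mf, ft / 4) + sw(2)) * e_add * e_fin
    gz <- (40 * G(mb, bs / 3.5) - 150 * G(md, ds / 3) +
             50 * G(mf, ft / 3.5) + 8 * G(fin + 0.30, 0.12) + sw(3)) *
      e_add * e_fin
    e_imp <- E(imp, 0.05)
    osc <- .impact_osc(t, imp, cfg$impact_amp_g[["head"]],
                       cfg$impact_decay_s[["head"]], cfg$impact_freq_hz[["head"]], "alpha")
    # a_x crosses zero at impact with steady slope, so the acceleration
    # norm has a clean quadratic minimum exactly at IMP; the brake/recover
    # bump pair on a_y flanks impact near-symmetrically and provides the
    # acceleration-norm peak used as the windowing proxy
    ax <- (-0.8 * G(bst, 0.12) +
             (0.6 * G(md, ds / 3) + 0.3 * G(mf, ft / 4) +
                0.15 * G(wag, 0.15) + 0.012 * sw(1)) * E(bst, 0.08)) * e_imp +
      0.8 * .zcp(t, imp, 0.08, 0.30, -1) * E(bst, 0.06)
    ay <- (0.5 * G(md, ds / 3) + 0.25 * G(mb, bs / 4) +
             0.2 * G(mf, ft / 4) + 0.012 * sw(2)) * e_imp +
      4.6 * G(imp - 0.09, 0.03) + 4.0 * G(imp + 0.09, 0.03) + osc
    az_motion <- 0 * t
  } else { # waist
    e_add <- E(add, 0.18)
    gy <- (-22 * G(add, 0.22) * E(bst, 0.06) +
             60 * .zcp(t, bst, 0.22, 0.55, -1) * e_add +
             (10 * G(wag, 0.15) + sw(1)) * e_add * E(bst, 0.09)) * e_fin
    gx <- (80 * G(mb, bs / 4) - 160 * G(md, ds / 3) + 50 * G(mf, ft / 4) +
             15 * G(fin + 0.25, 0.10) + sw(2)) * e_fin
    gz <- (60 * G(mb, bs / 3.5) - 140 * G(md, ds / 3) +
             45 * G(mf, ft / 3.5) + sw(3)) * e_fin
    osc <- .impact_osc(t, imp, cfg$impact_amp_g[["waist"]],
                       cfg$impact_decay_s[["waist"]], cfg$impact_freq_hz[["waist"]], "alpha")
    ax <- 0.9 * .zcp(t, imp, 0.20, 0.45, -1) +
      (0.3 * G(mb, bs / 4) + 0.2 * G(mf, ft / 4) + 0.010 * sw(1)) * E(imp, 0.06)
    ay <- (0.25 * G(md, ds / 3) + 0.2 * G(mb, bs / 4) + 0.010 * sw(2)) + osc
    az_motion <- 0.3 * G(md, ds / 3)
  }

  jump <- cfg$jump_amp_g[[placement]] * .gb(t, cfg$jump_time_s, cfg$jump_width_s)
  acc <- rbind(ax * m_a, ay * m_a, 1 + (az_motion + jump) * m_a)
  gyro <- rbind(gx, gy, gz) * m_g

  acc <- acc + matrix(stats::rnorm(length(acc), 0, cfg$noise_acc_g), nrow = 3)
  gyro <- gyro + matrix(stats::rnorm(length(gyro), 0, cfg$noise_gyro_dps),
                        nrow = 3)
  acc <- pmin(pmax(acc, -16), 16)
  gyro <- pmin(pmax(gyro, -2000), 2000)
  imu_recording(t, acc, gyro, placement, cfg$sample_rate_hz)
}

# clubhead speed profile: pre-swing waggle, backswing bump, sharp rise to
# the impact peak, follow-through decay; exact zeros (local minima) pinned
# at ADD, BST and FIN by envelopes. The width change at the impact peak is
# the one permitted non-smooth point.
.simulate_track <- function(t, anch, cfg, club) {
  add <- anch$add; bst <- anch$bst; imp <- anch$imp; fin <- anch$fin
  bs <- bst - add; ds <- imp - bst; ft <- fin - imp
  a_imp <- cfg$speed_peak_mps[[club]]
  sig <- ifelse(t <= imp, ds / 2.2, ft / 2.8)
  main <- a_imp * exp(-((t - imp)^2) / (2 * sig^2))
  speed <- (0.6 * .gb(t, add - 0.35, 0.12) +
              cfg$bs_speed_peak_mps * .gb(t, (add + bst) / 2, bs / 4) +
              main +
              0.5 * .gb(t, fin + 0.3, 0.12)) *
    .envmin(t, add, 0.06) * .envmin(t, bst, 0.05) * .envmin(t, fin, 0.06)
  speed <- pmax(speed, 0)
  # signed path coordinate: single monotone zero crossing, pinned at impact
  dt <- c(0, diff(t))
  cum <- cumsum((speed + c(speed[1], speed[-length(speed)])) / 2 * dt)
  ball <- cum - stats::approx(t, cum, xout = imp)$y
  clubhead_track(t, ball, speed)
}

.draw_duration <- function(mean, sd, bounds) {
  for (i in 1:200) {
    d <- stats::rnorm(1, mean, sd)
    if (d >= bounds[1] && d <= bounds[2]) return(d)
  }
  swingseg_error("duration_error", "cannot draw a feasible phase duration")
}

#' Simulate one labelled swing
#'
#' Draws phase durations, builds the reference clubhead track and the three
#' placements' IMU streams, and records the ground-truth dividing points.
#' In the noiseless limit every shipped heuristic indicator event occurs at
#' the true dividing point by construction.
#'
#' @param profile a [sample_subject_profile()] result.
#' @param config a [generator_config()].
#' @param club `"driver"` or `"iron7"`.
#' @param placements placements to synthesize (default all three).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param swing_id optional identifier.
#' @return A [swing_set()].
#' @export
simulate_swing <- function(profile, config, club = "driver",
                           placements = PLACEMENTS, seed = NULL,
                           swing_id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  for (i in 1:200) {
    bs <- .draw_duration(profile$dur_mult * config$bs_mean, config$bs_sd,
                         config$dur_bounds$bs)
    ds <- .draw_duration(profile$dur_mult * config$ds_mean, config$ds_sd,
                         config$dur_bounds$ds)
    ft <- .draw_duration(profile$dur_mult * config$ft_mean, config$ft_sd,
                         config$dur_bounds$ft)
    # keep ADD inside both the 2.5 s pre-impact half-window and the ADD
    # indicator search band; rejections sit > 2.8 SD out, so the duration
    # statistics are essentially unbiased
    if (bs + ds <= 2.4 && bs + ds >= 0.9) break
    if (i == 200) swingseg_error("duration_error",
                                 "drawn swing does not fit the analysis window")
  }
  add <- config$bf_pad_s
  anch <- list(add = add, bst = add + bs, imp = add + bs + ds,
               fin = add + bs + ds + ft)
  if (anch$imp < 2.5) {
    swingseg_error("duration_error",
                   "pre-impact padding too short for the 2.5 s half-window")
  }
  fs <- config$sample_rate_hz
  n <- ceiling((anch$fin + config$af_pad_s) * fs) + 1L
  t <- seq(0, by = 1 / fs, length.out = n)
  recs <- lapply(stats::setNames(placements, placements), function(pl)
    .simulate_placement(pl, t, anch, config, profile))
  track <- .simulate_track(t, anch, config, club)
  swing_set(profile$subject_id, club, recs, track,
            dividing_points(anch$add, anch$bst, anch$imp, anch$fin),
            swing_id = swing_id)
}

.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 8191) %% 2147483629)
}

#' Simulate a labelled swing dataset
#'
#' Draws one profile per subject, then simulates each subject's swings
#' (half driver, half 7-iron). Seeds are split hierarchically
#' subject -> swing, so adding subjects or swings never changes
#' previously generated ones.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param swings_per_subject swings per subject.
#' @param config a [generator_config()].
#' @param placements placements to synthesize.
#' @param seed dataset seed; defaults to `config$seed`.
#' @return List of [swing_set()] objects.
#' @export
simulate_dataset <- function(n_subjects = 20, swings_per_subject = 20,
                             config = generator_config(),
                             placements = PLACEMENTS, seed = config$seed) {
  if (n_subjects < 2) swingseg_error("config_error", "need >= 2 subjects")
  swings <- vector("list", n_subjects * swings_per_subject)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("%02d", i)
    s_seed <- .child_seed(seed, i)
    prof <- sample_subject_profile(config, subject_id = sid, seed = s_seed)
    for (j in seq_len(swings_per_subject)) {
      club <- if (j <= ceiling(swings_per_subject / 2)) "driver" else "iron7"
      k <- k + 1L
      swings[[k]] <- simulate_swing(prof, config, club, placements,
                                    seed = .child_seed(s_seed, j),
                                    swing_id = sprintf("%s_%02d", sid, j))
    }
  }
  swings
}

# ---- reference labeler ------------------------------------------------------

.runmean <- function(x, k) {
  # centred moving average with edge replication
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + length(x))]
}

.local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

# refine a smoothed argmin on the raw signal within +/- r samples
.refine_min <- function(x, i, r = 5L) {
  lo <- max(1L, i - r); hi <- min(length(x), i + r)
  lo + which.min(x[lo:hi]) - 1L
}

#' Reference dividing points from a clubhead track
#'
#' Labels a swing from the clubhead kinematics: IMP is the positive-slope
#' zero crossing of the ball-plane coordinate inside the high-speed region
#' (speed above 50% of its global maximum); BST is the speed minimum
#' between the backswing speed peak and IMP; ADD is the last speed local
#' minimum before the speed first rises above 5% of its maximum ahead of
#' the backswing peak; FIN is the first speed local minimum after IMP at
#' which the speed has fallen below 10% of its maximum.
#'
#' @param track a [clubhead_track()].
#' @return A [dividing_points()].
#' @export
label_reference <- function(track) {
  t <- track$t; v <- track$speed; b <- track$ball_coord
  vmax <- max(v)
  if (!(vmax > 0)) swingseg_error("unlabelable_track", "flat speed profile")
  vs <- .runmean(v, 5L)

  # impact: interpolated upward zero crossing of the ball coordinate where
  # the clubhead is fast
  hs <- v > 0.5 * vmax
  i_cross <- which(b[-length(b)] <= 0 & b[-1] > 0 &
                     (hs[-length(hs)] | hs[-1]))
  if (!length(i_cross)) {
    swingseg_error("unlabelable_track", "no ball-plane crossing at high speed")
  }
  i <- i_cross[1]
  imp <- t[i] + (0 - b[i]) / (b[i + 1] - b[i]) * (t[i + 1] - t[i])

  # backswing speed peak: largest local max of smoothed speed before the
  # speed first reaches half its global maximum
  i_half <- which(vs > 0.5 * vmax)[1]
  if (is.na(i_half) || i_half < 3L) {
    swingseg_error("unlabelable_track", "no backswing structure before impact")
  }
  n <- length(v)
  pre <- vs[1:(i_half - 1L)]
  lmax <- which(pre[2:(length(pre) - 1)] > pre[1:(length(pre) - 2)] &
                  pre[2:(length(pre) - 1)] >= pre[3:length(pre)]) + 1L
  if (!length(lmax)) {
    swingseg_error("unlabelable_track", "no backswing speed peak found")
  }
  i_pk <- lmax[which.max(vs[lmax])]

  # BST: speed minimum between the backswing peak and impact
  i_imp <- max(which(t <= imp))
  seg <- i_pk:i_imp
  bst <- t[seg[which.min(v[seg])]]

  # ADD: last local minimum before the 5% rise ahead of the backswing peak
  i_rise <- which(vs[1:i_pk] > 0.05 * vmax)[1]
  if (is.na(i_rise)) i_rise <- i_pk
  mins_pre <- .local_minima(vs[1:i_rise])
  if (!length(mins_pre)) {
    swingseg_error("unlabelable_track", "no pre-swing speed minimum found")
  }
  add <- t[.refine_min(v, mins_pre[length(mins_pre)])]

  # FIN: first local minimum after impact below 10% of the peak speed
  post <- .local_minima(vs)
  post <- post[post > i_imp + 2L & vs[post] < 0.10 * vmax]
  if (!length(post)) {
    swingseg_error("unlabelable_track", "no finish speed minimum found")
  }
  fin <- t[.refine_min(v, post[1])]

  dividing_points(add, bst, imp, fin)
}
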