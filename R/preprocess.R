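#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` low-pass Butterworth design forward and
#' backward (so the effective attenuation is the squared magnitude response
#' and the phase shift is zero), with odd-reflection edge padding of three
#' filter lengths.
#'
#' @param x numeric signal.
#' @param sample_rate_hz sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (Hz); default 10.
#' @param order filter order of the design; default 10.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, sample_rate_hz, cutoff_hz = 10, order = 10) {
  n <- length(x)
  if (n <= 3L * order) {
    swingseg_error("filter_length_error",
                   sprintf("signal length %d too short for order %d", n, order))
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  b <- as.numeric(bf$b)
  a <- as.numeric(bf$a)
  zi <- .lfilter_zi(b, a)
  p <- 3L * (order + 1L)
  left <- 2 * x[1] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  xp <- c(left, x, right)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(p + 1L):(p + n)]
}

# steady-state initial filter state for a unit step, so the forward and
# backward passes start in equilibrium at the edge value
.lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

#' Low-pass filter all channels of an IMU recording
#'
#' @param imu an [imu_recording()].
#' @inheritParams lowpass_zero_phase
#' @return A filtered `imu_recording`.
#' @export
filter_recording <- function(imu, cutoff_hz = 10, order = 10) {
  f <- function(m) t(apply(m, 1, lowpass_zero_phase,
                           sample_rate_hz = imu$sample_rate_hz,
                           cutoff_hz = cutoff_hz, order = order))
  out <- imu
  out$acc <- pmin(pmax(f(imu$acc), -16), 16)
  out$gyro <- pmin(pmax(f(imu$gyro), -2000), 2000)
  out
}

.acc_norm <- function(imu) sqrt(colSums(imu$acc^2))

#' Clock offset from the pre-swing jump peak
#'
#' Subjects jump lightly before each swing; the acceleration-norm peak of
#' that jump aligns the IMU clock with the reference system's clock.
#'
#' @param imu an [imu_recording()].
#' @param reference_t_peak jump-peak time on the reference clock (s).
#' @param search_window pre-swing interval (s) searched for the jump peak.
#' @return Offset in seconds; adding it to `imu$t` aligns the clocks.
#' @export
align_by_jump_peak <- function(imu, reference_t_peak,
                               search_window = c(0, 1)) {
  idx <- which(imu$t >= search_window[1] & imu$t <= search_window[2])
  if (!length(idx)) {
    swingseg_error("no_jump_peak", "search interval outside the recording")
  }
  nrm <- .acc_norm(imu)[idx]
  if (max(nrm) < stats::median(nrm) + 1.5) {
    swingseg_error("no_jump_peak",
                   "no jump peak at least 1.5 g above baseline in the interval")
  }
  reference_t_peak - imu$t[idx[which.max(nrm)]]
}

#' Impact time proxy from the acceleration peak
#'
#' The impact produces the dominant acceleration transient of a full swing;
#' its norm peak serves as the practical impact cue for windowing. Ties are
#' broken toward the earlier sample.
#'
#' @param imu an [imu_recording()].
#' @return Time (s) of the global acceleration-norm maximum.
#' @export
find_impact_proxy <- function(imu) {
  imu$t[which.max(.acc_norm(imu))]
}

#' Cut the impact-centred analysis window
#'
#' Extracts the fixed window from 2.5 s before to 1 s after the impact
#' time: exactly `round(3.5 * sample_rate)` samples (700 at 200 Hz),
#' starting at the first sample at or after `imp_time_s - 2.5`.
#'
#' @param imu an [imu_recording()].
#' @param imp_time_s impact time (s), truth or proxy.
#' @return A windowed `imu_recording`.
#' @export
cut_window <- function(imu, imp_time_s) {
  n_win <- round(3.5 * imu$sample_rate_hz)
  t0 <- imp_time_s - 2.5
  if (imu$t[1] > t0 + 1e-9) {
    swingseg_error("window_out_of_range",
                   "recording starts after the window start")
  }
  i0 <- which(imu$t >= t0 - 1e-9)[1]
  if (is.na(i0) || i0 + n_win - 1L > length(imu$t)) {
    swingseg_error("window_out_of_range",
                   "recording too short for the 3.5 s window")
  }
  idx <- i0:(i0 + n_win - 1L)
  imu_recording(imu$t[idx], imu$acc[, idx, drop = FALSE],
                imu$gyro[, idx, drop = FALSE], imu$placement,
                imu$sample_rate_hz)
}

#' Per-feature min-max normalization to [-1, 1]
#'
#' Each row is mapped by `2 * (x - min) / (max - min) - 1`, computed per
#' swing window. A constant row maps to all zeros.
#'
#' @param m feature matrix (features x samples).
#' @return Matrix of the same shape with entries in `[-1, 1]`.
#' @export
normalize_features <- function(m) {
  m <- as.matrix(m)
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  rng <- hi - lo
  out <- matrix(0, nrow(m), ncol(m))
  nz <- rng > 0
  out[nz, ] <- 2 * (m[nz, , drop = FALSE] - lo[nz]) / rng[nz] - 1
  out
}

#' Assemble the normalized model input matrix
#'
#' Stacks time plus the selected channels, then min-max normalizes each
#' feature row. With both modalities the input is 7 x N (time, 3-axis
#' acceleration, 3-axis angular velocity); with a single modality, 4 x N.
#'
#' @param imu a windowed, filtered [imu_recording()].
#' @param modality `"both"`, `"acc"` or `"gyro"`.
#' @return Normalized feature matrix.
#' @export
assemble_input <- function(imu, modality = c("both", "acc", "gyro")) {
  modality <- match.arg(modality)
  m <- switch(modality,
              both = rbind(imu$t, imu$acc, imu$gyro),
              acc = rbind(imu$t, imu$acc),
              gyro = rbind(imu$t, imu$gyro))
  normalize_features(m)
}

#' Encode ground-truth labels for a window
#'
#' Produces both label encodings used by the learned models: the
#' per-timestep phase class sequence (for the sequence classifier) and the
#' four dividing points as fractions of the window (for the regressor).
#'
#' @param imu the windowed [imu_recording()] defining the time base.
#' @param truth a [dividing_points()].
#' @return List with `blstm` (a `phase_sequence` of window length) and
#'   `cnn` (numeric length 4, strictly increasing, in (0, 1)).
#' @export
encode_labels <- function(imu, truth) {
  t <- imu$t
  t0 <- t[1]
  span <- (length(t) - 0) / imu$sample_rate_hz  # nominal 3.5 s
  if (truth[["add_s"]] < t0 - 1e-12 ||
      truth[["fin_s"]] > t[length(t)] + 1e-12) {
    swingseg_error("labels_out_of_window",
                   "ground truth falls outside the window")
  }
  blstm <- suppressWarnings(phases_from_points(truth, t))
  cnn <- (unclass(truth) - t0) / span
  list(blstm = blstm, cnn = as.numeric(cnn))
}

#' Build a windowed, labelled dataset from swings
#'
#' Runs the full preprocessing chain for one placement and modality:
#' zero-phase low-pass filtering, impact-centred windowing (using the
#' ground-truth impact for training data, or the acceleration-peak proxy as
#' at inference time), input assembly and label encoding.
#'
#' @param swings list of [swing_set()] objects.
#' @param placement which placement's recording to use.
#' @param modality `"both"`, `"acc"` or `"gyro"`.
#' @param impact `"truth"` or `"proxy"` impact time for window placement.
#' @param jitter_s training-time augmentation: each window is cut at the
#'   impact time plus a uniform shift in `[-jitter_s, jitter_s]` (clipped
#'   per swing so the window stays inside the recording and the labels stay
#'   inside the window). Mimics the window-placement jitter seen at
#'   inference and regularizes the learned models.
#' @param n_augment number of jittered copies per swing (1 = no copies).
#' @param cutoff_hz,order low-pass filter settings.
#' @return An object of class `swing_windows`: arrays `inputs`
#'   (n x F x 700), `blstm` (n x 700 integer codes), `cnn` (n x 4),
#'   `subject` (n), `t0` (n window start times), plus metadata.
#' @export
make_swing_windows <- function(swings, placement = "wrist",
                               modality = c("both", "acc", "gyro"),
                               impact = c("truth", "proxy"),
                               jitter_s = 0, n_augment = 1,
                               cutoff_hz = 10, order = 10) {
  modality <- match.arg(modality)
  impact <- match.arg(impact)
  fs <- swings[[1]]$recordings[[placement]]$sample_rate_hz
  n_win <- round(3.5 * fs)
  n_feat <- if (modality == "both") 7L else 4L
  n_swing <- length(swings)
  n <- n_swing * n_augment
  inputs <- array(NA_real_, c(n, n_feat, n_win))
  blstm <- matrix(NA_integer_, n, n_win)
  cnn <- matrix(NA_real_, n, 4L)
  t0 <- numeric(n)
  subject <- character(n)
  swing_id <- character(n)
  i <- 0L
  for (k in seq_len(n_swing)) {
    sw <- swings[[k]]
    imu <- filter_recording(sw$recordings[[placement]], cutoff_hz, order)
    imp <- if (impact == "truth") sw$truth[["imp_s"]] else find_impact_proxy(imu)
    tr <- imu$t
    for (a in seq_len(n_augment)) {
      j <- 0
      if (jitter_s > 0 && a > 1L) {
        lo <- max(-jitter_s, tr[1] + 2.5 - imp + 2 / fs,
                  sw$truth[["fin_s"]] - 1.0 - imp + 2 / fs)
        hi <- min(jitter_s, tr[length(tr)] - 1.0 - imp - 2 / fs,
                  sw$truth[["add_s"]] + 2.5 - imp - 2 / fs)
        if (hi > lo) j <- stats::runif(1, lo, hi)
      }
      win <- cut_window(imu, imp + j)
      lab <- encode_labels(win, sw$truth)
      i <- i + 1L
      inputs[i, , ] <- assemble_input(win, modality)
      blstm[i, ] <- unclass(lab$blstm)
      cnn[i, ] <- lab$cnn
      t0[i] <- win$t[1]
      subject[i] <- sw$subject_id
      swing_id[i] <- if (is.na(sw$swing_id)) sprintf("swing%04d", k) else
        sw$swing_id
    }
  }
  structure(list(inputs = inputs, blstm = blstm, cnn = cnn, t0 = t0,
                 subject = subject, swing_id = swing_id, sample_rate_hz = fs,
                 placement = placement, modality = modality,
                 window_s = 3.5),
            class = "swing_windows")
}

#' @export
print.swing_windows <- function(x, ...) {
  cat(sprintf("<swing_windows> %d swings, %s/%s, %d x %d inputs\n",
              dim(x$inputs)[1], x$placement, x$modality,
              dim(x$inputs)[2], dim(x$inputs)[3]))
  invisible(x)
}

#' Subset a windowed dataset
#' @param x a `swing_windows` object.
#' @param i integer or logical index over swings.
#' @param ... unused.
#' @export
`[.swing_windows` <- function(x, i, ...) {
  out <- x
  out$inputs <- x$inputs[i, , , drop = FALSE]
  out$blstm <- x$blstm[i, , drop = FALSE]
  out$cnn <- x$cnn[i, , drop = FALSE]
  out$t0 <- x$t0[i]
  out$subject <- x$subject[i]
  out$swing_id <- x$swing_id[i]
  out
}

#' Cache a windowed dataset on disk
#'
#' Lossless round trip of a `swing_windows` object via R serialization.
#' @param windows a `swing_windows` object.
#' @param path file path.
#' @export
write_windows <- function(windows, path) {
  saveRDS(windows, path)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) readRDS(path)
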