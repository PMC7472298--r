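#' @useDynLib swingseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal condition helper: every package error carries a stable condition
# class (e.g. "labels_out_of_window") that callers and tests can match on.
swingseg_error <- function(id, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(id, "swingseg_error", "error"),
                      call = call))
}

swingseg_warning <- function(id, message) {
  warning(warningCondition(message, class = c(id, "swingseg_warning", "warning")))
}

#' Swing phase labels
#'
#' The five phases of a full golf swing, in temporal order: before-swing,
#' backswing, downswing, follow-through and after-swing.
#' @export
PHASE_LEVELS <- c("BF", "BS", "DS", "FT", "AF")

#' Dividing-point labels
#'
#' The four instants separating consecutive phases: address, backswing top,
#' impact, and finish.
#' @export
POINT_LEVELS <- c("ADD", "BST", "IMP", "FIN")

#' Sensor placements
#' @export
PLACEMENTS <- c("wrist", "head", "waist")

.check_time_vector <- function(t, uniform = TRUE) {
  if (length(t) < 2L) return(invisible(t))
  dt <- diff(t)
  if (any(dt <= 0)) {
    swingseg_error("time_error", "time vector must be strictly increasing")
  }
  if (uniform && (max(dt) - min(dt)) > 1e-9) {
    swingseg_error("time_error", "time vector must be uniformly spaced (1e-9 s)")
  }
  invisible(t)
}

#' One placement's IMU recording
#'
#' Container for a single six-axis IMU stream: timestamps, 3-axis
#' acceleration in g, and 3-axis angular velocity in deg/s. The sensor is
#' modelled with a full-scale range of +/-16 g and +/-2000 dps; values
#' outside that range violate the class invariant.
#'
#' @param t numeric time vector in seconds, strictly increasing and uniform.
#' @param acc 3 x N matrix of local x/y/z acceleration in g.
#' @param gyro 3 x N matrix of local x/y/z angular velocity in deg/s.
#' @param placement one of `"wrist"`, `"head"`, `"waist"`.
#' @param sample_rate_hz sampling rate; defaults to 200.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyro, placement = c("wrist", "head", "waist"),
                          sample_rate_hz = 200) {
  placement <- match.arg(placement)
  t <- as.numeric(t)
  acc <- unname(as.matrix(acc))
  gyro <- unname(as.matrix(gyro))
  if (nrow(acc) != 3L || nrow(gyro) != 3L) {
    swingseg_error("schema_error", "acc and gyro must be 3 x N matrices")
  }
  if (ncol(acc) != length(t) || ncol(gyro) != length(t)) {
    swingseg_error("schema_error", "acc/gyro length must match the time vector")
  }
  .check_time_vector(t)
  if (any(abs(acc) > 16 + 1e-9)) {
    swingseg_error("range_error", "acceleration outside the +/-16 g sensor range")
  }
  if (any(abs(gyro) > 2000 + 1e-6)) {
    swingseg_error("range_error", "angular velocity outside the +/-2000 dps sensor range")
  }
  structure(list(placement = placement, sample_rate_hz = sample_rate_hz,
                 t = t, acc = acc, gyro = gyro),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s, %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
              x$placement, length(x$t), x$sample_rate_hz,
              x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Reference clubhead track
#'
#' Clubhead kinematics from the reference measurement system: a signed
#' position coordinate along the ball-plane normal (zero where the clubhead
#' passes the ball marker) and the clubhead speed. All dividing points are
#' defined on this track.
#'
#' @param t numeric time vector, seconds, strictly increasing.
#' @param ball_coord signed clubhead position along the ball-plane normal, m.
#' @param speed clubhead speed, m/s, non-negative.
#' @return An object of class `clubhead_track`.
#' @export
clubhead_track <- function(t, ball_coord, speed) {
  t <- as.numeric(t)
  .check_time_vector(t, uniform = FALSE)
  if (length(ball_coord) != length(t) || length(speed) != length(t)) {
    swingseg_error("schema_error", "ball_coord/speed must match the time vector")
  }
  if (any(speed < 0)) {
    swingseg_error("range_error", "clubhead speed must be non-negative")
  }
  structure(list(t = t, ball_coord = as.numeric(ball_coord),
                 speed = as.numeric(speed)),
            class = "clubhead_track")
}

#' @export
print.clubhead_track <- function(x, ...) {
  cat(sprintf("<clubhead_track> %d samples, peak speed %.1f m/s\n",
              length(x$t), max(x$speed)))
  invisible(x)
}

#' The four swing-phase dividing points
#'
#' Event times, in seconds, of address (ADD), backswing top (BST), impact
#' (IMP) and finish (FIN). Must be strictly increasing.
#'
#' @param add_s,bst_s,imp_s,fin_s event times in seconds.
#' @return An object of class `dividing_points` (named numeric of length 4).
#' @export
dividing_points <- function(add_s, bst_s, imp_s, fin_s) {
  p <- c(add_s = as.numeric(add_s), bst_s = as.numeric(bst_s),
         imp_s = as.numeric(imp_s), fin_s = as.numeric(fin_s))
  if (any(!is.finite(p))) {
    swingseg_error("order_violation", "dividing points must be finite")
  }
  if (is.unsorted(p, strictly = TRUE)) {
    swingseg_error("order_violation",
                   "dividing points must satisfy ADD < BST < IMP < FIN")
  }
  structure(p, class = "dividing_points")
}

#' @export
print.dividing_points <- function(x, ...) {
  cat(sprintf("<dividing_points> ADD %.3f  BST %.3f  IMP %.3f  FIN %.3f s\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Per-sample phase sequence
#'
#' A length-N factor-like vector over the five phases. When derived from a
#' `dividing_points` object the sequence is a monotone walk
#' BF -> BS -> DS -> FT -> AF.
#'
#' @param classes character or factor vector with levels among
#'   `PHASE_LEVELS`.
#' @return An object of class `phase_sequence` (integer codes 1..5 with a
#'   `levels` attribute).
#' @export
phase_sequence <- function(classes) {
  if (is.numeric(classes)) {
    codes <- as.integer(classes)
    if (any(codes < 1L | codes > 5L)) {
      swingseg_error("schema_error", "phase codes must be in 1..5")
    }
  } else {
    codes <- match(as.character(classes), PHASE_LEVELS)
    if (anyNA(codes)) {
      swingseg_error("schema_error", "unknown phase label")
    }
  }
  structure(codes, levels = PHASE_LEVELS, class = "phase_sequence")
}

#' @export
print.phase_sequence <- function(x, ...) {
  counts <- tabulate(unclass(x), nbins = 5L)
  cat("<phase_sequence> ",
      paste(sprintf("%s:%d", PHASE_LEVELS, counts), collapse = " "), "\n")
  invisible(x)
}

#' One labelled swing
#'
#' Bundles the per-placement IMU recordings, the reference clubhead track,
#' and the ground-truth dividing points for a single swing.
#'
#' @param subject_id subject identifier (character).
#' @param club `"driver"` or `"iron7"`.
#' @param recordings named list of `imu_recording` objects, names among
#'   `PLACEMENTS`.
#' @param track a `clubhead_track`.
#' @param truth a `dividing_points`.
#' @param swing_id optional swing identifier.
#' @return An object of class `swing_set`.
#' @export
swing_set <- function(subject_id, club = c("driver", "iron7"), recordings,
                      track, truth, swing_id = NA_character_) {
  club <- match.arg(club)
  if (!all(names(recordings) %in% PLACEMENTS)) {
    swingseg_error("schema_error", "recording names must be placements")
  }
  stopifnot(inherits(track, "clubhead_track"), inherits(truth, "dividing_points"))
  span_ok <- function(t) t[1] <= truth[["add_s"]] && t[length(t)] >= truth[["fin_s"]]
  if (!span_ok(track$t) || !all(vapply(recordings, function(r) span_ok(r$t), TRUE))) {
    swingseg_error("labels_out_of_window",
                   "member time vectors must cover the truth interval")
  }
  structure(list(subject_id = as.character(subject_id), club = club,
                 swing_id = as.character(swing_id),
                 recordings = recordings, track = track, truth = truth),
            class = "swing_set")
}

#' @export
print.swing_set <- function(x, ...) {
  cat(sprintf("<swing_set> subject %s, %s, placements: %s\n", x$subject_id,
              x$club, paste(names(x$recordings), collapse = ", ")))
  print(x$truth)
  invisible(x)
}
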