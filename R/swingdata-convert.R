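#' Per-sample phase labels from dividing points
#'
#' Labels each sample of a time base with its swing phase. Intervals are
#' half-open: a sample exactly on a dividing point belongs to the later
#' phase, which makes the conversion exactly invertible by
#' [points_from_phases()].
#'
#' @param points a [dividing_points()] object.
#' @param t uniform time vector covering the points.
#' @return A [phase_sequence()] of `length(t)`.
#' @details A window that clips the before-swing or after-swing phase (e.g.
#'   `add_s == t[1]`) produces an empty BF/AF segment; this raises a warning,
#'   not an error, because impact-centred windows may legitimately clip the
#'   padding phases. Points outside `[t[1], t[length(t)]]` are an error.
#' @export
phases_from_points <- function(points, t) {
  stopifnot(inherits(points, "dividing_points"))
  .check_time_vector(t)
  if (points[["add_s"]] < t[1] - 1e-12 || points[["fin_s"]] > t[length(t)] + 1e-12) {
    swingseg_error("labels_out_of_window",
                   "dividing points fall outside the window time base")
  }
  codes <- findInterval(t, unclass(points), left.open = FALSE) + 1L
  counts <- tabulate(codes, nbins = 5L)
  if (counts[1] == 0L || counts[5] == 0L) {
    swingseg_warning("clipped_padding_phase",
                     "window clips an empty BF or AF segment")
  }
  phase_sequence(codes)
}

#' Dividing points from a per-sample phase sequence
#'
#' Inverse of [phases_from_points()]: each dividing point is the time of the
#' first sample of the later phase's persistent run. Raw model output should
#' be passed through [clean_sequence()] first; this function requires an
#' already-monotone sequence containing every phase transition.
#'
#' @param seq a [phase_sequence()].
#' @param t matching time vector.
#' @return A [dividing_points()] object.
#' @export
points_from_phases <- function(seq, t) {
  stopifnot(inherits(seq, "phase_sequence"))
  codes <- unclass(seq)
  if (length(codes) != length(t)) {
    swingseg_error("schema_error", "sequence and time base differ in length")
  }
  if (is.unsorted(codes)) {
    swingseg_error("incomplete_phase_sequence",
                   "phase sequence must be monotone; run clean_sequence() first")
  }
  if (!all(1:5 %in% codes)) {
    swingseg_error("incomplete_phase_sequence",
                   "a phase is entirely missing from the sequence")
  }
  first_of <- function(k) t[match(k, codes)]
  dividing_points(first_of(2L), first_of(3L), first_of(4L), first_of(5L))
}

#' Phase lengths from dividing points
#'
#' Durations, in seconds, of the backswing, downswing and follow-through,
#' plus the full swing (ADD to FIN). The full-swing length equals the sum of
#' the three parts exactly.
#'
#' @param points a [dividing_points()] object.
#' @return Named numeric: `bs_s`, `ds_s`, `ft_s`, `full_s`.
#' @export
phase_lengths <- function(points) {
  stopifnot(inherits(points, "dividing_points"))
  p <- unclass(points)
  c(bs_s = p[["bst_s"]] - p[["add_s"]],
    ds_s = p[["imp_s"]] - p[["bst_s"]],
    ft_s = p[["fin_s"]] - p[["imp_s"]],
    full_s = p[["fin_s"]] - p[["add_s"]])
}
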