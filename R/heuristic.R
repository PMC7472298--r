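#' An indicator rule for heuristic segmentation
#'
#' One cell of the heuristic rule table: which signal feature (minimum,
#' maximum or zero crossing of an acceleration or angular-velocity channel)
#' marks a given dividing point at a given placement, searched within a
#' window anchored on the impact proxy.
#'
#' @param placement sensor placement the rule applies to.
#' @param point target dividing point, one of `POINT_LEVELS`.
#' @param source `"acc"` or `"gyro"`.
#' @param channel `"x"`, `"y"`, `"z"` or `"norm"` (Euclidean norm of the
#'   three filtered axes; never combined with a zero crossing).
#' @param event `"min"`, `"max"` or `"zero_crossing"`.
#' @param window search window relative to the impact proxy, `c(lo, hi)` s.
#' @param slope zero-crossing slope sign: `"+"`, `"-"` or `"either"`.
#' @return An object of class `indicator_rule`.
#' @export
indicator_rule <- function(placement, point, source, channel, event,
                           window = NULL, slope = "either") {
  stopifnot(placement %in% PLACEMENTS, point %in% POINT_LEVELS,
            source %in% c("acc", "gyro"),
            channel %in% c("x", "y", "z", "norm"),
            event %in% c("min", "max", "zero_crossing"),
            slope %in% c("+", "-", "either"))
  if (channel == "norm" && event == "zero_crossing") {
    swingseg_error("config_error", "norm channel cannot have a zero crossing")
  }
  if (is.null(window)) window <- default_search_windows()[[point]]
  if (!(window[1] < window[2])) {
    swingseg_error("config_error", "search window must have lo < hi")
  }
  structure(list(placement = placement, point = point, source = source,
                 channel = channel, event = event,
                 window = as.numeric(window), slope = slope),
            class = "indicator_rule")
}

#' @export
print.indicator_rule <- function(x, ...) {
  cat(sprintf("<indicator_rule> %s %s: %s of %s in %s, window [%g, %g] s\n",
              x$placement, x$point, x$event, x$source, x$channel,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Default per-point search windows
#'
#' Search intervals relative to the impact proxy, sized so that each
#' dividing point lies well inside its band under the reference
#' phase-length statistics.
#' @return Named list of `c(lo, hi)` second pairs.
#' @export
default_search_windows <- function() {
  list(ADD = c(-2.5, -0.8), BST = c(-0.8, -0.05),
       IMP = c(-0.05, 0.12), FIN = c(0.1, 1.1))
}

#' The shipped heuristic indicator rules
#'
#' The twelve selected indicators (four dividing points at three
#' placements), e.g. the wrist address indicator is the minimum of the
#' y-axis angular velocity. With `modality = "gyro"` or `"acc"` the
#' single-modality wrist rule sets used in the modality comparison are
#' returned; single-modality rule sets are only defined for the wrist.
#'
#' @param placement sensor placement.
#' @param modality `"both"` (the shipped mixed table), `"gyro"` or `"acc"`.
#' @return Named list of four `indicator_rule`s (ADD, BST, IMP, FIN).
#' @export
default_indicator_rules <- function(placement = "wrist",
                                    modality = c("both", "gyro", "acc")) {
  modality <- match.arg(modality)
  path <- system.file("extdata", "indicator-rules.yaml", package = "swingseg")
  all_rules <- read_indicator_rules(path)
  sel <- vapply(all_rules, function(r) r$placement == placement, TRUE) &
    vapply(all_rules, function(r) {
      if (modality == "both") is.null(attr(r, "modality_set")) ||
        attr(r, "modality_set") == "both"
      else identical(attr(r, "modality_set"), modality)
    }, TRUE)
  rules <- all_rules[sel]
  if (length(rules) != 4L) {
    swingseg_error("config_error",
                   sprintf("no complete %s rule set for placement %s",
                           modality, placement))
  }
  names(rules) <- vapply(rules, function(r) r$point, "")
  rules[POINT_LEVELS]
}

#' Read / write indicator rules as YAML
#' @param path YAML file path.
#' @return [read_indicator_rules()] returns a list of `indicator_rule`s.
#' @export
read_indicator_rules <- function(path) {
  lapply(yaml::read_yaml(path), function(e) {
    r <- indicator_rule(e$placement, e$point, e$source, e$channel, e$event,
                        window = if (!is.null(e$window)) unlist(e$window),
                        slope = if (!is.null(e$slope)) e$slope else "either")
    attr(r, "modality_set") <- e$modality_set
    r
  })
}

#' @rdname read_indicator_rules
#' @param rules list of `indicator_rule`s.
#' @export
write_indicator_rules <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(r) {
    out <- unclass(r)
    out$window <- as.list(out$window)
    if (!is.null(attr(r, "modality_set"))) {
      out$modality_set <- attr(r, "modality_set")
    }
    out
  }), path)
  invisible(path)
}

.rule_signal <- function(imu, rule) {
  m <- if (rule$source == "acc") imu$acc else imu$gyro
  switch(rule$channel,
         x = m[1, ], y = m[2, ], z = m[3, ],
         norm = sqrt(colSums(m^2)))
}

#' Detect one indicator event
#'
#' Finds the rule's event (argmin, argmax, or interpolated zero crossing
#' with the required slope sign) inside its search window anchored on the
#' impact proxy. With several equal extrema the earliest wins; with several
#' admissible crossings the one nearest the window centre wins.
#'
#' @param x numeric signal.
#' @param t matching time vector (s).
#' @param rule an [indicator_rule()].
#' @param t_impact_proxy anchor time (s) for the search window.
#' @return Event time in seconds.
#' @export
detect_event <- function(x, t, rule, t_impact_proxy) {
  lo <- t_impact_proxy + rule$window[1]
  hi <- t_impact_proxy + rule$window[2]
  idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  if (length(idx) < 2L) {
    swingseg_error("event_not_found",
                   sprintf("search window for %s outside the signal", rule$point))
  }
  xs <- x[idx]
  ts <- t[idx]
  if (rule$event %in% c("min", "max")) {
    i <- if (rule$event == "min") which.min(xs) else which.max(xs)
    return(ts[i])
  }
  s <- xs[-length(xs)] * xs[-1]
  cross <- which(s < 0 | (xs[-length(xs)] == 0 & xs[-1] != 0))
  if (rule$slope == "+") cross <- cross[xs[cross + 1L] > xs[cross]]
  if (rule$slope == "-") cross <- cross[xs[cross + 1L] < xs[cross]]
  if (!length(cross)) {
    swingseg_error("event_not_found",
                   sprintf("no %s zero crossing in the %s window",
                           rule$slope, rule$point))
  }
  tc <- vapply(cross, function(i) {
    if (xs[i] == 0) ts[i]
    else ts[i] + (0 - xs[i]) / (xs[i + 1L] - xs[i]) * (ts[i + 1L] - ts[i])
  }, 0)
  tc[which.min(abs(tc - (lo + hi) / 2))]
}

#' Heuristic swing segmentation
#'
#' Applies the placement's four indicator rules, anchored on the
#' acceleration-peak impact proxy, to estimate the four dividing points.
#'
#' @param imu an [imu_recording()] (filtered; see [filter_recording()]).
#' @param rules named list of four rules as from
#'   [default_indicator_rules()]; defaults to the shipped set for the
#'   recording's placement.
#' @param t_impact_proxy optional anchor override; defaults to
#'   [find_impact_proxy()].
#' @return A [dividing_points()].
#' @export
heuristic_segment <- function(imu, rules = NULL, t_impact_proxy = NULL) {
  if (is.null(rules)) rules <- default_indicator_rules(imu$placement)
  if (is.null(t_impact_proxy)) t_impact_proxy <- find_impact_proxy(imu)
  est <- vapply(POINT_LEVELS, function(p) {
    r <- rules[[p]]
    tryCatch(detect_event(.rule_signal(imu, r), imu$t, r, t_impact_proxy),
             swingseg_error = function(e) {
               swingseg_error("event_not_found",
                              sprintf("event_not_found: %s (%s)", p,
                                      conditionMessage(e)))
             })
  }, 0)
  if (is.unsorted(est, strictly = TRUE)) {
    swingseg_error("order_violation",
                   "heuristic events are not temporally ordered")
  }
  dividing_points(est[1], est[2], est[3], est[4])
}

#' Rank indicator-rule candidates by estimation error
#'
#' Evaluates each candidate rule on a labelled dataset and ranks all
#' candidates by mean absolute error against the ground truth, ascending;
#' the sort is stable, so ties keep their input order. The selection (best
#' rule per placement and point) mirrors how the twelve shipped indicators
#' were chosen from a larger candidate pool.
#'
#' @param candidates list of [indicator_rule()]s.
#' @param swings list of [swing_set()]s with ground truth.
#' @param cutoff_hz,order filter settings applied before detection.
#' @return A data frame with one row per candidate: placement, point,
#'   rule description, `mae_ms` and `n_detected`, sorted by `mae_ms`, with
#'   attribute `"selection"` naming the best rule per (placement, point).
#' @export
rank_indicator_candidates <- function(candidates, swings,
                                      cutoff_hz = 10, order = 10) {
  rows <- lapply(seq_along(candidates), function(k) {
    r <- candidates[[k]]
    errs <- vapply(swings, function(sw) {
      imu <- filter_recording(sw$recordings[[r$placement]], cutoff_hz, order)
      proxy <- find_impact_proxy(imu)
      est <- tryCatch(detect_event(.rule_signal(imu, r), imu$t, r, proxy),
                      swingseg_error = function(e) NA_real_)
      truth <- sw$truth[[c(ADD = "add_s", BST = "bst_s", IMP = "imp_s",
                           FIN = "fin_s")[[r$point]]]]
      abs(est - truth) * 1000
    }, 0)
    data.frame(candidate = k, placement = r$placement, point = r$point,
               rule = sprintf("%s of %s in %s", r$event, r$source, r$channel),
               mae_ms = mean(errs, na.rm = TRUE),
               n_detected = sum(!is.na(errs)))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$mae_ms), ]
  sel <- do.call(rbind, lapply(split(df, paste(df$placement, df$point)),
                               function(g) g[1, ]))
  attr(df, "selection") <- sel
  df
}
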