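.POINT_FIELDS <- c(ADD = "add_s", BST = "bst_s", IMP = "imp_s", FIN = "fin_s")

#' Subject-level mean absolute error summary
#'
#' Per-subject MAE (mean absolute error over that subject's swings), the
#' grand mean across subjects, and the between-subject SD.
#'
#' @param errors signed or absolute errors, one per swing (any unit).
#' @param subject_ids matching subject identifiers.
#' @return List: `per_subject` (named numeric), `grand_mean`, `sd`.
#' @export
mae_by_point <- function(errors, subject_ids) {
  stopifnot(length(errors) == length(subject_ids))
  per <- tapply(abs(errors), subject_ids, mean, na.rm = TRUE)
  per_subject <- stats::setNames(as.numeric(per), names(per))
  list(per_subject = per_subject,
       grand_mean = mean(per_subject, na.rm = TRUE),
       sd = stats::sd(per_subject))
}

#' Phase-length estimation error, percent
#'
#' Per phase (backswing, downswing, follow-through):
#' `100 * |L_est - L_truth| / L_truth`.
#'
#' @param est,truth [dividing_points()] objects.
#' @return Named numeric: `bs`, `ds`, `ft` (percent).
#' @export
phase_length_error_pct <- function(est, truth) {
  le <- phase_lengths(est)[1:3]
  lt <- phase_lengths(truth)[1:3]
  if (any(lt <= 0)) {
    swingseg_error("degenerate_phase", "zero-length reference phase")
  }
  stats::setNames(100 * abs(le - lt) / lt, c("bs", "ds", "ft"))
}

.loso_predict_fold <- function(swings, test_idx, method, placement, modality,
                               train_config, fold_seed) {
  mod_name <- switch(modality, `a+g` = "both", a = "acc", g = "gyro")
  if (method == "heuristic") {
    # resolve the rule set up front: a missing single-modality rule set is
    # a configuration error, not a per-swing detection failure
    rules <- default_indicator_rules(placement,
                                     switch(modality, `a+g` = "both",
                                            a = "acc", g = "gyro"))
    return(lapply(swings[test_idx], function(sw) {
      imu <- filter_recording(sw$recordings[[placement]])
      tryCatch(heuristic_segment(imu, rules),
               swingseg_error = function(e) NULL)
    }))
  }
  set.seed(fold_seed)
  train_w <- make_swing_windows(swings[-test_idx], placement, mod_name,
                                impact = "truth",
                                jitter_s = train_config$aug_jitter_s,
                                n_augment = train_config$augment)
  tta <- max(1L, train_config$tta %||% 1L)
  test_w <- make_swing_windows(swings[test_idx], placement, mod_name,
                               impact = "proxy",
                               jitter_s = if (tta > 1L) 0.25 else 0,
                               n_augment = tta)
  n_feat <- dim(train_w$inputs)[2]
  cfg <- train_config
  cfg$seed <- fold_seed
  model <- if (method == "blstm") {
    build_blstm(blstm_spec(input_features = n_feat), seed = fold_seed,
                n_time = dim(train_w$inputs)[3])
  } else {
    build_cnn(cnn_spec(input_features = n_feat), seed = fold_seed,
              n_time = dim(train_w$inputs)[3])
  }
  model <- train_model(model, train_w, cfg)
  preds <- predict_windows(model, test_w)
  if (tta == 1L) return(preds)
  # average each swing's predictions over its jittered window placements
  lapply(seq_along(test_idx), function(j) {
    grp <- preds[((j - 1L) * tta + 1L):(j * tta)]
    grp <- grp[!vapply(grp, is.null, TRUE)]
    if (!length(grp)) return(NULL)
    m <- colMeans(do.call(rbind, lapply(grp, unclass)))
    dividing_points(m[1], m[2], m[3], m[4])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the method is trained on all other subjects'
#' swings (the heuristic needs no training) and evaluated on the held-out
#' subject, mirroring how segmentation generalization to unseen golfers is
#' verified. Deterministic given `train_config$seed`.
#'
#' @param swings list of [swing_set()]s with ground truth.
#' @param method `"heuristic"`, `"blstm"` or `"cnn"`.
#' @param placement sensor placement.
#' @param modality `"a"`, `"g"` or `"a+g"`.
#' @param train_config a [train_config()] (ignored by the heuristic).
#' @return An object of class `segmentation_report` containing per-swing
#'   point errors (`errors`: subject, swing, point, error_ms) and phase
#'   length errors (`phase_errors`: subject, swing, phase, err_pct).
#' @export
loso_cv <- function(swings, method = c("heuristic", "blstm", "cnn"),
                    placement = "wrist", modality = "a+g",
                    train_config = train_config()) {
  method <- match.arg(method)
  subjects <- vapply(swings, function(s) s$subject_id, "")
  uniq <- unique(subjects)
  if (length(uniq) < 2L) swingseg_error("empty_fold", "need >= 2 subjects")
  err_rows <- list()
  len_rows <- list()
  for (fi in seq_along(uniq)) {
    s <- uniq[fi]
    test_idx <- which(subjects == s)
    if (!length(test_idx)) swingseg_error("empty_fold", "fold with no swings")
    preds <- .loso_predict_fold(swings, test_idx, method, placement, modality,
                                train_config,
                                .child_seed(train_config$seed, fi))
    for (k in seq_along(test_idx)) {
      sw <- swings[[test_idx[k]]]
      est <- preds[[k]]
      if (is.null(est)) {
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          subject = s, swing = sw$swing_id, point = POINT_LEVELS,
          error_ms = NA_real_)
        next
      }
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        subject = s, swing = sw$swing_id, point = POINT_LEVELS,
        error_ms = 1000 * (unclass(est) - unclass(sw$truth)))
      pl <- phase_length_error_pct(est, sw$truth)
      len_rows[[length(len_rows) + 1L]] <- data.frame(
        subject = s, swing = sw$swing_id, phase = names(pl),
        err_pct = as.numeric(pl))
    }
  }
  structure(list(method = method, placement = placement, modality = modality,
                 errors = do.call(rbind, err_rows),
                 phase_errors = do.call(rbind, len_rows),
                 n_subjects = length(uniq)),
            class = "segmentation_report")
}

#' Summarize a segmentation report
#'
#' @param object a `segmentation_report`.
#' @param ... unused.
#' @return Data frame with one row per metric cell:
#'   `method, placement, modality, metric, target, grand_mean, sd,
#'   n_subjects`. MAE rows are in ms; phase rows in percent.
#' @export
summary.segmentation_report <- function(object, ...) {
  rows <- list()
  for (p in POINT_LEVELS) {
    e <- object$errors[object$errors$point == p, ]
    m <- mae_by_point(e$error_ms, e$subject)
    rows[[length(rows) + 1L]] <- data.frame(
      method = object$method, placement = object$placement,
      modality = object$modality, metric = "mae_ms", target = p,
      grand_mean = m$grand_mean, sd = m$sd,
      n_subjects = length(m$per_subject))
  }
  if (!is.null(object$phase_errors)) {
    for (ph in c("bs", "ds", "ft")) {
      e <- object$phase_errors[object$phase_errors$phase == ph, ]
      m <- mae_by_point(e$err_pct, e$subject)
      rows[[length(rows) + 1L]] <- data.frame(
        method = object$method, placement = object$placement,
        modality = object$modality, metric = "phase_err_pct", target = ph,
        grand_mean = m$grand_mean, sd = m$sd,
        n_subjects = length(m$per_subject))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> %s @ %s (%s), %d subjects\n",
              x$method, x$placement, x$modality, x$n_subjects))
  print(summary(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-subject MAE vector from a report
#'
#' @param report a `segmentation_report`.
#' @param point one of `POINT_LEVELS`.
#' @return Named numeric of per-subject MAEs (ms).
#' @export
subject_mae <- function(report, point) {
  e <- report$errors[report$errors$point == point, ]
  mae_by_point(e$error_ms, e$subject)$per_subject
}

#' Modality ablation
#'
#' Runs matched leave-one-subject-out evaluations using only acceleration
#' (4 x 700 inputs), only angular velocity (4 x 700), and both (7 x 700),
#' with identical folds and seeds, so the three arms are directly
#' comparable. Single-modality heuristic rule sets are shipped for the
#' wrist only; arms without a rule set are returned as `NULL`.
#'
#' @inheritParams loso_cv
#' @param modalities arms to run.
#' @return Named list of `segmentation_report`s (`a`, `g`, `a+g`).
#' @export
modality_ablation <- function(swings, method = "heuristic",
                              placement = "wrist",
                              train_config = train_config(),
                              modalities = c("a", "g", "a+g")) {
  out <- list()
  for (m in modalities) {
    out[[m]] <- tryCatch(
      loso_cv(swings, method, placement, m, train_config),
      swingseg_error = function(e) NULL)
  }
  out
}

#' Paired significance test on subject-level MAEs
#'
#' Two-sided paired test across subjects (Wilcoxon signed-rank by default,
#' paired t-test optionally) for a contrast between two matched evaluation
#' arms.
#'
#' @param mae1,mae2 per-subject MAE vectors, paired by subject.
#' @param alpha significance level.
#' @param test `"wilcoxon"` or `"ttest"`.
#' @return List: `p_value`, `significant`, `test`.
#' @export
paired_significance <- function(mae1, mae2, alpha = 0.05,
                                test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  if (length(mae1) != length(mae2)) {
    swingseg_error("pairing_error", "arms have different numbers of subjects")
  }
  if (length(mae1) < 5L) {
    swingseg_error("pairing_error", "need at least 5 paired subjects")
  }
  d <- mae1 - mae2
  if (all(abs(d) < 1e-12)) {
    return(list(p_value = 1, significant = FALSE, test = test))
  }
  if (stats::sd(d) < 1e-12) {
    # identical nonzero shift in every pair: maximally significant
    return(list(p_value = 0, significant = TRUE, test = test))
  }
  p <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(mae1, mae2, paired = TRUE,
                                        exact = FALSE))$p.value
  } else {
    stats::t.test(mae1, mae2, paired = TRUE)$p.value
  }
  list(p_value = p, significant = is.finite(p) && p < alpha, test = test)
}

#' Render report tables and figures
#'
#' Writes `summary.csv` (one row per metric cell, schema
#' `method,placement,modality,metric,target,grand_mean,sd,n_subjects`),
#' `errors.csv` with the per-swing point errors, and bar charts of the
#' per-point MAE and per-phase length error with between-subject SD
#' whiskers.
#'
#' @param reports a `segmentation_report` or list of them.
#' @param out_dir output directory.
#' @return Paths of the files written, invisibly.
#' @export
render_report <- function(reports, out_dir) {
  if (inherits(reports, "segmentation_report")) reports <- list(reports)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- do.call(rbind, lapply(reports, summary))
  sum_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summ, sum_path, row.names = FALSE)
  err <- do.call(rbind, lapply(reports, function(r)
    cbind(method = r$method, placement = r$placement, modality = r$modality,
          r$errors)))
  err_path <- file.path(out_dir, "errors.csv")
  utils::write.csv(err, err_path, row.names = FALSE)
  paths <- c(sum_path, err_path)
  for (metric in unique(summ$metric)) {
    ss <- summ[summ$metric == metric, ]
    fig <- file.path(out_dir, paste0(metric, ".png"))
    grDevices::png(fig, width = 900, height = 520)
    lab <- paste(ss$method, ss$placement, ss$modality, ss$target, sep = "\n")
    h <- ss$grand_mean
    h[!is.finite(h)] <- 0  # cells where every prediction failed
    top <- max(h + ifelse(is.finite(ss$sd), ss$sd, 0), 1e-9)
    ylim <- c(0, top * 1.15)
    bp <- graphics::barplot(h, names.arg = lab, las = 1,
                            cex.names = 0.7, ylim = ylim,
                            ylab = if (metric == "mae_ms") "MAE (ms)"
                                   else "phase length error (%)")
    ok <- !is.na(ss$sd) & ss$sd > 0
    if (any(ok)) {
      # whiskers clipped at zero may degenerate on one side; that is fine
      suppressWarnings(
        graphics::arrows(bp[ok],
                         ss$grand_mean[ok] - pmin(ss$sd[ok], ss$grand_mean[ok]),
                         bp[ok], ss$grand_mean[ok] + ss$sd[ok],
                         angle = 90, code = 3, length = 0.04))
    }
    grDevices::dev.off()
    paths <- c(paths, fig)
  }
  invisible(paths)
}
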