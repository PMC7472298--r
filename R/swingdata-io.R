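IMU_CSV_COLS <- c("time_s", "acc_x_g", "acc_y_g", "acc_z_g",
                  "gyro_x_dps", "gyro_y_dps", "gyro_z_dps")
TRACK_CSV_COLS <- c("time_s", "ball_coord_m", "speed_mps")

.fmt_num <- function(x) formatC(x, format = "g", digits = 15)

.read_csv_checked <- function(path, cols) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    swingseg_error("schema_error",
                   paste0("missing column(s) in ", basename(path), ": ",
                          paste(missing, collapse = ", ")))
  }
  df[, cols, drop = FALSE]
}

#' Read / write a single-placement IMU CSV
#'
#' File dialect: header
#' `time_s,acc_x_g,acc_y_g,acc_z_g,gyro_x_dps,gyro_y_dps,gyro_z_dps`.
#' Numbers are written with 15 significant digits so write-read round trips
#' are exact to 1e-9 and a second write is byte-identical.
#'
#' @param path CSV file path.
#' @param placement sensor placement of the stream.
#' @param sample_rate_hz sampling rate stored on the returned object.
#' @return [read_imu_csv()] returns an `imu_recording`.
#' @export
read_imu_csv <- function(path, placement, sample_rate_hz = 200) {
  df <- .read_csv_checked(path, IMU_CSV_COLS)
  t <- df$time_s
  if (length(t) >= 2L && any(diff(t) <= 0)) {
    swingseg_error("time_error", "non-monotone time column")
  }
  imu_recording(t,
                acc = t(as.matrix(df[, 2:4])),
                gyro = t(as.matrix(df[, 5:7])),
                placement = placement, sample_rate_hz = sample_rate_hz)
}

#' @rdname read_imu_csv
#' @param imu an `imu_recording` to write.
#' @export
write_imu_csv <- function(imu, path) {
  df <- data.frame(time_s = .fmt_num(imu$t),
                   acc_x_g = .fmt_num(imu$acc[1, ]),
                   acc_y_g = .fmt_num(imu$acc[2, ]),
                   acc_z_g = .fmt_num(imu$acc[3, ]),
                   gyro_x_dps = .fmt_num(imu$gyro[1, ]),
                   gyro_y_dps = .fmt_num(imu$gyro[2, ]),
                   gyro_z_dps = .fmt_num(imu$gyro[3, ]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a clubhead-track CSV
#'
#' Dialect: header `time_s,ball_coord_m,speed_mps`.
#' @param path CSV file path.
#' @return [read_track_csv()] returns a `clubhead_track`.
#' @export
read_track_csv <- function(path) {
  df <- .read_csv_checked(path, TRACK_CSV_COLS)
  if (length(df$time_s) >= 2L && any(diff(df$time_s) <= 0)) {
    swingseg_error("time_error", "non-monotone time column")
  }
  clubhead_track(df$time_s, df$ball_coord_m, df$speed_mps)
}

#' @rdname read_track_csv
#' @param track a `clubhead_track` to write.
#' @export
write_track_csv <- function(track, path) {
  df <- data.frame(time_s = .fmt_num(track$t),
                   ball_coord_m = .fmt_num(track$ball_coord),
                   speed_mps = .fmt_num(track$speed))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ground-truth labels JSON
#'
#' Schema: `{"add_s":, "bst_s":, "imp_s":, "fin_s":, "subject_id":, "club":}`.
#' @param path JSON file path.
#' @return [read_labels_json()] returns a list with elements `points`
#'   (a `dividing_points`), `subject_id` and `club`.
#' @export
read_labels_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("add_s", "bst_s", "imp_s", "fin_s", "subject_id", "club")
  if (!all(need %in% names(x))) {
    swingseg_error("schema_error", "labels JSON missing required fields")
  }
  list(points = dividing_points(x$add_s, x$bst_s, x$imp_s, x$fin_s),
       subject_id = as.character(x$subject_id), club = x$club)
}

#' @rdname read_labels_json
#' @param points a `dividing_points`.
#' @param subject_id,club metadata stored alongside the points.
#' @export
write_labels_json <- function(points, subject_id, club, path) {
  jsonlite::write_json(
    list(add_s = points[["add_s"]], bst_s = points[["bst_s"]],
         imp_s = points[["imp_s"]], fin_s = points[["fin_s"]],
         subject_id = subject_id, club = club),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a swing dataset to disk
#'
#' Writes one IMU CSV per placement, a clubhead-track CSV and a labels JSON
#' per swing, plus a `manifest.json` listing all swings and file paths.
#'
#' @param swings list of `swing_set` objects.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_swing_dataset <- function(swings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(swings), function(i) {
    sw <- swings[[i]]
    stem <- sprintf("s%s_swing%03d", sw$subject_id, i)
    imu_files <- list()
    for (pl in names(sw$recordings)) {
      f <- paste0(stem, "_", pl, ".csv")
      write_imu_csv(sw$recordings[[pl]], file.path(dir, f))
      imu_files[[pl]] <- f
    }
    track_file <- paste0(stem, "_track.csv")
    write_track_csv(sw$track, file.path(dir, track_file))
    labels_file <- paste0(stem, "_labels.json")
    write_labels_json(sw$truth, sw$subject_id, sw$club,
                      file.path(dir, labels_file))
    list(subject_id = sw$subject_id, club = sw$club, swing_id = sw$swing_id,
         imu = imu_files, track = track_file, labels = labels_file)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_swings = length(swings), swings = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a swing dataset written by [write_swing_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @param sample_rate_hz sampling rate recorded on the IMU objects.
#' @return List of `swing_set` objects.
#' @export
read_swing_dataset <- function(dir, sample_rate_hz = 200) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  lapply(manifest$swings, function(e) {
    recs <- list()
    for (pl in names(e$imu)) {
      recs[[pl]] <- read_imu_csv(file.path(dir, e$imu[[pl]]), pl,
                                 sample_rate_hz)
    }
    lab <- read_labels_json(file.path(dir, e$labels))
    swing_set(e$subject_id, e$club, recs,
              read_track_csv(file.path(dir, e$track)), lab$points,
              swing_id = e$swing_id)
  })
}
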