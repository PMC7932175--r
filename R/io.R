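# File interchange: rig specification configs (YAML/JSON), corner tables and
# landmark tables (CSV), calibration files (JSON), survey tables (CSV) with a
# declarative column map.

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read a rig specification file
#'
#' Accepts YAML or JSON with fields `baseline_mm`, `toe_in_deg`, `fov_h_deg`,
#' `fov_v_deg`, `resolution`, `k1`, `laser_baseline_mm`; omitted fields take
#' the [default_pool_rig()] defaults.
#'
#' @param path Path to the config file.
#' @return A `stereo_rig`.
#' @export
read_rig_spec <- function(path) {
  cfg <- read_config_file(path)
  args <- cfg[intersect(names(cfg), names(formals(default_pool_rig)))]
  if (!is.null(args$resolution)) args$resolution <- as.numeric(unlist(args$resolution))
  do.call(default_pool_rig, args)
}

#' Write / read a calibration corner table (CSV)
#'
#' Long format: one row per frame, camera and corner with columns `frame_id`,
#' `camera` (`left`/`right`), `corner_index` (0-based, row-major) and pixel
#' coordinates `u`, `v`.
#'
#' @param frames Frame-pair list as produced by
#'   [simulate_calibration_session()] or [read_corner_table()].
#' @param path CSV path.
#' @return `write_corner_table` returns `path` invisibly;
#'   `read_corner_table` returns a frame-pair list.
#' @export
write_corner_table <- function(frames, path) {
  rows <- lapply(frames, function(fr) {
    n <- nrow(fr$left)
    data.frame(frame_id = fr$frame_id,
               camera = rep(c("left", "right"), each = n),
               corner_index = rep(0:(n - 1), 2),
               u = c(fr$left[, 1], fr$right[, 1]),
               v = c(fr$left[, 2], fr$right[, 2]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corner_table
#' @export
read_corner_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "camera", "corner_index", "u", "v")
  stopifnot(all(need %in% names(tab)))
  lapply(unique(tab$frame_id), function(fid) {
    sub <- tab[tab$frame_id == fid, ]
    side <- function(cam) {
      s <- sub[sub$camera == cam, ]
      s <- s[order(s$corner_index), ]
      cbind(u = s$u, v = s$v)
    }
    list(frame_id = fid, left = side("left"), right = side("right"))
  })
}

#' Write / read a calibration file (JSON)
#'
#' Serialises a [calibrate_stereo()] result (board spec, 11 + 11 DLT
#' coefficients, per-camera `k1`, reconstruction RMS, frame count, distortion
#' reference) at full floating-point precision so that a write/read round
#' trip reproduces the coefficients exactly.
#'
#' @param cal A `dlt_calibration`.
#' @param path JSON path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the `dlt_calibration`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "dlt_calibration"))
  payload <- list(
    spec = unclass(cal$spec),
    left_coeffs = cal$left_coeffs, right_coeffs = cal$right_coeffs,
    k1_left = cal$k1_left, k1_right = cal$k1_right,
    rms_reconstruction_mm = cal$rms_reconstruction_mm,
    n_frames = cal$n_frames,
    resolution = cal$resolution,
    distortion_ref = cal$distortion_ref,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    left_coeffs = as.numeric(p$left_coeffs),
    right_coeffs = as.numeric(p$right_coeffs),
    k1_left = p$k1_left, k1_right = p$k1_right,
    rms_reconstruction_mm = p$rms_reconstruction_mm,
    n_frames = p$n_frames,
    spec = do.call(checkerboard_spec, p$spec[c("nx", "ny", "square_mm")]),
    resolution = as.numeric(p$resolution),
    distortion_ref = list(fx = p$distortion_ref$fx, fy = p$distortion_ref$fy,
                          principal_point = as.numeric(p$distortion_ref$principal_point))
  ), class = "dlt_calibration")
}

#' Read a landmark table (CSV)
#'
#' Columns: `frame_id`, `landmark` (`snout`/`fork`/custom), `camera`
#' (`left`/`right`), `u`, `v`.
#'
#' @param path CSV path.
#' @return Tibble in the [measure_fork_lengths()] schema.
#' @export
read_landmark_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("frame_id", "landmark", "camera", "u", "v")
  stopifnot(all(need %in% names(tab)))
  tab
}

#' Read a laser-scaler observation table (CSV)
#'
#' Columns: `frame_id`, `target_px_len`, `laser_px_sep`, `lasers_on_target`,
#' `aoi_deg`.
#'
#' @param path CSV path.
#' @return Tibble of RLS observations.
#' @export
read_rls_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("frame_id", "target_px_len", "laser_px_sep", "lasers_on_target")
  stopifnot(all(need %in% names(tab)))
  tab
}

#' Read a survey table (CSV) through a declarative column map
#'
#' Renames the file's columns to the package's survey schema (`site_id`,
#' `species`, `system`, `fl_mm`, `aoi_deg`, `lasers_on_target`,
#' `both_views_visible`, `calibration_id`) via `column_map`, a named list
#' `schema_name = file_column_name`. Unmapped schema columns are left absent.
#'
#' @param path CSV path.
#' @param column_map Named list mapping schema names to file column names;
#'   `NULL` means the file already uses the schema names.
#' @return Survey tibble.
#' @export
read_survey_table <- function(path, column_map = NULL) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      file_col <- column_map[[schema_name]]
      if (!file_col %in% names(tab)) {
        stop("column map refers to missing column: ", file_col, call. = FALSE)
      }
      names(tab)[names(tab) == file_col] <- schema_name
    }
  }
  stopifnot(all(c("system") %in% names(tab)))
  tab
}
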