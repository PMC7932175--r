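#' Fork length from a digitized landmark pair
#'
#' Triangulates the snout and tail-fork landmarks of one synchronized frame
#' pair and returns the Euclidean distance between the two world points — the
#' fork-length (FL) estimate. The reported quality is the larger of the two
#' per-landmark reprojection RMS values.
#'
#' @param snout,fork Lists with `frame_id`, `left_px`, `right_px` (length-2
#'   pixel coordinates in the left/right views), as produced by
#'   [landmark_observation()].
#' @param cal A [calibrate_stereo()] result.
#' @return A one-row tibble: `frame_id`, `length_mm`, `system` ("SC"),
#'   `quality` (reprojection RMS, px).
#' @export
fork_length <- function(snout, fork, cal) {
  if (!identical(snout$frame_id, fork$frame_id)) {
    stop("frame mismatch: snout and fork landmarks come from different frames",
         call. = FALSE)
  }
  t1 <- triangulate(snout$left_px, snout$right_px, cal)
  t2 <- triangulate(fork$left_px, fork$right_px, cal)
  tibble::tibble(
    frame_id = snout$frame_id,
    length_mm = sqrt(sum((t1$point - t2$point)^2)),
    system = "SC",
    quality = max(t1$rms, t2$rms)
  )
}

#' One named landmark digitized in both views
#'
#' @param frame_id Frame-pair identifier.
#' @param landmark_name Landmark label, e.g. `"snout"` or `"fork"`.
#' @param left_px,right_px Length-2 pixel coordinates.
#' @return A list of class `landmark_observation`.
#' @export
landmark_observation <- function(frame_id, landmark_name, left_px, right_px) {
  stopifnot(nzchar(landmark_name),
            all(is.finite(left_px)), all(is.finite(right_px)))
  structure(list(frame_id = frame_id, landmark_name = landmark_name,
                 left_px = as.numeric(left_px), right_px = as.numeric(right_px)),
            class = "landmark_observation")
}

#' Red-laser-scaler length estimate
#'
#' Scales an on-screen target length by the on-screen separation of two
#' parallel laser points of known physical baseline:
#' `length = (target_px / laser_px) * laser_baseline_mm`. Both on-screen
#' quantities are Euclidean pixel distances in the centre camera's image.
#' Requires both lasers to strike the target.
#'
#' @param target_px_len On-screen target length, pixels.
#' @param laser_px_sep On-screen inter-laser-point distance, pixels.
#' @param lasers_on_target Number of laser points striking the target (0-2).
#' @param laser_baseline_mm Physical laser separation, mm (default 75).
#' @param frame_id Optional frame identifier carried through.
#' @return A one-row tibble: `frame_id`, `length_mm`, `system` ("RLS"),
#'   `quality` (the laser-point count).
#' @export
rls_length <- function(target_px_len, laser_px_sep, lasers_on_target = 2,
                       laser_baseline_mm = 75, frame_id = NA) {
  if (lasers_on_target < 2) {
    stop("ineligible: lasers — both laser points must strike the target",
         call. = FALSE)
  }
  if (!is.finite(laser_px_sep) || laser_px_sep <= 0) {
    stop("zero laser separation", call. = FALSE)
  }
  stopifnot(target_px_len > 0, laser_baseline_mm > 0)
  tibble::tibble(
    frame_id = frame_id,
    length_mm = (target_px_len / laser_px_sep) * laser_baseline_mm,
    system = "RLS",
    quality = as.numeric(lasers_on_target)
  )
}

#' Fork lengths for every frame of a landmark table
#'
#' Pairs the `snout` and `fork` rows of a long-format landmark table (one row
#' per frame, landmark and camera; see [read_landmark_table()]) and
#' triangulates each frame's fork length.
#'
#' @param landmarks Tibble with columns `frame_id`, `landmark`, `camera`
#'   (`"left"`/`"right"`), `u`, `v`.
#' @param cal A [calibrate_stereo()] result.
#' @return Tibble of per-frame fork-length estimates.
#' @export
measure_fork_lengths <- function(landmarks, cal) {
  need <- c("frame_id", "landmark", "camera", "u", "v")
  stopifnot(all(need %in% names(landmarks)))
  frames <- unique(landmarks$frame_id)
  out <- lapply(frames, function(fid) {
    sub <- landmarks[landmarks$frame_id == fid, ]
    get_px <- function(lm, camera) {
      row <- sub[sub$landmark == lm & sub$camera == camera, ]
      if (nrow(row) != 1) {
        stop(sprintf("frame %s: expected exactly one %s/%s row", fid, lm, camera),
             call. = FALSE)
      }
      c(row$u, row$v)
    }
    snout <- landmark_observation(fid, "snout",
                                  get_px("snout", "left"), get_px("snout", "right"))
    fork <- landmark_observation(fid, "fork",
                                 get_px("fork", "left"), get_px("fork", "right"))
    fork_length(snout, fork, cal)
  })
  dplyr::bind_rows(out)
}
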