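# Field-survey data model and summaries: eligibility filtering, per-site
# validation-object accuracy, length-frequency histograms and the
# stereo-vs-laser yield comparison.

#' Filter survey records by measurement eligibility
#'
#' Applies the orientation/visibility rules under which a length measurement
#' is accepted: stereo-camera (SC) records require both landmarks visible in
#' both views and an angle of incidence at or below `sc_max_aoi` (default
#' 25 degrees, the conservative field threshold); laser-scaler (RLS) records
#' require both laser points on the target and an AOI at or below
#' `rls_max_aoi` (default 10 degrees). Every excluded record is logged with
#' one primary reason code (`"visibility"`, `"lasers"` or `"aoi"`).
#'
#' @param records Tibble with at least `system` (`"SC"`/`"RLS"`) and
#'   `aoi_deg`; SC rows use `both_views_visible` (assumed `TRUE` when the
#'   column is absent), RLS rows use `lasers_on_target`.
#' @param sc_max_aoi,rls_max_aoi Eligibility thresholds, degrees, in (0, 90).
#' @return List with `eligible` (records) and `excluded` (records plus a
#'   `reason` column).
#' @export
filter_eligible <- function(records, sc_max_aoi = 25, rls_max_aoi = 10) {
  stopifnot(sc_max_aoi > 0, sc_max_aoi < 90, rls_max_aoi > 0, rls_max_aoi < 90)
  if (nrow(records) == 0) {
    return(list(eligible = records,
                excluded = dplyr::mutate(records, reason = character(0))))
  }
  vis <- if ("both_views_visible" %in% names(records)) {
    records$both_views_visible
  } else {
    rep(TRUE, nrow(records))
  }
  lasers <- if ("lasers_on_target" %in% names(records)) {
    records$lasers_on_target
  } else {
    rep(2, nrow(records))
  }
  is_sc <- records$system == "SC"
  reason <- rep(NA_character_, nrow(records))
  reason[is_sc & !vis] <- "visibility"
  reason[is_sc & vis & records$aoi_deg > sc_max_aoi] <- "aoi"
  reason[!is_sc & lasers < 2] <- "lasers"
  reason[!is_sc & lasers >= 2 & records$aoi_deg > rls_max_aoi] <- "aoi"
  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(eligible = records[keep, , drop = FALSE], excluded = excluded)
}

#' Validation-object accuracy per site
#'
#' Percent error of every estimate of a known-length validation object,
#' summarised per site (mean, standard error, n) and pooled across sites.
#' Sites whose absolute mean percent error exceeds the threshold are flagged.
#'
#' @param objects Tibble with `object_id` and `known_length_mm`.
#' @param estimates Tibble with `object_id`, `site_id`, `est_mm` and
#'   optionally `calibration_id`.
#' @param threshold_pct Accuracy flag threshold, percent.
#' @return List with `per_site` (tibble: `site_id`, `mean_pe`, `se_pe`, `n`,
#'   `flagged`) and `pooled` (one-row tibble over all estimates).
#' @export
validation_summary <- function(objects, estimates, threshold_pct = 5) {
  unknown <- setdiff(estimates$object_id, objects$object_id)
  if (length(unknown) > 0) {
    stop("unknown object id: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  est <- dplyr::left_join(estimates,
                          objects[, c("object_id", "known_length_mm")],
                          by = "object_id")
  est$pe_pct <- percent_error(est$est_mm, est$known_length_mm)
  per_site <- dplyr::summarise(
    dplyr::group_by(est, .data$site_id),
    mean_pe = mean(.data$pe_pct),
    se_pe = stats::sd(.data$pe_pct) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  per_site$flagged <- abs(per_site$mean_pe) > threshold_pct
  pooled <- tibble::tibble(
    mean_pe = mean(est$pe_pct),
    se_pe = stats::sd(est$pe_pct) / sqrt(nrow(est)),
    n = nrow(est))
  list(per_site = per_site, pooled = pooled)
}

#' Length-frequency histogram table
#'
#' Counts fork-length estimates in half-open bins `[k*bin, (k+1)*bin)`
#' anchored at 0 mm, per species and measurement system.
#'
#' @param records Tibble with `species`, `system`, `fl_mm`.
#' @param bin_mm Bin width, mm (default 30).
#' @return Tibble: `species`, `system`, `bin_lower_mm`, `bin_upper_mm`,
#'   `count`.
#' @export
length_frequency <- function(records, bin_mm = 30) {
  stopifnot(bin_mm > 0)
  rec <- records[!is.na(records$fl_mm), ]
  rec$bin_lower_mm <- floor(rec$fl_mm / bin_mm) * bin_mm
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$species, .data$system, .data$bin_lower_mm),
    count = dplyr::n(), .groups = "drop")
  out$bin_upper_mm <- out$bin_lower_mm + bin_mm
  out[, c("species", "system", "bin_lower_mm", "bin_upper_mm", "count")]
}

#' Stereo-camera vs laser-scaler yield comparison
#'
#' Compares the number of length estimates and of distinct measured species
#' between the two systems, with per-species mean fork length and standard
#' error for each system. Run on records already passed through
#' [filter_eligible()].
#'
#' @param records Tibble with `system`, `species`, `fl_mm`.
#' @return List with scalar counts `n_sc`, `n_rls`, `species_sc`,
#'   `species_rls`, exact ratios `ratio_n`, `ratio_species` (plus rounded
#'   1-decimal display values), and `per_species` (mean FL +/- SE per
#'   system). Ratios are `NA` with a warning marker when no RLS records
#'   exist.
#' @export
yield_comparison <- function(records) {
  sc <- records[records$system == "SC", ]
  rls <- records[records$system == "RLS", ]
  n_sc <- nrow(sc); n_rls <- nrow(rls)
  species_sc <- length(unique(sc$species))
  species_rls <- length(unique(rls$species))
  ratio_n <- if (n_rls > 0) n_sc / n_rls else NA_real_
  ratio_species <- if (species_rls > 0) species_sc / species_rls else NA_real_
  per_species <- dplyr::summarise(
    dplyr::group_by(records, .data$species, .data$system),
    mean_fl_mm = mean(.data$fl_mm),
    se_fl_mm = stats::sd(.data$fl_mm) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  list(n_sc = n_sc, n_rls = n_rls,
       species_sc = species_sc, species_rls = species_rls,
       ratio_n = ratio_n, ratio_species = ratio_species,
       ratio_n_display = round(ratio_n, 1),
       ratio_species_display = round(ratio_species, 1),
       division_by_zero = n_rls == 0,
       per_species = per_species)
}

#' Bundled reef-species registry
#'
#' Scientific and common names of the reef fishes observed during the field
#' surveys, used to validate species labels in survey tables.
#'
#' @return Tibble with `scientific_name` and `common_name`.
#' @export
species_registry <- function() {
  path <- system.file("extdata", "species_registry.csv", package = "rovstereo")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate species names against the bundled registry
#'
#' Unknown names pass with a warning (field identifications routinely include
#' taxa outside the registry); `"unidentified"` is always accepted.
#'
#' @param species Character vector of scientific names.
#' @return Logical vector, `TRUE` where the name is registered.
#' @export
check_species <- function(species) {
  reg <- species_registry()
  known <- species %in% c(reg$scientific_name, "unidentified")
  if (any(!known)) {
    warning("species not in registry: ",
            paste(unique(species[!known]), collapse = ", "), call. = FALSE)
  }
  known
}
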