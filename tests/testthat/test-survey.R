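make_survey <- function() {
  tibble::tibble(
    site_id = rep(1:2, each = 5),
    species = c("Lutjanus campechanus", "Lutjanus campechanus",
                "Haemulon aurolineatum", "Rhomboplites aurorubens",
                "Lutjanus campechanus", "Lutjanus campechanus",
                "Seriola dumerili", "Lutjanus synagris",
                "Lutjanus campechanus", "Pterois volitans"),
    system = c("SC", "SC", "SC", "SC", "RLS", "RLS", "SC", "SC", "SC", "SC"),
    fl_mm = c(393, 412, 160, 251, 400, 388, 705, 284, 360, 310),
    aoi_deg = c(10, 25, 26, 5, 8, 12, 20, 15, 3, 24),
    lasers_on_target = c(NA, NA, NA, NA, 2, 2, NA, NA, NA, NA),
    both_views_visible = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                           TRUE, TRUE))
}

test_that("eligibility filtering partitions records with one reason each", {
  rec <- make_survey()
  out <- filter_eligible(rec)
  expect_equal(nrow(out$eligible) + nrow(out$excluded), nrow(rec))
  expect_true(all(!is.na(out$excluded$reason)))
  # AOI exactly at the threshold stays eligible; one degree over does not
  expect_true(25 %in% out$eligible$aoi_deg[out$eligible$system == "SC"])
  expect_equal(out$excluded$reason[out$excluded$aoi_deg == 26], "aoi")
  expect_equal(out$excluded$reason[!out$excluded$both_views_visible &
                                     out$excluded$system == "SC"], "visibility")
  # RLS at 12 degrees exceeds its 10-degree threshold
  expect_equal(out$excluded$reason[out$excluded$system == "RLS"], "aoi")
  # single laser point excludes an RLS record regardless of AOI
  rls1 <- tibble::tibble(site_id = 1, species = "x", system = "RLS",
                         fl_mm = 100, aoi_deg = 5, lasers_on_target = 1,
                         both_views_visible = TRUE)
  expect_equal(filter_eligible(rls1)$excluded$reason, "lasers")
  # vacuous input
  empty <- filter_eligible(rec[0, ])
  expect_equal(nrow(empty$eligible), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("validation objects summarise to per-site and pooled percent error", {
  objects <- tibble::tibble(object_id = c("pipe603", "pipe364", "disc275"),
                            known_length_mm = c(603.3, 364.0, 274.6))
  estimates <- tibble::tibble(
    object_id = c("pipe364", "pipe364", "disc275", "disc275"),
    site_id = c(11, 11, 5, 5),
    est_mm = c(367.6, 364.0, 274.6, 280.1))
  out <- validation_summary(objects, estimates)
  expect_equal(out$per_site$n, c(2L, 2L))
  site11 <- out$per_site[out$per_site$site_id == 11, ]
  expect_equal(site11$mean_pe, mean(c(100 * 3.6 / 364, 0)), tolerance = 1e-10)
  expect_false(any(out$per_site$flagged))
  expect_equal(out$pooled$n, 4L)
  expect_error(validation_summary(objects[1, ], estimates), "unknown object id")
  # a perfectly calibrated synthetic session has zero error
  perfect <- tibble::tibble(object_id = "pipe603", site_id = 1, est_mm = 603.3)
  expect_lt(abs(validation_summary(objects, perfect)$pooled$mean_pe), 1e-6)
})

test_that("length-frequency bins are half-open, anchored at zero", {
  rec <- tibble::tibble(species = "Lutjanus campechanus", system = "SC",
                        fl_mm = c(393, 360.0, 389.999, 360.0))
  out <- length_frequency(rec)
  expect_equal(sum(out$count), nrow(rec))
  b390 <- out$count[out$bin_lower_mm == 390]
  b360 <- out$count[out$bin_lower_mm == 360]
  expect_equal(b390, 1L)  # 393 only; 389.999 stays below
  expect_equal(b360, 3L)  # both edge records fall in the lower-inclusive bin
  # conservation per species x system on a larger mixed table
  rec2 <- make_survey()
  out2 <- length_frequency(rec2)
  tot <- dplyr::count(rec2, species, system)
  agg <- dplyr::summarise(dplyr::group_by(out2, species, system),
                          n = sum(count), .groups = "drop")
  expect_equal(dplyr::arrange(agg, species, system)$n,
               dplyr::arrange(tot, species, system)$n)
})

test_that("yield comparison counts systems and species", {
  rec <- tibble::tibble(
    system = c(rep("SC", 20), rep("RLS", 5)),
    species = c(rep(c("a", "b", "c", "d"), 5), rep(c("a", "b"), c(3, 2))),
    fl_mm = 100 + seq_len(25))
  out <- yield_comparison(rec)
  expect_equal(out$n_sc, 20L)
  expect_equal(out$n_rls, 5L)
  expect_equal(out$ratio_n, 4)
  expect_equal(out$ratio_species, 2)
  # exact ratio consistency before rounding
  expect_equal(out$ratio_n * out$n_rls, out$n_sc)
  expect_false(out$division_by_zero)
  none <- yield_comparison(rec[rec$system == "SC", ])
  expect_true(none$division_by_zero)
  expect_true(is.na(none$ratio_n))
})

test_that("species names check against the bundled registry", {
  expect_true(all(check_species(c("Lutjanus campechanus", "unidentified"))))
  expect_warning(ok <- check_species(c("Lutjanus campechanus", "Nomen dubium")),
                 "not in registry")
  expect_equal(ok, c(TRUE, FALSE))
  reg <- species_registry()
  expect_equal(nrow(reg), 40)
})
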