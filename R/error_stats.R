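# Measurement-error analysis: percent error, per-cell summaries with
# t-based confidence intervals, the Gamma GLM with log link and fixed
# dispersion on APE + 1, and the minimum-measurable-length solver.

#' Percent error of a length estimate
#'
#' `PE = 100 * (estimated - actual) / actual`.
#'
#' @param est_mm Estimated length, mm.
#' @param actual_mm True length, mm; must be positive.
#' @return Signed percent error.
#' @export
percent_error <- function(est_mm, actual_mm) {
  if (any(actual_mm <= 0)) stop("zero actual length", call. = FALSE)
  100 * (est_mm - actual_mm) / actual_mm
}

#' Error records from a pool measurement table
#'
#' Adds signed and absolute percent error plus a system factor (the stereo
#' baselines and the laser scaler as four levels) to the output of
#' [run_pool_experiment()], dropping unmeasurable rows.
#'
#' @param measurements Tibble from [run_pool_experiment()] (or the same
#'   schema).
#' @return Tibble with `pe_pct`, `ape_pct`, `system_bd` (factor with the RLS
#'   as base level) and the original metadata columns.
#' @export
error_records <- function(measurements) {
  rec <- measurements[measurements$measurable & !is.na(measurements$est_fl_mm), ]
  rec$pe_pct <- percent_error(rec$est_fl_mm, rec$true_fl_mm)
  rec$ape_pct <- abs(rec$pe_pct)
  lab <- ifelse(rec$system == "RLS", "RLS",
                paste0("SC", match(rec$baseline_mm, sort(unique(
                  rec$baseline_mm[rec$system == "SC"])))))
  levs <- c("RLS", sort(unique(lab[lab != "RLS"])))
  rec$system_bd <- factor(lab, levels = intersect(levs, unique(lab)))
  rec
}

#' Per-cell mean percent error with 95% confidence intervals
#'
#' Summarises error records per (system, baseline, distance, AOI, model
#' length) cell: mean signed percent error, Student-t 95% confidence
#' half-width, and cell size. Cells with a single record carry an `NA`
#' half-width.
#'
#' @param records Tibble from [error_records()].
#' @return Tibble with one row per cell: `mean_pe`, `ci_halfwidth`, `n`.
#' @export
summarize_cells <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$system, .data$baseline_mm,
                    .data$distance_m, .data$aoi_deg, .data$true_fl_mm),
    mean_pe = mean(.data$pe_pct),
    ci_halfwidth = ifelse(dplyr::n() > 1,
                          stats::qt(0.975, dplyr::n() - 1) *
                            stats::sd(.data$pe_pct) / sqrt(dplyr::n()),
                          NA_real_),
    n = dplyr::n(),
    .groups = "drop")
}

#' Gamma GLM on x+1-transformed absolute percent errors
#'
#' Fits a Gamma generalized linear model with log link to `ape_pct + 1` by
#' iteratively reweighted least squares. The Gamma IRLS coefficient estimates
#' do not depend on the dispersion, so the point estimates equal the
#' unconstrained-dispersion fit; Wald z statistics and p-values are computed
#' with the dispersion fixed (default 1, i.e. an exponential error model,
#' appropriate for strictly positive data with multiplicative errors).
#'
#' @param records Tibble from [error_records()] (any data frame containing
#'   the variables in `formula`).
#' @param formula Model formula for the response `I(ape_pct + 1)` (or any
#'   strictly positive response).
#' @param dispersion Dispersion used for the Wald statistics (default 1).
#' @return Object of class `error_model_fit`: the underlying `glm` fit, a
#'   coefficient table (`estimate`, `se`, `z`, `p`) at the fixed dispersion,
#'   the dispersion convention, deviance and iteration count.
#' @export
fit_gamma_glm <- function(records,
                          formula = I(ape_pct + 1) ~ system_bd * distance_m * aoi_deg,
                          dispersion = 1) {
  fit <- stats::glm(formula, family = stats::Gamma(link = "log"),
                    data = records,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  mm_rank <- fit$rank
  p_model <- ncol(stats::model.matrix(fit))
  if (mm_rank < p_model) {
    stop("rank-deficient design: ", p_model - mm_rank,
         " coefficient(s) not estimable", call. = FALSE)
  }
  if (!fit$converged) stop("non-convergence: IRLS did not converge", call. = FALSE)
  # Newton polish on the dispersion-free estimating equations: IRLS stops on
  # a deviance criterion, which leaves the coefficients at ~sqrt(epsilon)
  # accuracy; a few Newton steps take them to machine precision.
  X <- stats::model.matrix(fit)
  y <- fit$y
  beta <- stats::coef(fit)
  for (i in 1:50) {
    mu <- as.numeric(exp(X %*% beta))
    step <- solve(crossprod(X, X * (y / mu)), crossprod(X, y / mu - 1))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-13) break
  }
  names(beta) <- colnames(X)
  fit$coefficients <- beta
  sm <- summary(fit)
  se <- sqrt(dispersion * diag(sm$cov.unscaled))
  z <- unname(beta) / se
  structure(list(
    fit = fit,
    formula = formula,
    coefficients = beta,
    wald = tibble::tibble(term = colnames(X),
                          estimate = unname(beta), se = unname(se),
                          z = z, p = 2 * stats::pnorm(-abs(z))),
    dispersion = dispersion,
    link = "log",
    deviance = fit$deviance,
    iterations = fit$iter
  ), class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat(sprintf("<error_model_fit> Gamma GLM, log link, dispersion fixed at %g\n",
              x$dispersion))
  print(x$wald, n = Inf)
  invisible(x)
}

#' Minimum measurable length at an error threshold
#'
#' For each stereo baseline, regresses `APE + 1` on fork length (Gamma GLM,
#' log link, fork length continuous) and solves for the length at which the
#' fitted curve crosses the error threshold:
#' `FL* = (log(threshold + 1) - b0) / b1`. When the fitted curve stays below
#' the threshold across the observed length range the baseline is reported as
#' "all lengths estimable". With the `"ape"` convention the fitted mean is
#' compared to the threshold directly (no +1 shift in the crossing equation).
#'
#' @param records Tibble from [error_records()]; only `system == "SC"` rows
#'   are used.
#' @param threshold_pct Error threshold, percent (default 5).
#' @param convention `"ape1"` (default; threshold crossing at fitted mean
#'   `threshold + 1`) or `"ape"` (crossing at fitted mean `threshold`).
#' @return Tibble with one row per baseline: `baseline_mm`, `threshold_pct`,
#'   `b0`, `b1`, `min_fl_mm` (`NA` when all lengths are estimable) and
#'   `all_estimable`.
#' @export
min_measurable_length <- function(records, threshold_pct = 5,
                                  convention = c("ape1", "ape")) {
  convention <- match.arg(convention)
  sc <- records[records$system == "SC", ]
  stopifnot(nrow(sc) > 0)
  target <- if (convention == "ape1") log(threshold_pct + 1) else log(threshold_pct)
  out <- lapply(sort(unique(sc$baseline_mm)), function(b) {
    sub <- sc[sc$baseline_mm == b, ]
    fit <- stats::glm(I(ape_pct + 1) ~ true_fl_mm,
                      family = stats::Gamma(link = "log"), data = sub,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    b0 <- stats::coef(fit)[[1]]
    b1 <- stats::coef(fit)[[2]]
    eps <- .Machine$double.eps^0.5
    if (abs(b1) < eps) {
      # flat fit: either every length sits at/below the threshold or none does
      if (b0 > target * (1 + 1e-8) + 1e-10) {
        stop("non-identified: flat fit above the error threshold", call. = FALSE)
      }
      min_fl <- NA_real_
      below <- TRUE
    } else if (b1 < 0) {
      # error shrinks with length: a minimum measurable length exists when the
      # fitted curve starts above the threshold at FL = 0
      if (b0 > target) {
        min_fl <- (target - b0) / b1
        below <- FALSE
      } else {
        min_fl <- NA_real_
        below <- TRUE
      }
    } else {
      # error grows with length: no lower threshold; report whether the fitted
      # curve stays below the threshold over the observed range
      min_fl <- NA_real_
      below <- b0 + b1 * max(sub$true_fl_mm) <= target
    }
    tibble::tibble(baseline_mm = b, threshold_pct = threshold_pct,
                   b0 = b0, b1 = b1, min_fl_mm = min_fl,
                   all_estimable = below)
  })
  dplyr::bind_rows(out)
}
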