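# Numeric post-processing: OxICAT oxidation degree and delta oxidation
# with significance, AMC-release protease kinetics, and qPCR relative
# expression.
#
# OxICAT labels reduced thiols light and originally oxidized thiols
# heavy, so %oxidation = heavy / (light + heavy) x 100. Delta oxidation
# compares a lethal against a non-lethal treatment in percentage points,
# with a two-tailed unpaired Student's t-test (pooled variance; Welch
# behind a flag). Kinetics converts initial fluorescence slopes to
# specific activity via an AMC calibration line.

#' Degree of cysteine oxidation from ICAT intensities
#'
#' @param light,heavy Non-negative intensity vectors; `light + heavy`
#'   must be positive for every record.
#' @return Percent oxidation in `[0, 100]`.
#' @export
oxidation_degree <- function(light, heavy) {
  stopifnot(all(light >= 0), all(heavy >= 0))
  tot <- light + heavy
  if (any(tot == 0)) {
    stop("oxidation_degree: light + heavy must be > 0")
  }
  100 * heavy / tot
}

#' Delta oxidation per cysteine site with significance
#'
#' For each `(protein, cys_pos)` site, oxidation degrees are computed
#' per replicate and `delta_ox = mean(lethal) - mean(nonlethal)` in
#' percentage points, with a two-tailed unpaired t-test on the replicate
#' oxidation degrees. Records with `light + heavy == 0` are dropped with
#' a warning; sites with fewer than 2 replicates in either group get a
#' `NA` p-value. With zero variance in both groups the t statistic is
#' undefined: p is 1 when the difference is 0, `NA` otherwise.
#'
#' @param records Tibble with columns `protein`, `cys_pos`, `treatment`,
#'   `replicate`, `light`, `heavy`.
#' @param lethal,nonlethal Treatment labels of the two groups.
#' @param welch Use the Welch (unpooled) test instead of Student's
#'   pooled-variance test. Default `FALSE`.
#' @param p_adjust Apply Benjamini-Hochberg across sites. Default
#'   `FALSE` (raw p-values).
#' @return Tibble per site: `protein`, `cys_pos`, `delta_ox`,
#'   `p_value`, `mean_lethal`, `mean_nonlethal`, `n_lethal`,
#'   `n_nonlethal` (plus `p_adjusted` when requested).
#' @export
delta_oxidation <- function(records, lethal, nonlethal, welch = FALSE,
                            p_adjust = FALSE) {
  stopifnot(all(c("protein", "cys_pos", "treatment", "light", "heavy")
                %in% names(records)))
  usable <- records$light + records$heavy > 0
  if (any(!usable)) {
    warning("delta_oxidation: dropped ", sum(!usable),
            " record(s) with light + heavy == 0")
    records <- records[usable, , drop = FALSE]
  }
  records$ox <- oxidation_degree(records$light, records$heavy)

  out <- records |>
    dplyr::filter(.data$treatment %in% c(lethal, nonlethal)) |>
    dplyr::group_by(.data$protein, .data$cys_pos) |>
    dplyr::group_modify(function(df, key) {
      a <- df$ox[df$treatment == lethal]
      b <- df$ox[df$treatment == nonlethal]
      d <- mean(a) - mean(b)
      p <- NA_real_
      if (length(a) >= 2 && length(b) >= 2) {
        if (stats::var(a) + stats::var(b) == 0) {
          p <- if (d == 0) 1 else NA_real_
        } else {
          p <- stats::t.test(a, b, var.equal = !welch,
                             alternative = "two.sided")$p.value
        }
      }
      tibble::tibble(delta_ox = d, p_value = p,
                     mean_lethal = mean(a), mean_nonlethal = mean(b),
                     n_lethal = length(a), n_nonlethal = length(b))
    }) |>
    dplyr::ungroup()
  if (p_adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Fit an AMC calibration line
#'
#' Ordinary least squares of fluorescence on AMC concentration, the
#' standard six-point curve (12, 6, 3, 1.5, 0.75, 0 uM in the assays
#' this package emulates).
#'
#' @param standards Tibble with columns `conc_um` and `rfu`
#'   (>= 3 standards, >= 2 distinct concentrations).
#' @return An object of class `mc_calibration`: `slope` (RFU per uM),
#'   `intercept` (RFU), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(standards) {
  stopifnot(all(c("conc_um", "rfu") %in% names(standards)),
            nrow(standards) >= 3)
  if (length(unique(standards$conc_um)) < 2) {
    stop("fit_calibration: need >= 2 distinct concentrations")
  }
  fit <- stats::lm(rfu ~ conc_um, data = standards)
  # R^2 computed directly: summary.lm warns on exact (noise-free) fits
  sst <- sum((standards$rfu - mean(standards$rfu))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst <= .Machine$double.eps) 0 else 1 - ssr / sst
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = min(max(r2, 0), 1),
    n = nrow(standards),
    fit = fit), class = "mc_calibration")
}

#' @export
print.mc_calibration <- function(x, ...) {
  cat(sprintf("<mc_calibration> slope %.4g RFU/uM, intercept %.4g RFU, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

# OLS slope of y on x, closed form.
ols_slope <- function(x, y) {
  stats::cov(x, y) / stats::var(x)
}

#' Specific protease activity from a fluorescence time course
#'
#' The initial slope (RFU/min) is the maximum OLS slope over a sliding
#' window of `window` consecutive points whose start lies within the
#' first third of the trace. It converts to a rate via the calibration
#' slope (uM/min), then to specific activity: rate x well volume (L)
#' gives umol/min (uM x L = umol), divided by protein mass (mg).
#'
#' @param trace Tibble with ascending `time_min` and `rfu` (>= 4
#'   points; at least `window` points).
#' @param cal An [fit_calibration()] object with positive slope.
#' @param volume_l Well volume in liters.
#' @param protein_mg Protein mass per well in mg (> 0).
#' @param window Points per initial-slope window (default 5).
#' @return One-row tibble: `slope_rfu_min`, `rate_um_min`,
#'   `activity_umol_min_mg`.
#' @export
compute_activity <- function(trace, cal, volume_l, protein_mg, window = 5) {
  stopifnot(inherits(cal, "mc_calibration"), protein_mg > 0,
            all(diff(trace$time_min) > 0), nrow(trace) >= 4)
  # tolerance absorbs the ~1e-16 numerical slope of a flat standards line
  if (cal$slope <= 1e-9) stop("compute_activity: calibration slope must be > 0")
  n <- nrow(trace)
  if (n < window) stop("compute_activity: fewer points than window")
  max_start <- max(1L, ceiling(n / 3))
  starts <- 1:min(max_start, n - window + 1L)
  slopes <- vapply(starts, function(s) {
    ix <- s:(s + window - 1L)
    ols_slope(trace$time_min[ix], trace$rfu[ix])
  }, double(1))
  slope_rfu <- max(slopes)
  rate <- slope_rfu / cal$slope          # uM/min
  activity <- rate * volume_l / protein_mg  # umol/min/mg
  tibble::tibble(slope_rfu_min = slope_rfu, rate_um_min = rate,
                 activity_umol_min_mg = activity)
}

#' Percent inhibition of an activity
#'
#' `100 x (1 - with/without)`, floored at 0.
#'
#' @param activity_with Activity with inhibitor.
#' @param activity_without Activity without inhibitor (> 0).
#' @return Percent inhibition.
#' @export
inhibition_percent <- function(activity_with, activity_without) {
  if (any(activity_without <= 0)) {
    stop("inhibition_percent: activity without inhibitor must be > 0")
  }
  pmax(0, 100 * (1 - activity_with / activity_without))
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes the target gene to a reference gene within each sample and
#' to a baseline sample:
#' `2^-((ct_target_sample - ct_ref_sample) - (ct_target_baseline - ct_ref_baseline))`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_baseline,ct_ref_baseline
#'   Finite Ct values (vectorized).
#' @return Fold change relative to the baseline sample.
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_baseline, ct_ref_baseline) {
  ct <- c(ct_target_sample, ct_ref_sample, ct_target_baseline, ct_ref_baseline)
  stopifnot(all(is.finite(ct)))
  2^-((ct_target_sample - ct_ref_sample) -
        (ct_target_baseline - ct_ref_baseline))
}
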