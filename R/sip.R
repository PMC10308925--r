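#' Fit a refractive-index to buoyant-density calibration
#'
#' CsCl buoyant density is linear in refractive index over the working
#' range; the calibration is an OLS fit to measured standards. With exactly
#' two standards the fit interpolates them exactly.
#'
#' @param standards Data frame with columns `ri` and `density` (>= 2 rows).
#' @return A list with `slope` and `intercept` (class `ri_calibration`).
#' @export
#' @examples
#' cal <- fit_ri_calibration(data.frame(ri = c(1.3990, 1.4052),
#'                                      density = c(1.690, 1.755)))
#' ri_to_density(1.4021, cal)  # 1.7225
fit_ri_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("ri", "density") %in% names(standards)))
    stop("standards needs columns ri and density", call. = FALSE)
  if (nrow(standards) < 2)
    stop("need at least 2 calibration standards", call. = FALSE)
  fit <- stats::lm(density ~ ri, data = standards)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "ri_calibration")
}

# Shipped placeholder calibration: the two-standard fit documented in the
# package vignette. Real analyses should supply their own standards.
default_ri_calibration <- function() {
  fit_ri_calibration(data.frame(ri = c(1.3990, 1.4052),
                                density = c(1.690, 1.755)))
}

#' Convert refractive index to buoyant density
#'
#' @param ri Refractive-index readings.
#' @param calibration A `ri_calibration`, or numeric `c(slope, intercept)`.
#' @return Densities in g/mL. Values outside 1.6-1.8 g/mL trigger a
#'   warning (reading or calibration likely wrong).
#' @export
ri_to_density <- function(ri, calibration = default_ri_calibration()) {
  if (is.numeric(calibration) && length(calibration) == 2) {
    calibration <- list(slope = calibration[1], intercept = calibration[2])
  }
  dens <- calibration$slope * ri + calibration$intercept
  if (any(dens < 1.6 | dens > 1.8))
    warning("converted density outside 1.6-1.8 g/mL", call. = FALSE)
  dens
}

# Extract one target's fractions from a long fraction table, ordered by
# fraction index (1 = heaviest).
target_profile_rows <- function(table, target) {
  rows <- table[table$target == target, , drop = FALSE]
  if (nrow(rows) == 0) stop("target '", target, "' not present", call. = FALSE)
  if (anyDuplicated(rows$fraction))
    stop("duplicate fraction indices for target '", target, "'",
         call. = FALSE)
  rows[order(rows$fraction), , drop = FALSE]
}

#' Normalize a target's fraction profile
#'
#' Divides each fraction's copies by the target's total over all fractions,
#' giving relative abundances that sum to one. This is the quantity plotted
#' in SIP fraction-profile figures and makes gradients with different DNA
#' loads comparable.
#'
#' @param table A `fraction_table` (long format) for one gradient.
#' @param target Target label to extract.
#' @return Numeric vector of relative abundances ordered by fraction index,
#'   with the fraction indices as names.
#' @export
normalize_profile <- function(table, target) {
  rows <- target_profile_rows(table, target)
  total <- sum(rows$copies)
  if (total <= 0)
    stop("cannot normalize: target '", target, "' has zero total copies",
         call. = FALSE)
  stats::setNames(rows$copies / total, rows$fraction)
}

#' Abundance-weighted mean buoyant density
#'
#' @param profile Relative abundances over fractions (normalized).
#' @param densities Fraction center densities, g/mL, same order.
#' @return Weighted mean density in g/mL.
#' @export
#' @examples
#' weighted_mean_density(rep(1 / 3, 3), c(1.70, 1.71, 1.72))  # 1.71
weighted_mean_density <- function(profile, densities) {
  if (length(profile) != length(densities))
    stop("profile and densities differ in length", call. = FALSE)
  sum(profile * densities)
}

#' Detect isotope labeling from paired 12C / 13C gradients
#'
#' Formalizes the visual peak-shift reading of SIP profiles with a dual
#' criterion: a target is called labeled when its weighted mean density
#' increases by at least `wmd_threshold`, or its peak moves at least
#' `peak_threshold` fractions toward the heavy end (lower index = heavier).
#'
#' @param table_12c,table_13c `fraction_table`s on the same fraction grid.
#' @param target Target label present in both tables.
#' @param wmd_threshold Minimum weighted-mean-density increase, g/mL.
#' @param peak_threshold Minimum heavy-ward peak shift, fractions.
#' @return An object of class `sip_result`: `target`, `wmd_12c`, `wmd_13c`,
#'   `delta_wmd`, `peak_12c`, `peak_13c`, `labeled`.
#' @export
detect_labeling <- function(table_12c, table_13c, target,
                            wmd_threshold = 0.004, peak_threshold = 1) {
  r12 <- target_profile_rows(table_12c, target)
  r13 <- target_profile_rows(table_13c, target)
  if (!identical(r12$fraction, r13$fraction) ||
      max(abs(r12$density - r13$density)) > 1e-9)
    stop("12C and 13C tables are on different fraction grids", call. = FALSE)
  p12 <- normalize_profile(r12, target)
  p13 <- normalize_profile(r13, target)
  wmd12 <- weighted_mean_density(p12, r12$density)
  wmd13 <- weighted_mean_density(p13, r13$density)
  # Peak = fraction with maximum copies; ties resolve to the heavier
  # (lower-index) fraction.
  peak12 <- r12$fraction[which.max(p12)]
  peak13 <- r13$fraction[which.max(p13)]
  delta <- wmd13 - wmd12
  structure(list(target = target, wmd_12c = wmd12, wmd_13c = wmd13,
                 delta_wmd = delta, peak_12c = peak12, peak_13c = peak13,
                 labeled = (delta >= wmd_threshold) ||
                   (peak12 - peak13 >= peak_threshold)),
            class = "sip_result")
}

#' @export
print.sip_result <- function(x, ...) {
  cat(sprintf(
    "<sip_result> %s: WMD %.4f -> %.4f g/mL (delta %+.4f), peak %d -> %d: %s\n",
    x$target, x$wmd_12c, x$wmd_13c, x$delta_wmd, x$peak_12c, x$peak_13c,
    if (x$labeled) "LABELED" else "unlabeled"))
  invisible(x)
}
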