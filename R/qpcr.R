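#' Fit a qPCR standard curve
#'
#' OLS of Cq against log10 copies for a 10-fold dilution series.
#' Amplification efficiency follows from the slope,
#' `E = 10^(-1/slope) - 1` (slope -3.3219 is perfect doubling, E = 100%).
#' Curves whose efficiency falls outside 83-94% or whose r-squared is not
#' above 0.99 raise a warning: those bands describe the assays of the study
#' this package models, so they flag departures rather than invalidate the
#' curve.
#'
#' @param dilutions Data frame with columns `log10_copies` and `cq`
#'   (>= 3 points; the series should span at least 3 orders of magnitude).
#' @param target Label carried into the result.
#' @return An object of class `standard_curve`: `target`, `slope`,
#'   `intercept`, `r2`, `efficiency`, `cq_range`, `qc_efficiency`, `qc_r2`.
#' @export
#' @examples
#' d <- data.frame(log10_copies = 1:7, cq = 38 - 3.3219 * (1:7))
#' suppressWarnings(fit_standard_curve(d))$efficiency  # 1 (100%)
fit_standard_curve <- function(dilutions, target = "amoA") {
  if (!is.data.frame(dilutions) ||
      !all(c("log10_copies", "cq") %in% names(dilutions)))
    stop("dilutions needs columns log10_copies and cq", call. = FALSE)
  if (nrow(dilutions) < 3)
    stop("need at least 3 dilution points", call. = FALSE)
  if (diff(range(dilutions$log10_copies)) < 3)
    warning("dilution series spans fewer than 3 orders of magnitude",
            call. = FALSE)
  fit <- stats::lm(cq ~ log10_copies, data = dilutions)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("invalid standard curve: slope must be negative", call. = FALSE)
  # exactly collinear dilution series are legitimate in synthetic checks
  r2 <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })$r.squared
  eff <- 10^(-1 / slope) - 1
  qc_eff <- eff >= 0.83 && eff <= 0.94
  qc_r2 <- r2 > 0.99
  if (!qc_eff)
    warning(sprintf("efficiency %.1f%% outside the 83-94%% QC band",
                    100 * eff), call. = FALSE)
  if (!qc_r2)
    warning(sprintf("standard-curve r2 = %.4f is not > 0.99", r2),
            call. = FALSE)
  structure(list(target = target, slope = slope,
                 intercept = unname(stats::coef(fit)[1]), r2 = r2,
                 efficiency = eff, cq_range = range(dilutions$cq),
                 qc_efficiency = qc_eff, qc_r2 = qc_r2),
            class = "standard_curve")
}

#' Absolute quantification from a Cq value
#'
#' Back-calculates template concentration from the standard curve,
#' `copies/uL = 10^((cq - intercept)/slope)`, then scales to copies per
#' gram of (wet) soil: times the DNA elution volume, divided by the
#' fraction of the elution used as template and by the extracted soil
#' mass. The default scaling (30 uL elution, 1/30 as template, 0.16 g
#' soil) is a declared placeholder configuration, not a measured one.
#'
#' @param cq Observed Cq value(s).
#' @param curve A `standard_curve`.
#' @param elution_volume DNA elution volume, uL.
#' @param template_fraction Fraction of the elution templated per reaction.
#' @param soil_mass Extracted soil mass, g.
#' @return Copies per gram of soil. Cq values outside the calibrated range
#'   trigger an extrapolation warning.
#' @export
quantify <- function(cq, curve, elution_volume = 30,
                     template_fraction = 1 / 30, soil_mass = 0.16) {
  stopifnot(inherits(curve, "standard_curve"))
  if (soil_mass <= 0 || elution_volume <= 0 || template_fraction <= 0)
    stop("scaling parameters must be > 0", call. = FALSE)
  pad <- 1  # one cycle of slack before calling it extrapolation
  if (any(cq < curve$cq_range[1] - pad | cq > curve$cq_range[2] + pad))
    warning("Cq outside the calibrated range; extrapolating", call. = FALSE)
  copies_per_ul <- 10^((cq - curve$intercept) / curve$slope)
  copies_per_ul * elution_volume / template_fraction / soil_mass
}

#' Abundance fold change
#'
#' @param initial,final Abundances in the same units (e.g. copies/g).
#' @return `final / initial`.
#' @export
#' @examples
#' fold_change(5e6, 1.5e7)  # 3
fold_change <- function(initial, final) {
  if (any(initial <= 0))
    stop("fold change undefined for non-positive initial abundance",
         call. = FALSE)
  final / initial
}

#' Simulate Cq values from a standard curve
#'
#' Generates threshold cycles for known template amounts under a given
#' curve, with optional Gaussian Cq noise; used to exercise the
#' quantification round trip and curve-recovery properties.
#'
#' @param log10_copies Log10 template copies per uL.
#' @param curve A `standard_curve`, or a list with `slope` and `intercept`.
#' @param noise_sd Gaussian Cq noise SD (cycles).
#' @param seed Optional integer seed.
#' @return Numeric Cq values.
#' @export
simulate_cq <- function(log10_copies, curve, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cq <- curve$intercept + curve$slope * log10_copies
  if (noise_sd > 0) cq <- cq + stats::rnorm(length(cq), 0, noise_sd)
  cq
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: Cq = %.3f %+.4f * log10(copies), r2 = %.4f, E = %.1f%%%s\n",
    x$target, x$intercept, x$slope, x$r2, 100 * x$efficiency,
    if (x$qc_efficiency && x$qc_r2) "" else " [QC flag]"))
  invisible(x)
}
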