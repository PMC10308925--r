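#' Density-gradient configuration
#'
#' Parameterizes a linear CsCl buoyant-density gradient collected from the
#' heavy end: fraction 1 is heaviest and fraction k has center density
#' `density_intercept - density_step * k`. The defaults reproduce the two
#' anchors of the study this package models: fraction 9 at 1.716 g/mL and
#' fraction 10 at 1.7075 g/mL.
#'
#' @param n_fractions Number of collected fractions (14-16 typical).
#' @param density_intercept Extrapolated density at fraction 0, g/mL.
#' @param density_step Density decrease per fraction, g/mL (> 0).
#' @param band_sd Within-taxon density spread, g/mL.
#' @param noise_cv Lognormal coefficient of variation of copy counts.
#' @param seed Integer seed for copy-count noise.
#' @return An object of class `gradient_config`.
#' @export
#' @examples
#' fraction_densities(gradient_config())[9:10]  # 1.716, 1.7075
gradient_config <- function(n_fractions = 15, density_intercept = 1.7925,
                            density_step = 0.0085, band_sd = 0.006,
                            noise_cv = 0.1, seed = 1L) {
  if (n_fractions < 2) stop("n_fractions must be >= 2", call. = FALSE)
  if (density_step <= 0) stop("density_step must be > 0", call. = FALSE)
  if (band_sd < 0 || noise_cv < 0)
    stop("band_sd and noise_cv must be >= 0", call. = FALSE)
  dens <- density_intercept - density_step * seq_len(n_fractions)
  if (any(dens < 1.60) || any(dens > 1.80))
    stop("fraction densities must lie within 1.60-1.80 g/mL", call. = FALSE)
  structure(list(n_fractions = as.integer(n_fractions),
                 density_intercept = density_intercept,
                 density_step = density_step, band_sd = band_sd,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "gradient_config")
}

#' Center densities of the gradient fractions
#'
#' @param gconfig A [gradient_config()].
#' @return Numeric vector of center densities (g/mL), heaviest first.
#' @export
fraction_densities <- function(gconfig) {
  stopifnot(inherits(gconfig, "gradient_config"))
  gconfig$density_intercept -
    gconfig$density_step * seq_len(gconfig$n_fractions)
}

#' Describe a taxon's DNA population in a gradient
#'
#' @param name Target label (e.g. `"CMX"` for comammox amoA).
#' @param gc Genomic GC content, fraction in \[0, 1\].
#' @param atom13c_excess Excess 13C atom fraction in \[0, 1\].
#' @param total_copies Total gene copies loaded on the gradient.
#' @return An object of class `taxon_band`.
#' @export
taxon_band <- function(name, gc, atom13c_excess = 0, total_copies = 1e6) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  if (atom13c_excess < 0 || atom13c_excess > 1)
    stop("atom13c_excess must lie in [0, 1]", call. = FALSE)
  if (total_copies < 0) stop("total_copies must be >= 0", call. = FALSE)
  structure(list(name = as.character(name), gc = gc,
                 atom13c_excess = atom13c_excess,
                 total_copies = total_copies),
            class = "taxon_band")
}

#' Buoyant density of a taxon's DNA
#'
#' Standard SIP physics for CsCl gradients: density rises linearly with GC
#' content and with 13C incorporation,
#' `rho = 1.660 + 0.098 * GC + 0.036 * excess` (g/mL). The constants are
#' conventional literature values and are arguments, not hard-coded truths.
#'
#' @param band A [taxon_band()].
#' @param gc_slope Density increase per unit GC fraction, g/mL.
#' @param label_shift Density increase per unit 13C atom-fraction excess,
#'   g/mL.
#' @param intercept Density of 0%-GC unlabeled DNA, g/mL.
#' @return Density in g/mL.
#' @export
#' @examples
#' taxon_density(taxon_band("x", gc = 0.5))            # 1.709
#' taxon_density(taxon_band("x", gc = 0.5, atom13c_excess = 1))  # 1.745
taxon_density <- function(band, gc_slope = 0.098, label_shift = 0.036,
                          intercept = 1.660) {
  stopifnot(inherits(band, "taxon_band"))
  intercept + gc_slope * band$gc + label_shift * band$atom13c_excess
}

#' Simulate a density-gradient fraction table
#'
#' Distributes each taxon band's copies over the fractions as the Gaussian
#' mass of `N(taxon_density, band_sd)` falling in each fraction's density
#' interval (center +/- step/2), then multiplies by mean-one lognormal noise
#' with the configured CV. Bands whose center density falls outside the
#' collected density range are truncated, with a warning.
#'
#' @param gconfig A [gradient_config()].
#' @param bands List of [taxon_band()] objects (at least one).
#' @param gradient_id,condition,isotope,replicate Labels attached to every
#'   row of the output table.
#' @return A `fraction_table` data frame in long format with columns
#'   `gradient_id`, `condition`, `isotope`, `replicate`, `fraction`,
#'   `density`, `target`, `copies`.
#' @export
simulate_gradient <- function(gconfig, bands, gradient_id = "G1",
                              condition = "freshwater", isotope = "12C",
                              replicate = 1L) {
  stopifnot(inherits(gconfig, "gradient_config"))
  if (inherits(bands, "taxon_band")) bands <- list(bands)
  if (length(bands) < 1) stop("need at least one band", call. = FALSE)
  dens <- fraction_densities(gconfig)
  half <- gconfig$density_step / 2
  lo <- min(dens) - half
  hi <- max(dens) + half

  set.seed(gradient_seed(gconfig$seed, gradient_id, isotope, replicate))
  rows <- lapply(bands, function(b) {
    stopifnot(inherits(b, "taxon_band"))
    mu <- taxon_density(b)
    if (mu < lo || mu > hi)
      warning("band '", b$name, "' (", signif(mu, 5),
              " g/mL) lies outside the gradient range; mass truncated",
              call. = FALSE)
    mass <- if (gconfig$band_sd <= 0) {
      as.numeric(abs(dens - mu) <= half)  # delta band: all-or-nothing
    } else {
      stats::pnorm(dens + half, mu, gconfig$band_sd) -
        stats::pnorm(dens - half, mu, gconfig$band_sd)
    }
    copies <- b$total_copies * mass
    if (gconfig$noise_cv > 0) {
      sdlog <- sqrt(log(1 + gconfig$noise_cv^2))
      copies <- copies * stats::rlnorm(length(copies), -sdlog^2 / 2, sdlog)
    }
    data.frame(gradient_id = gradient_id, condition = condition,
               isotope = isotope, replicate = replicate,
               fraction = seq_along(dens), density = dens,
               target = b$name, copies = copies, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fraction_table", "data.frame")
  out
}

gradient_seed <- function(seed, gradient_id, isotope, replicate) {
  id <- sum(utf8ToInt(paste0(gradient_id, isotope))) %% 100003
  as.integer((as.double(seed) * 48271 + id * 1117 +
                as.double(replicate) * 7) %% 2147483629)
}
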