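# Shared fixtures built in code.

# Noise-free configuration with the package's freshwater-anchored defaults.
quiet_config <- function(...) microcosm_config(meas_sd = 0, ...)

# Configuration whose guild rates correspond to the soil-normalized rates
# used in the recovery studies: comammox 4.4, AOB 3.6, AOA 0.1
# mg N/day/kg soil (divide by 84 for the liquid phase).
recovery_config <- function(seed = 1L, meas_sd = 0.002) {
  microcosm_config(
    guild_rates = c(AOA = 0.1, AOB = 3.6, CMX = 4.4, NOB = 20) / 84,
    meas_sd = meas_sd, seed = seed)
}

recovery_truth <- c(cmx = 4.4, aob = 3.6, aoa = 0.1)

# Independent fixed-step forward-Euler integrator used as the ODE oracle.
# Deliberately naive and separate from the package's Runge-Kutta path.
euler_oracle <- function(config, treatment, salinity, sample_times,
                         step_days = 5e-4) {
  doses <- config$dose_schedule
  if (treatment == "IV") doses$analyte <- ifelse(doses$analyte == "NH4",
                                                 "NO3", doses$analyte)
  r0 <- config$guild_rates * config$salinity_scale[[
    which(abs(as.numeric(names(config$salinity_scale)) - salinity) < 1e-9)]]
  if (treatment == "II") r0[c("CMX", "NOB")] <- 0
  if (treatment == "III") r0[c("CMX", "NOB", "AOB")] <- 0
  lag <- config$lag_hours / 24
  km <- config$km
  leak <- config$leak_fraction
  f <- function(s, k) if (k <= 0) as.numeric(s > 0) else s / (k + s)
  y <- c(config$init[["NH4"]], config$init[["NO2"]], config$init[["NO3"]], 0)
  for (i in which(doses$time_h <= 0)) {
    j <- if (doses$analyte[i] == "NH4") 1 else 3
    y[j] <- y[j] + doses$amount[i]
  }
  t <- 0
  out <- matrix(NA_real_, nrow = length(sample_times), ncol = 4)
  samp <- sample_times / 24
  pending <- doses[doses$time_h > 0, , drop = FALSE]
  record <- function(t) {
    hit <- which(abs(samp - t) < step_days / 4)
    for (h in hit) out[h, ] <<- y
  }
  record(0)
  horizon <- max(samp)
  while (t < horizon - 1e-12) {
    h <- min(step_days, horizon - t)
    ramp <- ifelse(lag > 0, pmin(1, pmax(0, t / lag)), 1)
    r <- r0 * ramp
    v <- c(r[["AOA"]] * f(y[1], km[["AOA"]]),
           r[["AOB"]] * f(y[1], km[["AOB"]]),
           r[["CMX"]] * f(y[1], km[["CMX"]]),
           r[["NOB"]] * f(y[2], km[["NOB"]]))
    vd <- config$dnra_rate * f(y[3], 0.005)
    dy <- c(-v[1] - v[2] - v[3],
            v[1] + v[2] + leak * v[3] - v[4],
            (1 - leak) * v[3] + v[4] - vd,
            vd)
    y <- y + h * dy
    t <- t + h
    record(t)
    due <- which(abs(pending$time_h / 24 - t) < step_days / 4)
    for (i in due) {
      j <- if (pending$analyte[i] == "NH4") 1 else 3
      y[j] <- y[j] + pending$amount[i]
    }
    if (length(due)) pending <- pending[-due, , drop = FALSE]
  }
  colnames(out) <- c("NH4", "NO2", "NO3", "DNRA")
  out
}

# Expected copies of a Gaussian band across gradient fractions, computed
# directly from normal-distribution mass (oracle for simulate_gradient).
gaussian_band_oracle <- function(gconfig, mu, total) {
  dens <- gconfig$density_intercept -
    gconfig$density_step * seq_len(gconfig$n_fractions)
  half <- gconfig$density_step / 2
  total * (pnorm(dens + half, mu, gconfig$band_sd) -
             pnorm(dens - half, mu, gconfig$band_sd))
}
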