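test_that("rate fitting recovers an exact line", {
  s <- data.frame(time_h = c(0, 24, 48), no2_mM = 0,
                  no3_mM = c(0, 0.1, 0.2))
  est <- fit_rate(s)
  expect_equal(est$slope, 0.1)
  expect_equal(est$r2, 1)
  expect_equal(est$rate_per_soil, 0.1 * 84)
  expect_equal(est$n_points, 3)
})

test_that("early-lag exclusion isolates the linear phase", {
  # flat for 12 h, then 0.1 mM/day
  t <- c(0, 6, 12, 24, 36, 48)
  y <- c(0, 0, 0, 0.05, 0.1, 0.15)
  s <- data.frame(time_h = t, no2_mM = y, no3_mM = 0)
  est <- fit_rate(s, exclude_before = 12)
  expect_equal(est$slope, 0.1, tolerance = 1e-12)
  expect_equal(est$window, c(12, 48))
  expect_equal(est$n_points, 4)

  # closed-form OLS on the full series for comparison
  full <- fit_rate(s)
  td <- t / 24
  slope_by_hand <- cov(td, y) / var(td)
  expect_equal(full$slope, slope_by_hand)
  expect_lt(full$slope, est$slope)
})

test_that("the estimated slope is invariant to row order", {
  set.seed(1)
  s <- data.frame(time_h = seq(0, 48, 6),
                  no2_mM = runif(9, 0, 0.01),
                  no3_mM = 0.05 + 0.004 * seq(0, 48, 6) + rnorm(9, 0, 0.002))
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(fit_rate(shuffled)$slope, fit_rate(s)$slope)
})

test_that("slope is non-decreasing as the exclusion window grows to the lag", {
  t <- seq(0, 48, 6)
  y <- pmax(0, (t - 12)) * 0.1 / 24  # lag until 12 h, then linear
  s <- data.frame(time_h = t, no2_mM = y, no3_mM = 0)
  slopes <- vapply(c(0, 3, 6, 9, 12), function(eb)
    fit_rate(s, exclude_before = eb)$slope, numeric(1))
  expect_true(all(diff(slopes) >= -1e-12))
  expect_equal(slopes[5], 0.1, tolerance = 1e-12)
})

test_that("fitting fails informatively on degenerate input", {
  s <- data.frame(time_h = c(0, 6), no2_mM = c(0, 0.1), no3_mM = 0)
  expect_error(fit_rate(s, exclude_before = 10), "fewer than 2")
  s2 <- data.frame(time_h = c(6, 6), no2_mM = c(0, 0.1), no3_mM = 0)
  expect_error(fit_rate(s2), "zero variance")
})

test_that("unit conversion follows the microcosm geometry", {
  expect_equal(convert_rate(0.1, 0.030, 0.005), 8.4)
  expect_equal(convert_rate(0), 0)
  # the slope scale behind the study's freshwater total rate
  expect_equal(round(convert_rate(0.0959, 0.030, 0.005), 2), 8.06)
  expect_error(convert_rate(0.1, 0, 0.005), "> 0")
})

test_that("the partition identity holds exactly for any inputs", {
  set.seed(42)
  for (i in 1:25) {
    x <- runif(3, 0, 10)
    p <- suppressWarnings(partition_guilds(x[1], x[2], x[3]))
    expect_identical(p$par_aoa + p$par_aob + p$par_cmx, p$par_total)
  }
  pd <- partition_guilds(5, 5, 5)
  expect_equal(c(pd$par_cmx, pd$par_aob, pd$par_aoa), c(0, 0, 5))
})

test_that("uncertainties on derived guilds propagate as root-sum-of-squares", {
  mk <- function(par, sd, tr) treatment_par(
    structure(list(rate_per_soil = par, rate_se_per_soil = sd),
              class = "rate_estimate"), treatment = tr)
  # single-replicate estimates: SE carries, replicate SD is zero
  p <- partition_guilds(mk(8, 0.4, "I"), mk(3, 0.3, "II"), mk(1, 0.1, "III"))
  expect_equal(p$se_cmx, sqrt(0.4^2 + 0.3^2))
  expect_equal(p$se_aob, sqrt(0.3^2 + 0.1^2))
  expect_equal(p$se_aoa, 0.1)
})

test_that("negative derived rates are flagged, not clipped", {
  expect_warning(p <- partition_guilds(2, 3, 1), "negative")
  expect_equal(p$par_cmx, -1)
})

test_that("contributions are integer percents of the treatment-I rate", {
  p <- partition_guilds(3, 2, 1)
  expect_equal(unname(contributions(p)), c(33, 33, 33))
  expect_error(contributions(partition_guilds(0, 0, 0)), "not positive")
})

test_that("the nitrate-only control detects declining nitrate", {
  flat <- data.frame(treatment = "IV", time_h = seq(0, 48, 12),
                     no2_mM = 0, no3_mM = 0.1)
  r <- check_dnra_control(flat)
  expect_true(r$ok)
  expect_equal(r$no3_slope, 0)

  declining <- data.frame(treatment = "IV", time_h = seq(0, 48, 12),
                          no2_mM = 0,
                          no3_mM = 0.1 - 0.05 * seq(0, 48, 12) / 24)
  expect_false(check_dnra_control(declining)$ok)
  expect_error(check_dnra_control(transform(flat, treatment = "I")),
               "treatment IV")
})

test_that("the control passes under simulator noise in >= 95% of runs", {
  times <- seq(0, 48, 6)
  ok <- vapply(1:200, function(i) {
    cfg <- microcosm_config(meas_sd = 0.002, dnra_rate = 0, seed = i)
    s <- simulate_microcosm(cfg, "IV", 0.06, times)
    check_dnra_control(s)$ok
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("noiseless simulator output yields the summed guild rates", {
  # substrate-replete potential-rate conditions: ample ammonium keeps the
  # Michaelis-Menten factor at ~1 so the slope is the sum of guild rates
  cfg <- quiet_config(init = c(NH4 = 5, NO2 = 0.001, NO3 = 0.05))
  s <- simulate_microcosm(cfg, "I", 0.06, seq(0, 48, 6))
  est <- fit_rate(s)
  expect_equal(est$slope,
               sum(cfg$guild_rates[c("AOA", "AOB", "CMX")]),
               tolerance = 1e-3)
})

test_that("the partition pipeline recovers known guild rates", {
  cfg <- recovery_config(seed = 11L)
  panel <- simulate_treatment_panel(cfg, 0.06, seq(0, 48, 6),
                                    treatments = c("I", "II", "III"))
  p <- estimate_partition(panel)
  tol <- pmax(0.1 * recovery_truth,
              2 * c(cmx = p$se_cmx, aob = p$se_aob, aoa = p$se_aoa))
  got <- c(cmx = p$par_cmx, aob = p$par_aob, aoa = p$par_aoa)
  expect_true(all(abs(got - recovery_truth) <= tol))
})

test_that("mixed salinity labels are rejected", {
  t1 <- treatment_par(structure(list(rate_per_soil = 5,
                                     rate_se_per_soil = 0.1),
                                class = "rate_estimate"), "I", salinity = 0.06)
  t2 <- treatment_par(structure(list(rate_per_soil = 3,
                                     rate_se_per_soil = 0.1),
                                class = "rate_estimate"), "II", salinity = 3)
  expect_error(partition_guilds(t1, t2, 1), "salinity")

  df <- data.frame(treatment = "I", salinity = c(0.06, 3), replicate = 1,
                   time_h = c(0, 24), no2_mM = 0, no3_mM = 0)
  expect_error(estimate_partition(df), "salinity")
})
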