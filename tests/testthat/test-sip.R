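test_that("refractive-index calibration interpolates its standards", {
  std <- data.frame(ri = c(1.3990, 1.4052), density = c(1.690, 1.755))
  cal <- fit_ri_calibration(std)
  expect_equal(ri_to_density(std$ri, cal), std$density, tolerance = 1e-12)
  expect_equal(ri_to_density(1.4021, cal), 1.7225, tolerance = 1e-9)
  # identity calibration passes values through
  expect_equal(ri_to_density(1.72, c(1, 0)), 1.72)
  expect_warning(ri_to_density(1.41, cal), "outside")
  expect_error(fit_ri_calibration(data.frame(ri = 1.4, density = 1.7)),
               "at least 2")
})

test_that("profile normalization divides by the target total", {
  tab <- data.frame(fraction = 1:5, density = seq(1.75, 1.67, -0.02),
                    target = "x", copies = c(0, 10, 30, 10, 0))
  p <- normalize_profile(tab, "x")
  expect_equal(unname(p), c(0, 0.2, 0.6, 0.2, 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # scale invariance
  tab7 <- transform(tab, copies = copies * 7)
  expect_equal(normalize_profile(tab7, "x"), p)
  # delta profile
  tabd <- transform(tab, copies = c(0, 0, 5, 0, 0))
  expect_equal(unname(normalize_profile(tabd, "x")), c(0, 0, 1, 0, 0))
  tab0 <- transform(tab, copies = 0)
  expect_error(normalize_profile(tab0, "x"), "zero total")
  expect_error(normalize_profile(tab, "missing"), "not present")
})

test_that("weighted mean density is the profile-density dot product", {
  expect_equal(weighted_mean_density(rep(1 / 3, 3), c(1.70, 1.71, 1.72)),
               1.71)
  expect_equal(weighted_mean_density(c(0, 0, 1, 0), c(1.7, 1.71, 1.716, 1.72)),
               1.716)
  dens <- fraction_densities(gradient_config())[8:12]
  prof <- c(0, 0.2, 0.6, 0.2, 0)
  by_hand <- 0.2 * dens[2] + 0.6 * dens[3] + 0.2 * dens[4]
  expect_equal(weighted_mean_density(prof, dens), by_hand)
  expect_error(weighted_mean_density(c(0.5, 0.5), 1.7), "length")
})

test_that("identical profiles are never called labeled", {
  g <- gradient_config(noise_cv = 0)
  tab <- simulate_gradient(g, taxon_band("x", gc = 0.45))
  r <- detect_labeling(tab, tab, "x")
  expect_equal(r$delta_wmd, 0)
  expect_false(r$labeled)
})

test_that("a one-fraction heavy shift at the printed densities is labeled", {
  g <- gradient_config(noise_cv = 0)
  t12 <- simulate_gradient(g, taxon_band("CMX", gc = 0.485))
  t13 <- simulate_gradient(
    g, taxon_band("CMX", gc = 0.485, atom13c_excess = 0.236),
    isotope = "13C")
  r <- detect_labeling(t12, t13, "CMX")
  expect_true(r$labeled)
  expect_equal(c(r$peak_12c, r$peak_13c), c(10, 9))
  expect_equal(r$wmd_13c - r$wmd_12c, 0.036 * 0.236, tolerance = 2e-4)
})

test_that("noiseless WMD shift equals 0.036 x atom excess", {
  g <- gradient_config(noise_cv = 0)
  t12 <- simulate_gradient(g, taxon_band("x", gc = 0.45))
  for (ex in c(0.1, 0.25, 0.5)) {
    t13 <- simulate_gradient(g, taxon_band("x", gc = 0.45,
                                           atom13c_excess = ex),
                             isotope = "13C")
    r <- detect_labeling(t12, t13, "x")
    expect_equal(r$delta_wmd, 0.036 * ex, tolerance = 0.002)
  }
})

test_that("WMD increases monotonically with the atom excess", {
  g <- gradient_config(noise_cv = 0)
  t12 <- simulate_gradient(g, taxon_band("x", gc = 0.40))
  wmds <- vapply(seq(0, 0.6, 0.1), function(ex) {
    t13 <- simulate_gradient(g, taxon_band("x", gc = 0.40,
                                           atom13c_excess = ex),
                             isotope = "13C")
    detect_labeling(t12, t13, "x")$wmd_13c
  }, numeric(1))
  expect_true(all(diff(wmds) > 0))
})

test_that("labeling calls are invariant to uniform copy scaling", {
  g <- gradient_config(noise_cv = 0.1, seed = 3L)
  t12 <- simulate_gradient(g, taxon_band("x", gc = 0.45))
  t13 <- simulate_gradient(g, taxon_band("x", gc = 0.45,
                                         atom13c_excess = 0.4),
                           isotope = "13C")
  r1 <- detect_labeling(t12, t13, "x")
  t12$copies <- t12$copies * 1e3
  t13$copies <- t13$copies * 1e3
  r2 <- detect_labeling(t12, t13, "x")
  expect_equal(r1$labeled, r2$labeled)
  expect_equal(r1$delta_wmd, r2$delta_wmd)
})

test_that("classification is reliable on noisy gradients", {
  calls <- vapply(1:100, function(i) {
    g <- gradient_config(band_sd = 0.006, noise_cv = 0.1, seed = i)
    t12 <- simulate_gradient(g, taxon_band("x", gc = 0.485))
    unl <- simulate_gradient(g, taxon_band("x", gc = 0.485,
                                           atom13c_excess = 0),
                             isotope = "13C", replicate = 2L)
    lab <- simulate_gradient(g, taxon_band("x", gc = 0.485,
                                           atom13c_excess = 0.5),
                             isotope = "13C", replicate = 3L)
    c(unlabeled_ok = !detect_labeling(t12, unl, "x")$labeled,
      labeled_ok = detect_labeling(t12, lab, "x")$labeled)
  }, logical(2))
  expect_gte(mean(calls["unlabeled_ok", ]), 0.95)
  expect_gte(mean(calls["labeled_ok", ]), 0.95)
})

test_that("mismatched fraction grids are rejected", {
  g <- gradient_config(noise_cv = 0)
  g2 <- gradient_config(n_fractions = 14, noise_cv = 0)
  t12 <- simulate_gradient(g, taxon_band("x", gc = 0.45))
  t13 <- simulate_gradient(g2, taxon_band("x", gc = 0.45), isotope = "13C")
  expect_error(detect_labeling(t12, t13, "x"), "different fraction grids")
})
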