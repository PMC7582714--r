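mm_points <- function(kcat, km, E0, S) E0 * kcat * S / (km + S)

test_that("double-reciprocal regression inverts noiseless kinetics exactly", {
  S <- c(5, 10, 15, 20, 25)
  v <- mm_points(1, 20, 2, S)
  fit <- double_reciprocal_fit(S, v, 2)
  expect_equal(fit$kcat, 1, tolerance = 1e-9)
  expect_equal(fit$km, 20, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$nonphysical)
})

test_that("two points give the closed-form line through both", {
  # hand algebra: y = E0/v, x = 1/S; slope = (y2-y1)/(x2-x1),
  # intercept = y1 - slope x1
  S <- c(5, 25); v <- c(0.9, 2.5); E0 <- 2
  x <- 1 / S; y <- E0 / v
  slope <- (y[2] - y[1]) / (x[2] - x[1])
  intercept <- y[1] - slope * x[1]
  fit <- double_reciprocal_fit(S, v, E0)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$kcat, 1 / intercept, tolerance = 1e-12)
  expect_equal(fit$km, slope / intercept, tolerance = 1e-12)
  expect_identical(fit$r_squared, 1)
})

test_that("degenerate double-reciprocal input is rejected or flagged", {
  expect_error(double_reciprocal_fit(c(5, 5, 5), mm_points(1, 20, 2, c(5, 5, 5)), 2),
               "distinct")
  expect_message(fit <- double_reciprocal_fit(c(5, 10, 15), c(0.5, 0, 0.9), 2),
                 "rejected")
  # decreasing velocity with substrate: negative slope/intercept flagged
  expect_message(fit2 <- double_reciprocal_fit(c(5, 10, 20), c(2, 1, 0.4), 2),
                 "non-physical")
  expect_true(fit2$nonphysical)
})

test_that("nonlinear Michaelis-Menten fit cross-checks the linear estimates", {
  S <- c(5, 10, 15, 20, 25)
  v <- mm_points(0.8, 35, 2, S)
  mm <- michaelis_menten_fit(S, v, 2)
  lb <- double_reciprocal_fit(S, v, 2)
  expect_equal(mm$kcat, 0.8, tolerance = 1e-7)
  expect_equal(mm$km, 35, tolerance = 1e-7)
  expect_equal(mm$kcat, lb$kcat, tolerance = 1e-6)
  expect_equal(mm$km, lb$km, tolerance = 1e-6)
  expect_true(mm$converged)
  # heteroscedastic noise: the two estimators genuinely differ, the
  # nonlinear one is the cross-check of record
  set.seed(42)
  vn <- v * (1 + stats::rnorm(5, 0, 0.05))
  mmn <- michaelis_menten_fit(S, vn, 2)
  lbn <- double_reciprocal_fit(S, vn, 2)
  expect_gt(abs(mmn$kcat - lbn$kcat), 1e-8)
  expect_equal(mmn$kcat, 0.8, tolerance = 0.5)
  expect_equal(lbn$kcat, 0.8, tolerance = 0.5)
})

test_that("linearity partition separates the double-reciprocal range", {
  sc <- fixture_scheme("H20S_LIKE")
  # clean Michaelis-Menten data spanning 5-100: linear everywhere, no flag
  d0 <- generate_dataset(sc, noise = noise_options(cv = 0))
  g <- d0[d0$modulator_uM == 1 & d0$replicate == 1, ]
  lp0 <- linearity_partition(g$substrate_uM, g$velocity_nM_per_s, 2)
  expect_false(lp0$flag)
  expect_gt(lp0$r2_full, 0.98)
  # all points already below the cutoff: nothing excluded
  gl <- g[g$substrate_uM <= 25, ]
  lp1 <- linearity_partition(gl$substrate_uM, gl$velocity_nM_per_s, 2)
  expect_false(lp1$flag)
  expect_identical(nrow(lp1$excluded), 0L)
  # substrate-inhibited data spanning 5-100 in the modulator-activated
  # regime: linearity lost on the full range, kept at or below 25 uM
  dsi <- generate_dataset(sc, noise = noise_options(
    cv = 0, substrate_inhibition_Ksi = 100))
  gs <- dsi[dsi$modulator_uM == 1 & dsi$replicate == 1, ]
  lp2 <- linearity_partition(gs$substrate_uM, gs$velocity_nM_per_s, 2)
  expect_true(lp2$flag)
  expect_lt(lp2$r2_full, 0.98)
  expect_gte(lp2$r2_retained, 0.98)
  expect_setequal(lp2$excluded$substrate_uM, c(50, 100))
  expect_error(linearity_partition(gs$substrate_uM, gs$velocity_nM_per_s, 2,
                                   S_cut = 1))
})

test_that("catalytic profile is a forward-inverse round trip on clean data", {
  sc <- fixture_scheme("H20S_LIKE")
  # single modulator concentration
  d1 <- generate_dataset(sc, assay_design(modulator_uM = 3),
                         noise = noise_options(cv = 0))
  p1 <- catalytic_profile(d1)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$kcat_obs_per_s, observed_kcat(sc, 3), tolerance = 1e-9)
  expect_equal(p1$km_obs_uM, observed_km(sc, 3), tolerance = 1e-9)
  expect_equal(p1$eff_obs, p1$kcat_obs_per_s / p1$km_obs_uM,
               tolerance = 1e-12)
  # replicate averaging is idempotent on identical replicates
  d3 <- generate_dataset(sc, assay_design(replicates = 3),
                         noise = noise_options(cv = 0))
  dA <- generate_dataset(sc, assay_design(replicates = 1),
                         noise = noise_options(cv = 0))
  p3 <- catalytic_profile(d3)
  pA <- catalytic_profile(dA)
  expect_equal(p3$kcat_obs_per_s, pA$kcat_obs_per_s, tolerance = 1e-12)
  expect_equal(p3$km_obs_uM, pA$km_obs_uM, tolerance = 1e-12)
  expect_identical(p3$n_replicates, rep(3L, 9))
  # full noiseless design recovers the forward curves at every level
  for (nm in fixture_names) {
    s <- fixture_scheme(nm)
    p <- catalytic_profile(generate_dataset(s, noise = noise_options(cv = 0)))
    expect_equal(p$kcat_obs_per_s, observed_kcat(s, p$modulator_uM),
                 tolerance = 1e-6)
    expect_equal(p$km_obs_uM, observed_km(s, p$modulator_uM),
                 tolerance = 1e-6)
    expect_equal(p$r_squared, rep(1, nrow(p)), tolerance = 1e-9)
  }
})

test_that("noisy profiles stay within their propagated uncertainties", {
  sc <- fixture_scheme("H20S_LIKE")
  d <- generate_dataset(sc, noise = noise_options(cv = 0.05, seed = 421))
  p <- suppressMessages(catalytic_profile(d))
  truth_k <- observed_kcat(sc, p$modulator_uM)
  truth_m <- observed_km(sc, p$modulator_uM)
  # typical standardized errors are O(1) when the delta-method propagation
  # is right (they would be tens if a factor were dropped); the hard cap is
  # generous because 1/v noise makes the ratio estimators heavy-tailed
  z_k <- abs(p$kcat_obs_per_s - truth_k) / p$kcat_se_per_s
  z_m <- abs(p$km_obs_uM - truth_m) / p$km_se_uM
  expect_lt(stats::median(z_k), 3)
  expect_lt(stats::median(z_m), 3)
  expect_lt(max(z_k, z_m), 15)
  expect_true(all(p$kcat_se_per_s > 0))
})
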