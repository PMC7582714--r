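test_that("goodness of fit follows the total-sum-of-squares definition", {
  g1 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_identical(g1$r_squared, 1)
  expect_identical(g1$rss, 0)
  obs <- c(2, 4, 9)
  g2 <- goodness_of_fit(obs, rep(mean(obs), 3))
  expect_equal(g2$r_squared, 0)
  expect_equal(g2$rss, sum((obs - mean(obs))^2))
  g3 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g3$rss, 1)
  expect_equal(g3$r_squared, 0.5)
  # zero total sum of squares: undefined r-squared sentinel
  g4 <- goodness_of_fit(c(2, 2, 2), c(2, 2, 1))
  expect_true(is.na(g4$r_squared))
  expect_error(goodness_of_fit(1, c(1, 2)))
})

test_that("turnover stage recovers its parameters from noiseless profiles", {
  for (nm in c("H20S_LIKE", "Y20S_LIKE")) {
    sc <- fixture_scheme(nm)
    prof <- forward_profile(sc, test_L_grid)
    s1 <- fit_turnover_stage(prof, sc$n)
    truth <- unlist(sc[c("kcat_A", "kcat_B", "K_AL", "K_BL", "L_L")])
    expect_lt(max(abs(s1$parameters - truth) / truth), 1e-2)
    expect_false(s1$degenerate)
    expect_equal(s1$r_squared, 1, tolerance = 1e-9)
  }
  # a profile flat in modulator concentration is degenerate for this stage
  flat <- forward_profile(
    two_state_scheme(kcat_A = 0.7, kcat_B = 0.7, km_0 = 60, km_B = 10,
                     K_AU = 0.01, K_BU = 40, K_AL = 0.005, K_BL = 53,
                     L_U = 3.1e-6, L_L = 4e-5, n = 3L), test_L_grid)
  s1f <- fit_turnover_stage(flat, 3)
  expect_true(s1f$degenerate)
  expect_equal(unname(s1f$parameters["kcat_A"]), 0.7, tolerance = 1e-9)
  expect_identical(s1f$parameters[["kcat_A"]], s1f$parameters[["kcat_B"]])
  expect_error(fit_turnover_stage(forward_profile(fixture_scheme("H20S_LIKE"),
                                                  c(0.5, 1, 3)), 3),
               "five distinct")
})

test_that("affinity stage recovers unbound-state parameters with stage 1 frozen", {
  sc <- fixture_scheme("H20S_LIKE")
  prof <- forward_profile(sc, test_L_grid)
  s1 <- fit_turnover_stage(prof, 3)
  s2 <- fit_affinity_stage(prof, s1, 3, 0)
  truth <- unlist(sc[c("km_0", "K_AU", "K_BU", "L_U")])
  est <- unlist(s2$parameters[names(truth)])
  expect_lt(max(abs(est - truth) / truth), 2e-2)
  expect_match(unname(s2$status["K_BI"]), "fixed")
  # inhibitory constant of the yeast-like scheme
  sy <- fixture_scheme("Y20S_LIKE")
  profy <- forward_profile(sy, test_L_grid)
  s1y <- fit_turnover_stage(profy, 2)
  s2y <- fit_affinity_stage(profy, s1y, 2, 1)
  expect_lt(abs(s2y$parameters[["K_BI"]] - sy$K_BI) / sy$K_BI, 2e-2)
  expect_match(unname(s2y$status["K_BU"]), "linkage")
})

test_that("a substrate-symmetric scheme gives equal stage-1 and stage-2 constants", {
  sym <- two_state_scheme(kcat_A = 1, kcat_B = 0.5, km_0 = 60, km_B = 10,
                          K_AU = 0.005, K_BU = 53, K_AL = 0.005, K_BL = 53,
                          L_U = 4e-5, L_L = 4e-5, n = 3L)
  prof <- forward_profile(sym, test_L_grid)
  s1 <- fit_turnover_stage(prof, 3)
  s2 <- fit_affinity_stage(prof, s1, 3, 0)
  expect_equal(s2$parameters[["K_AU"]], s1$parameters[["K_AL"]],
               tolerance = 1e-3)
  expect_equal(s2$parameters[["K_BU"]], s1$parameters[["K_BL"]],
               tolerance = 1e-3)
  expect_equal(s2$parameters[["L_U"]], s1$parameters[["L_L"]],
               tolerance = 1e-3)
})

test_that("minimal-structure selection returns the generating site numbers", {
  # human-like: three concerted sites, no inhibitory site
  selH <- select_site_numbers(forward_profile(fixture_scheme("H20S_LIKE"),
                                              test_L_grid))
  expect_identical(c(selH$n, selH$m), c(3L, 0L))
  # yeast-like: two concerted sites plus one competitive site
  selY <- select_site_numbers(forward_profile(fixture_scheme("Y20S_LIKE"),
                                              test_L_grid))
  expect_identical(c(selY$n, selY$m), c(2L, 1L))
  # non-cooperative single-site scheme
  s1 <- two_state_scheme(kcat_A = 1, kcat_B = 0.4, km_0 = 50, km_B = 15,
                         K_AU = 0.05, K_BU = 8, K_AL = 0.03, K_BL = 5,
                         L_U = 0.02, L_L = 0.05, n = 1L)
  sel1 <- select_site_numbers(forward_profile(s1, test_L_grid))
  expect_identical(c(sel1$n, sel1$m), c(1L, 0L))
  # monotone RSS: the generating structure never loses to smaller n
  tab <- selH$table
  rss_gen <- tab$rss_total[tab$n == 3 & tab$m == 0]
  expect_true(all(rss_gen <= tab$rss_total[tab$n < 3]))
  # the small-sample information criterion agrees on noiseless profiles
  selH_a <- select_site_numbers(forward_profile(fixture_scheme("H20S_LIKE"),
                                                test_L_grid),
                                criterion = "aicc")
  expect_identical(c(selH_a$n, selH_a$m), c(3L, 0L))
  expect_error(select_site_numbers(forward_profile(s1, test_L_grid),
                                   n_candidates = integer(0)))
})

test_that("stage-1 parameters pass through the full fit bit-identically", {
  prof <- forward_profile(fixture_scheme("H20S_LIKE"), test_L_grid)
  fit <- fit_modulation(prof, n = 3, m = 0)
  expect_identical(fit$scheme$kcat_A, fit$turnover$parameters[["kcat_A"]])
  expect_identical(fit$scheme$kcat_B, fit$turnover$parameters[["kcat_B"]])
  expect_identical(fit$scheme$K_AL, fit$turnover$parameters[["K_AL"]])
  expect_identical(fit$scheme$K_BL, fit$turnover$parameters[["K_BL"]])
  expect_identical(fit$scheme$L_L, fit$turnover$parameters[["L_L"]])
})

test_that("the fitted-model object supports the standard methods", {
  sc <- fixture_scheme("H20S_LIKE")
  prof <- forward_profile(sc, test_L_grid)
  fit <- fit_modulation(prof, n = 3, m = 0)
  out <- capture.output(print(fit))
  expect_true(any(grepl("n = 3 activating", out)))
  outs <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Parameter status", outs)))
  cf <- coef(fit)
  expect_true(all(c("kcat_A", "L_U", "n") %in% names(cf)))
  expect_equal(unname(cf["n"]), 3)
  # predictions reproduce the forward curves of the fitted scheme
  Lg <- c(0, 0.7, 4)
  expect_equal(predict(fit, Lg, what = "kcat"),
               observed_kcat(fit$scheme, Lg), tolerance = 1e-12)
  eb <- predict(fit, Lg, what = "efficiency_both")
  expect_identical(names(eb), c("modulator_uM", "eff_ratio", "eff_direct"))
  expect_equal(predict(fit, Lg, what = "velocity", substrate_uM = 10,
                       enzyme_nM = 2),
               velocity(fit$scheme, 2, 10, Lg), tolerance = 1e-12)
  # residuals are near zero on the noiseless profile
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_identical(length(residuals(fit, "turnover")), 9L)
  # plotting runs silently on a null device
  grDevices::pdf(NULL)
  expect_silent(plot(fit))
  grDevices::dev.off()
  # simulate() round-trips through the generator
  d <- simulate(fit, design = assay_design(replicates = 1), cv = 0)
  expect_s3_class(d, "velocity_dataset")
  expect_equal(d$velocity_nM_per_s[1],
               velocity(fit$scheme, 2, d$substrate_uM[1], d$modulator_uM[1]),
               tolerance = 1e-12)
})

test_that("residual bootstrap intervals are reproducible and tight when exact", {
  prof <- forward_profile(fixture_scheme("H20S_LIKE"), test_L_grid)
  fit <- fit_modulation(prof, n = 3, m = 0)
  ci1 <- bootstrap_confidence(fit, n_boot = 100, seed = 7)
  ci2 <- bootstrap_confidence(fit, n_boot = 100, seed = 7)
  expect_identical(ci1, ci2)
  # degenerate residuals of a noiseless profile give negligible widths;
  # weakly identified binding constants amplify the ~1e-9 residual jitter
  # by their inverse sensitivity, so their envelope is looser
  width <- (ci1$upper - ci1$lower) / abs(ci1$estimate)
  expect_true(all(width < 1e-4))
  expect_lt(width[ci1$parameter == "kcat_A"], 1e-6)
  expect_lt(width[ci1$parameter == "kcat_B"], 1e-6)
  expect_true(all(c("kcat_A", "L_U") %in% ci1$parameter))
  expect_error(bootstrap_confidence(fit, n_boot = 50, seed = 1), "100")
})
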