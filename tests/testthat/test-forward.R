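test_that("binding polynomial equals the binomial microstate sum", {
  expect_identical(binding_polynomial(0.5, 0, 3), 1)
  expect_identical(binding_polynomial(1, 2, 3), 27)
  expect_equal(binding_polynomial(0.02, 5, 2), 1.21, tolerance = 1e-12)
  # equivalence with the explicit occupancy expansion
  for (K in c(0, 0.3, 7)) for (s in 0:4) {
    cc <- c(0, 0.05, 1, 12)
    expect_equal(binding_polynomial(K, cc, s), oracle_binom_sum(K, cc, s),
                 tolerance = 1e-12)
  }
  expect_error(binding_polynomial(-1, 1, 2))
  expect_error(binding_polynomial(1, -1, 2))
  expect_error(binding_polynomial(1, 1, -2))
})

test_that("state populations conserve mass and match the enumeration oracle", {
  sc <- fixture_scheme("H20S_LIKE")
  # symmetric allosteric constant: equal populations at zero modulator
  sym <- two_state_scheme(kcat_A = 1, kcat_B = 0.5, km_0 = 60, km_B = 10,
                          K_AU = 0.01, K_BU = 40, K_AL = 0.005, K_BL = 53,
                          L_U = 1, L_L = 1, n = 3L)
  p0 <- state_populations(sym, 0, "substrate_bound")
  expect_equal(c(p0$f_A, p0$f_B), c(0.5, 0.5), tolerance = 1e-12)
  # vanishing L_U: state B inaccessible for the unbound enzyme
  tiny <- two_state_scheme(kcat_A = 1, kcat_B = 0.5, km_0 = 60, km_B = 10,
                           K_AU = 0.01, K_BU = 40, K_AL = 0.005, K_BL = 53,
                           L_U = 1e-300, L_L = 4e-5, n = 3L)
  pU <- state_populations(tiny, c(0, 1, 10), "unbound")
  expect_equal(pU$f_A, rep(1, 3), tolerance = 1e-12)
  # conservation and oracle agreement across fixtures, forms and a wide grid
  Lwide <- c(test_L_grid, 50, 1000)
  for (nm in fixture_names) {
    s <- fixture_scheme(nm)
    for (form in c("unbound", "substrate_bound")) {
      p <- state_populations(s, Lwide, form)
      expect_equal(p$f_A + p$f_B, rep(1, length(Lwide)), tolerance = 1e-12)
      o <- oracle_populations(s, Lwide,
                              if (form == "unbound") "unbound" else "bound")
      expect_equal(p$f_B, unname(o[, "f_B"]), tolerance = 1e-10)
    }
  }
})

test_that("observed kcat is the bounded population-weighted turnover", {
  sc <- fixture_scheme("H20S_LIKE")
  # identical state turnovers: flat curve
  flat <- two_state_scheme(kcat_A = 0.7, kcat_B = 0.7, km_0 = 60, km_B = 10,
                           K_AU = 0.01, K_BU = 40, K_AL = 0.005, K_BL = 53,
                           L_U = 3.1e-6, L_L = 4e-5, n = 3L)
  expect_equal(observed_kcat(flat, test_L_grid), rep(0.7, 9),
               tolerance = 1e-12)
  # zero-modulator limit by direct arithmetic
  expect_equal(observed_kcat(sc, 0),
               (sc$kcat_A + sc$L_L * sc$kcat_B) / (1 + sc$L_L),
               tolerance = 1e-14)
  expect_equal(observed_kcat(sc, 0), 0.99998, tolerance = 1e-5)
  # boundedness for all fixtures over a wide grid
  Lwide <- c(test_L_grid, 100, 1000)
  for (nm in fixture_names) {
    s <- fixture_scheme(nm)
    kc <- observed_kcat(s, Lwide)
    expect_true(all(kc >= min(s$kcat_A, s$kcat_B) - 1e-12))
    expect_true(all(kc <= max(s$kcat_A, s$kcat_B) + 1e-12))
  }
})

test_that("observed Km limits, constancy case and competitive signature", {
  sc <- fixture_scheme("H20S_LIKE")
  expect_equal(observed_km(sc, 0),
               sc$km_0 * (1 + sc$L_U) / (1 + sc$L_L), tolerance = 1e-14)
  expect_equal(observed_km(sc, 0), 59.9978, tolerance = 1e-4)
  # all four modulator constants equal, m = 0: weights cancel at every L
  eqK <- two_state_scheme(kcat_A = 1, kcat_B = 0.5, km_0 = 60, km_B = 10,
                          K_AU = 2, K_BU = 2, K_AL = 2, K_BL = 2,
                          L_U = 0.3, L_L = 0.02, n = 2L)
  expect_equal(observed_km(eqK, test_L_grid),
               rep(60 * 1.3 / 1.02, 9), tolerance = 1e-12)
  # m = 0: finite high-modulator limit km_0 L_U K_BU^n / (L_L K_BL^n)
  lim <- sc$km_0 * sc$L_U * sc$K_BU^sc$n / (sc$L_L * sc$K_BL^sc$n)
  expect_equal(observed_km(sc, 1e8), lim, tolerance = 1e-4)
  # m >= 1: eventually increasing and unbounded
  sy <- fixture_scheme("Y20S_LIKE")
  km_hi <- observed_km(sy, c(10, 100, 1000, 1e4))
  expect_true(all(diff(km_hi) > 0))
  expect_gt(km_hi[4], 100 * observed_km(sy, 0))
})

test_that("observed efficiency matches its printed form and limits", {
  # equal state efficiencies: constant at exp(1)
  eqE <- two_state_scheme(kcat_A = exp(1) * 50, kcat_B = exp(1) * 10,
                          km_0 = 50, km_A = 50, km_B = 10,
                          K_AU = 0.01, K_BU = 40, K_AL = 0.005, K_BL = 53,
                          L_U = 0.37, L_L = 4e-5, n = 3L)
  expect_equal(observed_efficiency(eqE, c(0, 1, 7)), rep(exp(1), 3),
               tolerance = 1e-12)
  # zero-modulator value
  sc <- fixture_scheme("H20S_LIKE")
  expect_equal(observed_efficiency(sc, 0),
               (sc$kcat_A / sc$km_A + sc$L_U * sc$kcat_B / sc$km_B) /
                 (1 + sc$L_U), tolerance = 1e-14)
  # m = 0 saturating limit; the residual A population at saturation is
  # (K_AU/K_BU)^n / L_U ~ 5e-6 for this fixture, bounding the approach
  expect_equal(observed_efficiency(sc, 1e6), sc$kcat_B / sc$km_B,
               tolerance = 1e-5)
})

test_that("forward equations agree with the enumeration oracle to 1e-10", {
  for (nm in fixture_names) {
    s <- fixture_scheme(nm)
    L <- test_L_grid
    expect_equal(observed_kcat(s, L), oracle_kcat(s, L), tolerance = 1e-10)
    expect_equal(observed_km(s, L), oracle_km(s, L), tolerance = 1e-10)
    expect_equal(observed_efficiency(s, L), oracle_efficiency(s, L),
                 tolerance = 1e-10)
  }
})

test_that("cooperativity of the population shift is capped by the site count", {
  Lg <- 10^seq(-3, 3, length.out = 400)
  for (nm in fixture_names) {
    s <- fixture_scheme(nm)
    for (form in c("substrate_bound", "unbound")) {
      p <- state_populations(s, Lg, form)
      slope <- diff(log(p$f_B / p$f_A)) / diff(log(Lg))
      cap <- if (form == "substrate_bound") s$n else s$n + s$m
      expect_lt(max(slope), cap + 1e-6)
    }
  }
})

test_that("the two specificity representations coincide only in degenerate schemes", {
  Lg <- c(0.1, 0.3, 1, 3, 10)
  # fully symmetric scheme: the algebra collapses
  sym <- two_state_scheme(kcat_A = 1, kcat_B = 0.5,
                          km_0 = 60, km_A = 60, km_B = 60,
                          K_AU = 0.01, K_BU = 40, K_AL = 0.01, K_BL = 40,
                          L_U = 4e-5, L_L = 4e-5, n = 3L)
  expect_lt(efficiency_consistency(sym, Lg), 1e-12)
  # effectively single-state scheme (state B unreachable), km_A = km_0,
  # equal modulator affinities of the A states
  one <- two_state_scheme(kcat_A = 1, kcat_B = 0.5, km_0 = 60, km_B = 10,
                          K_AU = 0.01, K_BU = 40, K_AL = 0.01, K_BL = 53,
                          L_U = 1e-300, L_L = 1e-300, n = 3L)
  expect_lt(efficiency_consistency(one, Lg), 1e-12)
  # anchored fixture: strictly positive gap, reported with every fit
  expect_gt(efficiency_consistency(fixture_scheme("H20S_LIKE"), Lg), 0.1)
  expect_error(efficiency_consistency(fixture_scheme("H20S_LIKE"),
                                      numeric(0)))
})

test_that("velocity obeys the Michaelis-Menten structure of the scheme", {
  sc <- fixture_scheme("H20S_LIKE")
  for (L in c(0, 0.5, 3)) {
    km <- observed_km(sc, L)
    kc <- observed_kcat(sc, L)
    # half-saturation
    expect_equal(velocity(sc, 2, km, L), 2 * kc / 2, tolerance = 1e-12)
    # saturation
    expect_equal(velocity(sc, 2, 1e9 * km, L), 2 * kc, tolerance = 1e-8)
    # zero substrate
    expect_identical(velocity(sc, 2, 0, L), 0)
  }
  # composition of the audited sub-results
  expect_equal(velocity(sc, 2, 10, 0),
               2 * observed_kcat(sc, 0) * 10 / (observed_km(sc, 0) + 10),
               tolerance = 1e-14)
})

test_that("ic50 finds the half-velocity point or reports not-found", {
  # all-B competitive degenerate scheme (the A weight is negligible):
  # closed form 1/K_BI when S << Km
  allB <- two_state_scheme(kcat_A = 1, kcat_B = 1, km_0 = 50, km_B = 50,
                           K_AU = 0, K_BU = 0, K_AL = 0, K_BL = 0,
                           K_BI = 2, L_U = 1e9, L_L = 1e9, n = 1L, m = 1L)
  r <- ic50(allB, 2, S = 0.001 * 50, L_max = 10)
  expect_true(r$found)
  expect_equal(r$ic50, 0.5, tolerance = 1e-2)
  # pure activator at 10 uM substrate: velocity never halves
  r2 <- ic50(fixture_scheme("H20S_LIKE"), 2, S = 10, L_max = 10)
  expect_false(r2$found)
  expect_true(is.na(r2$ic50))
  # yeast-like scheme at 25 uM substrate versus dense-grid brute force
  sy <- fixture_scheme("Y20S_LIKE")
  r3 <- ic50(sy, 2, S = 25, L_max = 20)
  expect_true(r3$found)
  grid <- seq(0, 20, by = 1e-3)
  ratio <- velocity(sy, 2, 25, grid) / velocity(sy, 2, 25, 0)
  brute <- grid[which(diff(sign(ratio - 0.5)) != 0)[1]]
  expect_equal(r3$ic50, brute, tolerance = 2e-3)
})
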