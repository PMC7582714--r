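# Independent enumeration oracle: every (1 + K c)^sites factor of the
# observed-parameter equations is replaced by the explicit sum over
# occupancy microstates with binomial weights. The oracle shares no code
# with the package's forward model.

oracle_binom_sum <- function(K, c, sites) {
  vapply(c, function(x) {
    i <- 0:sites
    sum(choose(sites, i) * (K * x)^i)
  }, 0)
}

oracle_weights <- function(s, L, form) {
  if (form == "unbound") {
    list(A = oracle_binom_sum(s$K_AU, L, s$n),
         B = s$L_U * oracle_binom_sum(s$K_BI, L, s$m) *
           oracle_binom_sum(s$K_BU, L, s$n))
  } else {
    list(A = oracle_binom_sum(s$K_AL, L, s$n),
         B = s$L_L * oracle_binom_sum(s$K_BL, L, s$n))
  }
}

oracle_kcat <- function(s, L) {
  w <- oracle_weights(s, L, "bound")
  (s$kcat_A * w$A + s$kcat_B * w$B) / (w$A + w$B)
}

oracle_km <- function(s, L) {
  u <- oracle_weights(s, L, "unbound")
  w <- oracle_weights(s, L, "bound")
  s$km_0 * (u$A + u$B) / (w$A + w$B)
}

oracle_efficiency <- function(s, L) {
  u <- oracle_weights(s, L, "unbound")
  (s$kcat_A / s$km_A * u$A + s$kcat_B / s$km_B * u$B) / (u$A + u$B)
}

oracle_populations <- function(s, L, form) {
  w <- oracle_weights(s, L, form)
  cbind(f_A = w$A / (w$A + w$B), f_B = w$B / (w$A + w$B))
}

# Shared study conditions
test_L_grid <- c(0, 0.1, 0.3, 0.5, 1, 2, 3, 5, 10)
fixture_names <- c("H20S_LIKE", "Y20S_LIKE", "A3DN_LIKE")

# Wild-type constants carried over for the gate-disrupted-mutant workflow
wt_binding_constants <- function() {
  as.list(unlist(fixture_scheme("Y20S_LIKE")[
    c("K_AU", "K_BU", "K_AL", "K_BL", "K_BI")]))
}
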