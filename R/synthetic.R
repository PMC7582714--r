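#' Assay design for synthetic velocity datasets
#'
#' Describes the fluorogenic-substrate assay layout emulated by the
#' generator: 2 nM enzyme pre-incubated with modulator at 0 and 0.1--10
#' micromolar, substrate between 5 and 100 micromolar, at least three
#' replicates per point, 37 degrees C. Substrate levels above the 25
#' micromolar linearity cutoff are part of the default plate (they exist so
#' substrate-linked loss of linearity can be demonstrated) but are excluded
#' from double-reciprocal fitting downstream by \code{S_cut}.
#'
#' @param enzyme_nM Enzyme concentration (nanomolar), default 2.
#' @param substrate_uM Substrate grid (micromolar), default
#'   \code{c(5, 10, 15, 20, 25, 50, 100)}.
#' @param modulator_uM Modulator grid (micromolar), default
#'   \code{c(0, 0.1, 0.3, 0.5, 1, 2, 3, 5, 10)}.
#' @param replicates Replicates per (substrate, modulator) cell, default 3.
#' @param temperature_K Assay temperature, default 310.15 K.
#' @return A list of class \code{"assay_design"}.
#' @export
assay_design <- function(enzyme_nM = 2,
                         substrate_uM = c(5, 10, 15, 20, 25, 50, 100),
                         modulator_uM = c(0, 0.1, 0.3, 0.5, 1, 2, 3, 5, 10),
                         replicates = 3L, temperature_K = 310.15) {
  if (enzyme_nM <= 0) stop("'enzyme_nM' must be positive")
  if (any(substrate_uM <= 0)) stop("substrate grid must be strictly positive")
  if (any(modulator_uM < 0)) stop("modulator grid must be non-negative")
  if (replicates < 1L) stop("'replicates' must be at least 1")
  structure(list(enzyme_nM = enzyme_nM,
                 substrate_uM = sort(unique(substrate_uM)),
                 modulator_uM = sort(unique(modulator_uM)),
                 replicates = as.integer(replicates),
                 temperature_K = temperature_K),
            class = "assay_design")
}

#' Default assay design
#'
#' @return The default [assay_design()].
#' @export
default_design <- function() assay_design()

#' Noise options for the synthetic-assay generator
#'
#' Multiplicative Gaussian velocity noise with optional phenomenological
#' substrate inhibition. The noise model (and the uncompetitive substrate-
#' inhibition term) are generator conveniences, not part of the allosteric
#' scheme: the inhibition term exists so that loss of double-reciprocal
#' linearity above the substrate cutoff can be produced and diagnosed.
#'
#' @param cv Relative coefficient of variation of the velocity (default
#'   0.05); \code{cv = 0} gives noiseless data.
#' @param seed Integer seed; required whenever \code{cv > 0}.
#' @param substrate_inhibition_Ksi Substrate-inhibition constant
#'   (micromolar); \code{NULL} (default) disables the term.
#' @return A list of class \code{"noise_options"}.
#' @export
noise_options <- function(cv = 0.05, seed = NULL,
                          substrate_inhibition_Ksi = NULL) {
  if (cv < 0) stop("'cv' must be non-negative")
  if (!is.null(substrate_inhibition_Ksi) && substrate_inhibition_Ksi <= 0)
    stop("'substrate_inhibition_Ksi' must be positive when given")
  structure(list(cv = cv, seed = seed,
                 substrate_inhibition_Ksi = substrate_inhibition_Ksi),
            class = "noise_options")
}

#' Anchored fixture schemes
#'
#' Three ready-made parameter sets used throughout the package's validation
#' studies. Their thermodynamic anchors are fixed by the free-energy values
#' the two-state analysis of 20S proteasome modulation reports: for the
#' human-like enzyme, an A-to-B gap of 32.7 kJ/mol substrate-free and 26.1
#' kJ/mol substrate-bound, a 4000-fold B/A affinity ratio for the
#' substrate-free enzyme and a 23.9 kJ/mol per-step contribution for the
#' substrate-bound one, with n = 3 concerted sites and no inhibitory site;
#' for the yeast-like enzyme n = 2 and one competitive inhibitory site
#' (K_BI = 2 per micromolar); for the gate-disrupted mutant a collapsed
#' 8.3 kJ/mol substrate-free gap with equal state turnover rates and
#' Michaelis constants above wild type. All remaining values (absolute
#' association-constant scales, turnover rates, Michaelis constants) are
#' fixture choices documented in the methods vignette, selected so that the
#' human-like activation completes by about 3 micromolar modulator and the
#' yeast-like one by about 1 micromolar, inside the standard 0--10
#' micromolar assay window. The yeast-like and mutant fixtures additionally
#' satisfy the linkage relation gamma = delta (the B/A affinity gain is the
#' same for substrate-free and substrate-bound enzyme), which is the
#' identifiability constraint the affinity stage imposes for their site
#' structure; see [fit_affinity_stage()].
#'
#' @param name \code{"H20S_LIKE"}, \code{"Y20S_LIKE"} or \code{"A3DN_LIKE"}.
#' @return A [two_state_scheme()].
#' @examples
#' fixture_scheme("H20S_LIKE")$L_U   # exp(-32.7 / RT) at 310.15 K
#' @export
fixture_scheme <- function(name = c("H20S_LIKE", "Y20S_LIKE", "A3DN_LIKE")) {
  name <- match.arg(name)
  RT <- .R_GAS * 310.15
  switch(name,
    H20S_LIKE = two_state_scheme(
      kcat_A = 1.0, kcat_B = 0.5, km_0 = 60, km_B = 10,
      K_AU = 0.01, K_BU = 0.01 * 4000,
      K_AL = 0.005, K_BL = 0.005 * exp(23.9 / RT),
      L_U = exp(-32.7 / RT), L_L = exp(-26.1 / RT),
      n = 3L, m = 0L),
    Y20S_LIKE = two_state_scheme(
      kcat_A = 1.2, kcat_B = 0.6, km_0 = 40, km_B = 8,
      K_AU = 0.01, K_BU = 20, K_AL = 0.025, K_BL = 50, K_BI = 2,
      L_U = 1e-3, L_L = 2e-3,
      n = 2L, m = 1L),
    A3DN_LIKE = two_state_scheme(
      kcat_A = 1.8, kcat_B = 1.8, km_0 = 120, km_B = 30,
      K_AU = 0.01, K_BU = 20, K_AL = 0.025, K_BL = 50, K_BI = 2,
      L_U = exp(-8.3 / RT), L_L = 0.1,
      n = 2L, m = 1L))
}

#' Generate a synthetic velocity dataset
#'
#' Evaluates the forward model of a scheme over an assay design and returns
#' replicate-level initial velocities, optionally perturbed by
#' multiplicative Gaussian noise and/or an uncompetitive substrate-
#' inhibition term \eqn{v = E_0 k_{cat} S / (K_m + S(1 + S/K_{si}))}.
#' Noisy draws are deterministic for a given seed (the global RNG state is
#' restored afterwards); negative draws are truncated at zero and counted
#' in a message.
#'
#' @param scheme A [two_state_scheme()].
#' @param design An [assay_design()].
#' @param noise A [noise_options()] list; default noiseless.
#' @return A data frame of class \code{"velocity_dataset"} with columns
#'   \code{substrate_uM}, \code{modulator_uM}, \code{replicate},
#'   \code{velocity_nM_per_s}, \code{enzyme_nM}.
#' @examples
#' d <- generate_dataset(fixture_scheme("H20S_LIKE"),
#'                       noise = noise_options(cv = 0))
#' head(d)
#' @export
generate_dataset <- function(scheme, design = default_design(),
                             noise = noise_options(cv = 0)) {
  .assert_scheme(scheme)
  if (!inherits(design, "assay_design"))
    stop("'design' must be an assay_design() object")
  if (!inherits(noise, "noise_options"))
    stop("'noise' must be a noise_options() object")
  if (noise$cv > 0 && is.null(noise$seed))
    stop("a seed is required for noisy output")

  grid <- expand.grid(replicate = seq_len(design$replicates),
                      substrate_uM = design$substrate_uM,
                      modulator_uM = design$modulator_uM,
                      KEEP.OUT.ATTRS = FALSE)
  kc <- observed_kcat(scheme, grid$modulator_uM)
  km <- observed_km(scheme, grid$modulator_uM)
  S <- grid$substrate_uM
  denom <- if (is.null(noise$substrate_inhibition_Ksi)) km + S
           else km + S * (1 + S / noise$substrate_inhibition_Ksi)
  v <- design$enzyme_nM * kc * S / denom

  if (noise$cv > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(noise$seed)
    v <- v * (1 + stats::rnorm(length(v), 0, noise$cv))
    n_neg <- sum(v < 0)
    if (n_neg > 0) {
      message(n_neg, " negative velocity draw(s) truncated at zero")
      v[v < 0] <- 0
    }
  }

  out <- data.frame(substrate_uM = grid$substrate_uM,
                    modulator_uM = grid$modulator_uM,
                    replicate = grid$replicate,
                    velocity_nM_per_s = v,
                    enzyme_nM = design$enzyme_nM)
  attr(out, "design") <- design
  attr(out, "noise") <- noise
  attr(out, "temperature_K") <- design$temperature_K
  class(out) <- c("velocity_dataset", "data.frame")
  out
}
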