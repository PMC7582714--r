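#' Construct a two-state concerted allosteric scheme
#'
#' Bundles every constant of the two-state concerted (MWC-type) description
#' of an enzyme whose conformations A and B interconvert in fast equilibrium
#' while a modulator binds cooperatively to \code{n} concerted activating
#' sites and, optionally, to \code{m} competitive inhibitory sites confined
#' to state B. Each conformational state obeys Michaelis--Menten kinetics
#' with its own turnover rate and Michaelis constant; the modulator shifts
#' the A/B equilibrium through its four state- and substrate-dependent
#' association constants.
#'
#' The canonical constraints of the concerted model are encoded as defaults:
#' the inhibitory site is absent in state A (\code{K_AI = 0}), turnover rates
#' do not change upon modulator binding (\code{sigma_A = sigma_B = 1}), and
#' every association constant is independent of how many modulator molecules
#' are already bound. Overriding \code{K_AI} or the sigma multipliers is
#' permitted at construction time (the override is recorded and warned
#' about), but the observed-parameter equations are only implemented in the
#' unit-sigma regime.
#'
#' @param kcat_A,kcat_B Turnover rates of states A and B (per second).
#' @param km_0 Michaelis constant in the absence of modulator (micromolar).
#' @param km_A,km_B Michaelis constants of states A and B (micromolar);
#'   \code{km_A} defaults to \code{km_0}.
#' @param K_AU,K_BU Modulator association constants of the substrate-free
#'   ("unbound") A and B states (per micromolar).
#' @param K_AL,K_BL Modulator association constants of the substrate-bound
#'   ("liganded") A and B states (per micromolar).
#' @param K_BI Association constant of the competitive inhibitory site on
#'   state B (per micromolar); only meaningful when \code{m >= 1}.
#' @param K_AI Association constant of the inhibitory site on state A,
#'   fixed at 0 by the model; a non-zero value is accepted with a warning.
#' @param L_U,L_L Allosteric constants, i.e. equilibrium ratios [B]/[A] for
#'   the substrate-free and substrate-bound enzyme (dimensionless, > 0).
#'   Values much below 1 mean state A is favored.
#' @param n Number of concerted activating modulator sites (integer >= 1).
#' @param m Number of competitive inhibitory sites (integer >= 0).
#' @param sigma_A,sigma_B Multipliers of the turnover rates upon modulator
#'   binding, fixed at 1 by the model.
#' @param temperature_K Absolute assay temperature in kelvin (default
#'   310.15, i.e. 37 degrees C).
#'
#' @return An object of class \code{"two_state_scheme"}: a named list of the
#'   validated parameters with an \code{overrides} field recording any
#'   relaxation of the fixed constraints.
#'
#' @examples
#' sc <- two_state_scheme(kcat_A = 1, kcat_B = 0.5, km_0 = 60, km_B = 10,
#'                        K_AU = 0.01, K_BU = 40, K_AL = 0.005, K_BL = 53,
#'                        L_U = 3.1e-6, L_L = 4e-5, n = 3)
#' print(sc)
#' @seealso [fixture_scheme()] for ready-made parameter sets,
#'   [observed_kcat()], [observed_km()], [observed_efficiency()] for the
#'   forward model, [energy_ladder()] for the linkage analysis.
#' @export
two_state_scheme <- function(kcat_A, kcat_B, km_0, km_B, km_A = km_0,
                             K_AU, K_BU, K_AL, K_BL,
                             L_U, L_L, n = 1L, m = 0L,
                             K_BI = 0, K_AI = 0,
                             sigma_A = 1, sigma_B = 1,
                             temperature_K = 310.15) {
  chk1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  kcat_A <- chk1(kcat_A, "kcat_A"); kcat_B <- chk1(kcat_B, "kcat_B")
  km_0 <- chk1(km_0, "km_0"); km_A <- chk1(km_A, "km_A")
  km_B <- chk1(km_B, "km_B")
  K_AU <- chk1(K_AU, "K_AU"); K_BU <- chk1(K_BU, "K_BU")
  K_AL <- chk1(K_AL, "K_AL"); K_BL <- chk1(K_BL, "K_BL")
  K_BI <- chk1(K_BI, "K_BI"); K_AI <- chk1(K_AI, "K_AI")
  L_U <- chk1(L_U, "L_U"); L_L <- chk1(L_L, "L_L")
  sigma_A <- chk1(sigma_A, "sigma_A"); sigma_B <- chk1(sigma_B, "sigma_B")
  temperature_K <- chk1(temperature_K, "temperature_K")

  if (min(kcat_A, kcat_B, K_AU, K_BU, K_AL, K_BL, K_BI, K_AI) < 0)
    stop("rate and association constants must be non-negative")
  if (min(km_0, km_A, km_B) <= 0)
    stop("Michaelis constants must be positive")
  if (L_U <= 0 || L_L <= 0)
    stop("allosteric constants L_U and L_L must be positive")
  if (temperature_K <= 0)
    stop("temperature_K must be positive")
  int1 <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        abs(x - round(x)) > 1e-8 || round(x) < min)
      stop(sprintf("'%s' must be an integer >= %d", nm, min), call. = FALSE)
    as.integer(round(x))
  }
  n <- int1(n, "n", 1L)
  m <- int1(m, "m", 0L)

  overrides <- character(0)
  if (K_AI != 0) {
    overrides <- c(overrides, "K_AI")
    warning("K_AI != 0 overrides the fixed constraint K_AI = 0 of the ",
            "two-state model; the override is recorded", call. = FALSE)
  }
  if (sigma_A != 1 || sigma_B != 1) {
    overrides <- c(overrides, "sigma")
    warning("sigma_A/sigma_B != 1 overrides the fixed unit-sigma constraint; ",
            "forward observed-parameter equations require unit sigma",
            call. = FALSE)
  }

  structure(list(
    kcat_A = kcat_A, kcat_B = kcat_B,
    km_0 = km_0, km_A = km_A, km_B = km_B,
    K_AU = K_AU, K_BU = K_BU, K_AL = K_AL, K_BL = K_BL,
    K_BI = K_BI, K_AI = K_AI,
    L_U = L_U, L_L = L_L,
    n = n, m = m,
    sigma_A = sigma_A, sigma_B = sigma_B,
    temperature_K = temperature_K,
    overrides = overrides
  ), class = "two_state_scheme")
}

#' Test whether an object is a two-state scheme
#' @param x An R object.
#' @return \code{TRUE} for objects created by [two_state_scheme()].
#' @export
is_two_state_scheme <- function(x) inherits(x, "two_state_scheme")

.assert_scheme <- function(scheme) {
  if (!is_two_state_scheme(scheme))
    stop("'scheme' must be a 'two_state_scheme' object", call. = FALSE)
  if (scheme$sigma_A != 1 || scheme$sigma_B != 1)
    stop("observed-parameter equations are implemented for the fixed ",
         "constraint sigma_A = sigma_B = 1 only", call. = FALSE)
  invisible(scheme)
}

#' @export
print.two_state_scheme <- function(x, ...) {
  cat("Two-state concerted allosteric scheme\n")
  cat(sprintf("  sites: n = %d activating (concerted), m = %d inhibitory (state B)\n",
              x$n, x$m))
  cat(sprintf("  state A: kcat = %.4g /s, Km = %.4g uM\n", x$kcat_A, x$km_A))
  cat(sprintf("  state B: kcat = %.4g /s, Km = %.4g uM\n", x$kcat_B, x$km_B))
  cat(sprintf("  Km (no modulator) = %.4g uM\n", x$km_0))
  cat(sprintf("  modulator association (1/uM): K_AU = %.4g, K_BU = %.4g, K_AL = %.4g, K_BL = %.4g\n",
              x$K_AU, x$K_BU, x$K_AL, x$K_BL))
  if (x$m > 0 || x$K_BI > 0)
    cat(sprintf("  inhibitory association (1/uM): K_BI = %.4g (K_AI = %.4g)\n",
                x$K_BI, x$K_AI))
  cat(sprintf("  allosteric constants [B]/[A]: L_U = %.4g, L_L = %.4g\n",
              x$L_U, x$L_L))
  cat(sprintf("  temperature: %.2f K\n", x$temperature_K))
  if (length(x$overrides))
    cat("  overridden fixed constraints:", paste(x$overrides, collapse = ", "), "\n")
  invisible(x)
}
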