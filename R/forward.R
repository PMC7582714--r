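#' Cooperative binding polynomial for independent identical sites
#'
#' The statistical weight \eqn{(1 + K c)^{s}} of \code{s} identical,
#' independent binding sites with association constant \code{K} at free
#' ligand concentration \code{c}. This factor is the building block of the
#' observed-parameter equations: it equals the explicit sum over occupancy
#' microstates with binomial coefficients,
#' \eqn{\sum_{i=0}^{s} \binom{s}{i} (Kc)^i}.
#'
#' @param K Association constant (per micromolar), \code{K >= 0}.
#' @param c Free ligand concentration (micromolar), \code{c >= 0}; may be a
#'   vector.
#' @param sites Number of sites (integer \code{>= 0}).
#' @return Dimensionless weight, same length as \code{c}.
#' @examples
#' binding_polynomial(1, 2, 3)      # 27
#' binding_polynomial(0.02, 5, 2)   # 1.21
#' @export
binding_polynomial <- function(K, c, sites) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 0)
    stop("'K' must be a single non-negative number")
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("'c' must be non-negative")
  if (!is.numeric(sites) || length(sites) != 1L || !is.finite(sites) ||
      sites < 0 || abs(sites - round(sites)) > 1e-8)
    stop("'sites' must be a non-negative integer")
  (1 + K * c)^as.integer(round(sites))
}

# Statistical weights of the two conformations at modulator concentration L.
# form = "unbound": substrate-free enzyme, weights (K_AU, K_BU, L_U) with the
# B weight carrying the inhibitory factor (1 + K_BI L)^m.
# form = "substrate_bound": weights (K_AL, K_BL, L_L), no inhibitory factor.
.state_weights <- function(scheme, L, form) {
  s <- scheme
  if (form == "unbound") {
    list(A = (1 + s$K_AU * L)^s$n,
         B = s$L_U * (1 + s$K_BI * L)^s$m * (1 + s$K_BU * L)^s$n)
  } else {
    list(A = (1 + s$K_AL * L)^s$n,
         B = s$L_L * (1 + s$K_BL * L)^s$n)
  }
}

#' Conformational state populations
#'
#' Fractional populations of states A and B at a given modulator
#' concentration, for either the substrate-free or the substrate-bound
#' enzyme. The B weight of the substrate-free form carries the competitive
#' inhibitory factor \eqn{(1+K_{BI} L)^m}, mirroring its placement in the
#' observed-Km equation.
#'
#' @param scheme A [two_state_scheme()].
#' @param L Modulator concentration (micromolar), vectorized.
#' @param form \code{"unbound"} (substrate-free) or \code{"substrate_bound"}.
#' @return A data frame with columns \code{modulator_uM}, \code{f_A},
#'   \code{f_B}; rows sum to 1.
#' @export
state_populations <- function(scheme, L,
                              form = c("unbound", "substrate_bound")) {
  .assert_scheme(scheme)
  form <- match.arg(form)
  if (any(!is.finite(L)) || any(L < 0)) stop("'L' must be non-negative")
  w <- .state_weights(scheme, L, form)
  tot <- w$A + w$B
  data.frame(modulator_uM = L, f_A = w$A / tot, f_B = w$B / tot)
}

#' Observed turnover rate as a function of modulator concentration
#'
#' Population-weighted turnover rate of the two-state scheme,
#' \deqn{{}^{obs}k_{cat}(L) = \frac{k_{catA}(1+K_{AL}L)^n +
#'   L_L\, k_{catB}(1+K_{BL}L)^n}{(1+K_{AL}L)^n + L_L (1+K_{BL}L)^n},}
#' using substrate-bound weights. Bounded between the two state turnover
#' rates for every \code{L}.
#'
#' @inheritParams state_populations
#' @return Observed kcat (per second), same length as \code{L}.
#' @export
observed_kcat <- function(scheme, L) {
  .assert_scheme(scheme)
  if (any(!is.finite(L)) || any(L < 0)) stop("'L' must be non-negative")
  w <- .state_weights(scheme, L, "substrate_bound")
  (scheme$kcat_A * w$A + scheme$kcat_B * w$B) / (w$A + w$B)
}

#' Observed Michaelis constant as a function of modulator concentration
#'
#' \deqn{{}^{obs}K_m(L) = {}^0K_m \frac{(1+K_{AU}L)^n +
#'   L_U (1+K_{BI}L)^m (1+K_{BU}L)^n}{(1+K_{AL}L)^n + L_L (1+K_{BL}L)^n}.}
#' For \code{m >= 1} the numerator grows without bound in \code{L} (the
#' competitive-inhibition signature); for \code{m = 0} the curve approaches
#' a finite limit.
#'
#' @inheritParams state_populations
#' @return Observed Km (micromolar), same length as \code{L}.
#' @export
observed_km <- function(scheme, L) {
  .assert_scheme(scheme)
  if (any(!is.finite(L)) || any(L < 0)) stop("'L' must be non-negative")
  u <- .state_weights(scheme, L, "unbound")
  w <- .state_weights(scheme, L, "substrate_bound")
  scheme$km_0 * (u$A + u$B) / (w$A + w$B)
}

#' Observed specificity constant as a function of modulator concentration
#'
#' The population-weighted specificity constant in its direct form,
#' \deqn{\left(\frac{k_{cat}}{K_m}\right)_{obs}(L) =
#'  \frac{\frac{k_{catA}}{K_{mA}}(1+K_{AU}L)^n +
#'        L_U \frac{k_{catB}}{K_{mB}} (1+K_{BI}L)^m (1+K_{BU}L)^n}
#'       {(1+K_{AU}L)^n + L_U (1+K_{BI}L)^m (1+K_{BU}L)^n},}
#' weighted by the substrate-free state populations. Note that this
#' expression is not algebraically identical to the ratio
#' \code{observed_kcat(scheme, L) / observed_km(scheme, L)} unless the
#' scheme is degenerate; see [efficiency_consistency()] and
#' [efficiency_ratio()].
#'
#' @inheritParams state_populations
#' @return Observed kcat/Km (per second per micromolar).
#' @export
observed_efficiency <- function(scheme, L) {
  .assert_scheme(scheme)
  if (any(!is.finite(L)) || any(L < 0)) stop("'L' must be non-negative")
  u <- .state_weights(scheme, L, "unbound")
  (scheme$kcat_A / scheme$km_A * u$A + scheme$kcat_B / scheme$km_B * u$B) /
    (u$A + u$B)
}

#' Specificity constant as the ratio of observed kcat and Km
#'
#' The alternative representation of the observed specificity constant,
#' \code{observed_kcat(scheme, L) / observed_km(scheme, L)}. Reports and
#' fits can use either this ratio or the direct form
#' [observed_efficiency()]; the two coincide only for degenerate schemes.
#'
#' @inheritParams state_populations
#' @return kcat/Km (per second per micromolar).
#' @export
efficiency_ratio <- function(scheme, L) {
  observed_kcat(scheme, L) / observed_km(scheme, L)
}

#' Discrepancy between the two specificity-constant representations
#'
#' Maximum relative discrepancy over a modulator grid between the direct
#' specificity-constant expression ([observed_efficiency()]) and the ratio
#' of the observed turnover and Michaelis curves ([efficiency_ratio()]).
#' Zero for degenerate schemes in which substrate-bound and substrate-free
#' constants coincide (\code{K_AU = K_AL}, \code{K_BU = K_BL},
#' \code{L_U = L_L}, \code{km_A = km_B = km_0}, \code{m = 0}); strictly
#' positive in general, and reported alongside every fit.
#'
#' @param scheme A [two_state_scheme()].
#' @param L_grid Non-empty vector of non-negative modulator concentrations.
#' @return Single number: \code{max |direct - ratio| / ratio} over the grid.
#' @export
efficiency_consistency <- function(scheme, L_grid) {
  .assert_scheme(scheme)
  if (length(L_grid) < 1L) stop("'L_grid' must be non-empty")
  if (any(!is.finite(L_grid)) || any(L_grid < 0))
    stop("'L_grid' must be non-negative")
  direct <- observed_efficiency(scheme, L_grid)
  ratio <- efficiency_ratio(scheme, L_grid)
  max(abs(direct - ratio) / ratio)
}

#' Initial velocity of the modulated enzyme
#'
#' Michaelis--Menten velocity with modulator-dependent observed parameters:
#' \eqn{v = E_0\, {}^{obs}k_{cat}(L)\, S / ({}^{obs}K_m(L) + S)}.
#'
#' @param scheme A [two_state_scheme()].
#' @param E0 Total enzyme concentration (nanomolar), \code{> 0}.
#' @param S Substrate concentration (micromolar), \code{>= 0}; vectorized.
#' @param L Modulator concentration (micromolar), \code{>= 0}; vectorized
#'   (recycled against \code{S}).
#' @return Initial velocity in nM substrate cleaved per second.
#' @export
velocity <- function(scheme, E0, S, L) {
  .assert_scheme(scheme)
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 <= 0)
    stop("'E0' must be a single positive number")
  if (any(!is.finite(S)) || any(S < 0)) stop("'S' must be non-negative")
  if (any(!is.finite(L)) || any(L < 0)) stop("'L' must be non-negative")
  kc <- observed_kcat(scheme, L)
  km <- observed_km(scheme, L)
  E0 * kc * S / (km + S)
}

#' Modulator concentration halving the velocity (IC50)
#'
#' Finds the modulator concentration at which the velocity drops to half of
#' its value at zero modulator, at a stated substrate concentration. The
#' ratio \code{v(L)/v(0) - 1/2} is scanned on a dense grid over
#' \code{[0, L_max]} and the first sign change is refined by bisection
#' (\code{stats::uniroot}). When the ratio never crosses one half, an
#' explicit not-found result is returned. With multiple crossings the
#' smallest is returned and a warning is emitted.
#'
#' @param scheme A [two_state_scheme()].
#' @param E0 Enzyme concentration (nanomolar).
#' @param S Substrate concentration (micromolar).
#' @param L_max Upper end of the search interval (micromolar), \code{> 0}.
#' @param tolerance Absolute bisection tolerance on L (micromolar).
#' @return A list with elements \code{found} (logical), \code{ic50}
#'   (micromolar, \code{NA} when not found) and \code{n_crossings}.
#' @export
ic50 <- function(scheme, E0, S, L_max = 100, tolerance = 1e-6) {
  .assert_scheme(scheme)
  if (!is.numeric(L_max) || length(L_max) != 1L || L_max <= 0)
    stop("'L_max' must be a single positive number")
  v0 <- velocity(scheme, E0, S, 0)
  f <- function(L) velocity(scheme, E0, S, L) / v0 - 0.5
  grid <- seq(0, L_max, length.out = 4096L)
  fg <- f(grid)
  sgn <- sign(fg)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
  if (length(cross) == 0L)
    return(list(found = FALSE, ic50 = NA_real_, n_crossings = 0L))
  if (length(cross) > 1L)
    warning("velocity ratio crosses one half more than once; ",
            "returning the smallest crossing")
  root <- stats::uniroot(f, lower = grid[cross[1L]],
                         upper = grid[cross[1L] + 1L],
                         tol = tolerance)$root
  list(found = TRUE, ic50 = root, n_crossings = length(cross))
}
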