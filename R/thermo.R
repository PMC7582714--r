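# Gas constant in kJ / (mol K); energies are reported in kJ/mol throughout.
.R_GAS <- 8.314e-3

#' Gibbs free energy of an equilibrium constant
#'
#' \eqn{\Delta G^0 = -RT \ln K} with \eqn{R = 8.314\times10^{-3}}
#' kJ/(mol K).
#'
#' @param K_eq Dimensionless equilibrium constant, \code{> 0}.
#' @param T Absolute temperature in kelvin (default 310.15).
#' @return Free energy in kJ/mol.
#' @examples
#' gibbs_free_energy(1)               # 0
#' gibbs_free_energy(4000, 310.15)    # about -21.4 kJ/mol
#' @export
gibbs_free_energy <- function(K_eq, T = 310.15) {
  if (!is.numeric(K_eq) || any(!is.finite(K_eq)) || any(K_eq <= 0))
    stop("'K_eq' must be positive")
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("'T' must be a single positive temperature in kelvin")
  -.R_GAS * T * log(K_eq)
}

#' Interaction ratios of the modulator association constants
#'
#' The four dimensionless ratios that summarize the linkage between
#' conformational state and substrate binding:
#' \eqn{\alpha = K_{AU}/K_{AL}}, \eqn{\beta = K_{BU}/K_{BL}},
#' \eqn{\gamma = K_{BU}/K_{AU}}, \eqn{\delta = K_{BL}/K_{AL}}.
#' They obey the algebraic identity \eqn{\alpha/\beta = \delta/\gamma}.
#'
#' @param scheme A [two_state_scheme()] with all four modulator association
#'   constants strictly positive.
#' @return A list of class \code{"interaction_ratios"} with elements
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{delta}.
#' @export
interaction_ratios <- function(scheme) {
  .assert_scheme(scheme)
  ks <- c(K_AU = scheme$K_AU, K_BU = scheme$K_BU,
          K_AL = scheme$K_AL, K_BL = scheme$K_BL)
  if (any(ks == 0))
    stop("interaction ratios require strictly positive modulator association",
         " constants; zero found for: ",
         paste(names(ks)[ks == 0], collapse = ", "))
  structure(list(alpha = scheme$K_AU / scheme$K_AL,
                 beta = scheme$K_BU / scheme$K_BL,
                 gamma = scheme$K_BU / scheme$K_AU,
                 delta = scheme$K_BL / scheme$K_AL),
            class = "interaction_ratios")
}

#' @export
print.interaction_ratios <- function(x, ...) {
  cat("Modulator interaction ratios (dimensionless)\n")
  cat(sprintf("  alpha = K_AU/K_AL = %.6g\n", x$alpha))
  cat(sprintf("  beta  = K_BU/K_BL = %.6g\n", x$beta))
  cat(sprintf("  gamma = K_BU/K_AU = %.6g\n", x$gamma))
  cat(sprintf("  delta = K_BL/K_AL = %.6g\n", x$delta))
  invisible(x)
}

#' Occupancy-resolved free-energy ladder of the A/B transition
#'
#' Free-energy differences of the A to B conformational transition as a
#' function of the number \code{i} of bound modulator molecules, for the
#' substrate-free and substrate-bound enzyme:
#' \deqn{\Delta G^{unbound}_i = -RT\ln(L_U \gamma^i), \qquad
#'       \Delta G^{bound}_i = -RT\ln(L_L \delta^i).}
#' The sign convention is \eqn{\Delta G(A \to B) = -RT\ln L}, so positive
#' values mean state A is favored; every row carries explicit favored-state
#' labels so the sign is never ambiguous. Successive occupancies differ by
#' the exact arithmetic decrements \eqn{RT\ln\gamma} (unbound) and
#' \eqn{RT\ln\delta} (bound); the ratios are used at full precision and
#' rounding happens only in printed output.
#'
#' @param scheme A [two_state_scheme()].
#' @param i_max Largest occupancy to tabulate (default \code{scheme$n});
#'   must not exceed \code{scheme$n}.
#' @return A data frame of class \code{"energy_ladder"} with columns
#'   \code{occupancy}, \code{dG_unbound_kJmol}, \code{dG_bound_kJmol},
#'   \code{favored_unbound}, \code{favored_bound}.
#' @export
energy_ladder <- function(scheme, i_max = scheme$n) {
  .assert_scheme(scheme)
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max < 0 ||
      abs(i_max - round(i_max)) > 1e-8)
    stop("'i_max' must be a non-negative integer")
  i_max <- as.integer(round(i_max))
  if (i_max > scheme$n)
    stop(sprintf("'i_max' (%d) must not exceed the number of concerted sites n (%d)",
                 i_max, scheme$n))
  ir <- interaction_ratios(scheme)
  RT <- .R_GAS * scheme$temperature_K
  i <- 0:i_max
  dG_u <- -RT * log(scheme$L_U) - i * RT * log(ir$gamma)
  dG_b <- -RT * log(scheme$L_L) - i * RT * log(ir$delta)
  lab <- function(x) ifelse(x > 0, "A", ifelse(x < 0, "B", "balanced"))
  out <- data.frame(occupancy = i,
                    dG_unbound_kJmol = dG_u,
                    dG_bound_kJmol = dG_b,
                    favored_unbound = lab(dG_u),
                    favored_bound = lab(dG_b),
                    stringsAsFactors = FALSE)
  attr(out, "temperature_K") <- scheme$temperature_K
  attr(out, "sign_convention") <-
    "dG(A->B) = -RT ln([B]/[A]); positive values favor state A"
  class(out) <- c("energy_ladder", "data.frame")
  out
}

#' @export
print.energy_ladder <- function(x, digits = 1, ...) {
  cat("A <-> B free-energy ladder (kJ/mol);",
      "positive = A favored\n")
  cat(sprintf("  temperature: %.2f K\n", attr(x, "temperature_K")))
  y <- data.frame(occupancy = x$occupancy,
                  dG_unbound = round(x$dG_unbound_kJmol, digits),
                  favored = x$favored_unbound,
                  dG_bound = round(x$dG_bound_kJmol, digits),
                  favored_S = x$favored_bound)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Export an energy ladder to CSV or JSON
#'
#' Writes the occupancy-resolved ladder at full numeric precision. The CSV
#' carries one row per occupancy with both favored-state labels; the JSON
#' mirrors the data frame plus the temperature and sign convention.
#'
#' @param ladder An [energy_ladder()].
#' @param path Output file path.
#' @param format \code{"csv"} or \code{"json"} (default from the file
#'   extension).
#' @return The path, invisibly.
#' @export
write_energy_ladder <- function(ladder, path,
                                format = c("auto", "csv", "json")) {
  if (!inherits(ladder, "energy_ladder"))
    stop("'ladder' must be an 'energy_ladder' object")
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    lines <- c("occupancy,dG_unbound_kJmol,dG_bound_kJmol,favored_unbound,favored_bound",
               sprintf("%d,%.15g,%.15g,%s,%s", ladder$occupancy,
                       ladder$dG_unbound_kJmol, ladder$dG_bound_kJmol,
                       ladder$favored_unbound, ladder$favored_bound))
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(temperature_K = attr(ladder, "temperature_K"),
           sign_convention = attr(ladder, "sign_convention"),
           ladder = as.data.frame(ladder)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
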