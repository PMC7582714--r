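#' Goodness of fit: r-squared and residual sum of squares
#'
#' \eqn{R^2 = 1 - RSS/TSS} with the total sum of squares taken about the
#' observed mean. A zero TSS (constant observations) yields an undefined
#' r-squared, returned as \code{NA}.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 2.
#' @return A list with \code{r_squared} and \code{rss}.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have the same length")
  if (length(observed) < 2L) stop("need at least two points")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - rss / tss
  list(r_squared = r2, rss = rss)
}

#' Control settings for the staged least-squares fits
#'
#' @param n_starts Number of deterministic multi-start initializations per
#'   stage (default 8).
#' @param maxiter Maximum Levenberg--Marquardt iterations per start.
#' @param ftol,ptol Convergence tolerances passed to
#'   \code{minpack.lm::nls.lm.control}.
#' @param rss_floor Weighted residual sum of squares below which a fit is
#'   treated as numerically exact for model selection (see
#'   [select_site_numbers()]); default \code{1e-6}. Noiseless fits of the
#'   generating structure land many orders of magnitude below this, while
#'   any structural misfit (and any fit to noisy data, whose weighted RSS
#'   is of the order of the number of residuals) lands far above it.
#' @return A list of control settings.
#' @export
fit_control <- function(n_starts = 8L, maxiter = 800L,
                        ftol = 1e-15, ptol = 1e-15, rss_floor = 1e-6) {
  list(n_starts = as.integer(n_starts), maxiter = as.integer(maxiter),
       ftol = ftol, ptol = ptol, rss_floor = rss_floor)
}

# Box constraints per parameter, natural scale. Optimization works on the
# log scale, so the boxes double as positivity constraints. The allosteric
# constants are capped at 1: state A is by definition the majority
# (reference) state of each ligation class in the absence of modulator,
# which removes the label-swapped mirror solutions of the two-state curves.
.par_box <- function(names) {
  lo <- c(kcat = 1e-5, km = 1e-3, K = 1e-7, L = 1e-16)
  hi <- c(kcat = 1e4, km = 1e5, K = 1e5, L = 1)
  fam <- function(nm) {
    if (nm %in% c("kcat_A", "kcat_B", "kcat")) "kcat"
    else if (nm %in% c("km_0", "km_B")) "km"
    else if (grepl("^K_", nm)) "K"
    else "L"
  }
  f <- vapply(names, fam, "")
  list(lower = unname(lo[f]), upper = unname(hi[f]))
}

# Multi-start bounded Levenberg-Marquardt on log-transformed parameters.
# starts: list of named numeric vectors (natural scale, same names/order).
#
# Just-identified stage systems can admit several numerically exact roots
# (finitely many solutions of the underlying polynomial system). Among runs
# whose RSS falls below control$rss_floor the canonical one is returned:
# the root with the largest value of `tie_prefer` (an allosteric constant),
# i.e. the representation ascribing the smallest A/B free-energy gap —
# the most conservative conformational bias that accounts for the data,
# in the same spirit as the minimal-(n, m) selection rule. The number of
# distinct exact roots encountered is reported.
.ls_multistart <- function(resid_fn, starts, control, tie_prefer = NULL) {
  nms <- names(starts[[1L]])
  box <- .par_box(nms)
  runs <- list()
  for (st in starts) {
    p0 <- pmin(pmax(unname(st[nms]), box$lower * 1.0000001),
               box$upper * 0.9999999)
    run <- tryCatch(
      minpack.lm::nls.lm(
        par = log(p0),
        lower = log(box$lower), upper = log(box$upper),
        fn = function(lp) resid_fn(stats::setNames(exp(lp), nms)),
        control = minpack.lm::nls.lm.control(
          maxiter = control$maxiter, ftol = control$ftol,
          ptol = control$ptol)),
      error = function(e) NULL)
    if (!is.null(run)) runs[[length(runs) + 1L]] <- run
  }
  if (!length(runs)) stop("all least-squares starts failed")
  dev <- vapply(runs, function(r) r$deviance, 0)
  exact <- which(dev <= control$rss_floor)
  n_roots <- 0L
  if (length(exact) && !is.null(tie_prefer) && tie_prefer %in% nms) {
    pars <- vapply(runs[exact], function(r) r$par[match(tie_prefer, nms)], 0)
    n_roots <- length(unique(signif(exp(pars), 4)))
    best <- runs[[exact[which.max(pars)]]]
  } else {
    best <- runs[[which.min(dev)]]
  }
  par <- stats::setNames(exp(best$par), nms)
  at_bound <- (abs(best$par - log(box$lower)) < 1e-6) |
    (abs(best$par - log(box$upper)) < 1e-6)
  list(par = par, rss = best$deviance,
       bound_hit = stats::setNames(at_bound, nms),
       n_exact_roots = n_roots,
       info = best$info, message = best$message)
}

# Per-point relative weight denominators: the relative standard error of
# the profile ordinate when available (floored so noiseless profiles keep a
# finite scale), 1 otherwise (plain relative residuals).
.rel_weights <- function(profile, se_col, obs) {
  if (se_col %in% names(profile)) {
    se <- profile[[se_col]]
    if (all(is.finite(se)) && all(se >= 0))
      return(pmax(se / abs(obs), 1e-4))
  }
  rep(1, length(obs))
}

.check_profile <- function(profile) {
  req <- c("modulator_uM", "kcat_obs_per_s", "km_obs_uM", "eff_obs")
  miss <- setdiff(req, names(profile))
  if (length(miss))
    stop("catalytic profile is missing column(s): ",
         paste(miss, collapse = ", "))
  profile[order(profile$modulator_uM), , drop = FALSE]
}

# Interpolated modulator concentration at which `y` crosses the midpoint of
# its range; used to seed the multi-start grids.
.midpoint_L <- function(L, y) {
  mid <- (max(y) + min(y)) / 2
  s <- sign(y - mid)
  idx <- which(s[-1] * s[-length(s)] <= 0)
  if (!length(idx)) return(stats::median(L[L > 0]))
  i <- idx[1L]
  if (y[i + 1L] == y[i]) return(max(L[i], min(L[L > 0])))
  Lh <- L[i] + (mid - y[i]) * (L[i + 1L] - L[i]) / (y[i + 1L] - y[i])
  max(Lh, min(L[L > 0]) / 10)
}

# Observed-kcat curve from a flat named parameter vector (plus fixed n).
.kcat_curve <- function(p, L, n) {
  wA <- (1 + p[["K_AL"]] * L)^n
  wB <- p[["L_L"]] * (1 + p[["K_BL"]] * L)^n
  (p[["kcat_A"]] * wA + p[["kcat_B"]] * wB) / (wA + wB)
}

.km_curve <- function(p, L, n, m) {
  uA <- (1 + p[["K_AU"]] * L)^n
  uB <- p[["L_U"]] * (1 + p[["K_BI"]] * L)^m * (1 + p[["K_BU"]] * L)^n
  wA <- (1 + p[["K_AL"]] * L)^n
  wB <- p[["L_L"]] * (1 + p[["K_BL"]] * L)^n
  p[["km_0"]] * (uA + uB) / (wA + wB)
}

.eff_direct_curve <- function(p, L, n, m) {
  uA <- (1 + p[["K_AU"]] * L)^n
  uB <- p[["L_U"]] * (1 + p[["K_BI"]] * L)^m * (1 + p[["K_BU"]] * L)^n
  # km_A is tied to km_0 during fitting
  (p[["kcat_A"]] / p[["km_0"]] * uA + p[["kcat_B"]] / p[["km_B"]] * uB) /
    (uA + uB)
}

#' Turnover stage: fit the observed-kcat equation
#'
#' First stage of the constrained fit: least squares of the observed
#' turnover equation to \code{kcat_obs} versus modulator concentration at a
#' fixed number of concerted sites \code{n}, estimating \code{kcat_A},
#' \code{kcat_B}, \code{K_AL}, \code{K_BL} and \code{L_L}. Relative
#' residuals are minimized from a deterministic grid of multi-start
#' initializations spanning the transition region, and the best
#' residual-sum-of-squares solution is returned. These parameters are then
#' frozen for the affinity stage.
#'
#' A profile with no modulator dependence of \code{kcat_obs} (relative
#' range below \code{1e-6}) is degenerate for this stage: the common
#' turnover value is returned with \code{kcat_A = kcat_B} and the binding
#' parameters flagged as not identifiable.
#'
#' @param profile A [catalytic_profile()] (or [forward_profile()]) with at
#'   least five distinct modulator concentrations including 0.
#' @param n Number of concerted activating sites (integer >= 1).
#' @param fixed Optional named list freezing any of the stage parameters at
#'   given values.
#' @param equal_kcat Constrain \code{kcat_A = kcat_B} (a single common
#'   turnover parameter), as appropriate for gate-disrupted mutants whose A
#'   and B states are kinetically indistinguishable in turnover.
#' @param start Optional named vector of starting values; when it covers
#'   the floated parameters it replaces the deterministic multi-start grid
#'   (used e.g. by the residual bootstrap to warm-start refits).
#' @param control A [fit_control()] list.
#' @return A list of class \code{"turnover_stage"}: \code{parameters}
#'   (named vector kcat_A, kcat_B, K_AL, K_BL, L_L), \code{status} (per
#'   parameter: fitted / fixed / degenerate / bound-hit), \code{rss} (sum
#'   of squared relative residuals), \code{r_squared} (on the kcat curve),
#'   \code{degenerate}, \code{fitted} (curve values), \code{n}.
#' @export
fit_turnover_stage <- function(profile, n, fixed = list(),
                               equal_kcat = FALSE, start = NULL,
                               control = fit_control()) {
  profile <- .check_profile(profile)
  L <- profile$modulator_uM
  obs <- profile$kcat_obs_per_s
  if (length(unique(L)) < 5L || !any(L == 0))
    stop("the turnover stage needs at least five distinct modulator ",
         "concentrations including 0")
  par_names <- c("kcat_A", "kcat_B", "K_AL", "K_BL", "L_L")

  rel_range <- (max(obs) - min(obs)) / max(mean(obs), .Machine$double.eps)
  if (rel_range < 1e-6) {
    kc <- mean(obs)
    pars <- c(kcat_A = kc, kcat_B = kc, K_AL = NA_real_, K_BL = NA_real_,
              L_L = NA_real_)
    status <- c(kcat_A = "degenerate", kcat_B = "degenerate",
                K_AL = "not-identifiable", K_BL = "not-identifiable",
                L_L = "not-identifiable")
    pred <- rep(kc, length(L))
    return(structure(list(parameters = pars, status = status,
                          rss = sum(((pred - obs) / obs)^2),
                          r_squared = goodness_of_fit(obs, pred)$r_squared,
                          degenerate = TRUE, fitted = pred, n = n,
                          equal_kcat = equal_kcat),
                     class = "turnover_stage"))
  }

  float <- setdiff(par_names, names(fixed))
  if (equal_kcat) float <- setdiff(float, c("kcat_A", "kcat_B"))
  assemble <- function(pv) {
    p <- c(pv, unlist(fixed))
    if (equal_kcat && !"kcat_A" %in% names(p)) {
      p[["kcat_A"]] <- pv[["kcat"]]
      p[["kcat_B"]] <- pv[["kcat"]]
    }
    p
  }
  wrel <- .rel_weights(profile, "kcat_se_per_s", obs)
  resid_fn <- function(pv) {
    p <- assemble(pv)
    (.kcat_curve(p, L, n) - obs) / (obs * wrel)
  }

  # deterministic multi-start: seed the substrate-bound transition midpoint
  L_half <- .midpoint_L(L, obs)
  kA0 <- obs[which.min(L)]
  kB0 <- obs[which.max(L)]
  if (abs(kA0 - kB0) / max(kA0, kB0) < 1e-3) kB0 <- kA0 * 0.5
  kbl_grid <- c(0.5, 1, 2, 5, 10, 20, 50, 100)[seq_len(control$n_starts)]
  starts <- lapply(kbl_grid / L_half, function(kbl) {
    full <- c(kcat_A = kA0, kcat_B = kB0, kcat = (kA0 + kB0) / 2,
              K_AL = kbl / 1000, K_BL = kbl,
              L_L = (1 + kbl * L_half)^(-n))
    full[c(float, if (equal_kcat) "kcat")]
  })
  want <- c(float, if (equal_kcat) "kcat")
  if (!is.null(start) && all(want %in% names(start)) &&
      all(is.finite(start[want])))
    starts <- list(start[want])
  fit <- .ls_multistart(resid_fn, starts, control, tie_prefer = "L_L")

  p_full <- assemble(fit$par)[par_names]
  status <- stats::setNames(rep("fitted", 5L), par_names)
  status[names(fixed)] <- "fixed"
  if (equal_kcat) status[c("kcat_A", "kcat_B")] <- "fitted (equal-kcat)"
  bh <- names(fit$bound_hit)[fit$bound_hit]
  bh <- intersect(bh, par_names)
  status[bh] <- "bound-hit"
  pred <- .kcat_curve(p_full, L, n)
  structure(list(parameters = p_full, status = status, rss = fit$rss,
                 r_squared = goodness_of_fit(obs, pred)$r_squared,
                 degenerate = FALSE, fitted = pred, n = n,
                 equal_kcat = equal_kcat, optimizer = fit[c("info", "message")]),
            class = "turnover_stage")
}

#' Affinity stage: fit the observed-Km and specificity equations
#'
#' Second stage of the constrained fit. With the turnover-stage parameters
#' frozen, the observed-Km equation and the chosen specificity-constant
#' representation are fitted jointly to \code{km_obs} and \code{eff_obs}
#' with equal weight on relative residuals, estimating \code{km_0},
#' \code{K_AU}, \code{K_BU}, \code{L_U} and, when \code{m >= 1},
#' \code{K_BI}. The constraint set of the concerted model is honored
#' throughout: occupancy-independent association constants, unit sigma
#' multipliers, no inhibitory site on state A.
#'
#' Two representations of the specificity ordinate are supported.
#' \code{"ratio"} (default) fits \code{kcat/km} as the ratio of the two
#' observed-parameter equations, which is exactly the quantity a
#' double-reciprocal analysis produces, so \code{km_B} does not enter and
#' is reported as the saturating-modulator limit of the observed Km
#' (status \code{"derived"}). \code{"eq_direct"} fits the direct
#' specificity-constant expression, in which case \code{km_B} is floated
#' (with \code{km_A} tied to \code{km_0}).
#'
#' When the turnover stage was degenerate (no kcat modulation, e.g. equal
#' state turnovers), its binding parameters \code{K_AL}, \code{K_BL} and
#' \code{L_L} carry no information and are floated here instead, unless
#' supplied through \code{fixed}.
#'
#' Under the ratio representation the observed-Km curve exposes exactly
#' \code{n + m + 1} polynomial coefficient combinations of the unbound-state
#' parameters, so site structures with fewer coefficients than floated
#' parameters (e.g. n = 2 with an inhibitory site) are rank-deficient: a
#' continuum of parameter sets fits the data exactly. When
#' \code{linkage_constraint = "auto"} (default) the stage restores
#' identifiability in that case by imposing the linkage relation
#' \eqn{\gamma = \delta}, i.e. \code{K_BU = K_AU * K_BL / K_AL}: the B/A
#' affinity gain of the modulator is taken to be the same for substrate-free
#' and substrate-bound enzyme, and \code{K_BU} is reported with status
#' \code{"derived"}. Set \code{linkage_constraint = "never"} to keep the
#' full float set (useful for quantifying the degeneracy).
#'
#' @param profile A catalytic profile, as in [fit_turnover_stage()].
#' @param turnover The first-stage result ([fit_turnover_stage()]).
#' @param n,m Site numbers (m = 0 forces \code{K_BI} frozen at 0).
#' @param efficiency \code{"ratio"} or \code{"eq_direct"}; see Details.
#' @param fixed Optional named list freezing any stage parameter.
#' @param linkage_constraint \code{"auto"} (impose gamma = delta exactly
#'   when the stage would otherwise be rank-deficient) or \code{"never"}.
#' @param start Optional named vector of starting values replacing the
#'   multi-start grid when it covers the floated parameters.
#' @param control A [fit_control()] list.
#' @return A list of class \code{"affinity_stage"}: \code{parameters}
#'   (km_0, km_B, K_AU, K_BU, L_U, K_BI, plus K_AL/K_BL/L_L when floated
#'   here), \code{status}, \code{rss}, \code{r_squared_km},
#'   \code{r_squared_eff}, \code{fitted_km}, \code{fitted_eff},
#'   \code{efficiency}, \code{n}, \code{m}.
#' @export
fit_affinity_stage <- function(profile, turnover, n, m,
                               efficiency = c("ratio", "eq_direct"),
                               fixed = list(),
                               linkage_constraint = c("auto", "never"),
                               start = NULL, control = fit_control()) {
  linkage_constraint <- match.arg(linkage_constraint)
  profile <- .check_profile(profile)
  efficiency <- match.arg(efficiency)
  if (!inherits(turnover, "turnover_stage"))
    stop("'turnover' must be a fit_turnover_stage() result")
  L <- profile$modulator_uM
  km_obs <- profile$km_obs_uM
  eff_obs <- profile$eff_obs

  frozen <- as.list(turnover$parameters[c("kcat_A", "kcat_B")])
  bound_names <- c("K_AL", "K_BL", "L_L")
  float_bound <- turnover$degenerate
  if (!float_bound) frozen <- c(frozen, as.list(turnover$parameters[bound_names]))

  float <- c("km_0", "K_AU", "K_BU", "L_U")
  if (m >= 1L) float <- c(float, "K_BI")
  if (efficiency == "eq_direct") float <- c(float, "km_B")
  if (float_bound) float <- c(float, setdiff(bound_names, names(fixed)))
  float <- setdiff(float, names(fixed))

  constants <- c(unlist(frozen), unlist(fixed))
  if (m == 0L && !"K_BI" %in% c(float, names(constants)))
    constants <- c(constants, K_BI = 0)

  # rank rule (ratio representation): n + m + 1 observable coefficient
  # combinations versus the core float set; impose gamma = delta when
  # rank-deficient and the bound-state constants are available to supply
  # delta
  core <- intersect(c("km_0", "K_AU", "K_BU", "L_U", "K_BI"), float)
  delta_fixed <- NA_real_
  constrain_gamma <- linkage_constraint == "auto" &&
    efficiency == "ratio" &&
    (n + m + 1L) < length(core) &&
    all(c("K_AU", "K_BU") %in% float) &&
    all(c("K_AL", "K_BL") %in% names(constants))
  if (constrain_gamma) {
    delta_fixed <- constants[["K_BL"]] / constants[["K_AL"]]
    float <- setdiff(float, "K_BU")
  }
  assemble <- function(pv) {
    p <- c(pv, constants)
    if (constrain_gamma) p[["K_BU"]] <- p[["K_AU"]] * delta_fixed
    if (!"K_BI" %in% names(p)) p[["K_BI"]] <- 0
    p
  }
  w_km <- .rel_weights(profile, "km_se_uM", km_obs)
  w_ef <- .rel_weights(profile, "eff_se", eff_obs)
  resid_fn <- function(pv) {
    p <- assemble(pv)
    km_hat <- .km_curve(p, L, n, m)
    eff_hat <- if (efficiency == "ratio")
      .kcat_curve(p, L, n) / km_hat
    else .eff_direct_curve(p, L, n, m)
    c((km_hat - km_obs) / (km_obs * w_km),
      (eff_hat - eff_obs) / (eff_obs * w_ef))
  }

  # multi-start over the substrate-free transition position
  L_mid <- sqrt(min(L[L > 0]) * max(L))
  km00 <- km_obs[which.min(L)]
  kbu_grid <- c(0.3, 1, 3, 10, 30, 100, 300, 1000)[seq_len(control$n_starts)]
  starts <- lapply(kbu_grid / L_mid, function(kbu) {
    st <- c(km_0 = km00, K_AU = kbu / 1000, K_BU = kbu,
            L_U = (1 + kbu * L_mid)^(-n),
            K_BI = 2 / max(L),
            km_B = max(km_obs[which.max(L)], 1e-2),
            K_AL = kbu / 1000, K_BL = 3 * kbu,
            L_L = (1 + kbu * L_mid)^(-n))
    st[float]
  })
  if (!is.null(start) && all(float %in% names(start)) &&
      all(is.finite(start[float])))
    starts <- list(start[float])
  fit <- .ls_multistart(resid_fn, starts, control, tie_prefer = "L_U")

  p_full <- assemble(fit$par)
  out_names <- unique(c("km_0", "km_B", "K_AU", "K_BU", "L_U", "K_BI",
                        if (float_bound) bound_names))
  status <- stats::setNames(rep("fitted", length(out_names)), out_names)
  status[setdiff(out_names, float)] <- "fixed"
  if (constrain_gamma)
    status["K_BU"] <- "derived (linkage constraint gamma = delta)"
  if (m == 0L) status["K_BI"] <- "fixed (m = 0)"
  bh <- intersect(names(fit$bound_hit)[fit$bound_hit], out_names)
  status[bh] <- "bound-hit"
  if (m >= 1L && "K_BI" %in% names(fit$par) &&
      fit$bound_hit[["K_BI"]] && fit$par[["K_BI"]] < 1e-6)
    status["K_BI"] <- "bound-hit (not identifiable: no high-modulator Km upturn)"

  if (efficiency == "ratio") {
    # report the B-state Michaelis constant as the saturating-modulator
    # limit of the observed Km (it does not enter the ratio representation)
    km_inf <- if (p_full[["K_BL"]] > 0)
      p_full[["km_0"]] * p_full[["L_U"]] * p_full[["K_BU"]]^n /
        (p_full[["L_L"]] * p_full[["K_BL"]]^n)
    else p_full[["km_0"]]
    p_full[["km_B"]] <- km_inf
    status["km_B"] <- "derived (high-modulator Km limit)"
  }

  km_hat <- .km_curve(p_full, L, n, m)
  eff_hat <- if (efficiency == "ratio") .kcat_curve(p_full, L, n) / km_hat
             else .eff_direct_curve(p_full, L, n, m)
  structure(list(parameters = p_full[out_names], status = status,
                 rss = fit$rss,
                 r_squared_km = goodness_of_fit(km_obs, km_hat)$r_squared,
                 r_squared_eff = goodness_of_fit(eff_obs, eff_hat)$r_squared,
                 fitted_km = km_hat, fitted_eff = eff_hat,
                 efficiency = efficiency, n = n, m = m,
                 float_bound = float_bound,
                 optimizer = fit[c("info", "message")]),
            class = "affinity_stage")
}

# Run both stages for one (n, m) candidate and assemble a full scheme.
.fit_two_state <- function(profile, n, m, efficiency = "ratio",
                           fixed = list(), equal_kcat = FALSE,
                           start = NULL, control = fit_control()) {
  s1_names <- c("kcat_A", "kcat_B", "K_AL", "K_BL", "L_L")
  turnover <- fit_turnover_stage(profile, n,
                                 fixed = fixed[intersect(names(fixed), s1_names)],
                                 equal_kcat = equal_kcat, start = start,
                                 control = control)
  s2_fix <- fixed[setdiff(names(fixed), s1_names)]
  if (turnover$degenerate)
    s2_fix <- c(s2_fix, fixed[intersect(names(fixed),
                                        c("K_AL", "K_BL", "L_L"))])
  affinity <- fit_affinity_stage(profile, turnover, n, m,
                                 efficiency = efficiency, fixed = s2_fix,
                                 start = start, control = control)
  pars <- c(affinity$parameters, turnover$parameters)
  pars <- pars[!duplicated(names(pars))]
  k_t <- sum(grepl("^fitted", turnover$status))
  if (turnover$degenerate) k_t <- 1L        # the common turnover level
  else if (turnover$equal_kcat) k_t <- k_t - 1L  # both rates count once
  k <- k_t + sum(grepl("^fitted", affinity$status))
  list(turnover = turnover, affinity = affinity, parameters = pars,
       rss_total = turnover$rss + affinity$rss, n = n, m = m,
       n_par = k, n_obs = 3L * nrow(profile))
}

#' Select the numbers of activating and inhibitory sites
#'
#' Runs the two-stage fit for every candidate pair (n, m) and applies the
#' minimal-complexity rule: the smallest pair in lexicographic order (n
#' first, then m) whose total residual sum of squares lies within
#' \code{rss_margin} of the global best is selected. On noiseless data,
#' fits of the generating structure reach numerically exact residuals; the
#' comparison therefore treats any RSS below \code{control$rss_floor} as
#' exact so that over-parameterized candidates cannot displace the minimal
#' structure that already accounts for the data. Ties break toward smaller
#' n, then smaller m, by construction of the candidate order.
#'
#' @param profile A catalytic profile.
#' @param n_candidates Candidate numbers of concerted activating sites
#'   (default 1:4).
#' @param m_candidates Candidate numbers of competitive inhibitory sites
#'   (default 0:2).
#' @param rss_margin Relative margin on the best RSS within which a simpler
#'   candidate is accepted (default 0.05).
#' @param efficiency Specificity representation, see [fit_affinity_stage()].
#' @param criterion \code{"rss_margin"} (default; the minimal-structure
#'   rule described above) or \code{"aicc"}, which selects the candidate
#'   with the smallest small-sample Akaike criterion computed from the
#'   pooled weighted RSS and the number of floated parameters. The RSS
#'   margin mirrors the "minimum structure that accounts for the data"
#'   logic and is exact on noiseless profiles; on noisy profiles it tends
#'   to over-select (extra parameters cut a noise-dominated RSS by more
#'   than the margin), where the AICc alternative is the better-calibrated
#'   choice.
#' @param fixed,equal_kcat,control Passed to the stage fits.
#' @return A list: \code{n}, \code{m}, \code{table} (one row per candidate
#'   with stage RSS, parameter count and acceptance), \code{rss_margin},
#'   \code{criterion}.
#' @export
select_site_numbers <- function(profile, n_candidates = 1:4,
                                m_candidates = 0:2, rss_margin = 0.05,
                                efficiency = c("ratio", "eq_direct"),
                                criterion = c("rss_margin", "aicc"),
                                fixed = list(), equal_kcat = FALSE,
                                control = fit_control()) {
  efficiency <- match.arg(efficiency)
  criterion <- match.arg(criterion)
  if (!length(n_candidates) || !length(m_candidates))
    stop("candidate sets must be non-empty")
  cand <- expand.grid(m = sort(m_candidates), n = sort(n_candidates))
  cand <- cand[order(cand$n, cand$m), c("n", "m")]
  fits <- vector("list", nrow(cand))
  rss <- rep(Inf, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fits[[i]] <- tryCatch(
      .fit_two_state(profile, cand$n[i], cand$m[i], efficiency = efficiency,
                     fixed = fixed, equal_kcat = equal_kcat,
                     control = control),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) rss[i] <- fits[[i]]$rss_total
  }
  if (all(!is.finite(rss))) stop("no candidate (n, m) could be fitted")
  k <- vapply(fits, function(f) if (is.null(f)) NA_integer_ else f$n_par, 0L)
  N <- vapply(fits, function(f) if (is.null(f)) NA_integer_ else f$n_obs, 0L)
  aicc <- N * log(pmax(rss, control$rss_floor) / N) + 2 * k +
    2 * k * (k + 1) / pmax(N - k - 1, 1)
  if (criterion == "rss_margin") {
    best <- min(rss)
    accept <- rss <= (1 + rss_margin) * max(best, control$rss_floor)
  } else {
    accept <- is.finite(aicc) & aicc <= min(aicc, na.rm = TRUE)
  }
  sel <- which(accept)[1L]
  tab <- data.frame(n = cand$n, m = cand$m,
                    rss_turnover = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$turnover$rss, 0),
                    rss_affinity = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$affinity$rss, 0),
                    rss_total = rss, n_par = k, aicc = aicc,
                    accepted = accept,
                    selected = seq_along(rss) == sel)
  list(n = cand$n[sel], m = cand$m[sel], table = tab,
       rss_margin = rss_margin, criterion = criterion, fit = fits[[sel]])
}

#' Fit the two-state concerted modulation model
#'
#' The main model-fitting entry point. Takes either a catalytic profile
#' (observed kcat, Km, kcat/Km per modulator concentration) or a raw
#' velocity dataset (in which case [catalytic_profile()] is run first),
#' selects the site numbers (n, m) by the minimal-complexity rule unless
#' they are supplied, performs the two-stage constrained fit at the
#' selected structure, and returns a fitted-model object with the usual
#' methods (\code{print}, \code{summary}, \code{coef}, \code{predict},
#' \code{residuals}, \code{plot}, \code{simulate}).
#'
#' The staged procedure mirrors how the observed curves constrain the
#' scheme: the turnover curve pins \code{kcat_A}, \code{kcat_B},
#' \code{K_AL}, \code{K_BL} and \code{L_L}; those are then frozen while the
#' Km and specificity curves pin \code{km_0}, \code{K_AU}, \code{K_BU},
#' \code{L_U} and, with an inhibitory site, \code{K_BI}.
#'
#' @param data A \code{catalytic_profile} data frame, or a velocity dataset
#'   with columns \code{substrate_uM}, \code{modulator_uM},
#'   \code{replicate}, \code{velocity_nM_per_s}, \code{enzyme_nM}.
#' @param n,m Fix the site numbers instead of selecting them (both must be
#'   given to skip selection).
#' @param n_candidates,m_candidates,rss_margin,criterion Selection
#'   settings, see [select_site_numbers()].
#' @param efficiency Specificity-constant representation fitted to
#'   \code{eff_obs}; see [fit_affinity_stage()].
#' @param fixed Named list of parameters to freeze (e.g. association
#'   constants carried over from a wild-type fit when analysing a mutant).
#' @param equal_kcat Constrain the two state turnover rates to a common
#'   value.
#' @param S_cut Substrate cutoff used when \code{data} is a velocity
#'   dataset.
#' @param control A [fit_control()] list.
#' @return An object of class \code{"modulation_fit"}.
#' @examples
#' sc <- fixture_scheme("H20S_LIKE")
#' prof <- forward_profile(sc, c(0, 0.1, 0.3, 0.5, 1, 2, 3, 5, 10))
#' fit <- fit_modulation(prof, n = 3, m = 0)
#' coef(fit)[c("kcat_A", "kcat_B")]
#' @export
fit_modulation <- function(data, n = NULL, m = NULL,
                           n_candidates = 1:4, m_candidates = 0:2,
                           rss_margin = 0.05,
                           efficiency = c("ratio", "eq_direct"),
                           criterion = c("rss_margin", "aicc"),
                           fixed = list(), equal_kcat = FALSE,
                           S_cut = 25, control = fit_control()) {
  cl <- match.call()
  efficiency <- match.arg(efficiency)
  criterion <- match.arg(criterion)
  if ("velocity_nM_per_s" %in% names(data))
    data <- catalytic_profile(data, S_cut = S_cut)
  profile <- .check_profile(data)

  selection <- NULL
  if (is.null(n) || is.null(m)) {
    selection <- select_site_numbers(profile, n_candidates, m_candidates,
                                     rss_margin, efficiency = efficiency,
                                     criterion = criterion, fixed = fixed,
                                     equal_kcat = equal_kcat,
                                     control = control)
    n <- selection$n; m <- selection$m
    two <- selection$fit
  } else {
    two <- .fit_two_state(profile, n, m, efficiency = efficiency,
                          fixed = fixed, equal_kcat = equal_kcat,
                          control = control)
  }

  pars <- two$parameters
  # degenerate turnover without floated bound parameters cannot yield a
  # complete scheme; refuse loudly rather than fabricate
  if (any(!is.finite(unlist(pars[c("K_AL", "K_BL", "L_L")]))))
    stop("turnover stage degenerate and bound-state parameters not ",
         "recoverable; supply them through 'fixed'")
  temperature <- attr(profile, "temperature_K")
  scheme <- two_state_scheme(
    kcat_A = pars[["kcat_A"]], kcat_B = pars[["kcat_B"]],
    km_0 = pars[["km_0"]], km_B = max(pars[["km_B"]], 1e-3),
    K_AU = pars[["K_AU"]], K_BU = pars[["K_BU"]],
    K_AL = pars[["K_AL"]], K_BL = pars[["K_BL"]],
    K_BI = pars[["K_BI"]],
    L_U = pars[["L_U"]], L_L = pars[["L_L"]],
    n = n, m = m,
    temperature_K = if (is.null(temperature)) 310.15 else temperature)

  t_keep <- setdiff(names(two$turnover$parameters),
                    names(two$affinity$parameters))
  status <- rbind(
    data.frame(parameter = t_keep,
               value = unname(two$turnover$parameters[t_keep]),
               status = unname(two$turnover$status[t_keep]),
               stage = "turnover"),
    data.frame(parameter = names(two$affinity$parameters),
               value = unname(unlist(two$affinity$parameters)),
               status = unname(two$affinity$status[names(two$affinity$parameters)]),
               stage = "affinity"))
  rownames(status) <- NULL

  consistency <- efficiency_consistency(scheme,
                                        profile$modulator_uM[profile$modulator_uM > 0])
  structure(list(call = cl, profile = profile, scheme = scheme,
                 n = n, m = m, selection = selection,
                 turnover = two$turnover, affinity = two$affinity,
                 status = status, rss_total = two$rss_total,
                 efficiency = efficiency, consistency = consistency,
                 fixed = fixed, equal_kcat = equal_kcat,
                 control = control),
            class = "modulation_fit")
}

#' @export
print.modulation_fit <- function(x, ...) {
  cat("Two-state concerted allosteric modulation fit\n")
  cat(sprintf("  selected sites: n = %d activating, m = %d inhibitory%s\n",
              x$n, x$m,
              if (is.null(x$selection)) " (fixed by user)" else ""))
  cat(sprintf("  turnover stage:  RSS = %.3g, R^2 = %.5f%s\n",
              x$turnover$rss, x$turnover$r_squared,
              if (x$turnover$degenerate) "  [degenerate: kcat flat]" else ""))
  cat(sprintf("  affinity stage:  RSS = %.3g, R^2(Km) = %.5f, R^2(eff) = %.5f\n",
              x$affinity$rss, x$affinity$r_squared_km,
              x$affinity$r_squared_eff))
  cat(sprintf("  specificity representation: %s\n", x$efficiency))
  cat(sprintf("  max relative gap between specificity representations: %.3g\n",
              x$consistency))
  p <- x$scheme
  cat(sprintf("  kcat_A = %.4g /s, kcat_B = %.4g /s, Km0 = %.4g uM\n",
              p$kcat_A, p$kcat_B, p$km_0))
  cat(sprintf("  K_AL = %.4g, K_BL = %.4g, K_AU = %.4g, K_BU = %.4g (1/uM)\n",
              p$K_AL, p$K_BL, p$K_AU, p$K_BU))
  cat(sprintf("  L_U = %.4g, L_L = %.4g", p$L_U, p$L_L))
  if (x$m > 0) cat(sprintf(", K_BI = %.4g 1/uM", p$K_BI))
  cat("\n")
  invisible(x)
}

#' @export
summary.modulation_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.modulation_fit")
}

#' @export
print.summary.modulation_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nParameter status:\n")
  st <- fit$status
  st$value <- signif(st$value, 6)
  print(st, row.names = FALSE)
  if (!is.null(fit$selection)) {
    cat("\nSite-number selection (total RSS per candidate):\n")
    tab <- fit$selection$table
    tab$rss_total <- signif(tab$rss_total, 4)
    print(tab[, c("n", "m", "rss_total", "accepted", "selected")],
          row.names = FALSE)
  }
  if (!is.null(fit$boot)) {
    cat("\nBootstrap 95% confidence intervals:\n")
    print(fit$boot, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.modulation_fit <- function(object, ...) {
  s <- object$scheme
  c(kcat_A = s$kcat_A, kcat_B = s$kcat_B, km_0 = s$km_0, km_B = s$km_B,
    K_AU = s$K_AU, K_BU = s$K_BU, K_AL = s$K_AL, K_BL = s$K_BL,
    K_BI = s$K_BI, L_U = s$L_U, L_L = s$L_L, n = s$n, m = s$m)
}

#' Predict observed catalytic parameters or velocities from a fit
#'
#' @param object A [fit_modulation()] result.
#' @param modulator_uM Modulator grid (default: the fitted profile's).
#' @param what \code{"kcat"}, \code{"km"}, \code{"efficiency"} (in the
#'   representation the fit used), \code{"efficiency_both"} (data frame
#'   with both representations) or \code{"velocity"}.
#' @param substrate_uM,enzyme_nM Required for \code{what = "velocity"}.
#' @param ... Unused.
#' @return A numeric vector, or a data frame for
#'   \code{"efficiency_both"}.
#' @export
predict.modulation_fit <- function(object, modulator_uM = NULL,
                                   what = c("kcat", "km", "efficiency",
                                            "efficiency_both", "velocity"),
                                   substrate_uM = NULL, enzyme_nM = 2, ...) {
  what <- match.arg(what)
  if (is.null(modulator_uM)) modulator_uM <- object$profile$modulator_uM
  s <- object$scheme
  switch(what,
    kcat = observed_kcat(s, modulator_uM),
    km = observed_km(s, modulator_uM),
    efficiency = if (object$efficiency == "ratio")
      efficiency_ratio(s, modulator_uM)
    else observed_efficiency(s, modulator_uM),
    efficiency_both = data.frame(
      modulator_uM = modulator_uM,
      eff_ratio = efficiency_ratio(s, modulator_uM),
      eff_direct = observed_efficiency(s, modulator_uM)),
    velocity = {
      if (is.null(substrate_uM))
        stop("'substrate_uM' is required for velocity predictions")
      velocity(s, enzyme_nM, substrate_uM, modulator_uM)
    })
}

#' @export
residuals.modulation_fit <- function(object,
                                     stage = c("both", "turnover",
                                               "affinity"), ...) {
  stage <- match.arg(stage)
  p <- object$profile
  r1 <- (object$turnover$fitted - p$kcat_obs_per_s) / p$kcat_obs_per_s
  r2 <- c((object$affinity$fitted_km - p$km_obs_uM) / p$km_obs_uM,
          (object$affinity$fitted_eff - p$eff_obs) / p$eff_obs)
  switch(stage, turnover = r1, affinity = r2, both = c(r1, r2))
}

#' Plot a fitted modulation model against its profile
#'
#' Three panels: observed kcat, Km and kcat/Km versus modulator
#' concentration, data points with the fitted curves. The specificity
#' panel shows both representations (the fitted one solid, the alternative
#' dashed).
#'
#' @param x A [fit_modulation()] result.
#' @param ... Passed to \code{plot()}.
#' @export
plot.modulation_fit <- function(x, ...) {
  p <- x$profile
  Lg <- seq(0, max(p$modulator_uM), length.out = 200L)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(p$modulator_uM, p$kcat_obs_per_s, xlab = "modulator (uM)",
                 ylab = "observed kcat (1/s)", main = "turnover", ...)
  graphics::lines(Lg, observed_kcat(x$scheme, Lg))
  graphics::plot(p$modulator_uM, p$km_obs_uM, xlab = "modulator (uM)",
                 ylab = "observed Km (uM)", main = "Michaelis constant", ...)
  graphics::lines(Lg, observed_km(x$scheme, Lg))
  graphics::plot(p$modulator_uM, p$eff_obs, xlab = "modulator (uM)",
                 ylab = "kcat/Km (1/s/uM)", main = "specificity", ...)
  if (x$efficiency == "ratio") {
    graphics::lines(Lg, efficiency_ratio(x$scheme, Lg))
    graphics::lines(Lg, observed_efficiency(x$scheme, Lg), lty = 2)
  } else {
    graphics::lines(Lg, observed_efficiency(x$scheme, Lg))
    graphics::lines(Lg, efficiency_ratio(x$scheme, Lg), lty = 2)
  }
  invisible(x)
}

#' Simulate velocity datasets from a fitted model
#'
#' @param object A [fit_modulation()] result.
#' @param nsim Number of datasets.
#' @param seed Seed for the noise generator (required when \code{cv > 0}).
#' @param design An [assay_design()].
#' @param cv Relative velocity noise (coefficient of variation).
#' @param ... Unused.
#' @return A velocity dataset (or a list of them when \code{nsim > 1}).
#' @export
simulate.modulation_fit <- function(object, nsim = 1, seed = NULL,
                                    design = default_design(), cv = 0.05,
                                    ...) {
  out <- lapply(seq_len(nsim), function(i) {
    generate_dataset(object$scheme, design,
                     noise_options(cv = cv,
                                   seed = if (!is.null(seed)) seed + i - 1L))
  })
  if (nsim == 1L) out[[1L]] else out
}

#' Residual-bootstrap confidence intervals for the floated parameters
#'
#' Resamples the relative residuals of each stage, rebuilds bootstrap
#' profiles around the fitted curves, refits the two stages at the selected
#' (n, m) starting from the fitted parameters, and reports percentile
#' intervals per floated parameter. Fully reproducible for a given seed;
#' replicate fits that fail are dropped and counted, with a warning beyond
#' a 20% failure rate.
#'
#' @param fit A [fit_modulation()] result.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed (required).
#' @param level Confidence level (default 0.95).
#' @return A data frame with one row per floated parameter: \code{lower},
#'   \code{upper}, \code{estimate}; attribute \code{n_failed}.
#' @export
bootstrap_confidence <- function(fit, n_boot = 200, seed, level = 0.95) {
  if (!inherits(fit, "modulation_fit"))
    stop("'fit' must be a modulation_fit object")
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  if (missing(seed)) stop("a seed is required for the bootstrap")
  p <- fit$profile
  nL <- nrow(p)
  r_k <- residuals(fit, "turnover")
  r_a <- residuals(fit, "affinity")
  r_km <- r_a[seq_len(nL)]
  r_ef <- r_a[nL + seq_len(nL)]
  floated <- fit$status$parameter[grepl("^fitted", fit$status$status)]
  ctrl <- fit$control
  warm <- c(fit$affinity$parameters, fit$turnover$parameters)
  warm <- unlist(warm[!duplicated(names(warm))])
  if (fit$equal_kcat) warm <- c(warm, kcat = unname(warm["kcat_A"]))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  draws <- matrix(NA_real_, n_boot, length(floated),
                  dimnames = list(NULL, floated))
  n_failed <- 0L
  start_fix <- fit$fixed
  for (b in seq_len(n_boot)) {
    bp <- p
    bp$kcat_obs_per_s <- fit$turnover$fitted * (1 + sample(r_k, nL, TRUE))
    bp$km_obs_uM <- fit$affinity$fitted_km * (1 + sample(r_km, nL, TRUE))
    bp$eff_obs <- fit$affinity$fitted_eff * (1 + sample(r_ef, nL, TRUE))
    res <- tryCatch(
      .fit_two_state(bp, fit$n, fit$m, efficiency = fit$efficiency,
                     fixed = start_fix, equal_kcat = fit$equal_kcat,
                     start = warm, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    pr <- res$parameters
    ok <- intersect(floated, names(pr))
    draws[b, ok] <- unlist(pr[ok])
  }
  if (n_failed > 0.2 * n_boot)
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  alpha <- (1 - level) / 2
  est <- c(fit$affinity$parameters, fit$turnover$parameters)
  est <- est[!duplicated(names(est))]
  ci <- data.frame(
    parameter = floated,
    estimate = unname(unlist(est[floated])),
    lower = apply(draws, 2, stats::quantile, probs = alpha, na.rm = TRUE),
    upper = apply(draws, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE))
  rownames(ci) <- NULL
  attr(ci, "n_failed") <- n_failed
  attr(ci, "n_boot") <- n_boot
  ci
}
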