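#' Lineweaver--Burk double-reciprocal estimation of kcat and Km
#'
#' Ordinary least squares on the transformed observations
#' \eqn{E_0/v = (K_m/k_{cat}) (1/S) + 1/k_{cat}}: the intercept gives
#' \code{1/kcat} and the slope \code{Km/kcat}. The classical unweighted
#' regression is used; [michaelis_menten_fit()] provides the nonlinear
#' cross-check.
#'
#' @param S Substrate concentrations (micromolar), all \code{> 0}.
#' @param v Initial velocities (nM/s), same length as \code{S}. Rows with
#'   \code{v <= 0} are rejected with a message before fitting.
#' @param E0 Enzyme concentration (nanomolar).
#' @return A list: \code{kcat} (per second), \code{km} (micromolar),
#'   \code{r_squared} of the transformed regression, \code{slope},
#'   \code{intercept}, \code{nonphysical} (TRUE when the intercept is not
#'   positive, in which case the values are still returned but flagged) and
#'   \code{n_points}.
#' @examples
#' S <- c(5, 10, 15, 20, 25)
#' v <- 2 * 1 * S / (20 + S)     # E0 = 2 nM, kcat = 1/s, Km = 20 uM
#' double_reciprocal_fit(S, v, E0 = 2)
#' @export
double_reciprocal_fit <- function(S, v, E0) {
  if (length(S) != length(v)) stop("'S' and 'v' must have the same length")
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 <= 0)
    stop("'E0' must be a single positive number")
  bad <- !is.finite(v) | v <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) with non-positive velocity rejected from the ",
            "double-reciprocal fit")
    S <- S[!bad]; v <- v[!bad]
  }
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (length(unique(S)) < 2L)
    stop("need at least two distinct substrate concentrations")
  x <- 1 / S
  y <- E0 / v
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  intercept <- unname(co[1L]); slope <- unname(co[2L])
  r2 <- if (length(y) == 2L) 1
        else goodness_of_fit(y, stats::fitted(fit))$r_squared
  nonphys <- !is.finite(intercept) || intercept <= 0 || slope / intercept <= 0
  if (nonphys)
    message("double-reciprocal intercept/slope non-physical; ",
            "estimates returned but flagged")
  # delta-method standard errors: kcat = 1/b0, km = b1/b0, kcat/km = 1/b1
  kcat_se <- km_se <- eff_se <- NA_real_
  if (length(y) > 2L && !nonphys) {
    # suppress the "essentially perfect fit" warning: noiseless input is a
    # legitimate case here and its near-zero SEs are floored downstream
    V <- suppressWarnings(stats::vcov(fit))
    kcat_se <- sqrt(V[1, 1]) / intercept^2
    g <- c(-slope / intercept^2, 1 / intercept)
    km_se <- sqrt(drop(t(g) %*% V %*% g))
    eff_se <- sqrt(V[2, 2]) / slope^2
  }
  list(kcat = 1 / intercept, km = slope / intercept, r_squared = r2,
       kcat_se = kcat_se, km_se = km_se, eff_se = eff_se,
       slope = slope, intercept = intercept, nonphysical = nonphys,
       n_points = length(S))
}

#' Nonlinear Michaelis--Menten estimation of kcat and Km
#'
#' Direct nonlinear least squares on
#' \eqn{v = E_0 k_{cat} S / (K_m + S)} by Levenberg--Marquardt
#' (\code{minpack.lm::nls.lm}) on log-transformed parameters, started from
#' the [double_reciprocal_fit()] estimates (or from a crude heuristic when
#' those are non-physical). Serves as the cross-check of the classical
#' double-reciprocal estimates; on noiseless data the two agree to
#' optimizer tolerance.
#'
#' @inheritParams double_reciprocal_fit
#' @param start Optional named list or vector with starting \code{kcat} and
#'   \code{km}.
#' @return A list: \code{kcat}, \code{km}, \code{r_squared} (on the
#'   untransformed velocities), \code{rss}, \code{converged} and
#'   \code{message} (optimizer diagnostics).
#' @export
michaelis_menten_fit <- function(S, v, E0, start = NULL) {
  if (length(S) != length(v)) stop("'S' and 'v' must have the same length")
  if (length(S) < 3L) stop("need at least three points")
  if (is.null(start)) {
    lb <- tryCatch(suppressMessages(double_reciprocal_fit(S, v, E0)),
                   error = function(e) NULL)
    start <- if (!is.null(lb) && !lb$nonphysical && lb$kcat > 0 && lb$km > 0)
      c(kcat = lb$kcat, km = lb$km)
    else
      c(kcat = max(v) / E0 * 1.2, km = stats::median(S))
  }
  start <- unlist(start)[c("kcat", "km")]
  resid_fn <- function(lp) {
    p <- exp(lp)
    E0 * p[1L] * S / (p[2L] + S) - v
  }
  out <- minpack.lm::nls.lm(
    par = log(pmax(start, 1e-12)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- exp(out$par)
  pred <- E0 * p[1L] * S / (p[2L] + S)
  gof <- goodness_of_fit(v, pred)
  converged <- out$info %in% 1:4
  if (!converged)
    warning("Michaelis-Menten fit did not converge: ", out$message)
  list(kcat = unname(p[1L]), km = unname(p[2L]),
       r_squared = gof$r_squared, rss = gof$rss,
       converged = converged, message = out$message)
}

#' Partition velocity points by the double-reciprocal linearity range
#'
#' Splits points at a substrate cutoff (default 25 micromolar) and flags
#' substrate-linked loss of linearity: the flag is raised when the
#' double-reciprocal regression over the full substrate range falls below
#' the linearity threshold while the retained low-substrate subset does
#' not. Clean Michaelis--Menten data are linear everywhere and never
#' flagged.
#'
#' @inheritParams double_reciprocal_fit
#' @param S_cut Substrate cutoff (micromolar), default 25.
#' @param r2_threshold Linearity threshold on the transformed regression
#'   r-squared, default 0.98.
#' @return A list: \code{retained} and \code{excluded} data frames (columns
#'   \code{substrate_uM}, \code{velocity_nM_per_s}), \code{flag},
#'   \code{r2_full}, \code{r2_retained}.
#' @export
linearity_partition <- function(S, v, E0, S_cut = 25, r2_threshold = 0.98) {
  if (!is.numeric(S_cut) || length(S_cut) != 1L || S_cut <= 0)
    stop("'S_cut' must be a single positive number")
  keep <- S <= S_cut
  if (!any(keep)) stop("no points retained at or below 'S_cut'")
  retained <- data.frame(substrate_uM = S[keep], velocity_nM_per_s = v[keep])
  excluded <- data.frame(substrate_uM = S[!keep], velocity_nM_per_s = v[!keep])
  r2_retained <- double_reciprocal_fit(retained$substrate_uM,
                                       retained$velocity_nM_per_s,
                                       E0)$r_squared
  r2_full <- if (any(!keep))
    double_reciprocal_fit(S, v, E0)$r_squared
  else r2_retained
  flag <- (r2_full < r2_threshold) && (r2_retained >= r2_threshold)
  list(retained = retained, excluded = excluded, flag = flag,
       r2_full = r2_full, r2_retained = r2_retained)
}

#' Catalytic profile: observed kcat, Km and kcat/Km per modulator level
#'
#' Groups a velocity dataset by modulator concentration and estimates the
#' observed catalytic parameters at each level. Replicates are averaged per
#' (substrate, modulator) cell before regression (per-replicate fitting is
#' available via \code{average_replicates = FALSE}); the fit is restricted
#' to the linear double-reciprocal range \code{S <= S_cut}, and a linearity
#' flag records substrate-linked loss of linearity over the full range.
#' The reported efficiency is the ratio \code{kcat_obs / km_obs}.
#'
#' Groups that cannot be fitted (fewer than two distinct substrate levels,
#' or no positive velocities) are skipped with a message rather than
#' failing the whole profile.
#'
#' @param dataset A velocity dataset: data frame with columns
#'   \code{substrate_uM}, \code{modulator_uM}, \code{replicate},
#'   \code{velocity_nM_per_s}, \code{enzyme_nM} (see [generate_dataset()]
#'   and [read_velocity_csv()]).
#' @param S_cut Substrate cutoff for the fitted range (micromolar).
#' @param r2_threshold Linearity threshold, see [linearity_partition()].
#' @param method \code{"lb"} for the classical double-reciprocal regression
#'   (default) or \code{"mm"} for the nonlinear fit.
#' @param average_replicates Average replicate velocities per cell before
#'   fitting (default TRUE).
#' @return A data frame of class \code{"catalytic_profile"} with columns
#'   \code{modulator_uM}, \code{kcat_obs_per_s}, \code{km_obs_uM},
#'   \code{eff_obs}, \code{r_squared}, \code{n_replicates},
#'   \code{linearity_flag}; one row per fitted modulator concentration.
#'   Delta-method standard errors of the double-reciprocal estimates are
#'   carried in additional in-memory columns (\code{kcat_se_per_s},
#'   \code{km_se_uM}, \code{eff_se}) which the staged fits use as weights;
#'   the CSV serialization keeps the seven-column dialect above.
#' @export
catalytic_profile <- function(dataset, S_cut = 25, r2_threshold = 0.98,
                              method = c("lb", "mm"),
                              average_replicates = TRUE) {
  method <- match.arg(method)
  req <- c("substrate_uM", "modulator_uM", "replicate",
           "velocity_nM_per_s", "enzyme_nM")
  miss <- setdiff(req, names(dataset))
  if (length(miss))
    stop("velocity dataset is missing column(s): ",
         paste(miss, collapse = ", "))
  levels_L <- sort(unique(dataset$modulator_uM))
  rows <- vector("list", length(levels_L))
  for (k in seq_along(levels_L)) {
    L <- levels_L[k]
    g <- dataset[dataset$modulator_uM == L, , drop = FALSE]
    E0 <- unique(g$enzyme_nM)
    if (length(E0) != 1L) {
      message("skipping modulator level ", L,
              " uM: enzyme concentration not constant within the group")
      next
    }
    n_rep <- length(unique(g$replicate))
    if (average_replicates) {
      vbar <- tapply(g$velocity_nM_per_s, g$substrate_uM, mean)
      S <- as.numeric(names(vbar))
      v <- as.numeric(vbar)
    } else {
      S <- g$substrate_uM
      v <- g$velocity_nM_per_s
    }
    lin <- tryCatch(
      linearity_partition(S, v, E0, S_cut = S_cut,
                          r2_threshold = r2_threshold),
      error = function(e) NULL)
    if (is.null(lin)) {
      message("skipping modulator level ", L, " uM: ",
              "no usable points in the linear range")
      next
    }
    est <- tryCatch({
      if (method == "lb")
        double_reciprocal_fit(lin$retained$substrate_uM,
                              lin$retained$velocity_nM_per_s, E0)
      else
        michaelis_menten_fit(lin$retained$substrate_uM,
                             lin$retained$velocity_nM_per_s, E0)
    }, error = function(e) {
      message("skipping modulator level ", L, " uM: ", conditionMessage(e))
      NULL
    })
    if (is.null(est)) next
    rows[[k]] <- data.frame(
      modulator_uM = L,
      kcat_obs_per_s = est$kcat,
      km_obs_uM = est$km,
      eff_obs = est$kcat / est$km,
      r_squared = est$r_squared,
      n_replicates = n_rep,
      linearity_flag = lin$flag,
      kcat_se_per_s = if (method == "lb") est$kcat_se else NA_real_,
      km_se_uM = if (method == "lb") est$km_se else NA_real_,
      eff_se = if (method == "lb") est$eff_se else NA_real_)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no modulator level could be fitted")
  rownames(out) <- NULL
  attr(out, "S_cut") <- S_cut
  attr(out, "method") <- method
  attr(out, "enzyme_nM") <- unique(dataset$enzyme_nM)
  class(out) <- c("catalytic_profile", "data.frame")
  out
}

#' Noiseless catalytic profile predicted by a scheme
#'
#' Evaluates the forward model on a modulator grid and packages the result
#' with the same columns as [catalytic_profile()], which makes round-trip
#' (forward then inverse) checks and direct profile fitting convenient.
#'
#' @param scheme A [two_state_scheme()].
#' @param modulator_uM Modulator grid (micromolar).
#' @param efficiency Which representation fills \code{eff_obs}:
#'   \code{"ratio"} for \code{kcat_obs/km_obs} (the observable a
#'   double-reciprocal analysis produces; default) or \code{"eq_direct"}
#'   for the direct specificity-constant expression
#'   ([observed_efficiency()]).
#' @return A \code{"catalytic_profile"} data frame.
#' @export
forward_profile <- function(scheme, modulator_uM,
                            efficiency = c("ratio", "eq_direct")) {
  .assert_scheme(scheme)
  efficiency <- match.arg(efficiency)
  kc <- observed_kcat(scheme, modulator_uM)
  km <- observed_km(scheme, modulator_uM)
  eff <- if (efficiency == "ratio") kc / km
         else observed_efficiency(scheme, modulator_uM)
  out <- data.frame(modulator_uM = modulator_uM,
                    kcat_obs_per_s = kc,
                    km_obs_uM = km,
                    eff_obs = eff,
                    r_squared = NA_real_,
                    n_replicates = NA_integer_,
                    linearity_flag = FALSE)
  attr(out, "efficiency") <- efficiency
  class(out) <- c("catalytic_profile", "data.frame")
  out
}
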