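# Unit strings attached to each scheme field in the JSON serialization.
.SCHEME_UNITS <- c(
  kcat_A = "s^-1", kcat_B = "s^-1",
  km_0 = "uM", km_A = "uM", km_B = "uM",
  K_AU = "uM^-1", K_BU = "uM^-1", K_AL = "uM^-1", K_BL = "uM^-1",
  K_BI = "uM^-1", K_AI = "uM^-1",
  L_U = "dimensionless", L_L = "dimensionless",
  n = "sites", m = "sites",
  sigma_A = "dimensionless", sigma_B = "dimensionless",
  temperature_K = "K")

#' Write a scheme to JSON
#'
#' Serializes every parameter (including the fixed ones, K_AI and the sigma
#' multipliers, at their defaults) as \code{{"value": x, "unit": "..."}}
#' pairs at full numeric precision.
#'
#' @param scheme A [two_state_scheme()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  if (!is_two_state_scheme(scheme))
    stop("'scheme' must be a 'two_state_scheme' object")
  fields <- names(.SCHEME_UNITS)
  obj <- lapply(fields, function(f)
    list(value = scheme[[f]], unit = unname(.SCHEME_UNITS[f])))
  names(obj) <- fields
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scheme from JSON
#'
#' Validates the serialization produced by [write_scheme()]: every known
#' field must carry a value and its expected unit string, unknown keys are
#' rejected by name, and a non-zero K_AI (a relaxation of the fixed
#' constraint of the two-state model) is loaded with an explicit warning.
#'
#' @param path JSON file path.
#' @return A [two_state_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fields <- names(.SCHEME_UNITS)
  unknown <- setdiff(names(obj), fields)
  if (length(unknown))
    stop("unknown key(s) in scheme JSON: ", paste(unknown, collapse = ", "))
  missing <- setdiff(fields, names(obj))
  if (length(missing))
    stop("scheme JSON is missing field(s): ", paste(missing, collapse = ", "))
  vals <- lapply(fields, function(f) {
    entry <- obj[[f]]
    if (!is.list(entry) || is.null(entry$value) || is.null(entry$unit))
      stop(sprintf("field '%s' must be an object with 'value' and 'unit'", f))
    if (!identical(entry$unit, unname(.SCHEME_UNITS[f])))
      stop(sprintf("field '%s' has unit '%s'; expected '%s'",
                   f, entry$unit, .SCHEME_UNITS[f]))
    entry$value
  })
  names(vals) <- fields
  do.call(two_state_scheme, vals)
}

#' Round-trip a scheme file
#'
#' Reads a scheme JSON, rewrites it, and returns the scheme; a convenience
#' wrapper whose read-write-read stability is part of the serialization
#' contract.
#'
#' @param path JSON file path (read and rewritten in place unless
#'   \code{out} is given).
#' @param out Optional output path.
#' @return The [two_state_scheme()], invisibly.
#' @export
roundtrip_scheme <- function(path, out = path) {
  scheme <- read_scheme(path)
  write_scheme(scheme, out)
  invisible(scheme)
}

.VELOCITY_HEADER <- c("substrate_uM", "modulator_uM", "replicate",
                      "velocity_nM_per_s", "enzyme_nM")
.PROFILE_HEADER <- c("modulator_uM", "kcat_obs_per_s", "km_obs_uM",
                     "eff_obs", "r_squared", "n_replicates",
                     "linearity_flag")

.read_checked_csv <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  extra <- setdiff(names(df), header)
  missing <- setdiff(header, names(df))
  if (length(missing) || length(extra))
    stop("CSV header mismatch in ", path,
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")))
  df[, header, drop = FALSE]
}

# Deterministic numeric formatting so identical inputs give byte-identical
# files.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

#' Read and write velocity datasets as CSV
#'
#' The on-disk dialect: header
#' \code{substrate_uM,modulator_uM,replicate,velocity_nM_per_s,enzyme_nM},
#' comma separator, decimal point, UTF-8, comment lines starting with
#' \code{#}. Writing is deterministic: identical data give byte-identical
#' files.
#'
#' @param path CSV file path.
#' @param dataset A velocity dataset data frame.
#' @param comments Optional character vector written as leading \code{#}
#'   comment lines.
#' @return \code{read_velocity_csv}: the dataset; \code{write_velocity_csv}:
#'   the path, invisibly.
#' @export
read_velocity_csv <- function(path) {
  df <- .read_checked_csv(path, .VELOCITY_HEADER)
  class(df) <- c("velocity_dataset", "data.frame")
  df
}

#' @rdname read_velocity_csv
#' @export
write_velocity_csv <- function(dataset, path, comments = NULL) {
  miss <- setdiff(.VELOCITY_HEADER, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(.VELOCITY_HEADER, collapse = ","),
    sprintf("%s,%s,%d,%s,%s",
            .fmt_num(dataset$substrate_uM), .fmt_num(dataset$modulator_uM),
            as.integer(dataset$replicate),
            .fmt_num(dataset$velocity_nM_per_s), .fmt_num(dataset$enzyme_nM)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write catalytic profiles as CSV
#'
#' Header: \code{modulator_uM,kcat_obs_per_s,km_obs_uM,eff_obs,r_squared,}
#' \code{n_replicates,linearity_flag}; otherwise the same dialect as the
#' velocity CSV.
#'
#' @param path CSV file path.
#' @param profile A \code{catalytic_profile} data frame.
#' @param comments Optional \code{#} comment lines.
#' @return \code{read_profile_csv}: the profile; \code{write_profile_csv}:
#'   the path, invisibly.
#' @export
read_profile_csv <- function(path) {
  df <- .read_checked_csv(path, .PROFILE_HEADER)
  df$linearity_flag <- as.logical(df$linearity_flag)
  class(df) <- c("catalytic_profile", "data.frame")
  df
}

#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path, comments = NULL) {
  miss <- setdiff(.PROFILE_HEADER, names(profile))
  if (length(miss))
    stop("profile is missing column(s): ", paste(miss, collapse = ", "))
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(.PROFILE_HEADER, collapse = ","),
    sprintf("%s,%s,%s,%s,%s,%s,%s",
            .fmt_num(profile$modulator_uM), .fmt_num(profile$kcat_obs_per_s),
            .fmt_num(profile$km_obs_uM), .fmt_num(profile$eff_obs),
            .fmt_num(profile$r_squared),
            ifelse(is.na(profile$n_replicates), "NA",
                   as.character(as.integer(profile$n_replicates))),
            ifelse(profile$linearity_flag, "TRUE", "FALSE")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fitted model to JSON
#'
#' Serializes a [fit_modulation()] result: the fitted scheme (values and
#' units), per-parameter status and stage, selected site numbers, stage RSS
#' and r-squared values, the specificity-representation gap, and bootstrap
#' intervals when present.
#'
#' @param fit A \code{modulation_fit}.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "modulation_fit"))
    stop("'fit' must be a modulation_fit object")
  fields <- names(.SCHEME_UNITS)
  scheme <- lapply(fields, function(f)
    list(value = fit$scheme[[f]], unit = unname(.SCHEME_UNITS[f])))
  names(scheme) <- fields
  obj <- list(
    selected = list(n = fit$n, m = fit$m),
    scheme = scheme,
    parameter_status = fit$status,
    stages = list(
      turnover = list(rss = fit$turnover$rss,
                      r_squared = fit$turnover$r_squared,
                      degenerate = fit$turnover$degenerate),
      affinity = list(rss = fit$affinity$rss,
                      r_squared_km = fit$affinity$r_squared_km,
                      r_squared_eff = fit$affinity$r_squared_eff,
                      efficiency_representation = fit$efficiency)),
    efficiency_consistency = fit$consistency,
    selection_table = if (!is.null(fit$selection)) fit$selection$table,
    bootstrap = fit$boot)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
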