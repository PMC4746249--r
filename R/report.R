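# End-to-end analysis report and the command-line entry points.

REPORT_SCHEMA_VERSION <- "1.0"

resolve_series_input <- function(x, what = "series") {
  if (is.character(x)) {
    return(list(series = read_isotope_series(x), digest = unname(tools::md5sum(x))))
  }
  if (inherits(x, "isotope_series")) {
    lst <- list(x)
    names(lst) <- attr(x, "compound")
    return(list(series = lst, digest = NA_character_))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "isotope_series"))) {
    if (is.null(names(x))) {
      names(x) <- vapply(x, attr, character(1), "compound")
    }
    return(list(series = x, digest = NA_character_))
  }
  abort_csia(sprintf("%s must be a file path, an isotope_series, or a list of them", what),
    "csiaray_input_error")
}

#' Run the full isotope + kinetics analysis pipeline
#'
#' Composes the pipeline on one dataset: Rayleigh enrichment-factor fits
#' for carbon and hydrogen, reactive-position correction and AKIE for each
#' element, the dual-isotope slope (both as a regression and as the
#' epsilon ratio), redox classification of the regression slope, and a
#' kinetics summary (lag, removal extent, halt) per compound with a
#' matched control. Stages whose inputs are absent (e.g. no hydrogen
#' deltas) are skipped with a warning when `allow_partial = TRUE`,
#' otherwise raise a stage-labeled error.
#'
#' @param series live-flask input: a path to a delimited time-series file,
#'   an [isotope_series()], or a list of them.
#' @param control matching abiotic-control input (same forms), or `NULL`
#'   to fall back on the `conc_control` column for kinetics.
#' @param isotope_compound compound to run the isotope stages on; default:
#'   the first compound carrying any delta values.
#' @param forced_origin passed to [fit_rayleigh()].
#' @param pos [position_params()] used for both elements' AKIE.
#' @param use_internal_std internal-standard normalization for kinetics
#'   (needs a control input with `conc_internal_std`).
#' @param allow_partial skip unavailable stages with a warning instead of
#'   failing.
#' @return An object of class `analysis_report`: a named list with
#'   `schema_version`, `package_version`, `input_digest`, `config`,
#'   `rayleigh_C`, `rayleigh_H`, `akie_C`, `akie_H`, `dual_isotope`,
#'   `lambda_epsilon_ratio`, `redox`, `kinetics`, and `warnings`.
#' @export
run_full_analysis <- function(series, control = NULL, isotope_compound = NULL,
                              forced_origin = FALSE, pos = position_params(),
                              use_internal_std = FALSE, allow_partial = TRUE) {
  live_in <- resolve_series_input(series, "series")
  ctrl_in <- if (!is.null(control)) resolve_series_input(control, "control") else NULL
  live <- live_in$series
  warnings <- character(0)
  note <- function(msg) warnings[[length(warnings) + 1L]] <<- msg

  stage <- function(label, expr, required = FALSE) {
    tryCatch(expr, csiaray_error = function(e) {
      if (required || !allow_partial) {
        abort_csia(sprintf("stage '%s' failed: %s", label, conditionMessage(e)),
          "csiaray_stage_error")
      }
      note(sprintf("stage '%s' skipped: %s", label, conditionMessage(e)))
      warning(sprintf("stage '%s' skipped: %s", label, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }

  if (is.null(isotope_compound)) {
    has_delta <- vapply(live, function(s) any(!is.na(s$delta13C)) || any(!is.na(s$delta2H)),
      logical(1))
    isotope_compound <- if (any(has_delta)) names(live)[which(has_delta)[1L]] else NA_character_
  }
  iso <- if (!is.na(isotope_compound) && isotope_compound %in% names(live)) {
    live[[isotope_compound]]
  } else {
    NULL
  }

  ray_C <- ray_H <- akie_C <- akie_H <- dual <- lam_ratio <- redox <- NULL
  if (is.null(iso)) {
    note("no compound carries isotope deltas: isotope stages skipped")
  } else {
    ray_C <- stage("fit_rayleigh C", fit_rayleigh(iso, "C", forced_origin = forced_origin))
    ray_H <- stage("fit_rayleigh H", fit_rayleigh(iso, "H", forced_origin = forced_origin))
    if (!is.null(ray_C)) {
      akie_C <- stage("akie C", akie(epsilon_reactive_position(ray_C, pos), pos,
        ci95_half_width = (pos$n_total / pos$x_reactive) * ray_C$ci95_half_width))
    }
    if (!is.null(ray_H)) {
      akie_H <- stage("akie H", akie(epsilon_reactive_position(ray_H, pos), pos,
        ci95_half_width = (pos$n_total / pos$x_reactive) * ray_H$ci95_half_width))
    }
    dual <- stage("fit_lambda", fit_lambda(iso))
    if (!is.null(ray_C) && !is.null(ray_H)) {
      lam_ratio <- stage("lambda ratio", lambda_from_epsilons(ray_H, ray_C))
    }
    if (!is.null(dual)) {
      redox <- stage("classify_redox",
        classify_redox(dual$lambda_slope, ci95_half_width = dual$ci95_half_width))
    }
  }

  kin <- list()
  for (nm in names(live)) {
    ctrl_s <- if (!is.null(ctrl_in) && nm %in% names(ctrl_in$series)) ctrl_in$series[[nm]] else NULL
    curve <- stage(sprintf("residual_percentage %s", nm),
      residual_percentage(live[[nm]], ctrl_s, use_internal_std = use_internal_std))
    if (!is.null(curve)) {
      kin[[nm]] <- stage(sprintf("kinetics_summary %s", nm), kinetics_summary(curve))
    }
  }

  structure(
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      package_version = as.character(utils::packageVersion("csiaray")),
      input_digest = c(series = live_in$digest,
        control = if (is.null(ctrl_in)) NA_character_ else ctrl_in$digest),
      config = list(isotope_compound = isotope_compound, forced_origin = forced_origin,
        position_params = unclass(pos), use_internal_std = use_internal_std,
        allow_partial = allow_partial),
      rayleigh_C = ray_C, rayleigh_H = ray_H,
      akie_C = akie_C, akie_H = akie_H,
      dual_isotope = dual, lambda_epsilon_ratio = lam_ratio,
      redox = redox, kinetics = kin,
      warnings = warnings
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> schema %s, csiaray %s\n", x$schema_version, x$package_version))
  fmt_fit <- function(f) {
    if (is.null(f)) return("unavailable")
    sprintf("%.3g +/- %.2g permil (R2 = %.3f, n = %d)",
      f$epsilon_bulk, f$ci95_half_width, f$r_squared, f$n_points)
  }
  # summary table in the layout of a literature enrichment-factor table
  cat(sprintf("  epsilon_C: %s\n", fmt_fit(x$rayleigh_C)))
  cat(sprintf("  epsilon_H: %s\n", fmt_fit(x$rayleigh_H)))
  if (!is.null(x$akie_C)) cat(sprintf("  AKIE_C:    %.4f\n", x$akie_C$akie))
  if (!is.null(x$akie_H)) cat(sprintf("  AKIE_H:    %.4f\n", x$akie_H$akie))
  if (!is.null(x$dual_isotope)) {
    cat(sprintf("  lambda:    %.3f +/- %.3f (regression; epsilon ratio %.3f)\n",
      x$dual_isotope$lambda_slope, x$dual_isotope$ci95_half_width,
      if (is.null(x$lambda_epsilon_ratio)) NA_real_ else x$lambda_epsilon_ratio))
  }
  if (!is.null(x$redox)) cat(sprintf("  redox:     %s\n", x$redox$category))
  for (k in x$kinetics) {
    cat("  "); print(k)
  }
  if (length(x$warnings)) cat(sprintf("  warnings: %s\n", paste(x$warnings, collapse = "; ")))
  invisible(x)
}

# Strip S3 classes recursively so jsonlite serializes plain structures.
as_plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x), stringsAsFactors = FALSE))
  if (is.list(x)) return(lapply(unclass(x), as_plain))
  x
}

#' Write an analysis report to disk
#'
#' @param report an [run_full_analysis()] report.
#' @param path output path.
#' @param format `"json"` (full nested report) or `"tsv"` (flat key/value
#'   table of the headline numbers).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as_plain(report), path, auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)
  } else {
    rows <- report_headline(report)
    utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

report_headline <- function(report) {
  grab <- function(obj, field) if (is.null(obj)) NA_real_ else obj[[field]]
  data.frame(
    quantity = c("epsilon_C_permil", "epsilon_C_ci95", "epsilon_H_permil", "epsilon_H_ci95",
      "akie_C", "akie_H", "lambda_regression", "lambda_ci95", "lambda_epsilon_ratio",
      "redox_category"),
    value = c(
      grab(report$rayleigh_C, "epsilon_bulk"), grab(report$rayleigh_C, "ci95_half_width"),
      grab(report$rayleigh_H, "epsilon_bulk"), grab(report$rayleigh_H, "ci95_half_width"),
      grab(report$akie_C, "akie"), grab(report$akie_H, "akie"),
      grab(report$dual_isotope, "lambda_slope"), grab(report$dual_isotope, "ci95_half_width"),
      if (is.null(report$lambda_epsilon_ratio)) NA_real_ else report$lambda_epsilon_ratio,
      if (is.null(report$redox)) NA else report$redox$category
    ),
    stringsAsFactors = FALSE
  )
}
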