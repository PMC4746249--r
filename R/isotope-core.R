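# Elementary delta-notation / isotope-ratio conversions and the
# isotope_series container consumed by every downstream stage.

#' Internal: raise a classed error
#'
#' @param msg message text
#' @param class subclass tag prepended to "csiaray_error"
#' @noRd
abort_csia <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "csiaray_error", "error", "condition")))
}

#' Isotope reference standards
#'
#' Returns the international reference standard for an element: VPDB for
#' carbon (13C/12C) and VSMOW for hydrogen (2H/1H), with its absolute
#' heavy/light abundance ratio. The absolute ratio is only needed when
#' exporting absolute isotope ratios; all regression math in this package
#' uses standard-free per-mil ratio factors, so the choice of absolute
#' value never enters a fit.
#'
#' @param element `"C"` or `"H"`.
#' @return A list with fields `element`, `name`, and `absolute_ratio`.
#' @examples
#' iso_standard("C")$name # "VPDB"
#' @export
iso_standard <- function(element = c("C", "H")) {
  element <- match.arg(element)
  switch(element,
    C = list(element = "C", name = "VPDB", absolute_ratio = 0.0111802),
    H = list(element = "H", name = "VSMOW", absolute_ratio = 0.00015576)
  )
}

check_delta_domain <- function(delta) {
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    abort_csia(
      "delta values must be finite and > -1000 permil (isotope ratio must stay positive)",
      "csiaray_domain_error"
    )
  }
  invisible(delta)
}

#' Convert a delta value (permil) to an absolute isotope ratio
#'
#' @param delta delta value(s) in permil relative to the element's standard.
#' @param element `"C"` (vs VPDB) or `"H"` (vs VSMOW).
#' @param standard an [iso_standard()]; must match `element`.
#' @return Absolute heavy/light isotope ratio(s): `(delta/1000 + 1) * R_standard`.
#' @seealso [ratio_to_delta()] for the exact inverse.
#' @examples
#' delta_to_ratio(0, "C") # the VPDB ratio itself
#' delta_to_ratio(-25.2, "C")
#' @export
delta_to_ratio <- function(delta, element = c("C", "H"), standard = iso_standard(element)) {
  element <- match.arg(element)
  if (!identical(standard$element, element)) {
    abort_csia(
      sprintf("standard '%s' is for element %s, not %s", standard$name, standard$element, element),
      "csiaray_element_error"
    )
  }
  check_delta_domain(delta)
  (delta / 1000 + 1) * standard$absolute_ratio
}

#' Convert an absolute isotope ratio to a delta value (permil)
#'
#' @param ratio absolute heavy/light isotope ratio(s), > 0.
#' @inheritParams delta_to_ratio
#' @return delta value(s) in permil: `(ratio/R_standard - 1) * 1000`.
#' @export
ratio_to_delta <- function(ratio, element = c("C", "H"), standard = iso_standard(element)) {
  element <- match.arg(element)
  if (!identical(standard$element, element)) {
    abort_csia(
      sprintf("standard '%s' is for element %s, not %s", standard$name, standard$element, element),
      "csiaray_element_error"
    )
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort_csia("isotope ratios must be finite and positive", "csiaray_domain_error")
  }
  (ratio / standard$absolute_ratio - 1) * 1000
}

#' Standard-free isotope ratio factor R_t/R_0
#'
#' Computes `R_t/R_0 = (delta_t + 1000) / (delta_0 + 1000)` directly from two
#' delta values of the same element. The reference-standard ratio cancels, so
#' the result is independent of VPDB/VSMOW absolute values. This is the form
#' used on the y axis of Rayleigh double-log plots.
#'
#' @param delta_t delta value at time t (permil).
#' @param delta_0 delta value at the reference point (permil).
#' @param element optional element tag for both values; purely a guard
#'   against accidentally mixing carbon and hydrogen deltas when the caller
#'   tracks elements, e.g. `ratio_factor(dC_t, dC_0, element = c("C", "C"))`.
#' @return Dimensionless ratio(s) R_t/R_0.
#' @examples
#' ratio_factor(-21.2, -25.2)
#' @export
ratio_factor <- function(delta_t, delta_0, element = NULL) {
  if (!is.null(element)) {
    element <- as.character(element)
    if (length(unique(element)) != 1L) {
      abort_csia("delta_t and delta_0 must be deltas of the same element", "csiaray_element_error")
    }
  }
  check_delta_domain(delta_t)
  check_delta_domain(delta_0)
  (delta_t + 1000) / (delta_0 + 1000)
}

#' Fraction of compound remaining
#'
#' `f = C_t / C_0` relative to the series' reference point. Values above 1
#' (evaporative or handling artifacts) are retained, never clipped; they are
#' reported through the `"above_unity"` attribute and a warning so that the
#' caller can decide whether to drop them.
#'
#' @param series an [isotope_series()].
#' @param t_index optional indices of the measurements to evaluate; default
#'   all measurements.
#' @return Numeric vector of f values with a logical attribute
#'   `"above_unity"` marking points with f > 1.
#' @export
fraction_remaining <- function(series, t_index = NULL) {
  stopifnot(inherits(series, "isotope_series"))
  t0 <- attr(series, "t0_index")
  c0 <- series$conc[t0]
  if (!is.finite(c0) || c0 <= 0) {
    abort_csia("reference concentration C_0 must be positive", "csiaray_domain_error")
  }
  if (is.null(t_index)) t_index <- seq_len(nrow(series))
  f <- series$conc[t_index] / c0
  above <- !is.na(f) & f > 1
  if (any(above)) {
    warning(sprintf("%d point(s) with f > 1 retained and flagged (not clipped)", sum(above)),
      call. = FALSE
    )
  }
  structure(f, above_unity = above)
}

#' Extent of degradation B (percent)
#'
#' `B = (1 - f) * 100`, the percentage of the compound removed.
#'
#' @param f fraction remaining, >= 0.
#' @return Extent of degradation in percent.
#' @examples
#' extent_of_degradation(0.40) # 60 percent removed
#' @export
extent_of_degradation <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) {
    abort_csia("fraction remaining f must be finite and >= 0", "csiaray_domain_error")
  }
  (1 - f) * 100
}

#' Construct a per-compound isotope measurement series
#'
#' The central container: an ordered time series of concentration and
#' (optionally) carbon/hydrogen isotope measurements for one compound in one
#' flask. Stored as a data frame with columns `time`, `conc`,
#' `conc_control`, `conc_internal_std`, `delta13C`, `delta2H`, plus
#' attributes `compound` and `t0_index` (the reference point all f values
#' and delta shifts are taken against).
#'
#' @param time sampling times in days, strictly increasing, >= 0.
#' @param conc compound concentration in ppm (mass fraction), >= 0.
#' @param compound compound name (e.g. `"benzene"`).
#' @param conc_control matching abiotic-control concentration (ppm), optional.
#' @param conc_internal_std internal-standard concentration in the same
#'   flask (ppm), optional.
#' @param delta13C delta13C of the residual compound (permil vs VPDB), optional.
#' @param delta2H delta2H of the residual compound (permil vs VSMOW), optional.
#' @param t0_index index of the reference measurement (default 1); must have
#'   `conc > 0`.
#' @return An object of class `isotope_series`.
#' @export
isotope_series <- function(time, conc, compound,
                           conc_control = NULL, conc_internal_std = NULL,
                           delta13C = NULL, delta2H = NULL, t0_index = 1L) {
  n <- length(time)
  if (n < 1L) abort_csia("an isotope_series needs at least one measurement", "csiaray_input_error")
  if (length(conc) != n) abort_csia("time and conc must have equal length", "csiaray_input_error")
  if (any(!is.finite(time)) || any(time < 0)) {
    abort_csia("times must be finite and >= 0 (days)", "csiaray_input_error")
  }
  if (any(diff(time) <= 0)) {
    abort_csia("times must be strictly increasing", "csiaray_input_error")
  }
  if (any(conc < 0, na.rm = TRUE)) {
    abort_csia("concentrations must be >= 0", "csiaray_input_error")
  }
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else {
    stopifnot(length(x) == n)
    as.numeric(x)
  }
  conc_control <- fill(conc_control)
  conc_internal_std <- fill(conc_internal_std)
  if (any(conc_control < 0, na.rm = TRUE) || any(conc_internal_std < 0, na.rm = TRUE)) {
    abort_csia("concentrations must be >= 0", "csiaray_input_error")
  }
  delta13C <- fill(delta13C)
  delta2H <- fill(delta2H)
  if (any(delta13C <= -1000, na.rm = TRUE) || any(delta2H <= -1000, na.rm = TRUE)) {
    abort_csia("delta values must be > -1000 permil", "csiaray_domain_error")
  }
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > n) abort_csia("t0_index out of range", "csiaray_input_error")
  if (is.na(conc[t0_index]) || conc[t0_index] <= 0) {
    abort_csia("the t0 measurement must have conc > 0", "csiaray_input_error")
  }
  out <- data.frame(
    time = as.numeric(time), conc = as.numeric(conc),
    conc_control = conc_control, conc_internal_std = conc_internal_std,
    delta13C = delta13C, delta2H = delta2H
  )
  structure(out,
    compound = as.character(compound), t0_index = t0_index,
    class = c("isotope_series", "data.frame")
  )
}

#' @export
print.isotope_series <- function(x, ...) {
  cat(sprintf(
    "<isotope_series> %s: %d measurements over %g-%g days (t0 = #%d)\n",
    attr(x, "compound"), nrow(x), min(x$time), max(x$time), attr(x, "t0_index")
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}

delta_column <- function(element) {
  switch(match.arg(element, c("C", "H")), C = "delta13C", H = "delta2H")
}

#' Read microcosm time-series tables
#'
#' Reads the package's delimited time-series format: a UTF-8 table (tab or
#' comma separated, autodetected) with header names `time_days`, `compound`,
#' `conc`, and optionally `conc_control`, `conc_internal_std`,
#' `delta13C_permil`, `delta2H_permil`. Empty cells are allowed in optional
#' columns; lines starting with `#` are comments. Rows are split by compound
#' into one [isotope_series()] each.
#'
#' @param path path to the delimited file.
#' @return A named list of `isotope_series`, one per compound, in order of
#'   first appearance.
#' @seealso [write_isotope_series()]
#' @export
read_isotope_series <- function(path) {
  if (!file.exists(path)) abort_csia(sprintf("input file not found: %s", path), "csiaray_io_error")
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  if (length(first) == 0L) abort_csia(sprintf("empty input file: %s", path), "csiaray_parse_error")
  sep <- if (grepl("\t", first[[1L]])) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, comment.char = "#",
    stringsAsFactors = FALSE, fileEncoding = "UTF-8", na.strings = c("NA", "")
  )
  required <- c("time_days", "compound", "conc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort_csia(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "csiaray_parse_error"
    )
  }
  opt <- function(col) if (col %in% names(df)) df[[col]] else rep(NA_real_, nrow(df))
  df$conc_control <- opt("conc_control")
  df$conc_internal_std <- opt("conc_internal_std")
  df$delta13C_permil <- opt("delta13C_permil")
  df$delta2H_permil <- opt("delta2H_permil")
  out <- list()
  for (cmp in unique(df$compound)) {
    rows <- df[df$compound == cmp, , drop = FALSE]
    rows <- rows[order(rows$time_days), , drop = FALSE]
    out[[cmp]] <- isotope_series(
      time = rows$time_days, conc = rows$conc, compound = cmp,
      conc_control = rows$conc_control, conc_internal_std = rows$conc_internal_std,
      delta13C = rows$delta13C_permil, delta2H = rows$delta2H_permil
    )
  }
  out
}

#' Write isotope series to the delimited time-series format
#'
#' @param series an `isotope_series` or a (possibly named) list of them.
#' @param path output file path; tab-separated with the documented header.
#' @return `path`, invisibly.
#' @export
write_isotope_series <- function(series, path) {
  if (inherits(series, "isotope_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(
      time_days = s$time, compound = attr(s, "compound"), conc = s$conc,
      conc_control = s$conc_control, conc_internal_std = s$conc_internal_std,
      delta13C_permil = s$delta13C, delta2H_permil = s$delta2H
    )
  }))
  utils::write.table(rows, path,
    sep = "\t", row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8", na = ""
  )
  invisible(path)
}
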