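# Degradation-monitoring bookkeeping: control-normalized residual curves,
# lag and halt detection, and biomass doubling time.

#' Control-normalized residual percentage curve
#'
#' Expresses the live-flask concentration as a percentage of the abiotic
#' control at the same time point: `100 * C_t / C_c`, or, with an internal
#' standard, `100 * (C_t / IS_t) / (C_c / IS_c)`. Internal-standard
#' normalization cancels physical losses shared by all compounds in a flask
#' (septa absorption, sampling), so only biological removal remains. Time
#' points must match exactly between live and control series; no
#' interpolation is performed — silent alignment errors are worse than a
#' hard failure.
#'
#' @param series live-flask [isotope_series()].
#' @param control matching abiotic-control `isotope_series`. May be `NULL`
#'   if `series` carries a `conc_control` column (single-file input), in
#'   which case internal-standard normalization is unavailable (the control
#'   flask's internal standard is not in that layout).
#' @param use_internal_std normalize both flasks to their
#'   `conc_internal_std` column (requires `control`).
#' @return An object of class `residual_curve`: data frame with `time`
#'   (days) and `residual_pct`, attributes `compound` and `normalization`
#'   (`"control_only"` or `"control_and_internal_std"`).
#' @export
residual_percentage <- function(series, control = NULL, use_internal_std = FALSE) {
  stopifnot(inherits(series, "isotope_series"))
  if (is.null(control)) {
    if (all(is.na(series$conc_control))) {
      abort_csia("no control series and no conc_control column: cannot normalize",
        "csiaray_input_error")
    }
    if (use_internal_std) {
      abort_csia("internal-standard normalization needs an explicit control series",
        "csiaray_input_error")
    }
    cc <- series$conc_control
    times <- series$time
    ct <- series$conc
  } else {
    stopifnot(inherits(control, "isotope_series"))
    if (nrow(series) != nrow(control) || any(series$time != control$time)) {
      abort_csia("live and control series must share exactly matching time points",
        "csiaray_input_error")
    }
    times <- series$time
    ct <- series$conc
    cc <- control$conc
    if (use_internal_std) {
      is_t <- series$conc_internal_std
      is_c <- control$conc_internal_std
      if (any(is.na(is_t)) || any(is.na(is_c))) {
        abort_csia("internal-standard concentrations missing in live or control series",
          "csiaray_input_error")
      }
      if (any(is_t <= 0) || any(is_c <= 0)) {
        abort_csia("internal-standard concentrations must be > 0", "csiaray_domain_error")
      }
      ct <- ct / is_t
      cc <- cc / is_c
    }
  }
  if (any(is.na(cc))) {
    abort_csia("missing matched control concentration", "csiaray_input_error")
  }
  if (any(cc <= 0)) {
    abort_csia("control concentration must be > 0 at every matched time", "csiaray_domain_error")
  }
  structure(
    data.frame(time = times, residual_pct = 100 * ct / cc),
    compound = attr(series, "compound"),
    normalization = if (use_internal_std) "control_and_internal_std" else "control_only",
    class = c("residual_curve", "data.frame")
  )
}

#' @export
print.residual_curve <- function(x, ...) {
  cat(sprintf(
    "<residual_curve> %s (%s): %d points, %g-%g days, final residual %.1f%%\n",
    attr(x, "compound"), attr(x, "normalization"), nrow(x),
    min(x$time), max(x$time), x$residual_pct[nrow(x)]
  ))
  invisible(x)
}

#' Detect the lag phase of a residual curve
#'
#' The lag is the first sampled time at which the residual drops below
#' `100 - threshold_pct` and stays below it for `sustain_points`
#' consecutive samples (the sustain requirement guards against single noisy
#' dips). Returns `NA` when removal never starts.
#'
#' @param curve a [residual_percentage()] curve.
#' @param threshold_pct removal (percentage points below 100) that counts
#'   as degradation onset; default 5.
#' @param sustain_points consecutive sub-threshold samples required;
#'   default 2.
#' @return Lag time in days, or `NA_real_` if no sustained onset is found.
#' @export
detect_lag <- function(curve, threshold_pct = 5, sustain_points = 2L) {
  stopifnot(inherits(curve, "residual_curve"))
  n <- nrow(curve)
  sustain_points <- as.integer(sustain_points)
  if (n < sustain_points + 1L) {
    abort_csia(sprintf("detect_lag: %d point(s); need >= sustain_points + 1 = %d",
      n, sustain_points + 1L), "csiaray_precondition_error")
  }
  below <- curve$residual_pct < (100 - threshold_pct)
  for (i in seq_len(n - sustain_points + 1L)) {
    if (all(below[i:(i + sustain_points - 1L)])) {
      return(curve$time[i])
    }
  }
  NA_real_
}

#' Detect a degradation halt (plateau before complete removal)
#'
#' Scans trailing windows of the residual curve for a plateau: the fitted
#' slope magnitude of a `window_points`-point window falls to
#' `slope_tol` or below while removal is under way (extent above
#' `min_extent_pct`) but not complete (residual above
#' `complete_below_pct`). This is the signature of an inhibited culture —
#' removal that stops partway and never resumes — as opposed to a curve
#' that simply runs to completion.
#'
#' @param curve a [residual_percentage()] curve.
#' @param window_points points per trailing window (default 3).
#' @param slope_tol maximum slope magnitude, %/day, that counts as flat
#'   (default 0.05).
#' @param min_extent_pct removal extent (%) that must have been reached for
#'   a plateau to count as a halt rather than "never started" (default 10).
#' @param complete_below_pct residual (%) at or below which removal counts
#'   as complete, not halted (default 5).
#' @return List with `halted` (flag), `halt_time` (start of the first flat
#'   window, days; `NA` if not halted), `halt_extent_pct` (removal extent
#'   at the plateau), and `low_confidence` (too few points to judge).
#' @export
detect_halt <- function(curve, window_points = 3L, slope_tol = 0.05,
                        min_extent_pct = 10, complete_below_pct = 5) {
  stopifnot(inherits(curve, "residual_curve"))
  window_points <- as.integer(window_points)
  if (window_points < 2L) abort_csia("window_points must be >= 2", "csiaray_input_error")
  n <- nrow(curve)
  if (n < window_points) {
    return(list(halted = FALSE, halt_time = NA_real_, halt_extent_pct = NA_real_,
      low_confidence = TRUE))
  }
  for (end in window_points:n) {
    idx <- (end - window_points + 1L):end
    tt <- curve$time[idx]
    rr <- curve$residual_pct[idx]
    slope <- stats::cov(tt, rr) / stats::var(tt)
    extent <- 100 - rr[length(rr)]
    if (abs(slope) <= slope_tol && extent > min_extent_pct &&
      rr[length(rr)] > complete_below_pct) {
      return(list(
        halted = TRUE, halt_time = tt[1L],
        halt_extent_pct = mean(100 - rr), low_confidence = FALSE
      ))
    }
  }
  list(halted = FALSE, halt_time = NA_real_, halt_extent_pct = NA_real_,
    low_confidence = FALSE)
}

#' Summarize degradation kinetics of one residual curve
#'
#' @param curve a [residual_percentage()] curve.
#' @param ... passed to [detect_lag()] and [detect_halt()] (their shared
#'   defaults apply).
#' @return An object of class `kinetics_summary`: `compound`, `lag_days`,
#'   `removal_extent_pct` (at the final sample, clamped into \[0, 100\] with
#'   an `extent_out_of_range` flag when noise pushes it outside), `halted`,
#'   `halt_time`, `halt_extent_pct`, `low_confidence`.
#' @export
kinetics_summary <- function(curve, ...) {
  stopifnot(inherits(curve, "residual_curve"))
  args <- list(...)
  lag_args <- args[intersect(names(args), c("threshold_pct", "sustain_points"))]
  halt_args <- args[intersect(
    names(args),
    c("window_points", "slope_tol", "min_extent_pct", "complete_below_pct")
  )]
  lag <- tryCatch(do.call(detect_lag, c(list(curve), lag_args)),
    csiaray_precondition_error = function(e) NA_real_)
  halt <- do.call(detect_halt, c(list(curve), halt_args))
  extent_raw <- 100 - curve$residual_pct[nrow(curve)]
  structure(
    list(
      compound = attr(curve, "compound"),
      lag_days = lag,
      removal_extent_pct = min(max(extent_raw, 0), 100),
      extent_out_of_range = extent_raw < 0 || extent_raw > 100,
      halted = halt$halted, halt_time = halt$halt_time,
      halt_extent_pct = halt$halt_extent_pct, low_confidence = halt$low_confidence
    ),
    class = "kinetics_summary"
  )
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(
    "<kinetics_summary> %s: lag = %s d, removal = %.1f%%%s\n",
    x$compound, if (is.na(x$lag_days)) "none" else format(x$lag_days),
    x$removal_extent_pct,
    if (x$halted) sprintf(", HALTED at day %g (%.0f%% removed)", x$halt_time, x$halt_extent_pct) else ""
  ))
  invisible(x)
}

#' Exponential-growth doubling time between two cell counts
#'
#' Assumes log-linear growth between the two observations:
#' `t_d = dt * ln 2 / ln(n2 / n1)`.
#'
#' @param n1,n2 cell densities (cells/mL) at the start and end; `n2 > n1`.
#' @param dt elapsed time in days, > 0.
#' @return Doubling time in days.
#' @examples
#' doubling_time(3.6e6, 1.2e7, 35)
#' @export
doubling_time <- function(n1, n2, dt) {
  if (any(c(n1, n2) <= 0) || dt <= 0) {
    abort_csia("cell counts and dt must be positive", "csiaray_domain_error")
  }
  if (n2 <= n1) {
    abort_csia("no growth observed (n2 <= n1): doubling time undefined", "csiaray_domain_error")
  }
  dt * log(2) / log(n2 / n1)
}
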