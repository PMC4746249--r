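# Linearized Rayleigh-model regression: bulk enrichment factors,
# position-specific correction, and apparent kinetic isotope effects.

#' Fit the linearized Rayleigh model to an isotope series
#'
#' Closed-system Rayleigh distillation predicts
#' `ln(R_t/R_0) = (epsilon/1000) * ln(C_t/C_0)`; the bulk enrichment factor
#' epsilon (permil) is the ordinary least-squares slope of `ln(R_t/R_0)` on
#' `ln f` multiplied by 1000. The reference point contributes the exact
#' point (0, 0). The linearization is exact (not a small-fractionation
#' approximation), so a noiseless Rayleigh series is recovered to machine
#' precision with R-squared 1.
#'
#' @param series an [isotope_series()] with concentrations and the chosen
#'   element's delta values.
#' @param element `"C"` or `"H"`.
#' @param forced_origin force the regression line through (0, 0). The
#'   default is a free intercept, reported as a diagnostic: a non-zero
#'   intercept flags departure from the Rayleigh form or a mis-chosen
#'   reference point. With a free intercept at least 3 usable points are
#'   required; with a forced origin, 2.
#' @return An object of class `rayleigh_fit`: a list with `element`,
#'   `epsilon_bulk` (permil), `ci95_half_width` (permil, two-sided 95%
#'   t-interval on the slope), `r_squared`, `n_points`, `intercept`
#'   (dimensionless diagnostic), `forced_origin`, `slope_se` (permil), and
#'   `data` (the regression points `ln_f`, `ln_R`, exportable as plot data).
#' @examples
#' f <- c(1, 0.7, 0.4, 0.19)
#' d <- ((-25.2) + 1000) * f^(-2.4 / 1000) - 1000
#' s <- isotope_series(time = 0:3 * 30, conc = 12 * f, compound = "benzene", delta13C = d)
#' fit_rayleigh(s, "C")
#' @export
fit_rayleigh <- function(series, element = c("C", "H"), forced_origin = FALSE) {
  stopifnot(inherits(series, "isotope_series"))
  element <- match.arg(element)
  dcol <- delta_column(element)
  t0 <- attr(series, "t0_index")
  d0 <- series[[dcol]][t0]
  c0 <- series$conc[t0]
  if (is.na(d0)) {
    abort_csia(sprintf("t0 measurement lacks %s", dcol), "csiaray_input_error")
  }
  if (!is.finite(c0) || c0 <= 0) {
    abort_csia("reference concentration C_0 must be positive", "csiaray_domain_error")
  }
  usable <- !is.na(series$conc) & !is.na(series[[dcol]])
  if (any(usable & series$conc == 0)) {
    abort_csia("all concentrations entering the fit must be > 0 (log undefined at C_t = 0)",
      "csiaray_domain_error")
  }
  ln_f <- log(series$conc[usable] / c0)
  ln_R <- log(ratio_factor(series[[dcol]][usable], d0))
  n <- length(ln_f)
  n_min <- if (forced_origin) 2L else 3L
  if (n < n_min) {
    abort_csia(
      sprintf("fit_rayleigh (%s): %d usable point(s); need >= %d%s", element, n, n_min,
        if (forced_origin) " with forced_origin" else ""),
      "csiaray_precondition_error"
    )
  }
  if (isTRUE(all.equal(stats::var(ln_f), 0)) || stats::var(ln_f) == 0) {
    abort_csia("zero variance in ln f: concentrations carry no degradation signal",
      "csiaray_precondition_error")
  }
  fit <- if (forced_origin) stats::lm(ln_R ~ 0 + ln_f) else stats::lm(ln_R ~ ln_f)
  # exact-model (noiseless) series are a designed use; muffle lm's
  # perfect-fit warning, the ~0 standard error is then the honest answer
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  slope_row <- sm$coefficients["ln_f", ]
  slope <- unname(slope_row["Estimate"])
  se <- unname(slope_row["Std. Error"])
  df <- fit$df.residual
  half <- if (df > 0) stats::qt(0.975, df) * se else NA_real_
  structure(
    list(
      element = element,
      epsilon_bulk = slope * 1000,
      ci95_half_width = half * 1000,
      r_squared = sm$r.squared,
      n_points = n,
      intercept = if (forced_origin) 0 else unname(stats::coef(fit)[["(Intercept)"]]),
      forced_origin = forced_origin,
      slope_se = se * 1000,
      data = data.frame(ln_f = ln_f, ln_R = ln_R)
    ),
    class = "rayleigh_fit"
  )
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat(sprintf(
    "<rayleigh_fit> %s: epsilon_bulk = %.4g permil (95%% CI +/- %.3g), R2 = %.4f, n = %d%s\n",
    x$element, x$epsilon_bulk, x$ci95_half_width, x$r_squared, x$n_points,
    if (x$forced_origin) ", forced origin" else sprintf(", intercept = %.3g", x$intercept)
  ))
  invisible(x)
}

#' Position parameters for intramolecular isotope bookkeeping
#'
#' Describes how many atoms of the fitted element sit in identical reactive
#' positions: `n_total` atoms in the molecule, `x_reactive` at the reactive
#' site, and `z` in identical reactive positions competing for the same
#' bond-breaking step. Benzene is fully symmetric for both carbon and
#' hydrogen, so the default is z = x = n = 6 and the bulk enrichment factor
#' needs no positional dilution correction.
#'
#' @param z atoms in identical reactive positions (default 6).
#' @param n_total atoms of the element in the molecule (default 6).
#' @param x_reactive atoms at the reactive site (default 6).
#' @return An object of class `position_params`.
#' @export
position_params <- function(z = 6L, n_total = 6L, x_reactive = 6L) {
  z <- as.integer(z); n_total <- as.integer(n_total); x_reactive <- as.integer(x_reactive)
  if (!(1L <= z && z <= x_reactive && x_reactive <= n_total)) {
    abort_csia("need 1 <= z <= x_reactive <= n_total", "csiaray_input_error")
  }
  structure(list(z = z, n_total = n_total, x_reactive = x_reactive),
    class = "position_params")
}

#' Reactive-position enrichment factor
#'
#' Dilution correction from the bulk to the reactive-position enrichment
#' factor: `epsilon_rp = (n_total / x_reactive) * epsilon_bulk`. For a fully
#' symmetric molecule like benzene (n = x) this is the identity.
#'
#' @param epsilon_bulk bulk enrichment factor in permil, or a `rayleigh_fit`.
#' @param pos a [position_params()].
#' @return Reactive-position enrichment factor in permil.
#' @export
epsilon_reactive_position <- function(epsilon_bulk, pos = position_params()) {
  stopifnot(inherits(pos, "position_params"))
  if (inherits(epsilon_bulk, "rayleigh_fit")) epsilon_bulk <- epsilon_bulk$epsilon_bulk
  (pos$n_total / pos$x_reactive) * epsilon_bulk
}

#' Apparent kinetic isotope effect
#'
#' `AKIE = 1 / (1 + z * epsilon_rp / 1000)` with z the number of atoms in
#' identical reactive positions (6 for benzene, carbon and hydrogen alike).
#' AKIE > 1 corresponds to a normal kinetic isotope effect (epsilon_rp < 0).
#' If a confidence half-width on epsilon_rp is supplied the same transform
#' is applied to the interval endpoints; because the transform is nonlinear
#' the interval is asymmetric and the larger half-width is reported, with
#' both bounds retained.
#'
#' @param epsilon_rp reactive-position enrichment factor in permil.
#' @param pos a [position_params()]; only `z` is used.
#' @param ci95_half_width optional 95% half-width on `epsilon_rp` (permil).
#' @return An object of class `akie_result`: list with `akie`,
#'   `ci95_half_width`, `ci_bounds` (lower/upper AKIE), and
#'   `epsilon_reactive_position`.
#' @examples
#' akie(-2.4) # benzene carbon
#' @export
akie <- function(epsilon_rp, pos = position_params(), ci95_half_width = NA_real_) {
  stopifnot(inherits(pos, "position_params"))
  denom <- 1 + pos$z * epsilon_rp / 1000
  if (!is.finite(denom) || denom <= 0) {
    abort_csia("AKIE undefined: 1 + z * epsilon_rp/1000 must be > 0", "csiaray_domain_error")
  }
  val <- 1 / denom
  bounds <- half <- NA_real_
  if (is.finite(ci95_half_width)) {
    ends <- 1 + pos$z * (epsilon_rp + c(-1, 1) * ci95_half_width) / 1000
    if (any(ends <= 0)) {
      abort_csia("AKIE CI endpoint outside the admissible domain", "csiaray_domain_error")
    }
    bounds <- sort(1 / ends)
    half <- max(abs(bounds - val))
  }
  structure(
    list(akie = val, ci95_half_width = half, ci_bounds = bounds,
      epsilon_reactive_position = epsilon_rp, z = pos$z),
    class = "akie_result"
  )
}

#' @export
print.akie_result <- function(x, ...) {
  ci <- if (is.finite(x$ci95_half_width)) sprintf(" +/- %.4f", x$ci95_half_width) else ""
  cat(sprintf("<akie_result> AKIE = %.4f%s (z = %d, epsilon_rp = %.3g permil)\n",
    x$akie, ci, x$z, x$epsilon_reactive_position))
  invisible(x)
}
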