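# Independent oracles and fixture builders shared across test files.
# These deliberately avoid the package's own fitting code paths.

# Closed-form least-squares slope from explicit sums (no lm()).
ols_slope_oracle <- function(x, y, forced_origin = FALSE) {
  n <- length(x)
  if (forced_origin) {
    return(sum(x * y) / sum(x * x))
  }
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x * x) - sum(x)^2)
}

# Exact Rayleigh delta trajectory: delta(f) = (d0 + 1000) * f^(eps/1000) - 1000.
exact_rayleigh_delta <- function(f, eps, delta0) {
  (delta0 + 1000) * f^(eps / 1000) - 1000
}

# Noiseless exact-Rayleigh isotope series on an f grid.
exact_series <- function(f, eps_C = -2.4, eps_H = -57,
                         delta13C_0 = -25.2, delta2H_0 = -43.5, c0 = 12) {
  isotope_series(
    time = (seq_along(f) - 1) * 30, conc = c0 * f, compound = "benzene",
    delta13C = exact_rayleigh_delta(f, eps_C, delta13C_0),
    delta2H = exact_rayleigh_delta(f, eps_H, delta2H_0)
  )
}

# Residual curve fixture from raw vectors (bypasses residual_percentage).
raw_curve <- function(time, residual_pct, compound = "benzene") {
  structure(
    data.frame(time = time, residual_pct = residual_pct),
    compound = compound, normalization = "control_only",
    class = c("residual_curve", "data.frame")
  )
}

# Canonical 10-point f grid spanning 1 -> 0.19, geometric spacing
# (uniform in time under first-order kinetics).
f_grid_10 <- exp(seq(0, log(0.19), length.out = 10))
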