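# Independent oracles used across tests.

# sd-ratio RMA slope, computed without touching the package internals
rma_slope_oracle <- function(x, y) {
  sign(stats::cor(x, y)) * stats::sd(y) / stats::sd(x)
}

# numerical integration of the cross-section of a linear taper between two
# diameters (cm) over a section of length L (m); volume in m^3
taper_integral_oracle <- function(d1_cm, d2_cm, L_m) {
  if (L_m == 0) return(0)
  stats::integrate(function(h) {
    d <- (d1_cm + (d2_cm - d1_cm) * h / L_m) / 100
    pi * d^2 / 4
  }, 0, L_m, rel.tol = 1e-12)$value
}

# one noisy log10-scale site on a known line, for fitting tests
make_log_site <- function(n, slope, intercept = 0, noise_sd = 0.05,
                          x_mean = 1, x_sd = 0.15) {
  x <- stats::rnorm(n, x_mean, x_sd)
  list(x = x, y = intercept + slope * x + stats::rnorm(n, 0, noise_sd))
}
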