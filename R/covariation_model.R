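#' The exponent-covariation model
#'
#' When stem volume follows V proportional to (D^2 H)^(1/phi) within a site,
#' the three site-level RMA exponents — x for H vs D, y' for D vs V, z' for
#' H vs V — are tied together by one shared parameter phi:
#' \deqn{y' = \phi / (2 + x), \quad z' = \phi / (1 + 2/x), \quad y' = (\phi - z')/2,}
#' and the normalization constants (log10 beta) move in lockstep with their
#' exponents. phi = 1 is the idealized V ~ D^2 H geometry; phi > 1 means the
#' taper-governed form factor shifts systematically with tree size. Because
#' phi enters each curve linearly, the least-squares estimate has a
#' closed form (zero-intercept regression on the curve's regressor).
#'
#' @name covariation_model
NULL

.curve_forms <- c("C1", "C2", "C3")

# regressor/response decomposition: response = phi * w for C1/C2;
# C3 rearranges to y' = (phi - z')/2, a shifted regression with d/dphi = 1/2
.phi_design <- function(curve_form, x, z) {
  switch(curve_form,
         C1 = {
           if (any(x <= -2)) stop("H-vs-D exponent x must exceed -2 for y' = phi/(2+x)")
           1 / (2 + x)
         },
         C2 = {
           if (any(x <= 0)) stop("H-vs-D exponent x must be positive for z' = phi/(1+2/x)")
           x / (2 + x)
         },
         C3 = {
           rep(0.5, length(z))
         })
}

#' Fit the shared covariation parameter phi
#'
#' Least-squares fit of one of the three exponent-covariation curves across
#' sites: `"C1"` fits y' = phi/(2+x) on (x, y') pairs, `"C2"` fits
#' z' = phi/(1+2/x) on (x, z') pairs, `"C3"` fits y' = (phi - z')/2 on
#' (z', y') pairs. phi is linear in every form, so the closed-form
#' zero-intercept solution is exact; r2 = 1 - SSE/SST with SST about the
#' response mean; the CI comes from the linear-model standard error with
#' n - 1 residual degrees of freedom.
#'
#' @param x Site H-vs-D RMA exponents (required for C1 and C2).
#' @param y Site D-vs-V RMA exponents y' (required for C1 and C3).
#' @param z Site H-vs-V RMA exponents z' (required for C2 and C3).
#' @param curve_form `"C1"`, `"C2"` or `"C3"`.
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `covariation_fit`: list with `curve_form`,
#'   `phi`, `ci_low`, `ci_high`, `r2`, `n_sites`.
#' @examples
#' x <- c(0.5, 1.0, 1.5)
#' fit_phi(x = x, y = 1.0 / (2 + x), curve_form = "C1")  # phi = 1 exactly
#' @export
fit_phi <- function(x = NULL, y = NULL, z = NULL,
                    curve_form = c("C1", "C2", "C3"), ci_level = 0.95) {
  curve_form <- match.arg(curve_form)
  resp <- switch(curve_form, C1 = y, C2 = z, C3 = y)
  if (is.null(resp)) stop("missing response exponents for curve ", curve_form)
  if (curve_form %in% c("C1", "C2")) {
    if (is.null(x)) stop("curve ", curve_form, " requires the H-vs-D exponents x")
    n <- length(x)
    if (length(resp) != n) stop("length mismatch between exponent vectors")
  } else {
    if (is.null(z)) stop("curve C3 requires the H-vs-V exponents z")
    n <- length(z)
    if (length(resp) != n) stop("length mismatch between exponent vectors")
  }
  if (n < 3) stop("at least 3 sites are required")
  w <- .phi_design(curve_form, x, z)
  # C3: y' + z'/2 = phi * (1/2); fold the shift into the response
  yy <- if (curve_form == "C3") resp + z / 2 else resp
  phi <- sum(w * yy) / sum(w^2)
  fitted <- if (curve_form == "C3") (phi - z) / 2 else phi * w
  res <- resp - fitted
  sse <- sum(res^2)
  sst <- sum((resp - mean(resp))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  se <- sqrt(sse / (n - 1)) / sqrt(sum(w^2))
  tq <- stats::qt(1 - (1 - ci_level) / 2, n - 1)
  structure(list(curve_form = curve_form, phi = phi,
                 ci_low = phi - tq * se, ci_high = phi + tq * se,
                 r2 = r2, n_sites = n),
            class = "covariation_fit")
}

#' @export
print.covariation_fit <- function(x, ...) {
  cat(sprintf("Covariation curve %s: phi = %.4f (%.4f-%.4f), r2 = %.4f, %d sites\n",
              x$curve_form, x$phi, x$ci_low, x$ci_high, x$r2, x$n_sites))
  invisible(x)
}

#' Linear fit of normalization constants against scaling exponents
#'
#' Within a species the log10 normalization constants track their own scaling
#' exponents linearly across sites (positively for D vs V and H vs V,
#' negatively for H vs D). Fits log10_constant = slope * exponent + intercept
#' by RMA (default, functional relationship) or OLS.
#'
#' @param exponent,log10_constant Numeric vectors, one value per site.
#' @param method `"RMA"` or `"OLS"`.
#' @param ci_level Confidence level for the slope interval.
#' @param relation Optional relation label carried through.
#' @return A `scaling_fit` whose `exponent` field is the line's slope and
#'   `log10_constant` its intercept.
#' @export
fit_constant_exponent_line <- function(exponent, log10_constant,
                                       method = c("RMA", "OLS"),
                                       ci_level = 0.95,
                                       relation = NA_character_) {
  method <- match.arg(method)
  n <- length(exponent)
  if (n < 3) stop("at least 3 points are required")
  if (length(log10_constant) != n) stop("length mismatch")
  if (stats::sd(exponent) == 0) stop("degenerate fit: exponents are constant")
  .fit_loglinear(exponent, log10_constant, method, ci_level, n,
                 NA_character_, relation)
}

#' Predicted exponents from the covariation curves
#'
#' @param phi Shared covariation parameter (> 0).
#' @param x H-vs-D scaling exponent(s) (> 0).
#' @return A list with `y` (= phi/(2+x), the D-vs-V exponent) and `z`
#'   (= phi/(1+2/x), the H-vs-V exponent); `z = x * y` and `2y + z = phi`
#'   hold identically.
#' @examples
#' covariation_predict(1.10, 1.0)
#' @export
covariation_predict <- function(phi, x) {
  if (any(phi <= 0)) stop("phi must be positive")
  if (any(x <= 0)) stop("the H-vs-D exponent x must be positive")
  list(y = phi / (2 + x), z = phi / (1 + 2 / x))
}

#' Predicted D-vs-V normalization constant from H-vs-D and H-vs-V fits
#'
#' For RMA fits sharing one set of trees, all three log-log lines pass
#' through the centroid, which forces
#' log10 beta5 = (log10 beta6 - log10 beta3) / x exactly. The function
#' evaluates that expression, predicting the D-vs-V constant from
#' nondestructively accessible fits.
#'
#' @param log_beta6 log10 normalization constant of H vs V.
#' @param log_beta3 log10 normalization constant of H vs D.
#' @param x H-vs-D scaling exponent (nonzero).
#' @return Predicted log10 beta5 (D-vs-V constant).
#' @export
predict_log_constant_DV <- function(log_beta6, log_beta3, x) {
  if (any(x == 0)) stop("the H-vs-D exponent x must be nonzero")
  (log_beta6 - log_beta3) / x
}
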