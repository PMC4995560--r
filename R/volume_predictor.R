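#' Nondestructive stem-volume prediction
#'
#' The prediction chain: (1) on development sites, fit phi on RMA exponent
#' pairs and OLS-regress the V-vs-D log10 constants on the V-vs-D exponents
#' to obtain log10 beta = c * alpha + d; (2) for a new site, convert its
#' (nondestructively measurable) H-vs-D exponent x into the V-vs-D exponent
#' alpha = (2 + x)/phi via the covariation curve; (3) predict each tree's
#' stem volume as log10 V = (c * alpha + d) + alpha * log10 D, V in m^3 and
#' D (DBH) in cm.
#'
#' @name volume_predictor
NULL

#' Calibrate the stem-volume prediction model
#'
#' OLS regression of development-site V-vs-D log10 constants on their
#' exponents, bundled with the covariation parameter phi.
#'
#' @param dev_site_fits Data frame of development-site fits with columns
#'   `site_id`, `exponent`, `log10_constant` — the V-vs-D OLS fits, one row
#'   per site (e.g. the `V_vs_D` rows of [fit_site_relations()] with
#'   `method = "OLS"`).
#' @param phi Covariation parameter, typically fitted on the same
#'   development sites with [fit_phi()].
#' @return An object of class `volume_model`: list with `phi`, `c`, `d`,
#'   `r2` (of the constant-vs-exponent regression), `calibration_sites`.
#' @export
calibrate_volume_model <- function(dev_site_fits, phi) {
  stopifnot(is.data.frame(dev_site_fits))
  need <- c("site_id", "exponent", "log10_constant")
  if (!all(need %in% names(dev_site_fits)))
    stop("dev_site_fits needs columns: ", paste(need, collapse = ", "))
  if (length(phi) != 1 || !is.finite(phi) || phi <= 0)
    stop("phi must be a single positive number")
  a <- dev_site_fits$exponent
  lb <- dev_site_fits$log10_constant
  if (length(a) < 3) stop("at least 3 development sites are required")
  if (stats::sd(a) == 0)
    stop("degenerate calibration: no spread in V-vs-D exponents")
  fit <- stats::lm(lb ~ a)
  cf <- unname(stats::coef(fit))
  r2 <- stats::cor(a, lb)^2
  structure(list(phi = phi, c = cf[2], d = cf[1], r2 = r2,
                 calibration_sites = as.character(dev_site_fits$site_id)),
            class = "volume_model")
}

#' @export
print.volume_model <- function(x, ...) {
  cat(sprintf(
    "Stem-volume prediction model: phi = %.4f, log10 beta = %.4f * alpha + %.4f (r2 = %.3f)\n",
    x$phi, x$c, x$d, x$r2))
  cat("Calibrated on", length(x$calibration_sites), "sites; V in m^3, D in cm\n")
  invisible(x)
}

#' V-vs-D exponent implied by a site's H-vs-D exponent
#'
#' @param x Site H-vs-D scaling exponent (> 0).
#' @param phi Covariation parameter (> 0).
#' @return The implied V-vs-D exponent (2 + x)/phi, the reciprocal of the
#'   covariation curve's y' = phi/(2 + x).
#' @examples
#' site_exponent_from_hd(1, 1)    # V ~ D^3 for an isometric cylinder
#' site_exponent_from_hd(1, 1.1)
#' @export
site_exponent_from_hd <- function(x, phi) {
  if (any(x <= 0)) stop("the H-vs-D exponent x must be positive")
  if (any(phi <= 0)) stop("phi must be positive")
  (2 + x) / phi
}

#' Predict stem volume nondestructively
#'
#' @param model A [calibrate_volume_model()] result.
#' @param x_site The target site's H-vs-D scaling exponent (> 0).
#' @param dbh_cm Tree diameter(s) at breast height, cm (> 0).
#' @return Predicted stem volume(s), m^3.
#' @export
predict_volume <- function(model, x_site, dbh_cm) {
  if (!inherits(model, "volume_model")) stop("model must be a volume_model")
  if (any(dbh_cm <= 0)) stop("DBH must be positive (cm)")
  alpha <- site_exponent_from_hd(x_site, model$phi)
  10^((model$c * alpha + model$d) + alpha * log10(dbh_cm))
}

#' Write / read a volume model as flat key-value text
#'
#' Plain-text serialization (one `key: value` per line) that round-trips a
#' `volume_model` losslessly (numbers stored at full precision).
#'
#' @param model A `volume_model`.
#' @param path File path.
#' @return `write_volume_model` returns `path` invisibly;
#'   `read_volume_model` returns the restored `volume_model`.
#' @export
write_volume_model <- function(model, path) {
  if (!inherits(model, "volume_model")) stop("model must be a volume_model")
  lines <- c(
    sprintf("phi: %.17g", model$phi),
    sprintf("c: %.17g", model$c),
    sprintf("d: %.17g", model$d),
    sprintf("r2: %.17g", model$r2),
    paste0("sites: ", paste(model$calibration_sites, collapse = ",")),
    "units: V in m^3, D in cm",
    paste0("created: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_volume_model
#' @export
read_volume_model <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- keys
  need <- c("phi", "c", "d", "r2", "sites")
  if (!all(need %in% keys)) stop("not a volume model file: missing keys")
  structure(list(phi = as.numeric(vals["phi"]), c = as.numeric(vals["c"]),
                 d = as.numeric(vals["d"]), r2 = as.numeric(vals["r2"]),
                 calibration_sites = strsplit(vals[["sites"]], ",")[[1]]),
            class = "volume_model")
}
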