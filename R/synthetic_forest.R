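#' Synthetic multi-site forests with known scaling ground truth
#'
#' Generates per-site tree tables (DBH, height, stem volume) and optional
#' stem-disc profiles that obey the covariation model exactly before noise:
#' within a site, log10 H = log10 beta3 + x * log10 D and
#' log10 V = log10 betaV + ((2 + x)/phi) * log10 D, with independent
#' lognormal (additive on log10) noise on H and V. All sites share the
#' covariation parameter phi and a pivot tree (DBH 15 cm, height 15 m), so
#' log10 beta3 = log10(15) * (1 - x): sites with steeper H-vs-D exponents
#' have lower constants, reproducing the empirical sign structure of the
#' constant-exponent relationships. The volume constant is anchored
#' geometrically: a pivot tree with the site's taper shape t, profile
#' d(h) = D_base * (1 - h/H)^t, has volume pi/4 * D_base^2 * H / (2t + 1),
#' and every simulated stem profile is scaled to integrate exactly to the
#' tree's noise-free volume.
#'
#' @name synthetic_forest
NULL

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic site
#'
#' @param site_id Site identifier.
#' @param n_trees Number of trees (>= 3).
#' @param x_true True H-vs-D scaling exponent (> 0).
#' @param phi_true Shared covariation parameter (> 0); default 1.10.
#' @param log_beta3_true log10 normalization constant of H vs D; defaults to
#'   the shared-pivot value `log10(15) * (1 - x_true)`.
#' @param dbh_mean_log10,dbh_sd_log10 Mean and sd of log10 DBH (cm); draws
#'   are truncated at 2.5 sd. Defaults 1.0 and 0.15 (median 10 cm).
#' @param noise_sd_logH,noise_sd_logV Log10-scale noise sds; defaults 0.05.
#' @param taper_shape Taper exponent t of the profile family
#'   `d(h) = D_base (1 - h/H)^t` (> 0); default 0.7, between a quadratic
#'   paraboloid (0.5) and a cone (1).
#' @param seed Integer seed; site generation is fully reproducible from it.
#' @return A `synthetic_site_spec` list.
#' @export
synthetic_site_spec <- function(site_id, n_trees = 50, x_true = 1,
                                phi_true = 1.10,
                                log_beta3_true = log10(15) * (1 - x_true),
                                dbh_mean_log10 = 1.0, dbh_sd_log10 = 0.15,
                                noise_sd_logH = 0.05, noise_sd_logV = 0.05,
                                taper_shape = 0.7, seed = 1L) {
  stopifnot(n_trees >= 3, x_true > 0, phi_true > 0, taper_shape > 0,
            noise_sd_logH >= 0, noise_sd_logV >= 0, dbh_sd_log10 >= 0)
  structure(list(site_id = site_id, n_trees = as.integer(n_trees),
                 x_true = x_true, phi_true = phi_true,
                 log_beta3_true = log_beta3_true,
                 dbh_mean_log10 = dbh_mean_log10, dbh_sd_log10 = dbh_sd_log10,
                 noise_sd_logH = noise_sd_logH, noise_sd_logV = noise_sd_logV,
                 taper_shape = taper_shape, seed = as.integer(seed)),
            class = "synthetic_site_spec")
}

# noise-free volume constant: pivot tree (15 cm, 15 m) with the site's taper
.log_betaV <- function(spec) {
  t <- spec$taper_shape
  h_ref <- 15
  d_ref <- 15
  d_base <- (d_ref / 100) / (1 - 1.3 / h_ref)^t
  v_ref <- pi / 4 * d_base^2 * h_ref / (2 * t + 1)
  alpha <- (2 + spec$x_true) / spec$phi_true
  log10(v_ref) - alpha * log10(d_ref)
}

#' Generate one synthetic site
#'
#' @param spec A [synthetic_site_spec()].
#' @param profiles If `TRUE`, also emit one [stem_profile()] per tree, with
#'   discs at [measurement_heights()] of the noise-free height and diameters
#'   scaled so the analytic taper integral equals the tree's noise-free
#'   volume.
#' @return A list with `trees` (data frame: `site_id`, `tree_id`, `dbh_cm`,
#'   `height_m`, `volume_m3`, `source = "synthetic"`), `profiles` (list of
#'   `stem_profile` or `NULL`), and `truth` (the spec plus derived
#'   `log_betaV_true` and `alpha_VD_true`).
#' @export
generate_site <- function(spec, profiles = FALSE) {
  if (!inherits(spec, "synthetic_site_spec")) stop("spec must be a synthetic_site_spec")
  alpha <- (2 + spec$x_true) / spec$phi_true
  lbV <- .log_betaV(spec)
  .with_seed(spec$seed, {
    z <- stats::rnorm(spec$n_trees)
    z <- pmin(pmax(z, -2.5), 2.5)
    ld <- spec$dbh_mean_log10 + spec$dbh_sd_log10 * z
    lh0 <- spec$log_beta3_true + spec$x_true * ld
    lv0 <- lbV + alpha * ld
    lh <- lh0 + stats::rnorm(spec$n_trees, 0, spec$noise_sd_logH)
    lv <- lv0 + stats::rnorm(spec$n_trees, 0, spec$noise_sd_logV)
    trees <- data.frame(
      site_id = as.character(spec$site_id),
      tree_id = sprintf("%s_t%03d", spec$site_id, seq_len(spec$n_trees)),
      dbh_cm = 10^ld, height_m = 10^lh, volume_m3 = 10^lv,
      source = "synthetic", stringsAsFactors = FALSE)
    profs <- NULL
    if (profiles) {
      t <- spec$taper_shape
      profs <- lapply(seq_len(spec$n_trees), function(i) {
        h0 <- 10^lh0[i]
        v0 <- 10^lv0[i]
        d_base_m <- sqrt(4 * v0 * (2 * t + 1) / (pi * h0))
        hs <- measurement_heights(h0)
        stem_profile(trees$tree_id[i], h0, hs,
                     100 * d_base_m * (1 - hs / h0)^t)
      })
    }
    truth <- c(unclass(spec), list(log_betaV_true = lbV, alpha_VD_true = alpha))
    list(trees = trees, profiles = profs, truth = truth)
  })
}

#' Generate a multi-site development/test study
#'
#' Builds `n_dev + n_test` sites whose true H-vs-D exponents are spread
#' evenly across `x_range` and alternately assigned to the development and
#' test partitions (so both partitions span the exponent range), all sharing
#' `phi_true`. Defaults mirror the study design the package targets: 12 + 12
#' sites, 50 trees per site, log10 noise sd 0.05, exponents spanning
#' 0.6-1.6.
#'
#' @param n_dev,n_test Numbers of development and test sites (>= 3 each).
#' @param n_trees Trees per site; scalar or vector of length
#'   `n_dev + n_test`.
#' @param phi_true Shared covariation parameter.
#' @param x_range Length-2 interval for the true H-vs-D exponents.
#' @param noise_sd Log10 noise sd applied to both H and V (scalar shortcut).
#' @param seed Study seed; per-site seeds are derived as
#'   `seed * 100 + site index`.
#' @param profiles Pass-through to [generate_site()].
#' @param ... Further per-site arguments forwarded to
#'   [synthetic_site_spec()] (e.g. `taper_shape`, `dbh_sd_log10`); each may
#'   be scalar or a vector over sites.
#' @return A list with `trees` (all sites stacked), `profiles`, `sites`
#'   (per-site truth table with `role` dev/test), `dev_sites`, `test_sites`,
#'   `phi_true`, `seed`.
#' @export
generate_study <- function(n_dev = 12, n_test = 12, n_trees = 50,
                           phi_true = 1.10, x_range = c(0.6, 1.6),
                           noise_sd = 0.05, seed = 1L, profiles = FALSE,
                           ...) {
  stopifnot(n_dev >= 3, n_test >= 3)
  if (length(x_range) != 2 || diff(x_range) <= 0 || x_range[1] <= 0)
    stop("x_range must be a positive, non-empty interval")
  k <- n_dev + n_test
  xs <- seq(x_range[1], x_range[2], length.out = k)
  role <- rep(c("dev", "test"), length.out = k)
  ids <- sprintf("S%02d", seq_len(k))
  n_trees <- rep(n_trees, length.out = k)
  extra <- lapply(list(...), function(v) rep(v, length.out = k))
  sites <- vector("list", k)
  for (i in seq_len(k)) {
    args <- c(list(site_id = ids[i], n_trees = n_trees[i], x_true = xs[i],
                   phi_true = phi_true, noise_sd_logH = noise_sd,
                   noise_sd_logV = noise_sd,
                   seed = seed * 100L + i),
              lapply(extra, `[[`, i))
    sites[[i]] <- generate_site(do.call(synthetic_site_spec, args),
                                profiles = profiles)
  }
  trees <- do.call(rbind, lapply(sites, `[[`, "trees"))
  rownames(trees) <- NULL
  truth <- do.call(rbind, lapply(sites, function(s)
    data.frame(site_id = as.character(s$truth$site_id),
               n_trees = s$truth$n_trees, x_true = s$truth$x_true,
               log_beta3_true = s$truth$log_beta3_true,
               phi_true = s$truth$phi_true,
               log_betaV_true = s$truth$log_betaV_true,
               alpha_VD_true = s$truth$alpha_VD_true,
               stringsAsFactors = FALSE)))
  truth$role <- role
  profs <- if (profiles) do.call(c, lapply(sites, `[[`, "profiles")) else NULL
  list(trees = trees, profiles = profs, sites = truth,
       dev_sites = ids[role == "dev"], test_sites = ids[role == "test"],
       phi_true = phi_true, seed = seed)
}
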