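#' Prediction-error evaluation
#'
#' Predicted volumes are scored by the absolute percentage error of each tree,
#' APE = 100 |V_obs - V_pred| / V_obs, and the mean absolute percentage error
#' (MAPE) over trees. Site-level MAPEs supply a standard error across sites.
#'
#' @name evaluation
NULL

#' Per-tree absolute percentage error
#'
#' @param v_obs Observed volumes, all > 0.
#' @param v_pred Predicted volumes, same length.
#' @return Vector of APE values in percent.
#' @export
ape <- function(v_obs, v_pred) {
  if (length(v_obs) != length(v_pred)) stop("length mismatch")
  if (length(v_obs) < 1) stop("at least one observation is required")
  if (any(!is.finite(v_obs)) || any(v_obs <= 0))
    stop("observed volumes must be positive")
  100 * abs(v_obs - v_pred) / v_obs
}

#' Mean absolute percentage error
#'
#' MAPE = (100/n) * sum(|V_obs - V_pred| / V_obs).
#'
#' @inheritParams ape
#' @return MAPE in percent.
#' @examples
#' mape(c(1, 2), c(1.1, 1.8))  # 10
#' @export
mape <- function(v_obs, v_pred) {
  mean(ape(v_obs, v_pred))
}

#' Evaluate predictions for one site
#'
#' @param site_id Site identifier.
#' @param v_obs,v_pred Observed and predicted volumes for the site's trees.
#' @return An `evaluation_report`: list with `per_tree_ape`, `mape`,
#'   `n_trees`, `n_sites` (= 1), `site_ids`.
#' @export
evaluate_site <- function(site_id, v_obs, v_pred) {
  a <- ape(v_obs, v_pred)
  structure(list(per_tree_ape = a, mape = mean(a), mape_se = NA_real_,
                 fraction_below = NULL, n_trees = length(a), n_sites = 1L,
                 site_ids = as.character(site_id),
                 site_mapes = stats::setNames(mean(a), as.character(site_id))),
            class = "evaluation_report")
}

#' Pool per-site evaluation reports
#'
#' Pools every tree's APE across sites; reports the overall MAPE, the
#' standard error of the site-level MAPEs, and the fraction of trees with
#' APE below each threshold.
#'
#' @param per_site_reports List of [evaluate_site()] reports (>= 1).
#' @param thresholds APE thresholds in percent (default `c(5, 10, 20)`).
#' @return An `evaluation_report` with pooled `per_tree_ape`, `mape`,
#'   `mape_se` (SE across site MAPEs; `NA` for a single site),
#'   `fraction_below` (named vector of proportions), `n_trees`, `n_sites`,
#'   `site_mapes`.
#' @export
ape_summary <- function(per_site_reports, thresholds = c(5, 10, 20)) {
  if (length(per_site_reports) < 1) stop("at least one site report is required")
  if (!all(vapply(per_site_reports, inherits, logical(1), "evaluation_report")))
    stop("inputs must be evaluation_report objects")
  all_ape <- unlist(lapply(per_site_reports, `[[`, "per_tree_ape"))
  site_mapes <- unlist(lapply(per_site_reports, `[[`, "site_mapes"))
  k <- length(site_mapes)
  se <- if (k > 1) stats::sd(site_mapes) / sqrt(k) else NA_real_
  frac <- vapply(thresholds, function(t) mean(all_ape < t), numeric(1))
  names(frac) <- paste0(thresholds, "%")
  structure(list(per_tree_ape = all_ape, mape = mean(all_ape), mape_se = se,
                 fraction_below = frac, n_trees = length(all_ape),
                 n_sites = k,
                 site_ids = unlist(lapply(per_site_reports, `[[`, "site_ids")),
                 site_mapes = site_mapes),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation: MAPE = %.2f%%", x$mape))
  if (is.finite(x$mape_se)) cat(sprintf(" +/- %.2f SE (across %d sites)", x$mape_se, x$n_sites))
  cat(sprintf(", %d trees\n", x$n_trees))
  if (!is.null(x$fraction_below)) {
    for (nm in names(x$fraction_below))
      cat(sprintf("  APE < %s: %.1f%% of trees\n", nm, 100 * x$fraction_below[[nm]]))
  }
  invisible(x)
}
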