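#' Tables, configuration and the end-to-end pipeline
#'
#' CSV readers/writers for the pipeline's tables, a validated study
#' configuration, and [run_pipeline()], which chains the stages in the
#' analysis order: per-site fits, covariation (phi), model calibration on
#' the development sites, prediction on the test sites, MAPE evaluation.
#'
#' @name io_pipeline
NULL

#' Read and validate a per-tree table
#'
#' @param path CSV with header columns `site_id`, `tree_id`, `dbh_cm`,
#'   `height_m` and optionally `volume_m3`; UTF-8, '.' decimal separator.
#' @return Data frame of validated tree records. Offending rows are reported
#'   by row number in the error message.
#' @examples
#' path <- system.file("extdata", "example_trees_synthetic.csv",
#'                     package = "stemallometry")
#' head(read_tree_table(path))
#' @export
read_tree_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "tree_id", "dbh_cm", "height_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("tree table ", path, " has a header but no rows")
    return(df)
  }
  df$site_id <- as.character(df$site_id)
  df$tree_id <- as.character(df$tree_id)
  bad <- which(!is.finite(df$dbh_cm) | df$dbh_cm <= 0)
  if (length(bad)) stop("nonpositive or missing dbh_cm in row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$height_m) | df$height_m <= 1.3)
  if (length(bad)) stop("height_m must exceed 1.3 m; bad row(s): ",
                        paste(bad, collapse = ", "))
  if ("volume_m3" %in% names(df)) {
    bad <- which(!is.na(df$volume_m3) & (!is.finite(df$volume_m3) | df$volume_m3 <= 0))
    if (length(bad)) stop("nonpositive volume_m3 in row(s): ",
                          paste(bad, collapse = ", "))
  }
  key <- paste(df$site_id, df$tree_id)
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate (site_id, tree_id) in row(s): ",
                        paste(dup, collapse = ", "))
  df
}

#' @rdname read_tree_table
#' @param trees Tree table data frame.
#' @param path Output CSV path.
#' @export
write_tree_table <- function(trees, path) {
  utils::write.csv(trees, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stem-profile table
#'
#' @param path CSV with header columns `tree_id`, `site_id`, `height_m`,
#'   `diameter_cm`, one row per disc, plus `total_height_m` (repeated per
#'   tree).
#' @return A list of [stem_profile()] objects, one per tree.
#' @export
read_stem_profile_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "site_id", "height_m", "diameter_cm", "total_height_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$tree_id), function(d) {
    d <- d[order(d$height_m), ]
    stem_profile(d$tree_id[1], d$total_height_m[1], d$height_m, d$diameter_cm)
  })
}

#' @rdname read_stem_profile_table
#' @param profiles List of `stem_profile` objects.
#' @param site_ids Optional site ids, recycled over profiles.
#' @param path Output CSV path.
#' @export
write_stem_profile_table <- function(profiles, path, site_ids = NA) {
  site_ids <- rep(site_ids, length.out = length(profiles))
  rows <- mapply(function(p, s) {
    data.frame(tree_id = p$tree_id, site_id = s, height_m = p$heights_m,
               diameter_cm = p$diameters_cm, total_height_m = p$total_height_m,
               stringsAsFactors = FALSE)
  }, profiles, site_ids, SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Study configuration
#'
#' @param dev_sites,test_sites Disjoint character vectors of site ids.
#' @param tree_table Path to a tree CSV, or a tree data frame.
#' @param fit_method Method for the functional site fits feeding phi
#'   (`"RMA"`, the default) — the prediction chain itself always calibrates
#'   with OLS.
#' @param x_method Method for the H-vs-D exponent entering prediction
#'   (`"OLS"` default; `"RMA"` available).
#' @param phi_curve Covariation curve used for phi (`"C1"` default).
#' @param phi_scope `"dev"` (default: phi fitted on development sites only)
#'   or `"all"`.
#' @param ci_level Confidence level for intervals.
#' @param thresholds APE thresholds (percent) for the evaluation report.
#' @param seed Integer seed recorded in outputs.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A validated `study_config` list.
#' @export
study_config <- function(dev_sites, test_sites, tree_table,
                         fit_method = "RMA", x_method = "OLS",
                         phi_curve = "C1", phi_scope = c("dev", "all"),
                         ci_level = 0.95, thresholds = c(5, 10, 20),
                         seed = 1L, out_dir = tempfile("stemallometry_run_")) {
  phi_scope <- match.arg(phi_scope)
  if (length(intersect(dev_sites, test_sites)))
    stop("dev and test site sets overlap: ",
         paste(intersect(dev_sites, test_sites), collapse = ", "))
  if (is.character(tree_table) && !file.exists(tree_table))
    stop("tree table path does not exist: ", tree_table)
  structure(list(dev_sites = dev_sites, test_sites = test_sites,
                 tree_table = tree_table, fit_method = fit_method,
                 x_method = x_method, phi_curve = phi_curve,
                 phi_scope = phi_scope, ci_level = ci_level,
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full covariation / prediction pipeline
#'
#' Stages: read and validate trees; fit the four relations per site (RMA for
#' the functional analysis, OLS for the prediction chain); test slope
#' heterogeneity of H vs D across sites; fit phi; calibrate the volume model
#' on the development sites; predict test-site volumes from each site's
#' H-vs-D exponent and tree diameters; evaluate by MAPE. Writes
#' `site_fits.csv`, `covariation.csv`, `model.txt`, `evaluation.json` and
#' `run_log.txt` into `config$out_dir`; floats in CSV outputs carry 6
#' significant digits.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `site_fits`, `covariation` (data frame of
#'   the three curve fits), `slope_test`, `model`, `predictions`,
#'   `evaluation`, `files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "study_config")) stop("config must be a study_config")
  trees <- .stage("read", {
    if (is.character(config$tree_table)) read_tree_table(config$tree_table)
    else config$tree_table
  })
  all_sites <- unique(trees$site_id)
  unknown <- setdiff(c(config$dev_sites, config$test_sites), all_sites)
  if (length(unknown))
    stop("[stage read] configured site(s) absent from data: ",
         paste(unknown, collapse = ", "))

  rma_fits <- .stage("site_fits", fit_site_relations(
    trees, method = "RMA", ci_level = config$ci_level))
  ols_fits <- .stage("site_fits", fit_site_relations(
    trees, method = "OLS", ci_level = config$ci_level))
  site_fits <- rbind(rma_fits, ols_fits)

  slope_test <- .stage("slope_heterogeneity", {
    groups <- lapply(split(trees, trees$site_id), function(d)
      list(x = log10(d$dbh_cm), y = log10(d$height_m)))
    common_slope_test(groups)
  })

  fun_fits <- if (config$fit_method == "RMA") rma_fits else ols_fits
  phi_src <- if (config$phi_scope == "dev")
    fun_fits[fun_fits$site_id %in% config$dev_sites, ] else fun_fits
  wide <- function(fits, rel, col = "exponent")
    fits[fits$relation == rel, col][order(fits[fits$relation == rel, "site_id"])]
  covar <- .stage("covariation", {
    x <- wide(phi_src, "H_vs_D"); y <- wide(phi_src, "D_vs_V")
    z <- wide(phi_src, "H_vs_V")
    fits <- list(fit_phi(x = x, y = y, curve_form = "C1", ci_level = config$ci_level),
                 fit_phi(x = x, z = z, curve_form = "C2", ci_level = config$ci_level),
                 fit_phi(y = y, z = z, curve_form = "C3", ci_level = config$ci_level))
    do.call(rbind, lapply(fits, function(f)
      data.frame(curve_form = f$curve_form, phi = f$phi, ci_low = f$ci_low,
                 ci_high = f$ci_high, r2 = f$r2, n_sites = f$n_sites)))
  })
  phi_hat <- covar$phi[covar$curve_form == config$phi_curve]

  model <- .stage("calibrate", {
    dev_vd <- ols_fits[ols_fits$relation == "V_vs_D" &
                         ols_fits$site_id %in% config$dev_sites, ]
    calibrate_volume_model(dev_vd, phi_hat)
  })

  x_fits <- if (config$x_method == "RMA") rma_fits else ols_fits
  predictions <- .stage("predict", {
    out <- lapply(config$test_sites, function(sid) {
      x_site <- x_fits[x_fits$relation == "H_vs_D" & x_fits$site_id == sid,
                       "exponent"]
      d <- trees[trees$site_id == sid, ]
      data.frame(site_id = sid, tree_id = d$tree_id, dbh_cm = d$dbh_cm,
                 volume_obs_m3 = d$volume_m3,
                 volume_pred_m3 = predict_volume(model, x_site, d$dbh_cm),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  evaluation <- .stage("evaluate", {
    reports <- lapply(split(predictions, predictions$site_id), function(d)
      evaluate_site(d$site_id[1], d$volume_obs_m3, d$volume_pred_m3))
    ape_summary(reports, thresholds = config$thresholds)
  })

  files <- .stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(config$out_dir,
                   c("site_fits.csv", "covariation.csv", "model.txt",
                     "evaluation.json", "run_log.txt"))
    names(f) <- c("site_fits", "covariation", "model", "evaluation", "log")
    num <- function(df) { # 6 significant digits in CSV outputs
      for (j in seq_along(df)) if (is.numeric(df[[j]]))
        df[[j]] <- signif(df[[j]], 6)
      df
    }
    utils::write.csv(num(site_fits), f["site_fits"], row.names = FALSE, quote = FALSE)
    utils::write.csv(num(covar), f["covariation"], row.names = FALSE, quote = FALSE)
    write_volume_model(model, f["model"])
    jsonlite::write_json(list(
      mape = evaluation$mape, mape_se = evaluation$mape_se,
      fraction_below = as.list(evaluation$fraction_below),
      n_trees = evaluation$n_trees, n_sites = evaluation$n_sites,
      site_mapes = as.list(evaluation$site_mapes)),
      f["evaluation"], auto_unbox = TRUE, digits = NA)
    writeLines(c(
      paste0("stemallometry version: ", as.character(utils::packageVersion("stemallometry"))),
      paste0("R version: ", R.version.string),
      paste0("seed: ", config$seed),
      paste0("functional fit method (phi): ", config$fit_method),
      paste0("prediction x method: ", config$x_method),
      paste0("calibration method: OLS"),
      paste0("phi curve: ", config$phi_curve, " on ", config$phi_scope, " sites"),
      paste0("ci level: ", config$ci_level),
      paste0("dev sites: ", paste(config$dev_sites, collapse = ",")),
      paste0("test sites: ", paste(config$test_sites, collapse = ",")),
      paste0("H-vs-D slope heterogeneity: LR = ",
             signif(slope_test$statistic, 6), ", df = ", slope_test$df,
             ", p = ", signif(slope_test$p_value, 6))),
      f["log"])
    f
  })

  invisible(list(site_fits = site_fits, covariation = covar,
                 slope_test = slope_test, model = model,
                 predictions = predictions, evaluation = evaluation,
                 files = files))
}
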