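#' Log-log power-law fitting by RMA and OLS
#'
#' Allometric relationships Y = beta * X^alpha are fitted on the log10 scale,
#' log10(Y) = log10(beta) + alpha * log10(X). Reduced major axis (RMA, also
#' called standardized major axis) regression is used for functional
#' relationships where neither variable is a predictor of the other; ordinary
#' least squares (OLS) is used when the aim is prediction. The RMA slope is
#' sign(r) * sd(log10 Y) / sd(log10 X) with the line through the centroid; its
#' confidence interval follows the standard F-based formula
#' b * (sqrt(B + 1) +/- sqrt(B)) with B = F(1 - level; 1, n - 2) * (1 - r^2) / (n - 2).
#'
#' @name allometric_fits
NULL

.relations <- c("D_vs_V", "H_vs_V", "H_vs_D", "V_vs_D")

#' Fit a power law on the log10 scale
#'
#' @param predictor,response Strictly positive vectors of equal length
#'   (original scale; log10 is taken internally).
#' @param method `"RMA"` (reduced major axis) or `"OLS"`.
#' @param ci_level Confidence level for the slope interval (default 0.95).
#' @param site_id,relation Optional labels carried into the result.
#' @return An object of class `scaling_fit`: a list with `exponent` (the
#'   slope alpha), `ci_low`, `ci_high`, `log10_constant` (the intercept
#'   log10 beta), `r2` (squared Pearson correlation of the log pairs), `n`,
#'   `method`, `site_id`, `relation`, and `low_n` (TRUE when n < 6).
#' @examples
#' d <- c(5, 10, 20, 40)
#' fit_power_law(d, 10 * d^2)  # recovers alpha = 2, log10 beta = 1
#' @export
fit_power_law <- function(predictor, response, method = c("RMA", "OLS"),
                          ci_level = 0.95, site_id = NA_character_,
                          relation = NA_character_) {
  method <- match.arg(method)
  if (length(predictor) != length(response)) stop("length mismatch")
  n <- length(predictor)
  if (n < 3) stop("at least 3 observations are required")
  if (any(!is.finite(predictor)) || any(!is.finite(response)) ||
      any(predictor <= 0) || any(response <= 0))
    stop("all values must be strictly positive and finite")
  lx <- log10(predictor)
  ly <- log10(response)
  .fit_loglinear(lx, ly, method, ci_level, n, site_id, relation)
}

# core fit on already-logged pairs (shared with the constant-exponent lines,
# which are linear in the exponent rather than in a log)
.fit_loglinear <- function(lx, ly, method, ci_level, n, site_id, relation) {
  sx <- stats::sd(lx)
  sy <- stats::sd(ly)
  if (sx == 0) stop("degenerate fit: predictor is constant")
  r <- suppressWarnings(stats::cor(lx, ly))
  if (!is.finite(r)) stop("degenerate fit: response is constant")
  if (method == "RMA") {
    if (r == 0) stop("degenerate fit: zero correlation, RMA slope sign undefined")
    b <- sign(r) * sy / sx
    B <- stats::qf(ci_level, 1, n - 2) * (1 - r^2) / (n - 2)
    ci <- sort(b * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  } else {
    fit <- stats::lm(ly ~ lx)
    b <- unname(stats::coef(fit)[2])
    # suppress summary.lm's "essentially perfect fit" note on noise-free data
    ci <- unname(suppressWarnings(stats::confint(fit, "lx", level = ci_level)))
  }
  a <- mean(ly) - b * mean(lx)
  structure(list(site_id = site_id, relation = relation, method = method,
                 exponent = b, ci_low = ci[1], ci_high = ci[2],
                 log10_constant = a, r2 = r^2, n = n, low_n = n < 6),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("%s fit%s%s: alpha = %.4f (%.4f-%.4f), log10 beta = %.4f, r2 = %.4f, n = %d%s\n",
              x$method,
              if (is.na(x$relation)) "" else paste0(" [", x$relation, "]"),
              if (is.na(x$site_id)) "" else paste0(" site ", x$site_id),
              x$exponent, x$ci_low, x$ci_high, x$log10_constant, x$r2, x$n,
              if (isTRUE(x$low_n)) " (low-n)" else ""))
  invisible(x)
}

#' Fit the four volume-scaling relations for every site
#'
#' For each site in a tree table, fits H vs D (exponent x), D vs V (y'),
#' H vs V (z') and V vs D on the log10 scale. The first variable named is the
#' response; e.g. `H_vs_D` fits log10 H = log10 beta3 + x log10 D.
#'
#' @param trees A tree table as returned by [generate_study()] or
#'   [read_tree_table()]: data frame with columns `site_id`, `tree_id`,
#'   `dbh_cm`, `height_m` and (for the volume relations) `volume_m3`.
#' @param method `"RMA"` or `"OLS"`.
#' @param relations Character subset of
#'   `c("D_vs_V", "H_vs_V", "H_vs_D", "V_vs_D")`.
#' @param ci_level Confidence level for slope intervals.
#' @return A data frame with one row per site x relation: `site_id`,
#'   `relation`, `method`, `exponent`, `ci_low`, `ci_high`, `log10_constant`,
#'   `r2`, `n`, `low_n`.
#' @export
fit_site_relations <- function(trees, method = c("RMA", "OLS"),
                               relations = .relations, ci_level = 0.95) {
  method <- match.arg(method)
  relations <- match.arg(relations, .relations, several.ok = TRUE)
  need_v <- any(relations != "H_vs_D")
  cols <- c("site_id", "dbh_cm", "height_m", if (need_v) "volume_m3")
  missing_cols <- setdiff(cols, names(trees))
  if (length(missing_cols))
    stop("tree table lacks columns: ", paste(missing_cols, collapse = ", "))
  var_of <- list(D = "dbh_cm", H = "height_m", V = "volume_m3")
  out <- list()
  for (sid in unique(trees$site_id)) {
    sub <- trees[trees$site_id == sid, , drop = FALSE]
    for (rel in relations) {
      parts <- strsplit(rel, "_vs_")[[1]]  # response_vs_predictor
      f <- fit_power_law(sub[[var_of[[parts[2]]]]], sub[[var_of[[parts[1]]]]],
                         method = method, ci_level = ci_level,
                         site_id = as.character(sid), relation = rel)
      out[[length(out) + 1L]] <- as.data.frame(unclass(f), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("site_id", "relation", "method", "exponent", "ci_low", "ci_high",
          "log10_constant", "r2", "n", "low_n")]
}

# Profile LR criterion for a common SMA slope b across groups: within each
# group the residual scores u = y - b x and axis scores v = y + b x are
# uncorrelated at that group's own SMA slope, so departure of cor(u, v) from
# zero under a shared b carries the heterogeneity evidence. The n - 2.5 factor
# is the usual small-sample calibration of the chi-square reference.
.sma_lr <- function(b, groups) {
  s <- 0
  for (g in groups) {
    u <- g$y - b * g$x
    v <- g$y + b * g$x
    r <- suppressWarnings(stats::cor(u, v))
    r2 <- if (is.finite(r)) r^2 else 0  # zero residual variance: exact fit
    r2 <- min(r2, 1 - 1e-12)
    s <- s - (g$n - 2.5) * log(1 - r2)
  }
  s
}

#' Test for a common RMA/SMA slope across groups
#'
#' Likelihood-ratio test that several groups of log10 pairs share one reduced
#' major axis slope. The common slope is profiled out by minimizing the LR
#' criterion; the statistic is referred to a chi-square distribution with
#' k - 1 degrees of freedom (k groups). A permutation reference is available
#' for small samples, permuting group labels and re-minimizing.
#'
#' @param groups A list with one element per group, each a list or data frame
#'   with components `x` and `y` holding log10-scale pairs (n >= 3 each).
#' @param method Currently only `"RMA"`.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations when `p_method = "permutation"`.
#' @return A list with `statistic`, `df`, `p_value`, `common_slope`, and
#'   `slopes` (the per-group SMA slopes).
#' @export
common_slope_test <- function(groups, method = "RMA",
                              p_method = c("chisq", "permutation"),
                              n_perm = 499) {
  if (method != "RMA") stop("only the RMA/SMA common-slope test is implemented")
  p_method <- match.arg(p_method)
  if (length(groups) < 2) stop("at least 2 groups are required")
  groups <- lapply(groups, function(g) {
    x <- g$x; y <- g$y
    if (length(x) < 3 || length(x) != length(y)) stop("each group needs >= 3 pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate group")
    r <- stats::cor(x, y)
    if (r == 0) stop("degenerate group: zero correlation")
    list(x = x, y = y, n = length(x), slope = sign(r) * stats::sd(y) / stats::sd(x))
  })
  slopes <- vapply(groups, `[[`, numeric(1), "slope")
  if (length(unique(sign(slopes))) > 1)
    stop("group SMA slopes differ in sign; no common slope exists")
  lo <- min(abs(slopes)) / 2
  hi <- max(abs(slopes)) * 2
  sg <- sign(slopes[1])
  opt <- stats::optimize(function(b) .sma_lr(sg * b, groups), c(lo, hi))
  # perfectly collinear groups make the criterion discontinuous at the true
  # slope; evaluate each group's own slope as a candidate minimizer too
  cand <- c(sg * opt$minimum, slopes)
  obj <- vapply(cand, .sma_lr, numeric(1), groups = groups)
  best <- which.min(obj)
  stat <- obj[best]
  b_hat <- cand[best]
  df <- length(groups) - 1L
  if (p_method == "chisq") {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    # permute residual/axis score pairing across groups by reassigning whole
    # observations to groups, preserving group sizes
    xs <- unlist(lapply(groups, `[[`, "x"))
    ys <- unlist(lapply(groups, `[[`, "y"))
    sizes <- vapply(groups, function(g) as.integer(g$n), integer(1))
    idx_end <- cumsum(sizes)
    idx_start <- c(1, idx_end[-length(idx_end)] + 1)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(length(xs))
      gp <- lapply(seq_along(sizes), function(j) {
        sel <- perm[idx_start[j]:idx_end[j]]
        list(x = xs[sel], y = ys[sel], n = sizes[j])
      })
      ok <- try({
        opt_p <- stats::optimize(function(b) .sma_lr(sg * b, gp), c(lo / 4, hi * 4))
        if (opt_p$objective >= stat) exceed <- exceed + 1L
      }, silent = TRUE)
      if (inherits(ok, "try-error")) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(statistic = stat, df = df, p_value = p, common_slope = b_hat,
       slopes = slopes)
}
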