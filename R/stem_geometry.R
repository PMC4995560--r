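#' Sectional stem volume from disc measurements
#'
#' Felled-tree stem volume is computed by slicing the stem at the heights where
#' discs were taken and summing the volume of each section, each section
#' modelled as a truncated cone (frustum) between its two bounding discs.
#' These functions implement the disc-placement protocol, the frustum formula
#' and the sectional summation.
#'
#' @name stem_geometry
NULL

#' Volume of a truncated cone from end diameters
#'
#' Computes the frustum volume \eqn{V = \pi L (d_1^2 + d_1 d_2 + d_2^2) / 12}
#' with diameters in cm and section length in m. Equal diameters reduce to a
#' cylinder; a zero diameter at one end gives a cone.
#'
#' @param d_lower_cm Diameter at one end, cm. Must be >= 0.
#' @param d_upper_cm Diameter at the other end, cm. Must be >= 0.
#' @param section_length_m Section length, m. Must be >= 0.
#' @return Volume in m^3. Vectorised over its arguments.
#' @examples
#' frustum_volume(20, 20, 1)   # cylinder: pi * 0.02^2 * 1
#' frustum_volume(20, 10, 1)
#' @export
frustum_volume <- function(d_lower_cm, d_upper_cm, section_length_m) {
  if (any(d_lower_cm < 0) || any(d_upper_cm < 0))
    stop("diameters must be non-negative (cm)")
  if (any(section_length_m < 0))
    stop("section length must be non-negative (m)")
  d1 <- d_lower_cm / 100
  d2 <- d_upper_cm / 100
  pi * section_length_m * (d1^2 + d1 * d2 + d2^2) / 12
}

#' Disc measurement heights for a felled stem
#'
#' Returns the heights (m above the base) at which stem discs are cut: breast
#' height (1.3 m), then every 1 m for trees shorter than 10 m or every 2 m for
#' trees of 10 m and taller, strictly below the tip. Trees under 10 m get an
#' additional disc at 0.5 m.
#'
#' @param total_height_m Total tree height, m. Must exceed 1.3.
#' @return Numeric vector of strictly increasing disc heights, m.
#' @examples
#' measurement_heights(9)
#' measurement_heights(12)
#' @export
measurement_heights <- function(total_height_m) {
  stopifnot(length(total_height_m) == 1, is.finite(total_height_m))
  if (total_height_m <= 1.3)
    stop("total height must exceed breast height (1.3 m); no disc protocol exists")
  step <- if (total_height_m < 10) 1 else 2
  h <- seq(1.3, total_height_m, by = step)
  h <- h[h < total_height_m]
  if (total_height_m < 10) h <- c(0.5, h)
  h
}

#' Construct a stem profile
#'
#' An ordered set of disc measurements along one felled stem, used by
#' [total_stem_volume()].
#'
#' @param tree_id Identifier for the tree.
#' @param total_height_m Total height, m; must exceed the highest disc.
#' @param heights_m Disc heights above the base, m, strictly increasing,
#'   all within `[0, total_height_m)`.
#' @param diameters_cm Disc diameters, cm, all positive, same length as
#'   `heights_m`.
#' @return An object of class `stem_profile`.
#' @export
stem_profile <- function(tree_id, total_height_m, heights_m, diameters_cm) {
  stopifnot(length(total_height_m) == 1, is.finite(total_height_m),
            length(heights_m) == length(diameters_cm))
  if (total_height_m <= 0) stop("total height must be positive")
  if (any(!is.finite(heights_m)) || any(!is.finite(diameters_cm)))
    stop("non-finite disc measurement")
  if (any(diameters_cm <= 0)) stop("all disc diameters must be positive (cm)")
  if (any(heights_m < 0) || any(heights_m > total_height_m))
    stop("disc heights must lie in [0, total height]")
  if (is.unsorted(heights_m, strictly = TRUE))
    stop("disc heights must be strictly increasing")
  if (is.unsorted(-diameters_cm))  # butt swell / irregular taper: allowed
    warning("non-monotone taper in stem profile for tree ", tree_id)
  structure(list(tree_id = tree_id,
                 total_height_m = total_height_m,
                 heights_m = as.numeric(heights_m),
                 diameters_cm = as.numeric(diameters_cm)),
            class = "stem_profile")
}

#' @export
print.stem_profile <- function(x, ...) {
  cat("Stem profile for tree", x$tree_id, "- height", x$total_height_m, "m,",
      length(x$heights_m), "discs\n")
  invisible(x)
}

#' Total stem volume by sectional summation
#'
#' Partitions the stem into sections bounded by consecutive discs and sums
#' their volumes. Between discs a truncated cone is used. The butt section
#' (ground to lowest disc) defaults to a cylinder with the lowest disc's
#' diameter, avoiding extrapolation into the butt swell; set
#' `base_rule = "frustum"` to linearly extrapolate the taper of the lowest
#' two discs to the ground instead. The top section runs from the highest
#' disc to the tip as a frustum whose upper diameter is `tip_diameter_cm`
#' (0 by default, i.e. a cone).
#'
#' @param profile A [stem_profile()].
#' @param base_rule `"cylinder"` (default) or `"frustum"` for the butt section.
#' @param tip_diameter_cm Diameter assumed at the very tip, cm (default 0).
#' @return A list with `volume_m3` (total) and `sections`, a data frame with
#'   columns `lower_height_m`, `upper_height_m`, `volume_m3`, `rule`.
#' @examples
#' p <- stem_profile("t1", 2, c(1, 2), c(10, 10))
#' total_stem_volume(p)$volume_m3
#' @export
total_stem_volume <- function(profile, base_rule = c("cylinder", "frustum"),
                              tip_diameter_cm = 0) {
  if (!inherits(profile, "stem_profile")) stop("profile must be a stem_profile")
  base_rule <- match.arg(base_rule)
  if (tip_diameter_cm < 0) stop("tip diameter must be non-negative")
  h <- profile$heights_m
  d <- profile$diameters_cm
  n <- length(h)
  if (n < 2) stop("at least 2 discs are required")

  lower <- upper <- vol <- numeric(0)
  rule <- character(0)

  # butt section: ground (0) up to the lowest disc
  if (h[1] > 0) {
    d0 <- if (base_rule == "cylinder") d[1] else {
      # extrapolate the linear taper of the two lowest discs down to the ground
      max(d[1] + (d[1] - d[2]) * h[1] / (h[2] - h[1]), 0)
    }
    lower <- c(lower, 0); upper <- c(upper, h[1])
    vol <- c(vol, frustum_volume(d0, d[1], h[1]))
    rule <- c(rule, if (base_rule == "cylinder") "cylinder" else "frustum")
  }

  # interior sections between consecutive discs
  if (n >= 2) {
    lower <- c(lower, h[-n]); upper <- c(upper, h[-1])
    vol <- c(vol, frustum_volume(d[-n], d[-1], diff(h)))
    rule <- c(rule, ifelse(d[-n] == d[-1], "cylinder", "frustum"))
  }

  # top section: highest disc to the tip (skipped if a disc sits at the tip)
  tip_len <- profile$total_height_m - h[n]
  if (tip_len > 0) {
    lower <- c(lower, h[n]); upper <- c(upper, profile$total_height_m)
    vol <- c(vol, frustum_volume(d[n], tip_diameter_cm, tip_len))
    rule <- c(rule, if (tip_diameter_cm == 0) "cone_tip" else "frustum")
  }

  sections <- data.frame(lower_height_m = lower, upper_height_m = upper,
                         volume_m3 = vol, rule = rule,
                         stringsAsFactors = FALSE)
  list(volume_m3 = sum(vol), sections = sections)
}
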