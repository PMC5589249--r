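#' Classify a normalized threat value into a magnitude class
#'
#' Five ordinal classes with the printed two-decimal interval semantics
#' (No threat <= 0.01; Low 0.01-0.1; Medium 0.11-0.3; High 0.31-0.7; Very
#' high 0.71-1). The gaps between printed bounds are resolved by midpoint
#' boundaries at 0.105, 0.305 and 0.705 (lower-exclusive, upper-inclusive),
#' so any value rounding to 0.71 is Very high and any rounding to 0.70 is
#' High. A `capped` threat (cotton) can never exceed High.
#'
#' @param value Numeric vector in `[0, 1]`.
#' @param capped If `TRUE`, Very high is mapped down to High.
#' @return Integer codes 0-4 (see [threat_levels()]).
#' @export
classify_magnitude <- function(value, capped = FALSE) {
  if (any(value < 0 | value > 1, na.rm = TRUE))
    stop("classify_magnitude: value outside [0, 1]")
  out <- integer(length(value))
  out[value > 0.01]  <- 1L
  out[value > 0.105] <- 2L
  out[value > 0.305] <- 3L
  out[value > 0.705] <- 4L
  if (capped) out <- pmin(out, 3L)
  out[is.na(value)] <- NA_integer_
  out
}

#' Species-specific threat map from intensity and sensitivity
#'
#' Multiplies the normalized threat intensity by the species' normalized
#' sensitivity weight pixel-by-pixel and classifies the product with
#' [classify_magnitude()], inside the species' distribution mask. Generic
#' threats use sensitivity 1; site-classified threats (mining, climate)
#' bypass this operation entirely.
#'
#' @param intensity A `[0, 1]` intensity `grid_layer` (its `capped`
#'   attribute, if set, caps the classification at High).
#' @param sensitivity Normalized sensitivity weight in `[0, 1]` (default 1).
#' @param distribution Optional 0/1 `grid_layer` or logical matrix
#'   restricting the map to the species' predicted presence.
#' @return A `class_layer`, masked to distribution and intensity validity.
#' @export
species_threat_map <- function(intensity, sensitivity = 1,
                               distribution = NULL) {
  stopifnot(inherits(intensity, "grid_layer"),
            sensitivity >= 0, sensitivity <= 1)
  capped <- isTRUE(attr(intensity, "capped"))
  mask <- intensity$mask
  if (!is.null(distribution)) {
    dmask <- if (inherits(distribution, "grid_layer"))
      distribution$values >= 1 & distribution$mask else as.matrix(distribution)
    mask <- mask & dmask
  }
  vals <- pmin(pmax(sensitivity * intensity$values, 0), 1)
  classes <- matrix(classify_magnitude(as.vector(vals), capped = capped),
                    intensity$spec$n_rows)
  classes[!mask] <- 0L
  cl <- class_layer(intensity$spec, classes, mask)
  attr(cl, "threat") <- attr(intensity, "threat")
  cl
}

#' Combine six individual threat maps into one
#'
#' The combined class is the highest class among the six layers, upgraded by
#' the 3-5 rule: three or more individual threats rated High raise the cell
#' to Very high; otherwise five or more rated Medium raise it to High.
#'
#' @param layers List of exactly six `class_layer`s on one grid.
#' @return A `class_layer` (mask = intersection of the input masks).
#' @export
combine_threats <- function(layers) {
  if (length(layers) != 6) stop("combine_threats needs exactly 6 layers")
  spec <- layers[[1]]$spec
  for (l in layers) {
    stopifnot(inherits(l, "class_layer"))
    if (!same_spec(l$spec, spec)) stop("layers on different grids")
  }
  codes <- lapply(layers, `[[`, "classes")
  combined <- Reduce(pmax, codes)
  n_high <- Reduce(`+`, lapply(codes, function(m) (m == 3L) * 1L))
  n_med  <- Reduce(`+`, lapply(codes, function(m) (m == 2L) * 1L))
  combined[n_high >= 3L] <- pmax(combined[n_high >= 3L], 4L)
  up_med <- n_high < 3L & n_med >= 5L
  combined[up_med] <- pmax(combined[up_med], 3L)
  mask <- Reduce(`&`, lapply(layers, `[[`, "mask"))
  class_layer(spec, combined, mask)
}

# literal transcription of the combination rule for a single cell's six
# codes; used as the independent oracle in tests and kept exported so the
# equivalence is reviewable
#' Single-cell combined threat class (reference rule)
#'
#' Scalar form of [combine_threats()] for one cell's six class codes:
#' maximum class, then the 3-High / 5-Medium upgrade.
#'
#' @param codes Integer vector of six class codes 0-4.
#' @return Combined class code.
#' @export
combine_rule <- function(codes) {
  stopifnot(length(codes) == 6, all(codes %in% 0:4))
  out <- max(codes)
  if (sum(codes == 3) >= 3) out <- max(out, 4)
  else if (sum(codes == 2) >= 5) out <- max(out, 3)
  as.integer(out)
}

#' Per-class and severe-threat area percentages
#'
#' For each individual threat layer: the percentage of the species'
#' distribution cells at severe level (High + Very high). For the combined
#' layer: the percentage at each of the five classes (rows sum to 100).
#'
#' @param threat_layers Named list of `class_layer`s (one per threat).
#' @param combined The combined `class_layer`.
#' @param distribution 0/1 `grid_layer` or logical matrix of the species'
#'   distribution (non-empty).
#' @return List with `severe` (named percentages per threat) and
#'   `combined` (named percentages per class, plus `severe`).
#' @export
scope_table <- function(threat_layers, combined, distribution) {
  dmask <- if (inherits(distribution, "grid_layer"))
    distribution$values >= 1 & distribution$mask else as.matrix(distribution)
  n <- sum(dmask)
  if (n == 0) stop("empty distribution mask")
  severe <- vapply(threat_layers, function(l)
    100 * sum(l$classes[dmask] >= 3L) / n, 0)
  cls <- factor(combined$classes[dmask], levels = 0:4,
                labels = threat_levels())
  comb_pct <- 100 * as.numeric(table(cls)) / n
  names(comb_pct) <- threat_levels()
  list(severe = severe,
       combined = c(comb_pct,
                    severe = sum(comb_pct[c("High", "Very high")])))
}

#' Multi-species severe-threat hotspot map
#'
#' Per cell, the number of species whose combined threat class there is
#' severe (High or Very high); species absent from a cell contribute 0.
#'
#' @param combined_layers List of per-species combined `class_layer`s
#'   (masked to each species' distribution).
#' @return A `grid_layer` of counts.
#' @export
hotspot_map <- function(combined_layers) {
  stopifnot(length(combined_layers) >= 1)
  spec <- combined_layers[[1]]$spec
  counts <- matrix(0, spec$n_rows, spec$n_cols)
  for (l in combined_layers) {
    if (!same_spec(l$spec, spec)) stop("layers on different grids")
    counts <- counts + (l$mask & l$classes >= 3L)
  }
  grid_layer(spec, counts)
}

#' Species richness map from presence masks
#'
#' Per-cell sum of species presence indicators.
#'
#' @param presence_layers List of per-species 0/1 `grid_layer`s.
#' @return A `grid_layer` of counts.
#' @export
richness_map <- function(presence_layers) {
  stopifnot(length(presence_layers) >= 1)
  spec <- presence_layers[[1]]$spec
  counts <- matrix(0, spec$n_rows, spec$n_cols)
  for (l in presence_layers) {
    if (!same_spec(l$spec, spec)) stop("layers on different grids")
    counts <- counts + (l$mask & l$values >= 1)
  }
  grid_layer(spec, counts)
}
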