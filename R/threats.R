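# Per-threat intensity and class layers (Table-1 semantics): each builder
# takes raw inputs and returns either a normalized [0,1] intensity layer
# tagged with its threat id, or a ready-made ordinal class layer for the
# threats that are classified directly (mining, climate change).

threat_intensity <- function(layer, threat, capped = FALSE,
                             species_specific = TRUE) {
  attr(layer, "threat") <- threat
  attr(layer, "capped") <- capped
  attr(layer, "species_specific") <- species_specific
  layer
}

#' Overexploitation intensity from a human-footprint layer
#'
#' The 0-100 human-footprint index (population density, land use,
#' infrastructure, accessibility) proxies harvesting pressure for food,
#' timber, fuelwood and fodder. The layer is resampled to the analysis grid
#' (bilinear) if needed and min-max normalized over the study area.
#'
#' @param footprint A `grid_layer` with non-negative values.
#' @param target Optional `grid_spec` to resample onto.
#' @return A `[0, 1]` intensity `grid_layer` tagged `overexploitation`.
#' @export
overexploitation_intensity <- function(footprint, target = NULL) {
  stopifnot(inherits(footprint, "grid_layer"))
  if (any(footprint$values[footprint$mask] < 0))
    stop("footprint values must be non-negative")
  if (!is.null(target)) footprint <- resample_bilinear(footprint, target)
  threat_intensity(normalize_minmax(footprint), "overexploitation")
}

#' Tropical livestock units per cell
#'
#' Standardizes livestock numbers as grazing equivalents of a 250 kg
#' ruminant using conversion factors cattle 0.7, goats 0.1, sheep 0.1.
#'
#' @param cattle,goats,sheep `grid_layer`s of head counts per cell (>= 0).
#' @return A `grid_layer` of TLU per cell.
#' @export
tlu <- function(cattle, goats, sheep) {
  stopifnot(inherits(cattle, "grid_layer"), inherits(goats, "grid_layer"),
            inherits(sheep, "grid_layer"))
  for (l in list(cattle, goats, sheep))
    if (any(l$values[l$mask] < 0)) stop("negative livestock density")
  mask <- cattle$mask & goats$mask & sheep$mask
  vals <- 0.7 * cattle$values + 0.1 * goats$values + 0.1 * sheep$values
  vals[!mask] <- 0
  grid_layer(cattle$spec, vals, mask)
}

#' Overgrazing intensity from a TLU layer
#'
#' Square-root transformed (the TLU distribution is heavily right-skewed)
#' then min-max normalized.
#'
#' @param tlu_layer A `grid_layer` of TLU per cell (>= 0).
#' @return A `[0, 1]` intensity `grid_layer` tagged `overgrazing`.
#' @export
overgrazing_intensity <- function(tlu_layer) {
  threat_intensity(normalize_minmax(sqrt_transform(tlu_layer)),
                   "overgrazing")
}

#' Mean annual weighted fire frequency per square kilometre
#'
#' Detections with confidence not exceeding `conf_threshold` are dropped;
#' late-season fires (months in `late_months`, the peak of the dry season
#' when fuel load is highest) receive double weight because tree mortality
#' roughly doubles in late burns. Per cell the weighted count is divided by
#' the number of years and the cell area in km^2. Events dated outside the
#' year window are dropped with a message.
#'
#' @param events Data frame with `lon`, `lat`, `date` (Date), `confidence`.
#' @param grid A `grid_spec`.
#' @param years Inclusive year window, e.g. `c(2007, 2012)`.
#' @param late_months Months counted as late season (default Jan-Mar).
#' @param conf_threshold Detections must exceed this confidence (default 30).
#' @param area Cell-area mode passed to [pixel_area_km2()]: `"geodesic"`
#'   uses each row's latitude, `"nominal"` the conventional 20.25 km^2.
#' @return A `grid_layer` of mean annual weighted fires per km^2.
#' @export
fire_frequency <- function(events, grid, years = c(2007, 2012),
                           late_months = 1:3, conf_threshold = 30,
                           area = c("geodesic", "nominal")) {
  stopifnot(inherits(grid, "grid_spec"), length(years) == 2,
            years[2] >= years[1])
  area <- match.arg(area)
  ev <- events[events$confidence > conf_threshold, , drop = FALSE]
  yr <- as.integer(format(ev$date, "%Y"))
  in_window <- yr >= years[1] & yr <= years[2]
  if (any(!in_window))
    message(sprintf("fire_frequency: dropped %d event(s) outside %d-%d",
                    sum(!in_window), years[1], years[2]))
  ev <- ev[in_window, , drop = FALSE]
  mo <- as.integer(format(ev$date, "%m"))
  w <- ifelse(mo %in% late_months, 2, 1)
  counts <- rasterize_points(ev$lon, ev$lat, grid, weights = w)
  n_years <- years[2] - years[1] + 1
  vals <- counts$values / n_years
  if (area == "nominal") {
    vals <- vals / pixel_area_km2(grid, mode = "nominal")
  } else {
    lat <- cell_center_lat(grid)
    for (i in seq_len(grid$n_rows))
      vals[i, ] <- vals[i, ] / pixel_area_km2(grid, lat[i])
  }
  grid_layer(grid, vals, counts$mask)
}

#' Fire intensity from a fire-frequency layer
#'
#' Same transform chain as overgrazing: square root, then min-max.
#'
#' @param freq A `grid_layer` of fire frequencies (>= 0).
#' @return A `[0, 1]` intensity `grid_layer` tagged `fire`.
#' @export
fire_intensity <- function(freq) {
  threat_intensity(normalize_minmax(sqrt_transform(freq)), "fire")
}

#' Cotton-production intensity from province statistics
#'
#' Each province's production is divided equally among its cotton-producing
#' cells, then the layer is min-max normalized. The result is flagged
#' `capped` so classification can never exceed High: the source mapping is
#' too coarse to resolve peaks of production intensity.
#'
#' @param province_stats Data frame with `province` (id) and `production`.
#' @param cotton_mask Logical matrix marking cotton-producing cells.
#' @param province_map A `grid_layer` of integer province ids.
#' @return A `[0, 1]` intensity `grid_layer` tagged `cotton`, with
#'   attributes `capped = TRUE` and `allocation` (per-cell raw values).
#' @export
cotton_intensity <- function(province_stats, cotton_mask, province_map) {
  stopifnot(inherits(province_map, "grid_layer"))
  spec <- province_map$spec
  cotton_mask <- as.matrix(cotton_mask)
  prov <- province_map$values
  vals <- matrix(0, spec$n_rows, spec$n_cols)
  cotton_provs <- unique(prov[cotton_mask])
  missing <- setdiff(cotton_provs, province_stats$province)
  if (length(missing))
    stop("cotton cell(s) in province(s) without production statistics: ",
         paste(missing, collapse = ", "))
  for (p in cotton_provs) {
    cells <- cotton_mask & prov == p
    prod <- province_stats$production[province_stats$province == p][1]
    vals[cells] <- prod / sum(cells)
  }
  raw <- grid_layer(spec, vals, province_map$mask)
  out <- threat_intensity(normalize_minmax(raw), "cotton", capped = TRUE,
                          species_specific = FALSE)
  attr(out, "allocation") <- vals
  out
}

#' Mining threat class layer from site points
#'
#' Every cell containing at least one active or prospective mining site is
#' rated Very high (the single-pixel footprint covers the site and its
#' degraded surroundings); all other cells are No threat. No intermediate
#' classes occur.
#'
#' @param mining_points Data frame with `lon`, `lat`, `status`
#'   (`"active"`, `"prospect"` counted; anything else ignored).
#' @param grid A `grid_spec`.
#' @return A `class_layer`.
#' @export
mining_class <- function(mining_points, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  act <- mining_points[mining_points$status %in% c("active", "prospect"), ,
                       drop = FALSE]
  classes <- matrix(0L, grid$n_rows, grid$n_cols)
  if (nrow(act)) {
    counts <- rasterize_points(act$lon, act$lat, grid)
    classes[counts$values >= 1] <- 4L
  }
  class_layer(grid, classes)
}

#' Climate-change threat class layer
#'
#' Ordered per-cell decision rules on presence and climatic novelty under
#' the two mid-century scenarios:
#' 1. RCP 4.5 predicts absence: Very high (the moderate scenario already
#'    loses the habitat);
#' 2. both scenarios predict presence in novel regional climate: High;
#' 3. RCP 4.5 predicts presence in novel climate (RCP 8.5 absent or not
#'    novel in agreement): Medium;
#' 4. RCP 4.5 presence but RCP 8.5 absence: Low;
#' 5. both present, neither novel under RCP 4.5: No threat.
#' The ordered list is total and single-valued over all 16 boolean
#' combinations.
#'
#' @param pres_45,pres_85 0/1 `grid_layer`s of predicted presence.
#' @param novel_45,novel_85 0/1 `grid_layer`s of climatic novelty.
#' @return A `class_layer`.
#' @export
climate_class <- function(pres_45, pres_85, novel_45, novel_85) {
  layers <- list(pres_45, pres_85, novel_45, novel_85)
  spec <- pres_45$spec
  for (l in layers)
    if (!same_spec(l$spec, spec)) stop("layers on different grids")
  p45 <- pres_45$values >= 1; p85 <- pres_85$values >= 1
  n45 <- novel_45$values >= 1; n85 <- novel_85$values >= 1
  classes <- matrix(climate_rule(p45, p85, n45, n85), spec$n_rows)
  mask <- Reduce(`&`, lapply(layers, `[[`, "mask"))
  class_layer(spec, classes, mask)
}

# vectorized ordered rule list; exported logic kept separate so the full
# 16-case truth table can be enumerated directly in tests
climate_rule <- function(p45, p85, n45, n85) {
  out <- integer(length(p45))
  out[] <- 0L                                   # both present, not novel
  out[p45 & p85 & !n45 & !n85] <- 0L
  out[p45 & !p85] <- 1L                         # only RCP 4.5 presence
  out[p45 & n45 & !(p85 & n85)] <- 2L           # 4.5 present in novel climate
  out[p45 & p85 & n45 & n85] <- 3L              # both present, both novel
  out[!p45] <- 4L                               # 4.5 already loses habitat
  out
}
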