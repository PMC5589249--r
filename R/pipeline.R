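#' Assemble a run configuration
#'
#' Collects every knob of the assessment with defaults equal to the standard
#' protocol: 2000 background locations, 4 folds, 5 repeats, VIF ceiling 20,
#' minimum 30 unique observations, late fire season January-March,
#' sensitivity normalization `(S - 1) / 4`.
#'
#' @param grid A `grid_spec` for the common analysis grid.
#' @param n_species Number of synthetic species in a demo run.
#' @param seed Master seed; all stage seeds derive from it.
#' @param sdm An [sdm_config()].
#' @param sensitivity_mode Passed to [normalize_sensitivity()].
#' @param fire_years Year window for fire frequency.
#' @param late_months Late-fire-season months.
#' @param n_occurrences Occurrence draws per synthetic species.
#' @param out_dir Optional output directory; when set, summary CSVs, ASCII
#'   grids and a JSON run manifest are written.
#' @return A list of class `run_config`.
#' @export
run_config <- function(grid = grid_spec(60, 80), n_species = 3, seed = 1,
                       sdm = sdm_config(), sensitivity_mode = "minus1_over4",
                       fire_years = c(2007, 2012), late_months = 1:3,
                       n_occurrences = 200, out_dir = NULL) {
  stopifnot(inherits(grid, "grid_spec"), n_species >= 1, n_occurrences >= 1)
  structure(list(grid = grid, n_species = n_species, seed = seed, sdm = sdm,
                 sensitivity_mode = sensitivity_mode,
                 fire_years = fire_years, late_months = late_months,
                 n_occurrences = n_occurrences, out_dir = out_dir),
            class = "run_config")
}

#' Validate raw pipeline inputs
#'
#' Schema and range checks: occurrence coordinates within bounds, expert
#' ratings in 1-5, fire confidences in 0-100, required columns present.
#' Returns a report rather than erroring.
#'
#' @param occurrences Optional occurrence data frame.
#' @param ratings Optional experts x items rating matrix.
#' @param fire_events Optional fire-event data frame.
#' @return Character vector of violations (empty when fully valid).
#' @export
validate_inputs <- function(occurrences = NULL, ratings = NULL,
                            fire_events = NULL) {
  v <- character(0)
  if (!is.null(occurrences)) {
    need <- c("species", "lon", "lat")
    miss <- setdiff(need, names(occurrences))
    if (length(miss))
      v <- c(v, sprintf("occurrences: missing column(s) %s",
                        paste(miss, collapse = ", ")))
    if (all(c("lon", "lat") %in% names(occurrences))) {
      if (any(abs(occurrences$lon) > 180, na.rm = TRUE))
        v <- c(v, "occurrences: longitude outside [-180, 180]")
      if (any(abs(occurrences$lat) > 90, na.rm = TRUE))
        v <- c(v, "occurrences: latitude outside [-90, 90]")
    }
  }
  if (!is.null(ratings)) {
    r <- as.matrix(ratings)
    if (any(r < 1 | r > 5, na.rm = TRUE))
      v <- c(v, "ratings: value(s) outside the 1-5 scale")
  }
  if (!is.null(fire_events)) {
    need <- c("lon", "lat", "date", "confidence")
    miss <- setdiff(need, names(fire_events))
    if (length(miss))
      v <- c(v, sprintf("fire_events: missing column(s) %s",
                        paste(miss, collapse = ", ")))
    if ("confidence" %in% names(fire_events) &&
        any(fire_events$confidence < 0 | fire_events$confidence > 100,
            na.rm = TRUE))
      v <- c(v, "fire_events: confidence outside [0, 100]")
  }
  v
}

# deterministic per-stage seeds below 2^31
stage_seed <- function(seed, k)
  as.integer((abs(seed) * 1009 + k * 9973) %% 2147483647)

#' Run the full multi-threat assessment on synthetic data
#'
#' End-to-end demonstration run: generates climate (current + two future
#' scenarios), species occurrences from known niches, raw threat inputs and
#' expert panels; calibrates per-species ensemble SDMs on the two variable
#' subsets (stepwise-VIF-selected set and the annual temperature/rainfall
#' pair), yielding four candidate distribution maps (2 subsets x 2
#' thresholds); selects the best map and the per-threat sensitivities by
#' expert consensus; builds the six threat layers; and combines, summarises
#' and (optionally) writes everything.
#'
#' @param config A [run_config()].
#' @return List with per-species results (`species`), the threat intensity
#'   layers (`intensities`), `hotspots`, `richness`, and summary data frames
#'   `table_severe` (per-threat severe percentages) and `table_combined`
#'   (per-class percentages of the combined map).
#' @export
run_threat_assessment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$grid

  clim <- gen_climate(spec, seed = stage_seed(config$seed, 1))
  inputs <- gen_threat_inputs(spec, seed = stage_seed(config$seed, 2))

  # shared generic threat layers
  overexp <- overexploitation_intensity(inputs$footprint)
  overgraze <- overgrazing_intensity(tlu(inputs$cattle, inputs$goats,
                                         inputs$sheep))
  freq <- fire_frequency(inputs$fire_events, spec, years = config$fire_years,
                         late_months = config$late_months)
  fire <- fire_intensity(freq)
  cotton <- cotton_intensity(inputs$cotton_stats, inputs$cotton_mask,
                             inputs$province_map)
  mining <- mining_class(inputs$mining_points, spec)
  intensities <- list(overexploitation = overexp, overgrazing = overgraze,
                      fire = fire, cotton = cotton)

  novel45 <- detect_novel(clim$current, clim$rcp45)
  novel85 <- detect_novel(clim$current, clim$rcp85)

  threat_items <- c("overexploitation", "overgrazing", "fire")
  species_results <- list()
  severe_rows <- list(); combined_rows <- list()
  presence_layers <- list(); combined_layers <- list()

  for (s in seq_len(config$n_species)) {
    sp_name <- sprintf("species_%02d", s)
    sp_seed <- stage_seed(config$seed, 10 + s)
    set.seed(sp_seed)
    niche <- niche_spec(
      optima = c(BIO1 = stats::runif(1, 27, 29),
                 BIO12 = stats::runif(1, 400, 900)),
      tolerances = c(BIO1 = stats::runif(1, 1, 2),
                     BIO12 = stats::runif(1, 150, 300)))
    occ <- gen_occurrences(niche, clim$current, n = config$n_occurrences,
                           seed = sp_seed, species = sp_name)

    # two variable subsets -> two calibrations -> four threshold variants
    retained <- vif_stepwise(clim$current, config$sdm$vif_threshold)
    fit_full <- calibrate_ensemble(occ, env_stack(clim$current[retained]),
                                   config$sdm, seed = sp_seed)
    fit_pair <- calibrate_ensemble(occ,
                                   env_stack(clim$current[c("BIO1", "BIO12")]),
                                   config$sdm, seed = sp_seed)
    variants <- list(
      model_1 = list(fit = fit_full, threshold = "tpr90"),
      model_2 = list(fit = fit_full, threshold = "minimum"),
      model_3 = list(fit = fit_pair, threshold = "tpr90"),
      model_4 = list(fit = fit_pair, threshold = "minimum"))

    # expert evaluation: SDM-variant block, then threat-sensitivity block
    sdm_panel <- gen_expert_panel(
      panel_spec(n_experts = 15, n_items = length(variants),
                 missing_rate = 0.1),
      seed = stage_seed(config$seed, 100 + s))
    sdm_cons <- consensus(sdm_panel$ratings)
    best <- match(sdm_cons$best, colnames(sdm_panel$ratings))
    chosen <- variants[[best]]

    sens_panel <- gen_expert_panel(
      panel_spec(n_experts = 15, n_items = length(threat_items),
                 missing_rate = 0.1),
      seed = stage_seed(config$seed, 200 + s))
    sens_cons <- consensus(sens_panel$ratings)
    sens <- normalize_sensitivity(sens_cons$scores, config$sensitivity_mode)
    names(sens) <- threat_items

    distribution <- predict_presence(chosen$fit, threshold = chosen$threshold)
    dmask <- distribution$values >= 1 & distribution$mask

    pres45 <- predict_presence(chosen$fit, clim$rcp45,
                               threshold = chosen$threshold)
    pres85 <- predict_presence(chosen$fit, clim$rcp85,
                               threshold = chosen$threshold)
    climate <- climate_class(pres45, pres85, novel45, novel85)

    to_dist <- function(cl) class_layer(spec, cl$classes, cl$mask & dmask)
    sp_layers <- list(
      overexploitation = species_threat_map(overexp,
                                            sens[["overexploitation"]],
                                            dmask),
      overgrazing = species_threat_map(overgraze, sens[["overgrazing"]],
                                       dmask),
      fire = species_threat_map(fire, sens[["fire"]], dmask),
      cotton = species_threat_map(cotton, 1, dmask),
      mining = to_dist(mining),
      climate = to_dist(climate))
    combined <- combine_threats(sp_layers)
    tab <- scope_table(sp_layers, combined, dmask)

    species_results[[sp_name]] <- list(
      occurrences = occ, niche = niche, fits = variants,
      model_selection = sdm_cons, best_variant = names(variants)[best],
      sensitivities = sens, sensitivity_consensus = sens_cons,
      distribution = distribution, threat_maps = sp_layers,
      combined = combined, scope = tab)
    severe_rows[[sp_name]] <- tab$severe
    combined_rows[[sp_name]] <- tab$combined
    presence_layers[[sp_name]] <- distribution
    combined_layers[[sp_name]] <- combined
  }

  hotspots <- hotspot_map(combined_layers)
  richness <- richness_map(presence_layers)
  table_severe <- as.data.frame(do.call(rbind, severe_rows))
  table_combined <- as.data.frame(do.call(rbind, combined_rows))

  result <- list(species = species_results, intensities = intensities,
                 mining = mining, hotspots = hotspots, richness = richness,
                 table_severe = table_severe,
                 table_combined = table_combined, config = config)
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(species = rownames(result$table_severe),
                         result$table_severe),
                   file.path(out_dir, "severe_threat_percent.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(species = rownames(result$table_combined),
                         result$table_combined),
                   file.path(out_dir, "combined_class_percent.csv"),
                   row.names = FALSE)
  write_asc(result$hotspots, file.path(out_dir, "hotspots.asc"))
  write_asc(result$richness, file.path(out_dir, "richness.asc"))
  for (sp in names(result$species)) {
    write_asc(result$species[[sp]]$combined,
              file.path(out_dir, sprintf("%s_combined.asc", sp)))
  }
  cfg <- result$config
  manifest <- list(
    package = "threatmapr",
    version = as.character(utils::packageVersion("threatmapr")),
    seed = cfg$seed,
    grid = unclass(cfg$grid),
    n_species = cfg$n_species,
    sdm = list(n_background = cfg$sdm$n_background,
               n_folds = cfg$sdm$n_folds, n_repeats = cfg$sdm$n_repeats,
               n_keep = cfg$sdm$n_keep,
               min_unique_obs = cfg$sdm$min_unique_obs,
               vif_threshold = cfg$sdm$vif_threshold,
               candidates = names(cfg$sdm$candidates)),
    sensitivity_mode = cfg$sensitivity_mode,
    fire_years = cfg$fire_years, late_months = cfg$late_months)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
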