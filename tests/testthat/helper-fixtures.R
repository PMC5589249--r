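# Shared fixtures. The ensemble calibration is expensive, so fixtures are
# computed once per test run and cached for every file that needs them.

fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

fx_spec <- function() grid_spec(60, 80)

fx_climate <- function() with_cache("climate", gen_climate(fx_spec(), seed = 7))

fx_niche <- function() {
  niche_spec(optima = c(BIO1 = 28, BIO12 = 700),
             tolerances = c(BIO1 = 1.5, BIO12 = 200))
}

fx_occurrences <- function() {
  with_cache("occ",
             gen_occurrences(fx_niche(), fx_climate()$current,
                             n = 200, seed = 7))
}

# full-protocol calibration: 12 candidates, 2000 background, 4 folds,
# 5 repeats on the 60 x 80 synthetic study area
fx_fit <- function() {
  with_cache("fit", suppressWarnings(suppressMessages(
    calibrate_ensemble(fx_occurrences(), fx_climate()$current,
                       sdm_config(), seed = 7))))
}

# a small fast candidate set for property tests that need repeated
# calibrations but not the full registry
fast_config <- function(...) {
  cands <- default_candidates()[c("glm_linear", "cart", "naive_bayes",
                                  "climate_envelope", "mahalanobis")]
  sdm_config(n_background = 300, n_folds = 3, n_repeats = 2,
             candidates = cands, ...)
}

# uniform small layer on an integer-degree grid (origin at lon 0, top lat =
# n_rows), handy for hand-computed examples
small_layer <- function(vals, mask = NULL, cell = 1) {
  vals <- as.matrix(vals)
  grid_layer(grid_spec(nrow(vals), ncol(vals), cell_size = cell,
                       origin_lon = 0, origin_lat = nrow(vals) * cell),
             vals, mask)
}

small_class <- function(codes, mask = NULL, cell = 1) {
  codes <- as.matrix(codes)
  class_layer(grid_spec(nrow(codes), ncol(codes), cell_size = cell,
                        origin_lon = 0, origin_lat = nrow(codes) * cell),
              codes, mask)
}

# boolean layers for the climate classifier
flag_layer <- function(vals) small_layer(as.matrix(vals) * 1)
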