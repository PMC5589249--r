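#' Bundle named climate layers into an environment stack
#'
#' @param layers Named list of `grid_layer`s sharing one `grid_spec`.
#' @return An object of class `env_stack` (a named list of layers).
#' @export
env_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  spec <- layers[[1]]$spec
  for (l in layers)
    if (!same_spec(l$spec, spec)) stop("env_stack layers on different grids")
  structure(layers, class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %s on %d x %d grid\n",
              paste(names(x), collapse = ", "),
              x[[1]]$spec$n_rows, x[[1]]$spec$n_cols))
  invisible(x)
}

# Spatially smooth Gaussian field: white noise blurred by repeated
# separable moving averages, rescaled to unit standard deviation.
smooth_noise <- function(n_rows, n_cols, passes = 3, window = 7) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  k <- rep(1 / window, window)
  blur <- function(m) {
    m <- apply(m, 2, function(col)
      stats::filter(col, k, sides = 2, circular = TRUE))
    t(apply(m, 1, function(row)
      stats::filter(row, k, sides = 2, circular = TRUE)))
  }
  for (p in seq_len(passes)) z <- blur(z)
  z / stats::sd(z)
}

#' Names of the bioclimatic variables used by the assessment
#' @export
climate_variables <- function() {
  c("BIO1", "BIO3", "BIO5", "BIO12", "BIO13", "BIO14", "LLDS", "PET")
}

#' Default future-scenario shifts
#'
#' Additive shifts for temperature-like variables and multiplicative factors
#' for precipitation-like ones. Defaults emulate a mid-century intermediate
#' pathway (RCP 4.5: +1.5 deg C, -10% rainfall) and a high pathway
#' (RCP 8.5: +3.0 deg C, -20% rainfall).
#'
#' @param bio1_add,bio5_add,pet_add,llds_add Additive shifts.
#' @param precip_mult Multiplier applied to BIO12/BIO13/BIO14.
#' @return A named list of shifts.
#' @export
climate_shift <- function(bio1_add = 1.5, bio5_add = 1.5, pet_add = 50,
                          llds_add = 0.5, precip_mult = 0.9) {
  list(bio1_add = bio1_add, bio5_add = bio5_add, pet_add = pet_add,
       llds_add = llds_add, precip_mult = precip_mult)
}

apply_shift <- function(stack, shift, noise_sd = 0) {
  out <- lapply(names(stack), function(nm) {
    l <- stack[[nm]]
    v <- l$values
    v <- switch(nm,
      BIO1  = v + shift$bio1_add,
      BIO5  = v + shift$bio5_add,
      PET   = v + shift$pet_add,
      LLDS  = v + shift$llds_add,
      BIO12 = v * shift$precip_mult,
      BIO13 = v * shift$precip_mult,
      BIO14 = v * shift$precip_mult,
      v)
    if (noise_sd > 0)
      v <- v + noise_sd * smooth_noise(nrow(v), ncol(v))
    grid_layer(l$spec, v, l$mask)
  })
  names(out) <- names(stack)
  env_stack(out)
}

#' Generate synthetic current and future climate stacks
#'
#' Emulates a semi-arid West African climate: temperature, dry-season length
#' and evapotranspiration increase northwards while rainfall decreases, each
#' overlaid with low-amplitude spatially autocorrelated noise. Future stacks
#' are the current one shifted (warming, drying) per [climate_shift()].
#' Deterministic for a given seed.
#'
#' @param spec A `grid_spec`.
#' @param seed Integer seed.
#' @param shift_rcp45,shift_rcp85 Shift lists from [climate_shift()].
#' @param noise_sd Amplitude of the smooth noise added to future stacks
#'   (same units as each variable's gradient amplitude fraction); default 0
#'   keeps the shifts exact.
#' @return List with elements `current`, `rcp45`, `rcp85` (each `env_stack`).
#' @export
gen_climate <- function(spec, seed = 1,
                        shift_rcp45 = climate_shift(),
                        shift_rcp85 = climate_shift(bio1_add = 3,
                                                    bio5_add = 3,
                                                    pet_add = 100,
                                                    llds_add = 1,
                                                    precip_mult = 0.8),
                        noise_sd = 0) {
  set.seed(seed)
  nr <- spec$n_rows; nc <- spec$n_cols
  # northness in [0, 1]: 1 at the top (Sahelian) row
  north <- matrix(seq(1, 0, length.out = nr), nr, nc)
  field <- function(base, amp, rel_noise = 0.05) {
    base + amp * north + rel_noise * abs(amp) * smooth_noise(nr, nc)
  }
  cur <- env_stack(list(
    BIO1  = grid_layer(spec, field(26.5, 2.5)),     # deg C
    BIO3  = grid_layer(spec, field(62, 10)),        # percent
    BIO5  = grid_layer(spec, field(35, 6)),         # deg C
    BIO12 = grid_layer(spec, field(1100, -800)),    # mm / year
    BIO13 = grid_layer(spec, field(280, -180)),     # mm
    BIO14 = grid_layer(spec, pmax(field(8, -7.5), 0)),
    LLDS  = grid_layer(spec, field(6, 3)),          # months
    PET   = grid_layer(spec, field(1500, 500))))    # mm / year
  list(current = cur,
       rcp45 = apply_shift(cur, shift_rcp45, noise_sd),
       rcp85 = apply_shift(cur, shift_rcp85, noise_sd))
}

#' Describe a species' climatic niche
#'
#' Gaussian response per variable: suitability is the product over variables
#' of `exp(-0.5 ((x - optimum) / tolerance)^2)`, scaled by `max_suit`.
#'
#' @param optima Named numeric vector of per-variable optima (names must be
#'   climate variables present in the stack used).
#' @param tolerances Named numeric vector of per-variable tolerances (> 0).
#' @param max_suit Peak suitability in `[0, 1]`.
#' @param prevalence Nominal fraction of cells intended to be occupied
#'   (metadata used by generators to scale sample sizes).
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(optima, tolerances, max_suit = 1, prevalence = 0.3) {
  stopifnot(all(tolerances > 0), max_suit >= 0, max_suit <= 1,
            prevalence > 0, prevalence < 1,
            identical(sort(names(optima)), sort(names(tolerances))))
  structure(list(optima = optima, tolerances = tolerances,
                 max_suit = max_suit, prevalence = prevalence),
            class = "niche_spec")
}

#' True suitability of a niche over an environment stack
#'
#' @param niche A `niche_spec`.
#' @param env An `env_stack` containing all the niche's variables.
#' @return A `grid_layer` of suitabilities in `[0, 1]`.
#' @export
niche_suitability <- function(niche, env) {
  stopifnot(inherits(niche, "niche_spec"))
  vars <- names(niche$optima)
  missing <- setdiff(vars, names(env))
  if (length(missing))
    stop("env stack lacks variable(s): ", paste(missing, collapse = ", "))
  spec <- env[[1]]$spec
  s <- matrix(niche$max_suit, spec$n_rows, spec$n_cols)
  mask <- env[[1]]$mask
  for (v in vars) {
    z <- (env[[v]]$values - niche$optima[[v]]) / niche$tolerances[[v]]
    s <- s * exp(-0.5 * z^2)
    mask <- mask & env[[v]]$mask
  }
  grid_layer(spec, s, mask)
}

#' Sample occurrence records from a known niche
#'
#' Cells are drawn with probability proportional to true suitability, then
#' deduplicated to unique cells ("unique observations"); coordinates are the
#' cell centers. Deterministic for a given seed.
#'
#' @param niche A `niche_spec`.
#' @param env An `env_stack`.
#' @param n Number of draws before deduplication.
#' @param seed Integer seed.
#' @param species Species label written into the table.
#' @param unique_cells Deduplicate draws to unique cells (default); set
#'   `FALSE` to keep every raw draw.
#' @return Data frame with columns `species`, `lon`, `lat`, `source`.
#' @export
gen_occurrences <- function(niche, env, n = 200, seed = 1,
                            species = "synthetic_species",
                            unique_cells = TRUE) {
  stopifnot(n >= 1)
  suit <- niche_suitability(niche, env)
  p <- suit$values
  p[!suit$mask] <- 0
  if (all(p <= 0)) stop("niche has zero suitability everywhere")
  set.seed(seed)
  cells <- sample.int(length(p), n, replace = TRUE, prob = as.vector(p))
  if (unique_cells) cells <- unique(cells)
  spec <- suit$spec
  ij <- arrayInd(cells, dim(p))
  data.frame(species = species,
             lon = cell_center_lon(spec)[ij[, 2]],
             lat = cell_center_lat(spec)[ij[, 1]],
             source = "synthetic")
}

#' Generate synthetic raw threat inputs
#'
#' Emulates the statistical structure the pipeline assumes from its real
#' sources: a 0-100 human-footprint surface with urban hotspots; right-skewed
#' (lognormal) livestock densities heavier in the north; fire detections over
#' a multi-year window spanning both early (Nov-Dec) and late (Jan-Mar) dry
#' season with uniform 0-100 confidence; cotton production confined to a
#' south-western block of axis-aligned synthetic provinces, with per-province
#' production statistics; and sparse mining points with an activity status.
#' Deterministic for a given seed.
#'
#' @param spec A `grid_spec`.
#' @param seed Integer seed.
#' @param n_fires Number of fire detections to draw.
#' @param n_mines Number of mining points.
#' @param years Year window covered by fire detections.
#' @return List with elements `footprint`, `cattle`, `goats`, `sheep`
#'   (`grid_layer`s), `fire_events`, `cotton_stats`, `mining_points` (data
#'   frames), `province_map` (`grid_layer` of province ids) and
#'   `cotton_mask` (logical matrix of cotton-producing cells).
#' @export
gen_threat_inputs <- function(spec, seed = 1, n_fires = 3000, n_mines = 25,
                              years = c(2007, 2012)) {
  set.seed(seed)
  nr <- spec$n_rows; nc <- spec$n_cols
  north <- matrix(seq(1, 0, length.out = nr), nr, nc)
  lonc <- cell_center_lon(spec); latc <- cell_center_lat(spec)

  # human footprint: background + a few exponential-decay urban hotspots
  fp <- 15 + 8 * smooth_noise(nr, nc)
  n_hot <- 4
  hot_i <- sample.int(nr, n_hot); hot_j <- sample.int(nc, n_hot)
  for (h in seq_len(n_hot)) {
    d2 <- outer((seq_len(nr) - hot_i[h])^2, (seq_len(nc) - hot_j[h])^2, `+`)
    fp <- fp + 70 * exp(-sqrt(d2) / (0.06 * max(nr, nc)))
  }
  fp <- pmin(pmax(fp, 0), 100)

  # livestock: lognormal, north-heavy gradient (traditional herding areas)
  herd <- function(mean_heads, grad) {
    mu <- log(mean_heads) + grad * (north - 0.5) + 0.4 * smooth_noise(nr, nc)
    matrix(stats::rlnorm(nr * nc, meanlog = as.vector(mu), sdlog = 0.8),
           nr, nc)
  }
  cattle <- herd(20, 1.2); goats <- herd(30, 1.5); sheep <- herd(25, 1.5)

  # fire detections: Nov-Mar season across the year window, more in the
  # wetter (southern, higher fuel load) half
  yr <- sample(seq(years[1], years[2]), n_fires, replace = TRUE)
  mo <- sample(c(11, 12, 1, 2, 3), n_fires, replace = TRUE,
               prob = c(0.15, 0.2, 0.3, 0.25, 0.1))
  day <- sample.int(28, n_fires, replace = TRUE)
  # months Jan-Mar fall in the dry season following a Nov/Dec start
  fire_row <- sample.int(nr, n_fires, replace = TRUE,
                         prob = 0.2 + seq(0, 1, length.out = nr))
  fire_col <- sample.int(nc, n_fires, replace = TRUE)
  jit <- function(n) stats::runif(n, -0.5, 0.4999) * spec$cell_size
  fire_events <- data.frame(
    lon = lonc[fire_col] + jit(n_fires),
    lat = latc[fire_row] + jit(n_fires),
    date = as.Date(sprintf("%d-%02d-%02d", yr, mo, day)),
    confidence = stats::runif(n_fires, 0, 100))

  # provinces: axis-aligned 3 x 4 partition; cotton in the south-west block
  prow <- cut(seq_len(nr), 3, labels = FALSE)
  pcol <- cut(seq_len(nc), 4, labels = FALSE)
  province <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    province[i, j] <- (prow[i] - 1L) * 4L + pcol[j]
  cotton_prov <- c(9L, 10L)  # bottom row (south), west half
  cotton_mask <- matrix(FALSE, nr, nc)
  in_cp <- province %in% cotton_prov
  cotton_mask[in_cp] <- stats::runif(sum(in_cp)) < 0.5
  cotton_stats <- data.frame(
    province = cotton_prov,
    production = stats::runif(length(cotton_prov), 5000, 60000))

  mi <- sample.int(nr, n_mines, replace = TRUE,
                   prob = seq(1, 0.2, length.out = nr))
  mj <- sample.int(nc, n_mines, replace = TRUE)
  mining_points <- data.frame(
    lon = lonc[mj], lat = latc[mi],
    status = sample(c("active", "prospect", "inactive"), n_mines,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2)))

  list(footprint = grid_layer(spec, fp),
       cattle = grid_layer(spec, cattle),
       goats = grid_layer(spec, goats),
       sheep = grid_layer(spec, sheep),
       fire_events = fire_events,
       cotton_stats = cotton_stats,
       mining_points = mining_points,
       province_map = grid_layer(spec, province),
       cotton_mask = cotton_mask)
}

#' Describe a synthetic expert panel
#'
#' @param n_experts,n_items Panel dimensions.
#' @param competences Per-expert competence in `[0, 1]`; default linearly
#'   spaced 0.1 to 1.
#' @param truth Shared latent item scores in `[1, 5]`; default drawn by the
#'   generator.
#' @param missing_rate Fraction of ratings dropped at random.
#' @param sigma0 Noise scale: rating noise SD is `sigma0 * (1 - competence)`.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_experts = 15, n_items = 12,
                       competences = seq(0.1, 1, length.out = n_experts),
                       truth = NULL, missing_rate = 0, sigma0 = 2) {
  stopifnot(length(competences) == n_experts,
            all(competences >= 0 & competences <= 1),
            missing_rate >= 0, missing_rate < 1, sigma0 >= 0)
  if (!is.null(truth)) stopifnot(length(truth) == n_items,
                                 all(truth >= 1 & truth <= 5))
  structure(list(n_experts = n_experts, n_items = n_items,
                 competences = competences, truth = truth,
                 missing_rate = missing_rate, sigma0 = sigma0),
            class = "panel_spec")
}

#' Generate expert ratings under a cultural-consensus model
#'
#' Each rating is the shared item truth plus Gaussian noise whose SD shrinks
#' with the expert's competence (`sigma0 * (1 - competence)`), clamped to the
#' 1-5 scale and rounded; entries are dropped at `missing_rate`.
#' Deterministic for a given seed.
#'
#' @param panel A `panel_spec`.
#' @param seed Integer seed.
#' @return List with `ratings` (experts x items matrix, `NA` = missing),
#'   `truth` and `competences`.
#' @export
gen_expert_panel <- function(panel, seed = 1) {
  stopifnot(inherits(panel, "panel_spec"))
  set.seed(seed)
  truth <- panel$truth
  if (is.null(truth)) truth <- stats::runif(panel$n_items, 1, 5)
  noise_sd <- panel$sigma0 * (1 - panel$competences)
  r <- matrix(NA_real_, panel$n_experts, panel$n_items)
  for (i in seq_len(panel$n_experts)) {
    raw <- truth + stats::rnorm(panel$n_items, sd = noise_sd[i])
    r[i, ] <- round(pmin(pmax(raw, 1), 5))
  }
  if (panel$missing_rate > 0) {
    drop <- matrix(stats::runif(length(r)) < panel$missing_rate, nrow(r))
    r[drop] <- NA
  }
  dimnames(r) <- list(paste0("expert_", seq_len(panel$n_experts)),
                      paste0("item_", seq_len(panel$n_items)))
  list(ratings = r, truth = truth, competences = panel$competences)
}
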