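make_stack <- function(mats, cell = 1) {
  spec <- grid_spec(nrow(mats[[1]]), ncol(mats[[1]]), cell_size = cell,
                    origin_lon = 0, origin_lat = nrow(mats[[1]]) * cell)
  env_stack(lapply(mats, function(m) grid_layer(spec, m)))
}

# independent brute-force VIF: regress each variable on the others
brute_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(k) {
    r2 <- summary(stats::lm(X[, k] ~ X[, -k, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

test_that("stepwise VIF elimination keeps independent variables and prunes collinear ones", {
  set.seed(21)
  nr <- 20; nc <- 25
  indep <- list(a = matrix(rnorm(nr * nc), nr),
                b = matrix(rnorm(nr * nc), nr),
                c = matrix(rnorm(nr * nc), nr))
  expect_equal(vif_stepwise(make_stack(indep)), c("a", "b", "c"))

  # duplicated variable: exactly one of the pair removed
  dup <- c(indep, list(a2 = indep$a))
  kept <- vif_stepwise(make_stack(dup))
  expect_equal(sum(c("a", "a2") %in% kept), 1)
  expect_true(all(c("b", "c") %in% kept))

  # near-linear combination: retained set passes the ceiling by brute force
  tri <- list(x1 = indep$a, x2 = indep$b,
              x3 = indep$a + indep$b + matrix(rnorm(nr * nc, sd = 1e-3), nr))
  kept3 <- vif_stepwise(make_stack(tri), threshold = 20)
  X <- sapply(tri[kept3], as.vector)
  expect_lte(max(brute_vif(X)), 20)
  expect_lt(length(kept3), 3)
})

test_that("AUC follows the Mann-Whitney form", {
  expect_equal(auc_mw(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_mw(rep(2, 5), rep(2, 7)), 0.5)
  # enumerate 2 pairs: one win, one loss
  expect_equal(auc_mw(c(1, 3), 2), 0.5)
  expect_error(auc_mw(numeric(0), 1), "empty")
  # complement property over random score sets
  set.seed(5)
  for (i in 1:20) {
    p <- sample(1:8, 9, replace = TRUE)
    n <- sample(1:8, 6, replace = TRUE)
    expect_equal(auc_mw(p, n) + auc_mw(n, p), 1)
  }
})

test_that("presence thresholds implement minimum and tpr90 order statistics", {
  expect_equal(threshold_min(c(0.3, 0.5)), 0.3)
  expect_equal(threshold_min(rep(0.4, 6)), 0.4)
  scores <- seq(0.1, 1, by = 0.1)
  t90 <- threshold_tpr90(scores)
  expect_equal(t90, 0.2)
  expect_gte(mean(scores >= t90), 0.9)
  expect_equal(threshold_tpr90(0.37), 0.37)
  # tpr90 never below the minimum threshold
  set.seed(9)
  for (i in 1:20) {
    s <- runif(sample(1:40, 1))
    expect_gte(threshold_tpr90(s), threshold_min(s))
  }
})

test_that("calibrated ensemble has valid weights and recovers the niche", {
  fit <- fx_fit()
  w <- coef(fit)
  expect_equal(sum(w), 1)
  expect_equal(sum(w > 0), 10)
  expect_equal(length(w), 12)
  # kept candidates separated presences from background
  kept_auc <- fit$candidates$mean_auc[fit$candidates$weight > 0]
  expect_true(all(kept_auc > 0.5))
  # ensemble held-out AUC is competitive with the best single candidate
  expect_gte(fit$ensemble_test_auc, max(fit$candidates$mean_auc) - 0.05)
  # suitability within [0, 1] and correlated with the generating truth
  s <- fit$suitability
  expect_true(all(s$values[s$mask] >= 0 & s$values[s$mask] <= 1))
  truth <- niche_suitability(fx_niche(), fx_climate()$current)
  rho <- cor(s$values[s$mask], truth$values[truth$mask],
             method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("species below the unique-observation minimum are rejected", {
  clim <- fx_climate()
  spec <- fx_spec()
  lon <- cell_center_lon(spec)[1:29]
  lat <- rep(cell_center_lat(spec)[5], 29)
  occ29 <- data.frame(lon = lon, lat = lat)
  expect_error(calibrate_ensemble(occ29, clim$current, sdm_config()),
               class = "species_rejected")
  expect_error(calibrate_ensemble(occ29, clim$current, sdm_config()),
               "minimum of 30")
  # duplicated records do not inflate the unique count
  occ_dup <- occ29[rep(1:29, 3), ]
  expect_error(calibrate_ensemble(occ_dup, clim$current, sdm_config()),
               class = "species_rejected")
})

test_that("shuffled presence labels drive the held-out ensemble AUC to chance", {
  clim <- fx_climate()
  spec <- fx_spec()
  set.seed(13)
  cells <- sample.int(spec$n_rows * spec$n_cols, 120)
  ij <- arrayInd(cells, c(spec$n_rows, spec$n_cols))
  occ <- data.frame(lon = cell_center_lon(spec)[ij[, 2]],
                    lat = cell_center_lat(spec)[ij[, 1]])
  fit <- suppressWarnings(suppressMessages(
    calibrate_ensemble(occ, clim$current, fast_config(), seed = 13)))
  expect_lt(abs(fit$ensemble_test_auc - 0.5), 0.1)
})

test_that("presence maps honour their thresholds on the calibration stack", {
  fit <- fx_fit()
  pres_min <- predict_presence(fit, threshold = "minimum")
  pres_90 <- predict_presence(fit, threshold = "tpr90")
  expect_equal(mean(pres_min$values[fit$presence_cells] >= 1), 1)
  expect_gte(mean(pres_90$values[fit$presence_cells] >= 1), 0.9)
  # tpr90 map nested inside the minimum-threshold map
  expect_true(all(pres_min$values[pres_90$values >= 1] >= 1))
  # missing variable named in the error
  clim <- fx_climate()
  partial <- env_stack(clim$rcp45[setdiff(names(clim$rcp45), "PET")])
  expect_error(predict_presence(fit, partial), "PET")
})

test_that("novel-climate detection uses the closed current min-max envelope", {
  clim <- fx_climate()
  none <- detect_novel(clim$current, clim$current)
  expect_true(all(none$values == 0))

  # raising one cell's BIO1 above the global current max flags only it
  fut <- clim$current
  i <- 7; j <- 9
  v <- fut$BIO1$values
  v[i, j] <- max(v) + 1
  fut$BIO1 <- grid_layer(fut$BIO1$spec, v, fut$BIO1$mask)
  nov <- detect_novel(clim$current, env_stack(fut))
  expect_equal(sum(nov$values), 1)
  expect_equal(nov$values[i, j], 1)

  # a value exactly at the current extreme is not novel (closed interval)
  fut2 <- clim$current
  v2 <- fut2$BIO1$values
  v2[i, j] <- max(clim$current$BIO1$values)
  fut2$BIO1 <- grid_layer(fut2$BIO1$spec, v2, fut2$BIO1$mask)
  nov2 <- detect_novel(clim$current, env_stack(fut2))
  expect_equal(sum(nov2$values), 0)

  # default warming/drying scenarios produce novel cells somewhere
  nov85 <- detect_novel(clim$current, clim$rcp85)
  expect_gt(sum(nov85$values), 0)
})
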