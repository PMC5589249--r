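test_that("magnitude classification uses the printed class intervals", {
  expect_equal(classify_magnitude(0.5), 3L)     # High: 0.31-0.7
  expect_equal(classify_magnitude(0), 0L)
  expect_equal(classify_magnitude(0.71), 4L)
  expect_equal(classify_magnitude(0.71, capped = TRUE), 3L)
  # midpoint boundaries: anything rounding to 0.70 stays High, to 0.71 is
  # Very high; same pattern at the lower cuts
  expect_equal(classify_magnitude(c(0.705, 0.706)), c(3L, 4L))
  expect_equal(classify_magnitude(c(0.305, 0.306)), c(2L, 3L))
  expect_equal(classify_magnitude(c(0.105, 0.106)), c(1L, 2L))
  expect_equal(classify_magnitude(c(0.01, 0.0100001)), c(0L, 1L))
  expect_error(classify_magnitude(1.2), "outside")
  expect_error(classify_magnitude(-0.1), "outside")
  # total monotone step function on a fine grid
  g <- seq(0, 1, by = 0.001)
  cls <- classify_magnitude(g)
  expect_true(all(diff(cls) >= 0))
  expect_equal(sort(unique(cls)), 0:4)
  expect_true(all(classify_magnitude(g, capped = TRUE) <= 3L))
})

test_that("species threat maps weight intensity by sensitivity inside the range", {
  intens <- small_layer(matrix(c(0.6, 0.2, 0.9, 0), 2, 2))
  # sensitivity 0: everything No threat
  expect_true(all(species_threat_map(intens, 0)$classes == 0))
  # sensitivity 1: classes of the raw intensity
  expect_equal(as.vector(species_threat_map(intens, 1)$classes),
               classify_magnitude(as.vector(intens$values)))
  # 0.6 x 0.5 = 0.30 -> Medium under the midpoint boundary rule
  expect_equal(species_threat_map(intens, 0.5)$classes[1, 1], 2L)
  # distribution mask excludes cells
  dist <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  m <- species_threat_map(intens, 1, dist)
  expect_equal(m$mask, dist)
  # capped intensity never yields Very high
  capped <- intens
  attr(capped, "capped") <- TRUE
  expect_true(all(species_threat_map(capped, 1)$classes <= 3L))
})

test_that("threat combination applies the max and the 3-5 upgrade rule", {
  mk <- function(...) {
    codes <- list(...)
    lapply(codes, function(k) small_class(matrix(k, 1, 1)))
  }
  comb1 <- combine_threats(mk(3, 3, 3, 0, 0, 0))
  expect_equal(comb1$classes[1, 1], 4L)          # three Highs -> Very high
  comb2 <- combine_threats(mk(2, 2, 2, 2, 2, 0))
  expect_equal(comb2$classes[1, 1], 3L)          # five Mediums -> High
  comb3 <- combine_threats(mk(3, 3, 2, 2, 0, 0))
  expect_equal(comb3$classes[1, 1], 3L)          # no upgrade fires
  expect_error(combine_threats(mk(1, 1, 1)), "exactly 6")

  # random spot-check against the scalar reference rule
  set.seed(41)
  for (i in 1:100) {
    codes <- sample(0:4, 6, replace = TRUE)
    expect_equal(do.call(combine_threats, list(mk(codes[1], codes[2],
                                                  codes[3], codes[4],
                                                  codes[5],
                                                  codes[6])))$classes[1, 1],
                 combine_rule(codes))
  }

  # monotonicity: raising one input class never lowers the combined class
  set.seed(42)
  for (i in 1:200) {
    codes <- sample(0:4, 6, replace = TRUE)
    k <- sample(6, 1)
    raised <- codes
    raised[k] <- min(raised[k] + sample(1:2, 1), 4)
    expect_gte(combine_rule(raised), combine_rule(codes))
  }
})

test_that("scope tables partition the distribution area", {
  spec <- grid_spec(10, 10, cell_size = 1, origin_lon = 0, origin_lat = 10)
  dist <- matrix(TRUE, 10, 10)
  uniform_high <- class_layer(spec, matrix(3L, 10, 10))
  half <- class_layer(spec, matrix(rep(c(3L, 0L), each = 50), 10, 10))
  combined <- class_layer(spec, matrix(sample(0:4, 100, replace = TRUE,
                                              prob = c(.1, .2, .3, .3, .1)),
                                       10, 10))
  tab <- scope_table(list(oe = uniform_high, half = half), combined, dist)
  expect_equal(unname(tab$severe["oe"]), 100)
  expect_equal(unname(tab$severe["half"]), 50)
  expect_equal(sum(tab$combined[threat_levels()]), 100, tolerance = 0.1)
  expect_equal(unname(tab$combined["severe"]),
               unname(tab$combined["High"] + tab$combined["Very high"]))
  expect_error(scope_table(list(oe = uniform_high), combined,
                           matrix(FALSE, 10, 10)), "empty")
})

test_that("hotspot and richness maps count species consistently", {
  spec <- grid_spec(4, 4, cell_size = 1, origin_lon = 0, origin_lat = 4)
  m1 <- matrix(FALSE, 4, 4); m1[1:2, ] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[3:4, ] <- TRUE   # disjoint ranges
  c1 <- class_layer(spec, matrix(3L, 4, 4), m1)
  c2 <- class_layer(spec, matrix(2L, 4, 4), m2)  # not severe
  hs <- hotspot_map(list(c1, c2))
  expect_equal(sum(hs$values), sum(m1))
  expect_equal(max(hs$values), 1)

  p1 <- grid_layer(spec, m1 * 1)
  p2 <- grid_layer(spec, m2 * 1)
  rich <- richness_map(list(p1, p2))
  expect_equal(max(rich$values), 1)              # disjoint: at most 1
  expect_equal(richness_map(list(p1))$values, m1 * 1)
  # richness bounds the hotspot count everywhere
  expect_true(all(rich$values >= hs$values))
  # all species severe in one cell counts them all
  both <- hotspot_map(list(c1, class_layer(spec, matrix(4L, 4, 4), m1)))
  expect_equal(max(both$values), 2)
})
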