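test_that("tropical livestock units use the standard conversion factors", {
  one_cow <- tlu(small_layer(matrix(1, 1, 1)), small_layer(matrix(0, 1, 1)),
                 small_layer(matrix(0, 1, 1)))
  expect_equal(one_cow$values[1, 1], 0.7)
  zero <- tlu(small_layer(matrix(0, 1, 1)), small_layer(matrix(0, 1, 1)),
              small_layer(matrix(0, 1, 1)))
  expect_equal(zero$values[1, 1], 0)
  mixed <- tlu(small_layer(matrix(10, 1, 1)), small_layer(matrix(5, 1, 1)),
               small_layer(matrix(5, 1, 1)))
  expect_equal(mixed$values[1, 1], 8)
  expect_error(tlu(small_layer(matrix(-1, 1, 1)),
                   small_layer(matrix(0, 1, 1)),
                   small_layer(matrix(0, 1, 1))), "negative")
})

test_that("overexploitation intensity normalizes the footprint", {
  fp <- small_layer(matrix(seq(0, 100, length.out = 12), 3, 4))
  out <- overexploitation_intensity(fp)
  expect_equal(min(out$values), 0)
  expect_equal(max(out$values), 1)
  expect_equal(which.max(out$values), which.max(fp$values))
  expect_equal(attr(out, "threat"), "overexploitation")
  expect_warning(flat <- overexploitation_intensity(
    small_layer(matrix(50, 2, 2))), "constant")
  expect_true(all(flat$values == 0))
})

test_that("overgrazing intensity is sqrt then min-max", {
  tl <- small_layer(matrix(c(0, 25, 100, 0), 2, 2))
  out <- overgrazing_intensity(tl)
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 1], 0.5)   # sqrt(25)/sqrt(100)
  expect_equal(out$values[1, 2], 1)
})

test_that("fire frequency filters, weights and normalizes per km2 and year", {
  spec <- grid_spec(2, 2, cell_size = 1, origin_lon = 0, origin_lat = 2)
  mk <- function(lon, lat, date, conf)
    data.frame(lon = lon, lat = lat, date = as.Date(date),
               confidence = conf)
  # confidence boundary: exactly 30 excluded, just above included
  ev <- mk(c(0.5, 0.5), c(1.5, 1.5), c("2008-12-01", "2008-12-02"),
           c(30, 30.0001))
  f <- fire_frequency(ev, spec, years = c(2007, 2012), area = "nominal")
  expect_equal(f$values[1, 1], 1 / (6 * 20.25))
  # late fires (Jan-Mar) weigh double relative to early (Nov-Dec)
  late <- fire_frequency(mk(0.5, 1.5, "2009-02-10", 80), spec,
                         area = "nominal")
  early <- fire_frequency(mk(0.5, 1.5, "2009-12-10", 80), spec,
                          area = "nominal")
  expect_equal(late$values[1, 1], 2 * early$values[1, 1])
  # one early event over 6 years in a nominal 20.25 km2 cell
  expect_equal(early$values[1, 1], 1 / (6 * 20.25))
  # events outside the year window dropped with a message
  expect_message(
    out <- fire_frequency(mk(0.5, 1.5, "2000-01-01", 80), spec,
                          area = "nominal"),
    "dropped 1")
  expect_true(all(out$values == 0))
  # additive over disjoint event sets
  e1 <- mk(0.5, 1.5, "2009-02-10", 80)
  e2 <- mk(1.5, 0.5, "2010-12-01", 80)
  both <- fire_frequency(rbind(e1, e2), spec, area = "nominal")
  expect_equal(both$values,
               fire_frequency(e1, spec, area = "nominal")$values +
                 fire_frequency(e2, spec, area = "nominal")$values)
  # geodesic mode scales with the cosine of the row latitude
  g <- fire_frequency(mk(0.5, 1.5, "2009-12-10", 80), spec)
  expect_equal(g$values[1, 1],
               1 / (6 * pixel_area_km2(spec, cell_center_lat(spec)[1])))
})

test_that("fire intensity shares the sqrt + min-max contract", {
  f0 <- 0.02
  freq <- small_layer(matrix(c(0, f0, 4 * f0, 0), 2, 2))
  out <- fire_intensity(freq)
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 1], 0.5)
  expect_equal(out$values[1, 2], 1)
})

test_that("cotton intensity splits province production equally and is capped", {
  spec <- grid_spec(2, 3, cell_size = 1, origin_lon = 0, origin_lat = 2)
  prov <- grid_layer(spec, matrix(c(1, 1, 1, 2, 2, 2), 2, 3))
  cotton <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), 2, 3)
  stats <- data.frame(province = c(1, 2), production = c(600, 100))
  out <- cotton_intensity(stats, cotton, prov)
  alloc <- attr(out, "allocation")
  # province 1: 600 over 2 cells; province 2: 100 over 1 cell
  expect_equal(alloc[1, 1], 300)
  expect_equal(alloc[2, 1], 300)
  expect_equal(alloc[1, 3], 100)
  expect_equal(sum(alloc), sum(stats$production))
  expect_true(isTRUE(attr(out, "capped")))
  expect_true(all(out$values >= 0 & out$values <= 1))
  # zero production province contributes zero intensity
  stats0 <- data.frame(province = c(1, 2), production = c(600, 0))
  out0 <- cotton_intensity(stats0, cotton, prov)
  expect_equal(attr(out0, "allocation")[1, 3], 0)
  # cotton cell in a province without statistics errors
  expect_error(cotton_intensity(data.frame(province = 1, production = 600),
                                cotton, prov), "without production")
})

test_that("mining sites become single Very-high pixels", {
  spec <- grid_spec(3, 3, cell_size = 1, origin_lon = 0, origin_lat = 3)
  none <- mining_class(data.frame(lon = numeric(0), lat = numeric(0),
                                  status = character(0)), spec)
  expect_true(all(none$classes == 0))
  # three sites in one cell still rate Very high, not more
  pts <- data.frame(lon = c(0.5, 0.5, 0.5), lat = c(2.5, 2.5, 2.5),
                    status = c("active", "active", "prospect"))
  cl <- mining_class(pts, spec)
  expect_equal(cl$classes[1, 1], 4L)
  expect_equal(sum(cl$classes), 4L)
  expect_true(all(cl$classes %in% c(0L, 4L)))
  # inactive-only sites leave No threat
  inact <- mining_class(data.frame(lon = 0.5, lat = 2.5,
                                   status = "inactive"), spec)
  expect_true(all(inact$classes == 0))
})

test_that("climate classifier matches its ordered rules on anchors and in full", {
  # all 16 combinations, expected classes derived by hand from the ordered
  # rule list (absence under RCP 4.5 dominates; novelty degrades presence)
  tt <- expand.grid(p45 = c(FALSE, TRUE), p85 = c(FALSE, TRUE),
                    n45 = c(FALSE, TRUE), n85 = c(FALSE, TRUE))
  expected <- integer(nrow(tt))
  for (k in seq_len(nrow(tt))) {
    r <- tt[k, ]
    expected[k] <- if (!r$p45) 4L
    else if (r$p85 && r$n45 && r$n85) 3L
    else if (r$n45) 2L
    else if (!r$p85) 1L
    else 0L
  }
  got <- climate_class(flag_layer(matrix(tt$p45, 4)),
                       flag_layer(matrix(tt$p85, 4)),
                       flag_layer(matrix(tt$n45, 4)),
                       flag_layer(matrix(tt$n85, 4)))
  expect_equal(as.vector(got$classes), expected)
  expect_true(all(got$classes %in% 0:4))

  # printed anchor cases
  one <- function(p45, p85, n45, n85)
    climate_class(flag_layer(p45), flag_layer(p85), flag_layer(n45),
                  flag_layer(n85))$classes[1, 1]
  expect_equal(one(TRUE, TRUE, FALSE, FALSE), 0L)  # both present: no threat
  expect_equal(one(FALSE, TRUE, FALSE, FALSE), 4L) # 4.5 already unsuitable
  expect_equal(one(TRUE, TRUE, TRUE, TRUE), 3L)    # both present but novel
})
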