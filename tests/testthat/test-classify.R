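test_that("fixed-band classification honours the interval convention", {
  sp <- grid_spec(2, 4, west = 0, north = 1, cell_size = 0.25)
  m <- suitability_map(sp, matrix(c(0.05, 0.2, 0.45, 0.75,
                                    0.10, 0.30, 0.60, 1.00), 2, 4,
                                  byrow = TRUE))
  cm <- classify_suitability(m)
  expect_equal(cm$classes[1, ], c(0L, 1L, 2L, 3L))
  # boundary values belong to the upper class; 1.0 is top-closed
  expect_equal(cm$classes[2, ], c(1L, 2L, 3L, 3L))
  expect_error(classify_suitability(m, c(0.3, 0.1, 0.6)), "thresholds")
})

test_that("Jenks breaks match exhaustive enumeration on small inputs", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), 10)
  expect_length(jenks_breaks(1:5, 1), 0)
  expect_equal(jenks_breaks(c(0, 0, 0, 5, 5, 5, 9, 9, 9), 3), c(5, 9))
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
  set.seed(8)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 10), 2)
    if (length(unique(x)) < k) next
    oracle <- jenks_exhaustive(x, k)
    got <- jenks_breaks(x, k)
    # same optimal SSE (breaks may differ only between tied optima)
    bounds <- c(-Inf, got, Inf)
    cls <- findInterval(sort(x), got)
    sse <- sum(tapply(sort(x), cls, function(v) sum((v - mean(v))^2)))
    expect_equal(sse, oracle$sse, tolerance = 1e-9)
  }
})

test_that("classify on jenks breaks reproduces the optimal partition", {
  set.seed(9)
  vals <- c(rnorm(40, 0.2, 0.03), rnorm(40, 0.5, 0.03), rnorm(20, 0.8, 0.02))
  vals <- pmin(pmax(vals, 0.01), 0.99)
  br <- jenks_breaks(vals, 4)
  sp <- grid_spec(10, 10, west = 0, north = 5, cell_size = 1)
  m <- suitability_map(sp, matrix(vals, 10, 10))
  cm <- classify_suitability(m, br)
  # class of each value equals its position relative to the breaks
  expect_equal(as.vector(cm$classes), findInterval(vals, br))
})

test_that("spherical cell areas match closed-form geometry", {
  # 1 deg x 1 deg cell centered on the equator
  sp <- grid_spec(2, 2, west = 0, north = 1, cell_size = 1)
  a <- cell_areas(sp)
  expect_equal(a[1], 12363.6, tolerance = 0.5)
  expect_equal(a[1], a[2])  # symmetric about the equator
  # same cell at 60N: about half the equatorial value
  sp60 <- grid_spec(1, 1, west = 0, north = 60.5, cell_size = 1)
  expect_equal(cell_areas(sp60) / a[1], cos(60 * pi / 180), tolerance = 0.01)
  # whole-earth total
  spw <- grid_spec(180, 360, west = -180, north = 90, cell_size = 1)
  total <- sum(cell_areas(spw)) * 360  # per-row cell area times columns
  expect_equal(total, 4 * pi * 6371.0088^2, tolerance = 4 * pi * 6371.0088^2 * 0.001)
})

test_that("area tables sum to the landscape with correct class accounting", {
  sp <- grid_spec(2, 2, west = 0, north = 1, cell_size = 1)
  m <- suitability_map(sp, matrix(c(0.75, 0.2, 0.2, 0.05), 2, 2))
  cm <- classify_suitability(m)
  at <- area_table(cm)
  aw <- cell_areas(sp)
  expect_equal(at$area_1e4_km2[at$class == "high"], aw[1] / 1e4)
  expect_equal(at$area_1e4_km2[at$class == "low"], (aw[2] + aw[1]) / 1e4)
  expect_equal(at$area_1e4_km2[at$class == "moderate"], 0)
  expect_equal(sum(at$area_1e4_km2[1:4]), sum(aw[c(1, 1, 2, 2)]) / 1e4,
               tolerance = 1e-9)
  expect_equal(sum(at$percent[1:4]), 100, tolerance = 1e-6)
  expect_equal(at$area_1e4_km2[at$class == "total_suitable"],
               sum(at$area_1e4_km2[2:4]))
})

test_that("change maps partition the landscape into the four transitions", {
  sp <- grid_spec(2, 2, west = 0, north = 1, cell_size = 1)
  cur <- suitability_map(sp, matrix(c(0.5, 0.5, 0.1, 0.1), 2, 2))
  fut <- suitability_map(sp, matrix(c(0.5, 0.1, 0.5, 0.1), 2, 2))
  cm <- change_map(cur, fut, threshold = 0.30)
  # cells: (1,1) retained, (2,1) lost, (1,2) new, (2,2) unsuitable
  expect_equal(cm$classes[1, 1], 3L)
  expect_equal(cm$classes[2, 1], 2L)
  expect_equal(cm$classes[1, 2], 1L)
  expect_equal(cm$classes[2, 2], 0L)
  aw <- cell_areas(sp)
  expect_equal(cm$areas$area_1e4_km2,
               c(aw[2], aw[1], aw[2], aw[1]) / 1e4, tolerance = 1e-9)
  # identical maps: no change classes
  cm0 <- change_map(cur, cur)
  expect_equal(sum(cm0$classes == 1L, na.rm = TRUE), 0)
  expect_equal(sum(cm0$classes == 2L, na.rm = TRUE), 0)
  # a current value of exactly 0.30 counts as suitable (>= threshold)
  cur2 <- suitability_map(sp, matrix(0.30, 2, 2))
  cm2 <- change_map(cur2, cur2)
  expect_true(all(cm2$classes == 3L))
})

test_that("change classes conserve cells and shifts never create losses", {
  st <- make_landscape(n = 25, seed = 161, mask = "sea_border")
  occ <- make_species_data(st, n_pres = 60, seed = 162)
  m <- maxent(occ, st, fc = "L", seed = 163)
  cur <- predict(m, st)
  fut <- predict(m, perturb_scenario(st, scenario_perturbation(
    shift = c(temp = 0.8))))
  cm <- change_map(cur, fut)
  n_classified <- sum(!is.na(cm$classes))
  expect_equal(n_classified, sum(st$mask))
  counts <- table(factor(cm$classes[!is.na(cm$classes)], levels = 0:3))
  expect_equal(sum(counts), sum(st$mask))
  # uniform upward shift of the map itself cannot create lost cells
  up <- suitability_map(cur$spec, pmin(cur$mat + 0.1, 1), cur$mask)
  cmu <- change_map(cur, up)
  expect_equal(sum(cmu$classes == 2L, na.rm = TRUE), 0)
})
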