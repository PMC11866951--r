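test_that("constant environment yields the uniform model", {
  st <- env_stack(grid_spec(5, 5, west = 0, north = 3, cell_size = 1),
                  list(a = matrix(3, 5, 5), b = matrix(7, 5, 5)))
  cc <- cell_centers(st$spec)
  occ <- occurrence_set(data.frame(lon = cc$lon[1:6], lat = cc$lat[1:6]))
  expect_warning(m <- maxent(occ, st, fc = "LQ", seed = 1), "constant")
  expect_length(coef(m), 0)
  pr <- predict(m, st, type = "raw")
  expect_equal(unique(as.vector(pr$mat)), 1 / m$meta$n_background,
               tolerance = 1e-12)
  pc <- predict(m, st, type = "cloglog")
  expect_equal(length(unique(as.vector(pc$mat))), 1)
})

test_that("raw output sums to one over background and cloglog is in (0,1)", {
  st <- make_landscape(n = 25, seed = 61)
  occ <- make_species_data(st, n_pres = 80, seed = 62)
  for (fc in c("L", "LQH")) {
    m <- maxent(occ, st, fc = fc, n_knots = 8, seed = 63)
    bg_raw <- extract_cells(st, m$background$row, m$background$col,
                            m$feature_spec$variables)
    raw_bg <- exp(nichecast:::maxent_eta(m, bg_raw) - m$logZ)
    expect_equal(sum(raw_bg), 1, tolerance = 1e-8)
    pc <- predict(m, st, type = "cloglog")
    v <- pc$mat[pc$mask]
    # open interval up to double underflow of the raw output
    expect_true(all(v >= 0 & v < 1))
    expect_gt(max(v), 0)
  }
})

test_that("solver trace decreases monotonically and satisfies the KKT box", {
  st <- make_landscape(n = 25, seed = 64)
  occ <- make_species_data(st, n_pres = 100, seed = 65)
  m <- maxent(occ, st, fc = "LQH", n_knots = 8, rm = 1, seed = 66)
  expect_true(all(diff(m$trace) <= 1e-12))
  # KKT: |E_q f_j - mean_presence f_j| <= pen_j for all features (with
  # equality binding only at active ones)
  bg_raw <- extract_cells(st, m$background$row, m$background$col,
                          m$feature_spec$variables)
  Fb <- expand_features(m$feature_spec, bg_raw)
  Fb <- Fb[, names(m$coefficients), drop = FALSE]
  q <- exp(as.numeric(Fb %*% m$coefficients) - m$logZ)
  gap <- abs(as.numeric(crossprod(Fb, q)) - m$presence_feature_means)
  expect_true(all(gap <= m$penalties + 1e-6))
})

test_that("fc=L recovery: signs match the synthetic truth, held-out AUC high", {
  sp <- grid_spec(60, 60, west = 100, north = 26, cell_size = 0.1)
  st <- gen_env_stack(sp, c("temp", "temp_range", "precip_cv", "soil_ph"),
                      autocorr_range = 3, seed = 71)
  truth <- synthetic_truth(c(temp = 2, precip_cv = -1))
  occ <- sample_presences(st, truth, 500, seed = 72)
  m <- maxent(occ, st, fc = "L", rm = 1, n_background = 1000, seed = 73)
  co <- coef(m, all = TRUE)
  expect_gt(co["L:temp"], 0)
  expect_lt(co["L:precip_cv"], 0)
  held <- sample_presences(st, truth, 500, seed = 74)
  pm <- predict(m, st, type = "raw")
  hcells <- cell_index(sp, held$lon, held$lat)
  bcells <- m$background
  expect_gt(auc(pm$mat[cbind(hcells$row, hcells$col)],
                pm$mat[cbind(bcells$row, bcells$col)]), 0.85)
})

test_that("active feature count is non-increasing along the RM path", {
  st <- make_landscape(n = 25, seed = 81)
  occ <- make_species_data(st, n_pres = 60, seed = 82)
  bg <- sample_background(st, 500, seed = 83)
  k <- vapply(seq(0.5, 4, by = 0.5), function(rm) {
    m <- maxent(occ, st, fc = "LQH", n_knots = 6, rm = rm, background = bg)
    sum(coef(m) != 0)
  }, numeric(1))
  expect_true(all(diff(k) <= 0))
})

test_that("fc=L coefficients match a generic convex optimizer", {
  # tiny problem: 2 variables, exact objective minimized by Nelder-Mead
  st <- make_landscape(n = 10, seed = 91, layers = c("a", "b"))
  occ <- make_species_data(st, n_pres = 40, seed = 92, coef = c(a = 1.5))
  bg <- sample_background(st, 100, seed = 93)
  m <- maxent(occ, st, fc = "L", rm = 1, background = bg)
  # independent objective evaluation
  pidx <- occ_cells(occ, st)
  bidx <- occ_cells(bg, st)
  fs <- m$feature_spec
  Fp <- expand_features(fs, extract_cells(st, pidx$row, pidx$col, fs$variables))
  Fb <- expand_features(fs, extract_cells(st, bidx$row, bidx$col, fs$variables))
  pen <- m$penalties
  obj <- function(l) {
    -sum(l * colMeans(Fp)) + log(sum(exp(Fb %*% l))) + sum(pen * abs(l))
  }
  nm <- optim(c(0, 0), obj, control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(coef(m, all = TRUE)), nm$par, tolerance = 1e-3)
  expect_lte(obj(coef(m, all = TRUE)), nm$value + 1e-6)
})

test_that("cloglog output is monotone in a single positive-coefficient variable", {
  st <- make_landscape(n = 20, seed = 95, layers = "temp")
  occ <- make_species_data(st, n_pres = 50, seed = 96, coef = c(temp = 2))
  m <- maxent(occ, st, fc = "L", seed = 97)
  rc <- response_curve(m, "temp", n_points = 50)
  expect_gt(coef(m, all = TRUE)["L:temp"], 0)
  expect_true(all(diff(rc$suitability) > 0))
})

test_that("response curves reflect coefficient structure", {
  st <- make_landscape(n = 25, seed = 98)
  occ <- make_species_data(st, n_pres = 80, seed = 99)
  m <- maxent(occ, st, fc = "L", seed = 100)
  co <- coef(m, all = TRUE)
  # a variable with zero coefficient has a flat curve
  zv <- sub("^L:", "", names(co)[co == 0])
  if (length(zv)) {
    rc0 <- response_curve(m, zv[1], n_points = 20)
    expect_equal(diff(range(rc0$suitability)), 0, tolerance = 1e-12)
  }
  # an LQ model with negative quadratic coefficient is unimodal
  stq <- make_landscape(n = 30, seed = 101, layers = "temp")
  # species peaked at intermediate temperature: density ~ exp(-(temp)^2)
  sv <- stack_values(stq)
  dens <- exp(-1.5 * sv$values[, "temp"]^2)
  idx <- local({
    set.seed(102)
    sample.int(length(dens), 200, replace = TRUE, prob = dens)
  })
  cc <- cell_centers(stq$spec, sv$rows[idx], sv$cols[idx])
  occq <- clean_occurrences(occ_at(cc$lon, cc$lat), stq)
  mq <- maxent(occq, stq, fc = "LQ", seed = 103)
  expect_lt(coef(mq, all = TRUE)["Q:temp"], 0)
  rcq <- response_curve(mq, "temp", n_points = 101)
  s <- rcq$suitability
  peak <- which.max(s)
  expect_gt(peak, 1)
  expect_lt(peak, length(s))
  expect_true(all(diff(s[1:peak]) >= -1e-12))
  expect_true(all(diff(s[peak:length(s)]) <= 1e-12))
})

test_that("SRE envelope reproduces the presence bounding box at quantile 0", {
  st <- make_landscape(n = 20, seed = 111, layers = c("a", "b"))
  occ <- make_species_data(st, n_pres = 40, seed = 112, coef = c(a = 1))
  env <- sre_envelope(occ, st, quantile = 0)
  idx <- occ_cells(occ, st)
  # every presence cell is suitable
  expect_true(all(env$mat[cbind(idx$row, idx$col)] == 1))
  # a cell outside any one variable's range is unsuitable
  pres <- extract_cells(st, idx$row, idx$col)
  sv <- stack_values(st)
  outside <- sv$values[, "a"] > max(pres[, "a"]) |
    sv$values[, "a"] < min(pres[, "a"]) |
    sv$values[, "b"] > max(pres[, "b"]) | sv$values[, "b"] < min(pres[, "b"])
  expect_true(all(env$mat[cbind(sv$rows, sv$cols)][outside] == 0))
  expect_true(all(env$mat[cbind(sv$rows, sv$cols)][!outside] == 1))
  expect_error(sre_envelope(occ, st, quantile = 0.6), "quantile")
})

test_that("model serialization round-trips to identical predictions", {
  st <- make_landscape(n = 20, seed = 121)
  occ <- make_species_data(st, n_pres = 60, seed = 122)
  m <- maxent(occ, st, fc = "LQH", n_knots = 5, seed = 123)
  f <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, f)
  m2 <- read_maxent(f)
  p1 <- predict(m, st, type = "cloglog")
  p2 <- predict(m2, st, type = "cloglog")
  expect_equal(p1$mat, p2$mat, tolerance = 1e-12)
  expect_equal(m2$entropy, m$entropy, tolerance = 1e-12)
})
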