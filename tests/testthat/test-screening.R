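test_that("Spearman matrix matches the rank formula and handles monotone maps", {
  x <- c(0.3, 1.1, 2.0, 2.7, 3.5, 4.2, 5.0, 5.9, 7.1, 8.0)
  st <- env_stack(grid_spec(1, 10, west = 0, north = 1, cell_size = 1),
                  list(x = matrix(x, 1), ex = matrix(exp(x), 1),
                       negx = matrix(-x, 1)))
  cc <- cell_centers(st$spec)
  occ <- occurrence_set(data.frame(lon = cc$lon, lat = cc$lat))
  rho <- spearman_matrix(st, occ)
  expect_equal(rho["x", "ex"], 1)     # monotone transform
  expect_equal(rho["x", "negx"], -1)
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, 3))

  # 5-point example against the rank formula 1 - 6*sum(d^2)/(n(n^2-1)):
  # x = 1..5, y = (2,1,4,3,5) -> d = (-1,1,-1,1,0), sum d^2 = 4, rho = 0.8
  st2 <- env_stack(grid_spec(1, 5, west = 0, north = 1, cell_size = 1),
                   list(a = matrix(1:5, 1), b = matrix(c(2, 1, 4, 3, 5), 1)))
  cc2 <- cell_centers(st2$spec)
  occ2 <- occurrence_set(data.frame(lon = cc2$lon, lat = cc2$lat))
  rho2 <- spearman_matrix(st2, occ2)
  expect_equal(rho2["a", "b"], 1 - 6 * 4 / (5 * 24))

  # constant variable flagged, treated as 0
  st3 <- env_stack(grid_spec(1, 5, west = 0, north = 1, cell_size = 1),
                   list(a = matrix(1:5, 1), k = matrix(rep(2, 5), 1)))
  expect_warning(rho3 <- spearman_matrix(st3, occ2), "constant")
  expect_equal(rho3["a", "k"], 0)
  expect_equal(rho3["k", "k"], 1)
})

test_that("greedy selection follows importance and the threshold rule", {
  rho <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("v1", "v2"),
                                                      c("v1", "v2")))
  expect_equal(select_uncorrelated(rho, c(v1 = 2, v2 = 1)), "v1")
  expect_equal(select_uncorrelated(rho, c(v1 = 1, v2 = 2)), "v2")
  # all below threshold -> all retained
  rho2 <- diag(3); dimnames(rho2) <- list(letters[1:3], letters[1:3])
  expect_setequal(select_uncorrelated(rho2, c(a = 3, b = 2, c = 1)),
                  c("a", "b", "c"))
  # documented trace: rho12 = rho13 = 0.8, rho23 = 0.1, imp v1 > v2 > v3
  rho3 <- matrix(c(1, .8, .8, .8, 1, .1, .8, .1, 1), 3,
                 dimnames = list(paste0("v", 1:3), paste0("v", 1:3)))
  expect_equal(select_uncorrelated(rho3, c(v1 = 3, v2 = 2, v3 = 1)), "v1")
  # ... and dropping v1's conflicts by lowering its importance keeps v2+v3
  expect_setequal(select_uncorrelated(rho3, c(v1 = 1, v2 = 3, v3 = 2)),
                  c("v2", "v3"))
})

test_that("selection is invariant to matrix ordering and monotone in threshold", {
  set.seed(31)
  n <- 6
  A <- matrix(rnorm(n * n), n)
  rho <- cov2cor(crossprod(A) + diag(n) * 0.5)
  vars <- paste0("v", 1:n)
  dimnames(rho) <- list(vars, vars)
  imp <- setNames(rnorm(n), vars)
  sel <- select_uncorrelated(rho, imp, 0.5)
  perm <- sample(n)
  sel_perm <- select_uncorrelated(rho[perm, perm], imp, 0.5)
  expect_setequal(sel, sel_perm)
  # limit cases of the threshold: everything passes just above the largest
  # off-diagonal correlation, and only the single most important variable
  # survives a near-zero threshold
  off <- max(abs(rho[upper.tri(rho)]))
  expect_setequal(select_uncorrelated(rho, imp, off + 1e-9), vars)
  expect_equal(select_uncorrelated(rho, imp, 1e-12), vars[which.max(imp)])
  # no pair in any selected set violates its own threshold
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    s <- select_uncorrelated(rho, imp, thr)
    if (length(s) > 1) {
      expect_lt(max(abs(rho[s, s][upper.tri(diag(length(s)))])), thr)
    }
  }
})

test_that("VIF matches closed forms and flags near-collinearity", {
  # orthogonal regressors -> VIF exactly 1
  n <- 16
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  st <- env_stack(grid_spec(1, n, west = 0, north = 1, cell_size = 1),
                  list(a = matrix(x1, 1), b = matrix(x2, 1)))
  cc <- cell_centers(st$spec)
  occ <- occurrence_set(data.frame(lon = cc$lon, lat = cc$lat))
  v <- vif_table(st, occ, c("a", "b"))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-9)

  # bivariate closed form: VIF = 1 / (1 - r^2)
  set.seed(77)
  z1 <- rnorm(40)
  z2 <- 0.6 * z1 + rnorm(40)
  st2 <- env_stack(grid_spec(1, 40, west = 0, north = 1, cell_size = 1),
                   list(a = matrix(z1, 1), b = matrix(z2, 1)))
  cc2 <- cell_centers(st2$spec)
  occ2 <- occurrence_set(data.frame(lon = cc2$lon, lat = cc2$lat))
  v2 <- vif_table(st2, occ2, c("a", "b"))
  r <- cor(z1, z2)
  expect_equal(v2$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-9)
  expect_true(all(v2$vif >= 1))

  # x2 = x1 + small noise -> VIF > 10, flagged
  z3 <- z1 + rnorm(40, sd = 0.01 * sd(z1))
  st3 <- env_stack(grid_spec(1, 40, west = 0, north = 1, cell_size = 1),
                   list(a = matrix(z1, 1), b = matrix(z3, 1)))
  v3 <- vif_table(st3, occ2, c("a", "b"))
  expect_gt(min(v3$vif), 10)
  expect_true(all(v3$flagged))
})

test_that("screen_variables assembles a coherent report", {
  st <- make_landscape(n = 25, seed = 41)
  occ <- make_species_data(st, n_pres = 60, seed = 42)
  rep <- screen_variables(st, occ)
  expect_s3_class(rep, "screening_report")
  expect_true(all(abs(rep$rho[rep$selected, rep$selected][
    upper.tri(diag(length(rep$selected)))]) < 0.7))
  expect_true(all(rep$importance >= 0.5 & rep$importance <= 1))
  if (!is.null(rep$vif)) expect_true(all(rep$vif$vif >= 1))
})
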