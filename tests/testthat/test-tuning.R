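test_that("partitioning gives the documented split sizes and reproducibility", {
  occ <- occ_at(runif(73, 100, 110), runif(73, 18, 27))
  sp <- partition_occurrences(occ, seed = 1)
  expect_length(sp, 10)
  expect_true(all(vapply(sp, function(s) length(s$train), numeric(1)) == 55))
  expect_true(all(vapply(sp, function(s) length(s$test), numeric(1)) == 18))
  for (s in sp) expect_length(intersect(s$train, s$test), 0)
  sp2 <- partition_occurrences(occ, seed = 1)
  expect_identical(sp, sp2)
  expect_error(partition_occurrences(occ, train_frac = 1), "empty")
  expect_error(partition_occurrences(occ_at(1:5, 1:5)), "at least 8")
})

test_that("AUC matches exhaustive pair counting including ties", {
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.6, 0.1)), 1)
  expect_equal(auc(c(0.8, 0.4), c(0.8, 0.3, 0.1)), 4.5 / 6)
  x <- c(0.2, 0.5, 0.9)
  expect_equal(auc(x, x), 0.5)
  # randomized oracle check with heavy ties
  set.seed(5)
  for (i in 1:20) {
    p <- sample(seq(0, 1, 0.1), sample(3:40, 1), replace = TRUE)
    b <- sample(seq(0, 1, 0.1), sample(3:40, 1), replace = TRUE)
    expect_equal(auc(p, b), auc_pairs(p, b))
  }
  # invariance under strictly monotone transforms
  set.seed(6)
  p <- runif(30); b <- runif(50)
  expect_equal(auc(exp(3 * p), exp(3 * b)), auc(p, b))
  expect_equal(auc(qlogis(p), qlogis(b)), auc(p, b))
})

test_that("10% omission uses the ceiling-rank threshold with strict counting", {
  train <- seq(0.1, 1.0, by = 0.1)
  expect_equal(omission10(train, 0.05), 1)     # below threshold 0.2
  expect_equal(omission10(train, c(0.5, 0.9)), 0)
  expect_equal(omission10(train, 0.2), 0)      # equal to threshold: kept
  expect_equal(omission10(train, c(0.05, 0.5)), 0.5)
  # shifting test scores downward never decreases omission
  set.seed(7)
  tr <- runif(40); te <- runif(25)
  o <- vapply(seq(0, 0.5, 0.05), function(d) omission10(tr, te - d),
              numeric(1))
  expect_true(all(diff(o) >= 0))
  expect_true(all(o >= 0 & o <= 1))
  expect_error(omission10(runif(5), 0.1), "at least 10")
})

test_that("AICc follows the corrected-AIC formula and its singularity", {
  # k=2, lnL=-10, n=10: AICc = 4 + 20 + 12/7
  eta_land <- rep(0, 100)                       # logZ = log(100)
  eta_occ <- rep(log(100) - 1, 10)              # lnL = -10
  expect_equal(nichecast:::aicc_from_eta(eta_occ, eta_land, 2),
               24 + 12 / 7)
  # k >= n-1 -> undefined
  expect_true(is.na(nichecast:::aicc_from_eta(eta_occ, eta_land, 9)))
  # k = 0 -> pure likelihood term
  expect_equal(nichecast:::aicc_from_eta(eta_occ, eta_land, 0), 20)
  # end-to-end: AICc of a fitted model is finite and k counts nonzero only
  st <- make_landscape(n = 20, seed = 131)
  occ <- make_species_data(st, n_pres = 60, seed = 132)
  m <- maxent(occ, st, fc = "L", seed = 133)
  a <- aicc(m, occ, st)
  expect_true(is.finite(a))
})

test_that("candidate selection minimizes AICc with the stated tie-breaks", {
  res <- data.frame(
    rm = c(1, 0.5, 1, 2), fc = c("LQ", "LQH", "L", "L"),
    aicc = c(100, 100, 100, 101)
  )
  # ties at 100: smaller RM wins -> rm=0.5 fc=LQH
  expect_equal(nichecast:::select_candidate(res), 2L)
  res2 <- data.frame(rm = c(1, 1), fc = c("LQH", "L"), aicc = c(50, 50))
  # equal rm: shorter fc string wins
  expect_equal(nichecast:::select_candidate(res2), 2L)
  res3 <- data.frame(rm = 1, fc = c("L", "LQ"), aicc = c(NA, 7))
  expect_equal(nichecast:::select_candidate(res3), 2L)
  expect_error(nichecast:::select_candidate(
    data.frame(rm = 1, fc = "L", aicc = NA_real_)), "undefined")
})

test_that("a reduced tuning grid selects a candidate with delta AICc zero", {
  st <- make_landscape(n = 30, seed = 141)
  occ <- make_species_data(st, n_pres = 80, seed = 142)
  tn <- tune_enm(occ, st, rms = c(1, 2), fcs = c("L", "LQH"), n_knots = 5,
                 repeats = 3, n_background = 400, seed = 143)
  expect_equal(nrow(tn$results), 4)
  expect_equal(sum(tn$results$selected), 1)
  expect_equal(tn$results$delta_aicc[tn$results$selected], 0)
  expect_equal(min(tn$results$delta_aicc, na.rm = TRUE), 0)
  expect_true(all(tn$results$delta_aicc >= 0, na.rm = TRUE))
  expect_true(all(tn$results$auc_test_avg >= 0 & tn$results$auc_test_avg <= 1))
  expect_true(all(tn$results$or10_avg >= 0 & tn$results$or10_avg <= 1))
})

test_that("model selection prefers the true feature class on linear truth", {
  # synthetic truth linear in 2 layers: FC=L should beat LQH most of the time
  # (landscape and background sizes matter: candidate discrimination needs
  # enough background cells to pin down the likelihood)
  wins <- 0
  for (s in 1:10) {
    sp <- grid_spec(50, 50, west = 100, north = 26, cell_size = 0.1)
    st <- gen_env_stack(sp, c("a", "b"), autocorr_range = 3, seed = 150 + s)
    occ <- make_species_data(st, n_pres = 200, seed = 250 + s,
                             coef = c(a = 2, b = -1))
    tn <- tune_enm(occ, st, rms = 1, fcs = c("L", "LQH"), n_knots = 5,
                   repeats = 2, n_background = 1000, seed = 350 + s)
    if (tn$selected$fc == "L") wins <- wins + 1
  }
  expect_gte(wins, 8)
})
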