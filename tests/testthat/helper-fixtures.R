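# shared fixture builders; everything generated in code, nothing on disk

# small 4-layer landscape with a known species
make_landscape <- function(n = 30, seed = 101, layers = c("temp", "temp_range",
                                                          "precip_cv", "soil_ph"),
                           autocorr_range = 3, ...) {
  sp <- grid_spec(n, n, west = 105, north = 27, cell_size = 0.1)
  gen_env_stack(sp, layers, autocorr_range = autocorr_range, seed = seed, ...)
}

make_species_data <- function(stack, n_pres = 120, seed = 202,
                              coef = c(temp = 2, precip_cv = -1)) {
  truth <- synthetic_truth(coef)
  occ <- sample_presences(stack, truth, n_pres, seed = seed)
  clean_occurrences(occ, stack)
}

# an occurrence set at explicit coordinates
occ_at <- function(lon, lat) {
  occurrence_set(data.frame(lon = lon, lat = lat))
}

# stack built from explicit matrices on a unit-degree grid at the equator
stack_from <- function(...) {
  mats <- list(...)
  sp <- grid_spec(nrow(mats[[1]]), ncol(mats[[1]]),
                  west = 0, north = nrow(mats[[1]]) / 2, cell_size = 1)
  env_stack(sp, mats)
}

# brute-force AUC by exhaustive pair counting (independent oracle)
auc_pairs <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(p) * length(b))
}

# brute-force Jenks by enumerating all partitions of sorted values
jenks_exhaustive <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  best_breaks <- NULL
  # choose k-1 cut positions between indices
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + sse(x[(bounds[i] + 1):bounds[i + 1]])
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- x[cuts[, j] + 1]  # min value of each upper class
    }
  }
  list(sse = best, breaks = best_breaks)
}

# direct implementation of the piecewise similarity formula (independent of
# the vectorized package path): scalar, loop-based
mess_bruteforce <- function(ref_list, vals) {
  # vals: matrix points x variables; returns list(mess, mod)
  npt <- nrow(vals)
  nv <- length(ref_list)
  sim <- matrix(NA_real_, npt, nv)
  for (j in seq_len(nv)) {
    ref <- ref_list[[j]]
    mn <- min(ref); mx <- max(ref); nref <- length(ref)
    for (i in seq_len(npt)) {
      p <- vals[i, j]
      f <- 100 * sum(ref < p) / nref
      sim[i, j] <- if (f == 0) {
        100 * (p - mn) / (mx - mn)
      } else if (f <= 50) {
        2 * f
      } else if (f < 100) {
        2 * (100 - f)
      } else {
        100 * (mx - p) / (mx - mn)
      }
    }
  }
  mod <- apply(sim, 1, which.min)
  list(mess = apply(sim, 1, min), mod = mod, sim = sim)
}
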