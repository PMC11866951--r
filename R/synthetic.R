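#' Generate a synthetic environmental stack
#'
#' Builds spatially autocorrelated continuous layers by smoothing Gaussian
#' white noise with a separable Gaussian kernel, standardizing each layer to
#' zero mean and unit variance over valid cells, and (optionally) imposing a
#' target inter-layer correlation structure by whitening the fields and
#' re-mixing them through the Cholesky factor of the target matrix. With a
#' target given, the empirical correlation matrix of the output equals the
#' target exactly (up to numerical round-off), comfortably inside the +-0.1
#' band expected of grids of 50 x 50 cells and larger.
#'
#' @param spec A [grid_spec()].
#' @param layer_names Character vector of layer names (non-empty).
#' @param autocorr_range Gaussian kernel standard deviation in cells (>= 0;
#'   0 gives independent cell noise).
#' @param target_corr Optional symmetric positive-semidefinite correlation
#'   matrix (unit diagonal) of dimension `length(layer_names)`.
#' @param seed Integer seed; identical seeds give bitwise-identical stacks.
#' @param mask Optional logical mask, or `"sea_border"` for a one-cell border
#'   of missing cells to exercise mask handling.
#' @param lat_gradient Optional named numeric vector: a deterministic
#'   latitudinal trend (units per degree latitude, relative to the grid's
#'   central latitude) added to the named layers before the final
#'   standardization — e.g. `c(temp = -0.5)` makes temperature decrease
#'   northward, the way real temperature fields do. Applied after any
#'   correlation mixing, so it perturbs `target_corr` for those layers.
#' @return An [env_stack()].
#' @examples
#' sp <- grid_spec(40, 40, west = 105, north = 25, cell_size = 0.1)
#' st <- gen_env_stack(sp, c("temp", "prec"), autocorr_range = 3, seed = 1)
#' @export
gen_env_stack <- function(spec, layer_names, autocorr_range = 3,
                          target_corr = NULL, seed = NULL, mask = NULL,
                          lat_gradient = NULL) {
  if (length(layer_names) == 0L) stop("layer_names must be non-empty")
  if (autocorr_range < 0) stop("autocorr_range must be >= 0")
  k <- length(layer_names)
  if (!is.null(target_corr)) {
    target_corr <- as.matrix(target_corr)
    if (!isTRUE(all.equal(dim(target_corr), c(k, k))) ||
        max(abs(target_corr - t(target_corr))) > 1e-8 ||
        max(abs(diag(target_corr) - 1)) > 1e-8) {
      stop("target_corr must be a symmetric correlation matrix with unit diagonal")
    }
    ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("target_corr is not positive semi-definite")
  }
  if (identical(mask, "sea_border")) {
    mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
    mask[1, ] <- mask[spec$n_rows, ] <- FALSE
    mask[, 1] <- mask[, spec$n_cols] <- FALSE
  }
  fields <- with_seed(seed, {
    lapply(seq_len(k), function(i) {
      z <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                  spec$n_rows, spec$n_cols)
      smooth_field(z, autocorr_range)
    })
  })
  std <- function(m, msk) {
    v <- m[msk]
    (m - mean(v)) / stats::sd(v)
  }
  msk <- if (is.null(mask)) matrix(TRUE, spec$n_rows, spec$n_cols) else mask
  fields <- lapply(fields, std, msk = msk)
  if (!is.null(target_corr) && k > 1L) {
    X <- vapply(fields, function(m) m[msk], numeric(sum(msk)))
    # whiten the empirical correlation, then color with the target
    Re <- stats::cor(X)
    W <- backsolve(chol(Re), diag(k))
    L <- chol_psd(target_corr)
    Y <- X %*% W %*% t(L)
    Y <- scale(Y)
    for (i in seq_len(k)) {
      m <- fields[[i]]
      m[msk] <- Y[, i]
      m[!msk] <- NA_real_
      fields[[i]] <- m
    }
  } else {
    fields <- lapply(fields, function(m) { m[!msk] <- NA_real_; m })
  }
  names(fields) <- layer_names
  if (!is.null(lat_gradient)) {
    unknown <- setdiff(names(lat_gradient), layer_names)
    if (length(unknown)) stop("lat_gradient names unknown layer(s): ",
                              paste(unknown, collapse = ", "))
    lat <- spec$north - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
    lat_dev <- matrix(lat - mean(lat), spec$n_rows, spec$n_cols)
    for (v in names(lat_gradient)) {
      m <- fields[[v]] + lat_gradient[[v]] * lat_dev
      fields[[v]] <- std(m, msk)
      fields[[v]][!msk] <- NA_real_
    }
  }
  env_stack(spec, fields, mask = msk)
}

# Cholesky-type factor tolerant of semi-definite targets
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), length(v)) %*% t(e$vectors)
}

# separable Gaussian smoothing; sigma in cells, reflective padding
smooth_field <- function(z, sigma) {
  if (sigma <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  pad_reflect <- function(x, h) {
    n <- length(x)
    c(x[pmin(h, n - 1):1 + 1], x, x[n - 1:pmin(h, n - 1)])
  }
  conv1 <- function(x) {
    n <- length(x)
    xp <- pad_reflect(x, half)
    out <- stats::filter(xp, kern, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  z <- apply(z, 2, conv1)
  t(apply(z, 1, conv1))
}

#' Define a synthetic species truth
#'
#' The species' log-density over the landscape is linear in a subset of
#' layers: `log density(cell) = intercept + sum(coef[v] * layer_v(cell))` —
#' exactly the Gibbs family the maxent model fits, so parameter recovery is
#' well-posed.
#'
#' @param coefficients Named numeric vector of log-density slopes; names must
#'   be layer names.
#' @param intercept Scalar intercept (affects nothing after normalization;
#'   kept for completeness).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(coefficients, intercept = 0) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    stop("coefficients must be a named vector")
  }
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "synthetic_truth")
}

#' Sample presence records from a synthetic truth
#'
#' Cells are drawn (with replacement) with probability proportional to
#' `exp(intercept + sum(coef * layer))` over valid cells; records are placed
#' at cell centers, so downstream grid snapping is exact.
#'
#' @param stack An [env_stack()].
#' @param truth A [synthetic_truth()]; every coefficient must name a layer.
#' @param n Number of presence records (>= 1).
#' @param seed Integer seed.
#' @param species Species label written into the records.
#' @return An [occurrence_set()] with `source = "synthetic"`.
#' @export
sample_presences <- function(stack, truth, n, seed = NULL,
                             species = "synthetic_sp") {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1)
  miss <- setdiff(names(truth$coefficients), names(stack$layers))
  if (length(miss)) stop("truth names unknown layer(s): ",
                         paste(miss, collapse = ", "))
  sv <- stack_values(stack, names(truth$coefficients))
  if (nrow(sv$values) == 0L) stop("stack has no valid cells")
  eta <- truth$intercept + as.numeric(sv$values %*% truth$coefficients)
  p <- exp(eta - max(eta))
  idx <- with_seed(seed, sample.int(length(p), n, replace = TRUE, prob = p))
  cc <- cell_centers(stack$spec, sv$rows[idx], sv$cols[idx])
  occurrence_set(data.frame(
    id = seq_len(n), species = species,
    lon = cc$lon, lat = cc$lat, source = "synthetic"
  ), spec = stack$spec)
}

#' Describe a scenario perturbation
#'
#' Emulates a future-climate contrast: per-layer additive mean shifts plus
#' per-layer standard-deviation multipliers. Layers not named are untouched.
#'
#' @param shift Named numeric vector of additive shifts (layer units).
#' @param sd_mult Named numeric vector of standard-deviation multipliers
#'   (>= 0, dimensionless).
#' @return An object of class `scenario_perturbation`.
#' @export
scenario_perturbation <- function(shift = numeric(0), sd_mult = numeric(0)) {
  if (length(shift) && is.null(names(shift))) stop("shift must be named")
  if (length(sd_mult)) {
    if (is.null(names(sd_mult))) stop("sd_mult must be named")
    if (any(sd_mult < 0)) stop("sd_mult must be >= 0")
  }
  structure(list(shift = shift, sd_mult = sd_mult),
            class = "scenario_perturbation")
}

#' Apply a scenario perturbation to a stack
#'
#' Each named layer `x` becomes `(x - mean(x)) * sd_mult + mean(x) + shift`,
#' so the layer mean changes by exactly `shift` and the standard deviation by
#' exactly the factor `sd_mult` (means over valid cells). The mask is
#' preserved; unnamed layers are returned bit-for-bit unchanged.
#'
#' @param stack An [env_stack()].
#' @param pert A [scenario_perturbation()]; must name a subset of layers.
#' @return A perturbed [env_stack()].
#' @export
perturb_scenario <- function(stack, pert) {
  stopifnot(inherits(pert, "scenario_perturbation"))
  touched <- union(names(pert$shift), names(pert$sd_mult))
  unknown <- setdiff(touched, names(stack$layers))
  if (length(unknown)) stop("perturbation names unknown layer(s): ",
                            paste(unknown, collapse = ", "))
  layers <- stack$layers
  for (v in touched) {
    m <- layers[[v]]
    vals <- m[stack$mask]
    mu <- mean(vals)
    s <- if (!is.null(pert$sd_mult[v]) && !is.na(pert$sd_mult[v])) pert$sd_mult[[v]] else 1
    d <- if (!is.null(pert$shift[v]) && !is.na(pert$shift[v])) pert$shift[[v]] else 0
    if (s != 1) m <- (m - mu) * s + mu
    if (d != 0) m <- m + d
    m[!stack$mask] <- NA_real_
    layers[[v]] <- m
  }
  env_stack(stack$spec, layers, mask = stack$mask)
}
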