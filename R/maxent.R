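#' Sample background (pseudo-absence) cells
#'
#' Draws cells uniformly without replacement from the valid (non-missing)
#' cells of a stack; presence cells are not excluded, the usual
#' presence/background convention.
#'
#' @param stack An [env_stack()].
#' @param n Number of background points (capped at the number of valid cells).
#' @param seed Integer seed.
#' @return An [occurrence_set()] with `source = "background"`.
#' @export
sample_background <- function(stack, n = 1000, seed = NULL) {
  sv <- stack_values(stack, names(stack$layers)[1])
  n <- min(n, length(sv$rows))
  idx <- with_seed(seed, sample.int(length(sv$rows), n))
  cc <- cell_centers(stack$spec, sv$rows[idx], sv$cols[idx])
  occurrence_set(data.frame(
    id = seq_len(n), species = "background",
    lon = cc$lon, lat = cc$lat, source = "background"
  ), spec = stack$spec)
}

# per-class base penalties; the linear/quadratic/product value is
# interpolated against the presence count (more data -> lighter penalty)
base_beta <- function(class, n_presence) {
  lqp <- stats::approx(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05),
                       xout = n_presence, rule = 2)$y
  unname(c(L = lqp, Q = lqp, P = lqp, H = 0.5, T = 1.0)[class])
}

#' Fit an L1-penalized maximum-entropy species distribution model
#'
#' Fits the Gibbs family `q(x) proportional to exp(sum_j lambda_j f_j(x))`,
#' normalized over a background sample, by minimizing the regularized
#' negative presence log-likelihood
#' \deqn{J(\lambda) = -\frac{1}{n_p}\sum_{presences}\eta(x) + \log Z_{bg}
#'   + \sum_j rm\,\beta_j s_j |\lambda_j|}
#' where `s_j` is the feature's presence-sample standard deviation and
#' `beta_j` a per-class base penalty scaled by the regularization multiplier
#' `rm`. The solver is cyclic coordinate descent with per-coordinate Newton
#' steps, soft-thresholding, and an exact backtracking line search, so the
#' objective decreases monotonically; convergence is declared when the
#' objective changes by less than `tol` between sweeps.
#'
#' @param occ Presence records: a cleaned [occurrence_set()] (>= 5 records).
#' @param stack An [env_stack()] with the model variables.
#' @param variables Variables to use (default all layers).
#' @param fc Feature-class string over {L, Q, H, P, T} (default `"LQHPT"`).
#' @param rm Regularization multiplier (> 0, default 1).
#' @param background Optional [occurrence_set()] of background cells;
#'   defaults to [sample_background()] with `n_background` cells.
#' @param n_background Background sample size when `background` is `NULL`.
#' @param n_knots Hinge/threshold knots per variable (default 50).
#' @param seed Seed for background sampling.
#' @param tol Convergence tolerance on the objective (default 1e-7).
#' @param max_iter Maximum coordinate-descent sweeps (default 10000).
#' @return An object of class `maxent_sdm` with components including
#'   `coefficients` (named vector `lambda`), `feature_spec`, `rm`,
#'   `penalties`, `logZ` (log partition over background), `entropy` (H of the
#'   fitted background distribution), `trace` (objective per sweep) and
#'   training metadata.
#' @seealso [predict.maxent_sdm()], [response_curve()], [tune_enm()]
#' @examples
#' sp <- grid_spec(30, 30, west = 105, north = 25, cell_size = 0.1)
#' st <- gen_env_stack(sp, c("temp", "prec"), seed = 1)
#' tr <- synthetic_truth(c(temp = 2))
#' occ <- sample_presences(st, tr, 80, seed = 2)
#' m <- maxent(occ, st, fc = "L", seed = 3)
#' coef(m)
#' @export
maxent <- function(occ, stack, variables = names(stack$layers), fc = "LQHPT",
                   rm = 1, background = NULL, n_background = 1000,
                   n_knots = 50, seed = NULL, tol = 1e-7, max_iter = 10000) {
  if (nrow(occ) < 5L) stop("need at least 5 presence records")
  if (rm <= 0) stop("rm must be > 0")
  if (is.null(background)) {
    background <- sample_background(stack, n_background, seed = seed)
  }
  fspec <- build_features(stack, variables, fc, n_knots)
  pidx <- occ_cells(occ, stack)
  bidx <- occ_cells(background, stack)
  pres_raw <- extract_cells(stack, pidx$row, pidx$col, variables)
  bg_raw <- extract_cells(stack, bidx$row, bidx$col, variables)
  Fp <- expand_features(fspec, pres_raw)
  Fb <- expand_features(fspec, bg_raw)
  fit <- maxent_fit_matrices(Fp, Fb, fspec$features$class, rm,
                             tol = tol, max_iter = max_iter)
  structure(list(
    coefficients = fit$lambda,
    feature_spec = fspec,
    dropped_features = fit$dropped,
    rm = rm,
    penalties = fit$pen,
    presence_sd = fit$s,
    presence_feature_means = fit$a,
    presence_raw_means = colMeans(pres_raw),
    logZ = fit$logZ,
    entropy = fit$entropy,
    trace = fit$trace,
    converged = fit$converged,
    n_iter = fit$iter,
    objective = fit$objective,
    background = data.frame(row = bidx$row, col = bidx$col),
    meta = list(n_presence = nrow(occ), n_background = nrow(background),
                seed = seed, fc = fspec$fc, variables = variables,
                n_knots = n_knots, tol = tol)
  ), class = "maxent_sdm")
}

# core solver on precomputed feature matrices; exported for tuning reuse
maxent_fit_matrices <- function(Fp, Fb, classes, rm, tol = 1e-7,
                                max_iter = 10000) {
  np <- nrow(Fp); nb <- nrow(Fb)
  # drop degenerate features: constant over presence+background, or exact
  # duplicates of an earlier feature (expansion hash)
  all_rng <- apply(rbind(Fp, Fb), 2, function(x) max(x) - min(x))
  keep <- all_rng > 0
  if (ncol(Fp) > 0) {
    hashes <- apply(rbind(Fp, Fb), 2, function(x) paste(signif(x, 12), collapse = ","))
    keep <- keep & !duplicated(hashes)
  }
  dropped <- colnames(Fp)[!keep]
  Fp <- Fp[, keep, drop = FALSE]
  Fb <- Fb[, keep, drop = FALSE]
  classes <- classes[keep]
  p <- ncol(Fp)
  a <- if (p) colMeans(Fp) else numeric(0)
  s <- if (p) apply(Fp, 2, stats::sd) else numeric(0)
  s <- pmax(s, 1e-4)  # floor so features constant on presences stay penalized
  beta <- if (p) base_beta(classes, np) else numeric(0)
  pen <- rm * beta * s

  sol <- cd_maxent(Fb, a, pen, tol, as.integer(max_iter))
  if (!sol$converged) {
    stop(sprintf("maxent solver did not converge after %d sweeps (objective %.8g)",
                 sol$iter, sol$objective))
  }
  lambda <- stats::setNames(sol$lambda, colnames(Fp))
  eta <- sol$eta
  m <- if (nb) max(eta) else 0
  logZ <- m + log(sum(exp(eta - m)))
  q <- exp(eta - logZ)
  entropy <- -sum(q * log(q))
  list(lambda = lambda, dropped = dropped, a = a, s = s, beta = beta,
       pen = pen, logZ = logZ, entropy = entropy, trace = sol$trace,
       converged = sol$converged, iter = sol$iter, objective = sol$objective,
       q = q)
}

#' @export
print.maxent_sdm <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<maxent_sdm> fc=%s, rm=%g: %d/%d nonzero feature(s)\n",
              x$meta$fc, x$rm, nz, length(x$coefficients)))
  cat(sprintf("  %d presences, %d background cells; entropy H = %.4f\n",
              x$meta$n_presence, x$meta$n_background, x$entropy))
  cat(sprintf("  converged in %d sweep(s), objective %.6f\n",
              x$n_iter, x$objective))
  invisible(x)
}

#' @export
coef.maxent_sdm <- function(object, all = FALSE, ...) {
  if (all) object$coefficients else
    object$coefficients[object$coefficients != 0]
}

#' @export
summary.maxent_sdm <- function(object, ...) {
  co <- coef(object)
  out <- list(
    fc = object$meta$fc, rm = object$rm,
    n_features = length(object$coefficients), n_active = length(co),
    entropy = object$entropy, objective = object$objective,
    coefficients = co[order(-abs(co))],
    n_presence = object$meta$n_presence,
    n_background = object$meta$n_background
  )
  class(out) <- "summary.maxent_sdm"
  out
}

#' @export
print.summary.maxent_sdm <- function(x, ...) {
  cat(sprintf("Maximum-entropy SDM (fc=%s, rm=%g)\n", x$fc, x$rm))
  cat(sprintf("  %d presences / %d background; %d of %d features active\n",
              x$n_presence, x$n_background, x$n_active, x$n_features))
  cat(sprintf("  objective %.6f, background entropy H = %.4f\n\n",
              x$objective, x$entropy))
  if (x$n_active) {
    cat("Active coefficients (by |lambda|):\n")
    print(round(x$coefficients, 5))
  } else cat("No active features (uniform model).\n")
  invisible(x)
}

# linear predictor eta for raw values (matrix cells x variables)
maxent_eta <- function(model, raw_vals) {
  Fm <- expand_features(model$feature_spec, raw_vals)
  Fm <- Fm[, names(model$coefficients), drop = FALSE]
  as.numeric(Fm %*% model$coefficients)
}

#' Predict habitat suitability over a stack
#'
#' `raw` output is the Gibbs weight normalized by the training background
#' partition function, `exp(eta(x)) / Z_bg` (it sums to 1 over the training
#' background sample); `cloglog` is the bounded transform
#' `1 - exp(-exp(H) * raw(x))` with `H` the entropy of the fitted background
#' distribution (the Maxent v3.4.4 default output); `logistic` is
#' `raw * exp(H) / (1 + raw * exp(H))`. Masked cells stay missing.
#'
#' @param object A fitted [maxent()] model.
#' @param stack An [env_stack()] providing every model variable.
#' @param type One of `"cloglog"`, `"raw"`, `"logistic"`.
#' @param ... Unused.
#' @return A `suitability_map`: list with `spec`, `mat` (values matrix) and
#'   `mask`.
#' @export
predict.maxent_sdm <- function(object, stack, type = c("cloglog", "raw", "logistic"),
                               ...) {
  type <- match.arg(type)
  miss <- setdiff(object$feature_spec$variables, names(stack$layers))
  if (length(miss)) stop("stack is missing model variable(s): ",
                         paste(miss, collapse = ", "))
  sv <- stack_values(stack, object$feature_spec$variables)
  eta <- maxent_eta(object, sv$values)
  raw <- exp(eta - object$logZ)
  vals <- switch(type,
    raw = raw,
    cloglog = 1 - exp(-exp(object$entropy) * raw),
    logistic = { r <- raw * exp(object$entropy); r / (1 + r) }
  )
  mat <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  mat[cbind(sv$rows, sv$cols)] <- vals
  suitability_map(stack$spec, mat, stack$mask)
}

#' Construct a suitability map
#'
#' @param spec A [grid_spec()].
#' @param mat Values matrix (NA on missing cells).
#' @param mask Logical validity mask.
#' @return An object of class `suitability_map`.
#' @export
suitability_map <- function(spec, mat, mask = !is.na(mat)) {
  stopifnot(all(dim(mat) == c(spec$n_rows, spec$n_cols)))
  structure(list(spec = spec, mat = mat, mask = mask),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$mat[x$mask]
  cat(sprintf("<suitability_map> %s; range [%.4g, %.4g], mean %.4g\n",
              format(x$spec), min(v), max(v), mean(v)))
  invisible(x)
}

#' Response curve of a fitted model along one variable
#'
#' Sweeps the variable over its training (normalizer) range while holding all
#' other variables at their presence-sample means, and evaluates the model.
#'
#' @param model A fitted [maxent()] model.
#' @param variable Variable name.
#' @param n_points Number of evaluation points (default 100).
#' @param type Output transform, as in [predict.maxent_sdm()].
#' @return Data frame with columns `value` (raw variable units) and
#'   `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           type = c("cloglog", "raw", "logistic")) {
  type <- match.arg(type)
  fs <- model$feature_spec
  if (!variable %in% fs$variables) stop("unknown variable: ", variable)
  i <- match(variable, fs$variables)
  xs <- seq(fs$lo[i], fs$hi[i], length.out = n_points)
  vals <- matrix(rep(model$presence_raw_means, each = n_points),
                 nrow = n_points,
                 dimnames = list(NULL, fs$variables))
  vals[, variable] <- xs
  eta <- maxent_eta(model, vals)
  raw <- exp(eta - model$logZ)
  suit <- switch(type,
    raw = raw,
    cloglog = 1 - exp(-exp(model$entropy) * raw),
    logistic = { r <- raw * exp(model$entropy); r / (1 + r) }
  )
  data.frame(value = xs, suitability = suit)
}

#' Plot response curves of a fitted model
#'
#' @param x A fitted [maxent()] model.
#' @param variables Variables to plot (default all).
#' @param n_points Points per curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.maxent_sdm <- function(x, variables = x$feature_spec$variables,
                            n_points = 100, ...) {
  k <- length(variables)
  old <- graphics::par(mfrow = grDevices::n2mfrow(k), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in variables) {
    rc <- response_curve(x, v, n_points)
    graphics::plot(rc$value, rc$suitability, type = "l",
                   xlab = v, ylab = "suitability", main = v, ...)
  }
  invisible(x)
}

#' Surface range envelope baseline
#'
#' Classifies a cell as suitable when every variable lies within the
#' `[quantile, 1 - quantile]` presence quantiles — the rectilinear climatic
#' envelope (SRE) baseline.
#'
#' @param occ Presence [occurrence_set()].
#' @param stack An [env_stack()].
#' @param quantile Tail fraction trimmed per side (`0 <= quantile < 0.5`;
#'   0 gives the presence min/max box).
#' @param variables Variables to use (default all).
#' @return A binary `suitability_map` (1 suitable, 0 not).
#' @export
sre_envelope <- function(occ, stack, quantile = 0.025,
                         variables = names(stack$layers)) {
  if (quantile < 0 || quantile >= 0.5) stop("quantile must be in [0, 0.5)")
  idx <- occ_cells(occ, stack)
  pres <- extract_cells(stack, idx$row, idx$col, variables)
  lo <- apply(pres, 2, stats::quantile, probs = quantile, names = FALSE)
  hi <- apply(pres, 2, stats::quantile, probs = 1 - quantile, names = FALSE)
  sv <- stack_values(stack, variables)
  ok <- rep(TRUE, nrow(sv$values))
  for (j in seq_along(variables)) {
    ok <- ok & sv$values[, j] >= lo[j] & sv$values[, j] <= hi[j]
  }
  mat <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  mat[cbind(sv$rows, sv$cols)] <- as.numeric(ok)
  suitability_map(stack$spec, mat, stack$mask)
}

#' Serialize a fitted model to JSON
#'
#' Round-trips through [read_maxent()] to identical predictions (full
#' double precision).
#'
#' @param model A fitted [maxent()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_maxent <- function(model, path) {
  obj <- model
  obj$feature_spec <- unclass(obj$feature_spec)
  obj$feature_spec$features <- as.list(obj$feature_spec$features)
  obj$background <- as.list(obj$background)
  # named numeric vectors must travel as JSON objects, not bare arrays
  for (f in c("coefficients", "penalties", "presence_sd",
              "presence_feature_means", "presence_raw_means")) {
    obj[[f]] <- as.list(obj[[f]])
  }
  obj$feature_spec$lo <- as.list(obj$feature_spec$lo)
  obj$feature_spec$hi <- as.list(obj$feature_spec$hi)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Deserialize a fitted model from JSON
#'
#' @param path JSON path written by [write_maxent()].
#' @return A `maxent_sdm` object.
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficients", "penalties", "presence_sd",
              "presence_feature_means", "presence_raw_means")) {
    obj[[f]] <- unlist(obj[[f]])
  }
  obj$feature_spec$features <- as.data.frame(obj$feature_spec$features,
                                             stringsAsFactors = FALSE)
  obj$feature_spec$lo <- unlist(obj$feature_spec$lo)
  obj$feature_spec$hi <- unlist(obj$feature_spec$hi)
  class(obj$feature_spec) <- "feature_spec"
  obj$background <- as.data.frame(obj$background)
  class(obj) <- "maxent_sdm"
  obj
}
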