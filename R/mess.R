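#' Build a reference envelope for similarity analysis
#'
#' Stores, per variable, the sorted reference values and their min/max,
#' taken either at the occurrence cells (default) or over all valid cells of
#' the reference stack.
#'
#' @param stack Reference-period [env_stack()].
#' @param occ A cleaned [occurrence_set()] (>= 2 records); ignored when
#'   `reference = "landscape"`.
#' @param variables Variables to include (default all layers).
#' @param reference `"occurrences"` (default) or `"landscape"`.
#' @return An object of class `reference_envelope`: named list of sorted
#'   numeric vectors with attributes `min`/`max` per variable.
#' @export
build_envelope <- function(stack, occ = NULL, variables = names(stack$layers),
                           reference = c("occurrences", "landscape")) {
  reference <- match.arg(reference)
  if (reference == "occurrences") {
    if (is.null(occ) || nrow(occ) < 2L) stop("need at least 2 occurrences")
    idx <- occ_cells(occ, stack)
    vals <- extract_cells(stack, idx$row, idx$col, variables)
  } else {
    vals <- stack_values(stack, variables)$values
  }
  env <- lapply(seq_along(variables), function(j) sort(vals[, j]))
  names(env) <- variables
  structure(env, class = "reference_envelope", reference = reference)
}

#' @export
print.reference_envelope <- function(x, ...) {
  cat(sprintf("<reference_envelope> %d variable(s), %d reference value(s) each (%s)\n",
              length(x), length(x[[1]]), attr(x, "reference")))
  for (v in names(x)) {
    cat(sprintf("  %s: [%.4g, %.4g]\n", v, x[[v]][1], x[[v]][length(x[[v]])]))
  }
  invisible(x)
}

#' Piecewise environmental similarity of one value
#'
#' With `f` the percentage of reference values strictly less than `p`
#' (ties not counted, so the `f = 0` and `f = 100` branches are reached
#' exactly at/below the minimum and strictly above the maximum):
#' \itemize{
#'   \item `f = 0`: `100 * (p - min) / (max - min)` (negative below the
#'     minimum — an anomaly);
#'   \item `0 < f <= 50`: `2 f`;
#'   \item `50 < f < 100`: `2 (100 - f)`;
#'   \item `f = 100`: `100 * (max - p) / (max - min)`.
#' }
#' A degenerate envelope (`min = max`) scores 0 at `p = min` and
#' `-100 * |p - min| / max(|min|, 1)` elsewhere (the formula's denominator
#' vanishes, so a scale-free penalty is used instead).
#'
#' @param envelope A [build_envelope()] result.
#' @param variable Variable name.
#' @param p Numeric vector of projection values.
#' @return Similarity score(s), at most 100; negative values flag conditions
#'   outside the reference range.
#' @examples
#' env <- structure(list(v = c(2, 4, 6, 8, 10)), class = "reference_envelope")
#' similarity(env, "v", 1)   # -12.5
#' similarity(env, "v", 10)  # 40
#' @export
similarity <- function(envelope, variable, p) {
  ref <- envelope[[variable]]
  if (is.null(ref)) stop("unknown variable: ", variable)
  n <- length(ref)
  mn <- ref[1]
  mx <- ref[n]
  if (mx - mn <= 0) {
    return(ifelse(p == mn, 0, -100 * abs(p - mn) / max(abs(mn), 1)))
  }
  # findInterval(..., left.open=TRUE) counts ref values strictly less than p
  f <- 100 * findInterval(p, ref, left.open = TRUE) / n
  out <- numeric(length(p))
  b0 <- f == 0
  b1 <- f > 0 & f <= 50
  b2 <- f > 50 & f < 100
  b3 <- f == 100
  out[b0] <- 100 * (p[b0] - mn) / (mx - mn)
  out[b1] <- 2 * f[b1]
  out[b2] <- 2 * (100 - f[b2])
  out[b3] <- 100 * (mx - p[b3]) / (mx - mn)
  out
}

#' Multivariate environmental similarity surface (MESS) and MoD
#'
#' Per cell, MESS is the minimum of the per-variable [similarity()] scores
#' and the most-dissimilar variable (MoD) the variable attaining it (ties go
#' to the lowest variable index). A cell with any variable outside its
#' reference range has MESS < 0 (a climate anomaly).
#'
#' @param envelope A [build_envelope()] result.
#' @param stack Projection [env_stack()] providing every envelope variable.
#' @param scenario Label stored with the grid.
#' @return A `mess_grid`: list with `spec`, `mess` (matrix), `mod` (integer
#'   matrix of variable indices), `variables`, `scenario`, `mean_mess`
#'   (mean over non-missing cells), `pct_anomaly`.
#' @export
mess_grid <- function(envelope, stack, scenario = "scenario") {
  vars <- names(envelope)
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss)) stop("stack is missing envelope variable(s): ",
                         paste(miss, collapse = ", "))
  sv <- stack_values(stack, vars)
  sim <- vapply(vars, function(v) similarity(envelope, v, sv$values[, v]),
                numeric(nrow(sv$values)))
  if (nrow(sv$values) == 1L) sim <- matrix(sim, nrow = 1)
  mod_idx <- max.col(-sim, ties.method = "first")
  mess_val <- sim[cbind(seq_len(nrow(sim)), mod_idx)]
  mess <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  mod <- matrix(NA_integer_, stack$spec$n_rows, stack$spec$n_cols)
  mess[cbind(sv$rows, sv$cols)] <- mess_val
  mod[cbind(sv$rows, sv$cols)] <- mod_idx
  structure(list(
    spec = stack$spec, mess = mess, mod = mod, variables = vars,
    scenario = scenario, mean_mess = mean(mess_val),
    pct_anomaly = 100 * mean(mess_val < 0)
  ), class = "mess_grid")
}

#' @export
print.mess_grid <- function(x, ...) {
  cat(sprintf("<mess_grid> scenario '%s': mean MESS %.2f, %.1f%% anomaly cells\n",
              x$scenario, x$mean_mess, x$pct_anomaly))
  tab <- table(factor(x$mod[!is.na(x$mod)], levels = seq_along(x$variables),
                      labels = x$variables))
  cat("  MoD counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Climate-anomaly mask of a MESS grid
#'
#' Flags cells with strictly negative MESS (at least one variable outside
#' its reference range); MESS = 0 is not flagged.
#'
#' @param grid A [mess_grid()] result.
#' @return Logical matrix (`NA` on missing cells).
#' @export
anomaly_mask <- function(grid) {
  grid$mess < 0
}
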