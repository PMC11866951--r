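#' Spearman rank correlation matrix at occurrence cells
#'
#' Computes the rank-based (Spearman) correlation of environmental variables
#' extracted at the occurrence cells, with ties mid-ranked (the standard
#' convention of [stats::cor()]). A constant variable, whose rank correlation
#' is undefined, is flagged with a warning and its correlations set to 0.
#'
#' @param stack An [env_stack()].
#' @param occ A cleaned [occurrence_set()] (>= 3 records).
#' @param variables Layer names (default all).
#' @param landscape If `TRUE`, correlate over all valid landscape cells
#'   instead of the occurrence cells.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(stack, occ = NULL, variables = names(stack$layers),
                            landscape = is.null(occ)) {
  if (landscape) {
    vals <- stack_values(stack, variables)$values
  } else {
    if (nrow(occ) < 3L) stop("need at least 3 occurrences")
    idx <- occ_cells(occ, stack)
    vals <- extract_cells(stack, idx$row, idx$col, variables)
  }
  rho <- suppressWarnings(stats::cor(vals, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant variable(s): undefined rank correlations set to 0")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Greedy selection of a low-collinearity variable subset
#'
#' Variables are visited in descending importance; a candidate is retained
#' only if its absolute correlation with every already-retained variable is
#' strictly below `threshold`. The retained set therefore has all pairwise
#' `|rho| < threshold`. Ties in importance are broken alphabetically so the
#' result does not depend on the order variables appear in the matrix.
#'
#' @param rho Correlation matrix (symmetric, unit diagonal, named dims).
#' @param importance Named numeric vector covering every variable in `rho`.
#' @param threshold Absolute-correlation cutoff (default 0.7).
#' @return Character vector of retained variable names, in retention order.
#' @export
select_uncorrelated <- function(rho, importance, threshold = 0.7) {
  vars <- rownames(rho)
  if (is.null(vars)) stop("rho must have dimnames")
  if (!all(vars %in% names(importance))) {
    stop("importance must cover every variable")
  }
  ord <- vars[order(-importance[vars], vars)]
  kept <- character(0)
  for (v in ord) {
    if (all(abs(rho[v, kept]) < threshold)) kept <- c(kept, v)
  }
  kept
}

#' Univariate discrimination importance of each variable
#'
#' Default importance score for [select_uncorrelated()]: the ability of each
#' variable alone to separate presence cells from background cells, measured
#' as `max(AUC, 1 - AUC)` of the raw variable values (so direction does not
#' matter).
#'
#' @param stack An [env_stack()].
#' @param occ A cleaned [occurrence_set()].
#' @param background An [occurrence_set()] of background cells, or `NULL` to
#'   use all valid landscape cells.
#' @param variables Layer names (default all).
#' @return Named numeric vector of importances in `[0.5, 1]`.
#' @export
variable_importance <- function(stack, occ, background = NULL,
                                variables = names(stack$layers)) {
  idx <- occ_cells(occ, stack)
  pres <- extract_cells(stack, idx$row, idx$col, variables)
  if (is.null(background)) {
    bg <- stack_values(stack, variables)$values
  } else {
    bidx <- occ_cells(background, stack)
    bg <- extract_cells(stack, bidx$row, bidx$col, variables)
  }
  vapply(variables, function(v) {
    a <- auc(pres[, v], bg[, v])
    max(a, 1 - a)
  }, numeric(1))
}

#' Variance inflation factors over occurrence cells
#'
#' For each variable, VIF = 1 / (1 - R^2) where R^2 comes from the ordinary
#' least-squares regression of that variable on all the others, using values
#' extracted at the occurrence cells. Perfect collinearity yields `Inf`.
#'
#' @param stack An [env_stack()].
#' @param occ A cleaned [occurrence_set()] with at least
#'   `length(variables) + 2` records.
#' @param variables Variable subset to assess.
#' @param anchor Optional single variable name: additionally reproduce the
#'   anchored layout in which each remaining variable is regressed on the
#'   anchor and the rest (column `vif_anchored`); the conventional VIF is
#'   always reported.
#' @return Data frame with columns `variable`, `vif` (and `vif_anchored`
#'   when `anchor` is given), plus a logical `flagged` column (`vif >= 10`).
#' @export
vif_table <- function(stack, occ, variables, anchor = NULL) {
  if (length(variables) < 2L) stop("need at least two variables")
  if (nrow(occ) < length(variables) + 2L) {
    stop("need at least length(variables) + 2 occurrence records")
  }
  idx <- occ_cells(occ, stack)
  vals <- as.data.frame(extract_cells(stack, idx$row, idx$col, variables))
  vif_one <- function(y, X) {
    fit <- stats::lm(y ~ ., data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  vif <- vapply(variables, function(v) {
    vif_one(vals[[v]], vals[setdiff(variables, v)])
  }, numeric(1))
  out <- data.frame(variable = variables, vif = vif,
                    flagged = vif >= 10, row.names = NULL)
  if (!is.null(anchor)) {
    stopifnot(anchor %in% variables)
    others <- setdiff(variables, anchor)
    out$vif_anchored <- NA_real_
    out$vif_anchored[match(others, out$variable)] <- vapply(others, function(v) {
      vif_one(vals[[v]], vals[setdiff(variables, v)])
    }, numeric(1))
  }
  out
}

#' Screen environmental variables by correlation and VIF
#'
#' Convenience wrapper running [spearman_matrix()], [variable_importance()],
#' [select_uncorrelated()] and [vif_table()] and assembling a screening
#' report.
#'
#' @param stack An [env_stack()].
#' @param occ A cleaned [occurrence_set()].
#' @param corr_threshold Absolute Spearman cutoff (default 0.7).
#' @param vif_threshold VIF flag level (default 10).
#' @param importance Optional named importance vector; defaults to
#'   [variable_importance()].
#' @return An object of class `screening_report`: list with `rho`,
#'   `importance`, `selected`, `vif`, `thresholds`.
#' @export
screen_variables <- function(stack, occ, corr_threshold = 0.7,
                             vif_threshold = 10, importance = NULL) {
  rho <- spearman_matrix(stack, occ)
  if (is.null(importance)) importance <- variable_importance(stack, occ)
  selected <- select_uncorrelated(rho, importance, corr_threshold)
  vif <- if (length(selected) >= 2L && nrow(occ) >= length(selected) + 2L) {
    vif_table(stack, occ, selected)
  } else NULL
  structure(list(
    rho = rho, importance = importance, selected = selected, vif = vif,
    thresholds = list(corr = corr_threshold, vif = vif_threshold)
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d variable(s) screened, %d selected (|rho| < %g)\n",
              nrow(x$rho), length(x$selected), x$thresholds$corr))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$vif)) {
    cat("  VIF range:", sprintf("%.2f-%.2f", min(x$vif$vif), max(x$vif$vif)),
        if (any(x$vif$flagged)) "(some flagged)" else "(none flagged)", "\n")
  }
  invisible(x)
}
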