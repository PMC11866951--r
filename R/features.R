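#' Build a feature expansion specification
#'
#' Defines the basis expansion of raw environmental variables used by the
#' maximum-entropy model. Variables are first min-max normalized to [0, 1]
#' using per-variable normalizers taken from the stack (values beyond the
#' training range are clamped at prediction time, the usual Maxent
#' behaviour). Feature classes:
#' \describe{
#'   \item{L}{the normalized variable itself;}
#'   \item{Q}{its square;}
#'   \item{P}{all pairwise products of normalized variables;}
#'   \item{H}{forward hinges `max(0, (x - k) / (1 - k))` and reverse hinges
#'     `max(0, (k - x) / k)` at each knot `k`;}
#'   \item{T}{step indicators `1[x > k]` at each knot.}
#' }
#' Knots are evenly spaced strictly inside (0, 1): `k_i = i / (n_knots + 1)`.
#'
#' @param stack An [env_stack()] providing the normalizers.
#' @param variables Variables to expand.
#' @param fc Feature-class string over the alphabet {L, Q, H, P, T},
#'   e.g. `"LQH"`.
#' @param n_knots Number of hinge/threshold knots per variable (default 50).
#' @return An object of class `feature_spec` with elements `variables`, `fc`,
#'   `lo`/`hi` (normalizers), `knots`, and a feature table (`name`, `class`).
#' @examples
#' sp <- grid_spec(10, 10)
#' st <- gen_env_stack(sp, c("a", "b"), seed = 1)
#' fs <- build_features(st, c("a", "b"), "LQ")
#' nrow(fs$features)  # 4
#' @export
build_features <- function(stack, variables = names(stack$layers), fc = "LQH",
                           n_knots = 50) {
  fc <- toupper(fc)
  classes <- strsplit(fc, "")[[1]]
  if (length(classes) == 0L) stop("fc must be non-empty")
  bad <- setdiff(classes, c("L", "Q", "H", "P", "T"))
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  classes <- unique(classes)
  sv <- stack_values(stack, variables)$values
  lo <- apply(sv, 2, min)
  hi <- apply(sv, 2, max)
  const <- hi - lo <= 0
  if (any(const)) {
    warning("constant variable(s) carry no features: ",
            paste(variables[const], collapse = ", "))
  }
  knots <- if (n_knots >= 1) seq_len(n_knots) / (n_knots + 1) else numeric(0)
  feats <- list()
  vs <- variables[!const]
  add <- function(name, class) feats[[length(feats) + 1]] <<- c(name, class)
  if ("L" %in% classes) for (v in vs) add(paste0("L:", v), "L")
  if ("Q" %in% classes) for (v in vs) add(paste0("Q:", v), "Q")
  if ("H" %in% classes) for (v in vs) for (k in knots) {
    add(sprintf("Hf:%s:%g", v, k), "H")
    add(sprintf("Hr:%s:%g", v, k), "H")
  }
  if ("P" %in% classes && length(vs) >= 2) {
    cmb <- utils::combn(vs, 2)
    for (i in seq_len(ncol(cmb))) add(paste0("P:", cmb[1, i], "*", cmb[2, i]), "P")
  }
  if ("T" %in% classes) for (v in vs) for (k in knots) {
    add(sprintf("T:%s:%g", v, k), "T")
  }
  features <- if (length(feats)) {
    stats::setNames(as.data.frame(do.call(rbind, feats),
                                  stringsAsFactors = FALSE),
                    c("name", "class"))
  } else {
    data.frame(name = character(0), class = character(0))
  }
  structure(list(
    variables = variables, fc = fc, lo = lo, hi = hi, knots = knots,
    features = features
  ), class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> fc=%s, %d variable(s), %d feature(s), %d knot(s)\n",
              x$fc, length(x$variables), nrow(x$features), length(x$knots)))
  invisible(x)
}

# normalize raw values (cells x variables) to [0,1], clamping outside range
normalize_values <- function(spec, vals) {
  vals <- vals[, spec$variables, drop = FALSE]
  for (j in seq_along(spec$variables)) {
    rng <- spec$hi[j] - spec$lo[j]
    if (rng <= 0) {
      vals[, j] <- 0
    } else {
      vals[, j] <- pmin(pmax((vals[, j] - spec$lo[j]) / rng, 0), 1)
    }
  }
  vals
}

#' Expand raw variable values into the feature matrix
#'
#' @param spec A [build_features()] spec.
#' @param vals Numeric matrix of raw values, one row per point, columns named
#'   by variable.
#' @return Numeric matrix, points x features, columns in the spec's feature
#'   order.
#' @export
expand_features <- function(spec, vals) {
  x <- normalize_values(spec, vals)
  n <- nrow(x)
  p <- nrow(spec$features)
  out <- matrix(0, n, p, dimnames = list(NULL, spec$features$name))
  for (j in seq_len(p)) {
    nm <- spec$features$name[j]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    out[, j] <- switch(parts[1],
      L = x[, parts[2]],
      Q = x[, parts[2]]^2,
      Hf = { k <- as.numeric(parts[3]); pmax(0, (x[, parts[2]] - k) / (1 - k)) },
      Hr = { k <- as.numeric(parts[3]); pmax(0, (k - x[, parts[2]]) / k) },
      T = { k <- as.numeric(parts[3]); as.numeric(x[, parts[2]] > k) },
      P = { vv <- strsplit(parts[2], "*", fixed = TRUE)[[1]]
            x[, vv[1]] * x[, vv[2]] },
      stop("corrupt feature name: ", nm)
    )
  }
  out
}
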