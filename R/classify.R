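#' Classify a suitability map into four grades
#'
#' Grades follow the fixed suitability bands: `[0, t1)` unsuitable,
#' `[t1, t2)` low, `[t2, t3)` moderate, `[t3, 1]` high — half-open intervals
#' with the top class closed, so classification is bit-reproducible at the
#' boundaries (a value exactly at a threshold belongs to the upper class).
#'
#' @param map A `suitability_map` (values in `[0, 1]`).
#' @param thresholds Numeric `(t1, t2, t3)` with `0 < t1 < t2 < t3 < 1`
#'   (default `c(0.10, 0.30, 0.60)`); pass [jenks_breaks()] output for
#'   natural-breaks classification.
#' @return A `class_map`: list with `spec`, `classes` (integer matrix,
#'   0 unsuitable / 1 low / 2 moderate / 3 high, `NA` missing), `levels`,
#'   `thresholds`.
#' @examples
#' sp <- grid_spec(2, 2)
#' m <- suitability_map(sp, matrix(c(0.05, 0.2, 0.45, 0.75), 2, 2))
#' classify_suitability(m)$classes
#' @export
classify_suitability <- function(map, thresholds = c(0.10, 0.30, 0.60)) {
  t <- as.numeric(thresholds)
  if (length(t) != 3L || any(diff(t) <= 0) || t[1] <= 0 || t[3] >= 1) {
    stop("thresholds must satisfy 0 < t1 < t2 < t3 < 1")
  }
  cls <- matrix(NA_integer_, map$spec$n_rows, map$spec$n_cols)
  v <- map$mat
  cls[map$mask] <- findInterval(v[map$mask], t)  # 0..3, right-open bins
  structure(list(
    spec = map$spec, classes = cls,
    levels = c("unsuitable", "low", "moderate", "high"),
    thresholds = t
  ), class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$classes[!is.na(x$classes)], levels = 0:3,
                      labels = x$levels))
  cat(sprintf("<class_map> thresholds %s\n",
              paste(x$thresholds, collapse = "/")))
  print(tab)
  invisible(x)
}

#' Jenks natural breaks (Fisher optimal 1-D partition)
#'
#' Finds the `k`-class partition of sorted values minimizing the total
#' within-class sum of squared deviations, by dynamic programming (exact and
#' deterministic). Breaks are reported as the minimum value of each upper
#' class, so classifying with half-open lower-closed intervals reproduces the
#' optimal partition exactly.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (>= 1).
#' @return Numeric vector of `k - 1` interior breaks (empty for `k = 1`).
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)  # 10
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (k < 1) stop("k must be >= 1")
  if (length(unique(x)) < k) stop("need at least k distinct values")
  if (k == 1) return(numeric(0))
  cs0 <- c(0, cumsum(x))
  cs20 <- c(0, cumsum(x^2))
  # D[m, j]: best SSE splitting x[1..j] into m classes; B[m, j]: first index
  # of the last class in that optimum
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  j <- seq_len(n)
  D[1, ] <- cs20[j + 1] - cs0[j + 1]^2 / j
  B[1, ] <- 1L
  for (m in 2:k) {
    for (j in m:n) {
      i <- m:j  # first index of the last class
      s <- cs0[j + 1] - cs0[i]
      s2 <- cs20[j + 1] - cs20[i]
      cand <- D[m - 1, i - 1] + s2 - s^2 / (j - i + 1)
      best <- which.min(cand)
      D[m, j] <- cand[best]
      B[m, j] <- i[best]
    }
  }
  breaks <- numeric(k - 1)
  j <- n
  for (m in k:2) {
    i <- B[m, j]
    breaks[m - 1] <- x[i]
    j <- i - 1L
  }
  breaks
}

#' Spherical cell areas per grid row
#'
#' Area of a `cell_size x cell_size` geographic cell in row `i`:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with
#' `R = 6371.0088` km (authalic Earth radius), so areas are exact on the
#' sphere and identical across platforms.
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of length `n_rows`: cell area in km^2 for each row
#'   (constant along a row).
#' @export
cell_areas <- function(spec) {
  R <- 6371.0088
  lat_top <- spec$north - (seq_len(spec$n_rows) - 1) * spec$cell_size
  lat_bot <- lat_top - spec$cell_size
  dlon <- spec$cell_size * pi / 180
  R^2 * dlon * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Class area accounting
#'
#' Sums spherical cell areas per suitability grade; "total suitable" is
#' low + moderate + high. Areas are reported in 10^4 km^2 (the usual
#' reporting unit) and as percent of the non-missing landscape.
#'
#' @param cmap A [classify_suitability()] result.
#' @return An `area_table` data frame with columns `class`, `area_1e4_km2`,
#'   `percent`; rows unsuitable/low/moderate/high/total_suitable.
#' @export
area_table <- function(cmap) {
  aw <- cell_areas(cmap$spec)
  w <- matrix(aw, cmap$spec$n_rows, cmap$spec$n_cols)
  ok <- !is.na(cmap$classes)
  total <- sum(w[ok])
  area <- vapply(0:3, function(cl) sum(w[ok & cmap$classes == cl]), numeric(1))
  out <- data.frame(
    class = c(cmap$levels, "total_suitable"),
    area_1e4_km2 = c(area, sum(area[2:4])) / 1e4,
    percent = 100 * c(area, sum(area[2:4])) / total
  )
  class(out) <- c("area_table", "data.frame")
  out
}

#' @export
print.area_table <- function(x, ...) {
  y <- x
  y$area_1e4_km2 <- round(y$area_1e4_km2, 2)
  y$percent <- round(y$percent, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Range change matrix between two suitability maps
#'
#' Binarizes both maps at `threshold` (suitable iff value >= threshold) and
#' assigns each non-missing cell one of the four transition classes:
#' `new` (0 to 1), `lost` (1 to 0), `retained` (1 to 1), `unsuitable`
#' (0 to 0). The four classes partition the non-missing landscape exactly.
#'
#' @param current,future `suitability_map`s on the same grid.
#' @param threshold Binarization threshold (default 0.30, the presence
#'   probability above which a cell counts as suitable).
#' @return A `change_map`: list with `spec`, `classes` (integer matrix,
#'   0 unsuitable / 1 new / 2 lost / 3 retained), `levels`, `threshold`,
#'   and `areas` (data frame of class areas in 10^4 km^2 and percent).
#' @export
change_map <- function(current, future, threshold = 0.30) {
  if (!grids_identical(current$spec, future$spec)) {
    stop("current and future maps are not on the same grid")
  }
  mask <- current$mask & future$mask
  b0 <- current$mat >= threshold
  b1 <- future$mat >= threshold
  cls <- matrix(NA_integer_, current$spec$n_rows, current$spec$n_cols)
  cls[mask & !b0 & !b1] <- 0L
  cls[mask & !b0 & b1] <- 1L
  cls[mask & b0 & !b1] <- 2L
  cls[mask & b0 & b1] <- 3L
  levels <- c("unsuitable", "new", "lost", "retained")
  aw <- cell_areas(current$spec)
  w <- matrix(aw, current$spec$n_rows, current$spec$n_cols)
  total <- sum(w[mask])
  area <- vapply(0:3, function(i) sum(w[mask & cls == i], na.rm = TRUE),
                 numeric(1))
  areas <- data.frame(class = levels, area_1e4_km2 = area / 1e4,
                      percent = 100 * area / total)
  structure(list(spec = current$spec, classes = cls, levels = levels,
                 threshold = threshold, areas = areas),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("<change_map> threshold %g\n", x$threshold))
  y <- x$areas
  y$area_1e4_km2 <- round(y$area_1e4_km2, 3)
  y$percent <- round(y$percent, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
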