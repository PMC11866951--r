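#' Construct an occurrence set
#'
#' @param records Data frame with at least `lon` and `lat` columns (decimal
#'   degrees, WGS84); `id`, `species` and `source` are added when absent.
#' @param spec Optional [grid_spec()] the records are snapped to.
#' @return An object of class `occurrence_set` (a data frame).
#' @export
occurrence_set <- function(records, spec = NULL) {
  stopifnot(is.data.frame(records), all(c("lon", "lat") %in% names(records)))
  if (nrow(records) < 1L) stop("an occurrence set needs at least one record")
  if (any(records$lon < -180 | records$lon > 180, na.rm = TRUE) ||
      any(records$lat < -90 | records$lat > 90, na.rm = TRUE)) {
    stop("coordinates outside [-180,180] x [-90,90]")
  }
  if (is.null(records$id)) records$id <- seq_len(nrow(records))
  if (is.null(records$species)) records$species <- "unknown"
  if (is.null(records$source)) records$source <- "unknown"
  records <- records[c("id", "species", "lon", "lat", "source")]
  structure(records, class = c("occurrence_set", "data.frame"), spec = spec)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d record(s)", nrow(x)))
  sp <- attr(x, "spec")
  if (!is.null(sp)) cat(" snapped to", format(sp))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Read occurrence records from CSV
#'
#' Accepts any CSV with recognizable longitude/latitude columns
#' (`lon`/`long`/`longitude`/`x` and `lat`/`latitude`/`y`, case-insensitive).
#' Rows whose coordinates cannot be parsed, are missing, or fall outside
#' [-180,180] x [-90,90] are excluded and counted in the attached report.
#'
#' @param path CSV file path.
#' @return An [occurrence_set()] with attribute `report`, a list with
#'   `n_input`, `n_kept`, `n_unparseable`, `n_out_of_range`.
#' @export
load_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty occurrence file: ", path)
  find_col <- function(cands) {
    hit <- which(tolower(names(raw)) %in% cands)
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }
  ilon <- find_col(c("lon", "long", "longitude", "x", "decimallongitude"))
  ilat <- find_col(c("lat", "latitude", "y", "decimallatitude"))
  if (is.na(ilon) || is.na(ilat)) {
    stop("could not find longitude/latitude columns in ", path)
  }
  lon <- suppressWarnings(as.numeric(raw[[ilon]]))
  lat <- suppressWarnings(as.numeric(raw[[ilat]]))
  unparseable <- is.na(lon) | is.na(lat)
  out_of_range <- !unparseable &
    (lon < -180 | lon > 180 | lat < -90 | lat > 90)
  keep <- !unparseable & !out_of_range
  if (!any(keep)) stop("no parseable in-range records in ", path)
  isp <- find_col(c("species", "taxon", "name"))
  isrc <- find_col(c("source", "basisofrecord"))
  occ <- occurrence_set(data.frame(
    id = seq_len(sum(keep)),
    species = if (!is.na(isp)) as.character(raw[[isp]][keep]) else "unknown",
    lon = lon[keep], lat = lat[keep],
    source = if (!is.na(isrc)) as.character(raw[[isrc]][keep]) else "unknown"
  ))
  attr(occ, "report") <- list(
    n_input = nrow(raw), n_kept = sum(keep),
    n_unparseable = sum(unparseable), n_out_of_range = sum(out_of_range)
  )
  occ
}

#' Write an occurrence set to CSV
#'
#' @param occ An [occurrence_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Clean occurrence records against an environmental stack
#'
#' Applies, in order, the three screening rules used when curating natural
#' distribution records:
#' \enumerate{
#'   \item \emph{unclear geography}: records off the grid or on masked
#'     (missing-data) cells are dropped;
#'   \item \emph{duplicates}: records sharing a grid cell are collapsed to
#'     the first (one record per cell);
#'   \item \emph{outliers}: records whose value on any layer has a robust
#'     z-score `|x - median| / (1.4826 * MAD)` above `outlier_z` are dropped,
#'     iterating (median and MAD recomputed on the survivors) until no record
#'     is flagged — so cleaning is idempotent by construction.
#' }
#'
#' @param occ An [occurrence_set()].
#' @param stack An [env_stack()].
#' @param outlier_z Robust z-score threshold (default 4.0).
#' @return A cleaned, grid-snapped [occurrence_set()] with attribute
#'   `report`: counts per rule (`n_input`, `n_off_grid`, `n_duplicate`,
#'   `n_outlier`, `n_kept`), satisfying
#'   `n_kept + n_off_grid + n_duplicate + n_outlier == n_input`.
#' @export
clean_occurrences <- function(occ, stack, outlier_z = 4.0) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "env_stack"))
  n_input <- nrow(occ)
  idx <- cell_index(stack$spec, occ$lon, occ$lat)
  on_grid <- !is.na(idx$row)
  valid <- on_grid
  valid[on_grid] <- stack$mask[cbind(idx$row[on_grid], idx$col[on_grid])]
  n_off_grid <- sum(!valid)

  occ2 <- occ[valid, , drop = FALSE]
  idx2 <- idx[valid, , drop = FALSE]
  cell <- (idx2$col - 1L) * stack$spec$n_rows + idx2$row
  first <- !duplicated(cell)
  n_duplicate <- sum(!first)
  occ3 <- occ2[first, , drop = FALSE]
  idx3 <- idx2[first, , drop = FALSE]

  vals <- extract_cells(stack, idx3$row, idx3$col)
  alive <- rep(TRUE, nrow(occ3))
  repeat {
    out <- rep(FALSE, sum(alive))
    for (j in seq_len(ncol(vals))) {
      x <- vals[alive, j]
      med <- stats::median(x)
      mad <- stats::mad(x)  # 1.4826 * median absolute deviation
      if (mad > 0) out <- out | (abs(x - med) / mad > outlier_z)
    }
    if (!any(out) || sum(alive) - sum(out) < 1L) break
    alive[alive] <- !out
  }
  n_outlier <- sum(!alive)
  keep <- occ3[alive, , drop = FALSE]
  idx4 <- idx3[alive, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no records survive cleaning")

  cc <- cell_centers(stack$spec, idx4$row, idx4$col)
  keep$lon <- cc$lon
  keep$lat <- cc$lat
  res <- occurrence_set(as.data.frame(keep), spec = stack$spec)
  attr(res, "report") <- list(
    n_input = n_input, n_off_grid = n_off_grid, n_duplicate = n_duplicate,
    n_outlier = n_outlier, n_kept = nrow(res)
  )
  res
}

# cell indices of a snapped occurrence set on a stack's grid
occ_cells <- function(occ, stack) {
  idx <- cell_index(stack$spec, occ$lon, occ$lat)
  if (anyNA(idx$row)) stop("occurrence off-grid; run clean_occurrences() first")
  idx
}
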