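#' Define a geographic grid
#'
#' A `grid_spec` describes a regular latitude/longitude grid in WGS84 decimal
#' degrees. Rows run north to south and columns west to east (the usual raster
#' convention); the cell in row `i`, column `j` has its center at
#' `lon = west + (j - 0.5) * cell_size`, `lat = north - (i - 0.5) * cell_size`.
#' Cell membership uses half-open intervals `[edge, edge + cell_size)`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param west Western edge of the grid, decimal degrees.
#' @param north Northern edge of the grid, decimal degrees.
#' @param cell_size Cell edge length, decimal degrees (> 0).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(10, 10, west = 100, north = 30, cell_size = 0.5)
#' @export
grid_spec <- function(n_rows, n_cols, west = 0, north = 0, cell_size = 1) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  east <- west + n_cols * cell_size
  south <- north - n_rows * cell_size
  if (west < -180 - 1e-9 || east > 180 + 1e-9 ||
      south < -90 - 1e-9 || north > 90 + 1e-9) {
    stop("grid must lie within [-180, 180] x [-90, 90]")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, west = west, north = north,
         cell_size = cell_size, crs = "WGS84"),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols, cell %g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g] (%s)\n",
              x$west, x$west + x$n_cols * x$cell_size,
              x$north - x$n_rows * x$cell_size, x$north, x$crs))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d grid, cell %g deg, origin (%g W, %g N)",
          x$n_rows, x$n_cols, x$cell_size, x$west, x$north)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$n_rows, b$n_rows)) && isTRUE(all.equal(a$n_cols, b$n_cols)) &&
    abs(a$west - b$west) < 1e-9 && abs(a$north - b$north) < 1e-9 &&
    abs(a$cell_size - b$cell_size) < 1e-12
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Optional row/column indices (recycled together); if omitted
#'   all cells are returned in column-major matrix order.
#' @return A data frame with columns `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(spec, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    idx <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
    rows <- idx$row; cols <- idx$col
  }
  data.frame(
    row = rows, col = cols,
    lon = spec$west + (cols - 0.5) * spec$cell_size,
    lat = spec$north - (rows - 0.5) * spec$cell_size
  )
}

#' Map coordinates to grid cells
#'
#' Cells are half-open: a point on a cell's west/north edge belongs to that
#' cell. Points outside the grid map to `NA`.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Coordinate vectors, decimal degrees.
#' @return A data frame with columns `row`, `col` (`NA` when off-grid).
#' @export
cell_index <- function(spec, lon, lat) {
  col <- floor((lon - spec$west) / spec$cell_size) + 1
  row <- floor((spec$north - lat) / spec$cell_size) + 1
  # points exactly on the south/east boundary fall out of the half-open cells
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Assemble an environmental stack
#'
#' An `env_stack` is a named set of co-registered environmental layers on a
#' shared [grid_spec()], with a common missing-data mask. Layers are stored as
#' `n_rows x n_cols` numeric matrices.
#'
#' @param spec A [grid_spec()].
#' @param layers Named list of numeric matrices with `dim = c(n_rows, n_cols)`.
#' @param mask Optional logical matrix, `TRUE` where data are valid. Cells that
#'   are `NA` in any layer are always treated as missing.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(spec, layers, mask = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(layers) == 0L) stop("at least one layer is required")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layers must have unique non-empty names")
  }
  for (l in layers) {
    if (!is.matrix(l) || !all(dim(l) == c(spec$n_rows, spec$n_cols))) {
      stop("every layer must be an n_rows x n_cols matrix")
    }
  }
  layers <- lapply(layers, function(l) {
    storage.mode(l) <- "double"
    l
  })
  if (is.null(mask)) {
    mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
  }
  stopifnot(is.logical(mask), all(dim(mask) == c(spec$n_rows, spec$n_cols)))
  for (l in layers) mask <- mask & !is.na(l)
  structure(list(spec = spec, layers = layers, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s) on %s\n",
              length(x$layers), format(x$spec)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

n_valid_cells <- function(stack) sum(stack$mask)

#' Extract layer values at grid cells
#'
#' @param stack An [env_stack()].
#' @param rows,cols Cell indices.
#' @param variables Layer names to extract (default all).
#' @return Numeric matrix, one row per cell, one column per variable; masked
#'   cells yield `NA`.
#' @export
extract_cells <- function(stack, rows, cols, variables = names(stack$layers)) {
  miss <- setdiff(variables, names(stack$layers))
  if (length(miss)) stop("unknown layer(s): ", paste(miss, collapse = ", "))
  idx <- cbind(rows, cols)
  out <- vapply(variables, function(v) {
    val <- stack$layers[[v]][idx]
    val[!stack$mask[idx]] <- NA_real_
    val
  }, numeric(length(rows)))
  if (length(rows) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, variables))
  out
}

#' Values of all valid cells as a matrix
#'
#' @param stack An [env_stack()].
#' @param variables Layer names (default all).
#' @return List with `values` (matrix, valid cells x variables), `rows`, `cols`
#'   (the cell indices, in column-major order of the grid).
#' @export
stack_values <- function(stack, variables = names(stack$layers)) {
  keep <- which(stack$mask)
  rows <- ((keep - 1L) %% stack$spec$n_rows) + 1L
  cols <- ((keep - 1L) %/% stack$spec$n_rows) + 1L
  vals <- vapply(variables, function(v) stack$layers[[v]][keep],
                 numeric(length(keep)))
  if (length(keep) == 1L) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, variables))
  list(values = vals, rows = rows, cols = cols)
}

# ---- ESRI ASCII grid I/O --------------------------------------------------
# Plain-text raster interchange (the format Maxent itself consumes); one file
# per layer. NODATA cells encode the mask.

#' Write a layer as an ESRI ASCII grid
#'
#' @param mat Numeric matrix (rows north to south).
#' @param spec The [grid_spec()] of the matrix.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(mat, spec, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$west),
    sprintf("yllcorner %.10g", spec$north - spec$n_rows * spec$cell_size),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `mat` (numeric matrix, `NA` for NODATA) and `spec`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  spec <- grid_spec(h[["nrows"]], h[["ncols"]],
                    west = h[["xllcorner"]],
                    north = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
                    cell_size = h[["cellsize"]])
  vals <- scan(path, skip = 6L, quiet = TRUE)
  mat <- matrix(vals, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  if ("nodata_value" %in% names(h)) mat[mat == h[["nodata_value"]]] <- NA_real_
  list(mat = mat, spec = spec)
}

#' Write an environmental stack to a directory
#'
#' One ASCII grid per layer plus a `manifest.csv` (columns layer, file,
#' scenario, period).
#'
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @param scenario,period Labels recorded in the manifest.
#' @return The manifest data frame, invisibly.
#' @export
write_stack <- function(stack, dir, scenario = "current", period = "current") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (v in names(stack$layers)) {
    m <- stack$layers[[v]]
    m[!stack$mask] <- NA_real_
    f <- file.path(dir, paste0(v, ".asc"))
    write_asc(m, stack$spec, f)
    files <- c(files, basename(f))
  }
  manifest <- data.frame(layer = names(stack$layers), file = files,
                         scenario = scenario, period = period)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an environmental stack written by [write_stack()]
#'
#' @param dir Directory holding `manifest.csv` and the `.asc` layers.
#' @return An [env_stack()].
#' @export
read_stack <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  layers <- list()
  spec <- NULL
  for (i in seq_len(nrow(manifest))) {
    g <- read_asc(file.path(dir, manifest$file[i]))
    if (is.null(spec)) spec <- g$spec
    else if (!grids_identical(spec, g$spec)) stop("layers are not co-registered")
    layers[[manifest$layer[i]]] <- g$mat
  }
  env_stack(spec, layers)
}
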