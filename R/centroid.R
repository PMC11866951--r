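#' Centroid of the suitable area
#'
#' Area-weighted mean of suitable-cell centers (weights are spherical cell
#' areas; in weighted mode, cell area times suitability). Longitudes are
#' averaged as unit vectors (atan2 of the weighted sine/cosine sums) so the
#' centroid respects the antimeridian; latitude is the weighted arithmetic
#' mean of cell-center latitudes.
#'
#' @param map A `suitability_map`.
#' @param threshold Suitability threshold defining the suitable set
#'   (default 0.30).
#' @param weighted If `TRUE`, weight cells by suitability as well as area.
#' @return Named numeric `c(lon, lat)` in decimal degrees.
#' @export
centroid <- function(map, threshold = 0.30, weighted = FALSE) {
  ok <- map$mask & !is.na(map$mat) & map$mat >= threshold
  if (!any(ok)) stop("no suitable cells at threshold ", threshold)
  idx <- which(ok, arr.ind = TRUE)
  cc <- cell_centers(map$spec, idx[, 1], idx[, 2])
  w <- cell_areas(map$spec)[idx[, 1]]
  if (weighted) w <- w * map$mat[ok]
  lam <- cc$lon * pi / 180
  lon <- atan2(sum(w * sin(lam)), sum(w * cos(lam))) * 180 / pi
  lat <- sum(w * cc$lat) / sum(w)
  c(lon = lon, lat = lat)
}

earth_radius_km <- 6371.0088

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance in km on a sphere of radius 6371.0088 km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * earth_radius_km * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in degrees clockwise from north, in `[0, 360)`; `NA` for
#'   coincident points.
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlon <- (lon2 - lon1) * to_rad
  y <- sin(dlon) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
  b <- atan2(y, x) * 180 / pi
  b <- (b + 360) %% 360
  b[lon1 == lon2 & lat1 == lat2] <- NA_real_
  b
}

#' Centroid migration track
#'
#' Given an ordered set of centroids (the reference period first), computes
#' each point's great-circle distance and initial bearing from the reference
#' point, and from the previous point in the track.
#'
#' @param points Data frame (or matrix) with columns `lon`, `lat` and
#'   optionally `label`; at least two rows, the first being the reference
#'   ("current") centroid.
#' @return A `centroid_track` data frame: `label`, `lon`, `lat`,
#'   `dist_from_current_km`, `bearing_from_current_deg`, `dist_step_km`,
#'   `bearing_step_deg`.
#' @export
migration <- function(points) {
  pts <- as.data.frame(points)
  if (nrow(pts) < 2L) stop("need at least 2 track points")
  if (is.null(pts$label)) pts$label <- c("current", paste0("step", seq_len(nrow(pts) - 1)))
  out <- data.frame(
    label = pts$label, lon = pts$lon, lat = pts$lat,
    dist_from_current_km = haversine_km(pts$lon[1], pts$lat[1], pts$lon, pts$lat),
    bearing_from_current_deg = bearing_deg(pts$lon[1], pts$lat[1], pts$lon, pts$lat),
    dist_step_km = c(NA, haversine_km(pts$lon[-nrow(pts)], pts$lat[-nrow(pts)],
                                      pts$lon[-1], pts$lat[-1])),
    bearing_step_deg = c(NA, bearing_deg(pts$lon[-nrow(pts)], pts$lat[-nrow(pts)],
                                         pts$lon[-1], pts$lat[-1]))
  )
  class(out) <- c("centroid_track", "data.frame")
  out
}

#' @export
print.centroid_track <- function(x, ...) {
  y <- as.data.frame(x)
  y$lon <- round(y$lon, 4); y$lat <- round(y$lat, 4)
  y$dist_from_current_km <- round(y$dist_from_current_km, 2)
  y$bearing_from_current_deg <- round(y$bearing_from_current_deg, 1)
  y$dist_step_km <- round(y$dist_step_km, 2)
  y$bearing_step_deg <- round(y$bearing_step_deg, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
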