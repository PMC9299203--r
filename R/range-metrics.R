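#' Area of occupancy on the standard grid
#'
#' AOO is the summed area of occupied grid cells, with the IUCN-recommended
#' 2 x 2 km (4 km^2) cell: each occupied vent field contributes the 4 km^2
#' cell it falls in, and multiple fields within one cell count once. Because
#' individual vent fields are far smaller than a cell, this is equivalent to
#' placing a 4 km^2 buffer around each field and summing.
#'
#' Sites are projected to a local equirectangular plane centred on the
#' species' coordinate centroid, and snapped to a grid anchored so that a
#' cell centre sits at the projection origin (cell edges at half-integer
#' multiples of `cell_km`). The anchoring is deterministic for a given set
#' of records, and centring a cell on the centroid avoids the artefact of a
#' close pair of sites straddling a cell edge through their own midpoint.
#'
#' @param fields A [vent_fields()] table.
#' @param config A [geo_config()].
#' @return AOO in km^2: number of distinct occupied cells times `cell_km^2`.
#' @examples
#' f <- vent_fields(c("a", "b"), lat = c(0, 0.001), lon = c(0, 0.001),
#'                  management_area_id = "x")
#' compute_aoo(f)  # same cell: 4 km^2
#' @export
compute_aoo <- function(fields, config = geo_config()) {
  fields <- validate_vent_fields(fields)
  xy <- project_equirectangular(fields$lat, fields$lon, config)
  cells <- unique(paste(floor(xy[, "x"] / config$cell_km + 0.5),
                        floor(xy[, "y"] / config$cell_km + 0.5)))
  length(cells) * config$cell_km^2
}

#' Extent of occurrence (minimum convex polygon)
#'
#' EOO is the area of the minimum convex polygon enclosing all known
#' occurrences; it measures the spatial spread of extinction risk. Site
#' coordinates are projected into a Lambert azimuthal equal-area plane
#' centred on their centroid (longitudes re-centred first, so ranges
#' spanning the antimeridian are handled), the convex hull is taken, and
#' its planar (shoelace) area is returned.
#'
#' Following standard IUCN guidance, an EOO smaller than the AOO — including
#' the degenerate single-site and collinear cases, whose hull area is
#' zero — is floored to the AOO.
#'
#' @param fields A [vent_fields()] table.
#' @param aoo_km2 The species' AOO in km^2 (the floor); computed via
#'   [compute_aoo()] if not supplied.
#' @param config A [geo_config()].
#' @return EOO in km^2, always >= `aoo_km2`.
#' @export
compute_eoo <- function(fields, aoo_km2 = compute_aoo(fields, config),
                        config = geo_config()) {
  fields <- validate_vent_fields(fields)
  xy <- unique(project_equal_area(fields$lat, fields$lon, config))
  area <- 0
  if (nrow(xy) >= 3) {
    hull <- grDevices::chull(xy[, 1], xy[, 2])
    area <- shoelace_area(xy[hull, , drop = FALSE])
  }
  max(area, aoo_km2)
}

#' Range metrics for an assessment
#'
#' Bundles the four geographic-range quantities that criteria B and D2
#' consume: number of occurrence sites, number of IUCN locations, AOO and
#' EOO.
#'
#' @param fields A [vent_fields()] table.
#' @param config A [geo_config()].
#' @param locations Optionally, a precomputed [cluster_locations()] result.
#' @param eoo_km2 Optionally, an externally supplied EOO in km^2 (for
#'   example a published estimate); when given it overrides the value
#'   recomputed from coordinates, but is still floored at the AOO.
#' @return An object of class `range_metrics`: list with `n_fields`,
#'   `n_locations`, `aoo_km2`, `eoo_km2`.
#' @examples
#' f <- vent_fields("only", lat = -37.78, lon = 49.65,
#'                  management_area_id = "ISA_COMRA")
#' compute_range_metrics(f)
#' @export
compute_range_metrics <- function(fields, config = geo_config(),
                                  locations = NULL, eoo_km2 = NULL) {
  fields <- validate_vent_fields(fields)
  if (is.null(locations)) locations <- cluster_locations(fields, config)
  aoo <- compute_aoo(fields, config)
  eoo <- if (is.null(eoo_km2)) {
    compute_eoo(fields, aoo, config)
  } else {
    max(as.numeric(eoo_km2), aoo)
  }
  structure(list(n_fields = nrow(fields),
                 n_locations = n_locations(locations),
                 aoo_km2 = aoo,
                 eoo_km2 = eoo),
            class = "range_metrics")
}

#' @export
print.range_metrics <- function(x, ...) {
  cat(sprintf(
    "Range metrics: %d field(s), %d location(s), AOO %.6g km^2, EOO %.6g km^2\n",
    x$n_fields, x$n_locations, x$aoo_km2, x$eoo_km2))
  invisible(x)
}
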