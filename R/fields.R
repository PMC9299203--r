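#' Construct a table of occurrence sites (vent fields)
#'
#' The basic spatial unit of an assessment is an occurrence site: for
#' hydrothermal-vent species, a vent field (individual fields are
#' consistently < 0.1 km^2, so sites are represented as points). Each site
#' belongs to exactly one management area, the unit over which a single
#' regulatory regime applies.
#'
#' @param site_id Character; unique site identifiers.
#' @param lat,lon Numeric; site centroid in decimal degrees WGS84.
#' @param management_area_id Character; key into a regime table.
#' @param name Character; free-text site names (optional).
#' @param species_id Character; species the records belong to (optional,
#'   single species per table).
#' @param footprint_km2 Optional positive numeric; informational site area.
#' @return A `data.frame` of class `vent_fields` with one row per site.
#' @examples
#' vent_fields(c("a", "b"), lat = c(-3.7, -3.2), lon = c(151.7, 150.3),
#'             management_area_id = "EEZ_PNG")
#' @export
vent_fields <- function(site_id, lat, lon, management_area_id,
                        name = site_id, species_id = NA_character_,
                        footprint_km2 = NA_real_) {
  df <- data.frame(site_id = as.character(site_id),
                   name = as.character(name),
                   lat = as.numeric(lat),
                   lon = as.numeric(lon),
                   management_area_id = as.character(management_area_id),
                   species_id = as.character(species_id),
                   footprint_km2 = as.numeric(footprint_km2),
                   stringsAsFactors = FALSE)
  validate_vent_fields(df)
}

#' Validate an occurrence table
#'
#' Checks coordinate bounds, uniqueness of site ids, presence of management
#' areas and positivity of optional footprints. Called by all range
#' operations; errors name the offending field and row.
#'
#' @param fields A data.frame with at least columns `site_id`, `lat`, `lon`,
#'   `management_area_id`.
#' @return The validated table, classed `vent_fields`, invisibly usable
#'   downstream.
#' @export
validate_vent_fields <- function(fields) {
  if (!is.data.frame(fields) || nrow(fields) == 0) {
    stop("no occurrence records", call. = FALSE)
  }
  need <- c("site_id", "lat", "lon", "management_area_id")
  miss <- setdiff(need, names(fields))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(fields$lat) | fields$lat < -90 | fields$lat > 90)
  if (length(bad)) {
    stop("invalid `lat` at row(s) ", paste(bad, collapse = ", "),
         ": must be in [-90, 90]", call. = FALSE)
  }
  bad <- which(!is.finite(fields$lon) | fields$lon < -180 | fields$lon >= 180)
  if (length(bad)) {
    stop("invalid `lon` at row(s) ", paste(bad, collapse = ", "),
         ": must be in [-180, 180)", call. = FALSE)
  }
  if (anyDuplicated(fields$site_id)) {
    dup <- unique(fields$site_id[duplicated(fields$site_id)])
    stop("duplicate `site_id`: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(fields$management_area_id) | fields$management_area_id == "")) {
    stop("every site requires a `management_area_id`", call. = FALSE)
  }
  if ("footprint_km2" %in% names(fields)) {
    fp <- fields$footprint_km2
    bad <- which(!is.na(fp) & fp <= 0)
    if (length(bad)) {
      stop("invalid `footprint_km2` at row(s) ", paste(bad, collapse = ", "),
           ": must be > 0", call. = FALSE)
    }
  }
  class(fields) <- unique(c("vent_fields", class(fields)))
  fields
}
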