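#' Regulatory regimes for management areas
#'
#' The threat state of a species is derived from the seabed-mining
#' regulatory regime of each management area its locations fall in. Four
#' regimes are recognised, in increasing severity:
#'
#' * `PROTECTED_EFFECTIVE` — effective protection from mining: an MPA with
#'   specific legislation preventing seabed mining, treaty protection, or an
#'   *enacted* mining moratorium. A merely proposed moratorium, or a generic
#'   MPA without a mining ban, does not qualify.
#' * `UNPROTECTED_NO_LICENSE` — a jurisdiction without a moratorium in which
#'   no mining license has been granted. Mining is plausible but not under
#'   way or contracted.
#' * `EXPLORATION_LICENSE` — an exploratory mining contract has been signed
#'   (e.g. by the ISA, or within an EEZ). Exploration contracts allow
#'   experimental extraction and testing, so activity may already have had
#'   an effect: a projected continuing decline.
#' * `ACTIVE_MINING` — commercial extraction under way; destroys all local
#'   habitat.
#'
#' @format `REGIMES` is a character vector of the four regime tokens in
#'   severity order.
#' @export
REGIMES <- c("PROTECTED_EFFECTIVE", "UNPROTECTED_NO_LICENSE",
             "EXPLORATION_LICENSE", "ACTIVE_MINING")

#' Construct a regime table
#'
#' @param management_area_id Character; management area identifiers.
#' @param regime Character; one of [REGIMES] per area.
#' @param jurisdiction Character; free text, e.g. `"ISA"`, `"EEZ:Fiji"`, or
#'   a treaty/MPA name. Optional.
#' @param notes Character; free text. Optional.
#' @return A `data.frame` of class `regime_table`.
#' @examples
#' regime_table(c("ISA_COMRA", "SGSSI"),
#'              c("EXPLORATION_LICENSE", "PROTECTED_EFFECTIVE"))
#' @export
regime_table <- function(management_area_id, regime,
                         jurisdiction = NA_character_,
                         notes = NA_character_) {
  df <- data.frame(management_area_id = as.character(management_area_id),
                   regime = as.character(regime),
                   jurisdiction = as.character(jurisdiction),
                   notes = as.character(notes),
                   stringsAsFactors = FALSE)
  validate_regime_table(df)
}

#' @rdname regime_table
#' @param regimes A data.frame with columns `management_area_id`, `regime`.
#' @export
validate_regime_table <- function(regimes) {
  need <- c("management_area_id", "regime")
  miss <- setdiff(need, names(regimes))
  if (length(miss)) {
    stop("regime table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(regimes$regime), REGIMES)
  if (length(bad)) {
    stop("unknown regime token(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(REGIMES, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(regimes$management_area_id)) {
    dup <- unique(
      regimes$management_area_id[duplicated(regimes$management_area_id)])
    stop("management area(s) mapped to more than one regime: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  class(regimes) <- unique(c("regime_table", class(regimes)))
  regimes
}

# internal: severity rank of a regime vector (1 = protected .. 4 = active)
regime_severity <- function(regime) match(regime, REGIMES)

#' Regime of a location
#'
#' All member sites of a location share one management area by
#' construction, so a location's regime is that area's regime.
#'
#' @param location_id A location id present in `locations`.
#' @param locations A `vent_locations` table from [cluster_locations()].
#' @param regimes A [regime_table()].
#' @return A single regime token.
#' @export
regime_of_location <- function(location_id, locations, regimes) {
  regimes <- validate_regime_table(regimes)
  areas <- location_areas(locations)
  if (!location_id %in% names(areas)) {
    stop("unknown location_id: ", location_id, call. = FALSE)
  }
  area <- areas[[location_id]]
  i <- match(area, regimes$management_area_id)
  if (is.na(i)) {
    stop("management_area_id not present in regime table: ", area,
         call. = FALSE)
  }
  regimes$regime[i]
}

# internal: regime token per location, named by location_id
location_regimes <- function(locations, regimes) {
  regimes <- validate_regime_table(regimes)
  areas <- location_areas(locations)
  i <- match(areas, regimes$management_area_id)
  if (anyNA(i)) {
    stop("management_area_id not present in regime table: ",
         paste(unique(areas[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(regimes$regime[i], names(areas))
}

#' Derive threat flags from location regimes
#'
#' Maps regulatory regimes onto the IUCN concepts the criteria consume:
#'
#' * *continuing decline* (observed or projected, here in habitat extent and
#'   quality) holds iff any location is under an exploration license or
#'   active mining;
#' * a *plausible future threat* holds iff any location is not effectively
#'   protected;
#' * `all_range_destroyed` flags commercial mining under way at every
#'   location — the trigger for the "possibly extinct" tag.
#'
#' Effective protection at every location means neither a continuing
#' decline nor a plausible threat is present.
#'
#' @param locations A `vent_locations` table from [cluster_locations()].
#' @param regimes A [regime_table()].
#' @return An object of class `threat_summary`: list with logical
#'   `continuing_decline`, `plausible_future_threat`, `all_range_destroyed`,
#'   integer `n_threatened_locations`, `n_protected_locations`, and the
#'   per-location regime vector `location_regimes`.
#' @examples
#' f <- vent_fields("only", lat = -37.78, lon = 49.65,
#'                  management_area_id = "ISA_COMRA")
#' locs <- cluster_locations(f)
#' derive_threat_summary(locs, regime_table("ISA_COMRA", "EXPLORATION_LICENSE"))
#' @export
derive_threat_summary <- function(locations, regimes) {
  lr <- location_regimes(locations, regimes)
  if (length(lr) == 0) stop("no locations", call. = FALSE)
  threatened <- lr != "PROTECTED_EFFECTIVE"
  declining <- lr %in% c("EXPLORATION_LICENSE", "ACTIVE_MINING")
  structure(list(
    continuing_decline = any(declining),
    plausible_future_threat = any(threatened),
    n_threatened_locations = sum(threatened),
    n_protected_locations = sum(!threatened),
    all_range_destroyed = all(lr == "ACTIVE_MINING"),
    location_regimes = lr
  ), class = "threat_summary")
}

#' @export
print.threat_summary <- function(x, ...) {
  cat(sprintf(
    "Threat: decline=%s, plausible=%s, %d threatened / %d protected location(s)%s\n",
    x$continuing_decline, x$plausible_future_threat,
    x$n_threatened_locations, x$n_protected_locations,
    if (x$all_range_destroyed) ", ENTIRE RANGE UNDER ACTIVE MINING" else ""))
  invisible(x)
}
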