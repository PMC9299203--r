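#' Define a regulatory-change scenario
#'
#' A scenario overrides the regime of named management areas — for example
#' "the MPA is dissolved and mining rights granted", or "a regional mining
#' moratorium is enacted" — so that the resulting shift in Red List
#' category can be examined.
#'
#' @param name Short scenario name.
#' @param overrides Named character vector or list: management_area_id ->
#'   regime token (one of [REGIMES]).
#' @param description Free text.
#' @return An object of class `regime_scenario`.
#' @examples
#' regime_scenario("mining rights granted",
#'                 c(SGSSI = "EXPLORATION_LICENSE"))
#' @export
regime_scenario <- function(name, overrides, description = "") {
  overrides <- unlist(overrides)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides))))) {
    stop("scenario overrides must be named by management_area_id",
         call. = FALSE)
  }
  bad <- setdiff(unique(overrides), REGIMES)
  if (length(bad)) {
    stop("unknown regime token(s) in scenario: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, overrides = overrides,
                 description = description),
            class = "regime_scenario")
}

# internal: apply overrides to a regime table
override_regimes <- function(regimes, scenario) {
  regimes <- validate_regime_table(regimes)
  unknown <- setdiff(names(scenario$overrides), regimes$management_area_id)
  if (length(unknown)) {
    stop("scenario overrides unknown management_area_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  i <- match(names(scenario$overrides), regimes$management_area_id)
  regimes$regime[i] <- unname(scenario$overrides)
  regimes
}

#' Re-assess a species under a regulatory scenario
#'
#' Recomputes the threat summary and Red List category with the scenario's
#' regime overrides applied, and reports the before/after transition.
#' Downlisting transitions (category decreasing) are flagged for the
#' five-year rule — a species may only move to a lower category once none
#' of the higher category's criteria has been met for five years — but the
#' engine never suppresses the computed category: the flag is metadata for
#' the assessor.
#'
#' @param fields A [vent_fields()] table for one species.
#' @param regimes A [regime_table()].
#' @param scenario A [regime_scenario()].
#' @param config A [geo_config()].
#' @param thresholds A [threshold_table()].
#' @param eoo_km2 Optional published EOO override, as in [assess_species()].
#' @return An object of class `scenario_transition`: list with `scenario`,
#'   `before` and `after` assessments, `category_before`, `category_after`,
#'   `direction` (`"uplisting"`, `"downlisting"`, `"unchanged"`), and
#'   `downlisting_deferred` (TRUE for downlisting transitions, which await
#'   the five-year rule).
#' @export
apply_scenario <- function(fields, regimes, scenario,
                           config = geo_config(),
                           thresholds = threshold_table(),
                           eoo_km2 = NULL) {
  before <- assess_species(fields, regimes, config, thresholds, eoo_km2)
  after <- assess_species(fields, override_regimes(regimes, scenario),
                          config, thresholds, eoo_km2)
  rb <- category_rank(before$category)
  ra <- category_rank(after$category)
  same_cat <- identical(before$category, after$category) &&
    identical(before$possibly_extinct, after$possibly_extinct)
  direction <- if (same_cat) {
    "unchanged"
  } else if (!is.na(rb) && !is.na(ra) && ra < rb) {
    "downlisting"
  } else {
    "uplisting"
  }
  structure(list(
    scenario = scenario,
    before = before, after = after,
    category_before = before$category,
    category_after = after$category,
    direction = direction,
    downlisting_deferred = identical(direction, "downlisting")
  ), class = "scenario_transition")
}

#' @export
print.scenario_transition <- function(x, ...) {
  tag <- function(a) paste0(a$category,
                            if (a$possibly_extinct) " (possibly extinct)" else "")
  cat(sprintf("Scenario '%s': %s -> %s [%s]%s\n", x$scenario$name,
              tag(x$before), tag(x$after), x$direction,
              if (x$downlisting_deferred)
                " (downlisting deferred: 5-year rule)" else ""))
  invisible(x)
}

#' Worst-case category for a species
#'
#' The category the species would receive were every one of its locations
#' put under an exploratory mining license (continuing decline and plausible
#' threat everywhere). Used by criterion D2 to decide whether a plausible
#' threat could "rapidly lead to CR or EX" (D2 fires only when the worst
#' case is CR), and reported to assessors as context.
#'
#' @inheritParams assess_species
#' @return A category string.
#' @export
worst_case_category <- function(fields, config = geo_config(),
                                thresholds = threshold_table(),
                                eoo_km2 = NULL) {
  fields <- validate_vent_fields(fields)
  metrics <- compute_range_metrics(fields, config, eoo_km2 = eoo_km2)
  category_under_full_license(metrics, thresholds)
}
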