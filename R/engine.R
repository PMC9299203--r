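#' Red List categories in increasing risk order
#'
#' @format Character vector `LC`, `NT`, `VU`, `EN`, `CR`. `DD` (data
#'   deficient) sits outside the ordered scale and is emitted only for empty
#'   occurrence sets.
#' @export
CATEGORIES <- c("LC", "NT", "VU", "EN", "CR")

# internal: rank on the ordered risk scale (DD -> NA)
category_rank <- function(category) match(category, CATEGORIES)

#' Quantitative thresholds for criteria B and D2
#'
#' The tier bounds of the IUCN Red List categories and criteria (version
#' 3.1, second edition): criterion B1 EOO bounds, B2 AOO bounds and the
#' shared location-count bounds for CR/EN/VU, plus the criterion D2 bounds
#' (AOO < 20 km^2 or at most 5 locations). They are exposed as
#' configuration rather than hard-coded so that a non-standard scheme can
#' be swapped in, but the defaults are the standard to which published
#' assessments adhere.
#'
#' @param b1_eoo_km2 Named numeric, EOO upper bounds (exclusive) for
#'   `cr`/`en`/`vu` under B1.
#' @param b2_aoo_km2 Named numeric, AOO upper bounds (exclusive) under B2.
#' @param max_locations Named numeric, location-count upper bounds
#'   (inclusive) for condition "a".
#' @param d2_aoo_km2 D2 AOO bound (exclusive).
#' @param d2_max_locations D2 location bound (inclusive).
#' @return An object of class `threshold_table`.
#' @examples
#' threshold_table()$b1_eoo_km2
#' @export
threshold_table <- function(
    b1_eoo_km2 = c(cr = 100, en = 5000, vu = 20000),
    b2_aoo_km2 = c(cr = 10, en = 500, vu = 2000),
    max_locations = c(cr = 1, en = 5, vu = 10),
    d2_aoo_km2 = 20,
    d2_max_locations = 5) {
  for (v in list(b1_eoo_km2, b2_aoo_km2, max_locations)) {
    if (!all(c("cr", "en", "vu") %in% names(v))) {
      stop("tier bounds need named elements cr, en, vu", call. = FALSE)
    }
    if (any(v <= 0) || any(diff(v[c("cr", "en", "vu")]) <= 0)) {
      stop("tier bounds must be positive and strictly increasing CR -> VU",
           call. = FALSE)
    }
  }
  structure(list(b1_eoo_km2 = b1_eoo_km2, b2_aoo_km2 = b2_aoo_km2,
                 max_locations = max_locations, d2_aoo_km2 = d2_aoo_km2,
                 d2_max_locations = d2_max_locations),
            class = "threshold_table")
}

# internal: result record for a single criterion
criterion_result <- function(criterion, tier, conditions = character(0)) {
  structure(list(criterion = criterion, tier = tier,
                 satisfied_conditions = conditions),
            class = "criterion_result")
}

#' Evaluate criterion B (geographic range)
#'
#' A tier (CR, EN or VU) fires under B1 when the EOO is below that tier's
#' bound, *and* the species occurs at no more locations than the tier allows
#' (condition a), *and* a continuing decline in habitat extent or quality is
#' observed or projected (condition b(iii)). B2 is identical with AOO in
#' place of EOO. A threatened listing under criterion B requires two of the
#' three conditions a/b/c; extreme fluctuations (condition c) are not
#' relevant for vent molluscs, so both a and b must hold. The highest tier
#' whose conditions all hold is reported.
#'
#' @param metrics A [compute_range_metrics()] result.
#' @param threat A [derive_threat_summary()] result.
#' @param thresholds A [threshold_table()].
#' @return List with elements `b1` and `b2`, each a `criterion_result` with
#'   `tier` in `CR`/`EN`/`VU`/`none` and the satisfied condition codes.
#' @export
evaluate_criterion_b <- function(metrics, threat,
                                 thresholds = threshold_table()) {
  eval_one <- function(criterion, value, bounds) {
    for (tier in c("cr", "en", "vu")) {
      size_ok <- value < bounds[[tier]]
      cond_a <- metrics$n_locations <= thresholds$max_locations[[tier]]
      cond_b <- isTRUE(threat$continuing_decline)
      if (size_ok && cond_a && cond_b) {
        return(criterion_result(
          criterion, toupper(tier),
          c(sprintf("a: n_locations=%d", metrics$n_locations),
            "b(iii): projected decline in extent/quality of habitat")))
      }
    }
    criterion_result(criterion, "none")
  }
  list(b1 = eval_one("B1", metrics$eoo_km2, thresholds$b1_eoo_km2),
       b2 = eval_one("B2", metrics$aoo_km2, thresholds$b2_aoo_km2))
}

#' Evaluate criterion D2 (very restricted population)
#'
#' D2 lists a species as VU when its range is very restricted (AOO below
#' 20 km^2 or at most 5 locations) *and* a plausible future threat exists
#' that, if realised, would rapidly drive the species to CR or extinction.
#' The "rapidly CR" clause is operationalised through the worst-case
#' category: the category the species would receive were every location
#' licensed for mining (see [worst_case_category()]). A near-miss in which
#' the worst case is EN does not fire D2; it is picked up downstream as NT.
#'
#' @param metrics A [compute_range_metrics()] result.
#' @param threat A [derive_threat_summary()] result.
#' @param thresholds A [threshold_table()].
#' @param worst_case Category under the all-locations-licensed scenario.
#' @return A `criterion_result` with tier `VU` or `none`.
#' @export
evaluate_criterion_d2 <- function(metrics, threat,
                                  thresholds = threshold_table(),
                                  worst_case) {
  restricted <- metrics$aoo_km2 < thresholds$d2_aoo_km2 ||
    metrics$n_locations <= thresholds$d2_max_locations
  if (restricted && isTRUE(threat$plausible_future_threat) &&
      identical(worst_case, "CR")) {
    criterion_result("D2", "VU", c(
      sprintf("restricted: AOO=%g km^2, n_locations=%d",
              metrics$aoo_km2, metrics$n_locations),
      "plausible future threat could rapidly lead to CR or EX"))
  } else {
    criterion_result("D2", "none")
  }
}

# internal: canonical IUCN criteria string for the assigned category.
# Only criteria that fired at the category's tier are listed; B1 and B2
# with identical condition sets merge as "B1ab(iii)+2ab(iii)"; D2 is
# appended after a semicolon.
build_criteria_string <- function(category, b1, b2, d2) {
  if (!category %in% c("VU", "EN", "CR")) return("")
  parts <- character(0)
  b_at <- function(r) identical(r$tier, category)
  if (b_at(b1) && b_at(b2)) {
    parts <- c(parts, "B1ab(iii)+2ab(iii)")
  } else if (b_at(b1)) {
    parts <- c(parts, "B1ab(iii)")
  } else if (b_at(b2)) {
    parts <- c(parts, "B2ab(iii)")
  }
  if (identical(d2$tier, category)) parts <- c(parts, "D2")
  paste(parts, collapse = "; ")
}

#' Assign the Red List category
#'
#' Combines the criterion results into a final assessment. The category is
#' the highest tier reached by B1, B2 or D2. When no tier fires, the
#' species is LC if no plausible threat exists anywhere in its range
#' (effective protection throughout), and NT otherwise — this covers both
#' mixed protected/unprotected ranges and near-misses where a plausible
#' threat could rapidly lead to an EN (but not CR) listing.
#'
#' Commercial mining under way across the entire known range forces CR with
#' the *possibly extinct* tag, reflecting that destruction of all local
#' habitat likely extirpates a vent-endemic species before reassessment is
#' possible.
#'
#' @param b1,b2 `criterion_result`s from [evaluate_criterion_b()].
#' @param d2 A `criterion_result` from [evaluate_criterion_d2()].
#' @param threat A [derive_threat_summary()] result.
#' @param worst_case Category under the all-locations-licensed scenario.
#' @param metrics Optional [compute_range_metrics()] result, carried into
#'   the assessment record.
#' @param species_id Optional species identifier for the record.
#' @return An object of class `redlist_assessment`: list with `category`,
#'   `possibly_extinct`, `criteria_string`, `rationale` (character vector),
#'   `criteria` (the three results), `metrics`, `threat`, `worst_case`.
#' @export
assign_category <- function(b1, b2, d2, threat, worst_case,
                            metrics = NULL, species_id = NA_character_) {
  tiers <- c(b1$tier, b2$tier, d2$tier)
  ranks <- category_rank(tiers)  # none -> NA
  rationale <- character(0)
  if (any(!is.na(ranks))) {
    category <- CATEGORIES[max(ranks, na.rm = TRUE)]
    for (r in list(b1, b2, d2)) {
      if (!identical(r$tier, "none")) {
        rationale <- c(rationale, sprintf(
          "%s met at %s: %s", r$criterion, r$tier,
          paste(r$satisfied_conditions, collapse = "; ")))
      }
    }
  } else if (!threat$plausible_future_threat) {
    category <- "LC"
    rationale <- "Effective protection from mining at every location: neither continuing decline nor plausible threat."
  } else {
    category <- "NT"
    rationale <- if (threat$n_protected_locations > 0) {
      "Mixed regimes: part of the range is protected, part exposed to a plausible mining threat; no criterion met at a threatened tier."
    } else {
      sprintf(
        "Plausible future mining threat across an unprotected range (worst case %s); no criterion met at a threatened tier.",
        worst_case)
    }
  }
  possibly_extinct <- FALSE
  if (isTRUE(threat$all_range_destroyed)) {
    if (!identical(category, "CR")) {
      rationale <- c(rationale,
        "Active commercial mining at every location: uplisted to CR.")
    }
    category <- "CR"
    possibly_extinct <- TRUE
    rationale <- c(rationale,
      "Tagged possibly extinct: ongoing extraction destroys all known habitat.")
  }
  structure(list(
    species_id = species_id,
    category = category,
    possibly_extinct = possibly_extinct,
    criteria_string = build_criteria_string(category, b1, b2, d2),
    rationale = rationale,
    criteria = list(b1 = b1, b2 = b2, d2 = d2),
    metrics = metrics,
    threat = threat,
    worst_case = worst_case
  ), class = "redlist_assessment")
}

# internal: category implied by metrics alone under universal licensing
# (continuing decline and plausible threat at every location). Shared by
# worst_case_category() and the D2 evaluation.
category_under_full_license <- function(metrics,
                                        thresholds = threshold_table()) {
  pseudo_threat <- structure(list(
    continuing_decline = TRUE, plausible_future_threat = TRUE,
    n_threatened_locations = metrics$n_locations,
    n_protected_locations = 0L, all_range_destroyed = FALSE,
    location_regimes = rep("EXPLORATION_LICENSE", metrics$n_locations)
  ), class = "threat_summary")
  b <- evaluate_criterion_b(metrics, pseudo_threat, thresholds)
  ranks <- category_rank(c(b$b1$tier, b$b2$tier))
  if (all(is.na(ranks))) "NT" else CATEGORIES[max(ranks, na.rm = TRUE)]
}

#' Assess one species end to end
#'
#' The main entry point: clusters the species' occurrence sites into
#' locations, computes range metrics, derives threat flags from the regime
#' table, evaluates criteria B1, B2 and D2, and assigns the category.
#'
#' @param fields A [vent_fields()] table for one species. An empty table (or
#'   `NULL`) yields a DD (data deficient) assessment.
#' @param regimes A [regime_table()] covering every referenced management
#'   area.
#' @param config A [geo_config()].
#' @param thresholds A [threshold_table()].
#' @param eoo_km2 Optional externally supplied EOO in km^2 (e.g. a published
#'   estimate) overriding the value recomputed from coordinates.
#' @return A `redlist_assessment` (see [assign_category()]).
#' @examples
#' f <- vent_fields("longqi", lat = -37.78, lon = 49.65,
#'                  management_area_id = "ISA_COMRA")
#' r <- regime_table("ISA_COMRA", "EXPLORATION_LICENSE")
#' assess_species(f, r)
#' @export
assess_species <- function(fields, regimes, config = geo_config(),
                           thresholds = threshold_table(), eoo_km2 = NULL) {
  if (is.null(fields) || nrow(fields) == 0) {
    return(structure(list(
      species_id = NA_character_, category = "DD", possibly_extinct = FALSE,
      criteria_string = "",
      rationale = "No occurrence records: data deficient.",
      criteria = NULL, metrics = NULL, threat = NULL, worst_case = NA
    ), class = "redlist_assessment"))
  }
  fields <- validate_vent_fields(fields)
  locations <- cluster_locations(fields, config)
  metrics <- compute_range_metrics(fields, config, locations, eoo_km2)
  threat <- derive_threat_summary(locations, regimes)
  worst_case <- category_under_full_license(metrics, thresholds)
  b <- evaluate_criterion_b(metrics, threat, thresholds)
  d2 <- evaluate_criterion_d2(metrics, threat, thresholds, worst_case)
  sp <- unique(fields$species_id)
  sp <- if (length(sp) == 1) sp else NA_character_
  assign_category(b$b1, b$b2, d2, threat, worst_case, metrics, sp)
}

#' @export
print.redlist_assessment <- function(x, ...) {
  tag <- if (x$possibly_extinct) " (possibly extinct)" else ""
  crit <- if (nzchar(x$criteria_string)) paste0(" ", x$criteria_string) else ""
  sp <- if (!is.na(x$species_id)) paste0(x$species_id, ": ") else ""
  cat(sprintf("%s%s%s%s\n", sp, x$category, tag, crit))
  if (!is.null(x$metrics)) print(x$metrics)
  if (!is.null(x$threat)) print(x$threat)
  for (r in x$rationale) cat(" -", r, "\n")
  invisible(x)
}
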