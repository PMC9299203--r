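#' Curated case-study fixtures
#'
#' Bundles of occurrence records, regime tables, a regulatory-change
#' scenario and the published Red List outcome for four vent-endemic
#' molluscs that exercise the full spread of threat contexts:
#'
#' * *Gigantopelta chessoia* — two East Scotia Ridge vent fields protected
#'   by the SGSSI MPA and the Antarctic Treaty; published LC. Scenario:
#'   protection removed and mining rights granted, shifting the species to
#'   EN.
#' * *Dracogyra subfusca* — a single Southwest Indian Ridge vent field
#'   (Longqi) inside an ISA exploration contract area; published CR.
#'   Scenario: exploitative mining commences, CR (possibly extinct).
#' * *Alviniconcha boucheti* — four southwestern Pacific vent fields in the
#'   EEZs of Papua New Guinea, Fiji and Tonga; published EN (mining license
#'   in PNG waters). Scenario: a regional mining moratorium is enacted,
#'   downlisting (deferred by the five-year rule) to LC.
#' * *Bathymodiolus manusensis* — three Manus Basin vent fields within
#'   80 km of each other, a single licensed location; published EN with
#'   AOO 12 km^2 and a published EOO of 171.23 km^2.
#'
#' Coordinates are approximate published vent-field positions encoded from
#' the assessments' cited localities (the assessments print no coordinate
#' tables); categories and site counts are the published values, while the
#' EOO carried for *B. manusensis* is the published 171.23 km^2 rather
#' than a value recomputed from the approximate coordinates.
#'
#' @return A named list of fixture bundles. Each bundle has `species`,
#'   `fields`, `regimes`, `expected_category`, `published_eoo_km2`
#'   (possibly `NA`), `scenario`, `expected_after` and
#'   `expected_after_possibly_extinct`.
#' @examples
#' fx <- case_study_fixtures()
#' assess_species(fx$g_chessoia$fields, fx$g_chessoia$regimes)$category
#' @export
case_study_fixtures <- function() {
  list(
    g_chessoia = list(
      species = "Gigantopelta chessoia",
      fields = vent_fields(
        site_id = c("E2", "E9"),
        name = c("East Scotia Ridge E2", "East Scotia Ridge E9"),
        lat = c(-56.089, -60.046), lon = c(-30.317, -29.984),
        management_area_id = c("SGSSI_MPA", "ANTARCTIC_TREATY"),
        species_id = "Gigantopelta chessoia"),
      regimes = regime_table(
        c("SGSSI_MPA", "ANTARCTIC_TREATY"),
        c("PROTECTED_EFFECTIVE", "PROTECTED_EFFECTIVE"),
        jurisdiction = c("SGSSI MPA", "Madrid Protocol, Antarctic Treaty")),
      expected_category = "LC",
      published_eoo_km2 = NA_real_,
      scenario = regime_scenario(
        "protection removed, mining rights granted",
        c(SGSSI_MPA = "EXPLORATION_LICENSE",
          ANTARCTIC_TREATY = "EXPLORATION_LICENSE"),
        "Worst case: MPA removed, treaty dissolved, licenses granted."),
      expected_after = "EN",
      expected_after_possibly_extinct = FALSE),

    d_subfusca = list(
      species = "Dracogyra subfusca",
      fields = vent_fields(
        site_id = "longqi",
        name = "Longqi vent field, Southwest Indian Ridge",
        lat = -37.78, lon = 49.65,
        management_area_id = "ISA_COMRA_SWIR",
        species_id = "Dracogyra subfusca"),
      regimes = regime_table("ISA_COMRA_SWIR", "EXPLORATION_LICENSE",
                             jurisdiction = "ISA"),
      expected_category = "CR",
      published_eoo_km2 = NA_real_,
      scenario = regime_scenario(
        "exploitative mining commences at Longqi",
        c(ISA_COMRA_SWIR = "ACTIVE_MINING"),
        "ISA allows exploitation; all known habitat removed."),
      expected_after = "CR",
      expected_after_possibly_extinct = TRUE),

    a_boucheti = list(
      species = "Alviniconcha boucheti",
      fields = vent_fields(
        site_id = c("manus", "nfiji", "abe", "mariner"),
        name = c("Manus Basin", "North Fiji Basin", "ABE, Lau Basin",
                 "Mariner, Lau Basin"),
        lat = c(-3.730, -16.990, -20.760, -22.180),
        lon = c(151.670, 173.920, -176.190, -176.570),
        management_area_id = c("EEZ_PNG", "EEZ_FIJI", "EEZ_TONGA",
                               "EEZ_TONGA"),
        species_id = "Alviniconcha boucheti"),
      regimes = regime_table(
        c("EEZ_PNG", "EEZ_FIJI", "EEZ_TONGA"),
        c("EXPLORATION_LICENSE", "UNPROTECTED_NO_LICENSE",
          "UNPROTECTED_NO_LICENSE"),
        jurisdiction = c("EEZ:Papua New Guinea", "EEZ:Fiji", "EEZ:Tonga")),
      expected_category = "EN",
      published_eoo_km2 = NA_real_,
      scenario = regime_scenario(
        "regional deep-sea mining moratorium enacted",
        c(EEZ_PNG = "PROTECTED_EFFECTIVE", EEZ_FIJI = "PROTECTED_EFFECTIVE",
          EEZ_TONGA = "PROTECTED_EFFECTIVE"),
        "Pacific Island countries impose a regional moratorium."),
      expected_after = "LC",
      expected_after_possibly_extinct = FALSE),

    b_manusensis = list(
      species = "Bathymodiolus manusensis",
      fields = vent_fields(
        site_id = c("pacmanus", "desmos", "susu"),
        name = c("PACMANUS", "DESMOS", "SuSu Knolls"),
        lat = c(-3.730, -3.693, -3.800),
        lon = c(151.670, 151.858, 152.100),
        management_area_id = "EEZ_PNG",
        species_id = "Bathymodiolus manusensis"),
      regimes = regime_table("EEZ_PNG", "EXPLORATION_LICENSE",
                             jurisdiction = "EEZ:Papua New Guinea"),
      expected_category = "EN",
      published_eoo_km2 = 171.23,
      scenario = regime_scenario(
        "no regulatory change", c(),
        "Identity scenario: the published context."),
      expected_after = "EN",
      expected_after_possibly_extinct = FALSE)
  )
}

#' Assess all case-study fixtures
#'
#' Runs [assess_species()] over every bundle of [case_study_fixtures()],
#' using each species' published EOO where one exists.
#'
#' @param config A [geo_config()].
#' @param thresholds A [threshold_table()].
#' @return A named list of `redlist_assessment`s.
#' @export
assess_fixtures <- function(config = geo_config(),
                            thresholds = threshold_table()) {
  lapply(case_study_fixtures(), function(fx) {
    eoo <- if (is.na(fx$published_eoo_km2)) NULL else fx$published_eoo_km2
    assess_species(fx$fields, fx$regimes, config, thresholds, eoo_km2 = eoo)
  })
}

#' Materialise the fixtures to disk
#'
#' Writes one occurrence CSV and one regime CSV covering the four
#' case-study species, plus each bundle's scenario as JSON.
#'
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- case_study_fixtures()
  write_occurrences(lapply(fx, `[[`, "fields"),
                    file.path(dir, "occurrences.csv"))
  regs <- unique(do.call(rbind, lapply(fx, function(b)
    as.data.frame(b$regimes))))
  rownames(regs) <- NULL
  utils::write.csv(regs, file.path(dir, "regimes.csv"), row.names = FALSE)
  for (nm in names(fx)) {
    s <- fx[[nm]]$scenario
    jsonlite::write_json(
      list(name = s$name, description = s$description,
           overrides = as.list(s$overrides)),
      file.path(dir, paste0("scenario_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
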