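# Independent oracles and random-instance generators shared across tests.
# These deliberately avoid the package's own code paths: distances come from
# geosphere, connectivity from boolean matrix closure, areas from Heron or
# geodesic polygon area, and the category decision table is written flat.

# random occurrence table: n sites scattered over a box of `span` degrees,
# split over up to `n_areas` management areas
random_fields <- function(n, span = 4, n_areas = 2,
                          lat0 = runif(1, -55, 55), lon0 = runif(1, -170, 170)) {
  vent_fields(
    site_id = sprintf("s%02d", seq_len(n)),
    lat = lat0 + runif(n, 0, span),
    lon = lon0 + runif(n, 0, span),
    management_area_id = sprintf("A%d", sample.int(n_areas, n, replace = TRUE)),
    species_id = "rand")
}

# geodesic distance matrix (km) from geosphere on the package's sphere
oracle_distm <- function(fields) {
  geosphere::distm(cbind(fields$lon, fields$lat),
                   fun = function(p1, p2)
                     geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
}

# brute-force location partition: transitive closure (boolean matrix
# powering) of the "same management area AND distance < threshold" relation
oracle_partition <- function(fields, threshold_km = 80) {
  d <- oracle_distm(fields)
  same_area <- outer(fields$management_area_id, fields$management_area_id, "==")
  A <- (d < threshold_km) & same_area
  diag(A) <- TRUE
  repeat {
    B <- (A %*% A) > 0
    if (identical(B, A)) break
    A <- B
  }
  # canonical labels: index of first member of each component
  apply(A, 1, function(r) which(r)[1])
}

# same-location indicator matrix from a cluster_locations() result
comembership <- function(locations, fields) {
  lab <- locations$location_id[match(fields$site_id, locations$site_id)]
  outer(lab, lab, "==")
}

# flat, independently written Red List decision table.
# regimes: character vector, one token per location.
oracle_category <- function(eoo, aoo, nloc, regimes) {
  decline <- any(regimes %in% c("EXPLORATION_LICENSE", "ACTIVE_MINING"))
  plausible <- any(regimes != "PROTECTED_EFFECTIVE")
  all_active <- all(regimes == "ACTIVE_MINING")
  worst <-
    if ((eoo < 100 || aoo < 10) && nloc <= 1) "CR" else
    if ((eoo < 5000 || aoo < 500) && nloc <= 5) "EN" else
    if ((eoo < 20000 || aoo < 2000) && nloc <= 10) "VU" else "NT"
  b1 <-
    if (!decline) "none" else
    if (eoo < 100 && nloc <= 1) "CR" else
    if (eoo < 5000 && nloc <= 5) "EN" else
    if (eoo < 20000 && nloc <= 10) "VU" else "none"
  b2 <-
    if (!decline) "none" else
    if (aoo < 10 && nloc <= 1) "CR" else
    if (aoo < 500 && nloc <= 5) "EN" else
    if (aoo < 2000 && nloc <= 10) "VU" else "none"
  d2 <- if ((aoo < 20 || nloc <= 5) && plausible && worst == "CR") "VU" else "none"
  ranks <- match(c(b1, b2, d2), c("LC", "NT", "VU", "EN", "CR"))
  cat <- if (all(is.na(ranks))) {
    if (plausible) "NT" else "LC"
  } else {
    c("LC", "NT", "VU", "EN", "CR")[max(ranks, na.rm = TRUE)]
  }
  pe <- FALSE
  if (all_active) {
    cat <- "CR"
    pe <- TRUE
  }
  list(category = cat, possibly_extinct = pe)
}

# run the package engine on abstract metrics + a per-location regime vector
# (bypasses coordinates: builds a degenerate one-site-per-location table)
engine_category <- function(eoo, aoo, nloc, regimes) {
  locs <- data.frame(location_id = sprintf("L%02d", seq_len(nloc)),
                     site_id = sprintf("s%02d", seq_len(nloc)),
                     management_area_id = sprintf("A%d", seq_len(nloc)),
                     stringsAsFactors = FALSE)
  regs <- regime_table(sprintf("A%d", seq_len(nloc)), regimes)
  threat <- derive_threat_summary(locs, regs)
  metrics <- structure(list(n_fields = nloc, n_locations = nloc,
                            aoo_km2 = aoo, eoo_km2 = eoo),
                       class = "range_metrics")
  worst <- ventrisk:::category_under_full_license(metrics)
  b <- evaluate_criterion_b(metrics, threat)
  d2 <- evaluate_criterion_d2(metrics, threat, worst_case = worst)
  assign_category(b$b1, b$b2, d2, threat, worst, metrics)
}
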