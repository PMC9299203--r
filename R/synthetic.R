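#' Specify a synthetic ridge system
#'
#' The synthetic-data generator emulates the geometry of a mid-ocean ridge
#' segment dotted with small vent fields: clusters of closely spaced fields
#' (tens of km apart) separated by long empty stretches, crossed by
#' management-area boundaries. Because the generator places fields
#' constructively — intra-cluster gaps below the location threshold,
#' inter-cluster gaps above it — it knows the true location partition,
#' which makes it an oracle for the clustering step.
#'
#' @param n_fields Total number of vent fields (>= 1).
#' @param n_clusters Number of spatial clusters the fields are spread over.
#' @param ridge_start,ridge_end Numeric `c(lat, lon)` pairs: the great-circle
#'   ridge axis.
#' @param mean_spacing_km Mean along-ridge spacing of consecutive fields
#'   within a cluster (km).
#' @param gap_km Along-ridge gap between consecutive clusters (km); must
#'   exceed the location threshold by more than the jitter allows.
#' @param jitter_km Uniform jitter (km) applied along- and across-ridge.
#' @param management_splits Strictly increasing fractions in (0, 1): breaks
#'   of the ridge arc into management areas `MA1`, `MA2`, ...
#' @param seed Integer random seed (mandatory: no hidden global state).
#' @param threshold_km Location threshold the construction must respect.
#' @return An object of class `ridge_spec`.
#' @export
synthetic_ridge_spec <- function(n_fields,
                                 n_clusters = 1,
                                 ridge_start = c(-60, -30),
                                 ridge_end = c(10, -13),
                                 mean_spacing_km = 20,
                                 gap_km = 200,
                                 jitter_km = 2,
                                 management_splits = numeric(0),
                                 seed,
                                 threshold_km = 80) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_fields < 1 || n_clusters < 1 || n_clusters > n_fields) {
    stop("need 1 <= n_clusters <= n_fields", call. = FALSE)
  }
  if (mean_spacing_km <= 0) stop("mean_spacing_km must be > 0", call. = FALSE)
  if (jitter_km < 0) stop("jitter_km must be >= 0", call. = FALSE)
  if (length(management_splits) &&
      (any(diff(management_splits) <= 0) ||
       any(management_splits <= 0 | management_splits >= 1))) {
    stop("management_splits must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  # feasibility: jittered intra-cluster spacing must stay under the
  # threshold, and jittered inter-cluster gaps above it
  if (mean_spacing_km + 3 * jitter_km >= threshold_km) {
    stop("infeasible spec: spacing plus jitter reaches the location threshold",
         call. = FALSE)
  }
  if (n_clusters > 1 && gap_km - 3 * jitter_km <= threshold_km) {
    stop("infeasible spec: cluster gap minus jitter does not exceed the ",
         "location threshold", call. = FALSE)
  }
  structure(list(n_fields = as.integer(n_fields),
                 n_clusters = as.integer(n_clusters),
                 ridge_start = ridge_start, ridge_end = ridge_end,
                 mean_spacing_km = mean_spacing_km, gap_km = gap_km,
                 jitter_km = jitter_km,
                 management_splits = management_splits,
                 seed = as.integer(seed), threshold_km = threshold_km),
            class = "ridge_spec")
}

# internal: point at fraction f along the great circle a -> b (slerp on the
# unit sphere); a, b are c(lat, lon) in degrees
gc_point <- function(a, b, f) {
  to_xyz <- function(p) {
    la <- p[1] * pi / 180; lo <- p[2] * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  u <- to_xyz(a); v <- to_xyz(b)
  om <- acos(pmin(pmax(sum(u * v), -1), 1))
  w <- if (om < 1e-12) u else (sin((1 - f) * om) * u + sin(f * om) * v) / sin(om)
  w <- w / sqrt(sum(w^2))
  c(lat = asin(w[3]) * 180 / pi, lon = atan2(w[2], w[1]) * 180 / pi)
}

#' Generate a synthetic ridge dataset
#'
#' Deterministic for a fixed seed. Fields are laid out cluster by cluster
#' along the ridge axis with jittered spacing; the true location partition
#' is the cross-classification of spatial cluster and management area and
#' is returned alongside the records.
#'
#' @param spec A [synthetic_ridge_spec()].
#' @param regime_cycle Character vector of regime tokens assigned to the
#'   management areas in rotation (default cycles through all four).
#' @return A list with `fields` (a [vent_fields()] table), `regimes` (a
#'   [regime_table()]), and `truth` (a data.frame `site_id`,
#'   `true_location`, the constructive ground-truth partition).
#' @examples
#' sim <- generate_synthetic_ridge(
#'   synthetic_ridge_spec(6, n_clusters = 3, mean_spacing_km = 10, seed = 7))
#' table(sim$truth$true_location)
#' @export
generate_synthetic_ridge <- function(spec,
                                     regime_cycle = REGIMES) {
  stopifnot(inherits(spec, "ridge_spec"))
  rng <- local({
    set.seed(spec$seed)
    function(n, half) stats::runif(n, -half, half)
  })
  sizes <- rep(spec$n_fields %/% spec$n_clusters, spec$n_clusters)
  extra <- spec$n_fields %% spec$n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  # along-ridge arc positions (km from ridge_start)
  pos <- numeric(0)
  cluster <- integer(0)
  cursor <- 0
  for (k in seq_len(spec$n_clusters)) {
    for (i in seq_len(sizes[k])) {
      if (length(pos) > 0) {
        step <- if (i == 1) spec$gap_km else spec$mean_spacing_km
        cursor <- cursor + step + rng(1, spec$jitter_km)
      }
      pos <- c(pos, cursor)
      cluster <- c(cluster, k)
    }
  }
  ridge_len <- geodesic_distance_km(spec$ridge_start[1], spec$ridge_start[2],
                                    spec$ridge_end[1], spec$ridge_end[2])
  if (max(pos) > ridge_len) {
    stop("infeasible spec: fields overrun the ridge axis (",
         round(max(pos)), " km needed, ridge is ", round(ridge_len), " km)",
         call. = FALSE)
  }
  pts <- t(vapply(pos / ridge_len,
                  function(f) gc_point(spec$ridge_start, spec$ridge_end, f),
                  numeric(2)))
  # small across-ridge jitter (latitudinal offset keeps it simple and exact)
  lat <- pts[, 1] + rng(nrow(pts), spec$jitter_km) / 6371.0088 * 180 / pi
  lon <- pts[, 2]
  # management areas from fractional breaks along the ridge
  breaks <- c(0, spec$management_splits, 1)
  area_idx <- findInterval(pos / ridge_len, breaks,
                           rightmost.closed = TRUE, left.open = FALSE)
  areas <- sprintf("MA%d", area_idx)
  fields <- vent_fields(
    site_id = sprintf("site%03d", seq_along(pos)),
    lat = lat, lon = lon,
    management_area_id = areas,
    species_id = "synthetic")
  truth_key <- paste(cluster, areas, sep = "/")
  truth <- data.frame(site_id = fields$site_id,
                      true_location = match(truth_key, unique(truth_key)),
                      stringsAsFactors = FALSE)
  uareas <- sprintf("MA%d", seq_len(length(breaks) - 1))
  regimes <- regime_table(
    uareas,
    regime_cycle[((seq_along(uareas) - 1) %% length(regime_cycle)) + 1])
  list(fields = fields, regimes = regimes, truth = truth, spec = spec)
}
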