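test_that("the generator is deterministic for a fixed seed", {
  spec <- synthetic_ridge_spec(9, n_clusters = 3, mean_spacing_km = 15,
                               gap_km = 250, seed = 99)
  a <- generate_synthetic_ridge(spec)
  b <- generate_synthetic_ridge(spec)
  expect_equal(a$fields, b$fields)
  expect_equal(a$truth, b$truth)
  c <- generate_synthetic_ridge(synthetic_ridge_spec(
    9, n_clusters = 3, mean_spacing_km = 15, gap_km = 250, seed = 100))
  expect_false(isTRUE(all.equal(a$fields$lat, c$fields$lat)))
})

test_that("constructive ground truth is recovered exactly by clustering", {
  set.seed(1)
  for (seed in c(7, 21, 63, 412)) {
    spec <- synthetic_ridge_spec(
      n_fields = sample(4:24, 1), n_clusters = sample(1:4, 1),
      mean_spacing_km = runif(1, 5, 25), gap_km = runif(1, 150, 400),
      jitter_km = runif(1, 0, 3), seed = seed)
    sim <- generate_synthetic_ridge(spec)
    locs <- cluster_locations(sim$fields)
    got <- locs$location_id[match(sim$fields$site_id, locs$site_id)]
    want <- sim$truth$true_location
    # same partition up to labelling
    expect_equal(outer(got, got, "=="), outer(want, want, "=="),
                 info = paste("seed", seed))
  }
})

test_that("a management split inside a cluster splits the location", {
  # one spatial cluster of 6 fields with an area boundary through the middle
  spec <- synthetic_ridge_spec(6, n_clusters = 1, mean_spacing_km = 20,
                               jitter_km = 0, management_splits = 0.0004,
                               ridge_start = c(-60, -30),
                               ridge_end = c(10, -13), seed = 3)
  sim <- generate_synthetic_ridge(spec)
  expect_gt(length(unique(sim$fields$management_area_id)), 1)
  locs <- cluster_locations(sim$fields)
  expect_equal(n_locations(locs), length(unique(sim$truth$true_location)))
  expect_gt(n_locations(locs), 1)
})

test_that("infeasible specs are rejected", {
  # spacing + jitter reaching the threshold breaks the construction
  expect_error(synthetic_ridge_spec(6, mean_spacing_km = 78, jitter_km = 1,
                                    seed = 1),
               "infeasible")
  # cluster gaps must clear the threshold even after jitter
  expect_error(synthetic_ridge_spec(6, n_clusters = 2, gap_km = 82,
                                    jitter_km = 1, seed = 1),
               "infeasible")
  expect_error(synthetic_ridge_spec(6, n_clusters = 2, seed = 1,
                                    management_splits = c(0.5, 0.2)),
               "management_splits")
  # seed is mandatory
  expect_error(synthetic_ridge_spec(6), "seed")
  # more fields than a short ridge can hold
  expect_error(generate_synthetic_ridge(synthetic_ridge_spec(
    50, n_clusters = 5, mean_spacing_km = 30, gap_km = 500,
    ridge_start = c(0, 0), ridge_end = c(1, 0), seed = 2)),
    "ridge")
})

test_that("generated regimes cover every generated management area", {
  spec <- synthetic_ridge_spec(12, n_clusters = 3,
                               management_splits = c(0.3, 0.7), seed = 5)
  sim <- generate_synthetic_ridge(spec)
  expect_true(all(sim$fields$management_area_id %in%
                    sim$regimes$management_area_id))
  # the full pipeline runs on generated data
  a <- assess_species(sim$fields, sim$regimes)
  expect_true(a$category %in% c(CATEGORIES, "DD"))
})
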