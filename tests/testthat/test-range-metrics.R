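deg_for_km <- function(km) km / (6371.0088 * pi / 180)

test_that("AOO counts occupied 2x2 km cells", {
  # three fields ~10 km apart: three distinct cells
  f <- vent_fields(c("a", "b", "c"),
                   lat = 0, lon = c(0, deg_for_km(10), deg_for_km(20)),
                   management_area_id = "M1")
  expect_equal(compute_aoo(f), 12)
  # two fields 0.5 km apart share a cell
  f2 <- vent_fields(c("a", "b"), lat = 0, lon = c(0, deg_for_km(0.5)),
                    management_area_id = "M1")
  expect_equal(compute_aoo(f2), 4)
  # a single field occupies one cell
  f3 <- vent_fields("a", lat = -37.78, lon = 49.65,
                    management_area_id = "M1")
  expect_equal(compute_aoo(f3), 4)
  # duplicate coordinates stay distinct fields but occupy one cell
  f4 <- vent_fields(c("a", "b"), lat = 1, lon = 1, management_area_id = "M1")
  expect_equal(compute_aoo(f4), 4)
  expect_equal(compute_range_metrics(f4)$n_fields, 2)
})

test_that("AOO is a multiple of the cell area, bounded by the field count", {
  set.seed(33)
  for (trial in 1:100) {
    n <- sample(1:50, 1)
    f <- random_fields(n, span = runif(1, 0.05, 4))
    aoo <- compute_aoo(f)
    expect_equal(aoo %% 4, 0)
    expect_gte(aoo, 4)
    expect_lte(aoo, 4 * n)
    # fields further apart than a cell diagonal cannot share a cell
    d <- oracle_distm(f)
    if (n > 1 && min(d[upper.tri(d)]) > 2 * sqrt(2)) {
      expect_equal(aoo, 4 * n)
    }
  }
})

test_that("degenerate hulls floor EOO to AOO", {
  f1 <- vent_fields("a", lat = 0, lon = 0, management_area_id = "M1")
  expect_equal(compute_eoo(f1, aoo_km2 = 4), 4)
  # collinear fields along the equator: zero-area hull
  f3 <- vent_fields(c("a", "b", "c"), lat = 0,
                    lon = c(0, deg_for_km(10), deg_for_km(20)),
                    management_area_id = "M1")
  expect_equal(compute_eoo(f3, aoo_km2 = 12), 12)
})

test_that("EOO of a triangle matches Heron's formula on geodesic sides", {
  f <- vent_fields(c("a", "b", "c"),
                   lat = c(0, 0, 0.4), lon = c(0, 0.5, 0.25),
                   management_area_id = "M1")
  p <- cbind(f$lon, f$lat)
  s <- c(geosphere::distHaversine(p[1, ], p[2, ], r = 6371008.8),
         geosphere::distHaversine(p[2, ], p[3, ], r = 6371008.8),
         geosphere::distHaversine(p[1, ], p[3, ], r = 6371008.8)) / 1000
  sp <- sum(s) / 2
  heron <- sqrt(sp * prod(sp - s))
  expect_equal(compute_eoo(f, aoo_km2 = 12), heron, tolerance = 2e-3)
})

test_that("EOO agrees with independent geodesic polygon area", {
  set.seed(77)
  for (trial in 1:30) {
    f <- random_fields(sample(5:50, 1), span = runif(1, 0.5, 3))
    eoo <- compute_eoo(f, aoo_km2 = 0.001)
    xy <- cbind(f$lon, f$lat)
    hull <- grDevices::chull(xy)
    ref <- geosphere::areaPolygon(xy[hull, ], a = 6371008.8, f = 0) / 1e6
    expect_equal(eoo, ref, tolerance = 1e-3, info = paste("trial", trial))
  }
})

test_that("EOO handles ranges spanning the antimeridian", {
  f <- vent_fields(c("a", "b", "c", "d"),
                   lat = c(-20, -21, -20.5, -19.5),
                   lon = c(179.5, -179.5, 179.8, -179.8),
                   management_area_id = "M1")
  eoo <- compute_eoo(f, aoo_km2 = 4)
  xy <- cbind(ifelse(f$lon < 0, f$lon + 360, f$lon), f$lat)
  hull <- grDevices::chull(xy)
  ref <- geosphere::areaPolygon(cbind(f$lon, f$lat)[hull, ],
                                a = 6371008.8, f = 0) / 1e6
  expect_equal(eoo, ref, tolerance = 1e-3)
  expect_lt(eoo, 50000)  # a sane local area, not a wrapped-globe artefact
})

test_that("range metrics bundle matches independent recomputation", {
  set.seed(55)
  for (trial in 1:20) {
    n <- 10
    f <- random_fields(n, span = 2, n_areas = 2)
    m <- compute_range_metrics(f)
    expect_equal(m$n_fields, n)
    expect_equal(m$n_locations, length(unique(oracle_partition(f))))
    expect_equal(m$aoo_km2, compute_aoo(f))
    expect_gte(m$eoo_km2, m$aoo_km2)
  }
})

test_that("a supplied published EOO overrides recomputation but keeps the floor", {
  f <- vent_fields(c("a", "b", "c"),
                   lat = c(-3.730, -3.693, -3.800),
                   lon = c(151.670, 151.858, 152.100),
                   management_area_id = "M1")
  m <- compute_range_metrics(f, eoo_km2 = 171.23)
  expect_equal(m$eoo_km2, 171.23)
  m2 <- compute_range_metrics(f, eoo_km2 = 1)  # below the AOO floor
  expect_equal(m2$eoo_km2, m2$aoo_km2)
})
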