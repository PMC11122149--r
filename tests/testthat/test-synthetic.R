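# Synthetic chamber generator: mesh sizing, wavefront simulation against
# analytic ground truths, voltage field arithmetic, study assembly.

test_that("ellipsoid meshes hit the target point density within 10%", {
  for (ch in c("RA", "LV")) {
    sp <- chamber_spec(ch)
    mesh <- make_chamber_mesh(sp, seed = 11)
    target <- sp$target_point_density * ellipsoid_area(sp$semi_axes)
    expect_lt(abs(nrow(mesh$vertices) - target) / target, 0.10)
  }
  # explicit sizing case: 30x30x40 mm semi-axes at 1.3 points/mm^2
  sp <- chamber_spec("LV", semi_axes = c(30, 30, 40), cutout_fraction = 0)
  mesh <- make_chamber_mesh(sp, seed = 1)
  expect_lt(abs(nrow(mesh$vertices) - 1.3 * ellipsoid_area(c(30, 30, 40))) /
              (1.3 * ellipsoid_area(c(30, 30, 40))), 0.10)
})

test_that("chamber meshes are closed surfaces with contiguous labels", {
  mesh <- make_chamber_mesh(chamber_spec("RV"), seed = 3)
  V <- nrow(mesh$vertices); F <- nrow(mesh$triangles)
  E <- nrow(circlemap:::mesh_edges(mesh$triangles))
  expect_equal(V - E + F, 2)  # Euler characteristic of a sphere
  expect_setequal(unique(mesh$wall),
                  c("anterior", "posterior", "lateral", "septal",
                    "unassigned"))
  atr <- make_chamber_mesh(chamber_spec("RA"), seed = 3)
  expect_true("superior" %in% atr$wall)
})

test_that("cutout_fraction 0 gives no cutouts; degenerate density errors", {
  mesh <- make_chamber_mesh(chamber_spec("RA", cutout_fraction = 0), seed = 2)
  expect_false(any(mesh$cutout))
  expect_error(make_chamber_mesh(
    chamber_spec("RA", target_point_density = 0.01), seed = 1), "degenerate")
})

test_that("mesh generation is deterministic in the seed", {
  m1 <- make_chamber_mesh(chamber_spec("LA"), seed = 42)
  m2 <- make_chamber_mesh(chamber_spec("LA"), seed = 42)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$cutout, m2$cutout)
  m3 <- make_chamber_mesh(chamber_spec("LA"), seed = 43)
  expect_false(identical(m1$vertices, m3$vertices))
})

test_that("planar activation spans width/speed on a flat strip", {
  p <- make_flat_patch(40, 10, density = 1.3)
  lat <- simulate_activation(p, source_spec("planar", direction = c(1, 0, 0)),
                             1.0)
  expect_equal(max(lat) - min(lat), 40)   # 40 mm at 1 mm/ms
  expect_equal(min(lat), 0)
  lat2 <- simulate_activation(p, source_spec("planar",
                                             direction = c(1, 0, 0)), 2.0)
  expect_equal(max(lat2), 20)
})

test_that("focal activation is 0 at the focus and matches great-circle
           distances on a sphere to within 5% on average", {
  sp <- chamber_spec("LV", semi_axes = c(20, 20, 20), cutout_fraction = 0,
                     target_point_density = 3)
  mesh <- make_chamber_mesh(sp, seed = 4)
  f <- mesh$vertices[10, ]
  lat <- simulate_activation(mesh, source_spec("focal", focus = f), 1.0)
  expect_equal(lat[10], 0)
  u <- mesh$vertices / 20
  fu <- f / sqrt(sum(f^2))
  dtrue <- 20 * acos(pmin(1, pmax(-1, as.numeric(u %*% fu))))
  sel <- dtrue > 5
  rel <- abs(lat[sel] - dtrue[sel]) / dtrue[sel]
  expect_lt(mean(rel), 0.05)
  # graph distances can only overestimate the true geodesic
  expect_gte(min(lat[sel] - dtrue[sel]), -1e-9)
})

test_that("focal source on a cutout vertex is rejected", {
  mesh <- make_chamber_mesh(chamber_spec("RA", cutout_fraction = 0.1),
                            seed = 5)
  f <- mesh$vertices[which(mesh$cutout)[1], ]
  expect_error(simulate_activation(mesh, source_spec("focal", focus = f), 1),
               "cutout")
})

test_that("voltage field reproduces the generating arithmetic when SDs are 0", {
  quiet_params <- generator_params(animal_sd = c(log_cv = 0, va_mv = 0),
                                   noise_sd = c(cv_log = 0, va_mv = 0),
                                   cv_point_jitter_sd_log = 0,
                                   va_regional_sd_mv = 0)
  mesh <- make_chamber_mesh(chamber_spec("RA", cutout_fraction = 0), seed = 6)
  meta <- default_meta("RA", hr = 145)
  amp <- simulate_voltage(mesh, quiet_params, meta, seed = 1)
  expect_true(all(amp == 3.0))   # chamber intercept at the reference rate
  meta2 <- default_meta("RA", hr = 245)
  amp2 <- simulate_voltage(mesh, quiet_params, meta2, seed = 1)
  expect_true(all(abs(amp2 - (3.0 - 1.2)) < 1e-12))  # slope -0.012 x 100 bpm
})

test_that("voltage sample mean matches its expectation within 3 SE", {
  params <- generator_params()
  mesh <- make_chamber_mesh(chamber_spec("LV", cutout_fraction = 0), seed = 7)
  meta <- default_meta("LV", hr = 120)
  amp <- simulate_voltage(mesh, params, meta, seed = 99)
  expected <- 13.3 + params$va_rate_slope_mv_per_bpm * (120 - 145)
  se <- params$noise_sd[["va_mv"]] / sqrt(nrow(mesh$vertices))
  # the regional field is centred per map, so only white noise moves the mean
  expect_lt(abs(mean(amp) - expected), 3 * se + 1e-6)
})

test_that("generate_study emulates the full protocol deterministically", {
  expect_identical(generate_study(default_protocol()[0, ], seed = 1), list())
  small <- lapply(CHAMBERS <- c("RA", "LA", "RV", "LV"), function(ch)
    chamber_spec(ch, semi_axes = chamber_spec(ch)$semi_axes * 0.45))
  names(small) <- CHAMBERS
  proto <- default_protocol()[c(1, 8, 13, 16), ]
  maps <- generate_study(proto, seed = 5, chamber_specs = small)
  expect_length(maps, 4L)
  expect_identical(names(maps), proto$map_id)
  # paced and sinus maps of the same animal/chamber share one mesh
  expect_identical(maps[[1]]$vertices, maps[[2]]$vertices)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(maps, d1)
  write_study(generate_study(proto, seed = 5, chamber_specs = small), d2)
  expect_identical(unname(tools::md5sum(list.files(d1, full.names = TRUE))),
                   unname(tools::md5sum(list.files(d2, full.names = TRUE))))
  maps2 <- generate_study(proto, seed = 6, chamber_specs = small)
  expect_false(identical(maps[[1]]$lat_ms, maps2[[1]]$lat_ms))
})

test_that("a protocol needing an unknown pacing multiplier is rejected", {
  proto <- default_protocol()[1, ]
  proto$rhythm <- "paced"; proto$pacing_site <- "LV"  # RA paced from LV
  proto$pacing_access <- "endo"
  expect_error(generate_study(proto, seed = 1), "RA:LV")
})
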