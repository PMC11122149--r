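# Fixtures built in code: small flat maps with exact planar activation, and
# a cached full-scale default study shared by the acceptance tests.

default_meta <- function(chamber = "RA", rhythm = "NSR", site = "none",
                         hr = 120, animal = "pig1") {
  map_meta(animal, chamber, rhythm, pacing_site = site,
           pacing_access = if (site == "none") "none" else "endo",
           heart_rate_bpm = hr)
}

# flat rectangular map with planar activation at `speed` m/s along +x and
# constant amplitude; h = 0.5 mm grid so x-extents of 5-mm balls centred on
# grid points are exact
flat_map <- function(width = 20, height = 20, density = 4, speed = 1.2,
                     amp = 5, meta = default_meta(), jitter = 0, seed = 1) {
  p <- make_flat_patch(width, height, density = density, jitter = jitter,
                       seed = seed)
  lat <- simulate_activation(p, source_spec("planar", direction = c(1, 0, 0)),
                             speed)
  map_surface(p$vertices, p$triangles, lat, rep(amp, nrow(p$vertices)),
              p$cutout, p$wall, meta)
}

# circle centers at interior grid vertices (>= radius away from the border)
interior_centers <- function(map, radius = 5) {
  v <- map$vertices
  ok <- v[, 1] >= radius & v[, 1] <= max(v[, 1]) - radius &
    v[, 2] >= radius & v[, 2] <= max(v[, 2]) - radius
  idx <- which(ok)
  v[idx[seq(1, length(idx), by = 37)], , drop = FALSE]
}

# hand-built circle_set wrapper for directly constructed circle records
fake_circle_set <- function(circles, radius_mm = 5, meta = NULL) {
  structure(list(circles = circles, radius_mm = radius_mm, meta = meta),
            class = "circle_set", dropped = 0L)
}

# Mesh-free circle-level table drawn directly from the statistical model the
# mixed-effects layer assumes -- an independent oracle for recovery tests.
# `maps` needs columns chamber, site ("NSR" or a chamber), hr, animal.
sim_metrics <- function(maps, circles_per_map = 60,
                        cv_base = 1.004, cv_intercepts = c(RA = 0.9, LA = 1.0,
                                                           RV = 0.8, LV = 0.9),
                        cv_mult = list(), sigma_log = 0.25,
                        va_slope = -0.012, va_intercepts = c(RA = 3, LA = 4.3,
                                                             RV = 8.4,
                                                             LV = 13.3),
                        va_offsets = list(), sigma_va = 1.0,
                        animal_sd_log = 0.08, animal_sd_va = 0.4,
                        ref_hr = 145, walls = "lateral", seed = 1) {
  set.seed(seed)
  animals <- unique(maps$animal)
  a_cv <- stats::setNames(rnorm(length(animals), 0, animal_sd_log), animals)
  a_va <- stats::setNames(rnorm(length(animals), 0, animal_sd_va), animals)
  rows <- lapply(seq_len(nrow(maps)), function(i) {
    m <- maps[i, ]
    key <- paste0(m$chamber, ":", m$site)
    lmu <- log(cv_intercepts[[m$chamber]]) +
      log(cv_base) * (m$hr - ref_hr) +
      log(if (!is.null(cv_mult[[key]])) cv_mult[[key]] else 1) +
      a_cv[[m$animal]]
    vmu <- va_intercepts[[m$chamber]] + va_slope * (m$hr - ref_hr) +
      (if (!is.null(va_offsets[[key]])) va_offsets[[key]] else 0) +
      a_va[[m$animal]]
    k <- circles_per_map
    data.frame(
      circle_id = sprintf("m%02d_c%03d", i, seq_len(k)),
      animal_id = m$animal, chamber = m$chamber,
      rhythm = if (m$site == "NSR") "NSR" else "paced",
      pacing_site = if (m$site == "NSR") "none" else m$site,
      heart_rate_bpm = m$hr,
      wall = rep_len(walls, k), n_points = 100L,
      cv_mps = exp(lmu + rnorm(k, 0, sigma_log)),
      va_mv = pmax(vmu + rnorm(k, 0, sigma_va), 0),
      excluded = FALSE, exclusion_reason = "none")
  })
  do.call(rbind, rows)
}

# simple map grid for sim_metrics: per group, n maps with HRs spread over
# 86-171 bpm, animals cycling
sim_maps <- function(groups, n_per_group = 4, animals = paste0("pig", 1:4)) {
  do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    data.frame(chamber = groups$chamber[g], site = groups$site[g],
               hr = round(seq(86, 171, length.out = n_per_group)),
               animal = rep_len(animals, n_per_group))
  }))
}

# one full-scale default-protocol study bundle at a fixed seed, computed
# once and shared across acceptance tests
.study_cache <- new.env(parent = emptyenv())
acceptance_bundle <- function() {
  if (is.null(.study_cache$bundle)) {
    .study_cache$bundle <- run_pipeline(pipeline_config(seed = 1))
  }
  .study_cache$bundle
}
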