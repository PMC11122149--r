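# Synthetic chamber maps with the statistical structure the downstream
# analysis assumes: a multiplicative per-bpm heart-rate effect on conduction
# velocity, a linear per-bpm effect on unipolar amplitude, chamber-specific
# intercepts, pacing-site effects, per-animal random intercepts, regional
# heterogeneity fields and cutout regions.

derive_seed <- function(seed, k) {
  # exact in doubles: |seed| < 2^31 so seed * 48271 < 2^53
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)) %%
               2147483647)
}

#' Chamber geometry and sampling specification
#'
#' @param chamber One of `"RA"`, `"LA"`, `"RV"`, `"LV"`.
#' @param semi_axes Ellipsoid semi-axes in mm; defaults give chamber surface
#'   areas of roughly 4200--4500 mm^2, matching the scale of high-density
#'   maps with ~5600 points at 1.3 points/mm^2.
#' @param target_point_density Measurement points per mm^2 (default 1.3).
#' @param cutout_fraction Fraction of vertices carved out as contiguous
#'   cutout patches (vessel/valve transitions), in `[0, 0.3]`.
#' @param superior_cap Fraction of the long semi-axis above which atrial
#'   vertices are labelled `"superior"`; `NA` disables the cap (ventricles).
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(chamber,
                         semi_axes = NULL,
                         target_point_density = 1.3,
                         cutout_fraction = 0.08,
                         superior_cap = NULL) {
  chamber <- match.arg(chamber, CHAMBERS)
  defaults <- list(RA = c(17, 17, 22), LA = c(18, 18, 19),
                   RV = c(16, 17, 24), LV = c(18, 18, 21))
  if (is.null(semi_axes)) semi_axes <- defaults[[chamber]]
  if (is.null(superior_cap)) {
    superior_cap <- if (chamber %in% c("RA", "LA")) 0.75 else NA
  }
  stopifnot(target_point_density > 0,
            cutout_fraction >= 0, cutout_fraction <= 0.3)
  structure(list(chamber = chamber, semi_axes = semi_axes,
                 target_point_density = target_point_density,
                 cutout_fraction = cutout_fraction,
                 superior_cap = superior_cap),
            class = "chamber_spec")
}

#' Wavefront source specification
#'
#' @param kind `"planar"` (uniform wavefront travelling along `direction`) or
#'   `"focal"` (activation spreading from `focus` along the mesh).
#' @param direction Unit 3-vector for planar sources.
#' @param focus 3-D location (mm) for focal sources; activation starts at the
#'   nearest non-cutout vertex.
#' @param base_speed_mps Baseline conduction speed, m/s, in (0.05, 6).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(kind = c("planar", "focal"), direction = NULL,
                        focus = NULL, base_speed_mps = 1) {
  kind <- match.arg(kind)
  if (!(base_speed_mps > 0.05 && base_speed_mps < 6)) {
    stop("base_speed_mps must lie in (0.05, 6) m/s", call. = FALSE)
  }
  if (kind == "planar") {
    stopifnot(length(direction) == 3)
    direction <- direction / sqrt(sum(direction^2))
  } else {
    stopifnot(length(focus) == 3)
  }
  structure(list(kind = kind, direction = direction, focus = focus,
                 base_speed_mps = base_speed_mps), class = "source_spec")
}

#' Generator parameters for synthetic studies
#'
#' Defaults encode the fitted effects the generator is meant to emulate: a
#' multiplicative conduction-velocity (CV) increase of x1.004 per bpm, a
#' linear unipolar-amplitude (VA) decrease of 0.012 mV per bpm, and
#' pacing-site effects on whole chambers (e.g. RA pacing scaling RA CV by
#' 0.75, LV pacing raising RV VA by 2.55 mV).  Chamber intercepts are
#' interpreted at `reference_hr_bpm` (145 bpm), so the CV law is applied as
#' `intercept * cv_rate_base^(HR - reference)`.
#'
#' @param cv_rate_base Per-bpm multiplicative CV effect (ratio).
#' @param va_rate_slope_mv_per_bpm Per-bpm additive VA effect (mV/bpm).
#' @param chamber_cv_intercepts Named m/s per chamber at the reference rate.
#' @param chamber_va_intercepts Named mV per chamber at the reference rate.
#' @param pacing_cv_multipliers Named list `"<chamber>:<pacing site>"` -> CV
#'   ratio versus sinus rhythm (1 = no effect).
#' @param pacing_va_offsets_mv Named list `"<chamber>:<pacing site>"` -> VA
#'   offset in mV versus sinus rhythm.
#' @param pacing_cv_wall_multipliers Optional per-wall override, named
#'   `"<chamber>:<site>:<wall>"` -> ratio, multiplied on top of the chamber
#'   multiplier to emulate regionally concentrated pacing effects.
#' @param pacing_va_wall_offsets_mv Optional per-wall additive override,
#'   named `"<chamber>:<site>:<wall>"` -> mV.
#' @param animal_sd Named vector: random-intercept SDs `log_cv` (log scale)
#'   and `va_mv` (mV), drawn once per animal and shared across its maps.
#' @param noise_sd Named vector: `cv_log` -- SD of the lognormal regional
#'   conduction-heterogeneity field (log scale, roughly the circle-level CV
#'   noise); `va_mv` -- SD of additive white per-point VA noise.
#' @param cv_point_jitter_sd_log SD of additional white per-point lognormal
#'   speed jitter.
#' @param va_regional_sd_mv SD of the smooth regional VA field (mV).
#' @param regional_scale_mm Named correlation lengths (mm) of the regional
#'   fields, `cv` and `va`.
#' @param reference_hr_bpm Heart rate at which intercepts are defined.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(
    cv_rate_base = 1.004,
    va_rate_slope_mv_per_bpm = -0.012,
    chamber_cv_intercepts = c(RA = 0.85, LA = 1.05, RV = 0.75, LV = 0.90),
    chamber_va_intercepts = c(RA = 3.0, LA = 4.3, RV = 8.4, LV = 13.3),
    pacing_cv_multipliers = list(
      "RA:RA" = 0.75, "RA:LA" = 1.44, "LA:RA" = 0.62,
      "RV:RA" = 0.75, "RV:LA" = 1.00, "RV:LV" = 1.00,
      "LV:RA" = 0.49, "LV:RV" = 1.40, "LV:LV" = 1.00),
    pacing_va_offsets_mv = list(
      "RA:RA" = 0, "RA:LA" = 0, "LA:RA" = 0,
      "RV:RA" = 1.21, "RV:LA" = 1.236, "RV:LV" = 2.55,
      "LV:RA" = -1.83, "LV:RV" = 0, "LV:LV" = 0),
    pacing_cv_wall_multipliers = NULL,
    pacing_va_wall_offsets_mv = NULL,
    animal_sd = c(log_cv = 0.1, va_mv = 0.5),
    noise_sd = c(cv_log = 0.3, va_mv = 1.5),
    cv_point_jitter_sd_log = 0.05,
    va_regional_sd_mv = 0.8,
    regional_scale_mm = c(cv = 6, va = 8),
    reference_hr_bpm = 145) {
  stopifnot(cv_rate_base > 0, all(unlist(pacing_cv_multipliers) > 0),
            all(animal_sd >= 0), all(noise_sd >= 0),
            cv_point_jitter_sd_log >= 0, va_regional_sd_mv >= 0,
            all(chamber_cv_intercepts > 0))
  structure(as.list(environment()), class = "generator_params")
}

#' The default 44-map study protocol
#'
#' One row per recorded map: mapped chamber, rhythm, pacing site and access,
#' mean heart rate (bpm), and a round-robin animal assignment over the four
#' animals.  Heart rates span 86--171 bpm across normal sinus rhythm and
#' pacing from RA, LA, RV and LV.
#'
#' @return A data frame with 44 rows and columns `map_id`, `animal_id`,
#'   `chamber`, `rhythm`, `pacing_site`, `pacing_access`, `heart_rate_bpm`.
#' @export
default_protocol <- function() {
  entry <- function(chamber, site, hrs, access) {
    data.frame(chamber = chamber,
               rhythm = if (site == "none") "NSR" else "paced",
               pacing_site = site, pacing_access = access,
               heart_rate_bpm = hrs)
  }
  p <- rbind(
    entry("RA", "none", c(115, 115, 120, 134, 130, 95, 145), "none"),
    entry("RA", "RA", c(145, 145, 145, 120, 146),
          c("epi", "epi", "epi", "endo", "endo")),
    entry("RA", "LA", c(145, 145, 145), "epi"),
    entry("LA", "none", c(86, 90, 145, 171), "none"),
    entry("LA", "RA", c(145, 171), "endo"),
    entry("RV", "none", c(104, 95, 135, 150, 110, 132), "none"),
    entry("RV", "RA", c(145, 145, 146), c("endo", "epi", "endo")),
    entry("RV", "LA", 145, "epi"),
    entry("RV", "LV", c(145, 170, 146), "endo"),
    entry("LV", "none", c(122, 130, 120, 86), "none"),
    entry("LV", "RA", c(145, 145, 145), "epi"),
    entry("LV", "RV", 145, "epi"),
    entry("LV", "LV", c(145, 145), c("epi", "endo"))
  )
  animals <- paste0("pig", 1:4)
  cell <- paste(p$chamber, p$pacing_site)
  p$animal_id <- unlist(lapply(split(seq_len(nrow(p)), cell)[unique(cell)],
                               function(i) animals[(seq_along(i) - 1L) %% 4L + 1L]))
  p$map_id <- sprintf("map%02d", seq_len(nrow(p)))
  rownames(p) <- NULL
  p[, c("map_id", "animal_id", "chamber", "rhythm", "pacing_site",
        "pacing_access", "heart_rate_bpm")]
}

# focal source locations in ellipsoid parameter angles (theta, phi, degrees);
# sinus sources sit high-posterior/septal, pacing entries on the wall facing
# the pacing chamber -- fixed but arbitrary anatomy-flavoured choices
source_location_angles <- function(chamber, site) {
  sinus <- list(RA = c(45, 135), LA = c(60, -80), RV = c(40, -90),
                LV = c(55, -95))
  if (site == "none") return(sinus[[chamber]])
  if (site == chamber) return(c(95, 90))
  atria <- c("RA", "LA")
  same_level <- (chamber %in% atria) == (site %in% atria)
  if (same_level) c(85, -90) else c(35, -90)
}

angles_to_xyz <- function(semi_axes, ang) {
  th <- ang[1] * pi / 180; ph <- ang[2] * pi / 180
  c(semi_axes[1] * sin(th) * cos(ph),
    semi_axes[2] * sin(th) * sin(ph),
    semi_axes[3] * cos(th))
}

#' Build a chamber mesh skeleton
#'
#' Generates a closed triangulated ellipsoid with vertex count matching
#' `target_point_density * surface area` (within a few percent), contiguous
#' cutout patches, and angular-sector wall labels.
#'
#' @param spec A [chamber_spec()].
#' @param seed Integer seed; identical seeds give identical meshes.
#' @return A `map_skeleton`: list with `vertices`, `triangles` (0-based),
#'   `cutout`, `wall`, `chamber` and `semi_axes`.
#' @export
make_chamber_mesh <- function(spec, seed = 1L) {
  n_target <- spec$target_point_density * ellipsoid_area(spec$semi_axes)
  mesh <- make_ellipsoid_mesh(spec$semi_axes, n_target, seed = seed)
  set.seed(derive_seed(seed, 7L))
  cut <- carve_cutouts(mesh$vertices, mesh$triangles, spec$cutout_fraction)
  wall <- assign_walls(mesh$vertices, spec$semi_axes, spec$superior_cap)
  wall[cut] <- "unassigned"
  structure(list(vertices = mesh$vertices, triangles = mesh$triangles,
                 cutout = cut, wall = wall, chamber = spec$chamber,
                 semi_axes = spec$semi_axes),
            class = "map_skeleton")
}

#' Simulate local activation times on a mesh
#'
#' Planar sources assign each vertex the travel time of a uniform wavefront:
#' projection onto the direction divided by the local speed, offset so the
#' earliest activation is 0 ms.  Focal sources propagate along mesh edges by
#' Dijkstra shortest paths, each edge costing its length divided by the mean
#' endpoint speed -- a graph approximation of geodesic wavefront spread.
#' Cutout vertices receive missing LAT.
#'
#' @param mesh A `map_skeleton` or `map_surface`.
#' @param source A [source_spec()].
#' @param speed_field Per-vertex conduction speed, m/s (positive on
#'   non-cutout vertices); a scalar is recycled.
#' @return Numeric per-vertex `lat_ms`.
#' @export
simulate_activation <- function(mesh, source, speed_field) {
  n <- nrow(mesh$vertices)
  speed_field <- rep_len(speed_field, n)
  open <- !mesh$cutout
  if (any(speed_field[open] <= 0)) {
    stop("speed_field must be positive on non-cutout vertices", call. = FALSE)
  }
  lat <- rep(NA_real_, n)
  if (source$kind == "planar") {
    proj <- drop(mesh$vertices %*% source$direction)
    lat[open] <- proj[open] / speed_field[open]
    lat[open] <- lat[open] - min(lat[open])
    return(lat)
  }
  d2 <- colSums((t(mesh$vertices) - source$focus)^2)
  focus_v <- which.min(d2)
  if (mesh$cutout[focus_v]) {
    stop("parameter error: focal source lies on a cutout vertex", call. = FALSE)
  }
  e <- mesh_edges(mesh$triangles) + 1L
  keep <- open[e[, 1]] & open[e[, 2]]
  e <- e[keep, , drop = FALSE]
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  w <- len / ((speed_field[e[, 1]] + speed_field[e[, 2]]) / 2)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  d <- as.numeric(igraph::distances(g, v = focus_v, weights = w))
  d[!open] <- NA_real_
  unreachable <- open & !is.finite(d)
  if (any(unreachable)) {
    warning(sum(unreachable), " non-cutout vertices unreachable from the focus",
            call. = FALSE)
    d[unreachable] <- NA_real_
  }
  d
}

# smooth zero-mean unit-sd random field: sum of Gaussian bumps at random
# vertices, standardised over the mesh (uses the current RNG stream)
smooth_field <- function(vertices, scale_mm, area = NULL) {
  n <- nrow(vertices)
  if (is.null(area)) area <- 4 * pi * (mean(apply(vertices, 2, sd)) * 1.6)^2
  k <- max(30L, min(300L, round(area / scale_mm^2)))
  centers <- vertices[sample.int(n, k, replace = TRUE), , drop = FALSE]
  amps <- rnorm(k)
  f <- numeric(n)
  for (i in seq_len(k)) {
    d2 <- (vertices[, 1] - centers[i, 1])^2 + (vertices[, 2] - centers[i, 2])^2 +
      (vertices[, 3] - centers[i, 3])^2
    f <- f + amps[i] * exp(-d2 / (2 * scale_mm^2))
  }
  (f - mean(f)) / max(sd(f), 1e-12)
}

#' Simulate per-vertex unipolar voltage amplitudes
#'
#' Amplitude = chamber intercept + rate slope x (HR - reference) + pacing
#' offset + animal intercept + smooth regional field + white noise, truncated
#' at 0 mV.  The regional field is centred to zero mean over the map, so it
#' models within-map heterogeneity without shifting the map mean.
#'
#' @param mesh A `map_skeleton` or `map_surface` (for vertex locations and
#'   cutout/wall labels).
#' @param params A [generator_params()].
#' @param meta A [map_meta()] providing chamber, pacing site and heart rate.
#' @param seed Integer seed.
#' @param animal_effect_mv Per-animal intercept deviation in mV (drawn once
#'   per animal by [generate_study()]; defaults to 0).
#' @return Numeric per-vertex `amplitude_mv` (NA on cutout vertices).
#' @export
simulate_voltage <- function(mesh, params, meta, seed = 1L,
                             animal_effect_mv = 0) {
  set.seed(seed)
  n <- nrow(mesh$vertices)
  hr_term <- params$va_rate_slope_mv_per_bpm *
    (meta$heart_rate_bpm - params$reference_hr_bpm)
  offset <- 0
  if (meta$rhythm == "paced") {
    key <- paste0(meta$chamber, ":", meta$pacing_site)
    off <- params$pacing_va_offsets_mv[[key]]
    if (is.null(off)) {
      stop("configuration error: no pacing VA offset for ", key, call. = FALSE)
    }
    offset <- off
  }
  base <- params$chamber_va_intercepts[[meta$chamber]] + hr_term + offset +
    animal_effect_mv
  amp <- rep(base, n)
  if (meta$rhythm == "paced" && !is.null(params$pacing_va_wall_offsets_mv)) {
    for (w in unique(mesh$wall)) {
      k <- paste0(meta$chamber, ":", meta$pacing_site, ":", w)
      o <- params$pacing_va_wall_offsets_mv[[k]]
      if (!is.null(o)) amp[mesh$wall == w] <- amp[mesh$wall == w] + o
    }
  }
  if (params$va_regional_sd_mv > 0) {
    amp <- amp + params$va_regional_sd_mv *
      smooth_field(mesh$vertices, params$regional_scale_mm[["va"]])
  }
  if (params$noise_sd[["va_mv"]] > 0) {
    amp <- amp + rnorm(n, 0, params$noise_sd[["va_mv"]])
  }
  amp <- pmax(amp, 0)
  amp[mesh$cutout] <- NA_real_
  amp
}

# per-vertex conduction speed field (m/s) for one map
cv_speed_field <- function(mesh, params, meta, animal_log_effect = 0) {
  base <- params$chamber_cv_intercepts[[meta$chamber]] *
    params$cv_rate_base^(meta$heart_rate_bpm - params$reference_hr_bpm) *
    exp(animal_log_effect)
  mult <- rep(1, nrow(mesh$vertices))
  if (meta$rhythm == "paced") {
    key <- paste0(meta$chamber, ":", meta$pacing_site)
    m <- params$pacing_cv_multipliers[[key]]
    if (is.null(m)) {
      stop("configuration error: no pacing CV multiplier for ", key,
           call. = FALSE)
    }
    mult <- mult * m
    if (!is.null(params$pacing_cv_wall_multipliers)) {
      for (w in unique(mesh$wall)) {
        k <- paste0(key, ":", w)
        wm <- params$pacing_cv_wall_multipliers[[k]]
        if (!is.null(wm)) mult[mesh$wall == w] <- mult[mesh$wall == w] * wm
      }
    }
  }
  lf <- 0
  if (params$noise_sd[["cv_log"]] > 0) {
    lf <- params$noise_sd[["cv_log"]] *
      smooth_field(mesh$vertices, params$regional_scale_mm[["cv"]])
  }
  jit <- if (params$cv_point_jitter_sd_log > 0) {
    rnorm(nrow(mesh$vertices), 0, params$cv_point_jitter_sd_log)
  } else 0
  base * mult * exp(lf + jit)
}

#' Generate a full synthetic mapping study
#'
#' One map per protocol row.  Meshes are generated once per (animal, chamber)
#' and shared across that animal's recordings of the chamber, so paced and
#' sinus maps of the same chamber can be matched circle-by-circle.  Sinus
#' maps activate from a chamber-specific sinus entry location, paced maps
#' from the pacing-site entry.  Per-animal random intercepts are drawn once
#' per animal.  Deterministic given `seed`.
#'
#' @param protocol Data frame as returned by [default_protocol()].
#' @param params A [generator_params()].
#' @param seed Integer seed.
#' @param chamber_specs Optional named list of [chamber_spec()] overrides per
#'   chamber (e.g. smaller chambers for quick experiments).
#' @return Named list of `map_surface` objects (names = `map_id`).
#' @export
generate_study <- function(protocol = default_protocol(),
                           params = generator_params(), seed = 1L,
                           chamber_specs = NULL) {
  if (nrow(protocol) == 0L) return(list())
  specs <- lapply(CHAMBERS, chamber_spec)
  names(specs) <- CHAMBERS
  if (!is.null(chamber_specs)) specs[names(chamber_specs)] <- chamber_specs
  paced <- which(protocol$pacing_site != "none")
  keys <- if (length(paced)) {
    unique(paste0(protocol$chamber[paced], ":", protocol$pacing_site[paced]))
  } else character(0)
  missing_keys <- setdiff(keys, names(params$pacing_cv_multipliers))
  if (length(missing_keys)) {
    stop("configuration error: protocol needs pacing CV multipliers for ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  animals <- sort(unique(protocol$animal_id))
  set.seed(derive_seed(seed, 1L))
  a_log_cv <- setNames(rnorm(length(animals), 0, params$animal_sd[["log_cv"]]),
                       animals)
  a_va <- setNames(rnorm(length(animals), 0, params$animal_sd[["va_mv"]]),
                   animals)
  mesh_key <- paste(protocol$animal_id, protocol$chamber)
  meshes <- list()
  for (k in unique(mesh_key)) {
    row <- protocol[match(k, mesh_key), ]
    meshes[[k]] <- make_chamber_mesh(
      specs[[row$chamber]],
      seed = derive_seed(seed, 1000L + match(k, unique(mesh_key)))
    )
  }
  maps <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    row <- protocol[i, ]
    mesh <- meshes[[mesh_key[i]]]
    meta <- map_meta(row$animal_id, row$chamber, row$rhythm, row$pacing_site,
                     row$pacing_access, row$heart_rate_bpm)
    set.seed(derive_seed(seed, 2000L + i))
    speed <- cv_speed_field(mesh, params, meta, a_log_cv[[row$animal_id]])
    ang <- source_location_angles(row$chamber, row$pacing_site)
    focus <- angles_to_xyz(mesh$semi_axes, ang)
    open_idx <- which(!mesh$cutout)
    d2 <- colSums((t(mesh$vertices[open_idx, , drop = FALSE]) - focus)^2)
    focus <- mesh$vertices[open_idx[which.min(d2)], ]
    src <- source_spec("focal", focus = focus,
                       base_speed_mps = params$chamber_cv_intercepts[[row$chamber]])
    lat <- suppressWarnings(simulate_activation(mesh, src, speed))
    stranded <- !mesh$cutout & is.na(lat)
    cut <- mesh$cutout | stranded
    amp <- simulate_voltage(mesh, params, meta,
                            seed = derive_seed(seed, 3000L + i),
                            animal_effect_mv = a_va[[row$animal_id]])
    amp[cut] <- NA_real_
    wall <- mesh$wall
    wall[cut] <- "unassigned"
    maps[[i]] <- map_surface(mesh$vertices, mesh$triangles, lat, amp, cut,
                             wall, meta)
  }
  names(maps) <- protocol$map_id
  maps
}

#' Write a study to disk in the map file format
#'
#' @param maps Named list of maps from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written `.vtk` paths, invisibly.
#' @export
write_study <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(names(maps), ".vtk"))
  for (i in seq_along(maps)) write_map(maps[[i]], paths[i])
  invisible(paths)
}
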