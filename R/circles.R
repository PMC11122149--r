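# Circle covering: place 5-mm-radius spherical filters over the non-cutout
# surface of a map and materialise each as a circle record with member
# points, covered area and majority wall label.

#' Sample circle centers by greedy farthest-point sampling
#'
#' Starting from a seeded initial vertex, repeatedly accepts the non-cutout
#' vertex farthest (Euclidean) from all accepted centers, until no vertex is
#' at least `spacing_mm` from every center.  The result is a well-separated,
#' near-complete covering of the open surface.  Deterministic given `seed`
#' (the seed only picks the starting vertex).
#'
#' @param map A `map_surface` or `map_skeleton`.
#' @param radius_mm Circle radius (used only for the precondition check).
#' @param spacing_mm Minimum center separation; must be at most
#'   `2 * radius_mm` or full coverage is impossible.
#' @param seed Integer seed.
#' @return Numeric k x 3 matrix of center coordinates (attribute
#'   `vertex_index` holds the 1-based vertex indices).
#' @export
sample_centers <- function(map, radius_mm = 5, spacing_mm = 4.4, seed = 1L) {
  if (spacing_mm > 2 * radius_mm) {
    stop("spacing_mm must be <= 2 * radius_mm for full coverage", call. = FALSE)
  }
  open_idx <- which(!map$cutout)
  if (length(open_idx) == 0L) {
    warning("map has no non-cutout vertices; no centers sampled", call. = FALSE)
    out <- matrix(numeric(0), 0, 3)
    attr(out, "vertex_index") <- integer(0)
    return(out)
  }
  pts <- map$vertices[open_idx, , drop = FALSE]
  set.seed(seed)
  cur <- sample.int(nrow(pts), 1L)
  chosen <- cur
  d <- sqrt(colSums((t(pts) - pts[cur, ])^2))
  repeat {
    cand <- which.max(d)
    if (d[cand] < spacing_mm) break
    chosen <- c(chosen, cand)
    d <- pmin(d, sqrt(colSums((t(pts) - pts[cand, ])^2)))
  }
  out <- pts[chosen, , drop = FALSE]
  attr(out, "vertex_index") <- open_idx[chosen]
  out
}

#' Materialise circles from centers
#'
#' Members are the non-cutout vertices within Euclidean distance
#' `radius_mm` of the center (boundary inclusive).  Covered area sums the
#' mesh triangles whose centroid lies inside the ball, excluding triangles
#' touching a cutout vertex.  Circles with fewer than `min_points` members
#' are dropped (recorded in the `dropped` attribute).
#'
#' @param map A `map_surface`.
#' @param centers Matrix of centers from [sample_centers()].
#' @param radius_mm Circle radius, mm (default 5).
#' @param min_points Minimum member count to keep a circle (default 10).
#' @return A `circle_set`: list with `circles` (list of circle records),
#'   `radius_mm` and the map's `meta`; attribute `dropped` counts discarded
#'   circles.
#' @export
build_circles <- function(map, centers, radius_mm = 5, min_points = 10) {
  if (nrow(centers) == 0L) stop("centers must be non-empty", call. = FALSE)
  n <- nrow(map$vertices)
  open <- !map$cutout
  tv <- map$triangles + 1L
  tri_ok <- open[tv[, 1]] & open[tv[, 2]] & open[tv[, 3]]
  centroids <- (map$vertices[tv[, 1], , drop = FALSE] +
                map$vertices[tv[, 2], , drop = FALSE] +
                map$vertices[tv[, 3], , drop = FALSE]) / 3
  areas <- triangle_areas(map$vertices, map$triangles)
  circles <- list()
  dropped <- 0L
  for (ci in seq_len(nrow(centers))) {
    cen <- centers[ci, ]
    dv <- sqrt(colSums((t(map$vertices) - cen)^2))
    members <- which(open & dv <= radius_mm)
    if (length(members) < min_points) {
      dropped <- dropped + 1L
      next
    }
    dt <- sqrt(colSums((t(centroids) - cen)^2))
    in_ball <- tri_ok & dt <= radius_mm
    cov <- sum(areas[in_ball])
    wtab <- table(map$wall[members])
    circles[[length(circles) + 1L]] <- list(
      circle_id = sprintf("c%03d", ci),
      center = cen, radius_mm = radius_mm,
      member_vertices = members,
      covered_area_mm2 = cov,
      wall = names(wtab)[which.max(wtab)]
    )
  }
  structure(list(circles = circles, radius_mm = radius_mm, meta = map$meta),
            class = "circle_set", dropped = dropped)
}

#' @export
print.circle_set <- function(x, ...) {
  cat(sprintf("circle_set: %d circles of radius %g mm (%d dropped)\n",
              length(x$circles), x$radius_mm, attr(x, "dropped")))
  invisible(x)
}

#' Summarise a circle covering
#'
#' @param circle_set A `circle_set` from [build_circles()].
#' @return A one-row data frame: `n_circles`, `mean_area_mm2`,
#'   `mean_points_per_circle` and `resolution_points_per_mm2`
#'   (= mean points / mean area).
#' @export
coverage_summary <- function(circle_set) {
  cs <- circle_set$circles
  if (length(cs) == 0L) stop("empty circle set", call. = FALSE)
  np <- vapply(cs, function(c) length(c$member_vertices), numeric(1))
  ar <- vapply(cs, function(c) c$covered_area_mm2, numeric(1))
  data.frame(n_circles = length(cs), mean_area_mm2 = mean(ar),
             mean_points_per_circle = mean(np),
             resolution_points_per_mm2 = mean(np) / mean(ar))
}

#' Export circles as a flat table
#'
#' @param circle_set A `circle_set`.
#' @return Data frame with one row per circle: id, map keys, center
#'   coordinates, radius, member count, covered area and wall label.
#' @export
circles_table <- function(circle_set) {
  cs <- circle_set$circles
  meta <- circle_set$meta
  do.call(rbind, lapply(cs, function(c) data.frame(
    circle_id = c$circle_id,
    animal_id = meta$animal_id, chamber = meta$chamber, rhythm = meta$rhythm,
    pacing_site = meta$pacing_site, heart_rate_bpm = meta$heart_rate_bpm,
    center_x = c$center[1], center_y = c$center[2], center_z = c$center[3],
    radius_mm = c$radius_mm, n_points = length(c$member_vertices),
    covered_area_mm2 = c$covered_area_mm2, wall = c$wall
  )))
}
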