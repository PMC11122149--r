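# Triangulated-surface utilities: ellipsoid chamber meshes built from
# latitude rings (arbitrary vertex counts, so a target point density can be
# hit), flat calibration patches, areas and adjacency.

#' Approximate surface area of an ellipsoid
#'
#' Thomsen's approximation (p = 1.6075), accurate to ~1% for moderate
#' eccentricities -- ample for sizing chamber meshes.
#'
#' @param semi_axes Numeric length-3 vector of semi-axes (mm).
#' @return Surface area in mm^2.
#' @export
ellipsoid_area <- function(semi_axes) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  p <- 1.6075
  a <- semi_axes[1]^p; b <- semi_axes[2]^p; c <- semi_axes[3]^p
  4 * pi * ((a * b + a * c + b * c) / 3)^(1 / p)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1] + 1L, , drop = FALSE]
  b <- vertices[triangles[, 2] + 1L, , drop = FALSE]
  c <- vertices[triangles[, 3] + 1L, , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$triangles))

# unique undirected edges as a 2-column 0-based matrix
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# adjacency list (1-based) from 0-based triangles
vertex_adjacency <- function(triangles, n) {
  e <- mesh_edges(triangles) + 1L
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  out <- vector("list", n)
  out[as.integer(names(adj))] <- adj
  out
}

# zig-zag merge of two closed vertex rings into a triangle strip; vertices at
# nominal angles 2*pi*j/n, triangles as 0-based index triples
stitch_rings <- function(idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  tris <- matrix(0L, na + nb, 3)
  i <- 0L; j <- 0L; t <- 0L
  while (i < na || j < nb) {
    t <- t + 1L
    adv_a <- i < na && (j >= nb || (i + 1) / na <= (j + 1) / nb)
    if (adv_a) {
      tris[t, ] <- c(idx_a[i %% na + 1L], idx_a[(i + 1L) %% na + 1L],
                     idx_b[j %% nb + 1L])
      i <- i + 1L
    } else {
      tris[t, ] <- c(idx_a[i %% na + 1L], idx_b[(j + 1L) %% nb + 1L],
                     idx_b[j %% nb + 1L])
      j <- j + 1L
    }
  }
  tris
}

# closed ellipsoid mesh with ~n_target approximately uniform vertices;
# latitude rings with point counts proportional to circumference, vertices
# jittered in parameter space so the lattice is not perfectly regular
make_ellipsoid_mesh <- function(semi_axes, n_target, jitter = 0.3, seed = 1L) {
  if (n_target < 100) {
    stop("parameter error: target vertex count ", round(n_target),
         " is degenerate (< 100); increase density or size", call. = FALSE)
  }
  set.seed(seed)
  R <- max(4L, round(sqrt(pi * n_target) / 2))
  ring_n <- pmax(3L, round(2 * R * sin((1:(R - 1)) * pi / R)))
  theta <- rep((1:(R - 1)) * pi / R, ring_n)
  phi <- unlist(lapply(ring_n, function(n) 2 * pi * (0:(n - 1)) / n))
  nv <- length(theta)
  theta <- theta + runif(nv, -jitter, jitter) * pi / R
  phi <- phi + runif(nv, -jitter, jitter) * 2 * pi / rep(ring_n, ring_n)
  verts <- rbind(
    c(0, 0, semi_axes[3]),
    cbind(semi_axes[1] * sin(theta) * cos(phi),
          semi_axes[2] * sin(theta) * sin(phi),
          semi_axes[3] * cos(theta)),
    c(0, 0, -semi_axes[3])
  )
  ring_idx <- split(seq_len(nv) + 1L, rep(seq_along(ring_n), ring_n))  # 1-based
  np <- nv + 2L
  tris <- list()
  first <- ring_idx[[1]]
  n1 <- length(first)
  tris[[1]] <- cbind(1L, first, c(first[-1], first[1]))
  for (k in seq_len(length(ring_idx) - 1L)) {
    tris[[k + 1L]] <- stitch_rings(ring_idx[[k]] - 1L, ring_idx[[k + 1L]] - 1L) + 1L
  }
  last <- ring_idx[[length(ring_idx)]]
  tris[[length(tris) + 1L]] <- cbind(np, c(last[-1], last[1]), last)
  triangles <- do.call(rbind, tris) - 1L
  list(vertices = verts, triangles = triangles)
}

#' Flat rectangular test patch
#'
#' A planar triangulated grid in the z = 0 plane, used for calibration and
#' ground-truth fixtures where analytic answers exist (planar wavefronts,
#' disc areas).
#'
#' @param width,height Patch extent in mm.
#' @param density Target point density, points/mm^2 (grid spacing
#'   `1/sqrt(density)`).
#' @param jitter Fraction of the grid spacing used for uniform in-plane
#'   jitter (0 keeps the exact grid).
#' @param seed RNG seed for the jitter.
#' @return A mesh skeleton: list with `vertices`, `triangles` (0-based),
#'   `cutout` (all `FALSE`) and `wall` (all `"unassigned"`).
#' @export
make_flat_patch <- function(width, height, density = 1.3, jitter = 0,
                            seed = 1L) {
  h <- 1 / sqrt(density)
  xs <- seq(0, width, length.out = max(2L, round(width / h) + 1L))
  ys <- seq(0, height, length.out = max(2L, round(height / h) + 1L))
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(x = xs, y = ys)
  verts <- cbind(g$x, g$y, 0)
  if (jitter > 0) {
    set.seed(seed)
    verts[, 1] <- verts[, 1] + runif(nrow(verts), -jitter, jitter) * h
    verts[, 2] <- verts[, 2] + runif(nrow(verts), -jitter, jitter) * h
  }
  id <- function(i, j) (j - 1L) * nx + i  # 1-based grid index
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  t1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
  t2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  structure(list(
    vertices = verts, triangles = rbind(t1, t2) - 1L,
    cutout = rep(FALSE, nrow(verts)),
    wall = rep("unassigned", nrow(verts))
  ), class = "map_skeleton")
}

# contiguous cutout patches grown by breadth-first search over mesh edges
carve_cutouts <- function(vertices, triangles, fraction, n_patches = 2L) {
  n <- nrow(vertices)
  cut <- rep(FALSE, n)
  target <- ceiling(fraction * n)
  if (target == 0L) return(cut)
  adj <- vertex_adjacency(triangles, n)
  seeds <- sample.int(n, n_patches)
  per_patch <- ceiling(target / n_patches)
  for (s in seeds) {
    frontier <- s; grabbed <- 0L
    while (length(frontier) && grabbed < per_patch && sum(cut) < target) {
      take <- head(frontier, per_patch - grabbed)
      new <- take[!cut[take]]
      cut[new] <- TRUE
      grabbed <- grabbed + length(new)
      frontier <- setdiff(unique(unlist(adj[take])), which(cut))
    }
  }
  cut
}

# angular-sector wall labels: four azimuth quadrants, plus a superior cap for
# the atria (upper portion of the long axis)
assign_walls <- function(vertices, semi_axes, superior_cap = NA) {
  phi <- atan2(vertices[, 2], vertices[, 1]) * 180 / pi
  wall <- rep("anterior", nrow(vertices))
  wall[phi >= 45 & phi < 135] <- "lateral"
  wall[phi >= 135 | phi < -135] <- "posterior"
  wall[phi >= -135 & phi < -45] <- "septal"
  if (!is.na(superior_cap)) {
    wall[vertices[, 3] > superior_cap * semi_axes[3]] <- "superior"
  }
  wall
}
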