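#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif quantile IQR median sd setNames coef vcov predict ave
#' @importFrom utils head read.csv write.csv
NULL

CHAMBERS <- c("RA", "LA", "RV", "LV")
WALLS <- c("unassigned", "anterior", "posterior", "lateral", "septal", "superior")
# integer codes used in mesh files; index into WALLS is code + 1
WALL_CODES <- setNames(0:5, WALLS)

#' Metadata record for one electroanatomic map
#'
#' Describes the recording context of a single chamber map: which animal and
#' chamber it was acquired from, whether it was recorded during normal sinus
#' rhythm (NSR) or pacing, the pacing site and access route, and the mean
#' heart rate over the recording.
#'
#' @param animal_id Identifier of the animal (coerced to character).
#' @param chamber Mapped chamber, one of `"RA"`, `"LA"`, `"RV"`, `"LV"`.
#' @param rhythm `"NSR"` or `"paced"`.
#' @param pacing_site `"none"` (required for NSR) or one of the chambers.
#' @param pacing_access `"none"`, `"endo"` or `"epi"`.
#' @param heart_rate_bpm Mean heart rate during the recording, beats/min.
#'   Must lie in a physiologically sane range (30--400 bpm).
#'
#' @return An object of class `map_meta` (a named list).
#' @export
#' @examples
#' map_meta("pig1", "RA", "NSR", heart_rate_bpm = 120)
map_meta <- function(animal_id, chamber, rhythm = c("NSR", "paced"),
                     pacing_site = "none", pacing_access = "none",
                     heart_rate_bpm) {
  rhythm <- match.arg(rhythm)
  chamber <- match.arg(chamber, CHAMBERS)
  pacing_site <- match.arg(pacing_site, c("none", CHAMBERS))
  pacing_access <- match.arg(pacing_access, c("none", "endo", "epi"))
  if (!is.numeric(heart_rate_bpm) || length(heart_rate_bpm) != 1L ||
      !is.finite(heart_rate_bpm) || heart_rate_bpm < 30 || heart_rate_bpm > 400) {
    stop("heart_rate_bpm must be a single value in [30, 400] bpm", call. = FALSE)
  }
  if ((rhythm == "NSR") != (pacing_site == "none")) {
    stop("rhythm 'NSR' requires pacing_site 'none' and vice versa", call. = FALSE)
  }
  structure(list(
    animal_id = as.character(animal_id), chamber = chamber, rhythm = rhythm,
    pacing_site = pacing_site, pacing_access = pacing_access,
    heart_rate_bpm = as.numeric(heart_rate_bpm)
  ), class = "map_meta")
}

#' Triangulated electroanatomic map surface
#'
#' The central container of the package: a triangulated chamber surface with
#' per-vertex scalar fields.  Coordinates are in mm, local activation time
#' (LAT) in ms, unipolar amplitude in mV.  Cutout vertices mark transitions
#' to vessels or neighbouring chambers and may carry missing LAT/amplitude;
#' non-cutout vertices must carry finite values.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param triangles Integer m x 3 matrix of 0-based vertex indices.
#' @param lat_ms Numeric vector of per-vertex activation times (ms); `NA` only
#'   on cutout vertices.
#' @param amplitude_mv Numeric vector of per-vertex unipolar amplitudes (mV);
#'   non-negative, `NA` only on cutout vertices.
#' @param cutout Logical vector flagging cutout vertices.
#' @param wall Character vector of wall labels (see [wall_labels()]).
#' @param meta A [map_meta()] record.
#' @param validate If `TRUE` (default) the invariants are checked and any
#'   violation raises an error.
#'
#' @return An object of class `map_surface`.
#' @seealso [validate_map()], [write_map()], [load_map()]
#' @export
map_surface <- function(vertices, triangles, lat_ms, amplitude_mv, cutout,
                        wall, meta, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  m <- structure(list(
    vertices = vertices, triangles = triangles,
    lat_ms = as.numeric(lat_ms), amplitude_mv = as.numeric(amplitude_mv),
    cutout = as.logical(cutout), wall = as.character(wall), meta = meta
  ), class = "map_surface")
  if (validate) {
    rep <- validate_map(m)
    if (length(rep$violations)) {
      stop("invalid map_surface:\n  ", paste(rep$violations, collapse = "\n  "),
           call. = FALSE)
    }
  }
  m
}

#' Recognised wall labels and their integer file codes
#' @return Named integer vector mapping wall label to file code.
#' @export
wall_labels <- function() WALL_CODES

n_vertices <- function(map) nrow(map$vertices)

#' @export
print.map_surface <- function(x, ...) {
  mt <- x$meta
  cat(sprintf("map_surface: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  %s %s (pacing %s/%s), %.0f bpm, animal %s\n",
              mt$chamber, mt$rhythm, mt$pacing_site, mt$pacing_access,
              mt$heart_rate_bpm, mt$animal_id))
  cat(sprintf("  cutout vertices: %d (%.1f%%)\n", sum(x$cutout),
              100 * mean(x$cutout)))
  invisible(x)
}

#' Validate a map surface against its invariants
#'
#' Checks field lengths, triangle index ranges, cutout/missing-value
#' consistency, amplitude non-negativity and wall labels.  Violations are
#' reported, not raised, so a partially corrupt map can be inspected.
#'
#' @param map A `map_surface` (checked structurally, so invalid objects are
#'   accepted and reported on).
#' @return An object of class `map_validation` with elements `valid` (logical)
#'   and `violations` (character vector, empty when valid).
#' @export
validate_map <- function(map) {
  v <- character(0)
  n <- nrow(map$vertices)
  if (!is.matrix(map$vertices) || ncol(map$vertices) != 3L) {
    v <- c(v, "vertices must be an n x 3 matrix")
  }
  if (!is.matrix(map$triangles) || ncol(map$triangles) != 3L ||
      nrow(map$triangles) < 1L) {
    v <- c(v, "triangles must be an m x 3 matrix with at least one triangle")
  } else {
    tri <- map$triangles
    if (anyNA(tri) || any(tri < 0L) || any(tri >= n)) {
      v <- c(v, sprintf("triangle indices out of range [0, %d]", n - 1L))
    }
  }
  for (f in c("lat_ms", "amplitude_mv", "cutout", "wall")) {
    if (length(map[[f]]) != n) {
      v <- c(v, sprintf("field '%s' has length %d, expected %d",
                        f, length(map[[f]]), n))
    }
  }
  if (length(map$cutout) == n && !anyNA(map$cutout)) {
    open <- !map$cutout
    if (length(map$lat_ms) == n && anyNA(map$lat_ms[open])) {
      v <- c(v, sprintf("%d non-cutout vertices with missing lat_ms",
                        sum(is.na(map$lat_ms[open]))))
    }
    if (length(map$amplitude_mv) == n) {
      if (anyNA(map$amplitude_mv[open])) {
        v <- c(v, sprintf("%d non-cutout vertices with missing amplitude_mv",
                          sum(is.na(map$amplitude_mv[open]))))
      }
      bad <- !is.na(map$amplitude_mv) & map$amplitude_mv < 0
      if (any(bad)) v <- c(v, sprintf("%d negative amplitude_mv values", sum(bad)))
    }
  } else if (length(map$cutout) == n) {
    v <- c(v, "cutout flags contain missing values")
  }
  if (length(map$wall) == n && !all(map$wall %in% WALLS)) {
    v <- c(v, sprintf("unknown wall labels: %s",
                      paste(unique(setdiff(map$wall, WALLS)), collapse = ", ")))
  }
  if (!inherits(map$meta, "map_meta")) v <- c(v, "meta is not a map_meta record")
  structure(list(valid = length(v) == 0L, violations = v),
            class = "map_validation")
}

#' @export
print.map_validation <- function(x, ...) {
  if (x$valid) cat("map is valid\n")
  else cat("map violations:\n  ", paste(x$violations, collapse = "\n  "), "\n")
  invisible(x)
}

fmt_num <- function(x) {
  # fixed formatting so repeated writes are byte-identical; %.9g keeps full
  # single-precision content and round-trips typical double fields
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "nan"
  out
}

#' Write a map surface to legacy VTK polydata plus a YAML sidecar
#'
#' The geometry and per-vertex fields go to an ASCII legacy VTK polydata file
#' readable by standard mesh viewers; metadata goes to `<path>.meta.yaml`.
#' Per-vertex arrays are named `lat_ms`, `amplitude_mv`, `cutout` and
#' `wall_id` (integer codes, see [wall_labels()]).  Missing scalars are
#' written as `nan` and are only legal on cutout vertices.  Writing the same
#' map twice yields byte-identical files.
#'
#' @param map A valid `map_surface`.
#' @param path Output file path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  rep <- validate_map(map)
  if (!rep$valid) {
    stop("refusing to write invalid map:\n  ",
         paste(rep$violations, collapse = "\n  "), call. = FALSE)
  }
  if (all(map$cutout)) {
    warning("writing a map whose vertices are all cutout", call. = FALSE)
  }
  n <- nrow(map$vertices)
  m <- nrow(map$triangles)
  con <- file(path, open = "wb")  # binary connection => LF endings everywhere
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con, sep = "\n")
  wl("# vtk DataFile Version 3.0", "electroanatomic map surface", "ASCII",
     "DATASET POLYDATA", sprintf("POINTS %d float", n))
  wl(apply(matrix(fmt_num(t(map$vertices)), nrow = 3), 2, paste, collapse = " "))
  wl(sprintf("POLYGONS %d %d", m, 4L * m))
  wl(paste(3L, map$triangles[, 1], map$triangles[, 2], map$triangles[, 3]))
  wl(sprintf("POINT_DATA %d", n))
  wl("SCALARS lat_ms float 1", "LOOKUP_TABLE default")
  wl(fmt_num(map$lat_ms))
  wl("SCALARS amplitude_mv float 1", "LOOKUP_TABLE default")
  wl(fmt_num(map$amplitude_mv))
  wl("SCALARS cutout int 1", "LOOKUP_TABLE default")
  wl(as.character(as.integer(map$cutout)))
  wl("SCALARS wall_id int 1", "LOOKUP_TABLE default")
  wl(as.character(WALL_CODES[map$wall]))
  meta <- map$meta
  yaml::write_yaml(list(
    animal_id = meta$animal_id, chamber = meta$chamber, rhythm = meta$rhythm,
    pacing_site = meta$pacing_site, pacing_access = meta$pacing_access,
    heart_rate_bpm = meta$heart_rate_bpm
  ), sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Load a map surface written by [write_map()]
#'
#' Reads an ASCII legacy VTK polydata file with the per-vertex arrays
#' `lat_ms`, `amplitude_mv`, `cutout` and `wall_id`, plus the YAML metadata
#' sidecar.  A missing scalar array or a length mismatch raises an error
#' naming the offending array.
#'
#' @param path Path to the `.vtk` file; `<path>.meta.yaml` must exist.
#' @return A validated `map_surface`.
#' @export
load_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar_path(path))) {
    stop("metadata sidecar not found: ", sidecar_path(path), call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 5L || !grepl("^# vtk DataFile", lines[1]) ||
      toupper(lines[3]) != "ASCII" || lines[4] != "DATASET POLYDATA") {
    stop("not an ASCII legacy VTK polydata file: ", path, call. = FALSE)
  }
  i <- grep("^POINTS ", lines)[1]
  if (is.na(i)) stop("format error: no POINTS section", call. = FALSE)
  n <- as.integer(strsplit(lines[i], " +")[[1]][2])
  verts <- matrix(as.numeric(unlist(strsplit(lines[(i + 1):(i + n)], " +"))),
                  ncol = 3, byrow = TRUE)
  j <- grep("^POLYGONS ", lines)[1]
  if (is.na(j)) stop("format error: no POLYGONS section", call. = FALSE)
  m <- as.integer(strsplit(lines[j], " +")[[1]][2])
  polys <- matrix(as.integer(unlist(strsplit(lines[(j + 1):(j + m)], " +"))),
                  ncol = 4, byrow = TRUE)
  if (any(polys[, 1] != 3L)) {
    stop("format error: non-triangular polygons present", call. = FALSE)
  }
  k <- grep("^POINT_DATA ", lines)[1]
  if (is.na(k)) stop("format error: no POINT_DATA section", call. = FALSE)
  nd <- as.integer(strsplit(lines[k], " +")[[1]][2])
  if (nd != n) {
    stop(sprintf("validation error: POINT_DATA length %d != %d vertices",
                 nd, n), call. = FALSE)
  }
  read_scalars <- function(name) {
    s <- grep(sprintf("^SCALARS %s ", name), lines)[1]
    if (is.na(s)) {
      stop(sprintf("format error: missing per-vertex scalar array '%s'", name),
           call. = FALSE)
    }
    vals <- lines[(s + 2):(s + 1 + n)]
    if (length(vals) != n || anyNA(suppressWarnings(as.numeric(vals[vals != "nan"])))) {
      stop(sprintf("validation error: array '%s' has inconsistent length", name),
           call. = FALSE)
    }
    suppressWarnings(as.numeric(vals))
  }
  lat <- read_scalars("lat_ms")
  amp <- read_scalars("amplitude_mv")
  cut <- read_scalars("cutout") != 0
  wid <- as.integer(read_scalars("wall_id"))
  if (any(!wid %in% WALL_CODES)) {
    stop("validation error: unknown wall_id codes in file", call. = FALSE)
  }
  meta_raw <- yaml::read_yaml(sidecar_path(path))
  meta <- map_meta(meta_raw$animal_id, meta_raw$chamber, meta_raw$rhythm,
                   meta_raw$pacing_site, meta_raw$pacing_access,
                   meta_raw$heart_rate_bpm)
  lat[is.nan(lat)] <- NA_real_
  amp[is.nan(amp)] <- NA_real_
  if (all(cut)) warning("loaded a map whose vertices are all cutout", call. = FALSE)
  map_surface(verts, polys[, 2:4], lat, amp, cut,
              names(WALL_CODES)[wid + 1L], meta)
}
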