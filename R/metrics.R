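# Per-circle conduction velocity and voltage amplitude, with the outlier
# rule applied: CV = theoretical diameter / (last - first activation),
# values above 6 m/s disregarded.

#' Analysis configuration
#'
#' @param radius_mm Circle radius, mm (default 5; the theoretical diameter
#'   used for CV is always `2 * radius_mm`).
#' @param cv_outlier_mps CV outlier threshold, m/s; values strictly greater
#'   are excluded (6.0 itself is kept).
#' @param reference_hr_bpm Heart rate (90 or 145 bpm) at which model
#'   estimates are normalised.
#' @param min_points Minimum member count per circle.
#' @param spacing_mm Center spacing for [sample_centers()].
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(radius_mm = 5, cv_outlier_mps = 6,
                            reference_hr_bpm = 145, min_points = 10,
                            spacing_mm = 4.4) {
  stopifnot(radius_mm > 0, cv_outlier_mps > 0,
            reference_hr_bpm %in% c(90, 145), min_points >= 2)
  structure(list(radius_mm = radius_mm, diameter_mm = 2 * radius_mm,
                 cv_outlier_mps = cv_outlier_mps,
                 reference_hr_bpm = reference_hr_bpm,
                 min_points = min_points, spacing_mm = spacing_mm),
            class = "analysis_config")
}

#' Conduction velocity of one circle
#'
#' The theoretical diameter of the circular area divided by the time
#' difference between the first and last activation within it.  With the
#' diameter in mm and LAT in ms the ratio is directly in m/s.
#'
#' @param lat_values Finite LATs (ms) of the circle's member points; at
#'   least two required.
#' @param diameter_mm Theoretical circle diameter, mm.
#' @return CV in m/s, or `NA` when all activations coincide (zero time
#'   difference).
#' @export
#' @examples
#' circle_cv(c(12, 15, 20), 10)  # 10 mm / 8 ms = 1.25 m/s
circle_cv <- function(lat_values, diameter_mm = 10) {
  lat_values <- lat_values[is.finite(lat_values)]
  if (length(lat_values) < 2L) {
    stop("circle_cv needs at least two finite LAT values", call. = FALSE)
  }
  dt <- max(lat_values) - min(lat_values)
  if (dt == 0) return(NA_real_)
  diameter_mm / dt
}

#' Mean voltage amplitude of one circle
#'
#' @param amplitudes Finite unipolar amplitudes (mV); at least one required.
#' @return Arithmetic mean, mV.
#' @export
circle_va <- function(amplitudes) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) == 0L) {
    stop("circle_va needs at least one finite amplitude", call. = FALSE)
  }
  mean(amplitudes)
}

#' Per-circle metrics for one map
#'
#' Computes CV and mean VA for every circle and applies the exclusion rules:
#' fewer than `min_points` members (`too_few_points`), coincident first/last
#' activation (`zero_dt`), and CV strictly above the outlier threshold
#' (`outlier_cv`; the threshold value itself is kept).  Excluded rows are
#' retained with their reason for audit; modelling tables should subset
#' `!excluded`.
#'
#' @param map The `map_surface` the circles were built from.
#' @param circle_set A `circle_set` from [build_circles()].
#' @param config An [analysis_config()].
#' @return Data frame with one row per circle: map keys, wall, `n_points`,
#'   `cv_mps`, `va_mv`, `excluded`, `exclusion_reason`.
#' @export
compute_map_metrics <- function(map, circle_set, config = analysis_config()) {
  meta <- map$meta
  rows <- lapply(circle_set$circles, function(c) {
    lat <- map$lat_ms[c$member_vertices]
    amp <- map$amplitude_mv[c$member_vertices]
    lat <- lat[is.finite(lat)]
    reason <- "none"
    cv <- NA_real_
    if (length(lat) < config$min_points) {
      reason <- "too_few_points"
    } else {
      dt <- max(lat) - min(lat)
      if (dt == 0) {
        reason <- "zero_dt"
      } else {
        cv <- config$diameter_mm / dt
        if (cv > config$cv_outlier_mps) reason <- "outlier_cv"
      }
    }
    data.frame(
      circle_id = c$circle_id, animal_id = meta$animal_id,
      chamber = meta$chamber, rhythm = meta$rhythm,
      pacing_site = meta$pacing_site, heart_rate_bpm = meta$heart_rate_bpm,
      wall = c$wall, n_points = length(c$member_vertices),
      cv_mps = cv, va_mv = if (any(is.finite(amp))) circle_va(amp) else NA_real_,
      excluded = reason != "none", exclusion_reason = reason
    )
  })
  do.call(rbind, rows)
}
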