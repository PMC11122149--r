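# Paired-map analysis: match circles between a paced map and the intrinsic
# sinus map of the same chamber and animal, then summarise the absolute and
# relative local differences.

circle_centers <- function(circle_set) {
  t(vapply(circle_set$circles, function(c) c$center, numeric(3)))
}

#' Match circles between a paced and an intrinsic map
#'
#' Mutual-nearest-center matching: circle i of the paced set pairs with
#' circle j of the intrinsic set iff each is the other's nearest center and
#' their distance is at most `tolerance_mm`.  Every circle pairs with at
#' most one partner; unmatched circles are dropped and counted.
#'
#' @param pace_circles,nsr_circles `circle_set`s from the paced and the
#'   sinus-rhythm map; must come from the same chamber of the same animal.
#' @param tolerance_mm Maximum center distance (default 2.5 mm, half the
#'   circle radius).
#' @return Data frame with `pace_id`, `intrinsic_id`, `distance_mm`;
#'   attribute `n_unmatched` counts dropped circles.
#' @export
match_circles <- function(pace_circles, nsr_circles, tolerance_mm = 2.5) {
  mp <- pace_circles$meta; mn <- nsr_circles$meta
  if (!is.null(mp) && !is.null(mn)) {
    if (mp$chamber != mn$chamber || mp$animal_id != mn$animal_id) {
      stop("maps must be the same chamber of the same animal (got ",
           mp$animal_id, "/", mp$chamber, " vs ", mn$animal_id, "/",
           mn$chamber, ")", call. = FALSE)
    }
  }
  a <- circle_centers(pace_circles)
  b <- circle_centers(nsr_circles)
  # full pairwise distance matrix (a few hundred circles at most)
  d <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
  nn_ab <- max.col(-d)                    # nearest intrinsic per paced
  nn_ba <- max.col(-t(d))                 # nearest paced per intrinsic
  i <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == i & d[cbind(i, nn_ab)] <= tolerance_mm
  # exact distances for the reported pairs (the matrix form above loses a
  # few digits to cancellation)
  exact <- sqrt(rowSums((a[i[mutual], , drop = FALSE] -
                           b[nn_ab[mutual], , drop = FALSE])^2))
  pairs <- data.frame(
    pace_id = vapply(pace_circles$circles[i[mutual]], `[[`, "", "circle_id"),
    intrinsic_id = vapply(nsr_circles$circles[nn_ab[mutual]], `[[`, "",
                          "circle_id"),
    distance_mm = exact
  )
  n_un <- (nrow(a) - nrow(pairs)) + (nrow(b) - nrow(pairs))
  if (nrow(pairs) == 0L) {
    warning("no circle pairs within the matching tolerance", call. = FALSE)
  }
  attr(pairs, "n_unmatched") <- n_un
  pairs
}

#' Attach metric values to matched circle pairs
#'
#' Joins the per-circle metric tables of both maps onto the matches and
#' drops pairs where either member was excluded (outlier, zero time
#' difference or too few points).
#'
#' @param matches Output of [match_circles()].
#' @param pace_metrics,nsr_metrics Metric tables from
#'   [compute_map_metrics()] for the paced and intrinsic map.
#' @param measure `"cv"` (m/s) or `"va"` (mV).
#' @return Data frame of circle pairs with `pace_value` and
#'   `intrinsic_value`.
#' @export
paired_values <- function(matches, pace_metrics, nsr_metrics,
                          measure = c("cv", "va")) {
  measure <- match.arg(measure)
  col <- if (measure == "cv") "cv_mps" else "va_mv"
  ip <- match(matches$pace_id, pace_metrics$circle_id)
  ii <- match(matches$intrinsic_id, nsr_metrics$circle_id)
  ok <- !is.na(ip) & !is.na(ii) &
    !pace_metrics$excluded[ip] & !nsr_metrics$excluded[ii]
  out <- data.frame(
    pace_id = matches$pace_id[ok], intrinsic_id = matches$intrinsic_id[ok],
    distance_mm = matches$distance_mm[ok],
    pace_value = pace_metrics[[col]][ip[ok]],
    intrinsic_value = nsr_metrics[[col]][ii[ok]]
  )
  out[is.finite(out$pace_value) & is.finite(out$intrinsic_value), ,
      drop = FALSE]
}

#' Paired difference summary
#'
#' Implements the four paired statistics exactly as defined: the mean of
#' absolute differences between corresponding circles; its ratio to the mean
#' intrinsic value; the per-circle relative change, each difference divided
#' by the MEAN intrinsic value of the map (in %); and the IQR of relative
#' change, the IQR over circles of each difference divided by ITS OWN
#' intrinsic value (in %).
#'
#' @param pairs Data frame with `pace_value` and `intrinsic_value`, e.g.
#'   from [paired_values()].
#' @param quantile_type Quantile convention for IQRs (default 7, linear
#'   interpolation).
#' @return An object of class `paired_summary`: list with `n_pairs`,
#'   `mean_abs_diff`, `iqr_abs_diff`, `abs_diff_ratio`, `relative_change`
#'   (vector, %), `iqr_relative_change` (%).
#' @export
paired_summary <- function(pairs, quantile_type = 7) {
  if (nrow(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  p <- pairs$pace_value; s <- pairs$intrinsic_value
  if (any(s == 0)) {
    stop("intrinsic value of 0 in pair(s) ",
         paste(which(s == 0), collapse = ", "),
         "; the IQR of relative change is undefined", call. = FALSE)
  }
  d <- p - s
  mean_abs <- mean(abs(d))
  structure(list(
    n_pairs = length(d),
    mean_abs_diff = mean_abs,
    iqr_abs_diff = IQR(abs(d), type = quantile_type),
    abs_diff_ratio = mean_abs / mean(s),
    relative_change = d / mean(s) * 100,
    iqr_relative_change = IQR(d / s, type = quantile_type) * 100
  ), class = "paired_summary")
}

#' @export
print.paired_summary <- function(x, ...) {
  cat(sprintf(paste0("paired_summary: %d pairs\n",
                     "  mean |diff| = %.3f, IQR |diff| = %.3f\n",
                     "  abs diff ratio = %.3f, IQR relative change = %.0f%%\n"),
              x$n_pairs, x$mean_abs_diff, x$iqr_abs_diff, x$abs_diff_ratio,
              x$iqr_relative_change))
  invisible(x)
}

#' One row of a paired-difference results table
#'
#' @param summary A `paired_summary`.
#' @param chamber,pacing_site Map keys for the row.
#' @return One-row data frame in the layout of the paired results tables.
#' @export
paired_summary_row <- function(summary, chamber, pacing_site) {
  data.frame(chamber = chamber, pacing_site = pacing_site,
             n_pairs = summary$n_pairs,
             mean_abs_diff = summary$mean_abs_diff,
             iqr_abs_diff = summary$iqr_abs_diff,
             abs_diff_ratio = summary$abs_diff_ratio,
             iqr_relative_change_pct = summary$iqr_relative_change)
}
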