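# End-to-end pipeline: simulate (or load) maps -> circle covering -> local
# metrics -> mixed models -> paired differences -> report files.

#' Pipeline configuration
#'
#' @param protocol Study protocol data frame (default [default_protocol()]).
#' @param params [generator_params()] for simulation.
#' @param analysis [analysis_config()].
#' @param seed Global seed (mandatory for simulation).
#' @param at_hr Reference heart rate for estimates, 90 or 145 bpm.
#' @param adjustment `"sidak"` or `"tukey"` contrast adjustment.
#' @param granularity `"chamber"` or `"wall"` model grouping.
#' @param maps_dir Optional directory of `.vtk` maps; when given, simulation
#'   is skipped and the maps are loaded instead.
#' @param chamber_specs Optional per-chamber [chamber_spec()] overrides.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = default_protocol(),
                            params = generator_params(),
                            analysis = analysis_config(),
                            seed = 1L, at_hr = 145,
                            adjustment = c("sidak", "tukey"),
                            granularity = c("chamber", "wall"),
                            maps_dir = NULL, chamber_specs = NULL) {
  adjustment <- match.arg(adjustment)
  granularity <- match.arg(granularity)
  stopifnot(at_hr %in% c(90, 145), length(seed) == 1L)
  structure(list(protocol = protocol, params = params, analysis = analysis,
                 seed = as.integer(seed), at_hr = at_hr,
                 adjustment = adjustment, granularity = granularity,
                 maps_dir = maps_dir, chamber_specs = chamber_specs),
            class = "pipeline_config")
}

stage_try <- function(stage, map_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for map '%s': %s", stage, map_id,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (skipped when `maps_dir` is given) -> circle covering ->
#' per-circle metrics -> mixed models with marginal means and contrasts ->
#' paired-map differences, and collects everything in a results bundle with
#' a reproducibility manifest (seed, per-stage counts, table checksums).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `results_bundle`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$maps_dir)) {
    paths <- list.files(config$maps_dir, pattern = "\\.vtk$",
                        full.names = TRUE)
    maps <- lapply(paths, load_map)
    names(maps) <- sub("\\.vtk$", "", basename(paths))
  } else {
    maps <- stage_try("simulate", "*", generate_study(
      config$protocol, config$params, config$seed, config$chamber_specs))
  }
  say("simulate: %d maps", length(maps))
  if (length(maps) == 0L) {
    return(structure(list(
      maps = maps, coverage = data.frame(), metrics = data.frame(),
      models = NULL, marginal_means = NULL, contrasts = NULL,
      rate_effects = NULL, paired = data.frame(), paired_pairs = data.frame(),
      manifest = list(seed = config$seed, n_maps = 0L,
                      counts = list(), hash = NA_character_)
    ), class = "results_bundle"))
  }
  ac <- config$analysis
  circle_sets <- list(); coverage <- list(); metrics <- list()
  for (id in names(maps)) {
    m <- maps[[id]]
    centers <- stage_try("cover", id, sample_centers(
      m, ac$radius_mm, ac$spacing_mm,
      seed = derive_seed(config$seed, 9000L + match(id, names(maps)))))
    cs <- stage_try("cover", id, build_circles(m, centers, ac$radius_mm,
                                               ac$min_points))
    circle_sets[[id]] <- cs
    cov <- coverage_summary(cs)
    cov$map_id <- id
    coverage[[id]] <- cov
    mt <- stage_try("metrics", id, compute_map_metrics(m, cs, ac))
    mt$map_id <- id
    metrics[[id]] <- mt
  }
  coverage <- do.call(rbind, coverage)
  metrics <- do.call(rbind, metrics)
  rownames(coverage) <- rownames(metrics) <- NULL
  say("cover: %.0f circles/map, metrics: %d rows (%d excluded)",
      mean(coverage$n_circles), nrow(metrics), sum(metrics$excluded))

  fits <- mmeans <- ctr <- reff <- NULL
  n_groups <- length(unique(make_group(metrics, config$granularity)))
  if (n_groups >= 2L && length(unique(metrics$animal_id)) >= 2L) {
    fits <- list(
      cv = stage_try("model", "*", fit_mixed_model(metrics, "log_cv",
                                                   config$granularity)),
      va = stage_try("model", "*", fit_mixed_model(metrics, "va",
                                                   config$granularity)))
    reff <- list(cv = rate_effect(fits$cv), va = rate_effect(fits$va))
    mmeans <- list(cv = marginal_means(fits$cv, config$at_hr),
                   va = marginal_means(fits$va, config$at_hr))
    ctr <- list(
      cv = contrasts_vs_nsr(fits$cv, config$at_hr, config$adjustment),
      va = contrasts_vs_nsr(fits$va, config$at_hr, config$adjustment))
  }

  paired_rows <- list(); all_pairs <- list()
  proto <- lapply(maps, function(m) m$meta)
  for (id in names(maps)) {
    mt <- proto[[id]]
    if (mt$rhythm != "paced") next
    nsr_ids <- names(maps)[vapply(proto, function(x) {
      x$rhythm == "NSR" && x$chamber == mt$chamber &&
        x$animal_id == mt$animal_id
    }, logical(1))]
    if (length(nsr_ids) == 0L) next
    hr_gap <- vapply(nsr_ids, function(x) abs(proto[[x]]$heart_rate_bpm -
                                                mt$heart_rate_bpm), numeric(1))
    nsr_id <- nsr_ids[which.min(hr_gap)]
    matches <- stage_try("diff", id, suppressWarnings(match_circles(
      circle_sets[[id]], circle_sets[[nsr_id]])))
    if (nrow(matches) == 0L) next
    for (measure in c("cv", "va")) {
      pv <- paired_values(matches, metrics[metrics$map_id == id, ],
                          metrics[metrics$map_id == nsr_id, ], measure)
      if (nrow(pv) == 0L) next
      pv$map_id <- id; pv$nsr_map_id <- nsr_id
      pv$chamber <- mt$chamber; pv$pacing_site <- mt$pacing_site
      pv$measure <- measure
      all_pairs[[paste(id, measure)]] <- pv
      ps <- paired_summary(pv)
      row <- paired_summary_row(ps, mt$chamber, mt$pacing_site)
      row$map_id <- id; row$nsr_map_id <- nsr_id; row$measure <- measure
      paired_rows[[paste(id, measure)]] <- row
    }
  }
  paired <- if (length(paired_rows)) do.call(rbind, paired_rows) else data.frame()
  all_pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else data.frame()
  rownames(paired) <- rownames(all_pairs) <- NULL
  # pooled per (chamber, pacing site, measure), the layout of the paired
  # results tables; relative changes pooled over the contributing map pairs
  pooled <- list()
  if (nrow(all_pairs)) {
    for (k in unique(paste(all_pairs$chamber, all_pairs$pacing_site,
                           all_pairs$measure))) {
      sub <- all_pairs[paste(all_pairs$chamber, all_pairs$pacing_site,
                             all_pairs$measure) == k, ]
      ps <- paired_summary(sub)
      row <- paired_summary_row(ps, sub$chamber[1], sub$pacing_site[1])
      row$measure <- sub$measure[1]
      pooled[[k]] <- row
    }
    pooled <- do.call(rbind, pooled)
    rownames(pooled) <- NULL
  } else pooled <- data.frame()
  say("diff: %d map pairs, %d pooled rows", nrow(paired), nrow(pooled))

  counts <- list(
    n_maps = length(maps),
    n_circles = nrow(metrics),
    n_excluded = sum(metrics$excluded),
    excluded_by_reason = as.list(table(
      metrics$exclusion_reason[metrics$excluded])),
    n_map_pairs = if (nrow(paired)) nrow(paired) / 2 else 0,
    mean_circles_per_map = mean(coverage$n_circles),
    mean_points_per_circle = mean(coverage$mean_points_per_circle)
  )
  bundle <- structure(list(
    maps = maps, circle_sets = circle_sets, coverage = coverage,
    metrics = metrics, models = fits, rate_effects = reff,
    marginal_means = mmeans, contrasts = ctr,
    paired = paired, paired_pooled = pooled, paired_pairs = all_pairs,
    config = config,
    manifest = list(seed = config$seed, n_maps = length(maps),
                    counts = counts, hash = NA_character_)
  ), class = "results_bundle")
  bundle$manifest$hash <- bundle_hash(bundle)
  bundle
}

# checksum over the numeric content of the bundle's tables
bundle_hash <- function(bundle) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  num <- function(d) {
    if (is.null(d) || !nrow(d)) return(invisible())
    for (cl in names(d)) {
      v <- d[[cl]]
      if (is.numeric(v)) writeBin(round(v, 9), con) else
        writeLines(as.character(v), con)
    }
  }
  num(bundle$coverage); num(bundle$metrics)
  if (!is.null(bundle$marginal_means)) {
    num(bundle$marginal_means$cv); num(bundle$marginal_means$va)
    num(bundle$contrasts$cv); num(bundle$contrasts$va)
  }
  num(bundle$paired); num(bundle$paired_pooled)
  close(con)
  unname(tools::md5sum(f))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle\n")
  cat(sprintf("  maps: %d, circles: %d (%d excluded)\n",
              x$manifest$n_maps, NROW(x$metrics),
              sum(x$metrics$excluded %||% 0)))
  if (!is.null(x$rate_effects)) {
    cat(sprintf("  CV rate effect x%.4f/bpm; VA slope %+.4f mV/bpm\n",
                x$rate_effects$cv$cv_multiplier_per_bpm,
                x$rate_effects$va$va_slope_mv_per_bpm))
  }
  cat(sprintf("  manifest hash: %s\n", x$manifest$hash))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render tables, figures and a text summary from a results bundle
#'
#' Writes the coverage, metrics, estimate, contrast and paired tables as
#' CSV; estimate-with-CI panels per chamber, heart-rate trend plots and
#' relative-change boxplots as PNG; and a plain-text summary of the fitted
#' rate effects and significant contrasts.  Each figure also gets a CSV of
#' exactly the data it displays.
#'
#' @param bundle A `results_bundle`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(d, name) {
    if (is.null(d) || !NROW(d)) return(invisible())
    p <- file.path(dir, name)
    write.csv(d, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(bundle$coverage, "coverage.csv")
  wcsv(bundle$metrics, "metrics.csv")
  wcsv(bundle$paired, "paired_by_map.csv")
  wcsv(bundle$paired_pooled, "paired_pooled.csv")
  wcsv(bundle$paired_pairs, "paired_circles.csv")
  png_dev <- function(name) {
    p <- file.path(dir, name)
    grDevices::png(p, width = 1400, height = 1000, res = 150)
    files <<- c(files, p)
    p
  }
  if (NROW(bundle$metrics)) {
    d <- bundle$metrics[!bundle$metrics$excluded, ]
    for (resp in c("cv", "va")) {
      d$y <- if (resp == "cv") d$cv_mps else d$va_mv
      png_dev(sprintf("rate_%s.png", resp))
      print(ggplot2::ggplot(d, ggplot2::aes(x = .data$heart_rate_bpm,
                                            y = .data$y,
                                            group = .data$heart_rate_bpm)) +
              ggplot2::geom_boxplot(outlier.size = 0.3) +
              ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                                   formula = y ~ x, se = FALSE,
                                   linewidth = 0.8) +
              ggplot2::facet_wrap(~chamber, scales = "free_y") +
              ggplot2::labs(x = "heart rate (bpm)",
                            y = if (resp == "cv") "CV (m/s)" else "VA (mV)"),
            )
      grDevices::dev.off()
      wcsv(d[, c("map_id", "chamber", "heart_rate_bpm", "y")],
           sprintf("rate_%s_data.csv", resp))
    }
  }
  if (!is.null(bundle$marginal_means)) {
    for (resp in c("cv", "va")) {
      mm <- bundle$marginal_means[[resp]]
      ct <- bundle$contrasts[[resp]]
      sig <- if (!is.null(ct)) ct[ct$p_adjusted < 0.05, ] else NULL
      mm$sig <- ""
      if (NROW(sig)) {
        mm$sig[match(paste(sig$chamber, sig$wall, sig$group),
                     paste(mm$chamber, mm$wall, mm$group))] <- "*"
      }
      wcsv(mm, sprintf("estimates_%s.csv", resp))
      wcsv(ct, sprintf("contrasts_%s.csv", resp))
      png_dev(sprintf("estimates_%s.png", resp))
      print(ggplot2::ggplot(mm, ggplot2::aes(x = .data$group,
                                             y = .data$estimate)) +
              ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                                    ymax = .data$ci_hi)) +
              ggplot2::geom_text(ggplot2::aes(label = .data$sig,
                                              y = .data$ci_hi),
                                 vjust = -0.4, size = 5) +
              ggplot2::facet_wrap(~chamber, scales = "free") +
              ggplot2::labs(x = "rhythm / pacing site",
                            y = if (resp == "cv")
                              sprintf("estimated CV at %d bpm (m/s)",
                                      mm$at_hr[1])
                            else sprintf("estimated VA at %d bpm (mV)",
                                         mm$at_hr[1])))
      grDevices::dev.off()
    }
  }
  if (NROW(bundle$paired_pairs)) {
    for (resp in c("cv", "va")) {
      pp <- bundle$paired_pairs[bundle$paired_pairs$measure == resp, ]
      if (!nrow(pp)) next
      pp$rel <- (pp$pace_value - pp$intrinsic_value) /
        ave(pp$intrinsic_value, pp$map_id) * 100
      png_dev(sprintf("relative_change_%s.png", resp))
      print(ggplot2::ggplot(pp, ggplot2::aes(x = .data$pacing_site,
                                             y = .data$rel)) +
              ggplot2::geom_boxplot(outlier.size = 0.3) +
              ggplot2::facet_wrap(~chamber, scales = "free_x") +
              ggplot2::labs(x = "pacing site",
                            y = sprintf("relative %s change (%%)",
                                        toupper(resp))))
      grDevices::dev.off()
      wcsv(pp, sprintf("relative_change_%s_data.csv", resp))
    }
  }
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  cat("Pipeline summary\n================\n", file = con)
  cat(sprintf("seed: %d, maps: %d, circles: %d (%d excluded)\n",
              bundle$manifest$seed, bundle$manifest$n_maps,
              NROW(bundle$metrics), sum(bundle$metrics$excluded %||% 0)),
      file = con)
  if (!is.null(bundle$rate_effects)) {
    cat(sprintf("CV rate effect: x%.4f per bpm (SE %.4f)\n",
                bundle$rate_effects$cv$cv_multiplier_per_bpm,
                bundle$rate_effects$cv$se), file = con)
    cat(sprintf("VA rate effect: %+.4f mV per bpm (SE %.4f)\n",
                bundle$rate_effects$va$va_slope_mv_per_bpm,
                bundle$rate_effects$va$se), file = con)
    for (resp in c("cv", "va")) {
      ct <- bundle$contrasts[[resp]]
      sig <- ct[ct$p_adjusted < 0.05, ]
      cat(sprintf("\nsignificant %s contrasts vs NSR (p < 0.05):\n",
                  toupper(resp)), file = con)
      if (nrow(sig)) {
        for (i in seq_len(nrow(sig))) {
          cat(sprintf("  %s (%s), pacing %s: %s%.3f (adj. p = %.4g)\n",
                      sig$chamber[i], sig$wall[i], sig$group[i],
                      if (resp == "cv") "x" else "", sig$effect[i],
                      sig$p_adjusted[i]), file = con)
        }
      } else cat("  none\n", file = con)
    }
  }
  close(con)
  files <- c(files, summary_path)
  invisible(files)
}
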