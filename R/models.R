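# Linear mixed-effects layer: log(CV) or VA ~ heart rate + location group
# with a random per-animal intercept; marginal means at a reference heart
# rate and adjusted paced-versus-sinus contrasts.

make_group <- function(metrics, granularity) {
  site <- ifelse(metrics$rhythm == "NSR", "NSR", metrics$pacing_site)
  if (granularity == "wall") {
    interaction(metrics$chamber, metrics$wall, site, sep = ":", drop = TRUE)
  } else {
    interaction(metrics$chamber, site, sep = ":", drop = TRUE)
  }
}

#' Fit the mixed-effects model for CV or VA
#'
#' Fits `response ~ heart_rate_bpm + group + (1 | animal_id)` by REML, where
#' `group` is the interaction of mapped chamber (or chamber and wall) with
#' the rhythm/pacing site, with no heart-rate-by-group interaction (the rate
#' effect is assumed common to all chambers).  CV is modelled on the natural
#' log scale.  Rows flagged `excluded` are dropped before fitting.
#'
#' @param metrics Metrics table from [compute_map_metrics()] (rows of several
#'   maps stacked).
#' @param response `"log_cv"` or `"va"`.
#' @param granularity `"chamber"` for whole-chamber groups, `"wall"` for
#'   chamber-wall subregion groups.
#' @return An object of class `model_fit`: the `lmerModLmerTest` fit plus the
#'   model frame and descriptors.
#' @export
fit_mixed_model <- function(metrics, response = c("log_cv", "va"),
                            granularity = c("chamber", "wall")) {
  response <- match.arg(response)
  granularity <- match.arg(granularity)
  d <- metrics[!metrics$excluded, , drop = FALSE]
  d$y <- if (response == "log_cv") log(d$cv_mps) else d$va_mv
  d <- d[is.finite(d$y), , drop = FALSE]
  d$group <- make_group(d, granularity)
  d$animal_id <- factor(d$animal_id)
  if (nlevels(d$animal_id) < 2L) {
    stop("need at least 2 animals to fit a random animal intercept",
         call. = FALSE)
  }
  if (nlevels(d$group) < 2L) stop("need at least 2 groups", call. = FALSE)
  tab <- table(d$group)
  if (any(tab < 2L)) {
    stop("groups with fewer than 2 observations: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  fit <- lmerTest::lmer(y ~ heart_rate_bpm + group + (1 | animal_id),
                        data = d, REML = TRUE)
  if (length(lme4::fixef(fit)) < nlevels(d$group) + 1L) {
    stop("unidentifiable fit: the grouping '", granularity,
         "' is rank deficient (confounded groups)", call. = FALSE)
  }
  if (lme4::isSingular(fit)) {
    warning("random-intercept variance estimated at the boundary (0); ",
            "fit accepted", call. = FALSE)
  }
  structure(list(model = fit, response = response, granularity = granularity,
                 data = d, hr_range = range(d$heart_rate_bpm)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %s ~ heart rate + %s group + (1 | animal)\n",
              x$response, x$granularity))
  cat(sprintf("  %d circles, %d groups, %d animals\n", nrow(x$data),
              nlevels(x$data$group), nlevels(x$data$animal_id)))
  re <- rate_effect(x)
  if (x$response == "log_cv") {
    cat(sprintf("  CV rate effect: x%.4f per bpm (SE %.4f)\n",
                re$cv_multiplier_per_bpm, re$se))
  } else {
    cat(sprintf("  VA rate effect: %+.4f mV per bpm (SE %.4f)\n",
                re$va_slope_mv_per_bpm, re$se))
  }
  invisible(x)
}

hr_coef <- function(fit) {
  s <- coef(summary(fit$model))
  s["heart_rate_bpm", c("Estimate", "Std. Error")]
}

#' Per-bpm rate effect of a fitted model
#'
#' For a log-CV fit the heart-rate coefficient is back-transformed to the
#' per-bpm multiplier `exp(b)` (SE by the delta method); for a VA fit the
#' slope is passed through in mV/bpm.
#'
#' @param fit A `model_fit`.
#' @return An object of class `rate_effect` with `cv_multiplier_per_bpm`,
#'   `va_slope_mv_per_bpm` (one of the two is `NA`), `se` and `response`.
#' @export
rate_effect <- function(fit) {
  b <- hr_coef(fit)
  if (fit$response == "log_cv") {
    structure(list(cv_multiplier_per_bpm = exp(b[[1]]),
                   va_slope_mv_per_bpm = NA_real_,
                   se = exp(b[[1]]) * b[[2]], response = "log_cv"),
              class = "rate_effect")
  } else {
    structure(list(cv_multiplier_per_bpm = NA_real_,
                   va_slope_mv_per_bpm = b[[1]],
                   se = b[[2]], response = "va"),
              class = "rate_effect")
  }
}

split_group <- function(labels, granularity) {
  parts <- strsplit(as.character(labels), ":", fixed = TRUE)
  if (granularity == "wall") {
    data.frame(chamber = vapply(parts, `[`, "", 1),
               wall = vapply(parts, `[`, "", 2),
               group = vapply(parts, `[`, "", 3))
  } else {
    data.frame(chamber = vapply(parts, `[`, "", 1),
               wall = "overall",
               group = vapply(parts, `[`, "", 2))
  }
}

emm_grid <- function(fit, at_hr) {
  lo <- fit$hr_range[1] * 0.8; hi <- fit$hr_range[2] * 1.2
  if (at_hr < lo || at_hr > hi) {
    warning(sprintf("at_hr = %g bpm extrapolates beyond the observed range %g-%g (+/-20%%)",
                    at_hr, fit$hr_range[1], fit$hr_range[2]), call. = FALSE)
  }
  emmeans::emmeans(fit$model, "group", at = list(heart_rate_bpm = at_hr),
                   lmer.df = "satterthwaite", lmerTest.limit = 1e5)
}

# emmeans names the CI columns asymp.LCL/UCL when it falls back to z tests
ci_cols <- function(s) {
  list(lo = s[[intersect(c("lower.CL", "asymp.LCL"), names(s))[1]]],
       hi = s[[intersect(c("upper.CL", "asymp.UCL"), names(s))[1]]])
}

#' Marginal group means at a reference heart rate
#'
#' Population-level predictions per location group with the heart rate fixed
#' at `at_hr` and the random animal intercept at its mean (0).  Log-CV fits
#' are back-transformed to m/s, with delta-method SEs and exponentiated
#' confidence limits.
#'
#' @param fit A `model_fit`.
#' @param at_hr Reference heart rate, bpm (conventionally 90 or 145); values
#'   beyond the observed range +/-20% trigger a warning.
#' @return Data frame with `chamber`, `wall`, `group` (pacing site or
#'   `"NSR"`), `estimate`, `se`, `ci_lo`, `ci_hi`, `at_hr`.
#' @export
marginal_means <- function(fit, at_hr = 145) {
  s <- summary(emm_grid(fit, at_hr), infer = c(TRUE, FALSE))
  out <- split_group(s$group, fit$granularity)
  ci <- ci_cols(s)
  if (fit$response == "log_cv") {
    out$estimate <- exp(s$emmean)
    out$se <- exp(s$emmean) * s$SE
    out$ci_lo <- exp(ci$lo); out$ci_hi <- exp(ci$hi)
  } else {
    out$estimate <- s$emmean; out$se <- s$SE
    out$ci_lo <- ci$lo; out$ci_hi <- ci$hi
  }
  out$at_hr <- at_hr
  out
}

#' Paced-versus-sinus contrasts at a reference heart rate
#'
#' Within each chamber (or chamber wall), contrasts each pacing group
#' against the sinus-rhythm group of the same family.  For log-CV fits the
#' contrast is reported as a back-transformed ratio (paced/NSR); for VA as a
#' difference in mV.  With `adjustment = "sidak"` only the targeted
#' paced-vs-NSR comparisons form the multiplicity family; with `"tukey"`
#' p-values come from the all-pairwise Tukey HSD family within the chamber
#' (wall), and only the vs-NSR rows are returned.
#'
#' @param fit A `model_fit`.
#' @param at_hr Reference heart rate, bpm.
#' @param adjustment `"sidak"` (targeted) or `"tukey"` (all pairwise).
#' @return Data frame with `chamber`, `wall`, `group`, `effect` (ratio or mV
#'   difference), `se`, `ci_lo`, `ci_hi`, `p_adjusted`, `adjustment`.
#' @export
contrasts_vs_nsr <- function(fit, at_hr = 145,
                             adjustment = c("sidak", "tukey")) {
  adjustment <- match.arg(adjustment)
  emm <- emm_grid(fit, at_hr)
  info <- split_group(summary(emm)$group, fit$granularity)
  fam <- paste(info$chamber, info$wall)
  out <- list()
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) < 2L) next
    if (!any(info$group[idx] == "NSR")) {
      stop("missing NSR reference group in family '", f, "'", call. = FALSE)
    }
    ref <- idx[info$group[idx] == "NSR"]
    trt <- setdiff(idx, ref)
    if (length(trt) == 0L) next
    sub <- emm[idx]
    ref_pos <- match(ref, idx)
    if (adjustment == "sidak") {
      ct <- emmeans::contrast(sub, method = "trt.vs.ctrl", ref = ref_pos,
                              adjust = "sidak")
      cs <- summary(ct, infer = c(TRUE, TRUE))
      lab <- sub("^group", "", sapply(strsplit(as.character(cs$contrast),
                                               " - "), `[`, 1))
      ci <- ci_cols(cs)
      est <- cs$estimate; se <- cs$SE
      lo <- ci$lo; hi <- ci$hi; pv <- cs$p.value
    } else {
      ct <- emmeans::contrast(sub, method = "pairwise", adjust = "tukey")
      cs <- summary(ct, infer = c(TRUE, TRUE))
      sides <- strsplit(as.character(cs$contrast), " - ")
      nsr_lab <- as.character(summary(emm)$group[ref])
      a <- sapply(sides, `[`, 1); b <- sapply(sides, `[`, 2)
      keep <- a == nsr_lab | b == nsr_lab
      cs <- cs[keep, , drop = FALSE]
      ci <- ci_cols(cs)
      flip <- a[keep] == nsr_lab  # orient as paced - NSR
      est <- ifelse(flip, -cs$estimate, cs$estimate)
      se <- cs$SE
      lo <- ifelse(flip, -ci$hi, ci$lo)
      hi <- ifelse(flip, -ci$lo, ci$hi)
      pv <- cs$p.value
      lab <- ifelse(flip, b[keep], a[keep])
    }
    lab_info <- split_group(lab, fit$granularity)
    res <- data.frame(chamber = lab_info$chamber, wall = lab_info$wall,
                      group = lab_info$group)
    if (fit$response == "log_cv") {
      res$effect <- exp(est); res$se <- exp(est) * se
      res$ci_lo <- exp(lo); res$ci_hi <- exp(hi)
    } else {
      res$effect <- est; res$se <- se; res$ci_lo <- lo; res$ci_hi <- hi
    }
    res$p_adjusted <- pv
    res$adjustment <- adjustment
    out[[f]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Predict CV or VA at a heart rate from a rate law
#'
#' Applies the fitted rate laws in their reported parameterisation:
#' CV = intercept x multiplier^hr; VA = intercept + slope x hr.
#'
#' @param intercept Chamber-specific intercept (m/s for CV, mV for VA).
#' @param rate_effect A `rate_effect` (or a bare number: the multiplier for
#'   CV, the slope for VA).
#' @param hr Heart rate, bpm (> 0, or 0 to read off the intercept).
#' @param response `"cv"` or `"va"`.
#' @return Predicted value.
#' @export
#' @examples
#' predict_rate(0.5, 1.004, hr = 100, response = "cv")  # ~0.745 m/s
predict_rate <- function(intercept, rate_effect, hr, response = c("cv", "va")) {
  response <- match.arg(response)
  val <- if (inherits(rate_effect, "rate_effect")) {
    if (response == "cv") rate_effect$cv_multiplier_per_bpm
    else rate_effect$va_slope_mv_per_bpm
  } else rate_effect
  if (response == "cv") intercept * val^hr else intercept + val * hr
}
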