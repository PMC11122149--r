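# Mixed-effects layer: rate-effect recovery, marginal means, contrasts.

four_chambers <- function(sites = c("NSR", "RA")) {
  expand.grid(chamber = c("RA", "LA", "RV", "LV"), site = sites,
              stringsAsFactors = FALSE)
}

test_that("a null simulation recovers a zero rate effect", {
  mt <- sim_metrics(sim_maps(four_chambers("NSR"), n_per_group = 8),
                    cv_base = 1.0, va_slope = 0, seed = 21)
  fit <- fit_mixed_model(mt, "log_cv")
  re <- rate_effect(fit)
  expect_lt(abs(re$cv_multiplier_per_bpm - 1.0), 2 * re$se)
  fitv <- fit_mixed_model(mt, "va")
  rev <- rate_effect(fitv)
  expect_lt(abs(rev$va_slope_mv_per_bpm), 2 * rev$se)
})

test_that("generating rate effects are recovered within 2 SE", {
  mt <- sim_metrics(sim_maps(four_chambers(), n_per_group = 6), seed = 22)
  re <- rate_effect(fit_mixed_model(mt, "log_cv"))
  expect_lt(abs(re$cv_multiplier_per_bpm - 1.004), 2 * re$se)
  rev <- rate_effect(fit_mixed_model(mt, "va"))
  expect_lt(abs(rev$va_slope_mv_per_bpm - (-0.012)), 2 * rev$se)
})

test_that("constant data give constant marginal means at any heart rate", {
  mt <- sim_metrics(sim_maps(four_chambers(), n_per_group = 4),
                    cv_base = 1.0, sigma_log = 0, animal_sd_log = 0,
                    cv_intercepts = c(RA = 0.7, LA = 0.7, RV = 0.7, LV = 0.7),
                    seed = 23)
  fit <- suppressWarnings(fit_mixed_model(mt, "log_cv"))
  for (hr in c(90, 145)) {
    mm <- suppressWarnings(marginal_means(fit, hr))
    expect_true(all(abs(mm$estimate - 0.7) < 1e-6))
  }
  ct <- suppressWarnings(contrasts_vs_nsr(fit, 145))
  expect_true(all(abs(ct$effect - 1) < 1e-6))
})

test_that("marginal means of a zero-slope fit equal group means on balanced
           data", {
  maps <- sim_maps(four_chambers(), n_per_group = 4,
                   animals = paste0("pig", 1:4))
  mt <- sim_metrics(maps, cv_base = 1.0, animal_sd_log = 0, seed = 24)
  fit <- suppressWarnings(fit_mixed_model(mt, "log_cv"))
  mm <- suppressWarnings(marginal_means(fit, 120))
  grp <- paste(mt$chamber, ifelse(mt$rhythm == "NSR", "NSR",
                                  mt$pacing_site), sep = ":")
  bylog <- tapply(log(mt$cv_mps), grp, mean)
  got <- mm$estimate[match(names(bylog), paste(mm$chamber, mm$group,
                                               sep = ":"))]
  # balanced design: back-transformed marginal means coincide with
  # exponentiated raw log-means up to the tiny fitted-slope adjustment
  expect_equal(got, as.numeric(exp(bylog)), tolerance = 0.02)
})

test_that("marginal means recover generator chamber intercepts under small
           noise", {
  mt <- sim_metrics(sim_maps(four_chambers("NSR"), n_per_group = 6),
                    sigma_log = 0.05, animal_sd_log = 0.01, seed = 25,
                    cv_intercepts = c(RA = 0.85, LA = 1.05, RV = 0.75,
                                      LV = 0.9))
  fit <- fit_mixed_model(mt, "log_cv")
  mm <- marginal_means(fit, 145)
  truth <- c(RA = 0.85, LA = 1.05, RV = 0.75, LV = 0.9)
  for (ch in names(truth)) {
    row <- mm[mm$chamber == ch, ]
    expect_lt(abs(row$estimate - truth[[ch]]), 2.5 * row$se + 0.01)
  }
})

test_that("pacing contrasts recover generating multipliers and offsets
           without bias over replicate simulations", {
  maps <- sim_maps(four_chambers(c("NSR", "RA", "LV")), n_per_group = 6)
  reps <- 8
  got <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("ra_ra", "lv_ra", "la_null",
                                        "rv_lv_va")))
  ses <- got
  for (r in seq_len(reps)) {
    mt <- sim_metrics(maps,
                      cv_mult = list("RA:RA" = 0.75, "LV:RA" = 0.49),
                      va_offsets = list("RV:LV" = 2.55, "LV:RA" = -1.83),
                      seed = 100 + r)
    ct <- contrasts_vs_nsr(fit_mixed_model(mt, "log_cv"), 145, "sidak")
    pick <- function(d, ch, g) d[d$chamber == ch & d$group == g, ]
    got[r, 1:3] <- c(pick(ct, "RA", "RA")$effect,
                     pick(ct, "LV", "RA")$effect,
                     pick(ct, "LA", "RA")$effect)
    ses[r, 1:3] <- c(pick(ct, "RA", "RA")$se, pick(ct, "LV", "RA")$se,
                     pick(ct, "LA", "RA")$se)
    cv <- contrasts_vs_nsr(fit_mixed_model(mt, "va"), 145, "sidak")
    got[r, 4] <- pick(cv, "RV", "LV")$effect
    ses[r, 4] <- pick(cv, "RV", "LV")$se
  }
  truth <- c(0.75, 0.49, 1.0, 2.55)
  for (k in 1:4) {
    # mean recovered effect within 2 SE of the replicate mean
    expect_lt(abs(mean(got[, k]) - truth[k]),
              2 * mean(ses[, k]) / sqrt(reps))
    # and every individual fit within 4 of its own SE
    expect_true(all(abs(got[, k] - truth[k]) < 4 * ses[, k]))
  }
})

test_that("tukey and sidak adjustments agree on effects, differ on family",
          {
  mt <- sim_metrics(sim_maps(four_chambers(c("NSR", "RA", "LV")),
                             n_per_group = 5),
                    cv_mult = list("RA:RA" = 0.8), seed = 27)
  fit <- fit_mixed_model(mt, "log_cv")
  cs <- contrasts_vs_nsr(fit, 145, "sidak")
  ctk <- contrasts_vs_nsr(fit, 145, "tukey")
  key <- function(d) paste(d$chamber, d$group)
  ctk <- ctk[match(key(cs), key(ctk)), ]
  expect_equal(cs$effect, ctk$effect, tolerance = 1e-8)
  expect_identical(unique(cs$adjustment), "sidak")
  expect_identical(unique(ctk$adjustment), "tukey")
})

test_that("missing NSR reference and deficient designs raise errors", {
  mt <- sim_metrics(sim_maps(data.frame(chamber = "RA",
                                        site = c("RA", "LA")),
                             n_per_group = 4), seed = 28)
  fit <- fit_mixed_model(mt, "log_cv")
  expect_error(contrasts_vs_nsr(fit, 145), "NSR")
  one_animal <- sim_metrics(sim_maps(four_chambers(), n_per_group = 2,
                                     animals = "pig1"), seed = 29)
  expect_error(fit_mixed_model(one_animal, "log_cv"), "animals")
  lone <- sim_metrics(sim_maps(four_chambers(), n_per_group = 4),
                      circles_per_map = 3, seed = 30)
  grp <- paste(lone$chamber, lone$pacing_site)
  lone <- lone[grp != "RA RA" | seq_len(nrow(lone)) ==
                 which(grp == "RA RA")[1], ]
  expect_error(fit_mixed_model(lone, "log_cv"), "fewer than 2")
})

test_that("wall-level grouping fits and contrasts per chamber wall", {
  maps <- sim_maps(four_chambers(c("NSR", "RA")), n_per_group = 5)
  mt <- sim_metrics(maps, walls = c("anterior", "posterior"),
                    cv_mult = list("RA:RA" = 0.7), seed = 31)
  fit <- fit_mixed_model(mt, "log_cv", granularity = "wall")
  ct <- contrasts_vs_nsr(fit, 145)
  expect_setequal(unique(ct$wall), c("anterior", "posterior"))
  r <- ct[ct$chamber == "RA" & ct$wall == "anterior" & ct$group == "RA", ]
  expect_lt(abs(r$effect - 0.7), 2.5 * r$se)
})

test_that("extrapolated reference heart rates warn", {
  mt <- sim_metrics(sim_maps(four_chambers(), n_per_group = 4), seed = 32)
  mt$heart_rate_bpm <- pmin(mt$heart_rate_bpm, 100)
  fit <- fit_mixed_model(mt, "log_cv")
  expect_warning(marginal_means(fit, 145), "extrapolate")
})

test_that("predict_rate applies the reported rate laws", {
  expect_equal(predict_rate(0.5, 1.004, hr = 0, response = "cv"), 0.5)
  expect_equal(predict_rate(0.5, 1.004, hr = 100, response = "cv"),
               0.7453, tolerance = 1e-4)
  expect_equal(predict_rate(6.0, -0.012, hr = 100, response = "va"), 4.8)
})

test_that("rate effects replicate across synthetic studies without bias and
           with near-nominal CI coverage", {
  small <- lapply(c("RA", "LA", "RV", "LV"), function(ch)
    chamber_spec(ch, semi_axes = chamber_spec(ch)$semi_axes * 0.5))
  names(small) <- c("RA", "LA", "RV", "LV")
  n_rep <- 20
  mult <- se_mult <- slope <- se_slope <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    maps <- generate_study(default_protocol(), seed = 4000 + r,
                           chamber_specs = small)
    mt <- do.call(rbind, lapply(maps, function(m) {
      cen <- sample_centers(m, 5, 4.4, seed = 1)
      compute_map_metrics(m, build_circles(m, cen))
    }))
    re <- rate_effect(fit_mixed_model(mt, "log_cv"))
    mult[r] <- re$cv_multiplier_per_bpm; se_mult[r] <- re$se
    rv <- rate_effect(fit_mixed_model(mt, "va"))
    slope[r] <- rv$va_slope_mv_per_bpm; se_slope[r] <- rv$se
  }
  # mean recovered effect within one average fitted SE of the truth
  expect_lt(abs(mean(mult) - 1.004), mean(se_mult))
  expect_lt(abs(mean(slope) + 0.012), mean(se_slope))
  # 95% CIs cover the generating values at least 90% of the time
  expect_gte(mean(abs(mult - 1.004) <= 1.96 * se_mult), 0.9)
  expect_gte(mean(abs(slope + 0.012) <= 1.96 * se_slope), 0.9)
})
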