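test_that("trophic level follows the single end-member nitrogen model", {
  cfg <- trophic_config()
  expect_equal(estimate_trophic_level(5, 5, cfg), 2.1)
  expect_equal(estimate_trophic_level(5 + 3.4, 5, cfg), 3.1)
  expect_equal(estimate_trophic_level(10.0, 4.9, cfg), 2.1 + 5.1 / 3.4)
  expect_equal(estimate_trophic_level(10.0, 4.9, cfg), 3.6, tolerance = 1e-12)
  # invariant to shifting both consumer and baseline
  expect_equal(estimate_trophic_level(12.3 + 7, 6.1 + 7, cfg),
               estimate_trophic_level(12.3, 6.1, cfg))
})

test_that("trophic levels below 1 are clamped with a warning", {
  expect_warning(tl <- estimate_trophic_level(0, 10, trophic_config()),
                 "clamped")
  expect_equal(tl, 1)
  expect_error(estimate_trophic_level(5, NA), "baseline")
})

test_that("baseline regression reproduces exact and noisy linear relations", {
  x <- 1:5
  r <- suppressWarnings(fit_baseline_regression(x, 2 * x + 1))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$adj_r_squared, 1)
  set.seed(11)
  x <- runif(30, 2, 12)
  y <- 0.9 * x - 0.5 + rnorm(30, 0, 0.3)
  r <- fit_baseline_regression(x, y)
  expect_lt(abs(r$slope - 0.9), 0.1)
  expect_gt(r$adj_r_squared, 0.9)
  expect_error(fit_baseline_regression(1:2, 1:2), "at least 3")
  expect_error(fit_baseline_regression(rep(1, 5), 1:5), "zero variance")
})

test_that("missing baselines are imputed through the regression, never silently dropped", {
  samples <- data.frame(
    lake_id = rep(c("A", "B", "C"), each = 2),
    taxon = c("cladocerans", "bulk_zoopl", "cladocerans", "bulk_zoopl",
              "fish_sp", "bulk_zoopl"),
    group = c("zooplankton", "zooplankton", "zooplankton", "zooplankton",
              "fish", "zooplankton"),
    d15n = c(5.0, 5.5, 6.0, 6.5, 12.0, 8.0))
  bl <- build_baselines(samples, c(zooplankton = "cladocerans",
                                   fish = "cladocerans"))
  expect_true(anyNA(bl$d15n_baseline)) # lake C lacks cladocerans
  reg <- list(cladocerans = list(predictor_taxon = "bulk_zoopl",
                                 slope = 0.872, intercept = -0.095))
  bl2 <- impute_missing_baselines(bl, samples, reg)
  imp <- bl2[bl2$lake_id == "C" & bl2$group == "zooplankton", ]
  expect_equal(imp$d15n_baseline, 0.872 * 8.0 - 0.095) # 6.881
  expect_equal(imp$d15n_baseline, 6.881, tolerance = 1e-12)
  expect_true(imp$imputed)
  # measured lakes keep their values and flags
  expect_false(any(bl2$imputed[bl2$lake_id %in% c("A", "B")]))
  # lake missing baseline and predictor -> error
  samples_bad <- samples[samples$taxon != "bulk_zoopl" | samples$lake_id != "C", ]
  expect_error(impute_missing_baselines(bl, samples_bad, reg), "cannot impute")
  expect_error(impute_missing_baselines(bl, samples, list()), "no regression")
})

test_that("methane-influenced zoobenthos get their trophic level fixed", {
  s <- data.frame(group = rep("zoobenthos_profundal", 3),
                  tl = c(3.0, 3.0, 3.0),
                  d13c = c(-40.1, -25, NA))
  out <- fix_methane_influenced(s, trophic_config())
  expect_equal(out$tl, c(2.1, 3.0, 3.0))
  expect_equal(out$methane_fixed, c(TRUE, FALSE, FALSE))
  s2 <- data.frame(group = "zoobenthos_profundal", tl = 3.0,
                   d13c = NA_real_)
  expect_message(out2 <- fix_methane_influenced(s2, trophic_config()),
                 "skipped")
  expect_equal(out2$tl, 3.0)
})

test_that("compound omega accumulates over trophic transfers", {
  expect_equal(omega_compound(0.23, 2), 0.23)
  expect_equal(omega_compound(0.5, 1), 0)
  expect_equal(omega_compound(0, 3.7), 0)
  # continuous, monotone in both arguments, bounded in [0, 1)
  tl <- seq(1, 4.5, by = 0.25)
  oc <- omega_compound(0.23, tl)
  expect_true(all(diff(oc) > 0))
  expect_true(all(oc >= 0 & oc < 1))
  expect_true(all(omega_compound(0.32, tl) >= oc))
  expect_error(omega_compound(0.23, 0.5), "below 1")
  expect_error(omega_compound(1, 2))
})

test_that("omega correction removes the water contribution", {
  expect_equal(omega_correct(-150, -60, 0), -150)
  # water value is a fixed point for any omega_compound
  expect_equal(omega_correct(-60, -60, 0.4), -60)
  expect_equal(omega_correct(-150, -60, 0.23), (-150 + 0.23 * 60) / 0.77)
  expect_equal(omega_correct(-150, -60, 0.23), -176.88312, tolerance = 1e-5)
  # linear in the measured value; deviations magnified by 1/(1 - omega_c)
  oc <- 0.35
  d <- omega_correct(c(-100, -110), -60, oc)
  expect_equal(diff(d), -10 / (1 - oc))
  expect_error(omega_correct(-150, -60, 1), "\\[0, 1\\)")
})

test_that("corrected SD is the configured preprocessing uncertainty", {
  expect_equal(corrected_sd(trophic_config()), 13)
  expect_equal(corrected_sd(trophic_config(extra_consumer_sd = 0)), 0)
  expect_equal(corrected_sd(trophic_config(extra_consumer_sd = 20)), 20)
})

test_that("prepare_consumers runs the full chain and flags derived columns", {
  st <- small_study(seed = 3)
  prep <- st$prep
  expect_true(all(c("tl", "omega_compound", "d2h_corrected", "sd_corrected",
                    "baseline_imputed", "methane_fixed") %in% names(prep)))
  expect_true(all(prep$tl >= 1))
  expect_true(all(prep$omega_compound >= 0 & prep$omega_compound < 1))
  expect_equal(unique(prep$sd_corrected), 13)
  # baseline taxa sit near the baseline trophic level
  expect_equal(mean(prep$tl[prep$taxon == "cladocerans"]), 2.1, tolerance = 0.15)
  expect_error(prepare_consumers(st$sim$samples,
                                 data.frame(lake_id = "X", d2h_water = -60)),
               "no water")
})
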