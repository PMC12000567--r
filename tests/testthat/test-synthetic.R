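test_that("lake generation spans the gradient deterministically under seed", {
  cfg <- sim_config(seed = 4)
  lakes <- generate_lakes(cfg)
  expect_equal(nrow(lakes), 35)
  expect_true(all(lakes$covariate >= cfg$covariate_range[1] &
                    lakes$covariate <= cfg$covariate_range[2]))
  lakes2 <- generate_lakes(sim_config(seed = 4))
  expect_identical(lakes, lakes2)
  expect_error(generate_lakes(sim_config(n_lakes = 1)), "at least 2")
})

test_that("nominal source separation follows the forward definitions", {
  # offset -20, discrimination -110, water -60 exactly:
  # terrestrial -80, aquatic -170, separation 90 per mil
  cfg <- sim_config(seed = 1, water_d2h_mean = -60, water_d2h_sd = 0,
                    inlet_dom_offset_mean = -20)
  lakes <- generate_lakes(cfg)
  expect_equal(unique(lakes$d2h_water), -60)
  expect_equal(unique(lakes$d2h_inlet_dom), -80)
  aquatic_nominal <- unique(lakes$d2h_water) + cfg$photosynthetic_discrimination
  expect_equal(aquatic_nominal, -170)
  expect_equal(unique(lakes$d2h_inlet_dom) - aquatic_nominal, 90)
  # default config places the separation in the intended band
  dflt <- sim_config(seed = 1)
  expect_equal(dflt$inlet_dom_offset_mean - dflt$photosynthetic_discrimination, 100)
})

test_that("degenerate forward model collapses to the terrestrial source", {
  # intercept pushed far terrestrial, all noise off: measured value equals
  # the realized terrestrial mean at every observation
  taxa <- data.frame(taxon = "cladocerans", group = "zooplankton", tl = 2,
                     ilr_intercept_offset = 0, ilr_slope_offset = 0)
  cfg <- sim_config(n_lakes = 3, taxa = taxa, samples_per_taxon_lake = 2,
                    global_ilr_intercept = -30, global_ilr_slope = 0,
                    sd_lake = 0, residual_sd = 0, omega_per_level = 0,
                    seed = 8)
  sim <- simulate_study(cfg)
  expect_equal(sim$truth$true_allochthony, rep(1, nrow(sim$truth)),
               tolerance = 1e-12)
  expect_equal(sim$samples$d2h, sim$truth$terrestrial_realized,
               tolerance = 1e-9)
})

test_that("measured values follow the compound-omega forward equation", {
  # omega 0.23 at TL 2: measured = 0.23 * water + 0.77 * mixture
  taxa <- data.frame(taxon = "cladocerans", group = "zooplankton", tl = 2,
                     ilr_intercept_offset = 0, ilr_slope_offset = 0)
  cfg <- sim_config(n_lakes = 2, taxa = taxa, samples_per_taxon_lake = 1,
                    global_ilr_slope = 0, sd_lake = 0, residual_sd = 0,
                    omega_per_level = 0.23, seed = 9)
  sim <- simulate_study(cfg)
  lakes <- sim$lakes
  manual <- 0.23 * lakes$d2h_water + 0.77 * sim$truth$mixture_mean
  expect_equal(sim$samples$d2h, manual, tolerance = 1e-9)
  # the worked instance: water -60, mixture -120
  expect_equal(0.23 * -60 + 0.77 * -120, -106.2)
})

test_that("omega correction inverts the noise-free forward model exactly", {
  cfg <- sim_config(n_lakes = 4, samples_per_taxon_lake = 2,
                    residual_sd = 0, seed = 10)
  sim <- simulate_study(cfg)
  oc <- omega_compound(cfg$omega_per_level, sim$truth$true_tl)
  water <- sim$lakes$d2h_water[match(sim$samples$lake_id, sim$lakes$lake_id)]
  rec <- omega_correct(sim$samples$d2h, water, oc)
  expect_equal(rec, sim$truth$mixture_mean, tolerance = 1e-9)
})

test_that("every sample has exactly one truth record and coherent allochthony", {
  sim <- simulate_study(small_sim_config(seed = 12))
  expect_identical(sim$samples$obs_id, sim$truth$obs_id)
  expect_true(all(sim$truth$true_allochthony >= 0 &
                    sim$truth$true_allochthony <= 1))
  # truth allochthony derives from true phi via the same inverse transform
  expect_equal(sim$truth$true_allochthony,
               1 - ilr_inverse(sim$truth$true_phi), tolerance = 1e-12)
})

test_that("true allochthony declines along the covariate for positive slopes", {
  taxa <- small_taxa()
  cfg <- sim_config(n_lakes = 12, taxa = taxa, samples_per_taxon_lake = 1,
                    sd_lake = 0, seed = 13)
  sim <- simulate_study(cfg)
  for (tx in taxa$taxon) {
    d <- sim$truth[sim$truth$taxon == tx, ]
    d <- d[order(sim$lakes$covariate[match(d$lake_id, sim$lakes$lake_id)]), ]
    expect_true(all(diff(d$true_allochthony) < 0), label = tx)
  }
})

test_that("simulate_study writes the four pipeline CSVs", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_sim_config(seed = 14), dir = dir)
  files <- c("consumers.csv", "sources.csv", "environment.csv", "truth.csv")
  expect_true(all(file.exists(file.path(dir, files))))
  cons <- read_consumers_csv(file.path(dir, "consumers.csv"))
  expect_equal(nrow(cons), nrow(sim$samples))
  env <- read_env_csv(file.path(dir, "environment.csv"))
  expect_gte(attr(env, "n_vars"), 15)
})
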