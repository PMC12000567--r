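# Shared fixtures built in code.

# small study: 6 lakes, 4 taxa (includes both baseline taxa), 2 reps
small_taxa <- function() {
  data.frame(
    taxon = c("cladocerans", "asellus", "planktivorous_fish", "chaoborus"),
    group = c("zooplankton", "zoobenthos_littoral", "fish", "zooplankton"),
    tl = c(2.1, 2.1, 3.2, 3.0),
    ilr_intercept_offset = c(0.3, -0.3, 0.2, -0.2),
    ilr_slope_offset = c(0.05, -0.05, 0.1, -0.1),
    stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(n_lakes = 6, taxa = small_taxa(), samples_per_taxon_lake = 2,
             seed = seed, ...)
}

# full small chain: simulated study -> prepared consumers + source pairs
small_study <- function(seed = 1, ...) {
  cfg <- small_sim_config(seed = seed, ...)
  sim <- simulate_study(cfg)
  water <- data.frame(lake_id = sim$lakes$lake_id,
                      d2h_water = sim$lakes$d2h_water)
  prep <- suppressMessages(suppressWarnings(
    prepare_consumers(sim$samples, water,
                      trophic_config(omega = cfg$omega_per_level))))
  src <- data.frame(lake_id = sim$lakes$lake_id,
                    d2h_water = sim$lakes$d2h_water,
                    d2h_inlet_dom = sim$lakes$d2h_inlet_dom,
                    d2h_benthic_algae = sim$lakes$aquatic_realized,
                    substitute_lake_id = NA_character_,
                    stringsAsFactors = FALSE)
  pairs <- build_source_pairs(src)
  cov <- data.frame(lake_id = sim$lakes$lake_id, pc1 = sim$lakes$covariate)
  list(cfg = cfg, sim = sim, water = water, prep = prep, src = src,
       pairs = pairs, cov = cov)
}

# single-exponential decadic absorbance spectrum a(l) = a0 * exp(-S * l)
exp_spectrum <- function(s = 0.015, a0 = 50, path = 0.01,
                         wl = seq(250, 420, by = 1)) {
  data.frame(wavelength = wl, absorbance = a0 * exp(-s * wl) * path)
}

quick_mix_config <- function(...) {
  args <- list(iterations = 6000, burn_in = 3000, thinning = 5, chains = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(mix_config, args)
}
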