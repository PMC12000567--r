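#' Default taxon table for the synthetic study
#'
#' Eight consumer taxa spanning trophic levels 2.1-4.0 across pelagic,
#' littoral, profundal and fish compartments, each with a fixed ILR-space
#' intercept and slope offset around the global coefficients. Cladocerans
#' and *Asellus* double as the isotopic baseline taxa, so every generated
#' lake carries its own baselines.
#'
#' @return Data frame with columns `taxon`, `group`, `tl`,
#'   `ilr_intercept_offset`, `ilr_slope_offset`.
#' @export
default_taxa <- function() {
  data.frame(
    taxon = c("cladocerans", "copepods", "chaoborus", "asellus",
              "chironomids_littoral", "chironomids_profundal",
              "planktivorous_fish", "piscivorous_fish"),
    group = c("zooplankton", "zooplankton", "zooplankton",
              "zoobenthos_littoral", "zoobenthos_littoral",
              "zoobenthos_profundal", "fish", "fish"),
    tl = c(2.1, 2.5, 3.0, 2.1, 2.4, 2.3, 3.2, 4.0),
    ilr_intercept_offset = c(0.5, 0.3, 0.1, -0.6, -0.4, -0.8, 0.4, 0.5),
    ilr_slope_offset = c(0.10, 0.05, -0.05, -0.10, 0.00, -0.15, 0.10, 0.05),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the study design the package targets: 35 boreal lakes
#' along one environmental gradient, two deuterium sources roughly 100 per
#' mil apart, spatiotemporal source SDs of 11.2 (terrestrial) and 23.6
#' (aquatic) per mil, per-trophic-level water incorporation of 0.23, and an
#' allochthony structure that is linear in ILR space with global slope 0.84
#' and a global intercept corresponding to about 12% allochthony at
#' covariate zero.
#'
#' @param n_lakes Number of lakes (>= 2; default 35).
#' @param taxa Taxon table as in [default_taxa()].
#' @param samples_per_taxon_lake Replicate samples per taxon per lake
#'   (default 3).
#' @param global_ilr_intercept Global ILR intercept (default
#'   `ilr_transform(0.88)`, i.e. 12% allochthony at covariate 0).
#' @param global_ilr_slope Global ILR slope per covariate unit (default
#'   0.84; positive means allochthony declines along the gradient).
#' @param sd_species_intercept,sd_species_slope,sd_lake Hierarchical SDs in
#'   ILR units; lake intercepts are drawn, taxon offsets come from `taxa`.
#' @param covariate_range Interval covered by the environmental covariate
#'   (default `c(-3, 3)`).
#' @param covariate_spacing `"even"` (default; guarantees an identifiable
#'   slope at small n) or `"uniform"` random.
#' @param water_d2h_mean,water_d2h_sd Lake water delta-2H distribution
#'   (per mil; defaults -60, 10).
#' @param inlet_dom_offset_mean Inlet DOM delta-2H minus water delta-2H
#'   (per mil; default -10, placing the terrestrial source 100 per mil above
#'   the photosynthesis-adjusted aquatic source).
#' @param photosynthetic_discrimination Per mil (default -110).
#' @param source_sd_terrestrial,source_sd_aquatic Spatiotemporal SDs used to
#'   draw realized per-lake source means (defaults 11.2, 23.6 per mil).
#' @param omega_per_level Per-trophic-level water contribution (default 0.23).
#' @param residual_sd Measurement/ecological noise on measured consumer
#'   delta-2H (per mil; default 10).
#' @param d15n_baseline_mean Baseline delta-15N (per mil; default 4.0).
#' @param d15n_tdf Nitrogen trophic discrimination factor (default 3.4).
#' @param d15n_noise_sd Noise on generated delta-15N (per mil; default 0.3).
#' @param methane_fraction Fraction of profundal zoobenthos samples given a
#'   methane-influenced delta-13C signature (default 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_lakes = 35, taxa = default_taxa(),
                       samples_per_taxon_lake = 3,
                       global_ilr_intercept = ilr_transform(0.88),
                       global_ilr_slope = 0.84,
                       sd_species_intercept = 0.5, sd_species_slope = 0.15,
                       sd_lake = 0.3,
                       covariate_range = c(-3, 3),
                       covariate_spacing = c("even", "uniform"),
                       water_d2h_mean = -60, water_d2h_sd = 10,
                       inlet_dom_offset_mean = -10,
                       photosynthetic_discrimination = -110,
                       source_sd_terrestrial = 11.2, source_sd_aquatic = 23.6,
                       omega_per_level = 0.23, residual_sd = 10,
                       d15n_baseline_mean = 4.0, d15n_tdf = 3.4,
                       d15n_noise_sd = 0.3, methane_fraction = 0,
                       seed = NULL) {
  covariate_spacing <- match.arg(covariate_spacing)
  stopifnot(nrow(taxa) >= 1, all(taxa$tl >= 1),
            omega_per_level >= 0, omega_per_level < 1,
            sd_species_intercept >= 0, sd_species_slope >= 0, sd_lake >= 0,
            source_sd_terrestrial >= 0, source_sd_aquatic >= 0,
            residual_sd >= 0, diff(range(covariate_range)) > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate synthetic lakes along an environmental gradient
#'
#' Assigns covariate values across `covariate_range` (evenly spaced by
#' default), draws lake water delta-2H, sets inlet DOM delta-2H as water
#' plus the configured offset, draws the per-lake lake-level ILR random
#' intercept, draws realized source means (one Normal draw per lake around
#' the nominal source mean with the stated spatiotemporal SD), and builds an
#' 18-variable environmental table with a single latent factor equal to the
#' covariate so that correlation PCA recovers the gradient.
#'
#' @param config A [sim_config()].
#' @return Data frame of lakes with nominal and realized source values, the
#'   covariate, the lake random effect, and environmental variables prefixed
#'   `env_` plus `forest_pct`.
#' @export
generate_lakes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lakes < 2) stop("need at least 2 lakes for a covariate regression")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_lakes
  covariate <- switch(config$covariate_spacing,
    even = seq(config$covariate_range[1], config$covariate_range[2], length.out = n),
    uniform = sort(stats::runif(n, config$covariate_range[1], config$covariate_range[2])))
  d2h_water <- stats::rnorm(n, config$water_d2h_mean, config$water_d2h_sd)
  d2h_inlet_dom <- d2h_water + config$inlet_dom_offset_mean
  aquatic_nominal <- d2h_water + config$photosynthetic_discrimination
  lakes <- data.frame(
    lake_id = sprintf("L%02d", seq_len(n)),
    covariate = covariate,
    d2h_water = d2h_water,
    d2h_inlet_dom = d2h_inlet_dom,
    terrestrial_realized = stats::rnorm(n, d2h_inlet_dom, config$source_sd_terrestrial),
    aquatic_realized = stats::rnorm(n, aquatic_nominal, config$source_sd_aquatic),
    lake_effect = stats::rnorm(n, 0, config$sd_lake),
    stringsAsFactors = FALSE)
  lakes <- cbind(lakes, synth_env_table(covariate))
  lakes
}

# 18 environmental variables driven by one latent factor (the covariate)
# plus noise; forest cover loads negatively so the PCA sign convention holds.
synth_env_table <- function(covariate) {
  n <- length(covariate)
  z <- as.numeric(scale(covariate))
  spec <- list( # name, latent loading, mean, sd of noise
    mean_depth_m = c(-0.3, 8, 3), max_depth_m = c(-0.3, 20, 6),
    shoreline_dev = c(0.2, 2.5, 0.6), lake_area_km2 = c(0.3, 5, 2),
    catchment_area_km2 = c(0.3, 60, 25), ca_la_ratio = c(0.2, 12, 4),
    tot_p_ugl = c(0.8, 30, 10), doc_mgl = c(-0.7, 12, 3),
    chl_a_ugl = c(0.8, 10, 4), ph = c(0.7, 7, 0.4),
    urban_pct = c(0.5, 5, 3), agricultural_pct = c(0.8, 12, 5),
    forest_pct = c(-0.9, 75, 8), wetland_pct = c(-0.4, 4, 2),
    waterbody_pct = c(0.2, 10, 4), suva = c(-0.7, 3, 0.7),
    sr_ratio = c(0.6, 0.9, 0.15), nc_pom = c(0.7, 0.12, 0.03)
  )
  out <- lapply(names(spec), function(v) {
    p <- spec[[v]]
    val <- p[2] + p[1] * p[3] * 2 * z + stats::rnorm(n, 0, p[3])
    if (grepl("_pct$", v)) val <- pmin(100, pmax(0, val))
    if (v %in% c("doc_mgl", "tot_p_ugl", "chl_a_ugl", "suva", "nc_pom",
                 "lake_area_km2", "catchment_area_km2")) val <- pmax(val, 0.01)
    val
  })
  names(out) <- names(spec)
  as.data.frame(out)
}

#' Generate consumer samples with known allochthony
#'
#' Forward model: each observation's true ILR coordinate is
#' `phi = (b0 + taxon intercept offset + lake effect) +
#' (b1 + taxon slope offset) * covariate`; the aquatic proportion is
#' `ilr_inverse(phi)` and the true allochthony is its complement. The
#' trophic-level-corrected mixture mean combines the lake's realized source
#' means, and the measured delta-2H adds back the compound water
#' contribution: `omega_c * water + (1 - omega_c) * mixture + noise` with
#' `omega_c = 1 - (1 - omega)^(TL - 1)`. delta-15N is baseline +
#' (TL - 2.1) * TDF + noise.
#'
#' @param lakes Output of [generate_lakes()].
#' @param config The same [sim_config()].
#' @return List with `samples` (consumer data frame) and `truth` (per
#'   observation: true phi, aquatic proportion, allochthony, realized
#'   sources; plus per-taxon and per-lake true effects as attributes
#'   `taxa` and `lakes`).
#' @export
generate_consumers <- function(lakes, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), nrow(config$taxa) >= 1)
  if (any(config$taxa$tl < 1)) stop("taxon trophic level below 1 is invalid")
  taxa <- config$taxa
  grid <- expand.grid(lake = seq_len(nrow(lakes)), taxon = seq_len(nrow(taxa)),
                      rep = seq_len(config$samples_per_taxon_lake),
                      KEEP.OUT.ATTRS = FALSE)
  li <- grid$lake; ti <- grid$taxon
  phi <- (config$global_ilr_intercept + taxa$ilr_intercept_offset[ti] +
            lakes$lake_effect[li]) +
    (config$global_ilr_slope + taxa$ilr_slope_offset[ti]) * lakes$covariate[li]
  p_aq <- ilr_inverse(phi)
  p_t <- 1 - p_aq
  m <- p_t * lakes$terrestrial_realized[li] + p_aq * lakes$aquatic_realized[li]
  tl <- taxa$tl[ti]
  om_c <- omega_compound(config$omega_per_level, tl)
  d2h <- om_c * lakes$d2h_water[li] + (1 - om_c) * m +
    stats::rnorm(nrow(grid), 0, config$residual_sd)
  d15n <- config$d15n_baseline_mean + (tl - 2.1) * config$d15n_tdf +
    stats::rnorm(nrow(grid), 0, config$d15n_noise_sd)
  d13c <- rep(NA_real_, nrow(grid))
  if (config$methane_fraction > 0) {
    prof <- which(taxa$group[ti] == "zoobenthos_profundal")
    n_hit <- round(config$methane_fraction * length(prof))
    if (n_hit > 0) {
      hit <- sample(prof, n_hit)
      d13c[hit] <- stats::rnorm(n_hit, -45, 2)
      other <- setdiff(seq_len(nrow(grid)), hit)
      d13c[other] <- stats::rnorm(length(other), -28, 2)
    }
  }
  samples <- data.frame(
    obs_id = sprintf("S%05d", seq_len(nrow(grid))),
    lake_id = lakes$lake_id[li],
    taxon = taxa$taxon[ti],
    group = taxa$group[ti],
    d2h = d2h, d15n = d15n, d13c = d13c,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    obs_id = samples$obs_id, lake_id = samples$lake_id, taxon = samples$taxon,
    true_tl = tl, true_phi = phi, true_p_aquatic = p_aq,
    true_allochthony = p_t, mixture_mean = m,
    terrestrial_realized = lakes$terrestrial_realized[li],
    aquatic_realized = lakes$aquatic_realized[li],
    stringsAsFactors = FALSE)
  attr(truth, "taxa") <- taxa
  attr(truth, "lakes") <- lakes[c("lake_id", "covariate", "lake_effect",
                                  "terrestrial_realized", "aquatic_realized")]
  attr(truth, "config") <- config
  list(samples = samples, truth = truth)
}

#' Simulate a full synthetic study and optionally write its input files
#'
#' Convenience wrapper: [generate_lakes()] then [generate_consumers()];
#' optionally writes the pipeline input CSVs (`consumers.csv`,
#' `sources.csv`, `environment.csv`) plus `truth.csv`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for the CSVs.
#' @return List with `lakes`, `samples`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  lakes <- generate_lakes(config)
  gc <- generate_consumers(lakes, config)
  out <- list(lakes = lakes, samples = gc$samples, truth = gc$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(gc$samples[c("lake_id", "taxon", "group", "d2h", "d15n", "d13c")],
                     file.path(dir, "consumers.csv"), row.names = FALSE, na = "")
    src <- data.frame(lake_id = lakes$lake_id, d2h_water = lakes$d2h_water,
                      d2h_inlet_dom = lakes$d2h_inlet_dom,
                      d2h_benthic_algae = lakes$aquatic_realized,
                      substitute_lake_id = "")
    utils::write.csv(src, file.path(dir, "sources.csv"), row.names = FALSE, na = "")
    env_cols <- c("lake_id", names(synth_env_table(0)))
    utils::write.csv(lakes[env_cols], file.path(dir, "environment.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(gc$truth[c("obs_id", "lake_id", "taxon", "true_phi",
                                "true_allochthony")],
                     file.path(dir, "truth.csv"), row.names = FALSE, na = "")
  }
  out
}
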