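#' Trophic and hydrogen-exchange configuration
#'
#' Collects the constants used to turn raw consumer isotope values into
#' trophic levels and omega-corrected delta-2H values.
#'
#' @param baseline_tl Trophic level assigned to the isotopic baseline taxa
#'   (herbivorous cladocerans, littoral *Asellus*). Default 2.1.
#' @param baseline_tl_sd SD of the baseline trophic level (default 0.1).
#' @param tdf_n Trophic discrimination factor for delta-15N, per trophic
#'   level, in per mil (default 3.4).
#' @param tdf_n_sd SD of `tdf_n` (default 1.0 per mil).
#' @param tdf_h Trophic discrimination factor for delta-2H (default 0; no
#'   variance term is carried for it).
#' @param omega Per-trophic-level proportion of tissue hydrogen derived from
#'   environmental water rather than diet, in `[0, 1)` (default 0.23).
#' @param omega_sd SD of `omega` (default 0.09); informational, used by
#'   sensitivity scenarios rather than propagated analytically.
#' @param extra_consumer_sd Additional observation-level SD (per mil) attached
#'   to every omega-corrected consumer value, covering baseline-TL and TDF
#'   uncertainty (default 13).
#' @param methane_d13c_threshold delta-13C threshold (per mil) at or below
#'   which a zoobenthos sample is treated as methane-influenced and its
#'   trophic level fixed to `baseline_tl` (default -40).
#' @return A list of class `"trophic_config"`.
#' @export
trophic_config <- function(baseline_tl = 2.1, baseline_tl_sd = 0.1,
                           tdf_n = 3.4, tdf_n_sd = 1.0, tdf_h = 0,
                           omega = 0.23, omega_sd = 0.09,
                           extra_consumer_sd = 13,
                           methane_d13c_threshold = -40) {
  stopifnot(omega >= 0, omega < 1, tdf_n > 0, extra_consumer_sd >= 0,
            baseline_tl >= 1)
  structure(list(baseline_tl = baseline_tl, baseline_tl_sd = baseline_tl_sd,
                 tdf_n = tdf_n, tdf_n_sd = tdf_n_sd, tdf_h = tdf_h,
                 omega = omega, omega_sd = omega_sd,
                 extra_consumer_sd = extra_consumer_sd,
                 methane_d13c_threshold = methane_d13c_threshold),
            class = "trophic_config")
}

#' Estimate consumer trophic level from nitrogen isotopes
#'
#' Single end-member nitrogen mixing model:
#' `TL = baseline_tl + (d15n_consumer - d15n_baseline) / tdf_n`.
#' Values below 1 are clamped to 1 with a warning (a consumer cannot sit
#' below the basal hydrogen source level used by the omega correction).
#'
#' @param d15n_consumer Consumer delta-15N (per mil, air-N2).
#' @param d15n_baseline Baseline delta-15N for the consumer's lake and
#'   food-web compartment (per mil).
#' @param cfg A [trophic_config()].
#' @return Trophic level(s) >= 1.
#' @export
estimate_trophic_level <- function(d15n_consumer, d15n_baseline,
                                   cfg = trophic_config()) {
  if (any(is.na(d15n_baseline))) {
    stop("unresolved baseline delta-15N: build or impute baselines first")
  }
  tl <- cfg$baseline_tl + (d15n_consumer - d15n_baseline) / cfg$tdf_n
  low <- !is.na(tl) & tl < 1
  if (any(low)) {
    warning(sprintf("%d trophic level estimate(s) below 1 clamped to 1", sum(low)))
    tl[low] <- 1
  }
  tl
}

#' Ordinary least-squares baseline regression between lake-mean groups
#'
#' Fits `y ~ x` across lake means, e.g. cladoceran delta-15N on bulk
#' zooplankton delta-15N, for imputing missing baselines.
#'
#' @param x Lake-mean delta-15N of the predictor group.
#' @param y Lake-mean delta-15N of the baseline group (paired with `x`).
#' @return A list with `slope`, `intercept`, `adj_r_squared`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_baseline_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("baseline regression needs at least 3 paired lakes")
  if (stats::var(x) <= 0) stop("baseline regression predictor has zero variance")
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       n = n, fit = fit)
}

# group label -> baseline taxon used for that food-web compartment
default_baseline_spec <- function() {
  c(zooplankton = "cladocerans",
    zoobenthos_littoral = "asellus",
    zoobenthos_profundal = "cladocerans",
    fish = "cladocerans")
}

#' Build per-lake, per-compartment baseline map from measured samples
#'
#' For each lake and food-web compartment, the baseline delta-15N is the mean
#' of that lake's samples of the designated baseline taxon (cladocerans for
#' pelagic/profundal/fish compartments, littoral *Asellus* for littoral
#' zoobenthos by default). Lakes lacking the baseline taxon get `NA` here and
#' are filled by [impute_missing_baselines()].
#'
#' @param samples Consumer data frame with columns `lake_id`, `taxon`,
#'   `group`, `d15n`.
#' @param baseline_spec Named character vector mapping group label to
#'   baseline taxon name.
#' @return Data frame (`lake_id`, `group`, `baseline_taxon`, `d15n_baseline`,
#'   `imputed`).
#' @export
build_baselines <- function(samples, baseline_spec = default_baseline_spec()) {
  groups <- intersect(names(baseline_spec), unique(samples$group))
  lakes <- unique(samples$lake_id)
  out <- expand.grid(lake_id = lakes, group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$baseline_taxon <- unname(baseline_spec[out$group])
  out$d15n_baseline <- NA_real_
  out$imputed <- FALSE
  for (i in seq_len(nrow(out))) {
    sel <- samples$lake_id == out$lake_id[i] &
      samples$taxon == out$baseline_taxon[i]
    if (any(sel)) out$d15n_baseline[i] <- mean(samples$d15n[sel], na.rm = TRUE)
  }
  out$d15n_baseline[is.nan(out$d15n_baseline)] <- NA_real_
  out
}

#' Impute missing lake baselines from fitted regressions
#'
#' Lakes with a measured baseline keep it; lakes without one get the value
#' predicted from the lake mean of a predictor group (e.g. bulk zooplankton)
#' through a regression from [fit_baseline_regression()], flagged `imputed`.
#' A lake lacking both baseline and predictor raises an error rather than
#' being dropped silently.
#'
#' @param baselines Output of [build_baselines()] (may contain `NA`s).
#' @param samples The consumer samples (to compute predictor lake means).
#' @param regressions Named list: for each baseline taxon needing imputation,
#'   a list with `predictor_taxon`, `slope`, `intercept` (e.g. from
#'   [fit_baseline_regression()]).
#' @return The baseline map with `NA`s filled and `imputed` flags set.
#' @export
impute_missing_baselines <- function(baselines, samples, regressions) {
  miss <- which(is.na(baselines$d15n_baseline))
  for (i in miss) {
    bt <- baselines$baseline_taxon[i]
    reg <- regressions[[bt]]
    if (is.null(reg)) {
      stop(sprintf("lake %s, compartment %s: no measured baseline '%s' and no regression supplied",
                   baselines$lake_id[i], baselines$group[i], bt))
    }
    sel <- samples$lake_id == baselines$lake_id[i] &
      samples$taxon == reg$predictor_taxon
    if (!any(sel) || all(is.na(samples$d15n[sel]))) {
      stop(sprintf("lake %s: neither baseline taxon '%s' nor predictor '%s' measured; cannot impute",
                   baselines$lake_id[i], bt, reg$predictor_taxon))
    }
    xbar <- mean(samples$d15n[sel], na.rm = TRUE)
    baselines$d15n_baseline[i] <- reg$intercept + reg$slope * xbar
    baselines$imputed[i] <- TRUE
  }
  baselines
}

#' Fix trophic level of methane-influenced samples
#'
#' Zoobenthos samples whose delta-13C is at or below the methane threshold
#' carry a methanogenic carbon signal; their nitrogen-derived trophic levels
#' are unreliable and are fixed to the baseline trophic level (2.1 by
#' default), flagged `methane_fixed`. Samples without delta-13C are left
#' untouched (the rule is skipped with a message).
#'
#' @param samples Data frame with a derived `tl` column and optionally `d13c`.
#' @param cfg A [trophic_config()].
#' @param groups Group labels the screen applies to (zoobenthos compartments).
#' @return `samples` with `tl` adjusted and a logical `methane_fixed` column.
#' @export
fix_methane_influenced <- function(samples, cfg = trophic_config(),
                                   groups = c("zoobenthos_littoral",
                                              "zoobenthos_profundal")) {
  samples$methane_fixed <- FALSE
  if (is.null(samples$d13c) || all(is.na(samples$d13c))) {
    message("no delta-13C values present; methane screen skipped")
    return(samples)
  }
  hit <- samples$group %in% groups & !is.na(samples$d13c) &
    samples$d13c <= cfg$methane_d13c_threshold
  samples$tl[hit] <- cfg$baseline_tl
  samples$methane_fixed <- hit
  samples
}

#' Compound water-hydrogen contribution across trophic levels
#'
#' The proportion of a consumer's tissue hydrogen that originates from
#' environmental water accumulates over the `TL - 1` trophic transfers
#' separating it from the basal hydrogen sources:
#' `omega_compound = 1 - (1 - omega)^(TL - 1)`. Continuous in TL; non-integer
#' trophic levels are used as-is.
#'
#' @param omega Per-trophic-level water contribution, in `[0, 1)`.
#' @param tl Trophic level(s) >= 1.
#' @return Compound proportion(s) in `[0, 1)`.
#' @examples
#' omega_compound(0.23, 2)  # one transfer: 0.23
#' omega_compound(0.23, 3)  # ~0.41
#' @export
omega_compound <- function(omega, tl) {
  stopifnot(omega >= 0, omega < 1)
  if (any(tl < 1, na.rm = TRUE)) stop("trophic level below 1 is invalid for the omega correction")
  1 - (1 - omega)^(tl - 1)
}

#' Correct measured consumer delta-2H for environmental water exchange
#'
#' Removes the compound water contribution so the corrected value sits at the
#' same trophic level as the basal sources:
#' `(d2h_c - omega_compound * d2h_water) / (1 - omega_compound)`.
#' The correction is linear in `d2h_c` and magnifies deviations from water by
#' `1 / (1 - omega_compound)`.
#'
#' @param d2h_c Measured consumer delta-2H (per mil, V-SMOW).
#' @param d2h_water Lake water delta-2H (per mil).
#' @param omega_compound Compound water proportion(s) in `[0, 1)`.
#' @return Omega-corrected delta-2H (per mil).
#' @export
omega_correct <- function(d2h_c, d2h_water, omega_compound) {
  if (any(omega_compound >= 1 | omega_compound < 0)) {
    stop("omega_compound must lie in [0, 1)")
  }
  (d2h_c - omega_compound * d2h_water) / (1 - omega_compound)
}

#' Observation-level SD attached to omega-corrected values
#'
#' Returns the extra per-sample SD (per mil) representing propagated
#' baseline-TL and TDF uncertainty; it enters the mixing model as an
#' independent additive observation variance.
#'
#' @param cfg A [trophic_config()].
#' @return A single SD in per mil (default 13).
#' @export
corrected_sd <- function(cfg = trophic_config()) cfg$extra_consumer_sd

#' Prepare consumer samples for mixing
#'
#' Full preprocessing chain: resolve baselines (measured, then regression
#' imputation), estimate trophic levels, fix methane-influenced zoobenthos,
#' compute compound omega and omega-corrected delta-2H against lake water,
#' and attach the corrected SD.
#'
#' @param samples Consumer data frame: `lake_id`, `taxon`, `group`, `d2h`,
#'   `d15n`, optional `d13c`.
#' @param water Data frame `lake_id`, `d2h_water`.
#' @param cfg A [trophic_config()].
#' @param baseline_spec Group-to-baseline-taxon map (see [build_baselines()]).
#' @param regressions Optional regressions for baseline imputation.
#' @return `samples` with added columns `d15n_baseline`, `baseline_imputed`,
#'   `tl`, `methane_fixed`, `tl_clamped`, `omega_compound`, `d2h_corrected`,
#'   `sd_corrected`.
#' @export
prepare_consumers <- function(samples, water, cfg = trophic_config(),
                              baseline_spec = default_baseline_spec(),
                              regressions = list()) {
  stopifnot(all(c("lake_id", "taxon", "group", "d2h", "d15n") %in% names(samples)))
  stopifnot(all(c("lake_id", "d2h_water") %in% names(water)))
  unknown <- setdiff(unique(samples$group), names(baseline_spec))
  if (length(unknown)) {
    stop("no baseline mapping for group(s): ", paste(unknown, collapse = ", "))
  }
  bl <- build_baselines(samples, baseline_spec)
  if (anyNA(bl$d15n_baseline)) {
    bl <- impute_missing_baselines(bl, samples, regressions)
  }
  key <- paste(samples$lake_id, samples$group)
  bkey <- paste(bl$lake_id, bl$group)
  idx <- match(key, bkey)
  samples$d15n_baseline <- bl$d15n_baseline[idx]
  samples$baseline_imputed <- bl$imputed[idx]

  tl_raw <- cfg$baseline_tl + (samples$d15n - samples$d15n_baseline) / cfg$tdf_n
  samples$tl_clamped <- !is.na(tl_raw) & tl_raw < 1
  samples$tl <- suppressWarnings(
    estimate_trophic_level(samples$d15n, samples$d15n_baseline, cfg))
  if (any(samples$tl_clamped)) {
    warning(sprintf("%d trophic level estimate(s) below 1 clamped to 1",
                    sum(samples$tl_clamped)))
  }
  samples <- fix_methane_influenced(samples, cfg)

  widx <- match(samples$lake_id, water$lake_id)
  if (anyNA(widx)) {
    stop("no water delta-2H for lake(s): ",
         paste(unique(samples$lake_id[is.na(widx)]), collapse = ", "))
  }
  d2h_water <- water$d2h_water[widx]
  samples$omega_compound <- omega_compound(cfg$omega, samples$tl)
  samples$d2h_corrected <- omega_correct(samples$d2h, d2h_water,
                                         samples$omega_compound)
  samples$sd_corrected <- corrected_sd(cfg)
  samples
}
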