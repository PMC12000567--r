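#' Source construction configuration
#'
#' @param photosynthetic_discrimination Hydrogen isotope discrimination of
#'   photosynthesis applied to lake water to obtain the aquatic source mean
#'   (per mil, default -110).
#' @param sd_terrestrial Spatiotemporal SD applied to the terrestrial (inlet
#'   DOM) source (per mil, default 11.2).
#' @param sd_aquatic Spatiotemporal SD applied to the aquatic source
#'   (per mil, default 23.6).
#' @param scenario One of `"inlet_dom"` (main model), `"bacterial"` (a
#'   microbial processing step between inlet DOM and consumers), or
#'   `"benthic_algae"` (measured benthic algae replace the
#'   discrimination-adjusted water as the aquatic source).
#' @param bacterial_omega Water contribution to bacterial tissue hydrogen in
#'   the bacterial scenario, in `[0, 1]` (default 0.17).
#' @return A list of class `"source_config"`.
#' @export
source_config <- function(photosynthetic_discrimination = -110,
                          sd_terrestrial = 11.2, sd_aquatic = 23.6,
                          scenario = c("inlet_dom", "bacterial", "benthic_algae"),
                          bacterial_omega = 0.17) {
  scenario <- match.arg(scenario)
  stopifnot(sd_terrestrial >= 0, sd_aquatic >= 0,
            bacterial_omega >= 0, bacterial_omega <= 1)
  structure(list(photosynthetic_discrimination = photosynthetic_discrimination,
                 sd_terrestrial = sd_terrestrial, sd_aquatic = sd_aquatic,
                 scenario = scenario, bacterial_omega = bacterial_omega),
            class = "source_config")
}

#' Aquatic source from lake water
#'
#' Photosynthetic-fixation-adjusted water: mean = water delta-2H +
#' photosynthetic discrimination; SD is the configured aquatic
#' spatiotemporal SD.
#'
#' @param d2h_water Lake water delta-2H (per mil).
#' @param cfg A [source_config()].
#' @return List with `mean` and `sd` (per mil).
#' @export
aquatic_source <- function(d2h_water, cfg = source_config()) {
  if (any(is.na(d2h_water))) stop("missing lake water delta-2H value")
  list(mean = d2h_water + cfg$photosynthetic_discrimination,
       sd = rep(cfg$sd_aquatic, length(d2h_water)))
}

#' Terrestrial source from inlet DOM
#'
#' @param d2h_inlet_dom Inlet dissolved organic matter delta-2H (per mil);
#'   `NA` allowed only where a substitute value is given.
#' @param cfg A [source_config()].
#' @param substitute_value Replacement delta-2H borrowed from the nearest
#'   lake's inlet, used where `d2h_inlet_dom` is missing.
#' @return List with `mean`, `sd`, and logical `substituted`.
#' @export
terrestrial_source <- function(d2h_inlet_dom, cfg = source_config(),
                               substitute_value = NULL) {
  n <- length(d2h_inlet_dom)
  sub <- rep(FALSE, n)
  if (!is.null(substitute_value)) {
    use <- is.na(d2h_inlet_dom) & !is.na(substitute_value)
    d2h_inlet_dom[use] <- substitute_value[use]
    sub[use] <- TRUE
  }
  if (any(is.na(d2h_inlet_dom))) {
    stop("missing inlet DOM delta-2H and no substitute lake value")
  }
  list(mean = d2h_inlet_dom, sd = rep(cfg$sd_terrestrial, n), substituted = sub)
}

#' Terrestrial source under the bacterial processing scenario
#'
#' Models a microbial step between terrestrial DOM and consumers: bacterial
#' tissue hydrogen mixes inlet DOM with lake water,
#' `inlet * (1 - omega) + water * omega`. The result always lies between the
#' inlet DOM and water values.
#'
#' @param d2h_inlet_dom Inlet DOM delta-2H (per mil).
#' @param d2h_water Lake water delta-2H (per mil).
#' @param cfg A [source_config()] (uses `bacterial_omega`, `sd_terrestrial`).
#' @return List with `mean` and `sd`.
#' @export
bacterial_scenario_source <- function(d2h_inlet_dom, d2h_water,
                                      cfg = source_config(scenario = "bacterial")) {
  if (any(is.na(d2h_inlet_dom)) || any(is.na(d2h_water))) {
    stop("bacterial scenario needs both inlet DOM and water delta-2H")
  }
  w <- cfg$bacterial_omega
  list(mean = d2h_inlet_dom * (1 - w) + d2h_water * w,
       sd = rep(cfg$sd_terrestrial, length(d2h_inlet_dom)))
}

#' Build per-lake source pairs under a scenario
#'
#' @param sources Data frame with `lake_id`, `d2h_water`, `d2h_inlet_dom`
#'   (NA allowed), optional `d2h_benthic_algae`, optional
#'   `substitute_lake_id`.
#' @param cfg A [source_config()]; `cfg$scenario` selects the construction.
#' @return Data frame (`lake_id`, `terrestrial_mean`, `terrestrial_sd`,
#'   `aquatic_mean`, `aquatic_sd`, `scenario`, `inlet_substituted`).
#' @export
build_source_pairs <- function(sources, cfg = source_config()) {
  stopifnot(all(c("lake_id", "d2h_water", "d2h_inlet_dom") %in% names(sources)))
  sub_val <- rep(NA_real_, nrow(sources))
  if (!is.null(sources$substitute_lake_id)) {
    has_sub <- !is.na(sources$substitute_lake_id) & sources$substitute_lake_id != ""
    idx <- match(sources$substitute_lake_id[has_sub], sources$lake_id)
    if (anyNA(idx)) {
      stop("substitute_lake_id refers to unknown lake(s): ",
           paste(sources$substitute_lake_id[has_sub][is.na(idx)], collapse = ", "))
    }
    sub_val[has_sub] <- sources$d2h_inlet_dom[idx]
  }
  inlet <- terrestrial_source(sources$d2h_inlet_dom, cfg, substitute_value = sub_val)
  terr <- switch(cfg$scenario,
    inlet_dom = inlet,
    bacterial = {
      filled <- sources$d2h_inlet_dom
      filled[inlet$substituted] <- inlet$mean[inlet$substituted]
      c(bacterial_scenario_source(filled, sources$d2h_water, cfg),
        list(substituted = inlet$substituted))
    },
    benthic_algae = inlet)
  aq <- if (cfg$scenario == "benthic_algae") {
    if (is.null(sources$d2h_benthic_algae) || any(is.na(sources$d2h_benthic_algae))) {
      stop("benthic_algae scenario needs a complete d2h_benthic_algae column")
    }
    list(mean = sources$d2h_benthic_algae,
         sd = rep(cfg$sd_aquatic, nrow(sources)))
  } else {
    aquatic_source(sources$d2h_water, cfg)
  }
  data.frame(lake_id = sources$lake_id,
             terrestrial_mean = terr$mean, terrestrial_sd = terr$sd,
             aquatic_mean = aq$mean, aquatic_sd = aq$sd,
             scenario = cfg$scenario, inlet_substituted = terr$substituted,
             stringsAsFactors = FALSE)
}

#' Screen consumers against the per-lake source envelope
#'
#' Diagnostic only: for each lake the envelope runs from the lower source
#' mean minus `k` times that source's own SD to the upper source mean plus
#' `k` times that source's SD. Counts of corrected consumer values outside
#' the envelope are reported per compartment and overall; no samples are
#' removed.
#'
#' @param prepared Prepared consumers (needs `lake_id`, `group`,
#'   `d2h_corrected`).
#' @param pairs Source pairs from [build_source_pairs()].
#' @param k SD multiplier (> 0), default 2.
#' @return List of class `"allomix_screening"` with per-sample `outside`
#'   flags, a per-group count table, `n_outside`, `n_total`, and `k`.
#' @export
screen_consumers <- function(prepared, pairs, k = 2) {
  stopifnot(k > 0)
  idx <- match(prepared$lake_id, pairs$lake_id)
  if (anyNA(idx)) stop("source pair missing for lake(s): ",
                       paste(unique(prepared$lake_id[is.na(idx)]), collapse = ", "))
  t_mean <- pairs$terrestrial_mean[idx]; t_sd <- pairs$terrestrial_sd[idx]
  a_mean <- pairs$aquatic_mean[idx];     a_sd <- pairs$aquatic_sd[idx]
  lo_is_aq <- a_mean <= t_mean
  lo <- ifelse(lo_is_aq, a_mean - k * a_sd, t_mean - k * t_sd)
  hi <- ifelse(lo_is_aq, t_mean + k * t_sd, a_mean + k * a_sd)
  outside <- prepared$d2h_corrected < lo | prepared$d2h_corrected > hi
  by_group <- tapply(outside, prepared$group, sum)
  structure(list(outside = outside,
                 by_group = data.frame(group = names(by_group),
                                       n_outside = as.integer(by_group),
                                       row.names = NULL),
                 n_outside = sum(outside), n_total = length(outside), k = k),
            class = "allomix_screening")
}

#' @export
print.allomix_screening <- function(x, ...) {
  cat(sprintf("Source-envelope screen (k = %g SD): %d of %d corrected samples outside\n",
              x$k, x$n_outside, x$n_total))
  if (x$n_outside > 0) print(x$by_group, row.names = FALSE)
  invisible(x)
}
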