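#' Read the consumer input CSV
#'
#' Schema: `lake_id, taxon, group, d2h, d15n, d13c` (d13c may be blank).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_consumers_csv <- function(path) {
  if (!file.exists(path)) stop("consumer file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lake_id", "taxon", "group", "d2h", "d15n")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("consumers.csv missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$d13c)) d$d13c <- NA_real_
  d
}

#' Read the per-lake source CSV
#'
#' Schema: `lake_id, d2h_water, d2h_inlet_dom, d2h_benthic_algae,
#' substitute_lake_id` (the last three may be blank).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_sources_csv <- function(path) {
  if (!file.exists(path)) stop("source file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lake_id", "d2h_water", "d2h_inlet_dom")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("sources.csv missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read the environmental table CSV
#'
#' Schema: `lake_id` plus numeric environmental variables; at least 15
#' complete numeric columns are required for the PCA. The number of
#' variables found is recorded as attribute `n_vars` (the table is not
#' required to have exactly 18 columns).
#'
#' @param path CSV path.
#' @param min_vars Minimum complete numeric columns (default 15).
#' @return Data frame with attribute `n_vars`.
#' @export
read_env_csv <- function(path, min_vars = 15) {
  if (!file.exists(path)) stop("environment file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"lake_id" %in% names(d)) stop("environment.csv missing lake_id column")
  num <- vapply(d[setdiff(names(d), "lake_id")],
                function(v) is.numeric(v) && !anyNA(v), logical(1))
  if (sum(num) < min_vars) {
    stop(sprintf("environment.csv has %d complete numeric columns; need >= %d",
                 sum(num), min_vars))
  }
  attr(d, "n_vars") <- sum(num)
  d
}

#' Pipeline run configuration
#'
#' @param consumers,sources,environment Paths to the three input CSVs, or
#'   `NULL` when `simulate` is given.
#' @param simulate Optional [sim_config()]; when present, inputs are
#'   generated rather than read.
#' @param trophic A [trophic_config()].
#' @param source_cfg A [source_config()].
#' @param mixing A [mix_config()].
#' @param out Output directory (`NULL` for no file output).
#' @param screen_k SD multiplier for the source-envelope screen (default 2).
#' @param omegas Omega values for [run_scenarios()] (default
#'   `c(0.14, 0.23, 0.32)`).
#' @param source_scenarios Source scenarios for [run_scenarios()].
#' @param seed Pipeline seed.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(consumers = NULL, sources = NULL, environment = NULL,
                       simulate = NULL, trophic = trophic_config(),
                       source_cfg = source_config(), mixing = mix_config(),
                       out = NULL, screen_k = 2,
                       omegas = c(0.14, 0.23, 0.32),
                       source_scenarios = "inlet_dom", seed = 1) {
  if (is.null(simulate) &&
      (is.null(consumers) || is.null(sources))) {
    stop("either input file paths or a simulate block must be given")
  }
  if (length(omegas) == 0 || length(source_scenarios) == 0) {
    stop("scenario grid is empty")
  }
  structure(list(consumers = consumers, sources = sources,
                 environment = environment, simulate = simulate,
                 trophic = trophic, source_cfg = source_cfg, mixing = mixing,
                 out = out, screen_k = screen_k, omegas = omegas,
                 source_scenarios = source_scenarios, seed = seed),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full allochthony pipeline
#'
#' Orchestrates: input loading (or simulation), environmental PCA when the
#' covariate is PC1, isotope preprocessing, source construction, the
#' source-envelope screen, the hierarchical mixing-model fit, and
#' summaries. When `config$out` is set, every stage's table and a JSON run
#' manifest (configuration, seed, stage counts, convergence status) are
#' written there.
#'
#' @param config A [run_config()].
#' @return List of class `"allomix_run"`: `inputs`, `pca`, `prepared`,
#'   `pairs`, `screening`, `fit`, `summary`, `manifest` (invisible tables
#'   also on disk when `out` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_study(config$simulate)
      env_cols <- c("lake_id", names(synth_env_table(0)))
      list(consumers = sim$samples,
           sources = data.frame(lake_id = sim$lakes$lake_id,
                                d2h_water = sim$lakes$d2h_water,
                                d2h_inlet_dom = sim$lakes$d2h_inlet_dom,
                                d2h_benthic_algae = sim$lakes$aquatic_realized,
                                substitute_lake_id = NA_character_,
                                stringsAsFactors = FALSE),
           environment = sim$lakes[env_cols], truth = sim$truth)
    } else {
      list(consumers = read_consumers_csv(config$consumers),
           sources = read_sources_csv(config$sources),
           environment = if (!is.null(config$environment))
             read_env_csv(config$environment) else NULL,
           truth = NULL)
    }
  })
  message(sprintf("[load] %d consumer samples, %d lakes",
                  nrow(inputs$consumers), nrow(inputs$sources)))

  covariate <- config$mixing$covariate
  pca <- NULL
  covariates <- NULL
  if (covariate == "pc1") {
    pca <- stage("pca", {
      if (is.null(inputs$environment)) stop("PC1 requested but no environmental table given")
      run_pca(inputs$environment)
    })
    covariates <- pc1_scores(pca)
    message(sprintf("[pca] %d variables; PC1 explains %.1f%% of variance",
                    pca$n_vars, 100 * pca$var_explained[1]))
  } else if (covariate != "none") {
    covariates <- stage("covariate", {
      if (is.null(inputs$environment) || !covariate %in% names(inputs$environment)) {
        stop("covariate column '", covariate, "' not in environmental table")
      }
      inputs$environment[c("lake_id", covariate)]
    })
  }

  prepared <- stage("isotope_prep",
    prepare_consumers(inputs$consumers, inputs$sources, config$trophic))
  message(sprintf("[prep] %d samples; %d imputed baselines; %d methane-fixed; %d TL-clamped",
                  nrow(prepared), sum(prepared$baseline_imputed),
                  sum(prepared$methane_fixed), sum(prepared$tl_clamped)))

  pairs <- stage("sources", build_source_pairs(inputs$sources, config$source_cfg))
  screening <- stage("screen", screen_consumers(prepared, pairs, k = config$screen_k))
  message(sprintf("[screen] %d of %d corrected values outside +/-%g SD envelope",
                  screening$n_outside, screening$n_total, config$screen_k))

  fit <- stage("mixing_model", {
    md <- mix_data(prepared, pairs, covariates, covariate)
    allomix(md, config$mixing)
  })
  if (!isTRUE(fit$converged)) {
    message("[mixing_model] WARNING: convergence diagnostics FAILED")
  }
  summ <- summarize_allochthony(fit, grid = default_grid(fit))

  manifest <- list(seed = config$seed, covariate = covariate,
                   scenario = config$source_cfg$scenario,
                   omega = config$trophic$omega,
                   n_samples = nrow(prepared), n_lakes = nrow(pairs),
                   n_imputed_baselines = sum(prepared$baseline_imputed),
                   n_methane_fixed = sum(prepared$methane_fixed),
                   n_outside_envelope = screening$n_outside,
                   converged = isTRUE(fit$converged),
                   mcmc = config$mixing[c("chains", "iterations", "burn_in",
                                          "thinning")],
                   r_version = as.character(getRversion()))
  res <- structure(list(inputs = inputs, pca = pca, prepared = prepared,
                        pairs = pairs, screening = screening, fit = fit,
                        summary = summ, manifest = manifest),
                   class = "allomix_run")
  if (!is.null(config$out)) write_run_outputs(res, config$out)
  res
}

default_grid <- function(fit) {
  if (fit$config$covariate == "none") 0 else
    seq(min(fit$data$x), max(fit$data$x), length.out = 25)
}

write_run_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE, na = "")
  w(res$prepared, "prepared_consumers.csv")
  w(res$pairs, "source_pairs.csv")
  w(cbind(obs = seq_along(res$screening$outside), outside = res$screening$outside),
    "screening.csv")
  draws_long <- do.call(rbind, lapply(seq_along(res$fit$draws), function(ch) {
    m <- res$fit$draws[[ch]][, res$fit$active, drop = FALSE]
    data.frame(chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  w(draws_long, "posterior_draws.csv")
  w(res$summary$curves, "allochthony_curves.csv")
  w(res$summary$intercepts, "allochthony_intercepts.csv")
  diag <- res$fit$diagnostics
  w(data.frame(parameter = names(diag$rhat), rhat = diag$rhat,
               geweke_max_abs_z = diag$geweke), "diagnostics.csv")
  if (!is.null(res$pca)) {
    w(data.frame(lake_id = res$pca$lake_id, res$pca$scores), "pca_scores.csv")
    w(data.frame(variable = rownames(res$pca$loadings), res$pca$loadings),
      "pca_loadings.csv")
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.allomix_run <- function(x, ...) {
  cat("allomix pipeline run\n")
  cat(sprintf("  %d samples, %d lakes; scenario %s, omega %.2f; covariate %s\n",
              x$manifest$n_samples, x$manifest$n_lakes, x$manifest$scenario,
              x$manifest$omega, x$manifest$covariate))
  print(x$fit)
  invisible(x)
}

#' Run omega and source-scenario sensitivity analyses
#'
#' Re-runs preprocessing and the mixing model over the cross product of the
#' requested omega values and source scenarios (covariate fixed). Reports
#' per-taxon intercept allochthony and ILR slope for every converged cell,
#' plus a pattern-consistency check: the Spearman rank correlation of taxon
#' intercept allochthony between each scenario and the base cell
#' (omega = base omega, scenario = first source scenario). Non-converged
#' cells are flagged and excluded from the consistency statistic.
#'
#' @param config A [run_config()]; `config$omegas` and
#'   `config$source_scenarios` define the grid.
#' @param base An optional existing base [run_pipeline()] result to reuse.
#' @return List of class `"allomix_scenarios"`: `table` (taxon x scenario
#'   summaries), `consistency` (Spearman rho per scenario vs base),
#'   `fits`, `grid`.
#' @export
run_scenarios <- function(config, base = NULL) {
  stopifnot(inherits(config, "run_config"))
  grid <- expand.grid(omega = config$omegas,
                      scenario = config$source_scenarios,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_omega <- config$trophic$omega
  base_scenario <- config$source_scenarios[[1]]
  rows <- list(); fits <- list(); consistency <- list()
  base_ranks <- NULL
  for (i in seq_len(nrow(grid))) {
    om <- grid$omega[i]; sc <- grid$scenario[i]
    cfg_i <- config
    cfg_i$trophic$omega <- om
    cfg_i$source_cfg$scenario <- sc
    cfg_i$out <- if (!is.null(config$out))
      file.path(config$out, sprintf("scenario_omega%.2f_%s", om, sc)) else NULL
    res <- if (!is.null(base) && om == base_omega && sc == base_scenario) base
           else run_pipeline(cfg_i)
    key <- sprintf("omega=%.2f/%s", om, sc)
    fits[[key]] <- res$fit
    ic <- res$summary$intercepts
    rows[[key]] <- data.frame(scenario = key, omega = om, source_scenario = sc,
                              converged = isTRUE(res$fit$converged), ic)
    if (om == base_omega && sc == base_scenario) {
      base_ranks <- stats::setNames(ic$allochthony, ic$taxon)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(base_ranks)) {
    for (key in names(fits)) {
      sub <- tab[tab$scenario == key, ]
      if (!all(sub$converged)) next
      rho <- stats::cor(base_ranks[sub$taxon], sub$allochthony,
                        method = "spearman")
      consistency[[key]] <- rho
    }
  }
  structure(list(table = tab,
                 consistency = data.frame(scenario = names(consistency),
                                          spearman_rho = unlist(consistency),
                                          row.names = NULL),
                 fits = fits, grid = grid),
            class = "allomix_scenarios")
}

#' @export
print.allomix_scenarios <- function(x, ...) {
  cat(sprintf("Sensitivity grid: %d scenario cell(s)\n", nrow(x$grid)))
  print(format(x$consistency, digits = 3), row.names = FALSE)
  invisible(x)
}
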