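#' Mixing model configuration
#'
#' MCMC and prior settings for the hierarchical two-source mixing model.
#' Defaults are test-scale; the study-scale settings used for final
#' inference in the field (3 chains of 1e6 iterations, burn-in 5e5,
#' thinning 500) are available by argument.
#'
#' @param covariate Which covariate column drives allochthony: `"pc1"`,
#'   `"forest_pct"`, `"nc_pom"`, or `"none"` (intercept-only model).
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations,burn_in,thinning MCMC length controls.
#' @param prior_sd_fixed Normal prior SD for the ILR-space fixed effects
#'   (default 10, weakly informative on the logit-like scale).
#' @param sd_upper Upper bound of the Uniform(0, bound) priors on the
#'   hierarchical SDs (default 5 ILR units).
#' @param xi_upper Upper bound of the Uniform prior on the multiplicative
#'   error factor (default 20).
#' @param include_random_effects Set `FALSE` for the reduced model used by
#'   the grid-integration oracle.
#' @param fix_xi `NULL` (sample xi) or a positive value to hold it fixed.
#' @param rhat_max,geweke_z_max Convergence thresholds (defaults 1.05, 2).
#' @param geweke_pass_frac Fraction of per-parameter, per-chain Geweke tests
#'   that must fall inside the z threshold (default 0.90: a |z| cutoff of 2
#'   has nominal coverage 95.4%, so demanding 95% of tests to pass would
#'   reject about half of perfectly stationary runs by chance; 0.90 keeps
#'   power against genuine drift, which pushes many z-scores far beyond 2).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return List of class `"mix_config"`.
#' @export
mix_config <- function(covariate = c("pc1", "forest_pct", "nc_pom", "none"),
                       chains = 3, iterations = 20000, burn_in = 10000,
                       thinning = 10, prior_sd_fixed = 10, sd_upper = 5,
                       xi_upper = 20, include_random_effects = TRUE,
                       fix_xi = NULL, rhat_max = 1.05, geweke_z_max = 2,
                       geweke_pass_frac = 0.90, seed = 1) {
  covariate <- match.arg(covariate)
  stopifnot(burn_in < iterations, thinning >= 1, chains >= 1,
            prior_sd_fixed > 0, sd_upper > 0, xi_upper > 0)
  if (!is.null(fix_xi)) stopifnot(fix_xi > 0)
  structure(list(covariate = covariate, chains = chains,
                 iterations = iterations, burn_in = burn_in,
                 thinning = thinning, prior_sd_fixed = prior_sd_fixed,
                 sd_upper = sd_upper, xi_upper = xi_upper,
                 include_random_effects = include_random_effects,
                 fix_xi = fix_xi, rhat_max = rhat_max,
                 geweke_z_max = geweke_z_max,
                 geweke_pass_frac = geweke_pass_frac, seed = seed),
            class = "mix_config")
}

#' Assemble the mixing-model data frame
#'
#' Joins prepared consumers to per-lake source pairs and the covariate,
#' producing one row per observation with everything the likelihood needs.
#'
#' @param prepared Prepared consumers (from [prepare_consumers()]; needs
#'   `lake_id`, `taxon`, `d2h_corrected`, `sd_corrected`).
#' @param pairs Source pairs from [build_source_pairs()].
#' @param covariates Data frame `lake_id` plus covariate column(s) (e.g.
#'   from [pc1_scores()]); ignored when `covariate = "none"`.
#' @param covariate Covariate column name, or `"none"`.
#' @return Data frame of class `"mix_data"`.
#' @export
mix_data <- function(prepared, pairs, covariates = NULL, covariate = "pc1") {
  stopifnot(all(c("lake_id", "taxon", "d2h_corrected", "sd_corrected") %in%
                  names(prepared)))
  idx <- match(prepared$lake_id, pairs$lake_id)
  if (anyNA(idx)) stop("source pair missing for lake(s): ",
                       paste(unique(prepared$lake_id[is.na(idx)]), collapse = ", "))
  if (any(pairs$terrestrial_sd <= 0) || any(pairs$aquatic_sd <= 0)) {
    stop("zero-SD sources are not admissible in the mixing model")
  }
  x <- if (covariate == "none") rep(0, nrow(prepared)) else {
    stopifnot(!is.null(covariates), covariate %in% names(covariates))
    cx <- covariates[[covariate]][match(prepared$lake_id, covariates$lake_id)]
    if (any(!is.finite(cx))) {
      stop("non-finite covariate value for lake(s): ",
           paste(unique(prepared$lake_id[!is.finite(cx)]), collapse = ", "))
    }
    cx
  }
  d <- data.frame(lake_id = prepared$lake_id, taxon = prepared$taxon,
                  y = prepared$d2h_corrected, sd_extra = prepared$sd_corrected,
                  x = x,
                  t_mean = pairs$terrestrial_mean[idx],
                  t_sd = pairs$terrestrial_sd[idx],
                  a_mean = pairs$aquatic_mean[idx],
                  a_sd = pairs$aquatic_sd[idx],
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$y)) || any(!is.finite(d$t_mean)) || any(!is.finite(d$a_mean))) {
    stop("non-finite observation or source value in mixing data")
  }
  d$taxon_index <- match(d$taxon, sort(unique(d$taxon)))
  d$lake_index <- match(d$lake_id, sort(unique(d$lake_id)))
  attr(d, "taxa") <- sort(unique(d$taxon))
  attr(d, "lakes") <- sort(unique(d$lake_id))
  attr(d, "covariate") <- covariate
  class(d) <- c("mix_data", "data.frame")
  d
}

# parameter vector layout shared with the C++ sampler
par_layout <- function(data) {
  taxa <- attr(data, "taxa"); lakes <- attr(data, "lakes")
  S <- length(taxa); L <- length(lakes)
  list(S = S, L = L,
       names = c("beta0", "beta1",
                 paste0("b0[", taxa, "]"), paste0("b1[", taxa, "]"),
                 paste0("u[", lakes, "]"),
                 "sigma_sp0", "sigma_sp1", "sigma_lake", "xi"),
       i_beta0 = 1L, i_beta1 = 2L,
       i_b0 = 2L + seq_len(S), i_b1 = 2L + S + seq_len(S),
       i_u = 2L + 2L * S + seq_len(L),
       i_s0 = 2L + 2L * S + L + 1L, i_s1 = 2L + 2L * S + L + 2L,
       i_sl = 2L + 2L * S + L + 3L, i_xi = 2L + 2L * S + L + 4L)
}

# per-observation ILR linear predictor for a parameter vector
mix_phi <- function(theta, data) {
  lay <- par_layout(data)
  (theta[lay$i_beta0] + theta[lay$i_b0][data$taxon_index] +
     theta[lay$i_u][data$lake_index]) +
    (theta[lay$i_beta1] + theta[lay$i_b1][data$taxon_index]) * data$x
}

#' Pointwise log-likelihood of the mixing model
#'
#' For each observation: aquatic proportion `p = ilr_inverse(phi)`, mixture
#' mean `m = (1-p) T + p A`, variance
#' `V = xi * ((1-p)^2 sd_T^2 + p^2 sd_A^2) + sd_extra^2`, and a Normal
#' density of the omega-corrected value at `(m, V)`.
#'
#' @param theta Full parameter vector in the layout used by the sampler
#'   (see [allomix()]; names from the fit's `par_names`).
#' @param data A [mix_data()] frame.
#' @return Vector of per-observation log-likelihood contributions.
#' @export
mix_loglik <- function(theta, data) {
  lay <- par_layout(data)
  p <- ilr_inverse(mix_phi(theta, data))
  q <- 1 - p
  m <- q * data$t_mean + p * data$a_mean
  v <- theta[lay$i_xi] * (q^2 * data$t_sd^2 + p^2 * data$a_sd^2) +
    data$sd_extra^2
  stats::dnorm(data$y, m, sqrt(v), log = TRUE)
}

#' Log posterior density of the mixing model
#'
#' Likelihood from [mix_loglik()] plus log-priors: Normal(0, prior_sd) on
#' the ILR fixed effects, Normal(0, sigma) hierarchies on the random
#' effects, Uniform(0, bound) on the hierarchical SDs and on the
#' multiplicative error factor (constant inside the bounds, -Inf outside).
#'
#' @inheritParams mix_loglik
#' @param config A [mix_config()] (priors and structure flags).
#' @return Scalar log posterior (up to the uniform priors' normalizing
#'   constants).
#' @export
mix_log_posterior <- function(theta, data, config = mix_config()) {
  theta <- unname(theta)
  lay <- par_layout(data)
  s0 <- theta[lay$i_s0]; s1 <- theta[lay$i_s1]; sl <- theta[lay$i_sl]
  xi <- theta[lay$i_xi]
  if (xi <= 0 || xi > config$xi_upper) return(-Inf)
  lp <- stats::dnorm(theta[lay$i_beta0], 0, config$prior_sd_fixed, log = TRUE)
  if (config$covariate != "none") {
    lp <- lp + stats::dnorm(theta[lay$i_beta1], 0, config$prior_sd_fixed, log = TRUE)
  }
  if (config$include_random_effects) {
    if (s0 <= 0 || s0 > config$sd_upper || sl <= 0 || sl > config$sd_upper) {
      return(-Inf)
    }
    lp <- lp + sum(stats::dnorm(theta[lay$i_b0], 0, s0, log = TRUE)) +
      sum(stats::dnorm(theta[lay$i_u], 0, sl, log = TRUE))
    if (config$covariate != "none") {
      if (s1 <= 0 || s1 > config$sd_upper) return(-Inf)
      lp <- lp + sum(stats::dnorm(theta[lay$i_b1], 0, s1, log = TRUE))
    }
  }
  lp + sum(mix_loglik(theta, data))
}
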