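#' Fit the hierarchical Bayesian two-source mixing model
#'
#' Estimates consumer allochthony in one-dimensional ILR space with the
#' structure `allochthony ~ 1 + x + (1 + x | taxon) + (1 | lake)`: a global
#' ILR intercept and covariate slope, taxon-level random intercepts and
#' slopes, lake-level random intercepts, and a multiplicative
#' process-by-residual error factor `xi` scaling the source-mixing variance,
#' plus an additive observation variance from the omega-correction
#' uncertainty. Sampling uses component-wise adaptive random-walk
#' Metropolis (adaptation restricted to burn-in); chains are seeded
#' independently from `config$seed` and convergence is checked with split
#' rank-normalized R-hat and Geweke diagnostics.
#'
#' @param data A [mix_data()] frame.
#' @param config A [mix_config()].
#' @param keep_loglik Keep the pointwise log-likelihood matrix per chain
#'   (needed for DIC / LOO export; default `TRUE`).
#' @return Object of class `"allomix"`: `draws` (list of chain matrices,
#'   iterations x parameters), `loglik` (list of chain matrices),
#'   `log_posterior`, `accept`, `par_names`, `active`, `data`, `config`,
#'   `diagnostics`, `converged`.
#' @seealso [summary.allomix()], [summarize_allochthony()],
#'   [compare_models()], [diagnose()]
#' @export
allomix <- function(data, config = mix_config(), keep_loglik = TRUE) {
  stopifnot(inherits(data, "mix_data"), inherits(config, "mix_config"))
  lay <- par_layout(data)
  use_cov <- config$covariate != "none"
  use_ranef <- config$include_random_effects
  if (use_ranef && (lay$S < 2 || lay$L < 2)) {
    stop("random-effect variances need at least 2 taxa and 2 lakes; ",
         "use include_random_effects = FALSE for the reduced model")
  }
  xi_free <- is.null(config$fix_xi)
  active <- c(TRUE, use_cov,
              rep(use_ranef, lay$S), rep(use_ranef && use_cov, lay$S),
              rep(use_ranef, lay$L),
              use_ranef, use_ranef && use_cov, use_ranef, xi_free)

  chains <- vector("list", config$chains)
  logliks <- vector("list", config$chains)
  lps <- vector("list", config$chains)
  accept <- NULL
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch)
    init <- numeric(length(lay$names))
    init[lay$i_beta0] <- stats::rnorm(1, 0, 1)
    if (use_cov) init[lay$i_beta1] <- stats::rnorm(1, 0, 1)
    if (use_ranef) {
      init[lay$i_b0] <- stats::rnorm(lay$S, 0, 0.1)
      if (use_cov) init[lay$i_b1] <- stats::rnorm(lay$S, 0, 0.1)
      init[lay$i_u] <- stats::rnorm(lay$L, 0, 0.1)
      init[c(lay$i_s0, lay$i_s1, lay$i_sl)] <- stats::runif(3, 0.2, 1)
    }
    init[lay$i_xi] <- if (xi_free) stats::runif(1, 0.5, 2) else config$fix_xi
    res <- run_chain_cpp(
      y = data$y, x = data$x,
      taxon = data$taxon_index - 1L, lake = data$lake_index - 1L,
      tmean = data$t_mean, tsd = data$t_sd,
      amean = data$a_mean, asd = data$a_sd, sdex = data$sd_extra,
      S = lay$S, L = lay$L,
      use_cov = use_cov, use_ranef = use_ranef, xi_free = xi_free,
      beta_prior_sd = config$prior_sd_fixed, sd_upper = config$sd_upper,
      xi_upper = config$xi_upper, init = init,
      n_iter = config$iterations, n_burn = config$burn_in,
      thin = config$thinning, keep_loglik = keep_loglik)
    colnames(res$draws) <- lay$names
    chains[[ch]] <- res$draws
    logliks[[ch]] <- if (keep_loglik) res$loglik else NULL
    lps[[ch]] <- res$log_posterior
    accept <- rbind(accept, res$accept)
  }
  fit <- structure(list(draws = chains, loglik = logliks,
                        log_posterior = lps, accept = accept,
                        par_names = lay$names, active = active,
                        layout = lay, data = data, config = config),
                   class = "allomix")
  fit$diagnostics <- diagnose(fit)
  fit$converged <- fit$diagnostics$pass
  fit
}

# draws of one or more parameters pooled across chains (matrix)
pooled_draws <- function(fit, cols = NULL) {
  m <- do.call(rbind, fit$draws)
  if (is.null(cols)) m else m[, cols, drop = FALSE]
}

#' @export
print.allomix <- function(x, ...) {
  lay <- x$layout
  cat("Hierarchical two-source ILR mixing model\n")
  cat(sprintf("  %d observations, %d taxa, %d lakes; covariate: %s\n",
              nrow(x$data), lay$S, lay$L, x$config$covariate))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thinning %d): %d draws\n",
              x$config$chains, x$config$iterations, x$config$burn_in,
              x$config$thinning, nrow(pooled_draws(x))))
  cat(sprintf("  convergence: %s (max R-hat %.3f)\n",
              if (isTRUE(x$converged)) "passed" else "NOT CONVERGED",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  gl <- stats::quantile(1 - ilr_inverse(pooled_draws(x, "beta0")),
                        c(0.5, 0.025, 0.975))
  cat(sprintf("  global intercept allochthony: %.2f (95%% CI %.2f-%.2f)\n",
              gl[1], gl[2], gl[3]))
  if (x$config$covariate != "none") {
    sl <- stats::quantile(pooled_draws(x, "beta1"), c(0.5, 0.025, 0.975))
    cat(sprintf("  global ILR slope: %.2f (95%% CI %.2f-%.2f)\n",
                sl[1], sl[2], sl[3]))
  }
  invisible(x)
}

#' Posterior medians of the model parameters
#'
#' @param object An `"allomix"` fit.
#' @param ... Unused.
#' @return Named vector of posterior medians for the sampled parameters.
#' @export
coef.allomix <- function(object, ...) {
  m <- pooled_draws(object)
  apply(m[, object$active, drop = FALSE], 2, stats::median)
}

#' Summarize an allochthony mixing-model fit
#'
#' @param object An `"allomix"` fit.
#' @param prob Credible-interval mass (default 0.95, equal-tailed).
#' @param ... Unused.
#' @return List of class `"summary.allomix"` with a parameter table
#'   (median, CI, R-hat) and the per-taxon intercept allochthony table.
#' @export
summary.allomix <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  m <- pooled_draws(object)[, object$active, drop = FALSE]
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.5, a, 1 - a)))
  par_table <- data.frame(parameter = rownames(qs), median = qs[, 1],
                          lo = qs[, 2], hi = qs[, 3],
                          rhat = object$diagnostics$rhat[rownames(qs)],
                          row.names = NULL)
  out <- list(par_table = par_table,
              intercepts = taxon_intercepts(object, prob = prob),
              converged = object$converged, config = object$config)
  class(out) <- "summary.allomix"
  out
}

#' @export
print.summary.allomix <- function(x, ...) {
  cat("Per-taxon intercept allochthony (covariate = 0):\n")
  print(format(x$intercepts, digits = 3), row.names = FALSE)
  cat("\nFixed effects and variance components:\n")
  keep <- !grepl("^(b0|b1|u)\\[", x$par_table$parameter)
  print(format(x$par_table[keep, ], digits = 3), row.names = FALSE)
  if (!isTRUE(x$converged)) cat("\nWARNING: convergence diagnostics failed\n")
  invisible(x)
}

# per-taxon intercept allochthony draws: 1 - ilr_inverse(beta0 + b0_s)
taxon_intercepts <- function(fit, prob = 0.95) {
  a <- (1 - prob) / 2
  taxa <- attr(fit$data, "taxa")
  m <- pooled_draws(fit)
  out <- lapply(seq_along(taxa), function(s) {
    phi <- m[, "beta0"] +
      if (fit$config$include_random_effects) m[, paste0("b0[", taxa[s], "]")] else 0
    al <- 1 - ilr_inverse(phi)
    qs <- stats::quantile(al, c(0.5, a, 1 - a))
    slope_med <- slope_lo <- slope_hi <- NA_real_
    if (fit$config$covariate != "none") {
      sl <- m[, "beta1"] +
        if (fit$config$include_random_effects) m[, paste0("b1[", taxa[s], "]")] else 0
      sq <- stats::quantile(sl, c(0.5, a, 1 - a))
      slope_med <- sq[1]; slope_lo <- sq[2]; slope_hi <- sq[3]
    }
    data.frame(taxon = taxa[s], allochthony = qs[1], lo = qs[2], hi = qs[3],
               ilr_slope = slope_med, slope_lo = slope_lo, slope_hi = slope_hi)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior allochthony summaries over a covariate grid
#'
#' For every taxon and grid point, allochthony draws are
#' `1 - ilr_inverse(phi)` with `phi = (beta0 + b0_s) + (beta1 + b1_s) x`
#' (lake effects at zero: curves describe an average lake). The
#' global-average consumer draws new taxon effects from their fitted
#' hierarchical SDs per posterior draw (`marginal = "sample"`), or sets them
#' to zero (`marginal = "zero"`). The ILR slope CI excluding zero indicates
#' a significant covariate effect, since the ILR space is one-dimensional.
#'
#' @param fit An `"allomix"` fit.
#' @param grid Covariate grid (nonempty numeric).
#' @param prob Credible mass (default 0.95).
#' @param marginal How the global-average consumer treats random effects.
#' @return List of class `"allochthony_summary"`: `intercepts` (per taxon at
#'   covariate 0, plus slope CI and significance), `curves` (taxon x grid
#'   median/CI), `global_curve`, `slope_significant`.
#' @export
summarize_allochthony <- function(fit, grid = seq(-3, 3, length.out = 25),
                                  prob = 0.95,
                                  marginal = c("sample", "zero")) {
  marginal <- match.arg(marginal)
  if (length(grid) == 0) stop("covariate grid is empty")
  a <- (1 - prob) / 2
  m <- pooled_draws(fit)
  taxa <- attr(fit$data, "taxa")
  ranef <- fit$config$include_random_effects
  use_cov <- fit$config$covariate != "none"

  curves <- do.call(rbind, lapply(seq_along(taxa), function(s) {
    ic <- m[, "beta0"] + if (ranef) m[, paste0("b0[", taxa[s], "]")] else 0
    sl <- if (use_cov) {
      m[, "beta1"] + if (ranef) m[, paste0("b1[", taxa[s], "]")] else 0
    } else 0
    do.call(rbind, lapply(grid, function(g) {
      al <- 1 - ilr_inverse(ic + sl * g)
      qs <- stats::quantile(al, c(0.5, a, 1 - a))
      data.frame(taxon = taxa[s], covariate = g,
                 median = qs[1], lo = qs[2], hi = qs[3])
    }))
  }))
  rownames(curves) <- NULL

  nd <- nrow(m)
  if (ranef && marginal == "sample") {
    b0_new <- stats::rnorm(nd, 0, m[, "sigma_sp0"])
    b1_new <- if (use_cov) stats::rnorm(nd, 0, m[, "sigma_sp1"]) else 0
    u_new <- stats::rnorm(nd, 0, m[, "sigma_lake"])
  } else {
    b0_new <- b1_new <- u_new <- 0
  }
  g_ic <- m[, "beta0"] + b0_new + u_new
  g_sl <- if (use_cov) m[, "beta1"] + b1_new else 0
  global_curve <- do.call(rbind, lapply(grid, function(g) {
    al <- 1 - ilr_inverse(g_ic + g_sl * g)
    qs <- stats::quantile(al, c(0.5, a, 1 - a))
    data.frame(covariate = g, median = qs[1], lo = qs[2], hi = qs[3])
  }))
  rownames(global_curve) <- NULL

  slope_sig <- NA
  if (use_cov) {
    sq <- stats::quantile(m[, "beta1"], c(a, 1 - a))
    slope_sig <- sq[1] > 0 || sq[2] < 0
  }
  structure(list(intercepts = taxon_intercepts(fit, prob = prob),
                 curves = curves, global_curve = global_curve,
                 slope_significant = unname(slope_sig), prob = prob),
            class = "allochthony_summary")
}

#' @export
print.allochthony_summary <- function(x, ...) {
  cat(sprintf("Allochthony summary (%.0f%% credible intervals)\n", 100 * x$prob))
  print(format(x$intercepts, digits = 3), row.names = FALSE)
  if (!is.na(x$slope_significant)) {
    cat(sprintf("Global ILR slope %s zero (covariate effect %s)\n",
                if (x$slope_significant) "excludes" else "includes",
                if (x$slope_significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' Predicted allochthony for new covariate values
#'
#' @param object An `"allomix"` fit.
#' @param newdata Data frame with a `covariate` column and optionally a
#'   `taxon` column (absent or `NA` rows give the global-average-consumer
#'   prediction with random effects at zero).
#' @param prob Credible mass.
#' @param ... Unused.
#' @return `newdata` with `median`, `lo`, `hi` allochthony columns.
#' @export
predict.allomix <- function(object, newdata, prob = 0.95, ...) {
  stopifnot("covariate" %in% names(newdata))
  a <- (1 - prob) / 2
  m <- pooled_draws(object)
  ranef <- object$config$include_random_effects
  use_cov <- object$config$covariate != "none"
  res <- t(vapply(seq_len(nrow(newdata)), function(i) {
    tx <- if ("taxon" %in% names(newdata)) newdata$taxon[i] else NA
    ic <- m[, "beta0"] +
      if (ranef && !is.na(tx)) m[, paste0("b0[", tx, "]")] else 0
    sl <- if (use_cov) {
      m[, "beta1"] + if (ranef && !is.na(tx)) m[, paste0("b1[", tx, "]")] else 0
    } else 0
    stats::quantile(1 - ilr_inverse(ic + sl * newdata$covariate[i]),
                    c(0.5, a, 1 - a))
  }, numeric(3)))
  newdata$median <- res[, 1]; newdata$lo <- res[, 2]; newdata$hi <- res[, 3]
  newdata
}

#' Posterior predictive simulation of corrected consumer values
#'
#' Draws replicate omega-corrected delta-2H observations from the fitted
#' likelihood at posterior parameter draws.
#'
#' @param object An `"allomix"` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix `nrow(data) x nsim`.
#' @export
simulate.allomix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- pooled_draws(object)
  data <- object$data
  lay <- object$layout
  pick <- sample(nrow(m), nsim, replace = nsim > nrow(m))
  out <- vapply(pick, function(d) {
    th <- m[d, ]
    p <- ilr_inverse(mix_phi(th, data))
    q <- 1 - p
    mu <- q * data$t_mean + p * data$a_mean
    v <- th[lay$i_xi] * (q^2 * data$t_sd^2 + p^2 * data$a_sd^2) + data$sd_extra^2
    stats::rnorm(nrow(data), mu, sqrt(v))
  }, numeric(nrow(data)))
  matrix(out, nrow = nrow(data))
}

#' Residuals of the mixing model at posterior-mean parameters
#'
#' @param object An `"allomix"` fit.
#' @param type `"raw"` (observed minus fitted mixture mean) or `"pearson"`
#'   (scaled by the fitted SD).
#' @param ... Unused.
#' @return Numeric vector, one value per observation.
#' @export
residuals.allomix <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  th <- colMeans(pooled_draws(object))
  data <- object$data
  lay <- object$layout
  p <- ilr_inverse(mix_phi(th, data))
  q <- 1 - p
  mu <- q * data$t_mean + p * data$a_mean
  r <- data$y - mu
  if (type == "pearson") {
    v <- th[lay$i_xi] * (q^2 * data$t_sd^2 + p^2 * data$a_sd^2) + data$sd_extra^2
    r <- r / sqrt(v)
  }
  r
}

#' Plot fitted allochthony along the environmental gradient
#'
#' Median curve with credible band for the global-average consumer, plus
#' per-taxon median curves.
#'
#' @param x An `"allomix"` fit.
#' @param grid Covariate grid; defaults to the observed covariate range.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.allomix <- function(x, grid = NULL, ...) {
  if (is.null(grid)) {
    grid <- if (x$config$covariate == "none") 0 else
      seq(min(x$data$x), max(x$data$x), length.out = 40)
  }
  s <- summarize_allochthony(x, grid = grid, marginal = "zero")
  gc <- s$global_curve
  graphics::plot(gc$covariate, gc$median, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = x$config$covariate,
                 ylab = "allochthony", ...)
  graphics::polygon(c(gc$covariate, rev(gc$covariate)), c(gc$lo, rev(gc$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  taxa <- unique(s$curves$taxon)
  for (i in seq_along(taxa)) {
    cc <- s$curves[s$curves$taxon == taxa[i], ]
    graphics::lines(cc$covariate, cc$median,
                    col = grDevices::adjustcolor("grey30", 0.6))
  }
  graphics::lines(gc$covariate, gc$median, lwd = 2, col = "steelblue4")
  invisible(s)
}

#' Compare mixing-model fits by DIC, Akaike weight and approximate R-squared
#'
#' DIC = Dbar + pD with pD = Dbar - D(posterior mean of parameters),
#' D = -2 log-likelihood. Akaike weights are proportional to
#' `exp(-0.5 * delta DIC)`. Approximate R-squared is the squared Pearson
#' correlation between the observations and the posterior-mean fitted
#' mixture means. The pointwise log-likelihood matrix of each fit is
#' retained (`fit$loglik`) so any external LOO tool can consume it.
#'
#' @param fits Named list of `"allomix"` fits on identical data.
#' @return Data frame with `model`, `dbar`, `pd`, `dic`, `delta_dic`,
#'   `akaike_weight`, `approx_r2`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  y0 <- fits[[1]]$data$y
  for (f in fits) {
    if (is.null(f$loglik[[1]])) stop("fit lacks pointwise log-likelihoods; rerun with keep_loglik = TRUE")
    if (length(f$data$y) != length(y0) || any(f$data$y != y0)) {
      stop("model comparison requires fits on identical data")
    }
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    ll <- do.call(rbind, f$loglik)        # draws x observations
    dev <- -2 * rowSums(ll)
    dbar <- mean(dev)
    th_bar <- colMeans(pooled_draws(f))
    dhat <- -2 * sum(mix_loglik(th_bar, f$data))
    pd <- dbar - dhat
    # posterior-mean fitted means for approximate R-squared
    m <- pooled_draws(f)
    fitted <- rowMeans(vapply(seq_len(nrow(m)), function(d) {
      p <- ilr_inverse(mix_phi(m[d, ], f$data))
      (1 - p) * f$data$t_mean + p * f$data$a_mean
    }, numeric(nrow(f$data))))
    data.frame(model = nm, dbar = dbar, pd = pd,
               approx_r2 = stats::cor(f$data$y, fitted)^2)
  })
  out <- do.call(rbind, rows)
  out$dic <- out$dbar + out$pd
  out$delta_dic <- out$dic - min(out$dic)
  w <- exp(-0.5 * out$delta_dic)
  out$akaike_weight <- w / sum(w)
  out[order(out$dic), c("model", "dbar", "pd", "dic", "delta_dic",
                        "akaike_weight", "approx_r2")]
}
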