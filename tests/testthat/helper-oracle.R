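# Independent 1-D grid-integration oracle for the reduced mixing model
# (one taxon, one lake, no covariate, no random effects, fixed xi).
# Integrates the exact posterior over the ILR coordinate phi on a fine grid
# and returns moments/quantiles of allochthony = 1 - ilr_inverse(phi).
# Deliberately shares no code with the sampler beyond the data frame.

grid_oracle <- function(y, t_mean, t_sd, a_mean, a_sd, sd_extra, xi,
                        prior_sd = 10, lo = -8, hi = 8, n_grid = 8001) {
  phi <- seq(lo, hi, length.out = n_grid)
  p <- plogis(sqrt(2) * phi)
  logpost <- vapply(seq_along(phi), function(k) {
    pk <- p[k]; qk <- 1 - pk
    m <- qk * t_mean + pk * a_mean
    v <- xi * (qk^2 * t_sd^2 + pk^2 * a_sd^2) + sd_extra^2
    sum(dnorm(y, m, sqrt(v), log = TRUE)) + dnorm(phi[k], 0, prior_sd, log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  al <- 1 - p
  # quantiles of allochthony: al is decreasing in phi, so reverse for cdf
  ord <- order(al)
  cdf <- cumsum(w[ord])
  qfun <- function(prob) al[ord][which.max(cdf >= prob)]
  list(mean = sum(w * al),
       sd = sqrt(sum(w * al^2) - sum(w * al)^2),
       q025 = qfun(0.025), q50 = qfun(0.5), q975 = qfun(0.975))
}

# Monte-Carlo standard errors for posterior mean and quantiles of a draw
# vector, based on the effective sample size.
mc_se <- function(draws, probs = c(0.025, 0.975)) {
  n_eff <- ess(draws)
  se_mean <- sd(draws) / sqrt(n_eff)
  dens <- density(draws)
  se_q <- vapply(probs, function(pr) {
    qv <- quantile(draws, pr)
    f <- approx(dens$x, dens$y, xout = qv)$y
    if (is.na(f) || f <= 0) f <- 1e-3
    sqrt(pr * (1 - pr) / n_eff) / f
  }, numeric(1))
  list(mean = se_mean, q = setNames(se_q, probs))
}
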