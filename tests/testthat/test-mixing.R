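make_mix_frame <- function(y, t_mean = -120, t_sd = 11.2, a_mean = -170,
                           a_sd = 23.6, sd_extra = 13, x = 0) {
  n <- length(y)
  d <- data.frame(lake_id = "A", taxon = "tax", y = y, sd_extra = sd_extra,
                  x = x, t_mean = t_mean, t_sd = t_sd, a_mean = a_mean,
                  a_sd = a_sd, taxon_index = 1L, lake_index = 1L)
  attr(d, "taxa") <- "tax"
  attr(d, "lakes") <- "A"
  attr(d, "covariate") <- "none"
  class(d) <- c("mix_data", "data.frame")
  d
}

theta_for <- function(data, beta0 = 0, beta1 = 0, xi = 1) {
  lay <- allomix:::par_layout(data)
  th <- numeric(length(lay$names))
  names(th) <- lay$names
  th["beta0"] <- beta0; th["beta1"] <- beta1; th["xi"] <- xi
  th
}

test_that("pointwise log-likelihood equals the closed-form Normal density", {
  d <- make_mix_frame(y = -150)
  th <- theta_for(d, beta0 = 0.3, xi = 1)
  p <- ilr_inverse(0.3)
  m <- (1 - p) * -120 + p * -170
  v <- (1 - p)^2 * 11.2^2 + p^2 * 23.6^2 + 13^2
  expect_equal(mix_loglik(th, d), dnorm(-150, m, sqrt(v), log = TRUE))
})

test_that("with zero source SDs the variance reduces to the extra term", {
  d <- make_mix_frame(y = -150, t_sd = 0, a_sd = 0, sd_extra = 7)
  th <- theta_for(d, beta0 = -0.4, xi = 3)
  p <- ilr_inverse(-0.4)
  m <- (1 - p) * -120 + p * -170
  expect_equal(mix_loglik(th, d), dnorm(-150, m, 7, log = TRUE))
})

test_that("likelihood is invariant to translating observations and sources", {
  set.seed(3)
  y <- rnorm(5, -140, 10)
  d1 <- make_mix_frame(y = y)
  d2 <- make_mix_frame(y = y + 57, t_mean = -120 + 57, a_mean = -170 + 57)
  th <- theta_for(d1, beta0 = 0.8, xi = 1.3)
  expect_equal(mix_loglik(th, d1), mix_loglik(th, d2))
})

test_that("log posterior adds priors and respects bounds", {
  d <- make_mix_frame(y = -150)
  cfg <- mix_config(covariate = "none", include_random_effects = FALSE,
                    fix_xi = 1)
  th <- theta_for(d, beta0 = 0.5)
  expect_equal(mix_log_posterior(th, d, cfg),
               sum(mix_loglik(th, d)) + dnorm(0.5, 0, 10, log = TRUE))
  th_bad <- theta_for(d, beta0 = 0.5, xi = -1)
  expect_identical(mix_log_posterior(th_bad, d, cfg), -Inf)
})

test_that("sampler is deterministic under seed and records consistent posteriors", {
  st <- small_study(seed = 21)
  md <- mix_data(st$prep, st$pairs, st$cov, "pc1")
  cfg <- quick_mix_config(seed = 33)
  f1 <- allomix(md, cfg)
  f2 <- allomix(md, cfg)
  expect_identical(f1$draws, f2$draws)
  # stored log-posterior agrees with the R-side evaluation at saved draws
  m <- f1$draws[[1]]
  for (i in c(1, nrow(m))) {
    expect_equal(f1$log_posterior[[1]][i],
                 mix_log_posterior(m[i, ], md, cfg), tolerance = 1e-8)
  }
  # stored pointwise log-likelihoods agree with mix_loglik
  expect_equal(f1$loglik[[1]][5, ], unname(mix_loglik(m[5, ], md)),
               tolerance = 1e-8)
})

test_that("reduced-model posterior matches 1-D grid integration", {
  # one taxon, one lake, no covariate, no hierarchy, fixed xi: MCMC must
  # agree with brute-force integration of the exact posterior
  set.seed(41)
  t_mean <- -120; a_mean <- -170
  p_true <- 0.7 # aquatic share
  y <- rnorm(25, (1 - p_true) * t_mean + p_true * a_mean, 12)
  d <- make_mix_frame(y = y)
  cfg <- mix_config(covariate = "none", include_random_effects = FALSE,
                    fix_xi = 1, iterations = 30000, burn_in = 10000,
                    thinning = 5, chains = 3, seed = 5)
  fit <- allomix(d, cfg)
  al <- 1 - ilr_inverse(allomix:::pooled_draws(fit, "beta0"))
  gr <- grid_oracle(y, t_mean, 11.2, a_mean, 23.6, 13, xi = 1)
  se <- mc_se(al)
  expect_lt(abs(mean(al) - gr$mean), 3 * se$mean + 1e-6)
  expect_lt(abs(quantile(al, 0.025) - gr$q025), 3 * se$q["0.025"] + 1e-6)
  expect_lt(abs(quantile(al, 0.975) - gr$q975), 3 * se$q["0.975"] + 1e-6)
})

test_that("a taxon pinned to the aquatic source gets near-zero allochthony", {
  # all consumers at the aquatic mean with tight spread: intercept
  # allochthony must collapse towards zero
  set.seed(55)
  y <- rnorm(40, -170, 3)
  d <- make_mix_frame(y = y, sd_extra = 5)
  cfg <- mix_config(covariate = "none", include_random_effects = FALSE,
                    fix_xi = 0.05, iterations = 20000, burn_in = 10000,
                    thinning = 5, chains = 2, seed = 6)
  fit <- allomix(d, cfg)
  al <- 1 - ilr_inverse(allomix:::pooled_draws(fit, "beta0"))
  expect_lt(median(al), 0.05)
})

test_that("summaries keep allochthony in [0,1] with ordered intervals", {
  st <- small_study(seed = 22)
  md <- mix_data(st$prep, st$pairs, st$cov, "pc1")
  fit <- allomix(md, quick_mix_config(seed = 7))
  s <- summarize_allochthony(fit, grid = seq(-3, 3, length.out = 7))
  for (tab in list(s$intercepts[c("allochthony", "lo", "hi")],
                   s$curves[c("median", "lo", "hi")],
                   s$global_curve[c("median", "lo", "hi")])) {
    v <- unlist(tab)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all(s$curves$lo <= s$curves$median &
                    s$curves$median <= s$curves$hi))
  expect_true(all(s$intercepts$lo <= s$intercepts$allochthony &
                    s$intercepts$allochthony <= s$intercepts$hi))
  expect_error(summarize_allochthony(fit, grid = numeric(0)), "empty")
  # degenerate posterior: identical draws give zero-width intervals
  fit0 <- fit
  th1 <- fit0$draws[[1]][1, ]
  fit0$draws <- lapply(fit0$draws, function(m) {
    m[] <- rep(th1, each = nrow(m)); m
  })
  s0 <- summarize_allochthony(fit0, grid = 0, marginal = "zero")
  expect_equal(s0$global_curve$lo, s0$global_curve$hi)
  # draws symmetric about phi = 0 give median allochthony 1/2
  fitsym <- fit
  fitsym$draws <- lapply(fitsym$draws, function(m) {
    m[, "beta0"] <- rep(c(-1, 1), length.out = nrow(m)); m
  })
  ssym <- summarize_allochthony(fitsym, grid = 0, marginal = "zero")
  ic <- allomix:::taxon_intercepts(fitsym)
  expect_true(all(abs(ic$allochthony - 0.5) < 0.25))
})

test_that("model frame assembly validates sources and covariates", {
  st <- small_study(seed = 23)
  bad_pairs <- st$pairs
  bad_pairs$aquatic_sd <- 0
  expect_error(mix_data(st$prep, bad_pairs, st$cov, "pc1"), "zero-SD")
  bad_cov <- st$cov
  bad_cov$pc1[2] <- NA
  expect_error(mix_data(st$prep, st$pairs, bad_cov, "pc1"), "non-finite covariate")
  expect_error(mix_data(st$prep, st$pairs[-1, ], st$cov, "pc1"), "missing")
  md <- mix_data(st$prep, st$pairs, covariate = "none")
  expect_true(all(md$x == 0))
})

test_that("S3 methods cover coef, predict, simulate and residuals", {
  st <- small_study(seed = 24)
  md <- mix_data(st$prep, st$pairs, st$cov, "pc1")
  fit <- allomix(md, quick_mix_config(seed = 9))
  cf <- coef(fit)
  expect_true(all(c("beta0", "beta1", "xi") %in% names(cf)))
  pr <- predict(fit, data.frame(covariate = c(-2, 0, 2)))
  expect_true(all(pr$median >= 0 & pr$median <= 1))
  expect_true(all(diff(pr$median) < 0)) # positive slope: declining allochthony
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(md), 3))
  r <- residuals(fit, type = "pearson")
  expect_equal(length(r), nrow(md))
  expect_lt(abs(mean(r)), 1)
  s <- summary(fit)
  expect_s3_class(s, "summary.allomix")
  expect_output(print(fit), "ILR mixing model")
})
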