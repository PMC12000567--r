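test_that("SUVA divides the 254 nm absorption coefficient by DOC", {
  sp <- data.frame(wavelength = c(250, 254, 260), absorbance = c(0.55, 0.5, 0.45))
  expect_equal(compute_suva(sp, doc = 10, path_length_m = 0.01), 5.0)
  sp0 <- data.frame(wavelength = c(250, 254, 260), absorbance = c(0, 0, 0))
  expect_equal(compute_suva(sp0, doc = 7), 0)
  # doubling DOC halves SUVA
  expect_equal(compute_suva(sp, doc = 20, path_length_m = 0.01), 2.5)
  # 254 nm interpolated when not sampled exactly
  sp2 <- data.frame(wavelength = c(252, 256), absorbance = c(0.6, 0.4))
  expect_equal(compute_suva(sp2, doc = 10, path_length_m = 0.01), 5.0)
  expect_error(compute_suva(sp, doc = 0), "positive")
  expect_error(compute_suva(data.frame(wavelength = 300:400,
                                       absorbance = rep(0.1, 101)), doc = 5),
               "254")
})

test_that("slope ratio matches constructed exponential spectra", {
  # single exponential: identical slopes in both windows -> SR = 1
  expect_equal(compute_sr(exp_spectrum(s = 0.018)), 1, tolerance = 1e-9)
  # piecewise exponential with S1 = 0.02, S2 = 0.01 -> SR = 2
  wl <- seq(250, 420, by = 1)
  a <- ifelse(wl <= 320, 40 * exp(-0.02 * wl), 40 * exp(-0.02 * 320) *
                exp(-0.01 * (wl - 320)))
  sp <- data.frame(wavelength = wl, absorbance = a * 0.01)
  expect_equal(compute_sr(sp), 2, tolerance = 1e-9)
  # flat spectrum: zero slopes surface as an error, not a silent Inf
  flat <- data.frame(wavelength = wl, absorbance = rep(0.2, length(wl)))
  expect_error(compute_sr(flat), "zero")
  # nonpositive absorbance in a window -> log-domain error
  bad <- exp_spectrum(); bad$absorbance[bad$wavelength == 280] <- 0
  expect_error(compute_sr(bad), "280|nonpositive")
  expect_error(compute_sr(exp_spectrum(wl = seq(274, 296, by = 1))),
               "350-400")
})

test_that("N:C mass ratio is a guarded division", {
  expect_equal(compute_nc_ratio(1, 10), 0.1)
  expect_equal(compute_nc_ratio(0, 5), 0)
  expect_equal(compute_nc_ratio(0.7, 4.5), 0.7 / 4.5)
  expect_equal(round(compute_nc_ratio(0.7, 4.5), 4), 0.1556)
  expect_error(compute_nc_ratio(1, 0), "positive")
  expect_error(compute_nc_ratio(-1, 2), "non-negative")
})

test_that("correlation PCA recovers degenerate and analytic structures", {
  # two perfectly correlated variables -> PC1 explains everything
  set.seed(2)
  v <- rnorm(10)
  env <- data.frame(lake_id = paste0("L", 1:10), a = v, b = 2 * v + 3)
  p <- run_pca(env, orient_by = "absent")
  expect_equal(p$var_explained[1], 1)
  # p mutually uncorrelated variables -> each PC explains about 1/p
  set.seed(7)
  n <- 4000
  env2 <- data.frame(lake_id = seq_len(n), w = rnorm(n), x = rnorm(n),
                     y = rnorm(n), z = rnorm(n))
  p2 <- run_pca(env2, orient_by = "absent")
  expect_equal(unname(p2$var_explained), rep(0.25, 4), tolerance = 0.06)
})

test_that("PCA scores and loadings satisfy the spectral identities", {
  st <- small_study(seed = 9)
  env <- st$sim$lakes[c("lake_id", names(st$sim$lakes)[grep("depth|pct|suva|sr_ratio|nc_pom|doc|chl|ph$|tot_p|area|ratio|shoreline",
                                                            names(st$sim$lakes))])]
  env <- env[!duplicated(names(env))]
  p <- run_pca(env)
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(apply(p$scores, 2, var)), unname(p$eigenvalues),
               tolerance = 1e-10)
  expect_true(all(abs(p$loadings) <= 1 + 1e-10))
  expect_true(all(p$var_explained >= 0 & p$var_explained <= 1))
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-10)
  # sign convention: forest loads negative on PC1; orientation idempotent
  expect_lt(p$loadings["forest_pct", 1], 0)
  p2 <- run_pca(env)
  expect_equal(p$scores, p2$scores)
})

test_that("PCA rejects constant or incomplete variables by name", {
  env <- data.frame(lake_id = c("A", "B", "C"), a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(run_pca(env), "'b' is constant")
  env2 <- data.frame(lake_id = c("A", "B", "C"), a = c(1, NA, 3), b = c(1, 2, 4))
  expect_error(run_pca(env2), "missing value in variable 'a' \\(lake B\\)")
  expect_error(run_pca(data.frame(lake_id = c("A", "B"), a = c(1, 2),
                                  b = c(2, 1))), "3 lakes")
})
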