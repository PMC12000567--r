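#' Split rank-normalized Gelman-Rubin R-hat
#'
#' Each chain is split in half, pooled draws are rank-normalized through the
#' inverse normal of fractional ranks, and the classic potential scale
#' reduction factor is computed on the normalized half-chains. Values near 1
#' indicate mixed, stationary chains.
#'
#' @param chain_list List of numeric vectors, one per chain (equal length).
#' @return Scalar R-hat (NA for a single split or constant draws).
#' @export
rhat_rank <- function(chain_list) {
  n <- length(chain_list[[1]])
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  splits <- unlist(lapply(chain_list, function(v) {
    list(v[seq_len(half)], v[(n - half + 1):n])
  }), recursive = FALSE)
  allv <- unlist(splits)
  # identical constant chains are perfectly mixed by definition
  if (stats::var(allv) == 0) return(1)
  N <- length(allv)
  z <- stats::qnorm((rank(allv, ties.method = "average") - 3 / 8) / (N + 1 / 4))
  zs <- split(z, rep(seq_along(splits), each = half))
  mns <- vapply(zs, mean, numeric(1))
  vrs <- vapply(zs, stats::var, numeric(1))
  m <- length(zs)
  w <- mean(vrs)
  b <- half * stats::var(mns)
  if (w == 0) return(Inf) # between-chain spread with frozen chains
  sqrt(((half - 1) / half * w + b / half) / w)
}

# spectral density at frequency zero via an AR fit (for Geweke SEs)
spectrum0 <- function(v) {
  v <- v - mean(v)
  if (stats::var(v) == 0) return(0)
  ar_fit <- try(stats::ar(v, aic = TRUE,
                          order.max = min(20, floor(length(v) / 3))),
                silent = TRUE)
  if (inherits(ar_fit, "try-error")) return(stats::var(v))
  if (ar_fit$order == 0) return(ar_fit$var.pred)
  ar_fit$var.pred / (1 - sum(ar_fit$ar))^2
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardized by spectral-density-based standard errors.
#'
#' @param v Numeric chain.
#' @param frac1,frac2 Window fractions (defaults 0.1 and 0.5).
#' @return z-score (NA for constant chains).
#' @export
geweke_z <- function(v, frac1 = 0.1, frac2 = 0.5) {
  n <- length(v)
  a <- v[seq_len(max(2, floor(frac1 * n)))]
  b <- v[(n - max(2, floor(frac2 * n)) + 1):n]
  s1 <- spectrum0(a) / length(a)
  s2 <- spectrum0(b) / length(b)
  if (s1 + s2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(s1 + s2)
}

#' Effective sample size (initial positive sequence estimator)
#'
#' @param v Numeric chain of draws.
#' @return Effective number of independent draws.
#' @export
ess <- function(v) {
  n <- length(v)
  if (n < 4 || stats::var(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[, 1, 1]
  # Geyer initial positive sequence: IACT = -1 + 2 * sum of positive
  # consecutive-pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  tau <- -1
  m <- 0
  repeat {
    i1 <- 2 * m + 1
    if (i1 > length(ac)) break
    g <- ac[i1] + if (i1 + 1 <= length(ac)) ac[i1 + 1] else 0
    if (g < 0) break
    tau <- tau + 2 * g
    m <- m + 1
  }
  max(1, n / max(tau, 1))
}

#' Convergence diagnostics for a mixing-model fit
#'
#' Per sampled parameter: split rank-normalized R-hat across chains and the
#' maximum absolute Geweke z-score over chains (first 10% vs last 50%).
#' The fit passes when every R-hat is at or below `config$rhat_max` and at
#' least `config$geweke_pass_frac` of parameters have
#' `|z| <= config$geweke_z_max`. With a single chain, R-hat is reported as
#' unavailable and only the Geweke screen applies.
#'
#' @param fit An `"allomix"` fit.
#' @return List of class `"allomix_diagnostics"`: `rhat`, `geweke`,
#'   `rhat_available`, `pass`, and the thresholds used.
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "allomix"))
  cfg <- fit$config
  pars <- fit$par_names[fit$active]
  rhat <- setNames(rep(NA_real_, length(pars)), pars)
  gew <- setNames(rep(NA_real_, length(pars)), pars)
  multi <- length(fit$draws) >= 2
  all_z <- NULL
  for (p in pars) {
    cl <- lapply(fit$draws, function(m) m[, p])
    if (multi) rhat[p] <- rhat_rank(cl)
    z <- abs(vapply(cl, geweke_z, numeric(1)))
    gew[p] <- max(z, na.rm = TRUE)
    all_z <- c(all_z, z)
  }
  rhat_ok <- if (multi) all(rhat <= cfg$rhat_max, na.rm = TRUE) else NA
  # fraction over all per-parameter, per-chain tests
  gew_ok <- mean(all_z <= cfg$geweke_z_max, na.rm = TRUE) >= cfg$geweke_pass_frac
  pass <- isTRUE(gew_ok) && (is.na(rhat_ok) || isTRUE(rhat_ok))
  structure(list(rhat = rhat, geweke = gew, rhat_available = multi,
                 rhat_max = cfg$rhat_max, geweke_z_max = cfg$geweke_z_max,
                 pass = pass),
            class = "allomix_diagnostics")
}

#' @export
print.allomix_diagnostics <- function(x, ...) {
  if (x$rhat_available) {
    cat(sprintf("max R-hat: %.3f (threshold %.2f)\n",
                max(x$rhat, na.rm = TRUE), x$rhat_max))
  } else {
    cat("R-hat unavailable (single chain)\n")
  }
  cat(sprintf("max |Geweke z|: %.2f (threshold %.1f)\n",
              max(x$geweke, na.rm = TRUE), x$geweke_z_max))
  cat("overall:", if (x$pass) "converged" else "NOT converged", "\n")
  invisible(x)
}
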