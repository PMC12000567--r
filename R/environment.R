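#' Specific ultraviolet absorbance at 254 nm (SUVA)
#'
#' SUVA is the decadic CDOM absorption coefficient at 254 nm divided by the
#' DOC concentration: `(A254 / pathlength_m) / doc`, in L mg-C^-1 m^-1. The
#' 254 nm absorbance is linearly interpolated when not sampled exactly.
#'
#' @param spectrum Data frame with strictly increasing `wavelength` (nm) and
#'   non-negative decadic `absorbance` columns covering 254 nm.
#' @param doc Dissolved organic carbon concentration (mg/L), > 0.
#' @param path_length_m Cuvette path length in metres (default 0.01, a
#'   standard 1 cm cell).
#' @return SUVA in L mg^-1 m^-1.
#' @export
compute_suva <- function(spectrum, doc, path_length_m = 0.01) {
  check_spectrum(spectrum)
  if (doc <= 0) stop("DOC must be positive")
  if (254 < min(spectrum$wavelength) || 254 > max(spectrum$wavelength)) {
    stop("spectrum does not cover 254 nm")
  }
  a254 <- stats::approx(spectrum$wavelength, spectrum$absorbance, xout = 254)$y
  (a254 / path_length_m) / doc
}

#' Spectral slope ratio (SR) of a CDOM absorbance spectrum
#'
#' Fits ordinary least squares of log absorption coefficient on wavelength
#' over 275-295 nm and 350-400 nm; each spectral slope S is the negated
#' fitted slope (positive for decaying spectra). Returns S275-295 / S350-400.
#' SR is inversely related to DOM molecular weight.
#'
#' @inheritParams compute_suva
#' @param path_length_m Path length in metres.
#' @return Dimensionless slope ratio.
#' @export
compute_sr <- function(spectrum, path_length_m = 0.01) {
  check_spectrum(spectrum)
  slope_in <- function(lo, hi) {
    w <- spectrum$wavelength >= lo & spectrum$wavelength <= hi
    if (sum(w) < 3) stop(sprintf("fewer than 3 spectral points in %d-%d nm window", lo, hi))
    a <- spectrum$absorbance[w] / path_length_m
    if (any(a <= 0)) stop(sprintf("nonpositive absorbance in %d-%d nm window; log slope undefined", lo, hi))
    -unname(stats::coef(stats::lm(log(a) ~ spectrum$wavelength[w]))[2])
  }
  s1 <- slope_in(275, 295)
  s2 <- slope_in(350, 400)
  if (abs(s2) < .Machine$double.eps^0.5) {
    stop("350-400 nm spectral slope is zero; slope ratio undefined")
  }
  s1 / s2
}

check_spectrum <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "absorbance") %in% names(spectrum)))
  if (any(diff(spectrum$wavelength) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(spectrum$absorbance < 0)) stop("absorbances must be non-negative")
  invisible(spectrum)
}

#' Nitrogen-to-carbon mass ratio
#'
#' @param n_mass Nitrogen mass fraction (>= 0).
#' @param c_mass Carbon mass fraction (> 0).
#' @return N:C by mass.
#' @export
compute_nc_ratio <- function(n_mass, c_mass) {
  if (any(c_mass <= 0)) stop("carbon mass fraction must be positive")
  if (any(n_mass < 0)) stop("nitrogen mass fraction must be non-negative")
  n_mass / c_mass
}

#' Correlation-matrix PCA of the lake environmental table
#'
#' Standardizes every variable (zero mean, unit variance) and
#' eigen-decomposes the correlation matrix, which puts differently scaled
#' morphometric, chemical, land-use and organic-matter-quality variables on
#' an equal footing. Loadings are reported as Pearson correlations between
#' each original variable and each score (eigenvector entries scaled by the
#' square root of the eigenvalue). The sign of PC1 is fixed so that forest
#' cover loads negatively: increasing PC1 runs from forested towards
#' agricultural/eutrophic catchments.
#'
#' @param env Data frame with a `lake_id` column plus numeric environmental
#'   variables; no missing values; every variable must vary.
#' @param orient_by Variable used to fix the PC1 sign (loading forced
#'   negative); default `"forest_pct"`, skipped if absent.
#' @return List of class `"allomix_pca"`: `scores` (lake x PC),
#'   `loadings` (variable-score correlations), `var_explained`
#'   (proportions), `eigenvalues`, `n_vars`, `lake_id`.
#' @export
run_pca <- function(env, orient_by = "forest_pct") {
  stopifnot(is.data.frame(env), "lake_id" %in% names(env))
  x <- env[setdiff(names(env), "lake_id")]
  num <- vapply(x, is.numeric, logical(1))
  x <- x[num]
  if (nrow(x) < 3) stop("PCA needs at least 3 lakes")
  for (v in names(x)) {
    if (anyNA(x[[v]])) {
      stop(sprintf("missing value in variable '%s' (lake %s)",
                   v, env$lake_id[which(is.na(x[[v]]))[1]]))
    }
    if (stats::var(x[[v]]) == 0) {
      stop(sprintf("variable '%s' is constant; correlation PCA undefined", v))
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  scores <- pc$x
  # loadings as variable-score correlations: eigenvector * sqrt(eigenvalue),
  # with the sample-variance normalisation of prcomp absorbed
  n <- nrow(x)
  load_cor <- stats::cor(scale(x), scores)
  if (orient_by %in% names(x)) {
    if (load_cor[orient_by, 1] > 0) {
      scores[, 1] <- -scores[, 1]
      load_cor[, 1] <- -load_cor[, 1]
    }
  }
  structure(list(scores = scores, loadings = load_cor,
                 var_explained = eig / sum(eig), eigenvalues = eig,
                 n_vars = ncol(x), lake_id = env$lake_id),
            class = "allomix_pca")
}

#' @export
print.allomix_pca <- function(x, ...) {
  cat(sprintf("Correlation PCA of %d environmental variables, %d lakes\n",
              x$n_vars, nrow(x$scores)))
  ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 1)
  cat("Variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' Extract PC1 scores as a covariate table
#'
#' @param pca An [run_pca()] result.
#' @return Data frame `lake_id`, `pc1`.
#' @export
pc1_scores <- function(pca) {
  stopifnot(inherits(pca, "allomix_pca"))
  data.frame(lake_id = pca$lake_id, pc1 = unname(pca$scores[, 1]),
             stringsAsFactors = FALSE)
}
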