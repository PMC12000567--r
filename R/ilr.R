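#' Isometric log-ratio transform for a two-source composition
#'
#' With only two sources the ILR space is one-dimensional. The composition is
#' ordered aquatic-first (alphabetical, as in common mixing-model software), so
#' the coordinate is \eqn{\phi = \sqrt{1/2}\,\log(p_{aq}/(1-p_{aq}))} and larger
#' \eqn{\phi} means a larger aquatic share, i.e. *lower* allochthony.
#'
#' @param p_aquatic Proportion of the aquatic source, strictly inside (0, 1).
#' @return ILR coordinate(s), same length as `p_aquatic`.
#' @seealso [ilr_inverse()]
#' @examples
#' ilr_transform(0.5)            # 0
#' ilr_inverse(ilr_transform(0.88))
#' @export
ilr_transform <- function(p_aquatic) {
  stopifnot(is.numeric(p_aquatic))
  if (any(!is.finite(p_aquatic)) || any(p_aquatic <= 0) || any(p_aquatic >= 1)) {
    stop("p_aquatic must lie strictly inside (0, 1); boundary compositions have infinite ILR coordinate")
  }
  sqrt(0.5) * log(p_aquatic / (1 - p_aquatic))
}

#' Inverse ILR transform (two sources)
#'
#' Maps an ILR coordinate back to the aquatic source proportion; allochthony is
#' `1 - ilr_inverse(phi)`. Saturates smoothly at 0/1 for large `|phi|`.
#'
#' @param phi ILR coordinate(s), finite reals.
#' @return Aquatic proportion(s) in (0, 1).
#' @export
ilr_inverse <- function(phi) {
  stopifnot(is.numeric(phi))
  # plogis is the logistic cdf; stable for large |phi|
  stats::plogis(sqrt(2) * phi)
}
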