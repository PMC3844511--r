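#' Genotype relative-risk model parameters
#'
#' Bundles the generative parameters of every conditional probability in the
#' package: the population frequency `p` of the risk allele A, and the
#' genotype relative risks `psi1 = f1/f0` and `psi2 = f2/f0`, where `f2`,
#' `f1`, `f0` are the penetrances of carrying two, one or zero copies of A.
#' The penetrances themselves are not identifiable from case-ascertained
#' family data and are never stored; only their ratios matter.
#'
#' `psi1 = psi2 = 1` is the null model of no association.  Zero relative
#' risks are admitted as boundary values (they arise naturally during
#' constrained optimization).
#'
#' @param p risk-allele frequency, strictly inside (0, 1).
#' @param psi1,psi2 nonnegative finite relative risks.
#' @return An object of class `risk_params`: a list with elements `p`,
#'   `psi1`, `psi2`.
#' @examples
#' risk_params(0.3, psi1 = 1.8, psi2 = 3.24)
#' @export
risk_params <- function(p, psi1 = 1, psi2 = 1) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`p` must be a single number strictly between 0 and 1", call. = FALSE)
  for (nm in c("psi1", "psi2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single finite nonnegative number", call. = FALSE)
  }
  structure(list(p = p, psi1 = psi1, psi2 = psi2), class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("Risk model: p = %g, psi1 = %g, psi2 = %g\n", x$p, x$psi1, x$psi2))
  invisible(x)
}

.as_risk_params <- function(params) {
  if (inherits(params, "risk_params")) return(params)
  if (is.numeric(params) && length(params) == 3L)
    return(risk_params(params[[1L]], params[[2L]], params[[3L]]))
  stop("`params` must be a `risk_params` object (see `risk_params()`)",
       call. = FALSE)
}

#' Disease-ascertainment normalizing constant R
#'
#' `R = p^2 psi2 + 2 p q psi1 + q^2` with `q = 1 - p`: the factor by which
#' the marginal disease probability exceeds the baseline penetrance `f0`.
#' Every conditional genotype probability in the model carries `1/R`.
#'
#' @param params a [risk_params()] object (or a numeric `c(p, psi1, psi2)`).
#' @return A single positive number.
#' @examples
#' risk_normalizer(risk_params(0.5, 1, 2))  # 1.25
#' @export
risk_normalizer <- function(params) {
  params <- .as_risk_params(params)
  q <- 1 - params$p
  params$p^2 * params$psi2 + 2 * params$p * q * params$psi1 + q^2
}
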