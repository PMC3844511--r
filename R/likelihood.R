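# Coefficients of log p, log q, log psi1, log psi2 in each cell's
# log-probability (cell ordering as in triad_cells()/dyad_cells()).
.TRIAD_COEF <- cbind(
  logp = c(4, 3, 3, 2, 2, 2, 2, 1, 1, 0),
  logq = c(0, 1, 1, 2, 2, 2, 2, 3, 3, 4),
  logpsi1 = c(0, 0, 1, 1, 0, 1, 0, 1, 0, 0),
  logpsi2 = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0)
)
.DYAD_COEF <- cbind(
  logp = c(3, 2, 2, 1, 1, 1, 0),
  logq = c(0, 1, 1, 1, 2, 2, 3),
  logpsi1 = c(0, 1, 0, 1, 0, 1, 0),
  logpsi2 = c(1, 0, 1, 0, 0, 0, 0)
)
.MONAD_COEF <- cbind(
  logp = c(2, 1, 0),
  logq = c(0, 1, 2),
  logpsi1 = c(0, 1, 0),
  logpsi2 = c(1, 0, 0)
)

.xlogy <- function(x, y) {
  # count * log(prob) with the multinomial convention 0 * log 0 = 0;
  # a positive count on a zero-probability cell gives -Inf, not an error
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(y[pos])
  out
}

#' Log-likelihood of counted family data
#'
#' Multinomial log-likelihoods of triad, dyad and monad cell counts under
#' the conditional probability model, and their sum
#' `logL(psi1, psi2, p)`.  Each is `sum(count * log(cell probability))`
#' with `0 * log 0 = 0`; the multinomial coefficient (constant in the
#' parameters) is omitted, so absolute values are comparable only within
#' this convention.  A positive count on a zero-probability cell (possible
#' only on the `psi = 0` boundary) yields `-Inf` rather than an error, so
#' optimizers can reject the point.
#'
#' @param counts a [triad_counts()], [dyad_counts()] or [monad_counts()]
#'   vector, as appropriate.
#' @inheritParams risk_normalizer
#' @return A single number (possibly `-Inf`).
#' @examples
#' loglik_monads(monad_counts(c(1, 2, 1)), risk_params(0.5))  # -6 log 2
#' @export
loglik_triads <- function(counts, params) {
  counts <- triad_counts(counts)
  sum(.xlogy(counts, triad_probabilities(params)))
}

#' @rdname loglik_triads
#' @export
loglik_dyads <- function(counts, params) {
  counts <- dyad_counts(counts)
  sum(.xlogy(counts, dyad_probabilities(params)))
}

#' @rdname loglik_triads
#' @export
loglik_monads <- function(counts, params) {
  counts <- monad_counts(counts)
  sum(.xlogy(counts, monad_probabilities(params)))
}

#' @rdname loglik_triads
#' @param data a [family_dataset()].
#' @export
loglik_combined <- function(data, params) {
  stopifnot(inherits(data, "family_dataset"))
  loglik_triads(data$triads, params) +
    loglik_dyads(data$dyads, params) +
    loglik_monads(data$monads, params)
}

#' Sufficient statistics of the combined log-likelihood
#'
#' Up to an additive constant, the combined log-likelihood is
#' `Kp log p + Kq log q + K1 log psi1 + K2 log psi2 - N log R`, where the
#' coefficients pool the per-cell allele and risk-class counts across
#' triads, dyads and monads and `N` is the total number of families.
#' `K2`, `K1` and `N - K1 - K2` are also the numbers of affected children
#' with genotypes AA, Aa and aa.
#'
#' @param data a [family_dataset()].
#' @return Named numeric vector `c(Kp, Kq, K1, K2, N)`.
#' @export
suff_stats <- function(data) {
  stopifnot(inherits(data, "family_dataset"))
  tri <- as.numeric(data$triads); dy <- as.numeric(data$dyads)
  mo <- as.numeric(data$monads)
  k <- drop(tri %*% .TRIAD_COEF + dy %*% .DYAD_COEF + mo %*% .MONAD_COEF)
  c(Kp = k[[1L]], Kq = k[[2L]], K1 = k[[3L]], K2 = k[[4L]],
    N = sum(tri) + sum(dy) + sum(mo))
}
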