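#' Transmission and score components from triad and dyad counts
#'
#' From the triad cells, `b` counts risk alleles transmitted by
#' heterozygous parents and `c` the untransmitted ones:
#' `b = n2 + 2 n5 + n6 + n8`, `c = n3 + n6 + 2 n7 + n9`.  The dyad
#' analogues are `b1 = m2 + m5` and `c1 = m3 + m6`.  The combined score
#' test uses `W = b + b1`, `A_com = (b + c)/2 + (b1 + c1)/2` and
#' `V_com = (b + c)/4 + (b1 + c1)/4`.
#'
#' @param triads a [triad_counts()] vector.
#' @param dyads a [dyad_counts()] vector (defaults to all-zero).
#' @return A named list with elements `b`, `c`, `b1`, `c1`, `W`, `A_com`,
#'   `V_com`.
#' @export
transmission_counts <- function(triads, dyads = dyad_counts()) {
  n <- as.numeric(triad_counts(triads))
  m <- as.numeric(dyad_counts(dyads))
  b <- n[2L] + 2 * n[5L] + n[6L] + n[8L]
  cc <- n[3L] + n[6L] + 2 * n[7L] + n[9L]
  b1 <- m[2L] + m[5L]
  c1 <- m[3L] + m[6L]
  list(b = b, c = cc, b1 = b1, c1 = c1,
       W = b + b1,
       A_com = (b + cc) / 2 + (b1 + c1) / 2,
       V_com = (b + cc) / 4 + (b1 + c1) / 4)
}

.new_test <- function(method, statistic, df, p_value, null_fit = NULL,
                      alt_fit = NULL, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p_value, null_fit = null_fit,
                   alt_fit = alt_fit), extra),
            class = "triad_test")
}

#' @export
print.triad_test <- function(x, ...) {
  ref <- if (identical(x$df, "normal")) "standard normal" else
    sprintf("chi-square, %d df", x$df)
  cat(sprintf("%s test: statistic = %.4f (%s), p-value = %.4g\n",
              x$method, x$statistic, ref, x$p_value))
  if (!is.null(x$alt_fit))
    cat(sprintf("  alternative MLE: p = %.4f, psi1 = %.4f, psi2 = %.4f\n",
                x$alt_fit$p, x$alt_fit$psi1, x$alt_fit$psi2))
  if (!is.null(x$null_fit))
    cat(sprintf("  null MLE: p = %.4f\n", x$null_fit$p))
  invisible(x)
}

#' Likelihood ratio test of association under a constrained risk model
#'
#' Computes `2 logL(alternative MLE) - 2 logL(null MLE)` and refers it to a
#' chi-square distribution with 2 df (`Unr`) or 1 df (`Dom`, `Rec`, `Mult`,
#' `Add`).  A negative statistic within `1e-8` of zero (numerical noise
#' when the data sit exactly at the null) is clamped to 0; anything more
#' negative indicates optimizer failure and raises an error rather than
#' being clamped silently.
#'
#' @param data a [family_dataset()].
#' @param model a model name or [model_spec()].
#' @return A `triad_test` object carrying the statistic, df, p-value and
#'   both fits.
#' @examples
#' d <- family_dataset(triads = c(1, 2, 2, 2, 1, 2, 1, 2, 2, 1))
#' lrt(d, "Dom")  # statistic 0, p-value 1 at exact null proportions
#' @export
lrt <- function(data, model) {
  model <- .match_model(model)
  null_fit <- mle_null(data)
  alt_fit <- mle_alternative(data, model)
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < 0) {
    if (stat < -1e-8)
      stop("negative likelihood-ratio statistic (", format(stat),
           "): constrained optimizer failed", call. = FALSE)
    stat <- 0
  }
  df <- model_spec(model)$df
  .new_test(model, stat, df, pchisq(stat, df, lower.tail = FALSE),
            null_fit = null_fit, alt_fit = alt_fit)
}

#' Transmission disequilibrium test from triads
#'
#' `TDT = (b - c)^2 / (b + c)` on risk alleles transmitted (`b`) and not
#' transmitted (`c`) by heterozygous parents, referred to chi-square with
#' 1 df.  Requires at least one informative transmission (`b + c > 0`).
#'
#' @param triads a [triad_counts()] vector.
#' @return A `triad_test` object (with `b` and `c` attached).
#' @export
tdt <- function(triads) {
  tc <- transmission_counts(triads)
  if (tc$b + tc$c == 0)
    stop("TDT undefined: no informative transmissions (b + c = 0)",
         call. = FALSE)
  stat <- (tc$b - tc$c)^2 / (tc$b + tc$c)
  .new_test("TDT", stat, 1L, pchisq(stat, 1L, lower.tail = FALSE),
            extra = list(b = tc$b, c = tc$c))
}

#' Combined score test from triads and dyads
#'
#' `z_com = (W - A_com) / sqrt(V_com)` combines the transmission counts of
#' triads and parent-child dyads (see [transmission_counts()]) and is
#' referred to a standard normal.  The rejection rule is two-sided: with no
#' dyads, `z_com^2` equals the TDT statistic exactly, so the two-sided rule
#' reproduces the TDT chi-square decision.  Requires `V_com > 0`.
#'
#' @param triads a [triad_counts()] vector.
#' @param dyads a [dyad_counts()] vector (defaults to all-zero).
#' @return A `triad_test` object with a standard-normal reference
#'   (`df = "normal"`) and a two-sided p-value.
#' @export
zcom <- function(triads, dyads = dyad_counts()) {
  tc <- transmission_counts(triads, dyads)
  if (tc$V_com == 0)
    stop("z_com undefined: no informative transmissions (V_com = 0)",
         call. = FALSE)
  z <- (tc$W - tc$A_com) / sqrt(tc$V_com)
  .new_test("zcom", z, "normal", 2 * pnorm(-abs(z)),
            extra = tc[c("b", "c", "b1", "c1")])
}
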