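#' Cell layouts for triad, dyad and monad counts
#'
#' The package freezes a fixed ordering of the multinomial cells; the
#' ordering is part of the public contract and matches the row order of the
#' conditional-probability tables for triads (cells `n1..n10`, indexed by
#' unordered parental mating type and affected-child genotype) and dyads
#' (cells `m1..m7`, indexed by observed-parent genotype and child genotype,
#' regardless of which parent is observed).  Monads are ordered
#' `(s2 = AA, s1 = Aa, s0 = aa)`.
#'
#' @return A data frame with one row per cell: the cell label, the parental
#'   configuration and the affected-child genotype.
#' @examples
#' triad_cells()
#' dyad_cells()
#' @export
triad_cells <- function() {
  data.frame(
    cell = paste0("n", 1:10),
    mating_type = c("AAxAA", "AAxAa", "AAxAa", "AAxaa", "AaxAa", "AaxAa",
                    "AaxAa", "Aaxaa", "Aaxaa", "aaxaa"),
    child = c("AA", "AA", "Aa", "Aa", "AA", "Aa", "aa", "Aa", "aa", "aa"),
    stringsAsFactors = FALSE
  )
}

#' @rdname triad_cells
#' @export
dyad_cells <- function() {
  data.frame(
    cell = paste0("m", 1:7),
    parent = c("AA", "AA", "Aa", "Aa", "Aa", "aa", "aa"),
    child = c("AA", "Aa", "AA", "Aa", "aa", "Aa", "aa"),
    stringsAsFactors = FALSE
  )
}

.TRIAD_LABELS <- paste0("n", 1:10)
.DYAD_LABELS <- paste0("m", 1:7)
.MONAD_LABELS <- c("AA", "Aa", "aa")

#' Conditional triad genotype probabilities
#'
#' Probability of each (parental mating type, affected-child genotype) cell,
#' conditional on the child being affected, under Hardy-Weinberg equilibrium
#' and random mating.  Ascertainment through the affected child multiplies
#' each Mendelian mating-type x transmission probability by the child's
#' relative risk and divides by the normalizer `R` (see [risk_normalizer()]).
#'
#' @inheritParams risk_normalizer
#' @return Named numeric vector of 10 probabilities (cells `n1..n10`,
#'   ordering per [triad_cells()]); sums to 1.
#' @examples
#' triad_probabilities(risk_params(0.5))        # HWE x Mendel at the null
#' triad_probabilities(risk_params(0.5, 1, 2))[1]  # p^4 psi2 / R = 0.1
#' @export
triad_probabilities <- function(params) {
  params <- .as_risk_params(params)
  p <- params$p; q <- 1 - p
  s1 <- params$psi1; s2 <- params$psi2
  R <- risk_normalizer(params)
  setNames(c(
    p^4 * s2,           # n1  AAxAA, AA
    2 * p^3 * q * s2,   # n2  AAxAa, AA
    2 * p^3 * q * s1,   # n3  AAxAa, Aa
    2 * p^2 * q^2 * s1, # n4  AAxaa, Aa
    p^2 * q^2 * s2,     # n5  AaxAa, AA
    2 * p^2 * q^2 * s1, # n6  AaxAa, Aa
    p^2 * q^2,          # n7  AaxAa, aa
    2 * p * q^3 * s1,   # n8  Aaxaa, Aa
    2 * p * q^3,        # n9  Aaxaa, aa
    q^4                 # n10 aaxaa, aa
  ) / R, .TRIAD_LABELS)
}

#' Conditional parent-child dyad genotype probabilities
#'
#' Probability of each (observed parent genotype, affected-child genotype)
#' cell for families with exactly one genotyped parent, conditional on the
#' child being affected.  The model is parent-sex-agnostic: the observed
#' parent may be either the mother or the father.  The `"simplified"`
#' version gives the closed forms (e.g. `p^2 q psi2 / R` for parent Aa,
#' child AA); the `"complex"` version sums the ordered triad probabilities
#' over the unobserved parent and is algebraically identical - it is kept as
#' a cross-check.
#'
#' @inheritParams risk_normalizer
#' @param version `"simplified"` (default) or `"complex"`.
#' @return Named numeric vector of 7 probabilities (cells `m1..m7`, ordering
#'   per [dyad_cells()]); sums to 1.
#' @examples
#' dyad_probabilities(risk_params(0.5))
#' dyad_probabilities(risk_params(0.5, 1, 2))["m3"]  # p^2 q psi2 / R = 0.2
#' @export
dyad_probabilities <- function(params, version = c("simplified", "complex")) {
  params <- .as_risk_params(params)
  version <- match.arg(version)
  p <- params$p; q <- 1 - p
  s1 <- params$psi1; s2 <- params$psi2
  R <- risk_normalizer(params)
  pr <- if (version == "simplified") {
    c(
      p^3 * s2,      # m1  AA, AA
      p^2 * q * s1,  # m2  AA, Aa
      p^2 * q * s2,  # m3  Aa, AA
      p * q * s1,    # m4  Aa, Aa
      p * q^2,       # m5  Aa, aa
      p * q^2 * s1,  # m6  aa, Aa
      q^3            # m7  aa, aa
    )
  } else {
    # per-cell sums over the missing parent of the ordered triad terms
    c(
      p^4 * s2 + p^3 * q * s2,
      p^3 * q * s1 + p^2 * q^2 * s1,
      p^3 * q * s2 + p^2 * q^2 * s2,
      p^3 * q * s1 + 2 * p^2 * q^2 * s1 + p * q^3 * s1,
      p^2 * q^2 + p * q^3,
      p^2 * q^2 * s1 + p * q^3 * s1,
      p * q^3 + q^4
    )
  }
  setNames(pr / R, .DYAD_LABELS)
}

#' Conditional monad (affected singleton) genotype probabilities
#'
#' Genotype distribution of an affected child with no genotyped parents:
#' `P(AA|D) = p^2 psi2 / R`, `P(Aa|D) = 2 p q psi1 / R`,
#' `P(aa|D) = q^2 / R`.
#'
#' @inheritParams risk_normalizer
#' @return Named numeric vector of 3 probabilities in order `(AA, Aa, aa)`;
#'   sums to 1.
#' @examples
#' monad_probabilities(risk_params(0.5, 1, 2))  # (0.4, 0.4, 0.2)
#' @export
monad_probabilities <- function(params) {
  params <- .as_risk_params(params)
  p <- params$p; q <- 1 - p
  R <- risk_normalizer(params)
  setNames(c(p^2 * params$psi2, 2 * p * q * params$psi1, q^2) / R,
           .MONAD_LABELS)
}

#' Unordered "either parent is Aa" probability (Schaid-Sommer form)
#'
#' Probability that the affected child is AA and *at least one* parent
#' (unordered, possibly the ungenotyped one) is Aa:
#' `p^2 q psi2 / R + p^3 q psi2 / R`.  This differs from the ordered dyad
#' cell `m3` (observed parent Aa, other parent missing) by the additive term
#' `p^3 q psi2 / R`.  It is retained only as a documented cross-check:
#' applying the unordered form to ordered dyad data would overstate the cell
#' probability.
#'
#' @inheritParams risk_normalizer
#' @return A single probability.
#' @examples
#' schaid_sommer_unordered(risk_params(0.5))  # 0.1875
#' @export
schaid_sommer_unordered <- function(params) {
  params <- .as_risk_params(params)
  p <- params$p; q <- 1 - p
  (p^2 * q * params$psi2 + p^3 * q * params$psi2) / risk_normalizer(params)
}
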