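---
title: "Likelihood-based association testing with triads, dyads and monads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based association testing with triads, dyads and monads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadlrt)
```

## The design and the model

Family studies of birth defects and other early-onset diseases typically
ascertain nuclear families through an affected child.  Some families arrive
complete (both parents genotyped: *triads*), some with a single genotyped
parent (*parent--child dyads*), and some as the affected child alone
(*monads*).  Discarding the incomplete families wastes genotypes and power;
imputing the missing parent adds machinery and assumptions.  `triadlrt`
instead evaluates the exact conditional probability of what was actually
observed, for each family type, and sums the log-likelihoods.

At a di-allelic locus with risk allele A at population frequency $p$
($q = 1-p$), write the penetrances $f_2, f_1, f_0$ for children carrying
2, 1, 0 copies of A.  Case-only ascertainment makes the baseline $f_0$
unidentifiable, so the model is parameterized by the genotype relative
risks
$$\psi_2 = f_2/f_0, \qquad \psi_1 = f_1/f_0,$$
with $H_0\colon \psi_1 = \psi_2 = 1$ meaning no association.  Under
Hardy--Weinberg equilibrium and random mating in the parental generation,
conditioning on the child being affected multiplies each Mendelian
mating-type $\times$ transmission probability by the child's relative risk
and divides by the normalizer
$$R = p^2\psi_2 + 2pq\psi_1 + q^2,$$
the factor by which the population disease probability exceeds $f_0$.
This yields 10 triad cells (unordered parental mating type $\times$ child
genotype, `triad_probabilities()`), 7 dyad cells (observed parent $\times$
child, `dyad_probabilities()`) and 3 monad cells
(`monad_probabilities()`).  Each simplified dyad cell equals the sum of
the ordered triad cells over the unobserved parent --- an identity the
test suite checks against the "complex" column --- and the dyad model is
deliberately parent-sex-agnostic.

A subtlety worth naming: the classical unordered probability that "a case
is AA and one parent is Aa, the other missing" exceeds the ordered cell
used here by an additive term $p^3 q \psi_2 / R$.  Real data files record
*which* parent was genotyped, so the ordered form is the correct one;
`schaid_sommer_unordered()` keeps the unordered form purely as a
documented cross-check.

The combined log-likelihood is multinomial in the observed cell counts
$(n_1..n_{10}, m_1..m_7, s_2, s_1, s_0)$ and, up to a constant, has
sufficient statistics $(K_p, K_q, K_1, K_2, N)$ --- the pooled
coefficients of $\log p$, $\log q$, $\log\psi_1$, $\log\psi_2$ and the
family total (`suff_stats()`).  $K_2$, $K_1$ and $N - K_1 - K_2$ are also
the counts of affected children with genotype AA, Aa, aa, a fact used
both for moment starting values and for intuition about when risk
parameters are weakly identified.

## Tests

Five constrained alternatives are fit by maximum likelihood and compared
to the null by likelihood ratio:

| model | constraint | df |
|-------|------------|----|
| Unr   | $\psi_1, \psi_2 \ge 0$ free | 2 |
| Dom   | $\psi_2 = \psi_1$ | 1 |
| Rec   | $\psi_1 = 1$ | 1 |
| Mult  | $\psi_2 = \psi_1^2$ | 1 |
| Add   | $\psi_2 = 2\psi_1 - 1$ | 1 |

Under $H_0$ the null has a closed-form allele-frequency MLE
$\hat p = K_p/(K_p + K_q)$ (with $\psi = 1$, $R = 1$ and the
log-likelihood is linear in $\log p$, $\log q$).  The nonparametric
companions are the transmission disequilibrium test
$\mathrm{TDT} = (b-c)^2/(b+c)$ on alleles transmitted/untransmitted by
heterozygous parents, and the combined score test
$z_{com} = (W - A_{com})/\sqrt{V_{com}}$ which adds the dyad transmission
counts.  `zcom()` uses a two-sided rule: with no dyads
$z_{com}^2$ equals the TDT statistic exactly, so only the two-sided
decision reproduces the TDT's chi-square decision --- that identity fixed
the choice, and the simulated power of the two-sided rule matches the
published reference values.

Note that $\hat p$ under the null is *not* a consistent estimate of the
population allele frequency when association is present: affected
children are enriched for the risk allele.  The unrestricted
$\tilde p$ is the estimate to interpret.

## Numerical strategy

Because the likelihood depends on the data only through
$(K_p, K_q, K_1, K_2, N)$, each fit optimizes a five-number summary, not
the raw counts.  Optimization runs on the transformed scale
$(\mathrm{logit}\,p,\ \log\psi_\cdot)$ --- for Add,
$\psi_1 = 1/2 + e^\theta$, which enforces the induced admissibility bound
$\psi_1 \ge 1/2$ --- with analytic gradients under `stats::nlminb`, from
three deterministic starts (null; moment estimates from the
affected-child genotype ratios; an overdispersed start), a box
$|\log\psi| \le 25$, and a coarse grid restart if the attained likelihood
ever falls below the null's.  Constraints hold exactly by construction
($\psi_2$ is recomputed from $\psi_1$).  Conventions: $0\log 0 = 0$; a
positive count on a zero-probability cell gives $-\infty$, never an
exception; LRT statistics within $10^{-8}$ below zero are clamped to
zero, anything more negative raises an error; estimates drifting to a
boundary are snapped to the box and flagged (`boundary = TRUE`), the
likelihood error of the snap being $O(e^{-25})$.

Monomorphic data ($K_p = 0$ or $K_q = 0$) are rejected as degenerate:
$\hat p$ would sit on 0 or 1 and no test is defined.

## The simulation engine

`run_study()` draws every replicate's triad, dyad and monad counts from
the three multinomials at the generating $(p, \psi_1, \psi_2)$ --- exactly
the data-generating process the probability model describes --- evaluates
the requested statistics, and reports rejection proportions against the
$\chi^2_2$ (Unr), $\chi^2_1$ (other LRTs, TDT) or two-sided normal
($z_{com}$) critical values, with Monte-Carlo standard errors.  One
seeded Mersenne-Twister stream drawn in deterministic order makes
(config, seed) fully reproducible; replicates with identical sufficient
statistics share one fit, which is why $10^5$-replicate studies run in
minutes on one core.

**Failure policy.**  A replicate on which a statistic is undefined
(degenerate data; $b + c = 0$; $V_{com} = 0$) or on which a free risk
parameter diverges to its admissibility boundary is recorded as failed
and excluded from both the numerator and the denominator of the
rejection proportion --- never silently kept or dropped --- and the
failure count is reported per statistic, with a warning above a 1%
failure rate.  The boundary rule deserves emphasis: at small $p$ many
null replicates contain no AA child at all, so the $\psi_2$ update of a
Newton-type iteration diverges ($\hat\psi_2 \to 0$) and cannot be said
to converge.  Treating those replicates as non-converged reproduces the
reference behavior of these tests at $p = 0.05$--$0.1$ (including the
flagged type-I inflation of Unr and Rec at $p = 0.05$, $n = 100$), which
an engine that kept boundary replicates would *not* show --- it would be
conservative there instead.  The per-dataset interface takes the
opposite, analysis-appropriate stance: `mle_alternative()` returns the
boundary fit with `boundary = TRUE` rather than discarding your data.

One known residual discrepancy is documented rather than hidden: around
$p \approx 0.2$ (where boundary events are negligible) the exact-MLE Unr
and Rec null rejection rates here sit close to the nominal level,
somewhat above the conservative reference values for the same design;
the constrained optima here are verified against brute-force grid
oracles, so we attribute the difference to additional conservatism of
the original optimizer rather than to the statistic itself.

**What the generator does and does not emulate.**  It reproduces the
study conditions behind the reference type-I-error and power tables:
counts at a single di-allelic marker under HWE, random mating, a
homogeneous population, and ascertainment through the affected child,
with independent triad/dyad/monad samples of fixed size.  It does not
emulate population stratification or admixture, genotyping error,
Mendelian inconsistencies, linkage disequilibrium between markers,
parental-sex effects or imprinting, or variable family sizes --- so
passing simulation checks says nothing about robustness to those; the
triad design's celebrated robustness to stratification, in particular, is
an assumption here, not a demonstrated property.

Default problem sizes in the shipped tests use 10,000 replicates per
study (Monte-Carlo SE $\approx 0.002$ at a true level of 0.05);
`scripts/acceptance.R` re-runs the headline quantities at the reference
scale of 100,000.

## Data interface choices

Family files are tab-delimited with columns `family_id`, `father`,
`mother`, `child`, genotypes as `AA`/`Aa`/`aa` or A-dosage `2`/`1`/`0`,
missing parents as `NA`/empty/`.`.  Homozygote tokens are matched
case-sensitively (`AA` vs `aa` *is* a case distinction; only the
heterozygote tolerates `aA`).  The risk allele is whichever is written
`A`/dosage-counted; because the model is not symmetric under allele
relabelling, there is no automatic minor-allele flip --- use
`risk_allele = "a"` to swap explicitly.  Mendelian-inconsistent families
are excluded with a warning and itemized in the tabulation report;
parsing problems (including a missing child genotype) abort with line
numbers, since silently dropping unparseable rows is how datasets rot.
Parent sex is read but never used in the likelihood.  Multiple-testing:
the five LRTs probe one association under different risk models, so they
are reported unadjusted by default, with an optional Bonferroni column.

## Limitations

Single marker per analysis (the CLI iterates files marker by marker);
trio/dyad/monad structures only, no sibships or general pedigrees; no
covariates, gene--environment terms, or stratification corrections; no
standard errors or confidence intervals for $\psi$ (the tests are the
inferential output); asymptotic reference distributions, which the
simulation engine exists to check at your design's actual sample sizes.
The estimation cost (a numerical fit per marker) makes the LRTs a
candidate-gene and follow-up tool, not a GWAS engine --- the TDT and
$z_{com}$ are the cheap first pass.
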