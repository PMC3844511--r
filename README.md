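# triadlrt

Family-based association testing between a di-allelic marker (e.g. a
candidate SNP) and a disease, for samples ascertained through an affected
child.  Real family collections are rarely all complete case-parent trios:
some families have one genotyped parent (parent–child *dyads*), some none
(affected *monads*).  `triadlrt` puts all three family types into a single
conditional multinomial likelihood — no imputation of the missing parent —
and tests association with likelihood ratio tests under five genetic risk
models, alongside the transmission disequilibrium test (TDT) and a combined
triad+dyad score test.

## The model in brief

With risk-allele frequency *p* (*q* = 1 − *p*) and genotype relative risks
ψ₂ = f₂/f₀, ψ₁ = f₁/f₀ (penetrance ratios for 2 and 1 copies of the risk
allele A), ascertainment through the affected child gives closed-form cell
probabilities for every observed family configuration, each normalized by

&nbsp;&nbsp;&nbsp;&nbsp;R = p²ψ₂ + 2pqψ₁ + q².

The combined log-likelihood over triad cells n₁..n₁₀, dyad cells m₁..m₇ and
monad genotype counts (s₂, s₁, s₀) is maximized under the null
H₀: ψ₁ = ψ₂ = 1 (closed form) and under five alternatives — **Unr**
(ψ₁, ψ₂ free; 2 df), **Dom** (ψ₂ = ψ₁), **Rec** (ψ₁ = 1), **Mult**
(ψ₂ = ψ₁²), **Add** (ψ₂ = 2ψ₁ − 1; each 1 df) — giving chi-square LRTs.
The TDT is (b − c)²/(b + c) on transmissions from heterozygous parents, and
z_com = (W − A_com)/√V_com adds the dyads' transmission information.  A
multinomial simulation engine estimates empirical type I error and power
for any design (n triads, m dyads, s monads).

## Worked example

Simulate a study of 300 triads, 80 dyads and 40 monads at a locus with a
true multiplicative effect (p = 0.3, ψ₁ = 1.8, ψ₂ = 3.24), then test:

```r
library(triadlrt)
cfg <- sim_config(p = 0.3, psi1 = 1.8, psi2 = 3.24,
                  n = 300, m = 80, s = 40, seed = 42)
d <- simulate_dataset(cfg)
analyze_families(d)
```

```
Association tests (300 triads, 80 dyads, 40 monads)
 model data_used p_hat p_tilde  psi1  psi2 statistic df   p_value
   Unr  FT+PD+AM   0.4  0.3099 2.008 3.898    39.883  2 2.185e-09
   Dom  FT+PD+AM   0.4  0.3517 1.878 1.878    21.290  1 3.949e-06
   Rec  FT+PD+AM   0.4  0.3645 1.000 1.830    15.294  1 9.201e-05
  Mult  FT+PD+AM   0.4  0.3099 1.976 3.906    39.854  1 2.737e-10
   Add  FT+PD+AM   0.4  0.3213 2.094 3.189    37.087  1 1.130e-09
   TDT        FT    NA      NA    NA    NA    21.974  1 2.764e-06
  zcom     FT+PD    NA      NA    NA    NA     3.275 NA 1.058e-03
```

Reading it: every test detects the association; the correctly specified
Mult model is the most decisive 1-df test (statistic 39.9), and its
estimates (p̃ = 0.31, ψ̃₁ = 1.98, ψ̃₂ = ψ̃₁²) recover the generating values
within sampling error.  `p_hat` is the *null-model* allele-frequency MLE —
biased upward here (0.40 vs true 0.30) because affected children are
enriched for the risk allele; interpret `p_tilde` instead.  The TDT and
z_com need no model fit but pay for it in power at such sample sizes.

Data can also come from a tab-delimited family file
(`analyze_families("families.tsv")`; columns `family_id father mother
child`, genotypes `AA/Aa/aa` or dosage `2/1/0`, missing parents `NA`), with
Mendelian-inconsistent families excluded and reported.  A command-line
wrapper is installed as `exec/triadlrt` (subcommands `test`, `simulate`,
`type1`, `power`; run it with no arguments for usage).

Simulation studies are one call:

```r
run_study(sim_config(p = 0.5, n = 100, m = 25, s = 50,
                     replicates = 10000, seed = 1),
          statistics = c("Unr", "Dom", "TDT"))
```

returning a tidy data frame of rejection proportions with Monte-Carlo
standard errors and per-statistic failure counts (replicates whose risk
parameter estimate diverges to a boundary are reported as non-converged and
excluded from the proportion, not silently kept or dropped).

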