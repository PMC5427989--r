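---
title: "Methods: twin-design EWAS and liability decomposition for chronic widespread pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-design EWAS and liability decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinewas)
```

## Overview

`twinewas` implements a twin-design epigenome-wide association analysis for
chronic widespread pain (CWP) on bin-level MeDIP-seq-style methylation data:
500 bp genomic bins on a 250 bp step, quantified as non-negative FPKM-like
values per sample. The pipeline proceeds through

1. **Quality control** — bins with zero methylation in at least 20% of
   individuals are excluded.
2. **Longitudinal stability** — among individuals measured twice at least
   three years apart, bins with a significant positive within-individual
   Pearson correlation (*p* < 0.05) are kept as longitudinally stable bins
   (lsBINs). A chronic condition should associate with persistent, not
   transient, methylation differences.
3. **Twin correlation profiling** — per-bin Pearson correlations across MZ
   and DZ pairs, and their dependence on the test-retest correlation; under
   an ACE model E[r~MZ~] = a² + c² and E[r~DZ~] = a²/2 + c².
4. **Two-stage association** — discovery by paired *t* test within
   CWP-discordant MZ pairs (genetic and shared-environment confounding
   cancels within pair), replication by Welch *t* test of age-adjusted
   methylation in the remaining sample, and Fisher combination
   χ² = −2(ln p₁ + ln p₂) on 4 df, restricted to bins nominally significant
   in both stages *with the same direction of effect*.
5. **Multiple-testing correction** — the effective number of independent
   tests from the eigenvalues of the bin correlation matrix, and
   Benjamini–Yekutieli FDR, which is valid under dependency.
6. **Covariate models** — per-bin and joint logistic regressions of CWP on
   standardized methylation with age, BMI and cotwin affection status;
   one-way-ANOVA η² for variance explained.
7. **Liability decomposition** — a maximum-likelihood liability-threshold
   model partitioning liability variance into additive-genetic (AGF),
   per-bin epigenetic (EGF) and residual (RES) fractions, with a
   boundary-corrected likelihood-ratio test for the genetic component.

## The liability-threshold model

A binary trait is modelled through a latent liability

$$L_i = \beta^\top x_i + \gamma^\top z_i + A_i + E_i, \qquad
  \text{case} \iff L_i > \tau,$$

where \(x_i\) are standardized covariates (age, BMI), \(z_i\) standardized
bin methylation, \(A\) an additive-genetic component with
\(\mathrm{Var}(A) = a^2\) and within-pair correlation 1 (MZ) or 0.5 (DZ),
and \(E\) unique environment with
\(\mathrm{Var}(E) = 1 - a^2 - \sum_j \gamma_j^2\), so that the
methylation-plus-residual liability variance is 1 and each bin contributes
\(\gamma_j^2\) of it. This is an AE decomposition: no shared-environment
component is fitted, because the reported components are additive-genetic,
epigenetic and residual; a C component would be absorbed into the genetic
fraction if present in the data, which is a stated limitation rather than a
hidden one.

Each complete twin pair contributes the bivariate-normal orthant probability
matching its affected/unaffected combination, with liability correlation
\(\rho = R\,a^2 / (1 - \sum_j\gamma_j^2)\), \(R \in \{1, 0.5\}\); singletons
contribute univariate tail probabilities (their recorded cotwin status is
kept as a covariate option for the regression models, not forced into the
likelihood). The orthant probabilities use the tetrachoric reduction

$$P(X > h, Y > k;\rho) = \Phi(-h)\Phi(-k) + \frac{1}{2\pi}
  \int_0^{\arcsin\rho} \exp\!\Big(-\frac{h^2 + k^2 - 2hk\sin t}
  {2\cos^2 t}\Big)\,dt,$$

evaluated by a 96-node Gauss–Legendre rule shared across all pairs. The
sine substitution keeps the integrand smooth; the tests verify absolute
agreement with an adaptive one-dimensional conditional-CDF integral to
better than 1e-10 across |ρ| up to 0.98, and that the four orthant
probabilities of any pair sum to one.

Optimization is bounded quasi-Newton (L-BFGS-B) over
\((\tau, \beta, \gamma, a^2)\) from multiple `a2` starting values
(0.1, 0.4, 0.7 by default); the best log-likelihood wins and exact ties go
to the smaller `a2`. Standard errors come from the observed information
(numerical Hessian) at the optimum. An estimate pinned at 0 or at the upper
bound is flagged `boundary`. The likelihood-ratio test for \(a^2 > 0\) uses
the boundary mixture \(\tfrac12\chi^2_0 + \tfrac12\chi^2_1\).

Two estimator properties matter when interpreting simulations. First, the
ML estimate of `a2` at the design size of 565 MZ + 244 DZ pairs carries a
small positive finite-sample bias (about +0.03 at a true value of 0.636);
it disappears at several thousand pairs, as the package's recovery tests
show. Second, squared-effect estimates \(\hat\gamma_j^2\) are inflated by
their own sampling noise, \(E[\hat\gamma^2] = \gamma^2 +
\mathrm{Var}(\hat\gamma)\); the recovery experiments therefore report the
unbiased version \(\hat\gamma_j^2 - \widehat{SE}(\hat\gamma_j)^2\) when
aggregating across replicates. The per-fit `variance_report()` reports the
fit's own decomposition \(\hat\gamma_j^2\) without correction.

## Effective number of tests

Overlapping 500 bp bins on a 250 bp step are strongly correlated, so the
raw bin count overstates the number of independent tests. Each eigenvalue
λ of the bin correlation matrix contributes
\(f(\lambda) = \mathbf{1}\{\lambda \ge 1\} + (\lambda - \lfloor\lambda\rfloor)\)
to the effective count (Li–Ji-style counting): a unit eigenvalue counts
fully, a large eigenvalue that absorbs many correlated bins counts once
plus its fractional remainder. At epigenome scale a dense
eigendecomposition is intractable, so the matrix is processed in contiguous
coordinate blocks that never span chromosomes (long-range
inter-chromosome methylation correlation is treated as negligible) and the
block contributions are summed; `block_size` is exposed, the blockwise
total equals the dense result exactly when a single block suffices, and
eigenvalues are snapped to nine decimals so the fractional-part rule is
stable at exact multiplicities. The per-test threshold is α / M~eff~. The
published estimates of M~eff~ for this design ranged over
236,923–365,101, giving thresholds around 1.4–2.1 × 10⁻⁷; the package
reports full precision rather than a truncated value.

## What the synthetic cohort emulates

`sim_config()` defaults describe the study conditions of a TwinsUK-like
female cohort; they are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_mz_pairs`, `n_dz_pairs`, `n_singletons` | 565 / 244 / 90 | 1708 individuals with methylation data |
| `prevalence` | 0.18 | upper end of the 5–15% lifetime CWP range, appropriate for an older female cohort; yields > 50 discordant MZ pairs |
| `bin_h2`, `bin_c2` | 0.15 / 0.05 | mean twin correlations of stable bins near the published r~MZ~ ≈ 0.21, r~DZ~ ≈ 0.16 |
| `test_retest_r` | 0.30 | within the published lsBIN stability range (0.114–0.905, median 0.145, with power concentrated above the median) |
| `frac_stable_bins` | 0.10 | lsBINs are ~11% of QC-passed bins |
| `zero_inflation` | 0.05 | keeps the QC filter exercised at a low rate |
| `liability_h2` | 0.636 | the reported liability heritability |
| `causal_bin_effects` | 4 bins, γ² = 0.015 each | four top bins jointly explaining ~6% of liability variance |
| `beta_age`, `beta_bmi` | 0.15 / 0.15 | affected women are older with higher BMI |
| `repeat_fraction` | 292/1708 | repeat-measured individuals used for stability testing |
| repeat gap | N(7, 1.2) years, ≥ 3.4 | published gap distribution |
| smoking | 45% ever among the 76.5% with known status | published smoking availability |

Methylation is generated per bin as μ + aA + cC + pP + tT with A shared
(fully within MZ, half within DZ), C shared within pair, and the unique
part split into a persistent component P and a transient component T so
that the expected test–retest correlation equals `test_retest_r` (this
requires `test_retest_r` ≥ `bin_h2` + `bin_c2`, which the configuration
validates). Unstable bins are pure noise regenerated at each visit.
Zero-inflation truncates randomly chosen entries to exactly 0 *before* the
liability is computed, so the trait depends on the observed methylation
values and the association estimands are well defined. Singletons are
generated as members of pairs whose cotwin's affection status is recorded
(`cotwin_cwp`, an extra cohort column) but whose methylation is dropped.

What the generator does **not** emulate: the right-skewed FPKM distribution
(values are Gaussian with zero-inflation — a stand-in, not claimed
equivalent), sequencing or MeDIP enrichment bias, batch effects,
correlation between adjacent overlapping bins, a smoking–CWP association,
and cell-composition effects (WBC counts are drawn independently of
status). Passing tests therefore demonstrate the statistical machinery
under the assumed structure, not robustness to these real-data features.

## Design choices on open points

- **Stability rule.** The QC wording is enforced as "exclude at ≥ 20%
  zeros", with the threshold exposed. The lsBIN rule demands *p* < 0.05
  **and** r > 0: all published lsBIN correlations are positive and negative
  "stability" is meaningless. With a fully permissive p threshold the
  positive-correlation requirement still binds, by design.
- **Pair ordering.** Twin correlations use Pearson correlation with a
  seeded random assignment of "twin 1"/"twin 2" per pair; an
  intraclass-correlation estimator would be the natural alternative but the
  random-ordering Pearson is unbiased for the pair correlation and keeps
  the estimator identical across MZ/DZ groups. Per-bin sample sizes are
  reported because real cohorts have per-bin missingness.
- **Replication test.** Welch (unequal-variance) two-sample *t*; the
  design only says "t test" and the affected group is much smaller than
  the unaffected one, where Welch is the safer default.
- **Combination gate.** Strictly *p* < 0.05 in both stages with equal
  signs. Both the gated count and the direction-concordant-only count are
  surfaced, since published gated/ungated counts are internally
  inconsistent (26,399 in the results vs 40,916 in the discussion); the
  results-section rule is implemented.
- **"Modified" logistic regression** is interpreted as standard ML
  logistic regression with the cotwin's affection status as a covariate to
  absorb familial dependence — the only modification the source design
  describes. No cluster-robust variances are applied. Smoking is coded
  ever/never; models are complete-case with per-model n reported.
- **"Modified" Li–Ji counting** is not recoverable in detail; canonical
  Li–Ji counting over contiguous genomic blocks is implemented, with the
  block size exposed. The published M~eff~ range itself indicates multiple
  estimates were produced.
- **Singletons in the liability likelihood** enter as univariate tail
  terms only.

## Numerical choices

- Orthant quadrature: 96 Gauss–Legendre nodes, |ρ| capped below 1;
  probabilities floored at 1e-300 before logging.
- Liability optimization: L-BFGS-B, 300 iterations, `a2` bounded in
  [0, 0.98], γ in [−0.9, 0.9], parameter sets violating
  Var(E) ≥ 0 rejected with a penalty.
- Paired *t* with identically zero differences returns t = 0, p = 1
  (identical twins are evidence of no effect); a constant non-zero
  difference leaves the statistic undefined and flags the record.
- Zero-variance bins: undefined correlations are `NA` and never lsBINs;
  the Meff computation drops them with a warning.
- Matrix TSVs are written with 17 significant digits so that
  write-then-read round-trips are bit-exact, which also makes pipeline
  artifacts byte-identical across reruns with the same seed.
- Ties in the top-k ranking break by larger χ², then bin id, so output
  order is deterministic.

## Problem sizes used by the test-suite experiments

The packaged experiments run at sizes chosen to make Monte-Carlo error
small relative to the tested effect while keeping the default suite quick:
type-I calibration of the two-stage gate uses 10,000 null bins at the full
cohort size (expected gate rate 0.05 × 0.05 × 0.5 = 0.00125); heritability
recovery uses 100 replicate cohorts at the design size with the
estimate-vs-2-SE coverage criterion; epigenetic-fraction recovery uses 12
replicates of the four-causal-bin design; determinism is checked end to end
at 5,000 bins × 1,708 individuals. The acceptance script repeats these
computations at comparable sizes from a caller-supplied seed.

## Known limitations

- The AE model cannot separate shared environment from additive genetics;
  with true C > 0 the genetic fraction is overstated.
- Replication treats twins as independent individuals (as the original
  design does); residual familial correlation makes the replication-stage
  type-I rate slightly liberal, which the null-calibration test bounds.
- The liability fit standardizes total non-covariate liability variance to
  1, so simulated data with covariate effects are recovered on a scale
  inflated by 1/(1 − β'β); recovery experiments therefore use zero
  covariate effects where exact scale equality matters.
- Bin values are generated independently across bins, so the blockwise
  M~eff~ of simulated data is close to the bin count; real overlapping
  bins would compress it far more.
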