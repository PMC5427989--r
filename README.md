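# twinewas

Twin-design epigenome-wide association analysis for chronic widespread
pain (CWP), with a liability-threshold variance decomposition.

## What this package is for

Chronic widespread pain is a common, heritable musculoskeletal condition.
Blood DNA methylation, quantified in 500 bp genomic bins (250 bp step,
MeDIP-seq-style FPKM values), may carry stable epigenetic signals
associated with it. A twin design makes this testable with unusual rigor:
CWP-discordant monozygotic (MZ) pairs are perfectly matched for genotype
and age, so a paired comparison within such pairs removes genetic
confounding entirely, and MZ/DZ correlation patterns identify how much
trait liability is genetic.

`twinewas` implements that analysis end to end for statisticians and
epigeneticists working with twin-cohort methylation data:

- **QC**: exclusion of bins with zero methylation in ≥ 20% of individuals.
- **Longitudinal stability**: bins whose repeated measures ≥ 3 years apart
  correlate within individuals (*p* < 0.05, r > 0) are kept as
  longitudinally stable bins (lsBINs).
- **Twin-correlation profiling**: per-bin r<sub>MZ</sub>, r<sub>DZ</sub>
  and their dependence on the test-retest correlation (under an ACE model,
  E[r<sub>MZ</sub>] = a² + c², E[r<sub>DZ</sub>] = a²/2 + c²).
- **Two-stage association**: paired *t* discovery in 50 CWP-discordant MZ
  pairs; Welch *t* replication on age- and age²-adjusted methylation in the
  remaining sample; Fisher combination χ² = −2(ln p₁ + ln p₂) on 4 df,
  restricted to bins nominally significant in both stages with the same
  direction of effect.
- **Multiple testing**: effective number of independent tests
  M<sub>eff</sub> from eigenvalues of the bin correlation matrix
  (Li–Ji-style counting f(λ) = 1{λ ≥ 1} + (λ − ⌊λ⌋), blockwise per
  chromosome), per-test threshold α/M<sub>eff</sub>, and
  Benjamini–Yekutieli FDR valid under dependency.
- **Covariate models**: per-bin and joint logistic regressions of CWP on
  standardized methylation with age, BMI and cotwin affection status;
  one-way-ANOVA η² for methylation variance explained by affection status.
- **Liability decomposition**: maximum-likelihood liability-threshold model
  L = β'x + γ'z + A + E (Var A = a², twin correlation 1/0.5), partitioning
  liability variance into additive-genetic (AGF = a²), per-bin epigenetic
  (EGF_j = γ_j²) and residual fractions, with a ½χ²₀+½χ²₁ boundary LRT for
  a² > 0.
- **Synthetic cohort generator**: twin cohorts (565 MZ + 244 DZ pairs + 90
  singletons = 1708 individuals by default) with per-bin ACE structure,
  prescribed test-retest correlation, zero inflation and a
  liability-threshold disease model, plus a ground-truth record for
  parameter-recovery experiments.

See `vignettes/twin-ewas-methods.Rmd` for the model details, parameter
defaults and design decisions.

## Worked example

```r
library(twinewas)

# simulate a cohort at the default study conditions: 1708 women,
# 2000 bins, 18% prevalence, liability h2 = 0.636, four causal bins
sim <- simulate_cohort(sim_config(n_bins = 2000, seed = 42))
d <- file.path(tempdir(), "inputs")
write_cohort_inputs(sim, d)        # bins.bed, methylation.tsv, cohort.csv

cfg <- pipeline_config(file.path(d, "bins.bed"),
                       file.path(d, "methylation.tsv"),
                       file.path(d, "cohort.csv"),
                       out_dir = file.path(tempdir(), "run"), seed = 42)
res <- run_pipeline(cfg)
res$summary$stability
#> $n_input: 2000    $n_lsbin: 152    $n_repeat_individuals: 292
res$summary$ewas
#> $n_bins: 152      $n_disc_nominal: 8     $n_rep_nominal: 14
#> $n_combined_gated: 2                     $n_concordant: 71
print(res$liability$full)
#> Liability-threshold variance decomposition
#>   a2 (liability heritability): 0.703 +/- 0.047
#>   epigenetic fractions: chr1_0=0.0155, chr1_500=0.0239 (total 0.039)
#>   residual: 0.257; logLik = -772.71 (565 MZ, 244 DZ pairs, 90 singletons)
```

Reading the output: of 2000 bins, 152 pass the stability screen with the
292 repeat-measured individuals; the two-stage gate (nominal significance
in both stages plus direction concordance) passes 2 bins, both true causal
bins of the simulation; their affection-status η² (`res$summary$models`)
is ~0.8% each, and the liability fit attributes ~70% of liability variance
to additive genetics and 1.6–2.4% to each recovered bin — the same orders
of magnitude the method reports on real twin-cohort data. Per-stage
artifacts (`stability.tsv`, `ewas.tsv`, `top_bins.tsv`, `meff.json`,
`liability.json`, `stage_summary.json`) are written under `out_dir`, and a
rerun with the same seed reproduces them byte for byte.

A thin command-line wrapper is installed at
`inst/scripts/twinewas-pipeline.R`:

```sh
Rscript inst/scripts/twinewas-pipeline.R simulate --out inputs --seed 1
Rscript inst/scripts/twinewas-pipeline.R run-all --bins inputs/bins.bed \
    --matrix inputs/methylation.tsv --cohort inputs/cohort.csv --out run
```

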