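# fpgi

Fixed-point gene sets and the random survival-association bias in
expression cohorts.

## What problem this solves

In a number of cancer cohorts, a gene set chosen *at random* splits patients
into groups with significantly different survival far more often than the 5%
a calibrated test allows — *positive random bias*. When half of all random
50-gene sets "predict survival", the significance of a published prognostic
signature carries little information. The usual explanation is a pervasive
transcriptional program (proliferation being the canonical one) whose
activity drives hazard and leaks into much of the genome, so almost every
random set carries a trace of it.

`fpgi` searches for the small gene set behind the bias by iterating a map on
size-m gene sets to its fixed points:

1. standardize the current set's genes and split the cohort at the median of
   the samples' first principal component into equal groups A and B;
2. screen with the two-group log-rank test (discard if p ≥ 0.05);
3. rerank all genes by the SAM statistic `d = (mean_A − mean_B)/(s + s0)`
   (`s` the pooled standard error, `s0` the median of all `s`) and keep the
   top m by `|d|`.

A set equal to its own reranking is a fixed point. The search restarts from
`n_runs` random sets (default 6000), pools all converged fixed sets, scores
each gene `w(g)` by the number of converged runs containing it, and calls
the distinct pooled genes the fixed-point set **Z**. Regressing the metagene
of the top 10% of Z (by score) out of the matrix is the bias correction; the
SSAR proportion — the fraction of random sets with log-rank p < 0.05 —
measured before and after quantifies its effect.

The package also ships a synthetic-cohort generator implementing the bias
mechanism (one latent factor driving hazard, a planted signature, and weak
leakage into 30% of the background genes), which is what the test suite
and the acceptance script run against.

For the modeling details, numerical conventions, and two calibration
subtleties worth reading before applying this to real data, see the methods
vignette: `vignettes/fixed-point-gene-sets.Rmd`.

## Worked example

```r
library(fpgi)

cohort <- simulate_cohort(sim_config(seed = 1))
#> Synthetic cohort: 2000 genes x 300 samples, 50 planted genes, theta = 1, 193 events

estimate_ssar(cohort$expr, cohort$surv,
              fpgi_config(set_size = 50, seed = 1), n_sets = 300)
#> SSAR estimate: 276 / 300 random 50-gene sets significant (92.0%) at alpha = 0.05

result <- run_fpgi(cohort$expr, cohort$surv,
                   fpgi_config(set_size = 50, n_runs = 200, seed = 1))
result
#> Fixed-point gene set search
#>   restarts: 200  set size: 50
#>   status:  not_significant=18, converged=182, cycled=0, max_iter_exceeded=0
#>   |Z| = 50 distinct genes; top score 182 ( g0001 )

top <- top_fraction(result)   # top 10% of Z by score
corrected <- remove_signature_effect(cohort$expr, top)
estimate_ssar(corrected, cohort$surv,
              fpgi_config(set_size = 50, seed = 1), n_sets = 300)
#> SSAR estimate: 16 / 300 random 50-gene sets significant (5.3%) at alpha = 0.05

recovery_metrics(result, cohort, k = length(top))
#> $precision [1] 1   $recall [1] 0.1   $k [1] 5
```

Reading: 92% of random sets on this cohort are survival-associated (massive
positive bias); all 182 converged restarts land on the same 50-gene fixed
point, which is exactly the planted signature (precision 1 at the top of the
score ranking); removing its metagene collapses the bias to 5.3%, at the
nominal level.

Real data goes through `load_dataset("expr.tsv", "surv.tsv")` — a
genes-by-samples TSV (first column gene id) and a `sample_id`/`time`/`event`
table; `exec/fpgi` wraps the same functions as a command-line tool with
`run`, `ssar`, `correct` and `simulate` subcommands.

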