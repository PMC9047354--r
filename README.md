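# methfert

Sperm DNA methylation analysis and fertility prediction for cattle, from
per-CpG bisulfite read counts and artificial-insemination (AI) records.

Bulls used for AI are mated with hundreds of cows across many herds, so male
fertility can be measured precisely in the field as a corrected non-return
rate and related to molecular features of the semen. `methfert` implements
that analysis end to end for reduced representation bisulfite sequencing
(RRBS) data:

* **Phenotype** — per-bull corrected non-return rates (NRR 56) estimated
  from binary AI scores by the mixed-model equations: a linear model on the
  0/1 score with fixed confounders (herd-year, month-year, parity, interval,
  weekday, technician, semen category) and a random bull effect with
  variance ratio `r_b = 0.01`, i.e. ridge `λ = (1 − r_b)/r_b = 99` (BLUP).
* **Site filtering** — CpG10 coverage rule (≥ 10 reads per cell), group
  presence in at least ⌈min class size / 2⌉ samples of each class, variant
  masking of the C and G positions, and Table-1-style global summaries
  (hypo < 20%, intermediate [20%, 80%], hyper > 80%).
* **Differential methylation** — a coverage-pooled binomial likelihood-ratio
  test (methylKit-like) and a dispersion-aware beta-binomial Wald test
  (DSS-like, method-of-moments dispersion); Benjamini–Hochberg q-values; a
  site is a DMC iff `q < 0.01` (pooled; 0.1 dispersion-aware) **and** the
  coverage-weighted class difference is ≥ 10 percentage points. DMRs are
  runs of ≥ 3 DMCs with inter-DMC gaps ≤ 100 bp.
* **Annotation** — gene features (TSS ±100 bp, promoter −2000..−100, TTS
  ±100, UTRs, exon/intron, ±10 kb flanks) with a fixed precedence, CpG
  island / 2 kb shore / 2 kb shelf / open sea context (75% overlap rule for
  regions), repeat overlap, and Fisher-exact enrichment versus the
  background.
* **Classification** — Random Forest (500 trees, `mtry = ⌊√p⌋`) on the
  samples × DMCs percentage matrix, missing features dropped or imputed by
  iterative low-rank SVD (< 10% missing), evaluated by 50× stratified 2/3–1/3
  resampling, by train-on-one-center/test-on-the-other splits, and on an
  independent cohort; metrics are accuracy, trapezoidal AUC, sensitivity and
  specificity with *fertile* as the positive class.
* **Synthetic data** — a generator for annotated toy genomes, AI records and
  bisulfite count matrices with known ground truth (planted DMC effects,
  genotype-confounded sites, inter-individual logit variability, missing
  coverage), so the whole pipeline is testable at desk scale.

## Worked example

A fully synthetic run: simulate a cohort of 20 fertile + 20 subfertile
samples with planted 30-point DMCs, filter, test, merge regions and
cross-validate the classifier.

```r
library(methfert)

ann    <- simulate_annotation(n_genes = 5, genome_length = 1e6, seed = 2)
params <- sim_params(n_fertile = 20, n_subfertile = 20, n_cpg = 3000,
                     frac_dmc = 0.04, effect_delta = 30, seed = 3)
sim    <- simulate_methylation(params, ann)
sim$matrix
#> MethCountMatrix: 3000 CpG sites x 40 samples (95.0% cells covered)

sheet <- attr(sim$matrix, "sample_sheet")
fl <- apply_site_filters(sim$matrix, sheet$fertility)
fl$report
#> FilterReport: 3000 sites in, 3000 out
#>   removed by scaffold: 0
#>   removed by variant_mask: 0
#>   removed by group_presence: 0

dmcs <- call_dmcs(fl$matrix, sheet$fertility, test = "pooled",
                  cpg10 = fl$cpg10)
nrow(dmcs)
#> [1] 147
head(dmcs[, c("chrom", "pos", "q", "delta", "direction")], 3)
#>   chrom   pos            q     delta direction
#> 1  chr1 20337 3.694348e-16 -26.26358      hypo
#> 2  chr1 20345 3.972410e-07 -17.66814      hypo
#> 3  chr1 21240 2.262592e-18 -26.92028      hypo

nrow(call_dmrs(dmcs))
#> [1] 13

feats <- prepare_features(fl$matrix, dmcs, "impute_lt_10pct", fl$cpg10,
                          seed = 4)
cv <- crossvalidate_resampled(feats, sheet$fertility, iterations = 50,
                              seed = 5)
round(cv$mean, 3)
#>    accuracy         auc sensitivity specificity
#>           1           1           1           1
```

With a 30-point planted effect and 40 samples the classes are fully
separable, so the cross-validated metrics sit at 1; `delta` is the
coverage-weighted difference (subfertile − fertile) in percentage points and
`direction = "hypo"` marks sites hypomethylated in the subfertile class. The
DMC table passes only sites meeting *both* the q-value and the 10-point
difference criterion.

The same flow runs from files (`read_bismark_cov()` + `assemble_matrix()` +
`read_sample_sheet()`), and `run_pipeline(default_config(...), outdir)` (or
the thin CLI in `inst/cli/methfert.R`) orchestrates
simulate → filter → dmc → dmr → annotate → classify with a hashed output
manifest.

Per-bull phenotypes come from raw AI records:

```r
ai  <- simulate_ai_records(n_bulls = 50, ai_per_bull = 300, seed = 1)
est <- estimate_bull_effects(ai$records)          # corrected NRR 56 (BLUP)
cls <- classify_fertility(est, "quantile", q = 0.43)
```

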