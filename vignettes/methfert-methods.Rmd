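---
title: "Methods: from bisulfite counts and insemination records to a fertility classifier"
author: "methfert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bisulfite counts and insemination records to a fertility classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfert)
```

# Scope

`methfert` implements an end-to-end analysis of sperm DNA methylation for
bull fertility: per-CpG bisulfite read counts and binary artificial
insemination (AI) outcomes come in; differentially methylated cytosines
(DMCs) and regions (DMRs), genomic annotations, and a Random-Forest fertility
classifier evaluated under three validation designs come out. Read trimming
and alignment are out of scope — the package starts from Bismark-style
coverage files. A synthetic-data module generates toy genomes, cohorts and
count matrices with known ground truth, so every stage can be exercised and
validated without any external data.

# The fertility phenotype: corrected non-return rates

Each AI record is scored 1 if the mated cow was not re-inseminated within 56
days (a proxy for conception), 0 otherwise. Fertility is a bull-level trait
estimated from thousands of such records by a **linear mixed model on the
0/1 score**:

$$y = X\beta + Z_b u + e, \qquad u \sim N(0, \sigma_b^2), \quad
\sigma_b^2 = r_b\,\sigma_p^2 .$$

The fixed effects $X\beta$ absorb herd-year, month-year, cow parity,
calving-to-insemination interval, weekday, technician and semen category;
the bull effect $u$ is the phenotype ("corrected NRR 56"). The mixed-model
equations add the ridge $\lambda_b = (1-r_b)/r_b$ to the bull block; with
the default $r_b = 0.01$ (bull variance = 1% of phenotypic variance, the
ratio used in national evaluations) $\lambda_b = 99$, so a bull with $n$
records is shrunk by $n/(n+99)$ toward zero. The model is deliberately
*linear*, not logistic: fidelity to the field's evaluation machinery is
preferred over statistical taste, and with success rates around 0.7 and
large $n$ the linear BLUP ranks bulls essentially identically.

Choices made where the design was open:

* **Intercept always included**, fixed effects one-hot with first-level
  reference. With an intercept, the bull BLUPs sum to exactly zero whenever
  every bull has records (the intercept row of the equations forces the
  residual sum to zero, hence $\lambda_b \sum u_i = 0$).
* **Cow permanent-environment effects** are supported (same ridge
  construction, own ratio) but off by default: at desk scale almost every
  cow appears once, so the effect is barely identifiable and folds into the
  residual. When disabled, the residual implicitly carries
  $(1-r_b)\sigma_p^2$ — a documented approximation.
* **The fertile/subfertile cut is a user decision** (`classify_fertility()`:
  quantile or fixed threshold, ties broken by bull id). The study this
  package operationalizes never publishes its numeric cut; only the class
  sizes (57 fertile / 43 subfertile of 100) are known, which a quantile rule
  of 0.43 reproduces.

# Site filtering

Methylation percentages are only trusted where they are measurable:

1. **CpG10 rule** — a cell (site × sample) counts only when covered by at
   least 10 uniquely mapped reads (inclusive: exactly 10 passes).
2. **Group presence** — a site enters the testing background only when it
   has CpG10 status in at least *half of the smallest class, rounded up*
   samples of **each** class (`"auto"`; 57/43 gives ⌈43/2⌉ = 22). The
   ceiling reading reproduces the published threshold of 22 and is adopted
   as the rule.
3. **Variant mask** — CpGs co-localizing with a sequence polymorphism are
   removed, testing both the C (`pos`) and the G (`pos + 1`) of the
   strand-merged CpG. Genotype, not methylation, drives the readout at such
   sites, and a class-imbalanced genotype masquerades as differential
   methylation.
4. **Chromosome allow-list** — stands in for the removal of unplaced
   scaffolds that lack variant information.

The `FilterReport` attributes removals by first-matching rule in this order;
the retained set itself is an order-independent intersection, which the test
suite asserts. Global summaries (per-sample mean methylation; fractions
hypomethylated `< 20%`, intermediate `[20%, 80%]` — closed interval — and
hypermethylated `> 80%`) are computed over CpG10 cells only; a sample with
no CpG10 cell is reported *undefined*, never 0.

# Differential methylation

Two site-level tests are provided because their disagreement is
scientifically meaningful.

**Coverage-pooled likelihood-ratio test** (`dmc_test_pooled`, methylKit-like).
Binomial (logistic) regression of `(methylated, unmethylated)` on class.
Class is the only covariate, so the maximum-likelihood fit is saturated in
the class-pooled proportions and the LR statistic has the closed form

$$\Lambda = 2\left[\ell(m_A, n_A, \hat p_A) + \ell(m_B, n_B, \hat p_B)
  - \ell(m_A, n_A, \hat p_0) - \ell(m_B, n_B, \hat p_0)\right]
  \sim \chi^2_1,$$

with $\hat p_g$ the pooled class proportions and $\hat p_0$ the overall
pooled proportion. Pooling reads across samples makes the test powerful —
and blind to inter-individual variability: a site where individuals vary a
lot but classes differ little can still reach astronomically small p-values.

**Dispersion-aware Wald test** (`dmc_test_dispersion`, DSS-like). The
per-class mean proportion keeps its beta-binomial variance
$\hat p(1-\hat p)\,[N + \hat\rho \sum_i n_i(n_i-1)]/N^2$, with the
intra-class correlation $\hat\rho$ estimated per class and per site by
method of moments from the per-sample proportions and coverages, floored at
0. No shrinkage or smoothing across sites is attempted (the published
smoothed-dispersion machinery is explicitly not reproduced). At zero
estimated dispersion the test reduces to a two-proportion z-test and tracks
the pooled test; under real inter-individual variability its p-values are
honestly larger. Sites with fewer than two CpG10 samples in a class are
skipped and counted, never imputed.

**Calling rule.** A DMC requires *both* a Benjamini–Hochberg q-value below
the threshold (pooled default 0.01; dispersion default 0.1) *and* an
absolute class difference of at least 10 percentage points, where the
difference is taken between **coverage-weighted** class percentages
($100\sum m / \sum n$ over CpG10 cells) — the pooled "calculation mode",
assumed also for the 10-point rule. BH replaces the original SLIM/IHW
adjustments (both bespoke published procedures); the threshold semantics are
kept and this is a documented deviation. Direction is reported as
hyper/hypomethylated *in the subfertile class* and never assumed; all tests
are two-sided.

**DMRs** are maximal runs of at least 3 DMCs with consecutive gaps of at
most 100 bp (inclusive: a gap of exactly 100 continues the run), spanning
first to last member. Nothing requires direction consistency — direction is
the sign of the mean member difference and mixed runs are flagged. Per-DMR,
per-sample means are unweighted averages over member CpG10 cells; samples
covering no member are missing, which drives "covered in all samples"
subsetting downstream.

**Consensus repeats.** `repeat_profile()` summarizes a matrix restricted to
one consensus-repeat coordinate system: per-position coverage-weighted class
means, their difference, and a moving-average trend (default window 5
positions). The profile makes visible the situation where a repeat family is
consistently but sub-threshold differentially methylated (a mean difference
of a few points never passes the 10-point rule, by design).

# Annotation

Windows are fixed constants recorded in every run's metadata: TSS ±100 bp;
promoter −2000..−100 bp of the TSS on the gene's strand; TTS ±100 bp;
upstream/downstream 10 kb; CpG-island shore up to 2 kb from an island; shelf
the next 2 kb. Each site gets exactly one gene-feature label by the
precedence TSS > promoter > TTS > 5′UTR > 3′UTR > exon > intron > upstream >
downstream > intergenic (the features' listing order), one CGI-context label
(CGI > shore > shelf > open sea) by point membership, a repeat flag set by
*any* overlap whatever its extent, and the list of all genes whose body
±10 kb contains it. Regions use any-overlap against gene windows
(midpoint rules were the alternative; any-overlap is assumed and noted for
sensitivity analysis) but a **75% length-overlap rule** for CGI context — a
region is "in" an island/shore/shelf only if ≥75% of its length overlaps
that band, so a region can fall through to open sea even when it touches an
island. The 75% rule applies to regions only; for 1-bp regions it
degenerates to containment and agrees with site annotation, which is
asserted in tests. Unstranded genes are treated as plus strand with a
warning; sites on chromosomes absent from the bundle are labelled
intergenic/open sea with a warning rather than erroring a whole run.
Enrichment of annotation categories among DMCs versus the background is a
two-sided Fisher exact test on the 2×2 counts, with fold = ratio of
proportions, computed separately for hyper- and hypomethylated subsets by
the caller.

# Classification

The feature matrix is samples × DMCs of methylation percentages (CpG10 cells
only). Two missing-value policies: `complete_only` keeps features with no
missing value; `impute_lt_10pct` keeps features with <10% missing and
completes them by **iterative truncated-SVD reconstruction** (missing cells
start at column means; alternate SVD-project and refill until the change is
below 10⁻⁶; the rank is chosen by internal cross-validation on 10% of
held-out observed cells, seed-fixed). This imputer stands in for PCA-based
imputation and is oracle-tested against exact low-rank completion.

The classifier is a Random Forest with 500 trees and
`mtry = floor(sqrt(p))`, the field-standard default. Three evaluation
designs:

1. **Repeated stratified resampling** — per class,
   `round_half_up(2/3 × size)` samples train (57/43 → 38+29 = 67 train,
   19+14 = 33 test; round-half-up is what reproduces those sizes), 50
   iterations, metrics averaged at iteration level (mean and SD reported;
   iteration-level averaging of AUC is assumed over score pooling).
2. **Group split** — train on one semen-collection center, test on the
   other, both directions, no resampling.
3. **Independent cohort** — train on the whole main cohort, test once on an
   unseen cohort restricted to the training feature columns.

Metrics: accuracy, AUC (trapezoidal integration of the ROC built from class
probabilities, undefined on a single-class test set), sensitivity and
specificity. **The positive class is `fertile`** — inverted relative to the
usual disease convention, and chosen so that "sensitivity" is the
fertile-detection rate, matching how the motivating study reports a higher
sensitivity than specificity when subfertile bulls are the ones
misclassified. Predicted class is positive at probability ≥ 0.5; ROC from
probabilities, not votes.

`misclassification_pca()` tags each sample FF/FS/SF/SS (actual then
predicted initial) on centered, unscaled principal components (percentages
share units; scaling is a toggle) — the display used to show that
misclassified samples carry the methylation signature of the opposite class.
Auxiliary operations follow the study's conventions: the two-sample t-test
is used only when all of (>15 values per group, Shapiro–Wilk normality,
F-test variance equality) hold, otherwise Wilcoxon; hierarchical clustering
uses 1 − Pearson distance with Ward linkage (`ward.D2`, i.e. Ward on the
distances); batch effects are removed as OLS residuals on batch indicators.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the emulated
cohort conditions:

| parameter | default | what it emulates |
|---|---|---|
| `n_fertile`, `n_subfertile` | 57, 43 | the two fertility classes |
| `cov_mean`, `cov_dispersion` | 23, 0.15 | ~23× mean per-CpG coverage, negative-binomial spread |
| `baseline_low/high/low_weight` | 0.05, 0.85, 0.5 | bimodal methylation, ~half of CpGs below 20% |
| `indiv_sd` | 0.5 | logit-scale inter-individual variability |
| `frac_dmc`, `effect_delta` | 0.005, 15 | sparse planted DMCs with >10-point effects |
| `frac_hypo_dmc` | 0.21 | minority of DMCs hypomethylated in subfertile |
| `hypo_cluster_size/width` | 5, 2000 | hypomethylated DMCs spatially clustered |
| `missing_rate` | 0.05 | cells with no coverage |
| `frac_variant_sites` | 0.02 | genotype-confounded CpGs |

Counts follow `total ~ NegBin(cov_mean, cov_dispersion)` (zeroed with
probability `missing_rate`; zero-coverage cells are *not covered*, a state
distinct from zero methylation) and
`methylated ~ Binomial(total, p)` with
`logit(p) = logit(baseline) + a_s + δ_j·1[subfertile]`. The beta-binomial
character of real RRBS arises from logit-normal individual effects `a_s`
composed additively with class and genotype effects, rather than from an
explicit beta — one mechanism, three phenomena. Effect sizes are specified
in percentage points and converted per site to the logit offset that moves
the baseline by exactly that amount, so a planted `effect_delta = 10`
matches the 10-point calling threshold's semantics. Planted effects are
placed at direction-compatible baselines (hyper where `baseline + δ ≤ 0.99`,
hypo where `baseline − δ ≥ 0.01`): the point of planting is that the truth
table really carries the stated effect, and only when no compatible sites
remain does the generator fall back to clipping with a warning. The
inter-individual logit SD is not quantified by any published value; its
default is an implementer choice and the tests sweep it rather than assert
it.

Genotype-confounded sites ignore the methylation model entirely: each sample
draws a dosage 0/1/2 from per-class allele frequencies and reads out
~100/50/0% methylation. Setting `variant_class_imbalance > 0` tilts the
allele frequencies between classes, reproducing the situation where a
pooled test eagerly calls genetic variants as DMCs while a dispersion-aware
test, seeing the bimodal within-class spread, does not.

AI records are simulated with a linear-on-probability outcome model
(`base_rate + bull effect + fixed effects`, clipped), mirroring the linear
evaluation model applied to the 0/1 scores.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (fastq, bisulfite-conversion
errors, multi-mapping), genome-wide CpG spatial autocorrelation beyond the
planted clusters, correlated batch/center effects on methylation, linkage
between variant sites, and realistic minor-allele-frequency spectra. Results
on synthetic cohorts validate the *machinery*, not effect sizes in any real
population.

# Numerical choices and degenerate inputs

* One top-level seed fans out through `derive_seed(seed, stage, index)` — a
  fixed integer hash of the stage name folded into the parent seed, kept
  inside the 32-bit range — so any stage can be re-run in isolation and
  reproduce its slice of a full run.
* Probabilities are kept in [0.01, 0.99] wherever an offset could escape;
  clipping is warned about, never silent.
* The pooled LR statistic is floored at 0 (guarding tiny negative values
  from floating point) and p is exactly 1 when the pooled proportions are
  equal. The dispersion estimator floors ρ at 0 and caps it at 1; a
  zero-variance contrast yields p = 1 when the means agree and p = 0
  otherwise.
* BH returns `NA` for skipped sites rather than repositioning them.
* Ties in `classify_fertility` and `stratified_split` are resolved by id
  order / seeded sampling, both documented and asserted.
* Empty inputs: an empty coverage file is an empty table, not an error; an
  empty DMC list yields an empty DMR table; zero surviving features is an
  error (a model without features is meaningless).

# Problem sizes

The test suite and the acceptance script run entirely on synthetic cohorts
sized for a desk machine, as the package's own choice of working scale:
6,000 null sites for calibration checks, 4,000 sites and 20+20 samples for
the pooled-versus-dispersion contrast and for planted-effect recovery, 3,000
sites for the end-to-end classifier (50 resampling iterations of a
500-tree forest), 50 bulls × 50–300 records for BLUP recovery, and 1,000
random position sets for the DMR-caller oracle. The full suite runs in well
under a minute.

# Known limitations

* The dispersion test's method-of-moments estimator is noisy at small
  per-class sample counts; it is honest (skips, never imputes) but
  low-powered there — consistent with the phenomenon it models.
* The BH substitution means q-values differ numerically from SLIM/IHW
  output; only threshold semantics are preserved.
* The annotator's any-overlap rule for region gene-features is one of
  several defensible conventions; the 75% rule is applied to CGI context
  only.
* `estimate_bull_effects` treats disabled random terms as residual variance;
  with cow effects off, the implied bull ratio is mildly misstated for cows
  with repeat records.
* Real-data headline numbers (e.g. hundreds of DMCs on 1.5M-site
  backgrounds) require the original sequencing data and variant masks and
  are out of scope; the package reproduces the *procedures* and their
  arithmetic exactly, and the study conditions statistically.
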