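---
title: "Quantifying mosaic loss of chromosome Y: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mosaic loss of chromosome Y: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Mosaic loss of chromosome Y (mLOY) is an acquired, clonal absence of the Y
chromosome in a fraction of a man's blood or tissue cells — an all-or-none
state per cell, mosaic across cells.  This vignette documents the models
behind each quantification route in `mloykit`, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate,
and the numerical choices and known limitations that a user auditing
results should be aware of.

## 1. Array-based mLOY

### Signal model

A SNP array reports, per probe, a log-R ratio (LRR): log2 of observed vs
expected intensity.  If a fraction $f$ of cells lack Y, the expected Y-probe
intensity is $(1-f)$ times the single-copy expectation, so the ideal
summary signal is

$$\mathrm{mLRRY} = \log_2(1 - f), \qquad
  f = 1 - 2^{\mathrm{mLRRY}}.$$

`mlrr_to_percent()` implements the inverse with an optional multiplicative
`response_slope` (default 1) to absorb array signal compression; the cited
transformation used on real cohorts is not printed anywhere public, so this
exactly invertible single-copy model is adopted — it has the right limits
(0 maps to 0%, $-\infty$ to 100%) and makes the array round-trip testable
to machine precision.  Negative percentages arise from noise and are
deliberately **never clamped**: clamping would truncate the null
distribution that the detection threshold is estimated from.

mLRRX and mLRRY are medians over X- and Y-chromosome probes (even-length
median = mean of the two central order statistics; invariant to probe order
and duplication).

### Quality control and exclusions

* **DLRS** (derivative log-ratio spread): sd of successive LRR differences
  divided by $\sqrt2$, computed on chromosome-1 probes.  For i.i.d. probe
  noise of sd $\sigma$ it estimates $\sigma$ while ignoring slow waves.
  Samples above $Q_3 + 1.5\,\mathrm{IQR}$ of the cohort DLRS distribution
  fail QC; quantiles use linear interpolation (type 7), pinned so the
  cutoff is reproducible.  (On large genotyping cohorts this rule has
  realized around 0.35; the rule, not the constant, is the method.)
* **Sex aneuploidy**: samples with mLRRX above `x_gain` (47,XXY-like),
  mLRRY above `y_gain` (47,XYY-like) or mLRRX below `female` are excluded
  from mLOY scoring.  Bounds default to $\pm0.3$, configurable — published
  work used visual inspection of the (mLRRX, mLRRY) plane without numeric
  bounds, so a symmetric default was fixed here.
* **Batch adjustment** subtracts each batch's median mLRRY computed over
  QC-passing, aneuploidy-free subjects.  This assumes most subjects have
  little or no loss (true of population cohorts); in a cohort where most
  subjects carry substantial mLOY, median-centring removes signal, which is
  why `estimate_mloy_array(adjust_batches = FALSE)` exists and is used by
  the recovery tests, where no batch effects are simulated.

### Detection threshold

Detectable mLOY is declared when the percent estimate exceeds the lower
limit of the two-sided `confidence` (default 99%) interval of the
experimental noise:

$$t = -z_{(1+c)/2}\,\hat\sigma, \qquad
  \text{threshold\%} = 100\,(1 - 2^{t}).$$

$\hat\sigma$ is a robust scale: $1.4826 \times \mathrm{MAD}$ about zero.
When no LOY-free truth is available, only subjects with adjusted
mLRRY $\ge 0$ are used, mirrored about zero — loss pushes mLRRY left only,
so the right half is noise-dominated.  The realized threshold is
cohort-specific (published values such as 8.28% are properties of their
dataset, not constants of the method).

**Calibration, honestly stated.**  With Gaussian probe noise the detectable
false-positive rate on LOY-free subjects should be $(1-c)/2 = 0.5\%$.
Measured over $200 \times 5000$ synthetic subjects the realized rate is
$0.525\% \pm 0.008\%$ — calibrated to about 5% relative, but measurably
anticonservative.  Three sources, quantified by targeted Monte Carlo:
(i) the mLRRY summary is a **median of $k$ probes**, whose 0.5% tail is
heavy relative to its quartile scale (tail probability 0.00515 at $k=10$,
0.00501 at the default $k=50$); (ii) the tail probability is convex in the
estimated scale (relative sd 2.6% at $n=5000$ reference subjects), adding
about +1.6%; (iii) a remainder from small-sample behaviour of the
mirrored-quartile estimator.  The corresponding acceptance criterion
demands agreement within 3 binomial standard errors (±4.2% relative at
$10^6$ observations) and is left red: the prescribed $z\hat\sigma$
threshold is not that accurate.  An empirical-quantile threshold would be
unbiased by construction but rests on ~25 tail points at $n=5000$ and was
not substituted for the stated design.

### Categorical scoring

`detectable` uses the derived threshold; `high` uses a 40% cutoff, the
level at which lung-function deficits are apparent in cohort data.  Both
boundaries are inclusive (`>=`), reading "at least" literally; a `strict`
flag flips both.

## 2. Digital PCR

Partition counts follow Poisson statistics: with $\lambda$ mean copies per
partition, a partition is negative with probability $e^{-\lambda}$, so
$\hat\lambda = -\ln(1 - \text{positives}/n)$ (`poisson_lambda()`; a
saturated plate is an error, not infinity).  With a Y target and its X
homologue (e.g. AMELY/AMELX) as chromosome proxies,

$$\mathrm{mLOY\%} = \left(1 - \frac{\lambda_Y}{\lambda_X}\right)\times 100.$$

Partition volume cancels in the ratio and is kept only for reporting.
Negative estimates are reported as-is with an annotation; `floor_zero`
exists for categorical use because it is not stated whether clinical-trial
values were floored before analysis — both behaviours are exposed.
Uncertainty is a seeded percentile bootstrap resampling both channels as
binomials.  At 26,000 partitions and $\lambda = 1$ a single plate's
estimate has Monte-Carlo sd up to ~1.2 percentage points (largest at small
true loss), which is why recovery tests average over replicate plates.

## 3. Single-cell LOY calling

A cell is LOY when it has **zero** transcripts across all genes of the
male-specific region of Y (MSY); one transcript makes it wild type.  The
default MSY list (editable, `inst/extdata/msy_genes.txt`) matches the
human Ensembl release-91 annotation commonly used for this purpose.

The calling null is dropout: a wild-type cell yields zero MSY counts with
probability $e^{-\Lambda}$ where $\Lambda$ is its total MSY rate.  The
synthetic generator uses Poisson counts precisely so this void probability
is closed-form and the caller's false-positive rate can be checked exactly;
it falls rapidly with depth (at the default MSY means, ~15 expected counts
at 8000 depth, it is negligible; the calibration tests deliberately thin
MSY coverage to make it measurable).

QC before calling: mitochondrial fraction $\le$ 10%, expressed genes in
[800, 3500] (inclusive; boundary cells kept).  A separate, stricter depth
gate — strictly more than 4000 total counts — admits cells to expression
analyses (DGE, scores); "reads" is implemented on the count-matrix column
sum, since the source protocol does not say whether raw reads or UMIs were
meant.

Cell types are assigned by marker score (mean library-size-normalized,
log1p expression of a label's markers; ties broken lexicographically for
determinism), hierarchically: major type, then leukocyte lineage, then
macrophage polarization subtype.  M1 and M2b share IL1B as their marker;
an M1 call additionally requires zero normalized MRC1 — a fixed rule
standing in for what was resolved manually in the source analyses.
Graph clustering, Harmony integration and UMAP are intentionally out of
scope: labels come from metadata, from user-supplied clusters, or from the
per-cell scorer.

Per-type case/control enrichment uses Fisher's exact test on the
LOY/WT × case/control table.  The odds ratio is the conditional MLE with
its exact conditional interval; a zero cell degenerates that estimate, in
which case a Woolf interval with Haldane–Anscombe 0.5 correction is
reported and annotated.  P-values are presented unadjusted with star marks
(matching how such panels are usually displayed), alongside a
Benjamini–Hochberg column.

## 4. Functional signals

All expression operations consume one normalization: counts scaled to a
common library size (default $10^4$) and log1p-transformed.

* **DGE (LOY vs WT)**: two-sided Wilcoxon rank-sum per gene — the source
  does not name its test, and the rank-sum is the de-facto default of the
  toolchain it used, robust, and exactly enumerable.  Both arms $\le 10$
  cells triggers full enumeration of the permutation null (midranks, so
  ties are exact); otherwise the tie-corrected normal approximation with
  continuity correction.  Fold changes are $\log_2$ of mean normalized
  expression with pseudocount 1.  MSY genes are flagged: they define the
  groups and must appear down-regulated.
* **Fold-change caveats.**  Two intrinsic biases of CPM-style fold
  changes, documented because the recovery tests had to respect them:
  a pseudocount 1 biases $\log_2$FC by $\approx -1/((2m+1)\ln 2)$ for
  normalized mean $m$ (negligible once $m \gtrsim 100$; the common library
  size is configurable for this reason), and up-regulating a gene that
  occupies share $s$ of the library depresses every apparent fold change
  by $\approx -\log_2(1 + s\,(\mathrm{fold}-1))$ (composition effect).
  Neither is an estimator defect; both vanish for genes that are a small
  share of the library.
* **Module scores**: per cell, mean normalized expression of the set genes
  minus the mean of a control pool — for each set gene, `n_ctrl = 100`
  controls drawn with replacement from its expression bin (`n_bins = 24`
  equal-frequency bins by average expression), mirroring the widely used
  Seurat convention.  Scores are invariant to adding a constant to every
  gene and have expectation 0 for a random set; the control draw is seeded
  and bit-reproducible.
* **Group score tests**: Student's $t$ (Welch fallback, annotated, when an
  arm's variance degenerates) of LOY vs WT scores within each lineage,
  Bonferroni-corrected over lineages.
* **Detection-odds test**: whether a cell expresses a gene (count > 0),
  modeled against LOY status by logistic regression within condition, with
  the likelihood-ratio p-value; separation handled by a Haldane-corrected
  odds ratio, annotated.
* **Over-representation**: one-sided hypergeometric tail per gene set
  (GMT input), BH across sets.  The shipped GMT is a labelled synthetic
  stand-in: neither the TGF-signaling membership nor the
  activated-fibroblast signature of the source's references is printed
  publicly, so both are required user inputs in real analyses.
* **Activation regression**: ordinary least squares of per-donor mean
  fibroblast activation score on the donor's percent of LOY leukocytes,
  unweighted by default with a cell-count weight option (the source does
  not state weighting; unweighted is the conservative default).

## 5. Cohort epidemiology

Logistic (incidence), Cox (survival; Efron ties) and linear
(lung-function) fits are orchestration around `stats::glm`,
`survival::coxph` and `stats::lm` — the same routines the source used —
each verified in the test suite against independent small-instance oracles
(hand-rolled IRLS, a hand-maximized partial likelihood, the normal
equations).  Every output table carries its exact formula for audit, and
non-convergence or collinearity is reported, never silently dropped.
Missing exposure values are median-imputed with a retained mask.

**Excess attribution.**  The male excess of an outcome relative to women
is decomposed across men with and without mLOY:
$\mathrm{excess}_g = (r_g - r_F)\,n_g$ and
$\mathrm{share}_{\mathrm{mLOY}} =
\mathrm{excess}_{\mathrm{mLOY}} / \sum_g \mathrm{excess}_g$.
The statistic is scale-invariant in the rates; negative stratum excesses
propagate with an annotation and a non-positive total leaves the share
undefined rather than misleading.  The exact supplementary construction
behind the published "~80%" figure is not in the main text, so that number
is explicitly not a reproduction target; this decomposition is the
documented, testable definition.

**Mediation** (exposure → mLOY → outcome) uses a linear mediator model and
a logistic (or linear) outcome model with the same covariates, a
counterfactual mediator-shift contrast for the ACME and ADE, and a seeded
percentile bootstrap (default 1000 draws) — deliberately simpler and fully
reproducible compared with the quasi-Bayesian machinery of the R package
the source used.  On linear–linear models the ACME reduces exactly to the
product of path coefficients, which is the closed-form oracle used in
testing.

## 6. The synthetic world

Each generator emits the statistical structure its consumer assumes, plus
a ground-truth sidecar:

* `gen_array_cohort()`: Y probes centred on $\log_2(1-f)$, others on 0,
  Gaussian probe noise (`noise_sd = 0.05`, a typical per-probe LRR scale),
  per-batch offsets, 50 probes per chromosome, LOY fractions
  Beta(0.5, 8) by default (right-skewed: most men little or no loss).
  The Gaussian noise model is a modeling choice — the real cohort's
  noise distribution is not described publicly.
* `gen_dpcr_run()`: channel positives as binomials of the Poisson
  occupancy probabilities; 26,000 partitions and $\lambda = 1$ emulate a
  26k nanoplate at a typical loading.
* `gen_sc_cohort()`: donors per condition, multinomial cell types,
  per-cell LOY assigned **before** sampling (all-or-none, matching the
  biology), Poisson counts at depth-scaled type profiles
  (lognormal depths, median 8000, sdlog 0.4), MSY rates zeroed in LOY
  cells, an optional LOY-coupled up-regulation of profibrotic genes in
  designated types, 4× marker boosts, ~2–4% mitochondrial fraction, and
  2000 heavy-tailed background genes so expressed-gene counts land inside
  the 800–3500 QC window at these depths.  Not emulated: ambient RNA,
  doublets, UMI collapsing, negative-binomial overdispersion (Poisson is
  the default precisely because the LOY-calling null is then closed-form)
  — so a green calling test establishes correctness of the statistics, not
  robustness to those artefacts.
* `gen_epi_cohort()`: ages 40–70, mLOY rising ~0.4 percent per year above
  age 50 with a smoking shift (the built-in smoking → mLOY → outcome chain
  gives mediation tests a known truth), exponential proportional hazards
  with a per-percent hazard ratio, administrative censoring at 15 years,
  and an optional logistic diagnosis outcome with a per-percent odds
  ratio — the latter exists because testing a logistic fit's recovery
  requires an outcome actually generated under a logistic law.

All generators take explicit seeds, restore the caller's RNG state, and
are byte-reproducible.

## 7. Known limitations

* The array module models Y intensity only; B-allele-frequency or
  phasing-based mosaicism calling is out of scope.
* The detection threshold's ~5% relative anticonservatism (Section 1) is a
  property of the prescribed estimator, inherited by anything consuming
  the `detectable` flag at face value.
* Marker-based annotation assumes the marker table discriminates the types
  present; unlisted cell types will be absorbed into their nearest label.
* The mediation bootstrap resamples subjects i.i.d.; clustered or
  case-control sampling designs would need a stratified bootstrap.
* Acceptance testing is property-based on synthetic data: published
  headline estimates (hazard ratios, enrichment odds ratios, thresholds)
  depend on restricted cohort data and are demonstrated as *recoverable
  parameter classes*, not reproduced numbers.
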