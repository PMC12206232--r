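# mloykit

Quantification of **mosaic loss of chromosome Y (mLOY)** — the most common
acquired mutation in aging men, in which a clonally expanding fraction of
blood (or tissue) cells lacks the Y chromosome — and the downstream
statistics that link it to disease, with idiopathic pulmonary fibrosis
(IPF) and its strong male excess as the motivating application.

The package is for genetic epidemiologists and single-cell analysts who
need the three measurement modalities and their associated inference in
one tested, scriptable toolkit:

| Modality | Core quantity | Entry point |
|---|---|---|
| SNP-array intensities | mLRRY = median Y-probe log-R ratio; %LOY = 100·(1 − 2^mLRRY) | `estimate_mloy_array()` |
| Digital PCR (Y/X homologue assay) | λ = −ln(1 − positives/n); mLOY% = (1 − λ_Y/λ_X)·100 | `estimate_mloy_dpcr()` |
| Single-cell RNA-seq | LOY cell ⇔ zero transcripts across all MSY genes | `call_loy()` |

Around these sit: DLRS-based array QC, sex-aneuploidy exclusion, batch
adjustment, and a noise-derived detection threshold (lower limit of the
99% confidence interval of the experimental noise); marker-based
hierarchical cell-type annotation and per-type case/control enrichment
(Fisher's exact test with conditional odds ratios); LOY-vs-WT differential
expression (exact small-sample rank-sum), binned-control module scores,
gene-set over-representation, and donor-level activation regression;
logistic/Cox/linear cohort models, bootstrap mediation
(smoking → mLOY → outcome), and a male-excess attribution decomposition.
Every input has a seeded synthetic generator (`gen_*`) with ground-truth
sidecars, so the full pipeline is testable with no external data.

## Worked example

```r
library(mloykit)

## Array: 200 men, 50 with true mosaic loss, typical probe noise
set.seed(1)
f <- c(rep(0, 150), rbeta(50, 2, 4))
sim <- gen_array_cohort(200, loy_dist = f, noise_sd = 0.05, seed = 11)
est <- estimate_mloy_array(sim$profiles)
attr(est, "threshold")
#> mLOY detection threshold: 1.80% (noise sd 0.0102, 99% confidence, n = 197, mirrored reference)
head(subset(est, detectable,
            select = c(subject_id, percent_loy, detectable, high)), 4)
#>     subject_id percent_loy detectable  high
#> 151      S0151    21.07997       TRUE FALSE
#> 152      S0152    37.70746       TRUE FALSE
#> 153      S0153    17.77602       TRUE FALSE
#> 154      S0154    41.48046       TRUE  TRUE
```

The threshold (1.80% here) is derived from this cohort's own noise — the
mirrored right half of the adjusted mLRRY distribution — so it shrinks
with probe count and cohort quality; subject S0154 also crosses the 40%
"high mLOY" cutoff used for lung-function contrasts.

```r
## Digital PCR: one 26k-partition plate, true loss 43%
plate <- gen_dpcr_run(true_f = 0.43, n_partitions = 26000,
                      mean_copies_per_partition = 1, seed = 3)
estimate_mloy_dpcr(plate, seed = 3)[, c("mloy_percent", "ci_low", "ci_high", "high")]
#>   mloy_percent   ci_low ci_high high
#> 1     43.50324 41.98608 44.9124 TRUE

## Single cell: macrophage LOY enriched in cases (generating odds ratio 3)
lf <- data.frame(condition = c("IPF", "control"), cell_type = "macrophage",
                 loy_frac = c(0.25, 0.10))
sc <- gen_sc_cohort(c(IPF = 3, control = 3), cells_per_donor = 800,
                    loy_frac = lf, seed = 5)
calls <- call_loy(sc$dataset)
enr <- loy_enrichment_by_type(calls, sc$dataset$cells$cell_type,
                              sc$dataset$cells$condition)
enr[enr$cell_type == "macrophage",
    c("a", "b", "c", "d", "odds_ratio", "ci_low", "ci_high", "p_value", "stars")]
#>     a   b  c   d odds_ratio   ci_low  ci_high      p_value stars
#> 4 164 547 84 673   2.400686 1.789137 3.238677 9.789232e-10  ****
```

164 of 711 QC-passing case macrophages are LOY (zero MSY transcripts)
versus 84 of 757 control macrophages: conditional-MLE odds ratio 2.40
(95% CI 1.79–3.24), consistent with the generating odds of
(0.25/0.75)/(0.10/0.90) = 3 given dropout-free calling and sampling error.

```r
## How much of the male excess sits in the mLOY stratum?
excess_attribution(rate_female = 0.0009, rate_male_no_mloy = 0.0026,
                   rate_male_mloy = 0.0077,
                   n_male_no_mloy = 160000, n_male_mloy = 56000)
#> Excess events: 380.80 in mLOY men, 272.00 in other men (total 652.80)
#> Share of male excess in the mLOY group: 58.3%
```

With these stratified rates, men with mLOY — a quarter of the men —
account for 58% of the male−female excess in events.

## Command line

An `exec/mloykit` script exposes subcommands `array`, `dpcr`, `sc` and
`epi` over CSV/MTX files, echoing all thresholds in effect; see
`?mloykit_cli`.

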