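# bimodetect

Detection of bimodal gene expression in tumor cohorts, with survival
stratification of the two expression modes.

## What it does, and for whom

Some genes are expressed in two distinct regimes across the patients of a
cohort: a low mode and a high mode, each corresponding to a subpopulation
(mutation or copy-number state, subtype, sex-linked expression, ...). For
anyone working with bulk RNA-seq cohorts — a gene × sample FPKM matrix plus a
clinical table — `bimodetect` answers two questions per gene:

1. **Is this gene bimodal?** The expression density is estimated with a
   Gaussian kernel using the rule-of-thumb bandwidth
   `0.9 · min(σ̂, IQR/1.34) · n^(−1/5)`; peaks are sign changes (+→−) of the
   spline-smoothed density derivative, pruned by two height rules (*Threshold
   Down*: peaks below 20% of the maximum density are dropped; *Threshold Up*:
   adjacent peak–valley pairs with a height gap below 10% are merged). Genes
   with exactly two peaks get a `k+1 = 3`-component Gaussian mixture fit by
   EM; samples in the extra (outlier-absorbing) component, samples with
   classification reliability ≤ 46%, and whole clusters holding < 10% of the
   samples are discarded; peak detection is then **re-run on the retained
   samples**, and only genes that again show two peaks are called bimodal.
2. **Do the two modes differ in prognosis?** Retained samples are labeled
   `peak1` (lower mode) / `peak2`, and for every bimodal gene the two groups
   are compared with the log-rank test
   `χ² = (O₁ − E₁)² / ΣVᵢ` over the pooled risk sets, with Kaplan–Meier
   curves available for plotting; genes are flagged at the 5% and 1% levels.

A synthetic-cohort generator with per-sample ground truth (log-normal
expression modes, exponential survival with a chosen hazard ratio and
censoring fraction) makes the whole pipeline testable without any download.

## Worked example

```r
library(bimodetect)
library(dplyr)

specs <- bind_rows(
  gene_spec("BM1", "bimodal", mode1_mean = 1, mode2_mean = exp(2.5), mode_sd = 0.5),
  gene_spec("UM1", "unimodal", mode1_mean = 4),
  gene_spec("UM2", "unimodal", mode1_mean = 6, mode_sd = 0.6)
)
sim <- simulate_cohort(300, specs, seed = 3)
res <- analyze_cohort(sim$expression, detection_config(use_log = "log2", seed = 4))
#> cohort SIM: bimodal=1, unimodal=2
res$calls |>
  select(gene_id, status, n_samples_used, peak1_location, peak2_location, peak1_n, peak2_n)
#> # A tibble: 3 × 7
#>   gene_id status   n_samples_used peak1_location peak2_location peak1_n peak2_n
#>   <chr>   <chr>             <int>          <dbl>          <dbl>   <int>   <int>
#> 1 BM1     bimodal             300       -0.00869           3.55     144     149
#> 2 UM1     unimodal            300       NA                NA         NA      NA
#> 3 UM2     unimodal            300       NA                NA         NA      NA
```

The planted gene `BM1` is recovered: two confirmed density peaks on the log2
scale near 0 and 3.55 (the planted modes are at log2(1) = 0 and
log2(e^2.5) ≈ 3.6), with 144 and 149 retained samples per mode — 7 of the
300 were discarded by the reliability/outlier filters. The unimodal genes
are left alone.

```r
labels <- sim$mode_labels |> filter(gene_id == "BM1")
clinical <- simulate_survival(labels, hazard_ratio = 3, censoring_rate = 0.2, seed = 5)
prognosis_screen(res$stratifications, clinical)
#> # A tibble: 1 × 10
#>   gene_id cohort_label n_group1 n_group2 events_group1 events_group2 chi_square
#>   <chr>   <chr>           <int>    <int>         <int>         <int>      <dbl>
#> 1 BM1     SIM               144      149            97           135       73.2
#> # ℹ 3 more variables: p_value <dbl>, significant_05 <lgl>, significant_01 <lgl>
```

With a threefold hazard difference planted between the modes, the log-rank
test is decisive (χ² = 73.2, flagged at both levels). `autoplot()` works on
`peak_set` and `km_curve` objects, and `plot_km_groups()` overlays the
Kaplan–Meier curves of the two modes.

Real cohorts follow the same path: `read_expression_matrix()` +
`read_clinical_table()` (TSV/CSV; month-based survival exports rescale via
`time_unit = "months"`; TCGA barcode suffixes reconcile via
`truncate_barcode`), `analyze_cohort()`, `cross_cohort_summary()` across
cohorts, `chromosome_bias_test()` for enrichment of a gene list on a target
chromosome, and `write_results()` for stable TSV outputs. A thin CLI over
these functions ships in `inst/cli/bimodality.R` (subcommands `simulate`,
`detect`, `summarize`, `survival`).

## Method notes

See the methods vignette (`vignettes/bimodal-detection-methods.Rmd`) for the
model, the seven tunable parameters and their defaults, the EM and
peak-calling conventions, what the synthetic generator does and does not
emulate, and known limitations.
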