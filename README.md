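# crossclock

Cross-species transcriptome aging clocks from multi-study RNA-seq count
data.

## What it does

Public sequence archives hold enough brain RNA-seq to ask whether the genes
whose expression tracks chronological age in one species do so in another —
for example human prefrontal cortex (ages in years) against *Drosophila*
head (ages in days). `crossclock` implements that analysis as a tested,
reusable pipeline:

1. **Ingest & filter** — validated genes x samples count matrices with
   per-sample metadata; genes kept iff counts exceed 10 in at least half the
   samples.
2. **Normalize** — TMM (trimmed mean of M-values) and RLE (median-of-ratios)
   scaling factors implemented from their published definitions, log2-CPM
   features, and a scalar *study-effect score* quantifying how well a method
   removes between-study shifts.
3. **Rank** — per-gene Pearson correlation *r* of expression with age;
   top-*k* (classically 1000) genes by |*r*|.
4. **Conserve** — greedy best-match resolution of a scored many-to-many
   ortholog table (DIOPT-style) into a one-to-one map, then intersection of
   the two species' top lists: the conserved aging gene set.
5. **Validate** — resampled evaluation: `n` independent 75/25 train/test
   splits (default 1000), gradient-boosted tree models on log-CPM features,
   mean R² / MSE / median absolute error with a 95% percentile interval for
   regression, and accuracy / macro-F1 with iteration-averaged confusion
   matrices for Young/Middle/Old classification (years: <30 / 30–60 / >60;
   days: <=10 / (10,29] / >29).
6. **Simulate** — a negative-binomial two-species generator with per-study
   library-depth regimes, uneven age windows, gene-by-study batch noise and
   planted age-associated ortholog pairs, so the whole pipeline is verified
   against known ground truth with no downloads.

All user-facing results are tibbles (with `tidy()`, `glance()`,
`autoplot()` methods), so the pipeline composes with ordinary tidyverse
workflows.

## Worked example

Simulate the standard two-species experiment (2000 genes/species, three
studies of 20 samples each, 40 planted conserved ortholog pairs), run the
full pipeline, and check recovery:

```r
library(crossclock)

sim  <- simulate_dataset(sim_config(seed = 1))
ds   <- filter_expressed(sim$dataset_a)        # 1923 of 2000 genes pass
fac  <- tmm_factors(ds)
corr <- correlate_with_age(log_cpm(ds, fac))
head(corr, 3)
#> # A tibble: 3 x 4
#>   gene_id         r abs_r  rank
#>   <chr>       <dbl> <dbl> <int>
#> 1 HGENE00095  0.758 0.758     1
#> 2 HGENE00088 -0.719 0.719     2
#> 3 HGENE00074 -0.717 0.717     3
```

The one-command demonstration wires every stage together and reports how
much of the planted truth came back:

```r
res <- run_demo(seed = 1, tasks = "regression")
#> planted conserved pairs: 40; recovered: 40; recall: 1.00
#>
#> == regression_a ==
#>     feature_set n_genes mean_r2 ... mean_median_ae r2_ci_low r2_ci_high
#> 1     all_genes    1923   0.516           8.15        0.0804      0.788
#> 2         top_k    1000   0.583           7.36        0.167       0.807
#> 3     conserved      53   0.665           6.19        0.316       0.847
#> 4 noise_control      39  -0.567          15.8        -1.69        0.0467
```

Read: all 40 planted pairs were recovered in the 53-pair conserved set; a
clock built on just the conserved genes predicts age on held-out samples
with mean R² 0.67 and a median absolute error of ~6 years, while a matched
noise-only gene set has no predictive value — the negative control the
selection must beat. `autoplot()` on any evaluation draws the R² histogram;
`plot_confusion()` shows classification structure.

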