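# exoshift

Detection of 5′→3′ exonucleolytic mRNA decay targets from comparative
RNA-seq coverage.

## What it does, and for whom

When a 5′→3′ exoribonuclease degrades a transcript, sequencing libraries
from the enzyme-bearing strain under-represent the transcript's 5′ end,
while a deletion mutant of the enzyme both stabilizes the transcript and
restores even coverage. exoshift is for microbiologists and RNA biologists
comparing such strain pairs (e.g. an archaeal or bacterial wild type
against an RNase deletion mutant, sampled in two growth phases with
replicates) who want a ranked, reproducible candidate list of the enzyme's
direct decay targets.

For each transcript and condition, per-base read depth is oriented 5′→3′,
normalized by the transcript's total depth, and rescaled to 100 positional
bins summing to 1. The per-bin wild-type minus mutant difference curve
`D_i` is fitted by ordinary least squares against normalized position
`x_i = (i − 0.5)/100`:

```
D_i = a + b·x_i ,   b = cov(x, D) / var(x) ,   a = −b/2
```

A positive slope `b` means the wild type is 5′-depleted relative to the
mutant — the footprint of directional decay. Differential abundance
(mutant over wild type) is estimated with a negative-binomial
exact-style test on raw counts, using median-of-ratios size factors and a
trend-moderated method-of-moments dispersion. A transcript is called a
candidate in a growth phase when **both**

* `log2fc ≥ mean + SD` of the background log₂ fold changes, and
* `slope ≥ mean + SD` of the background slopes, with `slope > 0`.

A seeded synthetic-data generator (two conditions × two phases ×
replicates, with a ground-truth table and a closed-form slope oracle
`expected_slope(d) = d / (100·(1 − d/2))`) makes the whole pipeline
testable end to end without any external data.

## Worked example

```r
library(exoshift)

cfg <- simulation_config(n_transcripts = 300, seed = 11)  # 10% true targets
res <- run_pipeline(cfg, "results_demo", phases = "log")

res$thresholds$log
#> selection_thresholds [log]: n=300
#>   log2fc cutoff 0.8372 (mean 0.1249 + sd 0.7123)
#>   slope  cutoff 0.003673 (mean 0.000870 + sd 0.002803)

head(subset(res$candidates, candidate)[, c("transcript_id", "log2fc", "slope")], 5)
#>  transcript_id   log2fc       slope
#>        TX_0012 1.793578 0.007759433
#>        TX_0015 2.121211 0.008047405
#>        TX_0017 1.943095 0.008679608
#>        TX_0034 1.796745 0.008504529
#>        TX_0074 2.495946 0.006621264
```

The thresholds line says the background of 300 scored transcripts had a
mean log₂ fold change of 0.12 (SD 0.71), so a candidate needs
`log2fc ≥ 0.84`, and analogously `slope ≥ 0.0037` per unit of normalized
position. The listed candidates clear both comfortably (slopes of
0.007–0.009 correspond to a strong linear 5′ depletion); checking them
against the generator's truth table, all 30 selected transcripts are true
planted targets (30/30 recovered). Output TSVs — `slopes.tsv`,
`differential_abundance.tsv`, `candidates.tsv`, a per-phase
`candidate_table.tsv`, the descriptive `de_significant.tsv`
(`padj < 0.1`) and a run log — land in the output directory.

Real datasets enter through `read_annotation()` (GFF3/BED),
`read_reads()` (per-sample BED intervals) and/or `read_counts()`; a thin
command-line dispatcher with subcommands `simulate`, `profiles`,
`slopes`, `de`, `select` and `all` is installed at
`inst/cli/exoshift.R` (`Rscript exoshift.R all --annotation ann.gff3
--samples samples.tsv --out results/`).

The methods vignette (`vignettes/decay-detection.Rmd`) documents the
model, the normalization and binning conventions, the generator's
assumptions, and the calibration of the NB test.

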