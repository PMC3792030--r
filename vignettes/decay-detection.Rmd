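---
title: "Detecting 5' to 3' exonucleolytic mRNA decay from coverage shifts"
author: "exoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 5' to 3' exonucleolytic mRNA decay from coverage shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoshift)
```

## The problem and the model

A 5' to 3' exoribonuclease attacks transcripts from their 5' end. In a
strain carrying the enzyme, partially degraded molecules are missing their
5'-most sequence, so RNA-seq coverage along an affected transcript rises
from the 5' toward the 3' end relative to a deletion mutant in which the
same transcript is degraded by other, less directional routes. Two
observable signatures follow: the transcript is *more abundant* in the
mutant (it is stabilized there), and its *relative coverage* in the wild
type is 5'-depleted compared with the mutant. exoshift quantifies both and
intersects them.

For each transcript and condition the pipeline:

1. computes per-base read depth, oriented 5' to 3' (minus-strand profiles
   are reversed, so index 1 is always the biological 5' end);
2. divides by the total depth of the transcript, giving a relative
   coverage that sums to 1;
3. rescales to a fixed length of 100 positional bins;
4. subtracts the mutant profile from the wild-type profile, bin by bin;
5. fits the resulting difference curve with ordinary least squares against
   normalized position, `D_i = a + b * x_i`, `x_i = (i - 0.5)/100`.

Because both binned profiles are probability vectors, the difference curve
sums to zero, and simple regression algebra then forces the fitted
intercept to equal `-slope/2`; both identities are asserted throughout the
test suite and make corruption of the normalization immediately visible.
A positive slope `b` means the wild type has relatively fewer reads at the
5' end — the directional-decay footprint. Swapping the two strains negates
the slope exactly.

Abundance changes are estimated by a classic two-condition
negative-binomial test on raw counts with median-of-ratios normalization
(see below). Finally, a transcript is called a candidate decay target in a
growth phase when **both** of these hold relative to the background of all
transcripts scored in that phase:

* `log2fc >= mean(log2fc) + sd(log2fc)` (mutant over wild type), and
* `slope >= mean(slope) + sd(slope)` with `slope > 0`.

Cutoff comparisons are inclusive, SDs use the sample (n−1) denominator,
and the background is *all* transcripts possessing both statistics, not
only significant ones — the two filters are deliberately independent, and
their conjunction is what makes the rule strict. Adjusted p-values are
reported (the descriptive differential-abundance table uses `padj < 0.1`)
but play no role in candidate selection.

## Coordinate and binning conventions

Internally every interval lives in a `GRanges` (1-based, closed — the
native Bioconductor convention); GFF3 (1-based) and BED (0-based,
half-open) are converted exactly once, at the I/O boundary, by
rtracklayer. Keeping a single convention inside the package and borrowing
the ecosystem's battle-tested converters removes the usual off-by-one
risks.

Base-to-bin assignment uses the floor rule: 0-based base `p` of a
transcript of length `L` belongs to bin `floor(100 p / L) + 1`, and bin
values are **sums** of relative coverage, not means. Summing conserves
total mass exactly for any `L`, which is what makes the sum-to-one (and
hence sum-to-zero) invariants hold to machine precision; averaging would
break them whenever `L` is not a multiple of 100. Transcripts shorter than
100 nt are excluded from the slope analysis (a 100-bin rescaling of fewer
than 100 bases is ill-defined) but remain eligible for the abundance test.

Replicates are pooled (read sets concatenated) per condition before
binning, producing one curve per condition and phase; coverage is
strand-specific by default (`stranded = FALSE` accommodates unstranded
libraries). A transcript enters the slope analysis only with at least
`min_reads` (default 50) pooled overlapping reads in *each* condition —
below that, a 100-bin profile is mostly sampling noise.

The regression abscissa is normalized position on (0, 1), not bin index;
slopes on the bin-index scale are `slope/100`. With bin values of order
0.01, typical decay slopes land in the few-per-thousand range on this
scale, the natural order of magnitude for this statistic.

## The synthetic-data generator

The generator emulates the study design end to end: two conditions (wild
type, deletion mutant) × two growth phases × `n_replicates` biological
replicates, with a ground-truth table naming the true targets. Its model
is deliberately the simplest one producing the decay signature:

* Per-transcript relative abundance is log-normal (`abundance_sigma`,
  mean 1), shared across phases.
* Replicate counts are negative binomial with overdispersion
  `nb_dispersion` (`Var = mu + alpha mu^2`); for a true target the mutant
  mean is `2^target_log2fc` times the wild-type mean.
* Read 5'-start positions are uniform along the transcript, except for
  wild-type copies of true targets, where the start weight at relative
  position `x` is `1 - d (1 - x)` — a linear 5' depletion of strength
  `d = decay_depth`. Each read extends `read_length` nt 3'-ward and is
  truncated at the transcript's 3' boundary (truncation, rather than
  discarding, preserves the configured depth; its only artifact is a
  shorter read at the extreme 3' end).

Under this model the noiseless 100-bin difference curve is *exactly*
linear with slope

\[ b(d) = \frac{d}{100\,(1 - d/2)}, \]

implemented as `expected_slope()` and used as the analytic oracle for the
whole coverage → binning → regression chain (`expected_slope(0.5)` is
1/150 ≈ 0.00667). Two caveats define its regime of validity, and both are
properties of coverage data generally, not of this implementation:

* the closed form describes the read-**start** density. Observed coverage
  is that density convolved with the read footprint, which attenuates the
  slope when `read_length` is not small against the transcript length.
  The empirical oracle checks therefore simulate with `read_length = 1`,
  where coverage and start density coincide; the detection-performance
  checks use the full default footprint, where the attenuation is part of
  the realism.
* the linear shape is a stand-in. The underlying biology constrains only
  the *sign* of the shift, not its shape; any monotone 5' depletion gives
  a positive slope (a property the tests assert on constructed
  stochastically-ordered profile pairs), so the statistic does not depend
  on the linearity assumption, only the closed-form expectation does.

Determinism is structural: transcript structure is drawn under
`set.seed(seed)`, and sample `j` (in the fixed phase × condition ×
replicate enumeration) under `set.seed((seed + j) %% 2^31-1)`, so adding a
replicate or sample never perturbs the data of existing ones, and an
identical configuration reproduces every file byte for byte.

Defaults (chosen once, as the simulated counterpart of the study
conditions): 500 transcripts of 300–3000 nt, 2 replicates, read footprint
76 nt (a typical single-end short-read length; fragment-size geometry is
not modeled), mean depth 1000 reads/transcript/sample (pooled ≥ 2000 per
condition), `abundance_sigma` 0.8, dispersion 0.05, 10% targets with
`d = 0.6` and `target_log2fc = 2`.

What the generator does **not** emulate: sequencing error, GC and
positional bias, paired-end geometry, multi-mapping, operonic
co-transcription, non-linear decay profiles, or between-phase abundance
changes. Passing tests therefore demonstrate that the statistics recover
the planted signal under clean NB noise — not that they are robust to
every artifact of a real library.

## The differential-abundance stage

The two-condition NB test is authored in the package in the classic
small-replicate style:

* **Size factors** are the median, over transcripts with nonzero counts
  in every sample, of the ratio of each sample's count to the
  transcript's geometric mean (with a per-sample positive-row fallback
  when no such transcript exists). The natural-scale median is used, and
  agrees with the standard Bioconductor implementation whenever the
  eligible row count is odd.
* **Dispersion** is estimated per transcript by pooled method of moments
  across conditions on normalized counts (subtracting the size-factor
  shot-noise term), then moderated by a parametric trend
  `alpha(mu) = a0 + a1/mu` fitted by least squares across transcripts.
  The final estimate is the **maximum** of the per-transcript estimate
  and the trend, floored at 1e-8. With two replicates the per-transcript
  estimate has roughly two residual degrees of freedom; averaging it with
  the trend leaves enough downward noise to make the test measurably
  anticonservative (empirical type-I ≈ 0.08 at nominal 0.05 in the null
  simulations), whereas the conservative maximum — the rule classically
  used at low replication — restores calibration (≈ 0.03–0.04). That
  measurement, reproduced by the null-calibration acceptance test, is why
  the maximum was adopted.
* **The p-value** conditions on the per-transcript total: the summed
  counts of the two conditions are modeled as NB with matched mean and
  variance, every split of the observed total is enumerated, and the
  probabilities of splits no more likely than the observed one are
  summed. Transcripts with zero counts everywhere are excluded and
  reported `NA`.
* **log2 fold change** (mutant over wild type) adds a pseudocount of 0.5
  normalized counts to numerator and denominator — reporting only, never
  testing — so zeros produce finite, shrunken estimates.

Exact numerical agreement with any particular historical DESeq release is
a non-goal; the published analysis this stage mirrors cannot be reproduced
at desk scale anyway, as it depends on the original accession data and
mapper.

## Validation sizes and numerical choices

The shipped tests and the acceptance script use these problem sizes,
chosen to make the statistical assertions sharp at interactive runtimes:

* invariant sweep: 1050 simulated transcripts (≥ 1000 scored curves),
  sum-to-zero and intercept identity at 1e-9;
* slope oracle: noiseless agreement with `expected_slope(d)` for
  `d ∈ {0.1, 0.3, 0.5, 0.8}`, plus 225 simulated targets at pooled depth
  2000 and `d = 0.5`, mean slope within 3 standard errors of 1/150;
* null calibration: 2000 transcripts, `d = 0`, `log2fc = 0`, mean depth
  200; type-I error at nominal 0.05 within [0.03, 0.07] and end-to-end
  candidate rate ≤ 5% (with both cutoffs at mean + 1 SD, two independent
  one-sided ~16% filters intersect at roughly 2–3%);
* recovery: the default configuration (above) at a fixed seed;
  sensitivity ≥ 0.7 and precision ≥ 0.8 against the truth table — in
  practice both reach 1.0 at these settings, as the planted effects are
  several background SDs above the cutoffs;
* oracle equivalence: 100 random fixtures per operation against
  brute-force reimplementations (size factors, BH step-up, binning,
  selection) at 1e-12.

Remaining numerical conventions: ties at the selection cutoffs are
included (`>=`); a degenerate background with all slopes equal makes the
slope SD zero and `slope > 0` alone decides; `r2` of the slope fit is
reported as a diagnostic but never used for selection; all result tables
are written with fixed columns and deterministic ordering so that
identical runs are byte-identical.

## Known limitations

* The linear-depletion generator is a modeling convenience; real decay
  intermediates need not deplete linearly, and the closed-form slope is
  specific to that shape (the sign is not).
* Pooling replicates before binning discards replicate-level variance of
  the *shape*; the slope statistic carries no per-transcript uncertainty
  and is interpreted only relative to its background distribution.
* The mean + SD rule adapts to whatever background it is given; on a
  dataset where many transcripts are genuinely shifted, the cutoffs rise
  and sensitivity falls — a property inherited from the original rule,
  not a bug.
* Reads are treated as single unspliced intervals, appropriate for
  archaeal and bacterial transcriptomes; spliced alignments, multi-mapper
  weighting and transcript isoforms are out of scope.
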