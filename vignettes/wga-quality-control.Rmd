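---
title: "Assessing whole-genome-amplification quality with wgaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing whole-genome-amplification quality with wgaqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgaqc)
```

## The problem

Whole genome amplification (WGA) — in particular multiple displacement
amplification (MDA) with φ29-family polymerases — makes it possible to
sequence samples that contain only picograms or femtograms of DNA. Two
failure modes dominate. First, amplification is uneven: some genomic
regions are amplified far more than others, so sequencing coverage is
biased and parts of the genome drop out. Second, reagents and consumables
carry contaminating DNA that, at very low template inputs, can out-compete
the template and dominate the sequenced reads. `wgaqc` quantifies both
failure modes from the standard text outputs of an amplify-and-sequence
experiment: per-base depth tracks, BLAST tabular hit tables, and qPCR
Cq tables.

## Coverage binning, breadth and balance

A depth track (`depth_track`) holds one read-depth value per reference
position. `bin_depth()` tiles the (single, linear) contig with half-open
`[start, end)` windows of `bin_size` bases — 500 bp by default, a
resolution fine enough to see MDA bias but coarse enough to average out
read-placement noise — and retains a terminal partial bin, averaging over
its actual width so the width-weighted bin means always reproduce the
genome mean exactly. Each bin's mean depth is divided by the genome-wide
mean depth (total sequenced bases / genome length); these *normalized*
depths are the unit of all downstream evenness statistics, which removes
differences in total sequencing effort between samples.

`breadth()` reports the percent of positions at or above each depth cutoff
(the familiar "% of genome at ≥1X / ≥5X"). `balance()` compares two
identically binned samples: for each bin where both normalized depths are
positive it reports the fold variation `max(a,b)/min(a,b)` (always ≥ 1)
and the signed `log2(a/b)` ratio, then summarizes the mean and SD of the
fold variation and the percent of bins within 2-fold and 4-fold. Bins with
a zero on either side are excluded from ratio statistics rather than
pseudo-counted — a pseudo-count would introduce an arbitrary constant into
a ratio scale — and their count is reported so the exclusion is visible.

```{r balance}
t1 <- simulate_depth(sim_config(seed = 1, genome_length = 2e5,
                                mean_depth = 64, bias_sigma = 0))
t2 <- simulate_depth(sim_config(seed = 2, genome_length = 2e5,
                                mean_depth = 64, bias_sigma = 0))
breadth(t1)
balance(bin_depth(t1, 500), bin_depth(t2, 500))
```

At 64X Poisson coverage over 500-bp bins the coefficient of variation of a
bin mean is about `1/sqrt(500 * 64)` ≈ 0.6%, so two unbiased replicates
should agree within 2-fold in essentially every bin — which is what the
example shows, and what the test suite asserts as the unbiased baseline.

## Lorenz curves and the Gini coefficient

`lorenz_curve()` sorts bins by ascending mean depth (ties broken by
genomic position, so the curve is deterministic) and plots the cumulative
share of total coverage against the cumulative share of bins. Perfectly
even coverage follows the diagonal; the further the curve sags below it,
the more of the coverage is concentrated in few bins. The Gini coefficient
is twice the area between the diagonal and the curve, computed by the
trapezoid rule; on equally weighted bins this is algebraically identical
to the mean-absolute-difference form `G = Σ|xᵢ−xⱼ| / (2n²μ)`, and the test
suite checks the two routes agree to 1e-9.

Samples sequenced to different depths are not directly comparable —
Poisson noise alone inflates the Gini of the shallower sample — so
`downsample_to_depth()` thins each position's depth with a
`Binomial(depth, p)` draw to a matched target mean before the comparison.
At depth-track resolution this is statistically equivalent to randomly
subsampling reads, and it needs no access to the alignments.

```{r lorenz}
biased <- simulate_depth(sim_config(seed = 3, genome_length = 2e5,
                                    mean_depth = 64, bias_sigma = 1))
matched <- downsample_to_depth(biased, 50, seed = 3)
lorenz_curve(bin_depth(matched, 500))
lorenz_curve(bin_depth(downsample_to_depth(t1, 50, seed = 3), 500))
```

## Weighted-vote read classification

Metagenomic hit tables (BLAST `outfmt 6`, with subjects resolved to
species through a two-column map) are classified read by read. Reads
shorter than `min_length` (default 100 bases) are removed, as are hits
with e-value above `max_evalue` (default 1e-10); a read survives only if
at least one hit survives.

Each surviving read then carries exactly one vote. The vote is split
equally, `1/k`, over the `k` distinct species in the read's hit set, so a
read whose sequence is shared across many species contributes little to
any one of them, while a species-specific read contributes a full vote.
We chose the equal split as the default because it is the minimal scheme
that down-weights shared sequence while conserving the vote total exactly
(`Σ votes = number of reads`, an invariant the tests enforce); a
score-proportional split (`weight_by = "score"`) is available for users
who want alignment quality to influence the partition. Multiple hits to
the same species count once per read, so redundancy among reference
entries cannot inflate a species. After weighting, votes are collapsed
through a clade map — by default the *Bacillus cereus* group
(*B. cereus*, *B. thuringiensis*, *B. anthracis*) reports as
*B. cereus* and *Escherichia*/*Shigella* as *E. coli*, since short reads
cannot distinguish within these groups — and converted to percent of
total votes.

```{r classify}
sim <- simulate_hits(sim_config(seed = 4,
                                composition = c("Bacillus thuringiensis" = 0.8,
                                                "Ralstonia pickettii" = 0.2),
                                ambiguity_rate = 0.1), 5000)
kept <- filter_reads(sim$hits, min_length = 100, max_evalue = 1e-10)
tally(kept$hits, n_reads_filtered = kept$n_dropped)
```

`relative_sensitivity()` compares the same species' vote percentage
between two classifications — e.g. two amplification chemistries run on
the same dilute template — as a fold ratio, optionally rounded to a given
number of significant figures; a zero denominator is flagged as infinite
rather than returned as a number.

## qPCR quantitation and decontamination bounds

`fit_standard_curve()` is ordinary least squares of Cq on
log10(quantity); the amplification efficiency follows from the slope as
`E = 10^(−1/slope) − 1` (a perfect assay doubles template per cycle:
slope −3.3219, E = 100%). `quantify()` inverts the line and censors
results below the assay's limit of detection (LOD), including wells that
never amplified.

Decontamination experiments typically drive treated replicates below the
LOD, so the true fold reduction is only bounded from below:
`fold_reduction()` divides the untreated mass by the LOD and flags the
result as a lower bound. Because "the untreated mass" can reasonably mean
either the replicate mean or the most conservative minimum, both bounds
are reported. If some treated replicates did amplify, their observed
masses enter the denominator and censored replicates contribute their LOD
(the largest mass consistent with censoring, keeping the result a lower
bound whenever any censoring remains). Mixing LODs across treated
replicates is rejected: a bound is only meaningful within one assay.

```{r decontam}
treated <- quant_result(rep(NA_real_, 15), lod = 0.350)
fold_reduction(parse_mass("21 ng"), treated)
amplification_metrics(input_mass = 1,
                      template_yield = parse_mass("37 ng"),
                      total_yield = parse_mass("10.9 ug"))
```

All masses are handled in picograms internally; `parse_mass()` converts
fg/pg/ng/µg-suffixed inputs at the I/O boundary.

## The synthetic-data generator

Real WGA validation data are large and tied to specific instruments, so
`wgaqc` ships a generator that emulates the three data types the pipeline
consumes, with known ground truth:

* **Depth tracks** (`simulate_depth()`): one multiplicative amplification
  bias factor per 500-bp window, drawn lognormal with
  `meanlog = −σ²/2` so the expected bias is exactly 1 and the realized
  genome mean converges to `mean_depth`; per-base depths are then
  Poisson. Bias is piecewise-constant at bin granularity — the same
  granularity at which the analysis operates — rather than per-base,
  which is cheap and matches what the analysis can resolve. No published
  generative model for MDA bias exists, so the lognormal scale σ is a
  free knob: σ = 0 is the unbiased (pure Poisson) control and the default
  σ = 1 produces the strong, visible skew characteristic of MDA from
  minute inputs.
* **Hit tables** (`simulate_hits()`): each read's true species is drawn
  from the configured composition; with probability `ambiguity_rate` the
  hit set gains one or more other species drawn uniformly. Ambiguous
  hits receive e-values from the *same* passing distribution as true hits
  (log-uniform between 1e-50 and 1e-10), deliberately leaving no e-value
  signal, so recovering the composition must come from the vote
  weighting.
* **qPCR series** (`simulate_qpcr()`): Cq values under the log-linear
  efficiency model with optional Gaussian Cq noise, for round-trip tests
  of the curve fit.

All generator randomness flows from the seed in `sim_config()`; identical
configurations give bit-identical output, and the generator restores the
caller's RNG state.

What the generator does **not** emulate: GC-dependent bias, chimeric
reads, per-base sequencing error, multi-contig references, and real
taxonomic structure beyond the configured species list. Tests passing on
synthetic data therefore demonstrate that the statistics and their
invariants are computed correctly, not that any particular laboratory
protocol is unbiased.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based appears only at
  the samtools-depth I/O boundary.
* The Lorenz sort breaks depth ties by genomic position, making curves
  and Gini values deterministic.
* An all-zero track has no Lorenz curve (the share of total coverage is
  undefined) and raises an error rather than returning NaN.
* `downsample_to_depth()` with a target equal to the current mean returns
  the input unchanged (thinning probability 1 draws no randomness).
* Reported problem sizes in the examples and tests (1-Mb genomes, 1e4
  reads, 2000 bins) are large enough for the binomial/Poisson
  concentration arguments used in the assertions — e.g. 3 multinomial
  SDs for composition recovery — while keeping examples instant.
* The pipeline writes no timestamps, so a run is byte-identical given
  the same configuration and seed.

## Limitations

Single linear chromosome only; no GC-bias regression, segmentation or
CNV calling; no BAM parsing (depth extraction with `samtools depth` is
upstream); no live taxonomy lookups (species resolution is delegated to
the user-supplied subject→species map); no confidence intervals on Gini
or balance statistics.
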