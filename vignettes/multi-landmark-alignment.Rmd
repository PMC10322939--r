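---
title: "Multi-landmark alignment: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-landmark alignment: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagene2d)
library(dplyr)
```

## The model

A base-resolution genomic signal `g(z)` — RNA-seq coverage, RAMPAGE,
DNase-seq, ChIP-seq — is aligned simultaneously to two ordered landmarks,
an upstream TSS at `z_U` and a downstream TSS at `z_D`, by expanding the
genomic coordinate into relative coordinates `x = z - z_U` and
`y = z - z_D`. Each landmark pair contributes its signal along the line
`y = x + z_U - z_D`; the Kronecker delta `delta(y, x + z_U - z_D)` encodes
this constraint, and a set of pairs with different separations fills a
two-dimensional region of the plane. All coordinates are
transcription-oriented: for a minus-strand gene, increasing `x` means
decreasing genomic coordinate, and the signal is read from the
minus-strand track when the assay is stranded.

Two estimators are built on this expansion:

* the **rectangular region average** `R_V[(x0,y0),(x1,y1)]`, the mean of
  `g` over all (pair, base) terms whose relative coordinates fall in the
  inclusive rectangle. Collapsing the delta constraint turns the double
  sum into a per-pair interval sum over
  `x = max(x0, y0 - z_U + z_D) .. min(x1, y1 - z_U + z_D)`, with the
  normalization `N` counting the contributing terms, so a genome-wide
  sweep is linear in the signal retrieved. The average is **defined** only
  when some pair satisfies `y0 - x1 <= z_U - z_D <= y1 - x0`; an undefined
  average is an ordinary result carrying `defined = FALSE`, because
  rectangles incompatible with every pair separation are expected and
  informative.
* the **signal density** `G(x,y)`, the region average over a moving window
  centered at `(x, y)` with half-widths `n_X`, `n_Y`.

The package keeps a literal brute-force evaluation of the double sum
(`region_average_bruteforce()`) purely as a testing oracle; the efficient
path must agree with it to within floating-point error, and the test suite
and acceptance script verify this on randomized instances.

The extension to three landmarks (`region_average_3d()`) adds a second
constraint `v = x + z_U - z_F` and averages over an inclusive box. No
efficiency derivation beyond interval intersection is provided; triple
analysis is exploratory.

## Parameters that matter

**Window half-widths.** `n_X = 99` bp for `-500 <= x <= 1000`,
`n_X = floor(x/4)` for `1000 < x <= 20000`, and symmetrically `n_Y = 99`
for `|y| <= 1000`, `n_Y = floor(-y/4)` for `-20000 <= y < -1000`. The
constant 99 bp window resolves promoter-scale structure; the proportional
growth keeps the relative smoothing scale constant in the distal zones,
where the density of contributing pairs thins out. The `floor` in `x/4`
is our reading of the rule as an integral half-width. Points outside
`-500 <= x <= 20000`, `-20000 <= y <= 1000` are an error: the window
rules are simply not specified elsewhere.

**Grid spacing.** Evaluation points default to 25 bp spacing in the
constant-window zone and half the local half-width beyond
(`grid_points()`). The underlying analysis defines densities pointwise,
so any grid is valid; this default resolves the 99 bp windows without
oversampling the distal smoothed zones.

**Canonical regions.** The seven rectangles (in bp, inclusive):
`A = [0,200] x [-20k,-10k]`, `Af = [300,1k] x [-20k,-10k]`,
`B = [0,200] x [-900,-200]`, `Bf = [300,1k] x [-900,-200]`,
`C = [0,200] x [0,200]`, `D = [300,1k] x [0,200]`,
`E = [10k,20k] x [0,200]`. A, Af, B, Bf measure the upstream TSS with the
downstream TSS distal or at intermediate distance; C, D, E measure the
downstream TSS with the upstream TSS proximal, intermediate, or distal.

**Derived metrics.** Eight log2 ratios of region averages (see
`metrics_panel()`). Seven follow the published definitions; *persistence
dominance* is stated in the source analyses only by name, as the
comparison of the two persistences, so this package defines it explicitly
as `log2((T_Bf/T_B)/(T_Af/T_A))`. This is flagged here because it is an
interpretation, although the only natural one: it is the difference of
the two persistence metrics listed alongside it.

**Normalization.** Tracks are divided by their genome-wide mean over all
whitelisted bases, including uncovered ones (absence in a coverage-style
track means zero, and "whole genome" is read literally). A
`covered_only` switch computes the mean over non-zero bases instead, for
tracks where absence means missing rather than zero. Stranded assays
normalize each strand's track by its own mean, since they are separate
files with separate sequencing depths. All derived metrics are ratios, so
they are invariant to normalization and to any rescaling of a track — a
property the acceptance tests check to 1e-9.

**Stratification.** Two schemes are provided. Gene-level: abundances at or
below a floor (default 0) form the "zero" stratum, and expressed genes
split into equal-count quantile bands (default five: low … high). Pair
level: each pair is ranked by its own single-pair region-C average and
split into quintiles (`stratify_pairs_by_region()`), which conditions on
local transcriptional output rather than whole-gene abundance. The scheme
is a configuration choice because the two answer different questions.

## Numerical and boundary choices

* Rectangle bounds are inclusive on all four edges, matching the defining
  sums.
* Windows that extend past a chromosome end draw zero-signal bases that
  still count in `N`. This keeps a genome-wide sweep total-count
  consistent and is the same convention as treating uncovered bases as
  zero; `boundary_reads()` exposes how often it happened. The alternative
  (excluding out-of-range bases from `N`) would make cell values near
  contig edges incomparable across cells.
* Duplicate TSS positions shared by transcripts of a gene are collapsed
  before ranking (configurable). A retained duplicate would create a pair
  with `z_U == z_D`, which makes `x` and `y` identical and double-counts
  signal; no such pair can occur after collapsing.
* TSS enumeration is in transcription orientation — "most upstream" is
  the largest coordinate on the minus strand — because the
  upstream/downstream semantics of the canonical regions are
  transcription-relative and the signal tracks are strand-specific.
* Genes are treated independently even when they overlap on opposite
  strands; stranded signal keeps their contributions separate, and
  unstranded assays genuinely mix them, which no pairing convention can
  undo.
* Spearman correlation uses average ranks for ties (the `stats::cor`
  default), and the concordance gate warns rather than aborts: the gate
  exists to select experiments, which is upstream of the computation
  itself.
* Pair-index summaries average the log2 metric across pair indices 3..10
  with equal weight per index (absences dropped, contributing counts
  reported). Pooling the pairs before computing `T` values is available
  by passing a combined pair set to `metrics_panel()`; per-index averaging
  is the default because it weights each positional class equally rather
  than by pair abundance.

## What the synthetic generator emulates

`synth_config()` builds a small genome of non-overlapping genes on both
strands, each with 1–6 TSSs (configurable counts and spacings). Every TSS
initiates at a base rate and contributes signal decaying exponentially
downstream over `decay_length`; the track is the additive sum of
contributions, as coverage is a sum over initiation events. Two planted
interactions mirror the phenomena the metrics are designed to measure: a
suppression factor `s` on a TSS whose next TSS lies within a distance
window, and a cooperativity factor `q` on a TSS whose previous TSS is
proximal. Per-gene log-normal noise (`noise_sigma`, default 0.25) models
biological and technical variability; replicates share structure and
differ in the noise draw. The default scale (300 genes, ~one minute for
the full pipeline) keeps simulation studies cheap.

What it does **not** emulate: splicing and exon structure, 5' capture
chemistry, fragment-size effects, mappability gaps, overlapping genes, or
expression correlations between neighboring genes. Passing tests
therefore demonstrate that the estimators recover planted positional
interactions from additive, exponentially decaying, noisy coverage — not
that any particular biological effect exists in real data.

## The planted-effect study scenarios

`synth_scenario()` fixes four configurations used by the acceptance
tests, each with 300 two-TSS genes whose spacing is drawn half from a
proximal/intermediate class and half from a distal class, so the
numerator and denominator regions of the tested metric are both
populated within one genome:

* **Suppression** (`s = 0.25`, window [200, 900] bp): spacings in
  [400, 900] versus [10200, 19800]. These bounds make the per-pair
  x-interval of regions A and B the full [0, 200] for every pair, so the
  B/A ratio estimates `s` with no window-truncation bias, and with a
  2 kb decay length the downstream TSS's own signal cannot reach region
  B. Expected upstream effects: `log2 0.25 = -2`.
* **Cooperativity** (`q = 4` within 200 bp): spacings in [50, 200] versus
  [10200, 19800], upstream TSS silent (`rate_by_rank = c(0, 1)`), decay
  length 20 kb. Two deliberate choices isolate the planted factor. With
  additive coverage, read-through from an expressed upstream TSS would
  contaminate region C (at 50–200 bp the decayed upstream signal is
  comparable to the downstream pulse), inflating the measured ratio by
  several tenths of a log2 unit; a silent first TSS removes this, and is
  itself a documented feature of highly transcribed genes, whose first
  annotated TSS often shows no signal. The long decay makes the profile
  nearly flat across the 200 bp measurement windows, so the slightly
  different per-pair window shapes of regions C and E (C's x-interval is
  [d, 200]) contribute a bias below 0.01 log2 units. Expected proximal
  cooperativity: `log2 4 = +2`.
* **Null runs** of both geometries (`s = q = 1`), expected 0.

Recovery is asserted as the mean over 20 independent genomes lying within
three standard errors of the planted log2 value. With the default noise,
the per-genome standard deviation is about 0.04 log2 units, so the
assertion tests the estimators to roughly ±0.03.

## Problem sizes

The test suite and acceptance script run entirely on generated data: 100
randomized oracle instances (signals up to 5 kb, up to 20 pairs), 20
simulated genomes of 300 genes per scenario (genomes of 6–13 Mb), and
small fixture genomes for the I/O and pipeline tests. These sizes give
stable estimates (standard errors well under the asserted tolerances)
while keeping a full run to a few minutes.

## Known limitations

* `region_average()` holds per-chromosome signal vectors in memory
  (~8 bytes/base/track); human-genome tracks fit comfortably, but many
  tracks at once may not.
* The density grid evaluates cells independently; it does not exploit
  overlap between neighboring windows, which a future sliding
  implementation could.
* Undefined and non-positive region averages propagate as absent metrics
  with reason codes rather than pseudocounts. On small pair sets this is
  the honest choice, but it means downstream averages (e.g. the
  pair-index summary) are over defined cases only, and their `n` must be
  read alongside the value.
* The concordance gate and stratification consume externally computed
  gene quantifications; the package performs no expression estimation.
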