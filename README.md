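# metagene2d

Two-dimensional metagene alignment of genomic signals to pairs of
transcription start sites (TSSs).

## The problem

The standard metagene profile aligns a base-resolution signal track
(RNA-seq or RAMPAGE coverage, DNase-seq, ChIP-seq) to a single landmark and
averages across loci. That one-dimensional view masks how a signal depends
on the *joint* arrangement of several DNA elements — for instance, how
transcription at one TSS of a gene changes with the distance to the gene's
next TSS. Most human protein-coding genes have several alternative TSSs, so
this interdependence is a genome-wide phenomenon, not an edge case.

`metagene2d` aligns a signal to *pairs* of landmarks simultaneously. Every
genomic position `z` is expanded into relative coordinates

```
x = z - z_U      (offset from the upstream TSS)
y = z - z_D      (offset from the downstream TSS)
```

which places the signal `g(z)` on the line `y = x + z_U - z_D` of the
`(x, y)` plane; different pairs contribute different lines, and together
they fill a two-dimensional density. The package is for regulatory
genomicists and transcriptomicists who want to quantify neighbor-TSS
effects (or any multi-landmark geometry) from standard signal tracks.

## The core quantities

* **Region average** `R_V[(x0,y0),(x1,y1)]`: the mean of
  `g(x + z_U) * delta(y, x + z_U - z_D)` over an inclusive rectangle and a
  pair set `V`, computed efficiently as a per-pair interval sum with the
  normalization `N` counting contributing (pair, base) terms. The average
  is *defined* only if some pair satisfies
  `y0 - x1 <= z_U - z_D <= y1 - x0`.
* **Signal density** `G(x,y) = R_V[(x-n_X, y-n_Y), (x+n_X, y+n_Y)]` with
  adaptive half-widths (`n_X = 99` near the TSS, `x/4` beyond 1 kb, and
  symmetrically for `y`).
* **Seven canonical regions** `T_A, T_Af, T_B, T_Bf, T_C, T_D, T_E` and the
  derived log2 metrics: proximal cooperativity `T_C/T_E`, upstream effects
  `T_B/T_A`, downstream effects `T_D/T_E`, positional dominance `T_E/T_A`,
  persistence with a distal / non-distal downstream TSS `T_Af/T_A` /
  `T_Bf/T_B`, signal dominance `T_Bf/T_Af`, and persistence dominance
  `(T_Bf/T_B)/(T_Af/T_A)`.
* **Replicate statistics**: per metric, the replicate mean
  `(log2 m1 + log2 m2)/2` and replicate noise `(log2 m1 - log2 m2)/2`, plus
  a Spearman (> 0.8) concordance gate between replicate gene
  quantifications.

A synthetic-genome generator with planted suppression and cooperativity
effects makes the whole pipeline testable without external downloads.

## Worked example

```r
library(metagene2d)

# a synthetic genome with a planted suppression effect: a downstream TSS
# within 200-900 bp quarters the initiation of its upstream neighbor
cfg <- synth_scenario("suppression", seed = 1)
ann <- generate_annotation(cfg)
sig <- normalize_genomewide(generate_signal(ann, cfg))

pairs <- consecutive_pairs(ann$tss, pair_index = 1)
panel <- metrics_panel(pairs, sig)
tidy(panel)
#> # A tibble: 8 x 5
#>   metric                 log2_ratio reason      pair_index stratum
#>   <chr>                       <dbl> <chr>            <int> <chr>
#> 1 proximal_cooperativity  NA        undefined_T          1 <NA>
#> 2 upstream_effects        -2.01e+ 0 <NA>                 1 <NA>
#> 3 downstream_effects       2.39e- 1 <NA>                 1 <NA>
#> 4 positional_dominance     1.41e-14 <NA>                 1 <NA>
#> 5 persistence_distal      -3.87e- 1 <NA>                 1 <NA>
#> 6 persistence_nondistal   -2.60e- 1 <NA>                 1 <NA>
#> 7 signal_dominance        -1.88e+ 0 <NA>                 1 <NA>
#> 8 persistence_dominance    1.27e- 1 <NA>                 1 <NA>
```

The planted factor of 0.25 is recovered as upstream effects near
`log2 0.25 = -2` (here -2.01 for one simulated genome; the mean over 20
genomes is -2.006). Positional dominance is exactly zero because both
distal TSSs initiate at the same rate in this scenario. Proximal
cooperativity is absent with a reason code: the scenario plants no TSS
pairs closer than 400 bp, so region C is never populated — absences are
data, not errors. `glance(panel)` returns the seven `T` values;
`autoplot(panel)` draws the metric bars; and

```r
grid <- density_grid(pairs, sig)
autoplot(grid)
```

renders the two-dimensional density with its adaptive smoothing windows.
On real data, start from `run_config()` / `run_metrics()` /
`run_density()`, which orchestrate GTF parsing, track normalization,
activity stratification, and the output tables
(see `inst/cli/metagene2d.R` for the shell entry point).

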