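Package: metagene2d
Title: Two-Dimensional Metagene Alignment of Genomic Signals to Pairs of
    Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns base-resolution genomic signal tracks (RNA-seq, RAMPAGE,
    DNase-seq, ChIP-seq coverage) simultaneously to pairs of genomic landmarks
    by expanding the genomic coordinate into relative coordinates from an
    upstream and a downstream transcription start site (TSS). Provides the
    efficient rectangular region average over pair sets with its normalization
    count, adaptive sliding-window two-dimensional signal densities, the seven
    canonical region averages used to quantify TSS interdependence, and the
    derived log2 metrics (proximal cooperativity, upstream and downstream
    effects, positional dominance, persistence, signal and persistence
    dominance) with replicate mean and noise statistics. Includes a synthetic
    genome and signal generator with planted TSS-interaction effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
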