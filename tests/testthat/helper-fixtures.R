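# Shared fixture builders. Signal values are dyadic rationals (multiples of
# 1/256) so sums are exact in double precision regardless of accumulation
# order, making "exact" comparisons meaningful.

dyadic_values <- function(n) {
  round(stats::runif(n) * 1023) / 256
}

toy_signal <- function(..., chrom = "chr1") {
  v <- c(...)
  genomic_signal(stats::setNames(list(as.numeric(v)), chrom))
}

random_signal <- function(len, chrom = "chr1") {
  genomic_signal(stats::setNames(list(dyadic_values(len)), chrom))
}

random_stranded <- function(len, chrom = "chr1") {
  stranded_signal(random_signal(len, chrom), random_signal(len, chrom))
}

# Random small instance for the oracle-equivalence properties: a signal of
# length <= 5 kb, <= 20 oriented pairs on mixed strands, and a random
# rectangle small enough for the literal double sum.
random_instance <- function() {
  len <- sample(2000:5000, 1)
  n_pairs <- sample(1:20, 1)
  z_U <- sample(200:(len - 200), n_pairs, replace = TRUE)
  d <- sample(1:1500, n_pairs, replace = TRUE)
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  pairs <- tibble::tibble(
    chrom = "chr1", strand = strand, z_U = z_U,
    z_D = ifelse(strand == "+", z_U + d, z_U - d)
  )
  x0 <- sample(-300:300, 1); y0 <- sample(-300:300, 1)
  region <- region_spec(x0, y0, x0 + sample(0:150, 1), y0 + sample(0:150, 1))
  signal <- if (stats::runif(1) < 0.5) {
    random_signal(len)
  } else {
    random_stranded(len)
  }
  list(signal = signal, pairs = pairs, region = region)
}

# A small GTF written from a transcript table (1-based starts/ends).
write_test_gtf <- function(tx, path = withr::local_tempfile(fileext = ".gtf",
                                                            .local_envir = parent.frame())) {
  lines <- sprintf(
    "%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_type \"%s\";",
    tx$chrom, tx$start, tx$end, tx$strand, tx$gene_id, tx$transcript_id,
    tx$gene_type)
  writeLines(lines, path)
  path
}

# Construct a metrics_panel object directly from named log2 metric values
# (for summary/replicate plumbing tests).
make_panel <- function(log2_values, pair_index = 1L, stratum = "high") {
  defs <- metagene2d:::derived_metric_defs()
  derived <- tibble::tibble(
    metric = defs$metric,
    log2_ratio = unname(log2_values[defs$metric]),
    reason = unname(ifelse(is.na(log2_values[defs$metric]), "undefined_T",
                           NA_character_))
  )
  structure(list(regions = NULL, derived = derived, pair_index = pair_index,
                 stratum = stratum, n_pairs = 1L),
            class = "metrics_panel")
}
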