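#' Construct a genomic signal from per-chromosome value vectors
#'
#' A `genomic_signal` holds a base-resolution, non-negative signal value for
#' every base of every chromosome. Position 0 of a chromosome maps to index 1
#' of its vector. Bases with no data carry 0. Strand-specific assays are
#' represented by [stranded_signal()], which bundles one `genomic_signal` per
#' strand.
#'
#' @param values Named list of numeric vectors, one per chromosome, at 1 bp
#'   resolution.
#' @param normalized Logical; whether the values have been divided by the
#'   genome-wide mean.
#' @param genome_mean Pre-normalization genome-wide mean (NA until
#'   [normalize_genomewide()] is applied).
#' @return An object of class `genomic_signal`.
#' @export
genomic_signal <- function(values, normalized = FALSE, genome_mean = NA_real_) {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)))
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.numeric(v)) stop("chromosome ", nm, ": values must be numeric")
    if (anyNA(v)) stop("chromosome ", nm, ": values must be finite (missing = 0)")
    if (any(v < 0)) stop("chromosome ", nm, ": negative signal values")
  }
  structure(
    list(values = values, normalized = normalized, genome_mean = genome_mean,
         cache = new.env(parent = emptyenv())),
    class = "genomic_signal"
  )
}

#' @export
print.genomic_signal <- function(x, ...) {
  sizes <- vapply(x$values, length, integer(1))
  cat("<genomic_signal> ", length(sizes), " chromosome(s), ",
      format(sum(sizes), big.mark = ","), " bases",
      if (isTRUE(x$normalized)) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' Bundle plus- and minus-strand signal tracks
#'
#' Stranded assays (e.g. strand-specific RNA-seq, RAMPAGE) report separate
#' tracks per strand; unstranded assays (DNase-seq, ChIP-seq) use a single
#' [genomic_signal()] for both strands.
#'
#' @param plus,minus `genomic_signal` objects for the plus and minus strands.
#' @return An object of class `stranded_signal`.
#' @export
stranded_signal <- function(plus, minus) {
  stopifnot(inherits(plus, "genomic_signal"), inherits(minus, "genomic_signal"))
  structure(list(plus = plus, minus = minus), class = "stranded_signal")
}

#' @export
print.stranded_signal <- function(x, ...) {
  cat("<stranded_signal>\n  [+] "); print(x$plus)
  cat("  [-] "); print(x$minus)
  invisible(x)
}

# Select the track serving a given strand.
track_for_strand <- function(signal, strand) {
  if (inherits(signal, "stranded_signal")) {
    if (strand == "+") signal$plus else signal$minus
  } else {
    signal
  }
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path Path to a chrom.sizes file (chromosome name, length in bp).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tbl$size, tbl$chrom)
}

# Resolve chromosome-name dialect ("chr1" vs "1") between a track and the
# whitelist; returns a map from track names to whitelist names.
match_chrom_names <- function(track_chroms, whitelist) {
  strip <- function(x) sub("^chr", "", x)
  map <- character(0)
  for (tc in track_chroms) {
    hit <- whitelist[whitelist == tc]
    if (length(hit) == 0) hit <- whitelist[strip(whitelist) == strip(tc)]
    if (length(hit) >= 1) map[[tc]] <- hit[[1]]
  }
  map
}

#' Load a base-resolution signal track
#'
#' Reads a bedGraph or bigWig file into a [genomic_signal()]. Intervals are
#' 0-based half-open; bases not covered by any record are assigned 0.
#' Chromosome-name dialects ("chr1" vs "1") are reconciled against
#' `chrom_sizes`.
#'
#' @param path Path to a `.bedGraph`/`.bg` or `.bw`/`.bigWig` file.
#' @param chrom_sizes Named vector of chromosome lengths (the whitelist), or a
#'   path to a chrom.sizes TSV. For bigWig input it may be NULL, in which case
#'   the file's own sequence lengths are used.
#' @return A [genomic_signal()].
#' @export
load_signal <- function(path, chrom_sizes = NULL) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext,
    "bedgraph" = "bedGraph", "bg" = "bedGraph",
    "bw" = "BigWig", "bigwig" = "BigWig",
    stop("unknown signal track format: .", ext,
         " (expected bedGraph/bg or bw/bigWig)")
  )
  gr <- rtracklayer::import(path, format = fmt)
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (anyNA(sl)) stop("no chrom_sizes given and track carries no sequence lengths")
    chrom_sizes <- sl
  }
  cmap <- match_chrom_names(as.character(unique(GenomeInfoDb::seqnames(gr))),
                            names(chrom_sizes))
  if (length(cmap) == 0 && length(gr) > 0) {
    stop("no chromosome in ", path, " matches the whitelist")
  }
  values <- lapply(chrom_sizes, function(n) numeric(n))
  starts <- GenomicRanges::start(gr) - 1L  # back to 0-based
  ends <- GenomicRanges::end(gr)           # half-open end
  chroms <- as.character(GenomicRanges::seqnames(gr))
  score <- gr$score
  score[is.na(score)] <- 0
  if (any(score < 0)) stop("negative signal values in ", path)
  for (i in seq_along(gr)) {
    wc <- cmap[[chroms[i]]]
    if (is.null(wc)) next
    L <- chrom_sizes[[wc]]
    a <- max(0L, starts[i]); b <- min(L, ends[i])
    if (a < b) values[[wc]][(a + 1L):b] <- values[[wc]][(a + 1L):b] + score[i]
  }
  genomic_signal(values)
}

#' Normalize a signal by its genome-wide mean
#'
#' Divides every base's value by the mean over all whitelisted bases so that
#' the normalized track has genome-wide mean 1. By default the mean includes
#' uncovered (zero) bases.
#'
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param covered_only If TRUE, the mean is taken over bases with non-zero
#'   signal only.
#' @return The normalized signal, with `genome_mean` recording the divisor.
#'   Normalizing an already-normalized signal is a no-op.
#' @export
normalize_genomewide <- function(signal, covered_only = FALSE) {
  UseMethod("normalize_genomewide")
}

#' @export
normalize_genomewide.genomic_signal <- function(signal, covered_only = FALSE) {
  if (isTRUE(signal$normalized)) return(signal)
  total <- sum(vapply(signal$values, sum, numeric(1)))
  nb <- if (covered_only) {
    sum(vapply(signal$values, function(v) sum(v > 0), numeric(1)))
  } else {
    sum(vapply(signal$values, length, numeric(1)))
  }
  m <- total / nb
  if (!is.finite(m) || m <= 0) stop("genome-wide mean is zero; cannot normalize")
  genomic_signal(lapply(signal$values, function(v) v / m),
                 normalized = TRUE, genome_mean = m)
}

#' @export
normalize_genomewide.stranded_signal <- function(signal, covered_only = FALSE) {
  stranded_signal(normalize_genomewide(signal$plus, covered_only),
                  normalize_genomewide(signal$minus, covered_only))
}

# Cumulative sums per chromosome, cached in the object's environment so
# repeated region averages on the same signal are O(1) per interval.
chrom_cumsum <- function(sig, chrom) {
  key <- paste0("cs_", chrom)
  cs <- sig$cache[[key]]
  if (is.null(cs)) {
    v <- sig$values[[chrom]]
    if (is.null(v)) stop("unknown chromosome: ", chrom)
    cs <- c(0, cumsum(v))
    sig$cache[[key]] <- cs
  }
  cs
}

# Sum of signal over the inclusive 0-based genomic interval [a, b], with
# positions outside the chromosome contributing 0.
interval_sum <- function(sig, chrom, a, b) {
  if (b < a) return(0)
  cs <- chrom_cumsum(sig, chrom)
  L <- length(cs) - 1L
  a2 <- max(a, 0); b2 <- min(b, L - 1)
  if (a2 > b2) return(0)
  cs[[b2 + 2]] - cs[[a2 + 1]]
}

#' Strand-oriented signal access
#'
#' Returns the signal value at a transcription-oriented offset from an anchor:
#' `g(anchor + offset)` on the plus strand, `g(anchor - offset)` on the minus
#' strand. Offsets falling outside the chromosome return 0; such boundary
#' reads are counted (see [boundary_reads()]).
#'
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param anchor 0-based genomic position of the landmark.
#' @param offset Integer offset (vectorized); positive offsets point
#'   downstream in transcription orientation.
#' @return Numeric vector of signal values, one per offset.
#' @export
oriented_value <- function(signal, chrom, strand, anchor, offset) {
  trk <- track_for_strand(signal, strand)
  v <- trk$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  pos <- if (strand == "+") anchor + offset else anchor - offset
  out <- numeric(length(pos))
  inside <- pos >= 0 & pos < length(v)
  out[inside] <- v[pos[inside] + 1L]
  n_out <- sum(!inside)
  if (n_out > 0) {
    trk$cache$boundary_reads <- (trk$cache$boundary_reads %||% 0L) + n_out
  }
  out
}

#' Count of out-of-chromosome reads served as zero
#'
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @return Integer count of oriented accesses that fell outside a chromosome
#'   since the object was created.
#' @export
boundary_reads <- function(signal) {
  if (inherits(signal, "stranded_signal")) {
    return(boundary_reads(signal$plus) + boundary_reads(signal$minus))
  }
  as.integer(signal$cache$boundary_reads %||% 0L)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted. Output intervals are
#' 0-based half-open.
#'
#' @param signal A [genomic_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(signal$values)) {
    r <- rle(signal$values[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                       starts[keep], ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Write chromosome sizes of a signal to a chrom.sizes TSV
#'
#' @param signal A [genomic_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(signal, path) {
  sizes <- vapply(signal$values, length, integer(1))
  utils::write.table(data.frame(names(sizes), unname(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
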