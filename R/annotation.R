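#' Extract ordered TSS lists per gene from a GTF annotation
#'
#' Each transcript contributes its 5' end (the `start` field on the plus
#' strand, the `end` field on the minus strand), converted to 0-based
#' coordinates. Duplicate TSS positions shared by transcripts of a gene are
#' collapsed (configurable), and the unique TSSs are ranked in transcription
#' order: ascending genomic coordinate on the plus strand, descending on the
#' minus strand, so rank 1 is always the most upstream TSS.
#'
#' @param path Path to a GTF file (Gencode dialect: attributes `gene_id`,
#'   `transcript_id`, `gene_type`).
#' @param gene_type_filter Keep only genes of this `gene_type` (default
#'   `"protein_coding"`); NULL keeps all.
#' @param chrom_whitelist Optional character vector of chromosomes to keep
#'   (e.g. reference chromosomes only).
#' @param collapse_duplicates Collapse identical TSS positions within a gene
#'   (default TRUE).
#' @return A tibble with one row per TSS: `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss_rank` (1 = most upstream), `position` (0-based).
#' @export
extract_tss <- function(path, gene_type_filter = "protein_coding",
                        chrom_whitelist = NULL, collapse_duplicates = TRUE) {
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_tx <- md$type == "transcript"
  if (!any(is_tx)) stop("GTF contains no transcript records")
  tx <- tibble::tibble(
    gene_id = as.character(md$gene_id[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_tx]),
    strand = as.character(GenomicRanges::strand(gr)[is_tx]),
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx],
    gene_type = if ("gene_type" %in% names(md)) {
      as.character(md$gene_type[is_tx])
    } else NA_character_
  )
  if (any(!tx$strand %in% c("+", "-"))) {
    stop("transcript records without +/- strand")
  }
  if (!is.null(gene_type_filter)) {
    tx <- dplyr::filter(tx, .data$gene_type %in% gene_type_filter)
  }
  if (!is.null(chrom_whitelist)) {
    tx <- dplyr::filter(tx, .data$chrom %in% chrom_whitelist)
  }
  if (nrow(tx) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), tss_rank = integer(),
                          position = integer()))
  }
  # 5' end in 0-based coordinates: GTF start is 1-based inclusive.
  tx$position <- ifelse(tx$strand == "+", tx$start - 1L, tx$end - 1L)
  out <- tx |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$strand, .data$position,
                    .keep_all = FALSE)
  if (!collapse_duplicates) {
    out <- dplyr::select(tx, "gene_id", "chrom", "strand", "position")
  }
  out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(
      dplyr::if_else(.data$strand == "+", 1, -1) * .data$position,
      .by_group = TRUE
    ) |>
    dplyr::mutate(tss_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", "strand", "tss_rank", "position") |>
    dplyr::arrange(.data$gene_id, .data$tss_rank)
}

# Minimal structural validation with line numbers; rtracklayer's own parse
# errors do not name the offending line.
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf < 9]
  if (length(bad) > 0) {
    stop("malformed GTF line ", bad[[1]], " in ", path,
         ": expected >= 9 tab-separated fields, found ",
         nf[match(bad[[1]], body)])
  }
  invisible(TRUE)
}

#' Form consecutive TSS pairs at a given pair index
#'
#' For each gene with at least `pair_index + 1` TSSs, emits the oriented
#' landmark pair (k-th, k+1-th TSS in transcription order). The upstream
#' member is `z_U`, the downstream member `z_D`; both are genomic 0-based
#' positions, and the oriented distance `z_D - z_U` (after strand
#' orientation) is strictly positive.
#'
#' @param tss TSS tibble as returned by [extract_tss()] (optionally carrying a
#'   `stratum` column, which is propagated).
#' @param pair_index Integer k >= 1: pair of the k-th and (k+1)-th TSSs.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `z_U`, `z_D`,
#'   `distance` (oriented, bp, > 0), `pair_index`, and `stratum` if present.
#' @export
consecutive_pairs <- function(tss, pair_index = 1L) {
  if (!is.numeric(pair_index) || length(pair_index) != 1 || pair_index < 1) {
    stop("pair_index must be a single integer >= 1")
  }
  k <- as.integer(pair_index)
  up <- dplyr::filter(tss, .data$tss_rank == k)
  dn <- dplyr::filter(tss, .data$tss_rank == k + 1L)
  keep <- c("gene_id", "chrom", "strand",
            intersect("stratum", names(tss)))
  pairs <- dplyr::inner_join(
    dplyr::select(up, dplyr::all_of(keep), z_U = "position"),
    dplyr::select(dn, "gene_id", z_D = "position"),
    by = "gene_id"
  )
  pairs |>
    dplyr::mutate(
      distance = dplyr::if_else(.data$strand == "+",
                                .data$z_D - .data$z_U,
                                .data$z_U - .data$z_D),
      pair_index = k
    ) |>
    dplyr::relocate(dplyr::any_of("stratum"), .after = dplyr::last_col())
}

#' Read an ENCODE-style gene quantification table
#'
#' @param path Tab-separated file with a header containing `gene_id` and an
#'   abundance column.
#' @param abundance_col Name of the abundance column (default `"TPM"`).
#' @param strip_versions Strip `".N"` version suffixes from gene ids for
#'   matching (default TRUE).
#' @return A tibble `gene_id`, `abundance`.
#' @export
read_quantification <- function(path, abundance_col = "TPM",
                                strip_versions = TRUE) {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tbl)) stop("quantification lacks a gene_id column")
  if (!abundance_col %in% names(tbl)) {
    stop("quantification lacks abundance column '", abundance_col, "'")
  }
  gid <- as.character(tbl$gene_id)
  if (strip_versions) gid <- sub("\\.\\d+$", "", gid)
  ab <- tbl[[abundance_col]]
  if (!is.numeric(ab)) {
    bad <- gid[which(is.na(suppressWarnings(as.numeric(ab))))[1]]
    stop("non-numeric abundance for gene ", bad)
  }
  tibble::tibble(gene_id = gid, abundance = as.numeric(ab))
}

#' Stratify genes by transcriptional activity
#'
#' Genes with abundance at or below `floor` are labelled `"zero"`; the
#' remaining (expressed) genes are split into `n_bands` equal-count quantile
#' bands from lowest to highest abundance. With the default 5 bands the
#' labels are `low`, `medium-low`, `medium`, `medium-high`, `high`.
#'
#' @param tss TSS tibble ([extract_tss()]); every gene must appear in
#'   `quantification` or it is assigned abundance 0.
#' @param quantification Tibble `gene_id`, `abundance`
#'   ([read_quantification()]), or a named numeric vector.
#' @param n_bands Number of quantile bands over expressed genes (default 5).
#' @param floor Abundance at or below which a gene is in the zero stratum
#'   (default 0).
#' @return The input tibble with `activity` and `stratum` columns added;
#'   `stratum` is a factor ordered zero < low < ... < high.
#' @export
stratify_by_activity <- function(tss, quantification, n_bands = 5L, floor = 0) {
  if (is.numeric(quantification) && !is.null(names(quantification))) {
    quantification <- tibble::tibble(gene_id = names(quantification),
                                     abundance = unname(quantification))
  }
  if (nrow(quantification) == 0) stop("empty quantification")
  if (!is.numeric(quantification$abundance)) {
    bad <- quantification$gene_id[!is.finite(
      suppressWarnings(as.numeric(quantification$abundance)))][1]
    stop("non-numeric abundance for gene ", bad)
  }
  if (any(quantification$abundance < 0)) stop("negative abundances")
  labels <- stratum_labels(n_bands)
  genes <- tss |>
    dplyr::distinct(.data$gene_id) |>
    dplyr::left_join(quantification, by = "gene_id") |>
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0))
  expressed <- genes$abundance > floor
  band <- rep(NA_integer_, nrow(genes))
  if (any(expressed)) {
    band[expressed] <- dplyr::ntile(genes$abundance[expressed],
                                    min(n_bands, sum(expressed)))
  }
  genes$stratum <- factor(
    ifelse(expressed, labels[band + 1L], "zero"),
    levels = labels
  )
  tss |>
    dplyr::left_join(
      dplyr::select(genes, "gene_id", activity = "abundance", "stratum"),
      by = "gene_id"
    )
}

stratum_labels <- function(n_bands) {
  bands <- if (n_bands == 5) {
    c("low", "medium-low", "medium", "medium-high", "high")
  } else if (n_bands == 1) {
    "expressed"
  } else {
    c(paste0("band", seq_len(n_bands - 1)), "high")
  }
  c("zero", bands)
}

#' Stratify TSS pairs by their own signal in a region
#'
#' The alternative stratification: instead of gene abundance, each pair is
#' assigned the region average of the signal over a rectangle (by default the
#' proximal-downstream region C) computed for that single pair, and pairs are
#' split into `n_bands` quantile bands. Pairs for which the region average is
#' undefined are dropped.
#'
#' @param pairs Pair tibble ([consecutive_pairs()]).
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param region One-row region tibble (default canonical region C).
#' @param n_bands Number of quantile bands (default 5).
#' @return `pairs` with `activity` (per-pair region average) and `stratum`
#'   columns.
#' @export
stratify_pairs_by_region <- function(pairs, signal,
                                     region = canonical_region("C"),
                                     n_bands = 5L) {
  region <- as_region_row(region)
  act <- vapply(seq_len(nrow(pairs)), function(i) {
    ra <- region_average(pairs[i, ], signal, region)
    if (ra$defined) ra$value else NA_real_
  }, numeric(1))
  labels <- stratum_labels(n_bands)[-1]
  out <- pairs
  out$activity <- act
  out <- dplyr::filter(out, is.finite(.data$activity))
  out$stratum <- factor(labels[dplyr::ntile(out$activity,
                                            min(n_bands, nrow(out)))],
                        levels = labels)
  out
}

#' Write / read the landmark interchange table
#'
#' TSV with columns `gene_id`, `chrom`, `strand`, `tss_rank`, `position`,
#' and `activity`/`stratum` when present. The round trip preserves positions,
#' strands, and strata exactly.
#'
#' @param tss TSS tibble.
#' @param path Output path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_landmarks <- function(tss, path) {
  readr::write_tsv(tss, path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", chrom = "c", strand = "c",
                           tss_rank = "i", position = "i",
                           .default = readr::col_guess()))
  if ("stratum" %in% names(tbl)) {
    lv <- stratum_labels(5)
    if (all(tbl$stratum %in% lv)) tbl$stratum <- factor(tbl$stratum, levels = lv)
  }
  tbl
}

#' Export TSSs as BED6
#'
#' One record per TSS (1 bp interval), named `gene_id:tss_rank`, score 0.
#'
#' @param tss TSS tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- data.frame(tss$chrom, tss$position, tss$position + 1L,
                    paste0(tss$gene_id, ":", tss$tss_rank), 0L, tss$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
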