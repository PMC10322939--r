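#' Load and validate a run configuration
#'
#' The configuration is a single declarative YAML file; the recognized keys
#' are `annotation` (GTF path), `chrom_sizes`, `signal_plus`, `signal_minus`
#' (or `signal` for unstranded assays), `quantification` and
#' `quantification_rep2` (TSV paths), `gene_type` (default
#' `"protein_coding"`), `chrom_whitelist`, `n_bands` (default 5),
#' `stratify_by` (`"gene_abundance"` or `"region_c"`), `pair_indices`
#' (default 1), `min_count`, `out_dir`, and `seed`. Individual keys may be
#' overridden programmatically via `...`.
#'
#' @param path Path to a YAML config file, or NULL to build from `...` only.
#' @param ... Key overrides.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  over <- list(...)
  cfg[names(over)] <- over
  defaults <- list(gene_type = "protein_coding", n_bands = 5L,
                   stratify_by = "gene_abundance", pair_indices = 1L,
                   min_count = 1L, out_dir = ".", seed = 1L,
                   chrom_whitelist = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("annotation", "chrom_sizes", "signal", "signal_plus",
              "signal_minus", "quantification", "quantification_rep2")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("run_config: path for '", k, "' does not exist: ", cfg[[k]])
    }
  }
  if (is.null(cfg$annotation)) stop("run_config: 'annotation' is required")
  if (is.null(cfg$signal) &&
      (is.null(cfg$signal_plus) || is.null(cfg$signal_minus))) {
    stop("run_config: give either 'signal' or both 'signal_plus' and 'signal_minus'")
  }
  if (any(cfg$pair_indices < 1)) stop("run_config: pair indices must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

load_config_inputs <- function(cfg) {
  sizes <- if (!is.null(cfg$chrom_sizes)) read_chrom_sizes(cfg$chrom_sizes)
  signal <- if (!is.null(cfg$signal)) {
    load_signal(cfg$signal, sizes)
  } else {
    stranded_signal(load_signal(cfg$signal_plus, sizes),
                    load_signal(cfg$signal_minus, sizes))
  }
  tss <- extract_tss(cfg$annotation, gene_type_filter = cfg$gene_type,
                     chrom_whitelist = cfg$chrom_whitelist)
  list(signal = normalize_genomewide(signal), tss = tss)
}

config_hash <- function(cfg) {
  keys <- cfg[order(names(unclass(cfg)))]
  keys <- keys[!vapply(keys, is.function, logical(1))]
  raw <- paste(utils::capture.output(utils::str(keys)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(raw) * seq_along(utf8ToInt(raw))) %%
            .Machine$integer.max)
}

#' Run the density stage of the pipeline
#'
#' Extracts TSSs, loads and normalizes the tracks, stratifies genes, and
#' writes one density-grid matrix (plus counts and metadata) per
#' (pair index, stratum) to `out_dir`.
#'
#' @param cfg A [run_config()].
#' @return Tibble of written grid files with pair counts, invisibly.
#' @export
run_density <- function(cfg) {
  inputs <- load_config_inputs(cfg)
  tss <- inputs$tss
  if (!is.null(cfg$quantification)) {
    quant <- read_quantification(cfg$quantification)
    tss <- stratify_by_activity(tss, quant, n_bands = cfg$n_bands)
  } else {
    tss$stratum <- factor("expressed")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  rows <- list()
  for (k in cfg$pair_indices) {
    pairs_k <- consecutive_pairs(tss, k)
    for (s in levels(droplevels(factor(tss$stratum)))) {
      ps <- dplyr::filter(pairs_k, .data$stratum == s)
      tag <- sprintf("pair%d_%s", k, gsub("[^a-zA-Z0-9]", "", s))
      if (nrow(ps) == 0) {
        writeLines(to_json(list(pair_index = k, stratum = s, n_pairs = 0,
                                config_hash = hash)),
                   file.path(cfg$out_dir, paste0("density_", tag, ".json")))
        rows[[tag]] <- tibble::tibble(pair_index = k, stratum = s,
                                      n_pairs = 0L, file = NA_character_)
        next
      }
      grid <- density_grid(ps, inputs$signal, min_count = cfg$min_count)
      path <- file.path(cfg$out_dir, paste0("density_", tag, ".tsv"))
      write_density_grid(grid, path)
      message("density ", tag, ": ", nrow(ps), " pairs, ",
              sum(!grid$defined), " masked cells")
      rows[[tag]] <- tibble::tibble(pair_index = k, stratum = s,
                                    n_pairs = nrow(ps), file = path)
    }
  }
  invisible(dplyr::bind_rows(rows))
}

#' Run the metrics stage of the pipeline
#'
#' Computes metrics panels per replicate, pair index, and stratum; replicate
#' mean/noise when a second quantification/track pair is configured; the
#' pair-index summary; and the Spearman concordance gate. Writes
#' `metrics.tsv`, `summary.tsv`, and `report.json` to `out_dir`.
#'
#' @param cfg A [run_config()].
#' @return A list with `metrics` (tibble), `summary` (tibble), and
#'   `concordance` (tibble or NULL), invisibly.
#' @export
run_metrics <- function(cfg) {
  inputs <- load_config_inputs(cfg)
  tss <- inputs$tss
  concordance <- NULL
  if (!is.null(cfg$quantification)) {
    quant <- read_quantification(cfg$quantification)
    tss <- stratify_by_activity(tss, quant, n_bands = cfg$n_bands)
    if (!is.null(cfg$quantification_rep2)) {
      quant2 <- read_quantification(cfg$quantification_rep2)
      concordance <- replicate_concordance(quant, quant2)
      if (!concordance$pass) {
        warning("replicate concordance gate failed (rho = ",
                round(concordance$rho, 3), "); computation continues")
      }
    }
  } else {
    tss$stratum <- factor("expressed")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- list()
  rows <- list()
  for (k in cfg$pair_indices) {
    pairs_k <- consecutive_pairs(tss, k)
    for (s in levels(droplevels(factor(tss$stratum)))) {
      ps <- dplyr::filter(pairs_k, .data$stratum == s)
      if (nrow(ps) == 0) next
      panel <- metrics_panel(ps, inputs$signal)
      panels[[length(panels) + 1]] <- panel
      rows[[length(rows) + 1]] <- dplyr::bind_rows(
        dplyr::mutate(panel$regions, kind = "region", metric = NA_character_,
                      log2_ratio = NA_real_, reason = NA_character_),
        dplyr::mutate(panel$derived, kind = "metric", label = NA_character_,
                      value = NA_real_, count = NA_real_, defined = NA)
      ) |>
        dplyr::mutate(pair_index = k, stratum = s, n_pairs = nrow(ps))
    }
  }
  metrics_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- pair_index_summary(panels)
  readr::write_tsv(metrics_tbl, file.path(cfg$out_dir, "metrics.tsv"))
  readr::write_tsv(summary_tbl, file.path(cfg$out_dir, "summary.tsv"))
  report <- list(config_hash = config_hash(cfg),
                 n_panels = length(panels),
                 concordance_rho = if (!is.null(concordance)) concordance$rho,
                 concordance_pass = if (!is.null(concordance)) concordance$pass)
  writeLines(to_json(report), file.path(cfg$out_dir, "report.json"))
  invisible(list(metrics = metrics_tbl, summary = summary_tbl,
                 concordance = concordance))
}

#' Write a complete synthetic fixture set
#'
#' Generates the annotation, two replicate signal tracks (bedGraph per
#' strand), chrom.sizes, the truth table, and a gene quantification TSV
#' derived from the per-gene total initiation rates.
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
make_fixtures <- function(config, dir) {
  ann <- generate_annotation(config)
  paths <- write_synth_annotation(ann, dir)
  for (rep in 1:2) {
    sig <- generate_signal(ann, config, seed = config$seed + 1000L * rep)
    pp <- file.path(dir, sprintf("signal_rep%d_plus.bedGraph", rep))
    mp <- file.path(dir, sprintf("signal_rep%d_minus.bedGraph", rep))
    write_bedgraph(sig$plus, pp)
    write_bedgraph(sig$minus, mp)
    paths <- c(paths, stats::setNames(c(pp, mp),
                                      sprintf(c("plus_rep%d", "minus_rep%d"),
                                              rep)))
    quant <- ann$truth |>
      dplyr::group_by(gene_id = .data$gene_id) |>
      dplyr::summarise(TPM = sum(.data$rate), .groups = "drop")
    qp <- file.path(dir, sprintf("quant_rep%d.tsv", rep))
    readr::write_tsv(quant, qp)
    paths <- c(paths, stats::setNames(qp, sprintf("quant_rep%d", rep)))
  }
  invisible(paths)
}
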