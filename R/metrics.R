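#' The seven canonical regions for TSS-pair interdependence
#'
#' Regions A and B measure transcription at the upstream TSS
#' (`0 <= x <= 200`) with the downstream TSS distal (`-20k <= y <= -10k`)
#' or at intermediate distance (`-900 <= y <= -200`); Af and Bf measure the
#' persistence zone `300 <= x <= 1000` for the same two y bands; C, D, and E
#' measure transcription at the downstream TSS (`0 <= y <= 200`) with the
#' upstream TSS proximal (`0 <= x <= 200`), intermediate
#' (`300 <= x <= 1000`), or distal (`10k <= x <= 20k`).
#'
#' @return A 7-row region tibble (`label`, `x0`, `y0`, `x1`, `y1`).
#' @export
canonical_regions <- function() {
  dplyr::bind_rows(
    region_spec(0, -20000, 200, -10000, "A"),
    region_spec(300, -20000, 1000, -10000, "Af"),
    region_spec(0, -900, 200, -200, "B"),
    region_spec(300, -900, 1000, -200, "Bf"),
    region_spec(0, 0, 200, 200, "C"),
    region_spec(300, 0, 1000, 200, "D"),
    region_spec(10000, 0, 20000, 200, "E")
  )
}

#' @rdname canonical_regions
#' @param label Region label (`"A"`, `"Af"`, `"B"`, `"Bf"`, `"C"`, `"D"`,
#'   `"E"`).
#' @export
canonical_region <- function(label) {
  cr <- canonical_regions()
  row <- cr[cr$label == label, ]
  if (nrow(row) != 1) stop("unknown canonical region: ", label)
  row
}

# The eight derived log2 interdependence metrics as (numerator, denominator)
# compositions over the canonical region averages. persistence_dominance is
# the ratio of the two persistences.
derived_metric_defs <- function() {
  tibble::tribble(
    ~metric,                  ~num,          ~den,
    "proximal_cooperativity", "C",           "E",
    "upstream_effects",       "B",           "A",
    "downstream_effects",     "D",           "E",
    "positional_dominance",   "E",           "A",
    "persistence_distal",     "Af",          "A",
    "persistence_nondistal",  "Bf",          "B",
    "signal_dominance",       "Bf",          "Af",
    "persistence_dominance",  "Bf/B",        "Af/A"
  )
}

#' Region averages and derived interdependence metrics for a pair set
#'
#' Computes the seven canonical region averages `T_A, T_Af, T_B, T_Bf, T_C,
#' T_D, T_E` over the pair set and the eight derived log2 ratios: proximal
#' cooperativity `log2(T_C/T_E)`, upstream effects `log2(T_B/T_A)`,
#' downstream effects `log2(T_D/T_E)`, positional dominance `log2(T_E/T_A)`,
#' persistence with a distal / non-distal downstream TSS `log2(T_Af/T_A)` /
#' `log2(T_Bf/T_B)`, signal dominance `log2(T_Bf/T_Af)`, and persistence
#' dominance `log2((T_Bf/T_B)/(T_Af/T_A))`. A ratio is reported only when
#' every constituent region average is defined and strictly positive;
#' otherwise the row carries NA with a machine-readable reason
#' (`"undefined_T"` or `"nonpositive_T"`), never a pseudocount.
#'
#' @param pairs Pair tibble ([consecutive_pairs()]); non-empty.
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @return A `metrics_panel` object: list with `regions` (tibble `label`,
#'   `value`, `count`, `defined`), `derived` (tibble `metric`, `log2_ratio`,
#'   `reason`), `pair_index`, `stratum`, `n_pairs`.
#' @export
metrics_panel <- function(pairs, signal) {
  if (nrow(pairs) == 0) stop("metrics_panel: empty pair set")
  regions <- region_average(pairs, signal, canonical_regions())
  tv <- stats::setNames(regions$value, regions$label)
  tdef <- stats::setNames(regions$defined, regions$label)
  defs <- derived_metric_defs()
  derived <- purrr::pmap_dfr(defs, function(metric, num, den) {
    parts <- unique(unlist(strsplit(c(num, den), "/", fixed = TRUE)))
    if (!all(tdef[parts])) {
      return(tibble::tibble(metric = metric, log2_ratio = NA_real_,
                            reason = "undefined_T"))
    }
    if (any(tv[parts] <= 0)) {
      return(tibble::tibble(metric = metric, log2_ratio = NA_real_,
                            reason = "nonpositive_T"))
    }
    ratio_of <- function(expr) {
      p <- strsplit(expr, "/", fixed = TRUE)[[1]]
      if (length(p) == 1) tv[[p]] else tv[[p[1]]] / tv[[p[2]]]
    }
    tibble::tibble(metric = metric,
                   log2_ratio = log2(ratio_of(num) / ratio_of(den)),
                   reason = NA_character_)
  })
  structure(
    list(
      regions = regions,
      derived = derived,
      pair_index = if ("pair_index" %in% names(pairs)) {
        pairs$pair_index[[1]]
      } else NA_integer_,
      stratum = if ("stratum" %in% names(pairs)) {
        as.character(pairs$stratum[[1]])
      } else NA_character_,
      n_pairs = nrow(pairs)
    ),
    class = "metrics_panel"
  )
}

#' @export
print.metrics_panel <- function(x, ...) {
  cat("<metrics_panel> pair_index=", x$pair_index,
      " stratum=", x$stratum %||% NA, " (", x$n_pairs, " pairs)\n", sep = "")
  print(x$regions)
  print(x$derived)
  invisible(x)
}

#' Extract a metric's log2 value from a panel
#'
#' @param panel A [metrics_panel()].
#' @param metric Metric name (see [metrics_panel()]).
#' @return The log2 ratio (NA when absent).
#' @export
panel_metric <- function(panel, metric) {
  i <- match(metric, panel$derived$metric)
  if (is.na(i)) stop("unknown metric: ", metric)
  panel$derived$log2_ratio[[i]]
}

#' Replicate mean and noise of the derived metrics
#'
#' For each metric m with replicate values m1, m2 (on the ratio scale), the
#' replicate mean is `(log2 m1 + log2 m2) / 2` and the replicate noise is
#' `(log2 m1 - log2 m2) / 2`, so mean + noise and mean - noise recover the
#' two replicate log2 values exactly. A metric absent (undefined or
#' non-positive T) in either replicate is reported with NA and a reason.
#'
#' @param panel_rep1,panel_rep2 [metrics_panel()] objects for the two
#'   replicates; must share `pair_index` and `stratum`.
#' @return A tibble `metric`, `replicate_mean`, `replicate_noise`, `reason`.
#' @export
replicate_stats <- function(panel_rep1, panel_rep2) {
  stopifnot(inherits(panel_rep1, "metrics_panel"),
            inherits(panel_rep2, "metrics_panel"))
  if (!identical(panel_rep1$pair_index, panel_rep2$pair_index) ||
      !identical(panel_rep1$stratum, panel_rep2$stratum)) {
    stop("replicate_stats: panels differ in pair_index or stratum")
  }
  d1 <- panel_rep1$derived; d2 <- panel_rep2$derived
  stopifnot(identical(d1$metric, d2$metric))
  tibble::tibble(
    metric = d1$metric,
    replicate_mean = (d1$log2_ratio + d2$log2_ratio) / 2,
    replicate_noise = (d1$log2_ratio - d2$log2_ratio) / 2,
    reason = dplyr::coalesce(d1$reason, d2$reason)
  )
}

#' Spearman concordance gate between replicate gene quantifications
#'
#' @param quant1,quant2 Tibbles `gene_id`, `abundance` (or named numeric
#'   vectors). The correlation is computed over shared genes (>= 3 required).
#' @param threshold Pass threshold on rho (default 0.8, strict inequality).
#' @return A one-row tibble `rho`, `pass`, `n_shared`.
#' @export
replicate_concordance <- function(quant1, quant2, threshold = 0.8) {
  as_quant <- function(q) {
    if (is.numeric(q) && !is.null(names(q))) {
      tibble::tibble(gene_id = names(q), abundance = unname(q))
    } else q
  }
  q1 <- as_quant(quant1); q2 <- as_quant(quant2)
  shared <- dplyr::inner_join(q1, q2, by = "gene_id",
                              suffix = c("_1", "_2"))
  if (nrow(shared) < 3) stop("replicate_concordance: fewer than 3 shared genes")
  rho <- stats::cor(shared$abundance_1, shared$abundance_2,
                    method = "spearman")
  tibble::tibble(rho = rho, pass = rho > threshold, n_shared = nrow(shared))
}

#' Summarize metrics over TSS-pair indices
#'
#' Emits, per stratum and metric, the log2 value for pair index 1, pair
#' index 2, and the unweighted mean of the log2 metric over pair indices 3
#' up to `max_index` (absent metrics excluded, with the contributing count
#' reported).
#'
#' @param panels List of [metrics_panel()] objects covering pair indices.
#' @param max_index Upper pair index of the pooled band (default 10, i.e. the
#'   pairs up to the 10th and 11th TSSs).
#' @return A tibble `stratum`, `metric`, `pair_group` (`"pair1"`, `"pair2"`,
#'   `"pairs3+"`), `log2_value`, `n`.
#' @export
pair_index_summary <- function(panels, max_index = 10L) {
  rows <- purrr::map_dfr(panels, function(p) {
    dplyr::mutate(p$derived, pair_index = p$pair_index,
                  stratum = p$stratum %||% NA_character_)
  })
  grp <- function(k) {
    dplyr::case_when(k == 1 ~ "pair1", k == 2 ~ "pair2",
                     k >= 3 & k <= max_index ~ "pairs3+",
                     TRUE ~ NA_character_)
  }
  rows |>
    dplyr::mutate(pair_group = grp(.data$pair_index)) |>
    dplyr::filter(!is.na(.data$pair_group), !is.na(.data$log2_ratio)) |>
    dplyr::group_by(.data$stratum, .data$metric, .data$pair_group) |>
    dplyr::summarise(log2_value = mean(.data$log2_ratio),
                     n = dplyr::n(), .groups = "drop")
}
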