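#' Define a rectangular region in relative-coordinate space
#'
#' A region is an inclusive rectangle `[x0, x1] x [y0, y1]` in the relative
#' coordinates `x = z - z_U` (offset from the upstream landmark) and
#' `y = z - z_D` (offset from the downstream landmark), both measured in bp
#' in transcription orientation.
#'
#' @param x0,x1 Inclusive x bounds (bp), `x0 <= x1`.
#' @param y0,y1 Inclusive y bounds (bp), `y0 <= y1`.
#' @param label Optional region label.
#' @return A one-row tibble with columns `label`, `x0`, `y0`, `x1`, `y1`.
#' @export
region_spec <- function(x0, y0, x1, y1, label = NA_character_) {
  if (x0 > x1) stop("region_spec: x0 > x1")
  if (y0 > y1) stop("region_spec: y0 > y1")
  tibble::tibble(label = label, x0 = as.numeric(x0), y0 = as.numeric(y0),
                 x1 = as.numeric(x1), y1 = as.numeric(y1))
}

as_region_row <- function(region) {
  if (is.list(region) && !is.data.frame(region)) {
    region <- do.call(region_spec, region[intersect(
      names(region), c("x0", "y0", "x1", "y1", "label"))])
  }
  stopifnot(is.data.frame(region), nrow(region) >= 1,
            all(c("x0", "y0", "x1", "y1") %in% names(region)))
  if (!"label" %in% names(region)) region$label <- NA_character_
  region
}

#' One-dimensional aligned (metagene) profile
#'
#' The classical single-landmark alignment: the mean of the oriented signal
#' over a set of anchors at each relative offset x.
#'
#' @param anchors Tibble with columns `chrom`, `strand`, `position` (0-based
#'   landmark positions); must be non-empty.
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param x_range Length-2 integer vector: inclusive offset range.
#' @return A tibble `x`, `value` (mean aligned signal), `n` (number of
#'   anchors).
#' @export
align_1d <- function(anchors, signal, x_range) {
  if (nrow(anchors) == 0) stop("align_1d: empty anchor set")
  offs <- seq.int(x_range[[1]], x_range[[2]])
  acc <- numeric(length(offs))
  for (i in seq_len(nrow(anchors))) {
    acc <- acc + oriented_value(signal, anchors$chrom[[i]],
                                anchors$strand[[i]], anchors$position[[i]],
                                offs)
  }
  tibble::tibble(x = offs, value = acc / nrow(anchors), n = nrow(anchors))
}

#' Rectangular region average over a set of landmark pairs
#'
#' The two-dimensional expansion places the signal value `g(z)` at relative
#' coordinates `(x, y) = (z - z_U, z - z_D)` for every landmark pair, i.e. on
#' the line `y = x + z_U - z_D`. The average over an inclusive rectangle
#' `[x0, x1] x [y0, y1]` and a pair set V is
#' `R_V = (1/N) * sum_pairs sum_x g(x + z_U)` where x runs over
#' `max(x0, y0 - z_U + z_D) .. min(x1, y1 - z_U + z_D)` and the normalization
#' N counts the contributing (pair, base) terms. The average is defined only
#' if at least one pair satisfies `y0 - x1 <= z_U - z_D <= y1 - x0`; an
#' undefined average is a normal return (`defined = FALSE`), not an error.
#'
#' All coordinates are transcription-oriented: for minus-strand pairs,
#' positive x points toward decreasing genomic coordinate, and the signal is
#' read from the minus-strand track of a [stranded_signal()].
#'
#' @param pairs Pair tibble ([consecutive_pairs()]): columns `chrom`,
#'   `strand`, `z_U`, `z_D` (genomic 0-based).
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param regions One or more regions ([region_spec()] rows or any data frame
#'   with `x0`, `y0`, `x1`, `y1`).
#' @return A tibble with one row per region: `label`, `value` (R_V, NA when
#'   undefined), `count` (N), `defined`.
#' @export
region_average <- function(pairs, signal, regions) {
  regions <- as_region_row(regions)
  d <- oriented_distances(pairs)
  n_pairs <- nrow(pairs)
  # Group pairs by (chrom, strand-resolved track) once; within a group the
  # interval sums are vectorized over the cached cumulative sums.
  if (n_pairs > 0) {
    plus <- pairs$strand == "+"
    grp_key <- if (inherits(signal, "stranded_signal")) {
      paste0(pairs$chrom, pairs$strand)
    } else {
      pairs$chrom
    }
    groups <- split(seq_len(n_pairs), grp_key)
    cs_of <- lapply(groups, function(idx) {
      chrom_cumsum(track_for_strand(signal, pairs$strand[[idx[[1]]]]),
                   pairs$chrom[[idx[[1]]]])
    })
    zU <- pairs$z_U
  }
  values <- counts <- numeric(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    x0 <- regions$x0[[r]]; x1 <- regions$x1[[r]]
    y0 <- regions$y0[[r]]; y1 <- regions$y1[[r]]
    total <- 0; count <- 0
    if (n_pairs > 0) {
      lo <- pmax(x0, y0 + d)  # y0 - z_U + z_D in oriented coordinates
      hi <- pmin(x1, y1 + d)
      live <- lo <= hi
      if (any(live)) {
        count <- sum(hi[live] - lo[live] + 1)
        a <- ifelse(plus, zU + lo, zU - hi)
        b <- ifelse(plus, zU + hi, zU - lo)
        for (gi in seq_along(groups)) {
          idx <- groups[[gi]][live[groups[[gi]]]]
          if (length(idx) == 0) next
          cs <- cs_of[[gi]]
          L <- length(cs) - 1
          a2 <- pmax(a[idx], 0); b2 <- pmin(b[idx], L - 1)
          ok <- a2 <= b2
          if (any(ok)) {
            total <- total + sum(cs[b2[ok] + 2] - cs[a2[ok] + 1])
          }
        }
      }
    }
    values[[r]] <- if (count > 0) total / count else NA_real_
    counts[[r]] <- count
  }
  tibble::tibble(label = regions$label, value = values, count = counts,
                 defined = counts > 0)
}

# Oriented distance z_D - z_U (> 0) per pair; z_U - z_D in the formulas is -d.
oriented_distances <- function(pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  d <- ifelse(pairs$strand == "+", pairs$z_D - pairs$z_U,
              pairs$z_U - pairs$z_D)
  if (any(d <= 0)) stop("pairs must have oriented z_D strictly downstream of z_U")
  d
}

#' Literal brute-force region average (testing oracle)
#'
#' Evaluates the defining double sum over every (x, y) cell of the rectangle
#' with the Kronecker-delta constraint `y = x + z_U - z_D`, one cell at a
#' time. Exists solely as the independent oracle for [region_average()]; it
#' refuses rectangles above `max_area` cells.
#'
#' @inheritParams region_average
#' @param max_area Refuse rectangles with more cells than this (default 4e6).
#' @return Same shape as [region_average()].
#' @export
region_average_bruteforce <- function(pairs, signal, regions,
                                      max_area = 4e6) {
  regions <- as_region_row(regions)
  out <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    x0 <- regions$x0[[r]]; x1 <- regions$x1[[r]]
    y0 <- regions$y0[[r]]; y1 <- regions$y1[[r]]
    if ((x1 - x0 + 1) * (y1 - y0 + 1) > max_area) {
      stop("region_average_bruteforce: rectangle exceeds max_area (oracle is for small instances)")
    }
    total <- 0; count <- 0
    ys <- seq.int(y0, y1)
    for (i in seq_len(nrow(pairs))) {
      zU <- pairs$z_U[[i]]; zD <- pairs$z_D[[i]]
      strand <- pairs$strand[[i]]; chrom <- pairs$chrom[[i]]
      d <- if (strand == "+") zD - zU else zU - zD
      for (x in seq.int(x0, x1)) {
        hits <- sum(ys == x - d)  # Kronecker delta over the y sum
        if (hits > 0) {
          g <- oriented_value(signal, chrom, strand, zU, x)
          total <- total + hits * g
          count <- count + hits
        }
      }
    }
    out[[r]] <- tibble::tibble(
      label = regions$label[[r]],
      value = if (count > 0) total / count else NA_real_,
      count = count,
      defined = count > 0
    )
  }
  dplyr::bind_rows(out)
}

#' Adaptive moving-window half-widths
#'
#' The smoothing window for the two-dimensional density is a rectangle of
#' dimensions `(2*n_X + 1) x (2*n_Y + 1)` whose half-widths grow with the
#' distance from the landmarks: `n_X = 99` for `-500 <= x <= 1000`,
#' `n_X = floor(x/4)` for `1000 < x <= 20000`; `n_Y = 99` for
#' `-1000 <= y <= 1000`, `n_Y = floor(-y/4)` for `-20000 <= y < -1000`.
#'
#' @param x,y Relative coordinates (bp); vectorized, recycled to a common
#'   length. Must lie in the analysis domain `-500 <= x <= 20000`,
#'   `-20000 <= y <= 1000`.
#' @return A tibble `x`, `y`, `n_x`, `n_y`.
#' @export
window_halfwidths <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(x < -500 | x > 20000)) {
    stop("window_halfwidths: x outside the analysis domain [-500, 20000]")
  }
  if (any(y < -20000 | y > 1000)) {
    stop("window_halfwidths: y outside the analysis domain [-20000, 1000]")
  }
  n_x <- ifelse(x <= 1000, 99, floor(x / 4))
  n_y <- ifelse(y >= -1000, 99, floor(-y / 4))
  tibble::tibble(x = x, y = y, n_x = as.integer(n_x), n_y = as.integer(n_y))
}

#' Default density-grid evaluation points
#'
#' Evaluation points are spaced 25 bp apart where the window half-width is
#' the constant 99 bp (|coordinate| <= 1 kb) and at half the local half-width
#' beyond, so the adaptive windows are resolved without oversampling the
#' smoothed distal zones.
#'
#' @param from,to Inclusive coordinate range along one axis.
#' @param near_spacing Spacing within the constant-window zone (default 25).
#' @return Integer vector of evaluation coordinates.
#' @export
grid_points <- function(from, to, near_spacing = 25L) {
  pts <- integer(0)
  p <- from
  while (p <= to) {
    pts <- c(pts, as.integer(p))
    hw <- max(abs(p) / 4, 99)
    step <- if (abs(p) <= 1000 && abs(p + near_spacing) <= 1000) {
      near_spacing
    } else {
      max(near_spacing, round(hw / 2))
    }
    p <- p + step
  }
  if (pts[[length(pts)]] != to) pts <- c(pts, as.integer(to))
  pts
}

#' Two-dimensional signal density over a pair set
#'
#' Evaluates `G(x, y) = R_V[(x - n_X, y - n_Y), (x + n_X, y + n_Y)]` at each
#' grid point, with the adaptive half-widths of [window_halfwidths()]. Cells
#' whose window contains no (pair, base) term are undefined and carry NA.
#'
#' @param pairs Pair tibble ([consecutive_pairs()]).
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param x_points,y_points Evaluation coordinates; defaults cover the
#'   analysis domain via [grid_points()].
#' @param min_count Cells with fewer contributing terms than this are masked
#'   (default 1, the literal definition).
#' @return A `density_grid` tibble: `x`, `y`, `n_x`, `n_y`, `value`, `count`,
#'   `defined`, with attributes `pair_index` and `stratum` when the pair set
#'   carries them.
#' @export
density_grid <- function(pairs, signal,
                         x_points = grid_points(-500, 20000),
                         y_points = grid_points(-20000, 1000),
                         min_count = 1L) {
  if (nrow(pairs) == 0) {
    warning("density_grid: empty pair set; all cells undefined")
  }
  cells <- tidyr::expand_grid(x = x_points, y = y_points)
  hw <- window_halfwidths(cells$x, cells$y)
  regions <- tibble::tibble(
    label = NA_character_,
    x0 = cells$x - hw$n_x, y0 = cells$y - hw$n_y,
    x1 = cells$x + hw$n_x, y1 = cells$y + hw$n_y
  )
  ra <- region_average(pairs, signal, regions)
  out <- tibble::tibble(
    x = cells$x, y = cells$y, n_x = hw$n_x, n_y = hw$n_y,
    value = ifelse(ra$count >= min_count, ra$value, NA_real_),
    count = ra$count,
    defined = ra$count >= min_count
  )
  attr(out, "pair_index") <- if ("pair_index" %in% names(pairs) &&
                                 nrow(pairs) > 0) {
    pairs$pair_index[[1]]
  } else NA_integer_
  attr(out, "stratum") <- if ("stratum" %in% names(pairs) && nrow(pairs) > 0) {
    as.character(pairs$stratum[[1]])
  } else NA_character_
  class(out) <- c("density_grid", class(out))
  out
}

#' Three-dimensional box average over landmark triples
#'
#' Extension to three landmarks `z_U < z_D < z_F` (oriented): the signal is
#' placed at `(x, y, v) = (z - z_U, z - z_D, z - z_F)`, i.e. subject to
#' `y = x + z_U - z_D` and `v = x + z_U - z_F`, and averaged over an
#' inclusive box.
#'
#' @param triples Tibble with columns `chrom`, `strand`, `z_U`, `z_D`, `z_F`
#'   (genomic 0-based; strictly increasing in the oriented frame).
#' @param signal A [genomic_signal()] or [stranded_signal()].
#' @param box List or one-row data frame with `x0`, `x1`, `y0`, `y1`, `v0`,
#'   `v1` (inclusive bounds).
#' @return A one-row tibble `value`, `count`, `defined`.
#' @export
region_average_3d <- function(triples, signal, box) {
  b <- as.list(box)
  stopifnot(all(c("x0", "x1", "y0", "y1", "v0", "v1") %in% names(b)))
  total <- 0; count <- 0
  for (i in seq_len(nrow(triples))) {
    strand <- triples$strand[[i]]
    sgn <- if (strand == "+") 1 else -1
    dD <- sgn * (triples$z_D[[i]] - triples$z_U[[i]])
    dF <- sgn * (triples$z_F[[i]] - triples$z_U[[i]])
    if (!(0 < dD && dD < dF)) {
      stop("triples must satisfy z_U < z_D < z_F in the oriented frame")
    }
    lo <- max(b$x0, b$y0 + dD, b$v0 + dF)
    hi <- min(b$x1, b$y1 + dD, b$v1 + dF)
    if (lo > hi) next
    trk <- track_for_strand(signal, strand)
    if (strand == "+") {
      a <- triples$z_U[[i]] + lo; z <- triples$z_U[[i]] + hi
    } else {
      a <- triples$z_U[[i]] - hi; z <- triples$z_U[[i]] - lo
    }
    total <- total + interval_sum(trk, triples$chrom[[i]], a, z)
    count <- count + (hi - lo + 1)
  }
  tibble::tibble(value = if (count > 0) total / count else NA_real_,
                 count = count, defined = count > 0)
}

#' Write a density grid as a TSV matrix with JSON metadata sidecar
#'
#' The matrix has x evaluation points as its first row and y points as its
#' first column; undefined cells are written as NA. A `<path>.counts.tsv`
#' matrix and a `<path>.json` metadata sidecar accompany it.
#'
#' @param grid A [density_grid()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  wide <- tidyr::pivot_wider(grid[, c("x", "y", "value")],
                             names_from = "x", values_from = "value")
  readr::write_tsv(wide, path)
  cw <- tidyr::pivot_wider(grid[, c("x", "y", "count")],
                           names_from = "x", values_from = "count")
  counts_path <- paste0(sub("\\.tsv$", "", path), ".counts.tsv")
  readr::write_tsv(cw, counts_path)
  meta <- list(
    pair_index = attr(grid, "pair_index"),
    stratum = attr(grid, "stratum"),
    n_cells = nrow(grid),
    n_defined = sum(grid$defined),
    window_rule = "n_X=99 for -500<=x<=1k, floor(x/4) for 1k<x<=20k; n_Y=99 for -1k<=y<=1k, floor(-y/4) for -20k<=y<-1k",
    counts_file = basename(counts_path)
  )
  writeLines(to_json(meta), paste0(sub("\\.tsv$", "", path), ".json"))
  invisible(path)
}

# Minimal JSON serialization for flat metadata lists (scalars only).
to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) return("null")
    if (is.character(v)) return(paste0('"', gsub('"', '\\\\"', v), '"'))
    format(v, digits = 15)
  }
  paste0("{", paste0('"', names(x), '": ', vapply(x, enc, character(1)),
                     collapse = ", "), "}")
}
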