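test_that("align_1d reduces to the oriented slice for a single anchor", {
  withr::local_seed(1)
  sig <- random_signal(500)
  anchors <- tibble::tibble(chrom = "chr1", strand = "+", position = 250L)
  prof <- align_1d(anchors, sig, c(-50, 50))
  expect_identical(prof$value, sig$values$chr1[201:301])
  expect_error(align_1d(anchors[0, ], sig, c(-5, 5)), "empty")
})

test_that("align_1d averages shifted pulses over multiple anchors", {
  v <- numeric(300); v[101] <- 8; v[201] <- 4  # pulses at 100 and 200
  sig <- toy_signal(v)
  anchors <- tibble::tibble(chrom = "chr1", strand = "+",
                            position = c(100L, 200L))
  prof <- align_1d(anchors, sig, c(-2, 2))
  expect_equal(prof$value, c(0, 0, 6, 0, 0))  # mean of the two pulses at x=0
  const <- align_1d(anchors, toy_signal(rep(3, 300)), c(-5, 5))
  expect_true(all(const$value == 3))
})

test_that("region_average reproduces the worked single-pair example", {
  sig <- toy_signal(as.numeric(0:999))  # g(z) = z
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 100, z_D = 160)
  ra <- region_average(pairs, sig, region_spec(0, -80, 10, -40))
  # x runs max(0,-20)..min(10,20) = 0..10 -> mean of g(100..110)
  expect_equal(ra$value, 105)
  expect_equal(ra$count, 11)
  expect_true(ra$defined)
})

test_that("region averages are undefined when no pair meets the condition", {
  sig <- toy_signal(rep(1, 2000))
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 1000, z_D = 1060)
  ra <- region_average(pairs, sig, region_spec(0, -900, 200, -200))
  expect_false(ra$defined)
  expect_equal(ra$count, 0)
  expect_true(is.na(ra$value))
  # and brute force agrees on the empty pair set
  empty <- pairs[0, ]
  expect_false(region_average_bruteforce(empty, sig,
                                         region_spec(0, 0, 5, 5))$defined)
})

test_that("a 1x1 region on the constraint line returns the single base", {
  withr::local_seed(2)
  sig <- random_signal(1000)
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 400, z_D = 500)
  # at x = 30 the line gives y = -70
  ra <- region_average_bruteforce(pairs, sig, region_spec(30, -70, 30, -70))
  expect_equal(ra$value, sig$values$chr1[431])
  expect_equal(ra$count, 1)
})

test_that("efficient and brute-force region averages agree on random instances", {
  withr::local_seed(101)
  for (i in 1:40) {
    inst <- random_instance()
    fast <- region_average(inst$pairs, inst$signal, inst$region)
    slow <- region_average_bruteforce(inst$pairs, inst$signal, inst$region)
    expect_identical(fast$count, slow$count)
    expect_identical(fast$defined, slow$defined)
    if (fast$defined) {
      expect_equal(fast$value, slow$value, tolerance = 1e-9)
    }
    # count closed form
    d <- ifelse(inst$pairs$strand == "+", inst$pairs$z_D - inst$pairs$z_U,
                inst$pairs$z_U - inst$pairs$z_D)
    n_expect <- sum(pmax(0, pmin(inst$region$x1, inst$region$y1 + d) -
                           pmax(inst$region$x0, inst$region$y0 + d) + 1))
    expect_equal(fast$count, n_expect)
  }
})

test_that("the brute-force oracle refuses oversized rectangles", {
  sig <- toy_signal(rep(1, 100))
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 10, z_D = 20)
  expect_error(
    region_average_bruteforce(pairs, sig, region_spec(0, -5000, 5000, 5000),
                              max_area = 1e6),
    "max_area")
})

test_that("region averages are linear in the signal", {
  withr::local_seed(3)
  v1 <- dyadic_values(800); v2 <- dyadic_values(800)
  pairs <- tibble::tibble(chrom = "chr1", strand = c("+", "-"),
                          z_U = c(300, 500), z_D = c(380, 420))
  reg <- region_spec(-20, -100, 60, 10)
  r1 <- region_average(pairs, toy_signal(v1), reg)$value
  r2 <- region_average(pairs, toy_signal(v2), reg)$value
  r12 <- region_average(pairs, toy_signal(2.5 * v1 + 4 * v2), reg)$value
  expect_equal(r12, 2.5 * r1 + 4 * r2, tolerance = 1e-12)
})

test_that("disjoint pair sets pool as count-weighted averages", {
  withr::local_seed(4)
  sig <- random_signal(3000)
  mk <- function(n) {
    z_U <- sample(300:2500, n)
    tibble::tibble(chrom = "chr1", strand = "+", z_U = z_U,
                   z_D = z_U + sample(50:400, n, replace = TRUE))
  }
  v1 <- mk(5); v2 <- mk(7)
  reg <- region_spec(0, -300, 150, 0)
  a <- region_average(v1, sig, reg); b <- region_average(v2, sig, reg)
  ab <- region_average(dplyr::bind_rows(v1, v2), sig, reg)
  expect_equal(ab$count, a$count + b$count)
  expect_equal(ab$value,
               (a$value * a$count + b$value * b$count) / (a$count + b$count),
               tolerance = 1e-12)
})

test_that("windows past chromosome ends draw zeros that still count", {
  sig <- toy_signal(rep(2, 100))
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 90, z_D = 95)
  # x window 0..20 extends 11 bases past the end
  ra <- region_average(pairs, sig, region_spec(0, -100, 20, 100))
  expect_equal(ra$count, 21)
  expect_equal(ra$value, 2 * 10 / 21)
  bf <- region_average_bruteforce(pairs, sig, region_spec(0, -100, 20, 100))
  expect_equal(bf$count, ra$count)
  expect_equal(bf$value, ra$value, tolerance = 1e-12)
})

test_that("adaptive window half-widths follow the boundary rules", {
  hw <- window_halfwidths(c(-500, 500, 1000, 1001, 2000, 20000),
                          c(1000, -500, -1000, -1001, -4000, -20000))
  expect_equal(hw$n_x, c(99L, 99L, 99L, 250L, 500L, 5000L))
  expect_equal(hw$n_y, c(99L, 99L, 99L, 250L, 1000L, 5000L))
  expect_error(window_halfwidths(-501, 0), "domain")
  expect_error(window_halfwidths(0, 1001), "domain")
  # floor, not rounding, keeps integral half-widths
  expect_equal(window_halfwidths(1003, 0)$n_x, 250L)
})

test_that("density grids are region averages over adaptive windows", {
  withr::local_seed(5)
  cfg <- synth_config(n_genes = 10, tss_counts = 2L, tss_count_prob = 1,
                      spacing_sampler = function(n) rep(500L, n),
                      noise_sigma = 0, seed = 9)
  ann <- generate_annotation(cfg)
  sig <- generate_signal(ann, cfg)
  pairs <- consecutive_pairs(ann$tss, 1)
  grid <- density_grid(pairs, sig, x_points = c(0, 100, 2000),
                       y_points = c(-700, 0))
  for (i in seq_len(nrow(grid))) {
    hw <- window_halfwidths(grid$x[[i]], grid$y[[i]])
    ra <- region_average(pairs, sig,
                         region_spec(grid$x[[i]] - hw$n_x, grid$y[[i]] - hw$n_y,
                                     grid$x[[i]] + hw$n_x, grid$y[[i]] + hw$n_y))
    expect_equal(grid$count[[i]], ra$count)
    if (ra$defined) expect_equal(grid$value[[i]], ra$value)
    else expect_true(is.na(grid$value[[i]]))
  }
  expect_warning(density_grid(pairs[0, ], sig, x_points = 0, y_points = 0),
                 "empty")
})

test_that("cells whose window misses the constraint line are masked", {
  sig <- toy_signal(rep(1, 5000))
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 2000, z_D = 2060)
  # d = 60; at (x, y) = (0, -700) the window [y-99, y+99] needs -d in it
  grid <- density_grid(pairs, sig, x_points = 0, y_points = c(-700, -100))
  expect_false(grid$defined[grid$y == -700])
  expect_true(grid$defined[grid$y == -100])
})

test_that("grid evaluation points resolve the near-TSS zone at 25 bp", {
  pts <- grid_points(-500, 20000)
  expect_true(all(diff(pts[pts <= 1000]) == 25))
  expect_true(all(diff(pts) > 0))
  expect_equal(pts[length(pts)], 20000L)
  hw_max <- max(window_halfwidths(pts, 0)$n_x)
  expect_true(all(diff(pts) <= hw_max))
})

test_that("density grids round trip through the TSV matrix export", {
  withr::local_seed(6)
  sig <- random_signal(5000)
  pairs <- tibble::tibble(chrom = "chr1", strand = "+", z_U = 2000,
                          z_D = 2100, pair_index = 1L)
  grid <- density_grid(pairs, sig, x_points = c(0, 50, 100),
                       y_points = c(-200, -100, 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_density_grid(grid, f)
  wide <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(wide), c("y", "0", "50", "100"))
  long <- tidyr::pivot_longer(wide, -y, names_to = "x",
                              values_to = "value") |>
    dplyr::mutate(x = as.integer(x)) |>
    dplyr::arrange(x, y)
  expect_equal(long$value, grid$value)
  expect_true(file.exists(sub("\\.tsv$", ".json", f)))
  expect_true(file.exists(sub("\\.tsv$", ".counts.tsv", f)))
})

test_that("3D box averages respect both constraints", {
  sig <- toy_signal(as.numeric(0:2999))
  triples <- tibble::tibble(chrom = "chr1", strand = "+",
                            z_U = 1000, z_D = 1100, z_F = 1500)
  # dD = 100, dF = 500; box selecting x in [0,10]
  box <- list(x0 = 0, x1 = 10, y0 = -100, y1 = -80, v0 = -500, v1 = -480)
  ra <- region_average_3d(triples, sig, box)
  expect_equal(ra$value, mean(1000:1010))
  expect_equal(ra$count, 11)
  # incompatible y/v ranges -> undefined
  bad <- list(x0 = 0, x1 = 10, y0 = -100, y1 = -90, v0 = -450, v1 = -440)
  expect_false(region_average_3d(triples, sig, bad)$defined)
  # constant field
  const <- region_average_3d(triples, toy_signal(rep(1, 3000)), box)
  expect_equal(const$value, 1)
  expect_error(
    region_average_3d(dplyr::mutate(triples, z_F = 1050), sig, box),
    "oriented")
})

test_that("3D box averages match direct enumeration on a minus-strand triple", {
  withr::local_seed(7)
  sig <- random_signal(3000)
  triples <- tibble::tibble(chrom = "chr1", strand = "-",
                            z_U = 2000, z_D = 1850, z_F = 1400)
  box <- list(x0 = 0, x1 = 400, y0 = -200, y1 = 100, v0 = -650, v1 = -550)
  ra <- region_average_3d(triples, sig, box)
  # direct: x with y = x - 150 in [-200,100] and v = x - 600 in [-650,-550]
  xs <- 0:400
  keep <- (xs - 150) >= -200 & (xs - 150) <= 100 &
    (xs - 600) >= -650 & (xs - 600) <= -550
  vals <- sig$values$chr1[2000 - xs[keep] + 1]
  expect_equal(ra$count, sum(keep))
  expect_equal(ra$value, mean(vals), tolerance = 1e-12)
})
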