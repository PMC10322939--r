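test_that("canonical regions carry the published rectangle bounds", {
  cr <- canonical_regions()
  expect_equal(nrow(cr), 7)
  a <- canonical_region("A")
  expect_equal(c(a$x0, a$y0, a$x1, a$y1), c(0, -20000, 200, -10000))
  c_ <- canonical_region("C")
  expect_equal(c(c_$x0, c_$y0, c_$x1, c_$y1), c(0, 0, 200, 200))
  e <- canonical_region("E")
  expect_equal(c(e$x0, e$y0, e$x1, e$y1), c(10000, 0, 20000, 200))
  bf <- canonical_region("Bf")
  expect_equal(c(bf$x0, bf$y0, bf$x1, bf$y1), c(300, -900, 1000, -200))
  expect_error(canonical_region("Z"), "unknown")
})

test_that("a normalized constant field gives unit T values and zero metrics", {
  cfg <- synth_config(n_genes = 30, tss_counts = 2:3,
                      tss_count_prob = c(0.5, 0.5),
                      spacing_sampler = function(n)
                        sample(c(100L, 500L, 15000L), n, replace = TRUE),
                      seed = 13)
  ann <- generate_annotation(cfg)
  L <- ann$chrom_sizes[[1]]
  const <- normalize_genomewide(
    genomic_signal(setNames(list(rep(7, L)), names(ann$chrom_sizes))))
  panel <- metrics_panel(consecutive_pairs(ann$tss, 1), const)
  defined <- panel$regions$defined
  expect_true(all(panel$regions$value[defined] == 1))
  present <- !is.na(panel$derived$log2_ratio)
  expect_true(any(present))
  expect_true(all(panel$derived$log2_ratio[present] == 0))
})

test_that("derived ratios are recomputable from the stored T values", {
  withr::local_seed(14)
  cfg <- synth_scenario("suppression", seed = 8)
  panel <- recover_planted_effects(cfg)
  tv <- setNames(panel$regions$value, panel$regions$label)
  expect_equal(panel_metric(panel, "upstream_effects"),
               log2(tv[["B"]] / tv[["A"]]))
  expect_equal(panel_metric(panel, "positional_dominance"),
               log2(tv[["E"]] / tv[["A"]]))
  expect_equal(panel_metric(panel, "persistence_dominance"),
               log2((tv[["Bf"]] / tv[["B"]]) / (tv[["Af"]] / tv[["A"]])))
  # cross-metric identity
  expect_equal(
    panel_metric(panel, "positional_dominance") +
      panel_metric(panel, "upstream_effects"),
    log2(tv[["E"]] * tv[["B"]] / (tv[["A"]] * tv[["A"]])),
    tolerance = 1e-12)
})

test_that("ratios with undefined or non-positive constituents carry reasons", {
  # all pair distances < 10 kb: regions A and Af cannot be populated
  sig <- toy_signal(rep(1, 50000))
  pairs <- tibble::tibble(chrom = "chr1", strand = "+",
                          z_U = c(5000, 20000), z_D = c(5400, 20500))
  panel <- metrics_panel(pairs, sig)
  expect_false(panel$regions$defined[panel$regions$label == "A"])
  d <- panel$derived
  expect_equal(d$reason[d$metric == "persistence_distal"], "undefined_T")
  expect_true(is.na(d$log2_ratio[d$metric == "upstream_effects"]))
  # zero signal in a defined region -> nonpositive_T
  v <- rep(0, 50000); v[20001:20201] <- 1  # only region C of the distal pair
  pairs2 <- tibble::tibble(chrom = "chr1", strand = "+",
                           z_U = c(20000, 5000), z_D = c(20100, 17000))
  panel2 <- metrics_panel(pairs2, toy_signal(v))
  d2 <- panel2$derived
  expect_equal(d2$reason[d2$metric == "proximal_cooperativity"],
               "nonpositive_T")
  expect_error(metrics_panel(pairs[0, ], sig), "empty")
})

test_that("derived metrics are invariant under signal scaling", {
  withr::local_seed(15)
  cfg <- synth_config(n_genes = 40, tss_counts = 2L, tss_count_prob = 1,
                      spacing_sampler = function(n)
                        sample(c(500L, 12000L), n, replace = TRUE),
                      noise_sigma = 0.3, seed = 4)
  ann <- generate_annotation(cfg)
  sig <- generate_signal(ann, cfg)
  pairs <- consecutive_pairs(ann$tss, 1)
  p1 <- metrics_panel(pairs, sig)
  scaled <- stranded_signal(
    genomic_signal(lapply(sig$plus$values, function(v) v * 3.7)),
    genomic_signal(lapply(sig$minus$values, function(v) v * 3.7)))
  p2 <- metrics_panel(pairs, scaled)
  expect_equal(p2$derived$log2_ratio, p1$derived$log2_ratio,
               tolerance = 1e-9)
  expect_equal(p2$regions$value, p1$regions$value * 3.7, tolerance = 1e-12)
})

test_that("replicate stats satisfy the half-sum/half-difference identities", {
  m1 <- c(proximal_cooperativity = log2(8), upstream_effects = log2(4))
  m2 <- c(proximal_cooperativity = log2(2), upstream_effects = log2(4))
  p1 <- make_panel(m1); p2 <- make_panel(m2)
  rs <- replicate_stats(p1, p2)
  pc <- rs[rs$metric == "proximal_cooperativity", ]
  expect_equal(pc$replicate_mean, 2)   # m1 = 8, m2 = 2
  expect_equal(pc$replicate_noise, 1)
  ue <- rs[rs$metric == "upstream_effects", ]
  expect_equal(ue$replicate_mean, 2)   # identical replicates: m = 4
  expect_equal(ue$replicate_noise, 0)
  # reconstruction of both replicate log2 values
  expect_equal(rs$replicate_mean + rs$replicate_noise,
               unname(m1[rs$metric]), tolerance = 1e-12)
  expect_equal(rs$replicate_mean - rs$replicate_noise,
               unname(m2[rs$metric]), tolerance = 1e-12)
})

test_that("replicate stats propagate absences and reject mismatched panels", {
  p1 <- make_panel(c(proximal_cooperativity = 1))
  p2 <- make_panel(c(proximal_cooperativity = NA))
  rs <- replicate_stats(p1, p2)
  pc <- rs[rs$metric == "proximal_cooperativity", ]
  expect_true(is.na(pc$replicate_mean))
  expect_equal(pc$reason, "undefined_T")
  p3 <- make_panel(c(proximal_cooperativity = 1), pair_index = 2L)
  expect_error(replicate_stats(p1, p3), "pair_index")
})

test_that("the Spearman gate passes monotone and fails scrambled replicates", {
  withr::local_seed(16)
  q1 <- tibble::tibble(gene_id = paste0("g", 1:100),
                       abundance = stats::rlnorm(100))
  doubled <- dplyr::mutate(q1, abundance = 2 * abundance)
  cc <- replicate_concordance(q1, doubled)
  expect_equal(cc$rho, 1)
  expect_true(cc$pass)
  reversed <- dplyr::mutate(q1, abundance = max(abundance) - abundance + 1)
  cc2 <- replicate_concordance(q1, reversed)
  expect_equal(cc2$rho, -1)
  expect_false(cc2$pass)
  big1 <- tibble::tibble(gene_id = paste0("g", 1:1000),
                         abundance = sample(1000))
  big2 <- dplyr::mutate(big1, abundance = sample(abundance))
  cc3 <- replicate_concordance(big1, big2)
  expect_lt(abs(cc3$rho), 0.2)
  expect_false(cc3$pass)
  expect_error(replicate_concordance(q1[1:2, ], q1[1:2, ]), "3 shared")
})

test_that("pair-index summaries report pair 1, pair 2, and the 3..10 average", {
  panels <- c(
    list(make_panel(c(upstream_effects = -2), pair_index = 1L),
         make_panel(c(upstream_effects = -1), pair_index = 2L)),
    lapply(3:10, function(k)
      make_panel(c(upstream_effects = 0.5), pair_index = k))
  )
  s <- pair_index_summary(panels)
  ue <- s[s$metric == "upstream_effects", ]
  expect_equal(ue$log2_value[ue$pair_group == "pair1"], -2)
  expect_equal(ue$log2_value[ue$pair_group == "pairs3+"], 0.5)
  expect_equal(ue$n[ue$pair_group == "pairs3+"], 8)
  # arithmetic mean over indices, absences excluded
  panels2 <- list(make_panel(c(downstream_effects = 1), pair_index = 3L),
                  make_panel(c(downstream_effects = 3), pair_index = 4L),
                  make_panel(c(downstream_effects = NA), pair_index = 5L))
  s2 <- pair_index_summary(panels2)
  de <- s2[s2$metric == "downstream_effects" & s2$pair_group == "pairs3+", ]
  expect_equal(de$log2_value, 2)
  expect_equal(de$n, 2)
})

test_that("tidy and glance expose panels as tibbles", {
  cfg <- synth_scenario("suppression", seed = 2)
  panel <- recover_planted_effects(cfg)
  td <- tidy(panel)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("metric", "log2_ratio", "pair_index") %in% names(td)))
  expect_equal(nrow(td), 8)
  gl <- glance(panel)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("T_A", "T_E", "n_pairs") %in% names(gl)))
  expect_equal(gl$n_pairs, panel$n_pairs)
})

test_that("autoplot methods return ggplot objects", {
  cfg <- synth_config(n_genes = 10, tss_counts = 2L, tss_count_prob = 1,
                      spacing_sampler = function(n) rep(300L, n), seed = 6)
  ann <- generate_annotation(cfg)
  sig <- generate_signal(ann, cfg)
  pairs <- consecutive_pairs(ann$tss, 1)
  grid <- density_grid(pairs, sig, x_points = c(0, 100), y_points = c(-100, 0))
  expect_s3_class(ggplot2::autoplot(grid), "ggplot")
  panel <- metrics_panel(pairs, sig)
  expect_s3_class(ggplot2::autoplot(panel), "ggplot")
})
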