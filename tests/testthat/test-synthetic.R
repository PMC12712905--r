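test_that("layout and counts are reproducible from the seed", {
  cfg <- small_config()
  l1 <- build_genome_layout(cfg)
  l2 <- build_genome_layout(cfg)
  expect_identical(l1$peaks, l2$peaks)
  expect_identical(l1$genes, l2$genes)
  expect_identical(l1$interactions, l2$interactions)
  s1 <- simulate_counts(l1, cfg, assays = c("ATAC", "H3K9me3"))
  s2 <- simulate_counts(l2, cfg, assays = c("ATAC", "H3K9me3"))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted trans-target peaks respect the configured bin", {
  cfg <- small_config()  # planted bin (-1e5, 0]
  lay <- build_genome_layout(cfg)
  tp <- lay$peaks[class == "trans_target"]
  g <- lay$genes[match(tp$linked_egene, gene_id)]
  d <- signed_distance(g$tss, g$strand, tp$start, tp$end)
  expect_true(all(d > -1e5 & d <= 0))
  # with several bins, every distance lands in one of them
  cfg2 <- small_config(rad_planted_bins = list(c(-1e5, 0), c(2e5, 3e5)))
  lay2 <- build_genome_layout(cfg2)
  tp2 <- lay2$peaks[class == "trans_target"]
  g2 <- lay2$genes[match(tp2$linked_egene, gene_id)]
  d2 <- signed_distance(g2$tss, g2$strand, tp2$start, tp2$end)
  expect_true(all((d2 > -1e5 & d2 <= 0) | (d2 > 2e5 & d2 <= 3e5)))
  # spatial null: no positional link to the eGene window is guaranteed
  cfg3 <- small_config(rad_planted_bins = NULL)
  lay3 <- build_genome_layout(cfg3)
  expect_equal(nrow(lay3$peaks[class == "trans_target"]),
               cfg3$n_trans_targets)
})

test_that("short-decoy fraction is exact and the rest span > 5 kb", {
  cfg <- small_config(n_interactions = 100L, frac_short_decoys = 0.1)
  lay <- build_genome_layout(cfg)
  spans <- interaction_span(lay$interactions)
  expect_equal(sum(spans <= 5000), 10)
  expect_equal(sum(spans > 5000), 90)
})

test_that("expected signal encodes cis additivity and dominant repression", {
  cfg <- small_config(d_true = -1, delta_k9 = 2, delta_active = 2,
                      cis_beta = 1.5)
  lay <- build_genome_layout(cfg)
  neutral <- lay$peaks[class == "neutral", peak_id][1]
  for (a in c("ATAC", "H3K9me3"))
    expect_equal(expected_log_signal(lay, neutral, a, "B6"),
                 expected_log_signal(lay, neutral, a, "D2-13B6"))

  tp_d2 <- lay$peaks[class == "trans_target" &
                       repressive_allele == "D2", peak_id][1]
  # dominance calibration: with d_true = -1 the F1 equals the repressed
  # homozygote exactly
  expect_equal(expected_log_signal(lay, tp_d2, "ATAC", "F1"),
               expected_log_signal(lay, tp_d2, "ATAC", "D2"))
  # genotype-swap symmetry of the congenics at a trans-only feature
  for (a in c("ATAC", "H3K9me3", "PET", "RNA", "H3K27ac")) {
    expect_equal(expected_log_signal(lay, tp_d2, a, "B6-13D2"),
                 expected_log_signal(lay, tp_d2, a, "D2"))
    expect_equal(expected_log_signal(lay, tp_d2, a, "D2-13B6"),
                 expected_log_signal(lay, tp_d2, a, "B6"))
  }
  # repression direction: K9 up, active assays down
  expect_equal(expected_log_signal(lay, tp_d2, "H3K9me3", "D2"), 2)
  expect_equal(expected_log_signal(lay, tp_d2, "ATAC", "D2"), -2)
  # cis target: additive in the local genotype, untouched at the master swap
  cp <- lay$peaks[class == "cis_target" & cis_high_allele == "B6",
                  peak_id][1]
  expect_equal(expected_log_signal(lay, cp, "ATAC", "B6"), 1.5)
  expect_equal(expected_log_signal(lay, cp, "ATAC", "F1"), 0.75)
  expect_equal(expected_log_signal(lay, cp, "ATAC", "D2"), 0)
  expect_equal(expected_log_signal(lay, cp, "ATAC", "B6-13D2"),
               expected_log_signal(lay, cp, "ATAC", "B6"))
  # intermediate dominance: d_true = 0 puts the F1 at the midparent
  cfg0 <- small_config(d_true = 0)
  lay0 <- build_genome_layout(cfg0)
  tp0 <- lay0$peaks[class == "trans_target" &
                      repressive_allele == "D2", peak_id][1]
  expect_equal(expected_log_signal(lay0, tp0, "ATAC", "F1"), -1)
  expect_error(expected_log_signal(lay, tp_d2, "CUTRUN", "B6"),
               "unknown assay")
})

test_that("counts follow the NB mean-variance model", {
  # 10,000 neutral features at a common mean give a Monte-Carlo check of
  # the variance function: phi = 0 is Poisson, phi = 0.5 is mu + phi mu^2
  base <- list(n_chromosomes = 2L, chrom_length_bp = 3e7, n_genes = 5L,
               n_peaks = 10000L, n_interactions = 0L, n_trans_targets = 0L,
               n_cis_targets = 0L, n_trans_egenes = 1L,
               baseline_log2_mean = log2(100), baseline_log2_sd = 0,
               sizefactor_log_sd = 0, replicates_per_strain = 2L,
               seed = 3L)
  cfg_p <- do.call(sim_config, c(base, dispersion = 0))
  sim_p <- simulate_counts(build_genome_layout(cfg_p), cfg_p,
                           assays = "ATAC")
  x <- sim_p$counts$ATAC[, 1]
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)

  cfg_nb <- do.call(sim_config, c(base, dispersion = 0.5))
  sim_nb <- simulate_counts(build_genome_layout(cfg_nb), cfg_nb,
                            assays = "ATAC")
  y <- sim_nb$counts$ATAC[, 1]
  expected_var <- 100 + 0.5 * 100^2
  expect_gt(var(y), expected_var * 0.9)
  expect_lt(var(y), expected_var * 1.1)

  # mean-model fidelity: empirical means track size-factor-scaled 2^eta
  mu_hat <- mean(y)
  expect_lt(abs(mu_hat - 100) / 100, 0.05)
})

test_that("infeasible placement and bad configs are rejected", {
  expect_error(small_config(frac_d2_repressive = 1.2))
  expect_error(small_config(dispersion = -1))
  expect_error(small_config(n_peaks = 10L), "n_peaks")
  expect_error(
    build_genome_layout(small_config(chrom_length_bp = 9e5)),
    "infeasible placement")
  expect_error(
    build_genome_layout(small_config(rad_planted_bins = list(c(6e5, 7e5)))),
    "infeasible placement")
})

test_that("truth table and written files are consistent", {
  cfg <- small_config()
  sim <- simulate_counts(build_genome_layout(cfg), cfg,
                         assays = c("ATAC", "RNA"))
  tr <- sim$truth
  expect_equal(sort(unique(tr$strain)), sort(strain_table()$strain))
  expect_equal(sum(tr$class == "trans_target" & tr$assay == "ATAC"),
               cfg$n_trans_targets * 5)
  tmp <- withr::local_tempdir()
  paths <- write_simulation(sim, tmp)
  expect_true(all(file.exists(paths)))
  m <- read_counts(paths[["counts_ATAC"]])
  expect_identical(m, sim$counts$ATAC * 1)
  got <- read_bed(paths[["peaks"]])
  expect_equal(got$start, sim$layout$peaks$start)
  targets <- data.table::fread(paths[["qtl_targets"]])
  # high allele must be consistent with the effect-size sign
  expect_true(all((targets$effect_size > 0) == (targets$high_allele == "B6")))
})
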