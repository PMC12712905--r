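test_that("signed distance is strand-aware", {
  expect_equal(signed_distance(100000, "+", 149000, 151000), 50000)
  expect_equal(signed_distance(100000, "-", 149000, 151000), -50000)
  expect_equal(signed_distance(150000, "+", 149500, 150500), 0)
  expect_equal(signed_distance(150000, "-", 149500, 150500), 0)
  expect_error(signed_distance(1, "*", 0, 10))
})

test_that("connections respect the window and boundary rules", {
  rc <- rad_config()
  genes <- data.table(chrom = "chr1", tss = 1e6, strand = "+",
                      gene_id = "g1")
  pk <- function(mid) data.table(peak_id = "p1", chrom = "chr1",
                                 start = mid - 50, end = mid + 50)
  # +50 kb: one connection in bin (0, +100000]
  conn <- build_connections(genes, pk(1e6 + 5e4), "g1", "p1", rc)
  expect_equal(nrow(conn), 1)
  expect_equal(rc$bins[bin == conn$bin, .(lower, upper)],
               data.table(lower = 0, upper = 1e5))
  # exactly +window: retained in the outermost bin (closed upper bound)
  conn_hi <- build_connections(genes, pk(1e6 + 5e5), "g1", "p1", rc)
  expect_equal(conn_hi$bin, 10L)
  # exactly -window: retained in the first bin (closed lower bound)
  conn_lo <- build_connections(genes, pk(1e6 - 5e5), "g1", "p1", rc)
  expect_equal(conn_lo$bin, 1L)
  # distance 0 goes to (-bin_width, 0]
  conn_0 <- build_connections(genes, pk(1e6), "g1", "p1", rc)
  expect_equal(conn_0$bin, 5L)
  # just outside: dropped
  conn_out <- build_connections(genes, pk(1e6 + 5e5 + 100), "g1", "p1", rc)
  expect_equal(nrow(conn_out), 0)
  expect_error(build_connections(genes[0], pk(1e6), character(), "p1", rc),
               "empty gene background")
  expect_error(build_connections(genes, pk(1e6), "gX", "p1", rc),
               "focal_genes")
  expect_error(rad_config(5e5, 3e5), "divisible")
})

test_that("connection set equals the brute-force double loop", {
  set.seed(40)
  rc <- rad_config()
  ng <- 50; np <- 50
  genes <- data.table(chrom = sample(c("chr1", "chr2"), ng, TRUE),
                      tss = sample(2e6, ng) + 1e6,
                      strand = sample(c("+", "-"), ng, TRUE),
                      gene_id = sprintf("g%d", 1:ng))
  st <- sample(5e6, np)
  peaks <- data.table(peak_id = sprintf("p%d", 1:np),
                      chrom = sample(c("chr1", "chr2"), np, TRUE),
                      start = st, end = st + 400)
  conn <- build_connections(genes, peaks, genes$gene_id[1:5],
                            peaks$peak_id[1:5], rc)
  brute <- list()
  for (i in 1:ng) for (j in 1:np) {
    if (genes$chrom[i] != peaks$chrom[j]) next
    d <- signed_distance(genes$tss[i], genes$strand[i],
                         peaks$start[j], peaks$end[j])
    if (d >= -rc$window_bp && d <= rc$window_bp)
      brute[[length(brute) + 1]] <- data.table(
        gene_id = genes$gene_id[i], peak_id = peaks$peak_id[j],
        distance = d)
  }
  brute <- rbindlist(brute)
  expect_equal(
    as.data.frame(conn[order(gene_id, peak_id),
                       .(gene_id, peak_id, distance)]),
    as.data.frame(brute[order(gene_id, peak_id)]))
  # invariant: per-bin trials sum to the total focal-peak connections
  enr <- rad_enrichment(conn, rc)
  expect_equal(sum(enr$n), conn[peak_focal == TRUE, .N])
})

test_that("RAD binomial arithmetic matches brute-force tails", {
  rc <- rad_config()
  # hand-built: one bin with n = 10 trials, k = 8 focal, p0 = 0.3
  conn <- data.table(gene_id = sprintf("g%d", 1:10),
                     peak_id = "p1", distance = -5e4, bin = 5L,
                     gene_focal = c(rep(TRUE, 8), rep(FALSE, 2)),
                     peak_focal = TRUE)
  enr <- rad_enrichment(conn, rc, n_total = 100, m_focal = 30)
  b5 <- enr[bin == 5]
  expect_equal(b5$pvalue, oracle_binom_tail(8, 10, 0.3), tolerance = 1e-12)
  expect_equal(b5$oe, (8 / 10) / 0.3, tolerance = 1e-12)
  # empty bins report p = 1 and flagged O/E
  expect_true(all(enr[bin != 5, pvalue] == 1))
  expect_true(all(is.na(enr[bin != 5, oe])))
  expect_true(all(enr[bin != 5, empty]))
  # O/E invariance under uniform duplication of every connection
  enr_dup <- rad_enrichment(rbind(conn, conn), rc,
                            n_total = 100, m_focal = 30)
  expect_equal(enr_dup[bin == 5, .(n, k)], data.table(n = 20L, k = 16L))
  expect_equal(enr_dup[bin == 5, oe], b5$oe)
  # degenerate focal set: p0 = 1, all successes, O/E = 1, p = 1
  enr_all <- rad_enrichment(conn[, gene_focal := TRUE], rc,
                            n_total = 100, m_focal = 100)
  expect_equal(enr_all[bin == 5, oe], 1)
  expect_equal(enr_all[bin == 5, pvalue], 1)
  # property: binomial p equals direct summation for n <= 1000
  set.seed(41)
  for (i in 1:10) {
    n <- sample(1000, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(pbinom(k - 1, n, p0, lower.tail = FALSE),
                 oracle_binom_tail(k, n, p0), tolerance = 1e-10)
  }
})

test_that("directional concordance: matched allele pairing enriches, crossed does not", {
  # B6-higher peaks planted near B6-higher genes, D2 near D2, plus noise
  set.seed(42)
  mk_genes <- function(n, off, tag)
    data.table(chrom = "chr1", tss = off + (1:n) * 3e6, strand = "+",
               gene_id = sprintf("%s%d", tag, 1:n))
  g_b6 <- mk_genes(15, 0, "gb")
  g_d2 <- mk_genes(15, 5e7, "gd")
  g_bg <- mk_genes(60, 1.2e8, "gx")
  genes <- rbind(g_b6, g_d2, g_bg)
  plant <- function(g, tag) {
    mid <- g$tss - sample(1e5, nrow(g))   # upstream within 100 kb
    data.table(peak_id = sprintf("%s%d", tag, seq_len(nrow(g))),
               chrom = "chr1", start = mid - 50, end = mid + 50)
  }
  p_b6 <- plant(g_b6, "pb")
  p_d2 <- plant(g_d2, "pd")
  st <- sample(3e8, 100)
  p_bg <- data.table(peak_id = sprintf("px%d", 1:100), chrom = "chr1",
                     start = st, end = st + 100)
  peaks <- rbind(p_b6, p_d2, p_bg)
  rc <- rad_config()
  run <- function(fg, fp) {
    conn <- build_connections(genes, peaks, fg, fp, rc)
    min(rad_enrichment(conn, rc)$qvalue)
  }
  expect_lt(run(g_b6$gene_id, p_b6$peak_id), 0.05)  # matched B6/B6
  expect_lt(run(g_d2$gene_id, p_d2$peak_id), 0.05)  # matched D2/D2
  expect_gt(run(g_b6$gene_id, p_d2$peak_id), 0.05)  # crossed
  expect_gt(run(g_d2$gene_id, p_b6$peak_id), 0.05)  # crossed
})
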