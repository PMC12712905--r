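test_that("TMM factors: identity, depth absorption, geometric mean, scale invariance", {
  set.seed(10)
  base <- rnbinom(500, mu = 200, size = 10) + 1
  m <- named_counts(cbind(base, base))
  f <- tmm_factors(m)
  expect_equal(f$tmm_factor, c(1, 1))

  # pure 2x depth difference: factors stay 1, library size absorbs it,
  # so CPM agree feature-by-feature
  m2 <- named_counts(cbind(base, base * 2))
  f2 <- tmm_factors(m2)
  expect_equal(f2$tmm_factor, c(1, 1), tolerance = 1e-12)
  cp <- cpm(m2, f2)
  expect_equal(cp[, 1], cp[, 2])

  # geometric mean is 1 and factors are invariant to global scaling
  m3 <- named_counts(matrix(rnbinom(500 * 4, mu = 100, size = 5) + 1,
                            ncol = 4))
  f3 <- tmm_factors(m3)
  expect_equal(exp(mean(log(f3$tmm_factor))), 1, tolerance = 1e-9)
  f3b <- tmm_factors(m3 * 3)
  expect_equal(f3b$tmm_factor, f3$tmm_factor, tolerance = 1e-12)

  expect_error(tmm_factors(named_counts(cbind(c(0, 0), c(1, 2)))),
               "all-zero")
})

test_that("TMM matches edgeR on clean NB data", {
  set.seed(11)
  m <- named_counts(matrix(rnbinom(2000 * 5, mu = 150, size = 8) + 1,
                           ncol = 5))
  f <- tmm_factors(m)
  f_edger <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(f$tmm_factor, unname(f_edger), tolerance = 1e-8)
})

test_that("confidence filter reproduces the hand-evaluated toy table", {
  ints <- data.table(
    int_id = sprintf("i%d", 1:6),
    chrom1 = "chr1", start1 = 0, end1 = 100, chrom2 = "chr1",
    start2 = c(4000, 6000, 6000, 6000, 6000, 6000) - 50,
    end2 = c(4000, 6000, 6000, 6000, 6000, 6000) + 50)
  cnt <- matrix(c(5, 5, 5, 5, 4, 4, 4, 3, 3, 3, 0, 9),
                ncol = 2, byrow = TRUE,
                dimnames = list(ints$int_id, c("s1", "s2")))
  res <- filter_interactions(ints, cnt, filter_spec())
  expect_identical(res$interactions$int_id, c("i2", "i3"))
  expect_equal(res$report$n_retained, 2)
  expect_equal(res$report$n_fail_span, 1)
  # min_count = 0 keeps everything that clears the span rule
  res0 <- filter_interactions(ints, cnt, filter_spec(min_count = 0))
  expect_equal(res0$report$n_retained, 5)
  # empty input is not an error
  res_e <- filter_interactions(ints[0], cnt, filter_spec())
  expect_equal(nrow(res_e$interactions), 0)
  expect_error(filter_interactions(ints, cnt[1:3, ], filter_spec()),
               "missing count row")
})

test_that("common dispersion estimator brackets the truth", {
  g <- rep(c("A", "B"), each = 3)
  set.seed(12)
  m_p <- named_counts(matrix(rpois(2000 * 6, 150), ncol = 6))
  expect_lt(estimate_common_dispersion(m_p, g), 0.02)
  m_nb <- named_counts(matrix(rnbinom(2000 * 6, mu = 200, size = 5),
                              ncol = 6))
  phi <- estimate_common_dispersion(m_nb, g)
  expect_gt(phi, 0.15)
  expect_lt(phi, 0.25)
  # exactly constant counts: clipped at zero
  m_c <- named_counts(matrix(100, nrow = 10, ncol = 4))
  expect_equal(estimate_common_dispersion(m_c, rep(c("A", "B"), 2)), 0)
  expect_error(estimate_common_dispersion(m_p[, 1, drop = FALSE], "A"),
               ">= 2 samples")
})

test_that("nb_exact_test equals the binomial-split oracle at phi = 0", {
  set.seed(13)
  m <- named_counts(matrix(rpois(300 * 6, 50), ncol = 6))
  fac <- equal_factors(m)
  g <- rep(c("A", "B"), each = 3)
  res <- nb_exact_test(m, g, 0, fac)
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    k <- sum(m[i, 1:3]); s <- sum(m[i, ])
    if (s == 0) return(1)
    min(1, 2 * min(pbinom(k, s, 0.5),
                   pbinom(k - 1, s, 0.5, lower.tail = FALSE)))
  }, numeric(1))
  expect_equal(res$pvalue, oracle, tolerance = 1e-12)
})

test_that("nb_exact_test is exchangeable under group swap and symmetric at equal means", {
  set.seed(14)
  m <- named_counts(matrix(rnbinom(200 * 6, mu = 80, size = 10), ncol = 6))
  fac <- tmm_factors(m)
  g <- rep(c("A", "B"), each = 3)
  r1 <- nb_exact_test(m, factor(g, levels = c("A", "B")), 0.1, fac)
  r2 <- nb_exact_test(m, factor(g, levels = c("B", "A")), 0.1, fac)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  # exactly mirrored counts: zero fold change
  m3 <- named_counts(matrix(c(5, 9, 7, 7, 9, 5), nrow = 1))
  fc <- nb_exact_test(m3, g, 0, equal_factors(m3))$log2fc
  expect_equal(fc, 0)
  expect_error(nb_exact_test(m, rep(c("A", "B", "C"), 2), 0.1, fac),
               "two groups")
})

test_that("BH adjustment equals brute force and p.adjust, and is stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(15)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(sort(bh_adjust(p[perm])), sort(q), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential calling recovers planted effects with monotone power", {
  set.seed(16)
  g <- rep(c("A", "B"), each = 3)
  power_at <- function(fold) {
    mu <- exp(rnorm(2000, log(100), 0.5))
    mu_b <- mu; mu_b[1:100] <- mu_b[1:100] * fold
    m <- named_counts(cbind(
      matrix(rnbinom(2000 * 3, mu = rep(mu, 3), size = 20), ncol = 3),
      matrix(rnbinom(2000 * 3, mu = rep(mu_b, 3), size = 20), ncol = 3)))
    fac <- tmm_factors(m)
    phi <- estimate_common_dispersion(m, g, fac)
    di <- call_differential(nb_exact_test(m, g, phi, fac), 0.2)
    sum(di$feature_id %in% sprintf("f%d", 1:100))
  }
  p4 <- power_at(4)
  expect_gte(p4, 90)
  expect_gte(p4, power_at(1.5))  # monotone in effect size
  # trivial thresholds
  r <- data.table(feature_id = c("a", "b"), log2fc = c(1, 0),
                  qvalue = c(0.5, 0.9))
  expect_equal(nrow(call_differential(r, 0.2)), 0)
  all_in <- call_differential(r, 1.0)
  expect_equal(nrow(all_in), 2)
  expect_true(is.na(all_in[feature_id == "b", direction]))
})
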