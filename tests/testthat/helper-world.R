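# Shared fixtures and independent oracles for the test-suite.
library(data.table)

# A small, fast world for determinism/structure tests (not for recovery).
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 4L, chrom_length_bp = 3e7, n_genes = 400L,
         n_peaks = 300L, n_interactions = 200L, n_trans_targets = 60L,
         n_cis_targets = 60L, n_trans_egenes = 12L,
         replicates_per_strain = 2L, seed = 7L),
    list(...))
  do.call(sim_config, args)
}

# brute-force BH step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)          # rank of p[i]
    q[i] <- min(1, min(p[o][r:m] * m / (r:m)))
  }
  q
}

# brute-force one-sided (greater) binomial tail
oracle_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
             numeric(1)))
}

# brute-force two-sided Fisher p by full hypergeometric enumeration
oracle_fisher <- function(a, b, c_, d) {
  rs1 <- a + b; cs1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, cs1 - (n - rs1)); hi <- min(rs1, cs1)
  pr <- vapply(lo:hi, function(x) dhyper(x, cs1, n - cs1, rs1), numeric(1))
  sum(pr[pr <= dhyper(a, cs1, n - cs1, rs1) * (1 + 1e-7)])
}

# exact two-sided rank-sum p by permuting group assignment of the values
oracle_ranksum_exact <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  r <- rank(v)
  ew <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - ew)
  sets <- utils::combn(n, n1)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(ws - ew) >= obs - 1e-12)
}

# one-way ANOVA F from first principles
oracle_anova_f <- function(y, grp) {
  grp <- factor(grp)
  gm <- mean(y)
  means <- tapply(y, grp, mean); ns <- tapply(y, grp, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[grp])^2)
  (ssb / (nlevels(grp) - 1)) / (ssw / (length(y) - nlevels(grp)))
}

# noise-free doubly-trimmed weighted mean TMM factor (one sample vs ref)
oracle_tmm_pair <- function(obs_c, ref_c, trim_m = 0.3, trim_a = 0.05) {
  keep <- obs_c > 0 & ref_c > 0
  o <- obs_c[keep]; r <- ref_c[keep]
  no <- sum(obs_c); nr <- sum(ref_c)
  m <- log2((o / no) / (r / nr))
  a <- 0.5 * log2((o / no) * (r / nr))
  w <- (no - o) / (no * o) + (nr - r) / (nr * r)
  nn <- length(m)
  lo_m <- floor(nn * trim_m) + 1; hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * trim_a) + 1; hi_a <- nn + 1 - lo_a
  k <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[k] / w[k]) / sum(1 / w[k]))
}

# counts matrix with named dims
named_counts <- function(m) {
  rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

# factors table forcing equal effective library sizes (identity CPM scale)
equal_factors <- function(m, eff = 1e6) {
  data.table::data.table(sample = colnames(m), lib_size = colSums(m),
                         tmm_factor = 1, eff_lib_size = eff)
}
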