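# TMM normalization, confidence filtering and exact negative-binomial
# differential testing for PET-count and peak-count matrices.
#
# The differential test is an exact conditional test with a single common
# dispersion: counts are quantile-adjusted to a common effective library
# size, and the group-sum split is compared with its conditional
# distribution given the total — beta-binomial with shape (n_A/phi,
# n_B/phi), collapsing to a binomial split when phi = 0.  This matches the
# small-replicate design (2-3 lines per strain) and has a closed-form
# oracle at phi = 0.

#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample (the one whose
#' upper-quartile of library-size-scaled counts is closest to the mean
#' upper-quartile).  Per-sample factors are inverse-variance-weighted means
#' of gene-wise log2 ratios after doubly trimming by log ratio (`trim_m`)
#' and by average abundance (`trim_a`); features with a zero in either
#' sample are excluded.  Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Count matrix, features x samples (>= 2 samples).
#' @param trim_m Two-sided trim fraction on M values (default 0.30).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @return `data.table` with columns sample, lib_size, tmm_factor,
#'   eff_lib_size.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("sample with all-zero counts: ",
                          colnames(counts)[which(lib <= 0)[1L]],
                          call. = FALSE)
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              trim_m, trim_a)
  }, numeric(1))
  f <- f / .geomean(f)
  data.table::data.table(sample = colnames(counts), lib_size = lib,
                         tmm_factor = f, eff_lib_size = lib * f)
}

# One sample vs reference: doubly-trimmed weighted mean of M values.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2) || sum(1 / w[keep2]) == 0) return(1)
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Counts per million on effective library sizes
#'
#' @param counts Count matrix.
#' @param factors A [tmm_factors()] table (computed if `NULL`).
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$eff_lib_size[match(colnames(counts), factors$sample)]
  if (anyNA(eff)) stop("factors missing for some samples", call. = FALSE)
  sweep(counts, 2, eff / 1e6, "/")
}

#' Confidence-filter specification
#'
#' High-confidence interactions span more than `min_span_bp` and carry at
#' least `min_count` PETs in at least `min_samples` samples.  The upstream
#' loop-caller confidence FDR (< 0.01) is treated as a property of the
#' called input interactions, not recomputed here.
#'
#' @param min_span_bp Minimum span, exclusive (default 5000).
#' @param confidence_fdr Upstream loop-call FDR accepted as given.
#' @param min_count Minimum per-sample count (default 4).
#' @param min_samples Minimum number of samples reaching it (default 2).
#' @param di_fdr FDR threshold for calling differential features.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(min_span_bp = 5000, confidence_fdr = 0.01,
                        min_count = 4, min_samples = 2, di_fdr = 0.2) {
  stopifnot(min_span_bp > 0, min_count >= 0, min_samples >= 0,
            di_fdr > 0, di_fdr <= 1)
  structure(list(min_span_bp = min_span_bp, confidence_fdr = confidence_fdr,
                 min_count = min_count, min_samples = min_samples,
                 di_fdr = di_fdr), class = "filter_spec")
}

#' Filter interactions for confidence
#'
#' Retains interactions with span strictly greater than `min_span_bp` AND
#' `min_count` counts in at least `min_samples` samples, preserving input
#' order, and reports how many failed each criterion (independently
#' tallied).
#'
#' @param interactions data.frame with chrom1..end2 and an id column
#'   (`int_id` or `name`) matching count rownames.
#' @param counts Count matrix with one row per interaction.
#' @param spec A [filter_spec()].
#' @return List with `interactions` (retained rows) and `report`.
#' @export
filter_interactions <- function(interactions, counts, spec = filter_spec()) {
  x <- data.table::as.data.table(interactions)
  idcol <- intersect(c("int_id", "name", "id"), names(x))[1L]
  if (is.na(idcol)) stop("interactions need an id column", call. = FALSE)
  ids <- x[[idcol]]
  if (!all(ids %in% rownames(counts)))
    stop("missing count row for interaction ",
         setdiff(ids, rownames(counts))[1L], call. = FALSE)
  cm <- counts[ids, , drop = FALSE]
  if (nrow(x) == 0)
    return(list(interactions = x,
                report = list(n_input = 0L, n_fail_span = 0L,
                              n_fail_count = 0L, n_retained = 0L)))
  ok_span <- interaction_span(x) > spec$min_span_bp
  ok_count <- rowSums(cm >= spec$min_count) >= spec$min_samples
  keep <- ok_span & ok_count
  list(interactions = x[keep],
       report = list(n_input = nrow(x),
                     n_fail_span = sum(!ok_span),
                     n_fail_count = sum(!ok_count),
                     n_retained = sum(keep)))
}

#' Method-of-moments common dispersion
#'
#' Counts are scaled to a common effective library size; for each feature
#' the pooled within-group sample variance is compared with the NB
#' mean-variance identity `var = mu + phi mu^2`, and per-feature moment
#' estimates are combined as a precision-weighted ratio (weights
#' proportional to the squared group means).  Clipped at 0.
#'
#' @param counts Count matrix.
#' @param groups Group label per sample (>= 2 groups, >= 2 samples in some
#'   group).
#' @param factors Optional [tmm_factors()] table.
#' @return Scalar phi >= 0.
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL) {
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$eff_lib_size[match(colnames(counts), factors$sample)]
  z <- sweep(counts, 2, eff / .geomean(eff), "/")
  num <- 0; den <- 0
  for (g in levels(groups)) {
    j <- which(groups == g)
    if (length(j) < 2L) next
    zg <- z[, j, drop = FALSE]
    m <- rowMeans(zg)
    v <- apply(zg, 1, var)
    df <- length(j) - 1L
    num <- num + df * (v - m)
    den <- den + df * m^2
  }
  if (all(den == 0)) stop("no group with >= 2 samples and signal",
                          call. = FALSE)
  max(0, sum(num) / sum(den))
}

# Quantile-map a count observed at mean mu_in to the count scale with mean
# mu_out, preserving its (mid-)percentile under the NB(phi) model.  With
# mu_in == mu_out this is the identity.
.q2q_counts <- function(y, mu_in, mu_out, phi) {
  if (phi > 0) {
    sz <- 1 / phi
    p_mid <- 0.5 * (pnbinom(y, size = sz, mu = mu_in) +
                      pnbinom(y - 1, size = sz, mu = mu_in))
    p_mid <- pmin(pmax(p_mid, 1e-12), 1 - 1e-12)
    qnbinom(p_mid, size = sz, mu = mu_out)
  } else {
    p_mid <- 0.5 * (ppois(y, mu_in) + ppois(y - 1, mu_in))
    p_mid <- pmin(pmax(p_mid, 1e-12), 1 - 1e-12)
    qpois(p_mid, mu_out)
  }
}

#' Exact conditional NB test for two groups
#'
#' Per feature, counts are quantile-adjusted to the common (geometric mean)
#' effective library size, then the first-group pseudo-count sum `k` is
#' tested against its conditional distribution given the total `s`:
#' beta-binomial(s, n_A/phi, n_B/phi), or binomial(s, n_A/(n_A+n_B)) when
#' `phi = 0`.  Two-sided p doubles the smaller tail, capped at 1.  Fold
#' changes are log2 ratios of group mean CPM with a 0.5 pseudo-count, in
#' first-level-over-second-level orientation.
#'
#' @param counts Count matrix.
#' @param groups Two-level factor (or coercible); the first level is the
#'   numerator of the fold change.
#' @param phi Common NB dispersion (>= 0).
#' @param factors Optional [tmm_factors()] table.
#' @return `data.table`: feature_id, group mean CPMs, log2fc, dispersion,
#'   pvalue, qvalue (BH).  Attribute `groups` records the level order.
#' @export
nb_exact_test <- function(counts, groups, phi, factors = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("nb_exact_test needs exactly two groups; run pairwise",
         call. = FALSE)
  stopifnot(phi >= 0)
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$eff_lib_size[match(colnames(counts), factors$sample)]
  if (anyNA(eff)) stop("factors missing for some samples", call. = FALSE)
  jA <- which(groups == levels(groups)[1L])
  jB <- which(groups == levels(groups)[2L])
  nA <- length(jA); nB <- length(jB)
  lstar <- .geomean(eff)
  lambda <- rowSums(counts) / sum(eff)
  pseudo <- counts
  for (j in seq_len(ncol(counts)))
    pseudo[, j] <- .q2q_counts(counts[, j], lambda * eff[j],
                               lambda * lstar, phi)
  kA <- round(rowSums(pseudo[, jA, drop = FALSE]))
  s <- kA + round(rowSums(pseudo[, jB, drop = FALSE]))
  nf <- nrow(counts)
  p <- rep(1, nf)
  if (phi == 0) {
    pr <- nA / (nA + nB)
    nz <- s > 0
    lo <- pbinom(kA[nz], s[nz], pr)
    hi <- pbinom(kA[nz] - 1, s[nz], pr, lower.tail = FALSE)
    p[nz] <- pmin(1, 2 * pmin(lo, hi))
  } else {
    a <- nA / phi; b <- nB / phi
    lbab <- lbeta(a, b)
    for (g in which(s > 0)) {
      sg <- s[g]
      k <- 0:sg
      pmf <- exp(lchoose(sg, k) + lbeta(k + a, sg - k + b) - lbab)
      pmf <- pmf / sum(pmf)
      lo <- sum(pmf[k <= kA[g]])
      hi <- sum(pmf[k >= kA[g]])
      p[g] <- min(1, 2 * min(lo, hi))
    }
  }
  cp <- cpm(counts, factors)
  mA <- rowMeans(cp[, jA, drop = FALSE])
  mB <- rowMeans(cp[, jB, drop = FALSE])
  out <- data.table::data.table(
    feature_id = if (is.null(rownames(counts)))
      sprintf("f%d", seq_len(nf)) else rownames(counts),
    mean_cpm_a = mA, mean_cpm_b = mB,
    log2fc = log2((mA + 0.5) / (mB + 0.5)),
    dispersion = phi, pvalue = p)
  out[, qvalue := bh_adjust(pvalue)]
  data.table::setattr(out, "groups", levels(groups))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; stable under
#' permutation of the input (same multiset of q values, original order
#' preserved).
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return Vector of q values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(pvals[o] * m / (m:1)))[ro]
}

#' Call differential features at an FDR threshold
#'
#' @param results A [nb_exact_test()] table (must carry `qvalue`).
#' @param di_fdr FDR threshold (default 0.2).
#' @return Subset with q <= `di_fdr` and a `direction` column
#'   (`higher_in_<group>`; `NA` for a log2 fold change of exactly 0, which
#'   is excluded from all downstream directional tallies).
#' @export
call_differential <- function(results, di_fdr = 0.2) {
  stopifnot("qvalue" %in% names(results))
  lv <- attr(results, "groups")
  if (is.null(lv)) lv <- c("A", "B")
  out <- data.table::as.data.table(results)[qvalue <= di_fdr]
  out[, direction := data.table::fifelse(
    log2fc > 0, sprintf("higher_in_%s", lv[1L]),
    data.table::fifelse(log2fc < 0, sprintf("higher_in_%s", lv[2L]),
                        NA_character_))]
  out
}
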