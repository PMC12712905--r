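# F1 inheritance mode per feature: the dominance coefficient d scales the
# F1's deviation from the parental midpoint by half the parental range, so
# d = -1 when the F1 equals the low parent (dominant repression), 0 at the
# midpoint (additive), +1 at the high parent; |d| > 1 (over-dominance) is
# representable.

#' Dominance coefficient
#'
#' `d = (F1 - MP) / (HP - MP)` with `MP = (B6 + D2) / 2`, `HP`/`LP` the
#' parental max/min.  Undefined (NA) when the half parental range is below
#' `epsilon`, where d is numerically unstable.
#'
#' @param b6_mean,d2_mean,f1_mean Normalized log2-scale strain means
#'   (vectorized).
#' @param epsilon Minimum half parental range in log2 units (default 0.05).
#' @return Numeric vector of d (NA where undefined).
#' @export
dominance_coefficient <- function(b6_mean, d2_mean, f1_mean,
                                  epsilon = 0.05) {
  hp <- pmax(b6_mean, d2_mean)
  mp <- (b6_mean + d2_mean) / 2
  denom <- hp - mp
  ifelse(denom < epsilon, NA_real_, (f1_mean - mp) / denom)
}

#' Classify the repressive allele of QTL targets
#'
#' The repressive allele is the QTL genotype associated with lower
#' accessibility: D2 when the B6-minus-D2 effect size is positive, B6 when
#' negative, unclassified (NA, excluded with a count) at exactly zero.
#'
#' @param targets data.frame with `target_id` (or `feature_id`) and
#'   `effect_size` signed B6-minus-D2.
#' @return List: `calls` (`data.table` feature_id, repressive_allele,
#'   effect_size), `n_unclassified`.
#' @export
classify_repressive_allele <- function(targets) {
  tg <- data.table::as.data.table(targets)
  idcol <- intersect(c("target_id", "feature_id", "id"), names(tg))[1L]
  stopifnot(!is.na(idcol), "effect_size" %in% names(tg))
  allele <- data.table::fifelse(tg$effect_size > 0, "D2",
                                data.table::fifelse(tg$effect_size < 0,
                                                    "B6", NA_character_))
  calls <- data.table::data.table(feature_id = tg[[idcol]],
                                  repressive_allele = allele,
                                  effect_size = tg$effect_size)
  list(calls = calls[!is.na(repressive_allele)],
       n_unclassified = sum(is.na(allele)))
}

#' Per-feature dominance table from counts
#'
#' TMM-normalizes the B6/D2/F1 samples of one assay together, takes
#' per-strain means of `log2(CPM + 0.5)`, joins the QTL-target table
#' (filtered at `min_lod`), and computes d per target.
#'
#' @param counts Count matrix for the assay.
#' @param sample_sheet Sample sheet (needs strains B6, D2, F1).
#' @param targets QTL-target table with target_id, mode, lod.
#' @param assay Assay label to select samples (default "ATAC").
#' @param min_lod LOD filter, exclusive (default 8, the high-confidence
#'   cutoff); set to `-Inf` to disable.
#' @param epsilon Passed to [dominance_coefficient()].
#' @return `data.table`: feature_id, mode, b6, d2, f1, d (NA when
#'   epsilon-gated); attribute `n_undefined`.
#' @export
dominance_table <- function(counts, sample_sheet, targets, assay = "ATAC",
                            min_lod = 8, epsilon = 0.05) {
  ss <- data.table::as.data.table(sample_sheet)
  a <- assay
  sel <- ss[assay == a & strain %in% c("B6", "D2", "F1")]
  if (length(unique(sel$strain)) < 3L)
    stop("need B6, D2 and F1 samples", call. = FALSE)
  m <- counts[, sel$sample, drop = FALSE]
  lc <- log2(cpm(m) + 0.5)
  sm <- sapply(c("B6", "D2", "F1"), function(s)
    rowMeans(lc[, sel$sample[sel$strain == s], drop = FALSE]))
  tg <- data.table::as.data.table(targets)
  tg <- tg[target_id %in% rownames(m) & (is.na(lod) | lod > min_lod)]
  tg <- tg[!is.na(lod)]
  out <- data.table::data.table(
    feature_id = tg$target_id, mode = tg$mode,
    b6 = sm[tg$target_id, "B6"], d2 = sm[tg$target_id, "D2"],
    f1 = sm[tg$target_id, "F1"])
  out[, d := dominance_coefficient(b6, d2, f1, epsilon)]
  data.table::setattr(out, "n_undefined", sum(is.na(out$d)))
  out
}

# Rank-sum machinery shared by dominance and congenic effect-size
# comparisons: two-sided, exact by rank-permutation enumeration for small
# samples, otherwise normal approximation with tie correction and
# continuity correction.
.ranksum <- function(x, y, exact_max = 10L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups need values", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])           # rank-sum statistic of group 1
  u <- w - n1 * (n1 + 1) / 2         # Mann-Whitney U
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) {
    return(list(W = w, U = u, z = 0, p = 1, r = 0, method = "degenerate"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  if (n <= exact_max) {
    ew <- n1 * (n + 1) / 2
    obs_dev <- abs(w - ew)
    sets <- utils::combn(n, n1)
    ws <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(ws - ew) >= obs_dev - 1e-12)
    method <- "exact"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = w, U = u, z = z, p = p, r = abs(z) / sqrt(n), method = method)
}

#' Compare dominance between trans and cis targets
#'
#' Two-sided Wilcoxon rank-sum on the per-feature d values (exact
#' enumeration for small samples, normal approximation with tie correction
#' otherwise), with effect size `abs(Z) / sqrt(N)` and group medians.
#'
#' @param trans_d,cis_d Numeric d vectors (non-finite values dropped).
#' @return List: W, z, p, effect_size, method, medians, n.
#' @export
compare_dominance <- function(trans_d, cis_d) {
  trans_d <- trans_d[is.finite(trans_d)]
  cis_d <- cis_d[is.finite(cis_d)]
  if (length(trans_d) < 2 || length(cis_d) < 2)
    stop("both groups need >= 2 finite values", call. = FALSE)
  rs <- .ranksum(trans_d, cis_d)
  list(W = rs$W, z = rs$z, p = rs$p, effect_size = rs$r,
       method = rs$method,
       medians = c(trans = median(trans_d), cis = median(cis_d)),
       n = c(trans = length(trans_d), cis = length(cis_d)))
}
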