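# Integration of differential interactions with QTL targets: anchor
# overlap classification, permutation enrichment, strength-effect
# correlation, allele concordance and factor-binding enrichment.

#' Classify anchor overlap of differential interactions with QTL targets
#'
#' A DI is `one_anchor` if exactly one anchor overlaps at least one target,
#' `both_anchors` if each anchor does, else `none`.  Overlap follows the
#' half-open >= 1 bp rule of [interval_overlaps()].
#'
#' @param dis data.frame of interactions (chrom1..end2, id column).
#' @param targets data.frame of target intervals (chrom, start, end).
#' @return List with `per_di` (id, category) and `proportions` (named
#'   vector over none/one_anchor/both_anchors, summing to 1).
#' @export
classify_anchor_overlap <- function(dis, targets) {
  x <- data.table::as.data.table(dis)
  tg <- data.table::as.data.table(targets)
  o1 <- .overlap_any(x[, .(chrom = chrom1, start = start1, end = end1)], tg)
  o2 <- .overlap_any(x[, .(chrom = chrom2, start = start2, end = end2)], tg)
  n_hit <- as.integer(o1) + as.integer(o2)
  category <- c("none", "one_anchor", "both_anchors")[n_hit + 1L]
  idcol <- intersect(c("int_id", "name", "id"), names(x))[1L]
  ids <- if (is.na(idcol)) sprintf("di_%d", seq_len(nrow(x))) else x[[idcol]]
  per_di <- data.table::data.table(id = ids, category = category)
  props <- c(none = mean(category == "none"),
             one_anchor = mean(category == "one_anchor"),
             both_anchors = mean(category == "both_anchors"))
  if (!nrow(x)) props <- c(none = NA_real_, one_anchor = NA_real_,
                           both_anchors = NA_real_)
  list(per_di = per_di, proportions = props)
}

#' Permutation enrichment of anchor-target overlap
#'
#' Null: draw `|targets|` peaks uniformly without replacement from the peak
#' universe, reclassify, and record the one-anchor and both-anchor
#' proportions.  Empirical p uses the add-one estimator
#' `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param dis Interactions data.frame.
#' @param target_idx Integer indices (rows of `peak_universe`) that are the
#'   observed targets, or a character vector matched against the universe's
#'   `peak_id`/`name` column.
#' @param peak_universe data.frame of all candidate peaks.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List of class `enrichment_result` with observed proportions,
#'   permutation matrices, empirical p per category, n_perm, seed and a
#'   `degenerate` flag when `n_perm = 0`.
#' @export
permutation_enrichment <- function(dis, target_idx, peak_universe,
                                   n_perm = 1000, seed = 1L) {
  uni <- data.table::as.data.table(peak_universe)
  if (is.character(target_idx)) {
    idcol <- intersect(c("peak_id", "name", "id"), names(uni))[1L]
    if (is.na(idcol)) stop("universe needs an id column", call. = FALSE)
    target_idx <- match(target_idx, uni[[idcol]])
    if (anyNA(target_idx)) stop("targets not in universe", call. = FALSE)
  }
  n_t <- length(target_idx)
  if (n_t > nrow(uni)) stop("more targets than universe peaks",
                            call. = FALSE)
  x <- data.table::as.data.table(dis)
  anchors <- data.table::rbindlist(list(
    x[, .(chrom = chrom1, start = start1, end = end1)],
    x[, .(chrom = chrom2, start = start2, end = end2)]))
  hits <- .overlap_pairs(anchors, uni)
  hit_list <- split(hits$s, hits$q)
  n_di <- nrow(x)

  prop_for <- function(member) {
    a_hit <- logical(2L * n_di)
    if (length(hit_list))
      a_hit[as.integer(names(hit_list))] <-
        vapply(hit_list, function(ix) any(member[ix]), logical(1))
    n_hit <- as.integer(a_hit[seq_len(n_di)]) +
      as.integer(a_hit[n_di + seq_len(n_di)])
    c(one_anchor = mean(n_hit == 1L), both_anchors = mean(n_hit == 2L))
  }
  member <- logical(nrow(uni)); member[target_idx] <- TRUE
  obs <- prop_for(member)

  set.seed(seed)
  perms <- matrix(NA_real_, nrow = max(n_perm, 0), ncol = 2,
                  dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_perm)) {
    pm <- logical(nrow(uni))
    pm[sample.int(nrow(uni), n_t)] <- TRUE
    perms[i, ] <- prop_for(pm)
  }
  pvals <- vapply(names(obs), function(k)
    (1 + sum(perms[, k] >= obs[[k]])) / (1 + n_perm), numeric(1))
  structure(list(observed = obs, perm = perms, p = pvals,
                 n_perm = n_perm, seed = seed,
                 degenerate = n_perm == 0),
            class = "enrichment_result")
}

#' Correlate interaction strength with QTL effect size
#'
#' Pearson correlation with a t-distributed two-sided p, on one row per
#' (DI, overlapping target) pair — a DI overlapping k targets contributes
#' k rows, mirroring the fact that individual anchors can harbor several
#' QTL targets.
#'
#' @param di_log2fc Numeric vector of DI log2 fold changes (paired).
#' @param target_effect_sizes Numeric vector of QTL effect sizes (paired).
#' @param mode Label recorded in the output ("cis" or "trans").
#' @return List with r, p, n, mode.
#' @export
correlate_strength_effect <- function(di_log2fc, target_effect_sizes,
                                      mode = c("cis", "trans")) {
  mode <- match.arg(mode)
  stopifnot(length(di_log2fc) == length(target_effect_sizes))
  if (length(di_log2fc) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(di_log2fc) == 0 || stats::sd(target_effect_sizes) == 0)
    stop("zero variance", call. = FALSE)
  ct <- cor.test(di_log2fc, target_effect_sizes, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(di_log2fc),
       mode = mode, pairing = "one row per (DI, overlapping target) pair")
}

#' Allele concordance between DI direction and QTL high allele
#'
#' Cross-tabulates the strain with the stronger interaction against the
#' QTL high allele and applies a Pearson chi-squared test without
#' continuity correction.  Margins that are entirely zero are dropped
#' (with a flag) and df adjusted; if fewer than 2x2 levels remain the
#' statistic is `NA`.
#'
#' @param di_directions Character vector, e.g. "B6"/"D2" (strain with
#'   higher interaction strength).
#' @param target_high_alleles Character vector of the same length.
#' @return List of class `concordance_table` with table, statistic, df, p,
#'   concordant_fraction, low_expected flag, dropped_margins flag.
#' @export
allele_concordance <- function(di_directions, target_high_alleles) {
  stopifnot(length(di_directions) == length(target_high_alleles))
  tab <- table(di = di_directions, allele = target_high_alleles)
  dropped <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  tab2 <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab2) < 2 || ncol(tab2) < 2) {
    stat <- NA_real_; df <- NA_integer_; p <- NA_real_; low <- FALSE
  } else {
    e <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
    stat <- sum((tab2 - e)^2 / e)
    df <- (nrow(tab2) - 1L) * (ncol(tab2) - 1L)
    p <- pchisq(stat, df, lower.tail = FALSE)
    low <- mean(e < 1) > 0.2
    if (low)
      warning("more than 20% of expected cells < 1; chi-squared unreliable",
              call. = FALSE)
  }
  list(table = tab, statistic = stat, df = df, p = p,
       concordant_fraction = mean(di_directions == target_high_alleles),
       low_expected = isTRUE(low), dropped_margins = dropped)
}

#' Factor-binding enrichment at trans-target anchors
#'
#' For each factor, builds the 2x2 table (anchor in the trans set?) x
#' (anchor overlaps >= 1 binding site?) over the anchor universe, tests it
#' with a two-sided Fisher exact test (conditional-MLE odds ratio), and
#' ranks factors by BH q then odds ratio.  A Haldane (+0.5) sample OR is
#' reported alongside for zero cells.
#'
#' @param binding_site_sets Named list of interval data.frames, one per
#'   factor.
#' @param trans_anchor_ids Character ids of anchors in the trans set.
#' @param universe data.frame of all anchors with an id column
#'   (`anchor_id`/`name`/`id`) and chrom/start/end.
#' @return `data.table`: factor, table cells, odds_ratio (conditional MLE),
#'   or_haldane, pvalue, qvalue, ordered by q then decreasing OR.
#' @export
factor_binding_enrichment <- function(binding_site_sets, trans_anchor_ids,
                                      universe) {
  uni <- data.table::as.data.table(universe)
  if (!nrow(uni)) stop("empty anchor universe", call. = FALSE)
  idcol <- intersect(c("anchor_id", "peak_id", "name", "id"), names(uni))[1L]
  if (is.na(idcol)) stop("universe needs an id column", call. = FALSE)
  in_trans <- uni[[idcol]] %in% trans_anchor_ids
  rows <- lapply(names(binding_site_sets), function(f) {
    sites <- data.table::as.data.table(binding_site_sets[[f]])
    in_site <- if (nrow(sites)) .overlap_any(uni, sites)
               else logical(nrow(uni))
    a <- sum(in_trans & in_site); b <- sum(in_trans & !in_site)
    c_ <- sum(!in_trans & in_site); d <- sum(!in_trans & !in_site)
    ft <- fisher.test(matrix(c(a, c_, b, d), 2), alternative = "two.sided")
    data.table::data.table(
      factor = f, n_trans_site = a, n_trans_nosite = b,
      n_other_site = c_, n_other_nosite = d,
      odds_ratio = unname(ft$estimate),
      or_sample = (a * d) / (b * c_),
      or_haldane = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
      pvalue = ft$p.value)
  })
  out <- data.table::rbindlist(rows)
  out[, qvalue := bh_adjust(pvalue)]
  data.table::setorder(out, qvalue, -odds_ratio)
  out
}
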