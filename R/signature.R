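# Cross-assay fold-change analysis separating trans from cis regulation:
# fold changes, correlations, discordant-chromatin-state calling, the
# trans-vs-cis odds-ratio contrast and the connectivity-expression
# analysis.

#' Per-assay log2 fold changes between two strains
#'
#' For each assay, TMM-normalizes the two strains' samples together and
#' returns per-feature `log2((mean CPM A + 0.5) / (mean CPM B + 0.5))`.
#'
#' @param count_matrices Named list of count matrices (one per assay).
#' @param sample_sheet Sample sheet covering their columns.
#' @param strain_pair Character(2): numerator strain, denominator strain.
#' @return `data.table`: feature_id, assay, log2fc.
#' @export
assay_foldchanges <- function(count_matrices, sample_sheet,
                              strain_pair = c("B6", "D2")) {
  stopifnot(length(strain_pair) == 2)
  ss <- data.table::as.data.table(sample_sheet)
  rows <- lapply(names(count_matrices), function(a) {
    m <- count_matrices[[a]]
    sel <- ss[assay == a & strain %in% strain_pair]
    for (s in strain_pair)
      if (!any(sel$strain == s))
        stop(sprintf("assay %s is missing strain %s", a, s), call. = FALSE)
    m <- m[, sel$sample, drop = FALSE]
    cp <- cpm(m)
    mA <- rowMeans(cp[, sel$sample[sel$strain == strain_pair[1L]],
                      drop = FALSE])
    mB <- rowMeans(cp[, sel$sample[sel$strain == strain_pair[2L]],
                      drop = FALSE])
    data.table::data.table(feature_id = rownames(m), assay = a,
                           log2fc = log2((mA + 0.5) / (mB + 0.5)))
  })
  data.table::rbindlist(rows)
}

#' Correlate fold changes between two assays on a feature subset
#'
#' @param fc_table Long table with feature_id, assay, log2fc (e.g. from
#'   [assay_foldchanges()] or [nb_exact_test()] results bound together).
#' @param assay_x,assay_y Assay names to pair.
#' @param feature_subset Feature ids to restrict to (default: all shared).
#' @return List with r, p, n.
#' @export
correlate_assays <- function(fc_table, assay_x, assay_y,
                             feature_subset = NULL) {
  ft <- data.table::as.data.table(fc_table)
  x <- ft[assay == assay_x, .(feature_id, fx = log2fc)]
  y <- ft[assay == assay_y, .(feature_id, fy = log2fc)]
  m <- merge(x, y, by = "feature_id")
  if (!is.null(feature_subset)) m <- m[feature_id %in% feature_subset]
  if (nrow(m) < 3) stop("need >= 3 paired features", call. = FALSE)
  if (stats::sd(m$fx) == 0 || stats::sd(m$fy) == 0)
    stop("zero variance", call. = FALSE)
  ct <- cor.test(m$fx, m$fy, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Call discordant chromatin states
#'
#' A feature is discordant when accessibility and H3K9me3 move in opposite
#' directions between the strains — i.e. H3K9me3 is higher in the strain
#' with lower accessibility.  By default both assays must also pass a
#' per-assay differential significance gate (`q <= q_threshold`), which
#' keeps noise-level sign flips from being called discordant; set
#' `gate = FALSE` for the raw-sign definition.
#'
#' @param fc_table Long table with feature_id, assay, log2fc, qvalue for at
#'   least the `atac_assay` and `k9_assay` rows.
#' @param q_threshold Per-assay significance gate (default 0.05).
#' @param gate Apply the significance gate (default `TRUE`).
#' @param atac_assay,k9_assay Assay labels (defaults "ATAC", "H3K9me3").
#' @return `data.table`: feature_id, fc_atac, q_atac, fc_k9, q_k9,
#'   discordant.
#' @export
call_discordance <- function(fc_table, q_threshold = 0.05, gate = TRUE,
                             atac_assay = "ATAC", k9_assay = "H3K9me3") {
  ft <- data.table::as.data.table(fc_table)
  need <- c("feature_id", "assay", "log2fc")
  stopifnot(all(need %in% names(ft)))
  if (!"qvalue" %in% names(ft)) ft[, qvalue := 0]
  a <- ft[assay == atac_assay,
          .(feature_id, fc_atac = log2fc, q_atac = qvalue)]
  k <- ft[assay == k9_assay, .(feature_id, fc_k9 = log2fc, q_k9 = qvalue)]
  m <- merge(a, k, by = "feature_id")
  if (!nrow(m)) stop("no features shared between the two assays",
                     call. = FALSE)
  opposite <- sign(m$fc_atac) * sign(m$fc_k9) < 0
  sig <- if (gate) m$q_atac <= q_threshold & m$q_k9 <= q_threshold
         else TRUE
  m[, discordant := opposite & sig]
  m
}

#' Odds ratio of discordance, trans vs cis targets
#'
#' Single-predictor logistic contrast: the log odds ratio equals the log of
#' the 2x2 sample odds ratio (Haldane +0.5 when any cell is zero), with a
#' Wald p from `beta / SE` and a 95% Wald confidence interval.
#'
#' @param discordant Logical vector of discordance calls.
#' @param class_labels Character vector ("trans"/"cis") per feature.
#' @return List of class `signature_contrast`: table, beta, or, se, z, p,
#'   ci (95%).
#' @export
discordance_odds_ratio <- function(discordant, class_labels) {
  stopifnot(length(discordant) == length(class_labels))
  if (!all(c("trans", "cis") %in% class_labels))
    stop("need both trans and cis features", call. = FALSE)
  a <- sum(discordant & class_labels == "trans")
  b <- sum(!discordant & class_labels == "trans")
  c_ <- sum(discordant & class_labels == "cis")
  d <- sum(!discordant & class_labels == "cis")
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("trans", "cis"),
                                c("discordant", "concordant")))
  if (any(tab == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  beta <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- beta / se
  list(table = tab, beta = beta, or = exp(beta), se = se, z = z,
       p = 2 * pnorm(-abs(z)),
       ci = exp(beta + c(-1, 1) * 1.96 * se))
}

#' Promoter connectivity vs expression
#'
#' Counts, per gene, the interactions with an anchor overlapping the
#' promoter (TSS +/- `promoter_halfwidth`), stratifies genes with at least
#' one contact into connectivity quartiles (ties to the lower quartile),
#' and tests mean log2 CPM expression across quartiles with a one-way
#' ANOVA plus all pairwise Tukey HSD comparisons (studentized-range
#' distribution).
#'
#' @param interactions Interactions data.frame (chrom1..end2).
#' @param genes Gene table (chrom, tss, strand, gene_id).
#' @param rna_counts RNA count matrix (rows = gene ids).
#' @param promoter_halfwidth Promoter half-width in bp (default 2000).
#' @return List: `records` (gene_id, n_contacts, quartile, expr),
#'   `anova` (F, df1, df2, p), `tukey` (pairwise table).
#' @export
connectivity_expression <- function(interactions, genes, rna_counts,
                                    promoter_halfwidth = 2000) {
  g <- data.table::as.data.table(genes)
  x <- data.table::as.data.table(interactions)
  prom <- g[, .(chrom, start = pmax(0, tss - promoter_halfwidth),
                end = tss + promoter_halfwidth)]
  anchors <- data.table::rbindlist(list(
    x[, .(chrom = chrom1, start = start1, end = end1, int = .I)],
    x[, .(chrom = chrom2, start = start2, end = end2, int = .I)]))
  hits <- .overlap_pairs(prom, anchors[, .(chrom, start, end)])
  # an interaction touching a promoter with both anchors counts once
  hits[, int := anchors$int[s]]
  cc <- hits[, .(n = data.table::uniqueN(int)), by = q]
  g[, n_contacts := 0L]
  g[cc$q, n_contacts := cc$n]

  rec <- g[n_contacts >= 1L & gene_id %in% rownames(rna_counts),
           .(gene_id, n_contacts)]
  if (length(unique(rec$n_contacts)) < 4L)
    stop("fewer than 4 distinct connectivity values; cannot quartile",
         call. = FALSE)
  cp <- cpm(rna_counts)
  rec[, expr := rowMeans(log2(cp[gene_id, , drop = FALSE] + 0.5))]
  qs <- quantile(rec$n_contacts, c(0.25, 0.5, 0.75))
  rec[, quartile := cut(n_contacts, c(-Inf, qs, Inf),
                        labels = paste0("Q", 1:4), right = TRUE)]
  res <- .oneway_tukey(rec$expr, rec$quartile)
  list(records = rec, anova = res$anova, tukey = res$tukey)
}

# One-way ANOVA and Tukey HSD from first principles (direct arithmetic, so
# the degenerate all-equal case yields F = 0 rather than NaN).
.oneway_tukey <- function(y, grp) {
  grp <- droplevels(factor(grp))
  k <- nlevels(grp)
  n <- length(y)
  means <- tapply(y, grp, mean)
  ns <- tapply(y, grp, length)
  gm <- mean(y)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((y - means[grp])^2)
  df1 <- k - 1L; df2 <- n - k
  msw <- ssw / df2
  f <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df1) / msw
  p <- if (ssb == 0) 1 else if (ssw == 0) 0 else pf(f, df1, df2,
                                                    lower.tail = FALSE)
  pairs <- utils::combn(levels(grp), 2)
  tukey <- data.table::data.table(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = means[pairs[2, ]] - means[pairs[1, ]])
  se <- sqrt(msw / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  qstat <- abs(tukey$diff) / se
  tukey[, p_adj := if (msw == 0) as.numeric(diff == 0)
        else ptukey(qstat, k, df2, lower.tail = FALSE)]
  list(anova = list(F = f, df1 = df1, df2 = df2, p = p),
       tukey = tukey)
}
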