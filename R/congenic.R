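# Reciprocal-congenic direction prediction and validation.
#
# BXD-derived repressive-allele calls translate into signed predictions:
# introducing the repressive allele into the other background should raise
# H3K9me3 and lower ATAC/H3K27ac/PET at trans-targets; introducing the
# non-repressive allele should do the opposite.  Observed directions are
# signs of mean CPM differences (no significance gate — every target is
# counted, zero differences excluded), scored against a p0 = 0.5 exact
# binomial null.

.CONGENIC_ASSAYS <- c("H3K9me3", "ATAC", "H3K27ac", "PET")

#' The two reciprocal congenic comparisons
#'
#' @return `data.table`: comparison, parent, congenic, introduced (the
#'   master-locus allele the congenic introduces into the parent
#'   background).
#' @export
congenic_comparisons <- function() {
  data.table::data.table(
    comparison = c("B6_to_B6-13D2", "D2_to_D2-13B6"),
    parent = c("B6", "D2"),
    congenic = c("B6-13D2", "D2-13B6"),
    introduced = c("D2", "B6")
  )
}

#' Predicted direction of change per feature, assay and comparison
#'
#' If the introduced allele equals the feature's repressive allele the
#' prediction is + for H3K9me3 and - for ATAC/H3K27ac/PET; if it is the
#' non-repressive allele, the signs flip.  Unclassified features (NA
#' allele) are skipped with a count.
#'
#' @param calls `data.table` with feature_id, repressive_allele (B6/D2/NA).
#' @param assays Assays to predict for (default all four).
#' @param comparisons Subset of [congenic_comparisons()]`$comparison`.
#' @return List: `predictions` (feature_id, assay, comparison, predicted in
#'   {-1, +1}), `n_skipped`.
#' @export
predict_directions <- function(calls, assays = .CONGENIC_ASSAYS,
                               comparisons =
                                 congenic_comparisons()$comparison) {
  cl <- data.table::as.data.table(calls)
  stopifnot(all(c("feature_id", "repressive_allele") %in% names(cl)))
  n_skipped <- sum(is.na(cl$repressive_allele) |
                     !cl$repressive_allele %in% c("B6", "D2"))
  cl <- cl[repressive_allele %in% c("B6", "D2")]
  cmp <- congenic_comparisons()[comparison %in% comparisons]
  grid <- data.table::CJ(feature_id = cl$feature_id, assay = assays,
                         comparison = cmp$comparison, sorted = FALSE)
  grid <- merge(grid, cl[, .(feature_id, repressive_allele)],
                by = "feature_id")
  grid <- merge(grid, cmp[, .(comparison, introduced)], by = "comparison")
  grid[, predicted := data.table::fifelse(
    introduced == repressive_allele, 1L, -1L)]
  grid[assay != "H3K9me3", predicted := -predicted]
  list(predictions = grid[, .(feature_id, assay, comparison, predicted)],
       n_skipped = n_skipped)
}

#' Observed direction and magnitude for one congenic comparison
#'
#' TMM-normalizes the comparison's samples (parent + congenic of one
#' assay) together and reports, per feature, the sign and absolute value
#' of (mean congenic CPM - mean parent CPM).  Exact zeros get sign 0 and
#' are excluded downstream with a count.
#'
#' @param counts Count matrix for the assay.
#' @param sample_sheet Sample sheet.
#' @param assay Assay label.
#' @param comparison One of [congenic_comparisons()]`$comparison`.
#' @return `data.table`: feature_id, assay, comparison, observed_sign,
#'   magnitude.
#' @export
observe_direction <- function(counts, sample_sheet, assay, comparison) {
  wanted <- comparison
  cmp <- congenic_comparisons()[comparison == wanted]
  if (!nrow(cmp)) stop("unknown comparison: ", comparison, call. = FALSE)
  ss <- data.table::as.data.table(sample_sheet)
  a <- assay
  sel <- ss[assay == a & strain %in% c(cmp$parent, cmp$congenic)]
  for (s in c(cmp$parent, cmp$congenic))
    if (!any(sel$strain == s))
      stop("missing strain ", s, " for assay ", a, call. = FALSE)
  m <- counts[, sel$sample, drop = FALSE]
  cp <- cpm(m)
  delta <- rowMeans(cp[, sel$sample[sel$strain == cmp$congenic],
                       drop = FALSE]) -
    rowMeans(cp[, sel$sample[sel$strain == cmp$parent], drop = FALSE])
  data.table::data.table(feature_id = rownames(m), assay = a,
                         comparison = cmp$comparison,
                         observed_sign = sign(delta),
                         magnitude = abs(delta))
}

#' Validate predicted vs observed directions
#'
#' Joins predictions and observations on (feature, assay, comparison),
#' excludes zero observed signs with a count, and reports per (assay,
#' comparison, predicted-direction stratum) and pooled per (assay,
#' comparison): n tested, n in the predicted direction, proportion, and a
#' one-sided exact binomial p against p0 = 0.5.
#'
#' @param predictions A [predict_directions()]`$predictions` table.
#' @param observations One or more [observe_direction()] tables bound
#'   together.
#' @return List: `per_feature` (joined table with `validated`), `strata`,
#'   `pooled`, `n_zero_excluded`.
#' @export
validate_predictions <- function(predictions, observations) {
  pr <- data.table::as.data.table(predictions)
  ob <- data.table::as.data.table(observations)
  j <- merge(pr, ob, by = c("feature_id", "assay", "comparison"))
  n_zero <- sum(j$observed_sign == 0)
  j <- j[observed_sign != 0]
  j[, validated := observed_sign == predicted]
  binom_p <- function(k, n) pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  strata <- j[, .(n_tested = .N, n_predicted = sum(validated),
                  proportion = mean(validated),
                  pvalue = binom_p(sum(validated), .N)),
              by = .(assay, comparison, predicted)]
  pooled <- j[, .(n_tested = .N, n_predicted = sum(validated),
                  proportion = mean(validated),
                  pvalue = binom_p(sum(validated), .N)),
              by = .(assay, comparison)]
  list(per_feature = j, strata = strata, pooled = pooled,
       n_zero_excluded = n_zero)
}

#' Effect sizes of validated vs non-validated features
#'
#' Two-sided rank-sum on |delta CPM| (or |delta PET|) between features
#' that changed in the predicted direction and those that did not; omitted
#' with a note when either group is empty.
#'
#' @param per_feature A [validate_predictions()]`$per_feature` table (or
#'   any table with `magnitude` and logical `validated`).
#' @return List: medians, p, W, n, or `omitted = TRUE` with a `note`.
#' @export
effectsize_validated_vs_not <- function(per_feature) {
  x <- data.table::as.data.table(per_feature)
  v <- x$magnitude[x$validated]
  nv <- x$magnitude[!x$validated]
  if (length(v) < 2 || length(nv) < 2)
    return(list(omitted = TRUE,
                note = "a group has < 2 features; comparison omitted"))
  rs <- .ranksum(v, nv)
  list(omitted = FALSE,
       medians = c(validated = median(v), not_validated = median(nv)),
       p = rs$p, W = rs$W, z = rs$z,
       n = c(validated = length(v), not_validated = length(nv)))
}

#' Map interactions to repressive-allele calls via anchor overlap
#'
#' For interaction-level validation, an interaction inherits the
#' repressive-allele call of any trans-target overlapping either anchor;
#' interactions whose overlapping targets disagree, or that overlap none,
#' are excluded with counts.
#'
#' @param interactions Interactions data.frame (chrom1..end2, id).
#' @param target_calls `data.table` with chrom, start, end,
#'   repressive_allele.
#' @return List: `calls` (feature_id, repressive_allele), `n_unmapped`,
#'   `n_conflicting`.
#' @export
map_interactions_to_targets <- function(interactions, target_calls) {
  x <- data.table::as.data.table(interactions)
  tg <- data.table::as.data.table(target_calls)
  idcol <- intersect(c("int_id", "name", "id"), names(x))[1L]
  ids <- if (is.na(idcol)) sprintf("di_%d", seq_len(nrow(x)))
         else x[[idcol]]
  anchors <- data.table::rbindlist(list(
    x[, .(chrom = chrom1, start = start1, end = end1, int = .I)],
    x[, .(chrom = chrom2, start = start2, end = end2, int = .I)]))
  hits <- .overlap_pairs(anchors[, .(chrom, start, end)], tg)
  hits[, `:=`(int = anchors$int[q], allele = tg$repressive_allele[s])]
  agg <- hits[, .(n_allele = data.table::uniqueN(allele),
                  allele = allele[1L]), by = int]
  ok <- agg[n_allele == 1L]
  list(calls = data.table::data.table(feature_id = ids[ok$int],
                                      repressive_allele = ok$allele),
       n_unmapped = nrow(x) - nrow(agg),
       n_conflicting = nrow(agg) - nrow(ok))
}
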