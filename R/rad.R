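# Spatial Region-Associated-Differential (RAD) enrichment: do focal peaks
# cluster near focal genes' TSSs, per signed-distance bin?
#
# Distances are strand-specific: negative means the peak midpoint lies
# upstream of the TSS in the direction of transcription.  Bins are
# half-open (lower, upper] ascending from -window; a distance of exactly
# -window is assigned to the first bin by closing its lower bound, and a
# distance of exactly 0 (peak midpoint on the TSS) falls in
# (-bin_width, 0].

#' RAD configuration
#'
#' @param window_bp Half-width of the window around the TSS (default
#'   500 kb); must be divisible by `bin_width_bp`.
#' @param bin_width_bp Bin width (default 100 kb).
#' @return List of class `rad_config` with a precomputed bin table.
#' @export
rad_config <- function(window_bp = 5e5, bin_width_bp = 1e5) {
  stopifnot(window_bp > 0, bin_width_bp > 0)
  if (window_bp %% bin_width_bp != 0)
    stop("window_bp must be divisible by bin_width_bp", call. = FALSE)
  edges <- seq(-window_bp, window_bp, by = bin_width_bp)
  bins <- data.table::data.table(
    bin = seq_len(length(edges) - 1L),
    lower = edges[-length(edges)], upper = edges[-1L])
  bins[, label := sprintf("(%g,%g]", lower, upper)]
  structure(list(window_bp = window_bp, bin_width_bp = bin_width_bp,
                 bins = bins, alternative = "greater"),
            class = "rad_config")
}

#' Strand-specific signed TSS-peak distance
#'
#' Raw distance is peak midpoint minus TSS; on the minus strand the sign is
#' flipped so that negative always means upstream in the direction of
#' transcription.
#'
#' @param tss TSS position(s).
#' @param strand "+" or "-" (recycled).
#' @param peak_start,peak_end Peak interval(s), half-open.
#' @return Signed distance(s) in bp.
#' @export
signed_distance <- function(tss, strand, peak_start, peak_end) {
  stopifnot(all(strand %in% c("+", "-")))
  mid <- floor((peak_start + peak_end) / 2)
  raw <- mid - tss
  ifelse(strand == "+", raw, -raw)
}

# bin index for a signed distance; -window closed into bin 1
.rad_bin <- function(d, config) {
  idx <- ceiling((d + config$window_bp) / config$bin_width_bp)
  idx[idx == 0L & d == -config$window_bp] <- 1L
  idx[d < -config$window_bp | d > config$window_bp] <- NA_integer_
  idx
}

#' Build gene-peak connections within the RAD window
#'
#' One connection per (gene, peak) pair with signed distance in
#' `[-window, +window]`; a peak within the window of several genes
#' contributes one trial per gene.  The gene background is the supplied
#' (expressed) gene set: `N_total = |genes|`, `M_focal = |focal_genes|`.
#'
#' @param genes Gene table (chrom, tss, strand, gene_id) — the background.
#' @param peaks Peak intervals with a `peak_id`/`name` column.
#' @param focal_genes Character ids, subset of `genes$gene_id`.
#' @param focal_peaks Character ids, subset of peak ids.
#' @param config A [rad_config()].
#' @return `data.table` of class-tagged connections: gene_id, peak_id,
#'   distance, bin, gene_focal, peak_focal; attributes `n_total`,
#'   `m_focal`.
#' @export
build_connections <- function(genes, peaks, focal_genes, focal_peaks,
                              config = rad_config()) {
  g <- data.table::as.data.table(genes)
  p <- data.table::as.data.table(peaks)
  if (!nrow(g)) stop("empty gene background", call. = FALSE)
  idcol <- intersect(c("peak_id", "name", "id"), names(p))[1L]
  if (is.na(idcol)) stop("peaks need an id column", call. = FALSE)
  if (!all(focal_genes %in% g$gene_id))
    stop("focal_genes not a subset of the gene background", call. = FALSE)
  if (!all(focal_peaks %in% p[[idcol]]))
    stop("focal_peaks not a subset of the peaks", call. = FALSE)
  w <- config$window_bp
  win <- g[, .(chrom, start = tss - w - 1, end = tss + w + 1)]
  mids <- floor((p$start + p$end) / 2)
  pk <- data.table::data.table(chrom = p$chrom, start = mids,
                               end = mids + 1)
  hits <- .overlap_pairs(win, pk)
  d <- signed_distance(g$tss[hits$q], g$strand[hits$q],
                       p$start[hits$s], p$end[hits$s])
  keep <- d >= -w & d <= w
  out <- data.table::data.table(
    gene_id = g$gene_id[hits$q][keep],
    peak_id = p[[idcol]][hits$s][keep],
    distance = d[keep])
  out[, bin := .rad_bin(distance, config)]
  out[, gene_focal := gene_id %in% focal_genes]
  out[, peak_focal := peak_id %in% focal_peaks]
  data.table::setattr(out, "n_total", nrow(g))
  data.table::setattr(out, "m_focal", length(unique(focal_genes)))
  out
}

#' Per-bin RAD binomial enrichment
#'
#' Over focal-peak connections only: per bin, `n_b` trials (connections in
#' the bin) of which `k_b` successes (connections to a focal gene), tested
#' one-sided (greater) against `p0 = M_focal / N_total` with an exact
#' binomial tail; BH correction across the bins of this analysis;
#' observed/expected ratio `(k_b/n_b)/p0`.
#'
#' @param connections A [build_connections()] table.
#' @param config The matching [rad_config()].
#' @param n_total,m_focal Background sizes; taken from the connection
#'   table's attributes when omitted.
#' @return `data.table`: bin, lower, upper, label, n, k, p0, pvalue,
#'   qvalue, oe (NA with an `empty` flag when n = 0).
#' @export
rad_enrichment <- function(connections, config = rad_config(),
                           n_total = attr(connections, "n_total"),
                           m_focal = attr(connections, "m_focal")) {
  stopifnot(!is.null(n_total), !is.null(m_focal), m_focal >= 1)
  p0 <- m_focal / n_total
  foc <- data.table::as.data.table(connections)[peak_focal == TRUE]
  res <- data.table::copy(config$bins)
  cnt <- foc[, .(n = .N, k = sum(gene_focal)), by = bin]
  res <- merge(res, cnt, by = "bin", all.x = TRUE)
  res[is.na(n), `:=`(n = 0L, k = 0L)]
  res[, p0 := p0]
  res[, pvalue := ifelse(n == 0, 1,
                         pbinom(k - 1, n, p0, lower.tail = FALSE))]
  res[, qvalue := bh_adjust(pvalue)]
  res[, oe := ifelse(n == 0, NA_real_, (k / n) / p0)]
  res[, empty := n == 0]
  data.table::setorder(res, bin)
  res[]
}
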