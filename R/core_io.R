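# Genomic primitives and plain-text readers/writers.
#
# All coordinates are 0-based half-open (BED/BEDPE convention).  1-based
# inputs are NOT auto-detected.  TSV inputs require a header line; BED and
# BEDPE files are headerless.  Parsers reject malformed input with the
# offending line number rather than silently coercing.

.fail_line <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

.check_coords <- function(path, start, end, line, label = "") {
  pre <- if (nzchar(label)) paste0(label, " ") else ""
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    .fail_line(path, line[bad[1L]], paste0(pre, "non-integer coordinate"))
  bad <- which(start < 0)
  if (length(bad))
    .fail_line(path, line[bad[1L]], paste0(pre, "negative start coordinate"))
  bad <- which(start >= end)
  if (length(bad))
    .fail_line(path, line[bad[1L]],
               sprintf("%sstart (%d) >= end (%d)", pre,
                       as.integer(start[bad[1L]]), as.integer(end[bad[1L]])))
  invisible(TRUE)
}

#' Read a BED3+ file of genomic intervals
#'
#' Headerless, tab-separated, 0-based half-open.  Columns beyond the fourth
#' are ignored; a fourth column, when present, is kept as `name`.
#'
#' @param path Path to a BED file.
#' @return A `data.table` with columns `chrom`, `start`, `end` and, if
#'   present in the file, `name`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          showProgress = FALSE, fill = TRUE)
  if (ncol(dt) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path),
                          call. = FALSE)
  out <- data.table::data.table(
    chrom = as.character(dt[[1L]]),
    start = suppressWarnings(as.numeric(dt[[2L]])),
    end = suppressWarnings(as.numeric(dt[[3L]]))
  )
  .check_coords(path, out$start, out$end, seq_len(nrow(out)))
  if (ncol(dt) >= 4L) out[, name := as.character(dt[[4L]])]
  out
}

#' Write intervals to a BED file
#'
#' @param x A data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  data.table::fwrite(data.table::as.data.table(x)[, cols, with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of paired anchors
#'
#' Headerless; columns chrom1,start1,end1,chrom2,start2,end2 and an optional
#' seventh name column.  Both anchors are validated as half-open intervals.
#'
#' @param path Path to a BEDPE file.
#' @return A `data.table` with the six coordinate columns and `name` (a
#'   generated `int_<i>` id when the file has no name column).
#' @export
read_bedpe <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          showProgress = FALSE, fill = TRUE)
  if (ncol(dt) < 6L) stop(sprintf("%s: BEDPE needs >= 6 columns", path),
                          call. = FALSE)
  out <- data.table::data.table(
    chrom1 = as.character(dt[[1L]]),
    start1 = suppressWarnings(as.numeric(dt[[2L]])),
    end1 = suppressWarnings(as.numeric(dt[[3L]])),
    chrom2 = as.character(dt[[4L]]),
    start2 = suppressWarnings(as.numeric(dt[[5L]])),
    end2 = suppressWarnings(as.numeric(dt[[6L]]))
  )
  ln <- seq_len(nrow(out))
  .check_coords(path, out$start1, out$end1, ln, "anchor1")
  .check_coords(path, out$start2, out$end2, ln, "anchor2")
  out[, name := if (ncol(dt) >= 7L) as.character(dt[[7L]])
      else sprintf("int_%d", .I)]
  out
}

#' Write interactions to a BEDPE file
#'
#' @param x A data.frame with chrom1,start1,end1,chrom2,start2,end2 and
#'   optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  cols <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name"), names(x))
  data.table::fwrite(data.table::as.data.table(x)[, cols, with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column holds feature ids (header name is free), remaining columns
#' one sample each.  Cells must be non-negative integers; the first
#' offending cell is reported by feature row and sample column.
#'
#' @param path Path to a tab-separated counts file with a header line.
#' @return Numeric matrix, features x samples, with dimnames.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  if (ncol(dt) < 2L) stop(sprintf("%s: counts need >= 2 columns", path),
                          call. = FALSE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate feature id '%s'", path,
                 ids[anyDuplicated(ids)]), call. = FALSE)
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "numeric"
  bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: non-integer count at feature '%s', sample '%s'",
                 path, ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a count matrix to TSV
#'
#' @param m Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  dt <- data.table::data.table(feature_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a gene model table
#'
#' Required header columns: `chrom`, `tss`, `strand`, `gene_id`.  `tss` is a
#' 0-based position; strand must be `+` or `-`.
#'
#' @param path Path to a genes TSV.
#' @return `data.table` with the four columns.
#' @export
read_genes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  need <- c("chrom", "tss", "strand", "gene_id")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  ln <- seq_len(nrow(dt)) + 1L  # header occupies line 1
  bad <- which(!is.finite(dt$tss) | dt$tss < 0 | dt$tss != floor(dt$tss))
  if (length(bad)) .fail_line(path, ln[bad[1L]], "invalid tss")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    .fail_line(path, ln[bad[1L]],
               sprintf("unknown strand '%s'", dt$strand[bad[1L]]))
  if (anyDuplicated(dt$gene_id))
    stop(sprintf("%s: duplicate gene_id", path), call. = FALSE)
  dt[, .(chrom = as.character(chrom), tss = as.numeric(tss),
         strand = as.character(strand), gene_id = as.character(gene_id))]
}

#' Read a sample sheet
#'
#' Required header columns: `sample`, `strain`, `assay`, `replicate`.  The
#' (strain, assay, replicate) triple must be unique.
#'
#' @param path Path to a sample-sheet TSV.
#' @return `data.table` with the four columns.
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  need <- c("sample", "strain", "assay", "replicate")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(dt$sample))
    stop(sprintf("%s: duplicate sample id", path), call. = FALSE)
  if (anyDuplicated(dt[, .(strain, assay, replicate)]))
    stop(sprintf("%s: duplicate (strain, assay, replicate)", path),
         call. = FALSE)
  dt
}

#' Pairwise interval overlap under half-open semantics
#'
#' Two intervals overlap iff they share a chromosome and at least one base:
#' `a.start < b.end && b.start < a.end`.  Vectorized with recycling.
#'
#' @param chrom_a,start_a,end_a First interval set.
#' @param chrom_b,start_b,end_b Second interval set.
#' @return Logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

# Which rows of `q` (chrom/start/end) overlap >= 1 row of `s`?
.overlap_any <- function(q, s) {
  hit <- logical(nrow(q))
  if (!nrow(q) || !nrow(s)) return(hit)
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    si <- which(s$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(q$start[qi] + 1L, q$end[qi])
    sr <- IRanges::IRanges(s$start[si] + 1L, s$end[si])
    hit[qi] <- IRanges::overlapsAny(qr, sr)
  }
  hit
}

# All (query, subject) overlap pairs; returns data.table(q, s) of row indices.
.overlap_pairs <- function(q, s) {
  res <- vector("list", 0L)
  if (!nrow(q) || !nrow(s))
    return(data.table::data.table(q = integer(), s = integer()))
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    si <- which(s$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(q$start[qi] + 1L, q$end[qi])
    sr <- IRanges::IRanges(s$start[si] + 1L, s$end[si])
    h <- IRanges::findOverlaps(qr, sr)
    res[[length(res) + 1L]] <- data.table::data.table(
      q = qi[S4Vectors::from(h)], s = si[S4Vectors::to(h)])
  }
  if (!length(res)) return(data.table::data.table(q = integer(),
                                                  s = integer()))
  data.table::rbindlist(res)
}

#' Interaction span (midpoint to midpoint)
#'
#' Span is the distance between the two anchor midpoints, rounded down.
#' Midpoints are anchor-width invariant, which matters because the
#' high-confidence filter excludes interactions spanning <= 5 kb.
#'
#' @param interactions data.frame with chrom1,start1,end1,chrom2,start2,end2.
#' @return Numeric vector of spans in bp.
#' @export
interaction_span <- function(interactions) {
  x <- data.table::as.data.table(interactions)
  inter <- which(x$chrom1 != x$chrom2)
  if (length(inter))
    stop(sprintf("span undefined for inter-chromosomal interaction (row %d)",
                 inter[1L]), call. = FALSE)
  floor(abs((x$start2 + x$end2) - (x$start1 + x$end1)) / 2)
}
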