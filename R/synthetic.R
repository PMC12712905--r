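# Synthetic multi-strain multi-omic data generator.
#
# The generator states a simulated world with the statistical structure the
# downstream analysis assumes: five strains (B6, D2, F1, B6-13D2, D2-13B6),
# negative-binomial counts, additive cis effects, dominant-repressive trans
# effects acting through a master locus on chr13 that raises H3K9me3 and
# lowers ATAC/H3K27ac/PET/RNA at designated targets, a genotype swap at the
# master locus in the reciprocal congenics, and spatial placement of
# trans-target peaks near their linked eGene TSSs.

.SIM_ASSAYS <- c("ATAC", "H3K27ac", "H3K9me3", "PET", "RNA")
.ACTIVE_ASSAYS <- c("ATAC", "H3K27ac", "PET", "RNA")

#' Simulation configuration
#'
#' Defaults describe the reference world used throughout the test-suite:
#' 2,000 peaks of which 300 are trans-targets of a chr13 master locus,
#' spread over 59 master-locus eGenes in a 9,660-gene expressed background
#' on a 19-autosome + chr13 genome; 84% of trans-targets are repressed by
#' the D2 allele, repression is 2 log2 units and fully dominant in the F1
#' (`d_true = -1`), NB dispersion is 0.05 with three replicate lines per
#' strain.
#'
#' @param n_chromosomes Number of chromosomes; the last one is `chr13`, the
#'   master-locus chromosome, which carries no simulated features.
#' @param chrom_length_bp Length of every chromosome.
#' @param n_genes,n_peaks,n_interactions Feature counts.
#' @param n_trans_targets,n_cis_targets Number of peaks under trans (master
#'   locus) and local cis genetic control; the rest are neutral.
#' @param n_trans_egenes Number of genes designated as eGenes of the master
#'   locus; trans-target peaks are spread evenly over them.
#' @param frac_d2_repressive Fraction of trans-target peaks (via their
#'   linked eGene) repressed by the D2 master-locus allele.  Applied as an
#'   exact composition, not a binomial draw.
#' @param delta_k9 log2 increase of H3K9me3 under full repression.
#' @param delta_active log2 decrease of ATAC/H3K27ac/PET/RNA under full
#'   repression.
#' @param d_true Dominance coefficient of repression in the F1; -1 means the
#'   heterozygote equals the repressed homozygote.
#' @param cis_beta log2 effect of a homozygous cis high allele (additive, so
#'   the heterozygote gets half).
#' @param dispersion NB dispersion phi >= 0; 0 gives Poisson counts.
#' @param replicates_per_strain Replicate lines per strain (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of
#'   per-feature baseline log2 expected counts.
#' @param library_size Expected reads per sample; per-sample size factors
#'   are drawn log-normally around `library_size / 1e6`.
#' @param sizefactor_log_sd sdlog of the size-factor distribution.
#' @param frac_short_decoys Fraction of interactions built with span
#'   <= 5 kb so the confidence filter is exercised in both directions.
#' @param peak_width Width of simulated peaks and anchors, bp.
#' @param rad_window_bp Half-width of the RAD window around TSSs.
#' @param rad_planted_bins List of `c(lower, upper)` signed-distance bins
#'   (half-open `(lower, upper]`) where trans-target peaks are placed
#'   relative to their linked eGene TSS; `NULL` places them uniformly.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 20L,
                       chrom_length_bp = 1.2e8,
                       n_genes = 9660L,
                       n_peaks = 2000L,
                       n_interactions = 1000L,
                       n_trans_targets = 300L,
                       n_cis_targets = 300L,
                       n_trans_egenes = 59L,
                       frac_d2_repressive = 0.84,
                       delta_k9 = 2,
                       delta_active = 2,
                       d_true = -1,
                       cis_beta = 1.5,
                       dispersion = 0.05,
                       replicates_per_strain = 3L,
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 1,
                       library_size = 1e6,
                       sizefactor_log_sd = 0.2,
                       frac_short_decoys = 0.1,
                       peak_width = 500L,
                       rad_window_bp = 5e5,
                       rad_planted_bins = list(c(-1e5, 0)),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length_bp > 0,
            cfg$n_genes >= 1, cfg$n_peaks >= 1, cfg$n_interactions >= 0,
            cfg$replicates_per_strain >= 2, cfg$dispersion >= 0,
            cfg$frac_d2_repressive >= 0, cfg$frac_d2_repressive <= 1,
            cfg$delta_k9 >= 0, cfg$delta_active >= 0,
            cfg$frac_short_decoys >= 0, cfg$frac_short_decoys <= 1,
            cfg$baseline_log2_sd >= 0, cfg$library_size > 0,
            cfg$peak_width >= 2)
  if (cfg$n_peaks < cfg$n_trans_targets + cfg$n_cis_targets)
    stop("n_peaks must be >= n_trans_targets + n_cis_targets", call. = FALSE)
  if (cfg$n_trans_targets > 0 &&
      (cfg$n_trans_egenes < 1 || cfg$n_trans_egenes > cfg$n_genes))
    stop("n_trans_egenes must be in [1, n_genes]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Strain design table
#'
#' Genotypes are encoded as the number of D2 alleles (0, 1 or 2).
#' `master_d2` is the genotype at the chr13 master locus, `background_d2`
#' everywhere else.  The congenics carry the opposite master-locus genotype
#' from their background; the F1 is heterozygous everywhere.
#'
#' @return `data.table` with columns strain, background, master_d2,
#'   background_d2.
#' @export
strain_table <- function() {
  data.table::data.table(
    strain = c("B6", "D2", "F1", "B6-13D2", "D2-13B6"),
    background = c("B6", "D2", "F1", "B6", "D2"),
    master_d2 = c(0L, 2L, 1L, 2L, 0L),
    background_d2 = c(0L, 2L, 1L, 0L, 2L)
  )
}

# Sample integers from (lo, hi] — used for planted-bin placement so the
# half-open bin convention of the RAD module is respected exactly.
.sample_halfopen <- function(n, lo, hi) {
  lo + sample.int(hi - lo, n, replace = TRUE)
}

#' Build a seeded genome layout
#'
#' Places genes, peaks and interaction anchor pairs on the simulated genome
#' and assigns effect classes (trans_target / cis_target / neutral for
#' peaks, trans_egene / neutral for genes).  Trans-target peaks are placed
#' in the configured signed-distance bins around their linked eGene TSS;
#' everything else is uniform.  Interactions borrow their first anchor from
#' a peak (inheriting its effect class) and an exact
#' `round(frac_short_decoys * n_interactions)` of them are short decoys
#' spanning <= 5 kb.
#'
#' @param config A [sim_config()].
#' @return List of class `genome_layout` with elements `chroms`,
#'   `master_chrom`, `genes`, `peaks`, `interactions`, `config`.
#' @export
build_genome_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  chroms <- if (n_chr >= 2) c(paste0("chr", seq_len(n_chr - 1)), "chr13")
            else "chr13"
  master <- "chr13"
  feat_chroms <- if (n_chr >= 2) setdiff(chroms, master) else chroms
  L <- config$chrom_length_bp
  hw <- config$peak_width / 2
  margin <- config$rad_window_bp + config$peak_width + 1000
  if (L <= 2 * margin)
    stop("infeasible placement: rad_window_bp too large for chromosome",
         call. = FALSE)

  ng <- config$n_genes
  genes <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(ng)),
    chrom = sample(feat_chroms, ng, replace = TRUE),
    tss = floor(runif(ng, margin, L - margin)),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    class = "neutral",
    repressive_allele = NA_character_
  )

  n_tr <- config$n_trans_targets
  n_ci <- config$n_cis_targets
  n_ne <- config$n_peaks - n_tr - n_ci

  # eGenes of the master locus, with an exact D2-repressive composition
  if (n_tr > 0) {
    ne <- config$n_trans_egenes
    eg_idx <- sample.int(ng, ne)
    n_d2 <- round(config$frac_d2_repressive * ne)
    alleles <- sample(c(rep("D2", n_d2), rep("B6", ne - n_d2)))
    genes[eg_idx, `:=`(class = "trans_egene", repressive_allele = alleles)]
    link_idx <- eg_idx[rep(seq_len(ne), length.out = n_tr)]
  }

  mk_uniform <- function(n) floor(runif(n, margin, L - margin))

  peak_mid <- numeric(config$n_peaks)
  peak_chrom <- character(config$n_peaks)
  cls <- c(rep("trans_target", n_tr), rep("cis_target", n_ci),
           rep("neutral", n_ne))
  rall <- rep(NA_character_, config$n_peaks)
  linked <- rep(NA_character_, config$n_peaks)
  chigh <- rep(NA_character_, config$n_peaks)

  if (n_tr > 0) {
    g <- genes[link_idx]
    rall[seq_len(n_tr)] <- g$repressive_allele
    linked[seq_len(n_tr)] <- g$gene_id
    if (is.null(config$rad_planted_bins)) {
      # spatial null: trans-targets are placed uniformly like any peak,
      # with no positional relationship to their linked eGene
      peak_chrom[seq_len(n_tr)] <- sample(feat_chroms, n_tr, replace = TRUE)
      peak_mid[seq_len(n_tr)] <- floor(runif(n_tr, margin, L - margin))
    } else {
      peak_chrom[seq_len(n_tr)] <- g$chrom
      bins <- config$rad_planted_bins
      pick <- sample.int(length(bins), n_tr, replace = TRUE)
      lo <- vapply(bins, `[`, numeric(1), 1L)[pick]
      hi <- vapply(bins, `[`, numeric(1), 2L)[pick]
      if (any(abs(c(lo, hi)) > config$rad_window_bp))
        stop("infeasible placement: planted bin outside rad window",
             call. = FALSE)
      u <- lo + sample(ceiling(hi - lo), n_tr, replace = TRUE)
      raw <- ifelse(g$strand == "+", u, -u)
      peak_mid[seq_len(n_tr)] <- g$tss + raw
      if (any(peak_mid[seq_len(n_tr)] < hw |
              peak_mid[seq_len(n_tr)] > L - hw))
        stop("infeasible placement: planted peak outside chromosome",
             call. = FALSE)
    }
  }
  if (n_ci + n_ne > 0) {
    rest <- seq.int(n_tr + 1L, config$n_peaks)
    peak_chrom[rest] <- sample(feat_chroms, length(rest), replace = TRUE)
    peak_mid[rest] <- mk_uniform(length(rest))
  }
  if (n_ci > 0)
    chigh[seq.int(n_tr + 1L, n_tr + n_ci)] <-
      sample(c("B6", "D2"), n_ci, replace = TRUE)

  lod <- runif(config$n_peaks, 5, 20)
  lod[cls == "neutral"] <- NA_real_

  peaks <- data.table::data.table(
    peak_id = sprintf("p%04d", seq_len(config$n_peaks)),
    chrom = peak_chrom,
    start = peak_mid - hw,
    end = peak_mid + hw,
    class = cls,
    repressive_allele = rall,
    linked_egene = linked,
    cis_high_allele = chigh,
    lod = lod
  )

  interactions <- .build_interactions(peaks, config, L)

  structure(list(chroms = chroms, master_chrom = master, genes = genes,
                 peaks = peaks, interactions = interactions,
                 config = config),
            class = "genome_layout")
}

.build_interactions <- function(peaks, config, L) {
  n <- config$n_interactions
  if (n == 0)
    return(data.table::data.table(
      int_id = character(), chrom1 = character(), start1 = numeric(),
      end1 = numeric(), chrom2 = character(), start2 = numeric(),
      end2 = numeric(), class = character(),
      repressive_allele = character(), cis_high_allele = character(),
      source_peak = character()))
  hw <- config$peak_width / 2
  src <- sample.int(nrow(peaks), n, replace = n > nrow(peaks))
  n_decoy <- round(config$frac_short_decoys * n)
  is_decoy <- seq_len(n) <= n_decoy  # first block; order is not meaningful
  gap <- numeric(n)
  gap[is_decoy] <- sample(1000:4500, sum(is_decoy), replace = TRUE)
  gap[!is_decoy] <- sample(20000:1000000, sum(!is_decoy), replace = TRUE)
  m1 <- (peaks$start[src] + peaks$end[src]) / 2
  dir <- ifelse(m1 + gap + hw < L, 1, -1)
  m2 <- m1 + dir * gap
  dt <- data.table::data.table(
    int_id = sprintf("int_%04d", seq_len(n)),
    chrom1 = peaks$chrom[src],
    start1 = pmin(m1, m2) - hw, end1 = pmin(m1, m2) + hw,
    chrom2 = peaks$chrom[src],
    start2 = pmax(m1, m2) - hw, end2 = pmax(m1, m2) + hw,
    class = peaks$class[src],
    repressive_allele = peaks$repressive_allele[src],
    cis_high_allele = peaks$cis_high_allele[src],
    source_peak = peaks$peak_id[src]
  )
  dt
}

# Vectorized expected effect (log2 units above baseline) for one assay.
.effect_log2 <- function(class, repressive_allele, cis_high_allele,
                         assay, strain, config) {
  st <- strain_table()
  i <- match(strain, st$strain)
  if (anyNA(i)) stop("unknown strain: ", strain[which(is.na(i))[1L]],
                     call. = FALSE)
  if (!all(assay %in% .SIM_ASSAYS))
    stop("unknown assay: ", setdiff(assay, .SIM_ASSAYS)[1L], call. = FALSE)
  master_d2 <- st$master_d2[i]
  background_d2 <- st$background_d2[i]

  # trans: copies of the repressive allele at the master locus
  r_copies <- ifelse(is.na(repressive_allele), 0L,
                     ifelse(repressive_allele == "D2", master_d2,
                            2L - master_d2))
  # dose scaling calibrated so the F1 dominance coefficient equals d_true
  scale <- ifelse(r_copies == 2L, 1,
                  ifelse(r_copies == 1L, (1 - config$d_true) / 2, 0))
  full <- ifelse(assay == "H3K9me3", config$delta_k9, -config$delta_active)
  trans_eff <- ifelse(class %in% c("trans_target", "trans_egene"),
                      scale * full, 0)

  # cis: additive in the local (background) genotype.  Cis variants act on
  # CRE activity (accessibility, H3K27ac, contacts, expression) but plant
  # no heterochromatin effect, so H3K9me3 stays at baseline.
  h_copies <- ifelse(is.na(cis_high_allele), 0L,
                     ifelse(cis_high_allele == "D2", background_d2,
                            2L - background_d2))
  cis_eff <- ifelse(class == "cis_target" & assay != "H3K9me3",
                    config$cis_beta * h_copies / 2, 0)
  trans_eff + cis_eff
}

#' Expected log2 signal of a feature
#'
#' Neutral features return the baseline.  cis-targets add `cis_beta` per
#' high-allele dose (additive).  trans-targets are repressed when the
#' master-locus genotype carries at least one copy of the repressive
#' allele: a homozygote takes the full effect (`+delta_k9` for H3K9me3,
#' `-delta_active` otherwise), a heterozygote an effect scaled so the
#' resulting dominance coefficient equals `d_true`; with `d_true = -1` the
#' F1 equals the repressed parent exactly.
#'
#' @param layout A [build_genome_layout()] result.
#' @param feature_id Peak, gene or interaction id(s).
#' @param assay One of ATAC, H3K27ac, H3K9me3, PET, RNA (recycled).
#' @param strain One of the five strains (recycled).
#' @param baseline Baseline log2 mean to add (default 0).
#' @return Numeric vector of expected log2 means.
#' @export
expected_log_signal <- function(layout, feature_id, assay, strain,
                                baseline = 0) {
  stopifnot(inherits(layout, "genome_layout"))
  lut <- data.table::rbindlist(list(
    layout$peaks[, .(id = peak_id, class, repressive_allele,
                     cis_high_allele)],
    layout$genes[, .(id = gene_id, class, repressive_allele,
                     cis_high_allele = NA_character_)],
    layout$interactions[, .(id = int_id, class, repressive_allele,
                            cis_high_allele)]
  ))
  i <- match(feature_id, lut$id)
  if (anyNA(i)) stop("unknown feature id", call. = FALSE)
  n <- max(length(i), length(assay), length(strain))
  baseline + .effect_log2(rep_len(lut$class[i], n),
                          rep_len(lut$repressive_allele[i], n),
                          rep_len(lut$cis_high_allele[i], n),
                          rep_len(assay, n), rep_len(strain, n),
                          layout$config)
}

#' Simulate count matrices for every assay
#'
#' Counts are negative binomial with mean `size_factor * 2^eta` and
#' variance `mu + phi * mu^2`, where `eta` is the per-feature expected log2
#' signal for the sample's strain; `phi = 0` reduces to Poisson.  Size
#' factors are sample-level, drawn log-normally around
#' `library_size / 1e6`, and recorded in the output so normalization
#' recovery can be asserted exactly.
#'
#' @param layout A [build_genome_layout()] result.
#' @param config The same [sim_config()] used for the layout.
#' @param assays Subset of assays to simulate.
#' @return List of class `sim_data`: `counts` (named list of matrices),
#'   `sample_sheet`, `truth` (feature x assay x strain expected log2 plus
#'   class labels), `size_factors`, `layout`, `config`.
#' @export
simulate_counts <- function(layout, config = layout$config,
                            assays = .SIM_ASSAYS) {
  stopifnot(inherits(layout, "genome_layout"))
  assays <- match.arg(assays, .SIM_ASSAYS, several.ok = TRUE)
  set.seed(config$seed + 1L)
  st <- strain_table()
  reps <- config$replicates_per_strain
  phi <- config$dispersion

  sheet <- data.table::CJ(assay = assays, strain = st$strain,
                          replicate = seq_len(reps), sorted = FALSE)
  sheet[, sample := sprintf("%s_%s_r%d", strain, assay, replicate)]
  sheet[, sf := (config$library_size / 1e6) *
          exp(rnorm(.N, 0, config$sizefactor_log_sd))]

  feat_of <- function(a) switch(a,
    PET = layout$interactions[, .(id = int_id, class, repressive_allele,
                                  cis_high_allele)],
    RNA = layout$genes[, .(id = gene_id, class, repressive_allele,
                           cis_high_allele = NA_character_)],
    layout$peaks[, .(id = peak_id, class, repressive_allele,
                     cis_high_allele)])

  counts <- list()
  truth <- list()
  for (a in assays) {
    ft <- feat_of(a)
    nf <- nrow(ft)
    base <- rnorm(nf, config$baseline_log2_mean, config$baseline_log2_sd)
    eta <- sapply(st$strain, function(s)
      base + .effect_log2(ft$class, ft$repressive_allele,
                          ft$cis_high_allele, a, s, config))
    ss <- sheet[assay == a]
    mu <- 2^eta[, ss$strain, drop = FALSE] *
      rep(ss$sf, each = nf)
    draw <- if (phi > 0) rnbinom(length(mu), mu = mu, size = 1 / phi)
            else rpois(length(mu), mu)
    m <- matrix(draw, nrow = nf, dimnames = list(ft$id, ss$sample))
    counts[[a]] <- m
    truth[[a]] <- data.table::data.table(
      feature_id = rep(ft$id, times = nrow(st)),
      assay = a,
      strain = rep(st$strain, each = nf),
      expected_log2 = as.vector(eta),
      class = rep(ft$class, times = nrow(st)),
      repressive_allele = rep(ft$repressive_allele, times = nrow(st))
    )
  }
  structure(list(counts = counts,
                 sample_sheet = sheet[, .(sample, strain, assay, replicate)],
                 truth = data.table::rbindlist(truth),
                 size_factors = sheet[, .(sample, sf)],
                 layout = layout, config = config),
            class = "sim_data")
}

#' Derive the QTL-target table from a layout
#'
#' One row per genetically controlled peak (modes cis and trans) and per
#' trans eGene, in the orientation the mapping study would report:
#' `effect_size` is B6-minus-D2 on the log2 scale of the relevant assay
#' (ATAC for peaks, RNA for genes), and `high_allele` is the strain allele
#' with higher signal — consistent with the effect sign by construction.
#'
#' @param layout A [build_genome_layout()] result.
#' @return `data.table` with target_id, type, chrom, start, end, mode,
#'   qtl_locus, high_allele, lod, effect_size, repressive_allele,
#'   linked_egene.
#' @export
make_qtl_targets <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  cfg <- layout$config
  pk <- layout$peaks[class != "neutral"]
  p_high <- ifelse(pk$class == "trans_target",
                   ifelse(pk$repressive_allele == "D2", "B6", "D2"),
                   pk$cis_high_allele)
  p_mag <- ifelse(pk$class == "trans_target", cfg$delta_active, cfg$cis_beta)
  pt <- data.table::data.table(
    target_id = pk$peak_id, type = "peak",
    chrom = pk$chrom, start = pk$start, end = pk$end,
    mode = ifelse(pk$class == "trans_target", "trans", "cis"),
    qtl_locus = ifelse(pk$class == "trans_target", layout$master_chrom,
                       pk$chrom),
    high_allele = p_high, lod = pk$lod,
    effect_size = ifelse(p_high == "B6", p_mag, -p_mag),
    repressive_allele = pk$repressive_allele,
    linked_egene = pk$linked_egene
  )
  eg <- layout$genes[class == "trans_egene"]
  if (nrow(eg)) {
    g_high <- ifelse(eg$repressive_allele == "D2", "B6", "D2")
    gt <- data.table::data.table(
      target_id = eg$gene_id, type = "gene",
      chrom = eg$chrom, start = eg$tss, end = eg$tss + 1,
      mode = "trans", qtl_locus = layout$master_chrom,
      high_allele = g_high, lod = NA_real_,
      effect_size = ifelse(g_high == "B6", cfg$delta_active,
                           -cfg$delta_active),
      repressive_allele = eg$repressive_allele,
      linked_egene = eg$gene_id
    )
    pt <- data.table::rbindlist(list(pt, gt))
  }
  pt
}

#' Write a simulation to plain-text files
#'
#' Emits peaks BED, genes TSV, interactions BEDPE, per-assay counts TSVs,
#' sample sheet, truth table, size factors and the QTL-target table, all
#' 0-based half-open.
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  lay <- sim$layout
  out <- c(peaks = p("peaks.bed"), genes = p("genes.tsv"),
           interactions = p("interactions.bedpe"),
           sample_sheet = p("sample_sheet.tsv"), truth = p("truth.tsv"),
           size_factors = p("size_factors.tsv"),
           qtl_targets = p("qtl_targets.tsv"))
  write_bed(lay$peaks[, .(chrom, start, end, name = peak_id)], out["peaks"])
  data.table::fwrite(lay$genes[, .(chrom, tss, strand, gene_id)],
                     out["genes"], sep = "\t")
  write_bedpe(lay$interactions[, .(chrom1, start1, end1, chrom2, start2,
                                   end2, name = int_id)],
              out["interactions"])
  data.table::fwrite(sim$sample_sheet, out["sample_sheet"], sep = "\t")
  data.table::fwrite(sim$truth, out["truth"], sep = "\t")
  data.table::fwrite(sim$size_factors, out["size_factors"], sep = "\t")
  data.table::fwrite(make_qtl_targets(lay), out["qtl_targets"], sep = "\t")
  for (a in names(sim$counts)) {
    f <- p(sprintf("counts_%s.tsv", a))
    write_counts(sim$counts[[a]], f)
    out[paste0("counts_", a)] <- f
  }
  invisible(out)
}
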