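# End-to-end orchestration: simulate -> normalize/diff -> QTL integration
# -> signature -> RAD -> dominance -> congenic validation, with seeded
# per-stage reproducibility and a machine-readable run report.

.PIPE_STAGES <- c("simulate", "differential", "qtl", "signature", "rad",
                  "dominance", "congenic")

# Deterministic per-stage seed derived from the global seed and the stage
# name, so stage-level reproducibility is independent of execution order.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param sim Named list of [sim_config()] overrides.
#' @param stages Analysis stages to run (subset of differential, qtl,
#'   signature, rad, dominance, congenic); `simulate` always runs.
#' @param thresholds Named list of overrides: di_fdr, discordance_q,
#'   min_lod, epsilon, n_perm.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param outdir Output directory, or `NULL` to keep results in memory
#'   only.
#' @return Validated list of class `pipeline_config`.  Unknown keys in
#'   `sim` or `thresholds` are rejected before any stage runs.
#' @export
pipeline_config <- function(sim = list(),
                            stages = setdiff(.PIPE_STAGES, "simulate"),
                            thresholds = list(), seed = 1L,
                            outdir = NULL) {
  bad <- setdiff(names(sim), names(formals(sim_config)))
  if (length(bad)) stop("unknown sim key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  thr <- list(di_fdr = 0.2, discordance_q = 0.05, min_lod = 8,
              epsilon = 0.05, n_perm = 1000L)
  bad <- setdiff(names(thresholds), names(thr))
  if (length(bad)) stop("unknown threshold key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  thr[names(thresholds)] <- thresholds
  stages <- unique(c("simulate", stages))
  bad <- setdiff(stages, .PIPE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(sim = sim, stages = stages, thresholds = thr,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

# B6-vs-D2 differential test for one assay of a simulation.
.diff_assay <- function(sim, assay_name, strains = c("B6", "D2")) {
  ss <- sim$sample_sheet[assay == assay_name & strain %in% strains]
  m <- sim$counts[[assay_name]][, ss$sample, drop = FALSE]
  fac <- tmm_factors(m)
  phi <- estimate_common_dispersion(m, ss$strain, fac)
  nb_exact_test(m, factor(ss$strain, levels = strains), phi, fac)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Stages run in dependency order; any failure aborts naming the stage.
#' With an `outdir`, every stage writes its tables and a `report.json`
#' whose per-stage records carry parameters, record counts and md5 digests
#' of the written files, so identical configs reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_run` with `results` per stage and
#'   `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  results <- list()
  files <- character()

  note <- function(stage, params, n_records, out_files = character()) {
    digests <- if (length(out_files))
      as.list(tools::md5sum(out_files)) else list()
    report$stages[[stage]] <<- list(params = params,
                                    n_records = n_records,
                                    outputs = digests)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) {
      report$stages[[stage]] <<- list(skipped = TRUE)
      return(invisible())
    }
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  run_stage("simulate", function() {
    sim_args <- config$sim
    sim_args$seed <- .stage_seed(config$seed, "simulate")
    scfg <- do.call(sim_config, sim_args)
    layout <- build_genome_layout(scfg)
    sim <- simulate_counts(layout, scfg)
    results$sim <<- sim
    out <- character()
    if (!is.null(outdir)) out <- write_simulation(sim, outdir)
    note("simulate", list(seed = scfg$seed, n_peaks = scfg$n_peaks,
                          n_genes = scfg$n_genes,
                          n_interactions = scfg$n_interactions),
         nrow(sim$truth), out)
  })
  sim <- results$sim

  # -- differential --------------------------------------------------------
  run_stage("differential", function() {
    fs <- filter_spec(di_fdr = thr$di_fdr)
    flt <- filter_interactions(sim$layout$interactions,
                               sim$counts$PET, fs)
    keep_ids <- flt$interactions$int_id
    diffs <- list()
    for (a in names(sim$counts)) {
      d <- .diff_assay(sim, a)
      if (a == "PET") d <- d[feature_id %in% keep_ids]
      d[, qvalue := bh_adjust(pvalue)]  # re-adjust after filtering
      data.table::setattr(d, "groups", c("B6", "D2"))
      diffs[[a]] <- d
    }
    dis <- call_differential(diffs$PET, thr$di_fdr)
    results$filter_report <<- flt$report
    results$diff <<- diffs
    results$dis <<- dis
    out <- character()
    if (!is.null(outdir)) {
      for (a in names(diffs)) {
        f <- file.path(outdir, sprintf("diff_%s.tsv", a))
        data.table::fwrite(diffs[[a]], f, sep = "\t")
        out <- c(out, f)
      }
      f <- file.path(outdir, "filter_report.json")
      jsonlite::write_json(flt$report, f, auto_unbox = TRUE)
      out <- c(out, f)
    }
    note("differential",
         list(di_fdr = thr$di_fdr, filter = flt$report),
         sum(vapply(diffs, nrow, 1L)), out)
  })

  targets <- make_qtl_targets(sim$layout)
  peak_targets <- targets[type == "peak"]

  need_upstream <- function(stage, what) {
    if (is.null(results[[what]]))
      stop(sprintf("stage '%s' needs missing upstream output '%s'",
                   stage, what), call. = FALSE)
  }

  # -- qtl -----------------------------------------------------------------
  run_stage("qtl", function() {
    need_upstream("qtl", "dis")
    dis_ints <- sim$layout$interactions[int_id %in% results$dis$feature_id]
    cls <- classify_anchor_overlap(dis_ints, peak_targets)
    enr <- permutation_enrichment(
      dis_ints, peak_targets$target_id,
      sim$layout$peaks[, .(peak_id, chrom, start, end)],
      n_perm = thr$n_perm, seed = .stage_seed(config$seed, "qtl"))
    # DI log2fc vs target effect size, one row per (DI, target) pair
    pairs <- .di_target_pairs(dis_ints, peak_targets, results$diff$PET)
    cors <- lapply(c("cis", "trans"), function(md) {
      px <- pairs[mode == md]
      if (nrow(px) >= 3 && stats::sd(px$log2fc) > 0 &&
          stats::sd(px$effect_size) > 0)
        correlate_strength_effect(px$log2fc, px$effect_size, md)
      else list(r = NA_real_, p = NA_real_, n = nrow(px), mode = md)
    })
    conc <- if (nrow(pairs))
      allele_concordance(ifelse(pairs$log2fc > 0, "B6", "D2"),
                         pairs$high_allele) else NULL
    results$qtl <<- list(classification = cls, enrichment = enr,
                         correlations = cors, concordance = conc)
    out <- character()
    if (!is.null(outdir)) {
      f <- file.path(outdir, "qtl_classification.tsv")
      data.table::fwrite(cls$per_di, f, sep = "\t")
      f2 <- file.path(outdir, "qtl_enrichment.json")
      jsonlite::write_json(list(observed = as.list(cls$proportions),
                                p = as.list(enr$p), n_perm = enr$n_perm),
                           f2, auto_unbox = TRUE, digits = NA)
      out <- c(f, f2)
    }
    note("qtl", list(n_perm = thr$n_perm), nrow(cls$per_di), out)
  })

  # -- signature -----------------------------------------------------------
  run_stage("signature", function() {
    need_upstream("signature", "diff")
    fc <- data.table::rbindlist(lapply(names(results$diff), function(a)
      results$diff[[a]][, .(feature_id, assay = a, log2fc, qvalue)]))
    calls <- call_discordance(fc, thr$discordance_q)
    cls_map <- setNames(
      ifelse(sim$layout$peaks$class == "trans_target", "trans",
             ifelse(sim$layout$peaks$class == "cis_target", "cis", NA)),
      sim$layout$peaks$peak_id)
    calls[, class := cls_map[feature_id]]
    sub <- calls[!is.na(class)]
    contrast <- discordance_odds_ratio(sub$discordant, sub$class)
    results$signature <<- list(foldchanges = fc, calls = calls,
                               contrast = contrast)
    out <- character()
    if (!is.null(outdir)) {
      f <- file.path(outdir, "discordance.tsv")
      data.table::fwrite(calls, f, sep = "\t")
      f2 <- file.path(outdir, "discordance_contrast.json")
      jsonlite::write_json(list(or = contrast$or, p = contrast$p,
                                ci = contrast$ci), f2, auto_unbox = TRUE,
                           digits = NA)
      out <- c(f, f2)
    }
    note("signature", list(q = thr$discordance_q), nrow(calls), out)
  })

  # -- rad -----------------------------------------------------------------
  run_stage("rad", function() {
    rc <- rad_config(sim$config$rad_window_bp)
    focal_genes <- sim$layout$genes[class == "trans_egene", gene_id]
    focal_peaks <- sim$layout$peaks[class == "trans_target", peak_id]
    conn <- build_connections(sim$layout$genes, sim$layout$peaks,
                              focal_genes, focal_peaks, rc)
    enr <- rad_enrichment(conn, rc)
    # control: same number of focal genes drawn from the non-linked set
    set.seed(.stage_seed(config$seed, "rad"))
    ctrl_genes <- sample(sim$layout$genes[class != "trans_egene", gene_id],
                         length(focal_genes))
    conn_c <- build_connections(sim$layout$genes, sim$layout$peaks,
                                ctrl_genes, focal_peaks, rc)
    enr_c <- rad_enrichment(conn_c, rc)
    results$rad <<- list(enrichment = enr, control = enr_c)
    out <- character()
    if (!is.null(outdir)) {
      f <- file.path(outdir, "rad_enrichment.tsv")
      data.table::fwrite(enr, f, sep = "\t")
      out <- f
    }
    note("rad", list(window = rc$window_bp, bin = rc$bin_width_bp),
         nrow(enr), out)
  })

  # -- dominance -----------------------------------------------------------
  run_stage("dominance", function() {
    need_upstream("dominance", "diff")
    dom <- dominance_table(sim$counts$ATAC, sim$sample_sheet, peak_targets,
                           assay = "ATAC", min_lod = thr$min_lod,
                           epsilon = thr$epsilon)
    cmpr <- compare_dominance(dom[mode == "trans", d], dom[mode == "cis", d])
    # repressive-allele classification from the estimated ATAC contrast
    est <- merge(peak_targets[mode == "trans",
                              .(target_id, true_allele = repressive_allele)],
                 results$diff$ATAC[, .(target_id = feature_id,
                                       effect_size = log2fc)],
                 by = "target_id")
    cls <- classify_repressive_allele(est)
    frac_d2 <- mean(cls$calls$repressive_allele == "D2")
    results$dominance <<- list(table = dom, comparison = cmpr,
                               allele_calls = cls, frac_d2 = frac_d2)
    out <- character()
    if (!is.null(outdir)) {
      f <- file.path(outdir, "dominance.tsv")
      data.table::fwrite(dom, f, sep = "\t")
      f2 <- file.path(outdir, "dominance_comparison.json")
      jsonlite::write_json(list(p = cmpr$p, effect_size = cmpr$effect_size,
                                medians = as.list(cmpr$medians),
                                frac_d2_repressive = frac_d2),
                           f2, auto_unbox = TRUE, digits = NA)
      out <- c(f, f2)
    }
    note("dominance", list(min_lod = thr$min_lod, epsilon = thr$epsilon),
         nrow(dom), out)
  })

  # -- congenic ------------------------------------------------------------
  run_stage("congenic", function() {
    calls <- peak_targets[mode == "trans",
                          .(feature_id = target_id, repressive_allele)]
    pet_calls <- map_interactions_to_targets(
      sim$layout$interactions,
      peak_targets[mode == "trans",
                   .(chrom, start, end, repressive_allele)])$calls
    pred_pk <- predict_directions(calls,
                                  assays = c("H3K9me3", "ATAC", "H3K27ac"))
    pred_pet <- predict_directions(pet_calls, assays = "PET")
    preds <- data.table::rbindlist(list(pred_pk$predictions,
                                        pred_pet$predictions))
    obs <- data.table::rbindlist(lapply(
      congenic_comparisons()$comparison, function(cmp)
        data.table::rbindlist(lapply(.CONGENIC_ASSAYS, function(a)
          observe_direction(sim$counts[[a]], sim$sample_sheet, a, cmp)))))
    val <- validate_predictions(preds, obs)
    es <- effectsize_validated_vs_not(val$per_feature)
    results$congenic <<- list(validation = val, effect_sizes = es)
    out <- character()
    if (!is.null(outdir)) {
      f <- file.path(outdir, "congenic_validation.tsv")
      data.table::fwrite(val$pooled, f, sep = "\t")
      f2 <- file.path(outdir, "congenic_per_feature.tsv")
      data.table::fwrite(val$per_feature, f2, sep = "\t")
      out <- c(f, f2)
    }
    note("congenic", list(), nrow(val$per_feature), out)
  })

  if (!is.null(outdir)) {
    f <- file.path(outdir, "report.json")
    jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
  }
  structure(list(results = results, report = report, config = config),
            class = "pipeline_run")
}

# One row per (significant DI, overlapping peak target).
.di_target_pairs <- function(dis_ints, peak_targets, pet_diff) {
  x <- data.table::as.data.table(dis_ints)
  tg <- data.table::as.data.table(peak_targets)
  anchors <- data.table::rbindlist(list(
    x[, .(chrom = chrom1, start = start1, end = end1, int = .I)],
    x[, .(chrom = chrom2, start = start2, end = end2, int = .I)]))
  hits <- .overlap_pairs(anchors[, .(chrom, start, end)], tg)
  if (!nrow(hits))
    return(data.table::data.table(int_id = character(),
                                  target_id = character(),
                                  mode = character(),
                                  high_allele = character(),
                                  effect_size = numeric(),
                                  log2fc = numeric()))
  out <- data.table::data.table(
    int_id = x$int_id[anchors$int[hits$q]],
    target_id = tg$target_id[hits$s],
    mode = tg$mode[hits$s],
    high_allele = tg$high_allele[hits$s],
    effect_size = tg$effect_size[hits$s])
  out <- unique(out)  # an interaction may hit the same target via both anchors
  merge(out, pet_diff[, .(int_id = feature_id, log2fc)], by = "int_id")
}
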