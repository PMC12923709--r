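#' End-to-end synthetic gene-prioritization run
#'
#' Simulates a two-ancestry GWAS over a block-LD genome and runs the full
#' prioritization pipeline: variant QC of the cross-ancestry meta-analysis
#' against the combined panel, LD clumping, region building, stepwise joint
#' selection, leave-one-hit-out conditional statistics, credible sets and
#' loci, per-ancestry gene-based tests with cross-ancestry meta-analysis,
#' feature-based priority scores with leave-one-chromosome-out ridge,
#' rule-based prioritization with the locus-gene classifier and enrichment
#' test, drug-tier annotation, and colocalization against a simulated
#' second trait sharing a subset of causal variants.
#'
#' @param outdir optional directory; when given, every declared output file
#'   is written there (summary statistics, panel matrix and metadata, truth
#'   tables, gene models BED, QC JSON, signals, credible sets, loci BED and
#'   gene counts, gene scores, priority scores, priority calls, coloc
#'   results).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param config named list overriding simulation settings; see Details.
#'
#' @details Default configuration: 20 LD blocks of 100 variants (10 kb
#' spacing) on 10 chromosomes; exchangeable within-block correlation 0.6
#' (ancestry A) and 0.4 (ancestry B); panels of 2,191 and 538 samples with
#' a combined panel mixing them 80/20; 2,000 overlapping 30 kb gene models;
#' 12 causal variants (one in each of 12 blocks) with standardized effects
#' drawn from U(0.02, 0.035); effective sample sizes 126,282 and 30,515;
#' 50 gene features with one feature enriched in causal genes by 2 SD; a
#' second trait (n_eff 100,000) sharing half the causal variants.
#'
#' @return list with all intermediate and final objects; `files` names the
#'   written paths when `outdir` was given.
#' @export
run_pipeline <- function(outdir = NULL, seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    n_blocks = 20L, block_size = 100L, n_chromosomes = 10L,
    spacing_bp = 10000L, rho_a = 0.6, rho_b = 0.4,
    n_samples_a = 2191L, n_samples_b = 538L, mix = 0.8,
    maf_range = c(0.05, 0.5),
    n_genes = 2000L, gene_width_bp = 30000L,
    n_causal = 12L, effect_range = c(0.02, 0.035),
    n_eff_a = 126282, n_eff_b = 30515,
    n_features = 50L, enrichment_effect = 2, n_enriched = 1L,
    n_eff_trait2 = 100000, shared_fraction = 0.5), config)

  chroms <- rep(as.character(seq_len(cfg$n_chromosomes)),
                length.out = cfg$n_blocks)
  block_sizes <- rep(cfg$block_size, cfg$n_blocks)
  panel_a <- simulate_reference_panel(cfg$n_samples_a, block_sizes,
                                      cfg$rho_a, cfg$maf_range,
                                      seed = seed + 11L,
                                      spacing_bp = cfg$spacing_bp,
                                      chromosomes = chroms)
  panel_b <- simulate_reference_panel(cfg$n_samples_b, block_sizes,
                                      cfg$rho_b, cfg$maf_range,
                                      seed = seed + 12L,
                                      spacing_bp = cfg$spacing_bp,
                                      chromosomes = chroms)
  n_mix_a <- round(cfg$mix / (1 - cfg$mix) * cfg$n_samples_b)
  n_mix_a <- min(n_mix_a, cfg$n_samples_a)
  vmix <- panel_a$variants
  vmix$freq <- cfg$mix * panel_a$variants$freq +
    (1 - cfg$mix) * panel_b$variants$freq
  panel_ab <- reference_panel(
    rbind(panel_a$genotypes[seq_len(n_mix_a), , drop = FALSE],
          panel_b$genotypes), vmix)

  genes <- simulate_gene_models(panel_a, cfg$n_genes, cfg$gene_width_bp)

  set.seed(seed + 21L)
  causal_blocks <- sort(sample(cfg$n_blocks, cfg$n_causal))
  v <- panel_a$variants
  causal_ids <- vapply(causal_blocks, function(b) {
    ids <- v$variant_id[v$block == b]
    ids[ceiling(length(ids) / 2)]
  }, "")
  effects <- stats::runif(cfg$n_causal, cfg$effect_range[1],
                          cfg$effect_range[2]) *
    sample(c(-1, 1), cfg$n_causal, replace = TRUE)
  causal_genes <- vapply(causal_ids, function(id) {
    i <- match(id, v$variant_id)
    nearest_gene(list(chr = v$chr[i], centroid = v$pos[i]), genes)$gene_id
  }, "")
  shared <- rep(FALSE, cfg$n_causal)
  shared[seq_len(max(1, round(cfg$shared_fraction * cfg$n_causal)))] <- TRUE
  truth <- architecture_truth(causal_ids, effects, unique(causal_genes),
                              shared_with_trait2 = shared, seed = seed)

  stats_a <- simulate_sumstats(panel_a, truth, cfg$n_eff_a,
                               seed = seed + 22L, ancestry = "ancA")
  stats_b <- simulate_sumstats(panel_b, truth, cfg$n_eff_b,
                               seed = seed + 23L, ancestry = "ancB")
  paired <- simulate_paired_traits(panel_a, truth, cfg$n_eff_a,
                                   cfg$n_eff_trait2, seed = seed + 24L)
  stats_t2 <- paired$trait2

  meta <- meta_sumstats(stats_a, stats_b)
  qc <- qc_filter(meta, panel_ab)

  signals <- isolate_signals(qc$table, panel_ab, genes)

  scores_a <- gene_scores(stats_a, genes, panel_a)
  scores_b <- gene_scores(stats_b, genes, panel_b)
  gscore <- meta_gene_scores(scores_a, cfg$n_eff_a, scores_b, cfg$n_eff_b)

  features <- simulate_gene_features(genes, truth, cfg$n_features,
                                     cfg$enrichment_effect,
                                     seed = seed + 31L,
                                     n_enriched = cfg$n_enriched)
  pops_a <- pops_fit(features, scores_a)
  pops_b <- pops_fit(features, scores_b)
  pscore <- meta_priority(pops_a$scores, cfg$n_eff_a,
                          pops_b$scores, cfg$n_eff_b)

  annotations <- simulate_gene_annotations(genes, truth, seed = seed + 41L)
  nonsyn <- simulate_nonsyn_flags(panel_ab, genes, truth, seed = seed + 42L)

  calls <- lapply(signals$loci, apply_criteria, scores = pscore,
                  nonsyn = nonsyn, annotations = annotations, genes = genes)
  prioritized <- unique(unlist(lapply(calls, `[[`, "prioritized_genes")))

  locus_genes <- psyops_inputs(signals$loci, genes)
  psyops <- if (length(unique(locus_genes$chr)) >= 2 &&
                length(unique(locus_genes$is_positive)) == 2)
    psyops_classify(locus_genes, annotations) else NULL

  universe <- unique(unlist(lapply(signals$loci, `[[`, "gene_ids")))
  enr <- if (length(universe))
    enrichment(intersect(prioritized, universe),
               intersect(annotations$gene_id[annotations$dd_asd_label],
                         universe), universe) else NULL

  set.seed(seed + 43L)
  has_drug <- annotations$gene_id[annotations$drug_phase != "none"]
  drug_table <- data.frame(
    gene_id = has_drug,
    phase = annotations$drug_phase[match(has_drug, annotations$gene_id)],
    indication_class = sample(.indication_classes, length(has_drug),
                              replace = TRUE),
    stringsAsFactors = FALSE)
  drug_table$indication_class[drug_table$phase == "tractable"] <- NA
  drugs <- annotate_drugs(prioritized, drug_table)

  signals_t2 <- isolate_signals(stats_t2, panel_a, genes)
  shared_loci <- overlap_loci(signals$loci, signals_t2$loci,
                              qc$table, stats_t2)
  coloc <- lapply(seq_len(nrow(shared_loci)), function(i) {
    ids <- shared_loci$variant_ids[[i]]
    if (length(ids) < 2) return(NULL)
    coloc_abf(subset_sumstats(qc$table, qc$table$variant_id %in% ids),
              subset_sumstats(stats_t2, stats_t2$variant_id %in% ids))
  })

  res <- list(config = cfg, seed = seed, truth = truth,
              panel_a = panel_a, panel_b = panel_b, panel_ab = panel_ab,
              genes = genes, stats_a = stats_a, stats_b = stats_b,
              stats_meta = meta, stats_trait2 = stats_t2,
              qc = qc, signals = signals,
              gene_scores_a = scores_a, gene_scores_b = scores_b,
              gene_scores_meta = gscore, features = features,
              pops_a = pops_a, pops_b = pops_b, priority_scores = pscore,
              annotations = annotations, nonsyn = nonsyn,
              calls = calls, prioritized = prioritized,
              psyops = psyops, enrichment = enr, drugs = drugs,
              signals_trait2 = signals_t2, shared_loci = shared_loci,
              coloc = coloc)
  if (!is.null(outdir)) res$files <- write_pipeline_outputs(res, outdir)
  res
}

# collect per-locus nearest-gene positives and other-gene negatives,
# deduplicated (a gene positive in any locus stays positive)
psyops_inputs <- function(loci, genes) {
  rows <- lapply(loci, function(l) {
    near <- nearest_gene(l$cs, genes)
    if (!length(l$gene_ids)) return(NULL)
    data.frame(gene_id = l$gene_ids,
               chr = l$chr,
               is_positive = l$gene_ids %in% near$gene_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame(gene_id = character(),
                                     chr = character(),
                                     is_positive = logical()))
  pos <- tapply(df$is_positive, df$gene_id, any)
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df$is_positive <- as.logical(pos[df$gene_id])
  rownames(df) <- NULL
  df
}

#' Isolate, fine-map, and localize the independent signals of one trait
#'
#' Runs clumping, region building, stepwise joint selection,
#' leave-one-hit-out conditional statistics, credible sets, and locus
#' definition for a harmonized summary-statistics table.
#'
#' @param table a [sumstats()] table harmonized to `panel`.
#' @param panel a [reference_panel()].
#' @param genes gene-model table.
#' @param p_threshold,r2_threshold,window_bp clumping settings.
#' @param region_pad_bp clump expansion (default 500 kb).
#' @param locus_pad_bp credible-set padding (default 300 kb).
#' @return list with `clumps`, `regions`, `hits` (data.frame of selected
#'   hits with region ids), `credible_sets`, `loci`.
#' @export
isolate_signals <- function(table, panel, genes, p_threshold = 5e-8,
                            r2_threshold = 0.1, window_bp = 3e6,
                            region_pad_bp = 5e5, locus_pad_bp = 3e5) {
  clumps <- clump(table, panel, p_threshold, r2_threshold, window_bp)
  regions <- build_regions(clumps, region_pad_bp)
  hits <- list(); css <- list(); loci <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    rs <- region_stats(table, reg)
    sel <- stepwise_joint(rs, panel, p_threshold)
    if (!nrow(sel)) next
    sel$region_id <- reg$region_id
    hits[[length(hits) + 1L]] <- sel
    for (k in seq_len(nrow(sel))) {
      others <- setdiff(sel$variant_id, sel$variant_id[k])
      cond <- conditional_sumstats(rs, panel, others)
      cs <- abf_credible_set(cond)
      attr(cs, "signal_id") <- sprintf("%s_hit%d", reg$region_id, k)
      attr(cs, "lead") <- sel$variant_id[k]
      css[[length(css) + 1L]] <- cs
      loci[[length(loci) + 1L]] <- define_locus(cs, genes, locus_pad_bp)
    }
  }
  list(clumps = clumps, regions = regions,
       hits = if (length(hits)) do.call(rbind, hits) else NULL,
       credible_sets = css, loci = loci)
}

# write every declared pipeline output file; returns named paths
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_synthetic_inputs(outdir, panel = res$panel_a,
                                  genes = res$genes, truth = res$truth)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["sumstats_a"] <- write_sumstats(res$stats_a,
                                        file.path(outdir, "sumstats_ancA.tsv"))
  paths["sumstats_b"] <- write_sumstats(res$stats_b,
                                        file.path(outdir, "sumstats_ancB.tsv"))
  paths["sumstats_meta"] <- write_sumstats(res$stats_meta,
                                           file.path(outdir, "sumstats_meta.tsv"))
  paths["sumstats_trait2"] <- write_sumstats(
    res$stats_trait2, file.path(outdir, "sumstats_trait2.tsv"))
  paths["qc_report"] <- write_qc_report(res$qc$report,
                                        file.path(outdir, "qc_report.json"))
  hits <- res$signals$hits
  paths["signals"] <- wt(if (is.null(hits)) data.frame() else hits,
                         "signals.tsv")
  cs_df <- do.call(rbind, lapply(res$signals$credible_sets, function(cs) {
    df <- as.data.frame(cs)
    df$signal_id <- attr(cs, "signal_id")
    df
  }))
  paths["credible_sets"] <- wt(cs_df %||% data.frame(), "credible_sets.tsv")
  loci_df <- do.call(rbind, lapply(res$signals$loci, function(l)
    data.frame(chr = l$chr, start = l$start - 1L, end = l$end,
               n_genes = l$n_genes, centroid = l$centroid)))
  paths["loci_bed"] <- wt(loci_df %||% data.frame(), "loci.bed")
  gene_counts <- do.call(rbind, lapply(res$signals$loci, function(l)
    data.frame(chr = l$chr, start = l$start, end = l$end,
               n_genes = l$n_genes)))
  paths["locus_gene_counts"] <- wt(gene_counts %||% data.frame(),
                                   "locus_gene_counts.tsv")
  paths["gene_scores"] <- wt(res$gene_scores_meta, "gene_scores_meta.tsv")
  paths["priority_scores"] <- wt(res$priority_scores, "priority_scores.tsv")
  calls_df <- do.call(rbind, lapply(seq_along(res$calls), function(i) {
    ev <- res$calls[[i]]$evidence
    if (!nrow(ev)) return(NULL)
    ev$locus_id <- i
    ev$excluded_large_locus <- res$calls[[i]]$excluded_large_locus
    ev
  }))
  paths["priority_calls"] <- wt(calls_df %||% data.frame(),
                                "priority_calls.tsv")
  coloc_df <- do.call(rbind, lapply(seq_along(res$coloc), function(i) {
    cc <- res$coloc[[i]]
    if (is.null(cc)) return(NULL)
    cbind(data.frame(interval = i, n_variants = cc$n_variants),
          as.data.frame(as.list(cc$pp)))
  }))
  paths["coloc"] <- wt(coloc_df %||% data.frame(), "coloc.tsv")
  paths["drugs"] <- wt(res$drugs, "drug_tiers.tsv")
  if (!is.null(res$psyops))
    paths["psyops"] <- wt(as.data.frame(res$psyops), "psyops.tsv")
  paths
}
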