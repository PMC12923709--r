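#' Ground-truth genetic architecture for simulations
#'
#' Records which panel variants are causal (with standardized per-allele
#' effect sizes), which genes are causal, and which causal variants are
#' shared with a second trait in paired-trait simulations. Recovery tests
#' compare pipeline output against this table.
#'
#' @param causal_variant_ids character vector of panel variant ids.
#' @param causal_effects numeric vector of standardized effect sizes, same
#'   length as `causal_variant_ids`; finite and nonzero.
#' @param causal_gene_ids character vector of causal gene ids (may be empty).
#' @param shared_with_trait2 logical vector, per causal variant; default all
#'   shared.
#' @param seed integer seed recorded with the truth.
#' @return An object of class `architecture_truth`.
#' @export
architecture_truth <- function(causal_variant_ids, causal_effects,
                               causal_gene_ids = character(),
                               shared_with_trait2 = NULL, seed = NA_integer_) {
  causal_variant_ids <- as.character(causal_variant_ids)
  if (length(causal_effects) != length(causal_variant_ids))
    stopf("need one effect per causal variant")
  if (length(causal_variant_ids) &&
      (any(!is.finite(causal_effects)) || any(causal_effects == 0)))
    stopf("causal effects must be finite and nonzero")
  shared_with_trait2 <- shared_with_trait2 %||%
    rep(TRUE, length(causal_variant_ids))
  if (length(shared_with_trait2) != length(causal_variant_ids))
    stopf("shared_with_trait2 must match causal variants in length")
  structure(list(causal_variant_ids = causal_variant_ids,
                 causal_effects = as.numeric(causal_effects),
                 causal_gene_ids = as.character(causal_gene_ids),
                 shared_with_trait2 = as.logical(shared_with_trait2),
                 seed = seed),
            class = "architecture_truth")
}

#' @export
print.architecture_truth <- function(x, ...) {
  cat(sprintf("Architecture truth: %d causal variant(s), %d causal gene(s)\n",
              length(x$causal_variant_ids), length(x$causal_gene_ids)))
  invisible(x)
}

#' Simulate a block-LD reference panel
#'
#' Variants form independent LD blocks laid consecutively along each
#' chromosome with fixed inter-variant spacing. Within a block, standardized
#' genotypes are exchangeable Gaussians with pairwise correlation
#' `within_block_correlation` (or AR(1) with that parameter as the lag-one
#' correlation); across blocks they are independent. Effect-allele
#' frequencies are drawn uniformly from `maf_range` as metadata.
#'
#' @param n_samples number of panel samples (>= 2).
#' @param block_sizes integer vector, one entry per block, all positive.
#' @param within_block_correlation value in `[0, 1)`.
#' @param maf_range length-2 interval within (0, 0.5].
#' @param seed integer seed; identical seeds give byte-identical panels.
#' @param spacing_bp base pairs between consecutive variants (default 10 kb).
#' @param chromosomes chromosome label per block; default all `"1"`.
#' @param ld_structure `"exchangeable"` (default) or `"ar1"`.
#' @return A [reference_panel()] whose variant metadata carries a `block`
#'   column.
#' @export
simulate_reference_panel <- function(n_samples, block_sizes,
                                     within_block_correlation,
                                     maf_range = c(0.05, 0.5),
                                     seed = 1L,
                                     spacing_bp = 10000L,
                                     chromosomes = NULL,
                                     ld_structure = c("exchangeable", "ar1")) {
  ld_structure <- match.arg(ld_structure)
  if (n_samples < 2) stopf("n_samples must be >= 2")
  if (!length(block_sizes) || any(block_sizes < 1))
    stopf("block_sizes must be a non-empty vector of positive integers")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must be a non-empty interval within (0, 0.5]")
  rho <- within_block_correlation
  if (rho < 0 || rho >= 1)
    stopf("within_block_correlation must lie in [0, 1)")
  n_blocks <- length(block_sizes)
  chromosomes <- as.character(chromosomes %||% rep("1", n_blocks))
  if (length(chromosomes) != n_blocks)
    stopf("chromosomes must have one entry per block")

  set.seed(seed)
  m_total <- sum(block_sizes)
  geno <- matrix(NA_real_, n_samples, m_total)
  col0 <- 0L
  for (b in seq_len(n_blocks)) {
    m <- block_sizes[b]
    if (ld_structure == "exchangeable") {
      f <- stats::rnorm(n_samples)
      e <- matrix(stats::rnorm(n_samples * m), n_samples, m)
      x <- sqrt(rho) * f + sqrt(1 - rho) * e
    } else {
      e <- matrix(stats::rnorm(n_samples * m), n_samples, m)
      x <- e
      if (m > 1) for (j in 2:m)
        x[, j] <- rho * x[, j - 1] + sqrt(1 - rho^2) * e[, j]
    }
    geno[, col0 + seq_len(m)] <- x
    col0 <- col0 + m
  }
  freq <- stats::runif(m_total, maf_range[1], maf_range[2])

  # positions: per chromosome, blocks laid end to end with uniform spacing
  pos <- integer(m_total); block_id <- integer(m_total)
  idx0 <- 0L
  for (chr in unique(chromosomes)) {
    at <- spacing_bp
    for (b in which(chromosomes == chr)) {
      m <- block_sizes[b]
      cols <- idx_block(block_sizes, b)
      pos[cols] <- seq(at, by = spacing_bp, length.out = m)
      block_id[cols] <- b
      at <- at + m * spacing_bp
    }
  }
  variants <- data.frame(
    variant_id = sprintf("v%05d", seq_len(m_total)),
    chr = rep(chromosomes, block_sizes),
    pos = pos,
    a1 = "A", a2 = "G",
    freq = freq,
    block = block_id,
    stringsAsFactors = FALSE)
  reference_panel(geno, variants)
}

idx_block <- function(block_sizes, b) {
  off <- if (b == 1) 0L else sum(block_sizes[seq_len(b - 1)])
  off + seq_len(block_sizes[b])
}

#' Simulate GWAS summary statistics from a reference panel and a truth table
#'
#' Per LD block, the marginal z-vector is drawn as
#' \eqn{z = R (\sqrt{n_{eff}}\, b) + \epsilon}, \eqn{\epsilon \sim N(0, R)},
#' where `R` is the block LD correlation matrix estimated from the panel and
#' `b` holds the standardized causal effects (zero off the causal set). On
#' the standardized scale `beta = z / sqrt(n_eff)` and `se = 1 / sqrt(n_eff)`.
#'
#' @param panel a [reference_panel()].
#' @param truth an [architecture_truth()]; all causal variants must exist in
#'   the panel.
#' @param n_eff effective sample size (> 0).
#' @param seed integer seed.
#' @param freq_perturb_sd optional Gaussian perturbation of the reported
#'   effect-allele frequency (for exercising the QC filters); default 0 (off).
#' @param ancestry,trait labels attached to the output table.
#' @return A `sumstats` data.frame (see [sumstats()]).
#' @export
simulate_sumstats <- function(panel, truth, n_eff, seed = 1L,
                              freq_perturb_sd = 0,
                              ancestry = "EUR", trait = "trait1") {
  if (n_eff <= 0) stopf("n_eff must be positive")
  miss <- setdiff(truth$causal_variant_ids, panel$variants$variant_id)
  if (length(miss))
    stopf("causal variant(s) missing from panel: %s",
          paste(miss, collapse = ", "))
  v <- panel$variants
  b <- numeric(nrow(v))
  b[match(truth$causal_variant_ids, v$variant_id)] <- truth$causal_effects

  set.seed(seed)
  z <- numeric(nrow(v))
  blocks <- if (!is.null(v$block)) v$block else rep(1L, nrow(v))
  for (blk in unique(blocks)) {
    cols <- which(blocks == blk)
    R <- panel_ld(panel, v$variant_id[cols])
    mu <- as.vector(R %*% (sqrt(n_eff) * b[cols]))
    L <- chol_psd(R)
    z[cols] <- mu + as.vector(t(L) %*% stats::rnorm(length(cols)))
  }
  freq <- v$freq
  if (freq_perturb_sd > 0)
    freq <- pmin(pmax(freq + stats::rnorm(length(freq), 0, freq_perturb_sd),
                      1e-3), 1 - 1e-3)
  sumstats(data.frame(
    variant_id = v$variant_id, chr = v$chr, pos = v$pos,
    a1 = v$a1, a2 = v$a2, freq = freq,
    beta = z / sqrt(n_eff), se = 1 / sqrt(n_eff),
    p = z_to_p(z), n_eff = n_eff,
    stringsAsFactors = FALSE), ancestry = ancestry, trait = trait)
}

# upper Cholesky factor tolerant of a PSD (rank-deficient) correlation matrix
chol_psd <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(out)) return(out)
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  t(eg$vectors %*% diag(sqrt(vals), length(vals)))
}

#' Simulate a tiled gene-model table over a panel's coordinate span
#'
#' Genes are laid along each chromosome as overlapping fixed-width windows so
#' that distance-based locus stages and the >= 3-variants-per-gene rule of
#' the gene-based test are exercised.
#'
#' @param panel a [reference_panel()].
#' @param n_genes total number of genes; allocated to chromosomes
#'   proportionally to their variant counts.
#' @param gene_width_bp gene body width in base pairs (default 30 kb, i.e.
#'   covering ~3 variants at the default 10 kb spacing).
#' @return A gene-model data.frame with columns `gene_id`, `symbol`, `chr`,
#'   `start`, `end` (1-based inclusive), `coding`.
#' @export
simulate_gene_models <- function(panel, n_genes, gene_width_bp = 30000L) {
  v <- panel$variants
  chrs <- unique(v$chr)
  counts <- table(factor(v$chr, levels = chrs))
  alloc <- pmax(1L, round(n_genes * as.numeric(counts) / nrow(v)))
  rows <- list()
  gi <- 0L
  for (k in seq_along(chrs)) {
    vv <- v[v$chr == chrs[k], ]
    span_lo <- min(vv$pos); span_hi <- max(vv$pos)
    starts <- round(seq(max(1, span_lo - gene_width_bp / 2),
                        max(1, span_hi - gene_width_bp / 2),
                        length.out = alloc[k]))
    rows[[k]] <- data.frame(
      gene_id = sprintf("g%04d", gi + seq_len(alloc[k])),
      symbol = sprintf("GENE%d", gi + seq_len(alloc[k])),
      chr = chrs[k],
      start = starts,
      end = starts + gene_width_bp - 1L,
      coding = TRUE,
      stringsAsFactors = FALSE)
    gi <- gi + alloc[k]
  }
  do.call(rbind, rows)
}

#' Simulate a standardized gene-by-feature matrix with causal enrichment
#'
#' Columns are independent standard-normal features, standardized to mean 0
#' and unit variance; a designated leading subset of `n_enriched` features
#' then has `enrichment_effect` added for causal genes, so the expected
#' causal-vs-other mean difference on those columns equals
#' `enrichment_effect`.
#'
#' @param genes gene-model table (rows define the matrix rows).
#' @param truth an [architecture_truth()] supplying `causal_gene_ids`.
#' @param n_features number of feature columns (>= 1).
#' @param enrichment_effect non-negative mean shift for causal genes.
#' @param seed integer seed.
#' @param n_enriched how many leading features carry the shift (default 1).
#' @return Numeric matrix (genes x features) with dimnames, carrying an
#'   `enriched` attribute naming the shifted columns.
#' @export
simulate_gene_features <- function(genes, truth, n_features,
                                   enrichment_effect = 0, seed = 1L,
                                   n_enriched = 1L) {
  if (n_features < 1) stopf("n_features must be >= 1")
  if (enrichment_effect < 0) stopf("enrichment_effect must be non-negative")
  n_enriched <- min(n_enriched, n_features)
  set.seed(seed)
  g <- nrow(genes)
  x <- matrix(stats::rnorm(g * n_features), g, n_features)
  if (g > 1) x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  causal <- genes$gene_id %in% truth$causal_gene_ids
  if (enrichment_effect > 0 && any(causal) && n_enriched > 0)
    x[causal, seq_len(n_enriched)] <-
      x[causal, seq_len(n_enriched)] + enrichment_effect
  dimnames(x) <- list(genes$gene_id, sprintf("f%04d", seq_len(n_features)))
  attr(x, "enriched") <- colnames(x)[seq_len(n_enriched)]
  x
}

#' Simulate summary statistics for two traits sharing causal variants
#'
#' Trait 1 uses all causal variants in `truth`; trait 2 uses those flagged
#' `shared_with_trait2` plus any trait-2-only causal set, with independent
#' sampling noise.
#'
#' @inheritParams simulate_sumstats
#' @param n_eff_1,n_eff_2 effective sample sizes of the two traits.
#' @param trait2_only optional list with `causal_variant_ids` and
#'   `causal_effects` for trait-2-only causal variants.
#' @return A list of two `sumstats` tables, `trait1` and `trait2`.
#' @export
simulate_paired_traits <- function(panel, truth, n_eff_1, n_eff_2, seed = 1L,
                                   trait2_only = NULL) {
  t2_ids <- truth$causal_variant_ids[truth$shared_with_trait2]
  t2_eff <- truth$causal_effects[truth$shared_with_trait2]
  if (!is.null(trait2_only)) {
    t2_ids <- c(t2_ids, trait2_only$causal_variant_ids)
    t2_eff <- c(t2_eff, trait2_only$causal_effects)
  }
  truth2 <- architecture_truth(t2_ids, t2_eff, truth$causal_gene_ids,
                               seed = truth$seed)
  list(
    trait1 = simulate_sumstats(panel, truth, n_eff_1, seed = seed,
                               trait = "trait1"),
    trait2 = simulate_sumstats(panel, truth2, n_eff_2, seed = seed + 1L,
                               trait = "trait2"))
}

#' Simulate per-gene annotations with causal enrichment
#'
#' Generates the binary gene annotations consumed by the prioritization
#' layer: a rare-variant burden significance flag, a developmental-disorder /
#' autism label, the three PsyOPS-style predictors (loss-of-function
#' intolerance, brain-specific expression, known neurodevelopmental gene),
#' and a drug phase. Causal genes are enriched for every annotation.
#'
#' @param genes gene-model table.
#' @param truth an [architecture_truth()].
#' @param seed integer seed.
#' @return data.frame with one row per gene: `gene_id`,
#'   `burden_fdr_significant`, `dd_asd_label`, `pli_flag`, `brain_flag`,
#'   `neurodev_flag`, `drug_phase`.
#' @export
simulate_gene_annotations <- function(genes, truth, seed = 1L) {
  set.seed(seed)
  g <- nrow(genes)
  causal <- genes$gene_id %in% truth$causal_gene_ids
  draw <- function(p_causal, p_null)
    stats::runif(g) < ifelse(causal, p_causal, p_null)
  phases <- c("approved", "investigational", "tractable", "none")
  data.frame(
    gene_id = genes$gene_id,
    burden_fdr_significant = draw(0.30, 0.005),
    dd_asd_label = draw(0.40, 0.02),
    pli_flag = draw(0.70, 0.10),
    brain_flag = draw(0.70, 0.15),
    neurodev_flag = draw(0.50, 0.05),
    drug_phase = sample(phases, g, replace = TRUE,
                        prob = c(0.02, 0.02, 0.06, 0.90)),
    stringsAsFactors = FALSE)
}

#' Simulate non-synonymous variant flags for causal variants
#'
#' Marks variants as non-synonymous (assigned to a containing gene) with a
#' higher rate at causal variants, and attaches the per-variant heritability
#' eligibility flag consumed by the non-synonymous prioritization route.
#'
#' @param panel a [reference_panel()].
#' @param genes gene-model table.
#' @param truth an [architecture_truth()].
#' @param prob_causal,prob_null non-synonymous probability for causal /
#'   non-causal variants.
#' @param seed integer seed.
#' @return data.frame `variant_id`, `gene_id`, `h2_ok` (one row per
#'   non-synonymous variant-gene assignment).
#' @export
simulate_nonsyn_flags <- function(panel, genes, truth,
                                  prob_causal = 0.5, prob_null = 0.01,
                                  seed = 1L) {
  set.seed(seed)
  v <- panel$variants
  causal <- v$variant_id %in% truth$causal_variant_ids
  is_ns <- stats::runif(nrow(v)) < ifelse(causal, prob_causal, prob_null)
  out <- list()
  for (i in which(is_ns)) {
    hit <- genes$chr == v$chr[i] & genes$start <= v$pos[i] &
      genes$end >= v$pos[i]
    if (!any(hit)) next
    # assign to the causal containing gene when there is one, else the first
    gid <- genes$gene_id[hit]
    gid <- if (any(gid %in% truth$causal_gene_ids))
      gid[gid %in% truth$causal_gene_ids][1] else gid[1]
    out[[length(out) + 1L]] <- data.frame(
      variant_id = v$variant_id[i], gene_id = gid, h2_ok = TRUE,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(), gene_id = character(),
                      h2_ok = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write synthetic inputs to disk
#'
#' Emits the plain-text artifacts of a simulation: summary statistics TSV,
#' panel genotype matrix and variant metadata TSV, truth table TSV, and a
#' BED-like gene-model table (0-based half-open coordinates).
#'
#' @param dir output directory (created if needed).
#' @param panel,genes,truth,stats simulation objects (any may be `NULL`).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_inputs <- function(dir, panel = NULL, genes = NULL,
                                   truth = NULL, stats = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(panel)) {
    gp <- file.path(dir, "panel_genotypes.tsv")
    utils::write.table(panel$genotypes, gp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    vp <- file.path(dir, "panel_variants.tsv")
    utils::write.table(panel$variants, vp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, panel_genotypes = gp, panel_variants = vp)
  }
  if (!is.null(genes)) {
    bp <- file.path(dir, "gene_models.bed")
    bed <- data.frame(chr = genes$chr, start = genes$start - 1L,
                      end = genes$end, gene_id = genes$gene_id,
                      symbol = genes$symbol,
                      coding = as.integer(genes$coding))
    utils::write.table(bed, bp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    paths <- c(paths, gene_models = bp)
  }
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.tsv")
    tt <- data.frame(variant_id = truth$causal_variant_ids,
                     effect = truth$causal_effects,
                     shared_with_trait2 = truth$shared_with_trait2)
    utils::write.table(tt, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    gp2 <- file.path(dir, "truth_genes.tsv")
    utils::write.table(data.frame(gene_id = truth$causal_gene_ids), gp2,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, truth = tp, truth_genes = gp2)
  }
  if (!is.null(stats)) {
    sp <- file.path(dir, "sumstats.tsv")
    write_sumstats(stats, sp)
    paths <- c(paths, sumstats = sp)
  }
  invisible(paths)
}
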