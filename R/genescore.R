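#' Map variants to genes by position
#'
#' A variant is assigned to every gene whose `[start, end]` interval
#' contains its position (no window padding). Variants whose panel minor
#' allele frequency is at or below `maf_min` are excluded first, and genes
#' with fewer than `min_variants` assigned variants are dropped.
#'
#' @param table a [sumstats()] table.
#' @param genes gene-model table.
#' @param panel a [reference_panel()] supplying the MAF filter frequencies.
#' @param maf_min MAF threshold; variants must have panel MAF strictly above
#'   it (default 0.01).
#' @param min_variants minimum mapped variants per gene (default 3).
#' @return Named list: per retained gene, the vector of mapped variant ids.
#' @export
map_variants_to_genes <- function(table, genes, panel, maf_min = 0.01,
                                  min_variants = 3L) {
  f <- panel_freq(panel, table$variant_id)
  maf <- pmin(f, 1 - f)
  tab <- subset_sumstats(table, maf > maf_min)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    hit <- tab$chr == genes$chr[i] & tab$pos >= genes$start[i] &
      tab$pos <= genes$end[i]
    out[[i]] <- tab$variant_id[hit]
  }
  out[vapply(out, length, 0L) >= min_variants]
}

#' Gene-level association statistic from per-variant z-scores
#'
#' The "SNP-wise mean" statistic is the mean per-variant chi-square,
#' `T = mean(z^2)`. Under the null, `m * T` follows the weighted mixture
#' \eqn{\sum_i \lambda_i \chi^2_1} with weights the eigenvalues of the
#' variants' LD correlation matrix; the p-value is the upper tail of that
#' mixture (numerical inversion with a moment-matched gamma fallback), and
#' the gene z-score is the one-sided probit \eqn{\Phi^{-1}(1-p)} clipped to
#' +/- 38. Negative eigenvalues beyond numerical tolerance are floored at
#' zero with a warning.
#'
#' @param z numeric vector of per-variant z-scores.
#' @param ld LD correlation matrix of the same variants (symmetric, PSD to
#'   tolerance).
#' @return list with `statistic` (mean chi-square), `p`, `z`, `n_variants`.
#' @export
gene_statistic <- function(z, ld) {
  m <- length(z)
  if (m < 1) stopf("gene statistic needs at least one variant")
  ld <- as.matrix(ld)
  if (!all(dim(ld) == m)) stopf("LD matrix dimension does not match z")
  lambda <- eigen((ld + t(ld)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(lambda < -1e-6))
    warnf("LD matrix not PSD (min eigenvalue %.3g); flooring at zero",
          min(lambda))
  lambda <- pmax(lambda, 0)
  q <- sum(z^2)
  p <- weighted_chisq_tail(q, lambda)
  list(statistic = q / m, p = p, z = p_to_z_onesided(p), n_variants = m)
}

#' Gene-based association scores for one ancestry
#'
#' Maps variants to genes, then computes the [gene_statistic()] per gene
#' using the panel LD of its mapped variants. For numerical stability the
#' per-gene LD matrix is shrunk by adding `shrink` to the diagonal and
#' renormalizing.
#'
#' @inheritParams map_variants_to_genes
#' @param shrink diagonal shrinkage epsilon (default 1e-3).
#' @return data.frame: `gene_id`, `symbol`, `chr`, `n_variants`,
#'   `statistic`, `p`, `z`, `ancestry`.
#' @export
gene_scores <- function(table, genes, panel, maf_min = 0.01,
                        min_variants = 3L, shrink = 1e-3) {
  mapping <- map_variants_to_genes(table, genes, panel, maf_min,
                                   min_variants)
  z_all <- sumstats_z(table)
  names(z_all) <- table$variant_id
  rows <- lapply(names(mapping), function(g) {
    ids <- mapping[[g]]
    R <- panel_ld(panel, ids)
    R <- (R + shrink * diag(nrow(R))) / (1 + shrink)
    gs <- gene_statistic(z_all[ids], R)
    gi <- match(g, genes$gene_id)
    data.frame(gene_id = g, symbol = genes$symbol[gi], chr = genes$chr[gi],
               n_variants = gs$n_variants, statistic = gs$statistic,
               p = gs$p, z = gs$z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), symbol = character(),
                      chr = character(), n_variants = integer(),
                      statistic = numeric(), p = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  out$ancestry <- attr(table, "ancestry") %||% NA_character_
  out
}

#' Meta-analyze gene scores across two ancestries
#'
#' Per gene, combines the ancestry-specific gene z-scores with [meta_z()]
#' weighted by the square root of the GWAS effective sample sizes. Genes
#' present in a single ancestry keep that z, with provenance recorded.
#'
#' @param scores_a,scores_b outputs of [gene_scores()].
#' @param n_a,n_b effective sample sizes of the two GWASes.
#' @return data.frame: `gene_id`, `symbol`, `chr`, `z`, `p`, `provenance`
#'   (`"both"`, `"a_only"`, `"b_only"`), `ancestry = "meta"`.
#' @export
meta_gene_scores <- function(scores_a, n_a, scores_b, n_b) {
  ids <- union(scores_a$gene_id, scores_b$gene_id)
  ia <- match(ids, scores_a$gene_id)
  ib <- match(ids, scores_b$gene_id)
  z <- meta_z(scores_a$z[ia], n_a, scores_b$z[ib], n_b)
  prov <- ifelse(is.na(ia), "b_only", ifelse(is.na(ib), "a_only", "both"))
  data.frame(
    gene_id = ids,
    symbol = ifelse(is.na(ia), scores_b$symbol[ib], scores_a$symbol[ia]),
    chr = ifelse(is.na(ia), scores_b$chr[ib], scores_a$chr[ia]),
    z = z, p = stats::pnorm(z, lower.tail = FALSE),
    provenance = prov, ancestry = "meta",
    stringsAsFactors = FALSE)
}
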