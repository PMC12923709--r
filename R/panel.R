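#' Reference panel of genotypes for LD estimation
#'
#' A reference panel couples a samples-by-variants genotype matrix (kept on
#' the standardized scale, so pairwise column correlations are the LD
#' correlations \eqn{r}) with per-variant metadata: identifier, chromosome,
#' position, alleles, and effect-allele frequency. Frequencies enter the
#' pipeline only through the minor-allele-count and allele-frequency QC
#' filters and the gene-test MAF filter; all association algebra operates on
#' the standardized-genotype scale.
#'
#' @param genotypes numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `variant_id`, `chr`, `pos`,
#'   `a1` (effect allele), `a2` (other allele), `freq` (effect-allele
#'   frequency in (0,1)); optionally `block`.
#' @return An object of class `ref_panel`.
#' @export
reference_panel <- function(genotypes, variants) {
  genotypes <- as.matrix(genotypes)
  req <- c("variant_id", "chr", "pos", "a1", "a2", "freq")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stopf("variant metadata missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (ncol(genotypes) != nrow(variants))
    stopf("genotype matrix has %d columns but metadata has %d rows",
          ncol(genotypes), nrow(variants))
  if (anyDuplicated(variants$variant_id))
    stopf("duplicate variant ids in panel")
  if (any(variants$freq <= 0 | variants$freq >= 1))
    stopf("panel frequencies must lie strictly in (0,1)")
  colnames(genotypes) <- variants$variant_id
  structure(list(genotypes = genotypes,
                 variants = as.data.frame(variants),
                 n_samples = nrow(genotypes)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d samples x %d variants on %d chromosome(s)\n",
              x$n_samples, nrow(x$variants), length(unique(x$variants$chr))))
  invisible(x)
}

#' LD correlation matrix for a set of panel variants
#'
#' @param panel a [reference_panel()].
#' @param ids variant identifiers; default all panel variants.
#' @return Correlation matrix with unit diagonal, dimnames = ids.
#' @export
panel_ld <- function(panel, ids = NULL) {
  ids <- ids %||% panel$variants$variant_id
  miss <- setdiff(ids, panel$variants$variant_id)
  if (length(miss)) stopf("variant(s) not in panel: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  r <- stats::cor(panel$genotypes[, ids, drop = FALSE])
  diag(r) <- 1
  r
}

#' Panel effect-allele frequencies
#' @inheritParams panel_ld
#' @export
panel_freq <- function(panel, ids = NULL) {
  ids <- ids %||% panel$variants$variant_id
  f <- panel$variants$freq[match(ids, panel$variants$variant_id)]
  names(f) <- ids
  f
}

#' Panel minor allele counts
#'
#' MAC is derived from the panel frequency and sample count as
#' `round(2 * N * min(f, 1 - f))`, matching the MAF-MAC correspondence used
#' by the low-count QC filter.
#' @inheritParams panel_ld
#' @export
panel_mac <- function(panel, ids = NULL) {
  f <- panel_freq(panel, ids)
  round(2 * panel$n_samples * pmin(f, 1 - f))
}

# matrix key chr:pos:sorted-allele-pair used for sumstats <-> panel matching
variant_key <- function(chr, pos, a1, a2) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  paste(chr, pos, lo, hi, sep = ":")
}
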