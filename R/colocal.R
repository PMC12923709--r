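#' Physically overlapping loci between two analyses
#'
#' Intersects same-chromosome locus intervals from two trait analyses. For
#' each overlapping pair the intersection and the union span are reported,
#' together with the variants present in both summary-statistics tables
#' within the union span (the shared locus uses all variants available to
#' both traits).
#'
#' @param loci_a,loci_b lists of `locus` objects (or data.frames with
#'   `chr`, `start`, `end`).
#' @param stats_a,stats_b optional [sumstats()] tables used to enumerate
#'   shared variants.
#' @return data.frame `chr`, `start`, `end` (intersection),
#'   `span_start`, `span_end` (union), `n_shared_variants`, plus a list
#'   column `variant_ids`; zero rows when nothing overlaps.
#' @export
overlap_loci <- function(loci_a, loci_b, stats_a = NULL, stats_b = NULL) {
  as_df <- function(loci) {
    if (is.data.frame(loci)) return(loci)
    do.call(rbind, lapply(loci, function(l)
      data.frame(chr = l$chr, start = l$start, end = l$end,
                 stringsAsFactors = FALSE)))
  }
  a <- as_df(loci_a); b <- as_df(loci_b)
  out <- list()
  if (!is.null(a) && !is.null(b)) for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      if (a$chr[i] != b$chr[j]) next
      lo <- max(a$start[i], b$start[j]); hi <- min(a$end[i], b$end[j])
      if (lo > hi) next
      sp_lo <- min(a$start[i], b$start[j]); sp_hi <- max(a$end[i], b$end[j])
      ids <- character()
      if (!is.null(stats_a) && !is.null(stats_b)) {
        in_a <- stats_a$variant_id[stats_a$chr == a$chr[i] &
                                     stats_a$pos >= sp_lo &
                                     stats_a$pos <= sp_hi]
        in_b <- stats_b$variant_id[stats_b$chr == a$chr[i] &
                                     stats_b$pos >= sp_lo &
                                     stats_b$pos <= sp_hi]
        ids <- intersect(in_a, in_b)
      }
      row <- data.frame(chr = a$chr[i], start = lo, end = hi,
                        span_start = sp_lo, span_end = sp_hi,
                        n_shared_variants = length(ids),
                        stringsAsFactors = FALSE)
      row$variant_ids <- I(list(ids))
      out[[length(out) + 1L]] <- row
    }
  if (!length(out))
    return(data.frame(chr = character(), start = integer(), end = integer(),
                      span_start = integer(), span_end = integer(),
                      n_shared_variants = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# per-variant log ABF (single-causal Wakefield form)
log_abf <- function(beta, se, w) {
  v <- se^2
  z <- beta / se
  0.5 * log(v / (v + w)) + w * z^2 / (2 * (v + w))
}

#' Colocalization posteriors for two traits over a shared locus
#'
#' Enumeration-based posterior probabilities of the five sharing
#' hypotheses, from per-variant approximate Bayes factors under a
#' single-causal-variant model per trait: H0 no association, H1/H2
#' association in one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant. Per-hypothesis weights are
#' `S0 = 1`, `S1 = p1 * sum_j A_j`, `S2 = p2 * sum_j B_j`,
#' `S3 = p1 p2 (sum_j A_j sum_k B_k - sum_j A_j B_j)`,
#' `S4 = p12 * sum_j A_j B_j`, all accumulated in log space, normalized to
#' posterior probabilities.
#'
#' @param stats_a,stats_b [sumstats()] tables restricted to the shared
#'   locus; variants are intersected by id and must agree on alleles.
#' @param w_a,w_b prior effect variances per trait (default 0.04).
#' @param p1,p2,p12 prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @return An object of class `coloc_result`: list with `pp` (named PP0..
#'   PP4 summing to 1), `n_variants`, and the per-variant log ABFs.
#' @export
coloc_abf <- function(stats_a, stats_b, w_a = 0.04, w_b = 0.04,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  ids <- intersect(stats_a$variant_id, stats_b$variant_id)
  if (length(ids) < 2)
    stopf("colocalization needs >= 2 shared variants (got %d)", length(ids))
  ia <- match(ids, stats_a$variant_id); ib <- match(ids, stats_b$variant_id)
  mismatch <- stats_a$a1[ia] != stats_b$a1[ib] |
    stats_a$a2[ia] != stats_b$a2[ib]
  if (any(mismatch))
    stopf("allele mismatch between traits at variant %s",
          ids[which(mismatch)[1]])
  la <- log_abf(stats_a$beta[ia], stats_a$se[ia], w_a)
  lb <- log_abf(stats_b$beta[ib], stats_b$se[ib], w_b)
  lsa <- logsumexp(la); lsb <- logsumexp(lb); lsab <- logsumexp(la + lb)
  ls0 <- 0
  ls1 <- log(p1) + lsa
  ls2 <- log(p2) + lsb
  # sum_{j != k} A_j B_k = (sum A)(sum B) - sum A B, in log space
  d <- lsab - (lsa + lsb)
  ls3 <- log(p1) + log(p2) + lsa + lsb +
    if (d < 0) log1p(-exp(d)) else -Inf
  ls4 <- log(p12) + lsab
  ls <- c(PP0 = ls0, PP1 = ls1, PP2 = ls2, PP3 = ls3, PP4 = ls4)
  pp <- exp(ls - logsumexp(ls))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_variants = length(ids),
                 log_abf_a = stats::setNames(la, ids),
                 log_abf_b = stats::setNames(lb, ids)),
            class = "coloc_result")
}

# O(m^2)-style reference computation of the same posteriors, used as an
# internal cross-check of the product-minus-diagonal identity
coloc_abf_enum <- function(stats_a, stats_b, w_a = 0.04, w_b = 0.04,
                           p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  ids <- intersect(stats_a$variant_id, stats_b$variant_id)
  ia <- match(ids, stats_a$variant_id); ib <- match(ids, stats_b$variant_id)
  A <- exp(log_abf(stats_a$beta[ia], stats_a$se[ia], w_a))
  B <- exp(log_abf(stats_b$beta[ib], stats_b$se[ib], w_b))
  s3 <- 0
  for (j in seq_along(A)) for (k in seq_along(B))
    if (j != k) s3 <- s3 + A[j] * B[k]
  s <- c(PP0 = 1, PP1 = p1 * sum(A), PP2 = p2 * sum(B),
         PP3 = p1 * p2 * s3, PP4 = p12 * sum(A * B))
  s / sum(s)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants\n", x$n_variants))
  print(round(x$pp, 4))
  invisible(x)
}
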