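#' Greedy LD clumping of genome-wide-significant variants
#'
#' Repeatedly takes the unassigned variant with the smallest p-value below
#' `p_threshold` as an index variant (ties broken by smaller genomic
#' position) and assigns to it every unassigned variant on the same
#' chromosome within `window_bp` whose squared LD correlation with the index
#' is at least `r2_threshold`. Each clump is reported as the span of its
#' assigned variants.
#'
#' @param table a [sumstats()] table harmonized to `panel`.
#' @param panel a [reference_panel()].
#' @param p_threshold significance threshold (default 5e-8).
#' @param r2_threshold LD assignment threshold (default 0.1).
#' @param window_bp assignment window around the index (default 3 Mb).
#' @return data.frame of clumps: `chr`, `start`, `end`, `index_id`,
#'   `index_p`, `n_variants`, and a list column `members`.
#' @export
clump <- function(table, panel, p_threshold = 5e-8, r2_threshold = 0.1,
                  window_bp = 3e6) {
  sig <- which(table$p < p_threshold)
  out <- list()
  assigned <- rep(FALSE, nrow(table))
  while (length(sig <- sig[!assigned[sig]])) {
    ord <- sig[order(table$p[sig], table$pos[sig])]
    idx <- ord[1]
    near <- which(!assigned & table$chr == table$chr[idx] &
                    abs(table$pos - table$pos[idx]) <= window_bp)
    r <- panel_ld(panel, c(table$variant_id[idx],
                           table$variant_id[near]))[1, -1, drop = TRUE]
    members <- near[r^2 >= r2_threshold | near == idx]
    members <- union(idx, members)
    assigned[members] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      chr = table$chr[idx],
      start = min(table$pos[members]),
      end = max(table$pos[members]),
      index_id = table$variant_id[idx],
      index_p = table$p[idx],
      n_variants = length(members),
      stringsAsFactors = FALSE)
    out[[length(out)]]$members <- I(list(table$variant_id[members]))
  }
  if (!length(out))
    return(data.frame(chr = character(), start = integer(), end = integer(),
                      index_id = character(), index_p = numeric(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chr, res$start), , drop = FALSE]
}

#' Expand clumps and merge overlapping boundaries into regions
#'
#' Each clump is expanded by `pad_bp` on both sides (floored at position 1);
#' expanded intervals on the same chromosome that overlap or abut are merged
#' into a single region.
#'
#' @param clumps output of [clump()].
#' @param pad_bp expansion on each side (default 500 kb).
#' @return data.frame of disjoint regions: `region_id`, `chr`, `start`,
#'   `end`, and a list column `index_ids` of the merged clump indices.
#' @export
build_regions <- function(clumps, pad_bp = 5e5) {
  if (!nrow(clumps))
    return(data.frame(region_id = character(), chr = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  cl <- clumps[order(clumps$chr, clumps$start), , drop = FALSE]
  cl$start <- pmax(1, cl$start - pad_bp)
  cl$end <- cl$end + pad_bp
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(cl))) {
    row <- cl[i, ]
    if (!is.null(cur) && row$chr == cur$chr && row$start <= cur$end + 1) {
      cur$end <- max(cur$end, row$end)
      cur$index_ids <- c(cur$index_ids, row$index_id)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(chr = row$chr, start = row$start, end = row$end,
                  index_ids = row$index_id)
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- data.frame(
    region_id = sprintf("region%03d", seq_along(out)),
    chr = vapply(out, `[[`, "", "chr"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    stringsAsFactors = FALSE)
  res$index_ids <- I(lapply(out, function(x) unique(x$index_ids)))
  res
}

#' Subset a summary-statistics table to one region
#'
#' @param table a [sumstats()] table.
#' @param region one row of [build_regions()] output (or any list with
#'   `chr`, `start`, `end`).
#' @return A [sumstats()] table restricted to the region.
#' @export
region_stats <- function(table, region) {
  keep <- table$chr == region$chr & table$pos >= region$start &
    table$pos <= region$end
  subset_sumstats(table, keep)
}

# conditional z-scores of targets given a selected set, on the standardized
# scale: z_{t|S} = (z_t - r_tS R_SS^{-1} z_S) / sqrt(1 - r_tS R_SS^{-1} r_St)
conditional_z <- function(z, R, targets, sel) {
  Rss <- R[sel, sel, drop = FALSE]
  Rinv <- tryCatch(solve(Rss), error = function(e)
    stopf("singular LD among conditioning variants"))
  rts <- R[targets, sel, drop = FALSE]
  adj <- as.vector(rts %*% (Rinv %*% z[sel]))
  r2 <- rowSums((rts %*% Rinv) * rts)
  list(z = (z[targets] - adj) / sqrt(pmax(1 - r2, 0)), r2 = r2)
}

#' Forward stepwise joint selection of independent hits in a region
#'
#' Starts from the top marginal hit with p below `p_threshold`; at each step
#' adds the variant with the smallest conditional p-value given the selected
#' set, skipping candidates whose squared LD with any selected variant
#' exceeds `collinearity_r2`; stops when no candidate reaches the threshold.
#' Joint effects for the selected set are then
#' \eqn{b_J = B^{-1} z / \sqrt{n}} with `B` the selected-set LD matrix and
#' joint standard errors \eqn{\sqrt{\mathrm{diag}(B^{-1})/n}}; selected hits
#' with joint p above the threshold are dropped.
#'
#' @param stats a region-restricted [sumstats()] table.
#' @param panel a [reference_panel()].
#' @param p_threshold selection and retention threshold (default 5e-8).
#' @param collinearity_r2 maximum squared LD between selected hits
#'   (default 0.9).
#' @return data.frame of selected hits with marginal and joint statistics
#'   (`beta_joint`, `se_joint`, `z_joint`, `p_joint`); zero rows when no
#'   variant is significant.
#' @export
stepwise_joint <- function(stats, panel, p_threshold = 5e-8,
                           collinearity_r2 = 0.9) {
  empty <- data.frame(variant_id = character(), chr = character(),
                      pos = integer(), beta = numeric(), se = numeric(),
                      p = numeric(), beta_joint = numeric(),
                      se_joint = numeric(), z_joint = numeric(),
                      p_joint = numeric(), stringsAsFactors = FALSE)
  if (!nrow(stats) || min(stats$p) >= p_threshold) return(empty)
  z <- sumstats_z(stats)
  n <- stats::median(stats$n_eff)
  R <- panel_ld(panel, stats$variant_id)
  m <- nrow(stats)
  sel <- integer()
  repeat {
    cand <- setdiff(seq_len(m), sel)
    if (length(sel)) {
      maxr2 <- apply(R[cand, sel, drop = FALSE]^2, 1, max)
      cand <- cand[maxr2 <= collinearity_r2]
    }
    if (!length(cand)) break
    if (!length(sel)) {
      pc <- stats$p[cand]
    } else {
      zc <- conditional_z(z, R, cand, sel)$z
      pc <- z_to_p(zc)
    }
    best <- which.min(pc)
    if (pc[best] >= p_threshold) break
    sel <- c(sel, cand[best])
  }
  if (!length(sel)) return(empty)
  B <- R[sel, sel, drop = FALSE]
  Binv <- tryCatch(solve(B), error = function(e) {
    worst <- which(abs(B - diag(nrow(B))) == max(abs(B - diag(nrow(B)))),
                   arr.ind = TRUE)[1, ]
    stopf("singular joint LD matrix; offending pair %s, %s",
          stats$variant_id[sel[worst[1]]], stats$variant_id[sel[worst[2]]])
  })
  b_j <- as.vector(Binv %*% z[sel]) / sqrt(n)
  se_j <- sqrt(pmax(diag(Binv), 0) / n)
  z_j <- b_j / se_j
  p_j <- z_to_p(z_j)
  keep <- p_j <= p_threshold
  sel <- sel[keep]
  if (!length(sel)) return(empty)
  data.frame(variant_id = stats$variant_id[sel], chr = stats$chr[sel],
             pos = stats$pos[sel], beta = stats$beta[sel],
             se = stats$se[sel], p = stats$p[sel],
             beta_joint = b_j[keep], se_joint = se_j[keep],
             z_joint = z_j[keep], p_joint = p_j[keep],
             stringsAsFactors = FALSE)
}

#' Leave-one-hit-out conditional summary statistics
#'
#' Conditions every variant in a region on a set of selected hits,
#' returning conditional effect estimates on the standardized scale. A
#' target in tight LD with the conditioning set (multiple correlation
#' squared above 0.9) is masked: its statistics are reported as missing.
#' An empty conditioning set returns the input unchanged.
#'
#' @param stats a region-restricted [sumstats()] table.
#' @param panel a [reference_panel()].
#' @param conditioning_ids variant ids to condition on (must be in panel).
#' @return A [sumstats()]-shaped data.frame with conditional `beta`, `se`,
#'   `p` (rows for conditioning variants and masked targets carry `NA`).
#' @export
conditional_sumstats <- function(stats, panel, conditioning_ids) {
  if (!length(conditioning_ids)) return(stats)
  miss <- setdiff(conditioning_ids, panel$variants$variant_id)
  if (length(miss)) stopf("conditioning variant(s) not in panel: %s",
                          paste(miss, collapse = ", "))
  miss <- setdiff(conditioning_ids, stats$variant_id)
  if (length(miss)) stopf("conditioning variant(s) not in region stats: %s",
                          paste(miss, collapse = ", "))
  out <- as.data.frame(stats)
  z <- sumstats_z(stats)
  n <- stats$n_eff
  ids <- stats$variant_id
  R <- panel_ld(panel, ids)
  sel <- match(conditioning_ids, ids)
  cz <- conditional_z(z, R, seq_along(ids), sel)
  # conditional scale: residual genotype variance 1 - R^2
  r2 <- pmin(cz$r2, 1)
  mask <- r2 > 0.9 | ids %in% conditioning_ids
  se_c <- 1 / sqrt(n * pmax(1 - r2, 1e-12))
  beta_c <- cz$z * se_c
  out$beta <- ifelse(mask, NA_real_, beta_c)
  out$se <- ifelse(mask, NA_real_, se_c)
  out$p <- ifelse(mask, NA_real_, z_to_p(cz$z))
  structure(out, class = c("sumstats", "data.frame"),
            ancestry = attr(stats, "ancestry"), trait = attr(stats, "trait"),
            masked = ids[mask])
}

#' Approximate-Bayes-factor fine-mapping and credible set
#'
#' Under a single-causal-variant assumption, each variant's log approximate
#' Bayes factor is
#' \eqn{\tfrac12 \log\{V/(V+W)\} + W z^2 / \{2 (V+W)\}} with `V = se^2`,
#' `z = beta/se`, and prior effect variance `W`. Posterior inclusion
#' probabilities normalize the ABFs over the signal's variants
#' (log-sum-exp); the credible set is the minimal PIP-descending prefix
#' whose cumulative PIP reaches `coverage`, and the centroid is the
#' PIP-weighted mean position over set members (renormalized within the
#' set).
#'
#' @param stats a [sumstats()] table for one isolated signal (conditional
#'   statistics when the region holds several hits); rows with missing
#'   `beta`/`se` are ignored.
#' @param prior_variance_w prior variance of the standardized effect
#'   (default 0.04, prior sd 0.2).
#' @param coverage credible-set coverage target (default 0.95).
#' @return An object of class `credible_set`: a data.frame (`variant_id`,
#'   `chr`, `pos`, `log_abf`, `pip`, `cum_pip`, `in_cs`) with attributes
#'   `centroid`, `chr`, `coverage`, `coverage_achieved`.
#' @export
abf_credible_set <- function(stats, prior_variance_w = 0.04,
                             coverage = 0.95) {
  ok <- is.finite(stats$beta) & is.finite(stats$se)
  stats <- subset_sumstats(stats, ok)
  if (!nrow(stats)) stopf("credible set needs at least one variant")
  V <- stats$se^2
  W <- prior_variance_w
  z <- stats$beta / stats$se
  labf <- 0.5 * log(V / (V + W)) + W * z^2 / (2 * (V + W))
  pip <- exp(labf - logsumexp(labf))
  ord <- order(-pip, stats$pos)
  df <- data.frame(variant_id = stats$variant_id[ord], chr = stats$chr[ord],
                   pos = stats$pos[ord], log_abf = labf[ord],
                   pip = pip[ord], stringsAsFactors = FALSE)
  df$cum_pip <- cumsum(df$pip)
  n_in <- which(df$cum_pip >= coverage)[1]
  if (is.na(n_in)) n_in <- nrow(df)
  df$in_cs <- seq_len(nrow(df)) <= n_in
  mem <- df[df$in_cs, ]
  centroid <- sum(mem$pip * mem$pos) / sum(mem$pip)
  structure(df, class = c("credible_set", "data.frame"),
            centroid = centroid, chr = mem$chr[1],
            coverage = coverage, coverage_achieved = df$cum_pip[n_in])
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("Credible set: %d/%d variants, coverage %.3f, centroid %.0f\n",
              sum(x$in_cs), nrow(x), attr(x, "coverage_achieved"),
              attr(x, "centroid")))
  invisible(x)
}

#' Define a locus around a credible set
#'
#' The locus interval spans the credible-set members padded by `pad_bp` on
#' each side (floored at position 1); locus genes are all gene models with
#' any base overlap with the interval.
#'
#' @param cs a `credible_set` from [abf_credible_set()].
#' @param genes gene-model table (`gene_id`, `chr`, `start`, `end`).
#' @param pad_bp padding (default 300 kb).
#' @return An object of class `locus`: list with `chr`, `start`, `end`,
#'   `centroid`, `gene_ids`, `n_genes`, `cs`.
#' @export
define_locus <- function(cs, genes, pad_bp = 3e5) {
  mem <- cs[cs$in_cs, ]
  chr <- attr(cs, "chr")
  start <- max(1, min(mem$pos) - pad_bp)
  end <- max(mem$pos) + pad_bp
  hit <- genes$chr == chr & genes$start <= end & genes$end >= start
  structure(list(chr = chr, start = start, end = end,
                 centroid = attr(cs, "centroid"),
                 gene_ids = genes$gene_id[hit], n_genes = sum(hit),
                 cs = cs),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("Locus %s:%d-%d | %d gene(s) | centroid %.0f\n",
              x$chr, x$start, x$end, x$n_genes, x$centroid))
  invisible(x)
}
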