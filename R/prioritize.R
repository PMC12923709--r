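#' Nearest gene to a fine-mapped signal
#'
#' Distance from the credible set's PIP-weighted centroid to a gene is zero
#' when the centroid falls inside the gene body and otherwise the distance
#' to the nearer gene end. The gene minimizing this distance is returned;
#' exact ties break to the lexicographically smaller gene id.
#'
#' @param cs a `credible_set` (or any list with attributes/fields `chr` and
#'   `centroid`).
#' @param genes gene-model table.
#' @return list with `gene_id` (`NA` when the chromosome has no genes) and
#'   `distance_kb`.
#' @export
nearest_gene <- function(cs, genes) {
  chr <- attr(cs, "chr") %||% cs$chr
  centroid <- attr(cs, "centroid") %||% cs$centroid
  g <- genes[genes$chr == chr, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance_kb = NA_real_))
  inside <- centroid >= g$start & centroid <= g$end
  d <- ifelse(inside, 0, pmin(abs(centroid - g$start), abs(centroid - g$end)))
  best <- which(d == min(d))
  best <- best[order(g$gene_id[best])][1]
  list(gene_id = g$gene_id[best], distance_kb = d[best] / 1000)
}

#' Summed PIP of non-synonymous credible-set variants per gene
#'
#' For each gene, sums the posterior inclusion probabilities of the
#' credible-set member variants annotated as non-synonymous for that gene,
#' restricted to variants passing the per-variant heritability eligibility
#' flag supplied with the annotation.
#'
#' @param cs a `credible_set`.
#' @param nonsyn data.frame `variant_id`, `gene_id`, `h2_ok`.
#' @return data.frame `gene_id`, `pip_sum` (genes with no qualifying
#'   variants are absent).
#' @export
nonsyn_evidence <- function(cs, nonsyn) {
  mem <- cs[cs$in_cs, , drop = FALSE]
  ns <- nonsyn[nonsyn$h2_ok %in% TRUE &
                 nonsyn$variant_id %in% mem$variant_id, , drop = FALSE]
  if (!nrow(ns))
    return(data.frame(gene_id = character(), pip_sum = numeric(),
                      stringsAsFactors = FALSE))
  ns$pip <- mem$pip[match(ns$variant_id, mem$variant_id)]
  agg <- stats::aggregate(pip ~ gene_id, data = ns, FUN = sum)
  data.frame(gene_id = agg$gene_id, pip_sum = agg$pip,
             stringsAsFactors = FALSE)
}

#' Apply the gene prioritization criteria to one locus
#'
#' Three evidence routes can prioritize a gene in a locus:
#' \describe{
#'   \item{pops_nearest}{the gene has the strictly largest raw priority
#'     score among locus genes, is the nearest gene to the credible-set
#'     centroid, and its genome-wide priority-score percentile is at least
#'     `top_decile`; blocked entirely when the locus holds more than
#'     `max_genes` genes (large loci are harder to resolve) or when the
#'     local top score is tied.}
#'   \item{nonsynonymous}{the summed PIP of the gene's non-synonymous
#'     credible-set variants exceeds `pip_sum_threshold` (the summed-PIP
#'     rule; see `nonsyn_mode`).}
#'   \item{burden}{the gene is significant (FDR < 5\%) in the supplied
#'     rare-variant burden annotation; unknown never counts as true.}
#' }
#'
#' @param locus a `locus` from [define_locus()].
#' @param scores priority-score data.frame (`gene_id`, `raw`,
#'   `percentile`).
#' @param nonsyn data.frame `variant_id`, `gene_id`, `h2_ok` of
#'   non-synonymous variant flags.
#' @param annotations gene annotation data.frame with `gene_id` and
#'   `burden_fdr_significant`.
#' @param genes gene-model table (for nearest-gene distances).
#' @param top_decile genome-wide percentile floor (default 0.9).
#' @param pip_sum_threshold non-synonymous summed-PIP threshold
#'   (default 0.5).
#' @param max_genes large-locus exclusion threshold (default 20).
#' @param nonsyn_mode `"summed"` (default) sums PIP per gene;
#'   `"per_variant"` requires a single non-synonymous variant with PIP
#'   above the threshold.
#' @return An object of class `priority_call`: list with
#'   `prioritized_genes`, `routes` (named list per prioritized gene),
#'   `excluded_large_locus`, `nearest`, and an `evidence` data.frame with
#'   one row per locus gene.
#' @export
apply_criteria <- function(locus, scores, nonsyn, annotations, genes,
                           top_decile = 0.9, pip_sum_threshold = 0.5,
                           max_genes = 20L,
                           nonsyn_mode = c("summed", "per_variant")) {
  nonsyn_mode <- match.arg(nonsyn_mode)
  gid <- locus$gene_ids
  large <- locus$n_genes > max_genes
  near <- nearest_gene(locus$cs, genes)
  ev <- data.frame(gene_id = gid, stringsAsFactors = FALSE)
  g <- genes[match(gid, genes$gene_id), , drop = FALSE]
  inside <- locus$centroid >= g$start & locus$centroid <= g$end
  ev$distance_kb <- ifelse(inside, 0,
                           pmin(abs(locus$centroid - g$start),
                                abs(locus$centroid - g$end))) / 1000
  ev$is_nearest <- gid == near$gene_id & !is.na(near$gene_id)
  si <- match(gid, scores$gene_id)
  ev$raw <- scores$raw[si]
  ev$percentile <- scores$percentile[si]
  ev$n_genes <- locus$n_genes

  if (nonsyn_mode == "summed") {
    nse <- nonsyn_evidence(locus$cs, nonsyn)
    ev$pip_sum <- nse$pip_sum[match(gid, nse$gene_id)]
  } else {
    mem <- locus$cs[locus$cs$in_cs, , drop = FALSE]
    ns <- nonsyn[nonsyn$h2_ok %in% TRUE &
                   nonsyn$variant_id %in% mem$variant_id, , drop = FALSE]
    ns$pip <- mem$pip[match(ns$variant_id, mem$variant_id)]
    ev$pip_sum <- vapply(gid, function(gg) {
      pp <- ns$pip[ns$gene_id == gg]
      if (length(pp)) max(pp) else NA_real_
    }, 0)
  }
  ev$pip_sum[is.na(ev$pip_sum)] <- 0
  ev$burden <- annotations$burden_fdr_significant[
    match(gid, annotations$gene_id)] %in% TRUE

  # pops_nearest: local strict top + nearest + genome-wide top decile
  route_pops <- rep(FALSE, length(gid))
  if (!large && length(gid)) {
    if (all(is.na(ev$raw))) {
      warnf("no priority scores for any gene in locus; pops_nearest skipped")
    } else {
      top_raw <- max(ev$raw, na.rm = TRUE)
      top_set <- which(!is.na(ev$raw) & ev$raw == top_raw)
      if (length(top_set) == 1) {
        k <- top_set
        route_pops[k] <- ev$is_nearest[k] &&
          !is.na(ev$percentile[k]) && ev$percentile[k] >= top_decile
      }
    }
  }
  route_ns <- ev$pip_sum > pip_sum_threshold
  route_burden <- ev$burden
  ev$route_pops_nearest <- route_pops
  ev$route_nonsynonymous <- route_ns
  ev$route_burden <- route_burden
  hit <- route_pops | route_ns | route_burden
  routes <- lapply(which(hit), function(i)
    c("pops_nearest", "nonsynonymous", "burden")[
      c(route_pops[i], route_ns[i], route_burden[i])])
  names(routes) <- gid[hit]
  structure(list(prioritized_genes = gid[hit], routes = routes,
                 excluded_large_locus = large, nearest = near,
                 evidence = ev),
            class = "priority_call")
}

#' @export
print.priority_call <- function(x, ...) {
  cat(sprintf("Priority call: %d gene(s) prioritized%s\n",
              length(x$prioritized_genes),
              if (x$excluded_large_locus) " (large locus: distance route off)"
              else ""))
  for (g in x$prioritized_genes)
    cat(sprintf("  %s via %s\n", g, paste(x$routes[[g]], collapse = ", ")))
  invisible(x)
}

# logistic fit with coefficients capped at |cap| on separation
capped_logistic <- function(X, y, cap = 8) {
  df <- as.data.frame(X)
  df$.y <- y
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  if (any(abs(b) > cap)) {
    warned <- TRUE
    b <- pmin(pmax(b, -cap), cap)
  }
  if (warned)
    warnf("separation in logistic fold; coefficients capped at |%g|", cap)
  b
}

#' Leave-one-chromosome-out logistic classifier of locus genes
#'
#' A three-predictor logistic regression (loss-of-function intolerance,
#' brain-specific expression, known neurodevelopmental gene) that treats
#' each locus's nearest gene as a positive and the other locus genes as
#' negatives. For each chromosome, the model is trained on the genes of all
#' other chromosomes and predicts held-out probabilities; a gene is flagged
#' when its predicted causal probability exceeds `prob_threshold`.
#' Separated folds have their coefficients capped at |8| with a warning.
#'
#' @param locus_genes data.frame `gene_id`, `chr`, `is_positive` (nearest
#'   gene per locus = `TRUE`).
#' @param annotations gene annotation data.frame with `gene_id`,
#'   `pli_flag`, `brain_flag`, `neurodev_flag`.
#' @param prob_threshold flagging threshold (default 0.5).
#' @return An object of class `psyops`: data.frame `gene_id`, `chr`,
#'   `prob`, `flag`, with the per-fold coefficient matrix as attribute
#'   `coefficients`.
#' @export
psyops_classify <- function(locus_genes, annotations, prob_threshold = 0.5) {
  chrs <- unique(locus_genes$chr)
  if (length(chrs) < 2) stopf("leave-one-chromosome-out needs >= 2 chromosomes")
  ai <- match(locus_genes$gene_id, annotations$gene_id)
  X <- cbind(pli = as.numeric(annotations$pli_flag[ai] %in% TRUE),
             brain = as.numeric(annotations$brain_flag[ai] %in% TRUE),
             neurodev = as.numeric(annotations$neurodev_flag[ai] %in% TRUE))
  y <- as.numeric(locus_genes$is_positive)
  prob <- numeric(nrow(locus_genes))
  coefs <- matrix(NA_real_, 4, length(chrs),
                  dimnames = list(c("(Intercept)", colnames(X)), chrs))
  for (ch in chrs) {
    tr <- locus_genes$chr != ch
    if (length(unique(y[tr])) < 2)
      stopf("training fold for chromosome %s lacks both classes", ch)
    b <- capped_logistic(X[tr, , drop = FALSE], y[tr])
    coefs[names(b), ch] <- b
    eta <- b[1] + X[!tr, , drop = FALSE] %*% b[-1]
    prob[!tr] <- stats::plogis(as.vector(eta))
  }
  out <- data.frame(gene_id = locus_genes$gene_id, chr = locus_genes$chr,
                    prob = prob, flag = prob > prob_threshold,
                    stringsAsFactors = FALSE)
  structure(out, class = c("psyops", "data.frame"), coefficients = coefs)
}

#' @export
print.psyops <- function(x, ...) {
  cat(sprintf("Locus-gene classifier: %d genes, %d flagged (prob > 0.5)\n",
              nrow(x), sum(x$flag)))
  invisible(x)
}

#' Fisher enrichment of prioritized genes in a labeled gene set
#'
#' Builds the 2x2 table of prioritized-by-labeled membership over the gene
#' universe. The odds ratio is the sample cross-product `(a*d)/(b*c)`; when
#' a cell is zero it is reported with the Haldane 0.5 correction and
#' flagged. The p-value is the two-sided Fisher exact test (sum of
#' hypergeometric probabilities no larger than the observed table's), which
#' the correction does not affect. Degenerate margins (labeled set empty or
#' equal to the universe) report p = 1 and are flagged.
#'
#' @param prioritized,labeled,universe character vectors of gene ids, with
#'   `prioritized` and `labeled` subsets of `universe`.
#' @return list `or`, `p`, `table` (2x2 counts), `haldane`, `degenerate`.
#' @export
enrichment <- function(prioritized, labeled, universe) {
  if (length(setdiff(prioritized, universe)) ||
      length(setdiff(labeled, universe)))
    stopf("prioritized and labeled gene sets must be subsets of the universe")
  u <- unique(universe)
  p_in <- u %in% prioritized
  l_in <- u %in% labeled
  a <- sum(p_in & l_in); b <- sum(p_in & !l_in)
  cc <- sum(!p_in & l_in); d <- sum(!p_in & !l_in)
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(prioritized = c("yes", "no"),
                                labeled = c("yes", "no")))
  degenerate <- (a + cc) == 0 || (b + d) == 0 || (a + b) == 0 || (cc + d) == 0
  haldane <- any(tab == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  list(or = or, p = p, table = tab, haldane = haldane,
       degenerate = degenerate)
}

.drug_phases <- c("approved", "investigational", "tractable", "none")
.indication_classes <- c("schizophrenia", "other_psychiatric",
                         "non_psychiatric")

#' Annotate prioritized genes with drug-target tiers
#'
#' Deterministic join of prioritized genes against a user-supplied
#' gene-to-drug table. Each gene receives its best phase
#' (`approved > investigational > tractable > none`); genes whose best
#' phase is a clinical phase are grouped by their best indication class
#' (`schizophrenia > other_psychiatric > non_psychiatric`), genes that are
#' only tractable form their own group.
#'
#' @param prioritized character vector of gene ids.
#' @param drug_table data.frame `gene_id`, `phase` (one of `approved`,
#'   `investigational`, `tractable`), optional `indication_class` (one of
#'   `schizophrenia`, `other_psychiatric`, `non_psychiatric`, or `NA`).
#' @return data.frame `gene_id`, `tier`, `group`, with a named
#'   `group_counts` attribute.
#' @export
annotate_drugs <- function(prioritized, drug_table) {
  if (nrow(drug_table)) {
    bad <- which(!drug_table$phase %in% setdiff(.drug_phases, "none"))
    if (length(bad))
      stopf("unknown drug phase '%s' at drug table row %d",
            drug_table$phase[bad[1]], bad[1])
  }
  if (is.null(drug_table$indication_class))
    drug_table$indication_class <- rep(NA_character_, nrow(drug_table))
  tier_of <- function(g) {
    rows <- drug_table[drug_table$gene_id == g, , drop = FALSE]
    if (!nrow(rows)) return(c("none", "none"))
    ph <- .drug_phases[min(match(rows$phase, .drug_phases))]
    if (ph == "tractable") return(c(ph, "tractable"))
    trial <- rows[rows$phase %in% c("approved", "investigational"), ]
    ic <- trial$indication_class
    ic <- ic[!is.na(ic)]
    grp <- if (length(ic))
      paste0("clinical_trial_",
             .indication_classes[min(match(ic, .indication_classes))])
    else "clinical_trial_unspecified"
    c(ph, grp)
  }
  tg <- vapply(prioritized, tier_of, character(2))
  out <- data.frame(gene_id = prioritized, tier = tg[1, ], group = tg[2, ],
                    stringsAsFactors = FALSE)
  counts <- table(out$group)
  attr(out, "group_counts") <- counts
  out
}
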