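# Shared in-code fixtures and independent oracles.

# a panel whose sample LD is exactly R: genotype rows are scaled columns of
# chol(R) replicated, so cor() recovers R up to numerical noise. For exact
# control we instead generate many Gaussian samples and rely on tests using
# tolerances; for exact R (e.g. identity, r = 1) craft columns directly.
make_panel <- function(R, n = 2000, chr = "1", pos = NULL, seed = 42,
                       freq = NULL) {
  m <- nrow(R)
  set.seed(seed)
  L <- priogwas:::chol_psd(R)
  X <- matrix(rnorm(n * m), n, m) %*% L
  # force the empirical correlation to equal R exactly: whiten, then color
  S <- cov(X)
  X <- scale(X, center = TRUE, scale = FALSE) %*% solve(chol(S)) %*% L
  pos <- pos %||% seq(10000, by = 10000, length.out = m)
  freq <- freq %||% rep(0.3, m)
  reference_panel(X, data.frame(
    variant_id = sprintf("v%05d", seq_len(m)), chr = chr, pos = pos,
    a1 = "A", a2 = "G", freq = freq, block = 1L,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a sumstats table directly from z-scores
make_sumstats <- function(z, n_eff = 10000, chr = "1", pos = NULL,
                          ids = NULL, freq = 0.3, ancestry = "EUR") {
  m <- length(z)
  pos <- pos %||% seq(10000, by = 10000, length.out = m)
  ids <- ids %||% sprintf("v%05d", seq_len(m))
  sumstats(data.frame(
    variant_id = ids, chr = rep_len(chr, m), pos = pos,
    a1 = rep_len("A", m), a2 = rep_len("G", m),
    freq = rep_len(freq, m), beta = z / sqrt(n_eff),
    se = rep_len(1 / sqrt(n_eff), m), p = 2 * pnorm(-abs(z)),
    n_eff = rep_len(n_eff, m),
    stringsAsFactors = FALSE), ancestry = ancestry)
}

# independent greedy-clumping oracle that re-sorts unassigned significant
# variants after every assignment
clump_oracle <- function(table, panel, p_threshold = 5e-8,
                         r2_threshold = 0.1, window_bp = 3e6) {
  R2 <- panel_ld(panel, table$variant_id)^2
  unassigned <- rep(TRUE, nrow(table))
  out <- list()
  repeat {
    sig <- which(unassigned & table$p < p_threshold)
    if (!length(sig)) break
    sig <- sig[order(table$p[sig], table$pos[sig])]
    idx <- sig[1]
    members <- which(unassigned & table$chr == table$chr[idx] &
                       abs(table$pos - table$pos[idx]) <= window_bp &
                       R2[idx, ] >= r2_threshold)
    members <- union(idx, members)
    unassigned[members] <- FALSE
    out[[length(out) + 1L]] <- list(index = table$variant_id[idx],
                                    members = sort(table$variant_id[members]))
  }
  out
}

# exhaustive nearest-gene scan
nearest_oracle <- function(chr, centroid, genes) {
  g <- genes[genes$chr == chr, ]
  d <- sapply(seq_len(nrow(g)), function(i) {
    if (centroid >= g$start[i] && centroid <= g$end[i]) 0
    else min(abs(centroid - g$start[i]), abs(centroid - g$end[i]))
  })
  best <- which(d == min(d))
  best <- best[order(g$gene_id[best])][1]
  list(gene_id = g$gene_id[best], distance_kb = d[best] / 1000)
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_oracle <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# order-insensitive comparison of clump output against the oracle
same_clumping <- function(mine, oracle) {
  if (nrow(mine) != length(oracle)) return(FALSE)
  for (cl in oracle) {
    k <- match(cl$index, mine$index_id)
    if (is.na(k)) return(FALSE)
    if (!identical(sort(mine$members[[k]]), cl$members)) return(FALSE)
  }
  TRUE
}

# plain iteratively-reweighted least-squares logistic fit
irls_logistic <- function(X, y, iter = 50) {
  X1 <- cbind(1, X)
  b <- rep(0, ncol(X1))
  for (i in seq_len(iter)) {
    eta <- as.vector(X1 %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    b <- solve(crossprod(X1, w * X1), crossprod(X1, w * z))
  }
  as.vector(b)
}

# small locus scaffolding used across the rule-engine tests
toy_locus <- function(n_genes = 8, centroid = 500000, pip = NULL,
                      cs_pos = centroid, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%02d", seq_len(n_genes))
  genes <- data.frame(
    gene_id = gene_ids, symbol = toupper(gene_ids), chr = "1",
    start = centroid - 5000 + seq_len(n_genes) * 10000 - 10000,
    end = centroid - 5000 + seq_len(n_genes) * 10000 - 10000 + 8000,
    coding = TRUE, stringsAsFactors = FALSE)
  pip <- pip %||% 1
  cs <- structure(data.frame(
    variant_id = sprintf("cv%02d", seq_along(pip)), chr = "1",
    pos = rep_len(cs_pos, length(pip)), log_abf = 0, pip = pip,
    cum_pip = cumsum(pip), in_cs = TRUE, stringsAsFactors = FALSE),
    class = c("credible_set", "data.frame"),
    centroid = centroid, chr = "1", coverage = 0.95,
    coverage_achieved = sum(pip))
  locus <- structure(list(chr = "1", start = centroid - 300000,
                          end = centroid + 300000, centroid = centroid,
                          gene_ids = gene_ids, n_genes = n_genes, cs = cs),
                     class = "locus")
  list(locus = locus, genes = genes, cs = cs)
}

no_ann <- function(gene_ids)
  data.frame(gene_id = gene_ids, burden_fdr_significant = FALSE,
             dd_asd_label = FALSE, pli_flag = FALSE, brain_flag = FALSE,
             neurodev_flag = FALSE, stringsAsFactors = FALSE)

no_nonsyn <- data.frame(variant_id = character(), gene_id = character(),
                        h2_ok = logical(), stringsAsFactors = FALSE)

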