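test_that("nearest gene uses body distance with deterministic ties", {
  genes <- data.frame(
    gene_id = c("gB", "gA", "gC"), symbol = c("B", "A", "C"), chr = "1",
    start = c(1000, 6000, 20000), end = c(2000, 7000, 21000), coding = TRUE)
  # centroid inside a gene body: distance zero
  res <- nearest_gene(list(chr = "1", centroid = 6500), genes)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$distance_kb, 0)
  # equidistant between gB (end 2000) and gA (start 6000): centroid 4000
  res2 <- nearest_gene(list(chr = "1", centroid = 4000), genes)
  expect_equal(res2$gene_id, "gA")  # lexicographically smaller id
  # no genes on the chromosome
  res3 <- nearest_gene(list(chr = "2", centroid = 100), genes)
  expect_true(is.na(res3$gene_id))
  # random instances match the exhaustive scan
  set.seed(80)
  for (i in 1:25) {
    g <- data.frame(gene_id = sprintf("g%02d", sample(99, 5)),
                    symbol = "s", chr = "1",
                    start = sort(sample(1e6, 5)) , coding = TRUE)
    g$end <- g$start + sample(1e4, 5)
    cent <- runif(1, 1, 1.1e6)
    mine <- nearest_gene(list(chr = "1", centroid = cent), g)
    ora <- nearest_oracle("1", cent, g)
    expect_equal(mine$gene_id, ora$gene_id)
    expect_equal(mine$distance_kb, ora$distance_kb)
  }
})

test_that("the distance route fires only under all of its conditions", {
  tl <- toy_locus(8)
  near <- nearest_gene(tl$cs, tl$genes)$gene_id
  scores <- data.frame(gene_id = tl$genes$gene_id,
                       raw = seq(0.1, 0.8, length.out = 8),
                       percentile = seq(0.2, 0.95, length.out = 8))
  # make the nearest gene the strict local top with percentile 0.95
  scores$raw[scores$gene_id == near] <- 1
  scores$percentile[scores$gene_id == near] <- 0.95
  call <- apply_criteria(tl$locus, scores, no_nonsyn,
                         no_ann(tl$genes$gene_id), tl$genes)
  expect_equal(call$prioritized_genes, near)
  expect_equal(call$routes[[near]], "pops_nearest")

  # percentile below the top decile blocks the route
  scores2 <- scores
  scores2$percentile[scores2$gene_id == near] <- 0.85
  call2 <- apply_criteria(tl$locus, scores2, no_nonsyn,
                          no_ann(tl$genes$gene_id), tl$genes)
  expect_equal(length(call2$prioritized_genes), 0L)

  # a tied local top blocks the route
  scores3 <- scores
  other <- setdiff(tl$genes$gene_id, near)[1]
  scores3$raw[scores3$gene_id == other] <- 1
  call3 <- apply_criteria(tl$locus, scores3, no_nonsyn,
                          no_ann(tl$genes$gene_id), tl$genes)
  expect_equal(length(call3$prioritized_genes), 0L)
})

test_that("large loci block the distance route but not the other routes", {
  tl <- toy_locus(21)
  near <- nearest_gene(tl$cs, tl$genes)$gene_id
  scores <- data.frame(gene_id = tl$genes$gene_id, raw = 0.1,
                       percentile = 0.5)
  scores$raw[scores$gene_id == near] <- 2
  scores$percentile[scores$gene_id == near] <- 0.99
  ns <- data.frame(variant_id = "cv01", gene_id = "g03", h2_ok = TRUE)
  call <- apply_criteria(tl$locus, scores, ns, no_ann(tl$genes$gene_id),
                         tl$genes)
  expect_true(call$excluded_large_locus)
  # distance route suppressed for the otherwise-qualifying nearest gene
  expect_false(near %in% names(call$routes)[
    vapply(call$routes, function(r) "pops_nearest" %in% r, TRUE)])
  # summed non-synonymous PIP 1 > 0.5 still prioritizes g03
  expect_true("g03" %in% call$prioritized_genes)
  expect_equal(call$routes[["g03"]], "nonsynonymous")
})

test_that("non-synonymous evidence sums member PIPs under the h2 flag", {
  tl <- toy_locus(4, pip = c(0.4, 0.3, 0.3))
  ns <- data.frame(variant_id = c("cv01", "cv02", "cv03"),
                   gene_id = c("g01", "g01", "g02"),
                   h2_ok = c(TRUE, TRUE, FALSE))
  ev <- nonsyn_evidence(tl$cs, ns)
  expect_equal(ev$pip_sum[ev$gene_id == "g01"], 0.7)
  expect_false("g02" %in% ev$gene_id)  # heritability-ineligible excluded
  # summed rule fires at > 0.5; per-variant mode needs a single PIP > 0.5
  scores <- data.frame(gene_id = tl$genes$gene_id, raw = 0, percentile = 0)
  call_sum <- apply_criteria(tl$locus, scores, ns, no_ann(tl$genes$gene_id),
                             tl$genes)
  expect_true("g01" %in% call_sum$prioritized_genes)
  call_pv <- apply_criteria(tl$locus, scores, ns, no_ann(tl$genes$gene_id),
                            tl$genes, nonsyn_mode = "per_variant")
  expect_false("g01" %in% call_pv$prioritized_genes)
})

test_that("the burden route fires on the FDR flag and unknown is never true", {
  tl <- toy_locus(5)
  scores <- data.frame(gene_id = tl$genes$gene_id, raw = 0, percentile = 0)
  ann <- no_ann(tl$genes$gene_id)
  ann$burden_fdr_significant[2] <- TRUE
  ann$burden_fdr_significant[3] <- NA
  call <- apply_criteria(tl$locus, scores, no_nonsyn, ann, tl$genes)
  expect_equal(call$prioritized_genes, tl$genes$gene_id[2])
  expect_equal(call$routes[[1]], "burden")
})

test_that("criteria are monotone in percentile and in locus size", {
  tl <- toy_locus(8)
  near <- nearest_gene(tl$cs, tl$genes)$gene_id
  base <- data.frame(gene_id = tl$genes$gene_id, raw = 0.1,
                     percentile = 0.1)
  base$raw[base$gene_id == near] <- 1
  base$percentile[base$gene_id == near] <- 0.9
  call <- apply_criteria(tl$locus, base, no_nonsyn,
                         no_ann(tl$genes$gene_id), tl$genes)
  expect_true(near %in% call$prioritized_genes)
  # raising the percentile never removes the call
  up <- base; up$percentile[up$gene_id == near] <- 0.99
  expect_true(near %in% apply_criteria(tl$locus, up, no_nonsyn,
                                       no_ann(tl$genes$gene_id),
                                       tl$genes)$prioritized_genes)
  # adding genes to the locus never adds a distance-route call
  tl2 <- toy_locus(22)
  near2 <- nearest_gene(tl2$cs, tl2$genes)$gene_id
  sc2 <- data.frame(gene_id = tl2$genes$gene_id, raw = 0.1, percentile = 0.1)
  sc2$raw[sc2$gene_id == near2] <- 1
  sc2$percentile[sc2$gene_id == near2] <- 0.99
  call2 <- apply_criteria(tl2$locus, sc2, no_nonsyn,
                          no_ann(tl2$genes$gene_id), tl2$genes)
  expect_equal(length(call2$prioritized_genes), 0L)
})

test_that("locus-gene classifier matches an IRLS fit and handles edge cases", {
  set.seed(81)
  n <- 240
  lg <- data.frame(gene_id = sprintf("g%03d", 1:n),
                   chr = rep(c("1", "2"), each = n / 2),
                   is_positive = rep(c(TRUE, FALSE, FALSE, FALSE), n / 4))
  ann <- no_ann(lg$gene_id)
  ann$pli_flag <- runif(n) < ifelse(lg$is_positive, 0.7, 0.2)
  ann$brain_flag <- runif(n) < 0.3
  ann$neurodev_flag <- runif(n) < ifelse(lg$is_positive, 0.5, 0.1)
  res <- psyops_classify(lg, ann)
  # held-out fold for chromosome 2 trains on chromosome 1: reproduce by IRLS
  tr <- lg$chr == "1"
  X <- cbind(as.numeric(ann$pli_flag), as.numeric(ann$brain_flag),
             as.numeric(ann$neurodev_flag))
  b <- irls_logistic(X[tr, ], as.numeric(lg$is_positive)[tr])
  eta <- b[1] + X[!tr, ] %*% b[-1]
  expect_equal(res$prob[!tr], as.vector(plogis(eta)), tolerance = 1e-6)
  expect_equal(res$flag, res$prob > 0.5)

  # all-identical predictors: probability = training base rate everywhere
  ann0 <- no_ann(lg$gene_id)
  res0 <- psyops_classify(lg, ann0)
  for (ch in c("1", "2"))
    expect_equal(res0$prob[lg$chr == ch],
                 rep(mean(lg$is_positive[lg$chr != ch]),
                     sum(lg$chr == ch)), tolerance = 1e-6)

  # perfectly separating predictor: capped with warning, ordering preserved
  ann1 <- no_ann(lg$gene_id)
  ann1$pli_flag <- lg$is_positive
  w <- capture_warnings(res1 <- psyops_classify(lg, ann1))
  expect_match(w, "capped", all = TRUE)
  expect_gte(length(w), 1L)
  expect_gt(min(res1$prob[lg$is_positive]), max(res1$prob[!lg$is_positive]))

  expect_error(psyops_classify(lg[lg$chr == "1", ], ann), "chromosomes")
})

test_that("enrichment reproduces the cross-product OR and exact p", {
  u <- sprintf("g%03d", 1:1000)
  prior <- u[1:100]           # a = 10, b = 90
  lab <- c(u[1:10], u[101:105])  # c = 5, d = 895
  res <- enrichment(prior, lab, u)
  expect_equal(res$or, (10 * 895) / (90 * 5), tolerance = 1e-12)
  expect_equal(res$p, fisher_oracle(10, 90, 5, 895), tolerance = 1e-9)
  # labeled = universe: degenerate margin
  res2 <- enrichment(prior, u, u)
  expect_true(res2$degenerate)
  expect_equal(res2$p, 1)
  # disjoint with strong deficit: OR < 1 (Haldane-corrected, flagged)
  res3 <- enrichment(u[1:200], u[201:900], u)
  expect_lt(res3$or, 1)
  expect_true(res3$haldane)
  expect_error(enrichment(c(u[1], "zz"), lab, u), "subset")
})

test_that("enrichment matches hypergeometric enumeration on small universes", {
  set.seed(82)
  for (i in 1:40) {
    nu <- sample(10:60, 1)
    u <- sprintf("u%02d", seq_len(nu))
    prior <- sample(u, sample(0:nu, 1))
    lab <- sample(u, sample(0:nu, 1))
    res <- enrichment(prior, lab, u)
    a <- length(intersect(prior, lab)); b <- length(setdiff(prior, lab))
    cc <- length(setdiff(lab, prior)); d <- nu - a - b - cc
    if (!res$degenerate)
      expect_equal(res$p, fisher_oracle(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("drug annotation assigns best tiers and groups like the published table", {
  expect_equal(annotate_drugs("g1", data.frame(gene_id = character(),
                                               phase = character()))$tier,
               "none")
  dt <- data.frame(gene_id = c("g1", "g1"),
                   phase = c("tractable", "approved"),
                   indication_class = c(NA, "schizophrenia"))
  expect_equal(annotate_drugs("g1", dt)$tier, "approved")
  expect_error(annotate_drugs("g1", data.frame(gene_id = "g1",
                                               phase = "phase9")),
               "row 1")

  # the 6 / 4 / 6 / 7 grouping of the published drug-target table
  tab1 <- data.frame(
    gene_id = c("DRD2", "GRIN2A", "CACNA1C", "GRM3", "CACNA1I", "PDE4B",
                "GABBR2", "CHRNA3", "CACNB2", "ACE",
                "CD47", "ATP2A2", "KCNJ3", "AKT3", "DPYD", "SNCA",
                "HCN1", "VRK2", "TRPC4", "EP300", "GRM1", "PTPRF", "MMP16"),
    phase = c(rep("approved", 3), "investigational", "approved", "approved",
              rep("approved", 4),
              "investigational", "investigational", "approved", "approved",
              "investigational", "investigational",
              rep("tractable", 7)),
    indication_class = c(rep("schizophrenia", 6),
                         rep("other_psychiatric", 4),
                         rep("non_psychiatric", 6), rep(NA, 7)),
    stringsAsFactors = FALSE)
  res <- annotate_drugs(tab1$gene_id, tab1)
  counts <- attr(res, "group_counts")
  expect_equal(unname(counts["clinical_trial_schizophrenia"]), 6L)
  expect_equal(unname(counts["clinical_trial_other_psychiatric"]), 4L)
  expect_equal(unname(counts["clinical_trial_non_psychiatric"]), 6L)
  expect_equal(unname(counts["tractable"]), 7L)
})
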