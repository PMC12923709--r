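test_that("sumstats read/write round-trips at full precision", {
  dir <- withr::local_tempdir()
  ss <- make_sumstats(c(1.234567891234, -0.5, 3.00000001), n_eff = 12345.5)
  path <- file.path(dir, "ss.tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(as.data.frame(back), as.data.frame(ss), tolerance = 1e-14)

  # zero data rows still parse into an empty table
  empty <- make_sumstats(numeric())
  write_sumstats(empty, path)
  expect_equal(nrow(read_sumstats(path)), 0L)

  # a missing required column is named in the error
  writeLines("CHR\tPOS\tA1\tA2\tFRQ\tBETA\tP\tNEFF", path)
  expect_error(read_sumstats(path), "SE")

  # unparsable rows are reported with a line number
  writeLines(c("SNP\tCHR\tPOS\tA1\tA2\tFRQ\tBETA\tSE\tP\tNEFF",
               "v1\t1\t100\tA\tG\t0.3\t0.1\t0.01\t0.5\t1000",
               "v2\t1\t200\tA\tG\t0.3\tnot_a_number\t0.01\t0.5\t1000"), path)
  expect_error(read_sumstats(path), "line 2")
})

test_that("sumstats validation enforces invariants", {
  df <- as.data.frame(make_sumstats(c(1, 2)))
  df$variant_id <- c("x", "x")
  expect_error(sumstats(df), "duplicate")
  df2 <- as.data.frame(make_sumstats(c(1, 2)))
  df2$p[1] <- 0.9  # wildly inconsistent with |beta/se|
  expect_warning(sumstats(df2), "inconsistent")
  # rows come back sorted by chromosome and position
  df3 <- as.data.frame(make_sumstats(c(1, 2, 3)))[c(3, 1, 2), ]
  expect_equal(sumstats(df3)$pos, sort(df3$pos))
})

test_that("harmonize flips swapped alleles and drops unmatched", {
  panel <- make_panel(diag(2), n = 100, pos = c(100, 200))
  df <- data.frame(
    variant_id = c("r1", "r2", "r3"),
    chr = "1", pos = c(100, 200, 300),
    a1 = c("G", "A", "A"), a2 = c("A", "G", "T"),
    freq = c(0.3, 0.4, 0.2), beta = c(0.1, 0.2, 0.3),
    se = 0.05, p = 2 * pnorm(-abs(c(0.1, 0.2, 0.3) / 0.05)), n_eff = 1000)
  h <- harmonize(sumstats(df), panel)
  info <- attr(h, "harmonization")
  # swapped record: beta sign flipped, frequency reflected
  r1 <- h[h$pos == 100, ]
  expect_equal(r1$beta, -0.1)
  expect_equal(r1$freq, 0.7)
  expect_equal(r1$a1, "A")
  # matching record unchanged
  expect_equal(h[h$pos == 200, ]$beta, 0.2)
  # unmatched allele pair dropped and counted
  expect_false(300 %in% h$pos)
  expect_equal(info$n_dropped_unmatched, 1L)
  expect_equal(info$n_flipped, 1L)
  # ids rewritten to panel ids
  expect_setequal(h$variant_id, c("v00001", "v00002"))
})

test_that("harmonize keeps the larger n_eff among duplicate keys", {
  panel <- make_panel(diag(1), n = 100, pos = 100)
  df <- data.frame(variant_id = c("d1", "d2"), chr = "1", pos = 100,
                   a1 = "A", a2 = "G", freq = 0.3, beta = c(0.1, 0.9),
                   se = 1, p = c(0.9, 0.4), n_eff = c(5000, 1000))
  h <- suppressWarnings(harmonize(sumstats(df), panel))
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_eff, 5000)
  expect_equal(attr(h, "harmonization")$n_dropped_duplicate, 1L)
})

test_that("strand-ambiguous variants are flagged and optionally dropped", {
  g <- matrix(rnorm(200), 100, 2)
  panel <- reference_panel(g, data.frame(
    variant_id = c("p1", "p2"), chr = "1", pos = c(100, 200),
    a1 = c("A", "A"), a2 = c("T", "G"), freq = 0.3))
  df <- data.frame(variant_id = c("r1", "r2"), chr = "1", pos = c(100, 200),
                   a1 = c("A", "A"), a2 = c("T", "G"), freq = 0.3,
                   beta = 0, se = 1, p = 1, n_eff = 100)
  h <- harmonize(sumstats(df), panel)
  expect_equal(h$ambiguous, c(TRUE, FALSE))
  h2 <- harmonize(sumstats(df), panel, drop_ambiguous = TRUE)
  expect_equal(nrow(h2), 1L)
})

test_that("qc_filter applies the three filters in order", {
  # panel frequencies: v1 rare (low MAC), v2/v3/v4 common enough
  g <- matrix(rnorm(4e4), 10000, 4)
  panel <- reference_panel(g, data.frame(
    variant_id = paste0("v", 1:4), chr = "1", pos = 1:4 * 100,
    a1 = "A", a2 = "G", freq = c(0.0002, 0.5, 0.5, 0.012)))
  mk <- function(freqs) sumstats(data.frame(
    variant_id = paste0("v", 1:4), chr = "1", pos = 1:4 * 100,
    a1 = "A", a2 = "G", freq = freqs, beta = 0, se = 1, p = 1,
    n_eff = 1000))
  # v1 fails MAC (round(2*10000*0.0002) = 4 < 10); v2 fails
  # |0.65 - 0.50| > 0.1; v3 and v4 pass everything.
  out <- qc_filter(mk(c(0.0009, 0.65, 0.5, 0.012)), panel)
  expect_equal(out$report$n_removed_mac, 1L)
  expect_equal(out$report$n_removed_abs_freq, 1L)
  expect_equal(out$report$n_removed_fold_freq, 0L)
  expect_setequal(out$table$variant_id, c("v3", "v4"))
  expect_equal(out$report$n_retained + out$report$n_removed_mac +
                 out$report$n_removed_abs_freq +
                 out$report$n_removed_fold_freq +
                 out$report$n_unmatched, out$report$n_input)
})

test_that("fold-change filter catches 13.3-fold differences", {
  g <- matrix(rnorm(200), 100, 2)
  panel <- reference_panel(g, data.frame(
    variant_id = c("v1", "v2"), chr = "1", pos = c(100, 200),
    a1 = "A", a2 = "G", freq = c(0.09, 0.5)))
  ss <- sumstats(data.frame(
    variant_id = c("v1", "v2"), chr = "1", pos = c(100, 200),
    a1 = "A", a2 = "G", freq = c(0.012, 0.5), beta = 0, se = 1, p = 1,
    n_eff = 100))
  # |0.012 - 0.09| = 0.078 passes the absolute filter, but the fold change
  # 0.09/0.012 = 7.5 passes 12; tighten to a 13.3-fold case:
  ss2 <- ss; ss2$freq[1] <- 0.09 / 13.3
  out <- qc_filter(ss2, panel, max_abs_freq_diff = 0.1)
  expect_equal(out$report$n_removed_fold_freq, 1L)
  expect_equal(out$table$variant_id, "v2")
})

test_that("qc_filter is idempotent and the identity on matched tables", {
  panel <- make_panel(diag(3), n = 200)
  ss <- make_sumstats(c(0, 1, 2), freq = panel_freq(panel))
  out1 <- qc_filter(ss, panel)
  expect_equal(out1$report$n_retained, 3L)
  expect_equal(out1$report$n_removed_mac + out1$report$n_removed_abs_freq +
                 out1$report$n_removed_fold_freq, 0L)
  out2 <- qc_filter(out1$table, panel)
  expect_equal(nrow(out2$table), nrow(out1$table))
  expect_equal(out2$report$n_removed_mac + out2$report$n_removed_abs_freq +
                 out2$report$n_removed_fold_freq, 0L)
})

test_that("qc report writes a JSON sidecar", {
  dir <- withr::local_tempdir()
  panel <- make_panel(diag(2), n = 100)
  out <- qc_filter(make_sumstats(c(0, 1), freq = panel_freq(panel)), panel)
  path <- write_qc_report(out$report, file.path(dir, "qc.json"))
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_retained, 2L)
})

test_that("meta_z matches the sqrt-n weighted formula and its invariants", {
  expect_equal(meta_z(3, 100, 1, 100), (3 + 1) / sqrt(2))
  # one-sided missing input returns the other unchanged
  expect_equal(meta_z(2.5, 1000, NA, 500), 2.5)
  expect_equal(meta_z(NA, 1000, -1.5, 500), -1.5)
  expect_error(meta_z(NA, 1, NA, 1), "missing")
  # sample sizes as used for the two-ancestry meta-analysis
  expect_equal(meta_z(2, 126282, 2, 30515),
               2 * (sqrt(126282) + sqrt(30515)) / sqrt(126282 + 30515))
  # scale invariance in (n_a, n_b)
  expect_equal(meta_z(1.7, 200, -0.3, 800), meta_z(1.7, 2, -0.3, 8))
  # two concordant studies reinforce by the sqrt-n weight identity
  for (nn in list(c(10, 1), c(5, 5), c(1, 1000)))
    expect_equal(meta_z(1.23, nn[1], 1.23, nn[2]),
                 1.23 * (sqrt(nn[1]) + sqrt(nn[2])) / sqrt(sum(nn)))
})

test_that("meta_sumstats combines tables on the standardized scale", {
  a <- make_sumstats(c(2, 2), n_eff = 126282)
  b <- make_sumstats(c(2, 2), n_eff = 30515, ancestry = "EAS")
  m <- meta_sumstats(a, b)
  zm <- m$beta / m$se
  expect_equal(zm, rep(2 * (sqrt(126282) + sqrt(30515)) /
                         sqrt(126282 + 30515), 2))
  expect_equal(m$n_eff, rep(126282 + 30515, 2))
})
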