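#' GWAS summary-statistics table
#'
#' Construct and validate a summary-statistics table for one trait and
#' ancestry: one row per variant with effect/other allele, effect-allele
#' frequency, effect size on the standardized-genotype scale, its standard
#' error, two-sided p-value, and effective sample size. Rows are sorted by
#' (chromosome, position) and variant ids must be unique. Where both are
#' present, `p` is checked against `2*pnorm(-|beta/se|)` to 10% relative
#' tolerance (a warning, since externally supplied tables may round).
#'
#' @param df data.frame with columns `variant_id`, `chr`, `pos`, `a1`, `a2`,
#'   `freq`, `beta`, `se`, `p`, `n_eff`.
#' @param ancestry,trait labels stored as attributes.
#' @return The validated data.frame with class `sumstats`.
#' @export
sumstats <- function(df, ancestry = "EUR", trait = "trait1") {
  req <- c("variant_id", "chr", "pos", "a1", "a2", "freq", "beta", "se",
           "p", "n_eff")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("sumstats missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$variant_id)) stopf("duplicate variant ids in sumstats")
  if (any(df$se <= 0, na.rm = TRUE)) stopf("standard errors must be positive")
  if (any(df$p <= 0 | df$p > 1, na.rm = TRUE))
    stopf("p-values must lie in (0, 1]")
  ok <- is.finite(df$beta) & is.finite(df$se) & is.finite(df$p) & df$p > 1e-300
  if (any(ok)) {
    pref <- z_to_p(df$beta[ok] / df$se[ok])
    bad <- abs(pref - df$p[ok]) > 0.1 * pmax(pref, df$p[ok])
    if (any(bad))
      warnf("%d variant(s) have p inconsistent with |beta/se| beyond 10%%",
            sum(bad))
  }
  df <- df[order(df$chr, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            ancestry = ancestry, trait = trait)
}

sumstats_z <- function(table) table$beta / table$se

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("Summary statistics: %d variants | trait %s | ancestry %s\n",
              nrow(x), attr(x, "trait") %||% "?",
              attr(x, "ancestry") %||% "?"))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# keep sumstats class + labels through row subsetting
subset_sumstats <- function(table, i) {
  out <- as.data.frame(table)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            ancestry = attr(table, "ancestry"), trait = attr(table, "trait"))
}

# column names of the on-disk TSV dialect
.ss_cols <- c(SNP = "variant_id", CHR = "chr", POS = "pos", A1 = "a1",
              A2 = "a2", FRQ = "freq", BETA = "beta", SE = "se", P = "p",
              NEFF = "n_eff")

#' Read / write summary statistics as tab-delimited text
#'
#' The dialect has a header row with columns `CHR POS A1 A2 FRQ BETA SE P
#' NEFF` and an optional leading `SNP` id column (ids default to
#' `chr:pos` when absent). `write_sumstats` writes all columns at full
#' precision so that a read/write round trip is the identity.
#'
#' @param path file path.
#' @param ancestry,trait labels for the resulting table.
#' @return `read_sumstats` returns a [sumstats()] table.
#' @export
read_sumstats <- function(path, ancestry = "EUR", trait = "trait1") {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  need <- setdiff(names(.ss_cols), "SNP")
  miss <- setdiff(need, hdr)
  if (length(miss)) stopf("sumstats file missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  out <- data.frame(
    variant_id = if ("SNP" %in% hdr) df$SNP else paste(df$CHR, df$POS, sep = ":"),
    chr = df$CHR, a1 = df$A1, a2 = df$A2, stringsAsFactors = FALSE)
  for (col in c("POS", "FRQ", "BETA", "SE", "P", "NEFF")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad))
      stopf("unparsable %s value at data line %d of %s", col, bad[1], path)
    out[[.ss_cols[[col]]]] <- val
  }
  sumstats(out[, .ss_cols], ancestry = ancestry, trait = trait)
}

#' @rdname read_sumstats
#' @param table a [sumstats()] table.
#' @export
write_sumstats <- function(table, path) {
  df <- as.data.frame(table)[, .ss_cols]
  names(df) <- names(.ss_cols)
  for (col in c("FRQ", "BETA", "SE", "P"))
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE,
                        scientific = NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize a summary-statistics table against a reference panel
#'
#' Variants are matched to the panel by chromosome, position, and unordered
#' allele pair. Records whose effect/other alleles are swapped relative to
#' the panel get their effect sign flipped and frequency reflected
#' (`eaf -> 1 - eaf`); records that cannot be matched even after a swap are
#' dropped and counted. Duplicate match keys keep the record with the larger
#' effective sample size. Strand-ambiguous (A/T, C/G) variants are retained
#' and flagged unless `drop_ambiguous`.
#'
#' @param table a [sumstats()] table.
#' @param panel a [reference_panel()].
#' @param drop_ambiguous drop strand-ambiguous variants (default `FALSE`).
#' @return A harmonized [sumstats()] table on panel variant ids, carrying a
#'   `harmonization` attribute with counts
#'   (`n_flipped`, `n_dropped_unmatched`, `n_dropped_duplicate`,
#'   `n_ambiguous`).
#' @export
harmonize <- function(table, panel, drop_ambiguous = FALSE) {
  v <- panel$variants
  pk <- variant_key(v$chr, v$pos, v$a1, v$a2)
  tk <- variant_key(table$chr, table$pos, table$a1, table$a2)
  keep <- tk %in% pk
  n_unmatched <- sum(!keep)
  tab <- as.data.frame(table)[keep, , drop = FALSE]
  tk <- tk[keep]
  # duplicates on the match key: keep the larger n_eff
  n_dup <- 0L
  if (anyDuplicated(tk)) {
    ord <- order(tk, -tab$n_eff)
    tab <- tab[ord, ]; tk <- tk[ord]
    dup <- duplicated(tk)
    n_dup <- sum(dup)
    tab <- tab[!dup, ]; tk <- tk[!dup]
  }
  pi <- match(tk, pk)
  swapped <- tab$a1 == v$a2[pi] & tab$a2 == v$a1[pi]
  tab$beta[swapped] <- -tab$beta[swapped]
  tab$freq[swapped] <- 1 - tab$freq[swapped]
  tab$a1 <- v$a1[pi]; tab$a2 <- v$a2[pi]
  tab$variant_id <- v$variant_id[pi]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- !is.na(comp[tab$a1]) & comp[tab$a1] == tab$a2
  tab$ambiguous <- ambiguous
  n_amb <- sum(ambiguous)
  if (drop_ambiguous) tab <- tab[!ambiguous, , drop = FALSE]
  out <- sumstats(tab, ancestry = attr(table, "ancestry"),
                  trait = attr(table, "trait"))
  attr(out, "harmonization") <- list(
    n_flipped = sum(swapped), n_dropped_unmatched = n_unmatched,
    n_dropped_duplicate = n_dup, n_ambiguous = n_amb)
  out
}

#' Variant quality control against a reference panel
#'
#' Applies, in a fixed order, the three panel-based filters: (1) panel minor
#' allele count below `min_mac` (panel frequencies of exactly 0 or 1 fall
#' here by convention); (2) absolute difference between the reported and
#' panel effect-allele frequency above `max_abs_freq_diff`; (3) fold
#' difference between the two frequencies above `max_fold_freq_diff`. Each
#' variant is counted once, at the first filter it fails. Variants not
#' matched to the panel are removed beforehand and counted separately. The
#' table is harmonized to the panel first so frequencies are compared on the
#' same effect allele.
#'
#' @param table a [sumstats()] table.
#' @param panel a [reference_panel()].
#' @param min_mac minimum panel minor allele count (default 10).
#' @param max_abs_freq_diff maximum |reported - panel| frequency difference
#'   (default 0.1).
#' @param max_fold_freq_diff maximum frequency fold change (default 12).
#' @return list with elements `table` (filtered [sumstats()]) and `report`
#'   (a `qc_report`).
#' @export
qc_filter <- function(table, panel, min_mac = 10, max_abs_freq_diff = 0.1,
                      max_fold_freq_diff = 12) {
  n_input <- nrow(table)
  h <- if (is.null(attr(table, "harmonization")))
    harmonize(table, panel) else table
  n_unmatched <- (attr(h, "harmonization")$n_dropped_unmatched %||% 0) +
    (attr(h, "harmonization")$n_dropped_duplicate %||% 0)
  f_panel <- panel_freq(panel, h$variant_id)
  mac <- panel_mac(panel, h$variant_id)
  fail1 <- mac < min_mac
  fail2 <- !fail1 & abs(h$freq - f_panel) > max_abs_freq_diff
  ratio <- pmax(h$freq / f_panel, f_panel / h$freq)
  fail3 <- !fail1 & !fail2 & ratio > max_fold_freq_diff
  keep <- !(fail1 | fail2 | fail3)
  report <- structure(list(
    n_input = n_input,
    n_unmatched = n_unmatched,
    n_removed_mac = sum(fail1),
    n_removed_abs_freq = sum(fail2),
    n_removed_fold_freq = sum(fail3),
    n_retained = sum(keep)), class = "qc_report")
  list(table = subset_sumstats(h, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant QC report\n")
  cat(sprintf("  input variants:        %d\n", x$n_input))
  cat(sprintf("  unmatched/duplicate:   %d\n", x$n_unmatched))
  cat(sprintf("  removed, MAC:          %d\n", x$n_removed_mac))
  cat(sprintf("  removed, |freq diff|:  %d\n", x$n_removed_abs_freq))
  cat(sprintf("  removed, fold change:  %d\n", x$n_removed_fold_freq))
  cat(sprintf("  retained:              %d\n", x$n_retained))
  invisible(x)
}

#' Write a QC report as a JSON sidecar
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Combines two z-scores weighted by the square root of their effective
#' sample sizes: `(sqrt(n_a) z_a + sqrt(n_b) z_b) / sqrt(n_a + n_b)`. A
#' missing input (`NA`) contributes zero weight, so a value present in only
#' one study is returned unchanged. Vectorized; both inputs missing at a
#' position is an error.
#'
#' @param z_a,z_b z-scores (may contain `NA`).
#' @param n_a,n_b effective sample sizes (> 0).
#' @return Meta-analyzed z-score(s).
#' @export
meta_z <- function(z_a, n_a, z_b, n_b) {
  n <- max(length(z_a), length(z_b))
  z_a <- rep_len(as.numeric(z_a %||% NA_real_), n)
  z_b <- rep_len(as.numeric(z_b %||% NA_real_), n)
  n_a <- rep_len(as.numeric(n_a %||% NA_real_), n)
  n_b <- rep_len(as.numeric(n_b %||% NA_real_), n)
  miss_a <- is.na(z_a); miss_b <- is.na(z_b)
  if (any(miss_a & miss_b)) stopf("both inputs missing")
  wa <- ifelse(miss_a, 0, sqrt(n_a))
  wb <- ifelse(miss_b, 0, sqrt(n_b))
  za <- ifelse(miss_a, 0, z_a)
  zb <- ifelse(miss_b, 0, z_b)
  (wa * za + wb * zb) / sqrt(wa^2 + wb^2)
}

#' Meta-analyze two summary-statistics tables
#'
#' Per-variant [meta_z()] on the union of variants; the combined table has
#' `n_eff = n_a + n_b` where both are present, and recomputed `beta`, `se`,
#' `p` on the standardized scale. Frequencies are the sample-size-weighted
#' average.
#'
#' @param a,b [sumstats()] tables harmonized to the same panel.
#' @param trait,ancestry labels for the output (default `"meta"` ancestry).
#' @return A [sumstats()] table.
#' @export
meta_sumstats <- function(a, b, trait = attr(a, "trait"),
                          ancestry = "meta") {
  ids <- union(a$variant_id, b$variant_id)
  ia <- match(ids, a$variant_id); ib <- match(ids, b$variant_id)
  za <- sumstats_z(a)[ia]; zb <- sumstats_z(b)[ib]
  na <- a$n_eff[ia]; nb <- b$n_eff[ib]
  z <- meta_z(za, na, zb, nb)
  n <- ifelse(is.na(na), 0, na) + ifelse(is.na(nb), 0, nb)
  wa <- ifelse(is.na(na), 0, na); wb <- ifelse(is.na(nb), 0, nb)
  fa <- ifelse(is.na(ia), 0, a$freq[ia]); fb <- ifelse(is.na(ib), 0, b$freq[ib])
  meta <- data.frame(
    variant_id = ids,
    chr = ifelse(is.na(ia), b$chr[ib], a$chr[ia]),
    pos = ifelse(is.na(ia), b$pos[ib], a$pos[ia]),
    a1 = ifelse(is.na(ia), b$a1[ib], a$a1[ia]),
    a2 = ifelse(is.na(ia), b$a2[ib], a$a2[ia]),
    freq = (wa * fa + wb * fb) / (wa + wb),
    beta = z / sqrt(n), se = 1 / sqrt(n), p = z_to_p(z), n_eff = n,
    stringsAsFactors = FALSE)
  sumstats(meta, ancestry = ancestry, trait = trait)
}
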