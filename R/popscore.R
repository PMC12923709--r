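#' Optional univariate feature screening before the ridge fit
#'
#' When enabled, keeps the features whose univariate regression on the gene
#' z-scores is significant at `alpha`; off (the default) it is the
#' identity.
#'
#' @param features gene-by-feature matrix (rownames = gene ids).
#' @param gene_z named numeric vector of gene z-scores aligned to the
#'   feature rows.
#' @param alpha univariate significance threshold (default 0.05).
#' @param screen logical; `FALSE` (default) returns the input unchanged.
#' @return The (possibly column-subset) feature matrix.
#' @export
select_features <- function(features, gene_z, alpha = 0.05, screen = FALSE) {
  if (!screen) return(features)
  y <- gene_z[rownames(features)]
  n <- sum(is.finite(y))
  keep <- apply(features, 2, function(x) {
    r <- suppressWarnings(stats::cor(x, y, use = "complete.obs"))
    if (!is.finite(r) || abs(r) >= 1) return(is.finite(r))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2) < alpha
  })
  features[, keep, drop = FALSE]
}

# closed-form ridge with unpenalized intercept: center y and standardize X
# on the training rows, then beta = (X'X + lambda I)^{-1} X'y
ridge_solve <- function(X, y, lambda) {
  XtX <- crossprod(X)
  solve(XtX + lambda * diag(ncol(X)), crossprod(X, y))
}

#' Fit a feature-based gene priority score by leave-one-chromosome-out ridge
#'
#' For each chromosome, a ridge regression of gene z-scores on the feature
#' matrix is fitted on the genes of all other chromosomes and used to
#' predict ("score") the held-out chromosome's genes, so a gene's score
#' never sees its own chromosome's association signal. Feature
#' standardization parameters and the intercept (the unpenalized training
#' mean) are computed on training folds only. The penalty is chosen by
#' k-fold cross-validation inside each training fold over a log-spaced grid
#' unless a fixed `lambda` is given. Non-autosomal genes are excluded.
#' Genes with missing feature values receive the training column mean
#' (zero after standardization) and are flagged.
#'
#' @param features gene-by-feature matrix (rownames = gene ids).
#' @param gene_scores data.frame with `gene_id`, `chr`, `z` (e.g. from
#'   [gene_scores()] or [meta_gene_scores()]).
#' @param lambda `"cv"` (default) or a fixed positive penalty.
#' @param lambda_grid penalty grid for cross-validation.
#' @param nfolds folds for the inner cross-validation (default 5).
#' @param autosomes chromosome labels considered autosomal; default all
#'   except `"X"`, `"Y"`, `"MT"`.
#' @param full_fit set `TRUE` to allow a single-chromosome input, fitted and
#'   scored in-sample (no held-out prediction).
#' @return An object of class `pops`: list with `scores` (data.frame
#'   `gene_id`, `chr`, `raw`, `percentile`, `imputed`), `lambda` (per
#'   chromosome), `coefficients` (feature-by-chromosome matrix),
#'   `ancestry`.
#' @export
pops_fit <- function(features, gene_scores, lambda = "cv",
                     lambda_grid = 10^seq(-2, 6), nfolds = 5L,
                     autosomes = NULL, full_fit = FALSE) {
  gs <- gene_scores[!is.na(gene_scores$z), , drop = FALSE]
  autosomes <- autosomes %||% setdiff(unique(gs$chr), c("X", "Y", "MT"))
  gs <- gs[gs$chr %in% autosomes, , drop = FALSE]
  chrs <- unique(gs$chr)
  if (length(chrs) < 2 && !full_fit)
    stopf(paste("leave-one-chromosome-out needs >= 2 chromosomes;",
                "set full_fit = TRUE to fit and score in-sample"))
  X <- matrix(0, nrow(gs), ncol(features),
              dimnames = list(gs$gene_id, colnames(features)))
  have <- gs$gene_id %in% rownames(features)
  X[have, ] <- features[gs$gene_id[have], , drop = FALSE]
  X[!is.finite(X)] <- NA_real_
  y <- gs$z

  cv_lambda <- function(Xtr, ytr) {
    if (is.numeric(lambda)) return(lambda)
    fold <- fold_assign(nrow(Xtr), nfolds)
    err <- vapply(lambda_grid, function(lam) {
      se <- 0
      for (k in seq_len(nfolds)) {
        tr <- fold != k
        if (!any(tr) || !any(!tr)) next
        st <- standardize_fit(Xtr[tr, , drop = FALSE])
        b <- ridge_solve(standardize_apply(Xtr[tr, , drop = FALSE], st),
                         ytr[tr] - mean(ytr[tr]), lam)
        pred <- mean(ytr[tr]) +
          standardize_apply(Xtr[!tr, , drop = FALSE], st) %*% b
        se <- se + sum((ytr[!tr] - pred)^2)
      }
      se
    }, 0)
    lambda_grid[which.min(err)]
  }

  fit_one <- function(train, test) {
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    lam <- cv_lambda(Xtr, ytr)
    st <- standardize_fit(Xtr)
    b <- ridge_solve(standardize_apply(Xtr, st), ytr - mean(ytr), lam)
    raw <- mean(ytr) + as.vector(
      standardize_apply(X[test, , drop = FALSE], st) %*% b)
    list(raw = raw, lambda = lam, beta = as.vector(b))
  }

  raw <- numeric(nrow(gs))
  lambdas <- stats::setNames(numeric(length(chrs)), chrs)
  coefs <- matrix(NA_real_, ncol(X), length(chrs),
                  dimnames = list(colnames(X), chrs))
  if (length(chrs) < 2) {
    f <- fit_one(seq_len(nrow(gs)), seq_len(nrow(gs)))
    raw[] <- f$raw; lambdas[] <- f$lambda; coefs[, 1] <- f$beta
  } else {
    for (ch in chrs) {
      test <- which(gs$chr == ch)
      f <- fit_one(which(gs$chr != ch), test)
      raw[test] <- f$raw
      lambdas[[ch]] <- f$lambda
      coefs[, ch] <- f$beta
    }
  }
  scores <- data.frame(gene_id = gs$gene_id, chr = gs$chr, raw = raw,
                       imputed = !have, stringsAsFactors = FALSE)
  scores$percentile <- rank(scores$raw, ties.method = "average") /
    nrow(scores)
  structure(list(scores = scores, lambda = lambdas, coefficients = coefs,
                 ancestry = unique(gs$ancestry) %||% NA_character_),
            class = "pops")
}

standardize_fit <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  sd <- apply(X, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

standardize_apply <- function(X, st) {
  Z <- sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
  Z[!is.finite(Z)] <- 0  # missing features impute to the training mean
  Z
}

#' @export
print.pops <- function(x, ...) {
  cat(sprintf(
    "Priority-score fit: %d genes, %d features, %d chromosome fold(s)\n",
    nrow(x$scores), nrow(x$coefficients), ncol(x$coefficients)))
  cat(sprintf("  lambda: %s\n",
              paste(format(unique(x$lambda)), collapse = ", ")))
  invisible(x)
}

#' @export
coef.pops <- function(object, ...) object$coefficients

#' @export
predict.pops <- function(object, ...) {
  s <- object$scores
  stats::setNames(s$raw, s$gene_id)
}

#' Genome-wide percentile ranks of priority scores
#'
#' Percentile = fraction of scored genes with a raw score at or below the
#' gene's, with ties averaged; 1 is the genome-wide maximum.
#'
#' @param scores data.frame with columns `gene_id` and `raw` (e.g.
#'   `pops$scores`).
#' @return The input with a recomputed `percentile` column.
#' @export
percentile_rank <- function(scores) {
  if (!nrow(scores)) stopf("no scores to rank")
  scores$percentile <- rank(scores$raw, ties.method = "average") /
    nrow(scores)
  scores
}

#' Meta-analyze priority scores across two ancestries
#'
#' Per gene, combines the ancestry-specific raw scores with [meta_z()]
#' weighted by the square root of sample size, then recomputes genome-wide
#' percentiles on the meta scores.
#'
#' @param scores_a,scores_b score data.frames (`gene_id`, `chr`, `raw`).
#' @param n_a,n_b effective sample sizes.
#' @return data.frame `gene_id`, `chr`, `raw`, `percentile`,
#'   `ancestry = "meta"`.
#' @export
meta_priority <- function(scores_a, n_a, scores_b, n_b) {
  ids <- union(scores_a$gene_id, scores_b$gene_id)
  ia <- match(ids, scores_a$gene_id)
  ib <- match(ids, scores_b$gene_id)
  raw <- meta_z(scores_a$raw[ia], n_a, scores_b$raw[ib], n_b)
  out <- data.frame(
    gene_id = ids,
    chr = ifelse(is.na(ia), scores_b$chr[ib], scores_a$chr[ia]),
    raw = raw, ancestry = "meta", stringsAsFactors = FALSE)
  percentile_rank(out)
}
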