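# Proteome normalization chain:
#   detection filter -> log2 -> quantile normalization ->
#   rank-based inverse normal transform -> residualization on covariates.
# Matrices are proteins x samples throughout, with NA marking undetected
# entries; no step fills a missing value silently.

#' Retain proteins detected in a minimum fraction of samples
#'
#' @param mat Proteins x samples matrix with `NA` for undetected entries.
#' @param min_fraction Minimum non-missing fraction, boundary inclusive
#'   (a protein detected in exactly 80% of samples is retained at the 0.8
#'   default).
#' @param annotation Optional gene annotation tibble with `protein_id` and
#'   `chrom`; when supplied, proteins mapping outside autosomes 1-22 are
#'   dropped as well.
#' @return The filtered matrix.
#' @export
detection_filter <- function(mat, min_fraction = 0.8, annotation = NULL) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  keep <- rowMeans(!is.na(mat)) >= min_fraction
  if (!is.null(annotation)) {
    auto <- annotation$protein_id[annotation$chrom %in% as.character(1:22)]
    keep <- keep & rownames(mat) %in% auto
  }
  mat[keep, , drop = FALSE]
}

#' Log2-transform intensities
#'
#' @param mat Positive intensity matrix; `NA` preserved.
#' @return Log2-scale matrix.
#' @export
log2_transform <- function(mat) {
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-positive intensity at protein '%s', sample '%s'.",
                  rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  log2(mat)
}

#' Across-sample quantile normalization
#'
#' Within each sample, present values are replaced by the mean across samples
#' of the order statistics at the matching quantile (with interpolation when
#' samples have unequal numbers of present values, and ties averaged), so
#' that every complete sample afterwards carries the identical sorted value
#' vector.
#'
#' @param mat Proteins x samples log-scale matrix.
#' @return Quantile-normalized matrix.
#' @export
quantile_normalize <- function(mat) {
  n_present <- colSums(!is.na(mat))
  if (any(n_present < 2)) {
    abort(sprintf("Sample '%s' has fewer than 2 present values.",
                  colnames(mat)[which(n_present < 2)[1]]))
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Rank-based inverse normal transform, per protein
#'
#' Each protein's present values are replaced by standard-normal quantiles of
#' their rankit positions `(rank - 0.5) / n_present`, with ties given average
#' ranks; missing entries are preserved. Constant proteins map to all zeros
#' with a warning.
#'
#' @param mat Proteins x samples matrix.
#' @return Transformed matrix.
#' @export
inverse_normal_transform <- function(mat) {
  out <- mat
  constant <- character(0)
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n == 0) next
    if (length(unique(x[ok])) == 1) {
      out[i, ok] <- 0
      constant <- c(constant, rownames(mat)[i] %||% as.character(i))
      next
    }
    out[i, ok] <- qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  }
  if (length(constant) > 0) {
    warn(paste0("Constant proteins set to zero after INT: ",
                paste(head(constant, 5), collapse = ", ")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deterministic_sign <- function(scores, loadings) {
  # largest-magnitude loading made positive, per component
  for (j in seq_len(ncol(scores))) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  scores
}

#' Genotype principal components
#'
#' Top-k principal component scores of the centered, variance-standardized
#' dosage matrix, with a deterministic sign convention (the
#' largest-magnitude variant loading of each component is positive).
#'
#' @param panel A QC'd `genotype_panel`.
#' @param k Number of components (default 3).
#' @return Samples x k score matrix (0 columns when `k = 0`).
#' @export
genotype_pcs <- function(panel, k = 3) {
  n <- n_samples(panel)
  if (k >= n) abort("k must be smaller than the sample count.")
  if (k == 0) {
    return(matrix(numeric(0), n, 0, dimnames = list(panel$sample_ids, NULL)))
  }
  X <- panel$dosages
  sds <- apply(X, 2, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  scores <- deterministic_sign(scores, sv$v)
  dimnames(scores) <- list(panel$sample_ids, paste0("PC", seq_len(k)))
  scores
}

#' Hidden-factor estimation from the normalized proteome
#'
#' Principal-component scores of the samples x proteins matrix (proteins
#' median-imputed and standardized), used as hidden technical-factor
#' covariates in place of a Bayesian factor model.
#'
#' @param mat Normalized proteins x samples matrix (missing allowed; imputed
#'   per-protein median for estimation only).
#' @param k Number of factors (default 15).
#' @return Samples x k factor-score matrix with an `"n_imputed"` attribute.
#' @export
estimate_hidden_factors <- function(mat, k = 15) {
  if (k >= min(dim(mat))) abort("k must be smaller than both matrix dimensions.")
  if (k == 0) {
    return(matrix(numeric(0), ncol(mat), 0, dimnames = list(colnames(mat), NULL)))
  }
  imp <- impute_row_median(mat)
  X <- t(imp$mat)                       # samples x proteins
  sds <- apply(X, 2, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  scores <- deterministic_sign(scores, sv$v)
  dimnames(scores) <- list(colnames(mat), paste0("F", seq_len(k)))
  attr(scores, "n_imputed") <- imp$n_imputed
  scores
}

impute_row_median <- function(mat) {
  n_imputed <- 0L
  for (i in seq_len(nrow(mat))) {
    miss <- is.na(mat[i, ])
    if (any(miss)) {
      mat[i, miss] <- median(mat[i, !miss])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  list(mat = mat, n_imputed = n_imputed)
}

#' Residualize the proteome on covariates
#'
#' Per protein, ordinary least-squares residuals from regression on an
#' intercept plus all covariate columns. Missing proteome entries are
#' median-imputed per protein before regression and the imputation count is
#' recorded on the result.
#'
#' @param mat Proteins x samples matrix.
#' @param covariates Data frame of per-sample covariates (rows aligned with
#'   matrix columns); must be complete.
#' @return Residual matrix (per-protein mean zero) with attribute
#'   `"n_imputed"`.
#' @export
residualize <- function(mat, covariates) {
  covariates <- as.data.frame(covariates)
  covariates$sample_id <- NULL
  if (anyNA(covariates)) abort("Covariates must be complete (no missing values).")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient covariates; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  imp <- impute_row_median(mat)
  res <- t(qr.resid(qrX, t(imp$mat)))
  dimnames(res) <- dimnames(mat)
  attr(res, "n_imputed") <- imp$n_imputed
  res
}

#' Run the full proteome preprocessing chain
#'
#' Detection filter, log2, across-sample quantile normalization, per-protein
#' inverse normal transform, then residualization on age + genotype PCs +
#' hidden factors, in that fixed order.
#'
#' @param mat Raw proteins x samples intensity matrix.
#' @param panel QC'd `genotype_panel` (for genotype PCs).
#' @param covariates Tibble with per-sample `age` (and `sample_id`).
#' @param k_hidden Number of hidden factors (default 15).
#' @param n_pcs Number of genotype PCs (default 3).
#' @param min_fraction Detection-filter threshold (default 0.8).
#' @param annotation Optional annotation for the autosome restriction.
#' @return List with `residuals` (ResidualMatrix), `covariates` (the full
#'   covariate table used), and `log` (imputation counts, dropped proteins).
#' @export
preprocess_proteome <- function(mat, panel, covariates, k_hidden = 15,
                                n_pcs = 3, min_fraction = 0.8,
                                annotation = NULL) {
  n_in <- nrow(mat)
  filtered <- detection_filter(mat, min_fraction, annotation)
  normd <- inverse_normal_transform(quantile_normalize(log2_transform(filtered)))
  k_hidden <- min(k_hidden, min(dim(normd)) - 1L)
  fac <- estimate_hidden_factors(normd, k = k_hidden)
  pcs <- genotype_pcs(panel, k = n_pcs)
  covar <- data.frame(age = covariates$age[match(colnames(mat), covariates$sample_id)],
                      pcs[colnames(mat), , drop = FALSE],
                      fac[colnames(mat), , drop = FALSE])
  res <- residualize(normd, covar)
  list(residuals = res, covariates = covar,
       log = list(n_proteins_in = n_in, n_proteins_kept = nrow(filtered),
                  n_imputed_factors = attr(fac, "n_imputed"),
                  n_imputed_residualize = attr(res, "n_imputed")))
}

#' Sweep the hidden-factor count against downstream model yield
#'
#' Re-runs preprocessing and cis-model training for several hidden-factor
#' counts and reports how many protein models pass the performance gate at
#' each, mirroring the usual factor-count selection curve.
#'
#' @inheritParams preprocess_proteome
#' @param annotation Gene annotation tibble (required here for training).
#' @param k_values Factor counts to try.
#' @param ... Passed to [build_models()].
#' @return Tibble with `k` and `n_models`.
#' @export
sweep_hidden_factors <- function(mat, panel, covariates, annotation,
                                 k_values = c(5, 10, 15, 20, 25), ...) {
  rows <- purrr::map(k_values, function(k) {
    pre <- preprocess_proteome(mat, panel, covariates, k_hidden = k,
                               annotation = annotation)
    db <- build_models(pre$residuals, panel, annotation, ...)
    tibble(k = k, n_models = sum(db$performance$retained))
  })
  structure(list_rbind(rows), class = c("factor_sweep", class(tibble())))
}
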