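# Per-protein cis elastic-net prediction models with five-fold
# cross-validated performance gating (R > 0.1 and p < 0.05, both strict).

#' Select cis variants for a gene
#'
#' Variants on the gene's chromosome within `window` bp of the gene body,
#' inclusive at both boundaries (positions are 1-based).
#'
#' @param gene One-row annotation (fields `chrom`, `start`, `end`).
#' @param panel A `genotype_panel`.
#' @param window Half-width in bp (default 500 kb).
#' @return Character vector of variant ids (possibly empty).
#' @export
select_cis_snps <- function(gene, panel, window = 5e5) {
  lo <- max(1, gene$start - window)
  hi <- gene$end + window
  v <- panel$variants
  v$variant_id[v$chrom == gene$chrom & v$pos >= lo & v$pos <= hi]
}

seeded_folds <- function(n, n_folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

#' Fit an elastic net on standardized dosages
#'
#' Minimizes `(1/2n)||y - Xb||^2 + lambda[alpha ||b||_1 + (1-alpha)/2 ||b||^2]`
#' on internally standardized predictor columns, choosing lambda by 5-fold
#' cross-validated mean squared error (minimum rule), and maps the nonzero
#' coefficients back to the per-allele (dosage) scale.
#'
#' @param X Dosage matrix (samples x variants, named columns).
#' @param y Response vector.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Seed for the internal fold assignment.
#' @param n_folds Internal CV folds (default 5).
#' @param lambda Optional fixed penalty value; when supplied the internal
#'   cross-validated lambda selection is skipped.
#' @param ... Further arguments passed to [glmnet::glmnet()] /
#'   [glmnet::cv.glmnet()] (e.g. `thresh`).
#' @return List with `weights` (tibble `variant_id`, `weight`, per-allele
#'   scale), `lambda`, and the column standard deviations used.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, seed = 1L, n_folds = 5,
                            lambda = NULL, ...) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 10)
  sds <- apply(X, 2, sd)
  use <- sds > 0
  if (sum(use) < 2) {
    # glmnet needs >= 2 columns; a single predictor degenerates to OLS with
    # vanishing penalty
    return(single_column_fit(X, y, use, sds))
  }
  Xs <- scale(X[, use, drop = FALSE])
  if (is.null(lambda)) {
    foldid <- seeded_folds(length(y), n_folds, seed)
    cvfit <- glmnet::cv.glmnet(Xs, y, alpha = alpha, foldid = foldid,
                               standardize = FALSE, ...)
    b <- as.vector(stats::coef(cvfit, s = "lambda.min"))[-1]
    sel <- cvfit$lambda.min
  } else {
    fit <- glmnet::glmnet(Xs, y, alpha = alpha, standardize = FALSE, ...)
    sel <- lambda
    b <- as.vector(stats::coef(fit, s = sel, exact = TRUE, x = Xs, y = y,
                               alpha = alpha, standardize = FALSE, ...))[-1]
  }
  nz <- which(b != 0)
  tibble_w <- tibble(variant_id = colnames(Xs)[nz],
                     weight = unname(b[nz] / sds[use][nz]))
  list(weights = tibble_w, lambda = sel, sds = sds)
}

single_column_fit <- function(X, y, use, sds) {
  if (sum(use) == 0) {
    return(list(weights = tibble(variant_id = character(0), weight = numeric(0)),
                lambda = NA_real_, sds = sds))
  }
  x <- scale(X[, use, drop = FALSE])[, 1]
  b <- sum(x * (y - mean(y))) / sum(x^2)
  list(weights = tibble(variant_id = colnames(X)[use],
                       weight = unname(b / sds[use])),
       lambda = 0, sds = sds)
}

#' Cross-validated prediction performance
#'
#' Samples are split into `n_folds` folds by a seeded shuffle; for each fold
#' an elastic net (lambda re-selected on the training folds) predicts the
#' held-out samples. Performance is the Pearson correlation R between the
#' pooled out-of-fold predictions and the observed response, with its
#' t-distribution p-value (df = n - 2). A constant prediction vector yields
#' R = 0, p = 1.
#'
#' @inheritParams fit_elastic_net
#' @param n_folds Outer folds (default 5).
#' @return List with `r`, `p`, and the pooled `predictions`.
#' @export
cross_validated_performance <- function(X, y, n_folds = 5, seed = 1L,
                                        alpha = 0.5) {
  n <- length(y)
  stopifnot(n >= n_folds)
  fold <- seeded_folds(n, n_folds, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    fit <- fit_elastic_net(X[!test, , drop = FALSE], y[!test], alpha = alpha,
                           seed = seed + f)
    w <- setNames(fit$weights$weight, fit$weights$variant_id)
    if (length(w) == 0) {
      pred[test] <- mean(y[!test])
    } else {
      pred[test] <- as.vector(X[test, names(w), drop = FALSE] %*% w)
    }
  }
  if (sd(pred) == 0 || sd(y) == 0) return(list(r = 0, p = 1, predictions = pred))
  r <- cor(pred, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2), predictions = pred)
}

#' Train and gate cis prediction models for every protein
#'
#' For each protein: select cis variants, measure five-fold cross-validated
#' performance, gate at R > 0.1 and p < 0.05 (both strict), and refit the
#' deployed weights on all samples. Failures (no cis variants, all-zero
#' model, gate miss) are recorded per protein, never raised.
#'
#' @param residuals Proteins x samples residual matrix.
#' @param panel QC'd `genotype_panel` aligned on samples.
#' @param annotation Gene annotation tibble (`protein_id`, `chrom`, `start`,
#'   `end`).
#' @param window Cis window half-width in bp (default 500 kb).
#' @param alpha Elastic-net mixing (default 0.5).
#' @param seed Base seed; each protein uses `seed + its index`.
#' @return A `model_db`: list with `weights` (tibble `protein_id`,
#'   `variant_id`, `effect_allele`, `weight`), `performance` (tibble
#'   `protein_id`, `r_cv`, `p_cv`, `n_snps_window`, `n_weights`, `lambda`,
#'   `retained`, `reason`), and `config`.
#' @export
build_models <- function(residuals, panel, annotation, window = 5e5,
                         alpha = 0.5, seed = 1L) {
  prot_ids <- intersect(rownames(residuals), annotation$protein_id)
  samp <- intersect(colnames(residuals), panel$sample_ids)
  if (length(samp) < 10) abort("Fewer than 10 shared samples between residuals and panel.")
  dos <- panel$dosages[samp, , drop = FALSE]
  ea <- setNames(panel$variants$effect_allele, panel$variants$variant_id)

  perf_rows <- vector("list", length(prot_ids))
  weight_rows <- vector("list", length(prot_ids))
  for (i in seq_along(prot_ids)) {
    pid <- prot_ids[i]
    gene <- annotation[annotation$protein_id == pid, ][1, ]
    cis <- select_cis_snps(gene, panel, window)
    row <- tibble(protein_id = pid, r_cv = NA_real_, p_cv = NA_real_,
                  n_snps_window = length(cis), n_weights = 0L,
                  lambda = NA_real_, retained = FALSE, reason = "")
    if (length(cis) == 0) {
      row$reason <- "no_cis_variants"
      perf_rows[[i]] <- row
      next
    }
    X <- dos[, cis, drop = FALSE]
    y <- residuals[pid, samp]
    cv <- cross_validated_performance(X, y, seed = seed + i, alpha = alpha)
    row$r_cv <- cv$r
    row$p_cv <- cv$p
    if (!(cv$r > 0.1 && cv$p < 0.05)) {
      row$reason <- "gate_failed"
      perf_rows[[i]] <- row
      next
    }
    fit <- fit_elastic_net(X, y, alpha = alpha, seed = seed + i)
    if (nrow(fit$weights) == 0) {
      row$reason <- "all_zero_weights"
      perf_rows[[i]] <- row
      next
    }
    row$n_weights <- nrow(fit$weights)
    row$lambda <- fit$lambda
    row$retained <- TRUE
    row$reason <- "retained"
    perf_rows[[i]] <- row
    weight_rows[[i]] <- fit$weights %>%
      mutate(protein_id = pid, effect_allele = unname(ea[.data$variant_id])) %>%
      select("protein_id", "variant_id", "effect_allele", "weight")
  }
  structure(list(weights = list_rbind(weight_rows),
                 performance = list_rbind(perf_rows),
                 config = list(window = window, alpha = alpha, seed = seed)),
            class = "model_db")
}

#' @exportS3Method base::print
print.model_db <- function(x, ...) {
  cat("<model_db> ", sum(x$performance$retained), " retained models / ",
      nrow(x$performance), " proteins attempted\n", sep = "")
  invisible(x)
}

#' @describeIn build_models `tidy()` returns the per-variant weight table.
#' @param x A `model_db`.
#' @param ... Unused.
#' @export
tidy.model_db <- function(x, ...) as_tibble(x$weights)

#' @describeIn build_models `glance()` returns one-row training summary.
#' @export
glance.model_db <- function(x, ...) {
  perf <- x$performance
  tibble(n_proteins = nrow(perf),
         n_retained = sum(perf$retained),
         retained_fraction = mean(perf$retained),
         median_r_cv = median(perf$r_cv, na.rm = TRUE))
}
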