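# Protein/RNA rank correlation with Fisher-z confidence intervals, and
# side-by-side PWAS/TWAS comparison.

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Rank correlation on average-ranked values with pairwise deletion of
#' missing pairs; p from the t approximation (df = n - 2) and the 95% CI by
#' Fisher z transformation with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y Numeric vectors of equal length (missing allowed).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `rho`, `ci_lo`, `ci_hi`, `p`, `n`, `status`.
#' @export
spearman_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4) abort("Need at least 4 complete pairs.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(tibble(rho = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                  p = NA_real_, n = n, status = "constant_input"))
  }
  rho <- cor(rank(x[ok]), rank(y[ok]))
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  zr <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  half <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  tibble(rho = rho, ci_lo = tanh(zr - half), ci_hi = tanh(zr + half),
         p = p, n = n, status = "ok")
}

#' Protein/RNA correlation table
#'
#' Spearman correlation (with CI and BH FDR across proteins) between each
#' protein's intensities and its encoding gene's RNA expression. The rank
#' correlation is invariant to the log scale, so raw or log2 inputs give
#' identical results.
#'
#' @param proteome Proteins x samples matrix.
#' @param rna Genes x samples matrix.
#' @param annotation Tibble mapping `protein_id` to `gene_id`.
#' @return Tibble of class `pwas_correlation`: `protein_id`, `gene_id`,
#'   `rho`, `ci_lo`, `ci_hi`, `p`, `q`, `n`.
#' @export
protein_rna_correlation <- function(proteome, rna, annotation) {
  map_tbl <- annotation %>%
    filter(.data$protein_id %in% rownames(proteome),
           .data$gene_id %in% rownames(rna))
  samp <- intersect(colnames(proteome), colnames(rna))
  rows <- purrr::map2(map_tbl$protein_id, map_tbl$gene_id, function(pid, gid) {
    spearman_with_ci(proteome[pid, samp], rna[gid, samp]) %>%
      mutate(protein_id = pid, gene_id = gid)
  })
  out <- list_rbind(rows)
  out$q <- bh_fdr(out$p)
  structure(out %>%
              select("protein_id", "gene_id", "rho", "ci_lo", "ci_hi",
                     "p", "q", "n", "status"),
            class = c("pwas_correlation", class(tibble())))
}

#' Compare PWAS and TWAS associations
#'
#' Joins protein-level and transcript-level association results on the
#' protein/gene pairing and flags sign concordance of the Z scores.
#'
#' @param pwas Association tibble with `protein_id`, `z`, `p` (and
#'   optionally `q`).
#' @param twas Tibble with `gene_id`, `z`, `p`.
#' @param annotation Tibble mapping `protein_id` to `gene_id`.
#' @return Tibble of class `pwas_twas_comparison` with a `summary`
#'   attribute (`n_pairs`, `n_concordant`, `n_both_nominal`); unmatched ids
#'   are recorded in attribute `unmatched`.
#' @export
compare_pwas_twas <- function(pwas, twas, annotation) {
  ptab <- as_tibble(pwas) %>%
    select("protein_id", pwas_z = "z", pwas_p = "p",
           dplyr::any_of(c(pwas_q = "q")))
  ttab <- as_tibble(twas) %>% select("gene_id", twas_z = "z", twas_p = "p")
  joined <- annotation %>%
    select("protein_id", "gene_id") %>%
    inner_join(ptab, by = "protein_id") %>%
    inner_join(ttab, by = "gene_id") %>%
    mutate(concordant = .data$pwas_z * .data$twas_z > 0)
  out <- structure(joined, class = c("pwas_twas_comparison", class(tibble())))
  attr(out, "summary") <- tibble(
    n_pairs = nrow(joined),
    n_concordant = sum(joined$concordant, na.rm = TRUE),
    n_both_nominal = sum(joined$pwas_p < 0.05 & joined$twas_p < 0.05,
                         na.rm = TRUE))
  attr(out, "unmatched") <- setdiff(ptab$protein_id, joined$protein_id)
  out
}
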