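# Summary-statistics protein-trait association:
#   Z_p = sum over model variants of  w_sp * (sigma_s / sigma_p) * (beta_s / se_s)
# with sigma_s the reference-panel dosage SD, sigma_p the SD of the
# model-predicted expression, both estimated from an LD reference panel.

#' Build an LD reference from a genotype panel
#'
#' Stores the reference dosages and per-variant standard deviations; dosage
#' covariance/correlation blocks for arbitrary variant sets (model variants,
#' conditional loci) are computed on request with the unbiased (n-1)
#' estimator.
#'
#' @param panel A `genotype_panel` (typically the reference draw).
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(panel) {
  sds <- apply(panel$dosages, 2, sd)
  structure(list(panel = panel, sigma = sds, variants = panel$variants),
            class = "ld_reference")
}

#' @exportS3Method base::print
print.ld_reference <- function(x, ...) {
  cat("<ld_reference> ", n_samples(x$panel), " samples x ",
      n_variants(x$panel), " variants\n", sep = "")
  invisible(x)
}

ld_cov <- function(ld, ids) {
  missing <- setdiff(ids, colnames(ld$panel$dosages))
  if (length(missing) > 0) {
    abort(paste0("Variants absent from LD reference: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  cov(ld$panel$dosages[, ids, drop = FALSE])
}

ld_cor <- function(ld, ids) {
  stats::cov2cor(ld_cov(ld, ids))
}

#' Standard deviation of model-predicted expression
#'
#' `sigma_p = sqrt(w' Gamma w)` with `Gamma` the reference dosage covariance
#' restricted to the model's variants.
#'
#' @param weights Tibble (`variant_id`, `weight`) for one protein.
#' @param ld An `ld_reference`.
#' @return Nonnegative scalar.
#' @export
predicted_expression_sd <- function(weights, ld) {
  G <- ld_cov(ld, weights$variant_id)
  sqrt(max(as.numeric(t(weights$weight) %*% G %*% weights$weight), 0))
}

#' Two-sided normal tail p-value for a Z score
#'
#' @param z Z score(s).
#' @return `2 * (1 - Phi(|z|))`, vectorized.
#' @export
#' @examples
#' z_to_p(4.13)  # 3.63e-5
z_to_p <- function(z) 2 * pnorm(-abs(z))

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#'
#' @param p Vector of p-values in [0, 1].
#' @return q-values, same length.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Summary-statistics association Z for one protein model
#'
#' Computes the weighted sum of marginal GWAS Z scores scaled by the
#' reference dosage SDs and the predicted-expression SD. Model variants
#' missing from the GWAS are dropped without renormalizing the remaining
#' weights; the drop count is reported.
#'
#' @param weights Tibble (`variant_id`, `weight`) for one protein, with
#'   weights on the effect-allele dosage scale and the GWAS already
#'   harmonized to the same effect alleles.
#' @param gwas Harmonized GWAS summary tibble.
#' @param ld An `ld_reference`.
#' @return One-row tibble: `z`, `p`, `sigma_p`, `n_snps_used`,
#'   `n_snps_dropped`, `status` (`"ok"`, `"untestable"`, `"degenerate"`).
#' @export
spredixcan_z <- function(weights, gwas, ld) {
  hit <- weights$variant_id %in% gwas$variant_id
  dropped <- sum(!hit)
  w <- weights[hit, , drop = FALSE]
  if (nrow(w) == 0) {
    return(tibble(z = NA_real_, p = NA_real_, sigma_p = NA_real_,
                  n_snps_used = 0L, n_snps_dropped = dropped,
                  status = "untestable"))
  }
  g <- gwas[match(w$variant_id, gwas$variant_id), ]
  sigma_p <- predicted_expression_sd(w, ld)
  if (sigma_p <= 0) {
    return(tibble(z = NA_real_, p = NA_real_, sigma_p = 0,
                  n_snps_used = nrow(w), n_snps_dropped = dropped,
                  status = "degenerate"))
  }
  sigma_s <- ld$sigma[w$variant_id]
  z <- sum(w$weight * (sigma_s / sigma_p) * (g$beta / g$se))
  tibble(z = z, p = z_to_p(z), sigma_p = sigma_p,
         n_snps_used = nrow(w), n_snps_dropped = dropped, status = "ok")
}

#' Annotate a gene's distance to known risk variants
#'
#' Distance is zero when a known variant lies inside the gene body, else the
#' minimum distance to the nearer gene boundary over same-chromosome
#' variants; the gene is flagged as a novel locus when every same-chromosome
#' variant is at least `window` bp away (variants on other chromosomes count
#' as infinitely far).
#'
#' @param gene One-row annotation (`chrom`, `start`, `end`).
#' @param known Tibble of known risk variants (`variant_id`, `chrom`, `pos`).
#' @param window Novelty window in bp (default 1 Mb, boundary inclusive:
#'   exactly 1 Mb away is still novel).
#' @return One-row tibble: `novel`, `nearest_variant`, `distance_bp`.
#' @export
annotate_novelty <- function(gene, known, window = 1e6) {
  k <- known[known$chrom == gene$chrom, , drop = FALSE]
  if (nrow(k) == 0) {
    return(tibble(novel = TRUE, nearest_variant = NA_character_,
                  distance_bp = Inf))
  }
  d <- ifelse(k$pos < gene$start, gene$start - k$pos,
              ifelse(k$pos > gene$end, k$pos - gene$end, 0))
  i <- which.min(d)
  tibble(novel = all(d >= window), nearest_variant = k$variant_id[i],
         distance_bp = as.numeric(d[i]))
}

#' Run the association scan across phenotypes
#'
#' Full cross of retained protein models with a named list of harmonized
#' GWAS summary tables. FDR is Benjamini-Hochberg within each phenotype.
#' Output is deterministically ordered by phenotype, then ascending p, ties
#' broken by protein id.
#'
#' @param modeldb A `model_db` from [build_models()].
#' @param gwas_set Named list of harmonized GWAS summary tibbles (one per
#'   phenotype).
#' @param ld An `ld_reference`.
#' @param known Optional known-risk-variant tibble for novelty annotation.
#' @param annotation Gene annotation tibble (needed with `known`).
#' @param fdr_threshold Significance threshold echoed into `significant`.
#' @param novelty_window Novelty window in bp (default 1 Mb).
#' @return Tibble of class `pwas_assoc`: `phenotype`, `protein_id`, `z`,
#'   `p`, `q`, `significant`, `n_snps_used`, `n_snps_dropped`, `status`,
#'   plus `novel`, `nearest_variant`, `distance_kb` when `known` is given.
#' @export
run_phenotypes <- function(modeldb, gwas_set, ld, known = NULL,
                           annotation = NULL, fdr_threshold = 0.1,
                           novelty_window = 1e6) {
  stopifnot(inherits(modeldb, "model_db"), is.list(gwas_set),
            !is.null(names(gwas_set)))
  retained <- modeldb$performance$protein_id[modeldb$performance$retained]
  rows <- purrr::imap(gwas_set, function(gwas, pheno) {
    per_prot <- purrr::map(retained, function(pid) {
      w <- modeldb$weights[modeldb$weights$protein_id == pid, ]
      spredixcan_z(w, gwas, ld) %>%
        mutate(phenotype = pheno, protein_id = pid)
    })
    tab <- list_rbind(per_prot)
    if (nrow(tab) > 0) tab$q <- bh_fdr(tab$p)
    tab
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(phenotype = character(0), protein_id = character(0),
                  z = numeric(0), p = numeric(0), q = numeric(0),
                  sigma_p = numeric(0), n_snps_used = integer(0),
                  n_snps_dropped = integer(0), status = character(0))
  }
  out <- out %>%
    mutate(significant = .data$q < fdr_threshold) %>%
    select("phenotype", "protein_id", "z", "p", "q", "significant",
           "n_snps_used", "n_snps_dropped", "status", "sigma_p") %>%
    arrange(.data$phenotype, .data$p, .data$protein_id)
  if (!is.null(known)) {
    stopifnot(!is.null(annotation))
    nov <- purrr::map(unique(out$protein_id), function(pid) {
      gene <- annotation[annotation$protein_id == pid, ][1, ]
      annotate_novelty(gene, known, novelty_window) %>%
        mutate(protein_id = pid)
    }) %>% list_rbind()
    out <- left_join(out, nov, by = "protein_id") %>%
      mutate(distance_kb = .data$distance_bp / 1000) %>%
      select(-"distance_bp")
  }
  structure(out, class = c("pwas_assoc", class(tibble())))
}

#' @export
glance.pwas_assoc <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$phenotype) %>%
    summarise(n_tested = sum(!is.na(.data$p)),
              n_significant = sum(.data$significant, na.rm = TRUE),
              min_p = min(.data$p, na.rm = TRUE), .groups = "drop")
}
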