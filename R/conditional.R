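# Approximate conditional analysis from summary statistics, in standardized
# Z space: for a non-index variant s and index set C,
#   z_{s|C} = (z_s - R_sC R_CC^{-1} z_C) / sqrt(1 - R_sC R_CC^{-1} R_Cs)
# with R from an LD reference. Standard errors are held fixed and beta is
# rebuilt as z * se, which is all the downstream association statistic
# consumes.

prune_index_set <- function(R, index_idx, p) {
  ord <- index_idx[order(p[index_idx])]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || all(abs(R[i, kept]) <= 0.9)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Conditional Z scores at a locus
#'
#' @param z Vector of marginal Z scores over the locus variants.
#' @param R Locus LD correlation matrix (same order as `z`).
#' @param index_idx Integer positions of the index (conditioned-on)
#'   variants; pairs with |r| > 0.9 within the set are pruned, keeping the
#'   smaller p-value.
#' @return List with `z_adj` (conditional Z; index variants set to 0),
#'   `fully_explained` (logical; residual variance below 0.01), and
#'   `index_kept` (pruned index positions).
#' @export
conditional_z <- function(z, R, index_idx) {
  stopifnot(length(index_idx) >= 1, nrow(R) == length(z))
  p <- z_to_p(z)
  C <- prune_index_set(R, index_idx, p)
  Rcc_inv <- tryCatch(solve(R[C, C, drop = FALSE]),
                      error = function(e) {
                        abort(paste0("Singular index LD block after pruning; variants ",
                                     paste(C, collapse = ", ")))
                      })
  z_adj <- z
  explained <- rep(FALSE, length(z))
  for (s in seq_along(z)) {
    if (s %in% C) {
      z_adj[s] <- 0
      explained[s] <- TRUE
      next
    }
    rsc <- R[s, C, drop = FALSE]
    proj <- as.numeric(rsc %*% Rcc_inv %*% z[C])
    denom2 <- 1 - as.numeric(rsc %*% Rcc_inv %*% t(rsc))
    if (denom2 < 0.01) {
      z_adj[s] <- 0
      explained[s] <- TRUE
    } else {
      z_adj[s] <- (z[s] - proj) / sqrt(denom2)
    }
  }
  list(z_adj = z_adj, fully_explained = explained, index_kept = C)
}

#' Condition GWAS summary statistics on known risk variants
#'
#' For every locus containing a known risk variant, replaces the Z scores of
#' all variants within `window` bp of an index variant by their conditional
#' values given the locus index set (overlapping windows are merged and
#' conditioned jointly); `beta` becomes `z_adj * se` with `se` unchanged.
#' Loci without index variants pass through untouched.
#'
#' @param gwas Harmonized GWAS summary tibble.
#' @param ld An `ld_reference` containing all windowed variants.
#' @param known Tibble of known risk variants (`variant_id`, `chrom`, `pos`).
#' @param window Half-width in bp (default 1 Mb).
#' @return The GWAS tibble with adjusted `beta` and a logical
#'   `conditioned` column.
#' @export
conditional_sumstats <- function(gwas, ld, known, window = 1e6) {
  gwas$conditioned <- FALSE
  if (is.null(known) || nrow(known) == 0) return(gwas)
  present <- known$variant_id %in% gwas$variant_id
  if (any(!present)) {
    warn(paste0("Index variants absent from GWAS, loci skipped: ",
                paste(known$variant_id[!present], collapse = ", ")))
    known <- known[present, , drop = FALSE]
  }
  if (nrow(known) == 0) return(gwas)
  for (ch in unique(known$chrom)) {
    k <- known[known$chrom == ch, , drop = FALSE]
    k <- k[order(k$pos), , drop = FALSE]
    # merge overlapping +/- window windows into joint conditioning loci
    grp <- cumsum(c(1, diff(k$pos) > 2 * window))
    for (g in unique(grp)) {
      kg <- k[grp == g, , drop = FALSE]
      in_locus <- gwas$chrom == ch &
        gwas$pos >= min(kg$pos) - window & gwas$pos <= max(kg$pos) + window &
        gwas$variant_id %in% colnames(ld$panel$dosages)
      ids <- gwas$variant_id[in_locus]
      if (length(ids) == 0) next
      R <- ld_cor(ld, ids)
      z <- gwas$beta[in_locus] / gwas$se[in_locus]
      idx <- match(kg$variant_id, ids)
      cz <- conditional_z(z, R, idx)
      gwas$beta[in_locus] <- cz$z_adj * gwas$se[in_locus]
      gwas$conditioned[in_locus] <- TRUE
    }
  }
  gwas
}

#' Conditional protein-trait association
#'
#' Re-runs the summary-statistics association on conditioned GWAS
#' statistics and reports marginal vs adjusted results side by side, with
#' the independence call at `p_adjusted < threshold`.
#'
#' @param modeldb A `model_db`.
#' @param gwas Marginal harmonized GWAS summary tibble.
#' @param gwas_conditional Output of [conditional_sumstats()].
#' @param ld An `ld_reference`.
#' @param known Known-risk-variant tibble (echoed into the output).
#' @param threshold Independence threshold on the adjusted p (default 1e-4).
#' @param phenotype Phenotype label for the output.
#' @return Tibble of class `pwas_conditional`: `protein_id`, `phenotype`,
#'   `index_variants`, `z_marginal`, `p_marginal`, `z_adjusted`,
#'   `p_adjusted`, `attenuation` (`1 - |z_adj| / |z_marg|`), `independent`.
#' @export
conditional_assoc <- function(modeldb, gwas, gwas_conditional, ld,
                              known = NULL, threshold = 1e-4,
                              phenotype = "overall") {
  retained <- modeldb$performance$protein_id[modeldb$performance$retained]
  idx_label <- if (is.null(known)) "" else paste(known$variant_id, collapse = ";")
  rows <- purrr::map(retained, function(pid) {
    w <- modeldb$weights[modeldb$weights$protein_id == pid, ]
    marg <- spredixcan_z(w, gwas, ld)
    adj <- spredixcan_z(w, gwas_conditional, ld)
    tibble(protein_id = pid, phenotype = phenotype,
           index_variants = idx_label,
           z_marginal = marg$z, p_marginal = marg$p,
           z_adjusted = adj$z, p_adjusted = adj$p,
           attenuation = ifelse(is.na(marg$z) | marg$z == 0, NA_real_,
                                1 - abs(adj$z) / abs(marg$z)),
           independent = !is.na(adj$p) & adj$p < threshold)
  })
  structure(list_rbind(rows) %>% arrange(.data$p_marginal, .data$protein_id),
            class = c("pwas_conditional", class(tibble())))
}
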