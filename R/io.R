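# Plain-text readers/writers for the pipeline's interchange dialects:
# PLINK-style .bim/.fam plus a dosage TSV (samples x variants), expression
# matrices as TSV with "NA" for missing, and GWAS summary TSVs.

#' Write / read a genotype panel
#'
#' The panel is stored as `<prefix>.bim` (chrom, variant_id, cM = 0, pos,
#' effect_allele, other_allele), `<prefix>.fam` (one row per sample), and
#' `<prefix>.dosage.tsv` (sample_id column followed by one dosage column per
#' variant), plus `<prefix>.info.tsv` carrying frequencies and
#' imputation-R2 tags.
#'
#' @param panel A `genotype_panel`.
#' @param prefix Path prefix for the four files.
#' @return `prefix`, invisibly.
#' @export
write_genotype_panel <- function(panel, prefix) {
  v <- panel$variants
  readr::write_tsv(tibble(chrom = v$chrom, variant_id = v$variant_id, cm = 0,
                          pos = v$pos, effect_allele = v$effect_allele,
                          other_allele = v$other_allele),
                   paste0(prefix, ".bim"), col_names = FALSE)
  readr::write_tsv(tibble(fid = panel$sample_ids, iid = panel$sample_ids,
                          pid = 0, mid = 0, sex = 2, pheno = -9),
                   paste0(prefix, ".fam"), col_names = FALSE)
  dos <- as_tibble(panel$dosages)
  readr::write_tsv(dplyr::bind_cols(tibble(sample_id = panel$sample_ids), dos),
                   paste0(prefix, ".dosage.tsv"))
  readr::write_tsv(v, paste0(prefix, ".info.tsv"))
  invisible(prefix)
}

#' @rdname write_genotype_panel
#' @export
read_genotype_panel <- function(prefix) {
  v <- readr::read_tsv(paste0(prefix, ".info.tsv"), show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c"))
  d <- readr::read_tsv(paste0(prefix, ".dosage.tsv"), show_col_types = FALSE)
  new_genotype_panel(d$sample_id, v,
                     as.matrix(d[, v$variant_id, drop = FALSE]))
}

#' Write / read an expression matrix as TSV
#'
#' Rows are proteins/genes (first column `feature_id`), columns are samples,
#' missing entries written as `NA`.
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  tb <- dplyr::bind_cols(tibble(feature_id = rownames(mat)), as_tibble(mat))
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb$feature_id
  m
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `beta`, `se`, `freq`, `n`.
#'
#' @param gwas GWAS summary tibble.
#' @param path File path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_gwas_tsv <- function(gwas, path) {
  readr::write_tsv(gwas[, c("variant_id", "chrom", "pos", "effect_allele",
                            "other_allele", "beta", "se", "freq", "n")], path)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c"))
}

#' Write the simulation truth to TSV
#'
#' One row per causal (protein, variant) pair with the raw weight, plus the
#' per-protein trait effect.
#'
#' @param truth The `truth` element of a `pwas_sim_proteome`.
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  rows <- purrr::imap(truth$causal_variants, function(ids, pid) {
    tibble(protein_id = pid, variant_id = ids,
           weight_raw = truth$weights_raw[[pid]],
           gamma = truth$gamma[[pid]])
  })
  readr::write_tsv(list_rbind(rows), path)
  invisible(path)
}
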