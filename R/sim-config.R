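#' Configuration for the synthetic PWAS study generator
#'
#' Bundles every knob of the synthetic-data module: panel sizes, LD structure,
#' cis-heritability of protein abundance, hidden technical factors,
#' detection-dependent missingness, and the protein-to-trait effect
#' distribution. Defaults emulate a tissue-panel PWAS design: 120 genotyped
#' tissue donors, a 500-sample LD reference, and GWAS summary statistics from
#' an effective sample of 50,000.
#'
#' @param seed Integer seed; identical configurations (including the seed)
#'   reproduce bit-identical panels, proteomes and summary statistics.
#' @param n_tissue Number of tissue donors (genotype + proteome + RNA).
#' @param n_ref Number of samples in the external LD reference panel.
#' @param n_gwas Effective GWAS sample size.
#' @param n_loci Number of independent cis loci; one gene/protein per locus.
#' @param snps_per_locus Variants per locus.
#' @param maf_range Range the per-variant minor allele frequency is drawn
#'   from, each endpoint in (0.01, 0.5).
#' @param ld_rho First-order autoregressive correlation between adjacent
#'   variants' latent liabilities, in [0, 0.99).
#' @param h2_cis Variance share of latent protein abundance explained by the
#'   cis genetic score, in [0, 1].
#' @param n_causal_snps Causal cis variants per protein.
#' @param k_hidden Number of hidden technical factors in the proteome.
#' @param factor_share Variance share of latent abundance taken by hidden
#'   factors; `h2_cis + factor_share` must not exceed 1.
#' @param missing_rate Target overall fraction of missing proteome entries;
#'   missingness is intensity-dependent (low abundance is missing more often).
#' @param prop_causal_proteins Fraction of proteins with a nonzero effect on
#'   the trait.
#' @param gamma_sd Standard deviation of the protein-to-trait effects (per SD
#'   of genetically predicted abundance, on the liability scale).
#' @param imp_r2_range Range of per-variant imputation-quality tags; dosage
#'   noise is calibrated so the squared correlation between the dosage and the
#'   underlying hard genotype equals the tag.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_loci = 4, snps_per_locus = 6)
#' cfg$n_tissue
sim_config <- function(seed = 1L,
                       n_tissue = 120L,
                       n_ref = 500L,
                       n_gwas = 50000L,
                       n_loci = 20L,
                       snps_per_locus = 20L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.7,
                       h2_cis = 0.3,
                       n_causal_snps = 2L,
                       k_hidden = 5L,
                       factor_share = 0.2,
                       missing_rate = 0.1,
                       prop_causal_proteins = 0.2,
                       gamma_sd = 0.05,
                       imp_r2_range = c(0.8, 1)) {
  counts <- c(n_tissue = n_tissue, n_ref = n_ref, n_gwas = n_gwas,
              n_loci = n_loci, snps_per_locus = snps_per_locus)
  if (any(counts < 1)) {
    abort(paste0("All counts must be >= 1; offending: ",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (length(maf_range) != 2 || diff(maf_range) < 0 ||
      maf_range[1] <= 0.01 - 1e-12 || maf_range[2] > 0.5) {
    abort("`maf_range` must be an ordered pair inside (0.01, 0.5].")
  }
  if (ld_rho < 0 || ld_rho >= 0.99) {
    abort("`ld_rho` must lie in [0, 0.99): larger values give a near-singular LD matrix.")
  }
  if (h2_cis < 0 || h2_cis > 1) abort("`h2_cis` must lie in [0, 1].")
  if (h2_cis + factor_share > 1) {
    abort("`h2_cis + factor_share` exceeds 1: latent abundance variance cannot be filled.")
  }
  if (n_causal_snps < 1 || n_causal_snps > snps_per_locus) {
    abort("`n_causal_snps` must lie in [1, snps_per_locus].")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must lie in [0, 1).")
  if (prop_causal_proteins < 0 || prop_causal_proteins > 1) {
    abort("`prop_causal_proteins` must lie in [0, 1].")
  }
  if (length(imp_r2_range) != 2 || diff(imp_r2_range) < 0 ||
      imp_r2_range[1] <= 0 || imp_r2_range[2] > 1) {
    abort("`imp_r2_range` must be an ordered pair in (0, 1].")
  }
  structure(list(
    seed = as.integer(seed), n_tissue = as.integer(n_tissue),
    n_ref = as.integer(n_ref), n_gwas = as.integer(n_gwas),
    n_loci = as.integer(n_loci), snps_per_locus = as.integer(snps_per_locus),
    maf_range = maf_range, ld_rho = ld_rho, h2_cis = h2_cis,
    n_causal_snps = as.integer(n_causal_snps), k_hidden = as.integer(k_hidden),
    factor_share = factor_share, missing_rate = missing_rate,
    prop_causal_proteins = prop_causal_proteins, gamma_sd = gamma_sd,
    imp_r2_range = imp_r2_range
  ), class = "sim_config")
}
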