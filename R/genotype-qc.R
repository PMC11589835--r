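# Variant/sample quality control and GWAS allele harmonization.

#' QC thresholds for genotype filtering
#'
#' Defaults are the conventional array-QC values: variant and sample call
#' rate >= 95%, minor allele frequency strictly above 5%, Hardy-Weinberg
#' P >= 1e-6, imputation R^2 >= 0.8, and allele-frequency agreement with an
#' external reference within 4 binomial standard errors.
#'
#' @param variant_call_rate_min,sample_call_rate_min Minimum call rates.
#' @param maf_min MAF threshold (variants kept iff MAF strictly greater).
#' @param hwe_p_min Hardy-Weinberg p-value threshold (kept iff p >= value).
#' @param imp_r2_min Imputation quality threshold (kept iff R^2 >= value).
#' @param af_dev_sd Allowed deviation from reference frequency, in binomial
#'   standard errors.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.95,
                          sample_call_rate_min = 0.95,
                          maf_min = 0.05,
                          hwe_p_min = 1e-6,
                          imp_r2_min = 0.8,
                          af_dev_sd = 4) {
  vals <- c(variant_call_rate_min, sample_call_rate_min, maf_min,
            hwe_p_min, imp_r2_min)
  if (any(vals < 0 | vals > 1) || af_dev_sd <= 0) {
    abort("QC thresholds must lie in [0, 1] (af_dev_sd > 0).")
  }
  structure(list(variant_call_rate_min = variant_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 imp_r2_min = imp_r2_min, af_dev_sd = af_dev_sd),
            class = "qc_thresholds")
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' Hardy-Weinberg expectations at the sample allele frequency. Monomorphic
#' variants return p = 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (from hard calls).
#' @return Two-sided p-value.
#' @export
#' @examples
#' hwe_chi2_test(30, 60, 30)   # exact HWE proportions -> p = 1
hwe_chi2_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n <= 0) abort("Total genotype count must be positive.")
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n_hom_ref, n_het, n_hom_alt) - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

qc_stage_row <- function(stage, removed, retained) {
  tibble(stage = stage, n_removed = length(removed), n_retained = retained,
         removed_ids = list(removed))
}

#' Filter variants by call rate, frequency consistency, HWE, MAF and
#' imputation quality
#'
#' Filters run in a fixed order (call rate, reference-frequency consistency,
#' Hardy-Weinberg, MAF, imputation R^2) so removal counts are deterministic.
#' Boundary conventions: MAF must be strictly greater than `maf_min`;
#' imputation R^2 is kept at exactly the threshold (`>=`).
#'
#' @param panel A `genotype_panel`.
#' @param thresholds A [qc_thresholds()].
#' @param ref_freq Optional tibble (`variant_id`, `ref_freq`) of external
#'   reference effect-allele frequencies; the consistency filter is skipped
#'   when absent.
#' @return List with the filtered `panel` and a `report` tibble (class
#'   `qc_report`) itemizing removals per stage.
#' @export
filter_variants <- function(panel, thresholds = qc_thresholds(),
                            ref_freq = NULL) {
  keep <- panel$variants$variant_id
  report <- list()
  dos <- panel$dosages

  present <- colMeans(!is.na(dos))
  drop <- keep[present[keep] < thresholds$variant_call_rate_min]
  keep <- setdiff(keep, drop)
  report$call_rate <- qc_stage_row("call_rate", drop, length(keep))

  freq <- colMeans(dos, na.rm = TRUE) / 2
  if (!is.null(ref_freq)) {
    rf <- setNames(ref_freq$ref_freq, ref_freq$variant_id)[keep]
    n2 <- 2 * nrow(dos)
    se <- sqrt(rf * (1 - rf) / n2)
    bad <- !is.na(rf) & abs(freq[keep] - rf) > thresholds$af_dev_sd * se
    drop <- keep[bad]
  } else {
    drop <- character(0)
  }
  keep <- setdiff(keep, drop)
  report$freq_consistency <- qc_stage_row("freq_consistency", drop, length(keep))

  hard <- round(dos[, keep, drop = FALSE])
  hwe_p <- vapply(seq_along(keep), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    hwe_chi2_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  drop <- keep[hwe_p < thresholds$hwe_p_min]
  keep <- setdiff(keep, drop)
  report$hwe <- qc_stage_row("hwe", drop, length(keep))

  maf <- pmin(freq[keep], 1 - freq[keep])
  drop <- keep[!(maf > thresholds$maf_min)]
  keep <- setdiff(keep, drop)
  report$maf <- qc_stage_row("maf", drop, length(keep))

  r2 <- setNames(panel$variants$imp_r2, panel$variants$variant_id)[keep]
  drop <- keep[!(r2 >= thresholds$imp_r2_min)]
  keep <- setdiff(keep, drop)
  report$imp_r2 <- qc_stage_row("imp_r2", drop, length(keep))

  if (length(keep) == 0) abort("All variants removed by QC filters.")
  out <- subset_panel_variants(panel, keep)
  rep_tbl <- structure(bind_rows(report), class = c("qc_report", class(tibble())))
  list(panel = out, report = rep_tbl)
}

subset_panel_variants <- function(panel, ids) {
  j <- match(ids, panel$variants$variant_id)
  new_genotype_panel(panel$sample_ids, panel$variants[j, , drop = FALSE],
                     panel$dosages[, j, drop = FALSE],
                     if (!is.null(panel$hard)) panel$hard[, j, drop = FALSE])
}

subset_panel_samples <- function(panel, ids) {
  i <- match(ids, panel$sample_ids)
  new_genotype_panel(panel$sample_ids[i], panel$variants,
                     panel$dosages[i, , drop = FALSE],
                     if (!is.null(panel$hard)) panel$hard[i, , drop = FALSE])
}

#' Filter samples by genotype call rate
#'
#' @inheritParams filter_variants
#' @return List with the filtered `panel` and a `report` tibble.
#' @export
filter_samples <- function(panel, thresholds = qc_thresholds()) {
  present <- rowMeans(!is.na(panel$dosages))
  drop <- panel$sample_ids[present < thresholds$sample_call_rate_min]
  keep <- setdiff(panel$sample_ids, drop)
  if (length(keep) == 0) abort("All samples removed by the call-rate filter.")
  rep_tbl <- structure(qc_stage_row("sample_call_rate", drop, length(keep)),
                       class = c("qc_report", class(tibble())))
  list(panel = subset_panel_samples(panel, keep), report = rep_tbl)
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize panel and GWAS alleles
#'
#' Intersects variants between a genotype panel and a GWAS summary table,
#' flips the GWAS effect (beta sign) and frequency where the effect/other
#' alleles are swapped relative to the panel, and drops variants with
#' incompatible allele pairs as well as strand-ambiguous pairs (A/T, C/G)
#' whose minor allele frequency exceeds 0.40 (for which strand cannot be
#' resolved from frequency).
#'
#' @param panel A `genotype_panel`.
#' @param gwas GWAS summary tibble.
#' @return List with the aligned `panel`, harmonized `gwas`, and a `report`
#'   tibble of flips and drops.
#' @export
harmonize_alleles <- function(panel, gwas) {
  if (anyDuplicated(gwas$variant_id) || anyDuplicated(panel$variants$variant_id)) {
    dups <- unique(c(gwas$variant_id[duplicated(gwas$variant_id)],
                     panel$variants$variant_id[duplicated(panel$variants$variant_id)]))
    abort(paste0("Duplicate variant keys: ", paste(head(dups, 5), collapse = ", ")))
  }
  shared <- intersect(panel$variants$variant_id, gwas$variant_id)
  g <- gwas[match(shared, gwas$variant_id), ]
  pv <- panel$variants[match(shared, panel$variants$variant_id), ]

  same <- g$effect_allele == pv$effect_allele & g$other_allele == pv$other_allele
  swapped <- g$effect_allele == pv$other_allele & g$other_allele == pv$effect_allele
  ambiguous <- is_strand_ambiguous(g$effect_allele, g$other_allele) &
    pmin(g$freq, 1 - g$freq) > 0.40
  status <- dplyr::case_when(
    ambiguous ~ "drop_ambiguous",
    same ~ "keep",
    swapped ~ "flip",
    TRUE ~ "drop_incompatible"
  )
  flip <- status == "flip"
  g$beta[flip] <- -g$beta[flip]
  g$freq[flip] <- 1 - g$freq[flip]
  tmp <- g$effect_allele[flip]
  g$effect_allele[flip] <- g$other_allele[flip]
  g$other_allele[flip] <- tmp

  keep <- shared[status %in% c("keep", "flip")]
  if (length(keep) == 0) abort("No variants left after allele harmonization.")
  rep_tbl <- structure(
    tibble(stage = c("flip", "drop_ambiguous", "drop_incompatible", "not_in_gwas"),
           n_removed = c(0L, sum(status == "drop_ambiguous"),
                         sum(status == "drop_incompatible"),
                         n_variants(panel) - length(shared)),
           n_retained = length(keep),
           removed_ids = list(shared[flip], shared[status == "drop_ambiguous"],
                              shared[status == "drop_incompatible"],
                              setdiff(panel$variants$variant_id, shared))),
    class = c("qc_report", class(tibble())))
  list(panel = subset_panel_variants(panel, keep),
       gwas = g[match(keep, g$variant_id), ],
       report = rep_tbl)
}

#' @export
tidy.qc_report <- function(x, ...) {
  as_tibble(x) %>% select("stage", "n_removed", "n_retained")
}
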