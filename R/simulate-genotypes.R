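# Genotype panel simulation: AR(1) latent liabilities thresholded to hard
# genotypes at Hardy-Weinberg proportions, then blurred to dosages whose
# squared correlation with the hard genotype equals a per-variant
# imputation-quality tag.

new_genotype_panel <- function(sample_ids, variants, dosages, hard = NULL) {
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosages = dosages, hard = hard),
            class = "genotype_panel")
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Number of samples / variants in a genotype panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "A", "T", "C", "G"),
                       ncol = 2, byrow = TRUE)

# Variant frame shared by all panels drawn from the same population:
# positions, alleles, true MAF, AR(1) locus membership, imputation-R2 tags.
sim_variant_frame <- function(config) {
  n_var <- config$n_loci * config$snps_per_locus
  locus <- rep(seq_len(config$n_loci), each = config$snps_per_locus)
  chrom <- as.character(((seq_len(config$n_loci) - 1L) %% 22L) + 1L)[locus]
  # loci sit 3 Mb apart so +/- 1 Mb windows never straddle two loci
  base <- (ceiling(seq_len(config$n_loci) / 22L) - 1L) * 3e6 + 1e6
  pos <- base[locus] + (seq_len(config$snps_per_locus) - 1L) * 2000L +
    sample.int(1500L, n_var, replace = TRUE)
  maf <- runif(n_var, config$maf_range[1], config$maf_range[2])
  pair <- allele_pairs[sample.int(4L, n_var, replace = TRUE), , drop = FALSE]
  imp_r2 <- runif(n_var, config$imp_r2_range[1], config$imp_r2_range[2])
  tibble(
    variant_id = sprintf("rs%d_%d", locus,
                         rep(seq_len(config$snps_per_locus), config$n_loci)),
    chrom = chrom, pos = as.integer(pos),
    other_allele = pair[, 1], effect_allele = pair[, 2],
    effect_allele_freq = maf, imp_r2 = imp_r2,
    locus = locus, maf_true = maf
  )
}

# Draw one panel (samples x variants) for a given variant frame.
draw_panel <- function(variants, n, config, prefix = "S") {
  n_var <- nrow(variants)
  dos <- matrix(0, n, n_var)
  hard <- matrix(0L, n, n_var)
  rho <- config$ld_rho
  for (l in unique(variants$locus)) {
    idx <- which(variants$locus == l)
    m <- length(idx)
    z <- matrix(0, n, m)
    z[, 1] <- rnorm(n)
    if (m > 1) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(n)
    }
    for (j in seq_len(m)) {
      p <- variants$maf_true[idx[j]]
      t0 <- qnorm((1 - p)^2)
      t1 <- qnorm((1 - p)^2 + 2 * p * (1 - p))
      g <- (z[, j] > t0) + (z[, j] > t1)
      r2 <- variants$imp_r2[idx[j]]
      vg <- stats::var(g)
      if (vg == 0) vg <- 2 * p * (1 - p)
      eps <- rnorm(n)
      base <- 2 * p + sqrt(r2) * (g - 2 * p)
      k0 <- sqrt((1 - r2) * vg)
      k <- k0
      if (r2 < 1 && stats::sd(g) > 0) {
        # clamping to [0, 2] raises the realized correlation; rescale the
        # noise so the post-clamp squared correlation hits the tag
        f <- function(k) cor(pmin(pmax(base + k * eps, 0), 2), g)^2 - r2
        k <- tryCatch(uniroot(f, c(0, 6 * k0 + 1e-9))$root,
                      error = function(e) k0)
      }
      dos[, idx[j]] <- pmin(pmax(base + k * eps, 0), 2)
      hard[, idx[j]] <- g
    }
  }
  new_genotype_panel(sprintf("%s%04d", prefix, seq_len(n)), variants, dos, hard)
}

# One gene per locus; the gene body sits inside the locus so every locus
# variant falls in the gene's cis window.
sim_gene_annotation <- function(variants) {
  variants %>%
    group_by(.data$locus, .data$chrom) %>%
    summarise(start = min(.data$pos) + 5000L,
              end = min(.data$pos) + 25000L, .groups = "drop") %>%
    mutate(gene_id = sprintf("GENE%03d", .data$locus),
           protein_id = sprintf("PROT%03d", .data$locus),
           strand = "+") %>%
    select("gene_id", "protein_id", "chrom", "start", "end", "strand", "locus") %>%
    arrange(.data$locus)
}

#' Simulate LD-structured genotype panels
#'
#' Generates a tissue panel and an LD reference panel from one synthetic
#' population. Per locus, latent standard-normal liabilities with first-order
#' autoregressive correlation `ld_rho` are thresholded into hard genotypes at
#' Hardy-Weinberg proportions for a minor allele frequency drawn uniformly
#' from `maf_range`; dosages are then perturbed toward `2 * freq` with noise
#' calibrated so that the squared dosage/hard-genotype correlation matches the
#' variant's imputation-quality tag, and clamped to [0, 2].
#'
#' @param config A [sim_config()].
#' @return A list of class `pwas_sim_genotypes` with elements `tissue` and
#'   `reference` (each a `genotype_panel`), `variants` (the shared variant
#'   frame) and `annotation` (one gene/protein per locus).
#' @export
#' @examples
#' sim <- simulate_genotypes(sim_config(seed = 7, n_loci = 2, snps_per_locus = 4))
#' dim(sim$tissue$dosages)
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  variants <- sim_variant_frame(config)
  tissue <- draw_panel(variants, config$n_tissue, config, prefix = "KT")
  reference <- draw_panel(variants, config$n_ref, config, prefix = "RF")
  structure(list(tissue = tissue, reference = reference,
                 variants = variants,
                 annotation = sim_gene_annotation(variants),
                 config = config),
            class = "pwas_sim_genotypes")
}

#' Draw an additional cohort from a simulated population
#'
#' Used by the cohort-mode GWAS generator and by individual-level oracles in
#' tests: a fresh sample of genotypes with the same variant frame (MAF, LD,
#' imputation tags) as an existing simulation.
#'
#' @param sim A `pwas_sim_genotypes` object.
#' @param n Cohort size.
#' @param seed Integer seed for the cohort draw.
#' @return A `genotype_panel`.
#' @export
draw_cohort <- function(sim, n, seed) {
  stopifnot(inherits(sim, "pwas_sim_genotypes"))
  set.seed(as.integer(seed))
  draw_panel(sim$variants, n, sim$config, prefix = "GW")
}
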