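# GWAS summary-statistic simulation. Signal flows from the simulated
# protein-weight vectors: the trait is a quantitative liability equal to the
# gamma-weighted sum of standardized cis genetic scores plus noise.
#
# Two generation modes:
#  * cohort  - an individual-level cohort is drawn and per-variant marginal
#              beta/se come from single-variant least squares (slow, exact);
#  * analytic- per-locus marginal Z vectors are drawn from the standard
#              multivariate-normal model Z ~ N(sqrt(n) R b_std, R) with R the
#              reference dosage correlation (fast, exact null).

# Standardized joint effect vector implied by the truth, per variant,
# using the given panel's dosage standard deviations.
truth_joint_effects <- function(panel, truth, gamma = truth$gamma) {
  b <- setNames(rep(0, n_variants(panel)), panel$variants$variant_id)
  sds <- apply(panel$dosages, 2, sd)
  for (p in names(gamma)) {
    if (gamma[[p]] == 0) next
    ids <- truth$causal_variants[[p]]
    w <- truth$weights_raw[[p]]
    g <- as.vector(panel$dosages[, ids, drop = FALSE] %*% w)
    sg <- sd(g)
    if (sg == 0) next
    b[ids] <- b[ids] + gamma[[p]] * w * sds[ids] / sg
  }
  b
}

chol_psd <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  jitter <- 1e-8
  while (is.null(out) && jitter <= 1e-2) {
    out <- tryCatch(chol(R + diag(jitter, nrow(R))), error = function(e) NULL)
    if (is.null(out)) jitter <- jitter * 10
  }
  if (is.null(out)) abort("LD correlation matrix is not positive definite even after ridge stabilisation.")
  if (jitter > 1e-8) inform(sprintf("LD matrix ridge-stabilised with jitter %g.", jitter))
  out
}

#' Simulate GWAS summary statistics from the synthetic truth
#'
#' @param sim A `pwas_sim_genotypes` object.
#' @param prot A `pwas_sim_proteome` object carrying the truth.
#' @param mode `"analytic"` (multivariate-normal marginal Z given LD) or
#'   `"cohort"` (individual-level cohort with per-variant least squares).
#' @param n_gwas Effective GWAS sample size (defaults to the config value).
#' @param seed Seed for this phenotype's draw.
#' @param gamma Optional named protein-to-trait effect vector overriding the
#'   truth (e.g. all zeros for an extra null phenotype).
#' @return A tibble with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `freq`, `n`. In cohort
#'   mode the cohort trait and dosage matrix are attached as attributes
#'   `"cohort_y"` / `"cohort_panel"` so individual-level oracles can reuse
#'   them.
#' @export
simulate_gwas_sumstats <- function(sim, prot, mode = c("analytic", "cohort"),
                                   n_gwas = sim$config$n_gwas,
                                   seed = sim$config$seed + 2000L,
                                   gamma = prot$truth$gamma) {
  mode <- match.arg(mode)
  ref <- sim$reference
  v <- sim$variants
  if (mode == "cohort") {
    cohort <- draw_cohort(sim, n_gwas, seed = seed)
    set.seed(seed + 1L)
    gshare <- sum(gamma^2)
    g <- rep(0, n_gwas)
    for (p in names(gamma)) {
      if (gamma[[p]] == 0) next
      ids <- prot$truth$causal_variants[[p]]
      w <- prot$truth$weights_raw[[p]]
      sc <- as.vector(cohort$dosages[, ids, drop = FALSE] %*% w)
      g <- g + gamma[[p]] * standardize_or_zero(sc)
    }
    y <- g + rnorm(n_gwas, sd = sqrt(max(1 - gshare, 0.05)))
    xc <- scale(cohort$dosages, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    sxx <- colSums(xc^2)
    beta <- unname(as.vector(crossprod(xc, yc)) / sxx)
    rss <- sum(yc^2) - beta^2 * sxx
    se <- unname(sqrt(rss / (n_gwas - 2) / sxx))
    out <- tibble(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                  effect_allele = v$effect_allele, other_allele = v$other_allele,
                  beta = beta, se = se,
                  freq = colMeans(cohort$dosages) / 2, n = n_gwas)
    attr(out, "cohort_y") <- y
    attr(out, "cohort_panel") <- cohort
    return(out)
  }
  # analytic mode
  set.seed(seed)
  b_std <- truth_joint_effects(ref, prot$truth, gamma)
  sds <- apply(ref$dosages, 2, sd)
  z <- rep(NA_real_, nrow(v))
  for (l in unique(v$locus)) {
    idx <- which(v$locus == l)
    R <- cor(ref$dosages[, idx, drop = FALSE])
    L <- chol_psd(R)
    mu <- sqrt(n_gwas) * as.vector(R %*% b_std[idx])
    z[idx] <- mu + as.vector(t(L) %*% rnorm(length(idx)))
  }
  se <- unname(1 / (sds * sqrt(n_gwas)))
  tibble(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
         effect_allele = v$effect_allele, other_allele = v$other_allele,
         beta = z * se, se = se,
         freq = colMeans(ref$dosages) / 2, n = n_gwas)
}

#' Inject a pure index-variant signal into GWAS summary statistics
#'
#' Adds `R[, index] * z_target` to the locus Z vector, where `R` is the
#' empirical dosage correlation in the supplied reference panel: every
#' apparent association at the locus is then attributable to the index
#' variant through LD. Used to construct conditional-analysis test cases
#' where full attenuation is guaranteed.
#'
#' @param gwas GWAS summary tibble (as from [simulate_gwas_sumstats()]).
#' @param panel Reference `genotype_panel` supplying LD.
#' @param index_variant Variant id receiving the signal.
#' @param z_target Z-score magnitude to inject.
#' @param window Half-width in bp of the locus around the index variant.
#' @return The updated GWAS summary tibble.
#' @export
inject_index_signal <- function(gwas, panel, index_variant, z_target,
                                window = 1e6) {
  if (!index_variant %in% gwas$variant_id || !index_variant %in% panel$variants$variant_id) {
    abort(sprintf("Unknown index variant '%s'.", index_variant))
  }
  if (z_target == 0) return(gwas)
  iv <- gwas[gwas$variant_id == index_variant, ]
  in_locus <- gwas$chrom == iv$chrom & abs(gwas$pos - iv$pos) <= window &
    gwas$variant_id %in% panel$variants$variant_id
  ids <- gwas$variant_id[in_locus]
  r <- as.vector(cor(panel$dosages[, ids, drop = FALSE],
                     panel$dosages[, index_variant]))
  z <- gwas$beta[in_locus] / gwas$se[in_locus] + r * z_target
  gwas$beta[in_locus] <- z * gwas$se[in_locus]
  gwas
}
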