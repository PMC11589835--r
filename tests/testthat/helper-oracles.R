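# Shared fixtures and independent oracles for the test suite.

# P(X < a, Y < b) for standard bivariate normal with correlation rho,
# by 1-D quadrature over x of phi(x) * Phi((b - rho x) / sqrt(1 - rho^2)).
bvn_cdf <- function(a, b, rho) {
  if (is.infinite(a) && a < 0) return(0)
  if (is.infinite(b) && b < 0) return(0)
  f <- function(x) dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2))
  integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Expected correlation of two hard genotypes obtained by thresholding a
# bivariate-normal pair at Hardy-Weinberg cutpoints for the same MAF.
threshold_genotype_cor <- function(rho, maf) {
  t0 <- qnorm((1 - maf)^2)
  t1 <- qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  cuts <- c(-Inf, t0, t1, Inf)
  pr <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      pr[i, j] <- bvn_cdf(cuts[i + 1], cuts[j + 1], rho) -
        bvn_cdf(cuts[i], cuts[j + 1], rho) -
        bvn_cdf(cuts[i + 1], cuts[j], rho) +
        bvn_cdf(cuts[i], cuts[j], rho)
    }
  }
  g <- 0:2
  p1 <- rowSums(pr)
  p2 <- colSums(pr)
  mu1 <- sum(g * p1); mu2 <- sum(g * p2)
  v1 <- sum(g^2 * p1) - mu1^2
  v2 <- sum(g^2 * p2) - mu2^2
  egg <- sum(outer(g, g) * pr)
  (egg - mu1 * mu2) / sqrt(v1 * v2)
}

# Small deterministic simulation reused by several test files.
small_sim <- function(seed = 42, n_loci = 6, snps_per_locus = 8,
                      n_tissue = 120, n_ref = 400, h2_cis = 0.5,
                      ld_rho = 0.6, prop_causal = 0.5, gamma_sd = 0.08,
                      missing_rate = 0.1, imp_r2_range = c(0.9, 1)) {
  cfg <- sim_config(seed = seed, n_loci = n_loci,
                    snps_per_locus = snps_per_locus, n_tissue = n_tissue,
                    n_ref = n_ref, h2_cis = h2_cis, ld_rho = ld_rho,
                    prop_causal_proteins = prop_causal, gamma_sd = gamma_sd,
                    missing_rate = missing_rate, k_hidden = 3,
                    imp_r2_range = imp_r2_range)
  sim <- simulate_genotypes(cfg)
  prot <- simulate_proteome(sim)
  list(cfg = cfg, sim = sim, prot = prot)
}

# Truth-implied model weight table in the model_db layout (per-allele raw
# weights), for oracle tests that bypass training.
truth_weights <- function(sim, prot) {
  ea <- setNames(sim$variants$effect_allele, sim$variants$variant_id)
  purrr::imap(prot$truth$causal_variants, function(ids, pid) {
    tibble::tibble(protein_id = pid, variant_id = ids,
                   effect_allele = unname(ea[ids]),
                   weight = prot$truth$weights_raw[[pid]])
  }) |> purrr::list_rbind()
}

# Wrap a weight table + performance stub as a model_db.
as_model_db <- function(weights) {
  perf <- tibble::tibble(protein_id = unique(weights$protein_id),
                         r_cv = 1, p_cv = 0,
                         n_snps_window = NA_integer_,
                         n_weights = NA_integer_, lambda = NA_real_,
                         retained = TRUE, reason = "retained")
  structure(list(weights = weights, performance = perf,
                 config = list(window = 5e5, alpha = 0.5, seed = 0L)),
            class = "model_db")
}
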