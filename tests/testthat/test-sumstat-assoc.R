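test_that("z_to_p reproduces two-sided normal tails", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(4.13), 3.63e-5, tolerance = 0.005)
  expect_equal(z_to_p(3.33), 8.68e-4, tolerance = 0.005)
  expect_equal(z_to_p(-2), z_to_p(2))
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  # step-up by hand: q_(i) = min_{j >= i} p_(j) * m / j
  expect_equal(bh_fdr(c(0.001, 0.01, 0.03, 0.6)),
               c(0.004, 0.02, 0.04, 0.6), tolerance = 1e-12)
})

test_that("predicted-expression SD matches a per-sample prediction oracle", {
  s <- small_sim(seed = 91, n_loci = 1, snps_per_locus = 5, ld_rho = 0.7)
  ld <- ld_reference(s$sim$reference)
  w <- tibble::tibble(variant_id = s$sim$variants$variant_id,
                      weight = c(0.5, -0.2, 0.1, 0.3, -0.4))
  sp <- predicted_expression_sd(w, ld)
  pred <- as.vector(s$sim$reference$dosages %*% w$weight)
  expect_equal(sp, sd(pred), tolerance = 1e-10)

  # single variant, unit weight -> sigma_p = sigma_s
  w1 <- w[1, ]; w1$weight <- 1
  expect_equal(predicted_expression_sd(w1, ld),
               unname(ld$sigma[w1$variant_id]), tolerance = 1e-12)
})

test_that("the association Z follows the weighted-sum formula on a hand fixture", {
  # three variants with known marginal Z, weights, and reference LD
  set.seed(92)
  n <- 500
  dos <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.2))
  dos[, 2] <- ifelse(runif(n) < 0.4, dos[, 1], dos[, 2])   # induce LD
  colnames(dos) <- c("va", "vb", "vc")
  v <- tibble::tibble(variant_id = colnames(dos), chrom = "1",
                      pos = c(100L, 200L, 300L), other_allele = "A",
                      effect_allele = "G", effect_allele_freq = 0.3, imp_r2 = 1)
  panel <- pwaskit:::new_genotype_panel(sprintf("S%03d", 1:n), v, dos)
  ld <- ld_reference(panel)
  w <- tibble::tibble(variant_id = colnames(dos), weight = c(0.5, -0.2, 0.1))
  zmarg <- c(2, 1, -1)
  se <- c(0.01, 0.02, 0.015)
  gwas <- tibble::tibble(variant_id = colnames(dos), chrom = "1",
                         pos = v$pos, effect_allele = "G", other_allele = "A",
                         beta = zmarg * se, se = se, freq = 0.3, n = 10000)
  out <- spredixcan_z(w, gwas, ld)
  # hand evaluation with explicit arithmetic
  G <- cov(dos)
  sig_p <- sqrt(0.5^2 * G[1, 1] + 0.2^2 * G[2, 2] + 0.1^2 * G[3, 3] +
                2 * (0.5 * -0.2 * G[1, 2] + 0.5 * 0.1 * G[1, 3] +
                     -0.2 * 0.1 * G[2, 3]))
  by_hand <- 0.5 * sd(dos[, 1]) / sig_p * 2 +
    (-0.2) * sd(dos[, 2]) / sig_p * 1 +
    0.1 * sd(dos[, 3]) / sig_p * (-1)
  expect_equal(out$z, by_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * (1 - pnorm(abs(by_hand))), tolerance = 1e-12)

  # single-variant model with w = 1 collapses to the marginal Z
  out1 <- spredixcan_z(tibble::tibble(variant_id = "va", weight = 1), gwas, ld)
  expect_equal(out1$z, 2, tolerance = 1e-12)

  # missing model variants are dropped without renormalization
  out2 <- spredixcan_z(w, gwas[1:2, ], ld)
  expect_equal(out2$n_snps_dropped, 1L)
  sig_p2 <- sqrt(0.5^2 * G[1, 1] + 0.2^2 * G[2, 2] -
                 2 * 0.5 * 0.2 * G[1, 2])
  expect_equal(out2$z, 0.5 * sd(dos[, 1]) / sig_p2 * 2 -
                 0.2 * sd(dos[, 2]) / sig_p2 * 1, tolerance = 1e-12)
  out3 <- spredixcan_z(w, gwas[0, ], ld)
  expect_equal(out3$status, "untestable")
})

test_that("association Z matches individual-level regression on a matched cohort", {
  cfg <- sim_config(seed = 93, n_loci = 110, snps_per_locus = 5,
                    n_tissue = 20, n_ref = 200, n_gwas = 20000, h2_cis = 0.3,
                    prop_causal_proteins = 0.5, gamma_sd = 0.02,
                    missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  prot <- simulate_proteome(sim)
  gwas <- simulate_gwas_sumstats(sim, prot, mode = "cohort", seed = 17)
  y <- attr(gwas, "cohort_y")
  cohort <- attr(gwas, "cohort_panel")
  ld <- ld_reference(cohort)          # LD and sumstats from the same samples
  w <- truth_weights(sim, prot)
  deltas <- purrr::map_dbl(unique(w$protein_id), function(pid) {
    wp <- w[w$protein_id == pid, ]
    zs <- spredixcan_z(wp, gwas, ld)$z
    pred <- as.vector(cohort$dosages[, wp$variant_id, drop = FALSE] %*% wp$weight)
    zi <- unname(summary(lm(y ~ pred))$coefficients[2, 3])
    zs - zi
  })
  expect_equal(length(deltas), 110)
  expect_lt(max(abs(deltas)), 0.05)
})

test_that("Z is invariant to rescaling the weights and flips with their sign", {
  s <- small_sim(seed = 94, n_loci = 2, snps_per_locus = 5, missing_rate = 0)
  gwas <- simulate_gwas_sumstats(s$sim, s$prot, mode = "analytic")
  ld <- ld_reference(s$sim$reference)
  w <- truth_weights(s$sim, s$prot)
  wp <- w[w$protein_id == w$protein_id[1], ]
  z0 <- spredixcan_z(wp, gwas, ld)$z
  for (c_mult in c(3.7, 0.01)) {
    wc <- wp; wc$weight <- wc$weight * c_mult
    expect_equal(spredixcan_z(wc, gwas, ld)$z, z0, tolerance = 1e-10)
  }
  wn <- wp; wn$weight <- -wn$weight
  expect_equal(spredixcan_z(wn, gwas, ld)$z, -z0, tolerance = 1e-10)
})

test_that("novelty annotation uses boundary-inclusive 1 Mb distances", {
  gene <- tibble::tibble(chrom = "5", start = 2e6, end = 2.05e6)
  known <- tibble::tibble(variant_id = c("in_body", "near", "far", "other_chr"),
                          chrom = c("5", "5", "5", "6"),
                          pos = c(2.01e6, 2e6 - 16540, 9e6, 2.02e6))
  out <- annotate_novelty(gene, known)
  expect_false(out$novel)
  expect_equal(out$distance_bp, 0)
  expect_equal(out$nearest_variant, "in_body")

  out2 <- annotate_novelty(gene, known[2, ])
  expect_equal(out2$distance_bp, 16540)
  expect_false(out2$novel)

  # exactly 1 Mb away: novel
  out3 <- annotate_novelty(gene, tibble::tibble(variant_id = "v1", chrom = "5",
                                                pos = 2e6 - 1e6))
  expect_true(out3$novel)
  expect_equal(out3$distance_bp, 1e6)
  # only variants on other chromosomes: infinitely far
  out4 <- annotate_novelty(gene, known[4, ])
  expect_true(out4$novel)
})

test_that("the phenotype scan orders rows deterministically and stratifies FDR", {
  s <- small_sim(seed = 95, n_loci = 5, snps_per_locus = 4, missing_rate = 0)
  ld <- ld_reference(s$sim$reference)
  db <- as_model_db(truth_weights(s$sim, s$prot))
  g1 <- simulate_gwas_sumstats(s$sim, s$prot, mode = "analytic", seed = 1)
  g2 <- simulate_gwas_sumstats(s$sim, s$prot, mode = "analytic", seed = 2)
  out <- run_phenotypes(db, list(overall = g1, er_positive = g2), ld,
                        known = sim_known_variants(s$sim, s$prot),
                        annotation = s$sim$annotation)
  expect_equal(nrow(out), 10)
  expect_equal(out$phenotype, rep(c("er_positive", "overall"), each = 5))
  expect_false(is.unsorted(out$p[out$phenotype == "overall"]))
  # FDR within phenotype equals BH of that phenotype's p-vector
  for (ph in c("overall", "er_positive")) {
    sub <- out[out$phenotype == ph, ]
    expect_equal(sub$q, bh_fdr(sub$p))
  }
  # constructed case where pooled and stratified BH differ
  pA <- c(0.001, 0.04, 0.9)
  pB <- c(0.5, 0.6, 0.7)
  expect_false(isTRUE(all.equal(c(bh_fdr(pA), bh_fdr(pB)),
                                bh_fdr(c(pA, pB))[seq_len(6)])))
  # single model x two phenotypes -> two rows; empty db -> empty table
  db1 <- as_model_db(truth_weights(s$sim, s$prot) %>%
                       dplyr::filter(protein_id == "PROT001"))
  expect_equal(nrow(run_phenotypes(db1, list(a = g1, b = g2), ld)), 2)
  dbe <- as_model_db(truth_weights(s$sim, s$prot)[0, ])
  expect_equal(nrow(run_phenotypes(dbe, list(a = g1), ld)), 0)
})

test_that("association Z is null-calibrated through the full pipeline machinery", {
  # proteins are heritable but none affects the trait
  cfg <- sim_config(seed = 96, n_loci = 60, snps_per_locus = 4, n_tissue = 120,
                    n_ref = 400, h2_cis = 0.5, prop_causal_proteins = 0,
                    missing_rate = 0.05, k_hidden = 3)
  sim <- simulate_genotypes(cfg)
  prot <- simulate_proteome(sim)
  pre <- preprocess_proteome(prot$proteome, sim$tissue, prot$covariates,
                             k_hidden = 3, annotation = prot$annotation)
  db <- build_models(pre$residuals, sim$tissue, prot$annotation, seed = 96)
  ld <- ld_reference(sim$reference)
  gwas_set <- lapply(setNames(1:6, paste0("null", 1:6)), function(i) {
    simulate_gwas_sumstats(sim, prot, mode = "analytic", seed = 960 + i)
  })
  out <- run_phenotypes(db, gwas_set, ld)
  z <- out$z[!is.na(out$z)]
  expect_gt(length(z), 150)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 0.05)
  expect_gt(var(z), 0.8)
  expect_lt(var(z), 1.2)
})
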