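gene_row <- function(chrom = "1", start = 1e6, end = 1.02e6) {
  tibble::tibble(gene_id = "G1", protein_id = "P1", chrom = chrom,
                 start = start, end = end, strand = "+")
}

panel_at <- function(pos, n = 20) {
  v <- tibble::tibble(variant_id = sprintf("v%03d", seq_along(pos)),
                      chrom = "1", pos = as.integer(pos), other_allele = "A",
                      effect_allele = "G", effect_allele_freq = 0.3,
                      imp_r2 = 1)
  pwaskit:::new_genotype_panel(sprintf("S%02d", seq_len(n)), v,
                               matrix(runif(n * length(pos), 0, 2), n))
}

test_that("cis window boundaries are inclusive at exactly 500 kb", {
  gene <- gene_row(start = 1e6, end = 1.02e6)
  panel <- panel_at(c(1e6 - 5e5, 1e6 - 5e5 - 1, 1.02e6 + 5e5, 1.02e6 + 5e5 + 1,
                      1.01e6))
  cis <- select_cis_snps(gene, panel)
  expect_setequal(cis, c("v001", "v003", "v005"))
  # brute-force scan oracle
  brute <- panel$variants$variant_id[
    sapply(panel$variants$pos,
           function(p) p >= gene$start - 5e5 && p <= gene$end + 5e5)]
  expect_setequal(cis, brute)
})

test_that("elastic net shrinks pure noise to zero and approaches OLS at small lambda", {
  set.seed(71)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(n)
  fit <- fit_elastic_net(X, y, lambda = 10)     # far above the data scale
  expect_equal(nrow(fit$weights), 0)

  x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "v1"))
  y1 <- 0.7 * x1[, 1] + rnorm(n, sd = 0.3)
  ols <- unname(coef(lm(y1 ~ x1[, 1]))[2])
  f1 <- fit_elastic_net(x1, y1)
  expect_equal(f1$weights$weight, ols, tolerance = 1e-4)
})

test_that("lasso limit equals soft-thresholded coordinate solutions on orthogonal designs", {
  set.seed(72)
  n <- 200
  # zero-mean orthonormal columns: orthogonality survives centring/scaling
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)))
  X <- Q %*% diag(4)
  colnames(X) <- paste0("v", 1:4)
  y <- as.vector(X %*% c(2, -1, 0.5, 0)) + rnorm(n, sd = 0.5)
  lam <- 0.08
  fit <- fit_elastic_net(X, y, alpha = 1, lambda = lam, thresh = 1e-14)
  # coordinate-descent closed form on the internally standardized columns
  Xs <- scale(X)
  yc <- y - mean(y)
  sds <- apply(X, 2, sd)
  expected <- vapply(1:4, function(j) {
    b <- mean(Xs[, j] * yc)
    s <- sign(b) * max(abs(b) - lam, 0) / mean(Xs[, j]^2)
    s / sds[j]
  }, numeric(1))
  got <- setNames(rep(0, 4), paste0("v", 1:4))
  got[fit$weights$variant_id] <- fit$weights$weight
  expect_equal(unname(got), expected, tolerance = 1e-6)
})

test_that("cross-validated performance detects perfect signal and is deterministic", {
  set.seed(73)
  n <- 60
  X <- matrix(runif(n * 4, 0, 2), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- X[, 2]
  cv <- cross_validated_performance(X, y, seed = 5)
  expect_gt(cv$r, 0.99)
  expect_lt(cv$p, 1e-10)
  cv2 <- cross_validated_performance(X, y, seed = 5)
  expect_identical(cv[c("r", "p")], cv2[c("r", "p")])
  cv3 <- cross_validated_performance(X, y, seed = 6)
  expect_false(identical(cv$predictions, cv3$predictions))
})

test_that("cross-validated p-values are calibrated under the null", {
  set.seed(74)
  n <- 50
  hits <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    X <- matrix(runif(n * 3, 0, 2), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
    y <- rnorm(n)
    cv <- cross_validated_performance(X, y, seed = 1000 + i)
    if (cv$p < 0.05) hits <- hits + 1
  }
  expect_equal(hits / n_rep, 0.05, tolerance = 0.03 / 0.05)
})

test_that("model gate is strict and bookkeeping reconciles", {
  s <- small_sim(seed = 75, n_loci = 12, snps_per_locus = 5, h2_cis = 0.45,
                 missing_rate = 0)
  res <- residualize(log2_transform(s$prot$proteome),
                     data.frame(age = s$prot$covariates$age))
  db <- build_models(res, s$sim$tissue, s$sim$annotation, seed = 75)
  perf <- db$performance
  expect_equal(nrow(perf), 12)
  expect_true(all(perf$r_cv[perf$retained] > 0.1))
  expect_true(all(perf$p_cv[perf$retained] < 0.05))
  expect_true(all(!perf$retained | perf$n_weights > 0))
  expect_equal(sum(perf$retained) + sum(!perf$retained), 12)
  # every stored weight variant lies in its protein's cis window
  for (pid in unique(db$weights$protein_id)) {
    gene <- s$sim$annotation[s$sim$annotation$protein_id == pid, ]
    cis <- select_cis_snps(gene, s$sim$tissue)
    expect_true(all(db$weights$variant_id[db$weights$protein_id == pid] %in% cis))
  }
  expect_equal(glance(db)$n_retained, sum(perf$retained))
  expect_gt(nrow(tidy(db)), 0)
})

test_that("retention increases with cis-heritability", {
  fracs <- purrr::map_dbl(c(0, 0.45), function(h2) {
    s <- small_sim(seed = 76, n_loci = 25, snps_per_locus = 4, h2_cis = h2,
                   missing_rate = 0)
    res <- residualize(log2_transform(s$prot$proteome),
                       data.frame(age = s$prot$covariates$age))
    db <- build_models(res, s$sim$tissue, s$sim$annotation, seed = 76)
    mean(db$performance$retained)
  })
  expect_lt(fracs[1], 0.2)
  expect_gt(fracs[2], fracs[1])
})

test_that("flipping a variant's allele labels flips its weight and preserves predictions", {
  s <- small_sim(seed = 77, n_loci = 1, snps_per_locus = 5, h2_cis = 0.6,
                 missing_rate = 0, n_tissue = 100)
  res <- residualize(log2_transform(s$prot$proteome),
                     data.frame(age = s$prot$covariates$age))
  y <- res[1, ]
  X <- s$sim$tissue$dosages
  fit <- fit_elastic_net(X, y, seed = 3)
  expect_gt(nrow(fit$weights), 0)
  flip_id <- fit$weights$variant_id[1]
  X2 <- X
  X2[, flip_id] <- 2 - X2[, flip_id]
  fit2 <- fit_elastic_net(X2, y, seed = 3)
  w1 <- setNames(fit$weights$weight, fit$weights$variant_id)
  w2 <- setNames(fit2$weights$weight, fit2$weights$variant_id)
  expect_setequal(names(w1), names(w2))
  expect_equal(w2[[flip_id]], -w1[[flip_id]], tolerance = 1e-8)
  pred1 <- as.vector(X[, names(w1), drop = FALSE] %*% w1)
  pred2 <- as.vector(X2[, names(w1), drop = FALSE] %*% w2[names(w1)])
  expect_equal(pred1 - mean(pred1), pred2 - mean(pred2), tolerance = 1e-8)
})

test_that("causal variants are recovered in most strongly heritable proteins", {
  n_hit <- 0
  n_prot <- 0
  for (seed in 81:82) {
    s <- small_sim(seed = seed, n_loci = 30, snps_per_locus = 4, h2_cis = 0.5,
                   missing_rate = 0)
    cfg2 <- s$cfg
    res <- residualize(log2_transform(s$prot$proteome),
                       data.frame(age = s$prot$covariates$age))
    db <- build_models(res, s$sim$tissue, s$sim$annotation, seed = seed)
    for (pid in unique(db$weights$protein_id)) {
      n_prot <- n_prot + 1
      got <- db$weights$variant_id[db$weights$protein_id == pid]
      truth <- s$prot$truth$causal_variants[[pid]]
      if (any(truth %in% got)) n_hit <- n_hit + 1
    }
  }
  expect_gt(n_prot, 30)
  expect_gte(n_hit / n_prot, 0.7)
})
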