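# Proteome, RNA and covariate simulation with recorded ground truth.
#
# Latent log2 abundance of each protein decomposes as
#   sqrt(h2_cis) * (standardized cis genetic score)
#   + sqrt(factor_share) * (standardized hidden-factor term)
#   + independent noise filling the variance to 1.
# Reported intensity is 2^(latent + protein baseline); missingness is
# intensity-dependent (a logistic left-censoring flavour emulating MS
# detection limits) with overall rate calibrated to `missing_rate`.

standardize_or_zero <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate a proteome (and matched RNA) with known ground truth
#'
#' @param sim A `pwas_sim_genotypes` object from [simulate_genotypes()].
#' @param config The same [sim_config()] used to build `sim` (defaults to the
#'   one stored in `sim`).
#' @return A list of class `pwas_sim_proteome`:
#'   \describe{
#'     \item{proteome}{proteins x samples intensity matrix with `NA` for
#'       entries below the detection mechanism.}
#'     \item{rna}{genes x samples expression matrix sharing the latent cis
#'       signal, with a per-gene protein/RNA correlation recorded in truth.}
#'     \item{covariates}{tibble with per-sample `age`.}
#'     \item{truth}{list with per-protein causal variant ids, raw and
#'       dosage-scale weights, trait effects `gamma`, hidden-factor loadings
#'       and scores, baselines and the protein/RNA latent correlations.}
#'   }
#' @export
simulate_proteome <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "pwas_sim_genotypes"))
  panel <- sim$tissue
  ann <- sim$annotation
  n <- n_samples(panel)
  n_prot <- nrow(ann)
  h2 <- config$h2_cis
  fs <- config$factor_share
  if (h2 + fs > 1) abort("h2_cis + factor_share > 1: cannot fill variance to 1.")
  set.seed(config$seed + 1000L)

  k <- config$k_hidden
  fac_scores <- matrix(rnorm(n * k), n, k)          # per-sample factor scores
  loadings <- matrix(rnorm(n_prot * k), n_prot, k)  # per-protein loadings

  causal <- sample.int(n_prot, size = round(config$prop_causal_proteins * n_prot))
  gamma <- rep(0, n_prot)
  gamma[causal] <- rnorm(length(causal), sd = config$gamma_sd)

  latent <- matrix(0, n_prot, n)
  rna_latent <- matrix(0, n_prot, n)
  baseline <- rnorm(n_prot, mean = 20, sd = 2)
  rho_pr <- runif(n_prot, -0.2, 0.7)   # protein/RNA latent correlation
  causal_ids <- vector("list", n_prot)
  weights_raw <- vector("list", n_prot)

  for (p in seq_len(n_prot)) {
    cis <- which(panel$variants$locus == ann$locus[p])
    if (length(cis) < config$n_causal_snps) {
      abort(sprintf("Protein %s has fewer cis variants than n_causal_snps.",
                    ann$protein_id[p]))
    }
    cv <- sort(sample(cis, config$n_causal_snps))
    w <- rnorm(length(cv))
    score <- as.vector(panel$dosages[, cv, drop = FALSE] %*% w)
    g_std <- standardize_or_zero(score)
    f_std <- standardize_or_zero(as.vector(fac_scores %*% loadings[p, ]))
    eps <- rnorm(n)
    latent[p, ] <- sqrt(h2) * g_std + sqrt(fs) * f_std +
      sqrt(max(1 - h2 - fs, 0)) * eps
    rna_latent[p, ] <- rho_pr[p] * latent[p, ] +
      sqrt(1 - rho_pr[p]^2) * rnorm(n)
    causal_ids[[p]] <- panel$variants$variant_id[cv]
    weights_raw[[p]] <- w
  }

  intensity <- 2^(latent + baseline)
  mask <- matrix(FALSE, n_prot, n)
  if (config$missing_rate > 0) {
    slope <- 1.5
    # global intercept so the mean missing probability hits missing_rate
    f <- function(a) mean(plogis(a - slope * latent)) - config$missing_rate
    a <- uniroot(f, c(-30, 30))$root
    mask <- matrix(rbinom(n_prot * n, 1, plogis(a - slope * latent)) == 1,
                   n_prot, n)
  }
  proteome <- intensity
  proteome[mask] <- NA_real_
  dimnames(proteome) <- list(ann$protein_id, panel$sample_ids)
  rna <- 2^(rna_latent + baseline)
  dimnames(rna) <- list(ann$gene_id, panel$sample_ids)

  covariates <- tibble(sample_id = panel$sample_ids,
                       age = round(runif(n, 30, 70)))

  truth <- list(
    protein_id = ann$protein_id,
    causal_variants = setNames(causal_ids, ann$protein_id),
    weights_raw = setNames(weights_raw, ann$protein_id),
    gamma = setNames(gamma, ann$protein_id),
    loadings = loadings, factor_scores = fac_scores,
    baseline = setNames(baseline, ann$protein_id),
    rho_protein_rna = setNames(rho_pr, ann$protein_id),
    latent = latent
  )
  structure(list(proteome = proteome, rna = rna, covariates = covariates,
                 truth = truth, annotation = ann, config = config),
            class = "pwas_sim_proteome")
}

#' Known-risk-variant list implied by the simulation's ground truth
#'
#' For each protein with a nonzero trait effect, its largest-weight causal
#' variant plays the role of a previously reported GWAS index variant; the
#' resulting table drives conditional analysis and novelty annotation in
#' synthetic runs.
#'
#' @param sim A `pwas_sim_genotypes` object.
#' @param prot A `pwas_sim_proteome` object.
#' @return Tibble with `variant_id`, `chrom`, `pos`.
#' @export
sim_known_variants <- function(sim, prot) {
  tr <- prot$truth
  hit <- names(tr$gamma)[tr$gamma != 0]
  ids <- vapply(hit, function(p) {
    w <- tr$weights_raw[[p]]
    tr$causal_variants[[p]][which.max(abs(w))]
  }, character(1))
  sim$variants %>%
    filter(.data$variant_id %in% ids) %>%
    select("variant_id", "chrom", "pos")
}
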