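# End-to-end orchestration: simulate -> qc -> preprocess -> train ->
# associate -> condition -> report, with a run manifest and content-hash
# stage skipping.

#' Pipeline configuration
#'
#' Defaults are the study's canonical thresholds: MAF > 5%, imputation
#' R^2 >= 0.8, cis window 500 kb, model gate R > 0.1 & p < 0.05, FDR < 0.1,
#' conditional independence p < 1e-4, novelty window 1 Mb. Any override is
#' echoed into the run manifest.
#'
#' @param sim A [sim_config()] for the synthetic stage.
#' @param qc A [qc_thresholds()].
#' @param k_hidden Hidden-factor count (default 15).
#' @param n_pcs Genotype PCs (default 3).
#' @param cis_window Cis window half-width in bp (default 500,000).
#' @param fdr_threshold FDR significance threshold (default 0.1).
#' @param conditional_threshold Independence threshold (default 1e-4).
#' @param novelty_window Novelty window in bp (default 1,000,000).
#' @param phenotypes Character vector of phenotype labels; each gets an
#'   independently seeded GWAS draw.
#' @param gwas_mode `"analytic"` or `"cohort"`.
#' @param seed Global seed fanned out to per-stage seeds by fixed offsets.
#' @return List of class `pwas_config`.
#' @export
pwas_config <- function(sim = sim_config(), qc = qc_thresholds(),
                        k_hidden = 15, n_pcs = 3, cis_window = 5e5,
                        fdr_threshold = 0.1, conditional_threshold = 1e-4,
                        novelty_window = 1e6, phenotypes = "overall",
                        gwas_mode = "analytic", seed = sim$seed) {
  structure(list(sim = sim, qc = qc, k_hidden = k_hidden, n_pcs = n_pcs,
                 cis_window = cis_window, fdr_threshold = fdr_threshold,
                 conditional_threshold = conditional_threshold,
                 novelty_window = novelty_window, phenotypes = phenotypes,
                 gwas_mode = gwas_mode, seed = as.integer(seed)),
            class = "pwas_config")
}

run_stage <- function(name, inputs, manifest_env, cache_dir, fn) {
  in_hash <- rlang::hash(inputs)
  cache_file <- if (!is.null(cache_dir)) {
    file.path(cache_dir, paste0(name, ".rds"))
  }
  prev <- manifest_env$previous
  skipped <- FALSE
  t0 <- Sys.time()
  if (!is.null(prev) && name %in% prev$stage &&
      prev$input_hash[prev$stage == name] == in_hash &&
      !is.null(cache_file) && file.exists(cache_file)) {
    out <- readRDS(cache_file)
    skipped <- TRUE
  } else {
    out <- fn()
    if (!is.null(cache_file)) saveRDS(out, cache_file)
  }
  manifest_env$rows[[name]] <- tibble(
    stage = name, input_hash = in_hash, output_hash = rlang::hash(out),
    skipped = skipped,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Run the full synthetic PWAS pipeline
#'
#' Executes simulation, genotype QC + harmonization, proteome preprocessing,
#' cis model training, association across phenotypes, conditional analysis
#' against the simulation's known risk variants, and the protein/RNA
#' correlation report. When `out_dir` is given, stage outputs are cached
#' there and a re-run with unchanged inputs skips completed stages
#' (content hashing of the stage inputs).
#'
#' @param config A [pwas_config()].
#' @param out_dir Optional directory for stage caches and the manifest.
#' @param twas Optional external TWAS table (`gene_id`, `z`, `p`) for the
#'   PWAS/TWAS comparison.
#' @return List of class `pwas_run`: `sim`, `proteome`, `qc`, `preprocess`,
#'   `models`, `associations`, `conditional`, `correlation`, `comparison`
#'   (when `twas` given) and `manifest`.
#' @export
run_pwas_pipeline <- function(config = pwas_config(), out_dir = NULL,
                              twas = NULL) {
  stopifnot(inherits(config, "pwas_config"))
  env <- new.env()
  env$rows <- list()
  env$previous <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    mf <- file.path(out_dir, "manifest.tsv")
    if (file.exists(mf)) {
      env$previous <- readr::read_tsv(mf, show_col_types = FALSE)
    }
  }

  sim <- run_stage("simulate_genotypes", config$sim, env, out_dir,
                   function() simulate_genotypes(config$sim))
  prot <- run_stage("simulate_proteome", list(config$sim, sim$variants), env,
                    out_dir, function() simulate_proteome(sim))
  gwas_raw <- run_stage("simulate_gwas", list(config$sim, config$phenotypes,
                                              config$gwas_mode), env, out_dir,
    function() {
      out <- purrr::imap(setNames(config$phenotypes, config$phenotypes),
        function(ph, i) {
          simulate_gwas_sumstats(sim, prot, mode = config$gwas_mode,
                                 seed = config$seed + 2000L +
                                   match(ph, config$phenotypes))
        })
      out
    })
  known <- sim_known_variants(sim, prot)

  qc <- run_stage("genotype_qc", list(sim$tissue$variants, config$qc), env,
                  out_dir, function() {
    s <- filter_samples(sim$tissue, config$qc)
    v <- filter_variants(s$panel, config$qc)
    h <- harmonize_alleles(v$panel, gwas_raw[[1]])
    list(panel = h$panel,
         gwas = purrr::map(gwas_raw, function(g) {
           harmonize_alleles(v$panel, g)$gwas
         }),
         reports = list(samples = s$report, variants = v$report,
                        harmonization = h$report))
  })

  pre <- run_stage("preprocess", list(dim(prot$proteome), config$k_hidden,
                                      config$n_pcs), env, out_dir, function() {
    preprocess_proteome(prot$proteome, qc$panel, prot$covariates,
                        k_hidden = config$k_hidden, n_pcs = config$n_pcs,
                        annotation = prot$annotation)
  })

  models <- run_stage("train", list(dim(pre$residuals), config$cis_window,
                                    config$seed), env, out_dir, function() {
    build_models(pre$residuals, qc$panel, prot$annotation,
                 window = config$cis_window, seed = config$seed)
  })

  ld <- ld_reference(subset_panel_variants(
    sim$reference, qc$panel$variants$variant_id))

  assoc <- run_stage("associate", list(models$weights, names(qc$gwas)), env,
                     out_dir, function() {
    run_phenotypes(models, qc$gwas, ld, known = known,
                   annotation = prot$annotation,
                   fdr_threshold = config$fdr_threshold,
                   novelty_window = config$novelty_window)
  })

  cond <- run_stage("condition", list(models$weights, known), env, out_dir,
                    function() {
    g <- qc$gwas[[1]]
    gc <- conditional_sumstats(g, ld, known, window = config$novelty_window)
    conditional_assoc(models, g, gc, ld, known = known,
                      threshold = config$conditional_threshold,
                      phenotype = names(qc$gwas)[1])
  })

  corr <- run_stage("report_correlation", dim(prot$proteome), env, out_dir,
                    function() {
    protein_rna_correlation(prot$proteome, prot$rna, prot$annotation)
  })

  comparison <- NULL
  if (!is.null(twas)) {
    comparison <- compare_pwas_twas(
      assoc %>% filter(.data$phenotype == names(qc$gwas)[1]),
      twas, prot$annotation)
  }

  manifest <- list_rbind(env$rows) %>%
    mutate(seed = config$seed, .before = 1)
  if (!is.null(out_dir)) {
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  structure(list(sim = sim, proteome = prot, qc = qc, preprocess = pre,
                 models = models, ld = ld, associations = assoc,
                 conditional = cond, correlation = corr,
                 comparison = comparison, known = known,
                 manifest = manifest, config = config),
            class = "pwas_run")
}

#' @exportS3Method base::print
print.pwas_run <- function(x, ...) {
  cat("<pwas_run>\n")
  print(glance(x$models))
  print(glance(x$associations))
  invisible(x)
}
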