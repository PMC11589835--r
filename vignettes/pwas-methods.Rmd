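---
title: "Methods: tissue PWAS from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue PWAS from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwaskit)
```

## The model

A proteome-wide association study (PWAS) asks whether the *genetically
predicted* abundance of each protein is associated with a trait. The chain
has two statistical halves. In the tissue panel, protein abundance
$y_p$ is modelled as a sparse linear function of cis genotype dosages,

$$\hat y_p = \sum_{s \in \text{cis}(p)} w_{sp} \, x_s,$$

with weights fit by an elastic net ($\alpha = 0.5$) on variants within
500 kb of the gene body. On the trait side, only marginal GWAS summary
statistics $(\hat\beta_s, \mathrm{se}(\hat\beta_s))$ are available, so the
association of $\hat y_p$ with the trait is reconstructed as

$$Z_p \;=\; \sum_{s \in \text{Model}_p} w_{sp}\,
  \frac{\hat\sigma_s}{\hat\sigma_p}\,
  \frac{\hat\beta_s}{\mathrm{se}(\hat\beta_s)},$$

where $\hat\sigma_s$ is the dosage standard deviation of variant $s$ and
$\hat\sigma_p = \sqrt{w^\top \Gamma w}$ the standard deviation of the
predicted abundance, both estimated from an LD reference panel ($\Gamma$ is
restricted to each model's own variants). $Z_p$ is the large-sample
equivalent of regressing the trait on $\hat y_p$ in the GWAS cohort; its
two-sided normal $p$-values are Benjamini–Hochberg adjusted within each
phenotype and called significant at FDR < 0.1.

Assumptions worth keeping in mind: effects are additive and linear in
dosage; the LD reference matches the GWAS population; model weights are
estimated independently of the GWAS; and marginal effects are small enough
that $\hat\beta_s/\mathrm{se}$ behaves like a standard normal score. The
statistic consumes only $\beta/\mathrm{se}$, so it is indifferent to whether
the GWAS trait is quantitative or a case-control log-odds scale — which is
why the synthetic trait can be a quantitative liability.

## Conditional analysis

To ask whether a protein association merely tags a known risk variant, the
marginal Z scores of all variants within ±1 Mb of known index variants are
replaced by their conditional values given the index set $C$:

$$z_{s\mid C} = \frac{z_s - R_{sC} R_{CC}^{-1} z_C}
  {\sqrt{1 - R_{sC} R_{CC}^{-1} R_{Cs}}},$$

with $R$ the reference LD correlation. This is the standardized-Z form of
summary-statistics conditional analysis (the GCTA-COJO family); we hold
$\mathrm{se}$ fixed and rebuild $\beta = z_{s|C}\,\mathrm{se}$ rather than
re-deriving allele-count algebra with effective sample sizes, because the
downstream statistic consumes only $\beta/\mathrm{se}$, and this form is
exactly testable against a joint-regression oracle on individual-level
data (agreement to |Δz| < 0.1 at cohort size 20,000 in the test suite; the
observed deviation is ~4×10⁻⁴). Index variants correlated at |r| > 0.9
within $C$ are pruned (keeping the smallest p) before inversion; a variant
whose residual variance $1 - R_{sC}R_{CC}^{-1}R_{Cs}$ falls below 0.01 is
flagged "fully explained" and set to zero. Overlapping ±1 Mb windows are
merged and conditioned jointly. An association is declared independent of
known signals when its conditional $p < 10^{-4}$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| detection filter | 0.80 | minimum fraction of samples a protein is detected in (boundary inclusive) |
| cis window | 500,000 bp | half-width around the gene body, boundaries inclusive |
| elastic-net α | 0.5 | L1/L2 mix; λ by 5-fold CV, minimum-MSE rule |
| model gate | R > 0.1, p < 0.05 | both strict, on pooled out-of-fold predictions |
| hidden factors k | 15 | proteome PCs used as covariates |
| genotype PCs | 3 | ancestry covariates |
| MAF filter | > 0.05 | strict inequality |
| imputation R² | ≥ 0.8 | boundary inclusive |
| HWE p | ≥ 1e−6 | 1-df chi-square on rounded hard calls |
| FDR threshold | 0.1 | BH, within phenotype |
| conditional threshold | 1e−4 | independence call |
| novelty window | 1,000,000 bp | "novel locus" iff every same-chromosome known variant is at least this far (boundary inclusive) |

Design choices where the convention was genuinely open:

* **Performance R pools out-of-fold predictions** across the five folds and
  takes one Pearson correlation (with the df = n − 2 t-test), rather than
  averaging per-fold correlations: pooling yields a single well-defined p
  and matches the PredictDB convention.
* **λ uses the minimum-MSE rule**, not the 1-SE rule, maximizing model
  yield; deployed weights are refit on all samples after gating.
* **Hidden factors are principal components** of the median-imputed,
  standardized proteome. A variational-Bayes factor model would serve the
  same role; PCs are the standard, hyperparameter-free substitute, and
  `sweep_hidden_factors()` reproduces the usual factor-count selection
  curve (model yield vs k over {5, 10, 15, 20, 25}).
* **Inverse-normal transform** uses the rankit offset $(r - 0.5)/n$ with
  average ranks for ties — the common eQTL convention.
* **Quantile normalization is across samples** (every complete sample ends
  with the identical sorted value vector), applied before the per-protein
  inverse-normal transform, in that order.
* **Missing model variants in a GWAS are dropped without renormalizing**
  the remaining weights, and the drop count is reported per association.
* **Strand-ambiguous variants** (A/T, C/G) are dropped during harmonization
  only when MAF > 0.40, where frequency cannot resolve strand.
* **Allele-frequency consistency** is a ±4 binomial-SE band around the
  reference frequency: an explicit, testable form of an "outlying
  frequency" filter.
* **Filter order is fixed** (call rate → frequency consistency → HWE →
  MAF → imputation R²) because per-stage removal counts depend on order.

## What the synthetic-data generator emulates

`simulate_genotypes()` builds loci of adjacent variants whose latent
liabilities follow a first-order autoregressive correlation `ld_rho`,
thresholded into hard genotypes at Hardy–Weinberg proportions for MAFs
drawn from `maf_range`. Imputation is emulated, not performed: each variant
carries an R² tag, and dosage noise toward $2f$ is calibrated — by root
finding on the post-clamping correlation — so that the squared correlation
between dosage and hard genotype equals the tag exactly. Separate draws
from the same population yield the tissue panel (default n = 120, the
typical size of a genotyped tissue-proteome panel), an LD reference
(n = 500), and, in cohort mode, a GWAS cohort.

`simulate_proteome()` composes latent log2 abundance from a standardized
cis genetic score (variance `h2_cis`), a shared hidden-factor term
(variance `factor_share`, default 0.2, emulating batch/technical
structure), and independent noise filling the variance to 1; intensity is
$2^{\text{latent} + \text{baseline}}$ with baselines ~ N(20, 2) on the
log2 scale, typical of MS reporter intensities. Missingness is logistic in
latent abundance (slope 1.5, intercept solved so the overall rate hits
`missing_rate`) — a left-censoring mechanism mirroring detection limits,
which is exactly why the 80% detection filter exists. A matched RNA matrix
shares each protein's latent signal with a per-gene correlation drawn from
U(−0.2, 0.7), spanning the negative-to-moderate range protein/RNA
correlations take in tissue data. Trait effects $\gamma_p$ are nonzero for
`prop_causal_proteins` of proteins, drawn N(0, `gamma_sd`²) with
`gamma_sd` = 0.05 per SD of genetic score — effect sizes that put
association Z scores in the single digits at GWAS sample size 50,000,
the realistic regime.

`simulate_gwas_sumstats()` has two modes. *Cohort* mode draws an
individual-level cohort, builds the quantitative liability, and computes
per-variant least-squares beta/se — slow but exactly the data-generating
process the summary statistic approximates. *Analytic* mode draws each
locus' marginal Z vector from $N(\sqrt{n}\,R\,b, R)$ with $b$ the
standardized joint effects implied by the truth — fast, with an exact null.
`inject_index_signal()` adds $R_{\cdot j}\,z^\*$ to a locus so that all
apparent signal is attributable to one index variant, the canonical
conditional-analysis test case.

What the generator does **not** emulate: haplotype/recombination-map LD
(AR(1) blocks only), population structure and admixture, genotyping batch
effects, trans-pQTLs, case-control ascertainment, and peptide-level
quantification noise. Passing tests therefore demonstrate the statistical
machinery is correct under its stated model, not that real-data
confounding is handled beyond the covariate adjustments implemented.

## Numerical choices and degenerate inputs

* Monomorphic variants get HWE p = 1 by convention; constant proteins map
  to all-zero INT values with a warning; a constant out-of-fold prediction
  vector scores R = 0, p = 1.
* Zero-variance dosage columns are excluded from standardization and PCA;
  PC and factor signs follow a deterministic convention (largest-magnitude
  loading positive).
* LD matrices that fail Cholesky are ridge-stabilized with escalating
  jitter (from 1e−8), with a message; a singular index block after pruning
  is an error, never silently dropped.
* Predicted-expression variance uses the unbiased (n − 1) covariance;
  σ_p = 0 marks the association "degenerate" and skips it.
* Median imputation of missing proteome entries happens only inside factor
  estimation and residualization, and every imputed cell is counted in the
  returned log — no silent filling.
* Fold assignment, per-protein training seeds, and all simulation draws
  derive from explicit seeds; identical configurations are bit-identical.

## Problem sizes used in the checks

The packaged verification suites run at desk scale, chosen so each check
has adequate Monte-Carlo resolution: the summary-vs-individual oracle uses
110 proteins in a cohort of 20,000 with `gamma_sd` = 0.02 — keeping |Z|
below ~8, the range the method actually reports, where the summary
statistic and the individual-level t statistic agree to O(|Z|³/n) ≈ 0.01
(at much larger |Z| the two estimators diverge by that same higher-order
term, which is a property of the normal approximation, not of the
implementation); null calibration uses 250 proteins × 5 null phenotypes
(≥ 1000 tests); the gate-yield curve uses 150 proteins per heritability
level at n = 120; genotype moment checks use 50,000–100,000 samples. The
heritability sweep and null calibration train real elastic-net models
end-to-end through the preprocessing chain.

## Known limitations

* The conditional statistic is an approximation to full joint estimation:
  se values are held fixed, so very strong index effects that materially
  change residual trait variance are attenuated slightly differently than
  a refit would show.
* With a small LD reference, σ_p and Γ carry sampling noise; the
  association Z inherits it (as in any summary-statistics method).
* The Fisher-z CI for Spearman correlations is validated by coverage
  simulation (95% ± 2% at n = 120), not against any external table; rank
  correlations on ~120 samples have wide intervals, and narrower published
  intervals would imply a different (unstated) resampling scheme.
* Attenuation `1 − |z_adj|/|z_marg|` can exceed [0, 1] slightly under
  noise; it is reported raw, not clipped.
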