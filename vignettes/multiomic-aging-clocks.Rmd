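---
title: "Multi-compartment omic aging clocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment omic aging clocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Proteomic and metabolomic panels measured in several physiological
compartments of the same person — plasma, urine, skeletal muscle — each
carry an imprint of chronological age, but individuals deviate from the
age expectation in ways that are biologically meaningful.  `omicage`
implements the full analysis chain for this setting:

1. quality control of log-scale abundance blocks (limit-of-detection and
   assay-level filters, reference-feature normalization);
2. per-feature, covariate-adjusted cross-sectional age association;
3. a repeated cross-validated elastic-net predictor of chronological age
   per compartment/omic block, with permutation-calibrated model- and
   feature-level significance;
4. conversion of out-of-bag predictions into *aging scores* and
   accelerated/decelerated flags, plus per-compartment composite scores;
5. a Spearman screen of composite scores against clinical covariates; and
6. leave-one-out validation of a fixed signature, with a cross-platform
   feature-intersection utility.

Because cohort data of this kind are rarely public, the package ships a
synthetic cohort generator with known ground truth; every stage of the
chain is tested against that truth.

# The data model

An `OmicsBlock` is a `SummarizedExperiment` with features in rows and
samples in columns, two assays (`abundance`, log scale; `belowLOD`,
logical censoring mask) and a block label such as `plasma_proteomic`.
Abundances are treated as already normalized and log-transformed
(NPX-like for PEA panels, log intensities for metabolomics).  Censored
values keep their reported value by default — the convention of PEA
platforms, which report values below the limit of detection — and
`maskBelowLOD()` switches to the treat-as-missing policy.

# The synthetic cohort generator

Each feature follows

$$x_{bij} = \beta_{0,bj} + \beta_{bj}\,(\mathrm{age}_i + w_b\,\delta_i)
  + \gamma^{sex}_{bj}\,\mathrm{sex}_i + \gamma^{BMI}_{bj}\,\mathrm{BMI}_i
  + \varepsilon_{bij},$$

where $\delta_i \sim N(0, \sigma_\delta)$ is a latent biological-age
deviation (years) shared across blocks, $w_b$ the block's loading on it,
and $\varepsilon \sim N(0, \sigma_b)$.  The choices behind this
structure:

* **$\delta$ independent of age.**  Aging scores are defined as
  residuals from the cohort prediction–age line, so the minimal latent
  structure consistent with them is an age-independent deviation.  The
  default $\sigma_\delta$ = 5 years is of the order reported for
  molecular clocks.
* **Demographics.**  Age is drawn from the five strata of a healthy-aging
  cohort design (counts 23/20/18/28/12 over 20–34 / 35–49 / 50–64 /
  65–79 / 80+ at $n$ = 101), uniform within stratum and clipped to
  22–92 years; other cohort sizes reapportion the counts by largest
  remainder.  Sex is male with probability 0.55, race white with
  probability 0.82, BMI $\sim N(25.6, 3)$ truncated to [18, 30]
  (healthy-cohort inclusion caps BMI below 30).
* **Blocks.**  The default layout is six blocks whose feature counts are
  the published panel sizes (1432 / 435 / 2516 / 144 / 1055 / 94)
  divided by 7, and whose cohort-coverage fractions follow the published
  per-block $n$ (muscle proteomics covers about half the cohort).  The
  fraction of age-associated features defaults to the published
  cross-sectional hit rates where available (plasma proteomics
  475/1432 ≈ 0.33, urine proteomics 113/1055 ≈ 0.11) and 0.30
  elsewhere.  Age slopes are half-normal with scale 0.02 log-units/year,
  positive with probability 0.8 (plasma-like over-representation);
  residual SD defaults to 0.5 log units.
* **Censoring.**  Values below each feature's `lodQuantile` marginal
  quantile (default 0.05) are flagged below-LOD.
* **Clinical covariates.**  Hemoglobin, quadriceps strength and usual
  walk speed load negatively on $\delta$; alkaline phosphatase and CRP
  positively; height is coupled to sex and to walk speed but not to
  $\delta$ — the directions expected under accelerated aging, which is
  what the correlate screen's sign checks test.

What the generator does **not** emulate: assay chemistry (PEA/NGS
counts), plate/batch structure, realistic feature–feature correlation
networks beyond the shared latent factor, and longitudinal follow-up
(two visits are emulated as two independent noise draws around a shared
truth).  Passing tests therefore certify the statistical machinery, not
robustness to batch artefacts or network-structured covariance.

# Cross-sectional association

Each feature is fitted by OLS, `abundance ~ age + sex + race + BMI`,
with a two-sided t-test on the age coefficient and Benjamini–Hochberg
adjustment across features of a block.  Covariates constant in a given
cohort draw (common for race in small synthetic cohorts) are dropped
with a warning.  Features with fewer non-missing values than
coefficients + 1 are skipped.  Significance for the "age-associated"
label defaults to BH q < 0.05 but raw p is retained — published
threshold wording is ambiguous between the two, so `classifyAndCount()`
exposes the choice.  P-values are clamped at the smallest positive
double to keep perfect fits (possible in noise-free fixtures) inside
(0, 1].

# The elastic-net clock

For response $y$ (age, years) and standardized features, the elastic net
minimizes $\frac{1}{2n}\lVert y - X\beta \rVert^2 +
\lambda\,(\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
\alpha\lVert\beta\rVert_1)$.  `runCvEnet()` wraps the glmnet solver in
the repeated, permutation-calibrated cross-validation design used for
compartment clocks:

* **Repeated CV.**  Per run, a fresh k-fold partition (default k = 5);
  features are standardized with training-fold statistics only; every
  subject is predicted exactly once per run; out-of-bag (OOB) mean and
  SD aggregate over runs (default 500 runs; desk-scale analyses here use
  10–20).
* **Quality factor.**  QF = Pearson correlation between age and the OOB
  mean, per (α, λ) grid point.  The best model is the grid argmax, ties
  broken toward larger λ then larger α (the sparser model).  The λ path
  is log-spaced over 20 points (12 in the pipeline default) from
  $\lambda_{max}$ (smallest all-zero penalty) down three decades;
  published analyses report only the selected pair, so the grid is a
  package choice.
* **Permutation nulls.**  Per run, `nPerm` replicates (default 125;
  desk-scale 1–25) rerun the identical procedure on a globally permuted
  response with the same folds.  The model empirical p is
  $(1 + \#\{QF_{null} \ge QF\})/(1 + \#null)$ — the +1/+1 correction
  guarantees p > 0.  Note that the p-value is exchangeable-valid at a
  *fixed* grid point; at the QF-argmax it inherits selection optimism,
  which is why the package's calibration tests evaluate a fixed
  mid-path point.
* **Feature metrics.**  Selection frequency = fraction of run × fold
  fits with a nonzero coefficient; the mean coefficient averages over
  the fits where the feature was selected (reported on the
  standardized-feature scale).  Both get empirical p-values against the
  null replicate ensemble (coefficients compared on magnitude).  With
  p < n and small λ the lasso saturates — observed *and* null fits
  select nearly everything, and frequency loses discrimination; this is
  inherent to the statistic, and signature extraction is most meaningful
  in the p > n regime the method targets.
* **Covariates.**  Sex enters every clock as an ordinary penalized
  feature; plain elastic net has no unpenalized-covariate facility, and
  the resulting shrinkage of the sex coefficient is the documented cost.
* **Missing values** are imputed with training-fold means (equivalently:
  standardized, then zeros), and prediction-time imputation reuses
  training means.  Zero-variance features keep zero coefficients.

`extractSignature()` returns the features passing the frequency
empirical-p filter at the best grid point, ordered by frequency, then
coefficient magnitude.

# Aging scores

The aging score is the residual of the OOB predicted age on the cohort
OLS line of prediction versus chronological age.  Residualizing — rather
than the naive predicted-minus-chronological difference — is the
operationalization of "departure from the expected predicted age for
that individual based on the full cohort": it absorbs constant bias and
the regression-to-the-mean compression of penalized clocks, and makes
scores sum to zero exactly.  Scores are then z-transformed per block
over non-missing subjects; |z| > 1.5 flags accelerated (positive) or
decelerated (negative) aging.  Composites average the *z*-scores (not
raw years, so omics with different error scales weigh equally) of a
compartment's available omic blocks.  Concordance matrices use Pearson
correlation on pairwise-complete subjects (Spearman by flag), requiring
at least 3 complete pairs.

# Clinical correlates

Subjects with scores in at least 4 of the 6 blocks enter the screen.
Each compartment composite is Spearman-correlated with each clinical
covariate; for covariates with a declared adjuster (height for
walk-based metrics) a symmetric partial Spearman is used: rank both
variables, residualize each on the ranked adjusters by OLS, Pearson on
the residuals, with the t-approximation p on df reduced by the number of
adjusters.  Ties take average ranks.  No multiple-testing correction is
applied — the screen is exploratory by design and the tier labels
(`(0.05<p<0.10)`, `*`, `**`, `***`) encode raw p.

# Numerical choices and degenerate inputs

* glmnet convergence threshold defaults to 1e-7; the OLS-equivalence
  test tightens it to 1e-14 and checks ridge at λ = 1e-9 against exact
  k-fold OLS within 1e-6.
* Constant response, k > n folds, zero-variance score columns, < 3
  subjects, and empty grids raise immediate errors; constant covariates
  and all-dropped features degrade with warnings.
* All delimited output is written with 17 significant digits, so
  write→read round trips are bit-exact and pipeline reruns under one
  seed are byte-identical (verified by MD5 in the run manifest).
* Every random draw flows from a single integer seed; the RNG state of
  the calling session is restored afterwards.

# Problem sizes used by the test suite

The suite exercises the clock at n = 80–100 subjects with 50–300
features, 6–20 runs and 1–25 permutations per run; null calibration
uses 20 seeded cohorts; FDR control uses 20 pure-null blocks of 2000
features; parameter recovery uses a six-block cohort of 150 features
per block with σ_δ = 5 years and loading 1.  These sizes keep a full
run on one core in the minutes range while leaving every statistic in
its intended regime.

# Known limitations

* The generator's independence of δ from age is an assumption; if real
  deviations grow with age, residual-based scores compress them.
* Sex is penalized inside the clock rather than forced in.
* The permutation model p at the selected grid point is optimistic;
  report it at a fixed point or treat it as descriptive.
* Composite scores average whatever omics are available, so their
  variance differs between subjects with one versus two omics per
  compartment.
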