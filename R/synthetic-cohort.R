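#' Configure one synthetic compartment/omic block
#'
#' Describes how one block of the synthetic cohort is generated.  Each
#' feature's log abundance follows
#' \deqn{x_{ij} = \beta_{0j} + \beta_j (age_i + loading \cdot \delta_i)
#'   + \gamma_{sex,j} sex_i + \gamma_{BMI,j} BMI_i + \epsilon_{ij}}
#' where \eqn{\delta_i} is the subject's latent biological-age deviation
#' (years) shared across blocks.  A fraction \code{fracAgeAssoc} of features
#' carries a nonzero age slope \eqn{\beta_j} (magnitude half-normal with
#' scale \code{effectSd}, positive with probability \code{fracPositive});
#' the rest have \eqn{\beta_j = 0}.
#'
#' @param name block label, \code{"<compartment>_<omic>"}.
#' @param nFeatures number of features (>= 1).
#' @param fracAgeAssoc fraction of features with a true age effect, in [0,1].
#' @param fracPositive fraction of age-associated features whose abundance
#'   increases with age (plasma proteomics in healthy adults runs ~80
#'   percent over-represented).
#' @param effectSd scale (log units per year) of the half-normal slope draw.
#' @param loading weight of the latent deviation \eqn{\delta} in this block.
#' @param noiseSd residual SD (log units).
#' @param sexEffectSd,bmiEffectSd SDs of the per-feature sex and BMI
#'   nuisance coefficients.
#' @param lodQuantile per-feature marginal quantile below which values are
#'   flagged below the limit of detection, in [0,1).
#' @param propSubjects fraction of the cohort measured in this block (the
#'   rest are missing, emulating incomplete compartment coverage).
#' @param beta,beta0 optional explicit per-feature age slopes / intercepts
#'   (length \code{nFeatures}); override the random draw when supplied.
#'
#' @return A classed list of generator settings.
#' @seealso \code{\link{cohortConfig}}, \code{\link{simulateCohort}}
#' @export
blockConfig <- function(name, nFeatures, fracAgeAssoc = 0.3,
                        fracPositive = 0.8, effectSd = 0.02, loading = 1,
                        noiseSd = 0.5, sexEffectSd = 0.1, bmiEffectSd = 0.02,
                        lodQuantile = 0.05, propSubjects = 1,
                        beta = NULL, beta0 = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  nFeatures <- as.integer(nFeatures)
  if (is.na(nFeatures) || nFeatures < 1L) stop("nFeatures must be >= 1")
  for (f in c(fracAgeAssoc, fracPositive, lodQuantile, propSubjects))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (lodQuantile >= 1) stop("lodQuantile must be < 1")
  if (!is.null(beta) && length(beta) != nFeatures)
    stop("beta must have length nFeatures")
  if (!is.null(beta0) && length(beta0) != nFeatures)
    stop("beta0 must have length nFeatures")
  structure(list(name = name, nFeatures = nFeatures,
                 fracAgeAssoc = fracAgeAssoc, fracPositive = fracPositive,
                 effectSd = effectSd, loading = loading, noiseSd = noiseSd,
                 sexEffectSd = sexEffectSd, bmiEffectSd = bmiEffectSd,
                 lodQuantile = lodQuantile, propSubjects = propSubjects,
                 beta = beta, beta0 = beta0),
            class = "blockConfig")
}

#' Default six-block layout
#'
#' Six compartment/omic blocks (plasma, muscle, urine; proteomic and
#' metabolomic each) with feature counts and cohort-coverage fractions
#' proportional to a published healthy-aging multi-omics study design
#' (1432/435/2516/144/1055/94 features at n between 50 and 100), scaled
#' down by \code{scale} for desk-size runs.  The plasma proteomic block
#' defaults to ~33 percent age-associated features and the urine proteomic
#' block to ~11 percent, matching the reported cross-sectional hit rates;
#' the remaining blocks default to 30 percent.
#'
#' @param scale divisor applied to the full-size feature counts (default 7).
#' @return List of \code{\link{blockConfig}} objects.
#' @export
defaultBlockConfigs <- function(scale = 7) {
  full <- c(plasma_proteomic = 1432, plasma_metabolomic = 435,
            muscle_proteomic = 2516, muscle_metabolomic = 144,
            urine_proteomic = 1055, urine_metabolomic = 94)
  nsub <- c(plasma_proteomic = 97, plasma_metabolomic = 100,
            muscle_proteomic = 50, muscle_metabolomic = 88,
            urine_proteomic = 94, urine_metabolomic = 81) / 101
  frac <- c(plasma_proteomic = 475 / 1432, plasma_metabolomic = 0.30,
            muscle_proteomic = 0.30, muscle_metabolomic = 0.30,
            urine_proteomic = 113 / 1055, urine_metabolomic = 0.30)
  lapply(names(full), function(nm)
    blockConfig(nm, nFeatures = max(10L, as.integer(round(full[[nm]] / scale))),
                fracAgeAssoc = frac[[nm]], propSubjects = nsub[[nm]]))
}

#' Configure a synthetic cohort
#'
#' Age is sampled by strata matching the source study's demographic table
#' (bins 20-34, 35-49, 50-64, 65-79, 80+ with counts 23/20/18/28/12 at
#' n = 101), uniform within bin and clipped to \code{ageRange}; other cohort
#' sizes reapportion the bin counts by largest remainder.  Sex is male with
#' probability 0.55, race white with probability 0.82, BMI ~ Normal(25.6, 3)
#' truncated to [18, 30].  The latent biological-age deviation
#' \eqn{\delta_i ~ Normal(0, latentSd)} is drawn independently of age.
#'
#' @param nSubjects cohort size (>= 3; default 101).
#' @param ageRange numeric length-2, inclusive age bounds in years.
#' @param ageBins optional matrix/data.frame with columns \code{low},
#'   \code{high}, \code{count}; counts must sum to \code{nSubjects}.
#'   \code{NULL} (default) uses the demographic-table strata; \code{NA}
#'   samples age uniformly over \code{ageRange}.
#' @param blocks list of \code{\link{blockConfig}}s
#'   (default \code{\link{defaultBlockConfigs}()}).
#' @param latentSd SD of the latent biological-age deviation, years.
#' @param seed integer seed; the cohort is fully reproducible from it.
#'
#' @return A classed list of settings for \code{\link{simulateCohort}}.
#' @export
cohortConfig <- function(nSubjects = 101, ageRange = c(22, 92),
                         ageBins = NULL, blocks = defaultBlockConfigs(),
                         latentSd = 5, seed = 1L) {
  nSubjects <- as.integer(nSubjects)
  if (is.na(nSubjects) || nSubjects < 3L) stop("nSubjects must be >= 3")
  if (length(ageRange) != 2L || ageRange[1L] >= ageRange[2L])
    stop("ageRange must be (low, high) with low < high")
  if (!length(blocks) || !all(vapply(blocks, inherits, logical(1L), "blockConfig")))
    if (length(blocks)) stop("blocks must be a list of blockConfig objects")
  if (is.null(ageBins)) {
    ref <- data.frame(low = c(20, 35, 50, 65, 80),
                      high = c(34, 49, 64, 79, 92),
                      count = c(23, 20, 18, 28, 12))
    ref$count <- .apportion(nSubjects, ref$count)
    ageBins <- ref
  } else if (!identical(ageBins, NA)) {
    ageBins <- as.data.frame(ageBins)
    if (!all(c("low", "high", "count") %in% names(ageBins)))
      stop("ageBins needs columns low, high, count")
    if (any(ageBins$low >= ageBins$high))
      stop("invalid age bin: low must be < high")
    if (sum(ageBins$count) != nSubjects)
      stop("age bin counts must sum to nSubjects")
  }
  if (latentSd < 0) stop("latentSd must be >= 0")
  structure(list(nSubjects = nSubjects, ageRange = ageRange,
                 ageBins = ageBins, blocks = blocks, latentSd = latentSd,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

.truncNorm <- function(n, mean, sd, low, high) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= low & draw <= high
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

.sampleAges <- function(config) {
  lo <- config$ageRange[1L]; hi <- config$ageRange[2L]
  if (identical(config$ageBins, NA))
    return(stats::runif(config$nSubjects, lo, hi))
  bins <- config$ageBins
  unlist(lapply(seq_len(nrow(bins)), function(b)
    stats::runif(bins$count[b], max(lo, bins$low[b]), min(hi, bins$high[b]))))
}

#' Simulate a multi-block cohort with known ground truth
#'
#' Generates subject metadata (age, sex, race, BMI plus clinical
#' covariates), one \linkS4class{OmicsBlock} per configured block, and the
#' generating truth.  Clinical covariates are coupled to the latent
#' deviation \eqn{\delta} with the directions expected under accelerated
#' aging: hemoglobin and quadriceps strength load negatively, alkaline
#' phosphatase and C-reactive protein positively, usual walk speed
#' negatively (and on height, which itself is independent of \eqn{\delta}).
#' Values below each feature's \code{lodQuantile} marginal quantile are
#' flagged in the \code{belowLOD} assay but keep their simulated value
#' (the Olink reporting convention); use \code{\link{maskBelowLOD}} to set
#' them to \code{NA}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A list with elements \code{blocks} (named list of
#'   \linkS4class{OmicsBlock}), \code{metadata} (data.frame keyed by
#'   \code{sample_id}), and \code{truth} (list: \code{delta}, per-block
#'   \code{betaAge} and \code{signalMask}, \code{clinicalLoadings},
#'   \code{clinicalVars}).
#' @examples
#' cfg <- cohortConfig(nSubjects = 30,
#'                     blocks = list(blockConfig("plasma_proteomic", 50)),
#'                     seed = 7)
#' cohort <- simulateCohort(cfg)
#' cohort$blocks$plasma_proteomic
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  .withSeed(config$seed, {
    n <- config$nSubjects
    ids <- sprintf("S%03d", seq_len(n))
    age <- .sampleAges(config)
    sex <- factor(ifelse(stats::runif(n) < 0.55, "male", "female"),
                  levels = c("female", "male"))
    race <- factor(ifelse(stats::runif(n) < 0.82, "white", "other"),
                   levels = c("other", "white"))
    bmi <- .truncNorm(n, 25.6, 3, 18, 30)
    delta <- stats::rnorm(n, 0, config$latentSd)
    names(delta) <- ids
    sexInd <- as.numeric(sex == "male")
    female <- as.numeric(sex == "female")

    # clinical covariates: baseline(age, sex) + loading * delta + noise
    height <- 176 * sexInd + 163 * female + stats::rnorm(n, 0, 6)
    loads <- c(hemoglobin = -0.06, alkaline_phosphatase = 1.2,
               quad_strength = -1.8, walk_speed = -0.012, crp = 0.08,
               height = 0)
    clinical <- data.frame(
      height = height,
      hemoglobin = 15.2 - 1.3 * female - 0.008 * age +
        loads[["hemoglobin"]] * delta + stats::rnorm(n, 0, 0.6),
      alkaline_phosphatase = 65 + 0.15 * age +
        loads[["alkaline_phosphatase"]] * delta + stats::rnorm(n, 0, 10),
      quad_strength = 170 - 25 * female - 0.9 * age +
        loads[["quad_strength"]] * delta + stats::rnorm(n, 0, 15),
      walk_speed = 1.1 - 0.004 * age + 0.004 * (height - 170) +
        loads[["walk_speed"]] * delta + stats::rnorm(n, 0, 0.08),
      crp = pmax(0.05, 1 + 0.01 * age + loads[["crp"]] * delta +
                   stats::rnorm(n, 0, 0.5)))

    metadata <- data.frame(sample_id = ids, age = age, sex = sex,
                           race = race, BMI = bmi, clinical,
                           stringsAsFactors = FALSE)

    blocks <- list()
    betaAge <- list()
    signalMask <- list()
    for (bc in config$blocks) {
      p <- bc$nFeatures
      feat <- sprintf("%s_F%04d", toupper(substr(bc$name, 1L, 2L)), seq_len(p))
      nSig <- round(bc$fracAgeAssoc * p)
      mask <- rep(FALSE, p)
      if (nSig > 0) mask[sample.int(p, nSig)] <- TRUE
      beta <- numeric(p)
      if (nSig > 0) {
        sgn <- ifelse(stats::runif(nSig) < bc$fracPositive, 1, -1)
        beta[mask] <- sgn * abs(stats::rnorm(nSig, 0, bc$effectSd))
      }
      if (!is.null(bc$beta)) {
        beta <- bc$beta
        mask <- beta != 0
      }
      beta0 <- if (!is.null(bc$beta0)) bc$beta0 else stats::rnorm(p, 3, 1)
      gSex <- if (bc$sexEffectSd > 0) stats::rnorm(p, 0, bc$sexEffectSd) else numeric(p)
      gBmi <- if (bc$bmiEffectSd > 0) stats::rnorm(p, 0, bc$bmiEffectSd) else numeric(p)

      keep <- sort(sample.int(n, max(3L, round(bc$propSubjects * n))))
      bioAge <- age[keep] + bc$loading * delta[keep]
      # features x samples
      sig <- outer(beta, bioAge) + beta0 +
        outer(gSex, sexInd[keep]) + outer(gBmi, bmi[keep])
      eps <- if (bc$noiseSd > 0)
        matrix(stats::rnorm(p * length(keep), 0, bc$noiseSd), p) else 0
      x <- sig + eps
      dimnames(x) <- list(feat, ids[keep])
      lod <- matrix(FALSE, p, length(keep), dimnames = dimnames(x))
      if (bc$lodQuantile > 0) {
        thr <- apply(x, 1L, stats::quantile, probs = bc$lodQuantile,
                     names = FALSE)
        lod <- x < thr
      }
      blocks[[bc$name]] <- OmicsBlock(x, lod, block = bc$name)
      names(beta) <- feat; names(mask) <- feat
      betaAge[[bc$name]] <- beta
      signalMask[[bc$name]] <- mask
    }

    truth <- list(delta = delta, betaAge = betaAge, signalMask = signalMask,
                  clinicalLoadings = loads,
                  clinicalVars = names(clinical))
    list(blocks = blocks, metadata = metadata, truth = truth)
  })
}
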