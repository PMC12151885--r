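#' Default end-to-end pipeline configuration
#'
#' Returns the configuration list consumed by \code{\link{runPipeline}},
#' with sections \code{cohort} (synthetic-cohort generation), \code{qc}
#' (LOD filtering), \code{cross_sectional}, \code{enet}, \code{scores} and
#' \code{correlates}.  Values are chosen for a smoke-scale run; the
#' full-protocol values (500 runs, 125 permutations) are impractical
#' outside a batch setting and can be set explicitly.
#'
#' @param nSubjects,blockScale,latentSd cohort size, block feature-count
#'   divisor and latent-deviation SD passed to \code{\link{cohortConfig}}.
#' @param nRuns,nPerm,alphaGrid elastic-net settings.
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(nSubjects = 60, blockScale = 12,
                                  latentSd = 5, nRuns = 20, nPerm = 5,
                                  alphaGrid = c(0.2, 0.8)) {
  list(
    cohort = list(n_subjects = nSubjects, latent_sd = latentSd,
                  block_scale = blockScale, seed = 1L),
    qc = list(max_frac_below = 0.70, lod_to_missing = FALSE),
    cross_sectional = list(covariates = c("sex", "race", "BMI"),
                           q_cut = 0.05, use = "q"),
    enet = list(alpha_grid = alphaGrid, n_lambda = 12, n_runs = nRuns,
                k_folds = 5, n_perm = nPerm),
    scores = list(z_cut = 1.5),
    correlates = list(min_blocks = 4, p_max = 0.10,
                      adjust = list(walk_speed = "height")))
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> LOD filter -> per-feature age association ->
#' elastic-net clock per block -> aging scores, flags and composites ->
#' clinical-correlate screen -> leave-one-out signature validation, and
#' writes every result table plus a run manifest (seed, configuration,
#' versions, and MD5 hashes of all numeric outputs) to \code{outDir}.
#' Reruns with the same seed and configuration produce byte-identical
#' outputs.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or path of a YAML/JSON file with
#'   the same structure; partial configs are merged over the defaults.
#'   Unknown section names are an error.
#' @param outDir output directory, created if needed.
#' @param seed integer; overrides \code{config$cohort$seed} and seeds every
#'   stage.
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, a list with the in-memory results (cohort, per-block
#'   association tables, clock fits, score table, composites, correlate
#'   screen, validation) and the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        seed = NULL, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("cohort", "qc", "cross_sectional", "enet", "scores",
             "correlates")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  if (!is.null(seed)) cfg$cohort$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!overwrite && length(list.files(outDir)))
    stop("output directory not empty (use overwrite = TRUE)")

  cohort <- .stage("simulate", {
    cc <- cohortConfig(
      nSubjects = cfg$cohort$n_subjects,
      blocks = defaultBlockConfigs(scale = cfg$cohort$block_scale),
      latentSd = cfg$cohort$latent_sd,
      seed = cfg$cohort$seed)
    simulateCohort(cc)
  })
  meta <- cohort$metadata

  blocks <- .stage("preprocess", {
    out <- lapply(cohort$blocks, filterLOD,
                  maxFracBelow = cfg$qc$max_frac_below)
    if (isTRUE(cfg$qc$lod_to_missing)) out <- lapply(out, maskBelowLOD)
    out
  })

  xsec <- .stage("cross_sectional", {
    lapply(blocks, fitFeatureLm, metadata = meta,
           covariates = cfg$cross_sectional$covariates)
  })

  clocks <- .stage("clock", {
    res <- list()
    for (i in seq_along(blocks)) {
      blk <- blocks[[i]]
      X <- t(abundance(blk))
      sexInd <- as.numeric(
        meta$sex[match(rownames(X), meta$sample_id)] == "male")
      ec <- enetConfig(alphaGrid = cfg$enet$alpha_grid,
                       nLambda = cfg$enet$n_lambda,
                       nRuns = cfg$enet$n_runs, kFolds = cfg$enet$k_folds,
                       nPerm = cfg$enet$n_perm,
                       seed = (cfg$cohort$seed + 101L * i) %% .Machine$integer.max)
      age <- meta$age[match(rownames(X), meta$sample_id)]
      res[[blockName(blk)]] <-
        runCvEnet(X, age, ec, covariates = cbind(sex_male = sexInd))
    }
    res
  })

  scoreTab <- .stage("scores", {
    ids <- meta$sample_id
    sc <- matrix(NA_real_, length(ids), length(clocks),
                 dimnames = list(ids, names(clocks)))
    for (nm in names(clocks)) {
      ob <- oobPredictions(clocks[[nm]])
      sc[ob$sample_id, nm] <- computeScores(ob$oob_mean, ob$age)
    }
    flagAcceleration(sc, zCut = cfg$scores$z_cut)
  })
  composites <- compositeScores(scoreTab)
  scoreCors <- scoreCorrelationMatrix(scoreTab, level = "block")

  correlates <- .stage("correlates", {
    keep <- filterMinBlocks(scoreTab, minBlocks = cfg$correlates$min_blocks)
    clinVars <- cohort$truth$clinicalVars
    clin <- meta[match(keep, meta$sample_id), c("sample_id", clinVars)]
    screen <- spearmanScreen(composites[keep, , drop = FALSE], clin,
                             adjust = cfg$correlates$adjust)
    list(screen = screen,
         heatmap = heatmapTable(screen, pMax = cfg$correlates$p_max),
         n_subjects = length(keep))
  })

  validation <- .stage("validate", {
    out <- list()
    for (nm in names(clocks)) {
      sig <- extractSignature(clocks[[nm]])
      sig <- sig[sig$feature_id %in% rownames(blocks[[nm]]), , drop = FALSE]
      blk <- blocks[[nm]]
      n <- ncol(blk)
      if (nrow(sig) == 0L || nrow(sig) >= n - 1L) {
        out[[nm]] <- list(signature = sig, r = NA_real_)
        next
      }
      X <- t(abundance(imputeFeatureMeans(blk))[sig$feature_id, ,
                                                drop = FALSE])
      age <- meta$age[match(rownames(X), meta$sample_id)]
      lo <- loocvPredict(X, age)
      out[[nm]] <- list(signature = sig, r = lo$r, p_value = lo$p_value,
                        predictions = lo$predictions)
    }
    out
  })

  # ---- write artifacts -------------------------------------------------
  .writeDataCSV(meta, file.path(outDir, "metadata.csv"))
  for (nm in names(xsec))
    .writeDataCSV(xsec[[nm]], file.path(outDir, paste0("age_assoc_", nm, ".csv")))
  for (nm in names(clocks)) {
    b <- clocks[[nm]]@best
    f <- clocks[[nm]]@fits[[b$alphaIdx]]
    .writeDataCSV(oobPredictions(clocks[[nm]]),
                  file.path(outDir, paste0("oob_", nm, ".csv")))
    .writeDataCSV(data.frame(alpha = b$alpha, lambda = b$lambda,
                             qf = b$qf, model_p = f$modelP[b$lambdaIdx]),
                  file.path(outDir, paste0("model_", nm, ".csv")))
    .writeDataCSV(validation[[nm]]$signature,
                  file.path(outDir, paste0("signature_", nm, ".csv")))
  }
  .writeDataCSV(scoresLongTable(scoreTab), file.path(outDir, "scores.csv"))
  .writeDataCSV(data.frame(sample_id = rownames(composites), composites),
                file.path(outDir, "composite_scores.csv"))
  .writeDataCSV(data.frame(block = rownames(scoreCors$r), scoreCors$r),
                file.path(outDir, "score_correlations.csv"))
  .writeDataCSV(correlates$screen, file.path(outDir, "correlates.csv"))
  .writeDataCSV(correlates$heatmap, file.path(outDir, "correlates_heatmap.csv"))
  val <- data.frame(block = names(validation),
                    n_signature = vapply(validation, function(v)
                      nrow(v$signature), integer(1L)),
                    loocv_r = vapply(validation, function(v)
                      if (is.null(v$r)) NA_real_ else v$r, numeric(1L)))
  .writeDataCSV(val, file.path(outDir, "validation.csv"))

  csvs <- sort(list.files(outDir, pattern = "\\.csv$", full.names = TRUE))
  manifest <- list(seed = cfg$cohort$seed, config = cfg,
                   r_version = R.version.string,
                   package_version = as.character(utils::packageVersion("omicage")),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(csvs)), basename(csvs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, blocks = blocks, crossSectional = xsec,
                 clocks = clocks, scores = scoreTab,
                 composites = composites, scoreCorrelations = scoreCors,
                 correlates = correlates, validation = validation,
                 manifest = manifest))
}
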