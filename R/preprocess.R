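#' Drop features measured mostly below the limit of detection
#'
#' Removes features whose fraction of below-LOD measurements is strictly
#' greater than \code{maxFracBelow} (default 0.70, i.e. a feature with more
#' than 70 percent of samples below LOD is excluded; exactly 70 percent is
#' retained).  The dropped IDs and their below-LOD fractions are recorded in
#' \code{metadata(result)$qc$lodFilter}.
#'
#' @param block an \linkS4class{OmicsBlock}.
#' @param maxFracBelow maximum tolerated below-LOD fraction.
#' @return A filtered \linkS4class{OmicsBlock}; the input is not modified.
#' @export
filterLOD <- function(block, maxFracBelow = 0.70) {
  stopifnot(is(block, "OmicsBlock"))
  frac <- rowMeans(belowLOD(block))
  drop <- frac > maxFracBelow
  report <- data.frame(feature_id = rownames(block),
                       frac_below_lod = unname(frac),
                       dropped = unname(drop))
  out <- block[!drop, ]
  if (all(drop)) warning("all features dropped by the LOD filter")
  metadata(out)$qc$lodFilter <- report
  message(sprintf("filterLOD [%s]: %d -> %d features (%d dropped at > %.0f%% below LOD)",
                  blockName(block), nrow(block), nrow(out), sum(drop),
                  100 * maxFracBelow))
  out
}

#' Exclude assays deviating from negative controls
#'
#' Features whose standardized deviation from the plate negative controls
#' exceeds \code{mean(deviation) + sdCut * sd(deviation)} are removed
#' (default cut 4 SD above the mean, the usual assay-QC rule for
#' PEA panels).  When no control vector is available -- the case for
#' synthetic data, which has no plates -- the block is returned unchanged
#' with a logged notice.
#'
#' @param block an \linkS4class{OmicsBlock}.
#' @param controlDeviation numeric vector of per-feature standardized
#'   deviations, aligned to (or named by) the block's features, or
#'   \code{NULL}.
#' @param sdCut exclusion threshold in control-deviation SD units.
#' @return A filtered \linkS4class{OmicsBlock}.
#' @export
qcExcludeAssays <- function(block, controlDeviation = NULL, sdCut = 4) {
  stopifnot(is(block, "OmicsBlock"))
  if (is.null(controlDeviation)) {
    message(sprintf("qcExcludeAssays [%s]: no control deviations supplied; skipped",
                    blockName(block)))
    return(block)
  }
  if (!is.null(names(controlDeviation)))
    controlDeviation <- controlDeviation[rownames(block)]
  if (length(controlDeviation) != nrow(block) || anyNA(controlDeviation))
    stop("controlDeviation must align with the block's features")
  s <- stats::sd(controlDeviation)
  thr <- mean(controlDeviation) + sdCut * (if (is.na(s)) 0 else s)
  drop <- controlDeviation > thr
  out <- block[!drop, ]
  metadata(out)$qc$assayExclusion <-
    data.frame(feature_id = rownames(block),
               deviation = unname(controlDeviation),
               dropped = unname(drop))
  message(sprintf("qcExcludeAssays [%s]: %d -> %d features (threshold %.3g)",
                  blockName(block), nrow(block), nrow(out), thr))
  out
}

#' Normalize a block against a reference feature
#'
#' Subtracts the reference feature's column (log scale) from every feature
#' and drops the reference from the output.  The canonical use is dividing
#' urinary protein abundances by urinary Cystatin C to cancel per-sample
#' urine dilution: any per-sample constant added to all log abundances
#' cancels exactly.
#'
#' @param block an \linkS4class{OmicsBlock}.
#' @param referenceFeature feature ID of the reference.
#' @return A normalized \linkS4class{OmicsBlock} without the reference row.
#' @export
normalizeByReference <- function(block, referenceFeature) {
  stopifnot(is(block, "OmicsBlock"))
  if (!referenceFeature %in% rownames(block))
    stop("reference feature '", referenceFeature, "' not present in block '",
         blockName(block), "'")
  ref <- abundance(block)[referenceFeature, ]
  if (anyNA(ref)) stop("reference feature '", referenceFeature,
                       "' has missing values")
  out <- block[rownames(block) != referenceFeature, ]
  a <- sweep(abundance(out), 2L, ref, "-")
  SummarizedExperiment::assay(out, "abundance") <- a
  message(sprintf("normalizeByReference [%s]: divided out %s (%d features kept)",
                  blockName(block), referenceFeature, nrow(out)))
  out
}

#' Set below-LOD measurements to missing
#'
#' By default censored values keep their reported value (the Olink
#' convention); this applies the alternative policy of treating them as
#' missing.
#'
#' @param block an \linkS4class{OmicsBlock}.
#' @return The block with masked entries set to \code{NA}.
#' @export
maskBelowLOD <- function(block) {
  stopifnot(is(block, "OmicsBlock"))
  a <- abundance(block)
  a[belowLOD(block)] <- NA_real_
  SummarizedExperiment::assay(block, "abundance") <- a
  block
}

#' Mean-impute missing abundances
#'
#' Replaces each feature's missing values by that feature's mean over the
#' non-missing samples.  Downstream model fits impute within their own
#' training data; this helper is for whole-block operations such as PCA.
#'
#' @param block an \linkS4class{OmicsBlock}.
#' @return The block with no missing abundances.
#' @export
imputeFeatureMeans <- function(block) {
  stopifnot(is(block, "OmicsBlock"))
  a <- abundance(block)
  bad <- is.na(a)
  if (any(bad)) {
    mu <- rowMeans(a, na.rm = TRUE)
    a[bad] <- mu[row(a)[bad]]
    SummarizedExperiment::assay(block, "abundance") <- a
  }
  block
}

#' PCA overview across blocks
#'
#' Stacks the samples of several blocks on their shared feature space,
#' standardizes features (zero mean, unit variance), and returns the first
#' \code{k} principal-component coordinates with block labels, for outlier
#' flagging and compartment-separation plots.  Missing values are
#' mean-imputed per block first.
#'
#' @param blocks list of \linkS4class{OmicsBlock}s (a single block is
#'   allowed).
#' @param k number of components to return (default 3).
#' @return List with \code{embedding} (data.frame: sample_id, block,
#'   PC1..PCk) and \code{varianceFraction} (per-component explained-variance
#'   fractions, non-increasing, summing to <= 1).
#' @export
pcaOverview <- function(blocks, k = 3) {
  if (is(blocks, "OmicsBlock")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L)
  shared <- Reduce(intersect, lapply(blocks, rownames))
  if (!length(shared))
    stop("blocks share no features; cannot stack on a common feature space")
  mats <- lapply(blocks, function(b)
    t(abundance(imputeFeatureMeans(b))[shared, , drop = FALSE]))
  x <- do.call(rbind, mats)
  if (nrow(x) < 2L) stop("need at least 2 samples for PCA")
  labs <- rep(vapply(blocks, blockName, character(1L)),
              vapply(mats, nrow, integer(1L)))
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  emb <- data.frame(sample_id = rownames(x), block = labs,
                    pc$x[, seq_len(k), drop = FALSE], row.names = NULL)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(embedding = emb, varianceFraction = vf)
}
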