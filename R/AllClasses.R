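#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
NULL

#' OmicsBlock: one compartment/omic abundance matrix
#'
#' An \code{OmicsBlock} holds the log-scale relative abundances of one
#' compartment-by-omic "block" (e.g. plasma proteomics) as a
#' \linkS4class{SummarizedExperiment} with features in rows and samples in
#' columns.  Two assays are carried: \code{"abundance"} (numeric, log scale)
#' and \code{"belowLOD"} (logical; \code{TRUE} marks measurements censored at
#' the assay's limit of detection).  The block label and its
#' compartment/omic decomposition live in \code{metadata()}.
#'
#' Values must be finite wherever the below-LOD mask is \code{FALSE};
#' censored entries may be either a reported value (the convention for
#' Olink-style data, which reports values below LOD) or \code{NA} after
#' \code{\link{maskBelowLOD}}.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{OmicsBlock}} (constructor), \code{\link{filterLOD}},
#'   \code{\link{fitFeatureLm}}
#' @name OmicsBlock-class
#' @rdname OmicsBlock-class
#' @exportClass OmicsBlock
setClass("OmicsBlock", contains = "SummarizedExperiment")

.validOmicsBlock <- function(object) {
  msg <- NULL
  an <- assayNames(object)
  if (!all(c("abundance", "belowLOD") %in% an))
    msg <- c(msg, "assays must include 'abundance' and 'belowLOD'")
  else {
    ab <- assay(object, "abundance")
    bl <- assay(object, "belowLOD")
    if (!is.numeric(ab)) msg <- c(msg, "'abundance' must be numeric")
    if (!is.logical(bl)) msg <- c(msg, "'belowLOD' must be logical")
    if (any(is.na(bl))) msg <- c(msg, "'belowLOD' mask must not contain NA")
    bad <- !bl & (is.na(ab) | !is.finite(ab))
    if (is.logical(bl) && any(bad))
      msg <- c(msg, "abundance values must be finite where not below LOD")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature IDs (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs (colnames) must be present and unique")
  if (is.null(metadata(object)$block) || !nzchar(metadata(object)$block))
    msg <- c(msg, "metadata()$block label is required")
  if (is.null(msg)) TRUE else msg
}
setValidity("OmicsBlock", .validOmicsBlock)

#' Construct an OmicsBlock
#'
#' @param abundance numeric matrix of log-scale abundances, features in rows,
#'   samples in columns, with unique dimnames.
#' @param belowLOD optional logical matrix of the same shape flagging
#'   below-limit-of-detection measurements; defaults to all \code{FALSE}.
#' @param block block label, conventionally \code{"<compartment>_<omic>"}.
#' @param compartment,omic the two halves of the block label; parsed from
#'   \code{block} when omitted.
#'
#' @return An \linkS4class{OmicsBlock}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' blk <- OmicsBlock(m, block = "plasma_proteomic")
#' blockName(blk)
#' @export
OmicsBlock <- function(abundance, belowLOD = NULL, block = "block",
                       compartment = NULL, omic = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(belowLOD)) {
    belowLOD <- matrix(FALSE, nrow(abundance), ncol(abundance),
                       dimnames = dimnames(abundance))
  }
  belowLOD <- as.matrix(belowLOD)
  storage.mode(belowLOD) <- "logical"
  if (is.null(compartment) || is.null(omic)) {
    parts <- strsplit(block, "_", fixed = TRUE)[[1L]]
    if (is.null(compartment))
      compartment <- if (length(parts) >= 2L) parts[1L] else block
    if (is.null(omic))
      omic <- if (length(parts) >= 2L) paste(parts[-1L], collapse = "_") else NA_character_
  }
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = abundance, belowLOD = belowLOD))
  metadata(se)$block <- block
  metadata(se)$compartment <- compartment
  metadata(se)$omic <- omic
  new("OmicsBlock", se)
}

#' EnetResult: a cross-validated elastic-net age predictor
#'
#' Holds the full output of \code{\link{runCvEnet}}: for every point of the
#' (alpha, lambda) grid, per-subject out-of-bag predicted age (mean and SD
#' over repeated cross-validation runs), the model quality factor (Pearson
#' correlation of true age with out-of-bag predicted age), the
#' permutation-null quality-factor ensemble and the resulting empirical model
#' p-value, and per-feature selection frequencies and mean nonzero
#' coefficients with their own empirical p-values.
#'
#' @slot alpha numeric vector, the mixing-parameter grid.
#' @slot fits list parallel to \code{alpha}; each element is a list with
#'   components \code{lambda}, \code{qf}, \code{oobMean}, \code{oobSd},
#'   \code{modelP}, \code{nullQf}, \code{featFreq}, \code{featCoef},
#'   \code{featFreqP}, \code{featCoefP}.
#' @slot y numeric, the response (chronological age, years).
#' @slot sampleIDs,featureIDs character identifiers.
#' @slot folds integer matrix (subjects x runs) of fold assignments.
#' @slot best list with the selected \code{alpha} and \code{lambda}
#'   (see \code{\link{selectBest}}).
#' @slot config the \code{\link{enetConfig}} used.
#' @name EnetResult-class
#' @rdname EnetResult-class
#' @exportClass EnetResult
setClass("EnetResult",
         representation(alpha = "numeric", fits = "list", y = "numeric",
                        sampleIDs = "character", featureIDs = "character",
                        folds = "matrix", best = "list", config = "list"))

#' AgingScoreTable: per-subject, per-block aging scores
#'
#' Aging scores measure the departure (in years) of a subject's out-of-bag
#' predicted age from the predicted age expected for their chronological age
#' under the cohort regression line.  After column-wise standardization,
#' |z| > zCut flags accelerated (z positive) or decelerated (z negative)
#' aging; subjects without a measurement in a block are flagged
#' \code{"missing"}.
#'
#' @slot raw numeric matrix, subjects x blocks, raw scores in years.
#' @slot z numeric matrix, column-standardized scores.
#' @slot flags character matrix in
#'   \code{c("accelerated","decelerated","none","missing")}.
#' @slot blockInfo data.frame with columns \code{block}, \code{compartment},
#'   \code{omic}, one row per score column.
#' @slot zCut numeric, the flagging threshold (default 1.5).
#' @name AgingScoreTable-class
#' @rdname AgingScoreTable-class
#' @exportClass AgingScoreTable
setClass("AgingScoreTable",
         representation(raw = "matrix", z = "matrix", flags = "matrix",
                        blockInfo = "data.frame", zCut = "numeric"))

.validAgingScoreTable <- function(object) {
  msg <- NULL
  if (!identical(dim(object@raw), dim(object@z)) ||
      !identical(dim(object@raw), dim(object@flags)))
    msg <- c(msg, "raw, z and flags must share dimensions")
  if (nrow(object@blockInfo) != ncol(object@raw))
    msg <- c(msg, "blockInfo must have one row per score column")
  ok <- object@flags %in% c("accelerated", "decelerated", "none", "missing")
  if (!all(ok)) msg <- c(msg, "invalid flag value")
  if (is.null(msg)) TRUE else msg
}
setValidity("AgingScoreTable", .validAgingScoreTable)
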