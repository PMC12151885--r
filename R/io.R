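# Delimited-text interchange: one CSV matrix per block (rows = samples,
# first column = sample ID, header = feature IDs), an optional sibling
# below-LOD mask, a metadata table keyed by sample ID, and ground-truth
# tables.  Numeric values are written with 17 significant digits so a
# write -> read cycle reproduces the doubles bit for bit.

.writeDataCSV <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) .fmtNum(col) else as.character(col)
  })
  header <- paste(names(df), collapse = ",")
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), path)
}

#' Read / write one omics block as delimited text
#'
#' The on-disk layout is a CSV with samples in rows: the first column holds
#' the sample ID, the header row the feature IDs.  The below-LOD mask is an
#' optional sibling CSV of the same shape holding TRUE/FALSE; when absent,
#' the mask is all \code{FALSE}.
#'
#' @param path path of the abundance CSV.
#' @param maskPath path of the mask CSV (for \code{readBlock}: default
#'   \code{<path minus .csv>_lod.csv} if that file exists, else no mask).
#' @param block,compartment,omic labels passed to \code{\link{OmicsBlock}};
#'   \code{block} defaults to the file name stem.
#' @return \code{readBlock}: an \linkS4class{OmicsBlock}.
#'   \code{writeBlock}: the paths written, invisibly.
#' @export
readBlock <- function(path, maskPath = NULL, block = NULL,
                      compartment = NULL, omic = NULL) {
  if (is.null(block))
    block <- sub("\\.csv$", "", basename(path))
  x <- .readMatrixCSV(path)
  if (is.null(maskPath)) {
    cand <- sub("\\.csv$", "_lod.csv", path)
    if (file.exists(cand)) maskPath <- cand
  }
  mask <- if (!is.null(maskPath)) .readMatrixCSV(maskPath, logical = TRUE)
  if (!is.null(mask) && !identical(dimnames(mask), dimnames(x)))
    stop("mask file does not match the abundance matrix")
  OmicsBlock(x, mask, block = block, compartment = compartment, omic = omic)
}

#' @rdname readBlock
#' @param x an \linkS4class{OmicsBlock} to write.
#' @param writeMask write the mask file even if no value is below LOD.
#' @export
writeBlock <- function(x, path, maskPath = NULL, writeMask = NULL) {
  stopifnot(is(x, "OmicsBlock"))
  .writeMatrixCSV(abundance(x), path)
  if (is.null(writeMask)) writeMask <- any(belowLOD(x))
  if (writeMask) {
    if (is.null(maskPath)) maskPath <- sub("\\.csv$", "_lod.csv", path)
    .writeMatrixCSV(belowLOD(x), maskPath, logical = TRUE)
  }
  invisible(c(path, if (writeMask) maskPath))
}

#' Write / read a full simulated cohort
#'
#' \code{writeCohort} lays a cohort out as one abundance (+ mask) CSV per
#' block, \code{metadata.csv}, and ground-truth tables
#' (\code{truth_delta.csv}, \code{truth_features_<block>.csv},
#' \code{truth_clinical_loadings.csv}).  \code{readCohort} reverses it,
#' re-aligning each block's samples to the metadata order by sample ID, so
#' the round trip is insensitive to row permutations on disk.
#'
#' @param cohort list as returned by \code{\link{simulateCohort}}
#'   (\code{truth} may be absent).
#' @param dir output directory (created if needed).
#' @param overwrite allow clobbering existing files (default FALSE).
#' @return \code{writeCohort}: the directory, invisibly.
#'   \code{readCohort}: a cohort list.
#' @export
writeCohort <- function(cohort, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "metadata.csv"),
             file.path(dir, paste0(names(cohort$blocks), ".csv")))
  hit <- paths[file.exists(paths)]
  if (length(hit) && !overwrite)
    stop("refusing to overwrite existing files: ",
         paste(basename(hit), collapse = ", "))
  if (!length(cohort$blocks))
    warning("no blocks to write; emitting metadata only")
  .writeDataCSV(cohort$metadata, file.path(dir, "metadata.csv"))
  for (nm in names(cohort$blocks))
    writeBlock(cohort$blocks[[nm]], file.path(dir, paste0(nm, ".csv")),
               writeMask = TRUE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    .writeDataCSV(data.frame(sample_id = names(tr$delta),
                             delta = unname(tr$delta)),
                  file.path(dir, "truth_delta.csv"))
    for (nm in names(tr$betaAge))
      .writeDataCSV(data.frame(feature_id = names(tr$betaAge[[nm]]),
                               beta_age = unname(tr$betaAge[[nm]]),
                               signal = unname(tr$signalMask[[nm]])),
                    file.path(dir, paste0("truth_features_", nm, ".csv")))
    .writeDataCSV(data.frame(covariate = names(tr$clinicalLoadings),
                             loading = unname(tr$clinicalLoadings)),
                  file.path(dir, "truth_clinical_loadings.csv"))
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ID in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  if ("sex" %in% names(meta))
    meta$sex <- factor(meta$sex, levels = c("female", "male"))
  if ("race" %in% names(meta))
    meta$race <- factor(meta$race, levels = c("other", "white"))
  files <- list.files(dir, pattern = "\\.csv$")
  bfiles <- setdiff(files, c("metadata.csv",
                             grep("^truth_|_lod\\.csv$", files, value = TRUE)))
  blocks <- list()
  for (f in bfiles) {
    nm <- sub("\\.csv$", "", f)
    blk <- readBlock(file.path(dir, f), block = nm)
    ord <- intersect(meta$sample_id, colnames(blk))
    blocks[[nm]] <- blk[, ord]
  }
  truth <- NULL
  dpath <- file.path(dir, "truth_delta.csv")
  if (file.exists(dpath)) {
    dd <- utils::read.csv(dpath, stringsAsFactors = FALSE)
    delta <- stats::setNames(dd$delta, dd$sample_id)
    betaAge <- list(); signalMask <- list()
    for (nm in names(blocks)) {
      fp <- file.path(dir, paste0("truth_features_", nm, ".csv"))
      if (file.exists(fp)) {
        ft <- utils::read.csv(fp, stringsAsFactors = FALSE)
        betaAge[[nm]] <- stats::setNames(ft$beta_age, ft$feature_id)
        signalMask[[nm]] <- stats::setNames(ft$signal, ft$feature_id)
      }
    }
    cl <- file.path(dir, "truth_clinical_loadings.csv")
    loads <- NULL
    if (file.exists(cl)) {
      lt <- utils::read.csv(cl, stringsAsFactors = FALSE)
      loads <- stats::setNames(lt$loading, lt$covariate)
    }
    truth <- list(delta = delta, betaAge = betaAge, signalMask = signalMask,
                  clinicalLoadings = loads,
                  clinicalVars = intersect(names(loads), names(meta)))
  }
  list(blocks = blocks, metadata = meta, truth = truth)
}
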