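#' @rdname OmicsBlock-class
#' @param x,object an \linkS4class{OmicsBlock}.
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname OmicsBlock-class
#' @export
setGeneric("belowLOD", function(x) standardGeneric("belowLOD"))

#' @rdname OmicsBlock-class
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))

#' @rdname OmicsBlock-class
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))

#' @rdname OmicsBlock-class
#' @export
setGeneric("omicType", function(x) standardGeneric("omicType"))

setMethod("abundance", "OmicsBlock", function(x) assay(x, "abundance"))
setMethod("belowLOD", "OmicsBlock", function(x) assay(x, "belowLOD"))
setMethod("blockName", "OmicsBlock", function(x) metadata(x)$block)
setMethod("compartment", "OmicsBlock", function(x) metadata(x)$compartment)
setMethod("omicType", "OmicsBlock", function(x) metadata(x)$omic)

#' @rdname OmicsBlock-class
setMethod("show", "OmicsBlock", function(object) {
  cat("OmicsBlock '", blockName(object), "' (",
      compartment(object), " / ", omicType(object), ")\n", sep = "")
  cat("  ", nrow(object), " features x ", ncol(object), " samples; ",
      sum(assay(object, "belowLOD")), " values below LOD\n", sep = "")
  invisible(NULL)
})

#' @rdname AgingScoreTable-class
#' @param x,object an \linkS4class{AgingScoreTable}.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname AgingScoreTable-class
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname AgingScoreTable-class
#' @export
setGeneric("flagMatrix", function(x) standardGeneric("flagMatrix"))

#' @rdname AgingScoreTable-class
#' @export
setGeneric("blockInfo", function(x) standardGeneric("blockInfo"))

setMethod("scoreMatrix", "AgingScoreTable", function(x) x@raw)
setMethod("zMatrix", "AgingScoreTable", function(x) x@z)
setMethod("flagMatrix", "AgingScoreTable", function(x) x@flags)
setMethod("blockInfo", "AgingScoreTable", function(x) x@blockInfo)

setMethod("show", "AgingScoreTable", function(object) {
  cat("AgingScoreTable: ", nrow(object@raw), " subjects x ",
      ncol(object@raw), " blocks (|z| > ", object@zCut, " flagged)\n",
      sep = "")
  tab <- table(factor(object@flags,
                      c("accelerated", "decelerated", "none", "missing")))
  cat("  flags:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "EnetResult", function(object) {
  b <- object@best
  cat("EnetResult: ", length(object@y), " subjects, ",
      length(object@featureIDs), " features\n", sep = "")
  cat("  grid: alpha {", paste(object@alpha, collapse = ", "), "}, ",
      length(object@fits[[1L]]$lambda), " lambda values; ",
      ncol(object@folds), " runs x ", object@config$kFolds, "-fold CV, ",
      object@config$nPerm, " permutations/run\n", sep = "")
  if (length(b)) {
    i <- b$alphaIdx; j <- b$lambdaIdx
    cat(sprintf("  best: alpha = %g, lambda = %.4g, QF = %.3f, model p = %.4g\n",
                b$alpha, b$lambda, object@fits[[i]]$qf[j],
                object@fits[[i]]$modelP[j]))
  }
  invisible(NULL)
})
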