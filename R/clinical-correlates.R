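#' Subjects with sufficient block coverage
#'
#' Retains subjects measured (non-missing score) in at least
#' \code{minBlocks} of the blocks -- the study convention of requiring
#' measurements in at least four of the six compartment/omics before
#' screening clinical correlates.
#'
#' @param table an \linkS4class{AgingScoreTable}.
#' @param minBlocks minimum number of non-missing block scores (default 4).
#' @return Character vector of retained subject IDs.
#' @export
filterMinBlocks <- function(table, minBlocks = 4L) {
  stopifnot(is(table, "AgingScoreTable"))
  nOk <- rowSums(!is.na(table@z))
  rownames(table@z)[nOk >= minBlocks]
}

# Spearman correlation with optional symmetric rank-residualization on
# adjustment covariates; p from the t approximation with df reduced by the
# number of adjusters.
.spearmanOne <- function(x, y, adj = NULL) {
  ok <- stats::complete.cases(x, y, adj)
  n <- sum(ok)
  if (n < 5L) return(list(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  nAdj <- 0L
  if (!is.null(adj)) {
    adj <- as.matrix(adj)[ok, , drop = FALSE]
    ra <- apply(adj, 2L, rank)
    nAdj <- ncol(ra)
    Z <- cbind(1, ra)
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
    # a variable fully explained by its adjusters has no partial signal
    if (stats::sd(rx) < 1e-8 * n || stats::sd(ry) < 1e-8 * n)
      return(list(rho = 0, p = 1, n = n))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - nAdj
  if (df < 1L || abs(rho) >= 1) {
    p <- if (abs(rho) >= 1) 0 else NA_real_
  } else {
    tt <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(rho = rho, p = p, n = n)
}

.tierOf <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.10) "(0.05<p<0.10)"
  else ""
}

#' Spearman screen of composite scores against clinical covariates
#'
#' Correlates each compartment's composite aging score with each clinical
#' covariate by Spearman correlation on pairwise-complete subjects.  For
#' covariates listed in \code{adjust} (the study adds height to walking
#' distance/speed metrics), a partial Spearman correlation is used: both
#' variables are rank-transformed, residualized by OLS on the ranked
#' adjusters, and Pearson-correlated, with the t-approximation p-value on
#' df reduced by the number of adjusters.  No multiple-testing correction
#' is applied, matching the exploratory screening design.
#'
#' @param scores numeric matrix, subjects x compartments (e.g. from
#'   \code{\link{compositeScores}}), rownames = subject IDs.
#' @param clinical data.frame of clinical covariates keyed by
#'   \code{sample_id} (or rownames).
#' @param adjust named list mapping covariate name -> character vector of
#'   adjustment covariate names, e.g.
#'   \code{list(walk_speed = "height")}.
#' @param minPairs minimum complete pairs per cell (default 5).
#' @return data.frame of \code{CorrelateResult} rows: \code{covariate},
#'   \code{compartment}, \code{rho}, \code{p_value}, \code{tier},
#'   \code{n_used}, \code{adjusted_for}.
#' @export
spearmanScreen <- function(scores, clinical, adjust = list(),
                           minPairs = 5L) {
  scores <- as.matrix(scores)
  if ("sample_id" %in% names(clinical)) {
    rownames(clinical) <- clinical$sample_id
    clinical$sample_id <- NULL
  }
  ids <- intersect(rownames(scores), rownames(clinical))
  if (length(ids) < minPairs) stop("too few subjects shared with clinical table")
  scores <- scores[ids, , drop = FALSE]
  clinical <- clinical[ids, , drop = FALSE]
  numCols <- names(clinical)[vapply(clinical, is.numeric, logical(1L))]
  rows <- list()
  for (cv in numCols) {
    adjNames <- adjust[[cv]]
    adjM <- if (length(adjNames)) {
      if (!all(adjNames %in% names(clinical)))
        stop("adjustment covariate missing: ",
             paste(setdiff(adjNames, names(clinical)), collapse = ", "))
      clinical[, adjNames, drop = FALSE]
    }
    for (cp in colnames(scores)) {
      est <- .spearmanOne(scores[, cp], clinical[[cv]], adjM)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, compartment = cp, rho = est$rho,
        p_value = est$p, tier = .tierOf(est$p), n_used = est$n,
        adjusted_for = paste(adjNames, collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Heatmap-ready table of screened correlates
#'
#' Filters \code{\link{spearmanScreen}} output to \code{p < pMax}, keeps
#' the direction sign and significance tier, and marks covariates that
#' reach the threshold in more than one compartment (rendered bold in the
#' study's heatmap).
#'
#' @param results data.frame from \code{\link{spearmanScreen}}.
#' @param pMax inclusion threshold (default 0.10).
#' @return Filtered data.frame with added \code{direction} and
#'   \code{multi_compartment} columns (zero rows in, zero rows out).
#' @export
heatmapTable <- function(results, pMax = 0.10) {
  if (!nrow(results))
    return(cbind(results[0, , drop = FALSE],
                 direction = character(0), multi_compartment = logical(0)))
  keep <- !is.na(results$p_value) & results$p_value < pMax
  out <- results[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$direction <- character(0)
    out$multi_compartment <- logical(0)
    return(out)
  }
  out$direction <- ifelse(out$rho > 0, "positive",
                          ifelse(out$rho < 0, "negative", "zero"))
  nComp <- table(out$covariate)
  out$multi_compartment <- nComp[out$covariate] > 1L
  rownames(out) <- NULL
  out
}
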