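#' Raw aging scores from out-of-bag predictions
#'
#' The aging score is the departure of a subject's out-of-bag predicted age
#' from the predicted age expected for their chronological age under the
#' full cohort: the residual from the cohort OLS regression of OOB
#' prediction on age.  Residualizing (rather than the naive
#' prediction-minus-age difference) absorbs both constant prediction bias
#' and the regression-to-the-mean compression typical of penalized clocks,
#' and makes the scores sum to zero exactly.
#'
#' @param oobMean per-subject out-of-bag predicted age, years.
#' @param age chronological age, years.
#' @return Numeric vector of raw scores (years), named like \code{oobMean}.
#' @examples
#' age <- c(30, 40, 50, 60, 70)
#' computeScores(age + 7, age)   # constant bias: all zero
#' @export
computeScores <- function(oobMean, age) {
  if (length(oobMean) != length(age)) stop("lengths differ")
  if (length(age) < 3L) stop("need at least 3 subjects")
  if (stats::sd(age) == 0) stop("constant age")
  ok <- is.finite(oobMean) & is.finite(age)
  out <- rep(NA_real_, length(age))
  fit <- stats::lm.fit(cbind(1, age[ok]), oobMean[ok])
  out[ok] <- fit$residuals
  names(out) <- names(oobMean)
  out
}

#' Column-standardize scores and flag accelerated/decelerated aging
#'
#' Each block's scores are z-transformed over its non-missing subjects;
#' subjects with \code{z > zCut} are flagged \code{"accelerated"}, those
#' with \code{z < -zCut} \code{"decelerated"}, missing measurements
#' \code{"missing"} and the rest \code{"none"}.
#'
#' @param scores numeric matrix, subjects x blocks, raw aging scores (NA =
#'   subject not measured in that block); a vector is treated as one
#'   column.
#' @param zCut flag threshold in SD units (default 1.5).
#' @param blockInfo optional data.frame (\code{block}, \code{compartment},
#'   \code{omic}) describing the columns; parsed from column names of the
#'   form \code{"<compartment>_<omic>"} when omitted.
#' @return An \linkS4class{AgingScoreTable}.
#' @export
flagAcceleration <- function(scores, zCut = 1.5, blockInfo = NULL) {
  if (is.null(dim(scores)))
    scores <- matrix(scores, ncol = 1L,
                     dimnames = list(names(scores), "block_score"))
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- sprintf("block%d", seq_len(ncol(scores)))
  z <- scores
  for (jj in seq_len(ncol(scores))) {
    v <- scores[, jj]
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      stop("column '", colnames(scores)[jj],
           "' has fewer than 2 non-missing scores")
    s <- stats::sd(v[ok])
    if (s == 0) stop("zero-variance score column '", colnames(scores)[jj], "'")
    z[ok, jj] <- (v[ok] - mean(v[ok])) / s
  }
  flags <- matrix("none", nrow(z), ncol(z), dimnames = dimnames(z))
  flags[!is.na(z) & z > zCut] <- "accelerated"
  flags[!is.na(z) & z < -zCut] <- "decelerated"
  flags[is.na(z)] <- "missing"
  if (is.null(blockInfo)) {
    parts <- strsplit(colnames(scores), "_", fixed = TRUE)
    blockInfo <- data.frame(
      block = colnames(scores),
      compartment = vapply(parts, `[`, character(1L), 1L),
      omic = vapply(parts, function(x)
        if (length(x) > 1L) paste(x[-1L], collapse = "_") else NA_character_,
        character(1L)),
      stringsAsFactors = FALSE)
  }
  new("AgingScoreTable", raw = scores, z = z, flags = flags,
      blockInfo = blockInfo, zCut = zCut)
}

#' Composite per-compartment scores
#'
#' Averages the z-scores of a compartment's available omic blocks
#' (proteomic and metabolomic) for each subject; the z scale is used so
#' that omics with different prediction-error magnitudes contribute
#' equally.  A subject missing every block of a compartment gets NA.
#'
#' @param table an \linkS4class{AgingScoreTable}.
#' @return Numeric matrix, subjects x compartments.
#' @export
compositeScores <- function(table) {
  stopifnot(is(table, "AgingScoreTable"))
  comps <- unique(table@blockInfo$compartment)
  out <- matrix(NA_real_, nrow(table@z), length(comps),
                dimnames = list(rownames(table@z), comps))
  for (cp in comps) {
    cols <- which(table@blockInfo$compartment == cp)
    sub <- table@z[, cols, drop = FALSE]
    mn <- rowMeans(sub, na.rm = TRUE)
    mn[!is.finite(mn)] <- NA_real_
    out[, cp] <- mn
  }
  out
}

#' Pairwise concordance of aging scores
#'
#' Correlation matrix of aging scores across blocks or compartments on
#' pairwise-complete subjects, with per-pair p-values and overlap counts.
#' Entries with fewer than \code{minPairs} complete pairs are NA.
#'
#' @param table an \linkS4class{AgingScoreTable}.
#' @param level \code{"block"} (z-scores per block) or \code{"compartment"}
#'   (composite scores).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param minPairs minimum complete pairs per entry (default 3).
#' @return List of matrices: \code{r} (symmetric, unit diagonal),
#'   \code{p}, \code{n}.
#' @export
scoreCorrelationMatrix <- function(table, level = c("block", "compartment"),
                                   method = c("pearson", "spearman"),
                                   minPairs = 3L) {
  stopifnot(is(table, "AgingScoreTable"))
  level <- match.arg(level)
  method <- match.arg(method)
  m <- if (level == "block") table@z else compositeScores(table)
  q <- ncol(m)
  r <- matrix(NA_real_, q, q, dimnames = list(colnames(m), colnames(m)))
  pv <- r
  nn <- matrix(0L, q, q, dimnames = dimnames(r))
  for (i in seq_len(q)) {
    r[i, i] <- 1; pv[i, i] <- 0
    nn[i, i] <- sum(!is.na(m[, i]))
    for (jx in seq_len(q)) {
      if (jx <= i) next
      ok <- !is.na(m[, i]) & !is.na(m[, jx])
      nn[i, jx] <- nn[jx, i] <- sum(ok)
      if (sum(ok) < minPairs) next
      ct <- suppressWarnings(
        stats::cor.test(m[ok, i], m[ok, jx], method = method,
                        exact = FALSE))
      r[i, jx] <- r[jx, i] <- unname(ct$estimate)
      pv[i, jx] <- pv[jx, i] <- ct$p.value
    }
  }
  list(r = r, p = pv, n = nn)
}

#' Long-format score table for heatmap plotting
#'
#' One row per subject x block with raw score, z and flag -- the layout of
#' a subjects-by-blocks acceleration heatmap.
#'
#' @param table an \linkS4class{AgingScoreTable}.
#' @return data.frame: \code{sample_id}, \code{block}, \code{raw}, \code{z},
#'   \code{flag}.
#' @export
scoresLongTable <- function(table) {
  stopifnot(is(table, "AgingScoreTable"))
  data.frame(
    sample_id = rep(rownames(table@raw), ncol(table@raw)),
    block = rep(colnames(table@raw), each = nrow(table@raw)),
    raw = as.vector(table@raw),
    z = as.vector(table@z),
    flag = as.vector(table@flags),
    stringsAsFactors = FALSE)
}
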