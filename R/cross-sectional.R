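#' Per-feature covariate-adjusted age association
#'
#' Fits one ordinary-least-squares model per feature,
#' \code{abundance ~ age + sex + race + BMI} (the covariate list is
#' configurable), and reports the age coefficient (log units per year of
#' age), its standard error, the two-sided p-value, the
#' Benjamini-Hochberg q-value, and the direction of the association
#' (\code{"over"}: higher at older age, \code{"under"}: lower).
#'
#' Covariates that are constant over the fitted samples (e.g. a single-race
#' cohort draw) are dropped with a warning rather than producing a
#' rank-deficient design.  Features with fewer non-missing observations
#' than model coefficients plus one are skipped with a notice and carry
#' \code{NA} statistics.
#'
#' @param block an \linkS4class{OmicsBlock}.
#' @param metadata data.frame keyed by \code{sample_id} covering all of the
#'   block's samples, with an \code{age} column and the covariates.
#' @param covariates character vector of metadata columns to adjust for.
#' @return data.frame with columns \code{feature_id}, \code{beta_age},
#'   \code{se}, \code{p_value}, \code{q_value}, \code{direction},
#'   \code{n_used}; one row per feature.
#' @examples
#' cfg <- cohortConfig(40, blocks = list(blockConfig("plasma_proteomic", 30)),
#'                     seed = 3)
#' co <- simulateCohort(cfg)
#' res <- fitFeatureLm(co$blocks[[1]], co$metadata)
#' head(res)
#' @export
fitFeatureLm <- function(block, metadata,
                         covariates = c("sex", "race", "BMI")) {
  stopifnot(is(block, "OmicsBlock"))
  if (!all(colnames(block) %in% metadata$sample_id))
    stop("metadata does not cover all block samples")
  meta <- metadata[match(colnames(block), metadata$sample_id), , drop = FALSE]
  if (!"age" %in% names(meta)) stop("metadata must contain 'age'")
  miss <- setdiff(covariates, names(meta))
  if (length(miss)) stop("covariates not in metadata: ",
                         paste(miss, collapse = ", "))
  keepCov <- vapply(covariates, function(cv) {
    v <- meta[[cv]]
    ok <- length(unique(v[!is.na(v)])) > 1L
    if (!ok) warning("covariate '", cv,
                     "' is constant in this cohort; dropped", call. = FALSE)
    ok
  }, logical(1L))
  covariates <- covariates[keepCov]
  form <- stats::reformulate(c("age", covariates))
  X <- stats::model.matrix(form, data = meta)
  ageCol <- which(colnames(X) == "age")
  q <- ncol(X)
  a <- abundance(block)
  p <- nrow(a)
  out <- data.frame(feature_id = rownames(a), beta_age = NA_real_,
                    se = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    direction = NA_character_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  nSkipped <- 0L
  for (j in seq_len(p)) {
    y <- a[j, ]
    ok <- is.finite(y)
    nOk <- sum(ok)
    if (nOk < q + 1L) { nSkipped <- nSkipped + 1L; next }
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    df <- nOk - fit$rank
    if (df < 1L || fit$rank < q) { nSkipped <- nSkipped + 1L; next }
    sigma2 <- sum(fit$residuals^2) / df
    R <- qr.R(fit$qr)
    piv <- fit$qr$pivot
    xi <- chol2inv(R)
    XtXinv <- matrix(NA_real_, q, q)
    XtXinv[piv, piv] <- xi
    seA <- sqrt(sigma2 * XtXinv[ageCol, ageCol])
    bA <- fit$coefficients[ageCol]
    tval <- bA / seA
    out$beta_age[j] <- bA
    out$se[j] <- seA
    # guard against numerical underflow on near-perfect fits
    out$p_value[j] <- max(2 * stats::pt(-abs(tval), df),
                          .Machine$double.xmin)
    out$n_used[j] <- nOk
  }
  if (nSkipped)
    message(sprintf("fitFeatureLm [%s]: %d features skipped (insufficient data)",
                    blockName(block), nSkipped))
  out$q_value <- rep(NA_real_, p)
  okp <- !is.na(out$p_value)
  out$q_value[okp] <- bhAdjust(out$p_value[okp])
  out$direction <- ifelse(is.na(out$beta_age), NA_character_,
                          ifelse(out$beta_age > 0, "over", "under"))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control; a thin, validated wrapper
#' so the multiple-testing rule used across the package lives in one place.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return q-values of the same length (empty in, empty out).
#' @export
bhAdjust <- function(pValues) {
  if (!length(pValues)) return(numeric(0))
  if (any(is.na(pValues)) || any(pValues <= 0 | pValues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Count significant age associations by direction
#'
#' @param results data.frame from \code{\link{fitFeatureLm}}.
#' @param cut significance cutoff (default 0.05).
#' @param use \code{"q"} (default, BH-adjusted) or \code{"p"} (raw); the
#'   source study's wording is ambiguous between the two, so both are
#'   supported.
#' @return List: \code{n_over}, \code{n_under}, \code{over_ids},
#'   \code{under_ids}.
#' @export
classifyAndCount <- function(results, cut = 0.05, use = c("q", "p")) {
  use <- match.arg(use)
  stopifnot(nrow(results) > 0L)
  v <- if (use == "q") results$q_value else results$p_value
  sig <- !is.na(v) & v < cut
  over <- sig & results$direction == "over"
  under <- sig & results$direction == "under"
  list(n_over = sum(over), n_under = sum(under),
       over_ids = results$feature_id[over],
       under_ids = results$feature_id[under])
}

#' Compare age effects between two visits
#'
#' Pearson-correlates per-feature age coefficients from two visits on the
#' matched (shared-feature) set, both over all shared features and over the
#' features significant at both visits.
#'
#' @param resultsV1,resultsV2 data.frames from \code{\link{fitFeatureLm}}.
#' @param cut,use significance rule, as in \code{\link{classifyAndCount}}.
#' @return List: \code{cor_all}, \code{cor_significant} (NA with a message
#'   when fewer than 3 features qualify), \code{shared_significant_ids},
#'   \code{n_shared}.
#' @export
compareVisits <- function(resultsV1, resultsV2, cut = 0.05,
                          use = c("q", "p")) {
  use <- match.arg(use)
  shared <- intersect(resultsV1$feature_id, resultsV2$feature_id)
  if (length(shared) < 3L) {
    message("fewer than 3 shared features; correlations undefined")
    return(list(cor_all = NA_real_, cor_significant = NA_real_,
                shared_significant_ids = character(0),
                n_shared = length(shared)))
  }
  i1 <- match(shared, resultsV1$feature_id)
  i2 <- match(shared, resultsV2$feature_id)
  b1 <- resultsV1$beta_age[i1]; b2 <- resultsV2$beta_age[i2]
  corAll <- stats::cor(b1, b2, use = "complete.obs")
  v1 <- if (use == "q") resultsV1$q_value[i1] else resultsV1$p_value[i1]
  v2 <- if (use == "q") resultsV2$q_value[i2] else resultsV2$p_value[i2]
  sig <- !is.na(v1) & !is.na(v2) & v1 < cut & v2 < cut
  corSig <- if (sum(sig) >= 3L) stats::cor(b1[sig], b2[sig]) else {
    message("fewer than 3 shared significant features; correlation undefined")
    NA_real_
  }
  list(cor_all = corAll, cor_significant = corSig,
       shared_significant_ids = shared[sig], n_shared = length(shared))
}

#' Volcano-ready export of age-association results
#'
#' @param results data.frame from \code{\link{fitFeatureLm}}.
#' @return data.frame with \code{feature_id}, \code{beta_age} (x-axis) and
#'   \code{neg_log10_p} (y-axis), plus \code{q_value} and \code{direction}.
#' @export
volcanoTable <- function(results) {
  data.frame(feature_id = results$feature_id,
             beta_age = results$beta_age,
             neg_log10_p = -log10(results$p_value),
             q_value = results$q_value,
             direction = results$direction,
             stringsAsFactors = FALSE)
}
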