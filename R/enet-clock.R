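#' Configure the cross-validated elastic-net age predictor
#'
#' Defaults follow the published protocol: 500 repeated runs of fivefold
#' cross-validation with 125 response-permutation null replicates per run.
#' The lambda path is log-spaced over \code{nLambda} points from
#' \eqn{\lambda_{max}} (the smallest penalty shrinking every coefficient to
#' zero at the given alpha) down \code{-log10(lambdaMinRatio)} decades.
#'
#' @param alphaGrid mixing parameters in [0, 1] (0 = ridge, 1 = lasso).
#' @param lambdaGrid optional explicit penalty sequence applied at every
#'   alpha; \code{NULL} (default) derives a per-alpha path from the data.
#' @param nLambda,lambdaMinRatio path length and depth when
#'   \code{lambdaGrid} is \code{NULL}.
#' @param nRuns number of repeated cross-validation runs.
#' @param kFolds folds per run (>= 2).
#' @param nPerm response-permutation null replicates per run (>= 1).
#' @param seed integer seed controlling folds and permutations.
#' @param standardize standardize features using training-fold statistics
#'   only (default TRUE).
#' @param thresh glmnet convergence threshold.
#' @return A classed list of settings.
#' @export
enetConfig <- function(alphaGrid = seq(0, 1, by = 0.2), lambdaGrid = NULL,
                       nLambda = 20, lambdaMinRatio = 1e-3, nRuns = 500,
                       kFolds = 5, nPerm = 125, seed = 1L,
                       standardize = TRUE, thresh = 1e-7) {
  if (any(alphaGrid < 0 | alphaGrid > 1)) stop("alpha must lie in [0, 1]")
  if (!length(alphaGrid)) stop("empty alpha grid")
  if (kFolds < 2) stop("kFolds must be >= 2")
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (nRuns < 1) stop("nRuns must be >= 1")
  structure(list(alphaGrid = sort(unique(alphaGrid)),
                 lambdaGrid = lambdaGrid, nLambda = nLambda,
                 lambdaMinRatio = lambdaMinRatio, nRuns = as.integer(nRuns),
                 kFolds = as.integer(kFolds), nPerm = as.integer(nPerm),
                 seed = as.integer(seed), standardize = standardize,
                 thresh = thresh),
            class = "enetConfig")
}

# lambda_max under the glmnet objective, on standardized columns.
.lambdaPath <- function(X, y, alpha, nLambda, minRatio) {
  n <- nrow(X)
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * max(alpha, 1e-3))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
}

# Standardize train/test with training-fold statistics; NA -> 0 after
# centering (training-mean imputation).  Zero-variance columns collapse to 0.
.stdFold <- function(Xtr, Xte, standardize) {
  mu <- colMeans(Xtr, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  if (standardize) {
    sd <- apply(Xtr, 2L, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- 1
  } else sd <- rep(1, ncol(Xtr))
  tr <- sweep(sweep(Xtr, 2L, mu), 2L, sd, "/")
  te <- sweep(sweep(Xte, 2L, mu), 2L, sd, "/")
  tr[is.na(tr)] <- 0
  te[is.na(te)] <- 0
  list(train = tr, test = te)
}

# One cross-validation pass at one alpha: every subject predicted exactly
# once; per-lambda out-of-bag predictions plus per-feature nonzero counts
# and coefficient sums over the k fold fits.
.cvPass <- function(X, y, foldid, alpha, lambda, standardize, thresh) {
  n <- nrow(X); p <- ncol(X); L <- length(lambda)
  pred <- matrix(NA_real_, n, L)
  nz <- matrix(0, p, L)
  csum <- matrix(0, p, L)
  for (f in sort(unique(foldid))) {
    te <- foldid == f
    std <- .stdFold(X[!te, , drop = FALSE], X[te, , drop = FALSE],
                    standardize)
    fit <- glmnet::glmnet(std$train, y[!te], family = "gaussian",
                          alpha = alpha, lambda = lambda,
                          standardize = FALSE, thresh = thresh)
    beta <- as.matrix(fit$beta)
    # glmnet can stop early on a degenerate path; pad with the last column
    if (ncol(beta) < L) {
      last <- beta[, ncol(beta), drop = FALSE]
      beta <- cbind(beta, last[, rep(1L, L - ncol(beta)), drop = FALSE])
      a0 <- c(fit$a0, rep(fit$a0[length(fit$a0)], L - length(fit$a0)))
    } else a0 <- fit$a0
    pred[te, ] <- std$test %*% beta + rep(a0, each = sum(te))
    nzb <- beta != 0
    nz <- nz + nzb
    csum <- csum + beta
  }
  list(pred = pred, nz = nz, csum = csum)
}

.safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Repeated cross-validated elastic net with permutation significance
#'
#' The hierarchical procedure behind the compartment aging clocks.  For
#' each of \code{nRuns} runs a fresh k-fold partition is drawn; within each
#' fold, features are standardized with training-fold statistics only, an
#' elastic net is fitted over the full lambda path, and the held-out fold is
#' predicted, so every subject is predicted exactly once per run.
#' Out-of-bag (OOB) predicted age is aggregated per subject as mean and SD
#' over runs, and the model quality factor (QF) at each (alpha, lambda) is
#' the Pearson correlation between chronological age and the OOB mean.
#'
#' Significance is calibrated by permutation: each run also executes
#' \code{nPerm} replicates of the identical procedure (same folds) on a
#' globally permuted response.  The model empirical p-value is
#' \code{(1 + #\{null QF >= QF\}) / (1 + #null)}.  At the feature level the
#' observed selection frequency (fraction of run-by-fold fits with a nonzero
#' coefficient) and mean nonzero coefficient are compared against the null
#' replicate ensemble in the same way (coefficients two-sided, on
#' magnitude).  Coefficients are reported on the standardized-feature
#' scale.
#'
#' @param X numeric matrix, samples x features (missing values are imputed
#'   with training-fold means inside each fit).
#' @param y chronological age, years.
#' @param config an \code{\link{enetConfig}}.
#' @param covariates optional matrix/data.frame of additional columns
#'   (e.g. sex indicator) appended to \code{X} as ordinary penalized
#'   features.
#' @return An \linkS4class{EnetResult} with the best grid point already
#'   selected (see \code{\link{selectBest}}).
#' @examples
#' set.seed(1)
#' n <- 60; age <- runif(n, 22, 92)
#' X <- cbind(signal = age + rnorm(n, 0, 4),
#'            matrix(rnorm(n * 9), n, dimnames = list(NULL, paste0("N", 1:9))))
#' cfg <- enetConfig(alphaGrid = 0.5, nRuns = 3, nPerm = 2, nLambda = 8,
#'                   seed = 9)
#' fit <- runCvEnet(X, age, cfg)
#' fit
#' @export
runCvEnet <- function(X, y, config = enetConfig(), covariates = NULL) {
  stopifnot(inherits(config, "enetConfig"))
  X <- as.matrix(X)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
    X <- cbind(X, covariates)
  }
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("F%04d", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (stats::sd(y) == 0) stop("constant response")
  if (config$kFolds > n) stop("kFolds exceeds the number of samples")
  if (n < 2 * config$kFolds)
    stop("need at least 2 * kFolds samples")
  zeroVar <- apply(X, 2L, function(v) stats::sd(v, na.rm = TRUE)) == 0
  if (any(zeroVar, na.rm = TRUE))
    warning(sum(zeroVar, na.rm = TRUE),
            " zero-variance feature(s); their coefficients stay zero")
  nRuns <- config$nRuns; nPerm <- config$nPerm; k <- config$kFolds
  nNull <- nRuns * nPerm

  drawn <- .withSeed(config$seed, {
    folds <- vapply(seq_len(nRuns),
                    function(r) sample(rep_len(seq_len(k), n)), integer(n))
    perms <- vapply(seq_len(nNull), function(m) sample.int(n), integer(n))
    list(folds = folds, perms = perms)
  })
  folds <- drawn$folds; perms <- drawn$perms

  fits <- vector("list", length(config$alphaGrid))
  names(fits) <- as.character(config$alphaGrid)
  for (ia in seq_along(config$alphaGrid)) {
    alpha <- config$alphaGrid[ia]
    lambda <- if (!is.null(config$lambdaGrid))
      sort(as.numeric(config$lambdaGrid), decreasing = TRUE)
    else .lambdaPath(X, y, alpha, config$nLambda, config$lambdaMinRatio)
    L <- length(lambda)
    oobSum <- matrix(0, n, L); oobSq <- matrix(0, n, L)
    nzTot <- matrix(0, p, L); coefTot <- matrix(0, p, L)
    for (r in seq_len(nRuns)) {
      cv <- .cvPass(X, y, folds[, r], alpha, lambda, config$standardize,
                    config$thresh)
      oobSum <- oobSum + cv$pred
      oobSq <- oobSq + cv$pred^2
      nzTot <- nzTot + cv$nz
      coefTot <- coefTot + cv$csum
    }
    oobMean <- oobSum / nRuns
    oobSd <- if (nRuns > 1) {
      v <- (oobSq - nRuns * oobMean^2) / (nRuns - 1)
      v[v < 0] <- 0   # numerical cancellation
      sqrt(v)
    } else matrix(0, n, L)
    qf <- apply(oobMean, 2L, .safeCor, b = y)
    featFreq <- nzTot / (nRuns * k)
    featCoef <- ifelse(nzTot > 0, coefTot / pmax(nzTot, 1), 0)

    nullQf <- matrix(NA_real_, nNull, L)
    freqExc <- matrix(0, p, L)
    coefExc <- matrix(0, p, L)
    absCoef <- abs(featCoef)
    for (r in seq_len(nRuns)) {
      for (m in seq_len(nPerm)) {
        idx <- (r - 1L) * nPerm + m
        yp <- y[perms[, idx]]
        cv <- .cvPass(X, yp, folds[, r], alpha, lambda, config$standardize,
                      config$thresh)
        nullQf[idx, ] <- vapply(seq_len(L), function(l)
          .safeCor(cv$pred[, l], yp), numeric(1L))
        nFreq <- cv$nz / k
        nCoef <- ifelse(cv$nz > 0, cv$csum / pmax(cv$nz, 1), 0)
        freqExc <- freqExc + (nFreq >= featFreq)
        coefExc <- coefExc + (abs(nCoef) >= absCoef)
      }
    }
    modelP <- vapply(seq_len(L), function(l) {
      nq <- nullQf[, l]
      (1 + sum(nq >= qf[l], na.rm = TRUE)) / (1 + nNull)
    }, numeric(1L))
    dimnames(featFreq) <- dimnames(featCoef) <- list(colnames(X), NULL)
    fits[[ia]] <- list(lambda = lambda, qf = qf, oobMean = oobMean,
                       oobSd = oobSd, modelP = modelP, nullQf = nullQf,
                       featFreq = featFreq, featCoef = featCoef,
                       featFreqP = (1 + freqExc) / (1 + nNull),
                       featCoefP = (1 + coefExc) / (1 + nNull))
  }

  res <- new("EnetResult", alpha = config$alphaGrid, fits = fits, y = y,
             sampleIDs = if (!is.null(rownames(X))) rownames(X)
                         else sprintf("S%03d", seq_len(n)),
             featureIDs = colnames(X), folds = folds, best = list(),
             config = unclass(config))
  res@best <- selectBest(res)
  res
}

#' Select the best (alpha, lambda) by quality factor
#'
#' Argmax of the quality factor over the whole grid; ties break toward the
#' larger lambda and then the larger alpha (the sparser model).
#'
#' @param result an \linkS4class{EnetResult}.
#' @return List: \code{alpha}, \code{lambda}, \code{alphaIdx},
#'   \code{lambdaIdx}, \code{qf}.
#' @export
selectBest <- function(result) {
  stopifnot(is(result, "EnetResult"))
  grid <- do.call(rbind, lapply(seq_along(result@alpha), function(ia) {
    f <- result@fits[[ia]]
    data.frame(alphaIdx = ia, lambdaIdx = seq_along(f$lambda),
               alpha = result@alpha[ia], lambda = f$lambda, qf = f$qf)
  }))
  if (!nrow(grid)) stop("empty grid")
  grid$qfKey <- ifelse(is.na(grid$qf), -Inf, grid$qf)
  ord <- order(-grid$qfKey, -grid$lambda, -grid$alpha)
  b <- grid[ord[1L], ]
  list(alpha = b$alpha, lambda = b$lambda, alphaIdx = b$alphaIdx,
       lambdaIdx = b$lambdaIdx, qf = b$qf)
}

#' Out-of-bag predictions at a grid point
#'
#' @param result an \linkS4class{EnetResult}.
#' @param alpha,lambda grid point; defaults to the selected best.
#' @return data.frame: \code{sample_id}, \code{age}, \code{oob_mean},
#'   \code{oob_sd}.
#' @export
oobPredictions <- function(result, alpha = NULL, lambda = NULL) {
  stopifnot(is(result, "EnetResult"))
  b <- result@best
  ia <- if (is.null(alpha)) b$alphaIdx else {
    i <- match(alpha, result@alpha)
    if (is.na(i)) stop("alpha not on the grid")
    i
  }
  f <- result@fits[[ia]]
  il <- if (is.null(lambda)) {
    if (ia == b$alphaIdx) b$lambdaIdx
    else which.max(ifelse(is.na(f$qf), -Inf, f$qf))
  } else {
    j <- which.min(abs(f$lambda - lambda))
    if (abs(f$lambda[j] - lambda) > 1e-8 * max(1, lambda))
      stop("lambda not on the grid")
    j
  }
  data.frame(sample_id = result@sampleIDs, age = result@y,
             oob_mean = f$oobMean[, il], oob_sd = f$oobSd[, il],
             stringsAsFactors = FALSE)
}

#' Extract the feature signature at the best grid point
#'
#' Features whose selection frequency is significant against the
#' permutation null (\code{freq_p < freqPCut}) and nonzero at least once,
#' ordered by decreasing selection frequency, with signed mean
#' (standardized-scale) coefficients.
#'
#' @param result an \linkS4class{EnetResult}.
#' @param freqPCut feature-level empirical-p cutoff (default 0.05).
#' @return data.frame: \code{feature_id}, \code{coef_mean}, \code{freq},
#'   \code{coef_p}, \code{freq_p}; zero rows when nothing passes.
#' @export
extractSignature <- function(result, freqPCut = 0.05) {
  stopifnot(is(result, "EnetResult"))
  b <- result@best
  f <- result@fits[[b$alphaIdx]]
  j <- b$lambdaIdx
  sig <- data.frame(feature_id = result@featureIDs,
                    coef_mean = f$featCoef[, j],
                    freq = f$featFreq[, j],
                    coef_p = f$featCoefP[, j],
                    freq_p = f$featFreqP[, j],
                    stringsAsFactors = FALSE)
  sig <- sig[sig$freq_p < freqPCut & sig$freq > 0, , drop = FALSE]
  sig <- sig[order(-sig$freq, -abs(sig$coef_mean), sig$feature_id), ,
             drop = FALSE]
  rownames(sig) <- NULL
  sig
}
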