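#' Leave-one-out validation of a fixed signature
#'
#' Refits a Gaussian identity-link linear model of age on the (already
#' selected) signature features, leaving each subject out in turn and
#' predicting it from the other n - 1, then correlates chronological age
#' with the LOOCV predictions.  No regularization is applied since feature
#' selection already happened upstream; a rank-deficient leave-one-out
#' design falls back to a minimally ridged solve with a logged notice.
#'
#' @param X numeric matrix, samples x signature features (no missing
#'   values).
#' @param y chronological age, years.
#' @param covariates optional extra columns (e.g. sex) appended to the
#'   design.
#' @return List: \code{predictions} (named numeric), \code{r} (Pearson
#'   correlation of age with predictions), \code{p_value} (two-sided).
#' @examples
#' x <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "f"))
#' loocvPredict(x, c(10, 20, 30, 40))$r
#' @export
loocvPredict <- function(X, y, covariates = NULL) {
  X <- as.matrix(X)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (anyNA(X)) stop("X must not contain missing values; impute upstream")
  if (ncol(X) >= n - 1L)
    stop("signature has too many features for leave-one-out refits ",
         "(need p < n - 1)")
  D <- cbind(`(Intercept)` = 1, X)
  pred <- rep(NA_real_, n)
  ridged <- FALSE
  for (i in seq_len(n)) {
    Dtr <- D[-i, , drop = FALSE]
    qrD <- qr(Dtr)
    if (qrD$rank < ncol(Dtr)) {
      ridged <- TRUE
      A <- crossprod(Dtr) + diag(1e-8, ncol(Dtr))
      beta <- solve(A, crossprod(Dtr, y[-i]))
    } else {
      beta <- qr.coef(qrD, y[-i])
    }
    pred[i] <- drop(D[i, , drop = FALSE] %*% beta)
  }
  if (ridged)
    message("loocvPredict: rank-deficient leave-one-out design; ",
            "used a tiny ridge penalty")
  names(pred) <- rownames(X)
  ct <- suppressWarnings(stats::cor.test(y, pred))
  list(predictions = pred, r = unname(ct$estimate), p_value = ct$p.value)
}

#' Intersect a signature with another platform's feature catalog
#'
#' Case-insensitive exact-identifier intersection (IDs are upper-cased and
#' trimmed before matching), used when carrying a signature to a platform
#' that measures a different feature panel.
#'
#' @param signature character vector of signature feature IDs (order is
#'   preserved in the overlap).
#' @param platformCatalog character vector of IDs available on the target
#'   platform.
#' @return List: \code{overlap} (IDs as spelled in \code{signature}),
#'   \code{dropped} (signature IDs absent from the catalog),
#'   \code{n_overlap}.
#' @export
intersectFeatures <- function(signature, platformCatalog) {
  norm <- function(x) toupper(trimws(x))
  hit <- norm(signature) %in% norm(platformCatalog)
  if (!any(hit)) warning("no overlap between signature and platform catalog")
  list(overlap = signature[hit], dropped = signature[!hit],
       n_overlap = sum(hit))
}
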