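# Compact helper: a strong single-signal regression problem.
enetToy <- function(n = 50, pNoise = 9, noise = 3, seed = 4) {
  set.seed(seed)
  age <- runif(n, 22, 92)
  X <- cbind(signal = age + rnorm(n, 0, noise),
             matrix(rnorm(n * pNoise), n,
                    dimnames = list(NULL, sprintf("N%02d", seq_len(pNoise)))))
  rownames(X) <- sprintf("S%03d", seq_len(n))
  list(X = X, age = age)
}

test_that("identical configuration and seed reproduce the fit exactly", {
  toy <- enetToy()
  cfg <- enetConfig(alphaGrid = c(0.2, 0.8), nRuns = 3, nPerm = 2,
                    nLambda = 6, seed = 12)
  f1 <- runCvEnet(toy$X, toy$age, cfg)
  f2 <- runCvEnet(toy$X, toy$age, cfg)
  expect_identical(f1@fits, f2@fits)
  expect_identical(f1@folds, f2@folds)
  expect_identical(f1@best, f2@best)
  f3 <- runCvEnet(toy$X, toy$age, enetConfig(alphaGrid = c(0.2, 0.8),
                                             nRuns = 3, nPerm = 2,
                                             nLambda = 6, seed = 13))
  expect_false(identical(f1@fits, f3@fits))
})

test_that("every subject is predicted exactly once per run", {
  toy <- enetToy(n = 23)
  fit <- runCvEnet(toy$X, toy$age,
                   enetConfig(alphaGrid = 0.5, nRuns = 4, nPerm = 1,
                              nLambda = 5, seed = 1))
  expect_equal(dim(fit@folds), c(23L, 4L))
  for (r in 1:4)
    expect_equal(sort(unique(fit@folds[, r])), 1:5)
  f <- fit@fits[[1]]
  expect_false(anyNA(f$oobMean))
  expect_true(all(f$oobSd >= 0))
})

test_that("quality factor is invariant to affine rescaling of a feature", {
  toy <- enetToy()
  cfg <- enetConfig(alphaGrid = 0.5, nRuns = 3, nPerm = 1,
                    lambdaGrid = c(5, 1, 0.2), seed = 6)
  f1 <- runCvEnet(toy$X, toy$age, cfg)
  X2 <- toy$X
  X2[, "signal"] <- 10 * X2[, "signal"] + 5
  f2 <- runCvEnet(X2, toy$age, cfg)
  expect_equal(f2@fits[[1]]$qf, f1@fits[[1]]$qf, tolerance = 1e-6)
})

test_that("grid selection maximizes QF and breaks ties toward sparsity", {
  mkres <- function(alpha, lambdas, qfs) {
    fits <- lapply(seq_along(alpha), function(i)
      list(lambda = lambdas[[i]], qf = qfs[[i]]))
    new("EnetResult", alpha = alpha, fits = fits, y = 1:10 + 0,
        sampleIDs = sprintf("S%d", 1:10), featureIDs = "F1",
        folds = matrix(1L, 10, 1), best = list(), config = list())
  }
  one <- mkres(0.5, list(1), list(0.7))
  expect_equal(selectBest(one)$lambda, 1)
  two <- mkres(0.5, list(c(1, 0.1)), list(c(0.5, 0.9)))
  expect_equal(selectBest(two)$lambda, 0.1)
  tieL <- mkres(0.5, list(c(1.0, 0.1)), list(c(0.9, 0.9)))
  expect_equal(selectBest(tieL)$lambda, 1.0)        # larger lambda wins
  tieA <- mkres(c(0.2, 0.8), list(1, 1), list(0.9, 0.9))
  expect_equal(selectBest(tieA)$alpha, 0.8)         # then larger alpha
  # NA quality factors lose to any finite one
  withNA <- mkres(0.5, list(c(1, 0.1)), list(c(NA_real_, 0.3)))
  expect_equal(selectBest(withNA)$lambda, 0.1)
})

test_that("a dominant true feature is found at the head of the signature", {
  # p > n so that lasso selection stays sparse and the null ensemble
  # spreads selections thinly across features
  set.seed(9)
  n <- 50; p <- 80
  age <- runif(n, 22, 92)
  X <- cbind(signal = age + rnorm(n, 0, 3),
             matrix(rnorm(n * (p - 1)), n,
                    dimnames = list(NULL, sprintf("N%02d", 1:(p - 1)))))
  fit <- runCvEnet(X, age, enetConfig(alphaGrid = 1, nRuns = 6, nPerm = 10,
                                      nLambda = 10, seed = 21))
  b <- fit@best
  f <- fit@fits[[1]]
  expect_gt(b$qf, 0.9)
  expect_gt(f$featFreq["signal", b$lambdaIdx], 0.9)
  sig <- extractSignature(fit, freqPCut = 0.05)
  expect_gt(nrow(sig), 0)
  expect_identical(sig$feature_id[1], "signal")
  expect_gt(sig$coef_mean[1], 0)
})

test_that("a huge penalty gives an all-zero model and an empty signature", {
  toy <- enetToy(n = 30)
  fit <- runCvEnet(toy$X, toy$age,
                   enetConfig(alphaGrid = 1, lambdaGrid = 1e6, nRuns = 2,
                              nPerm = 1, seed = 2))
  f <- fit@fits[[1]]
  expect_true(all(f$featFreq == 0))
  expect_equal(nrow(extractSignature(fit)), 0L)
})

test_that("selection frequency shrinks as the penalty grows", {
  co <- smallCohort(n = 60, p = 40, frac = 0.5, seed = 33, lodQuantile = 0)
  X <- t(abundance(co$blocks[[1]]))
  age <- co$metadata$age
  fit <- runCvEnet(X, age, enetConfig(alphaGrid = 1, nRuns = 4, nPerm = 1,
                                      nLambda = 10, seed = 5))
  f <- fit@fits[[1]]
  sel <- colMeans(f$featFreq)   # lambda decreasing along the path
  expect_lt(sel[1], sel[10])
  expect_lt(mean(diff(sel) < 1e-9), 0.35)  # broadly increasing as lambda drops
})

test_that("degenerate inputs are rejected with clear errors", {
  toy <- enetToy(n = 20)
  expect_error(runCvEnet(toy$X, rep(50, 20), enetConfig(alphaGrid = 0.5)),
               "constant response")
  expect_error(runCvEnet(toy$X, toy$age,
                         enetConfig(alphaGrid = 0.5, kFolds = 15)),
               "kFolds")
  expect_error(enetConfig(alphaGrid = 1.5), "alpha")
  expect_error(enetConfig(alphaGrid = numeric(0)), "empty")
  Xz <- cbind(toy$X, const = rep(1, 20))
  expect_warning(runCvEnet(Xz, toy$age,
                           enetConfig(alphaGrid = 0.5, nRuns = 2, nPerm = 1,
                                      nLambda = 4, seed = 1)),
                 "zero-variance")
})

test_that("missing values are imputed with training-fold means only", {
  toy <- enetToy(n = 40)
  Xna <- toy$X
  Xna[c(3, 17), "N01"] <- NA
  fit <- runCvEnet(Xna, toy$age,
                   enetConfig(alphaGrid = 0.5, nRuns = 2, nPerm = 1,
                              nLambda = 5, seed = 8))
  expect_false(anyNA(fit@fits[[1]]$oobMean))
  expect_gt(fit@best$qf, 0.8)
})
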