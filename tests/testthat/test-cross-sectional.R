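test_that("worked six-sample fixture recovers the age slope exactly", {
  # y = 0.5*age + 1*male: with age and sex in the design, OLS must return
  # beta_age = 0.5 with zero residual (hand normal equations give the same)
  ages <- c(20, 30, 40, 50, 60, 70)
  meta <- handMeta(sprintf("S%02d", 1:6), ages,
                   race = factor(rep("white", 6),
                                 levels = c("other", "white")))
  male <- as.numeric(meta$sex == "male")
  y <- 0.5 * ages + male
  blk <- handBlock(matrix(y, 1, 6), block = "plasma_proteomic")
  expect_warning(res <- fitFeatureLm(blk, meta), "constant")  # race dropped
  expect_equal(res$beta_age, 0.5, tolerance = 1e-10)
  expect_equal(res$direction, "over")
  expect_equal(res$n_used, 6L)
  # a feature equal to age itself has slope exactly 1
  blk2 <- handBlock(matrix(ages, 1, 6), block = "plasma_proteomic")
  expect_warning(res2 <- fitFeatureLm(blk2, meta), "constant")
  expect_equal(res2$beta_age, 1, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand step-up computation", {
  # step-up by hand for (0.01, 0.02, 0.03, 0.04), m = 4:
  #  q4 = 0.04*4/4 = 0.04; q3 = min(0.03*4/3, q4) = 0.04;
  #  q2 = min(0.02*4/2, 0.04) = 0.04; q1 = min(0.01*4, 0.04) = 0.04
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)                 # single p unchanged
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))   # ties: i = m dominates
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, NA)), "0, 1")
  # monotone and order-preserving
  p <- c(0.001, 0.04, 0.01, 0.9, 0.2)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
})

test_that("direction counts split significant features by sign", {
  res <- data.frame(feature_id = c("A", "B", "C", "D"),
                    beta_age = c(1, -1, 2, -2),
                    p_value = c(0.001, 0.002, 0.2, 0.3),
                    q_value = c(0.01, 0.01, 0.4, 0.4),
                    direction = c("over", "under", "over", "under"))
  cc <- classifyAndCount(res)
  expect_equal(cc$n_over, 1L)
  expect_equal(cc$n_under, 1L)
  expect_equal(cc$over_ids, "A")
  allNull <- res; allNull$q_value <- rep(1, 4)
  cc0 <- classifyAndCount(allNull)
  expect_equal(cc0$n_over + cc0$n_under, 0L)
  # raw-p variant is available (the published threshold wording is ambiguous)
  ccp <- classifyAndCount(res, use = "p")
  expect_equal(ccp$n_over, 1L)
})

test_that("visit comparison correlates matched age coefficients", {
  res <- data.frame(feature_id = sprintf("F%d", 1:6),
                    beta_age = c(1, -2, 3, -4, 5, -6) / 10,
                    p_value = rep(0.001, 6), q_value = rep(0.001, 6),
                    direction = rep(c("over", "under"), 3))
  same <- compareVisits(res, res)
  expect_equal(same$cor_all, 1)
  expect_equal(same$cor_significant, 1)
  expect_setequal(same$shared_significant_ids, res$feature_id)
  flipped <- res; flipped$beta_age <- -res$beta_age
  expect_equal(compareVisits(res, flipped)$cor_all, -1)
  expect_message(und <- compareVisits(res[1:2, ], res[1:2, ]), "fewer than 3")
  expect_true(is.na(und$cor_all))
})

test_that("two noise draws from one truth agree more on signal than null features", {
  set.seed(77)
  p <- 120
  beta <- numeric(p)
  beta[1:40] <- rnorm(40, 0, 0.04)            # fixed truth shared by visits
  mkv <- function(seed) {
    cfg <- cohortConfig(80, ageBins = NA,
      blocks = list(blockConfig("plasma_proteomic", p, noiseSd = 0.5,
                                lodQuantile = 0, beta = beta)),
      latentSd = 3, seed = seed)
    co <- simulateCohort(cfg)
    fitFeatureLm(co$blocks[[1]], co$metadata)
  }
  v1 <- mkv(101); v2 <- mkv(202)
  sigIdx <- beta != 0
  corSig <- cor(v1$beta_age[sigIdx], v2$beta_age[sigIdx])
  corNull <- cor(v1$beta_age[!sigIdx], v2$beta_age[!sigIdx])
  expect_gt(corSig, corNull)
  expect_gt(corSig, 0.5)
})

test_that("results are invariant to sample order and covariate rescaling", {
  co <- smallCohort(n = 30, p = 12, seed = 19)
  blk <- co$blocks[[1]]
  meta <- co$metadata
  r1 <- fitFeatureLm(blk, meta)
  perm <- sample(ncol(blk))
  r2 <- fitFeatureLm(blk[, perm], meta)
  expect_equal(r2$beta_age, r1$beta_age, tolerance = 1e-9)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-9)
  meta3 <- meta; meta3$BMI <- 10 * meta3$BMI - 7
  r3 <- fitFeatureLm(blk, meta3)
  expect_equal(r3$beta_age, r1$beta_age, tolerance = 1e-9)
})

test_that("p-values of a pure nuisance feature are uniform over replicates", {
  # feature = 3*sex + noise, no age effect: the age p-value across
  # replicates should be Uniform(0,1)
  set.seed(55)
  n <- 30
  ps <- vapply(seq_len(200), function(r) {
    meta <- handMeta(sprintf("S%02d", 1:n), runif(n, 22, 92),
                     sex = factor(sample(c("female", "male"), n, TRUE),
                                  levels = c("female", "male")))
    y <- 3 * as.numeric(meta$sex == "male") + rnorm(n)
    blk <- handBlock(matrix(y, 1, n), block = "b_p")
    fitFeatureLm(blk, meta, covariates = "sex")$p_value
  }, numeric(1L))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("age-effect estimates are unbiased on synthetic data", {
  co <- smallCohort(n = 120, p = 150, frac = 0.5, seed = 42, noiseSd = 0.4,
                    latentSd = 0, lodQuantile = 0)
  res <- fitFeatureLm(co$blocks[[1]], co$metadata)
  err <- res$beta_age - co$truth$betaAge[[1]][res$feature_id]
  mcErr <- 3 * sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), mcErr + 1e-4)
})

test_that("volcano export carries the plotting axes", {
  co <- smallCohort(n = 25, p = 6, seed = 2)
  res <- fitFeatureLm(co$blocks[[1]], co$metadata)
  v <- volcanoTable(res)
  expect_equal(v$neg_log10_p, -log10(res$p_value))
  expect_identical(v$feature_id, res$feature_id)
})
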