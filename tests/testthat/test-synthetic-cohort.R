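test_that("same seed reproduces the cohort bit-identically, different seed differs", {
  a <- smallCohort(seed = 5)
  b <- smallCohort(seed = 5)
  c <- smallCohort(seed = 6)
  expect_identical(abundance(a$blocks[[1]]), abundance(b$blocks[[1]]))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$delta, b$truth$delta)
  expect_false(identical(abundance(a$blocks[[1]]), abundance(c$blocks[[1]])))
})

test_that("a signal-free cohort has an empty signal mask and null-looking age fits", {
  co <- smallCohort(n = 60, p = 50, frac = 0, seed = 21, latentSd = 0)
  expect_false(any(co$truth$signalMask[[1]]))
  expect_true(all(co$truth$betaAge[[1]] == 0))
  res <- suppressMessages(fitFeatureLm(co$blocks[[1]], co$metadata))
  expect_lt(max(abs(res$beta_age)), 0.05)
  expect_lt(mean(res$p_value < 0.05), 0.2)
})

test_that("noise-free single-feature block with unit slope reproduces age exactly", {
  cfg <- cohortConfig(
    nSubjects = 20, ageBins = NA,
    blocks = list(blockConfig("x_omic", 1, noiseSd = 0, loading = 0,
                              sexEffectSd = 0, bmiEffectSd = 0,
                              lodQuantile = 0, beta = 1, beta0 = 0)),
    latentSd = 5, seed = 2)
  co <- simulateCohort(cfg)
  expect_equal(unname(abundance(co$blocks[[1]])[1, ]),
               co$metadata$age, tolerance = 1e-12)
})

test_that("per-feature censoring fraction tracks the configured LOD quantile", {
  co <- smallCohort(n = 300, p = 40, frac = 0, seed = 9, lodQuantile = 0.2)
  frac <- rowMeans(belowLOD(co$blocks[[1]]))
  expect_true(all(abs(frac - 0.2) < 0.05))
  co0 <- smallCohort(n = 50, p = 10, seed = 9, lodQuantile = 0)
  expect_false(any(belowLOD(co0$blocks[[1]])))
})

test_that("default age sampling follows the demographic strata", {
  cfg <- cohortConfig(nSubjects = 101, seed = 4)
  expect_equal(cfg$ageBins$count, c(23, 20, 18, 28, 12))
  co <- simulateCohort(cfg)
  age <- co$metadata$age
  cuts <- findInterval(age, c(20, 35, 50, 65, 80))
  expect_equal(as.integer(table(cuts)), c(23, 20, 18, 28, 12))
  expect_true(all(age >= 22 & age <= 92))
  # other cohort sizes reapportion proportionally
  cfg2 <- cohortConfig(nSubjects = 50)
  expect_equal(sum(cfg2$ageBins$count), 50L)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohortConfig(nSubjects = 2), "nSubjects")
  expect_error(cohortConfig(ageRange = c(90, 30)), "ageRange")
  expect_error(cohortConfig(nSubjects = 10,
                            ageBins = data.frame(low = 20, high = 90,
                                                 count = 9)),
               "sum to nSubjects")
  expect_error(cohortConfig(nSubjects = 10,
                            ageBins = data.frame(low = 50, high = 40,
                                                 count = 10)),
               "low must be < high")
  expect_error(blockConfig("b", 0), "nFeatures")
  expect_error(blockConfig("b", 10, fracAgeAssoc = 1.2), "fractions")
})

test_that("cohort write/read round-trips exactly and realigns permuted rows", {
  co <- smallCohort(n = 15, p = 8, seed = 13)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  back <- readCohort(d)
  expect_identical(abundance(back$blocks[[1]]), abundance(co$blocks[[1]]))
  expect_identical(belowLOD(back$blocks[[1]]), belowLOD(co$blocks[[1]]))
  expect_equal(back$metadata$age, co$metadata$age)
  expect_equal(back$truth$delta, co$truth$delta)
  expect_equal(back$truth$betaAge[[1]], co$truth$betaAge[[1]])

  # permute the sample rows on disk; the reader realigns by sample ID
  f <- file.path(d, "plasma_proteomic.csv")
  ln <- readLines(f)
  set.seed(1)
  writeLines(c(ln[1], sample(ln[-1])), f)
  fl <- file.path(d, "plasma_proteomic_lod.csv")
  ln2 <- readLines(fl)
  set.seed(1)
  writeLines(c(ln2[1], sample(ln2[-1])), fl)
  back2 <- readCohort(d)
  expect_identical(abundance(back2$blocks[[1]]), abundance(co$blocks[[1]]))

  # collision protection and the overwrite escape hatch
  expect_error(writeCohort(co, d), "overwrite")
  expect_silent(suppressWarnings(writeCohort(co, d, overwrite = TRUE)))
})

test_that("an empty block list writes metadata only, with a warning", {
  co <- smallCohort(n = 10, p = 4, seed = 3)
  co$blocks <- list()
  co$truth <- NULL
  d <- withr::local_tempdir()
  expect_warning(writeCohort(co, d), "metadata only")
  expect_identical(list.files(d), "metadata.csv")
})

test_that("age-association detection rate matches the oracle-calibrated rate", {
  # Oracle (run at 10x n, frozen): with 500 features, 33% carrying
  # half-normal(0.03)/year slopes and residual SD 0.5, essentially every
  # signal feature is detected at BH q < 0.05 when n = 1000, giving an
  # empirical detection fraction of 0.326 ~ the 0.33 signal fraction.
  # At the study-scale n = 100 the same conditions give 0.292 (seed 7).
  mk <- function(n, seed) cohortConfig(n, ageBins = NA,
    blocks = list(blockConfig("plasma_proteomic", 500, fracAgeAssoc = 0.33,
                              effectSd = 0.03, noiseSd = 0.5,
                              lodQuantile = 0)),
    latentSd = 5, seed = seed)
  co <- simulateCohort(mk(100, 7))
  res <- fitFeatureLm(co$blocks[[1]], co$metadata)
  frac <- mean(res$q_value < 0.05)
  expect_equal(frac, 0.292, tolerance = 0.01)
  # within binomial error of the configured signal fraction
  expect_lt(abs(frac - 0.33), 3 * sqrt(0.33 * 0.67 / 500) + 0.02)
  # detections are overwhelmingly true signals
  sig <- co$truth$signalMask[[1]][res$feature_id]
  fdp <- sum(res$q_value < 0.05 & !sig) / max(1, sum(res$q_value < 0.05))
  expect_lt(fdp, 0.15)
})
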