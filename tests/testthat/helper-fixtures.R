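# Shared fixture builders.  Everything is generated in code; no data files.

# Small single-block cohort for fast unit tests.
smallCohort <- function(n = 40, p = 30, frac = 0.4, seed = 11,
                        noiseSd = 0.4, lodQuantile = 0.05, latentSd = 5,
                        loading = 1) {
  cfg <- cohortConfig(
    nSubjects = n, ageBins = NA,
    blocks = list(blockConfig("plasma_proteomic", p, fracAgeAssoc = frac,
                              effectSd = 0.03, noiseSd = noiseSd,
                              loading = loading, lodQuantile = lodQuantile)),
    latentSd = latentSd, seed = seed)
  simulateCohort(cfg)
}

# Hand-built block with explicit values and mask.
handBlock <- function(values, mask = NULL, block = "plasma_proteomic") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  OmicsBlock(values, mask, block = block)
}

# Metadata table for a hand-built block (ages supplied, covariates simple).
handMeta <- function(ids, age, sex = NULL, race = NULL, bmi = NULL) {
  n <- length(ids)
  data.frame(
    sample_id = ids, age = age,
    sex = if (is.null(sex)) factor(rep(c("female", "male"), length.out = n),
                                   levels = c("female", "male")) else sex,
    race = if (is.null(race)) factor(rep(c("other", "white"), length.out = n),
                                     levels = c("other", "white")) else race,
    BMI = if (is.null(bmi)) rep(c(22, 27, 24, 29, 21, 26),
                                length.out = n) else bmi,
    stringsAsFactors = FALSE)
}

# Closed-form simple-OLS residuals (independent of lm/lm.fit): the oracle
# for residual aging scores.
olsResidOracle <- function(yhat, x) {
  b <- sum((x - mean(x)) * (yhat - mean(yhat))) / sum((x - mean(x))^2)
  a <- mean(yhat) - b * mean(x)
  yhat - (a + b * x)
}

# Hand leave-one-out simple OLS on one feature (explicit moment formulas).
looOracle1 <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    xi <- x[-i]; yi <- y[-i]
    b <- sum((xi - mean(xi)) * (yi - mean(yi))) / sum((xi - mean(xi))^2)
    a <- mean(yi) - b * mean(xi)
    a + b * x[i]
  }, numeric(1L))
}
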