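# Internal helpers: seeded evaluation and exact-precision delimited matrices.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Format doubles with 17 significant digits so write -> read round-trips
# bit-identically.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

# Write a samples x features matrix as CSV: first column sample IDs,
# header row feature IDs.  `mat` arrives features x samples (internal
# convention) and is transposed on the way out.
.writeMatrixCSV <- function(mat, path, idcol = "sample_id",
                            logical = FALSE) {
  tmat <- t(mat)
  header <- paste(c(idcol, colnames(tmat)), collapse = ",")
  rows <- vapply(seq_len(nrow(tmat)), function(i) {
    vals <- if (logical) as.character(tmat[i, ]) else .fmtNum(tmat[i, ])
    paste(c(rownames(tmat)[i], vals), collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
}

# Inverse of .writeMatrixCSV; returns a features x samples matrix.
.readMatrixCSV <- function(path, logical = FALSE) {
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L)
    stop("ragged rows in '", path, "'")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample ID in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (logical) storage.mode(m) <- "logical" else storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate feature ID in '", path, "'")
  t(m)
}

# Largest-remainder apportionment of n into counts proportional to `weights`.
.apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}
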