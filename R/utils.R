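# Internal helpers shared across modules.

#' @importFrom Matrix rowSums colSums colMeans t readMM writeMM sparseMatrix
#' @importFrom stats rnorm rnbinom rbinom runif quantile var sd p.adjust
#'   phyper wilcox.test t.test aov na.omit setNames
#' @importFrom utils read.delim write.table combn head
NULL

# Dense matrix coercion that tolerates sparse Matrix input.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so library code does not clobber user seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic fan-out of one pipeline seed into independent stage seeds.
# Changing or disabling one stage leaves the other stages' streams untouched.
child_seed <- function(seed, stage_index) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage_index)
}

# Seeded stochastic rounding: floor(x) + Bernoulli(frac(x)), so that expected
# value equals x and totals stay integers.
stochastic_round <- function(x) {
  lo <- floor(x)
  frac <- x - lo
  as.integer(lo + rbinom(length(x), 1L, frac))
}

# Brute-force k-nearest-neighbour search in Euclidean space.
# Returns an n x k integer matrix of neighbour indices (self excluded) and the
# matching distances. Ties are broken by index for determinism.
knn_brute <- function(coords, k) {
  coords <- as_dense(coords)
  n <- nrow(coords)
  if (k >= n) stop("`k` must be smaller than the number of cells", call. = FALSE)
  if (k <= 0L) stop("`k` must be positive", call. = FALSE)
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- sqrt(d2[i, o])
  }
  list(index = idx, dist = dst)
}

# Vector of detection fractions (share of cells with signal > 0) per gene.
detection_fraction <- function(mat, cells) {
  sub <- mat[cells, , drop = FALSE]
  Matrix::colMeans(sub > 0)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
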