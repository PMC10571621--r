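#' Representative cell: per-gene mean expression over a set of cells
#'
#' @param expr cells x genes log2(TP10K+1) matrix.
#' @param cell_indices Row indices or names of the cells to average.
#' @return Named numeric vector of per-gene means.
#' @export
representative_cell <- function(expr, cell_indices) {
  if (length(cell_indices) == 0L) stop("empty cell index set", call. = FALSE)
  Matrix::colMeans(expr[cell_indices, , drop = FALSE])
}

#' Euclidean distance between two groups' representative cells
#'
#' @param expr cells x genes expression matrix.
#' @param group_a_indices,group_b_indices Non-empty cell index sets.
#' @param genes Optional gene subset (ids or indices); all genes by default.
#' @return Non-negative scalar distance.
#' @export
shift_distance <- function(expr, group_a_indices, group_b_indices, genes = NULL) {
  if (!is.null(genes)) {
    if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
    expr <- expr[, genes, drop = FALSE]
  }
  a <- representative_cell(expr, group_a_indices)
  b <- representative_cell(expr, group_b_indices)
  sqrt(sum((a - b)^2))
}

#' Permutation test for a genotype-driven transcriptomic shift in one cell type
#'
#' The observed statistic is the Euclidean distance between the two
#' genotypes' representative cells (per-gene mean expression vectors)
#' within the cell type. The null distribution is built by randomly
#' reassigning genotype labels among the cell type's cells, preserving the
#' original group sizes, and recomputing the distance; the empirical
#' p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, so it is never
#' zero and is valid under exchangeability.
#'
#' @param expr cells x genes log2(TP10K+1) matrix.
#' @param meta Per-cell metadata with `genotype` and `cell_type` columns.
#' @param cell_type Cell type to test (needs >= 2 cells per genotype).
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @param genes Optional gene subset defining the feature space.
#' @return A `shift_result` list: `cell_type`, `n_cells_per_group`,
#'   `observed_distance`, `null_distances`, `p_empirical`, `p_bonferroni`
#'   (`NA` until set by [shift_test_all()]), `n_permutations`,
#'   `feature_space`, `seed`.
#' @export
permutation_shift_test <- function(expr, meta, cell_type,
                                   n_permutations = 1000, seed = 1L,
                                   genes = NULL) {
  stopifnot(n_permutations >= 1)
  cells <- which(meta$cell_type == cell_type)
  if (length(cells) == 0L) stop("cell type absent: ", cell_type, call. = FALSE)
  geno <- as.character(meta$genotype[cells])
  glev <- sort(unique(geno), decreasing = TRUE)  # "WT" before "TS"
  if (length(glev) != 2L)
    stop("cell type ", cell_type, " lacks one of the two genotypes", call. = FALSE)
  x <- as_dense(if (is.null(genes)) expr[cells, , drop = FALSE]
                else expr[cells, genes, drop = FALSE])
  ia <- which(geno == glev[1]); ib <- which(geno == glev[2])
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L)
    stop("cell type ", cell_type, " needs >= 2 cells per genotype", call. = FALSE)
  s_tot <- colSums(x)
  s_a <- colSums(x[ia, , drop = FALSE])
  delta <- s_a / na - (s_tot - s_a) / nb
  observed <- sqrt(sum(delta^2))
  n <- na + nb
  null_distances <- with_seed(seed, {
    ind <- matrix(0, n, n_permutations)
    for (p in seq_len(n_permutations))
      ind[sample.int(n, na), p] <- 1
    sp <- crossprod(x, ind)                       # genes x permutations
    dp <- sp * (1 / na + 1 / nb) - s_tot / nb     # mean_a - mean_b per perm
    sqrt(colSums(dp^2))
  })
  p_emp <- (1 + sum(null_distances >= observed - 1e-12)) / (1 + n_permutations)
  structure(list(
    cell_type = cell_type,
    n_cells_per_group = setNames(c(na, nb), glev),
    observed_distance = observed,
    null_distances = null_distances,
    p_empirical = p_emp,
    p_bonferroni = NA_real_,
    n_permutations = n_permutations,
    feature_space = if (is.null(genes)) "all-genes" else "subset",
    seed = as.integer(seed)
  ), class = "shift_result")
}

#' Shift test across all cell types with Bonferroni correction
#'
#' Runs [permutation_shift_test()] for every eligible cell type (>= 2 cells
#' per genotype; others are reported as skipped) and multiplies each
#' empirical p-value by the number of cell types actually tested, capped at
#' 1. Each cell type gets an independent child seed derived from `seed`.
#'
#' @inheritParams permutation_shift_test
#' @param cell_types Cell types to consider (default: all in `meta`).
#' @return A data.frame with one row per cell type: `cell_type`, `n_WT`,
#'   `n_TS`, `observed_distance`, `p_empirical`, `p_bonferroni`, `tested`;
#'   the full `shift_result` objects are attached as attribute
#'   `"results"`.
#' @export
shift_test_all <- function(expr, meta, cell_types = NULL,
                           n_permutations = 1000, seed = 1L, genes = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(as.character(meta$cell_type)))
  eligible <- vapply(cell_types, function(ct) {
    cells <- which(meta$cell_type == ct)
    tab <- table(as.character(meta$genotype[cells]))
    length(tab) == 2L && min(tab) >= 2L
  }, logical(1))
  if (!any(eligible)) stop("no eligible cell types", call. = FALSE)
  k <- sum(eligible)
  results <- list()
  rows <- lapply(seq_along(cell_types), function(i) {
    ct <- cell_types[i]
    if (!eligible[i]) {
      message("skipping ", ct, ": fewer than 2 cells in a genotype")
      return(data.frame(cell_type = ct, n_WT = NA_integer_, n_TS = NA_integer_,
                        observed_distance = NA_real_, p_empirical = NA_real_,
                        p_bonferroni = NA_real_, tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    res <- permutation_shift_test(expr, meta, ct, n_permutations,
                                  seed = child_seed(seed, i), genes = genes)
    res$p_bonferroni <- min(1, res$p_empirical * k)
    results[[ct]] <<- res
    ns <- res$n_cells_per_group
    data.frame(cell_type = ct,
               n_WT = unname(ns[grepl("^WT", names(ns))][1]),
               n_TS = unname(ns[!grepl("^WT", names(ns))][1]),
               observed_distance = res$observed_distance,
               p_empirical = res$p_empirical,
               p_bonferroni = res$p_bonferroni, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  attr(out, "n_tested") <- k
  out
}
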