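#' Diffusion-map embedding with a local-sigma Gaussian kernel
#'
#' Builds an anisotropic diffusion map over cells: a Gaussian kernel
#' `K(i,j) = exp(-||x_i - x_j||^2 / (sigma_i * sigma_j))` is evaluated on
#' the symmetrized union of k-nearest-neighbour pairs, with the local scale
#' `sigma_i` set to the distance from cell `i` to its `ceiling(k/2)`-th
#' nearest neighbour. The kernel is density-normalized (alpha = 1, entries
#' divided by the product of row sums) and row-normalized into a Markov
#' transition matrix, whose spectrum is obtained through the symmetric
#' conjugate matrix. The trivial constant eigenvector (eigenvalue 1) is
#' dropped; each returned component is the corresponding right eigenvector
#' scaled by its eigenvalue, with sign fixed so the largest-magnitude entry
#' is positive.
#'
#' @param pcs An `snshift_embedding` (typically the top 15 PCs) or a plain
#'   cells x d coordinate matrix.
#' @param k Neighbourhood size (default 30).
#' @param n_components Number of non-trivial components to return
#'   (default 2).
#' @return A `diffusion_embedding` list: `components` (cells x
#'   `n_components`, columns `DC1..`), `eigenvalues`, `trivial_eigenvalue`,
#'   `k`, `sigma_mode = "local"`, `sigmas`, and the sparse kernel (`kernel`)
#'   plus neighbour index matrix (`neighbors`) reused by [gene_relevance()].
#' @export
diffusion_map <- function(pcs, k = 30, n_components = 2) {
  coords <- if (inherits(pcs, "snshift_embedding")) pcs$coordinates else as_dense(pcs)
  n <- nrow(coords)
  if (k <= 0L) stop("`k` must be positive", call. = FALSE)
  if (k >= n) stop("`k` must be below the cell count", call. = FALSE)
  if (n < n_components + 2L) stop("too few cells for the requested components", call. = FALSE)
  nn <- knn_brute(coords, k)
  half <- ceiling(k / 2)
  sigma <- nn$dist[, half]
  if (any(sigma == 0)) {
    bad <- which(sigma == 0)
    warning(length(bad), " cell(s) with zero local sigma; using smallest ",
            "positive distance instead")
    for (i in bad) {
      d2i <- rowSums(sweep(coords, 2L, coords[i, ], "-")^2)
      pos <- d2i[d2i > 0]
      if (length(pos) == 0L)
        stop("all cells coincide; cannot set a local sigma", call. = FALSE)
      sigma[i] <- sqrt(min(pos))
    }
  }
  i_idx <- rep(seq_len(n), each = k)
  j_idx <- as.vector(t(nn$index))
  d2 <- as.vector(t(nn$dist))^2
  w <- exp(-d2 / (sigma[i_idx] * sigma[j_idx]))
  W <- Matrix::sparseMatrix(i = c(i_idx, j_idx), j = c(j_idx, i_idx),
                            x = c(w, w), dims = c(n, n), use.last.ij = TRUE)
  W <- methods::as(W, "CsparseMatrix")
  q <- Matrix::rowSums(W)
  Q <- Matrix::Diagonal(x = 1 / q) %*% W %*% Matrix::Diagonal(x = 1 / q)
  dd <- Matrix::rowSums(Q)
  S <- Matrix::Diagonal(x = 1 / sqrt(dd)) %*% Q %*% Matrix::Diagonal(x = 1 / sqrt(dd))
  S <- as.matrix((S + Matrix::t(S)) / 2)
  eg <- eigen(S, symmetric = TRUE)
  comp_idx <- 2L:(n_components + 1L)
  psi <- eg$vectors[, comp_idx, drop = FALSE] / sqrt(dd)
  lambda <- eg$values[comp_idx]
  comps <- sweep(psi, 2L, lambda, "*")
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  dimnames(comps) <- list(rownames(coords), paste0("DC", seq_len(n_components)))
  structure(list(components = comps, eigenvalues = lambda,
                 trivial_eigenvalue = eg$values[1], k = k,
                 sigma_mode = "local", sigmas = sigma,
                 kernel = W, neighbors = nn$index,
                 input = sprintf("top-%d coords", ncol(coords))),
            class = "diffusion_embedding")
}

#' Gene relevance: gradient-magnitude ranking of embedding drivers
#'
#' Estimates, for every cell and gene, the local partial derivative of each
#' diffusion component with respect to the gene's expression by weighted
#' least squares over the cell's kernel neighbours:
#' `d_hat = sum_j w_ij * dDC * dE / sum_j w_ij * dE^2` (0 when the
#' denominator is 0). The per-cell derivative field is then smoothed over
#' the same kernel neighbourhoods (one step of kernel-weighted averaging of
#' the signed derivatives), which cancels the sampling noise of
#' uninformative genes while leaving spatially coherent gradients intact.
#' The per-cell relevance is the Euclidean norm of the smoothed
#' component-wise derivatives multiplied by the gene's expression standard
#' deviation, making units comparable across genes without being dominated
#' by single-cell outliers; global relevance is the mean over cells. A gene
#' constant across all cells has relevance exactly 0. Ties in the ranking
#' are broken by gene id.
#'
#' @param embedding A `diffusion_embedding` from [diffusion_map()].
#' @param expr cells x genes log2(TP10K+1) matrix over the same cells.
#' @param smooth Number of kernel-smoothing passes over the gradient field
#'   (default 1; 0 disables smoothing).
#' @param ridge Regularization of the least-squares denominator as a
#'   fraction of the gene's global variance (default 0.05), so locally
#'   near-constant genes do not produce unstable derivative estimates.
#' @return A `relevance_result` list: `global` (named, per gene),
#'   `per_cell` (cells x genes matrix), `ranking` (gene ids by decreasing
#'   global relevance), `gene_scale`.
#' @export
gene_relevance <- function(embedding, expr, smooth = 1L, ridge = 0.05) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  x <- as_dense(expr)
  comps <- embedding$components
  if (nrow(x) != nrow(comps))
    stop("`expr` and embedding must share cells", call. = FALSE)
  n <- nrow(x); G <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("gene", seq_len(G))
  sdev <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, 0))
  d <- ncol(comps)
  W <- embedding$kernel
  # signed per-cell gradients, one (cells x genes) slab per component
  grads <- lapply(seq_len(d), function(m)
    matrix(0, n, G, dimnames = list(rownames(x), colnames(x))))
  for (i in seq_len(n)) {
    jj <- which(W[i, ] > 0)
    if (length(jj) == 0L) next
    w <- W[i, jj]
    dE <- x[jj, , drop = FALSE] -
      matrix(x[i, ], length(jj), G, byrow = TRUE)
    dC <- comps[jj, , drop = FALSE] -
      matrix(comps[i, ], length(jj), d, byrow = TRUE)
    # ridge term (fraction of the gene's global variance) keeps slopes
    # finite where a gene is locally near-constant
    denom <- colSums(w * dE^2) + ridge * sdev^2 * sum(w)
    numer <- crossprod(dE, w * dC)            # genes x components
    grad <- numer / ifelse(denom > 0, denom, 1)
    grad[denom == 0, ] <- 0
    for (m in seq_len(d)) grads[[m]][i, ] <- grad[, m]
  }
  if (smooth > 0L) {
    # row-normalized kernel with self-weight for gradient-field smoothing
    P <- W + Matrix::Diagonal(n)
    P <- Matrix::Diagonal(x = 1 / Matrix::rowSums(P)) %*% P
    for (s in seq_len(smooth))
      grads <- lapply(grads, function(gm) as.matrix(P %*% gm))
  }
  per_cell <- sqrt(Reduce(`+`, lapply(grads, function(gm) gm^2)))
  per_cell <- sweep(per_cell, 2L, sdev, "*")
  dimnames(per_cell) <- list(rownames(x), colnames(x))
  global <- colMeans(per_cell)
  ranking <- names(global)[order(-global, names(global))]
  structure(list(global = global, per_cell = per_cell,
                 ranking = ranking, gene_scale = sdev),
            class = "relevance_result")
}

#' Local gene relevance over a cell subset
#'
#' Mean per-cell relevance restricted to a subset of cells; with the full
#' cell set this equals the global relevance.
#'
#' @param result A `relevance_result` from [gene_relevance()].
#' @param cell_subset Non-empty row indices or names into the cell set.
#' @return Named numeric vector of per-gene local relevance.
#' @export
local_relevance <- function(result, cell_subset) {
  stopifnot(inherits(result, "relevance_result"))
  if (length(cell_subset) == 0L) stop("empty cell subset", call. = FALSE)
  colMeans(result$per_cell[cell_subset, , drop = FALSE])
}
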