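#' Quality-control filtering of cells and genes
#'
#' Removes low-quality nuclei and probable duplets, then rarely detected
#' genes, in two fixed passes: first cells whose detected-gene count (genes
#' with at least one UMI) is strictly below `min_genes` or strictly above
#' `max_genes`; then genes detected in fewer than `min_cells` of the
#' surviving cells. The boundary semantics follow "fewer than" / "more
#' than": a cell with exactly `min_genes` (or `max_genes`) detected genes is
#' kept, and a gene detected in exactly `min_cells` cells is kept. The
#' operation is idempotent.
#'
#' @param counts Sparse cells x genes count matrix with dimnames.
#' @param min_genes,max_genes Detected-gene bounds per cell (defaults 200
#'   and 2500).
#' @param min_cells Minimum number of surviving cells a gene must be
#'   detected in (default 6).
#' @return The filtered count matrix.
#' @export
qc_filter <- function(counts, min_genes = 200, max_genes = 2500, min_cells = 6) {
  stopifnot(min_genes > 0, max_genes > 0, min_cells > 0, min_genes < max_genes)
  detected <- Matrix::rowSums(counts > 0)
  keep_cells <- detected >= min_genes & detected <= max_genes
  if (!any(keep_cells))
    stop("no cells survive the detected-gene filter [", min_genes, ", ",
         max_genes, "]", call. = FALSE)
  out <- counts[keep_cells, , drop = FALSE]
  keep_genes <- Matrix::colSums(out > 0) >= min_cells
  out[, keep_genes, drop = FALSE]
}

#' TP10K log normalization
#'
#' Rescales each cell's counts to transcripts-per-10,000 and log-transforms:
#' `E[i, j] = log2(c[i, j] / sum_j(c[i, ]) * 10000 + 1)`. Cells with no
#' counts map to all-zero rows.
#'
#' @param counts Sparse cells x genes count matrix.
#' @return A sparse cells x genes matrix of log2(TP10K + 1) values with a
#'   `"provenance"` attribute.
#' @export
normalize_tp10k <- function(counts) {
  lib <- Matrix::rowSums(counts)
  scale <- ifelse(lib > 0, 1e4 / lib, 0)
  expr <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  expr <- Matrix::Diagonal(x = scale) %*% expr
  expr <- methods::as(expr, "CsparseMatrix")
  expr@x <- log2(expr@x + 1)
  dimnames(expr) <- dimnames(counts)
  attr(expr, "provenance") <- "log2(TP10K+1)"
  expr
}

#' Per-gene scaling and centering
#'
#' Z-scores each gene across cells using the population standard deviation
#' (divisor `n`), then clips values to `[-clip, clip]`. Genes constant
#' across cells become all-zero columns.
#'
#' @param expr cells x genes expression matrix (typically log2(TP10K+1)).
#' @param clip Clipping bound (default 10).
#' @return A dense cells x genes matrix with a `"clip_bound"` attribute.
#' @export
scale_genes <- function(expr, clip = 10) {
  stopifnot(clip > 0)
  x <- as_dense(expr)
  n <- nrow(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(x^2) - mu^2)
  sdev[sdev < .Machine$double.eps^0.5 * pmax(1, abs(mu))] <- 0
  xc <- sweep(x, 2L, mu, "-")
  nz <- sdev > 0
  xc[, nz] <- sweep(xc[, nz, drop = FALSE], 2L, sdev[nz], "/")
  xc[, !nz] <- 0
  xc[xc > clip] <- clip
  xc[xc < -clip] <- -clip
  attr(xc, "clip_bound") <- clip
  xc
}

#' Remove additive batch structure by per-batch gene centering
#'
#' Subtracts, for each gene, the per-batch mean. An additive per-batch
#' offset is removed exactly; with a single batch the input is returned
#' centered per gene (an identity for already-centered scaled data).
#'
#' @param scaled cells x genes matrix (typically from [scale_genes()]).
#' @param batches Batch label per cell (length `nrow(scaled)`).
#' @return The batch-centered matrix.
#' @export
batch_center <- function(scaled, batches) {
  x <- as_dense(scaled)
  if (length(batches) != nrow(x))
    stop("`batches` must have one label per cell", call. = FALSE)
  if (anyNA(batches)) stop("missing batch labels", call. = FALSE)
  for (b in unique(batches)) {
    rows <- which(batches == b)
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2L,
                       colMeans(x[rows, , drop = FALSE]), "-")
  }
  attr(x, "clip_bound") <- attr(scaled, "clip_bound")
  x
}

#' Select highly variable genes by binned dispersion
#'
#' Computes, per gene, the mean and dispersion (variance/mean) of the
#' back-transformed TP10K values (`2^E - 1`), bins genes into 20 mean
#' quantile bins, z-scores dispersions within each bin and ranks genes by
#' the standardized dispersion. Ties are broken lexicographically by gene
#' id; genes with zero mean rank last.
#'
#' @param expr cells x genes log2(TP10K+1) matrix with gene column names.
#' @param n_top Number of genes to return (default 2000, capped at the
#'   gene count).
#' @param n_bins Number of mean bins (default 20).
#' @return Character vector of `n_top` gene ids, ranked.
#' @export
select_hvg <- function(expr, n_top = 2000, n_bins = 20) {
  x <- as_dense(expr)
  stopifnot(!is.null(colnames(x)), n_top >= 1)
  n_top <- min(n_top, ncol(x))
  tp <- 2^x - 1
  mu <- colMeans(tp)
  v <- apply(tp, 2L, var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  breaks <- unique(quantile(mu[mu > 0], probs = seq(0, 1, length.out = n_bins + 1),
                            na.rm = TRUE))
  score <- rep(-Inf, ncol(x))
  if (length(breaks) >= 2) {
    bin <- cut(mu, breaks = breaks, include.lowest = TRUE)
    for (b in levels(bin)) {
      idx <- which(bin == b & !is.na(disp))
      if (length(idx) == 0L) next
      m <- mean(disp[idx]); s <- sd(disp[idx])
      score[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
    }
  } else {
    score[!is.na(disp)] <- disp[!is.na(disp)]
  }
  ord <- order(-score, colnames(x))
  colnames(x)[ord][seq_len(n_top)]
}

#' Principal component analysis of the scaled matrix
#'
#' Computes cell scores on the top principal components of the gene-centered
#' matrix via an exact eigendecomposition of the smaller Gram matrix.
#' Component signs are fixed by making the largest-magnitude gene loading of
#' each component positive, so results are reproducible across runs and cell
#' orderings.
#'
#' @param scaled cells x genes matrix (typically scaled, batch-centered).
#' @param n_components Number of components (default 60, must not exceed
#'   `min(dim(scaled))`).
#' @return An `snshift_embedding` list: `coordinates` (cells x d scores),
#'   `explained_values` (component variances, non-increasing), `loadings`
#'   (genes x d), `method = "PCA"`.
#' @export
run_pca <- function(scaled, n_components = 60) {
  x <- as_dense(scaled)
  n <- nrow(x); g <- ncol(x)
  if (n_components > min(n, g))
    stop("`n_components` exceeds min(cells, genes)", call. = FALSE)
  xc <- sweep(x, 2L, colMeans(x), "-")
  d <- n_components
  if (g <= n) {
    eg <- eigen(crossprod(xc), symmetric = TRUE)
    load <- eg$vectors[, seq_len(d), drop = FALSE]
    scores <- xc %*% load
    ev <- eg$values[seq_len(d)]
  } else {
    eg <- eigen(tcrossprod(xc), symmetric = TRUE)
    u <- eg$vectors[, seq_len(d), drop = FALSE]
    ev <- eg$values[seq_len(d)]
    sv <- sqrt(pmax(ev, 0))
    load <- crossprod(xc, u)
    load <- sweep(load, 2L, ifelse(sv > 0, sv, 1), "/")
    scores <- sweep(u, 2L, sv, "*")
  }
  for (j in seq_len(d)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(d)))
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(d)))
  structure(list(coordinates = scores,
                 explained_values = pmax(ev, 0) / max(1, n - 1),
                 loadings = load, method = "PCA"),
            class = "snshift_embedding")
}
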