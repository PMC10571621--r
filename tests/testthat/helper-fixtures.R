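# Shared fixtures and independent oracles used across test files.

# Seeded random toy count matrix (cells x genes, sparse-compatible dense).
toy_counts <- function(n_cells, n_genes, seed = 1, lambda = 2) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
    dimnames(m) <- list(sprintf("c%03d", seq_len(n_cells)),
                        sprintf("g%03d", seq_len(n_genes)))
    Matrix::Matrix(m, sparse = TRUE)
  })
}

# Small, fast simulation configuration for structural tests; any field can
# be overridden through `...`.
small_config <- function(seed = 1, ...) {
  args <- list(n_cell_types = 3L, cells_per_type_per_sample = 15L,
               n_genes = 300L, n_markers_per_type = 15L, n_dosage_genes = 5L,
               library_size_mean = 600, seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# Adjusted Rand index, written independently of any clustering code.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force QC oracle: direct double pass with explicit loops.
qc_oracle <- function(m, min_genes, max_genes, min_cells) {
  m <- as.matrix(m)
  keep_cells <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    d <- sum(m[i, ] > 0)
    keep_cells[i] <- d >= min_genes && d <= max_genes
  }
  m2 <- m[keep_cells, , drop = FALSE]
  keep_genes <- logical(ncol(m2))
  for (j in seq_len(ncol(m2)))
    keep_genes[j] <- sum(m2[, j] > 0) >= min_cells
  m2[, keep_genes, drop = FALSE]
}

# Benjamini-Hochberg step-up oracle, written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- Inf
  for (k in n:1) {
    cummin_rev <- min(cummin_rev, p[o[k]] * n / k)
    adj[o[k]] <- min(1, cummin_rev)
  }
  adj
}

# Exact upper-tail hypergeometric sum from the combinatorial definition.
hyper_oracle <- function(overlap, set_size, query_size, universe) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe - set_size, query_size - ks)) /
    choose(universe, query_size)
}

# Independent dense construction of the diffusion operator, mirroring the
# documented kernel: local-sigma Gaussian on the symmetrized kNN union,
# alpha = 1 density normalization, row-normalized transition matrix.
dense_diffusion_oracle <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nbr <- lapply(1:n, function(i) order(d[i, ], 1:n)[1:k])
  sigma <- sapply(1:n, function(i) sort(d[i, ])[ceiling(k / 2)])
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in nbr[[i]]) {
    w <- exp(-d[i, j]^2 / (sigma[i] * sigma[j]))
    W[i, j] <- w; W[j, i] <- w
  }
  q <- rowSums(W)
  Q <- W / outer(q, q)
  P <- Q / rowSums(Q)
  eg <- eigen(P)
  ord <- order(-Re(eg$values))
  list(values = Re(eg$values)[ord], vectors = Re(eg$vectors)[, ord])
}

# Within-cell-type diffusion + gene relevance, the standard recipe: subset
# HVGs, scale, batch-centre, top PCs, local-sigma diffusion map.
relevance_for_type <- function(expr, meta, cell_type, n_hvg = 300,
                               n_pcs = 15, k = 30) {
  cells <- which(meta$cell_type == cell_type)
  hvg <- select_hvg(expr[cells, , drop = FALSE], n_hvg)
  scaled <- batch_center(scale_genes(expr[cells, hvg, drop = FALSE]),
                         meta$batch[cells])
  dm <- diffusion_map(run_pca(scaled, n_pcs), k = k, n_components = 2)
  list(dm = dm, rel = gene_relevance(dm, expr[cells, , drop = FALSE]),
       cells = cells)
}

# QC + normalization front-end with thresholds proportionate to the small
# test panels (the full-scale defaults assume thousands of genes).
prep_sim <- function(sim, min_genes = 50) {
  counts <- qc_filter(sim$counts, min_genes = min_genes,
                      max_genes = ncol(sim$counts), min_cells = 6)
  expr <- normalize_tp10k(counts)
  meta <- sim$cell_meta[match(rownames(counts), sim$cell_meta$barcode), ]
  list(counts = counts, expr = expr, meta = meta)
}
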