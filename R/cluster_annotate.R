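#' Shared-nearest-neighbour graph on an embedding
#'
#' Finds each cell's `k` nearest neighbours (Euclidean, exact search) in the
#' embedding and builds an undirected graph over the symmetrized
#' neighbour pairs. The edge weight between two cells is the Jaccard overlap
#' of their neighbourhoods, where a cell's neighbourhood is itself plus its
#' `k` nearest neighbours; zero-weight edges are dropped and self-edges are
#' excluded.
#'
#' @param embedding An `snshift_embedding` (or a plain cells x d matrix).
#' @param k Neighbourhood size (default 20), must be below the cell count.
#' @return A weighted undirected `igraph` graph with cell names as vertices.
#' @export
knn_graph <- function(embedding, k = 20) {
  coords <- if (inherits(embedding, "snshift_embedding"))
    embedding$coordinates else as_dense(embedding)
  n <- nrow(coords)
  nn <- knn_brute(coords, k)
  # neighbourhood sets: self + k nearest
  hoods <- lapply(seq_len(n), function(i) c(i, nn$index[i, ]))
  pairs <- unique(rbind(
    cbind(rep(seq_len(n), each = k), as.vector(t(nn$index)))))
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, c(2, 1)]
  pairs <- unique(pairs)
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- hoods[[pairs[r, 1]]]; b <- hoods[[pairs[r, 2]]]
    ov <- length(intersect(a, b))
    ov / (2 * (k + 1) - ov)
  }, numeric(1))
  keep <- w > 0
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  igraph::V(g)$name <- rownames(coords) %||% as.character(seq_len(n))
  g
}

#' Leiden community detection on the SNN graph
#'
#' Runs modularity-optimizing Leiden clustering at the given resolution and
#' relabels communities by decreasing size so labels are stable. Cluster ids
#' are contiguous integers starting at 0. Deterministic given `seed`.
#'
#' @param graph Weighted `igraph` graph from [knn_graph()].
#' @param resolution Resolution parameter (default 0.6).
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations (default 10).
#' @return Named integer vector of per-cell cluster ids with a
#'   `"resolution"` attribute.
#' @export
cluster_graph <- function(graph, resolution = 0.6, seed = 1L, n_iterations = 10L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph", call. = FALSE)
  stopifnot(resolution > 0)
  memb <- with_seed(seed, igraph::cluster_leiden(
    graph, objective_function = "modularity",
    resolution = resolution, weights = igraph::E(graph)$weight,
    n_iterations = n_iterations)$membership)
  sizes <- table(memb)
  new_id <- setNames(seq_along(sizes) - 1L,
                     names(sizes)[order(-as.integer(sizes), as.integer(names(sizes)))])
  labels <- unname(new_id[as.character(memb)])
  names(labels) <- igraph::V(graph)$name
  attr(labels, "resolution") <- resolution
  labels
}

#' Cluster marker genes with effect-size and detection filters
#'
#' One-vs-rest comparison per cluster: the log-fold change is the difference
#' of mean log2(TP10K+1) expression between the cluster and all other cells,
#' and the detection fraction within the cluster is computed separately for
#' each genotype. A gene is retained as a marker when its log-fold change
#' exceeds `lfc_min` and it is detected in more than `pct_min` of the
#' cluster's cells in both genotypes. Retained genes get a Wilcoxon
#' rank-sum p-value (cluster vs rest) with Benjamini-Hochberg adjustment
#' within cluster; rows are sorted by decreasing log-fold change.
#'
#' @param expr cells x genes log2(TP10K+1) matrix.
#' @param labels Per-cell cluster ids (as from [cluster_graph()]).
#' @param genotypes Per-cell genotype labels (two levels).
#' @param lfc_min Log-fold-change threshold (default 0.25, strict).
#' @param pct_min Per-genotype detection threshold (default 0.20, strict).
#' @return A data.frame with columns `cluster`, `gene`, `log_fold_change`,
#'   `pct_in`, `pct_out`, `pct_in_WT`, `pct_in_TS`, `p_value`, `p_adjusted`.
#' @export
find_markers <- function(expr, labels, genotypes, lfc_min = 0.25, pct_min = 0.20) {
  x <- as_dense(expr)
  stopifnot(length(labels) == nrow(x), length(genotypes) == nrow(x))
  glev <- sort(unique(as.character(genotypes)))
  if (length(glev) != 2L) stop("`genotypes` must have exactly two levels", call. = FALSE)
  out <- list()
  for (cl in sort(unique(labels))) {
    inside <- which(labels == cl)
    if (length(inside) < 3L) {
      warning("cluster ", cl, " has fewer than 3 cells; markers skipped")
      next
    }
    outside <- which(labels != cl)
    if (length(outside) == 0L) next
    mean_in <- colMeans(x[inside, , drop = FALSE])
    mean_out <- colMeans(x[outside, , drop = FALSE])
    lfc <- mean_in - mean_out
    pct_in <- colMeans(x[inside, , drop = FALSE] > 0)
    pct_out <- colMeans(x[outside, , drop = FALSE] > 0)
    ga <- inside[genotypes[inside] == glev[1]]
    gb <- inside[genotypes[inside] == glev[2]]
    if (length(ga) == 0L || length(gb) == 0L) {
      warning("cluster ", cl, " lacks cells of one genotype; markers skipped")
      next
    }
    pct_a <- colMeans(x[ga, , drop = FALSE] > 0)
    pct_b <- colMeans(x[gb, , drop = FALSE] > 0)
    keep <- which(lfc > lfc_min & pct_a > pct_min & pct_b > pct_min)
    if (length(keep) == 0L) next
    p <- vapply(keep, function(j)
      suppressWarnings(wilcox.test(x[inside, j], x[outside, j])$p.value),
      numeric(1))
    df <- data.frame(
      cluster = cl, gene = colnames(x)[keep],
      log_fold_change = unname(lfc[keep]),
      pct_in = unname(pct_in[keep]), pct_out = unname(pct_out[keep]),
      p_value = p, p_adjusted = p.adjust(p, "BH"),
      stringsAsFactors = FALSE)
    df$pct_in_WT <- unname((if (glev[1] == "WT") pct_a else pct_b)[keep])
    df$pct_in_TS <- unname((if (glev[1] == "WT") pct_b else pct_a)[keep])
    out[[length(out) + 1L]] <- df[order(-df$log_fold_change, df$gene), ]
  }
  if (length(out) == 0L)
    return(data.frame(cluster = integer(0), gene = character(0),
                      log_fold_change = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), pct_in_WT = numeric(0),
                      pct_in_TS = numeric(0)))
  do.call(rbind, out)
}

# Jaccard coefficient between two sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Map clusters to reference regions by marker-set Jaccard overlap
#'
#' For each cluster, takes its top `top_n` markers by log-fold change and
#' computes the Jaccard coefficient against every reference region gene
#' set, plus an upper-tail hypergeometric overlap p-value given the gene
#' universe size. Each cluster is assigned the region with the largest
#' Jaccard coefficient (ties broken by smaller p-value, then region name).
#'
#' @param markers Marker table from [find_markers()].
#' @param reference Named list of region gene sets.
#' @param top_n Markers per cluster to use (default 300; all if fewer).
#' @param universe_size Number of genes in the universe (e.g. all genes
#'   passing QC).
#' @return A list with `jaccard` (clusters x regions matrix), `p_values`
#'   (same shape), and `assignment` (named character vector cluster ->
#'   region).
#' @export
jaccard_map <- function(markers, reference, top_n = 300, universe_size) {
  stopifnot(top_n >= 1)
  if (length(reference) == 0L) stop("empty reference", call. = FALSE)
  clusters <- sort(unique(markers$cluster))
  regions <- names(reference)
  J <- matrix(0, length(clusters), length(regions),
              dimnames = list(as.character(clusters), regions))
  P <- J + 1
  for (ci in seq_along(clusters)) {
    rows <- markers[markers$cluster == clusters[ci], ]
    rows <- rows[order(-rows$log_fold_change, rows$gene), ]
    a <- head(rows$gene, top_n)
    for (ri in seq_along(regions)) {
      b <- reference[[ri]]
      ov <- length(intersect(a, b))
      J[ci, ri] <- jaccard(a, b)
      P[ci, ri] <- phyper(ov - 1L, length(b), universe_size - length(b),
                          length(a), lower.tail = FALSE)
    }
  }
  assignment <- vapply(seq_along(clusters), function(ci) {
    ord <- order(-J[ci, ], P[ci, ], regions)
    regions[ord[1]]
  }, character(1))
  names(assignment) <- as.character(clusters)
  list(jaccard = J, p_values = P, assignment = assignment)
}

#' Per-sample marker-identity score for one cell type
#'
#' Measures, for each sample separately, how well the cell type's marker
#' programme matches its reference region set: within each sample, genes are
#' ranked by the one-vs-rest difference in mean log expression (that
#' sample's cells of the type vs its other cells), the top `top_n` genes
#' are taken, and the Jaccard coefficient against the reference set of
#' `region` is recorded. Genotype differences in the per-sample scores are
#' tested by one-way ANOVA.
#'
#' @param expr cells x genes log2(TP10K+1) matrix.
#' @param cell_types Per-cell cell-type labels.
#' @param cell_type The cell type to score.
#' @param sample_ids Per-cell sample ids.
#' @param genotypes Per-cell genotype labels.
#' @param reference Named list of region gene sets.
#' @param region Name of the reference set to compare against (typically
#'   the region assigned to this cell type).
#' @param top_n Genes per sample ranking (default 300).
#' @param min_cells Minimum cells of the type a sample must contribute
#'   (default 10; smaller samples are skipped with a warning).
#' @return A list with `scores` (data.frame: `sample`, `genotype`,
#'   `jaccard`) and `p_value` (ANOVA genotype effect; `NA` when fewer than
#'   two genotypes remain).
#' @export
marker_identity_score <- function(expr, cell_types, cell_type, sample_ids,
                                  genotypes, reference, region,
                                  top_n = 300, min_cells = 10) {
  x <- as_dense(expr)
  if (!cell_type %in% cell_types) stop("cell type absent", call. = FALSE)
  if (!region %in% names(reference)) stop("unknown region: ", region, call. = FALSE)
  ref <- reference[[region]]
  rows <- list()
  for (s in sort(unique(sample_ids))) {
    sc <- which(sample_ids == s)
    inside <- sc[cell_types[sc] == cell_type]
    outside <- sc[cell_types[sc] != cell_type]
    if (length(inside) < min_cells) {
      warning("sample ", s, " has fewer than ", min_cells,
              " cells of ", cell_type, "; skipped")
      next
    }
    diff <- colMeans(x[inside, , drop = FALSE]) -
      colMeans(x[outside, , drop = FALSE])
    top <- colnames(x)[order(-diff, colnames(x))][seq_len(min(top_n, ncol(x)))]
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, genotype = as.character(genotypes[sc[1]]),
      jaccard = jaccard(top, ref), stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  p <- NA_real_
  if (!is.null(scores) && length(unique(scores$genotype)) >= 2) {
    fit <- aov(jaccard ~ genotype, data = scores)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  list(scores = scores, p_value = p)
}
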