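test_that("SNN graph separates distant blobs and unifies duplicated points", {
  set.seed(12)
  blob1 <- matrix(rnorm(40, 0, 0.1), 20, 2)
  blob2 <- matrix(rnorm(40, 50, 0.1), 20, 2)
  coords <- rbind(blob1, blob2)
  rownames(coords) <- paste0("c", 1:40)
  g <- knn_graph(coords, k = 10)
  el <- igraph::as_edgelist(g, names = FALSE)
  # no edges across the two blobs when k is below the blob size
  expect_true(all((el[, 1] <= 20) == (el[, 2] <= 20)))

  # duplicated points share their entire neighbourhood: weight 1
  dup <- rbind(coords, coords[1, , drop = FALSE], coords[1, , drop = FALSE])
  rownames(dup) <- paste0("c", 1:42)
  g2 <- knn_graph(dup, k = 10)
  w <- igraph::E(g2)$weight[igraph::get_edge_ids(g2, c("c41", "c42"))]
  expect_equal(w, 1)
})

test_that("SNN graph equals a brute-force all-pairs construction", {
  set.seed(13)
  coords <- matrix(rnorm(100 * 3), 100, 3)
  rownames(coords) <- sprintf("c%03d", 1:100)
  k <- 8
  g <- knn_graph(coords, k = k)

  # independent O(n^2) oracle
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nbr <- lapply(1:100, function(i) order(d[i, ], 1:100)[1:k])
  hood <- lapply(1:100, function(i) c(i, nbr[[i]]))
  edges <- list()
  for (i in 1:99) for (j in (i + 1):100) {
    if (j %in% nbr[[i]] || i %in% nbr[[j]]) {
      ov <- length(intersect(hood[[i]], hood[[j]]))
      w <- ov / (2 * (k + 1) - ov)
      if (w > 0) edges[[length(edges) + 1]] <- c(i, j, w)
    }
  }
  oracle <- do.call(rbind, edges)
  el <- cbind(igraph::as_edgelist(g, names = FALSE), igraph::E(g)$weight)
  el[, 1:2] <- t(apply(el[, 1:2], 1, sort))
  el <- el[order(el[, 1], el[, 2]), ]
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), ]
  expect_equal(unname(el), unname(oracle), tolerance = 1e-12)
})

test_that("Leiden clustering separates components and is deterministic", {
  # two disconnected 10-cliques
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("c", 1:20)
  cl <- cluster_graph(g, resolution = 0.6, seed = 4)
  expect_equal(sort(unique(cl)), c(0L, 1L))
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  expect_identical(cl, cluster_graph(g, resolution = 0.6, seed = 4))
  expect_error(cluster_graph(igraph::make_empty_graph(0)), "empty")
})

test_that("clustering recovers the planted five-type structure", {
  for (s in 1:2) {
    sim <- simulate_dataset(sim_config(seed = 40 + s))
    prep <- prep_sim(sim, min_genes = 200)
    hvg <- select_hvg(prep$expr, 2000)
    scaled <- batch_center(scale_genes(prep$expr[, hvg]), prep$meta$batch)
    pcs <- run_pca(scaled, 60)
    cl <- cluster_graph(knn_graph(pcs, 20), 0.6, seed = s)
    expect_gte(adjusted_rand(cl, prep$meta$cell_type), 0.9)
  }
})

test_that("marker detection applies the stated thresholds per genotype", {
  # 2 clusters x 20 cells, half WT half TS in each
  set.seed(71)
  n <- 40
  labels <- rep(c(0L, 1L), each = 20)
  genotypes <- rep(rep(c("WT", "TS"), each = 10), 2)
  expr <- matrix(runif(n * 4, 0, 0.01), n, 4,
                 dimnames = list(paste0("c", 1:n),
                                 c("flat", "good", "wt_only", "weak")))
  expr[, "flat"] <- 1
  # good: high in cluster 0, detected in 50% of each genotype there
  expr[1:5, "good"] <- 3; expr[11:15, "good"] <- 3
  # wt_only: high in cluster 0 but detected in only 10% of TS cells
  expr[1:9, "wt_only"] <- 3; expr[11, "wt_only"] <- 3
  expr[expr[, "wt_only"] < 3, "wt_only"] <- 0
  mk <- find_markers(expr, labels, genotypes, lfc_min = 0.25, pct_min = 0.20)
  g0 <- mk$gene[mk$cluster == 0]
  expect_true("good" %in% g0)
  expect_false("wt_only" %in% g0)
  expect_false("flat" %in% mk$gene)
  expect_true(all(mk$log_fold_change > 0.25))
  expect_true(all(mk$pct_in_WT > 0.2 & mk$pct_in_TS > 0.2))
})

test_that("marker table matches an exhaustive per-gene oracle on a toy", {
  set.seed(72)
  n <- 60; G <- 30
  labels <- rep(0:2, each = 20)
  genotypes <- rep(rep(c("WT", "TS"), each = 10), 3)
  expr <- matrix(rexp(n * G, 2), n, G,
                 dimnames = list(paste0("c", 1:n), sprintf("g%02d", 1:G)))
  expr[labels == 1, 1:5] <- expr[labels == 1, 1:5] + 1.5
  mk <- find_markers(expr, labels, genotypes)

  oracle <- list()
  for (cl in 0:2) {
    for (j in seq_len(G)) {
      inside <- labels == cl
      lfc <- mean(expr[inside, j]) - mean(expr[!inside, j])
      pw <- mean(expr[inside & genotypes == "WT", j] > 0)
      pt <- mean(expr[inside & genotypes == "TS", j] > 0)
      if (lfc > 0.25 && pw > 0.2 && pt > 0.2)
        oracle[[length(oracle) + 1]] <- paste(cl, colnames(expr)[j])
    }
  }
  expect_setequal(paste(mk$cluster, mk$gene), unlist(oracle))
  # invariant to cell order
  perm <- sample(n)
  mk2 <- find_markers(expr[perm, ], labels[perm], genotypes[perm])
  expect_equal(mk2[order(mk2$cluster, mk2$gene), ],
               mk[order(mk$cluster, mk$gene), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Jaccard mapping follows set arithmetic and is symmetric", {
  mk <- data.frame(cluster = rep(0:1, each = 300),
                   gene = c(sprintf("a%03d", 1:300), sprintf("b%03d", 1:300)),
                   log_fold_change = rep(seq(3, 0.3, length.out = 300), 2))
  ref <- list(
    regionA = sprintf("a%03d", 1:300),                       # identical to cluster 0
    regionB = c(sprintf("a%03d", 1:100), sprintf("x%03d", 1:200)),  # 100 shared
    regionC = sprintf("z%03d", 1:300))                       # disjoint
  jm <- jaccard_map(mk, ref, top_n = 300, universe_size = 2000)
  expect_equal(jm$jaccard["0", "regionA"], 1)
  expect_equal(jm$jaccard["0", "regionB"], 100 / 500)
  expect_equal(jm$jaccard["0", "regionC"], 0)
  expect_equal(unname(jm$assignment["0"]), "regionA")
  # symmetry: treating the reference as the query changes nothing
  mk_t <- data.frame(cluster = 0L, gene = ref$regionB,
                     log_fold_change = seq(3, 0.3, length.out = 300))
  ref_t <- list(r = mk$gene[mk$cluster == 0])
  jm_t <- jaccard_map(mk_t, ref_t, top_n = 300, universe_size = 2000)
  expect_equal(unname(jm_t$jaccard["0", "r"]), unname(jm$jaccard["0", "regionB"]))
  expect_error(jaccard_map(mk, list(), 300, 2000), "empty")
})

test_that("per-sample identity scores hit 1 on perfect agreement and are deterministic", {
  set.seed(73)
  n <- 60
  cell_types <- rep(c("A", "B"), each = 30)
  samples <- rep(rep(c("s1", "s2"), each = 15), 2)
  genotypes <- rep(rep(c("WT", "TS"), each = 15), 2)
  expr <- matrix(runif(n * 20, 0, 0.01), n, 20,
                 dimnames = list(paste0("c", 1:n), sprintf("g%02d", 1:20)))
  expr[cell_types == "A", 1:5] <- expr[cell_types == "A", 1:5] + 2
  ref <- list(regA = sprintf("g%02d", 1:5))
  ms <- marker_identity_score(expr, cell_types, "A", samples, genotypes,
                              ref, "regA", top_n = 5)
  expect_equal(ms$scores$jaccard, c(1, 1))
  ms2 <- marker_identity_score(expr, cell_types, "A", samples, genotypes,
                               ref, "regA", top_n = 5)
  expect_identical(ms$scores, ms2$scores)
  expect_error(marker_identity_score(expr, cell_types, "Z", samples,
                                     genotypes, ref, "regA"), "absent")
})
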