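test_that("DE filters follow one-group detection and fold-change thresholds", {
  set.seed(81)
  n <- 40
  meta <- data.frame(genotype = rep(c("WT", "TS"), each = 20), cell_type = "ct")
  expr <- matrix(0, n, 4,
                 dimnames = list(paste0("c", 1:n),
                                 c("silent", "ts_only", "low_lfc", "strong")))
  # detected in 12% of TS cells only, clear fold change: tested
  expr[21:23, "ts_only"] <- 2
  # detected everywhere but |lfc| below 0.1: excluded
  expr[, "low_lfc"] <- 1; expr[21:40, "low_lfc"] <- 1.05
  expr[1:20, "strong"] <- 3; expr[21:40, "strong"] <- 1
  de <- de_per_celltype(expr, meta, "ct")
  expect_setequal(de$gene, c("ts_only", "strong"))
  expect_false("silent" %in% de$gene)
  expect_false("low_lfc" %in% de$gene)
  expect_equal(de$log_fold_change[de$gene == "strong"], -2)
  expect_true(all(de$significant == (de$p_adjusted < 0.001)))
  expect_error(de_per_celltype(expr, meta[meta$genotype == "WT", ], "ct"),
               "genotype")
})

test_that("DE p-values and BH adjustment match a brute-force oracle on a toy", {
  set.seed(82)
  n <- 80; G <- 40
  meta <- data.frame(genotype = rep(c("WT", "TS"), each = 40), cell_type = "ct")
  expr <- matrix(rexp(n * G, 1), n, G,
                 dimnames = list(paste0("c", 1:n), sprintf("g%02d", 1:G)))
  expr[meta$genotype == "TS", 1:6] <- expr[meta$genotype == "TS", 1:6] * 1.8
  de <- de_per_celltype(expr, meta, "ct")

  wt <- meta$genotype == "WT"; ts <- !wt
  tested <- character(0); p_raw <- numeric(0)
  for (j in seq_len(G)) {
    pw <- mean(expr[wt, j] > 0); pt <- mean(expr[ts, j] > 0)
    lfc <- mean(expr[ts, j]) - mean(expr[wt, j])
    if (max(pw, pt) >= 0.10 && abs(lfc) >= 0.1) {
      tested <- c(tested, colnames(expr)[j])
      p_raw <- c(p_raw,
                 suppressWarnings(wilcox.test(expr[ts, j], expr[wt, j])$p.value))
    }
  }
  expect_setequal(de$gene, tested)
  ord <- match(de$gene, tested)
  expect_equal(de$p_value, p_raw[ord], tolerance = 1e-12)
  expect_equal(de$p_adjusted, bh_oracle(p_raw)[ord], tolerance = 1e-12)
  # BH is monotone in the raw p-value rank
  expect_true(all(diff(de$p_adjusted[order(de$p_value)]) >= -1e-12))
})

test_that("pseudobulk DE works at the sample level", {
  set.seed(83)
  n_per <- 40
  meta <- data.frame(
    genotype = rep(c("WT", "TS"), each = 4 * n_per),
    sample = rep(paste0(rep(c("WT", "TS"), each = 4), 1:4), each = n_per),
    cell_type = "ct")
  G <- 6
  expr <- matrix(rnorm(nrow(meta) * G, 5, 0.3), nrow(meta), G,
                 dimnames = list(NULL, paste0("g", 1:G)))
  # g1: consistent planted shift of 2 with near-zero sample variance
  expr[meta$genotype == "TS", 1] <- rnorm(4 * n_per, 7, 0.05)
  expr[meta$genotype == "WT", 1] <- rnorm(4 * n_per, 5, 0.05)
  # g2: large effect confined to a single TS sample (cell-level significant,
  # diluted at the sample level)
  expr[meta$sample == "TS1", 2] <- expr[meta$sample == "TS1", 2] + 3
  pb <- pseudobulk_de(expr, meta, "ct")
  expect_identical(pb$gene[1], "g1")
  sc <- de_per_celltype(expr, meta, "ct")
  expect_true(sc$p_adjusted[sc$gene == "g2"] < 0.001)
  expect_gt(pb$p_value[pb$gene == "g2"], 0.05)
  # identical per-sample means give t = 0, p = 1
  flat <- matrix(rep(rep(c(1, 2), each = n_per), 4), nrow(meta), 2,
                 dimnames = list(NULL, c("h1", "h2")))
  pb_flat <- pseudobulk_de(flat + 0.5, meta, "ct", lfc_min = 0)
  expect_true(all(pb_flat$p_value == 1))
  expect_error(pseudobulk_de(expr, meta[meta$sample %in% c("WT1", "TS1", "TS2"), ],
                             "ct"), "2 samples")
})

test_that("chromosome breakdown accounts for every significant gene", {
  de <- data.frame(
    cell_type = "ct",
    gene = paste0("g", 1:10),
    log_fold_change = c(1, 1, -1, 1, -1, 1, 1, -1, 1, 1),
    p_value = 0.001, p_adjusted = c(rep(1e-5, 6), rep(0.5, 4)),
    significant = c(rep(TRUE, 6), rep(FALSE, 4)))
  map <- setNames(rep(c("chr16", "chr2"), each = 5), de$gene)
  cb <- chromosome_breakdown(de, map)
  expect_equal(cb$n_up + cb$n_down, cb$n_significant)
  expect_true(all(cb$prop_de >= 0 & cb$prop_de <= 1))
  expect_equal(sum(cb$n_significant), 6)
  # no significant genes: all proportions zero
  de0 <- de; de0$significant <- FALSE
  expect_true(all(chromosome_breakdown(de0, map)$prop_de == 0))
  # unmapped genes land in the NA bucket
  cb_na <- chromosome_breakdown(de, map[1:5])
  expect_true("NA" %in% cb_na$chromosome)
})

test_that("the planted downregulated programme is recovered by DE", {
  n_seeds <- 6
  driver_hit <- logical(n_seeds)
  module_down <- logical(n_seeds)
  module_enrich_p <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_dataset(sim_config(seed = 400 + s))
    prep <- prep_sim(sim, min_genes = 200)
    de <- de_per_celltype(prep$expr, prep$meta, sim$truth$shifted_cell_type)
    down <- de$gene[de$significant & de$log_fold_change < 0]
    driver_hit[s] <- sim$truth$driver_gene %in% down
    mod <- de[de$gene %in% sim$truth$module_genes, ]
    module_down[s] <- all(mod$log_fold_change < 0)
    module_enrich_p[s] <- overlap_test(down, intersect(sim$truth$module_genes,
                                                       de$gene),
                                       de$gene)$p_value
  }
  expect_true(all(driver_hit))
  expect_true(all(module_down))
  expect_true(all(module_enrich_p < 1e-6))
})

test_that("dosage genes make the trisomic chromosome the most upregulated", {
  sim <- simulate_dataset(small_config(seed = 19, cells_per_type_per_sample = 40L))
  prep <- prep_sim(sim)
  de <- de_per_celltype(prep$expr, prep$meta, "type2")
  cb <- chromosome_breakdown(de, sim$gene_chromosome)
  up <- setNames(cb$prop_up, cb$chromosome)
  expect_identical(names(which.max(up)), "chr16")
})

test_that("hypergeometric enrichment equals the exact combinatorial sum", {
  universe <- sprintf("u%03d", 1:100)
  query <- universe[1:10]
  sets <- list(hit = c(universe[6:10], universe[90:94]),   # overlap 5
               none = universe[50:59])
  enr <- hypergeom_enrichment(query, sets, universe)
  expect_equal(enr$p_value[enr$set_name == "hit"],
               hyper_oracle(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(enr$overlap[enr$set_name == "hit"], 5)
  expect_equal(enr$gene_ratio[enr$set_name == "hit"], 0.5)
  expect_equal(enr$fdr, bh_oracle(enr$p_value), tolerance = 1e-12)
  expect_true(all(enr$fdr >= enr$p_value))
  expect_error(hypergeom_enrichment(c("zzz"), sets, universe), "universe")
  expect_warning(hypergeom_enrichment(query, c(sets, list(out = "zzz")), universe),
                 "skipping")
})

test_that("overlap significance follows the hypergeometric upper tail", {
  universe <- sprintf("u%04d", 1:1000)
  a <- universe[1:50]; b <- c(universe[49:50], universe[101:138])
  ot <- overlap_test(a, b, universe)
  expect_equal(ot$overlap, 2)
  expect_equal(ot$p_value, hyper_oracle(2, 40, 50, 1000), tolerance = 1e-12)
  # identical sets are the most extreme configuration for their sizes
  self <- overlap_test(a, a, universe)
  expect_equal(self$overlap, 50)
  expect_lt(self$p_value, ot$p_value)
  # disjoint sets: upper tail at zero overlap is 1
  disj <- overlap_test(universe[1:10], universe[11:20], universe)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p_value, 1)
  expect_error(overlap_test(a, b, character(0)), "empty")
})
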