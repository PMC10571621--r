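#' Genotype differential expression within one cell type
#'
#' Compares trisomic (TS) to wild-type (WT) cells of one cell type. Genes
#' enter the test only when detected in at least `pct_min` of the cells of
#' at least one genotype and when the absolute difference of mean
#' log2(TP10K+1) expression is at least `lfc_min`. Surviving genes get a
#' Wilcoxon rank-sum p-value with Benjamini-Hochberg adjustment across the
#' tested genes of the cell type; `significant` flags
#' `p_adjusted < alpha`. The fold-change sign convention is TS minus WT.
#'
#' @param expr cells x genes log2(TP10K+1) matrix.
#' @param meta Per-cell metadata with `genotype` and `cell_type` columns;
#'   genotype labels must be "WT" and "TS".
#' @param cell_type Cell type to test.
#' @param pct_min Detection threshold in at least one genotype
#'   (default 0.10).
#' @param lfc_min Minimum absolute log2 fold change (default 0.1).
#' @param alpha Adjusted-p significance cutoff (default 0.001).
#' @return A data.frame with `cell_type`, `gene`, `log_fold_change`,
#'   `pct_WT`, `pct_TS`, `p_value`, `p_adjusted`, `significant`, sorted by
#'   p-value.
#' @export
de_per_celltype <- function(expr, meta, cell_type, pct_min = 0.10,
                            lfc_min = 0.1, alpha = 0.001) {
  x <- as_dense(expr)
  cells <- which(meta$cell_type == cell_type)
  if (length(cells) == 0L) stop("cell type absent: ", cell_type, call. = FALSE)
  geno <- as.character(meta$genotype[cells])
  wt <- cells[geno == "WT"]; ts <- cells[geno == "TS"]
  if (length(wt) == 0L || length(ts) == 0L)
    stop("both genotypes must be present in ", cell_type, call. = FALSE)
  pct_wt <- colMeans(x[wt, , drop = FALSE] > 0)
  pct_ts <- colMeans(x[ts, , drop = FALSE] > 0)
  lfc <- colMeans(x[ts, , drop = FALSE]) - colMeans(x[wt, , drop = FALSE])
  keep <- which(pmax(pct_wt, pct_ts) >= pct_min & abs(lfc) >= lfc_min)
  if (length(keep) == 0L)
    return(data.frame(cell_type = character(0), gene = character(0),
                      log_fold_change = numeric(0), pct_WT = numeric(0),
                      pct_TS = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  p <- vapply(keep, function(j)
    suppressWarnings(wilcox.test(x[ts, j], x[wt, j])$p.value), numeric(1))
  out <- data.frame(
    cell_type = cell_type, gene = colnames(x)[keep],
    log_fold_change = unname(lfc[keep]),
    pct_WT = unname(pct_wt[keep]), pct_TS = unname(pct_ts[keep]),
    p_value = p, p_adjusted = p.adjust(p, "BH"),
    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out[order(out$p_value, out$gene), ]
}

#' Pseudobulk differential expression within one cell type
#'
#' Aggregates the cell type's expression to per-sample gene means and
#' compares genotypes with a Welch (unequal-variance) two-sample t-test per
#' gene, with Benjamini-Hochberg adjustment. The same detection and
#' fold-change filters as [de_per_celltype()] are applied (detection at the
#' cell level; fold change as the difference of genotype means of the
#' per-sample means). Samples, not cells, are the units of replication, so
#' cell-level significance that is not consistent across animals is
#' diluted away.
#'
#' @inheritParams de_per_celltype
#' @return A data.frame like [de_per_celltype()]'s (with `n_samples_WT`,
#'   `n_samples_TS` added).
#' @export
pseudobulk_de <- function(expr, meta, cell_type, pct_min = 0.10,
                          lfc_min = 0.1, alpha = 0.001) {
  x <- as_dense(expr)
  cells <- which(meta$cell_type == cell_type)
  if (length(cells) == 0L) stop("cell type absent: ", cell_type, call. = FALSE)
  geno <- as.character(meta$genotype[cells])
  samp <- as.character(meta$sample[cells])
  wt_s <- unique(samp[geno == "WT"]); ts_s <- unique(samp[geno == "TS"])
  if (length(wt_s) < 2L || length(ts_s) < 2L)
    stop("need >= 2 samples per genotype", call. = FALSE)
  sample_means <- t(vapply(c(wt_s, ts_s), function(s)
    colMeans(x[cells[samp == s], , drop = FALSE]), numeric(ncol(x))))
  wt_m <- sample_means[wt_s, , drop = FALSE]
  ts_m <- sample_means[ts_s, , drop = FALSE]
  lfc <- colMeans(ts_m) - colMeans(wt_m)
  pct_wt <- colMeans(x[cells[geno == "WT"], , drop = FALSE] > 0)
  pct_ts <- colMeans(x[cells[geno == "TS"], , drop = FALSE] > 0)
  keep <- which(pmax(pct_wt, pct_ts) >= pct_min & abs(lfc) >= lfc_min)
  p <- vapply(keep, function(j) {
    tryCatch(t.test(ts_m[, j], wt_m[, j], var.equal = FALSE)$p.value,
             error = function(e) if (abs(lfc[j]) > 0) 0 else 1)
  }, numeric(1))
  out <- data.frame(
    cell_type = cell_type, gene = colnames(x)[keep],
    log_fold_change = unname(lfc[keep]),
    pct_WT = unname(pct_wt[keep]), pct_TS = unname(pct_ts[keep]),
    p_value = p, p_adjusted = p.adjust(p, "BH"),
    n_samples_WT = length(wt_s), n_samples_TS = length(ts_s),
    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out[order(out$p_value, out$gene), ]
}

#' Chromosome breakdown of differentially expressed genes
#'
#' Tabulates, per chromosome, the proportion of tested genes called
#' significant, split by direction of change. Genes without a chromosome
#' assignment fall into an `"NA"` bucket.
#'
#' @param de A [de_per_celltype()] result.
#' @param gene_chromosome Named gene -> chromosome vector.
#' @return A data.frame with `chromosome`, `n_tested`, `n_significant`,
#'   `n_up`, `n_down`, `prop_de`, `prop_up`, `prop_down`.
#' @export
chromosome_breakdown <- function(de, gene_chromosome) {
  chr <- unname(gene_chromosome[de$gene])
  chr[is.na(chr)] <- "NA"
  out <- do.call(rbind, lapply(sort(unique(chr)), function(cc) {
    rows <- de[chr == cc, ]
    n_sig <- sum(rows$significant)
    n_up <- sum(rows$significant & rows$log_fold_change > 0)
    data.frame(chromosome = cc, n_tested = nrow(rows),
               n_significant = n_sig, n_up = n_up, n_down = n_sig - n_up,
               prop_de = n_sig / nrow(rows), prop_up = n_up / nrow(rows),
               prop_down = (n_sig - n_up) / nrow(rows),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment with FDR control
#'
#' Upper-tail hypergeometric test of each gene set's overlap with the query
#' against a fixed gene universe, with Benjamini-Hochberg FDR across sets.
#' Sets are intersected with the universe first; sets that become empty are
#' skipped with a warning.
#'
#' @param query_genes Query gene set (e.g. significant DEGs), must lie in
#'   the universe.
#' @param gene_sets Named list of gene sets.
#' @param universe All genes eligible to be drawn (e.g. all genes passing
#'   QC).
#' @param fdr_max Significance cutoff on the FDR (default 0.05).
#' @return A data.frame with `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `gene_ratio`, `p_value`, `fdr`,
#'   `significant`, sorted by p-value.
#' @export
hypergeom_enrichment <- function(query_genes, gene_sets, universe,
                                 fdr_max = 0.05) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(query_genes) == 0L) stop("empty query", call. = FALSE)
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!all(query_genes %in% universe))
    stop("query genes must be contained in the universe", call. = FALSE)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("skipping sets with no genes in the universe: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no usable gene sets", call. = FALSE)
  U <- length(universe); q <- length(query_genes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- length(intersect(query_genes, s))
    data.frame(set_name = nm, overlap = ov, set_size = length(s),
               query_size = q, universe_size = U, gene_ratio = ov / q,
               p_value = phyper(ov - 1L, length(s), U - length(s), q,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, "BH")
  out$significant <- out$fdr < fdr_max
  out[order(out$p_value, out$set_name), ]
}

#' Significance of the overlap between two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two sets drawn from a common universe.
#'
#' @param set_a,set_b Gene sets, both contained in `universe`.
#' @param universe The common gene universe.
#' @return A list with `overlap` and `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be contained in the universe", call. = FALSE)
  ov <- length(intersect(set_a, set_b))
  p <- phyper(ov - 1L, length(set_b), length(universe) - length(set_b),
              length(set_a), lower.tail = FALSE)
  list(overlap = ov, p_value = p)
}
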