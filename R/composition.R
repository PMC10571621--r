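#' Per-sample cell-type proportions
#'
#' Normalizes the number of nuclei of each cell type to the total captured
#' per sample (library), so proportions sum to 1 within each sample.
#'
#' @param meta Per-cell metadata with `sample`, `cell_type` and (optionally)
#'   `genotype` columns.
#' @return A data.frame with `sample`, `genotype` (if available),
#'   `cell_type`, `count`, `proportion`; absent (sample, type) pairs get
#'   count 0.
#' @export
cell_type_proportions <- function(meta) {
  if (nrow(meta) == 0L) stop("no cells", call. = FALSE)
  samples <- sort(unique(as.character(meta$sample)))
  types <- sort(unique(as.character(meta$cell_type)))
  tab <- table(factor(meta$sample, samples), factor(meta$cell_type, types))
  totals <- rowSums(tab)
  if (any(totals == 0L)) stop("sample with zero cells", call. = FALSE)
  out <- expand.grid(sample = samples, cell_type = types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- as.integer(tab[cbind(out$sample, out$cell_type)])
  out$proportion <- out$count / totals[out$sample]
  if (!is.null(meta$genotype)) {
    map <- unique(meta[, c("sample", "genotype")])
    out$genotype <- map$genotype[match(out$sample, map$sample)]
    out <- out[, c("sample", "genotype", "cell_type", "count", "proportion")]
  }
  out[order(out$sample, out$cell_type), ]
}

#' Bootstrap confidence intervals for one cell type's proportion
#'
#' Resamples each sample's cells with replacement `B` times and reports the
#' percentile interval of the cell type's proportion. Descriptive only;
#' inference comes from [composition_test()].
#'
#' @param meta Per-cell metadata with `sample` and `cell_type` columns.
#' @param cell_type The cell type whose proportion is bootstrapped.
#' @param B Bootstrap replicates (default 1000, minimum 100).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed; deterministic given it.
#' @return A data.frame with `sample`, `estimate`, `lower`, `upper`, `B`,
#'   `level`.
#' @export
bootstrap_ci <- function(meta, cell_type, B = 1000, level = 0.95, seed = 1L) {
  stopifnot(B >= 100, level > 0, level < 1)
  samples <- sort(unique(as.character(meta$sample)))
  alpha <- (1 - level) / 2
  with_seed(seed, {
    rows <- lapply(samples, function(s) {
      is_type <- meta$cell_type[meta$sample == s] == cell_type
      n <- length(is_type)
      est <- mean(is_type)
      boot <- vapply(seq_len(B), function(b)
        mean(is_type[sample.int(n, n, replace = TRUE)]), numeric(1))
      ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
      data.frame(sample = s, estimate = est, lower = ci[1], upper = ci[2],
                 B = B, level = level, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Exact sample-label permutation test for composition differences
#'
#' Tests, per cell type, whether genotype mean proportions differ, by
#' enumerating every assignment of the genotype labels to the samples
#' (choose(n, n_WT) assignments; 70 for a 4 vs 4 design). The statistic is
#' the difference of genotype mean proportions; the two-sided p-value is
#' the fraction of assignments whose absolute statistic is at least the
#' observed one (the observed assignment is always counted, so p >=
#' 1/choose(n, n_WT) and p-values lie on the exact grid). P-values are
#' BH-adjusted across cell types.
#'
#' @param prop A proportions table from [cell_type_proportions()] with a
#'   `genotype` column, or `meta` to be tabulated first.
#' @return A data.frame with `cell_type`, `mean_WT`, `mean_TS`,
#'   `difference` (TS - WT), `p_value`, `p_adjusted`.
#' @export
composition_test <- function(prop) {
  if (!all(c("proportion", "genotype") %in% names(prop)))
    prop <- cell_type_proportions(prop)
  samples <- sort(unique(prop$sample))
  geno <- prop$genotype[match(samples, prop$sample)]
  glev <- sort(unique(as.character(geno)), decreasing = TRUE)  # WT first
  if (length(glev) != 2L) stop("need exactly two genotypes", call. = FALSE)
  n_a <- sum(geno == glev[1])
  if (n_a < 2L || length(samples) - n_a < 2L)
    stop("need >= 2 samples per genotype", call. = FALSE)
  assignments <- combn(length(samples), n_a)
  types <- sort(unique(prop$cell_type))
  rows <- lapply(types, function(ct) {
    p_s <- prop$proportion[match(paste(samples, ct),
                                 paste(prop$sample, prop$cell_type))]
    obs_a <- mean(p_s[geno == glev[1]])
    obs_b <- mean(p_s[geno != glev[1]])
    obs <- obs_a - obs_b
    total <- sum(p_s)
    stat <- apply(assignments, 2L, function(idx)
      mean(p_s[idx]) - (total - sum(p_s[idx])) / (length(samples) - n_a))
    p <- mean(abs(stat) >= abs(obs) - 1e-12)
    data.frame(cell_type = ct,
               mean_WT = if (glev[1] == "WT") obs_a else obs_b,
               mean_TS = if (glev[1] == "WT") obs_b else obs_a,
               difference = if (glev[1] == "WT") obs_b - obs_a else obs_a - obs_b,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, "BH")
  out
}
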