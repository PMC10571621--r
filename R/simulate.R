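#' Configuration for the synthetic snRNA-seq generator
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' defaults emulate the study design the analysis targets: two genotypes
#' ("WT" and trisomic "TS") with four animals each, several transcriptionally
#' distinct neuronal cell types, a ~1.5x dosage effect on a block of
#' "trisomic" genes, and one shifted cell type in which a highly expressed
#' driver gene is downregulated in trisomic cells together with a correlated
#' gene module, accompanied by reduced abundance of that cell type.
#'
#' @param n_cell_types Number of planted cell types.
#' @param cells_per_type_per_sample Baseline cells per type per sample.
#' @param n_samples_per_genotype Animals per genotype (default 4, a 4 vs 4
#'   design).
#' @param n_genes Total genes simulated.
#' @param n_markers_per_type Marker genes planted per cell type.
#' @param n_dosage_genes Genes carrying the trisomy dosage effect.
#' @param dosage_factor Mean multiplier on dosage genes in trisomic cells;
#'   the default 1.5 reflects the 3:2 copy-number ratio of a trisomy.
#' @param shifted_cell_type Index of the cell type carrying the planted
#'   transcriptomic shift, or `NA` for none.
#' @param driver_downregulation Multiplier in (0, 1] applied to the driver
#'   gene's mean in trisomic cells of the shifted type.
#' @param module_size Number of module genes co-downregulated with the
#'   driver (at `sqrt(driver_downregulation)`, a weaker correlated effect).
#' @param shifted_type_proportion_factor Abundance multiplier in (0, 1] for
#'   the shifted type in trisomic samples.
#' @param library_size_mean Expected UMI count per cell.
#' @param nb_dispersion Negative-binomial dispersion shared across cells
#'   (`size = 1/nb_dispersion`).
#' @param batch_effect_sd SD of the per-(batch, gene) log-normal batch
#'   factor. Samples are split 3 + 1 per genotype across two batches.
#' @param marker_boost Mean multiplier for a marker gene within its own
#'   cell type.
#' @param driver_base_boost Baseline mean multiplier for the driver gene
#'   within the shifted cell type (both genotypes), mimicking a driver that
#'   is a very highly expressed, type-enriched transcript.
#' @param module_base_boost Baseline mean multiplier for the module genes
#'   within the shifted cell type (both genotypes); type-enriched but less
#'   extreme than the driver.
#' @param module_activity_sd SD of the per-cell latent log-activity of the
#'   driver programme within the shifted type. Each cell's driver mean is
#'   multiplied by `exp(u)` and each module gene's mean by `exp(u/2)` with
#'   `u ~ N(0, module_activity_sd^2)`, so the programme is genuinely
#'   co-regulated across cells (a shared latent factor, the generative
#'   counterpart of a driver-correlated module) rather than independently
#'   noisy, and the within-type manifold has a dominant activity axis.
#' @param ts_activity_dispersion Multiplier (>= 1) on the latent activity
#'   SD in trisomic cells of the shifted type. Downregulation of a
#'   regulatory programme is heterogeneous across cells, so the trisomic
#'   population is stretched along the activity axis rather than uniformly
#'   shifted; default 2.5.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A validated `sim_config` object (a named list).
#' @export
sim_config <- function(n_cell_types = 5L,
                       cells_per_type_per_sample = 50L,
                       n_samples_per_genotype = 4L,
                       n_genes = 3000L,
                       n_markers_per_type = 40L,
                       n_dosage_genes = 5L,
                       dosage_factor = 1.5,
                       shifted_cell_type = 1L,
                       driver_downregulation = 0.4,
                       module_size = 30L,
                       shifted_type_proportion_factor = 0.7,
                       library_size_mean = 2500,
                       nb_dispersion = 0.3,
                       batch_effect_sd = 0.1,
                       marker_boost = 4,
                       driver_base_boost = 6,
                       module_base_boost = 3,
                       module_activity_sd = 0.6,
                       ts_activity_dispersion = 2.5,
                       seed = 1L) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type_per_sample = as.integer(cells_per_type_per_sample),
    n_samples_per_genotype = as.integer(n_samples_per_genotype),
    n_genes = as.integer(n_genes),
    n_markers_per_type = as.integer(n_markers_per_type),
    n_dosage_genes = as.integer(n_dosage_genes),
    dosage_factor = dosage_factor,
    shifted_cell_type = if (is.na(shifted_cell_type)) NA_integer_ else as.integer(shifted_cell_type),
    driver_downregulation = driver_downregulation,
    module_size = as.integer(module_size),
    shifted_type_proportion_factor = shifted_type_proportion_factor,
    library_size_mean = library_size_mean,
    nb_dispersion = nb_dispersion,
    batch_effect_sd = batch_effect_sd,
    marker_boost = marker_boost,
    driver_base_boost = driver_base_boost,
    module_base_boost = module_base_boost,
    module_activity_sd = module_activity_sd,
    ts_activity_dispersion = ts_activity_dispersion,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_cell_types >= 1L, cfg$cells_per_type_per_sample >= 1L,
    cfg$n_samples_per_genotype >= 1L, cfg$n_genes >= 1L,
    cfg$n_markers_per_type >= 0L, cfg$n_dosage_genes >= 0L,
    cfg$dosage_factor > 0, cfg$module_size >= 0L,
    cfg$driver_downregulation > 0, cfg$driver_downregulation <= 1,
    cfg$shifted_type_proportion_factor > 0, cfg$shifted_type_proportion_factor <= 1,
    cfg$library_size_mean > 0, cfg$nb_dispersion > 0,
    cfg$batch_effect_sd >= 0, cfg$marker_boost > 0, cfg$driver_base_boost > 0,
    cfg$module_base_boost > 0, cfg$module_activity_sd >= 0, cfg$ts_activity_dispersion >= 1
  )
  has_driver <- !is.na(cfg$shifted_cell_type)
  if (has_driver && (cfg$shifted_cell_type < 1L || cfg$shifted_cell_type > cfg$n_cell_types))
    stop("`shifted_cell_type` must index one of the cell types", call. = FALSE)
  n_special <- cfg$n_markers_per_type * cfg$n_cell_types + cfg$n_dosage_genes +
    if (has_driver) 1L + cfg$module_size else 0L
  if (n_special > cfg$n_genes)
    stop("gene roles (markers, dosage, driver, module) exceed `n_genes`; ",
         "the role sets must be disjoint", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a seeded synthetic snRNA-seq dataset
#'
#' Draws UMI counts from a negative binomial whose mean for each
#' (gene, cell type, genotype, sample) combination is a per-gene log-normal
#' baseline times a marker boost (markers in their own type), a dosage
#' factor (dosage genes in trisomic cells), a driver/module factor
#' (trisomic cells of the shifted type) and a per-(batch, gene) factor,
#' scaled so the genotype-neutral expectation of each cell's library equals
#' `library_size_mean`. Effect factors are applied after library scaling, so
#' planted fold changes are exact in expectation (a trisomic cell's library
#' is correspondingly slightly larger, as extra transcripts from a
#' triplicated segment would make it).
#'
#' Cell numbers per sample and type follow the configured design; the
#' shifted type's count in trisomic samples is multiplied by
#' `shifted_type_proportion_factor` with seeded stochastic rounding so
#' totals are integers with the right expectation.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, cells x genes, integer UMI counts.}
#'     \item{cell_meta}{data.frame with `barcode`, `sample`, `genotype`,
#'       `batch`, `cell_type` per cell.}
#'     \item{gene_chromosome}{named character vector gene -> chromosome;
#'       dosage genes sit on `"chr16"`.}
#'     \item{truth}{a `sim_truth` object recording the planted ground truth.}
#'   }
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  G <- cfg$n_genes
  Tt <- cfg$n_cell_types
  genes <- sprintf("g%04d", seq_len(G))
  types <- sprintf("type%d", seq_len(Tt))
  has_driver <- !is.na(cfg$shifted_cell_type)

  # Disjoint gene role blocks laid out front-to-back.
  cursor <- 0L
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- genes[(cursor + 1L):(cursor + n)]
    cursor <<- cursor + n
    out
  }
  marker_map <- setNames(
    lapply(seq_len(Tt), function(t) take(cfg$n_markers_per_type)), types)
  dosage_genes <- take(cfg$n_dosage_genes)
  driver_gene <- if (has_driver) take(1L) else character(0)
  module_genes <- if (has_driver) take(cfg$module_size) else character(0)

  # Dosage genes live on a single "trisomic" chromosome; the rest round-robin.
  other_chr <- paste0("chr", setdiff(1:19, 16))
  gene_chromosome <- setNames(rep_len(other_chr, G), genes)
  gene_chromosome[dosage_genes] <- "chr16"

  # Per-gene log-normal baseline, shared across types.
  baseline <- exp(rnorm(G, meanlog_baseline(), 1))
  if (has_driver && (cfg$module_size > 0 || length(driver_gene))) {
    # driver-programme genes draw from the moderately expressed range: a
    # co-regulated module is only observable among well-detected genes, so
    # genes near dropout cannot carry it
    prog <- c(driver_gene, module_genes)
    baseline[match(prog, genes)] <- exp(rnorm(length(prog), 0.5, 0.5))
  }

  # Type-specific relative expression programmes.
  rel <- matrix(rep(baseline, each = Tt), nrow = Tt, dimnames = list(types, genes))
  for (t in seq_len(Tt))
    rel[t, marker_map[[t]]] <- rel[t, marker_map[[t]]] * cfg$marker_boost
  if (has_driver) {
    st <- cfg$shifted_cell_type
    rel[st, driver_gene] <- rel[st, driver_gene] * cfg$driver_base_boost
    rel[st, module_genes] <- rel[st, module_genes] * cfg$module_base_boost
  }
  # Genotype-neutral library scaling: each type's profile sums to the target
  # library size before genotype effects are layered on.
  mu_type <- rel / rowSums(rel) * cfg$library_size_mean

  # Sample sheet: 3 + 1 animals per genotype across two processing batches.
  S <- cfg$n_samples_per_genotype
  samples <- data.frame(
    sample = c(paste0("WT", seq_len(S)), paste0("TS", seq_len(S))),
    genotype = rep(c("WT", "TS"), each = S),
    stringsAsFactors = FALSE
  )
  samples$batch <- ifelse(S > 1L & sub("^(WT|TS)", "", samples$sample) == as.character(S),
                          "batch2", "batch1")
  batch_factor <- sapply(c("batch1", "batch2"), function(b)
    exp(rnorm(G, 0, cfg$batch_effect_sd)))
  rownames(batch_factor) <- genes

  # Cell counts per (sample, type); shifted type thinned in trisomic samples.
  n_cells <- matrix(cfg$cells_per_type_per_sample, nrow(samples), Tt,
                    dimnames = list(samples$sample, types))
  if (has_driver && cfg$shifted_type_proportion_factor < 1) {
    ts_rows <- samples$genotype == "TS"
    n_cells[ts_rows, cfg$shifted_cell_type] <- stochastic_round(
      n_cells[ts_rows, cfg$shifted_cell_type] * cfg$shifted_type_proportion_factor)
  }
  if (sum(n_cells) == 0L) stop("configuration yields zero cells", call. = FALSE)

  expected_prop <- prop.table(
    rbind(colSums(n_cells[samples$genotype == "WT", , drop = FALSE]) /
            sum(samples$genotype == "WT"),
          colMeans_expected(cfg, Tt, types)), margin = 1)
  expected_prop <- data.frame(genotype = c("WT", "TS"),
                              as.data.frame(expected_prop),
                              stringsAsFactors = FALSE)
  rownames(expected_prop) <- NULL

  size <- 1 / cfg$nb_dispersion
  blocks <- list(); metas <- list(); bi <- 0L
  for (s in seq_len(nrow(samples))) {
    geno <- samples$genotype[s]
    bfac <- batch_factor[, samples$batch[s]]
    for (t in seq_len(Tt)) {
      nc <- n_cells[s, t]
      if (nc == 0L) next
      mu <- mu_type[t, ] * bfac
      if (geno == "TS") {
        mu[dosage_genes] <- mu[dosage_genes] * cfg$dosage_factor
        if (has_driver && t == cfg$shifted_cell_type) {
          mu[driver_gene] <- mu[driver_gene] * cfg$driver_downregulation
          mu[module_genes] <- mu[module_genes] * sqrt(cfg$driver_downregulation)
        }
      }
      mu_block <- matrix(rep(mu, each = nc), nrow = nc, ncol = G,
                         dimnames = list(NULL, genes))
      if (has_driver && t == cfg$shifted_cell_type && cfg$module_activity_sd > 0) {
        u_sd <- cfg$module_activity_sd *
          if (geno == "TS") cfg$ts_activity_dispersion else 1
        u <- rnorm(nc, 0, u_sd)
        # mean-one log-normal factors, so the configured fold changes stay
        # exact in expectation regardless of the activity dispersion
        mu_block[, driver_gene] <- mu_block[, driver_gene] *
          exp(u - u_sd^2 / 2)
        mu_block[, module_genes] <- mu_block[, module_genes] *
          exp(u / 2 - u_sd^2 / 8)
      }
      cnt <- matrix(rnbinom(nc * G, mu = as.vector(mu_block), size = size),
                    nrow = nc, ncol = G)
      bi <- bi + 1L
      blocks[[bi]] <- cnt
      metas[[bi]] <- data.frame(
        sample = samples$sample[s], genotype = geno,
        batch = samples$batch[s], cell_type = types[t],
        n = nc, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, lapply(metas, function(m)
    m[rep(1L, m$n), c("sample", "genotype", "batch", "cell_type")]))
  rownames(meta) <- NULL
  meta$barcode <- sprintf("cell%05d", seq_len(nrow(meta)))
  meta <- meta[, c("barcode", "sample", "genotype", "batch", "cell_type")]
  dimnames(counts) <- list(meta$barcode, genes)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  truth <- structure(list(
    shifted_cell_type = if (has_driver) types[cfg$shifted_cell_type] else NA_character_,
    driver_gene = if (has_driver) driver_gene else NA_character_,
    module_genes = module_genes,
    dosage_genes = dosage_genes,
    marker_map = marker_map,
    genes = genes,
    expected_proportions = expected_prop,
    seed = cfg$seed
  ), class = "sim_truth")

  list(counts = counts, cell_meta = meta,
       gene_chromosome = gene_chromosome, truth = truth)
}

# Baseline log-mean chosen so a typical gene is moderately expressed after
# library scaling.
meanlog_baseline <- function() 0

# Expected trisomic per-sample type proportions before rounding noise.
colMeans_expected <- function(cfg, Tt, types) {
  w <- rep(cfg$cells_per_type_per_sample, Tt)
  if (!is.na(cfg$shifted_cell_type))
    w[cfg$shifted_cell_type] <- w[cfg$shifted_cell_type] * cfg$shifted_type_proportion_factor
  setNames(w, types)
}

#' Build reference region gene sets from planted ground truth
#'
#' Stands in for atlas-derived region-enriched gene lists: one named set per
#' planted cell type, containing that type's planted markers. The shifted
#' type's set additionally carries its enriched driver programme (driver
#' gene, then module genes) after the markers — region-enriched atlas sets
#' include such type-enriched transcripts, and the per-sample marker
#' identity score relies on the reference carrying the programme that is
#' downregulated in trisomic cells. When `top_n` exceeds the available
#' genes the set is padded with seeded random unused genes (recorded in the
#' `"padded"` attribute); when smaller, the list is truncated to the first
#' `top_n` entries.
#'
#' @param truth A `sim_truth` object from [simulate_dataset()].
#' @param top_n Target set size per region.
#' @param seed Seed for padding draws.
#' @return A named list of character gene sets (class `reference_sets`),
#'   with attributes `top_n` and `padded` (named integer vector).
#' @export
make_reference_sets <- function(truth, top_n = NULL, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(truth$marker_map) == 0L)
    stop("`truth` has an empty marker map", call. = FALSE)
  base_sets <- truth$marker_map
  if (!is.na(truth$shifted_cell_type) && truth$shifted_cell_type %in% names(base_sets))
    base_sets[[truth$shifted_cell_type]] <- c(
      base_sets[[truth$shifted_cell_type]],
      truth$driver_gene, truth$module_genes)
  if (is.null(top_n)) top_n <- max(lengths(base_sets))
  stopifnot(top_n >= 1L)
  used <- unlist(base_sets, use.names = FALSE)
  pool <- setdiff(truth$genes, used)
  padded <- setNames(integer(length(base_sets)), names(base_sets))
  sets <- with_seed(seed, {
    lapply(names(base_sets), function(ty) {
      mk <- base_sets[[ty]]
      if (length(mk) >= top_n) return(mk[seq_len(top_n)])
      need <- top_n - length(mk)
      if (need > length(pool))
        stop("not enough unused genes to pad set for ", ty, call. = FALSE)
      padded[ty] <<- need
      c(mk, sample(pool, need))
    })
  })
  names(sets) <- names(truth$marker_map)
  if (any(padded > 0L))
    message("padded reference sets with non-marker genes: ",
            paste0(names(padded)[padded > 0L], "=", padded[padded > 0L], collapse = ", "))
  structure(sets, top_n = as.integer(top_n), padded = padded,
            class = "reference_sets")
}

#' Write or read planted ground truth as JSON
#'
#' @param truth A `sim_truth` object.
#' @param path Output file path; the parent directory must exist.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the `sim_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$marker_map <- lapply(raw$marker_map, as.character)
  raw$module_genes <- as.character(raw$module_genes %||% character(0))
  raw$dosage_genes <- as.character(raw$dosage_genes %||% character(0))
  raw$genes <- as.character(raw$genes)
  raw$expected_proportions <- as.data.frame(raw$expected_proportions)
  raw$seed <- as.integer(raw$seed)
  structure(raw, class = "sim_truth")
}
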