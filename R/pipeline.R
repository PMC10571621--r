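#' Default pipeline configuration
#'
#' All thresholds default to the analysis' standard settings: QC bounds of
#' 200-2500 detected genes and 6-cell gene detection, 2000 variable genes,
#' 60 principal components, SNN k = 20 with Leiden resolution 0.6, marker
#' filters of 0.25 log-fold and 20% per-genotype detection, Jaccard top
#' 300, diffusion over the top 15 PCs with k = 30, 1000 shift-test
#' permutations, DE filters of 10% detection and 0.1 log-fold with adjusted
#' p < 0.001, and enrichment FDR < 0.05.
#'
#' @return A nested named list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    input = list(mode = "simulate", dir = NULL, metadata = NULL),
    simulate = unclass(sim_config())[setdiff(names(sim_config()), "seed")],
    qc = list(min_genes = 200, max_genes = 2500, min_cells = 6),
    hvg = list(n_top = 2000),
    scale = list(clip = 10),
    batch = list(enabled = TRUE),
    pca = list(n_components = 60),
    cluster = list(k = 20, resolution = 0.6),
    markers = list(lfc_min = 0.25, pct_min = 0.20),
    jaccard = list(top_n = 300),
    diffusion = list(n_pcs = 15, k = 30, n_components = 2, n_hvg = 300),
    shift = list(n_permutations = 1000),
    de = list(pct_min = 0.10, lfc_min = 0.1, alpha = 0.001),
    enrichment = list(fdr = 0.05),
    composition = list(B = 1000, level = 0.95),
    seed = 1L,
    outdir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a (possibly partial) nested list, fills
#' unspecified values with [default_config()], rejects unknown keys by
#' name, and checks ranges before any computation happens.
#'
#' @param config A file path, a nested list, or `NULL` for pure defaults.
#' @return The resolved configuration (class `pipeline_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- default_config()
  config <- config %||% list()
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  merged <- merge_config(defaults, config, path = "")
  with(merged, {
    if (!input$mode %in% c("simulate", "10x-dir"))
      stop("input$mode must be 'simulate' or '10x-dir'", call. = FALSE)
    if (input$mode == "10x-dir" && is.null(input$dir))
      stop("input$dir required for mode '10x-dir'", call. = FALSE)
    if (qc$max_genes <= qc$min_genes)
      stop("qc$max_genes must exceed qc$min_genes", call. = FALSE)
    stopifnot(qc$min_genes > 0, qc$min_cells > 0,
              hvg$n_top >= 1, scale$clip > 0, pca$n_components >= 1,
              cluster$k >= 1, cluster$resolution > 0,
              markers$lfc_min >= 0, markers$pct_min >= 0, markers$pct_min < 1,
              jaccard$top_n >= 1, diffusion$n_pcs >= 1, diffusion$k >= 1,
              diffusion$n_hvg >= 1,
              diffusion$n_components >= 1, shift$n_permutations >= 1,
              de$pct_min >= 0, de$lfc_min >= 0, de$alpha > 0, de$alpha < 1,
              enrichment$fdr > 0, enrichment$fdr < 1,
              composition$B >= 100, composition$level > 0, composition$level < 1)
  })
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "pipeline_config")
}

# Recursive merge rejecting keys that do not exist in the defaults.
merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(if (nzchar(path)) paste0(path, "$") else "", unknown,
                collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key ", path, if (nzchar(path)) "$", k,
             " must be a block", call. = FALSE)
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(if (nzchar(path)) paste0(path, "$"), k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in dependency order: data simulation (or 10x ingestion), QC
#' filtering, TP10K log normalization, variable-gene selection, scaling,
#' batch centering, PCA, SNN/Leiden clustering, Jaccard cluster annotation
#' against reference sets, the per-cell-type shift permutation test,
#' diffusion-map gene relevance on the most-shifted cell type, per-cell-type
#' differential expression with chromosome breakdown and gene-set
#' enrichment, and composition analysis. All tabular outputs are TSV; a
#' JSON report records per-stage status, row counts, output paths with MD5
#' content hashes, timing and the seed, so identical config + seed runs are
#' byte-reproducible.
#'
#' @param config A [validate_config()] result, partial list, or config file
#'   path.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param reference Optional named list of reference region gene sets; in
#'   simulate mode defaults to sets built from the planted truth.
#' @return The run report (invisibly), a nested list also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, reference = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, package_version =
                   as.character(utils::packageVersion("snshift")),
                 stages = list(), outputs = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    report$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      message = if (ok) "" else conditionMessage(res),
      seconds = round(as.numeric(difftime(Sys.time(), ts, units = "secs")), 3))
    if (!ok) {
      write_report(report, outdir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    res
  }
  emit <- function(name, df) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv(df, path)
    report$outputs[[name]] <<- list(
      path = path, rows = nrow(df),
      md5 = unname(tools::md5sum(path)))
    invisible(path)
  }

  # --- input -----------------------------------------------------------
  dat <- stage("input", {
    if (cfg$input$mode == "simulate") {
      sim <- simulate_dataset(do.call(sim_config,
                                      c(cfg$simulate, list(seed = child_seed(cfg$seed, 1L)))))
      list(counts = sim$counts, meta = sim$cell_meta, truth = sim$truth,
           gene_chromosome = sim$gene_chromosome)
    } else {
      tenx <- read_10x(cfg$input$dir)
      meta <- read_cell_metadata(cfg$input$metadata)
      meta <- meta[match(rownames(tenx$counts), meta$barcode), ]
      list(counts = tenx$counts, meta = meta, truth = NULL,
           gene_chromosome = tenx$gene_chromosome)
    }
  })
  meta <- dat$meta

  # --- QC + normalization ---------------------------------------------
  counts <- stage("qc", qc_filter(dat$counts, cfg$qc$min_genes,
                                  cfg$qc$max_genes, cfg$qc$min_cells))
  meta <- meta[match(rownames(counts), meta$barcode), ]
  expr <- stage("normalize", normalize_tp10k(counts))
  hvg <- stage("hvg", select_hvg(expr, cfg$hvg$n_top))
  scaled <- stage("scale", {
    s <- scale_genes(expr[, hvg, drop = FALSE], cfg$scale$clip)
    if (cfg$batch$enabled) batch_center(s, meta$batch) else s
  })
  pcs <- stage("pca", run_pca(scaled, min(cfg$pca$n_components,
                                          min(dim(scaled)) - 1L)))
  emit("qc_summary", data.frame(
    n_cells = nrow(counts), n_genes = ncol(counts),
    n_hvg = length(hvg), n_pcs = ncol(pcs$coordinates)))

  # --- clustering + annotation ----------------------------------------
  labels <- stage("cluster", {
    g <- knn_graph(pcs, cfg$cluster$k)
    cluster_graph(g, cfg$cluster$resolution, seed = child_seed(cfg$seed, 2L))
  })
  reference <- reference %||%
    (if (!is.null(dat$truth)) make_reference_sets(dat$truth,
                                                  seed = child_seed(cfg$seed, 3L)))
  markers <- stage("markers", find_markers(expr, labels, meta$genotype,
                                           cfg$markers$lfc_min, cfg$markers$pct_min))
  emit("markers", markers)
  annotation <- NULL
  if (!is.null(reference)) {
    annotation <- stage("annotate", jaccard_map(markers, reference,
                                                cfg$jaccard$top_n, ncol(expr)))
    meta$cell_type <- unname(annotation$assignment[as.character(labels)])
    emit("annotation", data.frame(
      cluster = names(annotation$assignment),
      region = unname(annotation$assignment),
      n_cells = as.integer(table(factor(labels,
                                        as.integer(names(annotation$assignment))))),
      stringsAsFactors = FALSE))
  } else {
    meta$cell_type <- paste0("cluster", labels)
  }

  # --- shift test ------------------------------------------------------
  shift <- stage("shift_test", shift_test_all(
    expr, meta, n_permutations = cfg$shift$n_permutations,
    seed = child_seed(cfg$seed, 4L)))
  emit("shift_test", as.data.frame(shift))

  # --- diffusion relevance on the most-shifted type --------------------
  tested <- shift[shift$tested, ]
  focus <- tested$cell_type[order(tested$p_empirical,
                                  -tested$observed_distance)][1]
  relevance <- stage("relevance", {
    cells <- which(meta$cell_type == focus)
    # variable genes re-selected within the focus type: the within-type
    # manifold is what the diffusion map should resolve
    sub_hvg <- select_hvg(expr[cells, , drop = FALSE], cfg$diffusion$n_hvg)
    sub_scaled <- scale_genes(expr[cells, sub_hvg, drop = FALSE], cfg$scale$clip)
    if (cfg$batch$enabled) sub_scaled <- batch_center(sub_scaled, meta$batch[cells])
    sub_pcs <- run_pca(sub_scaled, min(cfg$diffusion$n_pcs,
                                       min(dim(sub_scaled)) - 1L))
    dm <- diffusion_map(sub_pcs, k = min(cfg$diffusion$k, length(cells) - 1L),
                        n_components = cfg$diffusion$n_components)
    gene_relevance(dm, expr[cells, , drop = FALSE])
  })
  emit("relevance", data.frame(
    gene = relevance$ranking, cell_type = focus,
    global_relevance = unname(relevance$global[relevance$ranking]),
    stringsAsFactors = FALSE))

  # --- differential expression ----------------------------------------
  de_all <- stage("de", do.call(rbind, lapply(
    unique(meta$cell_type), function(ct)
      de_per_celltype(expr, meta, ct, cfg$de$pct_min, cfg$de$lfc_min,
                      cfg$de$alpha))))
  emit("de", de_all)
  if (!is.null(dat$gene_chromosome)) {
    focus_de <- de_all[de_all$cell_type == focus, ]
    if (nrow(focus_de))
      emit("chromosome_breakdown",
           chromosome_breakdown(focus_de, dat$gene_chromosome))
  }
  if (!is.null(reference)) {
    degs <- de_all$gene[de_all$cell_type == focus & de_all$significant]
    if (length(degs))
      emit("enrichment", stage("enrichment", hypergeom_enrichment(
        degs, reference, colnames(expr), cfg$enrichment$fdr)))
  }

  # --- composition -----------------------------------------------------
  comp <- stage("composition", {
    prop <- cell_type_proportions(meta)
    test <- composition_test(prop)
    list(proportions = prop, test = test)
  })
  emit("composition_proportions", comp$proportions)
  emit("composition_test", comp$test)

  report$wall_clock_seconds <-
    round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  report$focus_cell_type <- focus
  write_report(report, outdir)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

write_report <- function(report, outdir) {
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
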