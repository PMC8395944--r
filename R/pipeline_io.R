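# Orchestration and format round-tripping: the 10x-style Matrix Market
# bundle for counts, TSV for every stage table, a JSON manifest with
# checksums, and per-stage seeds derived from the global seed so toggling
# one stage never shifts another stage's random stream.

#' Write a CountMatrix as a 10x-style bundle
#'
#' Writes `matrix.mtx` (genes x cells, Matrix Market), `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv` (barcode, condition, true_type)
#' into `dir`.
#'
#' @param m A `CountMatrix`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_bundle <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- Matrix::Matrix(t(m$counts), sparse = TRUE) # genes x cells, 10x layout
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  meta <- data.frame(barcode = m$cell_ids, condition = m$condition,
                     true_type = m$true_type %||% NA_character_)
  utils::write.table(meta, file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style bundle into a CountMatrix
#'
#' Expects `matrix.mtx` (genes x cells) plus `features.tsv` and
#' `barcodes.tsv`; `cell_metadata.tsv` (condition, true_type) is optional
#' but strongly recommended -- without it every cell is labeled `control`
#' with a warning. Write-then-read is the identity on counts, ids and
#' metadata.
#'
#' @param dir Directory holding the bundle.
#' @return A `CountMatrix`.
#' @export
read_counts_bundle <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stopf("missing bundle file(s): %s", paste(miss, collapse = ", "))
  # a truncated file only triggers a warning in readMM; treat any parse
  # anomaly as a hard error rather than a partial load
  sp <- tryCatch(Matrix::readMM(paths[1]),
                 error = function(e) stopf("cannot parse %s: %s", paths[1],
                                           conditionMessage(e)),
                 warning = function(w) stopf("cannot parse %s: %s", paths[1],
                                             conditionMessage(w)))
  genes <- readLines(paths[2])
  cells <- readLines(paths[3])
  if (nrow(sp) != length(genes))
    stopf("matrix.mtx has %d rows but features.tsv lists %d genes",
          nrow(sp), length(genes))
  if (ncol(sp) != length(cells))
    stopf("matrix.mtx has %d columns but barcodes.tsv lists %d barcodes",
          ncol(sp), length(cells))
  counts <- as.matrix(Matrix::t(sp))
  dimnames(counts) <- list(cells, genes)
  meta_path <- file.path(dir, "cell_metadata.tsv")
  condition <- rep("control", length(cells))
  true_type <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!all(c("barcode", "condition") %in% names(meta)))
      stopf("%s must have columns barcode and condition", meta_path)
    idx <- match(cells, meta$barcode)
    if (anyNA(idx)) stopf("%s does not cover every barcode", meta_path)
    condition <- meta$condition[idx]
    if ("true_type" %in% names(meta) && !all(is.na(meta$true_type)))
      true_type <- meta$true_type[idx]
  } else {
    warnf("no cell_metadata.tsv in %s: labeling every cell 'control'", dir)
  }
  count_matrix(counts, condition = condition, true_type = true_type)
}

#' Pipeline run configuration
#'
#' Bundles every stage parameter, the global seed and the stage toggles.
#' Input paths may be NULL when the corresponding stage is disabled or the
#' synthetic default is used.
#'
#' @param counts_dir Directory with the counts bundle (NULL = simulate with
#'   `scenario`).
#' @param scenario A `ScenarioConfig` used when `counts_dir` is NULL.
#' @param panel A `MarkerPanel`.
#' @param lr_pairs An `LRPairTable`.
#' @param growth A `GrowthCurveSet` or NULL to simulate `growth_scenario`.
#' @param growth_scenario A `GrowthScenario`.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param qc A `QCParams`.
#' @param scale Normalization scale factor.
#' @param k,n_pcs kNN-graph parameters.
#' @param margin_threshold Annotation-refinement margin (0 disables).
#' @param alpha DE/ligand selection significance cutoff.
#' @param min_pct,min_logfc DE gates.
#' @param r_min Coexpression edge threshold.
#' @param n_perm Growth permutation count.
#' @param seed Global seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @param stages Character vector of enabled stages, a subset of
#'   `c("qc", "cluster", "annotate", "popfreq", "de", "lrscore", "lrnet",
#'   "growth")`.
#' @return A `RunConfig` list.
#' @export
run_config <- function(counts_dir = NULL,
                       scenario = scenario_config(),
                       panel = default_marker_panel(),
                       lr_pairs = demo_lr_pairs(),
                       growth = NULL,
                       growth_scenario = immunorewire::growth_scenario(),
                       out_dir = tempfile("immunorewire_run_"),
                       qc = qc_params(),
                       scale = 1e4,
                       k = 15, n_pcs = 10,
                       margin_threshold = 0,
                       alpha = 0.05,
                       min_pct = 0.25, min_logfc = 0.25,
                       r_min = 0.3,
                       n_perm = 1000L,
                       seed = 1L,
                       stages = c("qc", "cluster", "annotate", "popfreq",
                                  "de", "lrscore", "lrnet", "growth")) {
  known <- c("qc", "cluster", "annotate", "popfreq", "de", "lrscore",
             "lrnet", "growth")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!is.null(counts_dir) && !dir.exists(counts_dir))
    stopf("counts_dir does not exist: %s", counts_dir)
  structure(list(counts_dir = counts_dir, scenario = scenario,
                 panel = panel, lr_pairs = lr_pairs, growth = growth,
                 growth_scenario = growth_scenario, out_dir = out_dir,
                 qc = qc, scale = scale, k = k, n_pcs = n_pcs,
                 margin_threshold = margin_threshold, alpha = alpha,
                 min_pct = min_pct, min_logfc = min_logfc, r_min = r_min,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 stages = stages),
            class = "RunConfig")
}

write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (`qc` -> `cluster` -> `annotate` ->
#' `popfreq`/`de` -> `lrscore` -> `lrnet`; `growth` is independent), writes
#' each stage's table under `cfg$out_dir` and returns a `RunManifest` with
#' md5 checksums of every output. Identical (config, seed) reproduces
#' identical checksums. A disabled stage is recorded as `"skipped"`;
#' downstream stages that need it are skipped too.
#'
#' @param cfg A `RunConfig`.
#' @return A `RunManifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  outputs <- character()
  note <- function(stage, status, files = character()) {
    stages[[stage]] <<- list(status = status, outputs = unname(files))
    outputs <<- c(outputs, files)
  }
  enabled <- function(s) s %in% cfg$stages

  # --- input counts -------------------------------------------------------
  m <- if (is.null(cfg$counts_dir)) {
    sc <- cfg$scenario
    sc$seed <- stage_seed(cfg$seed, "simulate")
    sim <- simulate_counts(sc, panel = cfg$panel)
    bundle <- file.path(cfg$out_dir, "counts")
    write_counts_bundle(sim, bundle)
    note("simulate", "ok", list.files(bundle, full.names = TRUE))
    sim
  } else read_counts_bundle(cfg$counts_dir)

  e <- NULL; clusters <- NULL; labels <- NULL; ann <- NULL; de <- NULL

  if (enabled("qc")) {
    m <- qc_filter(m, cfg$qc)
    e <- normalize_log1p(m, scale = cfg$scale)
    f <- write_stage_tsv(
      data.frame(cell_id = e$cell_ids, condition = e$condition),
      file.path(cfg$out_dir, "qc_cells.tsv"))
    note("qc", "ok", f)
  } else note("qc", "skipped")

  if (enabled("cluster") && !is.null(e)) {
    clusters <- cluster_cells(e, k = cfg$k, n_pcs = cfg$n_pcs,
                              seed = stage_seed(cfg$seed, "cluster"))
    f <- write_stage_tsv(
      data.frame(cell_id = names(clusters), cluster = unname(clusters)),
      file.path(cfg$out_dir, "clusters.tsv"))
    note("cluster", "ok", f)
  } else note("cluster", "skipped")

  if (enabled("annotate") && !is.null(clusters)) {
    ref <- refine_annotation(e, clusters, cfg$panel,
                             margin_threshold = cfg$margin_threshold,
                             k = cfg$k, n_pcs = cfg$n_pcs,
                             seed = stage_seed(cfg$seed, "annotate"))
    clusters <- ref$clusters
    ann <- ref$annotation
    labels <- cell_labels(ann, clusters)
    f <- c(write_stage_tsv(as.data.frame(ann),
                           file.path(cfg$out_dir, "annotation.tsv")),
           write_stage_tsv(
             data.frame(cell_id = names(labels), label = unname(labels)),
             file.path(cfg$out_dir, "cell_labels.tsv")))
    note("annotate", "ok", f)
  } else note("annotate", "skipped")

  if (enabled("popfreq") && !is.null(labels)) {
    cyto <- intersect(c("Gzmb", "Gzmk", "Prf1", "Ifng", "Lamp1"),
                      e$gene_ids)
    rows <- list()
    for (ct in intersect(c("CD8_T", "NK"), unique(labels))) {
      cmp <- tryCatch(ecdf_compare(e, labels, ct, cyto),
                      error = function(err) NULL)
      if (!is.null(cmp))
        rows[[ct]] <- data.frame(
          cell_type = ct, markers = paste(cmp$markers, collapse = ","),
          n_control = cmp$n_control, n_treated = cmp$n_treated,
          D = cmp$D, p = cmp$p, direction = cmp$direction)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cell_type = character(), markers = character(),
                 n_control = integer(), n_treated = integer(),
                 D = numeric(), p = numeric(), direction = numeric())
    f <- write_stage_tsv(tab, file.path(cfg$out_dir, "popfreq.tsv"))
    note("popfreq", "ok", f)
  } else note("popfreq", "skipped")

  if (enabled("de") && !is.null(labels)) {
    de <- de_test_all(e, labels, min_pct = cfg$min_pct,
                      min_logfc = cfg$min_logfc)
    f <- write_stage_tsv(de, file.path(cfg$out_dir, "de.tsv"))
    note("de", "ok", f)
  } else note("de", "skipped")

  lr_sel <- NULL
  if (enabled("lrscore") && !is.null(de)) {
    lr_sel <- suppressWarnings(select_ligands(de, cfg$lr_pairs,
                                              alpha = cfg$alpha))
    if (nrow(lr_sel)) {
      scores <- suppressWarnings(lr_score(e, labels, lr_sel))
      f <- write_stage_tsv(as.data.frame(scores),
                           file.path(cfg$out_dir, "lr_scores.tsv"))
      note("lrscore", "ok", f)
    } else note("lrscore", "empty")
  } else note("lrscore", "skipped")

  if (enabled("lrnet") && !is.null(lr_sel) && nrow(lr_sel)) {
    net <- lr_network_communities(lr_sel,
                                  seed = stage_seed(cfg$seed, "lrnet"))
    f <- write_stage_tsv(
      data.frame(gene = names(net$communities),
                 community = unname(net$communities)),
      file.path(cfg$out_dir, "lr_communities.tsv"))
    note("lrnet", "ok", f)
  } else note("lrnet", "skipped")

  if (enabled("growth")) {
    g <- cfg$growth
    if (is.null(g)) {
      gs <- cfg$growth_scenario
      gs$seed <- stage_seed(cfg$seed, "growth_sim")
      g <- simulate_growth(gs)
    }
    pt <- compare_growth_curves(g, n_perm = cfg$n_perm,
                                seed = stage_seed(cfg$seed, "growth"))
    f <- c(write_growth_tsv(g, file.path(cfg$out_dir, "growth.tsv")),
           write_stage_tsv(
             data.frame(statistic = pt$statistic, n_perm = pt$n_perm,
                        p = pt$p,
                        endpoint_reduction = endpoint_reduction(g)),
             file.path(cfg$out_dir, "growth_test.tsv")))
    note("growth", "ok", f)
  } else note("growth", "skipped")

  cfg_file <- tempfile()
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("immunorewire")),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = lapply(stages, function(s) {
      s$checksums <- if (length(s$outputs))
        as.list(tools::md5sum(s$outputs)) else list()
      s
    }))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  class(manifest) <- "RunManifest"
  manifest
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest (seed", x$seed, ")\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s (%d file(s))\n", s, x$stages[[s]]$status,
                length(x$stages[[s]]$outputs)))
  invisible(x)
}

#' Write a network edge list as GraphML
#'
#' Thin wrapper over igraph's GraphML writer (igraph is only suggested;
#' the function errors politely when it is unavailable).
#'
#' @param edges Data frame whose first two columns are node names.
#' @param path Output `.graphml` path.
#' @export
write_network_graphml <- function(edges, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stopf("write_network_graphml requires the igraph package")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
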