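# Marker-sign-panel annotation of clusters: cluster-mean expression of each
# panel gene is z-scored across clusters, and each cluster gets the cell
# type whose sign-weighted mean z is largest.

#' Annotate clusters against a marker-sign panel
#'
#' For each panel gene, compute the per-cluster mean expression and z-score
#' it across clusters (genes with zero variance across clusters get z = 0).
#' The score of cluster `c` for type `t` is the mean of `sign(t, g) *
#' z(c, g)` over the nonzero signs of `t`; dividing by each type's marker
#' count keeps marker-rich types from dominating. The label is the argmax
#' (alphabetical tie-break) and the margin is best minus second-best score.
#' Clusters with fewer than 3 cells are labeled `"unassigned"` with a
#' warning. With a single cluster, raw centered means replace z-scores;
#' with a single panel type the margin is 0 by convention.
#'
#' @param e An `ExprMatrix`.
#' @param clusters Named integer vector (cell id -> cluster id), e.g. from
#'   [cluster_cells()].
#' @param panel A `MarkerPanel`.
#' @return An `AnnotationResult`: data frame (`cluster`, `label`, `margin`,
#'   `n_cells`) with the full cluster x type score matrix in
#'   `attr(, "scores")`.
#' @export
annotate_clusters <- function(e, clusters, panel = default_marker_panel()) {
  stopifnot(inherits(e, "ExprMatrix"), inherits(panel, "MarkerPanel"))
  clusters <- clusters[e$cell_ids]
  if (anyNA(clusters)) stopf("clusters must cover every cell in the matrix")
  panel <- check_panel_genes(panel, e$gene_ids)

  ids <- sort(unique(clusters))
  cl_sizes <- vapply(ids, function(cl) sum(clusters == cl), numeric(1))
  genes <- colnames(panel)
  means <- do.call(rbind, lapply(ids, function(cl) {
    colMeans(e$values[clusters == cl, genes, drop = FALSE])
  }))
  # z across clusters; centered means when variance (or cluster count) is
  # degenerate
  ctr <- sweep(means, 2, colMeans(means))
  sds <- apply(means, 2, stats::sd)
  z <- sweep(ctr, 2, ifelse(is.na(sds) | sds == 0, 1, sds), "/")
  z[, is.na(sds) | sds == 0] <- 0
  if (length(ids) < 2L) z <- ctr

  signs <- unclass(panel)
  n_mark <- rowSums(signs != 0L)
  scores <- z %*% t(signs) / matrix(n_mark, nrow(z), length(n_mark),
                                    byrow = TRUE)
  rownames(scores) <- as.character(ids)

  types <- rownames(panel)
  res <- lapply(seq_along(ids), function(i) {
    s <- scores[i, ]
    best <- sort(types[s == max(s)])[1] # alphabetical tie-break
    margin <- if (length(s) > 1L) {
      max(s) - max(s[types != best])
    } else 0
    label <- best
    if (cl_sizes[i] < 3L) {
      warnf("cluster %s has %d cell(s) (< 3): labeled 'unassigned'",
            ids[i], cl_sizes[i])
      label <- "unassigned"
    }
    data.frame(cluster = ids[i], label = label, margin = margin,
               n_cells = cl_sizes[i])
  })
  out <- do.call(rbind, res)
  attr(out, "scores") <- scores
  class(out) <- c("AnnotationResult", "data.frame")
  out
}

#' Per-cell labels from a cluster annotation
#'
#' Every cell inherits the label of its cluster.
#'
#' @param annotation An `AnnotationResult`.
#' @param clusters Named integer vector, cell id -> cluster id.
#' @return Named character vector, cell id -> cell-type label.
#' @export
cell_labels <- function(annotation, clusters) {
  map <- stats::setNames(annotation$label, annotation$cluster)
  stats::setNames(unname(map[as.character(clusters)]), names(clusters))
}

#' Split low-confidence clusters and re-annotate
#'
#' Mixed clusters (e.g. one lymphoid blob holding CD4/CD8/NK cells) show up
#' as a small annotation margin. Any cluster with `margin <
#' margin_threshold` and at least `2 * (k + 1)` cells is re-clustered on its
#' own kNN graph, after which all clusters are re-annotated.
#'
#' @param e An `ExprMatrix`.
#' @param clusters Named integer vector, cell id -> cluster id.
#' @param panel A `MarkerPanel`.
#' @param margin_threshold Margin below which a cluster is split (0 disables).
#' @param k,n_pcs,seed Parameters for the within-cluster re-clustering.
#' @return A list with elements `clusters` (possibly refined) and
#'   `annotation` (an `AnnotationResult`).
#' @export
refine_annotation <- function(e, clusters, panel = default_marker_panel(),
                              margin_threshold = 0.1, k = 15, n_pcs = 10,
                              seed = 1L) {
  ann <- annotate_clusters(e, clusters, panel)
  if (margin_threshold <= 0) return(list(clusters = clusters,
                                         annotation = ann))
  low <- ann$cluster[ann$margin < margin_threshold &
                       ann$n_cells >= 2 * (k + 1)]
  if (!length(low)) return(list(clusters = clusters, annotation = ann))
  new <- clusters
  nxt <- max(clusters) + 1L
  for (cl in low) {
    cells <- names(clusters)[clusters == cl]
    sub <- expr_matrix(e$values[cells, , drop = FALSE],
                       condition = e$condition[match(cells, e$cell_ids)],
                       scale = e$scale)
    subcl <- cluster_cells(sub, k = k, n_pcs = n_pcs,
                           seed = stage_seed(seed, paste0("refine", cl)))
    new[cells] <- nxt + unname(subcl[cells])
    nxt <- nxt + max(subcl) + 1L
  }
  new <- densify_labels(new[e$cell_ids] + 1L, e$cell_ids)
  list(clusters = new, annotation = annotate_clusters(e, new, panel))
}

#' Fraction of marker-positive cells per type and condition
#'
#' A cell is marker-positive when its mean expression over `gene_set`
#' exceeds `threshold`. Fractions are reported per (cell type, condition);
#' a type absent from one condition gets `NA` there (flagged), never 0.
#'
#' @param e An `ExprMatrix`.
#' @param labels Named character vector, cell id -> cell-type label.
#' @param gene_set Nonempty character vector of genes.
#' @param threshold Positivity threshold on the mean log1p expression.
#' @param cell_types Types to report (default: all present).
#' @return Data frame (`cell_type`, `condition`, `n`, `fraction`).
#' @export
marker_positive_fraction <- function(e, labels, gene_set, threshold,
                                     cell_types = NULL) {
  stopifnot(inherits(e, "ExprMatrix"), length(gene_set) >= 1)
  labels <- labels[e$cell_ids]
  gene_set <- resolve_genes(e, gene_set, "marker_positive_fraction")
  if (!length(gene_set)) stopf("no gene of gene_set found in the matrix")
  score <- rowMeans(e$values[, gene_set, drop = FALSE])
  cell_types <- cell_types %||% sort(unique(labels))
  out <- expand.grid(cell_type = cell_types,
                     condition = c("control", "treated"),
                     stringsAsFactors = FALSE)
  out$n <- 0L
  out$fraction <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- labels == out$cell_type[i] & e$condition == out$condition[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0L) out$fraction[i] <- mean(score[sel] > threshold)
  }
  missing <- out$n == 0L
  if (any(missing))
    warnf("type(s) absent in a condition (fraction undefined): %s",
          paste(unique(out$cell_type[missing]), collapse = ", "))
  out
}
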