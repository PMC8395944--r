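# QC filtering and normalization. Bounds are strict on both sides: a cell
# survives iff min_features < detected features < max_features and
# mito% < max_mito_pct, with mito% on the percent scale.

#' QC parameters
#'
#' @param min_features Exclusive lower bound on detected features per cell.
#' @param max_features Exclusive upper bound on detected features per cell.
#' @param max_mito_pct Exclusive upper bound on the percentage of counts
#'   from mitochondrial genes (0-100 scale).
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes.
#' @return A validated `QCParams` list.
#' @export
qc_params <- function(min_features = 200, max_features = 4000,
                      max_mito_pct = 3, mito_prefix = "mt-") {
  p <- list(min_features = min_features, max_features = max_features,
            max_mito_pct = max_mito_pct, mito_prefix = mito_prefix)
  if (!(p$min_features >= 0 && p$min_features < p$max_features))
    stopf("need 0 <= min_features < max_features")
  if (p$max_mito_pct < 0 || p$max_mito_pct > 100)
    stopf("max_mito_pct must be in [0, 100]")
  structure(p, class = "QCParams")
}

#' Filter cells on detected features and mitochondrial percentage
#'
#' Retains exactly the cells with `min_features < n_detected < max_features`
#' (strict on both sides) and mitochondrial percentage strictly below
#' `max_mito_pct`, where mito% is 100 times the count fraction of genes
#' whose id starts with `mito_prefix`. Genes are never removed and cell
#' order is preserved, so the filter is idempotent.
#'
#' @param m A `CountMatrix`.
#' @param params A `QCParams`.
#' @return The filtered `CountMatrix`.
#' @export
qc_filter <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "CountMatrix"), inherits(params, "QCParams"))
  n_feat <- rowSums(m$counts > 0)
  total <- rowSums(m$counts)
  mito_gene <- startsWith(m$gene_ids, params$mito_prefix)
  mito_pct <- if (any(mito_gene)) {
    100 * rowSums(m$counts[, mito_gene, drop = FALSE]) / pmax(total, 1)
  } else rep(0, nrow(m$counts))
  keep <- n_feat > params$min_features & n_feat < params$max_features &
    mito_pct < params$max_mito_pct
  if (!any(keep))
    stopf("all %d cells removed by QC (%g < features < %g, mito%% < %g)",
          nrow(m$counts), params$min_features, params$max_features,
          params$max_mito_pct)
  subset_cells(m, which(keep))
}

#' Library-size normalization and log1p transform
#'
#' `value(c, g) = log(1 + scale * count(c, g) / total(c))`, the standard
#' single-cell normalization the downstream ECDF, DE and ligand-receptor
#' stages consume.
#'
#' @param m A `CountMatrix` (post-QC; zero-total cells are an error).
#' @param scale Library-size scaling factor (default `1e4`).
#' @return An `ExprMatrix`.
#' @export
normalize_log1p <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CountMatrix"), scale > 0)
  if (nrow(m$counts) == 0L) stopf("empty CountMatrix")
  total <- rowSums(m$counts)
  if (any(total == 0))
    stopf("%d cell(s) with zero total counts reached normalization; run QC",
          sum(total == 0))
  vals <- log1p(scale * m$counts / total)
  expr_matrix(vals, condition = m$condition, true_type = m$true_type,
              scale = scale)
}

#' Optional kNN-average smoothing of expression
#'
#' A simple stand-in for diffusion-based imputation: each cell's expression
#' is replaced by the average of itself and its `k` nearest neighbors in PC
#' space. It is *not* equivalent to MAGIC-style imputation and is off by
#' default throughout the pipeline.
#'
#' @param e An `ExprMatrix`.
#' @param k Number of neighbors to average over.
#' @param n_pcs PCs used for the neighbor search.
#' @return A smoothed `ExprMatrix`.
#' @export
smooth_expression <- function(e, k = 10, n_pcs = 10) {
  stopifnot(inherits(e, "ExprMatrix"), k >= 1, nrow(e$values) > k)
  nn <- knn_indices(pca_scores(e$values, n_pcs), k)
  sm <- t(vapply(seq_len(nrow(e$values)), function(i) {
    colMeans(e$values[c(i, nn[i, ]), , drop = FALSE])
  }, numeric(ncol(e$values))))
  dimnames(sm) <- dimnames(e$values)
  expr_matrix(sm, condition = e$condition, true_type = e$true_type,
              scale = e$scale)
}
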