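# Core data containers. Cells are rows, genes are columns throughout; the
# 10x-style on-disk bundle is the usual genes x cells Matrix Market triplet
# and is transposed on read/write (see read_counts_bundle).

#' Construct a CountMatrix
#'
#' A `CountMatrix` holds raw integer counts (cells x genes) together with the
#' per-cell condition label and, for synthetic data, the planted true type.
#'
#' @param counts Integer matrix, cells x genes, with unique rownames (cell
#'   ids) and colnames (gene ids).
#' @param condition Character/factor vector, one of `"control"`/`"treated"`
#'   per cell.
#' @param true_type Optional character vector of planted cell types (synthetic
#'   ground truth).
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `cell_ids`, `gene_ids`, `condition`, `true_type`.
#' @export
count_matrix <- function(counts, condition, true_type = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry cell ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(rownames(counts))) stopf("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate gene ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  condition <- as.character(condition)
  if (length(condition) != nrow(counts))
    stopf("condition must have one label per cell")
  bad <- setdiff(unique(condition), c("control", "treated"))
  if (length(bad))
    stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  if (!is.null(true_type)) {
    true_type <- as.character(true_type)
    if (length(true_type) != nrow(counts))
      stopf("true_type must have one label per cell")
  }
  structure(
    list(counts = counts, cell_ids = rownames(counts),
         gene_ids = colnames(counts), condition = condition,
         true_type = true_type),
    class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(condition = x$condition))
  if (!is.null(x$true_type))
    cat("planted types:", length(unique(x$true_type)), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

# subset cells, keeping metadata aligned
subset_cells <- function(m, keep) {
  count_matrix(m$counts[keep, , drop = FALSE],
               condition = m$condition[keep],
               true_type = if (!is.null(m$true_type)) m$true_type[keep])
}

#' Construct an ExprMatrix
#'
#' Normalized log1p expression (cells x genes) with cell metadata carried
#' over from the source `CountMatrix`.
#'
#' @param values Numeric matrix, cells x genes, nonnegative and finite.
#' @param condition Per-cell condition labels.
#' @param true_type Optional planted type labels.
#' @param scale The library-size scaling factor used in normalization.
#' @return An object of class `ExprMatrix`.
#' @export
expr_matrix <- function(values, condition, true_type = NULL, scale = NA_real_) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(values)) || any(values < 0))
    stopf("expression values must be finite and nonnegative")
  condition <- as.character(condition)
  stopifnot(length(condition) == nrow(values))
  structure(
    list(values = values, cell_ids = rownames(values),
         gene_ids = colnames(values), condition = condition,
         true_type = true_type, scale = scale),
    class = "ExprMatrix")
}

#' @export
print.ExprMatrix <- function(x, ...) {
  cat(sprintf("ExprMatrix: %d cells x %d genes (log1p, scale = %g)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExprMatrix <- function(x) dim(x$values)

# resolve a gene set against the matrix, warning on unmatched names
resolve_genes <- function(e, genes, what = "gene set") {
  hit <- genes %in% e$gene_ids
  if (!all(hit))
    warnf("%s: %d gene(s) not in matrix, dropped: %s", what, sum(!hit),
          paste(genes[!hit], collapse = ", "))
  genes[hit]
}
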