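# ECDF/Kolmogorov-Smirnov comparison of marker expression between treatment
# arms, and thresholded Pearson coexpression networks of cytotoxic markers.

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the exact supremum of the absolute difference between the two
#' step ECDFs, evaluated over the pooled sample points (correct under
#' ties). The p-value is the asymptotic Kolmogorov tail with the standard
#' small-sample correction: with `n_e = n_x * n_y / (n_x + n_y)` and
#' `lambda = (sqrt(n_e) + 0.12 + 0.11 / sqrt(n_e)) * D`,
#' `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)`, truncated once
#' terms drop below 1e-12 and clipped to (0, 1].
#'
#' @param x,y Numeric samples (each nonempty).
#' @return List with elements `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  D <- max(abs(fx - fy))
  list(D = D, p = ks_asymptotic_p(D, length(x), length(y)))
}

ks_asymptotic_p <- function(D, nx, ny) {
  if (D <= 0) return(1)
  ne <- nx * ny / (nx + ny)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  p <- 0
  for (k in seq_len(100)) {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    p <- p + term
    if (abs(term) < 1e-12) break
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Compare marker-expression ECDFs between conditions for one cell type
#'
#' Each cell is summarized by the mean (or sum) of its log1p expression
#' over `marker_set`; the control and treated distributions of this
#' statistic are compared with the two-sample KS test.
#'
#' @param e An `ExprMatrix`.
#' @param labels Named character vector, cell id -> cell-type label.
#' @param cell_type The type to compare.
#' @param marker_set Nonempty character vector of marker genes.
#' @param combine `"mean"` (default) or `"sum"` across markers.
#' @param min_cells Minimum cells required per arm (default 5).
#' @return An `ECDFComparison`: list with `cell_type`, `markers`,
#'   `n_control`, `n_treated`, `D`, `p`, `direction` (sign of treated minus
#'   control mean).
#' @export
ecdf_compare <- function(e, labels, cell_type, marker_set,
                         combine = c("mean", "sum"), min_cells = 5L) {
  stopifnot(inherits(e, "ExprMatrix"), length(marker_set) >= 1)
  combine <- match.arg(combine)
  labels <- labels[e$cell_ids]
  marker_set <- resolve_genes(e, marker_set, "ecdf_compare")
  if (!length(marker_set)) stopf("no marker of marker_set in the matrix")
  vals <- e$values[, marker_set, drop = FALSE]
  stat <- if (combine == "mean") rowMeans(vals) else rowSums(vals)
  ctl <- stat[labels == cell_type & e$condition == "control"]
  trt <- stat[labels == cell_type & e$condition == "treated"]
  if (length(ctl) < min_cells || length(trt) < min_cells)
    stopf("cell type '%s' has %d control / %d treated cells (need >= %d each)",
          cell_type, length(ctl), length(trt), min_cells)
  ks <- ks_two_sample(ctl, trt)
  structure(
    list(cell_type = cell_type, markers = marker_set,
         n_control = length(ctl), n_treated = length(trt),
         D = ks$D, p = ks$p,
         direction = sign(mean(trt) - mean(ctl))),
    class = "ECDFComparison")
}

#' @export
print.ECDFComparison <- function(x, ...) {
  cat(sprintf(
    "ECDF comparison, %s (%s): D = %.4f, p = %.3g, direction %+d (n = %d/%d)\n",
    x$cell_type, paste(x$markers, collapse = "+"), x$D, x$p,
    x$direction, x$n_control, x$n_treated))
  invisible(x)
}

#' Thresholded Pearson coexpression network of markers
#'
#' Pairwise Pearson correlation of `markers` across the cells of one type
#' and condition; edges where `|r| >= r_min`; communities by label
#' propagation on the thresholded graph (isolated markers stay singleton
#' communities). Zero-variance markers are excluded with a warning.
#'
#' @param e An `ExprMatrix`.
#' @param labels Named character vector, cell id -> cell-type label.
#' @param cell_type,condition Cell subset to correlate (>= 10 cells).
#' @param markers At least 3 marker genes.
#' @param r_min Absolute-correlation edge threshold (default 0.3).
#' @param seed Seed for the community tie-breaks.
#' @return A `CoexpressionNetwork`: list with `cell_type`, `condition`,
#'   `nodes`, `edges` (data frame `gene1`, `gene2`, `r`) and `communities`
#'   (named vector).
#' @export
coexpression_network <- function(e, labels, cell_type, condition, markers,
                                 r_min = 0.3, seed = 1L) {
  stopifnot(inherits(e, "ExprMatrix"), length(markers) >= 3)
  labels <- labels[e$cell_ids]
  markers <- resolve_genes(e, markers, "coexpression_network")
  sel <- labels == cell_type & e$condition == condition
  if (sum(sel) < 10)
    stopf("need >= 10 cells of '%s' in '%s', found %d", cell_type,
          condition, sum(sel))
  vals <- e$values[sel, markers, drop = FALSE]
  keep <- apply(vals, 2, stats::sd) > 0
  if (!all(keep))
    warnf("zero-variance marker(s) excluded: %s",
          paste(markers[!keep], collapse = ", "))
  vals <- vals[, keep, drop = FALSE]
  if (ncol(vals) < 3) stopf("fewer than 3 usable markers remain")
  r <- stats::cor(vals)
  idx <- which(upper.tri(r) & abs(r) >= r_min, arr.ind = TRUE)
  edges <- data.frame(gene1 = colnames(vals)[idx[, 1]],
                      gene2 = colnames(vals)[idx[, 2]],
                      r = r[idx])
  g <- neighbor_graph(colnames(vals),
                      data.frame(from = idx[, 1], to = idx[, 2],
                                 weight = abs(r[idx])))
  comm <- label_propagation_communities(g, seed = seed)
  structure(
    list(cell_type = cell_type, condition = condition,
         nodes = colnames(vals), edges = edges, communities = comm),
    class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf(
    "Coexpression network, %s/%s: %d markers, %d edges, %d communities\n",
    x$cell_type, x$condition, length(x$nodes), nrow(x$edges),
    length(unique(x$communities))))
  invisible(x)
}
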