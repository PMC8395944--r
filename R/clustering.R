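# kNN-graph construction and label-propagation community detection. Label
# propagation is the single community algorithm of the package, shared by
# cell clustering, coexpression networks and the ligand-receptor network.

# PCA scores of a cells x genes matrix (exact SVD on the centered matrix;
# fine at desk scale)
pca_scores <- function(values, n_pcs) {
  n_pcs <- min(n_pcs, nrow(values) - 1L, ncol(values))
  ctr <- sweep(values, 2, colMeans(values))
  sv <- svd(ctr, nu = n_pcs, nv = 0)
  sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
}

# row-wise k nearest neighbors (Euclidean), computed block-wise via the
# |x|^2 + |y|^2 - 2<x,y> expansion to bound memory
knn_indices <- function(x, k, block = 1024L) {
  n <- nrow(x)
  stopifnot(k < n)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf # exclude self
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Construct a NeighborGraph
#'
#' @param nodes Character node ids.
#' @param edges Data frame with columns `from`, `to` (integer indices into
#'   `nodes`) and `weight`.
#' @param k Neighbors-per-node parameter used to build the graph (NA for
#'   graphs not built from kNN).
#' @return A `NeighborGraph`.
#' @export
neighbor_graph <- function(nodes, edges, k = NA_integer_) {
  stopifnot(is.character(nodes), is.data.frame(edges),
            all(c("from", "to") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (any(edges$from == edges$to)) stopf("self-loops are not allowed")
  if (any(edges$weight < 0)) stopf("edge weights must be >= 0")
  if (nrow(edges) &&
      (max(edges$from, edges$to) > length(nodes) ||
       min(edges$from, edges$to) < 1L))
    stopf("edge endpoints out of range")
  structure(list(nodes = nodes, edges = edges, k = k),
            class = "NeighborGraph")
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph: %d nodes, %d undirected edges (k = %s)\n",
              length(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

#' Build a kNN graph on PCA-reduced expression
#'
#' PCA (exact SVD) to `n_pcs` on the centered log-expression, then an
#' undirected graph with an edge wherever either endpoint lists the other
#' among its `k` nearest Euclidean neighbors. Edges are unweighted
#' (weight 1).
#'
#' @param e An `ExprMatrix`.
#' @param k Neighbors per cell (`1 <= k < n_cells`).
#' @param n_pcs Number of principal components (>= 2).
#' @return A `NeighborGraph` over the cells of `e`.
#' @export
build_knn_graph <- function(e, k = 15, n_pcs = 10) {
  stopifnot(inherits(e, "ExprMatrix"), k >= 1, n_pcs >= 2)
  n <- nrow(e$values)
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)",
                    k, n)
  nn <- knn_indices(pca_scores(e$values, n_pcs), k)
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn))
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  neighbor_graph(e$cell_ids,
                 data.frame(from = a[keep], to = b[keep], weight = 1),
                 k = as.integer(k))
}

#' Label-propagation community detection
#'
#' Asynchronous label propagation: every node starts with a unique label;
#' nodes are visited in a seeded random order and each adopts the most
#' frequent label among its neighbors (ties broken by a seeded random
#' draw); iteration stops when a full pass changes no label or `max_iter`
#' passes have run. Disconnected components can never share a label;
#' isolated nodes stay singleton communities. Final labels are densified to
#' `0..K-1` by decreasing community size, ties by smallest member index.
#'
#' @param g A `NeighborGraph`.
#' @param seed Integer seed controlling visit order and tie-breaks.
#' @param max_iter Maximum number of full passes.
#' @return A `ClusterAssignment`: named integer vector (node id -> community
#'   id from 0).
#' @export
label_propagation_communities <- function(g, seed = 1L, max_iter = 100L) {
  stopifnot(inherits(g, "NeighborGraph"))
  n <- length(g$nodes)
  labels <- seq_len(n)
  if (n > 1L && nrow(g$edges)) {
    adj <- vector("list", n)
    ff <- c(g$edges$from, g$edges$to)
    tt <- c(g$edges$to, g$edges$from)
    ord <- order(ff)
    adj_split <- split(tt[ord], ff[ord])
    adj[as.integer(names(adj_split))] <- adj_split
    set.seed(as.integer(seed))
    for (iter in seq_len(max_iter)) {
      changed <- FALSE
      for (i in sample.int(n)) {
        nbr <- adj[[i]]
        if (is.null(nbr)) next
        new <- .mode_label(labels[nbr])
        if (new != labels[i]) {
          labels[i] <- new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  densify_labels(labels, g$nodes)
}

# relabel communities to dense 0-based ids ordered by decreasing size,
# ties by smallest member index
densify_labels <- function(labels, node_ids) {
  grp <- split(seq_along(labels), labels)
  ord <- order(-lengths(grp), vapply(grp, min, numeric(1)))
  new <- integer(length(labels))
  for (r in seq_along(ord)) new[grp[[ord[r]]]] <- r - 1L
  stats::setNames(new, node_ids)
}

#' Cluster cells end to end (kNN graph + label propagation)
#'
#' @inheritParams build_knn_graph
#' @inheritParams label_propagation_communities
#' @return A named integer vector, cell id -> cluster id (dense from 0).
#' @export
cluster_cells <- function(e, k = 15, n_pcs = 10, seed = 1L,
                          max_iter = 100L) {
  label_propagation_communities(build_knn_graph(e, k = k, n_pcs = n_pcs),
                                seed = seed, max_iter = max_iter)
}
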