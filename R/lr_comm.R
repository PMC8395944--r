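# Ligand-receptor communication scoring: score = mean ligand expression in
# the sender type x mean receptor expression in the receiver type, computed
# per condition; the treated-minus-control delta infers rewired signaling.

#' Construct a ligand-receptor pair table
#'
#' @param df Data frame with character columns `ligand` and `receptor`
#'   (optional `pathway`). Duplicate (ligand, receptor) rows are an error.
#' @return An `LRPairTable` (a validated data frame).
#' @export
lr_pair_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("ligand", "receptor") %in% names(df)))
  df$ligand <- as.character(df$ligand)
  df$receptor <- as.character(df$receptor)
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)))
    stopf("ligand and receptor gene names must be non-empty")
  if (anyDuplicated(df[, c("ligand", "receptor")]))
    stopf("duplicate (ligand, receptor) rows")
  rownames(df) <- NULL
  structure(df, class = c("LRPairTable", "data.frame"))
}

#' Read a ligand-receptor pair table from TSV
#'
#' @param path TSV with header `ligand<TAB>receptor` (optional `pathway`).
#' @return An `LRPairTable`.
#' @export
read_lr_pairs <- function(path) {
  lr_pair_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Bundled demo ligand-receptor table
#'
#' About 40 murine chemokine/cytokine pairs (Ccl/Ccr, Cxcl/Cxcr, Ifng,
#' Cd74, interleukins, Tnf, Csf) assembled from interactions commonly
#' discussed for tumor-immune crosstalk. It is a small synthetic stand-in
#' for a full curated ligand-receptor resource, bundled so the pipeline
#' runs without downloads.
#'
#' @return An `LRPairTable`.
#' @export
demo_lr_pairs <- function() {
  read_lr_pairs(system.file("extdata", "lr_pairs_demo.tsv",
                            package = "immunorewire", mustWork = TRUE))
}

#' Filter LR pairs to ligands differentially expressed in some sender type
#'
#' Retains the pairs whose ligand reaches `p < alpha` in the differential
#' expression results of at least one cell type; the qualifying sender
#' types are recorded per ligand in `attr(, "senders")`.
#'
#' @param de Data frame from [de_test()]/[de_test_all()] (columns
#'   `cell_type`, `gene`, `p`).
#' @param pairs An `LRPairTable`.
#' @param alpha Significance cutoff on the unadjusted DE p-value
#'   (default 0.05).
#' @return The filtered `LRPairTable` (possibly empty, with a warning).
#' @export
select_ligands <- function(de, pairs, alpha = 0.05) {
  stopifnot(is.data.frame(de), inherits(pairs, "LRPairTable"))
  hits <- de[de$p < alpha & de$gene %in% pairs$ligand, , drop = FALSE]
  keep <- pairs$ligand %in% hits$gene
  out <- pairs[keep, , drop = FALSE]
  if (!nrow(out)) warnf("no ligand passed DE selection at alpha = %g", alpha)
  rownames(out) <- NULL
  attr(out, "senders") <- if (nrow(hits))
    lapply(split(hits$cell_type, hits$gene), unique) else list()
  class(out) <- c("LRPairTable", "data.frame")
  out
}

#' Ligand-receptor communication scores per condition
#'
#' For each condition, sender type `s`, receiver type `r` and pair
#' `(l, q)`: `score = mean(expr of l over cells of s) * mean(expr of q over
#' cells of r)`, means taken over all cells of the type (zeros included).
#' All ordered (sender, receiver) combinations are scored, including
#' autocrine `s == r`. Pairs whose ligand or receptor is absent from the
#' matrix are skipped with a warning; a type absent from one condition
#' yields `NA` scores there (flagged in `missing`), never 0.
#'
#' @param e An `ExprMatrix` (normalized log1p values).
#' @param labels Named character vector, cell id -> cell-type label.
#' @param pairs An `LRPairTable`.
#' @param cell_types Types to score (default: all present in `labels`).
#' @return An `LRScoreTable`: data frame (`sender`, `receiver`, `ligand`,
#'   `receptor`, `score_control`, `score_treated`, `delta`, `missing`) with
#'   `delta = score_treated - score_control`.
#' @export
lr_score <- function(e, labels, pairs, cell_types = NULL) {
  stopifnot(inherits(e, "ExprMatrix"), inherits(pairs, "LRPairTable"))
  labels <- labels[e$cell_ids]
  cell_types <- cell_types %||% sort(unique(labels))

  genes <- unique(c(pairs$ligand, pairs$receptor))
  absent <- setdiff(genes, e$gene_ids)
  skip <- pairs$ligand %in% absent | pairs$receptor %in% absent
  if (any(skip))
    warnf("%d pair(s) skipped, gene(s) absent from matrix: %s", sum(skip),
          paste(intersect(absent, c(pairs$ligand, pairs$receptor)),
                collapse = ", "))
  pr <- pairs[!skip, , drop = FALSE]
  if (!nrow(pr)) stopf("no scoreable ligand-receptor pair")
  genes <- unique(c(pr$ligand, pr$receptor))

  # type x gene mean matrix per condition; NA row when a type is absent
  type_means <- function(cond) {
    m <- matrix(NA_real_, length(cell_types), length(genes),
                dimnames = list(cell_types, genes))
    for (ct in cell_types) {
      sel <- labels == ct & e$condition == cond
      if (any(sel)) m[ct, ] <- colMeans(e$values[sel, genes, drop = FALSE])
    }
    m
  }
  mc <- type_means("control")
  mt <- type_means("treated")

  combos <- expand.grid(sender = cell_types, receiver = cell_types,
                        pair = seq_len(nrow(pr)),
                        stringsAsFactors = FALSE)
  out <- data.frame(
    sender = combos$sender, receiver = combos$receiver,
    ligand = pr$ligand[combos$pair], receptor = pr$receptor[combos$pair])
  out$score_control <- mc[cbind(out$sender, out$ligand)] *
    mc[cbind(out$receiver, out$receptor)]
  out$score_treated <- mt[cbind(out$sender, out$ligand)] *
    mt[cbind(out$receiver, out$receptor)]
  out$delta <- out$score_treated - out$score_control
  out$missing <- is.na(out$score_control) | is.na(out$score_treated)
  if (any(out$missing))
    warnf("%d row(s) flagged missing (type absent in a condition)",
          sum(out$missing))
  attr(out, "n_skipped_pairs") <- sum(skip)
  class(out) <- c("LRScoreTable", "data.frame")
  out
}

#' Delta matrix for heatmap display
#'
#' Rows are (sender, receiver) combinations, columns are ligands. Deltas
#' are aggregated over receptors by the maximum absolute delta per ligand
#' (the chosen receptor is recorded in `attr(, "receptor_chosen")`).
#' Rows and columns are ordered by average-linkage hierarchical clustering
#' on Euclidean distance, which is deterministic.
#'
#' @param tbl An `LRScoreTable` (nonempty).
#' @return A numeric matrix of deltas with dimnames
#'   `"sender->receiver" x ligand`.
#' @export
lr_delta_heatmap <- function(tbl) {
  stopifnot(inherits(tbl, "LRScoreTable"), nrow(tbl) > 0)
  tbl$combo <- paste0(tbl$sender, "->", tbl$receiver)
  key <- paste(tbl$combo, tbl$ligand, sep = "\r")
  pick <- unlist(lapply(split(seq_len(nrow(tbl)), key), function(i) {
    a <- abs(tbl$delta[i])
    if (all(is.na(a))) i[1] else i[which.max(a)]
  }), use.names = FALSE)
  sel <- tbl[pick, , drop = FALSE]
  combos <- sort(unique(tbl$combo))
  ligands <- sort(unique(tbl$ligand))
  m <- matrix(NA_real_, length(combos), length(ligands),
              dimnames = list(combos, ligands))
  m[cbind(sel$combo, sel$ligand)] <- sel$delta
  chosen <- matrix(NA_character_, length(combos), length(ligands),
                   dimnames = dimnames(m))
  chosen[cbind(sel$combo, sel$ligand)] <- sel$receptor
  if (nrow(m) > 2) {
    hr <- stats::hclust(stats::dist(ifelse(is.na(m), 0, m)),
                        method = "average")
    m <- m[hr$order, , drop = FALSE]
    chosen <- chosen[hr$order, , drop = FALSE]
  }
  if (ncol(m) > 2) {
    hc <- stats::hclust(stats::dist(t(ifelse(is.na(m), 0, m))),
                        method = "average")
    m <- m[, hc$order, drop = FALSE]
    chosen <- chosen[, hc$order, drop = FALSE]
  }
  attr(m, "receptor_chosen") <- chosen
  m
}

#' Community structure of the ligand-receptor gene network
#'
#' Builds the undirected graph whose nodes are all ligand and receptor
#' genes and whose edges are the pairs, then detects communities by label
#' propagation. Community structure depends only on the pair table, never
#' on expression.
#'
#' @param pairs An `LRPairTable` (>= 1 pair).
#' @param seed Seed for the label-propagation tie-breaks.
#' @return An `LRNetwork`: list with `nodes`, `edges` (the pair table),
#'   `communities` (named vector, gene -> community id from 0) and
#'   `n_communities`.
#' @export
lr_network_communities <- function(pairs, seed = 1L) {
  stopifnot(inherits(pairs, "LRPairTable"), nrow(pairs) >= 1)
  nodes <- unique(c(pairs$ligand, pairs$receptor))
  edges <- data.frame(from = match(pairs$ligand, nodes),
                      to = match(pairs$receptor, nodes), weight = 1)
  edges <- edges[edges$from != edges$to, , drop = FALSE] # autocrine self-pair
  comm <- label_propagation_communities(neighbor_graph(nodes, edges),
                                        seed = seed)
  structure(list(nodes = nodes, edges = pairs, communities = comm,
                 n_communities = length(unique(comm))),
            class = "LRNetwork")
}

#' @export
print.LRNetwork <- function(x, ...) {
  cat(sprintf("LRNetwork: %d genes, %d pairs, %d communities\n",
              length(x$nodes), nrow(x$edges), x$n_communities))
  invisible(x)
}
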