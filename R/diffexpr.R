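# Differential expression between arms with detection-fraction (pct) and
# log-fold-change gates. The test statistic is a two-sided Wilcoxon
# rank-sum with normal approximation and tie correction -- a documented
# stand-in for a hurdle-model test; the pct/logFC gating contract (min pct
# 0.25, min |logFC| 0.25, pct as max over the two arms) is kept exact.

# rank-sum p (two-sided, normal approximation, tie-corrected, no
# continuity correction); all-tied input gives p = 1
wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - n1 * n2 / 2) / sqrt(sigma2)
  min(max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), 1)
}

#' Differential expression with pct and logFC gates
#'
#' For one cell type, compares treated vs control cells gene by gene.
#' `pct_1`/`pct_2` are the fractions of treated/control cells with nonzero
#' expression. The fold change is in natural log with the ecosystem's
#' +1-shifted mean-of-expm1 convention:
#' `logFC = ln(mean(expm1(x_treated)) + 1) - ln(mean(expm1(x_control)) + 1)`,
#' so positive values mean higher in treated. A gene is kept when
#' `max(pct_1, pct_2) >= min_pct` and `|logFC| >= min_logfc`; kept genes
#' get a Wilcoxon rank-sum p on the log1p values and Benjamini-Hochberg
#' adjustment within the cell type.
#'
#' @param e An `ExprMatrix`.
#' @param labels Named character vector, cell id -> cell-type label.
#' @param cell_type Type to test (>= 3 cells in each arm).
#' @param min_pct Detection-fraction gate (default 0.25).
#' @param min_logfc Absolute natural-log fold-change gate (default 0.25).
#' @param genes Genes to consider (default: all in the matrix).
#' @return Data frame (`cell_type`, `gene`, `logFC`, `pct_1`, `pct_2`, `p`,
#'   `p_adj`) for the genes passing both gates, ordered by `p`.
#' @export
de_test <- function(e, labels, cell_type, min_pct = 0.25,
                    min_logfc = 0.25, genes = NULL) {
  stopifnot(inherits(e, "ExprMatrix"))
  labels <- labels[e$cell_ids]
  genes <- if (is.null(genes)) e$gene_ids else
    resolve_genes(e, genes, "de_test")
  trt <- labels == cell_type & e$condition == "treated"
  ctl <- labels == cell_type & e$condition == "control"
  if (sum(trt) < 3 || sum(ctl) < 3)
    stopf("cell type '%s' needs >= 3 cells per arm (found %d treated, %d control)",
          cell_type, sum(trt), sum(ctl))
  xt <- e$values[trt, genes, drop = FALSE]
  xc <- e$values[ctl, genes, drop = FALSE]
  pct_1 <- colMeans(xt > 0)
  pct_2 <- colMeans(xc > 0)
  logfc <- log(colMeans(expm1(xt)) + 1) - log(colMeans(expm1(xc)) + 1)
  keep <- pmax(pct_1, pct_2) >= min_pct & abs(logfc) >= min_logfc
  kept <- genes[keep]
  p <- vapply(kept, function(g) wilcox_p(xt[, g], xc[, g]), numeric(1))
  out <- data.frame(cell_type = rep(cell_type, length(kept)), gene = kept,
                    logFC = logfc[keep], pct_1 = pct_1[keep],
                    pct_2 = pct_2[keep], p = unname(p),
                    p_adj = bh_adjust(unname(p)))
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Run de_test across several cell types
#'
#' @inheritParams de_test
#' @param cell_types Types to test; types with fewer than 3 cells in either
#'   arm are skipped with a message.
#' @return Row-bound data frame of per-type [de_test()] results.
#' @export
de_test_all <- function(e, labels, cell_types = NULL, min_pct = 0.25,
                        min_logfc = 0.25, genes = NULL) {
  labels <- labels[e$cell_ids]
  cell_types <- cell_types %||% sort(unique(labels))
  res <- lapply(cell_types, function(ct) {
    ok <- sum(labels == ct & e$condition == "treated") >= 3 &&
      sum(labels == ct & e$condition == "control") >= 3
    if (!ok) {
      message(sprintf("de_test_all: skipping '%s' (too few cells)", ct))
      return(NULL)
    }
    de_test(e, labels, ct, min_pct = min_pct, min_logfc = min_logfc,
            genes = genes)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cell_type = character(), gene = character(),
                      logFC = numeric(), pct_1 = numeric(),
                      pct_2 = numeric(), p = numeric(), p_adj = numeric())
  out
}
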