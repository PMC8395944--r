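# Marker-sign panel: cell type x gene -> {+1, -1, 0}. +1 means the type is
# expected high for the gene, -1 expected low, 0 uninformative.

#' Construct a MarkerPanel
#'
#' @param df Data frame with columns `cell_type`, `gene`, `sign`
#'   (values in -1/0/+1). Rows with sign 0 are allowed but ignored.
#' @return A `MarkerPanel`: an integer matrix (cell types x genes) of signs.
#' @export
marker_panel <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("cell_type", "gene", "sign") %in% names(df)))
  if (!all(df$sign %in% c(-1L, 0L, 1L)))
    stopf("panel signs must be -1, 0 or +1")
  types <- sort(unique(as.character(df$cell_type)))
  genes <- sort(unique(as.character(df$gene)))
  m <- matrix(0L, length(types), length(genes),
              dimnames = list(types, genes))
  m[cbind(match(df$cell_type, types), match(df$gene, genes))] <-
    as.integer(df$sign)
  nz <- rowSums(m != 0L)
  if (any(nz == 0L))
    stopf("cell type(s) with no informative marker: %s",
          paste(types[nz == 0L], collapse = ", "))
  structure(m, class = c("MarkerPanel", "matrix"))
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat(sprintf("MarkerPanel: %d cell types x %d genes (%d nonzero signs)\n",
              nrow(x), ncol(x), sum(x != 0L)))
  invisible(x)
}

#' Built-in marker panel for tumor-infiltrating CD45+ cells
#'
#' Fourteen populations typical of a myeloid-dominant murine prostate tumor
#' infiltrate: nine monocyte/macrophage states spanning the M1/M2
#' polarization spectrum, plus CD8/CD4 T cells, NK cells, T-cell-like
#' macrophages (T_M) and dendritic cells. Signs encode which markers each
#' population is expected to express highly (+1) or lack (-1) relative to
#' the other populations; Ncr1 is used as the canonical murine NK-defining
#' marker.
#'
#' @return A `MarkerPanel`.
#' @export
default_marker_panel <- function() {
  sgn <- function(type, plus = character(), minus = character()) {
    rbind(
      if (length(plus))
        data.frame(cell_type = type, gene = plus, sign = 1L),
      if (length(minus))
        data.frame(cell_type = type, gene = minus, sign = -1L))
  }
  df <- rbind(
    sgn("M2_noncommitted_NC",
        plus = c("Cd68", "Adgre1", "Cx3cr1", "Itgax", "Cxcl16"),
        minus = c("Ccr2", "Sell")),
    sgn("M2_partial",
        plus = c("Cd68", "Vegfa", "Arg1"),
        minus = c("Itgax", "Cxcl16")),
    sgn("M2",
        plus = c("H2-Aa", "H2-Ab1", "Cx3cr1", "Adgre1", "Ccl5", "Cxcl16")),
    sgn("Not_committed", plus = "Cd68"),
    sgn("M1_partial_TAM",
        plus = c("Arg2", "Il1b", "Cd80", "Csf2rb", "Sell"),
        minus = c("H2-Aa", "H2-Ab1")),
    sgn("M1_committed",
        plus = c("Csf2rb", "Cd80", "H2-Aa", "H2-Ab1", "Itgax", "Cd86",
                 "Il1b")),
    sgn("M1_polarized",
        plus = c("Cd80", "Csf2rb", "Cd86", "Ccl5", "Cxcl16")),
    sgn("M2_committed_NC",
        plus = c("Cx3cr1", "Adgre1", "Tlr8"),
        minus = "Cd86"),
    sgn("Classical_monocyte", plus = "Ly6c1"),
    sgn("CD8_T", plus = c("Cd3e", "Cd8a")),
    sgn("CD4_T", plus = c("Cd3e", "Cd4")),
    sgn("NK", plus = "Ncr1", minus = "Cd3e"),
    sgn("T_M",
        plus = c("Cd3e", "Cd68", "Tnf", "Lamp1", "Ccr5", "Il1b")),
    sgn("DC", plus = c("Itgax", "H2-Aa", "H2-Ab1")))
  marker_panel(df)
}

#' Read a marker panel from TSV
#'
#' @param path TSV file with header `cell_type<TAB>gene<TAB>sign`.
#' @return A `MarkerPanel`.
#' @export
read_marker_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  marker_panel(df)
}

#' Write a marker panel to TSV
#'
#' @param panel A `MarkerPanel`.
#' @param path Output TSV path.
#' @export
write_marker_panel <- function(panel, path) {
  idx <- which(unclass(panel) != 0L, arr.ind = TRUE)
  df <- data.frame(cell_type = rownames(panel)[idx[, 1]],
                   gene = colnames(panel)[idx[, 2]],
                   sign = panel[idx])
  df <- df[order(df$cell_type, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check panel genes against a gene universe; error only if a type would be
# left without any usable marker
check_panel_genes <- function(panel, gene_ids) {
  present <- colnames(panel) %in% gene_ids
  if (!all(present))
    warnf("panel gene(s) not in matrix: %s",
          paste(colnames(panel)[!present], collapse = ", "))
  sub <- panel[, present, drop = FALSE]
  usable <- rowSums(sub != 0L)
  if (any(usable < 1L))
    stopf("cell type(s) with no resolvable marker: %s",
          paste(rownames(panel)[usable < 1L], collapse = ", "))
  sub
}
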