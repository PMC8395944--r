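# Shared fixtures: small planted worlds and direct-constructed matrices.

# ExprMatrix straight from a numeric matrix (bypasses counts/normalization)
mk_expr <- function(values, condition, true_type = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  expr_matrix(values, condition = condition, true_type = true_type,
              scale = 1e4)
}

# CountMatrix from a plain matrix with auto ids
mk_counts <- function(counts, condition = rep("control", nrow(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  count_matrix(counts, condition = condition)
}

# permissive QC for small synthetic worlds whose gene universe is tiny
lax_qc <- qc_params(min_features = 0, max_features = 1e6,
                    max_mito_pct = 100)

# two-type world used by clustering/annotation/DE tests
two_type_config <- function(n = 100, seed = 1, props = c(M2 = 0.6, CD8_T = 0.4),
                            treatment_effects = NULL, ...) {
  scenario_config(
    n_cells_per_condition = n,
    cell_type_proportions = list(control = props, treated = props),
    extra_means = data.frame(cell_type = "CD8_T",
                             gene = c("Gzmb", "Gzmk", "Ccr5"), mean = 2),
    treatment_effects = treatment_effects,
    seed = seed, ...)
}

# single-type null world for calibration-style tests
null_config <- function(seed, n = 500, treatment_effects = NULL) {
  scenario_config(
    n_cells_per_condition = n,
    cell_type_proportions = list(control = c(CD8_T = 1),
                                 treated = c(CD8_T = 1)),
    extra_means = data.frame(cell_type = "CD8_T",
                             gene = c("Gzmb", "Gzmk", "Prf1"), mean = 2),
    treatment_effects = treatment_effects,
    n_background_genes = 10, n_program_genes = 0, n_mito_genes = 0,
    seed = seed)
}

sim_expr <- function(cfg) {
  m <- qc_filter(simulate_counts(cfg), lax_qc)
  list(m = m, e = normalize_log1p(m),
       labels = stats::setNames(m$true_type, m$cell_ids))
}

# restriction of the default panel to a subset of cell types
sub_panel <- function(types) {
  full <- default_marker_panel()
  idx <- which(unclass(full) != 0L, arr.ind = TRUE)
  df <- data.frame(cell_type = rownames(full)[idx[, 1]],
                   gene = colnames(full)[idx[, 2]],
                   sign = full[idx])
  marker_panel(df[df$cell_type %in% types, ])
}

# brute-force two-sample KS D: evaluate both step ECDFs on the pooled grid
brute_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# brute-force QC survivor set
brute_qc_keep <- function(counts, min_f, max_f, max_mito, prefix = "mt-") {
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    nf <- sum(counts[i, ] > 0)
    tot <- sum(counts[i, ])
    mito <- sum(counts[i, startsWith(colnames(counts), prefix)])
    pct <- if (tot > 0) 100 * mito / tot else 0
    keep[i] <- nf > min_f && nf < max_f && pct < max_mito
  }
  keep
}
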