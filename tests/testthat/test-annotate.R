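# one noise-free cluster per panel type, each built exactly on its profile
planted_profile_expr <- function(n_cells = 5, high = 4, low = 0.2) {
  panel <- default_marker_panel()
  types <- rownames(panel)
  vals <- do.call(rbind, lapply(types, function(ty) {
    prof <- ifelse(unclass(panel)[ty, ] == 1L, high, low)
    matrix(rep(prof, n_cells), n_cells, byrow = TRUE)
  }))
  colnames(vals) <- colnames(panel)
  rownames(vals) <- sprintf("c%03d", seq_len(nrow(vals)))
  list(e = mk_expr(vals, condition = rep("control", nrow(vals))),
       clusters = stats::setNames(rep(seq_along(types) - 1L,
                                      each = n_cells), rownames(vals)),
       types = types)
}

test_that("clusters built exactly on planted profiles get their own label", {
  w <- planted_profile_expr()
  ann <- annotate_clusters(w$e, w$clusters)
  got <- stats::setNames(ann$label, ann$cluster)
  for (type in c("M1_committed", "NK", "CD8_T", "M2", "DC",
                 "Classical_monocyte", "T_M", "CD4_T")) {
    expect_identical(unname(got[as.character(match(type, w$types) - 1L)]),
                     type)
  }
  expect_gte(min(ann$margin), 0)
})

test_that("single-type panel labels everything with margin 0", {
  w <- planted_profile_expr()
  single <- marker_panel(data.frame(cell_type = "NK", gene = "Ncr1",
                                    sign = 1L))
  ann <- annotate_clusters(w$e, w$clusters, single)
  expect_true(all(ann$label == "NK"))
  expect_true(all(ann$margin == 0))
})

test_that("tiny clusters are unassigned with a warning", {
  w <- planted_profile_expr(n_cells = 5)
  cl <- w$clusters
  cl[1:2] <- 99L # split 2 cells into their own cluster
  expect_warning(ann <- annotate_clusters(w$e, cl), "unassigned")
  expect_identical(ann$label[ann$cluster == 99], "unassigned")
})

test_that("scores are invariant to gene-wise affine rescaling", {
  w <- sim_expr(two_type_config(n = 60, seed = 23))
  cl <- cluster_cells(w$e, k = 10, seed = 1)
  s1 <- attr(annotate_clusters(w$e, cl), "scores")
  vals <- sweep(sweep(w$e$values, 2, runif(ncol(w$e$values), 0.5, 3), "*"),
                2, runif(ncol(w$e$values), 0, 2), "+")
  e2 <- mk_expr(vals, condition = w$e$condition)
  rownames(e2$values) <- w$e$cell_ids
  e2$cell_ids <- w$e$cell_ids
  s2 <- attr(annotate_clusters(e2, cl), "scores")
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("permuting cluster ids permutes the results identically", {
  w <- sim_expr(two_type_config(n = 60, seed = 29))
  cl <- cluster_cells(w$e, k = 10, seed = 1)
  ann <- annotate_clusters(w$e, cl)
  swap <- max(cl) + 1L - cl # reverse ids
  ann2 <- annotate_clusters(w$e, swap)
  m1 <- stats::setNames(ann$label, max(cl) + 1L - ann$cluster)
  m2 <- stats::setNames(ann2$label, ann2$cluster)
  expect_identical(m1[order(as.integer(names(m1)))],
                   m2[order(as.integer(names(m2)))])
})

test_that("cell labels inherit cluster labels consistently", {
  w <- sim_expr(two_type_config(n = 60, seed = 31))
  cl <- cluster_cells(w$e, k = 10, seed = 1)
  ann <- annotate_clusters(w$e, cl)
  labels <- cell_labels(ann, cl)
  for (i in seq_len(nrow(ann)))
    expect_true(all(labels[cl == ann$cluster[i]] == ann$label[i]))
})

test_that("marker_positive_fraction handles trivial and planted cases", {
  vals <- matrix(c(1, 2, 3, 4, 0, 0, 0, 0), 4, 2,
                 dimnames = list(sprintf("c%d", 1:4), c("pos", "zero")))
  e <- expr_matrix(vals, condition = c("control", "control", "treated",
                                       "treated"))
  lab <- stats::setNames(rep("T", 4), rownames(vals))
  f <- marker_positive_fraction(e, lab, "pos", threshold = 0)
  expect_equal(f$fraction[f$cell_type == "T"], c(1, 1))
  f0 <- marker_positive_fraction(e, lab, "zero", threshold = 0.1)
  expect_equal(f0$fraction[f0$cell_type == "T"], c(0, 0))

  # absent type in one arm -> NA and warning, not 0
  lab2 <- lab
  lab2[3:4] <- "B"
  expect_warning(f2 <- marker_positive_fraction(e, lab2, "pos", 0),
                 "absent")
  expect_true(is.na(f2$fraction[f2$cell_type == "T" &
                                  f2$condition == "treated"]))

  # planted 2x Ccr5 fold in treated M1_polarized cells
  cfg <- scenario_config(
    n_cells_per_condition = 400,
    cell_type_proportions = list(control = c(M1_polarized = 1),
                                 treated = c(M1_polarized = 1)),
    extra_means = data.frame(cell_type = "M1_polarized", gene = "Ccr5",
                             mean = 2),
    treatment_effects = data.frame(cell_type = "M1_polarized",
                                   gene = "Ccr5", fold = 2),
    n_background_genes = 20, n_program_genes = 0, seed = 37)
  w <- sim_expr(cfg)
  thr <- stats::median(w$e$values[, "Ccr5"])
  f3 <- marker_positive_fraction(w$e, w$labels, "Ccr5", thr)
  expect_gt(f3$fraction[f3$condition == "treated"],
            f3$fraction[f3$condition == "control"])
})

test_that("low-margin clusters can be split and re-annotated", {
  # two types forced into one cluster; refinement should separate them;
  # a type-restricted panel keeps the 2-cluster z-scores well conditioned
  w <- sim_expr(two_type_config(n = 80, seed = 41))
  panel2 <- sub_panel(c("M2", "CD8_T"))
  one <- stats::setNames(rep(0L, nrow(w$e$values)), w$e$cell_ids)
  ref <- refine_annotation(w$e, one, panel2, margin_threshold = 10,
                           k = 10, seed = 1)
  expect_gt(length(unique(ref$clusters)), 1)
  expect_setequal(unique(ref$annotation$label), c("M2", "CD8_T"))
  # cells carry their cluster's label faithfully
  labs <- cell_labels(ref$annotation, ref$clusters)
  expect_gt(mean(labs == w$m$true_type), 0.95)
})
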