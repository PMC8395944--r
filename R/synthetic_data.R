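# Synthetic two-condition CD45+ scRNA-seq counts and tumor growth curves
# with planted ground truth, so every downstream stage is testable without
# external data.

default_proportions <- function() {
  list(
    control = c(
      M2_noncommitted_NC = 0.08, M2_partial = 0.08, M2 = 0.08,
      Not_committed = 0.06, M1_partial_TAM = 0.06, M1_committed = 0.06,
      M1_polarized = 0.06, M2_committed_NC = 0.06,
      Classical_monocyte = 0.06,
      CD8_T = 0.10, CD4_T = 0.12, NK = 0.06, T_M = 0.04, DC = 0.08),
    treated = c(
      M2_noncommitted_NC = 0.07, M2_partial = 0.05, M2 = 0.07,
      Not_committed = 0.06, M1_partial_TAM = 0.07, M1_committed = 0.08,
      M1_polarized = 0.08, M2_committed_NC = 0.05,
      Classical_monocyte = 0.06,
      CD8_T = 0.14, CD4_T = 0.08, NK = 0.09, T_M = 0.05, DC = 0.05))
}

# effector/exhaustion genes expressed at an intermediate baseline in the
# lymphoid populations, plus chemokine/cytokine ligands and receptors in
# plausible sender/receiver types, so treatment folds and ligand-receptor
# scores act on a detectable base
default_extra_means <- function(mu_mid = 2) {
  cyto <- c("Gzmb", "Gzmk", "Prf1", "Ifng", "Cd69", "Pdcd1")
  exh <- c("Cd244", "Btla", "Cd160")
  em <- function(type, genes) data.frame(cell_type = type, gene = genes,
                                         mean = mu_mid)
  rbind(
    em("CD8_T", c(cyto, exh)),
    em("NK", cyto),
    em("T_M", c("Gzmk", "Ifng")),
    # ligand-receptor axes: monocyte recruitment (Ccl2/Ccl12-Ccr2),
    # T/B homing (Cxcl12/Cd74-Cxcr4, Cxcl13-Cxcr5, Ccl22-Ccr4),
    # interferon response (Ifng-Ifngr1/2)
    em("Classical_monocyte", c("Ccl2", "Ccl12", "Ccr2", "Cxcr2")),
    em("M2_partial", c("Ccl2", "Cxcl13")),
    em("Not_committed", c("Cxcl12", "Il1r1")),
    em("DC", c("Cd74", "Ccl22", "Ccl5")),
    em("M2", c("Cd74", "Ifngr1", "Ifngr2", "Tnfrsf1a")),
    em("M1_committed", c("Ifngr1", "Ifngr2", "Tnfrsf1a")),
    em("CD4_T", c("Cxcr4", "Ccr4", "Cxcr5")),
    em("CD8_T", c("Cxcr4", "Ccr5")))
}

# the planted biology: cytotoxic program up in CD8/NK, exhaustion down in
# CD8, Arg1+ M2 program down, Ccr5 up in activated M1 and T_M
default_treatment_effects <- function() {
  rbind(
    data.frame(cell_type = "CD8_T",
               gene = c("Gzmb", "Gzmk", "Prf1", "Ifng", "Lamp1", "Ccr5"),
               fold = 2),
    data.frame(cell_type = "NK",
               gene = c("Gzmb", "Gzmk", "Prf1", "Ifng", "Lamp1"),
               fold = 2),
    data.frame(cell_type = "CD8_T",
               gene = c("Cd244", "Btla", "Cd160"), fold = 0.5),
    data.frame(cell_type = "M2_partial", gene = "Arg1", fold = 0.5),
    data.frame(cell_type = "M1_polarized", gene = "Ccr5", fold = 2),
    data.frame(cell_type = "T_M", gene = c("Gzmk", "Ifng", "Ccr5"),
               fold = 2),
    # rewired chemokine signaling: Ccl5 from DCs and polarized M1, Ccl22
    # from DCs, Cxcl13 from M2-like senders, Cxcr4 on CD8 T cells
    data.frame(cell_type = "DC", gene = c("Ccl5", "Ccl22"), fold = 2),
    data.frame(cell_type = "M1_polarized", gene = "Ccl5", fold = 2),
    data.frame(cell_type = "M2_partial", gene = "Cxcl13", fold = 2),
    data.frame(cell_type = "CD8_T", gene = "Cxcr4", fold = 1.5))
}

#' Scenario configuration for the scRNA-seq count simulator
#'
#' Defaults describe the system the package targets: 3000 cells per
#' condition, 14 immune populations with a myeloid-dominant composition
#' (myeloid fractions sum to about 0.6), marker genes at negative-binomial
#' mean `mu_high` in their population and `mu_low` elsewhere, lognormal
#' library-size variation, and treatment effects raising the cytotoxic
#' program in CD8/NK cells while lowering exhaustion markers and the Arg1+
#' M2 program.
#'
#' @param n_cells_per_condition Cells simulated per arm.
#' @param cell_type_proportions Named list with elements `control` and
#'   `treated`, each a named numeric vector of type fractions summing to 1.
#' @param mu_high NB mean for a population's +1 markers.
#' @param mu_low NB mean for background/expected-low genes (>= 0).
#' @param dispersion NB size parameter (larger = less overdispersed).
#' @param n_background_genes Count of uninformative filler genes.
#' @param n_program_genes Per-type count of private "program" genes
#'   expressed at `mu_program` only in that type: the broad transcriptional
#'   identity real cell types carry beyond the handful of curated panel
#'   markers. They drive PCA/kNN separability; annotation still sees only
#'   the panel genes.
#' @param mu_program NB mean of a type's own program genes.
#' @param extra_means Data frame (`cell_type`, `gene`, `mean`) of baseline
#'   NB means overriding `mu_low` for specific type/gene combinations; used
#'   for effector/exhaustion genes absent from the panel.
#' @param treatment_effects Data frame (`cell_type`, `gene`, `fold`):
#'   multiplicative fold applied to the treated-arm NB mean.
#' @param library_size_cv Coefficient of variation of the lognormal per-cell
#'   library-size factor (mean 1).
#' @param n_mito_genes Number of mitochondrial filler genes (prefixed
#'   `mt-`), present so QC has something to measure.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output.
#' @return A validated `ScenarioConfig` list.
#' @export
scenario_config <- function(n_cells_per_condition = 3000,
                            cell_type_proportions = default_proportions(),
                            mu_high = 8,
                            mu_low = 0.3,
                            dispersion = 2,
                            n_background_genes = 700,
                            n_program_genes = 40,
                            mu_program = 4,
                            extra_means = default_extra_means(),
                            treatment_effects = default_treatment_effects(),
                            library_size_cv = 0.3,
                            n_mito_genes = 5,
                            seed = 1L) {
  cfg <- list(n_cells_per_condition = n_cells_per_condition,
              cell_type_proportions = cell_type_proportions,
              mu_high = mu_high, mu_low = mu_low, dispersion = dispersion,
              n_background_genes = n_background_genes,
              n_program_genes = n_program_genes, mu_program = mu_program,
              extra_means = extra_means,
              treatment_effects = treatment_effects,
              library_size_cv = library_size_cv,
              n_mito_genes = n_mito_genes,
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "ScenarioConfig")
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (n_cells_per_condition < 1) stopf("n_cells_per_condition must be >= 1")
    if (!all(c("control", "treated") %in% names(cell_type_proportions)))
      stopf("cell_type_proportions needs 'control' and 'treated' entries")
    for (cond in c("control", "treated")) {
      p <- cell_type_proportions[[cond]]
      if (abs(sum(p) - 1) > 1e-9)
        stopf("%s proportions sum to %.10f, not 1", cond, sum(p))
      if (any(p < 0)) stopf("%s proportions must be nonnegative", cond)
    }
    if (!setequal(names(cell_type_proportions$control),
                  names(cell_type_proportions$treated)))
      stopf("control and treated proportions must name the same cell types")
    if (!(mu_high > mu_low)) stopf("mu_high must exceed mu_low")
    if (mu_low < 0) stopf("mu_low must be >= 0")
    if (dispersion <= 0) stopf("dispersion must be > 0")
    if (n_background_genes < 0) stopf("n_background_genes must be >= 0")
    if (n_program_genes < 0) stopf("n_program_genes must be >= 0")
    if (n_program_genes > 0 && mu_program <= 0)
      stopf("mu_program must be > 0")
    if (library_size_cv < 0) stopf("library_size_cv must be >= 0")
  })
  invisible(cfg)
}

#' Simulate a two-condition scRNA-seq count matrix with planted structure
#'
#' For each cell its type is drawn from that condition's proportion vector.
#' Gene `g` in a cell of type `t` is negative-binomial with mean `mu_high`
#' when `panel[t, g] == +1` and `mu_low` otherwise (overridable via
#' `extra_means`), scaled by the cell's lognormal library-size factor and,
#' in the treated arm, by any matching treatment-effect fold. A single
#' seeded RNG stream is consumed in fixed order (types, then library
#' factors, then counts), so output is bit-identical for a given
#' config + seed.
#'
#' @param config A `ScenarioConfig`.
#' @param panel A `MarkerPanel`; defaults to [default_marker_panel()].
#' @return A `CountMatrix` with `true_type` filled in.
#' @export
simulate_counts <- function(config, panel = default_marker_panel()) {
  validate_scenario_config(config)
  types <- names(config$cell_type_proportions$control)
  panel_types <- intersect(types, rownames(panel))
  if (!length(panel_types))
    stopf("no overlap between configured cell types and panel types")

  genes <- colnames(panel)
  if (!is.null(config$extra_means) && nrow(config$extra_means))
    genes <- union(genes, config$extra_means$gene)
  n_prog <- config$n_program_genes %||% 0L
  if (n_prog > 0)
    genes <- c(genes, as.vector(vapply(types, function(ty) {
      sprintf("Prog-%s-%02d", ty, seq_len(n_prog))
    }, character(n_prog))))
  if (config$n_mito_genes > 0)
    genes <- c(genes, sprintf("mt-Sim%d", seq_len(config$n_mito_genes)))
  if (config$n_background_genes > 0)
    genes <- c(genes,
               sprintf("Bg%04d", seq_len(config$n_background_genes)))

  te <- config$treatment_effects
  if (!is.null(te) && nrow(te)) {
    bad_t <- setdiff(te$cell_type, types)
    if (length(bad_t))
      stopf("treatment_effects references unknown cell type(s): %s",
            paste(unique(bad_t), collapse = ", "))
    bad_g <- setdiff(te$gene, genes)
    if (length(bad_g))
      stopf("treatment_effects references unknown gene(s): %s",
            paste(unique(bad_g), collapse = ", "))
  }
  em <- config$extra_means
  if (!is.null(em) && nrow(em)) {
    bad_t <- setdiff(em$cell_type, types)
    if (length(bad_t))
      stopf("extra_means references unknown cell type(s): %s",
            paste(unique(bad_t), collapse = ", "))
  }

  # baseline mean per (type, gene): mu_high for +1 panel entries, mu_low
  # elsewhere (mitochondrial fillers stay at mu_low, giving a small but
  # nonzero mito fraction for QC to measure)
  base <- matrix(config$mu_low, length(types), length(genes),
                 dimnames = list(types, genes))
  pg <- intersect(colnames(panel), genes)
  pt <- intersect(rownames(panel), types)
  sub <- base[pt, pg, drop = FALSE]
  sub[unclass(panel)[pt, pg, drop = FALSE] == 1L] <- config$mu_high
  base[pt, pg] <- sub
  if (n_prog > 0)
    for (ty in types)
      base[ty, sprintf("Prog-%s-%02d", ty, seq_len(n_prog))] <-
        config$mu_program
  if (!is.null(em) && nrow(em))
    base[cbind(match(em$cell_type, types), match(em$gene, genes))] <- em$mean

  fold <- matrix(1, length(types), length(genes),
                 dimnames = list(types, genes))
  if (!is.null(te) && nrow(te))
    fold[cbind(match(te$cell_type, types), match(te$gene, genes))] <- te$fold

  n <- config$n_cells_per_condition
  condition <- rep(c("control", "treated"), each = n)
  set.seed(config$seed)
  # stream order: types -> library factors -> counts
  type_of <- c(
    sample(types, n, replace = TRUE,
           prob = config$cell_type_proportions$control),
    sample(types, n, replace = TRUE,
           prob = config$cell_type_proportions$treated))
  lib <- if (config$library_size_cv > 0) {
    s2 <- log(1 + config$library_size_cv^2)
    stats::rlnorm(2L * n, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else rep(1, 2L * n)

  mu <- base[type_of, , drop = FALSE]
  trt <- condition == "treated"
  mu[trt, ] <- mu[trt, , drop = FALSE] * fold[type_of[trt], , drop = FALSE]
  mu <- mu * lib
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = config$dispersion),
    nrow = nrow(mu),
    dimnames = list(sprintf("cell_%05d", seq_len(2L * n)), genes))

  count_matrix(counts, condition = condition, true_type = type_of)
}

#' Growth-curve scenario
#'
#' Defaults emulate a subcutaneous TRAMP C2 graft experiment: randomization
#' at about 75 mm3, measurements every 2-3 days over 4 weeks, exponential
#' growth at 0.12/day in controls, and a treated rate chosen so the
#' endpoint mean is reduced by 66% (rate difference `log(0.34)/28` per day).
#'
#' @param n_mice_per_group Mice per arm (>= 2).
#' @param days Strictly increasing measurement days.
#' @param v0_mean Initial tumor volume, mm3.
#' @param growth_rate_control,growth_rate_treated Exponential rates per day.
#' @param noise_cv Lognormal measurement noise CV (mean-1 factors).
#' @param aspect Fixed width/length ratio used to back-fill calliper
#'   dimensions from volume (<= 1 so width <= length).
#' @param seed Integer seed.
#' @return A validated `GrowthScenario` list.
#' @export
growth_scenario <- function(n_mice_per_group = 10,
                            days = c(0, 2, 5, 7, 10, 12, 14, 16, 19, 21,
                                     24, 26, 28),
                            v0_mean = 75,
                            growth_rate_control = 0.12,
                            growth_rate_treated = 0.12 + log(0.34) / 28,
                            noise_cv = 0.2,
                            aspect = 0.8,
                            seed = 1L) {
  sc <- list(n_mice_per_group = as.integer(n_mice_per_group), days = days,
             v0_mean = v0_mean,
             growth_rate_control = growth_rate_control,
             growth_rate_treated = growth_rate_treated,
             noise_cv = noise_cv, aspect = aspect, seed = as.integer(seed))
  if (sc$n_mice_per_group < 2) stopf("need >= 2 mice per group")
  if (any(diff(days) <= 0)) stopf("days must be strictly increasing")
  if (v0_mean <= 0) stopf("v0_mean must be > 0")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (aspect <= 0 || aspect > 1) stopf("aspect must be in (0, 1]")
  structure(sc, class = "GrowthScenario")
}

#' Simulate longitudinal tumor growth curves
#'
#' Per mouse, `V(day) = v0 * exp(rate_group * day) * noise` with lognormal
#' mean-1 noise. Calliper width and length are back-filled so that
#' `(W^2 * L) / 2 = V` with `W = aspect * L`.
#'
#' @param scenario A `GrowthScenario`.
#' @return A `GrowthCurveSet` (see [growth_curves()]).
#' @export
simulate_growth <- function(scenario) {
  stopifnot(inherits(scenario, "GrowthScenario"))
  n <- scenario$n_mice_per_group
  days <- scenario$days
  grid <- expand.grid(day = days, mouse = seq_len(2L * n))
  group <- ifelse(grid$mouse <= n, "control", "treated")
  rate <- ifelse(group == "control", scenario$growth_rate_control,
                 scenario$growth_rate_treated)
  set.seed(scenario$seed)
  noise <- if (scenario$noise_cv > 0) {
    s2 <- log(1 + scenario$noise_cv^2)
    stats::rlnorm(nrow(grid), meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else rep(1, nrow(grid))
  vol <- scenario$v0_mean * exp(rate * grid$day) * noise
  k <- scenario$aspect
  len <- (2 * vol / k^2)^(1 / 3)
  growth_curves(data.frame(
    mouse_id = sprintf("m%02d", grid$mouse),
    group = group,
    day = grid$day,
    width_mm = k * len,
    length_mm = len), aspect = k)
}
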