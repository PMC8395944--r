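# Tumor volume arithmetic and permutation comparison of group growth
# curves. Volume follows the standard calliper formula V = (W^2 * L) / 2
# with dimensions swap-normalized so that W <= L.

#' Tumor volume from calliper width and length
#'
#' `V = (W^2 * L) / 2` in mm3. Inputs are swap-normalized first so the
#' width is the smaller dimension; nonpositive dimensions are an error.
#'
#' @param width,length Calliper measurements in mm (vectorized).
#' @return Volumes in mm3.
#' @export
tumor_volume <- function(width, length) {
  stopifnot(is.numeric(width), is.numeric(length))
  if (any(width <= 0) || any(length <= 0))
    stopf("width and length must be positive")
  w <- pmin(width, length)
  l <- pmax(width, length)
  w^2 * l / 2
}

#' Construct a GrowthCurveSet
#'
#' Validates and normalizes longitudinal tumor records: width/length are
#' swapped where needed (logged via message), volume is (re)computed from
#' the formula, and days must be strictly increasing per mouse.
#'
#' @param df Data frame with columns `mouse_id`, `group`
#'   (control/treated), `day`, `width_mm`, `length_mm`.
#' @param aspect Optional fixed width/length ratio used when the curves
#'   were simulated (recorded, not enforced).
#' @return A `GrowthCurveSet` data frame with a `volume_mm3` column.
#' @export
growth_curves <- function(df, aspect = NA_real_) {
  need <- c("mouse_id", "group", "day", "width_mm", "length_mm")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  bad <- setdiff(unique(df$group), c("control", "treated"))
  if (length(bad))
    stopf("unknown group(s): %s", paste(bad, collapse = ", "))
  swapped <- df$width_mm > df$length_mm
  if (any(swapped)) {
    message(sprintf("growth_curves: width > length in %d record(s), swapped",
                    sum(swapped)))
    tmp <- df$width_mm[swapped]
    df$width_mm[swapped] <- df$length_mm[swapped]
    df$length_mm[swapped] <- tmp
  }
  df$volume_mm3 <- tumor_volume(df$width_mm, df$length_mm)
  ord <- order(df$mouse_id, df$day)
  df <- df[ord, , drop = FALSE]
  for (m in unique(df$mouse_id)) {
    d <- df$day[df$mouse_id == m]
    if (any(diff(d) <= 0))
      stopf("days not strictly increasing for mouse %s", m)
  }
  one_group <- tapply(df$group, df$mouse_id, function(g) length(unique(g)))
  if (any(one_group != 1L)) stopf("a mouse cannot change group")
  rownames(df) <- NULL
  attr(df, "aspect") <- aspect
  class(df) <- c("GrowthCurveSet", "data.frame")
  df
}

#' Read/write growth curves as TSV
#'
#' @param path TSV with header
#'   `mouse_id<TAB>group<TAB>day<TAB>width_mm<TAB>length_mm`.
#' @return A `GrowthCurveSet`.
#' @export
read_growth_tsv <- function(path) {
  growth_curves(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param g A `GrowthCurveSet`.
#' @rdname read_growth_tsv
#' @export
write_growth_tsv <- function(g, path) {
  stopifnot(inherits(g, "GrowthCurveSet"))
  utils::write.table(
    g[, c("mouse_id", "group", "day", "width_mm", "length_mm")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-mouse volume matrix on the days shared by both groups; exact match
# first, else nearest-day alignment within +/- 1 day (logged)
shared_day_matrix <- function(g) {
  days_c <- sort(unique(g$day[g$group == "control"]))
  days_t <- sort(unique(g$day[g$group == "treated"]))
  shared <- intersect(days_c, days_t)
  day_of <- g$day
  if (!length(shared)) {
    # nearest-day alignment: map every treated day to the closest control
    # day if within 1 day
    map <- vapply(days_t, function(d) {
      i <- which.min(abs(days_c - d))
      if (abs(days_c[i] - d) <= 1) days_c[i] else NA_real_
    }, numeric(1))
    if (all(is.na(map))) stopf("no shared measurement days between groups")
    message("compare_growth_curves: aligned treated days to nearest control day (within 1 day)")
    idx <- g$group == "treated"
    day_of[idx] <- map[match(g$day[idx], days_t)]
    shared <- days_c[days_c %in% map]
  }
  keep <- !is.na(day_of) & day_of %in% shared
  mice <- unique(g$mouse_id)
  v <- matrix(NA_real_, length(mice), length(shared),
              dimnames = list(mice, as.character(shared)))
  v[cbind(match(g$mouse_id[keep], mice),
          match(day_of[keep], shared))] <- g$volume_mm3[keep]
  list(volumes = v,
       group = g$group[match(mice, g$mouse_id)],
       days = shared)
}

# mean over shared days of |mean control volume - mean treated volume|
curve_distance <- function(v, is_control) {
  mean(abs(colMeans(v[is_control, , drop = FALSE], na.rm = TRUE) -
             colMeans(v[!is_control, , drop = FALSE], na.rm = TRUE)))
}

#' Permutation test comparing two groups of growth curves
#'
#' Observed statistic: the mean over shared measurement days of the
#' absolute difference between the group mean volumes. The null
#' distribution permutes mouse-to-group assignments (whole mice, not
#' observations, are exchanged, preserving within-mouse correlation), and
#' `p = (1 + #\{perm stat >= observed\}) / (1 + n_perm)`, which can never
#' be 0.
#'
#' @param g A `GrowthCurveSet` with >= 2 mice per group.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A `PermTestResult`: list with `statistic`, `n_perm`, `p`,
#'   `seed`, `n_days`.
#' @export
compare_growth_curves <- function(g, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(g, "GrowthCurveSet"), n_perm >= 1)
  sd <- shared_day_matrix(g)
  is_control <- sd$group == "control"
  if (sum(is_control) < 2 || sum(!is_control) < 2)
    stopf("need >= 2 mice per group")
  obs <- curve_distance(sd$volumes, is_control)
  n <- length(is_control)
  n_ctl <- sum(is_control)
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- logical(n)
    perm[sample.int(n, n_ctl)] <- TRUE
    if (curve_distance(sd$volumes, perm) >= obs) hits <- hits + 1L
  }
  structure(list(statistic = obs, n_perm = as.integer(n_perm),
                 p = (1 + hits) / (1 + n_perm), seed = as.integer(seed),
                 n_days = length(sd$days)),
            class = "PermTestResult")
}

#' @export
print.PermTestResult <- function(x, ...) {
  cat(sprintf(
    "Growth-curve permutation test: statistic = %.3f over %d days, p = %.4g (%d permutations)\n",
    x$statistic, x$n_days, x$p, x$n_perm))
  invisible(x)
}

#' Endpoint tumor-size reduction
#'
#' `1 - mean(treated final volumes) / mean(control final volumes)` at the
#' last day measured in both groups.
#'
#' @param g A `GrowthCurveSet`.
#' @return A single fraction (0.66 means a 66% reduction).
#' @export
endpoint_reduction <- function(g) {
  stopifnot(inherits(g, "GrowthCurveSet"))
  sd <- shared_day_matrix(g)
  last <- ncol(sd$volumes)
  vc <- sd$volumes[sd$group == "control", last]
  vt <- sd$volumes[sd$group == "treated", last]
  vc <- vc[!is.na(vc)]; vt <- vt[!is.na(vt)]
  if (!length(vc) || !length(vt))
    stopf("final shared day missing in one group")
  if (mean(vc) == 0) stopf("control endpoint mean volume is 0")
  1 - mean(vt) / mean(vc)
}
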