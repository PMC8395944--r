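# growth set with volumes specified directly (W = L so V = W^3 / 2)
mk_growth <- function(volumes_by_mouse, group_of, days) {
  df <- do.call(rbind, lapply(names(volumes_by_mouse), function(m) {
    v <- volumes_by_mouse[[m]]
    w <- (2 * v)^(1 / 3)
    data.frame(mouse_id = m, group = group_of[[m]], day = days,
               width_mm = w, length_mm = w)
  }))
  growth_curves(df)
}

test_that("tumor_volume follows the calliper formula with swap normalization", {
  expect_equal(tumor_volume(2, 3), 6)
  expect_equal(tumor_volume(1, 1), 0.5)
  expect_equal(tumor_volume(3, 2), tumor_volume(2, 3))
  expect_equal(tumor_volume(c(2, 3), c(3, 2)), c(6, 6))
  expect_error(tumor_volume(0, 1), "positive")
})

test_that("growth_curves normalizes and validates records", {
  df <- data.frame(mouse_id = "m1", group = "control", day = c(0, 3),
                   width_mm = c(3, 2), length_mm = c(2, 4))
  expect_message(g <- growth_curves(df), "swapped")
  expect_true(all(g$width_mm <= g$length_mm))
  expect_equal(g$volume_mm3, g$width_mm^2 * g$length_mm / 2)

  bad <- data.frame(mouse_id = "m1", group = "control", day = c(0, 0),
                    width_mm = 1, length_mm = 1)
  expect_error(growth_curves(bad), "strictly increasing")
  expect_error(growth_curves(transform(df, group = "placebo")), "placebo")
})

test_that("identical groups give statistic 0 and p = 1", {
  v <- list(m1 = c(10, 20, 40), m2 = c(12, 22, 44),
            t1 = c(10, 20, 40), t2 = c(12, 22, 44))
  grp <- list(m1 = "control", m2 = "control", t1 = "treated", t2 = "treated")
  g <- mk_growth(v, grp, days = c(0, 3, 6))
  res <- compare_growth_curves(g, n_perm = 200, seed = 1)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on 2+2 mice", {
  v <- list(m1 = c(10, 25, 60), m2 = c(12, 30, 70),
            t1 = c(9, 15, 20), t2 = c(11, 18, 26))
  grp <- list(m1 = "control", m2 = "control", t1 = "treated", t2 = "treated")
  g <- mk_growth(v, grp, days = c(0, 3, 6))

  # enumeration oracle over all C(4,2) label assignments
  vols <- rbind(v$m1, v$m2, v$t1, v$t2)
  obs <- mean(abs(colMeans(vols[1:2, ]) - colMeans(vols[3:4, ])))
  stats_all <- apply(combn(4, 2), 2, function(ctl) {
    mean(abs(colMeans(vols[ctl, , drop = FALSE]) -
               colMeans(vols[-ctl, , drop = FALSE])))
  })
  p_exact <- mean(stats_all >= obs - 1e-12)

  res <- compare_growth_curves(g, n_perm = 4000, seed = 2)
  expect_equal(res$statistic, obs, tolerance = 1e-9)
  expect_lt(abs(res$p - p_exact), 2 / sqrt(4000))
  expect_gt(res$p, 0)
})

test_that("permutation p is invariant to volume rescaling and mouse renaming", {
  set.seed(9)
  g <- simulate_growth(growth_scenario(n_mice_per_group = 4, seed = 5))
  p1 <- compare_growth_curves(g, n_perm = 300, seed = 3)$p
  g2 <- growth_curves(data.frame(
    mouse_id = paste0("zz_", g$mouse_id), group = g$group, day = g$day,
    width_mm = g$width_mm * 10^(1 / 3), length_mm = g$length_mm * 10^(1 / 3)))
  p2 <- compare_growth_curves(g2, n_perm = 300, seed = 3)$p
  expect_equal(p1, p2)
})

test_that("endpoint reduction matches planted arithmetic", {
  v <- list(m1 = c(10, 100), m2 = c(10, 100),
            t1 = c(10, 34), t2 = c(10, 34))
  grp <- list(m1 = "control", m2 = "control", t1 = "treated", t2 = "treated")
  g <- mk_growth(v, grp, days = c(0, 7))
  expect_equal(endpoint_reduction(g), 0.66, tolerance = 1e-9)

  expect_equal(endpoint_reduction(
    mk_growth(list(a = c(5, 50), b = c(5, 50), c = c(5, 50), d = c(5, 50)),
              list(a = "control", b = "control", c = "treated",
                   d = "treated"), days = c(0, 7))), 0)
})

test_that("default 66%-reduction scenario is detected with power", {
  hits <- 0L
  for (s in 1:12) {
    g <- simulate_growth(growth_scenario(seed = s))
    if (compare_growth_curves(g, n_perm = 300, seed = s)$p < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits, 11)
})

test_that("growth TSV round-trips", {
  g <- simulate_growth(growth_scenario(n_mice_per_group = 3, seed = 8))
  tmp <- tempfile(fileext = ".tsv")
  write_growth_tsv(g, tmp)
  g2 <- read_growth_tsv(tmp)
  expect_equal(g2$volume_mm3, g$volume_mm3, tolerance = 1e-6)
  expect_identical(g2$mouse_id, g$mouse_id)
})
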