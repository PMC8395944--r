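# hand-built world: 2 types x 2 conditions with known means
lr_toy <- function() {
  vals <- matrix(0, 10, 2, dimnames = list(sprintf("c%d", 1:10),
                                           c("Lig", "Rec")))
  cond <- rep(c("control", "treated"), each = 5)
  type <- rep(c("A", "A", "A", "B", "B"), 2)
  vals[cond == "control" & type == "A", "Lig"] <- c(1, 2, 3) # mean 2
  vals[cond == "control" & type == "B", "Rec"] <- c(2, 4)    # mean 3
  vals[cond == "treated" & type == "A", "Lig"] <- c(4, 5, 6) # mean 5
  vals[cond == "treated" & type == "B", "Rec"] <- c(1, 1)    # mean 1
  list(e = expr_matrix(vals, condition = cond),
       labels = stats::setNames(type, rownames(vals)))
}

test_that("lr_score is the product of means, exhaustive over type pairs", {
  w <- lr_toy()
  pairs <- lr_pair_table(data.frame(ligand = "Lig", receptor = "Rec"))
  sc <- lr_score(w$e, w$labels, pairs)
  expect_equal(nrow(sc), 4) # 2 types squared x 1 pair
  row <- sc[sc$sender == "A" & sc$receiver == "B", ]
  expect_equal(row$score_control, 2 * 3)
  expect_equal(row$score_treated, 5 * 1)
  expect_equal(row$delta, 5 - 6)
  expect_equal(sc$delta, sc$score_treated - sc$score_control)
})

test_that("absent genes skip the pair; absent types flag missing", {
  w <- lr_toy()
  pairs <- lr_pair_table(data.frame(ligand = c("Lig", "Ghost"),
                                    receptor = c("Rec", "Rec")))
  expect_warning(sc <- lr_score(w$e, w$labels, pairs), "Ghost")
  expect_equal(nrow(sc), 4)
  expect_false(any(sc$ligand == "Ghost"))

  # type C exists only in control
  lab2 <- w$labels
  lab2[6] <- "C"
  expect_warning(sc2 <- lr_score(w$e, lab2, lr_pair_table(
    data.frame(ligand = "Lig", receptor = "Rec"))), "missing")
  expect_true(all(is.na(sc2$delta[sc2$sender == "C" | sc2$receiver == "C"])))
  expect_true(all(sc2$missing[sc2$sender == "C"]))
})

test_that("swapping condition labels negates every delta exactly", {
  w <- lr_toy()
  pairs <- lr_pair_table(data.frame(ligand = "Lig", receptor = "Rec"))
  sc <- lr_score(w$e, w$labels, pairs)
  e2 <- w$e
  e2$condition <- ifelse(w$e$condition == "control", "treated", "control")
  sc2 <- lr_score(e2, w$labels, pairs)
  expect_equal(sc2$delta, -sc$delta)
})

test_that("lr_score is bilinear in expression scaling", {
  w <- lr_toy()
  pairs <- lr_pair_table(data.frame(ligand = "Lig", receptor = "Rec"))
  sc <- lr_score(w$e, w$labels, pairs)
  e2 <- w$e
  e2$values[w$labels[e2$cell_ids] == "A", "Lig"] <-
    3 * e2$values[w$labels[e2$cell_ids] == "A", "Lig"]
  sc2 <- lr_score(e2, w$labels, pairs)
  a_rows <- sc$sender == "A"
  expect_equal(sc2$score_control[a_rows], 3 * sc$score_control[a_rows])
  expect_equal(sc2$score_treated[a_rows], 3 * sc$score_treated[a_rows])
})

test_that("select_ligands honors alpha and records senders", {
  de <- data.frame(cell_type = c("A", "A", "B"),
                   gene = c("Lig", "Other", "Lig2"),
                   p = c(0.01, 0.2, 0.8))
  pairs <- lr_pair_table(data.frame(ligand = c("Lig", "Lig2", "Lig3"),
                                    receptor = c("R1", "R2", "R3")))
  sel <- select_ligands(de, pairs, alpha = 0.05)
  expect_identical(sel$ligand, "Lig")
  expect_identical(attr(sel, "senders")$Lig, "A")

  sel_all <- select_ligands(de, pairs, alpha = 1)
  expect_setequal(sel_all$ligand, c("Lig", "Lig2")) # Lig3 never tested
  expect_warning(select_ligands(de, pairs, alpha = 1e-9), "no ligand")
})

test_that("duplicate pairs are rejected and TSV round-trips", {
  expect_error(lr_pair_table(data.frame(ligand = c("A", "A"),
                                        receptor = c("B", "B"))),
               "duplicate")
  pairs <- demo_lr_pairs()
  expect_gte(nrow(pairs), 40)
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(pairs, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_identical(read_lr_pairs(tmp)$ligand, pairs$ligand)
})

test_that("delta heatmap aggregates by max |delta| and handles edge cases", {
  w <- lr_toy()
  pairs <- lr_pair_table(data.frame(ligand = "Lig", receptor = "Rec"))
  sc <- lr_score(w$e, w$labels, pairs)
  one <- sc[sc$sender == "A" & sc$receiver == "B", , drop = FALSE]
  class(one) <- class(sc)
  hm1 <- lr_delta_heatmap(one)
  expect_equal(dim(hm1), c(1, 1))
  expect_equal(hm1[1, 1], one$delta)

  hm <- lr_delta_heatmap(sc)
  expect_equal(dim(hm), c(4, 1))
  # planted strongest pair: A->A treated 5*? ... argmax |delta| matches direct
  expect_equal(rownames(hm)[which.max(abs(hm))],
               with(sc, paste0(sender, "->", receiver))[which.max(abs(sc$delta))])

  zero <- sc
  zero$delta <- 0
  expect_true(all(lr_delta_heatmap(zero) == 0))
})

test_that("network communities follow the pair-table topology only", {
  p1 <- lr_pair_table(data.frame(ligand = "A", receptor = "B"))
  n1 <- lr_network_communities(p1, seed = 1)
  expect_equal(n1$n_communities, 1)

  p2 <- lr_pair_table(data.frame(ligand = c("A", "A", "X"),
                                 receptor = c("B", "C", "Y")))
  n2 <- lr_network_communities(p2, seed = 1)
  expect_equal(n2$n_communities, 2)
  expect_false(n2$communities[["A"]] == n2$communities[["X"]])

  # three disconnected blocks -> exactly 3 communities, any seed
  blocks <- data.frame(
    ligand = c("L1", "L1", "L2", "M1", "M1", "N1", "N2"),
    receptor = c("R1", "R2", "R1", "S1", "S2", "T1", "T1"))
  for (s in 1:5)
    expect_equal(lr_network_communities(lr_pair_table(blocks),
                                        seed = s)$n_communities, 3)

  # determinism given seed
  expect_identical(lr_network_communities(p2, seed = 9)$communities,
                   lr_network_communities(p2, seed = 9)$communities)
})
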