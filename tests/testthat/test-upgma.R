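dmat <- function(M, labs) {
  dimnames(M) <- list(labs, labs)
  structure(M, metric = "euclidean_standardized",
            class = c("distance_matrix", "matrix", "array"))
}

test_that("UPGMA reproduces the hand-traced merges", {
  D <- dmat(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3), c("A", "B", "C"))
  tr <- upgma_tree(D)
  expect_equal(tr$height, c(2, 6))

  D2 <- dmat(matrix(c(0, 3, 3, 0), 2), c("A", "B"))
  expect_equal(upgma_tree(D2)$height, 3)

  # two tight pairs, all cross distances 10: average of cross pairs stays 10
  D4 <- matrix(10, 4, 4)
  D4[1, 2] <- D4[2, 1] <- 1
  D4[3, 4] <- D4[4, 3] <- 2
  diag(D4) <- 0
  tr4 <- upgma_tree(dmat(D4, LETTERS[1:4]))
  expect_equal(tr4$height, c(1, 2, 10))
})

test_that("fusion heights are non-decreasing and cophenetic entries read off merges", {
  D <- dmat(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3), c("A", "B", "C"))
  tr <- upgma_tree(D)
  cm <- cophenetic_matrix(tr)
  expect_equal(unname(cm["A", "B"]), 2)
  expect_equal(unname(cm["A", "C"]), 6)
  expect_equal(unname(cm["B", "C"]), 6)

  for (seed in 1:5) {
    Dr <- random_distance(12, seed = seed)
    trr <- upgma_tree(Dr)
    expect_true(all(diff(trr$height) >= -1e-12))
  }
})

test_that("cophenetic matrices are ultrametric (random triples)", {
  set.seed(99)
  checked <- 0
  for (seed in 1:4) {
    D <- random_distance(15, seed = seed)
    cm <- cophenetic_matrix(upgma_tree(D))
    n <- nrow(cm)
    tri <- matrix(sample(n, 3 * 3500, replace = TRUE), ncol = 3)
    tri <- tri[tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3], ,
               drop = FALSE]
    ok <- pmax(cm[cbind(tri[, 1], tri[, 2])], cm[cbind(tri[, 2], tri[, 3])]) >=
      cm[cbind(tri[, 1], tri[, 3])] - 1e-10
    expect_true(all(ok))
    checked <- checked + nrow(tri)
  }
  expect_gte(checked, 1e4)
})

test_that("an ultrametric input is reproduced exactly (cophenetic correlation 1)", {
  D <- random_distance(10, seed = 7)
  cm <- cophenetic_matrix(upgma_tree(D))        # ultrametric by construction
  cm2 <- cophenetic_matrix(upgma_tree(cm))
  expect_equal(unname(as.matrix(cm2)), unname(as.matrix(cm)), tolerance = 1e-10)
  v1 <- cm[upper.tri(cm)]; v2 <- cm2[upper.tri(cm2)]
  expect_equal(cor(v1, v2), 1, tolerance = 1e-12)
})

test_that("Mojena's rule computes h* = mean + c sd and cuts accordingly", {
  # heights {2, 6}, c = 1.25 -> h* ~ 7.536 -> nothing cut -> 1 group
  D <- dmat(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3), c("A", "B", "C"))
  mc <- mojena_cut(upgma_tree(D), c = 1.25)
  expect_equal(mc$cutoff, 4 + 1.25 * sqrt(8), tolerance = 1e-12)
  expect_equal(mc$n_groups, 1)

  # heights {1, 1, 10}, c = 0.5 -> h* ~ 6.60 -> top merge cut -> 2 groups
  D4 <- matrix(10, 4, 4)
  D4[1, 2] <- D4[2, 1] <- 1
  D4[3, 4] <- D4[4, 3] <- 1
  diag(D4) <- 0
  tr4 <- upgma_tree(dmat(D4, LETTERS[1:4]))
  expect_equal(tr4$height, c(1, 1, 10))
  mc4 <- mojena_cut(tr4, c = 0.5)
  expect_equal(mc4$cutoff, 4 + 0.5 * sqrt(54 / 2), tolerance = 1e-12)
  expect_equal(mc4$n_groups, 2)
  expect_equal(unname(mc4$membership["A"]), unname(mc4$membership["B"]))
  expect_false(mc4$membership["A"] == mc4$membership["C"])

  # equal heights: sd = 0, h* = mean, nothing exceeds -> 1 group
  De <- matrix(3, 3, 3); diag(De) <- 0
  mce <- mojena_cut(upgma_tree(dmat(De, c("x", "y", "z"))), c = 1)
  expect_equal(mce$n_groups, 1)

  # 2 leaves: sd undefined -> degenerate single group, flagged
  D2 <- dmat(matrix(c(0, 3, 3, 0), 2), c("A", "B"))
  mc2 <- mojena_cut(upgma_tree(D2))
  expect_true(mc2$degenerate)
  expect_equal(mc2$n_groups, 1)

  expect_error(mojena_cut(tr4, c = -1), class = "phenodiv_format_error")
})

test_that("the Mojena group count is non-increasing in c", {
  D <- random_distance(14, seed = 13)
  tr <- upgma_tree(D)
  prev <- Inf
  for (cc in c(0.1, 0.5, 1, 1.25, 2, 3)) {
    ng <- mojena_cut(tr, c = cc)$n_groups
    expect_lte(ng, prev)
    prev <- ng
  }
})

test_that("Newick export halves heights and round-trips through ape", {
  skip_if_not_installed("ape")
  D2 <- dmat(matrix(c(0, 2, 2, 0), 2), c("A", "B"))
  expect_equal(to_newick(upgma_tree(D2)), "(A:1,B:1);")

  D <- random_distance(10, seed = 31)
  tr <- upgma_tree(D)
  phy <- ape::read.tree(text = to_newick(tr))
  patristic <- ape::cophenetic.phylo(phy)
  cm <- cophenetic_matrix(tr)
  expect_equal(patristic[rownames(cm), colnames(cm)], unclass(as.matrix(cm)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # reserved characters get quoted
  Dq <- dmat(matrix(c(0, 1, 1, 0), 2), c("ge no", "g(2)"))
  nw <- to_newick(upgma_tree(Dq))
  expect_match(nw, "'ge no'", fixed = TRUE)
  phyq <- ape::read.tree(text = nw)
  # ape keeps the quoting characters on parsed labels; strip them to compare
  expect_setequal(gsub("^'|'$", "", phyq$tip.label), c("ge no", "g(2)"))
})

test_that("the merge table carries sizes and heights", {
  D <- random_distance(8, seed = 3)
  tr <- upgma_tree(D)
  mt <- merge_table(tr)
  expect_equal(nrow(mt), 7)
  expect_equal(mt$height, tr$height)
  expect_equal(mt$size[7], 8)
})
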