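test_that("pooled residual covariance matches the hand-computed example", {
  tab <- make_table(c(1, 3, 5, 7))
  pc <- pooled_residual_covariance(tab)
  expect_equal(unname(pc$S[1, 1]), 2)
  expect_equal(pc$df, 2L)
  expect_false(pc$singular)
})

test_that("zero within-genotype variation flags a singular matrix", {
  tab <- make_table(c(1, 1, 5, 5))
  pc <- pooled_residual_covariance(tab)
  expect_equal(unname(pc$S[1, 1]), 0)
  expect_true(pc$singular)
  mm <- genotype_means(tab)
  expect_error(mahalanobis_matrix(mm, pc), class = "phenodiv_singular_error")
})

test_that("pooled covariance estimates the residual covariance on simulation", {
  set.seed(3)
  g <- 40; k <- 50
  e1 <- rnorm(g * k, sd = 2)   # variance 4
  e2 <- rnorm(g * k, sd = 1)   # variance 1, independent
  gmu <- rep(rnorm(g, sd = 3), each = k)
  tab <- make_table(cbind(gmu + e1, gmu / 2 + e2), k = k, traits = c("a", "b"))
  S <- pooled_residual_covariance(tab)$S
  expect_equal(unname(S[1, 1]), 4, tolerance = 0.05)
  expect_equal(unname(S[2, 2]), 1, tolerance = 0.05)
  expect_lt(abs(S[1, 2]), 0.1)
})

test_that("Mahalanobis D2 reduces to squared Euclidean when S = I", {
  set.seed(8)
  M <- matrix(rnorm(6 * 3), 6, dimnames = list(paste0("g", 1:6), c("a", "b", "c")))
  mm <- structure(cbind(data.frame(genotype = rownames(M)), as.data.frame(M)),
                  class = c("means_matrix", "data.frame"),
                  traits = colnames(M), k = 2)
  S <- structure(list(S = diag(3), df = 10, condition = 1, singular = FALSE),
                 class = "pooled_cov")
  D <- mahalanobis_matrix(mm, S)
  # brute-force squared Euclidean
  for (i in 1:6) for (j in 1:6) {
    expect_equal(unname(D[i, j]), sum((M[i, ] - M[j, ])^2), tolerance = 1e-10)
  }
  expect_equal(unname(diag(D)), rep(0, 6))
  expect_equal(unname(D), unname(t(D)))
})

test_that("diagonal S weights each trait by its inverse variance", {
  mm <- structure(data.frame(genotype = c("a", "b"), x = c(2, 0), y = c(1, 0)),
                  class = c("means_matrix", "data.frame"),
                  traits = c("x", "y"), k = 2)
  S <- structure(list(S = diag(c(4, 1)), df = 2, condition = 4, singular = FALSE),
                 class = "pooled_cov")
  D <- mahalanobis_matrix(mm, S)
  expect_equal(unname(D["a", "b"]), 2)  # 4/4 + 1/1
})

test_that("D2 is invariant under simultaneous invertible linear transforms", {
  set.seed(15)
  for (i in 1:5) {
    M <- matrix(rnorm(8 * 4), 8, dimnames = list(paste0("g", 1:8), paste0("t", 1:4)))
    S0 <- crossprod(matrix(rnorm(16), 4)) + diag(4) * 0.5
    A <- matrix(rnorm(16), 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
    wrap <- function(M) structure(cbind(data.frame(genotype = rownames(M)),
                                        as.data.frame(M)),
                                  class = c("means_matrix", "data.frame"),
                                  traits = colnames(M), k = 2)
    pc <- function(S) structure(list(S = S, df = 10, condition = kappa(S),
                                     singular = FALSE), class = "pooled_cov")
    D1 <- mahalanobis_matrix(wrap(M), pc(S0))
    M2 <- M %*% t(A)
    colnames(M2) <- paste0("t", 1:4)
    D2 <- mahalanobis_matrix(wrap(M2), pc(A %*% S0 %*% t(A)))
    expect_equal(unname(as.matrix(D1)), unname(as.matrix(D2)), tolerance = 1e-8)
  }
})

test_that("standardized mean Euclidean distance matches its definition", {
  set.seed(19)
  M <- matrix(rnorm(5 * 3, 10, 2), 5,
              dimnames = list(paste0("g", 1:5), c("a", "b", "c")))
  mm <- structure(cbind(data.frame(genotype = rownames(M)), as.data.frame(M)),
                  class = c("means_matrix", "data.frame"),
                  traits = colnames(M), k = 2)
  D <- standardized_euclidean_matrix(mm)
  # independent computation with explicit loops
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (tr in colnames(M)) {
      z <- (M[, tr] - mean(M[, tr])) / sd(M[, tr])
      acc <- acc + (z[i] - z[j])^2
    }
    expect_equal(unname(D[i, j]), as.numeric(sqrt(acc / 3)), tolerance = 1e-12)
  }
})

test_that("standardized Euclidean distance ignores per-trait affine rescaling", {
  set.seed(23)
  M <- matrix(rnorm(6 * 2), 6, dimnames = list(paste0("g", 1:6), c("a", "b")))
  wrap <- function(M) structure(cbind(data.frame(genotype = rownames(M)),
                                      as.data.frame(M)),
                                class = c("means_matrix", "data.frame"),
                                traits = colnames(M), k = 2)
  D1 <- standardized_euclidean_matrix(wrap(M))
  M2 <- M
  M2[, "a"] <- 100 + 7 * M2[, "a"]
  M2[, "b"] <- -3 * M2[, "b"]
  D2 <- standardized_euclidean_matrix(wrap(M2))
  expect_equal(unname(as.matrix(D1)), unname(as.matrix(D2)), tolerance = 1e-12)

  # duplicate genotype rows are at distance zero
  M3 <- rbind(M, dup = M[1, ])
  rownames(M3) <- c(rownames(M), "dup")
  D3 <- standardized_euclidean_matrix(wrap(M3))
  expect_equal(unname(D3["g1", "dup"]), 0)

  # zero-variance trait errors, naming the trait
  M4 <- M; M4[, "b"] <- 5
  err <- expect_error(standardized_euclidean_matrix(wrap(M4)),
                      class = "phenodiv_singular_error")
  expect_match(conditionMessage(err), "b")
})

test_that("distance_pairs lists every unordered pair once", {
  D <- random_distance(5, seed = 2)
  pairs <- distance_pairs(D)
  expect_equal(nrow(pairs), choose(5, 2))
  expect_equal(pairs$distance[pairs$genotype_a == "1" & pairs$genotype_b == "2"],
               D["1", "2"])
})
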