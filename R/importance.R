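#' Singh's relative trait contributions to total divergence
#'
#' Decomposes the total pairwise generalized Mahalanobis distance into
#' additive per-trait contributions. With `W = S^-1` and `delta` the
#' mean-difference vector of a genotype pair, trait `j` contributes
#' `c_j = delta_j * (W delta)_j` to that pair's `D2`; summing over all
#' unordered pairs gives `S_j`, and `sum_j S_j` equals the total pairwise
#' `D2` exactly. Contributions are kept signed (no absolute values): under
#' strong trait correlation an individual percentage can be negative or
#' exceed 100 while the sum identity still holds.
#'
#' @param means A `means_matrix`.
#' @param S A `pooled_cov` (or covariance matrix); must be invertible.
#' @param ridge Optional ridge passed to the inversion (default 0).
#' @return Object of class `singh`: data frame `trait`, `S_j`, `percent`,
#'   `rank` (1 = largest contribution), plus attributes `total_d2`.
#' @export
singh_contributions <- function(means, S, ridge = 0) {
  M <- means_as_matrix(means)
  W <- inv_pooled(S, ridge = ridge)
  p <- ncol(M)
  n <- nrow(M)
  Sj <- numeric(p)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      delta <- M[a, ] - M[b, ]
      Sj <- Sj + delta * as.vector(W %*% delta)
    }
  }
  total <- sum(Sj)
  pct <- 100 * Sj / total
  out <- data.frame(trait = colnames(M), S_j = Sj, percent = pct,
                    rank = rank(-Sj, ties.method = "first"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, total_d2 = total, class = c("singh", "data.frame"))
}

#' Canonical variate analysis of a genotype trial
#'
#' Eigen-decomposition of `W^-1 B`, with `B` the between-genotype and `W`
#' the pooled within-genotype sums-of-products matrices of the
#' replicate-level data. For numerical stability the generalized
#' eigenproblem `B v = lambda W v` is solved in whitened coordinates: with
#' the Cholesky factor `W = U'U`, the symmetric matrix `U^-T B U^-1` is
#' decomposed and its eigenvectors mapped back by `v = U^-1 z`. At most
#' `min(p, g - 1)` canonical roots are non-zero.
#'
#' @param table A `phenotype_table`.
#' @param ridge Optional ridge added to `W` before factorization (default 0).
#' @return Object of class `canonical_variates`: list with `eigenvalues`
#'   (non-increasing), `proportion`, `cumulative`, `coefficients` (trait x
#'   variate matrix of canonical weights), `scores` (genotype x variate
#'   projections of the centered genotype means), `n_variates`.
#' @export
canonical_variates <- function(table, ridge = 0) {
  stopifnot(inherits(table, "phenotype_table"))
  traits <- attr(table, "traits")
  k <- attr(table, "k")
  X <- as.matrix(as.data.frame(table)[, traits, drop = FALSE])
  gfac <- factor(table$genotype)
  g <- nlevels(gfac)
  Gm <- apply(X, 2, function(col) tapply(col, gfac, mean))
  if (is.null(dim(Gm))) Gm <- matrix(Gm, nrow = g, dimnames = list(levels(gfac), traits))
  grand <- colMeans(X)
  C <- sweep(Gm, 2, grand)
  B <- k * crossprod(C)
  Wmat <- crossprod(X - apply(X, 2, function(col) ave(col, gfac)))
  if (ridge > 0) Wmat <- Wmat + diag(ridge, ncol(Wmat))
  U <- tryCatch(chol(Wmat), error = function(e) {
    pd_error("within-genotype matrix is singular; remove collinear traits or set a ridge",
             "phenodiv_singular_error")
  })
  A <- backsolve(U, t(backsolve(U, t(B), transpose = TRUE)), transpose = TRUE)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  nv <- min(length(traits), g - 1L)
  lambda <- pmax(eig$values, 0)
  coef <- backsolve(U, eig$vectors)
  lambda <- lambda[seq_len(nv)]
  coef <- coef[, seq_len(nv), drop = FALSE]
  dimnames(coef) <- list(traits, paste0("CV", seq_len(nv)))
  scores <- C %*% coef
  colnames(scores) <- colnames(coef)
  prop <- lambda / sum(lambda)
  structure(list(eigenvalues = lambda, proportion = prop,
                 cumulative = cumsum(prop), coefficients = coef,
                 scores = scores, n_variates = nv),
            class = "canonical_variates")
}

#' @export
print.canonical_variates <- function(x, ...) {
  cat("Canonical variate analysis\n")
  print(data.frame(variate = paste0("CV", seq_along(x$eigenvalues)),
                   eigenvalue = x$eigenvalues, proportion = x$proportion,
                   cumulative = x$cumulative), ...)
  invisible(x)
}
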