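#' Pooled residual (within-genotype) covariance matrix
#'
#' The matrix `S = E / df`, where `E` is the within-genotype sums-of-products
#' matrix of the replicate-level data and `df = g(k - 1)`. `S` is the
#' residual covariance that the generalized Mahalanobis distance inverts.
#'
#' @param table A `phenotype_table`.
#' @return Object of class `pooled_cov`: list with `S` (trait x trait
#'   matrix), `df`, `condition` (2-norm condition estimate) and `singular`
#'   flag (condition above 1e12 or non-finite).
#' @export
pooled_residual_covariance <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  traits <- attr(table, "traits")
  k <- attr(table, "k")
  X <- as.matrix(as.data.frame(table)[, traits, drop = FALSE])
  gfac <- factor(table$genotype)
  g <- nlevels(gfac)
  centered <- X - apply(X, 2, function(col) ave(col, gfac))
  E <- crossprod(centered)
  df <- g * (k - 1L)
  S <- E / df
  cond <- condition_number(S)
  structure(list(S = S, df = df, condition = cond,
                 singular = !is.finite(cond) || cond > 1e12),
            class = "pooled_cov")
}

condition_number <- function(mat) {
  sv <- tryCatch(svd(mat, nu = 0, nv = 0)$d, error = function(e) NULL)
  if (is.null(sv) || !all(is.finite(sv)) || min(sv) <= 0) return(Inf)
  max(sv) / min(sv)
}

inv_pooled <- function(S, ridge = 0) {
  mat <- if (inherits(S, "pooled_cov")) S$S else as.matrix(S)
  if (ridge > 0) mat <- mat + diag(ridge, nrow(mat))
  cond <- condition_number(mat)
  if (!is.finite(cond) || cond > 1e12) {
    pd_error(paste("pooled covariance matrix is (near-)singular;",
                   "remove collinear/constant traits or set a ridge > 0"),
             "phenodiv_singular_error")
  }
  solve(mat)
}

new_distance_matrix <- function(D, metric) {
  D <- (D + t(D)) / 2
  D[D < 0 & D > -1e-12] <- 0
  diag(D) <- 0
  structure(D, metric = metric, class = c("distance_matrix", "matrix", "array"))
}

#' Generalized Mahalanobis D2 distance matrix
#'
#' `D2(i, i') = (xbar_i - xbar_i')' S^-1 (xbar_i - xbar_i')` between every
#' pair of genotype mean vectors, with `S` the pooled residual covariance.
#' A (near-)singular `S` is an error — no silent pseudo-inverse; either drop
#' offending traits or pass a small `ridge` added to the diagonal of `S`.
#'
#' @param means A `means_matrix`.
#' @param S A `pooled_cov` (or plain covariance matrix).
#' @param ridge Optional non-negative ridge added to `diag(S)` (default 0).
#' @return A `distance_matrix` (symmetric, zero diagonal) with attribute
#'   `metric = "mahalanobis_d2"`.
#' @export
mahalanobis_matrix <- function(means, S, ridge = 0) {
  M <- means_as_matrix(means)
  W <- inv_pooled(S, ridge = ridge)
  if (ncol(M) != nrow(W)) {
    pd_error("trait sets of means and covariance differ", "phenodiv_format_error")
  }
  # D2(i,j) = q_i + q_j - 2 x_i' W x_j with q_i = x_i' W x_i
  XW <- M %*% W
  q <- rowSums(XW * M)
  D <- outer(q, q, "+") - 2 * XW %*% t(M)
  dimnames(D) <- list(rownames(M), rownames(M))
  new_distance_matrix(D, "mahalanobis_d2")
}

#' Standardized mean Euclidean distance matrix
#'
#' Each trait is centered and scaled to unit standard deviation across
#' genotype means; the distance is then
#' `d(i, i') = sqrt( (1/p) * sum_t (z_it - z_i't)^2 )` — the "mean"
#' Euclidean distance divides the squared sum by the number of traits `p`,
#' so the metric is comparable across trait sets. Invariant to per-trait
#' affine rescaling of the input.
#'
#' @param means A `means_matrix`.
#' @return A `distance_matrix` with attribute
#'   `metric = "euclidean_standardized"`.
#' @export
standardized_euclidean_matrix <- function(means) {
  M <- means_as_matrix(means)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    pd_error(sprintf("zero variance across genotypes for trait(s): %s",
                     paste(colnames(M)[sds == 0], collapse = ", ")),
             "phenodiv_singular_error")
  }
  Z <- scale(M)
  D <- as.matrix(stats::dist(Z))^2 / ncol(M)
  D <- sqrt(D)
  dimnames(D) <- list(rownames(M), rownames(M))
  new_distance_matrix(D, "euclidean_standardized")
}

#' Long-format pair list of a distance matrix
#'
#' @param D A `distance_matrix`.
#' @return Data frame `genotype_a`, `genotype_b`, `distance` over unordered
#'   pairs.
#' @export
distance_pairs <- function(D) {
  labs <- rownames(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  data.frame(genotype_a = labs[idx[, 1]], genotype_b = labs[idx[, 2]],
             distance = D[idx], stringsAsFactors = FALSE)
}
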