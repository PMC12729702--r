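#' Tocher inclusion threshold
#'
#' `theta = max_i min_{j != i} D(i, j)`: the largest nearest-neighbor
#' distance in the matrix. Computed once from the full matrix and never
#' updated while clusters form.
#'
#' @param D A `distance_matrix` (>= 2 genotypes).
#' @return Numeric threshold `theta`.
#' @export
tocher_threshold <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) pd_error("need at least 2 genotypes", "phenodiv_format_error")
  Dd <- D
  diag(Dd) <- Inf
  max(apply(Dd, 1, min))
}

#' Tocher (Rao) optimization clustering
#'
#' Iteratively grows clusters from a distance matrix: the current cluster is
#' seeded with the globally closest unassigned pair; the unassigned genotype
#' with the smallest mean distance to the cluster is admitted while that
#' mean distance does not exceed `theta` (boundary admits); when no
#' candidate qualifies the cluster is closed and the next one is seeded from
#' the closest remaining pair. A final lone genotype forms a singleton. Ties
#' are broken by (distance, label order), so relabeling genotypes permutes
#' the output identically.
#'
#' @param D A `distance_matrix` (>= 2 genotypes).
#' @return Object of class `tocher`: list with `clusters` (list of genotype
#'   label vectors, Roman-numeral names I, II, ... in formation order),
#'   `theta`, `membership` (named genotype -> cluster index), and
#'   `intra_mean` (mean within-cluster distance per cluster; `NA` for
#'   singletons).
#' @export
tocher_cluster <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  theta <- tocher_threshold(D)
  unassigned <- seq_len(n)
  clusters <- list()
  closest_pair <- function(idx) {
    best <- NULL; bestd <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        d <- D[idx[a], idx[b]]
        if (d < bestd) { bestd <- d; best <- c(idx[a], idx[b]) }
      }
    }
    best
  }
  while (length(unassigned) > 0) {
    if (length(unassigned) == 1) {
      clusters[[length(clusters) + 1L]] <- unassigned
      unassigned <- integer(0)
      break
    }
    cur <- closest_pair(unassigned)
    unassigned <- setdiff(unassigned, cur)
    repeat {
      if (!length(unassigned)) break
      mean_d <- vapply(unassigned, function(i) mean(D[i, cur]), 0)
      pick <- which.min(mean_d)        # first minimum = smallest label order
      if (mean_d[pick] <= theta) {
        cur <- c(cur, unassigned[pick])
        unassigned <- unassigned[-pick]
      } else break
    }
    clusters[[length(clusters) + 1L]] <- cur
  }
  names(clusters) <- as.character(utils::as.roman(seq_along(clusters)))
  membership <- integer(n)
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  names(membership) <- labs
  intra <- vapply(clusters, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(D[idx, idx][upper.tri(diag(length(idx)))])
  }, 0)
  structure(list(clusters = lapply(clusters, function(idx) labs[idx]),
                 theta = theta, membership = membership, intra_mean = intra),
            class = "tocher")
}

#' @export
print.tocher <- function(x, ...) {
  cat(sprintf("Tocher clustering: %d group(s), theta = %.6g\n",
              length(x$clusters), x$theta))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %-5s %s\n", nm, paste(x$clusters[[nm]], collapse = "-")))
  }
  invisible(x)
}

#' Table-style listing of a Tocher partition
#'
#' @param x A `tocher` result.
#' @return Data frame `group` (Roman numeral), `genotypes` (dash-separated
#'   labels), `size`, `intra_mean_distance`.
#' @export
tocher_listing <- function(x) {
  data.frame(group = names(x$clusters),
             genotypes = vapply(x$clusters, paste, "", collapse = "-"),
             size = lengths(x$clusters),
             intra_mean_distance = x$intra_mean,
             stringsAsFactors = FALSE, row.names = NULL)
}
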