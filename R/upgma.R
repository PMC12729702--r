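#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering: the closest pair of clusters is
#' merged repeatedly, the inter-cluster distance being the unweighted
#' average of all cross-pair leaf distances, and the fusion height being
#' that average distance (not halved). Fusion heights are therefore
#' non-decreasing along the merge sequence.
#'
#' @param D A `distance_matrix` (>= 2 genotypes).
#' @return Object of class `c("upgma_tree", "hclust")` — a standard
#'   [stats::hclust()] tree (fields `merge`, `height`, `labels`) tagged with
#'   the input metric.
#' @export
upgma_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) pd_error("need at least 2 genotypes", "phenodiv_format_error")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  hc$call <- NULL
  attr(hc, "metric") <- attr(D, "metric")
  class(hc) <- c("upgma_tree", "hclust")
  hc
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the fusion height of the first merge uniting leaves i and
#' j; the result is ultrametric by construction.
#'
#' @param tree An `upgma_tree` (or any `hclust`).
#' @return A `distance_matrix` with attribute `metric = "cophenetic"`.
#' @export
cophenetic_matrix <- function(tree) {
  M <- as.matrix(stats::cophenetic(tree))
  new_distance_matrix(M, "cophenetic")
}

#' Mojena cutoff of a dendrogram
#'
#' Cuts the tree at `h* = mean(h) + c * sd(h)`, where `h` are the `g - 1`
#' fusion heights and `sd` is the sample standard deviation (denominator
#' `g - 2`). Merges with height above `h*` are removed; the connected
#' clusters that remain are the groups. The constant `c` defaults to 1.25,
#' the value recommended in the clustering literature for this stopping
#' rule; it is a tunable parameter, not a fitted quantity.
#'
#' @param tree An `upgma_tree`.
#' @param c Positive Mojena constant (default 1.25).
#' @return Object of class `mojena_cut`: list with `cutoff`, `c`,
#'   `mean_height`, `sd_height`, `n_groups`, `membership` (named genotype ->
#'   group id, groups numbered in leaf order), and `degenerate` (TRUE when
#'   only one fusion height exists so the sd — and the rule — is undefined
#'   and a single group is returned).
#' @export
mojena_cut <- function(tree, c = 1.25) {
  if (c <= 0) pd_error("Mojena constant c must be > 0", "phenodiv_format_error")
  h <- tree$height
  if (length(h) < 2) {
    membership <- stats::setNames(rep(1L, length(tree$labels)), tree$labels)
    return(structure(list(cutoff = NA_real_, c = c, mean_height = mean(h),
                          sd_height = NA_real_, n_groups = 1L,
                          membership = membership, degenerate = TRUE),
                     class = "mojena_cut"))
  }
  hstar <- mean(h) + c * stats::sd(h)
  membership <- stats::cutree(tree, h = hstar)
  structure(list(cutoff = hstar, c = c, mean_height = mean(h),
                 sd_height = stats::sd(h), n_groups = max(membership),
                 membership = membership, degenerate = FALSE),
            class = "mojena_cut")
}

quote_newick_label <- function(x) {
  needs <- grepl("[][ \t():;,'\"]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Newick export of a UPGMA dendrogram
#'
#' Branch lengths follow the ultrametric convention that each leaf-to-root
#' path has length (root fusion height) / 2, so the patristic distance
#' between two leaves equals their cophenetic distance. Labels containing
#' Newick reserved characters are single-quoted.
#'
#' @param tree An `upgma_tree` (or any `hclust`).
#' @param digits Significant digits for branch lengths (default 10).
#' @return Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  m <- tree$merge
  h <- tree$height
  labs <- quote_newick_label(tree$labels)
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  node_str <- function(i) {
    parts <- vapply(m[i, ], function(ch) {
      if (ch < 0) paste0(labs[-ch], ":", fmt(h[i] / 2))
      else paste0(node_str(ch), ":", fmt((h[i] - h[ch]) / 2))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(node_str(nrow(m)), ";")
}

#' Merge table of a dendrogram
#'
#' @param tree An `upgma_tree`.
#' @return Data frame `step`, `node_a`, `node_b` (hclust convention:
#'   negative = leaf index, positive = earlier merge), `height`, `size`.
#' @export
merge_table <- function(tree) {
  sizes <- integer(nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    sizes[i] <- sum(vapply(tree$merge[i, ], function(ch) {
      if (ch < 0) 1L else sizes[ch]
    }, 1L))
  }
  data.frame(step = seq_len(nrow(tree$merge)),
             node_a = tree$merge[, 1], node_b = tree$merge[, 2],
             height = tree$height, size = sizes)
}

#' @export
print.mojena_cut <- function(x, ...) {
  if (x$degenerate) {
    cat("Mojena cut: single fusion height, sd undefined -> 1 group\n")
  } else {
    cat(sprintf("Mojena cut: h* = %.6g (mean %.6g + %g x sd %.6g) -> %d group(s)\n",
                x$cutoff, x$mean_height, x$c, x$sd_height, x$n_groups))
  }
  invisible(x)
}
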