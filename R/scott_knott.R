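#' Maximizing between-group sum of squares over contiguous splits
#'
#' For means sorted in ascending order, evaluates every split of the
#' sequence into a leading block of size `j` and a trailing block of size
#' `g - j` and returns the split maximizing the between-group sum of squares
#' `B0 = T1^2/j + T2^2/(g-j) - (T1+T2)^2/g`, where `T1`, `T2` are the block
#' totals. Ties are broken toward the smallest `j` for determinism.
#'
#' @param sorted_means Numeric vector of means sorted ascending, length >= 2.
#' @return List with `j` (split index: first block is `1:j`) and `B0`.
#' @export
max_between_ss <- function(sorted_means) {
  g <- length(sorted_means)
  if (g < 2) pd_error("need at least 2 means to split", "phenodiv_format_error")
  if (is.unsorted(sorted_means)) {
    pd_error("means must be sorted ascending", "phenodiv_format_error")
  }
  tot <- sum(sorted_means)
  t1 <- cumsum(sorted_means)[seq_len(g - 1)]
  j <- seq_len(g - 1)
  b0 <- t1^2 / j + (tot - t1)^2 / (g - j) - tot^2 / g
  jstar <- which.max(b0)              # which.max takes the first maximum
  list(j = jstar, B0 = b0[jstar])
}

#' Scott-Knott grouping of genotype means
#'
#' Recursive likelihood-ratio partitioning of ordered treatment means into
#' non-overlapping, statistically homogeneous groups. At each node the
#' candidate split maximizing the between-group sum of squares `B0` is
#' tested with `lambda = pi / (2 (pi - 2)) * B0 / sigma0_hat^2`, where
#' `sigma0_hat^2 = (sum (ybar_i - ybar)^2 + nu * s2y) / (gg + nu)` uses the
#' node's own means (`gg` of them), the global residual degrees of freedom
#' `nu` and the variance of a genotype mean `s2y = QMr / k`. The split is
#' accepted when `lambda` exceeds the chi-square quantile at fractional
#' degrees of freedom `gg / (pi - 2)`, and the procedure recurses on both
#' sides. Accepted groups are contiguous runs in the mean-sorted order;
#' letters are assigned from the highest-mean group (`"a"`) downward.
#'
#' @param means Named numeric vector of genotype means (names = genotype
#'   labels), or a `means_matrix` with `trait` given.
#' @param QMr Residual mean square of the trait's ANOVA.
#' @param k Replicate count.
#' @param df_residual Residual degrees of freedom `g(k-1)` (global; not
#'   re-estimated per subgroup).
#' @param alpha Significance level of the chi-square test (default 0.05).
#' @param trait Trait name when `means` is a `means_matrix`.
#' @return Object of class `scott_knott`: list with `groups` (data frame
#'   `genotype`, `mean`, `group` letter, sorted by decreasing mean),
#'   `splits` (record of every accepted split: node size, `j`, `B0`,
#'   `lambda`, `chi2_critical`), `n_groups`, `alpha`, `trait`.
#' @export
scott_knott <- function(means, QMr, k, df_residual, alpha = 0.05, trait = NULL) {
  if (inherits(means, "means_matrix")) {
    if (is.null(trait)) pd_error("give 'trait' with a means_matrix", "phenodiv_format_error")
    v <- as.data.frame(means)[[trait]]
    names(v) <- means$genotype
    means <- v
  }
  stopifnot(is.numeric(means))
  if (is.null(names(means))) names(means) <- seq_along(means)
  if (!(alpha > 0 && alpha < 1)) pd_error("alpha must be in (0,1)", "phenodiv_format_error")
  if (QMr < 0) pd_error("QMr must be >= 0", "phenodiv_format_error")
  g_all <- length(means)
  ord <- order(means, names(means))    # ascending; stable on ties by label
  sorted <- means[ord]
  s2y <- QMr / k
  nu <- df_residual
  lambda_const <- pi / (2 * (pi - 2))

  splits <- list()
  # returns integer vector of group sizes over the (contiguous) node
  partition <- function(y) {
    gg <- length(y)
    if (gg < 2) return(gg)
    sp <- max_between_ss(y)
    s0sq <- (sum((y - mean(y))^2) + nu * s2y) / (gg + nu)
    if (sp$B0 <= 0 || s0sq <= 0) return(gg)
    lambda <- lambda_const * sp$B0 / s0sq
    crit <- stats::qchisq(1 - alpha, df = gg / (pi - 2))
    if (lambda > crit) {
      splits[[length(splits) + 1L]] <<- data.frame(
        node_size = gg, j = sp$j, B0 = sp$B0, lambda = lambda,
        chi2_critical = crit)
      c(partition(y[seq_len(sp$j)]), partition(y[(sp$j + 1):gg]))
    } else {
      gg
    }
  }
  sizes <- partition(unname(sorted))
  n_groups <- length(sizes)
  # groups in ascending-mean order; letter "a" goes to the highest-mean group
  grp_idx_asc <- rep(seq_along(sizes), sizes)
  letters_for <- function(i) {
    # supports > 26 groups: a..z, aa, ab, ...
    out <- character(length(i))
    for (q in seq_along(i)) {
      n <- i[q]; s <- ""
      while (n > 0) { r <- (n - 1) %% 26; s <- paste0(letters[r + 1], s); n <- (n - 1) %/% 26 }
      out[q] <- s
    }
    out
  }
  letter_asc <- letters_for(rev(seq_len(n_groups)))[grp_idx_asc]
  res <- data.frame(genotype = names(sorted), mean = unname(sorted),
                    group = letter_asc, stringsAsFactors = FALSE)
  res <- res[rev(seq_len(nrow(res))), , drop = FALSE]   # highest mean first
  rownames(res) <- NULL
  structure(list(groups = res,
                 splits = if (length(splits)) do.call(rbind, splits) else NULL,
                 n_groups = n_groups, alpha = alpha,
                 QMr = QMr, k = k, df_residual = df_residual,
                 trait = trait %||% NA_character_),
            class = "scott_knott")
}

#' Scott-Knott letters for every trait of a phenotype table
#'
#' @param table A `phenotype_table`.
#' @param alpha Significance level.
#' @return Long data frame `genotype`, `trait`, `mean`, `group`.
#' @export
scott_knott_table <- function(table, alpha = 0.05) {
  traits <- attr(table, "traits")
  means <- genotype_means(table)
  rows <- lapply(traits, function(tr) {
    an <- anova_crd(table, tr)
    sk <- scott_knott(means, QMr = an$QMr, k = an$k,
                      df_residual = an$df_residual, alpha = alpha, trait = tr)
    cbind(sk$groups[, "genotype", drop = FALSE], trait = tr,
          sk$groups[, c("mean", "group")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.scott_knott <- function(x, ...) {
  cat(sprintf("Scott-Knott grouping%s: %d group(s) at alpha = %g\n",
              if (is.na(x$trait)) "" else sprintf(" for trait '%s'", x$trait),
              x$n_groups, x$alpha))
  print(x$groups, ...)
  invisible(x)
}
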