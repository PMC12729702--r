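#' One-way ANOVA for a balanced completely randomized design
#'
#' Decomposes the total sum of squares of a single trait into a
#' between-genotype and a residual component under the one-way model
#' `Y_ij = mu + G_i + e_ij` (genotype `i`, replicate `j`). The F statistic
#' `QMg / QMr` is referred to the F distribution with `(g - 1, g(k - 1))`
#' degrees of freedom.
#'
#' @param table A `phenotype_table` (balanced, `g >= 2` genotypes,
#'   `k >= 2` replicates).
#' @param trait Name of the trait column to analyze.
#' @return Object of class `trait_anova`: a list with `trait`, sums of
#'   squares (`SS_genotype`, `SS_residual`, `SS_total`), degrees of freedom,
#'   mean squares `QMg` and `QMr`, `F`, `p_value`, `significance_code`
#'   (`"**"` p < 0.01, `"*"` p < 0.05, else `"ns"`), the grand mean `m`,
#'   and `g`, `k`.
#' @export
anova_crd <- function(table, trait) {
  stopifnot(inherits(table, "phenotype_table"))
  if (!trait %in% attr(table, "traits")) {
    pd_error(sprintf("unknown trait '%s'", trait), "phenodiv_format_error")
  }
  y <- table[[trait]]
  gfac <- factor(table$genotype)
  g <- nlevels(gfac)
  k <- attr(table, "k")
  if (g < 2) pd_error("need at least 2 genotypes", "phenodiv_format_error")
  m <- mean(y)
  ss_total <- sum((y - m)^2)
  gm <- tapply(y, gfac, mean)
  ss_g <- k * sum((gm - m)^2)
  ss_e <- ss_total - ss_g
  if (ss_e < 0 && ss_e > -1e-8 * max(ss_total, 1)) ss_e <- 0
  df_g <- g - 1L
  df_e <- g * (k - 1L)
  QMg <- ss_g / df_g
  QMr <- ss_e / df_e
  if (QMr > 0) {
    Fv <- QMg / QMr
    p <- stats::pf(Fv, df_g, df_e, lower.tail = FALSE)
  } else {
    warning(sprintf("trait '%s': zero residual mean square (degenerate input)", trait))
    Fv <- if (QMg > 0) Inf else NaN
    p <- if (QMg > 0) 0 else NA_real_
  }
  structure(list(trait = trait,
                 SS_genotype = ss_g, SS_residual = ss_e, SS_total = ss_total,
                 df_genotype = df_g, df_residual = df_e,
                 QMg = QMg, QMr = QMr, F = Fv, p_value = p,
                 significance_code = sig_code(p),
                 m = m, g = g, k = k),
            class = "trait_anova")
}

sig_code <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Genetic parameters from genotype and residual mean squares
#'
#' Estimates the variance components and derived selection statistics of a
#' balanced one-way genotype trial from its mean squares:
#' phenotypic variance (of genotype means) `sigma2_f = QMg / k`,
#' environmental variance `sigma2_e = QMr / k`, genetic variance
#' `sigma2_g = (QMg - QMr) / k`, broad-sense heritability
#' `h2 = 100 (QMg - QMr) / QMg` (%), genetic coefficient of variation
#' `CVg = 100 sqrt(sigma2_g) / m`, experimental/environmental coefficient
#' of variation `CVe = CV = 100 sqrt(QMr) / m`, and the ratio
#' `CVg / CVe = sqrt((QMg - QMr) / (k QMr))`.
#'
#' Note that `CVe` uses the residual standard deviation on the plot basis,
#' `sqrt(QMr)`, not `sqrt(QMr / k)`; this is the convention under which the
#' experiment-wide CV and CVe coincide and the CVg/CVe ratio takes the form
#' above. When `QMg < QMr` the raw (negative) `sigma2_g` is preserved and
#' flagged and `h2` is floored at 0, so simulation studies can examine
#' estimator bias.
#'
#' @param anova A `trait_anova` object, or any list carrying `QMg` and
#'   `QMr` (so printed mean squares from a published ANOVA table can be fed
#'   in directly).
#' @param m Grand mean of the trait; taken from `anova` when present there.
#'   `CV` quantities are `NA` (flagged) when `m` is missing or zero.
#' @param k Number of replicates; taken from `anova` when present.
#' @return Object of class `genetic_params` (a list).
#' @export
genetic_parameters <- function(anova, m = NULL, k = NULL) {
  QMg <- anova$QMg
  QMr <- anova$QMr
  if (is.null(QMg) || is.null(QMr)) {
    pd_error("'anova' must carry QMg and QMr", "phenodiv_format_error")
  }
  if (is.null(k)) k <- anova$k
  if (is.null(k) || k < 2) pd_error("k >= 2 is required", "phenodiv_format_error")
  if (is.null(m)) m <- anova$m
  sigma2_f <- QMg / k
  sigma2_e <- QMr / k
  sigma2_g <- (QMg - QMr) / k
  neg <- sigma2_g < 0
  h2 <- if (QMg > 0) 100 * max(0, (QMg - QMr) / QMg) else 0
  m_ok <- !is.null(m) && !is.na(m) && m != 0
  if (m_ok) {
    CVg <- if (neg) NA_real_ else 100 * sqrt(sigma2_g) / m
    CVe <- 100 * sqrt(QMr) / m
  } else {
    CVg <- CVe <- NA_real_
  }
  ratio <- if (neg || QMr <= 0) NA_real_ else sqrt((QMg - QMr) / (k * QMr))
  structure(list(trait = anova$trait %||% NA_character_,
                 sigma2_f = sigma2_f, sigma2_e = sigma2_e, sigma2_g = sigma2_g,
                 h2_percent = h2,
                 CVg_percent = CVg, CVe_percent = CVe, CV_percent = CVe,
                 CVg_over_CVe = ratio,
                 grand_mean = if (m_ok) m else NA_real_, k = k,
                 negative_variance_flag = neg,
                 mean_undefined_flag = !m_ok),
            class = "genetic_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-trait ANOVA and genetic-parameter table
#'
#' Runs [anova_crd()] and [genetic_parameters()] for every trait of a
#' phenotype table and assembles the classical genotype-trial summary: mean
#' squares with F-test stars, heritability, CVg/CVe and CV per trait.
#'
#' @param table A `phenotype_table`.
#' @return Data frame with one row per trait (columns `trait`, `QMg`, `QMr`,
#'   `F`, `p_value`, `significance`, `h2_percent`, `CVg_percent`,
#'   `CVe_percent`, `CVg_over_CVe`, `CV_percent`, `grand_mean`).
#' @export
genetic_parameters_table <- function(table) {
  traits <- attr(table, "traits")
  rows <- lapply(traits, function(tr) {
    an <- anova_crd(table, tr)
    gp <- genetic_parameters(an)
    data.frame(trait = tr, QMg = an$QMg, QMr = an$QMr, F = an$F,
               p_value = an$p_value, significance = an$significance_code,
               h2_percent = gp$h2_percent, CVg_percent = gp$CVg_percent,
               CVe_percent = gp$CVe_percent, CVg_over_CVe = gp$CVg_over_CVe,
               CV_percent = gp$CV_percent, grand_mean = an$m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix over genotype means
#'
#' Computes `r = cov(x, y) / (s_x s_y)` between every pair of traits across
#' genotype means, with a two-sided p-value from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (`n` = number of genotypes). Traits with zero variance across genotypes
#' get `NA` correlations and are flagged rather than starred.
#'
#' @param means A `means_matrix` (or a numeric matrix with genotypes in
#'   rows and traits in columns).
#' @return Object of class `correlation_matrix`: list with matrices `r`,
#'   `p_value` and `significance` (`"**"`, `"*"`, `"ns"`), `n`, and
#'   `zero_variance` (character vector of degenerate traits).
#' @export
pearson_matrix <- function(means) {
  m <- if (inherits(means, "means_matrix")) means_as_matrix(means) else as.matrix(means)
  n <- nrow(m)
  if (n < 3) pd_error("need at least 3 genotypes for correlations", "phenodiv_format_error")
  sds <- apply(m, 2, stats::sd)
  degen <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  diag(r) <- ifelse(colnames(m) %in% degen, NA_real_, 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(0, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  sig <- matrix("ns", nrow(r), ncol(r), dimnames = dimnames(r))
  sig[!is.na(p) & p < 0.05] <- "*"
  sig[!is.na(p) & p < 0.01] <- "**"
  sig[is.na(r)] <- NA_character_
  structure(list(r = r, p_value = p, significance = sig, n = n,
                 zero_variance = degen),
            class = "correlation_matrix")
}

#' @export
print.trait_anova <- function(x, ...) {
  cat(sprintf("One-way CRD ANOVA for trait '%s' (g = %d, k = %d)\n",
              x$trait, x$g, x$k))
  cat(sprintf("  QMg = %.6g (df %d), QMr = %.6g (df %d)\n",
              x$QMg, x$df_genotype, x$QMr, x$df_residual))
  cat(sprintf("  F = %.6g, p = %.4g %s\n", x$F, x$p_value, x$significance_code))
  invisible(x)
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf("Genetic parameters (trait %s, k = %d)\n", x$trait, x$k))
  cat(sprintf("  sigma2_f = %.6g, sigma2_e = %.6g, sigma2_g = %.6g%s\n",
              x$sigma2_f, x$sigma2_e, x$sigma2_g,
              if (x$negative_variance_flag) " [negative, flagged]" else ""))
  cat(sprintf("  h2 = %.2f%%, CVg = %.4g%%, CVe = CV = %.4g%%, CVg/CVe = %.4g\n",
              x$h2_percent, x$CVg_percent, x$CVe_percent, x$CVg_over_CVe))
  invisible(x)
}
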