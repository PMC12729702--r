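# Independent oracles and small data builders used across the suite.
# Everything here is written from the definitions, not by calling the
# package functions it checks.

make_table <- function(values, genotypes = NULL, k = NULL, traits = "y") {
  # values: matrix (g*k) x p, or vector for one trait
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (is.null(k)) k <- 2
  g <- nrow(values) / k
  if (is.null(genotypes)) {
    labs <- if (g <= 26) LETTERS[seq_len(g)] else sprintf("G%03d", seq_len(g))
    genotypes <- rep(labs, each = k)
  }
  df <- data.frame(genotype = genotypes,
                   replicate = rep(seq_len(k), times = g))
  for (j in seq_len(ncol(values))) df[[traits[j]]] <- values[, j]
  as_phenotype_table(df, traits = traits)
}

random_table <- function(g, k, p = 1, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(g * k * p, mean = 10, sd = 2), g * k, p)
  make_table(vals, k = k, traits = paste0("t", seq_len(p)))
}

# Brute-force one-way ANOVA sums of squares by explicit double loops.
oracle_anova_ss <- function(df, trait) {
  gens <- unique(df$genotype)
  m <- mean(df[[trait]])
  ss_t <- 0; ss_g <- 0; ss_e <- 0
  for (gi in gens) {
    y <- df[[trait]][df$genotype == gi]
    for (v in y) {
      ss_t <- ss_t + (v - m)^2
      ss_e <- ss_e + (v - mean(y))^2
    }
    ss_g <- ss_g + length(y) * (mean(y) - m)^2
  }
  list(SS_genotype = ss_g, SS_residual = ss_e, SS_total = ss_t)
}

# Independent Scott-Knott: enumerate every contiguous split decision with
# direct sums (no shared code with the package implementation).
oracle_scott_knott_sizes <- function(means_sorted, QMr, k, nu, alpha) {
  recurse <- function(y) {
    gg <- length(y)
    if (gg < 2) return(gg)
    best_b0 <- -Inf; best_j <- NA
    for (j in 1:(gg - 1)) {
      t1 <- sum(y[1:j]); t2 <- sum(y[(j + 1):gg])
      b0 <- t1^2 / j + t2^2 / (gg - j) - (t1 + t2)^2 / gg
      if (b0 > best_b0 + 1e-12) { best_b0 <- b0; best_j <- j }
    }
    s0 <- (sum((y - mean(y))^2) + nu * QMr / k) / (gg + nu)
    if (best_b0 <= 0 || s0 <= 0) return(gg)
    lam <- pi / (2 * (pi - 2)) * best_b0 / s0
    if (lam > qchisq(1 - alpha, gg / (pi - 2))) {
      c(recurse(y[1:best_j]), recurse(y[(best_j + 1):gg]))
    } else gg
  }
  recurse(means_sorted)
}

# Random symmetric distance matrix with zero diagonal.
random_distance <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  structure(D, metric = "euclidean_standardized",
            class = c("distance_matrix", "matrix", "array"))
}

# Fitted h2 (as a proportion) over nsim independent simulated trials at
# the emulated design size g = 38, k = 4.
h2_hat_sims <- function(h2, nsim, seed_base, s2e = 1) {
  reg <- data.frame(trait = "y", mu = 10, h2 = h2, sigma2_resid = s2e)
  vapply(seq_len(nsim), function(i) {
    cfg <- sim_config(g = 38, k = 4, traits = reg, genetic_cor = diag(1),
                      env_cor = diag(1), seed = seed_base + i)
    an <- anova_crd(simulate_phenotypes(cfg), "y")
    (an$QMg - an$QMr) / an$QMg
  }, 0)
}

# Parse the dash-separated reference group listings shipped in extdata.
read_reference_groups <- function(file) {
  path <- system.file("extdata", file, package = "phenodiv")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(lapply(strsplit(tab$genotypes, "-", fixed = TRUE), as.integer),
                  tab$group)
}
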