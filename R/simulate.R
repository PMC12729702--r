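#' Default trait regime for the umbu diaspore simulator
#'
#' Per-trait grand means, target broad-sense heritabilities and
#' replicate-level residual variances emulating a field characterization of
#' umbu diaspores: ten traits spanning fruit dimensions (mm), masses (g),
#' and emergence physiology (SE %, ESI index, MET days), with
#' heritabilities from 0.63 (MET) to 0.985 (FL) and residual variances
#' giving experimental CVs of roughly 2% (dimensions) to 49% (emergence
#' traits).
#'
#' @return Data frame `trait`, `mu`, `h2`, `sigma2_resid`.
#' @export
default_trait_regime <- function() {
  data.frame(
    trait = umbu_traits,
    mu = c(34.2, 31.0, 20.6, 19.6, 13.6, 10.7, 1.46, 23.4, 0.21, 44.8),
    h2 = c(0.985, 0.977, 0.976, 0.956, 0.950, 0.923, 0.960, 0.906, 0.918, 0.631),
    sigma2_resid = c(0.55, 0.65, 1.81, 0.41, 0.27, 0.24, 0.01, 99.40, 0.01, 265.81),
    stringsAsFactors = FALSE)
}

#' Default genetic correlation matrix for the simulator
#'
#' Block-structured correlations among the ten default traits: fruit
#' dimensions/mass strongly inter-correlated (0.9), endocarp traits
#' moderately (0.6), SE and ESI strongly (0.9), a moderate fruit-endocarp
#' and size-emergence link (0.4 / 0.3), and MET correlated only with ESI
#' (-0.33). The matrix is symmetric positive definite.
#'
#' @return 10 x 10 correlation matrix with trait dimnames.
#' @export
default_genetic_correlations <- function() {
  tr <- umbu_traits
  R <- diag(10)
  dimnames(R) <- list(tr, tr)
  set_block <- function(a, b, r) {
    for (i in a) for (j in b) if (i != j) R[i, j] <<- R[j, i] <<- r
  }
  fruit <- c("FL", "FD", "FFM"); endo <- c("EL", "EW", "ET", "EM")
  emer <- c("SE", "ESI")
  set_block(fruit, fruit, 0.9)
  set_block(endo, endo, 0.6)
  set_block(emer, emer, 0.9)
  set_block(fruit, endo, 0.4)
  set_block(c(fruit, endo), emer, 0.3)
  set_block("MET", "ESI", -0.33)
  R
}

#' Genetic variance needed to hit a target heritability
#'
#' Inverts the expected-mean-square relations of the balanced one-way
#' model: with replicate-level residual variance `sigma2_e`,
#' `E[QMg] = k sigma2_g + sigma2_e` and `E[QMr] = sigma2_e`, so
#' `sigma2_g = h2 * sigma2_e / (k (1 - h2))` makes the expected
#' heritability estimate `k sigma2_g / (k sigma2_g + sigma2_e)` equal `h2`.
#'
#' @param h2 Target broad-sense heritability in `[0, 1)`.
#' @param sigma2_e Replicate-level residual variance (> 0).
#' @param k Replicate count.
#' @return `sigma2_g`.
#' @export
sigma_g_for_h2 <- function(h2, sigma2_e, k) {
  if (any(h2 < 0 | h2 >= 1)) pd_error("h2 must be in [0, 1)", "phenodiv_format_error")
  if (any(sigma2_e <= 0)) pd_error("sigma2_e must be > 0", "phenodiv_format_error")
  h2 * sigma2_e / (k * (1 - h2))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generator. Defaults emulate the
#' study design the package targets: 38 genotypes in 3 natural populations
#' (13 + 8 + 17), 4 replicates, the ten-trait regime of
#' [default_trait_regime()] with the block genetic correlations of
#' [default_genetic_correlations()], uncorrelated residuals, 25 seeds sown
#' per emergence replicate, genotype emergence probabilities uniform on
#' [0.02, 0.50] (population means near 10-30% with occasional
#' high-emergence genotypes), and lognormal emergence timing with median 40
#' days (sdlog 0.3) truncated to the 90-day observation window.
#'
#' @param g Number of genotypes.
#' @param k Replicates per genotype.
#' @param populations Named integer vector of genotypes per population
#'   (must sum to `g`); genotypes are numbered consecutively across
#'   populations.
#' @param traits Data frame `trait`, `mu`, `h2`, `sigma2_resid`.
#' @param genetic_cor Genetic correlation matrix (symmetric PD).
#' @param env_cor Environmental (residual) correlation matrix.
#' @param pop_shift Optional named list/vector of per-population additive
#'   mean shifts applied to every trait in units of the genetic standard
#'   deviation (default 0: populations carry labels, no effect).
#' @param seeds_sown Seeds per emergence replicate.
#' @param emergence_prob_range Length-2 range of per-genotype emergence
#'   probabilities.
#' @param timing_meanlog,timing_sdlog Lognormal emergence-day parameters.
#' @param window Emergence observation window (days).
#' @param seed Integer RNG seed.
#' @return List of class `sim_config` (validated).
#' @export
sim_config <- function(g = 38, k = 4,
                       populations = c("Sao Jose da Mata" = 13,
                                       "Algodao de Jandaira" = 8,
                                       "Boa Vista" = 17),
                       traits = default_trait_regime(),
                       genetic_cor = default_genetic_correlations()[traits$trait, traits$trait, drop = FALSE],
                       env_cor = diag(nrow(traits)),
                       pop_shift = NULL,
                       seeds_sown = 25,
                       emergence_prob_range = c(0.02, 0.50),
                       timing_meanlog = log(40), timing_sdlog = 0.3,
                       window = 90, seed = 1L) {
  if (g < 2 || k < 2) pd_error("need g >= 2 and k >= 2", "phenodiv_format_error")
  if (sum(populations) != g) {
    if (missing(populations)) {
      populations <- c(genotypes = g)   # custom g with default allocation: one population
    } else {
      pd_error("population sizes must sum to g", "phenodiv_format_error")
    }
  }
  stopifnot(nrow(traits) >= 1, all(c("trait", "mu", "h2", "sigma2_resid") %in% names(traits)))
  if (any(traits$h2 < 0 | traits$h2 >= 1)) pd_error("h2 targets must be in [0, 1)", "phenodiv_format_error")
  p <- nrow(traits)
  check_cor <- function(R, what) {
    R <- as.matrix(R)
    if (nrow(R) != p || ncol(R) != p || max(abs(R - t(R))) > 1e-10) {
      pd_error(sprintf("%s correlation matrix must be symmetric %dx%d", what, p, p),
               "phenodiv_format_error")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
      pd_error(sprintf("%s correlation matrix is not positive definite", what),
               "phenodiv_format_error")
    }
    R
  }
  structure(list(g = as.integer(g), k = as.integer(k), populations = populations,
                 traits = traits,
                 genetic_cor = check_cor(genetic_cor, "genetic"),
                 env_cor = check_cor(env_cor, "environmental"),
                 pop_shift = pop_shift, seeds_sown = as.integer(seeds_sown),
                 emergence_prob_range = emergence_prob_range,
                 timing_meanlog = timing_meanlog, timing_sdlog = timing_sdlog,
                 window = as.integer(window), seed = as.integer(seed)),
            class = "sim_config")
}

cov_from_cor <- function(R, variances) {
  d <- sqrt(variances)
  R * tcrossprod(d)
}

population_labels <- function(config) {
  rep(names(config$populations), config$populations)
}

#' Simulate a replicate-level phenotype table
#'
#' Runs the one-way model forward: genotype effect vectors are drawn from a
#' zero-mean multivariate normal with covariance built from the per-trait
#' genetic variances (chosen via [sigma_g_for_h2()] to hit the target
#' heritabilities) and the genetic correlation matrix; residuals likewise
#' from the environmental covariance; `Y = mu + G + e`. Fully reproducible
#' from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `phenotype_table` with `population` labels.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- config$traits
  p <- nrow(tr)
  s2g <- sigma_g_for_h2(tr$h2, tr$sigma2_resid, config$k)
  Sg <- cov_from_cor(config$genetic_cor, s2g)
  Se <- cov_from_cor(config$env_cor, tr$sigma2_resid)
  zero_g <- s2g == 0
  G <- matrix(0, config$g, p)
  if (any(!zero_g)) {
    G[, !zero_g] <- MASS::mvrnorm(config$g, mu = rep(0, sum(!zero_g)),
                                  Sigma = Sg[!zero_g, !zero_g, drop = FALSE])
  }
  n <- config$g * config$k
  E <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Se)
  geno <- rep(seq_len(config$g), each = config$k)
  Y <- matrix(tr$mu, n, p, byrow = TRUE) + G[geno, , drop = FALSE] + E
  pops <- population_labels(config)
  if (!is.null(config$pop_shift)) {
    shift <- unlist(config$pop_shift)[pops[geno]]
    shift[is.na(shift)] <- 0
    Y <- Y + outer(shift, sqrt(pmax(s2g, 0)))
  }
  out <- data.frame(genotype = as.character(geno),
                    population = pops[geno],
                    replicate = rep(seq_len(config$k), times = config$g),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) out[[tr$trait[j]]] <- Y[, j]
  as_phenotype_table(out, traits = tr$trait)
}

#' Simulate daily seedling-emergence counts
#'
#' Per genotype an emergence probability is drawn uniformly from
#' `emergence_prob_range`; per replicate the emerged total is binomial
#' (seeds sown, probability), and each emerged seedling's day is drawn from
#' the lognormal timing distribution truncated to `[1, window]` and binned
#' to integer days. Replicates with zero emergence are represented by a
#' single zero-count row at the window's last day so no replicate silently
#' disappears. Reproducible from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return An `emergence_counts` table; attribute `true_prob` carries the
#'   per-genotype emergence probabilities.
#' @export
simulate_emergence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lo <- stats::plnorm(1, config$timing_meanlog, config$timing_sdlog)
  hi <- stats::plnorm(config$window, config$timing_meanlog, config$timing_sdlog)
  prob <- stats::runif(config$g, config$emergence_prob_range[1],
                       config$emergence_prob_range[2])
  rows <- vector("list", config$g * config$k)
  idx <- 0L
  for (i in seq_len(config$g)) {
    for (j in seq_len(config$k)) {
      idx <- idx + 1L
      n_em <- stats::rbinom(1, config$seeds_sown, prob[i])
      if (n_em == 0) {
        rows[[idx]] <- data.frame(genotype = as.character(i), replicate = j,
                                  day = config$window, emerged = 0L,
                                  sown = config$seeds_sown)
        next
      }
      u <- stats::runif(n_em, lo, hi)
      day <- pmin(pmax(round(stats::qlnorm(u, config$timing_meanlog,
                                           config$timing_sdlog)), 1L),
                  config$window)
      tab <- table(day)
      rows[[idx]] <- data.frame(genotype = as.character(i), replicate = j,
                                day = as.integer(names(tab)),
                                emerged = as.integer(tab),
                                sown = config$seeds_sown)
    }
  }
  out <- as_emergence_counts(do.call(rbind, rows), window = config$window)
  attr(out, "true_prob") <- stats::setNames(prob, as.character(seq_len(config$g)))
  out
}
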