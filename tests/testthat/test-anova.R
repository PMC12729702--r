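test_that("CRD ANOVA reproduces the hand-computed two-genotype example", {
  tab <- make_table(c(1, 3, 5, 7))
  an <- anova_crd(tab, "y")
  expect_equal(an$SS_genotype, 16)
  expect_equal(an$SS_residual, 4)
  expect_equal(an$SS_total, 20)
  expect_equal(an$QMg, 16)
  expect_equal(an$QMr, 2)
  expect_equal(an$F, 8)
  expect_equal(an$df_genotype, 1L)
  expect_equal(an$df_residual, 2L)
  expect_equal(an$p_value, pf(8, 1, 2, lower.tail = FALSE))
})

test_that("constant data takes the degenerate path", {
  tab <- make_table(rep(3, 8), k = 2)
  expect_warning(an <- anova_crd(tab, "y"), "degenerate")
  expect_equal(an$SS_genotype, 0)
  expect_equal(an$SS_residual, 0)
})

test_that("sums of squares agree with brute force and with stats::lm", {
  for (seed in 1:3) {
    tab <- random_table(10, 4, seed = seed)
    an <- anova_crd(tab, "t1")
    or <- oracle_anova_ss(as.data.frame(tab), "t1")
    expect_equal(an$SS_genotype, or$SS_genotype, tolerance = 1e-10)
    expect_equal(an$SS_residual, or$SS_residual, tolerance = 1e-10)
    expect_equal(an$SS_genotype + an$SS_residual, an$SS_total, tolerance = 1e-10)
    fit <- stats::anova(stats::lm(t1 ~ factor(genotype), data = as.data.frame(tab)))
    expect_equal(an$QMg, fit$`Mean Sq`[1])
    expect_equal(an$QMr, fit$`Mean Sq`[2])
    expect_equal(an$F, fit$`F value`[1])
    expect_equal(an$p_value, fit$`Pr(>F)`[1])
  }
})

test_that("genetic parameters follow the mean-square estimators", {
  gp <- genetic_parameters(list(QMg = 1061.12, QMr = 99.40), m = 23.4, k = 4)
  expect_equal(gp$sigma2_f, 1061.12 / 4)
  expect_equal(gp$sigma2_e, 99.40 / 4)
  expect_equal(gp$sigma2_g, (1061.12 - 99.40) / 4)
  expect_equal(gp$h2_percent, 100 * (1061.12 - 99.40) / 1061.12)
  expect_equal(gp$CVg_over_CVe, sqrt((1061.12 - 99.40) / (4 * 99.40)))
  expect_equal(gp$CVe_percent, gp$CV_percent)
  expect_equal(gp$CVg_percent / gp$CVe_percent, gp$CVg_over_CVe)

  # no genetic variance: everything collapses to zero
  gp0 <- genetic_parameters(list(QMg = 2, QMr = 2), m = 5, k = 4)
  expect_equal(gp0$sigma2_g, 0)
  expect_equal(gp0$h2_percent, 0)
  expect_equal(gp0$CVg_over_CVe, 0)

  # negative variance estimate is preserved and flagged, h2 floored
  gpn <- genetic_parameters(list(QMg = 1, QMr = 2), m = 5, k = 4)
  expect_true(gpn$negative_variance_flag)
  expect_equal(gpn$sigma2_g, -0.25)
  expect_equal(gpn$h2_percent, 0)

  expect_error(genetic_parameters(list(QMg = 1, QMr = 1), m = 1, k = 1),
               class = "phenodiv_format_error")
})

test_that("h2, CVg/CVe and F are scale-invariant; CVs are location-sensitive", {
  set.seed(4)
  geno_eff <- rep(rnorm(8, sd = 3), each = 3)
  tab <- make_table(10 + geno_eff + rnorm(24), k = 3, traits = "t1")
  an <- anova_crd(tab, "t1")
  gp <- genetic_parameters(an)
  scaled <- as.data.frame(tab)
  scaled$t1 <- scaled$t1 * 7.3
  an2 <- anova_crd(as_phenotype_table(scaled, "t1"), "t1")
  gp2 <- genetic_parameters(an2)
  expect_equal(gp2$h2_percent, gp$h2_percent, tolerance = 1e-10)
  expect_equal(gp2$CVg_over_CVe, gp$CVg_over_CVe, tolerance = 1e-10)
  expect_equal(an2$F, an$F, tolerance = 1e-10)
  expect_equal(gp2$CVg_percent, gp$CVg_percent, tolerance = 1e-10)  # scale cancels in CV

  shifted <- as.data.frame(tab)
  shifted$t1 <- shifted$t1 + 100
  gp3 <- genetic_parameters(anova_crd(as_phenotype_table(shifted, "t1"), "t1"))
  expect_false(isTRUE(all.equal(gp3$CVg_percent, gp$CVg_percent)))
  expect_false(isTRUE(all.equal(gp3$CVe_percent, gp$CVe_percent)))
  expect_equal(gp3$h2_percent, gp$h2_percent, tolerance = 1e-10)
})

test_that("expected mean squares are recovered on simulated data", {
  # E[QMg] = k sigma_g^2 + sigma_e^2, E[QMr] = sigma_e^2
  k <- 4; g <- 38; s2g <- 2.25; s2e <- 1
  reg <- data.frame(trait = "y", mu = 10,
                    h2 = k * s2g / (k * s2g + s2e), sigma2_resid = s2e)
  qmg <- qmr <- numeric(500)
  for (i in seq_len(500)) {
    cfg <- sim_config(g = g, k = k, traits = reg, genetic_cor = diag(1),
                      env_cor = diag(1), seed = i)
    an <- anova_crd(simulate_phenotypes(cfg), "y")
    qmg[i] <- an$QMg; qmr[i] <- an$QMr
  }
  expect_equal(mean(qmg), k * s2g + s2e, tolerance = 0.02)
  expect_equal(mean(qmr), s2e, tolerance = 0.02)
})

test_that("Pearson matrix matches direct evaluation and is well formed", {
  m <- structure(data.frame(genotype = c("a", "b", "c"),
                            x = c(1, 2, 3), y = c(1, 2, 4), z = c(3, 5, 7)),
                 class = c("means_matrix", "data.frame"),
                 traits = c("x", "y", "z"), k = 2)
  cm <- pearson_matrix(m)
  expect_equal(cm$r["x", "y"], 1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(cm$r["x", "y"], 0.982, tolerance = 1e-3)
  expect_equal(cm$r["x", "z"], 1)          # z = 2x + 1
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$n, 3)
  # p-value from t with n-2 df
  r <- cm$r["x", "y"]
  tstat <- r * sqrt(1) / sqrt(1 - r^2)
  expect_equal(cm$p_value["x", "y"], 2 * pt(tstat, 1, lower.tail = FALSE))
})

test_that("zero-variance traits are flagged, not starred", {
  m <- structure(data.frame(genotype = c("a", "b", "c"),
                            x = c(1, 2, 3), const = c(4, 4, 4)),
                 class = c("means_matrix", "data.frame"),
                 traits = c("x", "const"), k = 2)
  cm <- pearson_matrix(m)
  expect_equal(cm$zero_variance, "const")
  expect_true(is.na(cm$r["x", "const"]))
  expect_true(is.na(cm$significance["x", "const"]))
})

test_that("the correlation matrix is positive semidefinite", {
  set.seed(11)
  for (i in 1:5) {
    M <- matrix(rnorm(20 * 6), 20)
    colnames(M) <- paste0("t", 1:6)
    cm <- pearson_matrix(M)
    expect_gte(min(eigen(cm$r, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})
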