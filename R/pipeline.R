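#' Run the full phenotypic-divergence pipeline
#'
#' Orchestrates every stage of the analysis on a replicate-level phenotype
#' table: per-trait ANOVA and genetic parameters, Scott-Knott letters,
#' pooled residual covariance, Mahalanobis D2 and standardized mean
#' Euclidean distances, Tocher clustering (on Mahalanobis D2 by default),
#' UPGMA with Mojena cutoff (on the standardized Euclidean distance by
#' default, the conventional pairing for dendrograms of trait means),
#' Singh's trait-importance decomposition, canonical variates, and the
#' Pearson correlation matrix of genotype means. Daily emergence counts,
#' when given, are converted to per-replicate SE/ESI/MET values and appended
#' to the phenotype table before analysis.
#'
#' The `config` may be a list or the path to a YAML file with (any of) the
#' fields `input`, `emergence` (CSV paths), `traits`, `decimal`
#' (`"point"`/`"comma"`), `alpha`, `distance_tocher`, `distance_upgma`
#' (`"mahalanobis"` or `"euclidean_standardized"`), `mojena_c`, `ridge`,
#' `seed`, and `simulation` (logical or a list of [sim_config()] arguments;
#' used when no `input` is given).
#'
#' @param config List or YAML path as described above.
#' @return Object of class `divergence_report`; see [write_report()].
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      pd_error(sprintf("config file not found: %s", config), "phenodiv_format_error")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(alpha = 0.05, mojena_c = 1.25, ridge = 0,
                                distance_tocher = "mahalanobis",
                                distance_upgma = "euclidean_standardized",
                                decimal = "point", seed = 1L),
                           config)
  dec <- if (identical(cfg$decimal, "comma")) "," else "."
  input_hashes <- character(0)

  if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input)) {
      pd_error(sprintf("input file not found: %s", cfg$input), "phenodiv_format_error")
    }
    table <- read_phenotype_table(cfg$input, trait_names = cfg$traits, dec = dec)
    input_hashes["input"] <- unname(tools::md5sum(cfg$input))
  } else {
    sim_args <- if (is.list(cfg$simulation)) cfg$simulation else list()
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    table <- simulate_phenotypes(scfg)
    cfg$simulation_config <- scfg
  }

  emergence_block <- NULL
  if (!is.null(cfg$emergence)) {
    counts <- if (is.character(cfg$emergence)) {
      if (!file.exists(cfg$emergence)) {
        pd_error(sprintf("emergence file not found: %s", cfg$emergence),
                 "phenodiv_format_error")
      }
      input_hashes["emergence"] <- unname(tools::md5sum(cfg$emergence))
      read_emergence_counts(cfg$emergence, dec = dec)
    } else cfg$emergence
    per_rep <- emergence_metrics(counts)
    emergence_block <- list(per_replicate = per_rep,
                            per_genotype = genotype_emergence_means(counts))
    df <- merge(as.data.frame(table), per_rep,
                by = c("genotype", "replicate"), all.x = TRUE)
    if (anyNA(df$SE)) {
      pd_error("emergence counts do not cover every (genotype, replicate)",
               "phenodiv_format_error")
    }
    # MET is undefined for zero-emergence replicates; the balanced ANOVA
    # needs a finite value, so such replicates take their genotype's mean
    # MET over the emerging replicates (genotypes with no emergence at all
    # cannot carry a MET and are an error).
    if (anyNA(df$MET)) {
      gmet <- tapply(df$MET, df$genotype, mean, na.rm = TRUE)
      if (any(!is.finite(gmet))) {
        pd_error(sprintf("no emergence in any replicate of genotype(s): %s; drop MET or these genotypes",
                         paste(names(gmet)[!is.finite(gmet)], collapse = ", ")),
                 "phenodiv_format_error")
      }
      na_i <- is.na(df$MET)
      df$MET[na_i] <- gmet[df$genotype[na_i]]
    }
    table <- as_phenotype_table(df, traits = c(attr(table, "traits"),
                                               "SE", "ESI", "MET"))
  }

  anova_tab <- genetic_parameters_table(table)
  sk_tab <- scott_knott_table(table, alpha = cfg$alpha)
  means <- genotype_means(table)
  pooled <- pooled_residual_covariance(table)
  D_mah <- mahalanobis_matrix(means, pooled, ridge = cfg$ridge)
  D_euc <- standardized_euclidean_matrix(means)
  pick <- function(which) switch(which,
                                 mahalanobis = , mahalanobis_d2 = D_mah,
                                 euclidean_standardized = , `euclidean-std` = D_euc,
                                 pd_error(sprintf("unknown distance '%s'", which),
                                          "phenodiv_format_error"))
  toc <- tocher_cluster(pick(cfg$distance_tocher))
  tree <- upgma_tree(pick(cfg$distance_upgma))
  moj <- mojena_cut(tree, c = cfg$mojena_c)
  singh <- singh_contributions(means, pooled, ridge = cfg$ridge)
  cva <- canonical_variates(table, ridge = cfg$ridge)
  cors <- pearson_matrix(means)

  structure(list(
    anova = anova_tab, scott_knott = sk_tab, means = means,
    pooled_covariance = pooled,
    distances = list(mahalanobis_d2 = D_mah, euclidean_standardized = D_euc),
    tocher = toc, upgma = tree, mojena = moj,
    singh = singh, canonical = cva, correlations = cors,
    emergence = emergence_block,
    provenance = list(
      package_version = as.character(utils::packageVersion("phenodiv")),
      config = cfg[setdiff(names(cfg), "emergence")],
      seed = cfg$seed, input_md5 = input_hashes,
      g = length(unique(table$genotype)), k = attr(table, "k"),
      traits = attr(table, "traits"))),
    class = "divergence_report")
}

fmt4 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 4, format = "fg"))

#' @export
print.divergence_report <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("Phenotypic divergence report (phenodiv %s)\n", pv$package_version))
  cat(sprintf("Design: %d genotypes x %d replicates, %d traits\n\n",
              pv$g, pv$k, length(pv$traits)))
  cat("== ANOVA and genetic parameters ==\n")
  tab <- x$anova
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], fmt4)
  print(tab, row.names = FALSE)
  cat(sprintf("\n== Tocher clustering (theta = %s) ==\n", fmt4(x$tocher$theta)))
  print(tocher_listing(x$tocher), row.names = FALSE)
  cat("\n== UPGMA / Mojena ==\n")
  print(x$mojena)
  cat("\n== Singh relative importance ==\n")
  sg <- as.data.frame(x$singh)
  sg$S_j <- fmt4(sg$S_j); sg$percent <- fmt4(sg$percent)
  print(sg[order(sg$rank), ], row.names = FALSE)
  cat("\n== Canonical variates ==\n")
  print(data.frame(variate = paste0("CV", seq_along(x$canonical$eigenvalues)),
                   proportion = fmt4(x$canonical$proportion),
                   cumulative = fmt4(x$canonical$cumulative)), row.names = FALSE)
  cat("\n== Pearson correlations (genotype means) ==\n")
  r <- x$correlations$r
  disp <- matrix(paste0(fmt4(r), " ", x$correlations$significance),
                 nrow(r), dimnames = dimnames(r))
  diag(disp) <- "1"
  print(as.data.frame(disp))
  invisible(x)
}

#' Write every pipeline output to a directory
#'
#' Emits the per-module CSVs (ANOVA/genetic parameters, Scott-Knott
#' letters, genotype means, both distance matrices and pair lists, Tocher
#' listing, UPGMA merge table and Mojena membership, Singh contributions,
#' canonical-variate summary and scores, correlation matrix), the Newick
#' dendrogram, a human-readable `report.txt`, and a machine-readable
#' `report.json` with full-precision values and the provenance block.
#'
#' @param report A `divergence_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "divergence_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(report$anova, "anova_genetic_parameters.csv")
  w(report$scott_knott, "scott_knott_groups.csv")
  w(cbind(as.data.frame(report$means), k = attr(report$means, "k")),
    "genotype_means.csv")
  for (nm in names(report$distances)) {
    D <- report$distances[[nm]]
    utils::write.csv(as.data.frame(as.matrix(D)), file.path(dir, paste0("distance_", nm, ".csv")))
    w(distance_pairs(D), paste0("distance_", nm, "_pairs.csv"))
  }
  w(tocher_listing(report$tocher), "tocher_groups.csv")
  w(merge_table(report$upgma), "upgma_merges.csv")
  w(data.frame(genotype = names(report$mojena$membership),
               group = as.integer(report$mojena$membership)),
    "upgma_mojena_membership.csv")
  writeLines(to_newick(report$upgma), file.path(dir, "upgma_dendrogram.nwk"))
  w(as.data.frame(report$singh), "singh_contributions.csv")
  w(data.frame(variate = paste0("CV", seq_along(report$canonical$eigenvalues)),
               eigenvalue = report$canonical$eigenvalues,
               proportion = report$canonical$proportion,
               cumulative = report$canonical$cumulative),
    "canonical_variates.csv")
  utils::write.csv(as.data.frame(report$canonical$scores),
                   file.path(dir, "canonical_scores.csv"))
  utils::write.csv(as.data.frame(report$correlations$r),
                   file.path(dir, "correlations_r.csv"))
  utils::write.csv(as.data.frame(report$correlations$significance),
                   file.path(dir, "correlations_significance.csv"))
  if (!is.null(report$emergence)) {
    w(report$emergence$per_replicate, "emergence_per_replicate.csv")
    w(report$emergence$per_genotype, "emergence_per_genotype.csv")
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  machine <- list(
    provenance = report$provenance[c("package_version", "seed", "input_md5", "g", "k", "traits")],
    anova = report$anova,
    scott_knott = report$scott_knott,
    tocher = list(theta = report$tocher$theta, clusters = report$tocher$clusters),
    mojena = report$mojena[c("cutoff", "c", "n_groups")],
    singh = as.data.frame(report$singh),
    canonical = list(eigenvalues = report$canonical$eigenvalues,
                     proportion = report$canonical$proportion),
    correlations = list(r = report$correlations$r,
                        significance = report$correlations$significance))
  jsonlite::write_json(machine, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  invisible(dir)
}
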