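#' Default diaspore trait set
#'
#' Short labels for the ten fruit/endocarp/emergence traits commonly scored
#' on umbu (*Spondias tuberosa*) diaspores: fruit length (FL, mm), fruit
#' diameter (FD, mm), fresh fruit mass (FFM, g), endocarp length (EL, mm),
#' endocarp width (EW, mm), endocarp thickness (ET, mm), endocarp mass
#' (EM, g), seedling emergence (SE, %), emergence speed index (ESI, index)
#' and mean emergence time (MET, days). Trait names elsewhere in the package
#' are free labels; this vector is only a convenient default.
#'
#' @format Character vector of length 10.
#' @export
umbu_traits <- c("FL", "FD", "FFM", "EL", "EW", "ET", "EM", "SE", "ESI", "MET")

pd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phenodiv_error")))
}

#' Validate a replicate-level phenotype table
#'
#' Checks a data frame against the contract assumed by every downstream
#' analysis: columns `genotype` and `replicate` (plus optional `population`),
#' one numeric column per trait, every (genotype, replicate) pair unique, all
#' trait values finite, and a balanced completely randomized design with a
#' common replicate count `k >= 2` per genotype. Unbalanced input is rejected
#' rather than approximated, because the expected-mean-square algebra used for
#' the genetic parameters assumes a common `k`.
#'
#' @param x Data frame with columns `genotype`, `replicate`, optionally
#'   `population`, and one column per trait.
#' @param traits Character vector of trait column names. Defaults to every
#'   column other than the identifier columns.
#' @return `x` with class `phenotype_table` and attributes `traits` and `k`.
#' @export
as_phenotype_table <- function(x, traits = NULL) {
  if (!is.data.frame(x)) pd_error("input must be a data frame", "phenodiv_format_error")
  for (col in c("genotype", "replicate")) {
    if (!col %in% names(x)) {
      pd_error(sprintf("required column '%s' is missing", col), "phenodiv_format_error")
    }
  }
  if (is.null(traits)) {
    traits <- setdiff(names(x), c("genotype", "replicate", "population"))
  }
  if (length(traits) < 1) pd_error("no trait columns found", "phenodiv_format_error")
  missing_tr <- setdiff(traits, names(x))
  if (length(missing_tr)) {
    pd_error(sprintf("missing trait column(s): %s", paste(missing_tr, collapse = ", ")),
             "phenodiv_format_error")
  }
  for (tr in traits) {
    v <- x[[tr]]
    if (!is.numeric(v)) {
      pd_error(sprintf("trait column '%s' is not numeric", tr), "phenodiv_parse_error")
    }
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      pd_error(sprintf("trait '%s' has a non-finite value in row %d", tr, bad),
               "phenodiv_parse_error")
    }
  }
  x$genotype <- as.character(x$genotype)
  x$replicate <- as.integer(x$replicate)
  key <- paste(x$genotype, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE]
    pd_error(sprintf("duplicated (genotype, replicate) pair(s), e.g. (%s, %d)",
                     dup$genotype[1], dup$replicate[1]), "phenodiv_format_error")
  }
  reps <- table(x$genotype)
  if (length(unique(as.integer(reps))) != 1L) {
    k_mode <- as.integer(names(which.max(table(as.integer(reps)))))
    off <- names(reps)[as.integer(reps) != k_mode]
    pd_error(sprintf("unbalanced design: genotypes with deviant replicate counts: %s",
                     paste(off, collapse = ", ")), "phenodiv_balance_error")
  }
  k <- as.integer(reps[1])
  if (k < 2) pd_error("at least k = 2 replicates per genotype are required", "phenodiv_balance_error")
  if ("population" %in% names(x)) {
    pop_per_gen <- tapply(as.character(x$population), x$genotype,
                          function(p) length(unique(p)))
    if (any(pop_per_gen > 1)) {
      pd_error("a genotype is assigned to more than one population", "phenodiv_format_error")
    }
  }
  structure(x, class = c("phenotype_table", "data.frame"),
            traits = traits, k = k)
}

#' Read a replicate-level phenotype table from CSV
#'
#' Expects an RFC-4180 CSV with header columns `genotype`, `replicate`,
#' optionally `population`, and one numeric column per trait. The decimal
#' separator is never guessed: pass `dec = ","` for comma-decimal files.
#'
#' @param path Path to the CSV file.
#' @param trait_names Trait columns to keep; default all non-identifier
#'   columns.
#' @param dec Decimal separator, `"."` (default) or `","`.
#' @return A [as_phenotype_table()]-validated `phenotype_table`.
#' @export
read_phenotype_table <- function(path, trait_names = NULL, dec = ".") {
  if (!file.exists(path)) {
    pd_error(sprintf("input file not found: %s", path), "phenodiv_format_error")
  }
  raw <- utils::read.csv(path, dec = dec, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (is.null(trait_names)) {
    trait_names <- setdiff(names(raw), c("genotype", "replicate", "population"))
  }
  missing_tr <- setdiff(c("genotype", "replicate", trait_names), names(raw))
  if (length(missing_tr)) {
    pd_error(sprintf("missing column(s) in %s: %s", path,
                     paste(missing_tr, collapse = ", ")), "phenodiv_format_error")
  }
  for (tr in trait_names) {
    v <- raw[[tr]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad)) {
        pd_error(sprintf("non-numeric value '%s' for trait '%s' in data row %d",
                         v[bad[1]], tr, bad[1]), "phenodiv_parse_error")
      }
      raw[[tr]] <- num
    }
  }
  as_phenotype_table(raw[, c(intersect(c("genotype", "population", "replicate"),
                                       names(raw)), trait_names)],
                     traits = trait_names)
}

#' Write a phenotype table (or genotype-mean matrix) to CSV
#'
#' Numeric values are formatted with 12 significant digits so that a
#' write-then-read round trip preserves values to at least 1e-10 relative
#' precision.
#'
#' @param x A `phenotype_table` or `means_matrix` (or plain data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.12g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genotype means of a phenotype table
#'
#' Arithmetic mean of the `k` replicate values per genotype and trait. Rows
#' are ordered by genotype label (numerically when all labels are numbers),
#' so the result is invariant to the row order of the input.
#'
#' @param table A `phenotype_table`.
#' @return Data frame of class `means_matrix` with a `genotype` column and
#'   one column per trait; attributes `k` (replicate count), `traits`, and
#'   `populations` (named genotype -> population map when available).
#' @export
genotype_means <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  traits <- attr(table, "traits")
  gen <- table$genotype
  lev <- unique(gen)
  num <- suppressWarnings(as.numeric(lev))
  lev <- if (!anyNA(num)) lev[order(num)] else sort(lev)
  gfac <- factor(gen, levels = lev)
  mm <- data.frame(genotype = lev, stringsAsFactors = FALSE)
  for (tr in traits) mm[[tr]] <- as.vector(tapply(table[[tr]], gfac, mean))
  pops <- NULL
  if ("population" %in% names(table)) {
    pops <- vapply(lev, function(g) as.character(table$population[gen == g][1]), "")
    names(pops) <- lev
  }
  structure(mm, class = c("means_matrix", "data.frame"),
            k = attr(table, "k"), traits = traits, populations = pops)
}

means_as_matrix <- function(means) {
  traits <- attr(means, "traits")
  m <- as.matrix(as.data.frame(means)[, traits, drop = FALSE])
  rownames(m) <- means$genotype
  m
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("Phenotype table: %d genotypes x %d replicates, %d trait(s)\n",
              length(unique(x$genotype)), attr(x, "k"), length(attr(x, "traits"))))
  cat("Traits:", paste(attr(x, "traits"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
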