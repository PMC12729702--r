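#' Validate a daily emergence-count table
#'
#' Long-format daily seedling-emergence counts: one row per (genotype,
#' replicate, day) with the number of seedlings newly emerged that day and
#' the number of seeds sown in the replicate. Days are days after sowing,
#' strictly increasing within a replicate; total emergence may not exceed
#' the seeds sown; the observation window defaults to 90 days.
#'
#' @param x Data frame with columns `genotype`, `replicate`, `day`,
#'   `emerged`, `sown`.
#' @param cumulative If `TRUE`, `emerged` holds cumulative counts and is
#'   differenced to daily counts.
#' @param window Maximum day after sowing (default 90).
#' @return `x` (daily counts) with class `emergence_counts`.
#' @export
as_emergence_counts <- function(x, cumulative = FALSE, window = 90) {
  need <- c("genotype", "replicate", "day", "emerged", "sown")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    pd_error(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
             "phenodiv_format_error")
  }
  x$genotype <- as.character(x$genotype)
  x$replicate <- as.integer(x$replicate)
  x$day <- as.integer(x$day)
  x$emerged <- as.integer(x$emerged)
  x$sown <- as.integer(x$sown)
  if (any(x$day < 1)) pd_error("days must be >= 1", "phenodiv_format_error")
  if (any(x$day > window)) {
    pd_error(sprintf("day beyond the %d-day observation window", window),
             "phenodiv_format_error")
  }
  x <- x[order(x$genotype, x$replicate, x$day), , drop = FALSE]
  parts <- split(x, interaction(x$genotype, x$replicate, drop = TRUE))
  parts <- lapply(parts, function(d) {
    if (anyDuplicated(d$day)) {
      pd_error(sprintf("duplicate day for genotype %s replicate %d",
                       d$genotype[1], d$replicate[1]), "phenodiv_format_error")
    }
    if (length(unique(d$sown)) != 1) {
      pd_error(sprintf("inconsistent 'sown' for genotype %s replicate %d",
                       d$genotype[1], d$replicate[1]), "phenodiv_format_error")
    }
    if (cumulative) {
      d$emerged <- diff(c(0L, d$emerged))
    }
    if (any(d$emerged < 0)) {
      pd_error(sprintf("negative daily count for genotype %s replicate %d",
                       d$genotype[1], d$replicate[1]), "phenodiv_format_error")
    }
    if (sum(d$emerged) > d$sown[1]) {
      pd_error(sprintf("more seedlings than seeds sown for genotype %s replicate %d",
                       d$genotype[1], d$replicate[1]), "phenodiv_format_error")
    }
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("emergence_counts", "data.frame"), window = window)
}

#' Read daily emergence counts from CSV
#'
#' @param path CSV with columns `genotype`, `replicate`, `day`, `emerged`,
#'   `sown`.
#' @param cumulative Counts are cumulative and must be differenced.
#' @param dec Decimal separator (counts are integers; kept for symmetry).
#' @param window Observation window in days.
#' @return An `emergence_counts` table.
#' @export
read_emergence_counts <- function(path, cumulative = FALSE, dec = ".", window = 90) {
  if (!file.exists(path)) {
    pd_error(sprintf("input file not found: %s", path), "phenodiv_format_error")
  }
  as_emergence_counts(utils::read.csv(path, dec = dec, stringsAsFactors = FALSE),
                      cumulative = cumulative, window = window)
}

#' Emergence percentage of one replicate
#'
#' `SE = 100 * (total emerged) / (seeds sown)`.
#'
#' @param days Integer days of the daily records.
#' @param emerged Newly emerged counts per day.
#' @param sown Seeds sown in the replicate.
#' @return Percentage in `[0, 100]`.
#' @export
emergence_percent <- function(days, emerged, sown) {
  if (sown <= 0) pd_error("seeds sown must be > 0", "phenodiv_format_error")
  100 * sum(emerged) / sown
}

#' Maguire's emergence speed index
#'
#' `ESI = sum_i n_i / t_i`: each day's newly emerged count divided by its
#' day after sowing, summed. Zero emergence gives 0.
#'
#' @param days Integer days.
#' @param emerged Newly emerged counts per day.
#' @return Index (seedlings/day).
#' @export
maguire_esi <- function(days, emerged) {
  if (!length(days)) return(0)
  sum(emerged / days)
}

#' Edmond-Drapalla mean emergence time
#'
#' `MET = sum_i n_i t_i / sum_i n_i`, the count-weighted mean day of
#' emergence. Undefined (`NA`) when nothing emerged.
#'
#' @param days Integer days.
#' @param emerged Newly emerged counts per day.
#' @return Days, or `NA_real_` for zero emergence.
#' @export
mean_emergence_time <- function(days, emerged) {
  tot <- sum(emerged)
  if (tot == 0) return(NA_real_)
  sum(emerged * days) / tot
}

#' Per-replicate emergence metrics
#'
#' @param counts An `emergence_counts` table.
#' @return Data frame `genotype`, `replicate`, `SE`, `ESI`, `MET` (one row
#'   per replicate; `MET` is `NA` where nothing emerged).
#' @export
emergence_metrics <- function(counts) {
  stopifnot(inherits(counts, "emergence_counts"))
  parts <- split(as.data.frame(counts),
                 interaction(counts$genotype, counts$replicate, drop = TRUE))
  rows <- lapply(parts, function(d) {
    data.frame(genotype = d$genotype[1], replicate = d$replicate[1],
               SE = emergence_percent(d$day, d$emerged, d$sown[1]),
               ESI = maguire_esi(d$day, d$emerged),
               MET = mean_emergence_time(d$day, d$emerged),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genotype emergence metric means
#'
#' Averages the per-replicate metrics over replicates. Replicates with zero
#' emergence contribute `SE = 0` and `ESI = 0` but are excluded from the
#' `MET` mean (their MET is undefined); excluded replicates are reported in
#' the `met_excluded` attribute.
#'
#' @param counts An `emergence_counts` table.
#' @return Data frame `genotype`, `SE`, `ESI`, `MET` (`MET` is `NA` when no
#'   replicate of the genotype emerged) with attribute `met_excluded`.
#' @export
genotype_emergence_means <- function(counts) {
  met <- emergence_metrics(counts)
  excluded <- met[is.na(met$MET), c("genotype", "replicate"), drop = FALSE]
  agg <- lapply(split(met, met$genotype), function(d) {
    data.frame(genotype = d$genotype[1], SE = mean(d$SE), ESI = mean(d$ESI),
               MET = if (all(is.na(d$MET))) NA_real_ else mean(d$MET, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(out, met_excluded = excluded)
}
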