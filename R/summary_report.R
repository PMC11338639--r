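#' Round half-up at a given number of decimals
#'
#' Reported percentages use round-half-up (not banker's rounding): printed
#' genome ratios such as 526/667 -> 79 % match half-up rounding.
#'
#' @param x Numeric vector.
#' @param decimals Number of decimals.
#' @return Rounded values.
#' @export
round_half_up <- function(x, decimals = 0L) {
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Percentage of a count ratio, rounded half-up
#'
#' @param numerator,denominator Nonnegative counts, numerator <= denominator,
#'   denominator > 0.
#' @param decimals Decimals to keep (default 1).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
proportion_pct <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be positive")
  stopifnot(numerator >= 0, numerator <= denominator)
  round_half_up(100 * numerator / denominator, decimals)
}

#' Count records by grouping keys
#'
#' One row per key combination plus a totals row; deterministic sort by key.
#' Grouped counts always partition the total.
#'
#' @param records data.frame carrying the grouping keys.
#' @param group_keys Character vector of column names to group by.
#' @return data.frame with the key columns, `n`, and a final totals row
#'   (keys = "total").
#' @export
summarize_counts <- function(records, group_keys) {
  missing <- setdiff(group_keys, names(records))
  if (length(missing) > 0) stop("unknown grouping key(s): ",
                                paste(missing, collapse = ", "))
  if (nrow(records) == 0) {
    out <- as.data.frame(as.list(stats::setNames(rep("total",
                                                     length(group_keys)),
                                                 group_keys)),
                         stringsAsFactors = FALSE)
    out$n <- 0L
    return(out)
  }
  keys <- lapply(group_keys, function(k) as.character(records[[k]]))
  names(keys) <- group_keys
  agg <- stats::aggregate(list(n = rep(1L, nrow(records))), by = keys, FUN = sum)
  agg <- agg[do.call(order, agg[group_keys]), , drop = FALSE]
  total <- agg[1, , drop = FALSE]
  total[group_keys] <- "total"
  total$n <- sum(agg$n)
  out <- rbind(agg, total)
  rownames(out) <- NULL
  out
}

#' Histogram of per-genome pCODH gene counts
#'
#' Number of genomes carrying one, two, three, ... validated pCODH genes
#' (genome-level dual of the per-gene clade table).
#'
#' @param validated data.frame with genome_id of validated pCODH genes (one
#'   row per gene).
#' @return data.frame genes_per_genome, n_genomes.
#' @export
pcodh_copy_histogram <- function(validated) {
  per_genome <- table(validated$genome_id)
  h <- table(factor(as.integer(per_genome)))
  data.frame(genes_per_genome = as.integer(names(h)),
             n_genomes = as.integer(h), stringsAsFactors = FALSE)
}
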