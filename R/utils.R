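# internal helpers shared across modules

# all intervals in the package are 0-based half-open; GRanges is 1-based
# inclusive, so conversion happens exactly here and nowhere else
as_granges <- function(tbl, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(tbl)) tbl$strand else "*"
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

check_strand <- function(strand, what = "feature") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf(
      "%s strand must be '+' or '-' (found %s)",
      what, paste(unique(strand[bad]), collapse = ", ")
    ))
  }
  invisible(strand)
}

check_intervals <- function(tbl, what = "interval") {
  if (any(tbl$start >= tbl$end)) {
    abort(sprintf("%s requires start < end (0-based half-open)", what))
  }
  invisible(tbl)
}

# interval bounds check against a chrom -> length lookup
check_bounds <- function(tbl, chrom_lengths, what = "feature") {
  len <- chrom_lengths[tbl$chrom]
  if (anyNA(len)) {
    missing <- unique(tbl$chrom[is.na(len)])
    abort(sprintf("%s on unknown chromosome: %s", what,
                  paste(missing, collapse = ", ")))
  }
  if (any(tbl$start < 0) || any(tbl$end > len)) {
    abort(sprintf("%s outside chromosome bounds", what))
  }
  invisible(tbl)
}

geometric_mean <- function(x) exp(mean(log(x)))

# round half away from zero, the convention used for printed percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count as an integer percentage
#'
#' Percentage of `numerator / denominator`, rounded half away from zero to a
#' whole percent, the convention used when reporting per-class antisense
#' proportions (for example 93/146 prints as 64).
#'
#' @param numerator,denominator Numeric vectors.
#' @return Integer vector of percentages.
#' @examples
#' format_percent(93, 146)
#' @export
format_percent <- function(numerator, denominator) {
  as.integer(round_half_up(100 * numerator / denominator))
}
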