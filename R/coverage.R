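# coverage_norm: strand-specific fragment coverage, size factors from
# spike-ins or ORF totals, FPKM and per-feature tag densities.

# add per-position coverage for a set of intervals on one chromosome vector
add_interval_coverage <- function(v, start, end) {
  # difference-array trick: +1 at start, -1 at end, cumulative sum
  d <- numeric(length(v) + 1L)
  tab_s <- tabulate(start + 1L, nbins = length(v))
  tab_e <- tabulate(end + 1L, nbins = length(v) + 1L)
  d[seq_along(v)] <- tab_s
  d <- d - tab_e
  v + cumsum(d[seq_along(v)])
}

#' Build strand-specific fragment coverage
#'
#' Position p on strand s takes the number of fragments (reads or read-pair
#' inserts) covering p on s.
#'
#' @param fragments Data frame with columns `chrom`, `start`, `end`,
#'   `strand`, and optionally `sample` (0-based half-open intervals).
#' @param annotation A [genome_annotation()] supplying chromosome lengths.
#' @return If `fragments` has a `sample` column with more than one value, a
#'   named list of [stranded_signal()] per sample; otherwise a single
#'   [stranded_signal()].
#' @export
build_fragment_coverage <- function(fragments, annotation) {
  fragments <- as_tibble(fragments)
  lens <- chrom_lengths(annotation)
  if (nrow(fragments) > 0) {
    check_strand(fragments$strand, "fragment")
    check_intervals(fragments, "fragment")
    check_bounds(fragments, lens, "fragment")
  }
  one_sample <- function(fr) {
    sig <- stranded_signal(lens)
    if (nrow(fr) == 0) return(sig)
    for (slot in c("plus", "minus")) {
      st <- if (slot == "plus") "+" else "-"
      sub <- fr[fr$strand == st, ]
      for (ch in unique(sub$chrom)) {
        rows <- sub[sub$chrom == ch, ]
        sig[[slot]][[ch]] <- add_interval_coverage(
          sig[[slot]][[ch]], rows$start, rows$end)
      }
    }
    sig
  }
  if ("sample" %in% names(fragments) &&
      length(unique(fragments$sample)) > 1) {
    lapply(split(fragments, fragments$sample), one_sample)
  } else {
    one_sample(fragments)
  }
}

size_factors_from_totals <- function(totals, what) {
  if (is.data.frame(totals)) {
    totals <- setNames(totals$total, totals$sample)
  }
  if (length(totals) == 0) abort(sprintf("no %s totals supplied", what))
  if (any(totals <= 0) || anyNA(totals)) {
    abort(sprintf("all %s totals must be > 0", what))
  }
  tibble(sample = names(totals),
         size_factor = as.numeric(totals) / geometric_mean(totals))
}

#' Size factors from spike-in totals
#'
#' `factor_i = total_i / geometric mean(totals)`; dividing each sample's
#' signal by its factor equalizes the spike-in signal across samples. The
#' factors have geometric mean 1.
#'
#' @param spike_counts Named numeric vector of per-sample spike-in totals,
#'   or a data frame with columns `sample` and `total`.
#' @return Tibble with columns `sample`, `size_factor`.
#' @export
spikein_size_factors <- function(spike_counts) {
  size_factors_from_totals(spike_counts, "spike-in")
}

#' Size factors from reads uniquely mapped on ORFs
#'
#' Used for datasets without spike-ins: tag densities are normalized on the
#' total number of reads uniquely mapped on ORFs.
#'
#' @param orf_counts Named numeric vector of per-sample ORF-mapped totals,
#'   or a data frame with columns `sample` and `total`.
#' @return Tibble with columns `sample`, `size_factor`.
#' @export
orf_size_factors <- function(orf_counts) {
  size_factors_from_totals(orf_counts, "ORF")
}

#' Median-of-ratios size factors from a count matrix
#'
#' The standard between-sample normalization used when neither spike-ins
#' nor an ORF-total convention applies: per-sample median of count ratios to
#' the per-feature geometric mean, rescaled to geometric mean 1.
#'
#' @param counts Numeric matrix, features x samples.
#' @return Tibble with columns `sample`, `size_factor`.
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  logmean <- rowMeans(log(counts))
  use <- is.finite(logmean)
  if (!any(use)) abort("no feature with all-positive counts")
  sf <- apply(counts[use, , drop = FALSE], 2, function(x) {
    exp(median(log(x) - logmean[use]))
  })
  tibble(sample = colnames(counts), size_factor = sf / geometric_mean(sf))
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / (feature_length / 1000) / (library_size / 1e6)`.
#'
#' @param count Fragments on the feature (vectorized).
#' @param feature_length Feature length in nt (> 0).
#' @param library_size Total mapped fragments in the library (> 0),
#'   excluding spike-ins.
#' @return Numeric FPKM values.
#' @examples
#' fpkm(10, 1000, 1e6) # 10
#' @export
fpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) abort("feature_length must be > 0")
  if (any(library_size <= 0)) abort("library_size must be > 0")
  count / (feature_length / 1000) / (library_size / 1e6)
}

#' Per-feature normalized tag density
#'
#' Density of a feature is the summed per-position signal over the feature
#' interval on the feature's strand, divided by feature length and by the
#' sample's size factor (tags/nt).
#'
#' @param signal A [stranded_signal()].
#' @param features Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param size_factor Positive scale factor for the sample (default 1).
#' @return Tibble with columns `id`, `density`.
#' @export
feature_density <- function(signal, features, size_factor = 1) {
  features <- as_tibble(features)
  check_bounds(features, attr(signal, "chrom_lengths"), "feature")
  dens <- vapply(seq_len(nrow(features)), function(i) {
    slot <- strand_slot(features$strand[i])
    v <- signal[[slot]][[features$chrom[i]]]
    sum(v[(features$start[i] + 1):features$end[i]]) /
      (features$end[i] - features$start[i])
  }, numeric(1))
  tibble(id = features$id, density = dens / size_factor)
}

#' Count fragments per feature and sample
#'
#' A fragment is assigned to a feature when its midpoint falls inside the
#' feature interval on the same strand, so each fragment counts at most
#' once per disjoint feature set.
#'
#' @param fragments Data frame with columns `chrom`, `start`, `end`,
#'   `strand`, `sample`.
#' @param features Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param samples Optional character vector fixing the column order.
#' @return Integer matrix, features x samples, with feature ids as rownames.
#' @export
count_fragments <- function(fragments, features, samples = NULL) {
  fragments <- as_tibble(fragments)
  features <- as_tibble(features)
  if (is.null(samples)) samples <- sort(unique(fragments$sample))
  mat <- matrix(0L, nrow = nrow(features), ncol = length(samples),
                dimnames = list(features$id, samples))
  if (nrow(fragments) == 0 || nrow(features) == 0) return(mat)
  mid <- (fragments$start + fragments$end) %/% 2L
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom, IRanges::IRanges(mid + 1L, width = 1L),
    strand = fragments$strand)
  feat_gr <- as_granges(features)
  hits <- GenomicRanges::findOverlaps(frag_gr, feat_gr)
  if (length(hits) > 0) {
    idx <- tibble(
      feature = S4Vectors::subjectHits(hits),
      sample = fragments$sample[S4Vectors::queryHits(hits)]
    )
    tab <- table(factor(idx$feature, levels = seq_len(nrow(features))),
                 factor(idx$sample, levels = samples))
    mat <- matrix(as.integer(tab), nrow = nrow(features),
                  dimnames = list(features$id, samples))
  }
  mat
}
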