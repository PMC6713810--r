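# antisense_analysis: antisense/solo partition, sense-antisense overlap
# lengths, cumulative coding coverage, and the rank statistics behind the
# per-class box-plot comparisons.

#' Flag antisense transcripts and find their paired-sense mates
#'
#' A transcript is antisense when it intersects a feature of the chosen
#' universe on the opposite strand by at least one nucleotide; otherwise it
#' is solo. The mate is the feature with the largest overlap, ties broken by
#' the leftmost feature start.
#'
#' @param transcripts Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param features Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (and `kind` when `universe = "orf"`).
#' @param universe `"orf"` (default: only ORF features count) or `"all"`
#'   (any feature of `features` counts).
#' @return `transcripts` with added columns `antisense` (logical),
#'   `mate_id`, `overlap_bp` (NA/0 for solo transcripts).
#' @export
annotate_antisense <- function(transcripts, features,
                               universe = c("orf", "all")) {
  universe <- match.arg(universe)
  transcripts <- as_tibble(transcripts)
  features <- as_tibble(features)
  if (universe == "orf" && "kind" %in% names(features)) {
    features <- features[features$kind == "ORF", ]
  }
  transcripts$antisense <- FALSE
  transcripts$mate_id <- NA_character_
  transcripts$overlap_bp <- 0L
  if (nrow(transcripts) == 0 || nrow(features) == 0) return(transcripts)
  # flip transcript strands so same-strand overlap search = antisense
  flipped <- transcripts
  flipped$strand <- ifelse(transcripts$strand == "+", "-", "+")
  hits <- GenomicRanges::findOverlaps(
    as_granges(flipped), as_granges(features), minoverlap = 1L,
    ignore.strand = FALSE)
  if (length(hits) == 0) return(transcripts)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(transcripts$end[qi], features$end[si]) -
        pmax(transcripts$start[qi], features$start[si])
  cand <- tibble(q = qi, s = si, ov = ov,
                 mate_start = features$start[si])
  best <- cand |>
    arrange(.data$q, dplyr::desc(.data$ov), .data$mate_start) |>
    distinct(.data$q, .keep_all = TRUE)
  transcripts$antisense[best$q] <- TRUE
  transcripts$mate_id[best$q] <- features$id[best$s]
  transcripts$overlap_bp[best$q] <- as.integer(best$ov)
  transcripts
}

#' Overlap lengths of antisense pairs
#'
#' @param pairs Output of [annotate_antisense()] (antisense rows).
#' @return Tibble with columns `id`, `mate_id`, `overlap_bp`.
#' @export
overlap_lengths <- function(pairs) {
  pairs <- as_tibble(pairs)
  if ("antisense" %in% names(pairs)) pairs <- pairs[pairs$antisense, ]
  pairs[, c("id", "mate_id", "overlap_bp")]
}

#' Cumulative coverage of coding regions by antisense transcripts
#'
#' For each transcript set (and their union), the percentage of coding-
#' strand bases whose opposite strand is covered by at least one transcript
#' of the set. The denominator counts each coding base once even where ORFs
#' overlap.
#'
#' @param transcript_sets Named list of data frames (columns `chrom`,
#'   `start`, `end`, `strand`), e.g. one per lncRNA class.
#' @param orfs Data frame of coding features (columns `chrom`, `start`,
#'   `end`, `strand`).
#' @return Tibble with columns `set`, `covered`, `total`, `fraction`
#'   (percent); one row per set plus a `union` row when more than one set
#'   is given.
#' @export
cumulative_coding_coverage <- function(transcript_sets, orfs) {
  if (is.data.frame(transcript_sets)) {
    transcript_sets <- list(transcripts = transcript_sets)
  }
  orfs <- as_tibble(orfs)
  orf_gr <- as_granges(orfs)
  total <- sum(IRanges::width(GenomicRanges::reduce(orf_gr)))
  one <- function(tx) {
    tx <- as_tibble(tx)
    if (nrow(tx) == 0 || total == 0) return(0)
    flipped <- tx
    flipped$strand <- ifelse(tx$strand == "+", "-", "+")
    inter <- GenomicRanges::intersect(
      GenomicRanges::reduce(orf_gr),
      GenomicRanges::reduce(as_granges(flipped)))
    sum(IRanges::width(inter))
  }
  covered <- vapply(transcript_sets, one, numeric(1))
  out <- tibble(set = names(transcript_sets), covered = covered,
                total = total,
                fraction = ifelse(total > 0, 100 * covered / total, 0))
  if (length(transcript_sets) > 1) {
    un <- one(bind_rows(lapply(transcript_sets, function(x)
      as_tibble(x)[, c("chrom", "start", "end", "strand")])))
    out <- bind_rows(out, tibble(set = "union", covered = un, total = total,
                                 fraction = ifelse(total > 0,
                                                   100 * un / total, 0)))
  }
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the smaller group has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return Tibble with columns `n_x`, `n_y`, `statistic` (Mann-Whitney U of
#'   `x`), `p`, `exact`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  tibble(n_x = length(x), n_y = length(y),
         statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Compare a metric between two transcript sets
#'
#' Applies the sub-`min_len_filter` removal to both inputs (to avoid a size
#' bias when one annotation set contains short transcripts), then reports
#' group medians and the two-sided rank-sum test. When called through a
#' family of comparisons, adjust the returned P-values with [bh_adjust()]
#' across that family.
#'
#' @param set_a,set_b Data frames with a `length` column (nt) and, for
#'   `metric = "overlap_bp"`, an `overlap_bp` column.
#' @param metric `"size"` (transcript length) or `"overlap_bp"`.
#' @param min_len_filter Minimum transcript length kept (default 200 nt).
#' @return One-row tibble: `metric`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `statistic`, `p`.
#' @export
compare_sets <- function(set_a, set_b, metric = c("size", "overlap_bp"),
                         min_len_filter = 200) {
  metric <- match.arg(metric)
  pick <- function(s) {
    s <- as_tibble(s)
    if (!"length" %in% names(s)) s$length <- s$end - s$start
    s <- s[s$length >= min_len_filter, ]
    if (metric == "size") s$length else s$overlap_bp
  }
  a <- pick(set_a)
  b <- pick(set_b)
  wt <- wilcoxon_ranksum(a, b)
  tibble(metric = metric, n_a = length(a), n_b = length(b),
         median_a = median(a), median_b = median(b),
         statistic = wt$statistic, p = wt$p)
}

#' Box-plot style comparison of solo versus antisense densities
#'
#' @param densities Data frame with columns `class`, `antisense` (logical),
#'   `density`.
#' @return Tibble with one row per class: group sizes, medians, two-sided
#'   rank-sum `p` and BH-adjusted `padj` across the classes of this report.
#' @export
solo_antisense_tests <- function(densities) {
  densities <- as_tibble(densities)
  res <- densities |>
    group_by(.data$class) |>
    summarise(
      n_antisense = sum(.data$antisense),
      n_solo = sum(!.data$antisense),
      median_antisense = median(.data$density[.data$antisense]),
      median_solo = median(.data$density[!.data$antisense]),
      p = if (sum(.data$antisense) > 0 && sum(!.data$antisense) > 0) {
        wilcoxon_ranksum(.data$density[.data$antisense],
                         .data$density[!.data$antisense])$p
      } else NA_real_,
      .groups = "drop"
    )
  ok <- !is.na(res$p)
  res$padj <- NA_real_
  res$padj[ok] <- bh_adjust(res$p[ok])
  res
}

#' Box plot of per-feature densities by class and antisense status
#'
#' @param densities Data frame with columns `class`, `antisense`, `density`.
#' @param log2_scale Plot density on a log2 axis (default TRUE).
#' @return A ggplot object.
#' @export
plot_density_box <- function(densities, log2_scale = TRUE) {
  densities <- as_tibble(densities)
  densities$group <- ifelse(densities$antisense, "antisense", "solo")
  p <- ggplot2::ggplot(densities,
                       ggplot2::aes(x = .data$class, y = .data$density,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::scale_fill_manual(values = c(antisense = "grey80",
                                          solo = "grey40")) +
    ggplot2::labs(x = NULL, y = "density (tag/nt)", fill = NULL) +
    ggplot2::theme_minimal()
  if (log2_scale) {
    p <- p + ggplot2::scale_y_continuous(trans = "log2")
  }
  p
}
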