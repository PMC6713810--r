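# smallrna_profiles: size x 5'-base profiling, 22-23-nt siRNA filtering,
# heterologous spike-in normalization and genotype density ratios.

RNA_BASES <- c("A", "C", "G", "U")

#' Size by 5'-base count matrix of small-RNA reads
#'
#' Counts uniquely mapped reads by (length, 5' base), in the RNA alphabet
#' (genomic T is reported as U). Reads overlapping features of the excluded
#' kinds (default tRNA and rRNA, on either strand) are dropped first.
#'
#' @param reads Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `length`, `first_base`, `unique`.
#' @param annotation Optional [genome_annotation()] supplying the features
#'   used for exclusion.
#' @param exclude_kinds Feature kinds whose overlapping reads are excluded.
#' @return Tibble with columns `length`, `first_base`, `count`, one row per
#'   observed (length, base) cell (long form; pivot for a matrix).
#' @export
size_base_matrix <- function(reads, annotation = NULL,
                             exclude_kinds = c("tRNA", "rRNA")) {
  reads <- as_tibble(reads)
  if ("unique" %in% names(reads)) reads <- reads[reads$unique, ]
  if (nrow(reads) > 0) {
    reads$first_base <- toupper(reads$first_base)
    reads$first_base[reads$first_base == "T"] <- "U"
    bad <- !reads$first_base %in% RNA_BASES
    if (any(bad)) {
      abort(paste0("invalid 5' base(s): ",
                   paste(unique(reads$first_base[bad]), collapse = ", ")))
    }
  }
  if (!is.null(annotation) && nrow(reads) > 0) {
    excl <- annotation$features[annotation$features$kind %in% exclude_kinds, ]
    if (nrow(excl) > 0) {
      hits <- GenomicRanges::findOverlaps(
        as_granges(reads), as_granges(excl), ignore.strand = TRUE)
      drop <- unique(S4Vectors::queryHits(hits))
      if (length(drop) > 0) reads <- reads[-drop, ]
    }
  }
  if (nrow(reads) == 0) {
    return(tibble(length = integer(), first_base = character(),
                  count = integer()))
  }
  reads |>
    dplyr::count(.data$length, .data$first_base, name = "count") |>
    arrange(.data$length, .data$first_base)
}

#' Keep bona fide siRNA reads
#'
#' Retains reads of length 22 or 23 nt, uniquely mapped, from the target
#' genome (spike reads are excluded). Idempotent.
#'
#' @param reads Data frame with columns `length`, `unique` and optionally
#'   `genome_tag`.
#' @return The kept rows.
#' @export
filter_sirna <- function(reads) {
  reads <- as_tibble(reads)
  keep <- reads$length %in% c(22L, 23L) & reads$unique
  if ("genome_tag" %in% names(reads)) {
    keep <- keep & reads$genome_tag == "target"
  }
  reads[keep, ]
}

#' Size factors from heterologous siRNA spike-ins
#'
#' Totals of 22-23-nt spike-genome reads per sample, scaled to geometric
#' mean 1; densities divided by these factors are comparable across
#' samples.
#'
#' @param reads Data frame with columns `sample`, `length`, `genome_tag`
#'   (spike reads tagged `"spike"`), or a named numeric vector / data frame
#'   of per-sample totals as for [spikein_size_factors()].
#' @param samples Optional character vector of expected samples; a sample
#'   with no spike reads is an error.
#' @return Tibble with columns `sample`, `size_factor`.
#' @export
sirna_size_factors <- function(reads, samples = NULL) {
  if (is.data.frame(reads) && all(c("sample", "length") %in% names(reads))) {
    reads <- as_tibble(reads)
    spike <- reads[reads$length %in% c(22L, 23L), ]
    if ("genome_tag" %in% names(spike)) {
      spike <- spike[spike$genome_tag == "spike", ]
    }
    totals <- table(spike$sample)
    totals <- setNames(as.numeric(totals), names(totals))
    if (!is.null(samples)) {
      missing <- setdiff(samples, names(totals))
      if (length(missing) > 0) {
        abort(paste0("no 22-23-nt spike reads for sample(s): ",
                     paste(missing, collapse = ", ")))
      }
      totals <- totals[samples]
    }
  } else {
    totals <- reads
  }
  size_factors_from_totals(totals, "siRNA spike")
}

#' Normalized siRNA density over features
#'
#' Density is the 22-23-nt read-base coverage summed over the feature,
#' divided by feature length and by the sample's size factor (tag/nt).
#'
#' @param sirna_reads Filtered reads ([filter_sirna()]) for one sample, with
#'   columns `chrom`, `start`, `end`, `strand`.
#' @param features Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param size_factor Positive scale factor for the sample (default 1).
#' @param annotation A [genome_annotation()] supplying chromosome lengths.
#' @param stranded Count only reads on the feature strand (default FALSE:
#'   siRNAs from a double-stranded precursor map to both strands).
#' @return Tibble with columns `id`, `density`.
#' @export
sirna_feature_density <- function(sirna_reads, features, size_factor = 1,
                                  annotation = NULL, stranded = FALSE) {
  sirna_reads <- as_tibble(sirna_reads)
  features <- as_tibble(features)
  if (is.null(annotation)) {
    lens_tbl <- bind_rows(
      sirna_reads[, c("chrom", "end")], features[, c("chrom", "end")])
    lens <- tapply(lens_tbl$end, lens_tbl$chrom, max)
    lens <- setNames(as.numeric(lens), names(lens))
  } else {
    lens <- chrom_lengths(annotation)
  }
  sig <- build_fragment_coverage(
    sirna_reads[, c("chrom", "start", "end", "strand")],
    genome_annotation(lens, tibble(id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), kind = character())))
  dens <- vapply(seq_len(nrow(features)), function(i) {
    idx <- (features$start[i] + 1):features$end[i]
    tot <- if (stranded) {
      sum(sig[[strand_slot(features$strand[i])]][[features$chrom[i]]][idx])
    } else {
      sum(sig$plus[[features$chrom[i]]][idx]) +
        sum(sig$minus[[features$chrom[i]]][idx])
    }
    tot / (features$end[i] - features$start[i])
  }, numeric(1))
  tibble(id = features$id, density = dens / size_factor)
}

#' Per-feature log2 density ratio between two genotypes
#'
#' `log2((d_a + pseudo) / (d_b + pseudo))` over matched feature sets. The
#' default pseudo-density is half the smallest non-zero density in either
#' input, which keeps zero-density features finite without dominating the
#' ratio of expressed features.
#'
#' @param densities_a,densities_b Tibbles with columns `id`, `density`
#'   (matched ids).
#' @param pseudo Pseudo-density; default as described above.
#' @return Tibble with columns `id`, `log2_ratio`.
#' @export
genotype_density_ratio <- function(densities_a, densities_b, pseudo = NULL) {
  a <- as_tibble(densities_a)
  b <- as_tibble(densities_b)
  if (!setequal(a$id, b$id)) abort("feature ids do not match between genotypes")
  b <- b[match(a$id, b$id), ]
  if (is.null(pseudo)) {
    nz <- c(a$density[a$density > 0], b$density[b$density > 0])
    pseudo <- if (length(nz) > 0) min(nz) / 2 else 1
  }
  tibble(id = a$id,
         log2_ratio = log2((a$density + pseudo) / (b$density + pseudo)))
}

#' Bar plot of the small-RNA size and 5'-base distribution
#'
#' @param matrix_long Output of [size_base_matrix()].
#' @return A ggplot object: read counts by length, filled by 5' base.
#' @export
plot_size_base_matrix <- function(matrix_long) {
  ggplot2::ggplot(as_tibble(matrix_long),
                  ggplot2::aes(x = factor(.data$length), y = .data$count,
                               fill = .data$first_base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "reads", fill = "5' base") +
    ggplot2::theme_minimal()
}
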