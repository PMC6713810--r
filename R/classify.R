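# lncrna_classify: novelty filter, decay-class decision rules with
# precedence, and overlap-based deduplication between annotation sets.

LNC_CLASSES <- c("SUT", "CUT", "XUT", "DUT")

#' Novelty filter for candidate segments
#'
#' Keeps segments at least `min_len` nt long with zero same-strand overlap
#' (a single overlapping nucleotide disqualifies) with any feature of the
#' excluded kinds. Opposite-strand overlap, e.g. a candidate antisense to an
#' ORF, does not disqualify.
#'
#' @param segments Data frame with columns `chrom`, `start`, `end`, `strand`.
#' @param annotation A [genome_annotation()].
#' @param min_len Minimum segment length in nt (default 200).
#' @param excluded_kinds Feature kinds that disqualify on same-strand
#'   overlap (default ORF, tRNA, snRNA, snoRNA, rRNA).
#' @return The kept rows of `segments`.
#' @export
novelty_filter <- function(segments, annotation, min_len = 200,
                           excluded_kinds = c("ORF", "tRNA", "snRNA",
                                              "snoRNA", "rRNA")) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0) return(segments)
  keep_len <- (segments$end - segments$start) >= min_len
  excl <- annotation$features[annotation$features$kind %in% excluded_kinds, ]
  if (nrow(excl) == 0) return(segments[keep_len, ])
  hits <- GenomicRanges::findOverlaps(
    as_granges(segments), as_granges(excl), minoverlap = 1L,
    ignore.strand = FALSE)
  overlapping <- logical(nrow(segments))
  overlapping[unique(S4Vectors::queryHits(hits))] <- TRUE
  segments[keep_len & !overlapping, ]
}

#' Assign decay classes to filtered segments
#'
#' Applies the class decision rules to segments carrying per-contrast
#' sensitivity calls:
#' * from the main segmentation set: `XUT` when Xrn1-sensitive (this takes
#'   precedence: a transcript sensitive to both Dicer and Xrn1 is an XUT),
#'   `DUT` when Dicer-sensitive and not Xrn1-sensitive, putative `SUT`
#'   when insensitive in every contrast but expressed at `>= sut_min_fpkm`
#'   FPKM in the wild type;
#' * from the exosome-mutant segmentation set: `CUT` when Rrp6-sensitive.
#'
#' Segments matching no rule are dropped. Sensitivity columns absent from
#' the input are treated as all-FALSE; cross-sensitivity flags present on
#' the input are carried through unchanged.
#'
#' @param segments Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, a `set` column in `{"main", "rrp6"}`, and logical columns
#'   among `sensitive_dcr1`, `sensitive_xrn1`, `sensitive_rrp6`, plus
#'   `fpkm_wt`.
#' @param sut_min_fpkm Wild-type FPKM gate for putative SUTs (default 1).
#' @return Tibble of classified transcripts with a `class` column; putative
#'   SUTs are labeled `"SUT"` and still require [dedup_suts()].
#' @export
assign_classes <- function(segments, sut_min_fpkm = 1) {
  segments <- as_tibble(segments)
  if (anyDuplicated(segments$id)) abort("duplicate segment ids")
  for (col in c("sensitive_dcr1", "sensitive_xrn1", "sensitive_rrp6")) {
    if (!col %in% names(segments)) segments[[col]] <- FALSE
  }
  if (!"set" %in% names(segments)) segments$set <- "main"
  if (!"fpkm_wt" %in% names(segments)) segments$fpkm_wt <- NA_real_
  main <- segments$set == "main"
  cls <- dplyr::case_when(
    !main & segments$sensitive_rrp6 ~ "CUT",
    main & segments$sensitive_xrn1 ~ "XUT",
    main & segments$sensitive_dcr1 ~ "DUT",
    main & segments$fpkm_wt >= sut_min_fpkm ~ "SUT",
    .default = NA_character_
  )
  segments$class <- cls
  segments[!is.na(cls), ]
}

#' Fraction of interval a covered by interval b
#'
#' `|a intersect b| / |a|`, in `[0, 1]`. Vectorized; strand handling is the
#' caller's responsibility.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (0-based half-open).
#' @return Numeric fractions.
#' @export
overlap_fraction <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  inter / (a_end - a_start)
}

# largest fraction of each `a` interval covered by any `b` interval
max_overlap_fraction <- function(a, b, same_strand = TRUE) {
  if (nrow(a) == 0) return(numeric(0))
  frac <- numeric(nrow(a))
  if (nrow(b) == 0) return(frac)
  hits <- GenomicRanges::findOverlaps(
    as_granges(a), as_granges(b), ignore.strand = !same_strand)
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    f <- overlap_fraction(a$start[qi], a$end[qi], b$start[si], b$end[si])
    best <- tapply(f, qi, max)
    frac[as.integer(names(best))] <- best
  }
  frac
}

#' Deduplicate putative SUTs against CUTs
#'
#' Putative SUTs whose interval is overlapped strictly more than `min_frac`
#' by any CUT are removed: they are exosome-sensitive transcripts already
#' annotated in the other set, not stable transcripts.
#'
#' @param putative_suts,cuts Data frames with columns `chrom`, `start`,
#'   `end`, `strand`.
#' @param min_frac Overlap fraction above which a putative SUT is removed
#'   (strict `>`, default 0.5).
#' @param same_strand Require the CUT on the same strand (default TRUE).
#' @return The kept rows of `putative_suts`.
#' @export
dedup_suts <- function(putative_suts, cuts, min_frac = 0.5,
                       same_strand = TRUE) {
  putative_suts <- as_tibble(putative_suts)
  if (nrow(putative_suts) == 0) return(putative_suts)
  frac <- max_overlap_fraction(putative_suts, as_tibble(cuts), same_strand)
  putative_suts[frac <= min_frac, ]
}

#' Cross-class overlap between CUTs and XUTs
#'
#' Reports CUTs with at least `min_frac` (inclusive) of their length covered
#' by an XUT; the fraction is always of the CUT.
#'
#' @param cuts,xuts Data frames with columns `id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param min_frac Inclusive overlap fraction (default 0.5).
#' @param same_strand Require same-strand overlap (default TRUE).
#' @return Tibble with columns `cut_id`, `xut_id`, `fraction`, one row per
#'   qualifying (CUT, XUT) pair.
#' @export
cross_class_overlap <- function(cuts, xuts, min_frac = 0.5,
                                same_strand = TRUE) {
  cuts <- as_tibble(cuts)
  xuts <- as_tibble(xuts)
  empty <- tibble(cut_id = character(), xut_id = character(),
                  fraction = numeric())
  if (nrow(cuts) == 0 || nrow(xuts) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(
    as_granges(cuts), as_granges(xuts), ignore.strand = !same_strand)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  frac <- overlap_fraction(cuts$start[qi], cuts$end[qi],
                           xuts$start[si], xuts$end[si])
  keep <- frac >= min_frac
  tibble(cut_id = cuts$id[qi][keep], xut_id = xuts$id[si][keep],
         fraction = frac[keep])
}
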