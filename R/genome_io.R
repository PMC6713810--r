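# genome_io: standard-format input/output and the single internal
# coordinate convention (0-based half-open everywhere; 1-based only at the
# GFF3/GRanges boundary, handled in as_granges()/from_granges()).

FEATURE_KINDS <- c("ORF", "tRNA", "snRNA", "snoRNA", "rRNA", "lncRNA")

# default mapping from GFF3 "type" column to the internal feature kinds
DEFAULT_KIND_MAP <- c(
  gene = "ORF", CDS = "ORF", ORF = "ORF", mRNA = "ORF",
  tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA", rRNA = "rRNA",
  ncRNA = "lncRNA", lncRNA = "lncRNA", lnc_RNA = "lncRNA"
)

#' Construct a genome annotation
#'
#' Bundles chromosome lengths with a feature table under the package's
#' internal coordinate convention (0-based half-open intervals, strands
#' restricted to `+`/`-`).
#'
#' @param chromosomes Named numeric vector of chromosome lengths (nt), or a
#'   data frame with columns `chrom` and `length`.
#' @param features Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `kind`. `kind` must be one of ORF, tRNA, snRNA, snoRNA,
#'   rRNA, lncRNA.
#' @return An object of class `genome_annotation`: a list with elements
#'   `chromosomes` (tibble `chrom`, `length`) and `features` (tibble).
#' @export
genome_annotation <- function(chromosomes, features) {
  if (is.data.frame(chromosomes)) {
    chrom_tbl <- as_tibble(chromosomes)[, c("chrom", "length")]
  } else {
    chrom_tbl <- tibble(chrom = names(chromosomes),
                        length = as.numeric(chromosomes))
  }
  features <- as_tibble(features)
  required <- c("id", "chrom", "start", "end", "strand", "kind")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    abort(paste0("features is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  features <- features[, union(required, names(features))]
  bad_kind <- setdiff(unique(features$kind), FEATURE_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste0("unknown feature kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  check_strand(features$strand)
  if (nrow(features) > 0) {
    check_intervals(features, "feature")
    check_bounds(features, chrom_lengths(chrom_tbl), "feature")
  }
  structure(list(chromosomes = chrom_tbl, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d chromosome(s), %s nt, %d feature(s)\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              nrow(x$features)))
  if (nrow(x$features) > 0) {
    print(table(x$features$kind))
  }
  invisible(x)
}

# named chrom -> length lookup from either an annotation or its chrom table
chrom_lengths <- function(x) {
  tbl <- if (inherits(x, "genome_annotation")) x$chromosomes else x
  setNames(tbl$length, tbl$chrom)
}

# light line-level validation so malformed input errors name the line
validate_tab_file <- function(path, min_fields, numeric_fields,
                              comment = "#") {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, comment) ||
        startsWith(line, "track") || startsWith(line, "browser")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < min_fields) {
      abort(sprintf("%s: malformed line %d (expected >= %d tab-separated fields)",
                    path, i, min_fields))
    }
    vals <- suppressWarnings(as.numeric(fields[numeric_fields]))
    if (anyNA(vals)) {
      abort(sprintf("%s: malformed line %d (non-numeric coordinate)", path, i))
    }
  }
  invisible(lines)
}

from_granges <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a genome annotation from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) and BED coordinates (0-based
#' half-open) are both converted to the internal 0-based half-open
#' convention on input. Chromosome lengths come from `##sequence-region`
#' pragmas (GFF3) or must be supplied via `chrom_lengths` (BED). BED input
#' must carry the feature kind in a 7th column.
#'
#' @param path Path to a GFF3 or BED file.
#' @param format `"auto"` (from the extension), `"gff3"`, or `"bed"`.
#' @param chrom_lengths Named vector of chromosome lengths; required for BED,
#'   overrides pragmas for GFF3.
#' @param kind_map Named character vector mapping GFF3 `type` values to
#'   internal kinds; unknown types are an error.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed"),
                            chrom_lengths = NULL, kind_map = DEFAULT_KIND_MAP) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path)) "gff3" else "bed"
  }
  if (format == "gff3") {
    lines <- validate_tab_file(path, min_fields = 8, numeric_fields = c(4, 5))
    if (is.null(chrom_lengths)) {
      pragma <- grep("^##sequence-region", lines, value = TRUE)
      if (length(pragma) == 0) {
        abort("GFF3 file has no ##sequence-region pragmas; supply chrom_lengths")
      }
      parts <- strsplit(trimws(pragma), "\\s+")
      chrom_lengths <- setNames(
        vapply(parts, function(p) as.numeric(p[[4]]), numeric(1)),
        vapply(parts, function(p) p[[2]], character(1))
      )
    }
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    type <- as.character(mc$type)
    unknown <- setdiff(unique(type), names(kind_map))
    if (length(unknown) > 0) {
      abort(paste0("unknown GFF3 feature type(s): ",
                   paste(unknown, collapse = ", ")))
    }
    ids <- if (!is.null(mc$ID)) as.character(mc$ID) else NA_character_
    if (anyNA(ids) && !is.null(mc$Name)) {
      ids[is.na(ids)] <- as.character(mc$Name)[is.na(ids)]
    }
    feats <- from_granges(gr)
    feats$id <- ids
    feats$kind <- unname(kind_map[type])
  } else {
    validate_tab_file(path, min_fields = 7, numeric_fields = c(2, 3))
    gr <- rtracklayer::import(path, format = "bed",
                              extraCols = c(kind = "character"))
    if (is.null(chrom_lengths)) {
      abort("BED annotation input requires chrom_lengths")
    }
    feats <- from_granges(gr)
    feats$id <- as.character(S4Vectors::mcols(gr)$name)
    feats$kind <- as.character(S4Vectors::mcols(gr)$kind)
  }
  feats <- feats[, c("id", "chrom", "start", "end", "strand", "kind")]
  genome_annotation(chrom_lengths, feats)
}

#' Write a genome annotation to GFF3
#'
#' Serializes features back to 1-based inclusive GFF3 with
#' `##sequence-region` pragmas so that [read_annotation()] round-trips.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  feats <- annotation$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d",
                     annotation$chromosomes$chrom,
                     as.integer(annotation$chromosomes$length)), con)
  if (nrow(feats) > 0) {
    gff_type <- ifelse(feats$kind == "ORF", "gene", feats$kind)
    writeLines(sprintf("%s\tcrypticlnc\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       feats$chrom, gff_type,
                       as.integer(feats$start) + 1L, as.integer(feats$end),
                       feats$strand, feats$id), con)
  }
  invisible(path)
}

#' Construct an all-zero stranded coverage signal
#'
#' A stranded signal holds one non-negative numeric vector per
#' (chromosome, strand), with vector length equal to the chromosome length
#' (tags/nt at each position).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths, or a
#'   [genome_annotation()].
#' @return An object of class `stranded_signal`.
#' @export
stranded_signal <- function(chrom_lengths) {
  if (inherits(chrom_lengths, "genome_annotation")) {
    chrom_lengths <- chrom_lengths(chrom_lengths)
  }
  zero <- lapply(chrom_lengths, function(n) numeric(n))
  structure(list(plus = zero, minus = zero),
            chrom_lengths = chrom_lengths, class = "stranded_signal")
}

#' @export
print.stranded_signal <- function(x, ...) {
  lens <- attr(x, "chrom_lengths")
  tot_p <- sum(vapply(x$plus, sum, numeric(1)))
  tot_m <- sum(vapply(x$minus, sum, numeric(1)))
  cat(sprintf("<stranded_signal> %d chromosome(s), %s nt; total signal +%g / -%g\n",
              length(lens), format(sum(lens), big.mark = ","), tot_p, tot_m))
  invisible(x)
}

strand_slot <- function(strand) {
  check_strand(strand, "signal")
  if (strand == "+") "plus" else "minus"
}

#' Read per-base coverage from a bedGraph file
#'
#' Builds the dense per-position array for one strand; positions absent from
#' the file are zero. Records must not overlap and values must be
#' non-negative.
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param annotation A [genome_annotation()] (supplies chromosome lengths).
#' @param strand `"+"` or `"-"`: which strand the file describes.
#' @return A [stranded_signal()] with the given strand filled.
#' @export
read_coverage <- function(path, annotation, strand) {
  slot <- strand_slot(strand)
  lens <- chrom_lengths(annotation)
  sig <- stranded_signal(lens)
  if (file.size(path) == 0) return(sig)
  validate_tab_file(path, min_fields = 4, numeric_fields = c(2, 3, 4))
  gr <- rtracklayer::import(path, format = "bedGraph")
  tbl <- from_granges(gr)
  tbl$value <- as.numeric(S4Vectors::mcols(gr)$score)
  if (nrow(tbl) == 0) return(sig)
  if (any(tbl$value < 0)) abort(sprintf("%s: negative coverage value", path))
  check_bounds(tbl, lens, "coverage record")
  for (ch in unique(tbl$chrom)) {
    rows <- tbl[tbl$chrom == ch, ]
    rows <- rows[order(rows$start), ]
    if (nrow(rows) > 1 && any(rows$start[-1] < rows$end[-nrow(rows)])) {
      abort(sprintf("%s: overlapping bedGraph records on %s", path, ch))
    }
    v <- sig[[slot]][[ch]]
    for (i in seq_len(nrow(rows))) {
      v[(rows$start[i] + 1):rows$end[i]] <- rows$value[i]
    }
    sig[[slot]][[ch]] <- v
  }
  sig
}

#' Write one strand of a stranded signal as bedGraph
#'
#' Zero runs are omitted, so [read_coverage()] round-trips the signal.
#'
#' @param signal A [stranded_signal()].
#' @param path Output path.
#' @param strand `"+"` or `"-"`.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(signal, path, strand) {
  slot <- strand_slot(strand)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(signal[[slot]])) {
    v <- signal[[slot]][[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", ch,
                         as.integer(starts[keep]), as.integer(ends[keep]),
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Write classified transcripts to BED6 or GFF3
#'
#' The class label travels in the BED name field (`id|class`) or in the GFF3
#' `class` attribute, so [read_transcripts()] recovers identical intervals,
#' strands and class labels.
#'
#' @param transcripts Data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `class`.
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  tx <- as_tibble(transcripts)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bed") {
    if (nrow(tx) > 0) {
      writeLines(sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                         tx$chrom, as.integer(tx$start), as.integer(tx$end),
                         tx$id, tx$class, tx$strand), con)
    }
  } else {
    writeLines("##gff-version 3", con)
    if (nrow(tx) > 0) {
      writeLines(sprintf("%s\tcrypticlnc\tlncRNA\t%d\t%d\t.\t%s\t.\tID=%s;class=%s",
                         tx$chrom, as.integer(tx$start) + 1L,
                         as.integer(tx$end), tx$strand, tx$id, tx$class), con)
    }
  }
  invisible(path)
}

#' Read classified transcripts written by [write_transcripts()]
#'
#' @param path BED6 or GFF3 file.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return Tibble with columns `id`, `chrom`, `start`, `end`, `strand`,
#'   `class`.
#' @export
read_transcripts <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path)) "gff3" else "bed"
  }
  empty <- tibble(id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), class = character())
  if (file.size(path) == 0) return(empty)
  if (format == "bed") {
    validate_tab_file(path, min_fields = 6, numeric_fields = c(2, 3))
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) return(empty)
    tbl <- from_granges(gr)
    name <- as.character(S4Vectors::mcols(gr)$name)
    parts <- strsplit(name, "|", fixed = TRUE)
    tbl$id <- vapply(parts, `[`, character(1), 1)
    tbl$class <- vapply(parts, `[`, character(1), 2)
  } else {
    validate_tab_file(path, min_fields = 8, numeric_fields = c(4, 5))
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) return(empty)
    tbl <- from_granges(gr)
    mc <- S4Vectors::mcols(gr)
    tbl$id <- as.character(mc$ID)
    tbl$class <- as.character(mc$class)
  }
  tbl[, c("id", "chrom", "start", "end", "strand", "class")]
}
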