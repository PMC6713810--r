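test_that("GFF3 and BED coordinates both land on the internal 0-based half-open convention", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 1000",
    "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1"
  ), gff)
  ann <- read_annotation(gff)
  expect_equal(ann$features$start, 0)
  expect_equal(ann$features$end, 10)
  expect_equal(ann$features$kind, "ORF")

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10\tg1\t0\t+\tORF", bed)
  ann2 <- read_annotation(bed, chrom_lengths = c(chr1 = 1000))
  expect_equal(ann2$features$start, 0)
  expect_equal(ann2$features$end, 10)
})

test_that("annotation contract violations error informatively", {
  expect_error(
    genome_annotation(c(chr1 = 100),
                      tibble::tibble(id = "x", chrom = "chrZ", start = 0,
                                     end = 10, strand = "+", kind = "ORF")),
    "unknown chromosome")
  expect_error(
    genome_annotation(c(chr1 = 100),
                      tibble::tibble(id = "x", chrom = "chr1", start = 0,
                                     end = 200, strand = "+", kind = "ORF")),
    "bounds")
  expect_error(
    genome_annotation(c(chr1 = 100),
                      tibble::tibble(id = "x", chrom = "chr1", start = 0,
                                     end = 10, strand = ".", kind = "ORF")),
    "strand")
  expect_error(
    genome_annotation(c(chr1 = 100),
                      tibble::tibble(id = "x", chrom = "chr1", start = 0,
                                     end = 10, strand = "+", kind = "exon")),
    "kind")
})

test_that("malformed annotation lines are reported with their line number", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 1000",
    "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1",
    "chr1\tbroken line"
  ), gff)
  expect_error(read_annotation(gff), "line 4")
})

test_that("annotation round-trips through GFF3", {
  ann <- tiny_annotation()
  path <- tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back$chromosomes, ann$chromosomes)
  expect_equal(back$features[, names(ann$features)], ann$features)
})

test_that("bedGraph coverage reads densely with absent positions at zero", {
  ann <- genome_annotation(c(chr1 = 20), tibble::tibble(
    id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), kind = character()))
  path <- tempfile(fileext = ".bedgraph")
  writeLines("", path)
  sig0 <- read_coverage(path, ann, "+")
  expect_equal(sum(sig0$plus$chr1), 0)

  writeLines("chr1\t0\t5\t3", path)
  sig <- read_coverage(path, ann, "+")
  expect_equal(sig$plus$chr1, c(rep(3, 5), rep(0, 15)))
  expect_equal(sum(sig$minus$chr1), 0)
})

test_that("bedGraph contract violations error", {
  ann <- genome_annotation(c(chr1 = 20), tibble::tibble(
    id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), kind = character()))
  path <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t5\t3", "chr1\t3\t8\t2"), path)
  expect_error(read_coverage(path, ann, "+"), "overlap")
  writeLines("chr1\t0\t5\t-1", path)
  expect_error(read_coverage(path, ann, "+"), "negative")
})

test_that("coverage round-trips through bedGraph on random signals", {
  set.seed(11)
  lens <- c(chrA = 300, chrB = 150)
  ann <- genome_annotation(lens, tibble::tibble(
    id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), kind = character()))
  sig <- stranded_signal(lens)
  sig$plus$chrA <- sample(0:5, 300, replace = TRUE)
  sig$minus$chrB <- sample(0:3, 150, replace = TRUE)
  pp <- tempfile(fileext = ".plus.bedgraph")
  mp <- tempfile(fileext = ".minus.bedgraph")
  write_coverage(sig, pp, "+")
  write_coverage(sig, mp, "-")
  back_p <- read_coverage(pp, ann, "+")
  back_m <- read_coverage(mp, ann, "-")
  expect_equal(back_p$plus$chrA, as.numeric(sig$plus$chrA))
  expect_equal(back_m$minus$chrB, as.numeric(sig$minus$chrB))
})

test_that("classified transcripts round-trip with class labels preserved", {
  set.seed(5)
  tx <- tibble::tibble(
    id = sprintf("t%02d", 1:10),
    chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
    start = as.integer(seq(0, 900, 100)),
    end = as.integer(seq(0, 900, 100) + sample(200:400, 10)),
    strand = sample(c("+", "-"), 10, replace = TRUE),
    class = sample(c("SUT", "CUT", "XUT", "DUT"), 10, replace = TRUE)
  )
  for (fmt in c("bed", "gff3")) {
    path <- tempfile(fileext = paste0(".", if (fmt == "bed") "bed" else "gff3"))
    write_transcripts(tx, path, fmt)
    back <- read_transcripts(path)
    back <- back[match(tx$id, back$id), ]
    expect_equal(tibble::as_tibble(back), tx, ignore_attr = TRUE)
  }
  # empty set writes a valid, readable file
  empty <- tx[0, ]
  path <- tempfile(fileext = ".bed")
  write_transcripts(empty, path, "bed")
  expect_equal(nrow(read_transcripts(path)), 0)
})
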