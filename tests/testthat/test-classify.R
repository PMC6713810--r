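test_that("novelty filter removes short and same-strand-overlapping segments", {
  ann <- tiny_annotation()
  segs <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    chrom = "chr1",
    start = c(2499L, 3000L, 1000L, 6000L),
    end = c(2749L, 3199L, 1250L, 6400L),
    strand = c("+", "+", "-", "+")
  )
  # a: 250 nt but 1-nt same-strand overlap with orfA (ends 2500) -> removed
  # b: 199 nt clean -> removed (length gate)
  # c: 250 nt antisense to orfA (opposite strand only) -> kept
  # d: 400 nt clean -> kept
  kept <- novelty_filter(segs, ann)
  expect_setequal(kept$id, c("c", "d"))
})

test_that("class assignment applies precedence and the SUT expression gate", {
  segs <- tibble::tibble(
    id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    chrom = "chr1", start = c(0L, 500L, 1000L, 1500L, 2000L, 2500L),
    end = c(400L, 900L, 1400L, 1900L, 2400L, 2900L),
    strand = "+",
    set = c("main", "main", "main", "main", "rrp6", "rrp6"),
    sensitive_dcr1 = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    sensitive_xrn1 = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    sensitive_rrp6 = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    fpkm_wt = c(9, 9, 2, 0.3, 5, 5)
  )
  cls <- assign_classes(segs)
  expect_equal(cls$class[cls$id == "s1"], "XUT")  # dual-sensitive -> XUT only
  expect_equal(cls$class[cls$id == "s2"], "DUT")
  expect_equal(cls$class[cls$id == "s3"], "SUT")
  expect_false("s4" %in% cls$id)                  # WT FPKM below the gate
  expect_equal(cls$class[cls$id == "s5"], "CUT")
  expect_false("s6" %in% cls$id)                  # rrp6-set, insensitive
  # one final class per transcript; classes partition the classified set
  expect_equal(anyDuplicated(cls$id), 0)
  expect_true(all(table(cls$id, cls$class) <= 1))
  expect_error(assign_classes(dplyr::bind_rows(segs, segs[1, ])),
               "duplicate")
})

test_that("overlap fraction is the covered share of the first interval", {
  expect_equal(overlap_fraction(0, 100, 0, 100), 1)
  expect_equal(overlap_fraction(0, 100, 200, 300), 0)
  expect_equal(overlap_fraction(0, 100, 50, 200), 0.5)
  expect_equal(overlap_fraction(c(0, 10), c(100, 20), c(50, 0), c(200, 15)),
               c(0.5, 0.5))
})

test_that("SUT deduplication removes only strictly >50%-overlapped transcripts", {
  puts <- tibble::tibble(
    id = c("p1", "p2", "p3"), chrom = "chr1",
    start = c(0L, 1000L, 2000L), end = c(400L, 1400L, 2400L), strand = "+")
  expect_equal(dedup_suts(puts, puts[0, ]), puts)  # no CUTs: identity
  cuts <- tibble::tibble(
    id = c("c1", "c2"), chrom = "chr1",
    start = c(0L, 1000L), end = c(200L, 1400L), strand = "+")
  kept <- dedup_suts(puts, cuts)
  # p1 overlapped exactly 50% -> kept (strict); p2 fully overlapped -> removed
  expect_setequal(kept$id, c("p1", "p3"))
  # strandedness: an opposite-strand CUT does not dedup by default
  cuts_flip <- cuts
  cuts_flip$strand <- "-"
  expect_equal(nrow(dedup_suts(puts, cuts_flip)), 3)
  expect_equal(nrow(dedup_suts(puts, cuts_flip, same_strand = FALSE)), 2)
})

test_that("CUT-XUT cross overlap is inclusive at 50% and fractions refer to the CUT", {
  cuts <- tibble::tibble(id = c("c1", "c2"), chrom = "chr1",
                         start = c(0L, 1000L), end = c(100L, 2000L),
                         strand = "+")
  xuts <- tibble::tibble(id = "x1", chrom = "chr1", start = 0L, end = 1500L,
                         strand = "+")
  res <- cross_class_overlap(cuts, xuts)
  expect_equal(res$cut_id, c("c1", "c2"))
  expect_equal(res$fraction, c(1, 0.5))  # c2: 500/1000 of the CUT, inclusive
  xuts49 <- tibble::tibble(id = "x2", chrom = "chr1", start = 0L, end = 49L,
                           strand = "+")
  expect_equal(nrow(cross_class_overlap(cuts[1, ], xuts49)), 0)
})
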