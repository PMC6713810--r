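test_that("antisense needs >= 1 bp of opposite-strand overlap; mate is the largest", {
  orfs <- tibble::tibble(
    id = c("o1", "o2", "o3"), chrom = "chr1",
    start = c(100L, 1000L, 1060L), end = c(500L, 1030L, 1200L),
    strand = "+", kind = "ORF")
  tx <- tibble::tibble(
    id = c("t1", "t2", "t3", "t4"),
    chrom = "chr1",
    start = c(499L, 100L, 990L, 2000L),
    end = c(800L, 400L, 1130L, 2500L),
    strand = c("-", "+", "-", "-"))
  res <- annotate_antisense(tx, orfs)
  # t1: single-bp opposite overlap -> antisense
  expect_true(res$antisense[res$id == "t1"])
  expect_equal(res$overlap_bp[res$id == "t1"], 1L)
  # t2: same-strand overlap only -> solo
  expect_false(res$antisense[res$id == "t2"])
  # t3 overlaps o2 by 30 bp and o3 by 70 bp -> mate o3
  expect_equal(res$mate_id[res$id == "t3"], "o3")
  expect_equal(res$overlap_bp[res$id == "t3"], 70L)
  # t4: no overlap -> solo; antisense + solo = class size
  expect_equal(sum(res$antisense) + sum(!res$antisense), nrow(tx))
  pl <- overlap_lengths(res)
  expect_setequal(pl$id, c("t1", "t3"))
})

test_that("overlap lengths match interval arithmetic", {
  orfs <- tibble::tibble(id = "o", chrom = "chr1", start = 400L, end = 900L,
                         strand = "+", kind = "ORF")
  tx <- tibble::tibble(id = c("nested", "edge"), chrom = "chr1",
                       start = c(500L, 0L), end = c(800L, 500L),
                       strand = "-")
  res <- annotate_antisense(tx, orfs)
  expect_equal(res$overlap_bp[res$id == "nested"], 300L)
  expect_equal(res$overlap_bp[res$id == "edge"], 100L)
  expect_equal(nrow(overlap_lengths(res[0, ])), 0)
})

test_that("cumulative coding coverage counts opposite-strand covered coding bases", {
  orfs <- tibble::tibble(id = "o1", chrom = "chr1", start = 0L, end = 1000L,
                         strand = "+", kind = "ORF")
  none <- cumulative_coding_coverage(
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character()), orfs)
  expect_equal(none$fraction, 0)
  half <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L, strand = "-")
  expect_equal(cumulative_coding_coverage(half, orfs)$fraction, 50)
  # duplicates do not change coverage; union bounded by members' sum
  sets <- list(a = half, b = dplyr::bind_rows(half, half))
  cov <- cumulative_coding_coverage(sets, orfs)
  expect_equal(cov$fraction[cov$set == "a"], cov$fraction[cov$set == "b"])
  expect_lte(cov$fraction[cov$set == "union"],
             sum(cov$fraction[cov$set != "union"]))
  expect_gte(cov$fraction[cov$set == "union"],
             max(cov$fraction[cov$set != "union"]))
  # same-strand transcripts contribute nothing
  same <- half
  same$strand <- "+"
  expect_equal(cumulative_coding_coverage(same, orfs)$fraction, 0)
})

test_that("rank-sum test is exact for small untied groups and matches enumeration", {
  res <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p, 0.1)
  same <- wilcoxon_ranksum(c(5, 9, 12, 20), c(5, 9, 12, 20))
  expect_equal(same$p, 1)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "non-empty")
  set.seed(71)
  for (i in 1:15) {
    x <- sample(100, sample(2:6, 1))
    y <- sample(200:300, sample(2:6, 1))
    expect_equal(wilcoxon_ranksum(x, y)$p, wilcox_enum_p(x, y))
  }
})

test_that("set comparisons filter short transcripts and report medians", {
  a <- tibble::tibble(length = c(150, seq(300, 700, 100)))
  b <- a
  res <- compare_sets(a, b, "size")
  expect_equal(res$p, 1)
  expect_equal(res$median_a, res$median_b)
  expect_equal(res$n_a, 5)  # the 150-nt transcript is removed
  long <- tibble::tibble(length = seq(300, 700, 100))
  shifted <- tibble::tibble(length = long$length + 100)
  res2 <- compare_sets(long, shifted, "size")
  expect_equal(res2$median_b - res2$median_a, 100)
})

test_that("printed percentages use round-half-away-from-zero", {
  expect_equal(format_percent(93, 146), 64L)
  expect_equal(format_percent(1, 200), 1L)   # 0.5% rounds up
  expect_equal(format_percent(125, 1000), 13L)
})

test_that("solo/antisense density tests adjust within the report family", {
  set.seed(72)
  dens <- tibble::tibble(
    class = rep(c("SUT", "CUT", "XUT"), each = 20),
    antisense = rep(c(TRUE, FALSE), 30),
    density = c(runif(20, 0, 1), runif(20, 1, 2), runif(20, 2, 3))
  )
  res <- solo_antisense_tests(dens)
  expect_equal(nrow(res), 3)
  expect_equal(res$padj, bh_adjust(res$p))
  expect_true(all(res$n_antisense + res$n_solo == 20))
})
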