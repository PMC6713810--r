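test_that("the generator is deterministic and honors its invariants", {
  cfg <- small_sim_config()
  g1 <- generate_genome(cfg, seed = 9)
  g2 <- generate_genome(cfg, seed = 9)
  expect_identical(g1, g2)
  truth <- g1$truth
  expect_true(all(truth$length >= 200))
  expect_true(all(truth$end > truth$start))
  # sensitivity structure per class
  expect_true(all(truth$fold_xrn1[truth$class == "XUT"] > 1))
  expect_true(all(truth$fold_rrp6[truth$class == "CUT"] > 1))
  expect_true(all(truth$fold_dcr1[truth$class == "DUT"] > 1))
  suts <- truth[truth$class == "SUT", ]
  expect_true(all(suts$fold_dcr1 == 1 & suts$fold_xrn1 == 1 &
                    suts$fold_rrp6 == 1))
  # annotated features do not contain the planted lncRNAs
  expect_false(any(truth$id %in% g1$annotation$features$id))
  # antisense plants overlap their mate ORF on the opposite strand
  feats <- g1$annotation$features
  as_rows <- truth[truth$antisense, ]
  mates <- feats[match(as_rows$mate_id, feats$id), ]
  expect_true(all(mates$strand != as_rows$strand))
  ov <- pmin(as_rows$end, mates$end) - pmax(as_rows$start, mates$start)
  expect_true(all(ov >= 1))
  expect_equal(as.integer(ov), as.integer(as_rows$overlap_bp))
})

test_that("antisense_fraction = 0 plants no antisense transcripts", {
  cfg <- small_sim_config()
  cfg$antisense_fraction <- 0
  g <- generate_genome(cfg, seed = 3)
  expect_false(any(g$truth$antisense))
})

test_that("simulated counts track planted folds in expectation", {
  cfg <- sim_config(dispersion = 0.05)
  # law-of-large-numbers check over 1,000 planted features, no genome needed
  units <- tibble::tibble(
    id = sprintf("u%04d", 1:1000), chrom = "chr1",
    start = 0L, end = 500L, strand = "+", kind = "lncRNA",
    baseline_mean = 100, fold_dcr1 = 1, fold_xrn1 = 4, fold_rrp6 = 1)
  sim <- simulate_counts(units, c("WT", "xrn1"), cfg, seed = 5)
  s <- sim$samples
  wt <- rowMeans(sim$counts[, s$sample[s$genotype == "WT"]]) /
    mean(s$depth[s$genotype == "WT"])
  mut <- rowMeans(sim$counts[, s$sample[s$genotype == "xrn1"]]) /
    mean(s$depth[s$genotype == "xrn1"])
  expect_lt(abs(mean(mut) / mean(wt) - 4), 0.4)
  # spike-in rows are unaffected by genotype (depth-corrected means agree)
  sp <- sim$spike_counts
  sp_wt <- colSums(sp[, s$genotype == "WT"]) / s$depth[s$genotype == "WT"]
  sp_mut <- colSums(sp[, s$genotype == "xrn1"]) / s$depth[s$genotype == "xrn1"]
  expect_lt(abs(mean(sp_mut) / mean(sp_wt) - 1), 0.15)
  # determinism
  expect_identical(sim$counts,
                   simulate_counts(units, c("WT", "xrn1"), cfg, seed = 5)$counts)
})

test_that("simulated coverage is strand-restricted and consistent with counts", {
  cfg <- small_sim_config()
  g <- generate_genome(cfg, seed = 7)
  cnt <- simulate_counts(g$units, "WT", cfg, seed = 8)
  fr <- simulate_coverage(g$units, cnt$counts, cfg, seed = 9)
  expect_equal(nrow(fr), sum(cnt$counts))
  # zero-count units contribute no fragments
  zero <- g$units$id[rowSums(cnt$counts) == 0]
  if (length(zero) > 0) {
    zu <- g$units[g$units$id %in% zero, ]
    for (k in seq_len(nrow(zu))) {
      inside <- fr$chrom == zu$chrom[k] & fr$strand == zu$strand[k] &
        fr$start >= zu$start[k] & fr$end <= zu$end[k]
      expect_equal(sum(inside), 0)
    }
  }
  # fragments stay within their unit's interval and strand: every fragment
  # midpoint falls in some same-strand unit
  cntmat <- count_fragments(dplyr::mutate(fr, sample = "s"), g$units)
  expect_equal(sum(cntmat), nrow(fr))
})

test_that("segmentation recovers planted transcript bases at the default threshold", {
  cfg <- small_sim_config()
  g <- generate_genome(cfg, seed = 13)
  cnt <- simulate_counts(g$units, c("WT", "dcr1", "xrn1", "dcr1xrn1"), cfg,
                         seed = 14)
  fr <- simulate_coverage(g$units, cnt$counts, cfg, seed = 15)
  pooled <- build_fragment_coverage(
    fr[, c("chrom", "start", "end", "strand")], g$annotation)
  seg <- segment_signal(pooled, window = 10, threshold = 27.36)
  truth <- g$truth
  covered <- 0
  for (k in seq_len(nrow(truth))) {
    sub <- seg[seg$chrom == truth$chrom[k] & seg$strand == truth$strand[k], ]
    if (nrow(sub) == 0) next
    covered <- covered + sum(pmax(
      0, pmin(sub$end, truth$end[k]) - pmax(sub$start, truth$start[k])))
  }
  expect_gt(covered / sum(truth$length), 0.9)
})

test_that("small-RNA simulation has the planted size, base and genotype structure", {
  cfg <- small_sim_config()
  g <- generate_genome(cfg, seed = 17)
  wt <- simulate_small_rna(g$truth, "WT", cfg, seed = 18)
  dcr <- simulate_small_rna(g$truth, "dcr1", cfg, seed = 19)
  pair_reads <- wt[wt$genome_tag == "target" & wt$length %in% 22:23, ]
  expect_gt(nrow(pair_reads), 100)
  # Dicer-null: no overlap-region siRNA burst, only scattered background
  in_overlap <- function(reads) {
    tr <- g$truth[g$truth$dsrna, ]
    hit <- rep(FALSE, nrow(reads))
    for (k in seq_len(nrow(tr))) {
      hit <- hit | (reads$chrom == tr$chrom[k] &
                      reads$start < tr$ov_end[k] &
                      reads$end > tr$ov_start[k])
    }
    hit
  }
  dcr_t <- dcr[dcr$genome_tag == "target" & dcr$length %in% 22:23, ]
  expect_lt(nrow(dcr_t), 50)
  wt_t <- wt[wt$genome_tag == "target" & wt$length %in% 22:23, ]
  expect_gt(mean(in_overlap(wt_t)), 0.95)
  # 5'-U fraction recovers the configured probability (binomial error)
  n <- nrow(pair_reads)
  u <- mean(pair_reads$first_base == "U")
  expect_lt(abs(u - cfg$sirna_u5_prob), 4 * sqrt(0.9 * 0.1 / n))
  # spike reads always emitted, 22-23 nt
  expect_true(all(dcr$length[dcr$genome_tag == "spike"] %in% 22:23))
  expect_gt(sum(dcr$genome_tag == "spike"), 0)
})

test_that("the full dataset bundle is reproducible per seed", {
  cfg <- small_sim_config()
  s1 <- simulate_dataset(cfg, seed = 23)
  s2 <- simulate_dataset(cfg, seed = 23)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$main$counts, s2$main$counts)
  expect_identical(s1$main$fragments, s2$main$fragments)
  expect_identical(s1$smallrna, s2$smallrna)
  s3 <- simulate_dataset(cfg, seed = 24)
  expect_false(identical(s1$main$counts, s3$main$counts))
})
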