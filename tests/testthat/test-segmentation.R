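test_that("windowed log2 score matches closed-form values on constant signals", {
  expect_equal(windowed_log2(numeric(50), 10), numeric(50))
  expect_equal(windowed_log2(rep(7, 20), 1), rep(3, 20))
  s <- windowed_log2(rep(7, 30), 10)
  expect_equal(s[1:21], rep(30, 21))
  # trailing window truncates at the end of the chromosome
  expect_equal(s[30], 3)
  expect_error(windowed_log2(rep(1, 5), 0), "window")
  # mean statistic = sum / window on full windows
  expect_equal(windowed_log2(rep(7, 30), 10, stat = "mean")[1:21],
               rep(3, 21))
})

test_that("segment calling uses strict thresholds and maximal runs", {
  score <- numeric(30)
  score[6:15] <- 3
  seg <- call_segments(score, 2.9)
  expect_equal(seg, tibble::tibble(start = 5L, end = 15L))
  expect_equal(nrow(call_segments(score, max(score))), 0)
})

test_that("segment calling equals the brute-force scan on random signals", {
  set.seed(301)
  for (i in 1:200) {
    n <- sample(10:300, 1)
    score <- round(runif(n, 0, 5), 2)
    tau <- runif(1, 0, 5)
    expect_identical(call_segments(score, tau),
                     brute_force_segments(score, tau))
  }
})

test_that("segments nest as the threshold rises", {
  set.seed(302)
  for (i in 1:20) {
    score <- abs(cumsum(rnorm(500)))
    t1 <- quantile(score, 0.4)
    t2 <- quantile(score, 0.7)
    lo <- call_segments(score, t1)
    hi <- call_segments(score, t2)
    if (nrow(hi) == 0) next
    # every high-threshold segment lies inside exactly one low-threshold one
    parent <- vapply(seq_len(nrow(hi)), function(k) {
      sum(lo$start <= hi$start[k] & lo$end >= hi$end[k])
    }, integer(1))
    expect_true(all(parent == 1L))
    expect_lte(sum(hi$end - hi$start), sum(lo$end - lo$start))
  }
})

test_that("at threshold 0 and window 1 every positive position is segmented", {
  set.seed(303)
  x <- rpois(400, 0.5)
  seg <- call_segments(windowed_log2(x, 1), 0)
  covered <- logical(400)
  for (k in seq_len(nrow(seg))) covered[(seg$start[k] + 1):seg$end[k]] <- TRUE
  expect_identical(covered, x > 0)
})

test_that("segment_signal reports per-segment means and sorted disjoint intervals", {
  sig <- bump_signal(len = 2000, value = 7, at = c(500, 900))
  seg <- segment_signal(sig, window = 10, threshold = 25)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$strand, "+")
  # interior of the bump scores 30 > 25; boundaries are near the bump edges
  expect_lt(abs(seg$start - 500), 12)
  expect_lt(abs(seg$end - 900), 12)
  expect_equal(seg$mean_signal, mean(sig$plus$chrT[(seg$start + 1):seg$end]))
})

test_that("the parameter grid enumerates all combinations with monotone bases", {
  sig <- bump_signal(len = 400, value = 20, at = c(100, 250))
  g1 <- segment_grid(sig, windows = 10, thresholds = 5)
  expect_equal(nrow(g1), 1)
  g <- segment_grid(sig, windows = c(5, 10), thresholds = c(1, 5, 20, 50))
  expect_equal(nrow(g), 8)
  for (w in unique(g$window)) {
    sub <- g[g$window == w, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$bases) <= 0))
    expect_true(all(diff(sub$n_segments) <= 0 | diff(sub$bases) <= 0))
  }
  expect_error(segment_grid(sig, windows = numeric(0), thresholds = 1),
               "non-empty")
})

test_that("pooling signals is additive, commutative and shape-checked", {
  a <- bump_signal(len = 100, value = 3, at = c(10, 40))
  z <- stranded_signal(c(chrT = 100))
  expect_equal(pooled_signal(list(a, z)), a)
  doubled <- pooled_signal(list(a, a))
  expect_equal(doubled$plus$chrT, 2 * a$plus$chrT)
  b <- bump_signal(len = 100, value = 5, at = c(50, 80))
  expect_equal(pooled_signal(list(a, b)), pooled_signal(list(b, a)))
  short <- stranded_signal(c(chrT = 50))
  expect_error(pooled_signal(list(a, short)), "mismatch")
})
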