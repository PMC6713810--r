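# fixtures and independent oracles, built in code

tiny_annotation <- function() {
  genome_annotation(
    c(chr1 = 10000, chr2 = 5000),
    tibble::tibble(
      id = c("orfA", "orfB", "trn1", "sno1"),
      chrom = c("chr1", "chr1", "chr2", "chr2"),
      start = c(1000L, 4000L, 500L, 2000L),
      end = c(2500L, 5200L, 575L, 2120L),
      strand = c("+", "-", "+", "-"),
      kind = c("ORF", "ORF", "tRNA", "snoRNA")
    )
  )
}

small_sim_config <- function() {
  sim_config(
    n_chrom = 2, chrom_length = 120000,
    n_orf = 60, n_trna = 8, n_snorna = 5, n_snrna = 2, n_rrna = 1,
    class_counts = c(SUT = 10, CUT = 12, XUT = 14, DUT = 4)
  )
}

# brute-force per-position scan: the independent segmentation oracle
brute_force_segments <- function(score, tau) {
  starts <- integer(0)
  ends <- integer(0)
  in_seg <- FALSE
  for (p in seq_along(score)) {
    if (score[p] > tau && !in_seg) {
      starts <- c(starts, p - 1L)
      in_seg <- TRUE
    }
    if (score[p] <= tau && in_seg) {
      ends <- c(ends, p - 1L)
      in_seg <- FALSE
    }
  }
  if (in_seg) ends <- c(ends, length(score))
  tibble::tibble(start = starts, end = ends)
}

# literal step-up formula: the BH oracle
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# exhaustive enumeration of the rank-sum null: the Wilcoxon oracle
wilcox_enum_p <- function(x, y) {
  n <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(vals), n)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# deterministic stranded signal with one rectangular bump per strand
bump_signal <- function(len = 2000, value = 7, at = c(500, 900)) {
  sig <- stranded_signal(c(chrT = len))
  sig$plus$chrT[(at[1] + 1):at[2]] <- value
  sig
}
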