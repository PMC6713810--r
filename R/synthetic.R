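# synthetic_data: fully specified synthetic inputs with the statistical
# structure the analysis assumes, plus planted ground truth.

#' Simulation configuration
#'
#' Defaults describe a compact two-chromosome yeast-like genome with
#' non-overlapping ORF/tRNA/sn(o)RNA/rRNA features and ~180 planted
#' lncRNAs across the four decay classes, sequenced as biological
#' duplicates with negative-binomial replicate noise, ERCC-style spike-in
#' rows, and 22-23-nt siRNA reads with a 5'-U bias concentrated in
#' sense-antisense overlap regions.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (nt).
#' @param n_orf,n_trna,n_snorna,n_snrna,n_rrna Feature counts per kind.
#' @param class_counts Named integer vector of planted lncRNAs per class.
#' @param antisense_fraction Fraction of planted lncRNAs antisense
#'   (>= 1-bp opposite-strand overlap) to an ORF.
#' @param dual_fraction Fraction of XUTs additionally Dicer-sensitive.
#' @param stabilization_fold Mean fold stabilization in the matched mutant.
#' @param dispersion Negative-binomial dispersion (variance mu + a mu^2).
#' @param n_replicates Biological replicates per genotype.
#' @param orf_mean_log,orf_sd_log Log-normal parameters of ORF baseline
#'   expression (mean fragments per replicate).
#' @param lnc_mean_range Uniform range of lncRNA baseline mean fragments.
#' @param fragment_length Mean insert length for coverage placement (nt).
#' @param depth_sd Log-normal sdlog of per-sample depth distortion.
#' @param n_spike_rows Number of ERCC-style spike-in rows.
#' @param spike_mean_log,spike_sd_log Log-normal parameters of spike-row
#'   means.
#' @param sirna_yield Mean 22-23-nt siRNA reads per dsRNA-forming pair in a
#'   Dicer-positive genotype.
#' @param sirna_u5_prob Probability that a siRNA 5' base is U.
#' @param xut_wt_boost,xut_xrn1_boost siRNA yield multipliers for XUT pairs
#'   in WT and in the Xrn1 mutant.
#' @param sirna_background Mean background small-RNA reads per sample.
#' @param sirna_nonunique_frac Fraction of reads flagged non-unique.
#' @param spike_sirna_total Mean 22-23-nt spike-genome reads per sample.
#' @param spike_chrom_length Length of the spike chromosome.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2,
                       chrom_length = 250000,
                       n_orf = 180, n_trna = 20, n_snorna = 15,
                       n_snrna = 5, n_rrna = 2,
                       class_counts = c(SUT = 40, CUT = 60, XUT = 70,
                                        DUT = 10),
                       antisense_fraction = 0.65,
                       dual_fraction = 0.15,
                       stabilization_fold = 4,
                       dispersion = 0.05,
                       n_replicates = 2,
                       orf_mean_log = log(250), orf_sd_log = 0.6,
                       lnc_mean_range = c(30, 80),
                       fragment_length = 200,
                       depth_sd = 0.15,
                       n_spike_rows = 40,
                       spike_mean_log = log(200), spike_sd_log = 1,
                       sirna_yield = 200,
                       sirna_u5_prob = 0.9,
                       xut_wt_boost = 2,
                       xut_xrn1_boost = 4,
                       sirna_background = 100,
                       sirna_nonunique_frac = 0.05,
                       spike_sirna_total = 2000,
                       spike_chrom_length = 10000) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("stabilization_fold", "dispersion", "sirna_yield",
                       "sirna_u5_prob")]) < 0)) {
    abort("rates must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome annotation with planted lncRNAs
#'
#' Places non-overlapping loci (ORFs, tRNAs, sn(o)RNAs, rRNAs, solo
#' lncRNAs) sequentially with intergenic gaps; antisense lncRNAs are placed
#' on the strand opposite a host ORF with a partial overlap. Deterministic
#' given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory).
#' @return List with elements `annotation` (a [genome_annotation()];
#'   planted lncRNAs are not part of it), `truth` (planted lncRNA registry
#'   with class, folds, mate and overlap region), and `units` (all
#'   expressed units - features and lncRNAs - with baseline means and
#'   per-mutant folds, the input to [simulate_counts()]).
#' @export
generate_genome <- function(config = sim_config(), seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  cc <- config$class_counts
  n_lnc <- sum(cc)
  lnc <- tibble(
    id = sprintf("lnc%04d", seq_len(n_lnc)),
    class = rep(names(cc), cc),
    length = as.integer(round(runif(n_lnc, 300, 1200)))
  )
  lnc <- lnc[sample.int(n_lnc), ]
  lnc$antisense <- runif(n_lnc) < config$antisense_fraction
  dual <- lnc$class == "XUT" & runif(n_lnc) < config$dual_fraction
  f <- config$stabilization_fold
  lnc$fold_dcr1 <- ifelse(lnc$class == "DUT" | dual, f, 1)
  lnc$fold_xrn1 <- ifelse(lnc$class == "XUT", f, 1)
  lnc$fold_rrp6 <- ifelse(lnc$class == "CUT", f, 1)

  as_pool <- which(lnc$antisense)
  if (length(as_pool) > config$n_orf) {
    abort("infeasible packing: more antisense lncRNAs than host ORFs")
  }
  host_orf <- sample.int(config$n_orf, length(as_pool))

  # locus blueprint: each row one placement unit
  loci <- bind_rows(
    tibble(type = "orf", idx = seq_len(config$n_orf)),
    tibble(type = "solo", idx = which(!lnc$antisense)),
    tibble(type = "tRNA", idx = seq_len(config$n_trna)),
    tibble(type = "snoRNA", idx = seq_len(config$n_snorna)),
    tibble(type = "snRNA", idx = seq_len(config$n_snrna)),
    tibble(type = "rRNA", idx = seq_len(config$n_rrna))
  )
  loci <- loci[sample.int(nrow(loci)), ]
  small_len <- c(tRNA = 75, snoRNA = 120, snRNA = 150, rRNA = 1800)

  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  cursor <- 0
  chrom_i <- 1
  feats <- list()
  planted <- list()
  for (k in seq_len(nrow(loci))) {
    type <- loci$type[k]
    idx <- loci$idx[k]
    strand <- sample(c("+", "-"), 1)
    if (type == "orf") {
      len <- as.integer(round(runif(1, 900, 1800)))
      ext <- 0L
      as_k <- match(idx, host_orf)
      if (!is.na(as_k)) {
        li <- as_pool[as_k]
        llen <- min(lnc$length[li], len)
        ovfrac <- runif(1, 0.5, 1)
        ov <- max(200L, as.integer(round(ovfrac * llen)))
        ov <- min(ov, llen, len)
        ext <- llen - ov
      }
      extent <- len + ext
    } else if (type == "solo") {
      extent <- lnc$length[loci$idx[k]]
    } else {
      extent <- small_len[[type]]
    }
    gap <- as.integer(round(runif(1, 250, 600)))
    if (cursor + extent + gap > config$chrom_length) {
      chrom_i <- chrom_i + 1
      if (chrom_i > config$n_chrom) {
        abort("infeasible packing: features do not fit in the genome")
      }
      cursor <- 0
    }
    ch <- chroms[chrom_i]
    start <- cursor
    if (type == "orf") {
      end <- start + len
      feats[[length(feats) + 1]] <- tibble(
        id = sprintf("orf%04d", idx), chrom = ch, start = start, end = end,
        strand = strand, kind = "ORF")
      if (!is.na(as_k)) {
        # antisense lncRNA: 3' portion overlaps the ORF end, remainder
        # extends into the downstream gap, opposite strand
        li <- as_pool[as_k]
        orf_end <- end
        l_start <- orf_end - ov
        l_end <- l_start + llen
        planted[[length(planted) + 1]] <- tibble(
          row = li, chrom = ch, start = l_start, end = l_end,
          strand = if (strand == "+") "-" else "+",
          mate_id = sprintf("orf%04d", idx),
          ov_start = l_start, ov_end = orf_end)
      }
    } else if (type == "solo") {
      end <- start + extent
      planted[[length(planted) + 1]] <- tibble(
        row = idx, chrom = ch, start = start, end = end, strand = strand,
        mate_id = NA_character_, ov_start = NA_integer_,
        ov_end = NA_integer_)
    } else {
      end <- start + extent
      feats[[length(feats) + 1]] <- tibble(
        id = sprintf("%s%03d", tolower(type), idx), chrom = ch,
        start = start, end = end, strand = strand, kind = type)
    }
    cursor <- start + extent + gap
  }
  features <- bind_rows(feats)
  placed <- bind_rows(planted)
  placed <- placed[order(placed$row), ]
  truth <- bind_cols(lnc[placed$row, ], placed[, -1])
  truth$length <- truth$end - truth$start
  truth$overlap_bp <- ifelse(truth$antisense,
                             truth$ov_end - truth$ov_start, 0L)
  truth$dsrna <- truth$antisense
  truth$baseline_mean <- runif(nrow(truth), config$lnc_mean_range[1],
                               config$lnc_mean_range[2])
  truth <- truth[order(truth$id), ]

  features$baseline_mean <- dplyr::case_when(
    features$kind == "ORF" ~ rlnorm(nrow(features), config$orf_mean_log,
                                    config$orf_sd_log),
    .default = rlnorm(nrow(features), log(150), 0.4)
  )
  chrom_lens <- setNames(rep(config$chrom_length, config$n_chrom), chroms)
  chrom_lens <- c(chrom_lens, spike = config$spike_chrom_length)
  annotation <- genome_annotation(
    chrom_lens, features[, c("id", "chrom", "start", "end", "strand", "kind")])

  units <- bind_rows(
    tibble(id = features$id, chrom = features$chrom, start = features$start,
           end = features$end, strand = features$strand,
           kind = features$kind, baseline_mean = features$baseline_mean,
           fold_dcr1 = 1, fold_xrn1 = 1, fold_rrp6 = 1),
    tibble(id = truth$id, chrom = truth$chrom, start = truth$start,
           end = truth$end, strand = truth$strand, kind = "lncRNA",
           baseline_mean = truth$baseline_mean,
           fold_dcr1 = truth$fold_dcr1, fold_xrn1 = truth$fold_xrn1,
           fold_rrp6 = truth$fold_rrp6)
  )
  list(annotation = annotation,
       truth = truth[, c("id", "class", "chrom", "start", "end", "strand",
                         "length", "antisense", "mate_id", "ov_start",
                         "ov_end", "overlap_bp", "dsrna", "baseline_mean",
                         "fold_dcr1", "fold_xrn1", "fold_rrp6")],
       units = units)
}

genotype_fold <- function(units, genotype) {
  switch(genotype,
         WT = rep(1, nrow(units)),
         dcr1 = units$fold_dcr1,
         xrn1 = units$fold_xrn1,
         dcr1xrn1 = units$fold_dcr1 * units$fold_xrn1,
         rrp6 = units$fold_rrp6,
         abort(paste0("unknown genotype: ", genotype)))
}

#' Simulate replicate counts for a set of genotypes
#'
#' Counts are negative-binomial with mean `baseline x fold(genotype) x
#' depth`, where depth is a per-sample log-normal distortion; spike-in rows
#' share the depth but are unaffected by genotype. Deterministic per seed.
#'
#' @param units `units` table from [generate_genome()].
#' @param genotypes Character vector among `WT`, `dcr1`, `xrn1`,
#'   `dcr1xrn1`, `rrp6`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sample_prefix Optional prefix for sample names.
#' @return List with `counts` (units x samples integer matrix),
#'   `spike_counts` (spike rows x samples), and `samples` (tibble `sample`,
#'   `genotype`, `replicate`, `depth`).
#' @export
simulate_counts <- function(units, genotypes, config = sim_config(), seed,
                            sample_prefix = "") {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  samples <- tidyr::expand_grid(genotype = genotypes,
                                replicate = seq_len(config$n_replicates))
  samples$sample <- paste0(sample_prefix, samples$genotype, "_",
                           samples$replicate)
  samples$depth <- rlnorm(nrow(samples), 0, config$depth_sd)
  size <- 1 / config$dispersion
  counts <- matrix(0L, nrow(units), nrow(samples),
                   dimnames = list(units$id, samples$sample))
  spike_means <- rlnorm(config$n_spike_rows, config$spike_mean_log,
                        config$spike_sd_log)
  spikes <- matrix(0L, config$n_spike_rows, nrow(samples),
                   dimnames = list(sprintf("spike%03d",
                                           seq_len(config$n_spike_rows)),
                                   samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- units$baseline_mean * genotype_fold(units, samples$genotype[j]) *
      samples$depth[j]
    counts[, j] <- rnbinom(nrow(units), mu = mu, size = size)
    spikes[, j] <- rnbinom(config$n_spike_rows,
                           mu = spike_means * samples$depth[j], size = size)
  }
  list(counts = counts, spike_counts = spikes,
       samples = samples[, c("sample", "genotype", "replicate", "depth")])
}

#' Simulate stranded fragment coverage consistent with a count matrix
#'
#' Each counted fragment is placed uniformly within its unit's interval on
#' the unit's strand, with fragment length `min(fragment_length, unit
#' length)`, so the per-position coverage integrates back to
#' `count x fragment length`.
#'
#' @param units `units` table from [generate_genome()].
#' @param counts Count matrix from [simulate_counts()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble of fragments: `chrom`, `start`, `end`, `strand`,
#'   `sample`.
#' @export
simulate_coverage <- function(units, counts, config = sim_config(), seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  flen <- pmin(config$fragment_length, units$end - units$start)
  out <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    n <- counts[, j]
    tot <- sum(n)
    if (tot == 0) next
    ui <- rep.int(seq_len(nrow(units)), n)
    fl <- flen[ui]
    start <- units$start[ui] +
      floor(runif(tot) * (units$end[ui] - units$start[ui] - fl + 1))
    out[[j]] <- tibble(chrom = units$chrom[ui], start = as.integer(start),
                       end = as.integer(start + fl),
                       strand = units$strand[ui],
                       sample = colnames(counts)[j])
  }
  bind_rows(out)
}

sample_first_base <- function(n, u_prob) {
  ifelse(runif(n) < u_prob, "U", sample(c("A", "C", "G"), n, replace = TRUE))
}

#' Simulate small-RNA reads for one genotype
#'
#' In Dicer-positive genotypes (`WT`, `xrn1`), 22-23-nt reads are drawn
#' from the sense-antisense overlap regions of dsRNA-forming pairs on both
#' strands with a configurable 5'-U probability; XUT pairs yield more reads
#' (moderately in WT, strongly in the Xrn1 mutant). Dicer-null genotypes
#' (`dcr1`, `dcr1xrn1`) produce only background reads. Spike-genome reads
#' are always emitted.
#'
#' @param truth `truth` table from [generate_genome()].
#' @param genotype One of `WT`, `xrn1`, `dcr1`, `dcr1xrn1`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sample Sample name (defaults to the genotype).
#' @return Tibble of reads: `chrom`, `start`, `end`, `strand`, `length`,
#'   `first_base`, `unique`, `sample`, `genome_tag`.
#' @export
simulate_small_rna <- function(truth, genotype, config = sim_config(), seed,
                               sample = genotype) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  dicer_on <- genotype %in% c("WT", "xrn1")
  reads <- list()
  if (dicer_on) {
    pairs <- truth[truth$dsrna, ]
    if (nrow(pairs) > 0) {
      boost <- rep(1, nrow(pairs))
      boost[pairs$class == "XUT"] <-
        if (genotype == "xrn1") config$xut_xrn1_boost else config$xut_wt_boost
      ny <- rpois(nrow(pairs), config$sirna_yield * boost)
      tot <- sum(ny)
      if (tot > 0) {
        pi <- rep.int(seq_len(nrow(pairs)), ny)
        len <- base::sample(c(22L, 23L), tot, replace = TRUE)
        span <- pairs$ov_end[pi] - pairs$ov_start[pi] - len + 1
        start <- pairs$ov_start[pi] + floor(runif(tot) * pmax(span, 1))
        reads[[length(reads) + 1]] <- tibble(
          chrom = pairs$chrom[pi], start = as.integer(start),
          end = as.integer(start + len),
          strand = base::sample(c("+", "-"), tot, replace = TRUE),
          length = len,
          first_base = sample_first_base(tot, config$sirna_u5_prob),
          unique = runif(tot) >= config$sirna_nonunique_frac,
          genome_tag = "target")
      }
    }
  }
  # background degradation fragments, anywhere in the genome
  nb <- rpois(1, config$sirna_background)
  if (nb > 0) {
    chroms <- unique(truth$chrom)
    len <- base::sample(18:28, nb, replace = TRUE)
    ch <- base::sample(chroms, nb, replace = TRUE)
    start <- floor(runif(nb) * (config$chrom_length - 100))
    reads[[length(reads) + 1]] <- tibble(
      chrom = ch, start = as.integer(start), end = as.integer(start + len),
      strand = base::sample(c("+", "-"), nb, replace = TRUE), length = len,
      first_base = base::sample(RNA_BASES, nb, replace = TRUE),
      unique = runif(nb) >= config$sirna_nonunique_frac,
      genome_tag = "target")
  }
  # heterologous spike: centromeric-like 22-23-nt reads on the spike genome
  ns <- rpois(1, config$spike_sirna_total * rlnorm(1, 0, config$depth_sd))
  len <- base::sample(c(22L, 23L), ns, replace = TRUE)
  start <- floor(runif(ns) * (config$spike_chrom_length - 30))
  reads[[length(reads) + 1]] <- tibble(
    chrom = "spike", start = as.integer(start),
    end = as.integer(start + len),
    strand = base::sample(c("+", "-"), ns, replace = TRUE), length = len,
    first_base = sample_first_base(ns, config$sirna_u5_prob),
    unique = TRUE, genome_tag = "spike")
  out <- bind_rows(reads)
  out$sample <- sample
  out
}

#' Simulate a complete synthetic dataset
#'
#' Generates the genome and planted truth, the main decay-mutant RNA-seq
#' set (WT, dcr1, xrn1, dcr1xrn1 duplicates with spike-in rows), the
#' exosome-mutant set (its own WT control and rrp6 duplicates, no
#' spike-ins), and small-RNA samples for the four main genotypes.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all sub-simulations derive their seeds from
#'   it.
#' @return List of class `lnc_sim` with elements `config`, `annotation`,
#'   `truth`, `units`, `main` (`samples`, `counts`, `spike_counts`,
#'   `fragments`), `rrp6` (`samples`, `counts`, `fragments`), `smallrna`
#'   (read tibble with `genotype`).
#' @export
simulate_dataset <- function(config = sim_config(), seed) {
  if (missing(seed)) abort("seed is mandatory")
  gen <- generate_genome(config, seed)
  main_cnt <- simulate_counts(gen$units, c("WT", "dcr1", "xrn1", "dcr1xrn1"),
                              config, seed + 1L)
  main_frag <- simulate_coverage(gen$units, main_cnt$counts, config,
                                 seed + 2L)
  rrp6_cnt <- simulate_counts(gen$units, c("WT", "rrp6"), config, seed + 3L,
                              sample_prefix = "r")
  rrp6_frag <- simulate_coverage(gen$units, rrp6_cnt$counts, config,
                                 seed + 4L)
  genos <- c("WT", "xrn1", "dcr1", "dcr1xrn1")
  sr <- bind_rows(lapply(seq_along(genos), function(i) {
    r <- simulate_small_rna(gen$truth, genos[i], config, seed + 10L + i,
                            sample = paste0("sr_", genos[i]))
    r$genotype <- genos[i]
    r
  }))
  structure(list(config = config, annotation = gen$annotation,
                 truth = gen$truth, units = gen$units,
                 main = c(main_cnt[c("samples", "counts", "spike_counts")],
                          list(fragments = main_frag)),
                 rrp6 = c(rrp6_cnt[c("samples", "counts")],
                          list(fragments = rrp6_frag)),
                 smallrna = sr),
            class = "lnc_sim")
}

#' @export
print.lnc_sim <- function(x, ...) {
  cat(sprintf("<lnc_sim> %d planted lncRNAs (%s); %d main + %d rrp6-set samples; %d small-RNA reads\n",
              nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", "),
              nrow(x$main$samples), nrow(x$rrp6$samples),
              nrow(x$smallrna)))
  invisible(x)
}
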