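# pipeline: orchestrates coverage -> segmentation -> differential
# expression -> classification -> antisense -> small-RNA reporting.

#' Pipeline parameters
#'
#' All thresholds of the annotation pipeline with their selected defaults:
#' sliding window 10 nt with thresholds 27.36 (main set) and 12.96
#' (exosome-mutant set), a 200-nt novelty filter against ORF/tRNA/
#' sn(o)RNA/rRNA same-strand overlap, and the sensitivity gates (mutant
#' FPKM >= 1, mutant/WT ratio > 2, BH-adjusted P < 0.05).
#'
#' @param window Sliding-window length (nt).
#' @param threshold_main,threshold_rrp6 Segmentation thresholds for the two
#'   datasets.
#' @param stat Windowed statistic, `"sum"` or `"mean"`.
#' @param min_len Novelty-filter minimum segment length (nt).
#' @param excluded_kinds Feature kinds disqualifying on same-strand overlap.
#' @param fpkm_threshold,ratio_threshold,alpha Sensitivity gates.
#' @param gate_raw_p Gate on raw instead of adjusted P.
#' @param sut_min_fpkm WT FPKM gate for putative SUTs.
#' @param dedup_min_frac SUT/CUT overlap fraction for deduplication
#'   (strict).
#' @param universe Antisense universe, `"orf"` or `"all"`.
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(window = 10, threshold_main = 27.36,
                            threshold_rrp6 = 12.96, stat = "sum",
                            min_len = 200,
                            excluded_kinds = c("ORF", "tRNA", "snRNA",
                                               "snoRNA", "rRNA"),
                            fpkm_threshold = 1, ratio_threshold = 2,
                            alpha = 0.05, gate_raw_p = FALSE,
                            sut_min_fpkm = 1, dedup_min_frac = 0.5,
                            universe = "orf") {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Read pipeline parameters from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_params()].
#' @return A `pipeline_params` object.
#' @export
read_pipeline_params <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_params)))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_params, vals)
}

# normalized mean density ratio with a pseudo-floor of one normalized
# fragment, and the NB Wald contrast, for one mutant vs its control
contrast_table <- function(counts, samples, genotype_mut, genotype_wt,
                           size_factors, lib_sizes, seg_len, params) {
  mut_s <- samples$sample[samples$genotype == genotype_mut]
  wt_s <- samples$sample[samples$genotype == genotype_wt]
  use <- c(wt_s, mut_s)
  cond <- factor(rep(c("WT", "mut"), c(length(wt_s), length(mut_s))),
                 levels = c("WT", "mut"))
  sf <- size_factors[match(use, size_factors$sample), ]
  fit <- nb_wald_test(counts[, use, drop = FALSE], cond, sf)
  res <- fit$results
  sfv <- setNames(sf$size_factor, sf$sample)
  norm <- sweep(counts[, use, drop = FALSE], 2, sfv[use], "/")
  m_wt <- rowMeans(norm[, wt_s, drop = FALSE])
  m_mut <- rowMeans(norm[, mut_s, drop = FALSE])
  ratio <- pmax(m_mut, 1) / pmax(m_wt, 1)
  fpkm_of <- function(ss) {
    rowMeans(vapply(ss, function(s) {
      fpkm(counts[, s], seg_len, lib_sizes[[s]])
    }, numeric(nrow(counts))))
  }
  out <- tibble(feature = res$feature,
                fpkm_wt = fpkm_of(wt_s),
                fpkm_mut = fpkm_of(mut_s),
                ratio = ratio,
                log2fc = res$log2fc,
                p = res$p,
                padj = res$padj)
  out$sensitive <- call_sensitivity(
    out, fpkm_threshold = params$fpkm_threshold,
    ratio_threshold = params$ratio_threshold,
    alpha = params$alpha, gate_raw_p = params$gate_raw_p)
  out
}

#' Run the full annotation and classification pipeline
#'
#' Stages, in order: pooled strand-specific coverage; sliding-window
#' segmentation of the main and exosome-mutant datasets; novelty filter;
#' per-segment fragment counting; negative-binomial stabilization tests
#' per contrast (Dicer and Xrn1 mutants against the main WT with spike-in
#' size factors; the exosome mutant against its own control with ORF-total
#' factors); class assignment with XUT-over-DUT precedence; SUT
#' deduplication against CUTs; antisense annotation and summary
#' statistics; small-RNA profiling when reads are present.
#'
#' @param sim An `lnc_sim` bundle from [simulate_dataset()], or a list with
#'   the same structure built from real data.
#' @param params A [pipeline_params()].
#' @return An object of class `lnc_pipeline`; see [tidy.lnc_pipeline()] and
#'   [glance.lnc_pipeline()].
#' @export
run_pipeline <- function(sim, params = pipeline_params()) {
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1]] <<- tibble(stage = stage, detail = detail)
  }
  annotation <- sim$annotation
  orfs <- annotation$features[annotation$features$kind == "ORF", ]

  # -- coverage (pooled across samples per dataset) --
  pooled_main <- build_fragment_coverage(
    sim$main$fragments[, c("chrom", "start", "end", "strand")], annotation)
  pooled_rrp6 <- build_fragment_coverage(
    sim$rrp6$fragments[, c("chrom", "start", "end", "strand")], annotation)
  note("coverage", sprintf("pooled %d main + %d rrp6-set fragments",
                           nrow(sim$main$fragments),
                           nrow(sim$rrp6$fragments)))

  # -- segmentation --
  seg_main <- segment_signal(pooled_main, params$window,
                             params$threshold_main, params$stat)
  seg_rrp6 <- segment_signal(pooled_rrp6, params$window,
                             params$threshold_rrp6, params$stat)
  seg_main$id <- paste0("m_", seg_main$id)
  seg_rrp6$id <- paste0("r_", seg_rrp6$id)
  note("segmentation", sprintf("%d main segments, %d rrp6-set segments",
                               nrow(seg_main), nrow(seg_rrp6)))

  # -- novelty filter --
  cand_main <- novelty_filter(seg_main, annotation, params$min_len,
                              params$excluded_kinds)
  cand_rrp6 <- novelty_filter(seg_rrp6, annotation, params$min_len,
                              params$excluded_kinds)
  note("novelty_filter", sprintf("%d/%d main and %d/%d rrp6-set segments kept",
                                 nrow(cand_main), nrow(seg_main),
                                 nrow(cand_rrp6), nrow(seg_rrp6)))

  # -- counting and normalization --
  main_samples <- sim$main$samples
  rrp6_samples <- sim$rrp6$samples
  cnt_main <- count_fragments(sim$main$fragments, cand_main,
                              main_samples$sample)
  cnt_rrp6 <- count_fragments(sim$rrp6$fragments, cand_rrp6,
                              rrp6_samples$sample)
  sf_main <- spikein_size_factors(colSums(sim$main$spike_counts))
  orf_totals <- colSums(count_fragments(sim$rrp6$fragments, orfs,
                                        rrp6_samples$sample))
  sf_rrp6 <- orf_size_factors(orf_totals)
  lib_main <- table(sim$main$fragments$sample)
  lib_rrp6 <- table(sim$rrp6$fragments$sample)
  note("normalization", sprintf(
    "spike-in factors %s; ORF-total factors %s",
    paste(sprintf("%.2f", sf_main$size_factor), collapse = "/"),
    paste(sprintf("%.2f", sf_rrp6$size_factor), collapse = "/")))

  # -- differential expression per contrast --
  de <- list(
    dcr1 = contrast_table(cnt_main, main_samples, "dcr1", "WT", sf_main,
                          lib_main, cand_main$length, params),
    xrn1 = contrast_table(cnt_main, main_samples, "xrn1", "WT", sf_main,
                          lib_main, cand_main$length, params),
    rrp6 = contrast_table(cnt_rrp6, rrp6_samples, "rrp6", "WT", sf_rrp6,
                          lib_rrp6, cand_rrp6$length, params)
  )
  note("diff_expression", sprintf(
    "sensitive segments: dcr1 %d, xrn1 %d, rrp6 %d",
    sum(de$dcr1$sensitive), sum(de$xrn1$sensitive), sum(de$rrp6$sensitive)))

  # -- classification --
  main_rec <- cand_main |>
    mutate(set = "main",
           sensitive_dcr1 = de$dcr1$sensitive[match(.data$id, de$dcr1$feature)],
           sensitive_xrn1 = de$xrn1$sensitive[match(.data$id, de$xrn1$feature)],
           fpkm_wt = de$xrn1$fpkm_wt[match(.data$id, de$xrn1$feature)])
  rrp6_rec <- cand_rrp6 |>
    mutate(set = "rrp6",
           sensitive_rrp6 = de$rrp6$sensitive[match(.data$id, de$rrp6$feature)],
           fpkm_wt = de$rrp6$fpkm_wt[match(.data$id, de$rrp6$feature)])
  classified <- assign_classes(bind_rows(main_rec, rrp6_rec),
                               sut_min_fpkm = params$sut_min_fpkm)
  puts <- classified[classified$class == "SUT", ]
  cuts <- classified[classified$class == "CUT", ]
  suts <- dedup_suts(puts, cuts, params$dedup_min_frac)
  classified <- bind_rows(
    classified[classified$class %in% c("XUT", "DUT", "CUT"), ], suts)
  note("classify", sprintf(
    "%d putative SUTs, %d removed by >%d%% CUT overlap; final %s",
    nrow(puts), nrow(puts) - nrow(suts),
    round(100 * params$dedup_min_frac),
    paste(sprintf("%s=%d", names(table(classified$class)),
                  table(classified$class)), collapse = " ")))

  # -- antisense analysis --
  classified <- annotate_antisense(classified, annotation$features,
                                   universe = params$universe)
  as_summary <- classified |>
    group_by(.data$class) |>
    summarise(n = dplyr::n(), n_antisense = sum(.data$antisense),
              n_solo = sum(!.data$antisense), .groups = "drop") |>
    mutate(antisense_percent = format_percent(.data$n_antisense, .data$n))
  cov_sets <- split(classified[classified$antisense, ],
                    classified$class[classified$antisense])
  coverage <- cumulative_coding_coverage(cov_sets, orfs)
  # WT tag densities (spike-in normalized mean over WT replicates)
  wt_s <- main_samples$sample[main_samples$genotype == "WT"]
  sfv <- setNames(sf_main$size_factor, sf_main$sample)
  cnt_all <- count_fragments(sim$main$fragments, classified,
                             main_samples$sample)
  wt_density <- rowMeans(vapply(wt_s, function(s) {
    cnt_all[, s] / sfv[[s]] / classified$length
  }, numeric(nrow(classified))))
  density_tbl <- tibble(id = classified$id, class = classified$class,
                        antisense = classified$antisense,
                        density = wt_density)
  density_tests <- solo_antisense_tests(density_tbl)
  note("antisense", sprintf("%d/%d antisense overall",
                            sum(classified$antisense), nrow(classified)))

  # -- small RNA --
  smallrna <- NULL
  if (!is.null(sim$smallrna) && nrow(sim$smallrna) > 0) {
    sr <- as_tibble(sim$smallrna)
    sirna <- filter_sirna(sr)
    sf_sr <- sirna_size_factors(sr, samples = unique(sr$sample))
    dens_by_geno <- lapply(split(sirna, sirna$genotype), function(reads) {
      s <- reads$sample[1]
      sirna_feature_density(reads, classified,
                            size_factor = sf_sr$size_factor[
                              sf_sr$sample == s],
                            annotation = annotation)
    })
    ratio <- NULL
    if (all(c("WT", "dcr1") %in% names(dens_by_geno))) {
      ratio <- genotype_density_ratio(dens_by_geno$WT, dens_by_geno$dcr1)
      ratio$class <- classified$class[match(ratio$id, classified$id)]
      ratio$antisense <- classified$antisense[match(ratio$id,
                                                    classified$id)]
    }
    u5 <- mean(sirna$first_base[sirna$genome_tag == "target"] == "U")
    smallrna <- list(size_factors = sf_sr, densities = dens_by_geno,
                     wt_dcr1_ratio = ratio, u5_fraction = u5)
    note("smallrna", sprintf("%d filtered siRNA reads, 5'-U fraction %.3f",
                             nrow(sirna), u5))
  }

  structure(list(params = params,
                 segments = list(main = cand_main, rrp6 = cand_rrp6),
                 de = de,
                 classified = classified,
                 antisense_summary = as_summary,
                 coverage_summary = coverage,
                 density_tests = density_tests,
                 densities = density_tbl,
                 smallrna = smallrna,
                 log = bind_rows(log)),
            class = "lnc_pipeline")
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("<lnc_pipeline>\n")
  cls <- table(x$classified$class)
  cat(sprintf("  classified: %s (total %d)\n",
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
              nrow(x$classified)))
  cat(sprintf("  antisense: %d (%d%%)\n", sum(x$classified$antisense),
              format_percent(sum(x$classified$antisense),
                             nrow(x$classified))))
  invisible(x)
}

#' Tidy the classified transcript set of a pipeline run
#'
#' @param x An `lnc_pipeline` object.
#' @param ... Unused.
#' @return Tibble of classified transcripts with class, sensitivity flags,
#'   WT FPKM, antisense status, mate and overlap length.
#' @export
tidy.lnc_pipeline <- function(x, ...) as_tibble(x$classified)

#' One-row summary of a pipeline run
#'
#' @param x An `lnc_pipeline` object.
#' @param ... Unused.
#' @return Tibble with per-class counts, the overall antisense percentage
#'   and the cumulative antisense coverage of coding regions.
#' @export
glance.lnc_pipeline <- function(x, ...) {
  cls <- x$classified$class
  un <- x$coverage_summary
  tibble(
    n_sut = sum(cls == "SUT"), n_cut = sum(cls == "CUT"),
    n_xut = sum(cls == "XUT"), n_dut = sum(cls == "DUT"),
    n_total = length(cls),
    n_antisense = sum(x$classified$antisense),
    antisense_percent = format_percent(sum(x$classified$antisense),
                                       length(cls)),
    coding_coverage_percent =
      if ("union" %in% un$set) un$fraction[un$set == "union"]
      else if (nrow(un) > 0) un$fraction[1] else 0
  )
}

#' Class-size box plot of a pipeline run
#'
#' @param object An `lnc_pipeline` object.
#' @param ... Unused.
#' @export
autoplot.lnc_pipeline <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object$classified),
                  ggplot2::aes(x = .data$class, y = .data$length,
                               fill = .data$antisense)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "transcript length (nt)",
                  fill = "antisense") +
    ggplot2::theme_minimal()
}

#' Write the result bundle of a pipeline run to a directory
#'
#' Emits `transcripts.bed` and `transcripts.gff3`, one TSV per contrast,
#' and TSV summaries (antisense, coverage, density tests, log).
#'
#' @param pipeline An `lnc_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- pipeline$classified
  write_transcripts(tx, file.path(dir, "transcripts.bed"), "bed")
  write_transcripts(tx, file.path(dir, "transcripts.gff3"), "gff3")
  readr::write_tsv(tx, file.path(dir, "transcripts.tsv"))
  for (ctr in names(pipeline$de)) {
    readr::write_tsv(pipeline$de[[ctr]],
                     file.path(dir, sprintf("de_%s.tsv", ctr)))
  }
  readr::write_tsv(pipeline$antisense_summary,
                   file.path(dir, "antisense_summary.tsv"))
  readr::write_tsv(pipeline$coverage_summary,
                   file.path(dir, "coding_coverage.tsv"))
  readr::write_tsv(pipeline$density_tests,
                   file.path(dir, "density_tests.tsv"))
  readr::write_tsv(pipeline$log, file.path(dir, "pipeline_log.tsv"))
  invisible(dir)
}

#' Compare classified transcripts against planted truth
#'
#' A planted lncRNA is recovered when some classified transcript on the
#' same strand reciprocally overlaps it (> 50% of each) and carries the
#' planted class; a classified transcript is a false discovery when no
#' planted lncRNA of its class matches it.
#'
#' @param pipeline An `lnc_pipeline` object (or a classified tibble).
#' @param truth `truth` table from [generate_genome()].
#' @return List with `sensitivity`, `fdr`, `per_class` tibble, and
#'   `dual_as_xut` (TRUE when every planted transcript sensitive to both
#'   Dicer and Xrn1 is recovered as XUT).
#' @export
recovery_metrics <- function(pipeline, truth) {
  called <- if (inherits(pipeline, "lnc_pipeline")) {
    pipeline$classified
  } else {
    as_tibble(pipeline)
  }
  truth <- as_tibble(truth)
  match_tbl <- tibble(truth_id = character(), called_id = character(),
                      truth_class = character(), called_class = character())
  if (nrow(called) > 0 && nrow(truth) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(truth),
                                        as_granges(called),
                                        ignore.strand = FALSE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    f_truth <- overlap_fraction(truth$start[qi], truth$end[qi],
                                called$start[si], called$end[si])
    f_called <- overlap_fraction(called$start[si], called$end[si],
                                 truth$start[qi], truth$end[qi])
    keep <- f_truth > 0.5 & f_called > 0.5
    match_tbl <- tibble(truth_id = truth$id[qi][keep],
                        called_id = called$id[si][keep],
                        truth_class = truth$class[qi][keep],
                        called_class = called$class[si][keep])
  }
  good <- match_tbl[match_tbl$truth_class == match_tbl$called_class, ]
  sens <- mean(truth$id %in% good$truth_id)
  fdr <- if (nrow(called) > 0) {
    1 - mean(called$id %in% good$called_id)
  } else {
    0
  }
  per_class <- truth |>
    group_by(.data$class) |>
    summarise(planted = dplyr::n(),
              recovered = sum(.data$id %in% good$truth_id),
              .groups = "drop")
  dual_ids <- truth$id[truth$fold_dcr1 > 1 & truth$fold_xrn1 > 1]
  dual_ok <- all(dual_ids %in%
                   good$truth_id[good$called_class == "XUT"])
  list(sensitivity = sens, fdr = fdr, per_class = per_class,
       dual_as_xut = dual_ok)
}
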