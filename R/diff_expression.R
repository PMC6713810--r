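# diff_expression: two-group negative-binomial Wald test with moderated
# dispersion, BH adjustment, and the decision rules for stabilization calls.

#' Two-group negative-binomial Wald test
#'
#' Tests per-feature stabilization of a mutant versus its wild-type control
#' from small replicate groups (typically 2 vs 2). Counts are normalized by
#' size factors, per-feature dispersions are estimated by method of moments
#' on 2 residual degrees of freedom, shrunk 50/50 toward the across-feature
#' trend mean, and floored at the trend (with so few replicates, per-feature
#' estimates below the trend are indistinguishable from estimation noise and
#' produce anti-conservative tests if trusted). The reported log2 fold
#' change is the log2 ratio of normalized group means with a pseudo-mean of
#' 1/2 added to each, and the two-sided P-value comes from a Wald statistic
#' with a delta-method standard error.
#'
#' Features with zero counts in all samples report `log2fc = 0`, `p = 1`.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param condition Factor (or vector) of length `ncol(counts)` with exactly
#'   two levels; the first level is the reference (wild type).
#' @param size_factors Optional tibble from [spikein_size_factors()] /
#'   [orf_size_factors()] / [median_ratio_size_factors()], or a named
#'   numeric vector; defaults to median-of-ratios factors from `counts`.
#' @return An object of class `nb_fit`; use [tidy()] for the per-feature
#'   table (`feature`, `base_mean`, `log2fc`, `p`, `padj`, `dispersion`)
#'   and [glance()] for a one-row summary.
#' @export
nb_wald_test <- function(counts, condition, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  condition <- as.factor(condition)
  condition <- droplevels(condition)
  if (nlevels(condition) != 2) abort("condition must have exactly two levels")
  if (length(condition) != ncol(counts)) {
    abort("length(condition) must equal ncol(counts)")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  }
  if (is.null(size_factors)) {
    size_factors <- median_ratio_size_factors(counts)
  }
  if (is.data.frame(size_factors)) {
    sf <- setNames(size_factors$size_factor, size_factors$sample)
    sf <- if (!is.null(colnames(counts)) && all(colnames(counts) %in% names(sf))) {
      sf[colnames(counts)]
    } else {
      unname(sf)[seq_len(ncol(counts))]
    }
  } else {
    sf <- as.numeric(size_factors)
  }
  if (any(sf <= 0)) abort("size factors must be positive")

  norm <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[2]
  g0 <- !g1
  n1 <- sum(g1)
  n0 <- sum(g0)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m0 <- rowMeans(norm[, g0, drop = FALSE])
  mu <- rowMeans(norm)

  # method-of-moments dispersion on within-group residuals
  ss <- rowSums((norm[, g1, drop = FALSE] - m1)^2) +
        rowSums((norm[, g0, drop = FALSE] - m0)^2)
  df <- ncol(counts) - 2
  s2 <- if (df > 0) ss / df else rep(NA_real_, nrow(counts))
  shot <- mu * mean(1 / sf)  # Poisson part of the NB variance, normalized
  alpha_raw <- pmax((s2 - shot) / mu^2, 1e-8)
  alpha_raw[!is.finite(alpha_raw)] <- 1e-8
  expressed <- mu > 0
  alpha_trend <- if (any(expressed)) mean(alpha_raw[expressed]) else 1e-8
  alpha <- pmax(0.5 * alpha_raw + 0.5 * alpha_trend, alpha_trend)

  m1p <- m1 + 0.5
  m0p <- m0 + 0.5
  log2fc <- log2(m1p / m0p)
  v1 <- (m1p * mean(1 / sf[g1]) + alpha * m1p^2) / n1
  v0 <- (m0p * mean(1 / sf[g0]) + alpha * m0p^2) / n0
  se <- sqrt(v1 / m1p^2 + v0 / m0p^2) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  allzero <- rowSums(counts) == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1

  tbl <- tibble(
    feature = rownames(counts),
    base_mean = unname(mu),
    mean_ref = unname(m0),
    mean_alt = unname(m1),
    log2fc = unname(log2fc),
    p = unname(p),
    padj = unname(bh_adjust(p)),
    dispersion = unname(alpha)
  )
  structure(
    list(results = tbl, condition = condition,
         size_factors = tibble(sample = colnames(counts) %||%
                                 paste0("sample", seq_len(ncol(counts))),
                               size_factor = sf),
         dispersion_trend = alpha_trend),
    class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  lv <- levels(x$condition)
  cat(sprintf("<nb_fit> %s vs %s (reference): %d features, %d significant at padj < 0.05\n",
              lv[2], lv[1], nrow(x$results), sum(x$results$padj < 0.05)))
  invisible(x)
}

#' @rdname nb_wald_test
#' @param x An `nb_fit` object.
#' @param ... Unused.
#' @export
tidy.nb_fit <- function(x, ...) x$results

#' @rdname nb_wald_test
#' @export
glance.nb_fit <- function(x, ...) {
  tibble(
    n_features = nrow(x$results),
    n_significant = sum(x$results$padj < 0.05),
    dispersion_trend = x$dispersion_trend
  )
}

#' @rdname nb_wald_test
#' @param object An `nb_fit` object.
#' @export
autoplot.nb_fit <- function(object, ...) {
  tbl <- object$results
  ggplot2::ggplot(tbl, ggplot2::aes(x = log2(.data$base_mean + 0.5),
                                    y = .data$log2fc,
                                    colour = .data$padj < 0.05)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = "padj < 0.05") +
    ggplot2::labs(x = "log2 mean normalized count",
                  y = "log2 fold change (mutant / WT)") +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted P-values controlling the false discovery rate; a thin,
#' domain-checked wrapper around [stats::p.adjust()].
#'
#' @param pvals Numeric vector of raw P-values in \[0, 1\].
#' @return Adjusted P-values, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Decide per-segment stabilization in a mutant
#'
#' A segment is called sensitive to the mutated decay factor when its
#' mutant-condition expression is at least `fpkm_threshold` FPKM, the
#' mutant/WT density ratio strictly exceeds `ratio_threshold`, and the
#' (BH-adjusted) P-value is below `alpha`.
#'
#' @param records Data frame with columns `fpkm_mut`, `ratio`, `padj` (and
#'   `p` when `gate_raw_p = TRUE`).
#' @param fpkm_threshold Minimum mutant FPKM (default 1).
#' @param ratio_threshold Ratio gate, strict (default 2).
#' @param alpha Significance gate (default 0.05).
#' @param gate_raw_p Gate on the raw instead of the adjusted P-value.
#' @return Logical vector, one call per row of `records`.
#' @export
call_sensitivity <- function(records, fpkm_threshold = 1, ratio_threshold = 2,
                             alpha = 0.05, gate_raw_p = FALSE) {
  records <- as_tibble(records)
  pcol <- if (gate_raw_p) "p" else "padj"
  needed <- c("fpkm_mut", "ratio", pcol)
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records is missing columns: ", paste(missing, collapse = ", ")))
  }
  records$fpkm_mut >= fpkm_threshold &
    records$ratio > ratio_threshold &
    records[[pcol]] < alpha
}

#' Classify per-gene response to a mutant
#'
#' Genes are `up` when the fold change is at least 2 (inclusive) with a
#' significant adjusted P-value, `down` when the fold change is below 0.5
#' with a significant adjusted P-value, and `unchanged` otherwise.
#'
#' @param records Data frame with columns `fc` (mutant/WT fold change) and
#'   `padj`.
#' @param alpha Significance gate (default 0.05).
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
classify_gene_sensitivity <- function(records, alpha = 0.05) {
  records <- as_tibble(records)
  dplyr::case_when(
    records$fc >= 2 & records$padj < alpha ~ "up",
    records$fc < 0.5 & records$padj < alpha ~ "down",
    .default = "unchanged"
  )
}
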