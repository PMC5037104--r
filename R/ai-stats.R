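#' Median-of-ratios size factors
#'
#' The DESeq-style normalization: per gene, the geometric mean of its
#' counts across columns; each column's factor is the median, over genes
#' with no zero count, of the ratio of the column count to that geometric
#' mean. The median is taken on the ratio scale (DESeq2 interpolates even
#' medians in log space instead, which differs only in the 6th decimal or
#' so; the two are cross-checked in the test suite).
#'
#' @param counts integer matrix, genes x samples (here the four
#'   allele-by-replicate columns of one condition).
#' @return numeric vector of per-column size factors.
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  geo <- exp(rowMeans(log(counts)))    # 0 for any gene with a zero count
  ok <- is.finite(geo) & geo > 0
  if (!any(ok))
    .stopf(paste("no gene has all-positive counts across columns;",
                 "filter to informative genes before normalization"))
  apply(counts, 2L, function(col) stats::median(col[ok] / geo[ok]))
}

#' Normalize counts and combine replicates per allele
#'
#' Divides each column by its size factor, then sums the normalized counts
#' of the two replicates of each allele.
#'
#' @param counts genes x samples raw count matrix.
#' @param factors per-column size factors (positive).
#' @param allele character vector, one of `"apo"`/`"ir64"` per column.
#' @return data frame `gene_id`, `apo_combined`, `ir64_combined`, with the
#'   full normalized matrix in the `normalized` attribute.
#' @export
normalize_and_combine <- function(counts, factors,
                                  allele = c("apo", "apo", "ir64", "ir64")) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts))
    .stopf("one size factor per column required")
  if (any(factors <= 0)) .stopf("size factors must be positive")
  if (length(allele) != ncol(counts))
    .stopf("one allele label per column required")
  norm <- sweep(counts, 2L, factors, "/")
  out <- data.frame(
    gene_id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
              else rownames(counts),
    apo_combined = rowSums(norm[, allele == "apo", drop = FALSE]),
    ir64_combined = rowSums(norm[, allele == "ir64", drop = FALSE]),
    stringsAsFactors = FALSE)
  attr(out, "normalized") <- norm
  out
}

#' Exact binomial test of allelic imbalance
#'
#' Two-sided exact binomial test of the Apo count against an expected 1:1
#' allelic ratio: the p-value sums the probabilities of all outcomes no more
#' likely than the observed one, capped at 1. Inputs are rounded to the
#' nearest integer (normalized combined counts are fractional). A gene with
#' both counts zero is undefined and returns `NA` with a notice.
#'
#' @param apo,ir64 combined (normalized) allele counts; vectorized.
#' @return p-value(s).
#' @export
binomial_ai_test <- function(apo, ir64) {
  x <- round(apo)
  y <- round(ir64)
  n <- x + y
  p <- rep(NA_real_, length(n))
  zero <- n == 0
  if (any(zero, na.rm = TRUE))
    message(sum(zero, na.rm = TRUE),
            " gene(s) with zero combined counts skipped by the binomial test")
  for (i in which(!zero & !is.na(n))) {
    if (n[i] <= 100000) {
      d <- stats::dbinom(0:n[i], n[i], 0.5)
      # relative tolerance guards ties against floating-point noise
      p[i] <- min(1, sum(d[d <= d[x[i] + 1L] * (1 + 1e-7)]))
    } else {
      m <- min(x[i], n[i] - x[i])
      p[i] <- min(1, 2 * stats::pbinom(m, n[i], 0.5))
    }
  }
  p
}

#' Chi-square test of allelic imbalance with small-expectation filter
#'
#' One-degree-of-freedom chi-square of the observed allele counts against
#' equal expectation (n/2, n/2), without continuity correction. Genes whose
#' expected value n/2 falls below `min_expected` (default 5) are filtered
#' (NA), the usual validity requirement of the normal approximation.
#'
#' @inheritParams binomial_ai_test
#' @param min_expected filter threshold on n/2.
#' @return p-value(s); `NA` where filtered or undefined.
#' @export
chisq_ai_test <- function(apo, ir64, min_expected = 5) {
  x <- round(apo)
  y <- round(ir64)
  n <- x + y
  e <- n / 2
  stat <- (x - e)^2 / e + (y - e)^2 / e
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p[e < min_expected] <- NA_real_
  p
}

#' Allelic fold change
#'
#' The expression ratio Apo over IR64, its log2, the fold magnitude
#' (max/min, >= 1, infinite for monoallelic genes) and the favored
#' direction.
#'
#' @inheritParams binomial_ai_test
#' @return data frame `fc`, `log2fc`, `magnitude`, `direction`
#'   (`"Apo"`/`"IR64"`/`"none"`), `monoallelic`.
#' @export
fold_change <- function(apo, ir64) {
  if (any(apo < 0 | ir64 < 0, na.rm = TRUE)) .stopf("counts must be >= 0")
  fc <- ifelse(ir64 > 0, apo / ir64, ifelse(apo > 0, Inf, NA_real_))
  magnitude <- ifelse(apo == 0 & ir64 == 0, NA_real_,
                      pmax(apo, ir64) / pmin(apo, ir64))
  direction <- ifelse(apo > ir64, "Apo", ifelse(ir64 > apo, "IR64", "none"))
  direction[apo == 0 & ir64 == 0] <- NA_character_
  data.frame(fc = fc, log2fc = log2(fc), magnitude = magnitude,
             direction = direction,
             monoallelic = (apo == 0) != (ir64 == 0),
             stringsAsFactors = FALSE)
}

#' Classify allele-specific expression at a fold threshold
#'
#' A gene is `not_significant` when its p-value is at or above `alpha`;
#' `biallelic` when significant but below the fold threshold; otherwise it
#' favors the higher-expressed parental allele (`apo_favoring` /
#' `ir64_favoring`), with a `monoallelic_*` subclass when the other allele
#' contributed zero counts. A magnitude exactly at the threshold is
#' asymmetric ("equal to or more than").
#'
#' @param records data frame with columns `p`, `magnitude`, `direction`,
#'   `apo_combined`, `ir64_combined` (e.g. rows of an `ai_result`).
#' @param threshold fold-change threshold (1.25 or 2.0 in the standard
#'   analysis).
#' @param alpha significance level.
#' @return character vector of classes.
#' @export
classify_ase <- function(records, threshold = 1.25, alpha = 0.05) {
  with(records, {
    cls <- rep("not_significant", nrow(records))
    sig <- !is.na(p) & p < alpha
    cls[sig & magnitude < threshold] <- "biallelic"
    asym <- sig & magnitude >= threshold
    cls[asym & direction == "Apo" & ir64_combined > 0] <- "apo_favoring"
    cls[asym & direction == "Apo" & ir64_combined == 0] <- "monoallelic_apo"
    cls[asym & direction == "IR64" & apo_combined > 0] <- "ir64_favoring"
    cls[asym & direction == "IR64" & apo_combined == 0] <- "monoallelic_ir64"
    cls
  })
}

#' Test allelic imbalance for every gene of one condition
#'
#' The condition-level AI analysis: size factors over the four
#' allele-by-replicate columns, normalization, replicate combination, exact
#' binomial and chi-square tests, fold changes, and ASE classes at the 1.25x
#' and 2.0x thresholds. Classification is gated on the exact binomial
#' p-value; the chi-square p (with its expected-value filter) and a
#' Benjamini-Hochberg adjusted column are reported for information.
#'
#' @param counts genes x 4 matrix of raw informative-read counts with
#'   columns (apo rep1, apo rep2, ir64 rep1, ir64 rep2); rownames are gene
#'   ids.
#' @param condition condition label carried in the result.
#' @param alpha significance level for classification.
#' @param thresholds fold thresholds for the reported class columns.
#' @param allele per-column allele labels.
#' @param min_expected chi-square expected-value filter.
#' @return data frame of class `ai_result`: `gene_id`, `condition`,
#'   `apo_combined`, `ir64_combined`, `fc`, `log2fc`, `magnitude`,
#'   `direction`, `p_binomial`, `p_chisq`, `padj_binomial`, `class_125`,
#'   `class_200`. Size factors are kept in the `size_factors` attribute.
#' @export
ai_test <- function(counts, condition = "control", alpha = 0.05,
                    thresholds = c(1.25, 2.0),
                    allele = c("apo", "apo", "ir64", "ir64"),
                    min_expected = 5) {
  counts <- as.matrix(counts)
  sf <- compute_size_factors(counts)
  nc <- normalize_and_combine(counts, sf, allele = allele)
  keep <- round(nc$apo_combined) + round(nc$ir64_combined) >= 1
  nc <- nc[keep, , drop = FALSE]
  fcs <- fold_change(nc$apo_combined, nc$ir64_combined)
  res <- data.frame(gene_id = nc$gene_id, condition = condition,
                    apo_combined = nc$apo_combined,
                    ir64_combined = nc$ir64_combined,
                    fcs,
                    p_binomial = binomial_ai_test(nc$apo_combined,
                                                  nc$ir64_combined),
                    p_chisq = chisq_ai_test(nc$apo_combined,
                                            nc$ir64_combined,
                                            min_expected = min_expected),
                    stringsAsFactors = FALSE)
  res$padj_binomial <- stats::p.adjust(res$p_binomial, method = "BH")
  res$p <- res$p_binomial
  for (th in thresholds) {
    res[[sprintf("class_%d", round(th * 100))]] <-
      classify_ase(res, threshold = th, alpha = alpha)
  }
  res$p <- NULL
  attr(res, "size_factors") <- sf
  attr(res, "alpha") <- alpha
  attr(res, "thresholds") <- thresholds
  class(res) <- c("ai_result", "data.frame")
  res
}

#' @export
print.ai_result <- function(x, ...) {
  cat(sprintf("Allelic-imbalance results: %d genes, condition '%s'\n",
              nrow(x), x$condition[1] %||% "?"))
  cat(sprintf("  significant (binomial P < %.2g): %d\n",
              attr(x, "alpha"), sum(x$p_binomial < attr(x, "alpha"),
                                    na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4L)
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
summary.ai_result <- function(object, threshold = 1.25, ...) {
  summarize_ai(object, threshold = threshold)
}

#' Summarize allelic imbalance at one fold threshold
#'
#' Counts of genes favoring each parental allele (monoallelic genes counted
#' within their favored side), the AI total, the number of genes with a
#' significant allelic difference, and the percentage of significant genes
#' that show AI (one decimal).
#'
#' @param records an `ai_result` (or data frame with `p_binomial` and the
#'   threshold's class column).
#' @param threshold fold threshold whose class column is summarized.
#' @param alpha significance level (defaults to the result's own).
#' @return object of class `ai_summary`.
#' @export
summarize_ai <- function(records, threshold = 1.25, alpha = NULL) {
  alpha <- alpha %||% attr(records, "alpha") %||% 0.05
  col <- sprintf("class_%d", round(threshold * 100))
  if (!col %in% names(records))
    .stopf("records carry no class column for threshold %.2f", threshold)
  cls <- records[[col]]
  n_apo <- sum(cls %in% c("apo_favoring", "monoallelic_apo"))
  n_ir64 <- sum(cls %in% c("ir64_favoring", "monoallelic_ir64"))
  n_sig <- sum(records$p_binomial < alpha, na.rm = TRUE)
  ai_summary_counts(n_apo, n_ir64, n_sig,
                    n_biallelic = sum(cls == "biallelic"),
                    n_monoallelic_apo = sum(cls == "monoallelic_apo"),
                    n_monoallelic_ir64 = sum(cls == "monoallelic_ir64"),
                    threshold = threshold)
}

#' @rdname summarize_ai
#' @param n_apo_favoring,n_ir64_favoring genes preferring each allele
#'   (monoallelic included).
#' @param n_significant genes with a significant allelic difference.
#' @param n_biallelic,n_monoallelic_apo,n_monoallelic_ir64 optional detail
#'   counts.
#' @export
ai_summary_counts <- function(n_apo_favoring, n_ir64_favoring, n_significant,
                              n_biallelic = NA_integer_,
                              n_monoallelic_apo = NA_integer_,
                              n_monoallelic_ir64 = NA_integer_,
                              threshold = 1.25) {
  n_total <- n_apo_favoring + n_ir64_favoring
  pct <- if (n_significant > 0) round(100 * n_total / n_significant, 1L)
         else NA_real_
  structure(list(threshold = threshold,
                 n_apo_favoring = n_apo_favoring,
                 n_ir64_favoring = n_ir64_favoring,
                 n_total_ai = n_total,
                 n_significant = n_significant,
                 pct_ai_over_significant = pct,
                 n_biallelic = n_biallelic,
                 n_monoallelic_apo = n_monoallelic_apo,
                 n_monoallelic_ir64 = n_monoallelic_ir64),
            class = "ai_summary")
}

#' @export
print.ai_summary <- function(x, ...) {
  cat(sprintf("AI summary at %.2fx (monoallelic genes inside their favored side)\n",
              x$threshold))
  cat(sprintf("  genes preferring the Apo-specific allele:  %d\n",
              x$n_apo_favoring))
  cat(sprintf("  genes preferring the IR64-specific allele: %d\n",
              x$n_ir64_favoring))
  cat(sprintf("  total genes exhibiting AI:                 %d\n",
              x$n_total_ai))
  cat(sprintf("  significant genes (P < 0.05):              %d\n",
              x$n_significant))
  cat(sprintf("  %% AI over significant:                     %s\n",
              format(x$pct_ai_over_significant)))
  invisible(x)
}
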