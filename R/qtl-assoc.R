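#' Co-localize genes with markers by physical distance
#'
#' For every same-chromosome gene-marker pair, the distance is 0 kb when
#' the marker lies within the gene span and otherwise the bp gap to the
#' nearer gene end, in kb. Pairs within `window_kb` are returned sorted by
#' distance.
#'
#' @param genes data frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive bp).
#' @param markers data frame `name`, `chrom`, `pos_bp`.
#' @param window_kb maximum distance reported (default 500 kb).
#' @return data frame `marker`, `gene_id`, `chrom`, `distance_kb`.
#' @export
colocalize <- function(genes, markers, window_kb = 500) {
  out <- list()
  for (ch in intersect(unique(genes$chrom), unique(markers$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    m <- markers[markers$chrom == ch, , drop = FALSE]
    pr <- expand.grid(gi = seq_len(nrow(g)), mi = seq_len(nrow(m)))
    d_bp <- pmax(0L, g$start[pr$gi] - m$pos_bp[pr$mi],
                 m$pos_bp[pr$mi] - g$end[pr$gi])
    keep <- d_bp / 1000 <= window_kb
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      marker = m$name[pr$mi[keep]],
      gene_id = g$gene_id[pr$gi[keep]],
      chrom = ch,
      distance_kb = d_bp[keep] / 1000,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(marker = character(), gene_id = character(),
               chrom = integer(), distance_kb = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$distance_kb, res$marker, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Least-squares means of replicate phenotypes
#'
#' With a balanced two-replicate design the LS mean equals the arithmetic
#' mean of the replicates; a missing replicate leaves the other value.
#'
#' @param phenotypes matrix or data frame, lines x replicates; `NA` for
#'   missing.
#' @return named numeric vector of per-line means.
#' @export
ls_means <- function(phenotypes) {
  m <- as.matrix(phenotypes)
  if (any(rowSums(!is.na(m)) == 0L))
    .stopf("every line needs at least one non-missing replicate")
  rowMeans(m, na.rm = TRUE)
}

#' Select the phenotypic tails of a population
#'
#' The highest and lowest `ceiling(n * fraction / 2)` lines by mean
#' phenotype (ties broken by line id): 160 lines at 25 % yield the 20 + 20
#' design of tail-based selective genotyping.
#'
#' @param line_means named numeric vector of per-line phenotype means.
#' @param fraction total fraction of the population to select, in (0, 1].
#' @return character vector of selected line ids, with `high`/`low`
#'   attributes.
#' @export
select_tails <- function(line_means, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1) .stopf("fraction must be in (0, 1]")
  n <- length(line_means)
  ids <- names(line_means) %||% as.character(seq_len(n))
  k <- ceiling(n * fraction / 2)
  lo <- ids[order(line_means, ids)][seq_len(k)]
  hi <- ids[order(-line_means, ids)][seq_len(k)]
  sel <- unique(c(hi, lo))
  attr(sel, "high") <- hi
  attr(sel, "low") <- lo
  sel
}

#' Single-marker regression of phenotype on genotype score
#'
#' Ordinary least squares of the line-mean phenotype on an additive
#' genotype score (IR64 homozygote 0, heterozygote 1, Apo homozygote 2;
#' missing calls excluded), reporting the slope, R-squared as a percent and
#' the F-test p-value on 1 and n-2 degrees of freedom. A marker with a
#' single observed genotype class is flagged monomorphic (`NA` statistics).
#'
#' @param panel a [simulate_ril_panel()] object (or a list with a
#'   `genotypes` code matrix and `phenotypes`).
#' @param marker marker name (column of the genotype matrix).
#' @param lines optional line ids to restrict to (e.g. the selected tails).
#' @param line_means optional precomputed per-line means; defaults to
#'   [ls_means()] of the panel phenotypes.
#' @return one-row data frame `marker`, `n`, `slope`, `r2_pct`, `p_value`,
#'   `monomorphic`.
#' @export
single_marker_regression <- function(panel, marker, lines = NULL,
                                     line_means = NULL) {
  g <- panel$genotypes
  if (!marker %in% colnames(g)) .stopf("unknown marker '%s'", marker)
  if (is.null(line_means)) line_means <- ls_means(panel$phenotypes)
  if (is.null(lines)) lines <- rownames(g)
  code <- g[lines, marker]
  y <- line_means[lines]
  keep <- code != 0L
  code <- code[keep]
  y <- y[keep]
  if (length(y) < 3L)
    .stopf("fewer than 3 lines with non-missing genotype at %s", marker)
  score <- c(`1` = 0, `2` = 2, `3` = 1)[as.character(code)]
  if (length(unique(score)) < 2L) {
    return(data.frame(marker = marker, n = length(y), slope = NA_real_,
                      r2_pct = NA_real_, p_value = NA_real_,
                      monomorphic = TRUE, stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ score)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  data.frame(marker = marker, n = length(y),
             slope = unname(stats::coef(fit)[2L]),
             r2_pct = 100 * sm$r.squared,
             p_value = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                 lower.tail = FALSE),
             monomorphic = FALSE, stringsAsFactors = FALSE)
}

#' Marker-trait association over a set of markers
#'
#' Runs [single_marker_regression()] for each marker (default: all
#' polymorphic markers of the panel) on the given lines and returns a
#' ranked association table.
#'
#' @inheritParams single_marker_regression
#' @param markers marker names; defaults to the panel's polymorphic markers.
#' @return data frame of class `marker_assoc`, sorted by p-value.
#' @export
marker_association <- function(panel, lines = NULL, markers = NULL) {
  if (is.null(markers)) {
    markers <- if (!is.null(panel$markers))
      panel$markers$name[panel$markers$polymorphic]
    else colnames(panel$genotypes)
  }
  lm_ <- ls_means(panel$phenotypes)
  rows <- lapply(markers, function(m)
    single_marker_regression(panel, m, lines = lines, line_means = lm_))
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("marker_assoc", "data.frame")
  res
}

#' @export
print.marker_assoc <- function(x, ...) {
  y <- as.data.frame(x)
  y$sig <- ifelse(is.na(y$p_value), "",
                  ifelse(y$p_value < 0.01, "**",
                         ifelse(y$p_value < 0.05, "*", "")))
  cat("Single-marker regression (selective genotyping)\n")
  print.data.frame(y, digits = 4L, row.names = FALSE)
  invisible(x)
}
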