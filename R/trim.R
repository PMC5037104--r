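#' Quality-trim a replicate by per-position quality percentiles
#'
#' Computes, at each read position across the whole replicate, the
#' configured percentile (default the 75th) of the Phred base qualities, and
#' removes every position whose percentile falls below the threshold
#' (default Q28) from all reads. Failing positions are removed wherever they
#' occur, not only at the 3' end; the dropped positions are recorded in the
#' `dropped_positions` attribute (1-based).
#'
#' @param reads data frame `read_id`, `sequence`, `quality` for one
#'   replicate; all reads must have the same length.
#' @param threshold Phred score a position's percentile must reach.
#' @param percentile percentile (fraction) of the per-position quality
#'   distribution that is compared with `threshold`.
#' @return trimmed reads (same data frame shape, all reads the new common
#'   length) with attribute `dropped_positions`.
#' @export
quality_trim_replicate <- function(reads, threshold = 28, percentile = 0.75) {
  .check_reads(reads)
  if (nrow(reads) == 0L) .stopf("empty replicate")
  L <- unique(nchar(reads$sequence))
  if (length(L) != 1L)
    .stopf("reads in a replicate must have uniform length")
  qm <- matrix(utf8ToInt(paste(reads$quality, collapse = "")) - 33L,
               nrow = L)
  pos_q <- apply(qm, 1L, stats::quantile, probs = percentile, names = FALSE)
  keep <- pos_q >= threshold
  if (!any(keep)) .stopf("replicate entirely trimmed")
  if (all(keep)) {
    attr(reads, "dropped_positions") <- integer(0)
    return(reads)
  }
  sm <- matrix(strsplit(paste(reads$sequence, collapse = ""), "")[[1]],
               nrow = L)
  tm <- matrix(strsplit(paste(reads$quality, collapse = ""), "")[[1]],
               nrow = L)
  out <- data.frame(
    read_id = reads$read_id,
    sequence = apply(sm[keep, , drop = FALSE], 2L, paste, collapse = ""),
    quality = apply(tm[keep, , drop = FALSE], 2L, paste, collapse = ""),
    stringsAsFactors = FALSE)
  attr(out, "dropped_positions") <- which(!keep)
  out
}
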