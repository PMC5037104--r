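#' Build per-position pileups from ungapped alignments
#'
#' Tallies, for every covered transcript position, the observed bases of
#' all mapped reads. Short InDels between the sample and the reference are
#' recovered by comparing each read with the reference over its ungapped
#' placement: a read whose Hamming mismatches reach `gap_trigger` is tested
#' for a single 1-3 bp insertion/deletion breakpoint (on either flank of
#' its placement diagonal), and when the explanation saves more than
#' `gap_penalty` mismatches the read's bases are tallied on the corrected
#' diagonals and the event recorded. Alignments that already carry an indel
#' (SAM import) are honored as given. Deleted columns count a deletion
#' observation, so depth (bases + deletions) is conserved over aligned
#' reference positions.
#'
#' @param alignments alignment table from [map_reads()] or
#'   [import_alignments()].
#' @param reads the reads the alignments refer to.
#' @param reference named character vector the alignments were made against.
#' @param gap_trigger minimum ungapped mismatch count that triggers the
#'   single-indel comparison.
#' @param gap_penalty mismatch-equivalent cost an indel explanation must
#'   beat.
#' @return object of class `pileup`: per-transcript base-count matrices
#'   (4 x length, rows A/C/G/T), deletion-observation vectors, and an
#'   `indels` data frame (`transcript_id`, `kind`, `pos`, `len`, `seq`,
#'   `count`).
#' @export
build_pileup <- function(alignments, reads, reference, gap_trigger = 4L,
                         gap_penalty = 3L) {
  .check_reads(reads)
  .check_reference(reference)
  ids <- names(reference)
  lens <- stats::setNames(nchar(reference), ids)
  mp <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(mp) && !all(mp$transcript_id %in% ids))
    .stopf("alignments refer to transcripts absent from the reference")
  ridx <- match(mp$read_id, reads$read_id)
  if (anyNA(ridx)) .stopf("alignments refer to unknown reads")
  L <- nchar(reads$sequence[ridx])
  ref_extra <- ifelse(is.na(mp$indel_kind), 0L,
                      ifelse(mp$indel_kind == "del", mp$indel_len,
                             -mp$indel_len))
  if (any(mp$start < 0L | mp$start + L + ref_extra > lens[mp$transcript_id]))
    .stopf("alignment out of transcript bounds")

  cols <- lapply(ids, function(tx)
    list(bases = matrix(0L, 4L, lens[[tx]],
                        dimnames = list(.BASES, NULL)),
         del = integer(lens[[tx]])))
  names(cols) <- ids

  ev_tx <- ev_kind <- ev_seq <- character(0)
  ev_pos <- ev_len <- integer(0)
  if (nrow(mp)) {
    refraw <- lapply(reference, charToRaw)
    txf <- factor(mp$transcript_id, levels = ids)
    for (tx in levels(txf)[tabulate(txf, nbins = length(ids)) > 0L]) {
      rows <- which(mp$transcript_id == tx)
      len <- lens[[tx]]
      fr <- refraw[[tx]]
      poss <- codess <- vector("list", length(rows))
      delpos <- integer(0)
      for (r in seq_along(rows)) {
        a <- rows[r]
        sq <- reads$sequence[ridx[a]]
        code <- .base_codes(sq)
        Lr <- length(code)
        s <- mp$start[a]
        kind <- mp$indel_kind[a]
        b <- mp$break_at[a]
        d <- mp$indel_len[a]
        if (is.na(kind)) {
          nm <- mp$mismatches[a]
          if (is.na(nm))
            nm <- sum(charToRaw(sq) != fr[(s + 1L):(s + Lr)])
          if (nm >= gap_trigger) {
            ge <- .gap_extend(charToRaw(sq), fr, s,
                              max_mm = nm - gap_penalty - 1L)
            if (!is.null(ge)) {   # single-indel explanation of the run
              kind <- ge$kind
              b <- ge$b
              d <- ge$len
              s <- ge$start
            }
          }
        }
        if (is.na(kind)) {
          pos <- s + 0:(Lr - 1L)
        } else if (kind == "del") {
          pos <- c(s + 0:(b - 1L), s + b + d + 0:(Lr - b - 1L))
          delpos <- c(delpos, s + b + 0:(d - 1L))
          ev_tx <- c(ev_tx, tx); ev_kind <- c(ev_kind, "del")
          ev_pos <- c(ev_pos, s + b); ev_len <- c(ev_len, d)
          ev_seq <- c(ev_seq, substr(reference[[tx]], s + b + 1L,
                                     s + b + d))
        } else {  # ins: inserted read bases are not reference columns
          keep <- c(seq_len(b), if (b + d < Lr) (b + d + 1L):Lr)
          ev_tx <- c(ev_tx, tx); ev_kind <- c(ev_kind, "ins")
          ev_pos <- c(ev_pos, s + b - 1L); ev_len <- c(ev_len, d)
          ev_seq <- c(ev_seq, substr(sq, b + 1L, b + d))
          code <- code[keep]
          pos <- s + 0:(length(code) - 1L)
        }
        poss[[r]] <- pos
        codess[[r]] <- code
      }
      pos <- unlist(poss, use.names = FALSE)
      code <- unlist(codess, use.names = FALSE)
      keep <- code > 0L & pos >= 0L & pos < len
      tab <- tabulate(pos[keep] * 4L + code[keep], nbins = 4L * len)
      cols[[tx]]$bases <- matrix(tab, nrow = 4L,
                                 dimnames = list(.BASES, NULL))
      delpos <- delpos[delpos >= 0L & delpos < len]
      if (length(delpos))
        cols[[tx]]$del <- tabulate(delpos + 1L, nbins = len)
    }
  }

  indels <- if (length(ev_tx)) {
    agg <- stats::aggregate(
      list(count = rep(1L, length(ev_tx))),
      by = list(transcript_id = ev_tx, kind = ev_kind, pos = ev_pos,
                len = ev_len, seq = ev_seq),
      FUN = sum)
    agg[order(agg$transcript_id, agg$pos), , drop = FALSE]
  } else {
    data.frame(transcript_id = character(), kind = character(),
               pos = integer(), len = integer(), seq = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  rownames(indels) <- NULL
  structure(list(columns = cols, indels = indels, ids = ids,
                 lens = lens, n_alignments = nrow(mp)),
            class = "pileup")
}

#' Column depth of a pileup (bases + deletion observations)
#'
#' @param pileup a [build_pileup()] object.
#' @param transcript_id transcript name.
#' @return integer vector of per-position depths.
#' @export
pileup_depth <- function(pileup, transcript_id) {
  col <- pileup$columns[[transcript_id]]
  if (is.null(col)) .stopf("unknown transcript '%s'", transcript_id)
  as.integer(colSums(col$bases)) + col$del
}

#' Pool pileups of several samples
#'
#' @param pileups list of `pileup` objects built against the same reference.
#' @return a pooled `pileup`.
#' @export
pool_pileups <- function(pileups) {
  stopifnot(length(pileups) >= 1L)
  base <- pileups[[1L]]
  for (p in pileups[-1L]) {
    if (!identical(p$ids, base$ids))
      .stopf("pileups were built against different references")
    for (tx in base$ids) {
      base$columns[[tx]]$bases <- base$columns[[tx]]$bases +
        p$columns[[tx]]$bases
      base$columns[[tx]]$del <- base$columns[[tx]]$del + p$columns[[tx]]$del
    }
    base$indels <- rbind(base$indels, p$indels)
    base$n_alignments <- base$n_alignments + p$n_alignments
  }
  if (nrow(base$indels)) {
    agg <- stats::aggregate(count ~ transcript_id + kind + pos + len + seq,
                            data = base$indels, FUN = sum)
    base$indels <- agg[order(agg$transcript_id, agg$pos), , drop = FALSE]
    rownames(base$indels) <- NULL
  }
  base
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("Pileup over %d transcripts, %d alignments, %d distinct indel events\n",
              length(x$ids), x$n_alignments, nrow(x$indels)))
  invisible(x)
}
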