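#' Read and write FASTA / FASTQ files
#'
#' Thin wrappers around Biostrings I/O returning the package's plain
#' representations: a named character vector for sequence sets, and a
#' data frame with columns `read_id`, `sequence`, `quality` for reads.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  .check_reference(sequences)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 70L)
  invisible(path)
}

#' @rdname read_fasta
#' @return `read_fastq()`: data frame with `read_id`, `sequence`, `quality`
#'   (Sanger/Phred+33 encoded quality strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param reads reads data frame (`read_id`, `sequence`, `quality`).
#' @export
write_fastq <- function(reads, path) {
  .check_reads(reads)
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Export alignments as minimal SAM
#'
#' Writes the minimal SAM dialect used by the pipeline: header `@HD`/`@SQ`
#' lines, then QNAME, FLAG (0 mapped / 4 unmapped), RNAME, POS (1-based),
#' MAPQ, CIGAR (`<n>M`, optionally with one `I`/`D` operation), RNEXT, PNEXT,
#' TLEN, SEQ, QUAL.
#'
#' @param alignments alignment table from [map_reads()] / [import_alignments()].
#' @param reads reads data frame the alignments refer to.
#' @param reference named character vector of reference sequences.
#' @param path output file.
#' @export
write_sam <- function(alignments, reads, reference, path) {
  .check_reads(reads)
  .check_reference(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)),
             con)
  ridx <- match(alignments$read_id, reads$read_id)
  if (anyNA(ridx)) .stopf("alignments refer to unknown read ids")
  L <- nchar(reads$sequence[ridx])
  cigar <- ifelse(alignments$mapped, paste0(L, "M"), "*")
  gap <- which(alignments$mapped & !is.na(alignments$indel_kind))
  for (i in gap) {
    b <- alignments$break_at[i]
    len <- alignments$indel_len[i]
    cigar[i] <- if (alignments$indel_kind[i] == "del") {
      sprintf("%dM%dD%dM", b, len, L[i] - b)
    } else {
      sprintf("%dM%dI%dM", b, len, L[i] - b - len)
    }
  }
  out <- paste(alignments$read_id,
               ifelse(alignments$mapped, 0L, 4L),
               ifelse(alignments$mapped, alignments$transcript_id, "*"),
               ifelse(alignments$mapped, alignments$start + 1L, 0L),
               ifelse(alignments$mapped, 255L, 0L),
               cigar, "*", 0L, 0L,
               reads$sequence[ridx], reads$quality[ridx],
               sep = "\t")
  writeLines(out, con)
  invisible(path)
}

#' Import alignments from a minimal SAM stream
#'
#' Converts mapped SAM records to the internal alignment table (0-based
#' starts); the unmapped flag (0x4) is honored. Mismatch counts are
#' recomputed against `reference`. CIGARs may contain `M` runs with at most
#' one `I` or `D` operation; anything else is rejected.
#'
#' @param path SAM file path.
#' @param reference named character vector the header must be consistent with.
#' @return alignment data frame (see [map_reads()]).
#' @export
import_alignments <- function(path, reference) {
  .check_reference(reference)
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ\t", lines)]
  if (length(sq)) {
    sn <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
    bad <- setdiff(sn, names(reference))
    if (length(bad))
      .stopf("SAM header sequence(s) not in reference: %s",
             paste(bad, collapse = ", "))
  }
  body <- which(!hdr)
  n <- length(body)
  aln <- .empty_alignments(n)
  reflen <- stats::setNames(nchar(reference), names(reference))
  for (j in seq_len(n)) {
    ln <- body[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      .stopf("malformed SAM record at line %d: fewer than 11 fields", ln)
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) .stopf("malformed SAM record at line %d: bad FLAG", ln)
    aln$read_id[j] <- f[1]
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    tx <- f[3]
    pos <- suppressWarnings(as.integer(f[4]))
    if (!tx %in% names(reference))
      .stopf("SAM record at line %d refers to unknown sequence '%s'", ln, tx)
    if (is.na(pos) || pos < 1L)
      .stopf("malformed SAM record at line %d: bad POS", ln)
    cig <- .parse_cigar(f[6], ln)
    seq <- f[10]
    L <- nchar(seq)
    if (sum(cig$len[cig$op != "D"]) != L)
      .stopf("malformed SAM record at line %d: CIGAR/SEQ length mismatch", ln)
    aln$mapped[j] <- TRUE
    aln$transcript_id[j] <- tx
    aln$start[j] <- pos - 1L
    io <- which(cig$op %in% c("I", "D"))
    if (length(io)) {
      b <- sum(cig$len[seq_len(io - 1L)])
      len <- cig$len[io]
      if (cig$op[io] == "D") {
        aln$indel_kind[j] <- "del"
        aln$indel_pos[j] <- pos - 1L + b
        aln$indel_seq[j] <- substr(reference[[tx]], pos + b, pos + b + len - 1L)
      } else {
        aln$indel_kind[j] <- "ins"
        aln$indel_pos[j] <- pos - 1L + b - 1L
        aln$indel_seq[j] <- substr(seq, b + 1L, b + len)
      }
      aln$indel_len[j] <- len
      aln$break_at[j] <- b
    }
    ref_end <- aln$start[j] + sum(cig$len[cig$op != "I"])
    if (ref_end > reflen[[tx]])
      .stopf("SAM record at line %d extends past end of '%s'", ln, tx)
    aln$mismatches[j] <- .count_mismatches(seq, reference[[tx]], aln$start[j],
                                           aln$indel_kind[j], aln$break_at[j],
                                           aln$indel_len[j])
  }
  aln
}

.parse_cigar <- function(cigar, line) {
  if (cigar == "*") .stopf("malformed SAM record at line %d: mapped with CIGAR *", line)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar))
    .stopf("malformed SAM record at line %d: bad CIGAR '%s'", line, cigar)
  op <- substr(toks, nchar(toks), nchar(toks))
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  if (any(!op %in% c("M", "I", "D")))
    .stopf("unsupported CIGAR operation at line %d: '%s'", line, cigar)
  if (sum(op %in% c("I", "D")) > 1L)
    .stopf("at most one indel per alignment is supported (line %d)", line)
  list(op = op, len = len)
}

# Hamming mismatches of a (possibly single-indel) placement.
.count_mismatches <- function(seq, refseq, start, indel_kind, break_at, indel_len) {
  rr <- charToRaw(seq)
  fr <- charToRaw(refseq)
  L <- length(rr)
  if (is.na(indel_kind)) {
    return(sum(rr != fr[(start + 1L):(start + L)]))
  }
  b <- break_at
  if (indel_kind == "del") {
    sum(rr[1:b] != fr[(start + 1L):(start + b)]) +
      sum(rr[(b + 1L):L] != fr[(start + b + indel_len + 1L):(start + L + indel_len)])
  } else {
    left <- sum(rr[1:b] != fr[(start + 1L):(start + b)])
    if (b + indel_len < L) {
      left + sum(rr[(b + indel_len + 1L):L] !=
                   fr[(start + b + 1L):(start + L - indel_len)])
    } else left
  }
}

.empty_alignments <- function(n) {
  data.frame(read_id = character(n),
             transcript_id = NA_character_,
             start = NA_integer_,
             mismatches = NA_integer_,
             mapped = logical(n),
             indel_kind = NA_character_,
             indel_pos = NA_integer_,
             indel_len = NA_integer_,
             indel_seq = NA_character_,
             break_at = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Write a data frame as TSV
#'
#' @param x data frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
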