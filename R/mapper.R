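#' Build a k-mer seed index over a reference
#'
#' Exact k-mers at every position of every transcript, hashed to their
#' positions. Reused across [map_reads()] calls on the same reference.
#'
#' @param reference named character vector of transcript sequences.
#' @param k seed length in bp.
#' @return opaque index object for [map_reads()].
#' @export
kmer_index <- function(reference, k) {
  .check_reference(reference)
  k <- as.integer(k)
  ids <- names(reference)
  lens <- nchar(reference)
  off <- cumsum(c(0L, unname(lens)))
  kl <- gp <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    nk <- lens[i] - k + 1L
    if (nk < 1L) next
    kl[[i]] <- substring(reference[[i]], 1:nk, k:(k + nk - 1L))
    gp[[i]] <- off[i] + 1:nk
  }
  kmers <- unlist(kl, use.names = FALSE)
  gpos <- unlist(gp, use.names = FALSE)
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(length(kmers), 1L))
  if (length(kmers)) list2env(split(gpos, kmers), envir = env)
  structure(list(env = env, k = k, off = off, ids = ids,
                 lens = unname(lens),
                 genes = .gene_of(ids)),
            class = "kmer_index")
}

#' Map reads to a transcript reference (seed-and-extend)
#'
#' A minimal internal mapper: exact seeds of `seed_length` drawn at regular
#' offsets along each read are looked up in a k-mer index of the reference;
#' each candidate placement is extended ungapped and scored by Hamming
#' distance. The best placement with at most `max_mismatches` mismatches is
#' reported; reads whose best extension exceeds the cap are unmapped.
#' Mapping is strictly ungapped: short InDels between sample and reference
#' surface later, as mismatch runs that [build_pileup()] explains by
#' read-versus-reference comparison, while reads an InDel garbles beyond
#' the mismatch cap stay unmapped (gapped alignments can be brought in via
#' [import_alignments()]).
#'
#' Ties: a best score shared by placements in transcripts of different genes
#' makes the read unmapped; ties among splice variants of one gene resolve
#' to the lexicographically first transcript; two tied placements within one
#' transcript are ambiguous and unmapped.
#'
#' @param reads reads data frame.
#' @param reference named character vector of transcript sequences.
#' @param max_mismatches mismatch cap; default `ceiling(0.3 * read length)`
#'   ("lenient").
#' @param seed_length exact-seed length (must not exceed the read length).
#' @param index optional prebuilt [kmer_index()] for `reference`.
#' @return data frame with one row per read: `read_id`, `transcript_id`,
#'   `start` (0-based), `mismatches`, `mapped`, and indel fields
#'   (`indel_kind` "ins"/"del", `indel_pos` 0-based deletion start or
#'   insertion anchor, `indel_len`, `indel_seq`, `break_at`; `NA` here --
#'   the internal mapper is ungapped, the fields are filled by SAM import).
#' @export
map_reads <- function(reads, reference, max_mismatches = NULL,
                      seed_length = 20L, index = NULL) {
  .check_reads(reads)
  .check_reference(reference)
  n <- nrow(reads)
  aln <- .empty_alignments(n)
  aln$read_id <- reads$read_id
  if (n == 0L) return(aln)
  seqs <- reads$sequence
  rlen <- nchar(seqs)
  seed_length <- as.integer(seed_length)
  if (seed_length > min(rlen))
    .stopf("seed_length (%d) exceeds shortest read (%d)",
           seed_length, min(rlen))
  if (is.null(max_mismatches)) max_mismatches <- ceiling(0.3 * max(rlen))
  if (is.null(index)) index <- kmer_index(reference, seed_length)
  if (index$k != seed_length) .stopf("index seed length differs")
  k <- index$k
  off <- index$off
  lens <- index$lens
  # the whole reference as one integer byte vector; global 1-based
  # coordinates are offsets into it
  rcat <- as.integer(charToRaw(paste(reference, collapse = "")))

  out_map <- logical(n)
  out_tx <- integer(n)
  out_st <- integer(n)
  out_mm <- integer(n)
  for (L in unique(rlen)) {
    grp <- which(rlen == L)
    gseq <- seqs[grp]
    ng <- length(grp)
    # read bytes as an L x ng matrix for vectorized column comparisons
    B <- matrix(as.integer(charToRaw(paste(gseq, collapse = ""))), nrow = L)
    # candidate (read, global start) pairs from seeds at offsets
    # 0, k, 2k, ... plus a final flush seed at the read end
    offs <- unique(c(seq(0L, L - k, by = k), L - k))
    ri <- gs <- integer(0)
    for (o in offs) {
      hits <- mget(substring(gseq, o + 1L, o + k),
                   envir = index$env, ifnotfound = list(NULL))
      nh <- lengths(hits)
      ri <- c(ri, rep.int(seq_len(ng), nh))
      gs <- c(gs, unlist(hits, use.names = FALSE) - o)
    }
    if (!length(ri)) next
    keep <- !duplicated(ri * 2^32 + gs)          # exact in doubles
    ri <- ri[keep]; gs <- gs[keep]
    tx <- findInterval(gs - 1L, off)
    st <- gs - off[tx] - 1L                      # 0-based local start
    ok <- st >= 0L & st + L <= lens[tx]
    ri <- ri[ok]; gs <- gs[ok]; tx <- tx[ok]; st <- st[ok]
    if (!length(ri)) next
    # Hamming distance of every candidate, one read position at a time
    mm <- integer(length(ri))
    gs0 <- gs - 1L
    for (p in seq_len(L)) mm <- mm + (rcat[gs0 + p] != B[p, ri])
    ok <- mm <= max_mismatches
    ri <- ri[ok]; tx <- tx[ok]; st <- st[ok]; mm <- mm[ok]
    if (!length(ri)) next
    ord <- order(ri, mm, tx, st)
    ri_o <- ri[ord]; mm_o <- mm[ord]
    fpos <- which(!duplicated(ri_o))
    bi <- ord[fpos]                              # best candidate per read
    nxt <- fpos + 1L
    tied <- nxt <= length(ord) & ri_o[pmin(nxt, length(ord))] == ri_o[fpos] &
      mm_o[pmin(nxt, length(ord))] == mm_o[fpos]
    # untied reads are settled; tied reads go through slow resolution
    for (jj in seq_along(bi)) {
      i <- grp[ri[bi[jj]]]
      if (!tied[jj]) {
        out_map[i] <- TRUE
        out_tx[i] <- tx[bi[jj]]
        out_st[i] <- st[bi[jj]]
        out_mm[i] <- mm[bi[jj]]
      } else {
        sel <- which(ri == ri[bi[jj]] & mm == mm[bi[jj]])
        pick <- .resolve_tie(seq_along(sel), tx[sel], st[sel], index)
        if (is.na(pick)) next
        out_map[i] <- TRUE
        out_tx[i] <- tx[sel[pick]]
        out_st[i] <- st[sel[pick]]
        out_mm[i] <- mm[bi[jj]]
      }
    }
  }
  aln$mapped <- out_map
  aln$transcript_id <- ifelse(out_map, index$ids[pmax(out_tx, 1L)],
                              NA_character_)
  aln$start <- ifelse(out_map, out_st, NA_integer_)
  aln$mismatches <- ifelse(out_map, out_mm, NA_integer_)
  aln
}

# deterministic tie resolution among equally good placements
.resolve_tie <- function(idx, tx, st, index) {
  if (length(idx) == 1L) return(idx)
  t <- tx[idx]
  if (anyDuplicated(t)) return(NA_integer_)           # two placements, one tx
  if (length(unique(index$genes[t])) > 1L) return(NA_integer_)
  idx[order(index$ids[t])[1L]]                        # first splice variant
}

# Single-indel extension at candidate diagonal `s` (0-based). Considers a
# left segment on diagonal jL and right segment on diagonal jR with
# jR - jL = +d (deletion of d) or -d (insertion of d), d in 1..3, with the
# candidate diagonal being either flank. Returns the canonical alignment
# (start = left diagonal) with minimal mismatches <= max_mm, or NULL.
.gap_extend <- function(rr, fr, s, max_mm, max_shift = 3L) {
  L <- length(rr)
  reflen <- length(fr)
  cums <- list()
  cum_j <- function(j) {
    key <- as.character(j)
    if (is.null(cums[[key]])) {
      lo <- s + 1L + j
      hi <- s + L + j
      if (lo < 1L || hi > reflen) return(NULL)
      cums[[key]] <<- cumsum(fr[lo:hi] != rr)
    }
    cums[[key]]
  }
  best <- NULL
  consider <- function(mm, b, jL, kind, len) {
    cand <- list(mm = mm, b = b, start = s + jL, kind = kind, len = len)
    if (is.null(best) || cand$mm < best$mm ||
        (cand$mm == best$mm && cand$len < best$len) ||
        (cand$mm == best$mm && cand$len == best$len &&
         kind == "del" && best$kind == "ins")) best <<- cand
  }
  for (d in seq_len(max_shift)) {
    # deletion of d: (jL, jR) in {(0, d), (-d, 0)}
    for (jL in c(0L, -d)) {
      jR <- jL + d
      cl <- cum_j(jL); cr <- cum_j(jR)
      if (is.null(cl) || is.null(cr)) next
      b <- seq_len(L - 1L)
      cost <- cl[b] + (cr[L] - cr[b])
      w <- which.min(cost)
      if (cost[w] <= max_mm) consider(cost[w], w, jL, "del", d)
    }
    # insertion of d: (jL, jR) in {(0, -d), (d, 0)}
    for (jL in c(0L, d)) {
      jR <- jL - d
      cl <- cum_j(jL); cr <- cum_j(jR)
      if (is.null(cl) || is.null(cr)) next
      if (L - d - 1L < 1L) next
      b <- seq_len(L - d - 1L)
      cost <- cl[b] + (cr[L] - cr[b + d])
      w <- which.min(cost)
      if (cost[w] <= max_mm) consider(cost[w], w, jL, "ins", d)
    }
  }
  if (!is.null(best) && (best$start < 0L ||
      best$start + L + (if (best$kind == "del") best$len else -best$len) >
        reflen))
    return(NULL)
  best
}

#' Percent of reads mapped
#'
#' @param alignments alignment table.
#' @return mapped reads / total reads, as a percent.
#' @export
compute_mapping_rate <- function(alignments) {
  if (nrow(alignments) == 0L) .stopf("no reads")
  100 * mean(alignments$mapped)
}
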