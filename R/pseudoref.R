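#' Call variants shared by both parents against the reference
#'
#' A site is called only if, in each parent independently, the column depth
#' reaches the minimum and the same non-reference allele passes its
#' proportion threshold: SNPs need proportion strictly greater than
#' `snp_min_prop` (default 0.8) at depth >= 5; InDels need proportion at
#' least `indel_min_prop` (default 0.5, inclusive) at depth >= 5, with the
#' identical event (kind, position, sequence) observed in both parents.
#' The proportion denominator is the column depth (reads spanning the
#' site). Sites where the two parents pass with different alternative
#' alleles are skipped: a shared variant must be identical in both.
#'
#' @param pileup_apo,pileup_ir64 pooled parental [build_pileup()] objects
#'   against the same reference.
#' @param reference the reference the pileups were built against.
#' @param snp_min_depth,snp_min_prop SNP thresholds (proportion exclusive).
#' @param indel_min_depth,indel_min_prop InDel thresholds (proportion
#'   inclusive).
#' @return data frame of variant calls: `transcript_id`, `pos` (0-based;
#'   deletion start or insertion anchor), `kind` (`SNP`, `insertion`,
#'   `deletion`), `ref_allele`, `alt_allele`, `len`, `depth_apo`,
#'   `depth_ir64`, `prop_apo`, `prop_ir64`.
#' @export
call_shared_variants <- function(pileup_apo, pileup_ir64, reference,
                                 snp_min_depth = 5L, snp_min_prop = 0.8,
                                 indel_min_depth = 5L, indel_min_prop = 0.5) {
  .check_reference(reference)
  if (!identical(pileup_apo$ids, pileup_ir64$ids))
    .stopf("parental pileups were built against different references")
  out <- list()
  for (tx in pileup_apo$ids) {
    refcode <- .base_codes(reference[[tx]])
    a <- pileup_apo$columns[[tx]]
    b <- pileup_ir64$columns[[tx]]
    da <- colSums(a$bases) + a$del
    db <- colSums(b$bases) + b$del
    len <- length(da)
    ji <- seq_len(len)
    ma <- a$bases; ma[cbind(refcode, ji)] <- 0L
    mb <- b$bases; mb[cbind(refcode, ji)] <- 0L
    alt_a <- pmax(ma[1L, ], ma[2L, ], ma[3L, ], ma[4L, ])
    alt_b <- pmax(mb[1L, ], mb[2L, ], mb[3L, ], mb[4L, ])
    hit <- which(da >= snp_min_depth & db >= snp_min_depth &
                   alt_a / pmax(da, 1L) > snp_min_prop &
                   alt_b / pmax(db, 1L) > snp_min_prop)
    for (p in hit) {
      ca <- which.max(ma[, p])
      cb <- which.max(mb[, p])
      if (ca != cb) next                       # different alt alleles
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, pos = p - 1L, kind = "SNP",
        ref_allele = .BASES[refcode[p]], alt_allele = .BASES[ca], len = 1L,
        depth_apo = da[p], depth_ir64 = db[p],
        prop_apo = alt_a[p] / da[p], prop_ir64 = alt_b[p] / db[p],
        stringsAsFactors = FALSE)
    }
  }
  snps <- if (length(out)) do.call(rbind, out) else NULL

  # InDels: identical event required in both parents
  ia <- pileup_apo$indels
  ib <- pileup_ir64$indels
  indels <- NULL
  if (nrow(ia) && nrow(ib)) {
    key <- function(x) paste(x$transcript_id, x$kind, x$pos, x$len, x$seq)
    m <- match(key(ia), key(ib))
    hit <- which(!is.na(m))
    rows <- list()
    for (h in hit) {
      tx <- ia$transcript_id[h]
      p <- ia$pos[h]
      # anchor column: first deleted base for deletions, the anchor base
      # for insertions
      da <- pileup_depth(pileup_apo, tx)[p + 1L]
      db <- pileup_depth(pileup_ir64, tx)[p + 1L]
      ca <- ia$count[h]
      cb <- ib$count[m[h]]
      # deletion observations are part of depth; insertion carriers are
      # counted within the anchor-column base depth
      if (da < indel_min_depth || db < indel_min_depth) next
      if (ca / da < indel_min_prop || cb / db < indel_min_prop) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, pos = p,
        kind = if (ia$kind[h] == "del") "deletion" else "insertion",
        ref_allele = if (ia$kind[h] == "del") ia$seq[h] else "",
        alt_allele = if (ia$kind[h] == "del") "" else ia$seq[h],
        len = ia$len[h],
        depth_apo = da, depth_ir64 = db,
        prop_apo = ca / da, prop_ir64 = cb / db,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) indels <- do.call(rbind, rows)
  }
  res <- rbind(snps, indels)
  if (is.null(res))
    res <- data.frame(transcript_id = character(), pos = integer(),
                      kind = character(), ref_allele = character(),
                      alt_allele = character(), len = integer(),
                      depth_apo = numeric(), depth_ir64 = numeric(),
                      prop_apo = numeric(), prop_ir64 = numeric(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$transcript_id, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the consensus pseudo-reference
#'
#' Edits the called shared variants into the reference: SNP substitutions,
#' then InDels applied right-to-left per transcript so earlier coordinates
#' stay valid. Every length change is recorded in a lift-over map.
#'
#' @param reference named character vector.
#' @param variants variant table from [call_shared_variants()], sorted and
#'   non-overlapping per transcript.
#' @return object of class `pseudo_reference`: `sequences`, `provenance`
#'   (the applied variants), `liftover` (see [lift_coordinate()]).
#' @export
build_pseudo_reference <- function(reference, variants) {
  .check_reference(reference)
  v <- variants[order(variants$transcript_id, variants$pos), , drop = FALSE]
  # overlap check: occupied span per variant (insertions occupy the
  # junction after their anchor base)
  for (tx in unique(v$transcript_id)) {
    w <- v[v$transcript_id == tx, , drop = FALSE]
    from <- w$pos
    to <- ifelse(w$kind == "deletion", w$pos + w$len - 1L, w$pos)
    if (nrow(w) > 1L && any(from[-1L] <= to[-nrow(w)])) {
      bad <- which(from[-1L] <= to[-nrow(w)])
      .stopf("overlapping variants in %s at positions %s", tx,
             paste(w$pos[c(bad, bad + 1L)], collapse = ", "))
    }
  }
  seqs <- reference
  lift <- list()
  for (tx in unique(v$transcript_id)) {
    if (!tx %in% names(seqs)) .stopf("variant in unknown transcript '%s'", tx)
    w <- v[v$transcript_id == tx, , drop = FALSE]
    s <- seqs[[tx]]
    for (j in rev(seq_len(nrow(w)))) {
      p <- w$pos[j] + 1L
      if (w$kind[j] == "SNP") {
        if (substr(s, p, p) != w$ref_allele[j])
          .stopf("reference mismatch applying SNP at %s:%d", tx, w$pos[j])
        substr(s, p, p) <- w$alt_allele[j]
      } else if (w$kind[j] == "insertion") {
        s <- paste0(substr(s, 1L, p), w$alt_allele[j],
                    substr(s, p + 1L, nchar(s)))
      } else {
        s <- paste0(substr(s, 1L, p - 1L), substr(s, p + w$len[j], nchar(s)))
      }
    }
    seqs[[tx]] <- s
    ev <- w[w$kind != "SNP", , drop = FALSE]
    if (nrow(ev))
      lift[[tx]] <- data.frame(
        pos = ev$pos,
        kind = ifelse(ev$kind == "insertion", "ins", "del"),
        len = ev$len, stringsAsFactors = FALSE)
  }
  structure(list(sequences = seqs, provenance = v,
                 liftover = structure(lift, lens = nchar(reference),
                                      class = "liftover_map")),
            class = "pseudo_reference")
}

#' @export
print.pseudo_reference <- function(x, ...) {
  k <- table(factor(x$provenance$kind,
                    levels = c("SNP", "insertion", "deletion")))
  cat(sprintf("Pseudo-reference: %d transcripts; %d SNPs, %d insertions, %d deletions edited in\n",
              length(x$sequences), k[["SNP"]], k[["insertion"]],
              k[["deletion"]]))
  invisible(x)
}

#' Lift a coordinate through the InDel edits of a pseudo-reference
#'
#' Forward lifts original-reference coordinates to pseudo-reference
#' coordinates; inverse goes back. Positions inside a span that does not
#' exist on the target side (a deleted span forward, an inserted span
#' inverse) map to the span's left edge and are flagged in the `in_gap`
#' attribute.
#'
#' @param position integer vector of 0-based positions.
#' @param transcript_id single transcript name.
#' @param map a `liftover_map` (from [build_pseudo_reference()]'s
#'   `liftover` element, or a `pseudo_reference` object).
#' @param direction `"forward"` (original to pseudo) or `"inverse"`.
#' @return integer vector of lifted 0-based positions with logical
#'   attribute `in_gap`.
#' @export
lift_coordinate <- function(position, transcript_id, map,
                            direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (inherits(map, "pseudo_reference")) map <- map$liftover
  lens <- attr(map, "lens")
  if (!transcript_id %in% names(lens))
    .stopf("unknown transcript '%s'", transcript_id)
  ev <- map[[transcript_id]]
  L <- lens[[transcript_id]]
  newlen <- L + if (is.null(ev)) 0L else
    sum(ifelse(ev$kind == "ins", ev$len, -ev$len))
  maxpos <- if (direction == "forward") L else newlen
  if (any(position < 0L | position >= maxpos))
    .stopf("position out of transcript bounds")
  if (is.null(ev) || nrow(ev) == 0L) {
    attr(position, "in_gap") <- rep(FALSE, length(position))
    return(position)
  }
  if (direction == "inverse") ev <- .invert_liftover(ev)
  out <- integer(length(position))
  gap <- logical(length(position))
  for (i in seq_along(position)) {
    p <- position[i]
    delta <- 0L
    flagged <- FALSE
    for (j in seq_len(nrow(ev))) {
      if (ev$kind[j] == "ins") {
        if (p > ev$pos[j]) delta <- delta + ev$len[j]
      } else {
        d <- ev$pos[j]
        if (p >= d + ev$len[j]) {
          delta <- delta - ev$len[j]
        } else if (p >= d) {          # inside the deleted span
          out[i] <- d + delta
          gap[i] <- TRUE
          flagged <- TRUE
          break
        }
      }
    }
    if (!flagged) out[i] <- p + delta
  }
  attr(out, "in_gap") <- gap
  out
}

# express the forward events in target (pseudo) coordinates with the roles
# of insertions and deletions exchanged
.invert_liftover <- function(ev) {
  delta <- 0L
  out <- ev
  for (j in seq_len(nrow(ev))) {
    if (ev$kind[j] == "ins") {
      # inserted bases occupy [pos+1, pos+len] in the new frame: a span to
      # delete when lifting back; its left edge maps to the anchor
      out$pos[j] <- ev$pos[j] + delta + 1L
      out$kind[j] <- "del"
    } else {
      # the junction left of the removed span anchors the inverse insertion
      out$pos[j] <- ev$pos[j] + delta - 1L
      out$kind[j] <- "ins"
    }
    delta <- delta + if (ev$kind[j] == "ins") ev$len[j] else -ev$len[j]
  }
  out
}
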