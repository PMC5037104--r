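#' Call inter-parental SNPs on the pseudo-reference
#'
#' A site is emitted when each parent shows, at depth >= `min_depth`
#' (default 3), a single majority allele with proportion strictly greater
#' than `min_prop` (default 0.8) of the column depth, and the two majority
#' alleles differ. Either allele may match the pseudo-reference base: the
#' contrast is between the parents, not against the reference.
#'
#' @param pileup_apo,pileup_ir64 pooled parental pileups on the
#'   pseudo-reference.
#' @param min_depth minimum column depth per parent.
#' @param min_prop majority-allele proportion threshold (exclusive).
#' @return data frame `transcript_id`, `pos` (0-based), `apo_allele`,
#'   `ir64_allele`, `depth_apo`, `depth_ir64`, `prop_apo`, `prop_ir64`.
#' @export
call_parental_snps <- function(pileup_apo, pileup_ir64,
                               min_depth = 3L, min_prop = 0.8) {
  if (!identical(pileup_apo$ids, pileup_ir64$ids))
    .stopf("parental pileups were built against different references")
  out <- list()
  for (tx in pileup_apo$ids) {
    a <- pileup_apo$columns[[tx]]$bases
    b <- pileup_ir64$columns[[tx]]$bases
    da <- colSums(a) + pileup_apo$columns[[tx]]$del
    db <- colSums(b) + pileup_ir64$columns[[tx]]$del
    maj_a <- pmax(a[1L, ], a[2L, ], a[3L, ], a[4L, ])
    maj_b <- pmax(b[1L, ], b[2L, ], b[3L, ], b[4L, ])
    hit <- which(da >= min_depth & db >= min_depth &
                   maj_a / pmax(da, 1L) > min_prop &
                   maj_b / pmax(db, 1L) > min_prop)
    for (p in hit) {
      ca <- which.max(a[, p])
      cb <- which.max(b[, p])
      if (ca == cb) next
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, pos = p - 1L,
        apo_allele = .BASES[ca], ir64_allele = .BASES[cb],
        depth_apo = da[p], depth_ir64 = db[p],
        prop_apo = maj_a[p] / da[p], prop_ir64 = maj_b[p] / db[p],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(), pos = integer(),
               apo_allele = character(), ir64_allele = character(),
               depth_apo = numeric(), depth_ir64 = numeric(),
               prop_apo = numeric(), prop_ir64 = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assign F1 reads to parental alleles, read-wise
#'
#' For each mapped F1 read, every inter-parental SNP position it covers is
#' inspected: the read base votes for the parent whose allele it matches
#' (a base matching neither allele, e.g. a sequencing error, is ignored).
#' A read voting only Apo is an APO read; only IR64, an IR64 read; both, a
#' CONFLICT; none, UNINFORMATIVE. Each read contributes at most one count
#' to its gene -- the read, not the SNP observation, is the counting unit.
#' CONFLICT and UNINFORMATIVE reads are "unspecified".
#'
#' @param alignments F1 alignments on pseudo-reference coordinates.
#' @param reads the F1 reads.
#' @param snps inter-parental SNP table from [call_parental_snps()].
#' @param reference optional pseudo-reference sequences; when supplied, a
#'   SNP position beyond its transcript's end raises an error (guards
#'   against lift-over mistakes).
#' @return list with `assignments` (per-read: `read_id`, `transcript_id`,
#'   `informative_snps_covered`, `votes_apo`, `votes_ir64`, `klass`) and
#'   `gene_counts` (per-gene: `gene_id`, `apo`, `ir64`, `unspecified`).
#' @export
assign_reads_readwise <- function(alignments, reads, snps, reference = NULL) {
  if (!is.null(reference)) {
    lens <- stats::setNames(nchar(reference), names(reference))
    bad <- snps$pos >= lens[snps$transcript_id] | snps$pos < 0L
    if (any(is.na(bad)) || any(bad))
      .stopf("SNP position outside transcript bounds")
  }
  obs <- .snp_observations(alignments, reads, snps)
  mp <- obs$mapped
  asn <- data.frame(read_id = mp$read_id,
                    transcript_id = mp$transcript_id,
                    informative_snps_covered = obs$covered,
                    votes_apo = obs$votes_apo,
                    votes_ir64 = obs$votes_ir64,
                    stringsAsFactors = FALSE)
  asn$klass <- ifelse(asn$votes_apo > 0L & asn$votes_ir64 == 0L, "APO",
                ifelse(asn$votes_ir64 > 0L & asn$votes_apo == 0L, "IR64",
                 ifelse(asn$votes_apo > 0L & asn$votes_ir64 > 0L,
                        "CONFLICT", "UNINFORMATIVE")))
  gene <- .gene_of(asn$transcript_id)
  gl <- sort(unique(gene))
  gf <- factor(gene, levels = gl)
  gene_counts <- data.frame(
    gene_id = gl,
    apo = as.integer(tapply(asn$klass == "APO", gf, sum)),
    ir64 = as.integer(tapply(asn$klass == "IR64", gf, sum)),
    unspecified = as.integer(tapply(
      asn$klass %in% c("CONFLICT", "UNINFORMATIVE"), gf, sum)),
    stringsAsFactors = FALSE)
  list(assignments = asn, gene_counts = gene_counts)
}

#' Count parental SNP observations, SNP-wise
#'
#' The contrasting strategy: every (read, SNP) observation counts, with no
#' read-level deduplication, so a read covering two Apo alleles adds two to
#' the Apo tally. Always at least the read-wise count; used for comparison
#' only.
#'
#' @inheritParams assign_reads_readwise
#' @return data frame `gene_id`, `apo_obs`, `ir64_obs`.
#' @export
count_snpwise <- function(alignments, reads, snps) {
  obs <- .snp_observations(alignments, reads, snps)
  gene <- .gene_of(obs$mapped$transcript_id)
  gl <- sort(unique(gene))
  gf <- factor(gene, levels = gl)
  data.frame(gene_id = gl,
             apo_obs = as.integer(tapply(obs$votes_apo, gf, sum)),
             ir64_obs = as.integer(tapply(obs$votes_ir64, gf, sum)),
             stringsAsFactors = FALSE)
}

# per-read SNP votes over mapped alignments
.snp_observations <- function(alignments, reads, snps) {
  mp <- alignments[alignments$mapped, , drop = FALSE]
  ridx <- match(mp$read_id, reads$read_id)
  if (anyNA(ridx)) .stopf("alignments refer to unknown reads")
  n <- nrow(mp)
  votes_apo <- votes_ir64 <- covered <- integer(n)
  if (n) {
    L <- nchar(reads$sequence[ridx])
    stx <- split(seq_len(n), mp$transcript_id)
    snp_by_tx <- split(snps, snps$transcript_id)
    for (tx in names(stx)) {
      sn <- snp_by_tx[[tx]]
      if (is.null(sn) || nrow(sn) == 0L) next
      for (i in stx[[tx]]) {
        if (!is.na(mp$indel_kind[i])) next  # gapped reads stay uninformative
        s <- mp$start[i]
        w <- which(sn$pos >= s & sn$pos < s + L[i])
        if (!length(w)) next
        covered[i] <- length(w)
        rel <- sn$pos[w] - s + 1L
        base <- substring(reads$sequence[ridx[i]], rel, rel)
        votes_apo[i] <- sum(base == sn$apo_allele[w])
        votes_ir64[i] <- sum(base == sn$ir64_allele[w])
      }
    }
  }
  list(mapped = mp, votes_apo = votes_apo, votes_ir64 = votes_ir64,
       covered = covered)
}

#' Percent of mapped reads assignable to a parental allele
#'
#' `(apo + ir64) / mapped * 100`, truncated (not rounded) to two decimals,
#' the convention of the printed per-sample summaries.
#'
#' @param apo,ir64 assigned read counts.
#' @param mapped total mapped reads.
#' @return percent, truncated to 2 decimals.
#' @export
percent_assignable <- function(apo, ir64, mapped) {
  .trunc_pct(100 * (apo + ir64) / mapped, 2L)
}

#' Tabulate allele counts per sample
#'
#' Builds the per-sample summary: assigned Apo and IR64 reads, unspecified
#' reads (mapped minus assigned), and the truncated percent assignable.
#'
#' @param samples data frame with columns `condition`, `replicate`, `apo`,
#'   `ir64`, `mapped`.
#' @return the same rows with `unspecified` and `pct_assignable` added.
#' @export
tabulate_allele_counts <- function(samples) {
  need <- c("condition", "replicate", "apo", "ir64", "mapped")
  if (!all(need %in% names(samples)))
    .stopf("samples must have columns %s", paste(need, collapse = ", "))
  samples$unspecified <- samples$mapped - samples$apo - samples$ir64
  if (any(samples$unspecified < 0))
    .stopf("assigned reads exceed mapped reads")
  samples$pct_assignable <- percent_assignable(samples$apo, samples$ir64,
                                               samples$mapped)
  samples
}
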