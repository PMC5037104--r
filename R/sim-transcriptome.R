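#' Generate a reference transcriptome
#'
#' Draws `n_genes` random transcript sequences with lengths uniform over the
#' configured range. Identifiers follow a LOC-style scheme
#' (`LOC_Os<chr>g<num>.1`) with genes laid out along 12 chromosomes;
#' physical gene coordinates are attached as the `gene_loci` attribute for
#' downstream marker co-localization.
#'
#' @param config a [sim_config()] object.
#' @return named character vector of sequences with attribute `gene_loci`
#'   (data frame: `gene_id`, `chrom`, `start`, `end`, 1-based inclusive bp).
#' @export
generate_reference_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1L) .stopf("n_genes must be >= 1")
  if (config$gene_length_range[1] < config$read_length)
    .stopf("gene_length_range lower bound < read_length")
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 n, replace = TRUE)
  chrom <- ((seq_len(n) - 1L) %% 12L) + 1L
  num <- 10L * seq_len(n)
  ids <- sprintf("LOC_Os%02dg%05d.1", chrom, num)
  seqs <- vapply(lens, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- ids
  # genomic placement: successive genes on each chromosome separated by
  # 20-200 kb intergenic gaps
  start <- integer(n)
  pos <- integer(12)
  gaps <- sample(20000:200000, n, replace = TRUE)
  for (i in seq_len(n)) {
    start[i] <- pos[chrom[i]] + gaps[i]
    pos[chrom[i]] <- start[i] + lens[i]
  }
  attr(seqs, "gene_loci") <- data.frame(
    gene_id = .gene_of(ids), chrom = chrom,
    start = start, end = start + lens - 1L,
    stringsAsFactors = FALSE)
  seqs
}

#' Gene coordinates attached to a simulated transcriptome
#'
#' @param reference output of [generate_reference_transcriptome()].
#' @return data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_loci <- function(reference) {
  gl <- attr(reference, "gene_loci")
  if (is.null(gl)) .stopf("reference carries no gene_loci attribute")
  gl
}

#' Derive the two parental haplotypes and the variant truth set
#'
#' Plants, per transcript, (a) SNPs and 1-3 bp InDels present identically in
#' both parents (Poisson with per-kb rates from `config`) and (b)
#' inter-parental SNPs (Poisson per gene) at which the two parents carry
#' different alleles, one of them matching the reference. Event positions are
#' drawn with a minimum spacing of 4 bp so no two events overlap. The truth
#' table records every planted event with its reference coordinate and its
#' coordinate in the shared-edited (pseudo-reference) frame.
#'
#' @param reference named character vector from
#'   [generate_reference_transcriptome()].
#' @param config a [sim_config()] object.
#' @return list with elements `apo`, `ir64` (named character haplotypes,
#'   identical names and lengths) and `truth`, a data frame with columns
#'   `transcript_id`, `kind` (`shared_snp`, `shared_ins`, `shared_del`,
#'   `parental_snp`), `ref_pos` (0-based), `edited_pos` (0-based, after
#'   shared edits), `len`, `ref_allele`, `alt_allele`, `apo_allele`,
#'   `ir64_allele`.
#' @export
derive_parental_haplotypes <- function(reference, config) {
  .check_reference(reference)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- names(reference)
  truth <- vector("list", length(ids))
  apo <- ir64 <- character(length(ids))
  for (i in seq_along(ids)) {
    s <- reference[[i]]
    L <- nchar(s)
    n_snp <- stats::rpois(1L, config$shared_snp_rate * L / 1000)
    n_ind <- stats::rpois(1L, config$shared_indel_rate * L / 1000)
    n_psn <- stats::rpois(1L, config$parental_snp_rate)
    ntot <- n_snp + n_ind + n_psn
    if (ntot == 0L) {
      apo[i] <- ir64[i] <- s
      next
    }
    pos <- .spaced_positions(L, ntot, min_gap = 4L)
    kind <- c(rep("shared_snp", n_snp), rep("shared_indel", n_ind),
              rep("parental_snp", n_psn))[sample.int(ntot)]
    ref_base <- substring(s, pos, pos)
    ev <- data.frame(transcript_id = ids[i], kind = kind,
                     ref_pos = pos - 1L, edited_pos = NA_integer_,
                     len = 1L, ref_allele = ref_base,
                     alt_allele = NA_character_, apo_allele = NA_character_,
                     ir64_allele = NA_character_, stringsAsFactors = FALSE)
    # shared SNPs: same non-reference base in both parents
    sh <- which(ev$kind == "shared_snp")
    for (j in sh) {
      ev$alt_allele[j] <- sample(setdiff(.BASES, ev$ref_allele[j]), 1L)
      ev$apo_allele[j] <- ev$ir64_allele[j] <- ev$alt_allele[j]
    }
    # shared InDels: 1-3 bp, insertion or deletion with equal probability
    ind <- which(ev$kind == "shared_indel")
    for (j in ind) {
      l <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        ev$kind[j] <- "shared_ins"
        ev$len[j] <- l
        # inserted after the anchor base at ref_pos
        ev$ref_allele[j] <- ""
        ev$alt_allele[j] <- paste(sample(.BASES, l, replace = TRUE),
                                  collapse = "")
      } else {
        ev$kind[j] <- "shared_del"
        ev$len[j] <- l
        ev$ref_allele[j] <- substr(s, ev$ref_pos[j] + 1L, ev$ref_pos[j] + l)
        ev$alt_allele[j] <- ""
      }
    }
    # inter-parental SNPs: one parent keeps the reference base
    ps <- which(ev$kind == "parental_snp")
    for (j in ps) {
      alt <- sample(setdiff(.BASES, ev$ref_allele[j]), 1L)
      if (stats::runif(1) < 0.5) {
        ev$apo_allele[j] <- alt; ev$ir64_allele[j] <- ev$ref_allele[j]
      } else {
        ev$apo_allele[j] <- ev$ref_allele[j]; ev$ir64_allele[j] <- alt
      }
    }
    ev <- ev[order(ev$ref_pos), , drop = FALSE]
    # coordinate of each event after applying the shared InDels
    delta <- ifelse(ev$kind == "shared_ins", ev$len,
                    ifelse(ev$kind == "shared_del", -ev$len, 0L))
    shift <- c(0L, cumsum(delta))[seq_len(nrow(ev))]
    ev$edited_pos <- ev$ref_pos + shift
    apo[i] <- .apply_events(s, ev, "apo_allele")
    ir64[i] <- .apply_events(s, ev, "ir64_allele")
    truth[[i]] <- ev
  }
  names(apo) <- names(ir64) <- ids
  truth <- if (any(!vapply(truth, is.null, logical(1)))) {
    do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  } else {
    data.frame(transcript_id = character(), kind = character(),
               ref_pos = integer(), edited_pos = integer(), len = integer(),
               ref_allele = character(), alt_allele = character(),
               apo_allele = character(), ir64_allele = character(),
               stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  list(apo = apo, ir64 = ir64, truth = truth)
}

# distinct positions in 1..(L-3), pairwise >= min_gap apart (re-draw on
# conflict so no two planted events ever overlap)
.spaced_positions <- function(L, n, min_gap = 4L) {
  hi <- L - 3L
  if (n * min_gap >= hi)
    .stopf("cannot place %d events on a %d bp transcript", n, L)
  for (try in 1:200) {
    pos <- sort(sample.int(hi, n))
    if (n == 1L || min(diff(pos)) >= min_gap) return(pos)
  }
  .stopf("failed to place %d non-overlapping events on %d bp", n, L)
}

# apply planted events to a sequence; `allele_col` selects the parent
.apply_events <- function(s, ev, allele_col) {
  for (j in rev(seq_len(nrow(ev)))) {   # right-to-left keeps positions valid
    p <- ev$ref_pos[j] + 1L             # 1-based
    al <- ev[[allele_col]][j]
    if (ev$kind[j] %in% c("shared_snp", "parental_snp")) {
      substr(s, p, p) <- al
    } else if (ev$kind[j] == "shared_ins") {
      s <- paste0(substr(s, 1L, p), ev$alt_allele[j],
                  substr(s, p + 1L, nchar(s)))
    } else {                            # shared_del
      s <- paste0(substr(s, 1L, p - 1L),
                  substr(s, p + ev$len[j], nchar(s)))
    }
  }
  s
}
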