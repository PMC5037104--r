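#' Simulate an RNA-seq library from the two parental haplotypes
#'
#' Per transcript, the read count is Poisson with mean `config$depth_per_gene`
#' (0 for genes flagged unexpressed). Each read is drawn from the Apo
#' haplotype with the transcript's mixture fraction (1 for an Apo parental
#' library, 0 for IR64, intermediate for the F1), placed uniformly, and hit
#' by independent substitution errors at `config$base_error_rate`. Base
#' qualities are constant Q35 except an optional low-quality (Q15) 3' tail of
#' `config$lowq_tail` positions. Read ids encode transcript and haplotype of
#' origin, so every read is truth-labelled.
#'
#' @param haplotypes list with named character vectors `apo` and `ir64`
#'   (equal names and lengths), e.g. from [derive_parental_haplotypes()].
#' @param mixture named numeric in `[0, 1]`: per-transcript probability that
#'   a read originates from the Apo haplotype. Names must cover the
#'   haplotype transcripts.
#' @param config a [sim_config()] object.
#' @param seed seed for this library (defaults to `config$seed`).
#' @param expressed optional named logical; unexpressed transcripts get no
#'   reads.
#' @param prefix read-id prefix identifying the library.
#' @return list with `reads` (data frame `read_id`, `sequence`, `quality`)
#'   and `truth` (data frame `read_id`, `transcript_id`, `haplotype`,
#'   `start` 0-based on the source haplotype).
#' @export
simulate_reads <- function(haplotypes, mixture, config,
                           seed = config$seed, expressed = NULL,
                           prefix = "lib") {
  if (is.null(haplotypes$apo) || is.null(haplotypes$ir64) ||
      length(haplotypes$apo) == 0L)
    .stopf("empty haplotype set")
  .check_prob(mixture[!is.na(mixture)], "mixture")
  ids <- names(haplotypes$apo)
  if (!all(ids %in% names(mixture)))
    .stopf("mixture must name every transcript")
  set.seed(seed)
  rl <- config$read_length
  e <- config$base_error_rate
  qual_tmpl <- paste(rep(rawToChar(as.raw(33L + 35L)), rl), collapse = "")
  if (config$lowq_tail > 0L) {
    t0 <- rl - min(config$lowq_tail, rl) + 1L
    substr(qual_tmpl, t0, rl) <- paste(rep(rawToChar(as.raw(33L + 15L)),
                                           rl - t0 + 1L), collapse = "")
  }
  out_r <- out_t <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tx <- ids[i]
    if (!is.null(expressed) && isFALSE(expressed[[tx]])) next
    n <- stats::rpois(1L, config$depth_per_gene)
    if (n == 0L) next
    frac <- mixture[[tx]]
    if (is.na(frac)) frac <- 0.5
    hap <- ifelse(stats::runif(n) < frac, "APO", "IR64")
    seqs <- character(n)
    starts <- integer(n)
    for (h in c("APO", "IR64")) {
      w <- which(hap == h)
      if (!length(w)) next
      src <- if (h == "APO") haplotypes$apo[[tx]] else haplotypes$ir64[[tx]]
      hl <- nchar(src)
      if (hl < rl) .stopf("haplotype %s of %s shorter than read length", h, tx)
      st <- sample.int(hl - rl + 1L, length(w), replace = TRUE) - 1L
      seqs[w] <- substring(src, st + 1L, st + rl)
      starts[w] <- st
    }
    if (e > 0) {
      nerr <- stats::rbinom(n, rl, e)
      for (w in which(nerr > 0L)) {
        r <- charToRaw(seqs[w])
        p <- sample.int(rl, nerr[w])
        for (pp in p) {
          cur <- rawToChar(r[pp])
          r[pp] <- charToRaw(sample(setdiff(.BASES, cur), 1L))
        }
        seqs[w] <- rawToChar(r)
      }
    }
    rid <- sprintf("%s|%s|%s|%06d", prefix, tx, hap, seq_len(n))
    out_r[[i]] <- data.frame(read_id = rid, sequence = seqs,
                             quality = qual_tmpl, stringsAsFactors = FALSE)
    out_t[[i]] <- data.frame(read_id = rid, transcript_id = tx,
                             haplotype = hap, start = starts,
                             stringsAsFactors = FALSE)
  }
  keep <- !vapply(out_r, is.null, logical(1))
  empty_reads <- data.frame(read_id = character(), sequence = character(),
                            quality = character(), stringsAsFactors = FALSE)
  empty_truth <- data.frame(read_id = character(), transcript_id = character(),
                            haplotype = character(), start = integer(),
                            stringsAsFactors = FALSE)
  list(reads = if (any(keep)) do.call(rbind, out_r[keep]) else empty_reads,
       truth = if (any(keep)) do.call(rbind, out_t[keep]) else empty_truth)
}

#' Read-origin truth encoded in simulated read ids
#'
#' @param read_id character vector of ids produced by [simulate_reads()].
#' @return data frame `read_id`, `transcript_id`, `haplotype`.
#' @export
read_truth_from_ids <- function(read_id) {
  parts <- strsplit(read_id, "|", fixed = TRUE)
  data.frame(read_id = read_id,
             transcript_id = vapply(parts, `[`, character(1), 2L),
             haplotype = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Simulate the full 12-library experiment
#'
#' Two parents and the F1 hybrid, each under both conditions with two
#' replicates. Parent libraries are pure (mixture 1 for Apo, 0 for IR64) and
#' express all genes; F1 libraries follow the per-gene allelic-ratio truth
#' (truth classes drawn from `config$class_probs` and realised through
#' `config$ratio_spec`, including tPAV expression on/off flags).
#'
#' @param config a [sim_config()] object.
#' @return list: `reference`, `haplotypes` (with variant truth),
#'   `libraries` (named list of read sets, names like `f1.stress.rep1`),
#'   `read_truth`, `class_truth` (data frame `gene_id`, `transcript_id`,
#'   `class`), `ratio_truth` (gene x condition Apo fractions and expression
#'   flags).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reference <- generate_reference_transcriptome(config)
  haps <- derive_parental_haplotypes(reference, config)
  ids <- names(reference)
  set.seed(config$seed + 2L)
  cls <- sample(names(config$class_probs), length(ids), replace = TRUE,
                prob = config$class_probs)
  rs <- config$ratio_spec
  m <- match(cls, rs$class)
  ratio_truth <- data.frame(
    transcript_id = ids, gene_id = .gene_of(ids), class = cls,
    frac_control = rs$frac_control[m], frac_stress = rs$frac_stress[m],
    expr_control = rs$expr_control[m], expr_stress = rs$expr_stress[m],
    stringsAsFactors = FALSE)
  # orientation is randomized per gene for the direction-free classes, so
  # the two parental alleles are favored equally often genome-wide (the
  # normalization's balanced-majority assumption then holds by design)
  flip <- cls %in% c("bidirectional", "unidirectional", "tPAV_normal",
                     "tPAV_stress") & stats::runif(length(cls)) < 0.5
  ratio_truth$frac_control[flip] <- 1 - ratio_truth$frac_control[flip]
  ratio_truth$frac_stress[flip] <- 1 - ratio_truth$frac_stress[flip]
  genos <- c("apo", "ir64", "f1")
  libs <- list()
  truths <- list()
  seeds <- .derive_seeds(config$seed + 3L, length(genos) * 2L * 2L)
  si <- 0L
  for (g in genos) for (cond in config$conditions) for (rep in 1:2) {
    si <- si + 1L
    nm <- sprintf("%s.%s.rep%d", g, cond, rep)
    mix <- switch(g,
      apo = stats::setNames(rep(1, length(ids)), ids),
      ir64 = stats::setNames(rep(0, length(ids)), ids),
      f1 = stats::setNames(
        if (cond == config$conditions[1]) ratio_truth$frac_control
        else ratio_truth$frac_stress, ids))
    expr <- if (g == "f1") {
      stats::setNames(if (cond == config$conditions[1])
        ratio_truth$expr_control else ratio_truth$expr_stress, ids)
    } else NULL
    lib <- simulate_reads(haps, mix, config, seed = seeds[si],
                          expressed = expr, prefix = nm)
    libs[[nm]] <- lib$reads
    truths[[nm]] <- lib$truth
  }
  list(reference = reference, haplotypes = haps, libraries = libs,
       read_truth = truths, class_truth = ratio_truth[, c("gene_id",
         "transcript_id", "class")], ratio_truth = ratio_truth)
}
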