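# Shared fixtures and independent oracles. Expensive simulations are
# memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

make_reads <- function(sequences, ids = sprintf("r%03d", seq_along(sequences)),
                       q = "D") {
  data.frame(read_id = ids, sequence = sequences,
             quality = vapply(nchar(sequences), function(L)
               paste(rep(q, L), collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

make_aln <- function(read_id, transcript_id, start, mismatches = 0L) {
  n <- length(read_id)
  data.frame(read_id = read_id, transcript_id = transcript_id,
             start = as.integer(start), mismatches = as.integer(mismatches),
             mapped = TRUE, indel_kind = NA_character_,
             indel_pos = NA_integer_, indel_len = NA_integer_,
             indel_seq = NA_character_, break_at = NA_integer_,
             stringsAsFactors = FALSE)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# step-by-step median-of-ratios, written independently of the package path
oracle_size_factors <- function(m) {
  geo <- apply(m, 1L, function(r) exp(mean(log(r))))
  ok <- apply(m, 1L, function(r) all(r > 0))
  apply(m, 2L, function(col) stats::median(col[ok] / geo[ok]))
}

# brute-force pileup recount (ungapped alignments only)
oracle_pileup <- function(aln, reads, reference) {
  out <- lapply(reference, function(s)
    matrix(0L, 4L, nchar(s), dimnames = list(c("A", "C", "G", "T"), NULL)))
  for (i in which(aln$mapped)) {
    sq <- reads$sequence[match(aln$read_id[i], reads$read_id)]
    ch <- strsplit(sq, "")[[1]]
    for (j in seq_along(ch)) {
      p <- aln$start[i] + j
      out[[aln$transcript_id[i]]][ch[j], p] <-
        out[[aln$transcript_id[i]]][ch[j], p] + 1L
    }
  }
  out
}

# exhaustive best ungapped placement of one read (Hamming over all offsets)
oracle_best_placement <- function(seq, reference) {
  best <- list(mm = Inf, hits = list())
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  for (tx in names(reference)) {
    rch <- strsplit(reference[[tx]], "")[[1]]
    if (length(rch) < L) next
    for (s in 0:(length(rch) - L)) {
      mm <- sum(ch != rch[(s + 1):(s + L)])
      if (mm < best$mm) best <- list(mm = mm, hits = list(c(tx = tx, s = s)))
      else if (mm == best$mm)
        best$hits[[length(best$hits) + 1L]] <- c(tx = tx, s = s)
    }
  }
  best
}

# the schematic two-SNP fixture: 12 informative reads over one transcript,
# read-wise Apo/IR64 = 8/4 while SNP-wise observations = 10/6
fig_s5_fixture <- function() {
  set.seed(404)
  ref <- c(T1 = random_seq(120))
  snps <- data.frame(transcript_id = "T1", pos = c(20L, 70L),
                     apo_allele = "A", ir64_allele = "G",
                     stringsAsFactors = FALSE)
  mk <- function(start, len, allele) {
    s <- substr(ref[["T1"]], start + 1L, start + len)
    for (p in snps$pos) {
      if (p >= start && p < start + len)
        substr(s, p - start + 1L, p - start + 1L) <- allele
    }
    s
  }
  specs <- rbind(
    data.frame(start = 10, len = 70, allele = "A", n = 2),  # 2 Apo x 2 SNPs
    data.frame(start = 0,  len = 40, allele = "A", n = 3),  # Apo x 1 SNP
    data.frame(start = 55, len = 40, allele = "A", n = 3),
    data.frame(start = 12, len = 65, allele = "G", n = 2),  # 2 IR64 x 2 SNPs
    data.frame(start = 5,  len = 30, allele = "G", n = 2))  # IR64 x 1 SNP
  seqs <- character(0); starts <- integer(0)
  for (i in seq_len(nrow(specs))) {
    seqs <- c(seqs, rep(mk(specs$start[i], specs$len[i], specs$allele[i]),
                        specs$n[i]))
    starts <- c(starts, rep(specs$start[i], specs$n[i]))
  }
  reads <- make_reads(seqs)
  list(reference = ref, snps = snps, reads = reads,
       alignments = make_aln(reads$read_id, "T1", starts))
}

# parent-only simulation at ~30x pooled coverage used for the variant-recall
# and mapping-improvement checks
recall_fixture <- function() {
  cached("recall", {
    cfg <- sim_config(n_genes = 50, gene_length_range = c(500, 1500),
                      depth_per_gene = 85, parental_snp_rate = 2,
                      base_error_rate = 0.001, seed = 42)
    ref <- generate_reference_transcriptome(cfg)
    haps <- derive_parental_haplotypes(ref, cfg)
    seeds <- 1000 + 1:8
    libs <- list()
    i <- 0
    for (par in c("apo", "ir64")) for (s in 1:4) {
      i <- i + 1
      mix <- stats::setNames(rep(if (par == "apo") 1 else 0, length(ref)),
                             names(ref))
      libs[[sprintf("%s.%d", par, s)]] <-
        simulate_reads(haps, mix, cfg, seed = seeds[i],
                       prefix = sprintf("%s.%d", par, s))$reads
    }
    idx <- kmer_index(ref, 20)
    aln_orig <- lapply(libs, map_reads, reference = ref, index = idx)
    piles <- mapply(build_pileup, aln_orig, libs,
                    MoreArgs = list(reference = ref), SIMPLIFY = FALSE)
    pool_a <- pool_pileups(piles[grep("^apo", names(piles))])
    pool_i <- pool_pileups(piles[grep("^ir64", names(piles))])
    vars <- call_shared_variants(pool_a, pool_i, ref)
    pse <- build_pseudo_reference(ref, vars)
    idx_ps <- kmer_index(pse$sequences, 20)
    aln_ps <- lapply(libs, map_reads, reference = pse$sequences,
                     index = idx_ps)
    piles_ps <- mapply(build_pileup, aln_ps, libs,
                       MoreArgs = list(reference = pse$sequences),
                       SIMPLIFY = FALSE)
    pool_a_ps <- pool_pileups(piles_ps[grep("^apo", names(piles_ps))])
    pool_i_ps <- pool_pileups(piles_ps[grep("^ir64", names(piles_ps))])
    snps <- call_parental_snps(pool_a_ps, pool_i_ps)
    list(cfg = cfg, reference = ref, haplotypes = haps, libs = libs,
         vars = vars, pse = pse, snps = snps,
         pool_a_ps = pool_a_ps, pool_i_ps = pool_i_ps,
         rate_orig = vapply(aln_orig, compute_mapping_rate, numeric(1)),
         rate_ps = vapply(aln_ps, compute_mapping_rate, numeric(1)))
  })
}

shared_truth_keys <- function(truth) {
  shared <- truth[truth$kind %in% c("shared_snp", "shared_ins", "shared_del"), ]
  paste(shared$transcript_id, shared$ref_pos,
        c(shared_snp = "SNP", shared_ins = "insertion",
          shared_del = "deletion")[shared$kind])
}
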