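test_that("quality trimming removes exactly the failing percentile positions", {
  # all positions at Q35: identity
  reads <- make_reads(rep("ACGTAC", 10), q = "D")
  expect_identical(quality_trim_replicate(reads)$sequence, reads$sequence)
  expect_length(attr(quality_trim_replicate(reads), "dropped_positions"), 0)
  # threshold 0: identity
  expect_identical(quality_trim_replicate(reads, threshold = 0)$sequence,
                   reads$sequence)
  # constructed fixture, expected kept set worked out by hand from the
  # type-7 quantile: pos1 all Q35 (keep), pos2 all Q20 (drop), pos3
  # 5xQ40+15xQ10 -> 17.5 (drop), pos4 10xQ40+10xQ10 -> 40 (keep),
  # pos5 all Q28 (keep, >= threshold), pos6 all Q27 (drop)
  qc <- function(q) rawToChar(as.raw(33L + q))
  qual <- function(p3, p4) paste0(qc(35), qc(20), qc(p3), qc(p4), qc(28),
                                  qc(27))
  quals <- c(vapply(1:5, function(i) qual(40, 40), ""),
             vapply(6:10, function(i) qual(10, 40), ""),
             vapply(11:20, function(i) qual(10, 10), ""))
  fx <- data.frame(read_id = sprintf("r%02d", 1:20),
                   sequence = rep("ACGTAC", 20), quality = quals,
                   stringsAsFactors = FALSE)
  tr <- quality_trim_replicate(fx)
  expect_identical(attr(tr, "dropped_positions"), c(2L, 3L, 6L))
  expect_identical(unique(tr$sequence), "ATA")  # positions 1, 4, 5 kept
  expect_identical(nchar(tr$quality), rep(3L, 20))
  # idempotence
  tr2 <- quality_trim_replicate(tr)
  expect_identical(tr2$sequence, tr$sequence)
  # a replicate failing everywhere is an error
  allbad <- make_reads(rep("ACGTAC", 4), q = qc(10))
  expect_error(quality_trim_replicate(allbad), "entirely trimmed")
  expect_error(quality_trim_replicate(make_reads(c("ACGT", "ACGTA"))),
               "uniform")
})

test_that("the mapper reports the exhaustively best ungapped placement", {
  set.seed(21)
  ref <- c(A.1 = random_seq(400), B.1 = random_seq(380), C.1 = random_seq(350))
  # exact unique substring: mapped with 0 mismatches at the right offset
  reads <- make_reads(substr(ref[["A.1"]], 101, 160))
  aln <- map_reads(reads, ref, max_mismatches = 4, seed_length = 20)
  expect_true(aln$mapped)
  expect_identical(aln$transcript_id, "A.1")
  expect_identical(aln$start, 100L)
  expect_identical(aln$mismatches, 0L)
  # max_mismatches + 1 substitutions: unmapped
  s <- substr(ref[["B.1"]], 51, 110)
  for (p in c(25, 30, 35, 40, 45)) {  # clear of the first seed
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  aln2 <- map_reads(make_reads(s), ref, max_mismatches = 4, seed_length = 20)
  expect_false(aln2$mapped)
  # random reads with few errors agree with the exhaustive oracle
  set.seed(22)
  qs <- character(30); truth <- list()
  for (i in 1:30) {
    tx <- sample(names(ref), 1)
    st <- sample(0:(nchar(ref[[tx]]) - 60), 1)
    sq <- substr(ref[[tx]], st + 1, st + 60)
    nerr <- sample(0:2, 1)
    if (nerr) for (p in sample(60, nerr)) {
      cur <- substr(sq, p, p)
      substr(sq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    qs[i] <- sq
  }
  reads <- make_reads(qs)
  aln3 <- map_reads(reads, ref, max_mismatches = 4, seed_length = 20)
  for (i in 1:30) {
    o <- oracle_best_placement(qs[i], ref)
    if (aln3$mapped[i]) {
      expect_lte(aln3$mismatches[i], 4)
      expect_equal(aln3$mismatches[i], o$mm)
      expect_true(any(vapply(o$hits, function(h)
        h[["tx"]] == aln3$transcript_id[i] &&
          as.integer(h[["s"]]) == aln3$start[i], logical(1))))
    }
  }
  expect_error(map_reads(make_reads("ACGT"), ref, seed_length = 20),
               "seed_length")
})

test_that("best-score ties across genes unmap; ties among splice variants pick the first", {
  base <- random_seq(300, seed = 33)
  shared <- substr(base, 101, 160)
  # same 60-mer embedded in two different genes -> ambiguous, unmapped
  two_genes <- c(X.1 = base, Y.1 = paste0(random_seq(100), shared,
                                          random_seq(100)))
  aln <- map_reads(make_reads(shared), two_genes, max_mismatches = 2,
                   seed_length = 20)
  expect_false(aln$mapped)
  # two splice variants of one gene -> lexicographically first variant
  variants <- c(X.2 = base, X.1 = base)
  aln2 <- map_reads(make_reads(shared), variants, max_mismatches = 2,
                    seed_length = 20)
  expect_true(aln2$mapped)
  expect_identical(aln2$transcript_id, "X.1")
})

test_that("an error-free simulated library maps completely to its own haplotypes", {
  cfg <- sim_config(n_genes = 10, gene_length_range = c(500, 900),
                    depth_per_gene = 40, base_error_rate = 0, seed = 15)
  ref <- generate_reference_transcriptome(cfg)
  h <- derive_parental_haplotypes(ref, cfg)
  mix <- stats::setNames(rep(0.5, length(ref)), names(ref))
  lib <- simulate_reads(h, mix, cfg, seed = 16)
  # mapping against the union of both haplotype sequence sets would be
  # ambiguous; per-haplotype mapping of the matching reads must be total
  apo_reads <- lib$reads[lib$truth$haplotype == "APO", ]
  aln <- map_reads(apo_reads, h$apo)
  expect_equal(compute_mapping_rate(aln), 100)
  expect_true(all(aln$mismatches == 0))
})

test_that("SAM import honors coordinates and flags, and round-trips exactly", {
  set.seed(44)
  ref <- c(T1.1 = random_seq(200), T2.1 = random_seq(180))
  reads <- make_reads(c(substr(ref[["T1.1"]], 1, 50),
                        substr(ref[["T2.1"]], 31, 80),
                        random_seq(50)))
  aln <- map_reads(reads, ref, max_mismatches = 3, seed_length = 20)
  expect_identical(aln$start[1], 0L)     # POS 1 is internal start 0
  expect_false(aln$mapped[3])
  tmp <- tempfile(fileext = ".sam")
  write_sam(aln, reads, ref, tmp)
  lines <- readLines(tmp)
  expect_identical(sum(grepl("^@SQ", lines)), 2L)
  body <- strsplit(grep("^@", lines, value = TRUE, invert = TRUE), "\t")
  expect_identical(body[[1]][4], "1")    # 1-based POS on output
  expect_identical(body[[3]][2], "4")    # unmapped flag
  back <- import_alignments(tmp, ref)
  expect_equal(back, aln)
  # header naming a sequence absent from the reference is rejected
  expect_error(import_alignments(tmp, ref[1]), "not in reference")
  # malformed record carries its line number
  writeLines(c("@HD\tVN:1.6", "only\tthree\tfields"), tmp)
  expect_error(import_alignments(tmp, ref), "line 2")
})

test_that("mapping rate is mapped over total, in percent", {
  aln <- data.frame(mapped = c(rep(TRUE, 8), rep(FALSE, 2)))
  expect_equal(compute_mapping_rate(aln), 80)
  expect_equal(compute_mapping_rate(data.frame(mapped = rep(TRUE, 5))), 100)
})

test_that("pileups match a brute-force recount and conserve depth", {
  set.seed(55)
  ref <- c(T1.1 = random_seq(150), T2.1 = random_seq(120))
  # one error-free read: every covered column has depth 1, base == reference
  r1 <- make_reads(substr(ref[["T1.1"]], 11, 40))
  a1 <- make_aln(r1$read_id, "T1.1", 10L)
  p1 <- build_pileup(a1, r1, ref)
  d <- pileup_depth(p1, "T1.1")
  expect_identical(unname(d[11:40]), rep(1L, 30))
  expect_identical(sum(d), 30L)
  refcodes <- strsplit(ref[["T1.1"]], "")[[1]]
  hit <- apply(p1$columns[["T1.1"]]$bases[, 11:40], 2, function(cl)
    rownames(p1$columns[["T1.1"]]$bases)[cl > 0])
  expect_identical(hit, refcodes[11:40])
  # two overlapping reads disagreeing at one site: two base types, depth 2
  s2 <- substr(ref[["T1.1"]], 11, 40)
  substr(s2, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(s2, 5, 5))[1]
  r2 <- make_reads(c(substr(ref[["T1.1"]], 11, 40), s2))
  a2 <- make_aln(r2$read_id, "T1.1", c(10L, 10L))
  p2 <- build_pileup(a2, r2, ref)
  expect_identical(unname(pileup_depth(p2, "T1.1")[15]), 2L)
  expect_identical(sum(p2$columns[["T1.1"]]$bases[, 15] > 0), 2L)
  # random fixture vs brute-force recount
  n <- 40L
  txs <- sample(names(ref), n, replace = TRUE)
  starts <- vapply(txs, function(tx)
    sample(0:(nchar(ref[[tx]]) - 30), 1), numeric(1))
  seqs <- vapply(seq_len(n), function(i) {
    s <- substr(ref[[txs[i]]], starts[i] + 1, starts[i] + 30)
    if (i %% 3 == 0) {
      p <- sample(30, 1)
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    s
  }, character(1))
  rr <- make_reads(seqs)
  aa <- make_aln(rr$read_id, txs, starts)
  pp <- build_pileup(aa, rr, ref)
  oo <- oracle_pileup(aa, rr, ref)
  for (tx in names(ref))
    expect_identical(unname(pp$columns[[tx]]$bases), unname(oo[[tx]]))
  # depth conservation: total depth equals total aligned bases
  expect_identical(sum(vapply(names(ref), function(tx)
    sum(pileup_depth(pp, tx)), integer(1))), n * 30L)
  # out-of-bounds alignment is rejected
  bad <- make_aln("rX", "T2.1", 110L)
  expect_error(build_pileup(bad, make_reads("ACGTACGTACGTACGTACGT", "rX"),
                            ref), "bounds")
})
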