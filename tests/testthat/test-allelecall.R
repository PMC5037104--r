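# helper: parental pileups with given allele counts at one position
two_parent_pileups <- function(ref, pos, a_base, b_base, n_a, n_b) {
  mk <- function(base, n) {
    s0 <- max(0L, pos - 10L)
    s <- substr(ref[["T1.1"]], s0 + 1L, s0 + 40L)
    substr(s, pos - s0 + 1L, pos - s0 + 1L) <- base
    reads <- make_reads(rep(s, n))
    build_pileup(make_aln(reads$read_id, "T1.1", s0), reads, ref)
  }
  list(apo = mk(a_base, n_a), ir64 = mk(b_base, n_b))
}

test_that("inter-parental SNP calling follows the 3x / >0.8 rule", {
  set.seed(71)
  ref <- c(T1.1 = random_seq(120))
  p <- two_parent_pileups(ref, 30L, "A", "G", 10, 10)
  sn <- call_parental_snps(p$apo, p$ir64)
  expect_identical(nrow(sn), 1L)
  expect_identical(sn$pos, 30L)
  expect_identical(sn$apo_allele, "A")
  expect_identical(sn$ir64_allele, "G")
  # one parent below 3x: not emitted
  p2 <- two_parent_pileups(ref, 30L, "A", "G", 2, 10)
  expect_identical(nrow(call_parental_snps(p2$apo, p2$ir64)), 0L)
  # identical majority alleles: not a parental SNP
  p3 <- two_parent_pileups(ref, 30L, "A", "A", 10, 10)
  expect_identical(nrow(call_parental_snps(p3$apo, p3$ir64)), 0L)
})

test_that("planted inter-parental SNPs are recalled against the pseudo-reference", {
  fx <- recall_fixture()
  tr <- fx$haplotypes$truth
  par <- tr[tr$kind == "parental_snp", ]
  called <- paste(fx$snps$transcript_id, fx$snps$pos)
  expect_gte(mean(paste(par$transcript_id, par$edited_pos) %in% called), 0.95)
  # called alleles match the planted ones
  m <- match(paste(par$transcript_id, par$edited_pos), called)
  ok <- !is.na(m)
  expect_identical(fx$snps$apo_allele[m[ok]], par$apo_allele[ok])
  expect_identical(fx$snps$ir64_allele[m[ok]], par$ir64_allele[ok])
})

test_that("read-wise assignment counts reads once, handles conflicts and errors", {
  set.seed(72)
  ref <- c(G1.1 = random_seq(150))
  snps <- data.frame(transcript_id = "G1.1", pos = c(20L, 50L),
                     apo_allele = "A", ir64_allele = "G",
                     stringsAsFactors = FALSE)
  mk <- function(b1, b2) {
    # read spans 0-based positions 10..69; SNP pos 20 is read base 11,
    # SNP pos 50 is read base 41
    s <- substr(ref[["G1.1"]], 11, 70)
    substr(s, 11, 11) <- b1
    substr(s, 41, 41) <- b2
    s
  }
  reads <- make_reads(c(mk("A", "A"),   # two Apo votes -> one APO read
                        mk("A", "G"),   # conflict -> unspecified
                        mk("C", "A"),   # error base ignored -> APO
                        mk("C", "T"),   # nothing matches -> uninformative
                        mk("G", "G")))  # IR64
  aln <- make_aln(reads$read_id, "G1.1", 10L)
  res <- assign_reads_readwise(aln, reads, snps, reference = ref)
  expect_identical(res$assignments$klass,
                   c("APO", "CONFLICT", "APO", "UNINFORMATIVE", "IR64"))
  expect_identical(res$assignments$informative_snps_covered, rep(2L, 5))
  gc <- res$gene_counts
  expect_identical(gc$apo, 2L)
  expect_identical(gc$ir64, 1L)
  expect_identical(gc$unspecified, 2L)
  # partition invariant: apo + ir64 + unspecified == mapped reads
  expect_identical(gc$apo + gc$ir64 + gc$unspecified, sum(aln$mapped))
  # SNP-wise counts every observation, conflict reads included
  sw <- count_snpwise(aln, reads, snps)
  expect_identical(sw$apo_obs, 4L)   # 2 (read 1) + 1 (read 2) + 1 (read 3)
  expect_identical(sw$ir64_obs, 3L)  # 1 (read 2) + 2 (read 5)
  # a SNP placed beyond the transcript end trips the lift-over guard
  bad <- rbind(snps, data.frame(transcript_id = "G1.1", pos = 500L,
                                apo_allele = "A", ir64_allele = "G"))
  expect_error(assign_reads_readwise(aln, reads, bad, reference = ref),
               "outside transcript")
})

test_that("the two-SNP schematic yields read-wise 8/4 and SNP-wise 10/6", {
  fx <- fig_s5_fixture()
  rw <- assign_reads_readwise(fx$alignments, fx$reads, fx$snps,
                              reference = fx$reference)
  expect_identical(rw$gene_counts$apo, 8L)
  expect_identical(rw$gene_counts$ir64, 4L)
  sw <- count_snpwise(fx$alignments, fx$reads, fx$snps)
  expect_identical(sw$apo_obs, 10L)
  expect_identical(sw$ir64_obs, 6L)
})

test_that("SNP-wise dominates read-wise, with equality iff one SNP per read", {
  # random fixtures: snpwise >= readwise componentwise
  set.seed(73)
  for (rep in 1:5) {
    ref <- c(H1.1 = random_seq(300))
    snppos <- sort(sample(seq(10, 280, by = 15), 5))
    snps <- data.frame(transcript_id = "H1.1", pos = snppos,
                       apo_allele = "A", ir64_allele = "G",
                       stringsAsFactors = FALSE)
    n <- 25
    starts <- sample(0:(300 - 60), n, replace = TRUE)
    seqs <- vapply(starts, function(s0) {
      s <- substr(ref[["H1.1"]], s0 + 1, s0 + 60)
      for (p in snppos[snppos >= s0 & snppos < s0 + 60])
        substr(s, p - s0 + 1, p - s0 + 1) <- sample(c("A", "G"), 1)
      s
    }, character(1))
    reads <- make_reads(seqs)
    aln <- make_aln(reads$read_id, "H1.1", starts)
    rw <- assign_reads_readwise(aln, reads, snps)$gene_counts
    sw <- count_snpwise(aln, reads, snps)
    expect_gte(sw$apo_obs, rw$apo)
    expect_gte(sw$ir64_obs, rw$ir64)
  }
  # exhaustive enumeration on single-SNP-per-read fixtures: exact equality
  ref <- c(E1.1 = random_seq(120, seed = 74))
  snps1 <- data.frame(transcript_id = "E1.1", pos = 60L,
                      apo_allele = "A", ir64_allele = "G",
                      stringsAsFactors = FALSE)
  for (combo in 0:7) {
    alleles <- ifelse(bitwAnd(combo, 2^(0:2)) > 0, "A", "G")
    seqs <- vapply(alleles, function(al) {
      s <- substr(ref[["E1.1"]], 41, 100)
      substr(s, 20, 20) <- al
      s
    }, character(1))
    reads <- make_reads(unname(seqs))
    aln <- make_aln(reads$read_id, "E1.1", 40L)
    rw <- assign_reads_readwise(aln, reads, snps1)$gene_counts
    sw <- count_snpwise(aln, reads, snps1)
    expect_identical(sw$apo_obs, rw$apo)
    expect_identical(sw$ir64_obs, rw$ir64)
  }
})

test_that("swapping the parent labels of all SNPs swaps the counts exactly", {
  fx <- fig_s5_fixture()
  sw_snps <- fx$snps
  sw_snps$apo_allele <- fx$snps$ir64_allele
  sw_snps$ir64_allele <- fx$snps$apo_allele
  a <- assign_reads_readwise(fx$alignments, fx$reads, fx$snps)$gene_counts
  b <- assign_reads_readwise(fx$alignments, fx$reads, sw_snps)$gene_counts
  expect_identical(a$apo, b$ir64)
  expect_identical(a$ir64, b$apo)
  expect_identical(a$unspecified, b$unspecified)
})

test_that("assignable percentages reproduce the published per-sample arithmetic", {
  # control rep 1 and rep 2, water-stress rep 2 of the published run
  expect_identical(percent_assignable(276827, 282901, 21860178), 2.56)
  expect_identical(percent_assignable(1378264, 1403493, 51364894), 5.41)
  expect_identical(percent_assignable(1399485, 1454190, 54525736), 5.23)
  expect_identical(percent_assignable(0, 0, 1000), 0)
  tab <- tabulate_allele_counts(data.frame(
    condition = "control", replicate = "rep1",
    apo = 276827, ir64 = 282901, mapped = 21860178))
  expect_identical(tab$unspecified, 21860178 - 276827 - 282901)
  expect_identical(tab$pct_assignable, 2.56)
})

test_that("a 70:30 allelic mixture is recovered within the binomial interval", {
  cfg <- sim_config(n_genes = 3, gene_length_range = c(600, 900),
                    depth_per_gene = 500, parental_snp_rate = 6,
                    shared_snp_rate = 0, shared_indel_rate = 0,
                    base_error_rate = 0, seed = 75)
  ref <- generate_reference_transcriptome(cfg)
  h <- derive_parental_haplotypes(ref, cfg)
  mix <- stats::setNames(rep(0.7, length(ref)), names(ref))
  lib <- simulate_reads(h, mix, cfg, seed = 76)
  aln <- map_reads(lib$reads, ref)
  tr <- h$truth[h$truth$kind == "parental_snp", ]
  snps <- data.frame(transcript_id = tr$transcript_id, pos = tr$edited_pos,
                     apo_allele = tr$apo_allele,
                     ir64_allele = tr$ir64_allele, stringsAsFactors = FALSE)
  gc <- assign_reads_readwise(aln, lib$reads, snps)$gene_counts
  n <- sum(gc$apo + gc$ir64)
  share <- sum(gc$apo) / n
  expect_lt(abs(share - 0.7), stats::qnorm(0.995) * sqrt(0.7 * 0.3 / n))
})
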