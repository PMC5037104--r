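#' Pipeline configuration
#'
#' Every tunable of the end-to-end analysis in one validated list: the
#' simulation block and the thresholds of each stage (shared-variant and
#' parental-SNP calling, trimming, mapping, AI testing, profile
#' classification, marker association).
#'
#' @param sim a [sim_config()] (the pipeline's input generator).
#' @param snp_min_depth,snp_min_prop shared-SNP thresholds (depth >= 5,
#'   proportion > 0.8).
#' @param indel_min_depth,indel_min_prop shared-InDel thresholds (depth >=
#'   5, proportion >= 0.5).
#' @param parental_min_depth,parental_min_prop inter-parental SNP
#'   thresholds (depth >= 3, proportion > 0.8).
#' @param fc_thresholds fold thresholds for ASE classes.
#' @param alpha significance level.
#' @param chisq_min_expected expected-value filter of the chi-square test.
#' @param trim_threshold,trim_percentile quality-trimming parameters.
#' @param seed_length,max_mismatches mapper parameters (`NULL` mismatch cap
#'   means lenient: 30 % of the read length).
#' @param window_kb co-localization window.
#' @param tail_fraction selective-genotyping tail fraction.
#' @param mode profile significance rule, `"lenient"` or `"stringent"`.
#' @param n_lines RIL panel size.
#' @param n_markers,n_polymorphic,n_qtl,qtl_effect,heritability RIL marker
#'   survey and trait architecture.
#' @param map_f1_to_original also map F1 libraries to the original
#'   reference to report their mapping-rate improvement.
#' @param seed master seed of the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            snp_min_depth = 5L, snp_min_prop = 0.8,
                            indel_min_depth = 5L, indel_min_prop = 0.5,
                            parental_min_depth = 3L, parental_min_prop = 0.8,
                            fc_thresholds = c(1.25, 2.0),
                            alpha = 0.05,
                            chisq_min_expected = 5,
                            trim_threshold = 28, trim_percentile = 0.75,
                            seed_length = 20L, max_mismatches = NULL,
                            window_kb = 500, tail_fraction = 0.25,
                            mode = "lenient",
                            n_lines = 160L, n_markers = 153L,
                            n_polymorphic = 22L, n_qtl = 2L,
                            qtl_effect = 2.0, heritability = 0.6,
                            map_f1_to_original = TRUE,
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  for (v in c(snp_min_depth, snp_min_prop, indel_min_depth, indel_min_prop,
              parental_min_depth, parental_min_prop, fc_thresholds,
              window_kb, tail_fraction))
    if (any(v <= 0)) .stopf("thresholds must be positive")
  if (alpha < 0 || alpha > 1) .stopf("alpha must be in [0, 1]")
  if (!mode %in% c("lenient", "stringent")) .stopf("unknown mode '%s'", mode)
  cfg <- list(sim = sim, snp_min_depth = snp_min_depth,
              snp_min_prop = snp_min_prop,
              indel_min_depth = indel_min_depth,
              indel_min_prop = indel_min_prop,
              parental_min_depth = parental_min_depth,
              parental_min_prop = parental_min_prop,
              fc_thresholds = fc_thresholds, alpha = alpha,
              chisq_min_expected = chisq_min_expected,
              trim_threshold = trim_threshold,
              trim_percentile = trim_percentile,
              seed_length = as.integer(seed_length),
              max_mismatches = max_mismatches,
              window_kb = window_kb, tail_fraction = tail_fraction,
              mode = mode, n_lines = as.integer(n_lines),
              n_markers = as.integer(n_markers),
              n_polymorphic = as.integer(n_polymorphic),
              n_qtl = as.integer(n_qtl), qtl_effect = qtl_effect,
              heritability = heritability,
              map_f1_to_original = isTRUE(map_f1_to_original),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] defaults; keys under `sim`
#' override [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim %||% list()
  y$sim <- NULL
  cfg <- do.call(sim_config, simargs)
  do.call(pipeline_config, c(list(sim = cfg), y))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full ASE pipeline on simulated data
#'
#' Executes simulate, trim, map (original reference), pseudo-reference
#' construction, re-map (pseudo-reference), inter-parental SNP calling,
#' read-wise F1 allele assignment, per-condition AI testing, cross-condition
#' profile classification and the marker association stage (co-localization
#' plus tail-selected single-marker regression), and evaluates every stage
#' against the simulation truth. Re-running with the same configuration
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all stage tables plus a
#'   run manifest are written there (see [write_pipeline_reports()]).
#' @param verbose print stage progress.
#' @return object of class `ase_pipeline_run`; see the elements
#'   `allele_counts`, `ai`, `ai_summaries`, `profiles`, `profile_summary`,
#'   `colocalization`, `association`, `evaluation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  conds <- config$sim$conditions

  say("simulate")
  sim <- .stage("simulate", simulate_experiment(config$sim))
  libs <- sim$libraries

  say("trim")
  libs <- .stage("trim", lapply(libs, quality_trim_replicate,
                                threshold = config$trim_threshold,
                                percentile = config$trim_percentile))

  mm <- config$max_mismatches %||% ceiling(0.3 * config$sim$read_length)
  parent_libs <- grep("^(apo|ir64)\\.", names(libs), value = TRUE)
  f1_libs <- grep("^f1\\.", names(libs), value = TRUE)

  say("map to original reference")
  idx_orig <- kmer_index(sim$reference, config$seed_length)
  orig_libs <- if (config$map_f1_to_original) names(libs) else parent_libs
  aln_orig <- .stage("map", lapply(
    stats::setNames(orig_libs, orig_libs),
    function(nm) map_reads(libs[[nm]], sim$reference, max_mismatches = mm,
                           seed_length = config$seed_length,
                           index = idx_orig)))
  rate_orig <- vapply(aln_orig, compute_mapping_rate, numeric(1))

  say("pseudo-reference")
  pse <- .stage("pseudoref", {
    piles <- lapply(parent_libs, function(nm)
      build_pileup(aln_orig[[nm]], libs[[nm]], sim$reference))
    names(piles) <- parent_libs
    pool_a <- pool_pileups(piles[grep("^apo\\.", parent_libs, value = TRUE)])
    pool_i <- pool_pileups(piles[grep("^ir64\\.", parent_libs, value = TRUE)])
    vars <- call_shared_variants(pool_a, pool_i, sim$reference,
                                 snp_min_depth = config$snp_min_depth,
                                 snp_min_prop = config$snp_min_prop,
                                 indel_min_depth = config$indel_min_depth,
                                 indel_min_prop = config$indel_min_prop)
    build_pseudo_reference(sim$reference, vars)
  })

  say("map to pseudo-reference")
  idx_ps <- kmer_index(pse$sequences, config$seed_length)
  aln_ps <- .stage("map", lapply(
    stats::setNames(names(libs), names(libs)),
    function(nm) map_reads(libs[[nm]], pse$sequences, max_mismatches = mm,
                           seed_length = config$seed_length,
                           index = idx_ps)))
  rate_ps <- vapply(aln_ps, compute_mapping_rate, numeric(1))
  mapping <- data.frame(
    library = names(rate_ps),
    rate_original = unname(rate_orig[names(rate_ps)]),
    rate_pseudo = unname(rate_ps),
    stringsAsFactors = FALSE)
  mapping$improvement <- mapping$rate_pseudo - mapping$rate_original

  say("parental SNPs")
  snps <- .stage("snp", {
    piles <- lapply(parent_libs, function(nm)
      build_pileup(aln_ps[[nm]], libs[[nm]], pse$sequences))
    names(piles) <- parent_libs
    call_parental_snps(
      pool_pileups(piles[grep("^apo\\.", parent_libs, value = TRUE)]),
      pool_pileups(piles[grep("^ir64\\.", parent_libs, value = TRUE)]),
      min_depth = config$parental_min_depth,
      min_prop = config$parental_min_prop)
  })

  say("assign F1 reads")
  assign_res <- .stage("assign", lapply(
    stats::setNames(f1_libs, f1_libs),
    function(nm) assign_reads_readwise(aln_ps[[nm]], libs[[nm]], snps,
                                       reference = pse$sequences)))
  sample_tab <- do.call(rbind, lapply(f1_libs, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    gc <- assign_res[[nm]]$gene_counts
    data.frame(condition = parts[2], replicate = parts[3],
               apo = sum(gc$apo), ir64 = sum(gc$ir64),
               mapped = sum(aln_ps[[nm]]$mapped),
               stringsAsFactors = FALSE)
  }))
  allele_counts <- tabulate_allele_counts(sample_tab)

  say("AI test")
  ai <- .stage("aitest", {
    res <- list()
    for (cond in conds) {
      mats <- lapply(1:2, function(r) {
        gc <- assign_res[[sprintf("f1.%s.rep%d", cond, r)]]$gene_counts
        gc[gc$apo + gc$ir64 > 0, , drop = FALSE]
      })
      genes <- sort(unique(c(mats[[1]]$gene_id, mats[[2]]$gene_id)))
      if (!length(genes)) {
        res[[cond]] <- NULL
        next
      }
      m <- matrix(0L, length(genes), 4L,
                  dimnames = list(genes, c("apo_rep1", "apo_rep2",
                                           "ir64_rep1", "ir64_rep2")))
      for (r in 1:2) {
        i <- match(mats[[r]]$gene_id, genes)
        m[i, r] <- mats[[r]]$apo
        m[i, r + 2L] <- mats[[r]]$ir64
      }
      res[[cond]] <- ai_test(m, condition = cond, alpha = config$alpha,
                             thresholds = config$fc_thresholds,
                             min_expected = config$chisq_min_expected)
    }
    res
  })
  ai_summaries <- lapply(ai, function(r)
    lapply(config$fc_thresholds, function(th) summarize_ai(r, threshold = th)))

  say("profiles")
  profiles <- .stage("profiles", compare_conditions(
    ai[[conds[1]]], ai[[conds[2]]], mode = config$mode,
    threshold = config$fc_thresholds[1], alpha = config$alpha))
  prof_sum <- profile_summary(profiles)

  say("markers and RILs")
  loci <- gene_loci(sim$reference)
  seeds <- .derive_seeds(config$seed + 11L, 2L)
  markers <- simulate_marker_map(loci, n_markers = config$n_markers,
                                 n_polymorphic = config$n_polymorphic,
                                 n_qtl = config$n_qtl,
                                 qtl_effect = config$qtl_effect,
                                 seed = seeds[1])
  panel <- simulate_ril_panel(ril_truth(markers, config$heritability),
                              n_lines = config$n_lines, seed = seeds[2])
  means <- ls_means(panel$phenotypes)
  tails <- select_tails(means, config$tail_fraction)
  assoc <- .stage("smr", marker_association(panel, lines = tails))
  ai_genes <- loci[loci$gene_id %in% profiles$gene_id, , drop = FALSE]
  coloc <- .stage("colocalize",
                  colocalize(ai_genes, markers, window_kb = config$window_kb))

  evaluation <- .evaluate_run(sim, pse, snps, profiles, mapping, assoc,
                              markers)
  manifest <- list(
    package = "asepipe",
    version = as.character(utils::packageVersion("asepipe")),
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("sim"))],
    sim = config$sim[setdiff(names(config$sim),
                             c("ratio_spec", "class_probs"))],
    n_reads = vapply(libs, nrow, integer(1)),
    n_shared_variants = nrow(pse$provenance),
    n_parental_snps = nrow(snps))

  run <- structure(list(config = config, truth = sim[c("class_truth",
                          "ratio_truth")],
                        variant_truth = sim$haplotypes$truth,
                        mapping = mapping, pseudo_reference = pse,
                        parental_snps = snps,
                        allele_counts = allele_counts, ai = ai,
                        ai_summaries = ai_summaries, profiles = profiles,
                        profile_summary = prof_sum, markers = markers,
                        panel = panel, tails = tails,
                        colocalization = coloc, association = assoc,
                        evaluation = evaluation, manifest = manifest),
                   class = "ase_pipeline_run")
  if (!is.null(outdir)) write_pipeline_reports(run, outdir)
  run
}

# compare recovered results against planted truth
.evaluate_run <- function(sim, pse, snps, profiles, mapping, assoc, markers) {
  tr <- sim$haplotypes$truth
  # shared-variant recall (called at the planted reference coordinate)
  shared <- tr[tr$kind %in% c("shared_snp", "shared_ins", "shared_del"), ]
  called <- pse$provenance
  key_called <- paste(called$transcript_id, called$pos,
                      ifelse(called$kind == "SNP", "snp", called$kind))
  key_truth <- paste(shared$transcript_id, shared$ref_pos,
                     c(shared_snp = "snp", shared_ins = "insertion",
                       shared_del = "deletion")[shared$kind])
  shared_recall <- if (nrow(shared)) mean(key_truth %in% key_called) else NA
  # parental-SNP recall in pseudo-reference coordinates (equal to the
  # generator's shared-edited coordinates when every shared call is exact)
  par <- tr[tr$kind == "parental_snp", ]
  pkey_called <- paste(snps$transcript_id, snps$pos)
  pkey_truth <- paste(par$transcript_id, par$edited_pos)
  parental_recall <- if (nrow(par)) mean(pkey_truth %in% pkey_called) else NA
  # profile-class recovery for planted tPAV / bidirectional / unidirectional
  # (expected subtype from the realised per-gene orientation)
  rt <- sim$ratio_truth
  ev <- rt[rt$class %in% c("tPAV_normal", "tPAV_stress", "bidirectional",
                           "unidirectional"), , drop = FALSE]
  expected <- ifelse(ev$class %in% c("tPAV_normal", "tPAV_stress"), ev$class,
    ifelse(ev$class == "unidirectional",
           ifelse(ev$frac_control > 0.5, "unidirectional_apo",
                  "unidirectional_ir64"),
           ifelse(ev$frac_control > 0.5, "bidirectional_apo_to_ir64",
                  "bidirectional_ir64_to_apo")))
  got <- profiles$class[match(ev$gene_id, profiles$gene_id)]
  profile_recovery <- if (nrow(ev))
    100 * mean(!is.na(got) & got == expected) else NA
  qtl <- markers$name[markers$effect != 0]
  top <- assoc$marker[which.min(assoc$p_value)]
  list(shared_variant_recall = shared_recall,
       parental_snp_recall = parental_recall,
       profile_recovery_pct = profile_recovery,
       min_mapping_improvement = min(mapping$improvement),
       mean_mapping_improvement = mean(mapping$improvement),
       qtl_markers = qtl,
       top_marker = top,
       qtl_is_top = top %in% qtl)
}

#' Write the report bundle of a pipeline run
#'
#' One TSV per stage (sample allele counts, AI results and summaries per
#' condition and threshold, profile table and summary, variant and SNP
#' tables, mapping rates, co-localization and association tables) plus a
#' JSON manifest capturing the seed and every threshold. Output is
#' deterministic: re-running an identical configuration reproduces the
#' files byte for byte.
#'
#' @param run an `ase_pipeline_run`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_reports <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(run$allele_counts, p("allele_counts.tsv"))
  for (cond in names(run$ai))
    write_tsv(as.data.frame(run$ai[[cond]]), p(sprintf("ai_%s.tsv", cond)))
  sum_rows <- list()
  for (cond in names(run$ai_summaries))
    for (s in run$ai_summaries[[cond]])
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        condition = cond, threshold = s$threshold,
        n_apo_favoring = s$n_apo_favoring,
        n_ir64_favoring = s$n_ir64_favoring,
        n_total_ai = s$n_total_ai, n_significant = s$n_significant,
        pct_ai_over_significant = s$pct_ai_over_significant,
        n_biallelic = s$n_biallelic, stringsAsFactors = FALSE)
  write_tsv(do.call(rbind, sum_rows), p("ai_summary.tsv"))
  write_tsv(as.data.frame(run$profiles), p("profiles.tsv"))
  ps <- run$profile_summary
  write_tsv(data.frame(class = ps$class_names, count = ps$class_counts,
                       pct = ps$class_pct, stringsAsFactors = FALSE),
            p("profile_summary.tsv"))
  write_tsv(run$pseudo_reference$provenance, p("shared_variants.tsv"))
  write_tsv(run$parental_snps, p("parental_snps.tsv"))
  write_tsv(run$mapping, p("mapping_rates.tsv"))
  write_tsv(run$colocalization, p("colocalization.tsv"))
  write_tsv(as.data.frame(run$association), p("association.tsv"))
  write_fasta(run$pseudo_reference$sequences, p("pseudo_reference.fasta"))
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.ase_pipeline_run <- function(x, ...) {
  cat("ASE pipeline run\n")
  cat(sprintf("  %d shared variants edited into the pseudo-reference; %d inter-parental SNPs\n",
              nrow(x$pseudo_reference$provenance), nrow(x$parental_snps)))
  cat(sprintf("  mean mapping-rate improvement on the pseudo-reference: %.2f %%\n",
              mean(x$mapping$improvement)))
  cat(sprintf("  profile universe: %d genes; planted-profile recovery %.1f %%\n",
              x$profile_summary$n_total, x$evaluation$profile_recovery_pct))
  invisible(x)
}
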