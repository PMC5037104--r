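#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study system: a japonica-like cDNA reference; two indica-like parents
#' (Apo, IR64) sharing about 0.92 SNPs/kb and 0.07 InDels/kb against that
#' reference; sparse inter-parental SNPs (Poisson mean 0.72 per gene);
#' single-end 90 bp reads.
#'
#' @param n_genes number of transcripts to simulate (>= 1).
#' @param gene_length_range integer length-2 vector, transcript length bounds
#'   in bp; the lower bound must be >= `read_length`.
#' @param shared_snp_rate SNPs/kb common to both parents vs the reference.
#' @param shared_indel_rate InDels/kb common to both parents vs the reference.
#' @param parental_snp_rate Poisson mean of inter-parental SNPs per gene.
#' @param read_length read length in bp.
#' @param depth_per_gene mean reads per gene per library (Poisson).
#' @param base_error_rate per-base substitution error probability.
#' @param conditions condition labels; the first is the control.
#' @param class_probs named numeric, mixing proportions of the truth classes;
#'   must sum to 1 and use the same names as `ratio_spec`.
#' @param ratio_spec data frame mapping each truth class to its Apo allelic
#'   fraction and expression flag per condition; see [default_ratio_spec()].
#' @param lowq_tail number of 3' positions given low (Q15) base quality to
#'   exercise trimming; 0 disables.
#' @param seed integer master seed; a fixed seed gives byte-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200L,
                       gene_length_range = c(500L, 3000L),
                       shared_snp_rate = 0.92,
                       shared_indel_rate = 0.07,
                       parental_snp_rate = 0.72,
                       read_length = 90L,
                       depth_per_gene = 100,
                       base_error_rate = 0.001,
                       conditions = c("control", "stress"),
                       class_probs = NULL,
                       ratio_spec = default_ratio_spec(),
                       lowq_tail = 0L,
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    .stopf("n_genes must be >= 1")
  if (length(gene_length_range) != 2L ||
      gene_length_range[1] > gene_length_range[2])
    .stopf("gene_length_range must be an increasing length-2 interval")
  if (gene_length_range[1] < read_length)
    .stopf("gene_length_range lower bound (%d) < read_length (%d)",
           gene_length_range[1], read_length)
  for (r in c(shared_snp_rate, shared_indel_rate, parental_snp_rate,
              depth_per_gene))
    if (r < 0) .stopf("rates must be >= 0")
  .check_prob(base_error_rate, "base_error_rate")
  if (length(conditions) != 2L) .stopf("exactly two conditions are supported")
  if (is.null(class_probs)) {
    class_probs <- c(biallelic = 0.40, apo_favoring = 0.06,
                     ir64_favoring = 0.06, monoallelic_apo = 0.02,
                     monoallelic_ir64 = 0.02, tPAV_normal = 0.06,
                     tPAV_stress = 0.04, bidirectional = 0.05,
                     unidirectional = 0.29)
  }
  if (abs(sum(class_probs) - 1) > 1e-8) .stopf("class_probs must sum to 1")
  if (!setequal(names(class_probs), ratio_spec$class))
    .stopf("class_probs names must match ratio_spec classes")
  if (length(seed) != 1L || is.na(seed)) .stopf("seed must be a single integer")
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 shared_snp_rate = shared_snp_rate,
                 shared_indel_rate = shared_indel_rate,
                 parental_snp_rate = parental_snp_rate,
                 read_length = as.integer(read_length),
                 depth_per_gene = depth_per_gene,
                 base_error_rate = base_error_rate,
                 conditions = conditions,
                 class_probs = class_probs,
                 ratio_spec = ratio_spec,
                 lowq_tail = as.integer(lowq_tail),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default allelic-ratio assignments per truth class
#'
#' For each truth class, the Apo fraction of F1 transcripts per condition and
#' whether the gene is expressed in the F1 under that condition. Monoallelic
#' classes use fractions of exactly 0 or 1; tPAV classes are expressed in one
#' condition only. The true per-gene ratios of the organism are unknowable,
#' so these are the generator's own choices (see the methods vignette).
#'
#' @return data frame with columns `class`, `frac_control`, `frac_stress`,
#'   `expr_control`, `expr_stress`.
#' @export
default_ratio_spec <- function() {
  data.frame(
    class = c("biallelic", "apo_favoring", "ir64_favoring", "monoallelic_apo",
              "monoallelic_ir64", "tPAV_normal", "tPAV_stress",
              "bidirectional", "unidirectional"),
    frac_control = c(0.5, 0.70, 0.30, 1, 0, 0.75, NA, 0.75, 0.80),
    frac_stress  = c(0.5, 0.50, 0.50, 1, 0, NA, 0.25, 0.25, 0.80),
    expr_control = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    expr_stress  = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genes: %d (%d-%d bp), reads: %d bp, depth %s/gene\n",
              x$n_genes, x$gene_length_range[1], x$gene_length_range[2],
              x$read_length, format(x$depth_per_gene)))
  cat(sprintf("  shared variants: %.2f SNPs/kb, %.2f InDels/kb; parental SNPs: %.2f/gene\n",
              x$shared_snp_rate, x$shared_indel_rate, x$parental_snp_rate))
  cat(sprintf("  base error %.4g, conditions: %s, seed %d\n",
              x$base_error_rate, paste(x$conditions, collapse = "/"), x$seed))
  invisible(x)
}
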