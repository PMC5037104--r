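#' Simulate an SSR marker map over the simulated genome
#'
#' Places RM-style microsatellite markers on the chromosomes spanned by the
#' simulated genes. A fixed number are polymorphic between the two parents
#' (only those can be scored in the RIL panel), and a subset of the
#' polymorphic markers carry planted additive effects on the phenotype.
#'
#' @param loci gene coordinate table from [gene_loci()].
#' @param n_markers total markers surveyed.
#' @param n_polymorphic markers polymorphic between the parents.
#' @param n_qtl markers (among the polymorphic) with a planted effect.
#' @param qtl_effect phenotype units per allele substitution at each QTL.
#' @param seed integer seed.
#' @return data frame `name`, `chrom`, `pos_bp`, `polymorphic`, `effect`.
#' @export
simulate_marker_map <- function(loci, n_markers = 153L, n_polymorphic = 22L,
                                n_qtl = 2L, qtl_effect = 2.0, seed = 1L) {
  if (n_polymorphic > n_markers) .stopf("n_polymorphic > n_markers")
  if (n_qtl > n_polymorphic) .stopf("n_qtl > n_polymorphic")
  set.seed(seed)
  chroms <- sort(unique(loci$chrom))
  span <- stats::aggregate(end ~ chrom, data = loci, FUN = max)
  chrom <- sample(chroms, n_markers, replace = TRUE)
  pos <- integer(n_markers)
  for (i in seq_len(n_markers)) {
    hi <- span$end[span$chrom == chrom[i]] + 500000L
    pos[i] <- sample.int(hi, 1L)
  }
  poly <- logical(n_markers)
  poly[sample.int(n_markers, n_polymorphic)] <- TRUE
  eff <- numeric(n_markers)
  eff[sample(which(poly), n_qtl)] <- qtl_effect
  data.frame(name = sprintf("RM%04d", seq_len(n_markers) * 7L),
             chrom = chrom, pos_bp = pos, polymorphic = poly,
             effect = eff, stringsAsFactors = FALSE)
}

#' Ground truth for a recombinant-inbred-line panel
#'
#' @param markers marker map from [simulate_marker_map()] (or any data frame
#'   with `name`, `polymorphic`, `effect`).
#' @param heritability fraction of single-replicate phenotypic variance
#'   explained by the planted marker effects, in `[0, 1]`.
#' @return object of class `ril_truth`.
#' @export
ril_truth <- function(markers, heritability = 0.6) {
  if (!is.numeric(heritability) || length(heritability) != 1L ||
      is.na(heritability) || heritability < 0 || heritability > 1)
    .stopf("heritability must be in [0, 1]")
  if (any(!is.finite(markers$effect))) .stopf("effect sizes must be finite")
  structure(list(markers = markers, heritability = heritability),
            class = "ril_truth")
}

#' Simulate a recombinant-inbred-line (RIL) panel
#'
#' Emulates an F3:5 panel from a biparental cross: at each polymorphic
#' marker, lines are IR64 homozygotes (code 1) or Apo homozygotes (code 2)
#' in near-equal proportions with a residual heterozygote fraction of
#' 1/16 (code 3, the expectation after three selfing generations); a small
#' fraction of calls is missing (code 0). Monomorphic markers score
#' identically in every line. Phenotypes are the sum of planted additive
#' marker effects (scores 0/1/2 on the true genotype) plus Gaussian noise
#' scaled so the planted effects explain `heritability` of the
#' single-replicate variance; two replicate values per line are returned.
#' With zero planted effects and `heritability = 1` all phenotypes are
#' equal; with zero effects and `heritability < 1` the phenotype is pure
#' noise with variance `1 - heritability`.
#'
#' @param truth a [ril_truth()] object.
#' @param n_lines number of lines (>= 4).
#' @param seed integer seed.
#' @param het_fraction heterozygote fraction at polymorphic markers.
#' @param missing_fraction fraction of genotype calls set to missing.
#' @return object of class `ril_panel`: list with `genotypes` (lines x
#'   markers integer codes 0/1/2/3), `phenotypes` (lines x 2),
#'   `markers`, `truth`, and `true_genotypes` (codes before missingness).
#' @export
simulate_ril_panel <- function(truth, n_lines = 160L, seed = 1L,
                               het_fraction = 1 / 16,
                               missing_fraction = 0.02) {
  stopifnot(inherits(truth, "ril_truth"))
  if (n_lines < 4L) .stopf("n_lines must be >= 4")
  set.seed(seed)
  mk <- truth$markers
  nm <- nrow(mk)
  lines <- sprintf("RIL%03d", seq_len(n_lines))
  g <- matrix(1L, n_lines, nm, dimnames = list(lines, mk$name))
  p_hom <- (1 - het_fraction) / 2
  for (j in which(mk$polymorphic)) {
    g[, j] <- sample(c(1L, 2L, 3L), n_lines, replace = TRUE,
                     prob = c(p_hom, p_hom, het_fraction))
  }
  score <- matrix(c(`1` = 0, `2` = 2, `3` = 1)[as.character(g)],
                  n_lines, nm)
  gval <- drop(score %*% mk$effect)
  var_g <- stats::var(gval)
  h2 <- truth$heritability
  sigma2 <- if (var_g > 0) {
    if (h2 == 0) .stopf("heritability 0 with non-zero planted effects")
    var_g * (1 - h2) / h2
  } else {
    1 - h2
  }
  phen <- matrix(gval, n_lines, 2) +
    matrix(stats::rnorm(2L * n_lines, sd = sqrt(sigma2)), n_lines, 2)
  dimnames(phen) <- list(lines, c("rep1", "rep2"))
  gobs <- g
  if (missing_fraction > 0) {
    miss <- matrix(stats::runif(n_lines * nm) < missing_fraction, n_lines, nm)
    gobs[miss] <- 0L
  }
  structure(list(genotypes = gobs, true_genotypes = g, phenotypes = phen,
                 markers = mk, truth = truth, lines = lines),
            class = "ril_panel")
}

#' @export
print.ril_panel <- function(x, ...) {
  cat(sprintf("RIL panel: %d lines x %d markers (%d polymorphic), 2 phenotype replicates\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$markers$polymorphic)))
  invisible(x)
}
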