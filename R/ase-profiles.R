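#' Classify condition-mediated ASE profiles between two conditions
#'
#' Pairwise comparison of per-gene allelic imbalance between control and
#' stress. The gene universe contains genes with informative counts in at
#' least one condition that pass the mode's significance rule: lenient, P <
#' alpha in one or both conditions; stringent, P < alpha in both (tPAV genes
#' need it only in their expressed condition). Classes:
#'
#' * `tPAV_normal` / `tPAV_stress`: detected (>= 1 informative read) in one
#'   condition only -- transcript presence/absence variation;
#' * `bidirectional_apo_to_ir64` / `bidirectional_ir64_to_apo`: asymmetric
#'   (fold magnitude >= `threshold`) in both conditions with opposite
#'   favored alleles, sub-typed by the control-to-stress change;
#' * `unidirectional_apo` / `unidirectional_ir64`: asymmetric in both with
#'   the same favored allele;
#' * `biallelic_unclassified`: below the fold threshold in either condition;
#'   the condition-mediated behavior of such genes cannot be ascertained.
#'
#' @param records_control,records_stress `ai_result` tables of the two
#'   conditions over the same gene universe.
#' @param mode `"lenient"` (default) or `"stringent"` significance rule.
#' @param threshold fold threshold defining asymmetry.
#' @param alpha significance level.
#' @return data frame of class `ase_profiles`: `gene_id`, `class`,
#'   `log2fc_control`, `log2fc_stress`, `p_control`, `p_stress`.
#' @export
compare_conditions <- function(records_control, records_stress,
                               mode = c("lenient", "stringent"),
                               threshold = 1.25, alpha = 0.05) {
  mode <- match.arg(mode)
  for (r in list(records_control, records_stress))
    if (anyDuplicated(r$gene_id))
      .stopf("duplicate gene ids within one condition's records")
  gc <- records_control$gene_id
  gs <- records_stress$gene_id
  all_g <- sort(union(gc, gs))
  mc <- match(all_g, gc)
  ms <- match(all_g, gs)
  det_c <- !is.na(mc) &
    (records_control$apo_combined[mc] + records_control$ir64_combined[mc]) > 0
  det_s <- !is.na(ms) &
    (records_stress$apo_combined[ms] + records_stress$ir64_combined[ms]) > 0
  p_c <- ifelse(is.na(mc), NA, records_control$p_binomial[mc])
  p_s <- ifelse(is.na(ms), NA, records_stress$p_binomial[ms])
  sig_c <- det_c & !is.na(p_c) & p_c < alpha
  sig_s <- det_s & !is.na(p_s) & p_s < alpha
  in_universe <- if (mode == "lenient") {
    (det_c | det_s) & (sig_c | sig_s)
  } else {
    ifelse(det_c & det_s, sig_c & sig_s,           # common genes: both
           ifelse(det_c, sig_c, sig_s))            # tPAV: its own condition
  }
  keep <- which(in_universe)
  mag_c <- records_control$magnitude[mc]
  mag_s <- records_stress$magnitude[ms]
  dir_c <- records_control$direction[mc]
  dir_s <- records_stress$direction[ms]
  cls <- character(length(all_g))
  for (i in keep) {
    cls[i] <- if (det_c[i] && !det_s[i]) {
      "tPAV_normal"
    } else if (det_s[i] && !det_c[i]) {
      "tPAV_stress"
    } else if (!is.na(mag_c[i]) && !is.na(mag_s[i]) &&
               mag_c[i] >= threshold && mag_s[i] >= threshold) {
      if (dir_c[i] == dir_s[i]) {
        if (dir_c[i] == "Apo") "unidirectional_apo" else "unidirectional_ir64"
      } else {
        if (dir_c[i] == "Apo") "bidirectional_apo_to_ir64"
        else "bidirectional_ir64_to_apo"
      }
    } else {
      "biallelic_unclassified"
    }
  }
  out <- data.frame(gene_id = all_g[keep], class = cls[keep],
                    log2fc_control = records_control$log2fc[mc[keep]],
                    log2fc_stress = records_stress$log2fc[ms[keep]],
                    p_control = p_c[keep], p_stress = p_s[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("ase_profiles", "data.frame")
  out
}

#' Summarize ASE profile classes
#'
#' Class counts and their percentages of the profile universe (one
#' decimal), plus the split into genes common to both conditions and genes
#' unique to one.
#'
#' @param records an `ase_profiles` table.
#' @return object of class `ase_profile_summary`.
#' @export
profile_summary <- function(records) {
  lv <- c("tPAV_normal", "tPAV_stress", "bidirectional_ir64_to_apo",
          "bidirectional_apo_to_ir64", "unidirectional_apo",
          "unidirectional_ir64", "biallelic_unclassified")
  counts <- table(factor(records$class, levels = lv))
  n_total <- nrow(records)
  n_unique_control <- unname(counts[["tPAV_normal"]])
  n_unique_stress <- unname(counts[["tPAV_stress"]])
  grouped <- c(tPAV = n_unique_control + n_unique_stress,
               bidirectional = unname(counts[["bidirectional_ir64_to_apo"]] +
                                        counts[["bidirectional_apo_to_ir64"]]),
               unidirectional = unname(counts[["unidirectional_apo"]] +
                                         counts[["unidirectional_ir64"]]),
               biallelic_unclassified =
                 unname(counts[["biallelic_unclassified"]]))
  structure(list(n_total = n_total,
                 n_common = n_total - n_unique_control - n_unique_stress,
                 n_unique_control = n_unique_control,
                 n_unique_stress = n_unique_stress,
                 class_counts = as.integer(counts),
                 class_names = lv,
                 grouped_counts = grouped,
                 class_pct = profile_percent(as.integer(counts), n_total),
                 grouped_pct = profile_percent(grouped, n_total)),
            class = "ase_profile_summary")
}

#' Percent of the profile universe, one decimal
#'
#' @param count class count(s).
#' @param n_total universe size.
#' @return `100 * count / n_total` rounded to one decimal.
#' @export
profile_percent <- function(count, n_total) {
  if (n_total <= 0) return(rep(NA_real_, length(count)))
  round(100 * count / n_total, 1L)
}

#' @export
print.ase_profile_summary <- function(x, ...) {
  cat(sprintf("ASE profile universe: %d genes (%d common, %d control-only, %d stress-only)\n",
              x$n_total, x$n_common, x$n_unique_control, x$n_unique_stress))
  for (i in seq_along(x$grouped_counts))
    cat(sprintf("  %-24s %5d  (%.1f %%)\n", names(x$grouped_counts)[i],
                x$grouped_counts[i], x$grouped_pct[i]))
  invisible(x)
}
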