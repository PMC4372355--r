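# Delta-delta Ct relative quantification and its concordance with the
# RNA-Seq calls. Multiple reference (housekeeping) genes are combined by
# the arithmetic mean of their Ct values per replicate; amplification
# efficiency is fixed at 2 (the classical method).

as_ref_matrix <- function(refs) {
  if (is.null(dim(refs))) refs <- matrix(refs, ncol = 1)
  refs
}

#' Delta-delta Ct relative abundance
#'
#' Per condition, delta Ct is the mean target Ct minus the mean of the
#' per-replicate combined (averaged across reference genes) reference Ct;
#' delta-delta Ct is the treated minus the control delta Ct; the relative
#' abundance is `2^-ddCt`.
#'
#' @param target_treated,target_control Numeric vectors of replicate target
#'   Ct values.
#' @param refs_treated,refs_control Reference Ct values: a vector (one
#'   reference gene) or a replicates x reference-genes matrix.
#' @return Relative abundance (treated/control), > 0.
#' @export
#' @examples
#' delta_delta_ct(24, 20, 25, 20)  # ddCt = -1 -> 2
delta_delta_ct <- function(target_treated, refs_treated,
                           target_control, refs_control) {
  refs_treated <- as_ref_matrix(refs_treated)
  refs_control <- as_ref_matrix(refs_control)
  stop_if_not(length(target_treated) >= 1 && length(target_control) >= 1,
              "need at least one replicate per condition")
  vals <- c(target_treated, target_control, refs_treated, refs_control)
  stop_if_not(!anyNA(vals), "missing Ct measurements")
  stop_if_not(all(vals > 0), "Ct values must be positive")
  dct_treated <- mean(target_treated) - mean(rowMeans(refs_treated))
  dct_control <- mean(target_control) - mean(rowMeans(refs_control))
  2^-(dct_treated - dct_control)
}

#' Relative abundances from a Ct table
#'
#' @param ct_table Data frame with columns gene_id, sample ("control" /
#'   "treated"), replicate, ct, is_reference, as produced by
#'   [gen_qpcr_ct()] or read from TSV.
#' @return Named numeric vector: relative abundance (treated/control) per
#'   target gene.
#' @export
qpcr_relative_abundance <- function(ct_table) {
  needed <- c("gene_id", "sample", "replicate", "ct", "is_reference")
  stop_if_not(all(needed %in% names(ct_table)),
              "Ct table must have gene_id, sample, replicate, ct, is_reference")
  refs <- ct_table[ct_table$is_reference, , drop = FALSE]
  stop_if_not(nrow(refs) > 0, "missing reference measurements")
  ref_mat <- function(sample) {
    sub <- refs[refs$sample == sample, , drop = FALSE]
    stop_if_not(nrow(sub) > 0, "missing reference measurements")
    m <- tapply(sub$ct, list(sub$replicate, sub$gene_id), mean)
    stop_if_not(!anyNA(m), "unbalanced reference replicates")
    m
  }
  targets <- unique(ct_table$gene_id[!ct_table$is_reference])
  rt <- ref_mat("treated")
  rc <- ref_mat("control")
  out <- vapply(targets, function(g) {
    tt <- ct_table$ct[ct_table$gene_id == g & ct_table$sample == "treated" &
                        !ct_table$is_reference]
    tc <- ct_table$ct[ct_table$gene_id == g & ct_table$sample == "control" &
                        !ct_table$is_reference]
    delta_delta_ct(tt, rt, tc, rc)
  }, numeric(1))
  stats::setNames(out, targets)
}

#' Concordance of qPCR ratios with RNA-Seq calls
#'
#' A gene agrees when the sign of its log2 qPCR ratio matches the RNA-Seq
#' call direction (up with positive, down with negative). A ratio of exactly
#' 1 has no direction and never agrees; non-directional RNA-Seq calls
#' ("not_significant", "undetected") likewise never agree.
#'
#' @param qpcr_ratios Named numeric vector of relative abundances.
#' @param rnaseq_calls Named character vector of calls over {"up", "down",
#'   "not_significant", "undetected"}.
#' @return A list with `fraction` (agreeing/total over the shared genes),
#'   `n_agree`, `n_total` and the per-gene logical `agree`.
#' @export
concordance <- function(qpcr_ratios, rnaseq_calls) {
  shared <- intersect(names(qpcr_ratios), names(rnaseq_calls))
  stop_if_not(length(shared) > 0, "no shared genes between qPCR and RNA-Seq")
  lr <- log2(qpcr_ratios[shared])
  calls <- rnaseq_calls[shared]
  agree <- (calls == "up" & lr > 0) | (calls == "down" & lr < 0)
  list(fraction = mean(agree), n_agree = sum(agree),
       n_total = length(shared), agree = agree)
}
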