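# Cross-root-type aggregation of differential-transcription calls:
# up/down tallies per root, the union of salinity-regulated genes, the
# root-specific sets, and the down-regulated fractions.

#' Percentage of down-regulated genes among a root's DTGs
#'
#' @param up_count,down_count Per-root up- and down-regulated gene counts;
#'   their sum must be positive.
#' @return 100 * down / (up + down), rounded half away from zero to one
#'   decimal.
#' @export
#' @examples
#' down_fraction(13, 199)  # 93.9
#' down_fraction(54, 94)   # 63.5
down_fraction <- function(up_count, down_count) {
  stop_if_not(all(up_count >= 0) && all(down_count >= 0),
              "counts must be non-negative")
  stop_if_not(all(up_count + down_count > 0),
              "no called genes: up + down must be positive")
  round_half_up(100 * down_count / (up_count + down_count), 1)
}

#' Summarise DTG calls across the three root types
#'
#' "Regulated" means call is "up" or "down"; undetected and non-significant
#' genes never enter the union or the specific sets. A gene regulated in
#' several roots (even in opposite directions) counts once in the union and
#' belongs to no root-specific set.
#'
#' @param calls_by_root Named list of three per-comparison call tables (the
#'   output of [run_comparison()], or any data frame with `gene_id` and
#'   `call`), one per root type.
#' @return A list of class `root_comparison_summary`: `per_root` (data frame
#'   with root, up_count, down_count, total_count, specific_count,
#'   down_pct), `union_count`, `union_gene_ids` and `specific_gene_ids`
#'   (named list).
#' @export
summarize_roots <- function(calls_by_root) {
  stop_if_not(length(calls_by_root) == 3 && !is.null(names(calls_by_root)),
              "calls_by_root must be a named list of three call tables")
  regulated <- lapply(calls_by_root, function(df) {
    stop_if_not(all(c("gene_id", "call") %in% names(df)),
                "call tables need gene_id and call columns")
    stop_if_not(!anyDuplicated(df$gene_id),
                "duplicated gene ids within a comparison")
    df$gene_id[df$call %in% c("up", "down")]
  })
  union_genes <- sort(unique(unlist(regulated, use.names = FALSE)))
  membership <- vapply(regulated, function(g) union_genes %in% g,
                       logical(length(union_genes)))
  if (length(union_genes) == 1L) membership <- matrix(membership, nrow = 1)
  n_roots_per_gene <- if (length(union_genes)) rowSums(membership) else integer()
  specific <- lapply(seq_along(regulated), function(i)
    union_genes[membership[, i] & n_roots_per_gene == 1])
  names(specific) <- names(calls_by_root)
  per_root <- do.call(rbind, lapply(names(calls_by_root), function(root) {
    calls <- calls_by_root[[root]]$call
    up <- sum(calls == "up")
    down <- sum(calls == "down")
    data.frame(root = root, up_count = up, down_count = down,
               total_count = up + down,
               specific_count = length(specific[[root]]),
               down_pct = if (up + down > 0) down_fraction(up, down) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_root = per_root,
                 union_count = length(union_genes),
                 union_gene_ids = union_genes,
                 specific_gene_ids = specific),
            class = "root_comparison_summary")
}
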