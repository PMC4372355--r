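# RPKM quantification and mapping summaries.
#
# RPKM = 1e6 * C / (N * L / 1e3), where C is the number of reads uniquely
# aligned to the gene, N the total number of reads uniquely aligned to all
# genes in the library, and L the gene length in bases. N is the
# gene-mapped total (not the genome-mapped one), following the formula's
# own definition of N.

#' Reads per kilobase per million uniquely gene-mapped reads
#'
#' @param C Per-gene uniquely aligned read count (vectorised).
#' @param N Total reads uniquely aligned to all genes in the library; > 0.
#' @param L Gene length in bases; >= 1.
#' @return RPKM values, non-negative and finite.
#' @export
#' @examples
#' rpkm(5, 1e6, 2000)  # 2.5
rpkm <- function(C, N, L) {
  stop_if_not(all(N > 0), "library total N must be positive")
  stop_if_not(all(L >= 1), "gene length L must be >= 1")
  stop_if_not(all(C >= 0), "counts must be non-negative")
  1e6 * as.numeric(C) / (as.numeric(N) * as.numeric(L) / 1e3)
}

#' RPKM matrix across libraries
#'
#' @param libraries Named list of [count_library()] objects sharing the same
#'   gene list and lengths.
#' @return A list with `rpkm` (genes x libraries numeric matrix) and
#'   `not_expressed` (logical matrix flagging zero-count cells, the "gray"
#'   class of downstream displays).
#' @export
rpkm_matrix <- function(libraries) {
  stop_if_not(length(libraries) >= 1, "need at least one library")
  ref <- libraries[[1]]
  for (lib in libraries) {
    stop_if_not(identical(names(lib$counts), names(ref$counts)),
                "libraries disagree on the gene list")
    stop_if_not(identical(unname(lib$gene_lengths), unname(ref$gene_lengths)),
                "libraries disagree on gene lengths")
  }
  ids <- unname(vapply(libraries, `[[`, character(1), "library_id"))
  mat <- vapply(libraries, function(lib)
    rpkm(lib$counts, lib$total_unique, lib$gene_lengths),
    numeric(length(ref$counts)))
  dimnames(mat) <- list(names(ref$counts), ids)
  not_expressed <- vapply(libraries, function(lib) lib$counts == 0,
                          logical(length(ref$counts)))
  dimnames(not_expressed) <- dimnames(mat)
  list(rpkm = mat, not_expressed = not_expressed)
}

#' Mapping summary with percentages
#'
#' Recomputes the percentage arithmetic of a library mapping summary:
#' mapped and unmapped percentages against both the reference-gene and the
#' reference-genome totals, at two decimals, half away from zero.
#'
#' @param total_reads Total raw reads in the library; > 0.
#' @param mapped_to_genes Reads mapped to reference genes; <= total.
#' @param mapped_to_genome Reads mapped to the reference genome; <= total.
#'   Optional (`NA` to skip).
#' @return One-row data frame with counts and derived percentages
#'   (`genes_mapped_pct`, `genes_unmapped_pct`, `genome_mapped_pct`,
#'   `genome_unmapped_pct`).
#' @export
#' @examples
#' mapping_percentages(8278219, 5473192, 6613863)  # 66.12 / 79.89
mapping_percentages <- function(total_reads, mapped_to_genes,
                                mapped_to_genome = NA) {
  stop_if_not(total_reads > 0, "total_reads must be positive")
  stop_if_not(mapped_to_genes <= total_reads && mapped_to_genes >= 0,
              "mapped_to_genes must lie in [0, total_reads]")
  pct <- function(m) round_half_up(100 * m / total_reads, 2)
  out <- data.frame(total_reads = total_reads,
                    mapped_to_genes = mapped_to_genes,
                    genes_mapped_pct = pct(mapped_to_genes),
                    genes_unmapped_pct = pct(total_reads - mapped_to_genes))
  if (!is.na(mapped_to_genome)) {
    stop_if_not(mapped_to_genome <= total_reads && mapped_to_genome >= 0,
                "mapped_to_genome must lie in [0, total_reads]")
    out$mapped_to_genome <- mapped_to_genome
    out$genome_mapped_pct <- pct(mapped_to_genome)
    out$genome_unmapped_pct <- pct(total_reads - mapped_to_genome)
  }
  out
}
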