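# GO-term over-representation of a DTG set against a background.
# One-sided hypergeometric upper tail per term (the test behind standard
# annotation-enrichment tools), Bonferroni-corrected over the number of
# tested terms; significance at corrected p <= 0.05.

#' Hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` term-annotated genes when `n` genes
#' are drawn from a background of `N` genes of which `K` are annotated.
#'
#' @param k Annotated genes in the drawn (DTG) set.
#' @param n Size of the drawn set.
#' @param K Annotated genes in the background.
#' @param N Background size.
#' @return P(X >= k), in [0, 1]. Vectorised.
#' @export
#' @examples
#' overrep_pvalue(4, 4, 5, 10)  # C(5,4)/C(10,4) = 5/210
overrep_pvalue <- function(k, n, K, N) {
  stop_if_not(all(k >= 0) && all(k <= n), "need 0 <= k <= n")
  stop_if_not(all(K <= N), "need K <= N")
  stop_if_not(all(n <= N), "need n <= N")
  stop_if_not(all(k <= K), "need k <= K")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param raw_p Raw p-values.
#' @param m Number of tests; >= 1.
#' @return min(1, raw_p * m).
#' @export
bonferroni <- function(raw_p, m) {
  stop_if_not(all(m >= 1), "m must be >= 1")
  pmin(1, raw_p * m)
}

#' Term over-representation of a DTG set
#'
#' Tests every term with at least one annotated background gene; m for the
#' Bonferroni correction is the number of such terms. The significant set is
#' independent of the input ordering of the annotation table.
#'
#' @param dtg_set Character vector of differentially transcribed gene ids;
#'   must be a subset of `background_set`.
#' @param background_set Character vector of background gene ids.
#' @param annotations Data frame with columns `gene_id` and `term_id` (one
#'   gene-term pair per row).
#' @param alpha Significance threshold on the corrected p; default 0.05.
#' @return Data frame sorted by corrected then raw p: term_id, k, n, K, N,
#'   raw_p, corrected_p, significant.
#' @export
enrich <- function(dtg_set, background_set, annotations, alpha = 0.05) {
  stop_if_not(all(c("gene_id", "term_id") %in% names(annotations)),
              "annotations need gene_id and term_id columns")
  dtg_set <- unique(dtg_set)
  background_set <- unique(background_set)
  stop_if_not(all(dtg_set %in% background_set),
              "DTG set contains genes outside the background")
  ann <- annotations[annotations$gene_id %in% background_set, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  terms <- sort(unique(ann$term_id))
  if (length(terms) == 0)
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), raw_p = numeric(),
                      corrected_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  N <- length(background_set)
  n <- length(dtg_set)
  m <- length(terms)
  K <- vapply(terms, function(tm) sum(ann$term_id == tm), integer(1))
  k <- vapply(terms, function(tm)
    sum(ann$gene_id[ann$term_id == tm] %in% dtg_set), integer(1))
  raw_p <- overrep_pvalue(k, n, K, N)
  corrected_p <- bonferroni(raw_p, m)
  out <- data.frame(term_id = terms, k = unname(k), n = n, K = unname(K),
                    N = N, raw_p = unname(raw_p),
                    corrected_p = unname(corrected_p),
                    significant = unname(corrected_p <= alpha),
                    stringsAsFactors = FALSE)
  out <- out[order(out$corrected_p, out$raw_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
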