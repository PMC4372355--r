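# Exact between-library differential-transcription test.
#
# For one gene with clean-tag counts x and y in two libraries of totals N1
# and N2, the probability of observing y given x is
#
#   p(y | x) = (N2/N1)^y * (x+y)! / (x! y!) * (1 + N2/N1)^-(x+y+1)
#
# the classic single-library digital-gene-expression (tag-count) test.
# Evaluation is done in log-gamma space so large counts neither overflow
# nor lose the leading digits. A two-sided p-value is built from the
# cumulative tails of this mass, doubled and capped at 1.

#' Exact test probability mass p(y | x)
#'
#' @param x,y Non-negative integer clean-tag counts of the gene in the
#'   control (x) and treatment (y) library. Vectorised.
#' @param N1,N2 Total clean tags in the control and treatment library; > 0.
#' @return Probability mass in (0, 1].
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
#' ac_probability(1, 1, 1e6, 1e6)  # 0.25
ac_probability <- function(x, y, N1, N2) {
  stop_if_not(all(x >= 0) && all(y >= 0), "counts must be non-negative")
  stop_if_not(all(N1 > 0) && all(N2 > 0), "library totals must be positive")
  r <- N2 / N1
  # the lgamma terms are grouped so the expression is exactly symmetric in
  # (x, y) when N1 = N2 (addition commutes bitwise, subtraction chains don't)
  exp(y * log(r) + lgamma(x + y + 1) - (lgamma(x + 1) + lgamma(y + 1)) -
        (x + y + 1) * log1p(r))
}

# lower cumulative tail P(Y <= y | x); y = -1 gives 0
ac_lower_tail <- function(x, y, N1, N2) {
  if (y < 0) return(0)
  r <- N2 / N1
  k <- 0:y
  sum(exp(k * log(r) + lgamma(x + k + 1) - (lgamma(x + 1) + lgamma(k + 1)) -
            (x + k + 1) * log1p(r)))
}

#' Two-sided exact test p-value
#'
#' Doubles the smaller of the two cumulative tails of `p(. | x)` at the
#' observed y and caps at 1. The upper tail is evaluated as one minus the
#' lower tail below y, so no infinite summation is needed.
#'
#' @inheritParams ac_probability
#' @return Two-sided p-values in (0, 1]. Vectorised over `x`, `y`.
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  stop_if_not(all(x >= 0) && all(y >= 0), "counts must be non-negative")
  stop_if_not(all(N1 > 0) && all(N2 > 0), "library totals must be positive")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) {
    lower <- ac_lower_tail(x[i], y[i], N1[i], N2[i])
    # roundoff in the cumulative sum can push the complement a few ulp
    # outside [0, 1]; clamp before doubling
    upper <- max(0, 1 - ac_lower_tail(x[i], y[i] - 1, N1[i], N2[i]))
    min(1, max(0, 2 * min(lower, upper)))
  }, numeric(1))
}

#' One-sided tails of the exact test (for audit)
#'
#' @inheritParams ac_probability
#' @return A list with `lower` = P(Y <= y | x) and `upper` = P(Y >= y | x).
#' @export
ac_tails <- function(x, y, N1, N2) {
  list(lower = min(1, ac_lower_tail(x, y, N1, N2)),
       upper = max(0, 1 - ac_lower_tail(x, y - 1, N1, N2)))
}

#' False discovery rate adjustment
#'
#' Benjamini-Hochberg step-up by default; Benjamini-Yekutieli available for
#' dependence-robust control. Output order matches input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method "BH" (default) or "BY".
#' @return Adjusted q-values in input order.
#' @export
fdr_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  stop_if_not(all(p >= 0 & p <= 1, na.rm = FALSE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Calling thresholds for differentially transcribed genes
#'
#' @param fdr_max Maximum FDR q-value; default 0.001.
#' @param min_abs_log2 Minimum |log2(treatment/control)|; default 1.
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(fdr_max = 0.001, min_abs_log2 = 1.0) {
  stop_if_not(fdr_max > 0 && fdr_max <= 1, "fdr_max must lie in (0, 1]")
  stop_if_not(min_abs_log2 >= 0, "min_abs_log2 must be >= 0")
  structure(list(fdr_max = fdr_max, min_abs_log2 = min_abs_log2),
            class = "calling_thresholds")
}

#' Call differential-transcription status
#'
#' A gene is called up when q <= fdr_max and log2 ratio >= min_abs_log2,
#' down when q <= fdr_max and log2 ratio <= -min_abs_log2 (both boundaries
#' inclusive). Genes with zero expression in at least one library are
#' "undetected" and never receive a directional call; everything else is
#' "not_significant".
#'
#' @param q_value FDR-adjusted values.
#' @param log2_ratio log2(treatment/control) expression ratios (NA allowed
#'   for undetected genes).
#' @param undetected Logical: zero expression in >= 1 library.
#' @param thresholds A [calling_thresholds()].
#' @return Character vector over {"up", "down", "not_significant",
#'   "undetected"}.
#' @export
call_dtg <- function(q_value, log2_ratio, undetected,
                     thresholds = calling_thresholds()) {
  n <- max(length(q_value), length(log2_ratio), length(undetected))
  q_value <- rep_len(q_value, n)
  log2_ratio <- rep_len(log2_ratio, n)
  undetected <- rep_len(undetected, n)
  call <- rep("not_significant", n)
  sig <- !undetected & !is.na(q_value) & q_value <= thresholds$fdr_max
  call[sig & log2_ratio >= thresholds$min_abs_log2] <- "up"
  call[sig & log2_ratio <= -thresholds$min_abs_log2] <- "down"
  call[undetected] <- "undetected"
  call
}

#' Run one treatment-vs-control comparison
#'
#' Tests every shared gene on its raw clean-tag counts (x = control,
#' y = treatment), adjusts the p-values across all genes of the comparison,
#' computes the log2 ratio from RPKM (library size and gene length cancel
#' consistently) and applies the calling thresholds. Genes with zero RPKM in
#' either library are flagged "undetected" rather than pseudocounted.
#'
#' @param control,treatment [count_library()] objects over the same genes.
#' @param thresholds A [calling_thresholds()].
#' @param fdr_method "BH" or "BY".
#' @return Data frame with one row per gene: gene_id, x, y, N1, N2,
#'   rpkm_control, rpkm_treatment, log2_ratio, p_value, q_value, call.
#' @export
run_comparison <- function(control, treatment,
                           thresholds = calling_thresholds(),
                           fdr_method = "BH") {
  stop_if_not(identical(names(control$counts), names(treatment$counts)),
              "control and treatment disagree on the gene list")
  stop_if_not(identical(unname(control$gene_lengths),
                        unname(treatment$gene_lengths)),
              "control and treatment disagree on gene lengths")
  x <- control$counts
  y <- treatment$counts
  N1 <- control$total_unique
  N2 <- treatment$total_unique
  rpkm_c <- rpkm(x, N1, control$gene_lengths)
  rpkm_t <- rpkm(y, N2, treatment$gene_lengths)
  undetected <- rpkm_c == 0 | rpkm_t == 0
  log2_ratio <- ifelse(undetected, NA_real_, log2(rpkm_t / rpkm_c))
  p <- ac_pvalue(x, y, N1, N2)
  q <- fdr_adjust(p, fdr_method)
  data.frame(gene_id = names(x), x = unname(x), y = unname(y),
             N1 = N1, N2 = N2,
             rpkm_control = unname(rpkm_c), rpkm_treatment = unname(rpkm_t),
             log2_ratio = unname(log2_ratio),
             p_value = unname(p), q_value = unname(q),
             call = call_dtg(q, log2_ratio, undetected, thresholds),
             stringsAsFactors = FALSE)
}
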