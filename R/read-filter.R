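# Clean-read filtering. Raw reads are removed by three ordered rules:
# (1) the read contains an adaptor sequence, (2) more than 10 percent of its
# bases are N, (3) more than 50 percent of its bases have quality <= 5.
# Both thresholds are strict ("greater than"), and a removed read is
# attributed to the first rule it violates.

#' Filtering policy for clean-read selection
#'
#' @param adaptor_sequences Character vector of adaptor sequences (may be
#'   empty); a read matching any of them verbatim is removed.
#' @param max_n_fraction Maximum tolerated N fraction; reads strictly above
#'   it are removed. Default 0.10.
#' @param low_quality_threshold A base is "low quality" when its Phred score
#'   is <= this value. Default 5.
#' @param max_low_quality_fraction Maximum tolerated fraction of low-quality
#'   bases; reads strictly above it are removed. Default 0.50.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(adaptor_sequences = character(),
                          max_n_fraction = 0.10,
                          low_quality_threshold = 5L,
                          max_low_quality_fraction = 0.50) {
  stop_if_not(max_n_fraction >= 0 && max_n_fraction <= 1,
              "max_n_fraction must lie in [0, 1]")
  stop_if_not(max_low_quality_fraction >= 0 && max_low_quality_fraction <= 1,
              "max_low_quality_fraction must lie in [0, 1]")
  stop_if_not(low_quality_threshold >= 0,
              "low_quality_threshold must be >= 0")
  structure(list(adaptor_sequences = toupper(adaptor_sequences),
                 max_n_fraction = max_n_fraction,
                 low_quality_threshold = as.integer(low_quality_threshold),
                 max_low_quality_fraction = max_low_quality_fraction),
            class = "filter_policy")
}

#' Does a read contain an adaptor?
#'
#' Exact contiguous substring match of the full adaptor; no mismatches and no
#' partial-prefix mode.
#'
#' @param bases Base string (or vector of base strings).
#' @param policy A [filter_policy()].
#' @return Logical vector.
#' @export
has_adaptor <- function(bases, policy) {
  hit <- rep(FALSE, length(bases))
  for (ad in policy$adaptor_sequences)
    hit <- hit | grepl(ad, bases, fixed = TRUE)
  hit
}

#' Fraction of unknown (N) bases in a read
#'
#' @param bases Base string (or vector); must be non-empty.
#' @return Numeric vector of N fractions. A read fails the N rule when its
#'   fraction is strictly greater than the policy's `max_n_fraction`.
#' @export
n_fraction <- function(bases) {
  len <- nchar(bases)
  stop_if_not(all(len > 0), "empty read")
  vapply(bases, function(b) sum(utf8ToInt(b) == utf8ToInt("N")),
         numeric(1), USE.NAMES = FALSE) / len
}

#' Fraction of low-quality bases in a read
#'
#' @param qual Phred+33 quality string (or vector); must be non-empty.
#' @param policy A [filter_policy()]; bases at quality <=
#'   `low_quality_threshold` count as low quality.
#' @return Numeric vector of low-quality base fractions. A read fails the
#'   quality rule when strictly greater than `max_low_quality_fraction`.
#' @export
low_quality_fraction <- function(qual, policy) {
  len <- nchar(qual)
  stop_if_not(all(len > 0), "empty quality string")
  thr <- policy$low_quality_threshold
  vapply(qual, function(q) sum(qual_to_int(q) <= thr),
         numeric(1), USE.NAMES = FALSE) / len
}

#' Filter raw reads into clean reads
#'
#' Applies the three rules in order (adaptor, N content, base quality); each
#' removed read is attributed to the first rule it violates, and the retained
#' reads keep their input order.
#'
#' @param reads A [fastq_reads()] data frame.
#' @param policy A [filter_policy()].
#' @return A list with `clean` (the retained `fastq_reads`), `stats` (a
#'   one-row data frame: input_count, removed_by_adaptor, removed_by_n,
#'   removed_by_quality, retained_count) and `rule` (per-read attribution:
#'   "clean", "adaptor", "high_n" or "low_quality").
#' @export
filter_reads <- function(reads, policy) {
  stop_if_not(all(nchar(reads$bases) == nchar(reads$qual)),
              "bases and qualities differ in length")
  n <- nrow(reads)
  rule <- rep("clean", n)
  if (n > 0) {
    ad <- has_adaptor(reads$bases, policy)
    nn <- n_fraction(reads$bases) > policy$max_n_fraction
    lq <- low_quality_fraction(reads$qual, policy) >
      policy$max_low_quality_fraction
    rule[!ad & !nn & lq] <- "low_quality"
    rule[!ad & nn] <- "high_n"
    rule[ad] <- "adaptor"
  }
  keep <- rule == "clean"
  stats <- data.frame(input_count = n,
                      removed_by_adaptor = sum(rule == "adaptor"),
                      removed_by_n = sum(rule == "high_n"),
                      removed_by_quality = sum(rule == "low_quality"),
                      retained_count = sum(keep))
  clean <- reads[keep, , drop = FALSE]
  rownames(clean) <- NULL
  class(clean) <- c("fastq_reads", "data.frame")
  list(clean = clean, stats = stats, rule = rule)
}
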