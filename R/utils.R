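#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moved away from zero,
#' the convention the mapping-summary and down-fraction percentages use
#' (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3
#' round_half_up(66.115, 2)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exact halves in decimal
  # but sit just below .5 in binary still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Write a data frame as tab-separated values
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by this package
#'
#' @param path File path.
#' @return A data frame; column names are kept verbatim.
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
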