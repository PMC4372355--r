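# FASTQ input/output. Reads are carried internally as a plain data frame
# ("fastq_reads"): read_id, bases, qual, where qual is the Phred+33-encoded
# quality string. Parsing and serialisation are delegated to Biostrings.

#' Construct a read table
#'
#' @param read_id Character vector of read identifiers.
#' @param bases Character vector of base strings over A, C, G, T, N.
#' @param qual Character vector of Phred+33-encoded quality strings,
#'   same per-element width as `bases`.
#' @return A data frame of class `fastq_reads`.
#' @export
fastq_reads <- function(read_id, bases, qual) {
  stop_if_not(length(read_id) == length(bases) && length(bases) == length(qual),
              "read_id, bases and qual must have equal length")
  stop_if_not(all(nchar(bases) == nchar(qual)),
              "each read must have one quality score per base")
  out <- data.frame(read_id = as.character(read_id),
                    bases = as.character(bases),
                    qual = as.character(qual),
                    stringsAsFactors = FALSE)
  class(out) <- c("fastq_reads", "data.frame")
  out
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual A single quality string.
#' @return Integer vector of per-base quality values.
#' @export
qual_to_int <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Encode integer quality scores as a Phred+33 string
#'
#' @param q Integer vector of quality values (all >= 0).
#' @return A single character string.
#' @export
int_to_qual <- function(q) {
  stop_if_not(all(q >= 0), "quality values must be non-negative")
  intToUtf8(as.integer(q) + 33L)
}

#' Read a FASTQ file
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @param phred64 If `TRUE`, interpret qualities as Phred+64 (old Illumina
#'   dialect); they are re-encoded to Phred+33 internally.
#' @return A `fastq_reads` data frame.
#' @export
read_fastq <- function(path, phred64 = FALSE) {
  scoring <- if (phred64) "illumina" else "phred"
  # Biostrings emits a harmless note about dropped metadata columns when
  # re-encoding non-default quality scorings; silence just that
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = scoring),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qints <- as(Biostrings::quality(x), "IntegerList")
  fastq_reads(read_id = names(x),
              bases = as.character(x),
              qual = vapply(qints, int_to_qual, character(1)))
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads A `fastq_reads` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- reads$read_id
  x <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
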