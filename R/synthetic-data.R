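# Synthetic-data generators. Every input the pipeline consumes can be
# generated with known ground truth: FASTQ reads with planted contamination
# classes, six count libraries (three root types x control/salt) with planted
# differential transcription, gene-to-GO annotation tables with one planted
# enriched term, and qPCR Ct tables with planted expression ratios.
# All generators are deterministic functions of their arguments including
# the seed.

ROOT_TYPES <- c("PR", "CR", "SR")
DEFAULT_LIBRARY_IDS <- c("PR", "PR-salt", "CR", "CR-salt", "SR", "SR-salt")

salt_library <- function(root) paste0(root, "-salt")

with_seed <- function(seed, expr) {
  stop_if_not(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_bases <- function(n_reads, read_length) {
  vapply(seq_len(n_reads), function(i) {
    paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# regenerate until none of the sequences contains the adaptor by chance;
# keeps the "clean reads violate no rule" contract exact
without_adaptor <- function(bases, adaptor) {
  if (!nzchar(adaptor)) return(bases)
  repeat {
    hit <- grepl(adaptor, bases, fixed = TRUE)
    if (!any(hit)) return(bases)
    bases[hit] <- random_bases(sum(hit), nchar(bases[hit][1]))
  }
}

high_quals <- function(n_reads, read_length) {
  vapply(seq_len(n_reads), function(i) {
    int_to_qual(sample(30:40, read_length, replace = TRUE))
  }, character(1))
}

#' Specification for the FASTQ generator
#'
#' @param n_reads Number of reads to generate.
#' @param read_length Read length in bases.
#' @param adaptor_fraction,high_n_fraction,low_quality_fraction Proportions of
#'   reads planted with, respectively, a verbatim adaptor insertion, an
#'   N-content strictly above 10 percent, and more than half of bases at
#'   quality <= 5. The three classes are mutually exclusive per read and the
#'   fractions must sum to at most 1.
#' @param adaptor_sequence Adaptor to plant (and to search for downstream).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A list of class `fastq_sim_spec`.
#' @export
fastq_sim_spec <- function(n_reads = 10000L, read_length = 49L,
                           adaptor_fraction = 0.05, high_n_fraction = 0.03,
                           low_quality_fraction = 0.07,
                           adaptor_sequence = "AGATCGGAAGAGC", seed = 1L) {
  spec <- list(n_reads = as.integer(n_reads),
               read_length = as.integer(read_length),
               adaptor_fraction = adaptor_fraction,
               high_n_fraction = high_n_fraction,
               low_quality_fraction = low_quality_fraction,
               adaptor_sequence = toupper(adaptor_sequence),
               seed = as.integer(seed))
  stop_if_not(spec$n_reads > 0, "n_reads must be positive")
  stop_if_not(spec$read_length > 0, "read_length must be positive")
  fr <- c(adaptor_fraction, high_n_fraction, low_quality_fraction)
  stop_if_not(all(fr >= 0) && all(fr <= 1),
              "planted fractions must lie in [0, 1]")
  stop_if_not(sum(fr) <= 1,
              "planted fractions overlap: adaptor + high-N + low-quality fractions exceed 1")
  stop_if_not(nchar(spec$adaptor_sequence) <= spec$read_length,
              "adaptor_sequence longer than read_length")
  class(spec) <- "fastq_sim_spec"
  spec
}

#' Generate FASTQ reads with planted contamination classes
#'
#' Plants exactly `round(n_reads * fraction)` reads of each defect class:
#' adaptor-bearing, high-N (N fraction strictly > 0.10) and low-quality
#' (> 50 percent of bases at quality <= 5). The remaining reads violate none
#' of the three filtering rules. Defects are mutually exclusive per read, so
#' re-applying the filter reproduces the planted labels exactly.
#'
#' @param spec A [fastq_sim_spec()].
#' @return A list with `reads` (a [fastq_reads()] data frame) and `truth`
#'   (character vector: "clean", "adaptor", "high_n" or "low_quality").
#' @export
gen_fastq <- function(spec) {
  stop_if_not(inherits(spec, "fastq_sim_spec"), "spec must be a fastq_sim_spec")
  n <- spec$n_reads
  L <- spec$read_length
  n_ad <- round(n * spec$adaptor_fraction)
  n_nn <- round(n * spec$high_n_fraction)
  n_lq <- round(n * spec$low_quality_fraction)
  stop_if_not(n_ad + n_nn + n_lq <= n,
              "planted fractions overlap: rounded class sizes exceed n_reads")
  n_cl <- n - n_ad - n_nn - n_lq
  with_seed(spec$seed, {
    blocks <- list()

    if (n_ad > 0) {
      b <- random_bases(n_ad, L)
      alen <- nchar(spec$adaptor_sequence)
      start <- sample.int(L - alen + 1L, n_ad, replace = TRUE)
      substr(b, start, start + alen - 1L) <- spec$adaptor_sequence
      blocks$adaptor <- fastq_reads(rep("", n_ad), b, high_quals(n_ad, L))
    }
    if (n_nn > 0) {
      n_ns <- floor(0.10 * L) + 1L  # strictly more than 10 percent
      b <- vapply(seq_len(n_nn), function(i) {
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        s[sample.int(L, n_ns)] <- "N"
        paste(s, collapse = "")
      }, character(1))
      # N substitution cannot create the (N-free) adaptor, but the backbone can
      b <- without_adaptor(b, spec$adaptor_sequence)
      blocks$high_n <- fastq_reads(rep("", n_nn), b, high_quals(n_nn, L))
    }
    if (n_lq > 0) {
      b <- without_adaptor(random_bases(n_lq, L), spec$adaptor_sequence)
      n_low <- floor(0.50 * L) + 1L  # strictly more than half
      q <- vapply(seq_len(n_lq), function(i) {
        qi <- sample(30:40, L, replace = TRUE)
        qi[sample.int(L, n_low)] <- sample(0:5, n_low, replace = TRUE)
        int_to_qual(qi)
      }, character(1))
      blocks$low_quality <- fastq_reads(rep("", n_lq), b, q)
    }
    if (n_cl > 0) {
      b <- without_adaptor(random_bases(n_cl, L), spec$adaptor_sequence)
      blocks$clean <- fastq_reads(rep("", n_cl), b, high_quals(n_cl, L))
    }

    truth <- rep(names(blocks), times = vapply(blocks, nrow, integer(1)))
    reads <- do.call(rbind, blocks)
    perm <- sample.int(n)
    reads <- reads[perm, , drop = FALSE]
    truth <- truth[perm]
    reads$read_id <- sprintf("read_%06d", seq_len(n))
    rownames(reads) <- NULL
    class(reads) <- c("fastq_reads", "data.frame")
    list(reads = reads, truth = truth)
  })
}

#' A single count library
#'
#' One sequencing library of one root type x condition: per-gene uniquely
#' aligned read counts, gene lengths, and the library total (the sum of the
#' per-gene counts — the N of the RPKM formula and the exact test).
#'
#' @param library_id Library label, e.g. "PR" or "PR-salt".
#' @param counts Named non-negative integer vector of per-gene counts.
#' @param gene_lengths Named vector of gene lengths in bases (>= 1), with the
#'   same gene names as `counts`.
#' @return A list of class `count_library` with fields `library_id`, `counts`,
#'   `gene_lengths` and `total_unique`.
#' @export
count_library <- function(library_id, counts, gene_lengths) {
  stop_if_not(!is.null(names(counts)) && all(nzchar(names(counts))),
              "counts must be named by gene id")
  stop_if_not(identical(names(counts), names(gene_lengths)),
              "counts and gene_lengths must share the same gene names")
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  stop_if_not(all(gene_lengths >= 1), "gene lengths must be >= 1")
  structure(list(library_id = library_id,
                 counts = counts,
                 gene_lengths = gene_lengths,
                 total_unique = sum(as.numeric(counts))),
            class = "count_library")
}

#' Specification for the count-library generator
#'
#' Emulates the study design: six single libraries (PR, CR, SR, each with and
#' without salt) with no replicate structure, matching the one-library-per-
#' condition design the exact test assumes.
#'
#' @param n_genes Number of genes.
#' @param library_ids Six library labels, ordered control/treatment per root.
#' @param baseline_mean Expected count per gene per library.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mean + dispersion * mean^2); 0 gives the Poisson limit.
#' @param planted_de Data frame with columns `gene` (index), `comparison`
#'   (root type: "PR", "CR" or "SR") and `log2fc`; the treatment-library mean
#'   of each planted gene is multiplied by `2^log2fc`.
#' @param gene_length_range Length-2 integer range of gene lengths in bases.
#' @param seed Integer seed.
#' @return A list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 20000L,
                           library_ids = DEFAULT_LIBRARY_IDS,
                           baseline_mean = 250,
                           dispersion = 0,
                           planted_de = NULL,
                           gene_length_range = c(200L, 5000L),
                           seed = 1L) {
  if (is.null(planted_de))
    planted_de <- data.frame(gene = integer(), comparison = character(),
                             log2fc = numeric())
  spec <- list(n_genes = as.integer(n_genes), library_ids = library_ids,
               baseline_mean = baseline_mean, dispersion = dispersion,
               planted_de = planted_de,
               gene_length_range = as.integer(gene_length_range),
               seed = as.integer(seed))
  stop_if_not(spec$n_genes > 0, "n_genes must be positive")
  stop_if_not(length(library_ids) == 6L && !anyDuplicated(library_ids),
              "library_ids must be six distinct labels")
  stop_if_not(baseline_mean > 0, "baseline_mean must be positive")
  stop_if_not(dispersion >= 0, "dispersion must be >= 0")
  stop_if_not(all(c("gene", "comparison", "log2fc") %in% names(planted_de)),
              "planted_de needs columns gene, comparison, log2fc")
  stop_if_not(nrow(planted_de) <= spec$n_genes,
              "more planted DE genes than genes")
  stop_if_not(all(is.finite(planted_de$log2fc)),
              "planted log2 fold-changes must be finite")
  stop_if_not(all(planted_de$gene >= 1 & planted_de$gene <= spec$n_genes),
              "planted gene indices out of range")
  stop_if_not(all(planted_de$comparison %in% ROOT_TYPES),
              "planted comparisons must be PR, CR or SR")
  stop_if_not(spec$gene_length_range[1] >= 1 &&
                spec$gene_length_range[2] >= spec$gene_length_range[1],
              "invalid gene_length_range")
  class(spec) <- "count_sim_spec"
  spec
}

#' Generate six count libraries with planted differential transcription
#'
#' Non-planted genes share the same expected count in every library; each
#' planted gene's salt-library mean is scaled by `2^log2fc`, so its expected
#' treatment/control count ratio equals the planted fold change after
#' library-size scaling. Counts are negative binomial (Poisson when
#' `dispersion = 0`).
#'
#' @param spec A [count_sim_spec()].
#' @return A list with `libraries` (named list of [count_library()]),
#'   `counts` (genes x libraries integer matrix), `gene_lengths`, and
#'   `truth` (the planted-DE table with gene ids attached).
#' @export
gen_counts <- function(spec) {
  stop_if_not(inherits(spec, "count_sim_spec"), "spec must be a count_sim_spec")
  n <- spec$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  with_seed(spec$seed, {
    lens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]),
                   n, replace = TRUE)
    names(lens) <- gene_ids
    mu <- matrix(spec$baseline_mean, nrow = n, ncol = 6L,
                 dimnames = list(gene_ids, spec$library_ids))
    if (nrow(spec$planted_de) > 0) {
      treat_lib <- salt_library(spec$planted_de$comparison)
      stop_if_not(all(treat_lib %in% spec$library_ids),
                  "library_ids must contain a <root>-salt label per planted comparison")
      for (i in seq_len(nrow(spec$planted_de))) {
        g <- spec$planted_de$gene[i]
        mu[g, treat_lib[i]] <- mu[g, treat_lib[i]] * 2^spec$planted_de$log2fc[i]
      }
    }
    counts <- matrix(0L, nrow = n, ncol = 6L,
                     dimnames = dimnames(mu))
    for (j in seq_len(6L)) {
      counts[, j] <- if (spec$dispersion <= 0) stats::rpois(n, mu[, j])
      else stats::rnbinom(n, mu = mu[, j], size = 1 / spec$dispersion)
    }
    truth <- spec$planted_de
    truth$gene_id <- gene_ids[truth$gene]
    libs <- lapply(spec$library_ids, function(id)
      count_library(id, stats::setNames(counts[, id], gene_ids), lens))
    names(libs) <- spec$library_ids
    list(libraries = libs, counts = counts, gene_lengths = lens, truth = truth)
  })
}

#' Generate a gene-to-GO annotation table with one planted enriched term
#'
#' Every term annotates background genes at `base_rate`; the planted term
#' annotates genes of `target_gene_set` at the probability whose odds are
#' `odds_ratio` times the background odds, so it is the only term enriched in
#' the target set by construction.
#'
#' @param n_genes Number of background genes (`gene_00001` ...), matching the
#'   ids produced by [gen_counts()].
#' @param n_terms Number of GO terms (`GO:0000001` ...). May be 0.
#' @param planted_term Which term id carries the enrichment; defaults to the
#'   first term.
#' @param target_gene_set Character vector of gene ids enriched for the
#'   planted term; must be non-empty.
#' @param odds_ratio Annotation odds ratio for target vs background genes.
#' @param base_rate Background annotation probability per gene per term.
#' @param seed Integer seed.
#' @return A list with `annotations` (data frame gene_id, term_id),
#'   `planted_term` and `target_gene_set`.
#' @export
gen_annotations <- function(n_genes, n_terms, planted_term = NULL,
                            target_gene_set, odds_ratio = 10,
                            base_rate = 0.05, seed = 1L) {
  stop_if_not(length(target_gene_set) > 0, "target_gene_set must be non-empty")
  stop_if_not(odds_ratio > 0, "odds_ratio must be positive")
  stop_if_not(base_rate > 0 && base_rate < 1, "base_rate must lie in (0, 1)")
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  stop_if_not(all(target_gene_set %in% gene_ids),
              "target_gene_set contains unknown gene ids")
  term_ids <- if (n_terms > 0) sprintf("GO:%07d", seq_len(n_terms)) else character()
  if (is.null(planted_term)) planted_term <- term_ids[1]
  if (n_terms > 0)
    stop_if_not(planted_term %in% term_ids, "planted_term not among the terms")
  odds0 <- base_rate / (1 - base_rate)
  p_target <- odds_ratio * odds0 / (1 + odds_ratio * odds0)
  with_seed(seed, {
    pairs <- lapply(term_ids, function(tm) {
      p <- rep(base_rate, n_genes)
      if (identical(tm, planted_term))
        p[gene_ids %in% target_gene_set] <- p_target
      hit <- stats::runif(n_genes) < p
      if (!any(hit)) return(NULL)
      data.frame(gene_id = gene_ids[hit], term_id = tm,
                 stringsAsFactors = FALSE)
    })
    annotations <- do.call(rbind, pairs)
    if (is.null(annotations))
      annotations <- data.frame(gene_id = character(), term_id = character(),
                                stringsAsFactors = FALSE)
    rownames(annotations) <- NULL
    list(annotations = annotations,
         planted_term = if (n_terms > 0) planted_term else NA_character_,
         target_gene_set = target_gene_set)
  })
}

#' Generate a qPCR Ct table with planted expression ratios
#'
#' Emulates the validation assay: per gene, replicate Ct values for the
#' target and for each reference (housekeeping) gene in a control and a
#' salt-treated sample. A planted log2 ratio r shifts the treated target Ct
#' by -r cycles, so the delta-delta Ct estimate recovers `2^r` up to noise.
#'
#' @param log2_ratios Named numeric vector: planted log2(treated/control)
#'   abundance ratio per target gene.
#' @param reference_genes Reference gene names; the classic trio is
#'   Zm18S rRNA, ZmActin and ZmUBQ.
#' @param n_replicates Replicates per sample.
#' @param target_ct Baseline target Ct in the control sample.
#' @param reference_ct Baseline Ct of each reference gene (recycled).
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param seed Integer seed.
#' @return Data frame with columns gene_id, sample ("control"/"treated"),
#'   replicate, ct, is_reference.
#' @export
gen_qpcr_ct <- function(log2_ratios,
                        reference_genes = c("Zm18S", "ZmActin", "ZmUBQ"),
                        n_replicates = 3L, target_ct = 25,
                        reference_ct = c(12, 20, 22), noise_sd = 0.15,
                        seed = 1L) {
  stop_if_not(!is.null(names(log2_ratios)) && all(nzchar(names(log2_ratios))),
              "log2_ratios must be named by gene")
  stop_if_not(n_replicates >= 1, "need at least one replicate")
  reference_ct <- rep_len(reference_ct, length(reference_genes))
  with_seed(seed, {
    rows <- list()
    k <- 0L
    for (g in names(log2_ratios)) {
      for (sample in c("control", "treated")) {
        shift <- if (sample == "treated") -log2_ratios[[g]] else 0
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene_id = g, sample = sample, replicate = seq_len(n_replicates),
          ct = target_ct + shift + stats::rnorm(n_replicates, 0, noise_sd),
          is_reference = FALSE, stringsAsFactors = FALSE)
        for (j in seq_along(reference_genes)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            gene_id = reference_genes[j], sample = sample,
            replicate = seq_len(n_replicates),
            ct = reference_ct[j] + stats::rnorm(n_replicates, 0, noise_sd),
            is_reference = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write generated count libraries as a TSV count table
#'
#' Columns: gene_id, length_bp, then one count column per library.
#'
#' @param sim Output of [gen_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(sim, path) {
  df <- data.frame(gene_id = names(sim$gene_lengths),
                   length_bp = as.integer(sim$gene_lengths),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (id in names(sim$libraries)) df[[id]] <- sim$libraries[[id]]$counts
  write_tsv_file(df, path)
}

#' Read a TSV count table into count libraries
#'
#' @param path Path to a TSV with columns gene_id, length_bp and one column
#'   per library.
#' @return Named list of [count_library()] objects.
#' @export
read_count_table <- function(path) {
  df <- read_tsv_file(path)
  stop_if_not(all(c("gene_id", "length_bp") %in% names(df)),
              "count table needs gene_id and length_bp columns")
  lens <- stats::setNames(df$length_bp, df$gene_id)
  lib_cols <- setdiff(names(df), c("gene_id", "length_bp"))
  libs <- lapply(lib_cols, function(id)
    count_library(id, stats::setNames(df[[id]], df$gene_id), lens))
  stats::setNames(libs, lib_cols)
}
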