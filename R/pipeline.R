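# End-to-end pipeline over synthetic data: simulate -> filter -> quantify
# -> dge -> compare -> cluster -> enrich. Configuration is a nested list
# (optionally read from YAML) validated before any computation; every stage
# writes TSV (or FASTQ) outputs and the run ends with a manifest of file
# hashes and parameters, so an identical configuration reproduces identical
# outputs.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 10,000-read FASTQ with 15 percent planted
#' contamination, six 2,000-gene libraries with ten planted differentially
#' transcribed genes per root type at |log2 fold change| 3, 200 GO terms
#' with one planted enriched term.
#'
#' @param out_dir Output directory for all stage files.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("rootdge_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(
      fastq = list(n_reads = 10000L, read_length = 49L,
                   adaptor_fraction = 0.05, high_n_fraction = 0.03,
                   low_quality_fraction = 0.07,
                   adaptor_sequence = "AGATCGGAAGAGC"),
      counts = list(n_genes = 2000L, baseline_mean = 250, dispersion = 0,
                    n_planted_per_root = 10L, planted_log2fc = 3),
      annotations = list(n_terms = 200L, odds_ratio = 10, base_rate = 0.05)
    ),
    dge = list(fdr_max = 0.001, min_abs_log2 = 1.0, fdr_method = "BH"),
    enrichment = list(alpha = 0.05)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects any out-of-range threshold or malformed section before any
#' computation runs.
#'
#' @param config Nested configuration list (see [default_config()]).
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  stop_if_not(is.list(config) && !is.null(config$out_dir),
              "config must be a list with an out_dir")
  stop_if_not(is.numeric(config$seed) && length(config$seed) == 1,
              "config$seed must be a single integer")
  fq <- config$simulate$fastq
  stop_if_not(fq$n_reads > 0, "simulate$fastq$n_reads must be positive")
  fr <- c(fq$adaptor_fraction, fq$high_n_fraction, fq$low_quality_fraction)
  stop_if_not(all(fr >= 0 & fr <= 1) && sum(fr) <= 1,
              "planted FASTQ fractions must lie in [0,1] and sum to at most 1")
  ct <- config$simulate$counts
  stop_if_not(ct$n_genes > 0, "simulate$counts$n_genes must be positive")
  stop_if_not(ct$baseline_mean > 0, "baseline_mean must be positive")
  stop_if_not(ct$dispersion >= 0, "dispersion must be >= 0")
  stop_if_not(3 * ct$n_planted_per_root <= ct$n_genes,
              "more planted genes than genes")
  dg <- config$dge
  stop_if_not(dg$fdr_max > 0 && dg$fdr_max <= 1,
              "dge$fdr_max must lie in (0, 1]")
  stop_if_not(dg$min_abs_log2 >= 0, "dge$min_abs_log2 must be >= 0")
  stop_if_not(dg$fdr_method %in% c("BH", "BY"),
              "dge$fdr_method must be BH or BY")
  al <- config$enrichment$alpha
  stop_if_not(al > 0 && al <= 1, "enrichment$alpha must lie in (0, 1]")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Values absent from the file fall back to [default_config()].
#'
#' @param path Path to a YAML file with the same nesting as
#'   [default_config()].
#' @param seed Optional seed overriding the file's value.
#' @return Validated configuration list.
#' @export
load_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), user)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  config
}

stage_log <- function(stage, ...) {
  message(sprintf("[rootdge:%s] %s", stage, paste0(...)))
}

# deterministic per-stage seeds derived from the master seed
stage_seed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2147483647L

#' Run the full pipeline on synthetic data
#'
#' Stages run in order: simulate, filter, quantify, dge (one comparison per
#' root type), compare, cluster, enrich. Each stage's output files are the
#' next stage's input; a manifest records every file with its MD5 hash, so
#' rerunning with an identical configuration reproduces identical outputs.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before anything runs.
#' @return Invisibly, a list with `manifest` (data frame stage/file/md5),
#'   `filter_stats`, `comparisons`, `summary` (the
#'   [summarize_roots()] output), `clustering` and `enrichment`.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  # register an output; hashing happens once at the end, after all writes
  add_file <- function(stage, path) {
    files[[length(files) + 1]] <<- data.frame(stage = stage, path = path,
                                              stringsAsFactors = FALSE)
    path
  }
  out <- function(name) file.path(config$out_dir, name)

  ## simulate -------------------------------------------------------------
  fq <- config$simulate$fastq
  stage_log("simulate", sprintf("FASTQ n_reads=%d planted=%g/%g/%g",
                                fq$n_reads, fq$adaptor_fraction,
                                fq$high_n_fraction, fq$low_quality_fraction))
  fsim <- gen_fastq(fastq_sim_spec(
    n_reads = fq$n_reads, read_length = fq$read_length,
    adaptor_fraction = fq$adaptor_fraction,
    high_n_fraction = fq$high_n_fraction,
    low_quality_fraction = fq$low_quality_fraction,
    adaptor_sequence = fq$adaptor_sequence,
    seed = stage_seed(config$seed, 1L)))
  write_fastq(fsim$reads, add_file("simulate", out("raw_reads.fastq")))

  ct <- config$simulate$counts
  npr <- ct$n_planted_per_root
  planted <- data.frame(
    gene = seq_len(3 * npr),
    comparison = rep(ROOT_TYPES, each = npr),
    log2fc = rep(c(ct$planted_log2fc, -ct$planted_log2fc),
                 length.out = 3 * npr))
  stage_log("simulate", sprintf("counts n_genes=%d baseline=%g planted=%d",
                                ct$n_genes, ct$baseline_mean, nrow(planted)))
  csim <- gen_counts(count_sim_spec(
    n_genes = ct$n_genes, baseline_mean = ct$baseline_mean,
    dispersion = ct$dispersion, planted_de = planted,
    seed = stage_seed(config$seed, 2L)))
  write_count_table(csim, add_file("simulate", out("counts.tsv")))

  an <- config$simulate$annotations
  asim <- gen_annotations(
    n_genes = ct$n_genes, n_terms = an$n_terms,
    target_gene_set = csim$truth$gene_id,
    odds_ratio = an$odds_ratio, base_rate = an$base_rate,
    seed = stage_seed(config$seed, 3L))
  write_tsv_file(asim$annotations, add_file("simulate", out("annotations.tsv")))

  ## filter ---------------------------------------------------------------
  policy <- filter_policy(adaptor_sequences = fq$adaptor_sequence)
  filt <- filter_reads(fsim$reads, policy)
  stage_log("filter", sprintf("retained %d of %d reads",
                              filt$stats$retained_count, filt$stats$input_count))
  write_fastq(filt$clean, add_file("filter", out("clean_reads.fastq")))
  write_tsv_file(filt$stats, add_file("filter", out("filter_stats.tsv")))

  ## quantify -------------------------------------------------------------
  expr <- rpkm_matrix(csim$libraries)
  stage_log("quantify", sprintf("%d genes x %d libraries",
                                nrow(expr$rpkm), ncol(expr$rpkm)))
  rdf <- data.frame(gene_id = rownames(expr$rpkm), expr$rpkm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(rdf, add_file("quantify", out("rpkm.tsv")))

  ## dge ------------------------------------------------------------------
  thresholds <- calling_thresholds(config$dge$fdr_max, config$dge$min_abs_log2)
  comparisons <- lapply(ROOT_TYPES, function(root) {
    res <- run_comparison(csim$libraries[[root]],
                          csim$libraries[[salt_library(root)]],
                          thresholds, config$dge$fdr_method)
    stage_log("dge", sprintf("%s: %d up, %d down", root,
                             sum(res$call == "up"), sum(res$call == "down")))
    write_tsv_file(res, add_file("dge", out(sprintf("dge_%s.tsv", root))))
    res
  })
  names(comparisons) <- ROOT_TYPES

  ## compare --------------------------------------------------------------
  summary <- summarize_roots(comparisons)
  stage_log("compare", sprintf("union of regulated genes: %d",
                               summary$union_count))
  write_tsv_file(summary$per_root, add_file("compare", out("root_summary.tsv")))
  for (root in ROOT_TYPES) {
    p <- out(sprintf("specific_%s.txt", root))
    writeLines(summary$specific_gene_ids[[root]], p)
    add_file("compare", p)
  }

  ## cluster --------------------------------------------------------------
  profiles <- vapply(comparisons, function(res)
    stats::setNames(res$log2_ratio, res$gene_id),
    numeric(nrow(comparisons[[1]])))
  profiles <- profiles[rownames(profiles) %in% summary$union_gene_ids, ,
                       drop = FALSE]
  clust <- NULL
  if (sum(rowSums(is.na(profiles)) == 0) >= 2) {
    clust <- cluster_profiles(profiles)
    stage_log("cluster", sprintf("%d profiles clustered, %d gray-masked",
                                 nrow(clust$ordered) - length(clust$masked_rows),
                                 length(clust$masked_rows)))
    merges <- data.frame(member_a = clust$dendrogram$merge[, 1],
                         member_b = clust$dendrogram$merge[, 2],
                         height = clust$dendrogram$height)
    write_tsv_file(merges, add_file("cluster", out("cluster_merges.tsv")))
    odf <- data.frame(gene_id = rownames(clust$ordered), clust$ordered,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_file(odf, add_file("cluster", out("cluster_profiles.tsv")))
  } else stage_log("cluster", "fewer than two complete profiles; skipped")

  ## enrich ---------------------------------------------------------------
  background <- intersect(unique(asim$annotations$gene_id),
                          rownames(csim$counts))
  dtg_in_bg <- intersect(summary$union_gene_ids, background)
  enr <- enrich(dtg_in_bg, background, asim$annotations,
                alpha = config$enrichment$alpha)
  stage_log("enrich", sprintf("%d terms tested, %d significant",
                              nrow(enr), sum(enr$significant)))
  write_tsv_file(enr, add_file("enrich", out("enrichment.tsv")))

  ## manifest -------------------------------------------------------------
  manifest <- do.call(rbind, files)
  manifest$md5 <- unname(tools::md5sum(manifest$path))
  manifest$file <- basename(manifest$path)
  manifest <- manifest[, c("stage", "file", "md5")]
  manifest$seed <- config$seed
  write_tsv_file(manifest, out("manifest.tsv"))
  stage_log("done", sprintf("%d files in %s", nrow(manifest), config$out_dir))
  invisible(list(manifest = manifest, filter_stats = filt$stats,
                 comparisons = comparisons, summary = summary,
                 clustering = clust, enrichment = enr,
                 truth = list(fastq = fsim$truth, counts = csim$truth,
                              planted_term = asim$planted_term)))
}
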