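test_that("gen_fastq plants exactly the requested defect classes", {
  spec <- fastq_sim_spec(n_reads = 1000, adaptor_fraction = 0.05,
                         high_n_fraction = 0.03, low_quality_fraction = 0.07,
                         seed = 1)
  sim <- gen_fastq(spec)
  expect_equal(nrow(sim$reads), 1000)
  expect_equal(sum(sim$truth != "clean"), 150)
  expect_equal(as.vector(table(sim$truth)[c("adaptor", "high_n", "low_quality")]),
               c(50L, 30L, 70L))
  # ground truth round-trips: re-checking every read against the three rules
  # reproduces the planted labels exactly
  relabel <- vapply(seq_len(nrow(sim$reads)), function(i)
    naive_filter_label(sim$reads$bases[i], sim$reads$qual[i],
                       spec$adaptor_sequence), character(1))
  expect_identical(relabel, sim$truth)
})

test_that("gen_fastq with nothing planted yields reads passing every rule", {
  sim <- gen_fastq(fastq_sim_spec(n_reads = 200, adaptor_fraction = 0,
                                  high_n_fraction = 0,
                                  low_quality_fraction = 0, seed = 3))
  expect_true(all(sim$truth == "clean"))
  pol <- filter_policy(adaptor_sequences = "AGATCGGAAGAGC")
  res <- filter_reads(sim$reads, pol)
  expect_equal(res$stats$retained_count, 200)
})

test_that("gen_fastq is deterministic for a fixed seed, byte for byte", {
  spec <- fastq_sim_spec(n_reads = 300, seed = 11)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(gen_fastq(spec)$reads, f1)
  write_fastq(gen_fastq(spec)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".fastq")
  write_fastq(gen_fastq(fastq_sim_spec(n_reads = 300, seed = 12))$reads, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("overlapping planted fractions are rejected", {
  expect_error(fastq_sim_spec(adaptor_fraction = 0.6, high_n_fraction = 0.3,
                              low_quality_fraction = 0.2),
               "overlap")
})

test_that("generated libraries conserve totals and planted fold changes", {
  planted <- data.frame(gene = 1, comparison = "PR", log2fc = 3)
  sim <- gen_counts(count_sim_spec(n_genes = 500, baseline_mean = 1000,
                                   dispersion = 0, planted_de = planted,
                                   seed = 5))
  for (lib in sim$libraries)
    expect_equal(lib$total_unique, sum(as.numeric(lib$counts)))
  # realized count ratio of the planted gene within 10 percent of 2^3
  ratio <- sim$libraries[["PR-salt"]]$counts[1] / sim$libraries[["PR"]]$counts[1]
  expect_lt(abs(ratio - 8) / 8, 0.10)
})

test_that("null count simulation centres empirical log ratios at zero", {
  sim <- gen_counts(count_sim_spec(n_genes = 2000, baseline_mean = 200,
                                   dispersion = 0, seed = 8))
  a <- sim$libraries[["CR"]]$counts
  b <- sim$libraries[["CR-salt"]]$counts
  keep <- a > 0 & b > 0
  expect_lt(abs(mean(log2(b[keep] / a[keep]))), 0.02)
})

test_that("count generator seeds and error conditions behave", {
  s1 <- gen_counts(count_sim_spec(n_genes = 50, seed = 1))
  s2 <- gen_counts(count_sim_spec(n_genes = 50, seed = 2))
  expect_false(identical(s1$counts, s2$counts))
  expect_identical(s1$counts,
                   gen_counts(count_sim_spec(n_genes = 50, seed = 1))$counts)
  expect_error(count_sim_spec(n_genes = 2,
                              planted_de = data.frame(gene = 1:3,
                                                      comparison = "PR",
                                                      log2fc = 1)),
               "more planted")
})

test_that("count tables round-trip through TSV", {
  sim <- gen_counts(count_sim_spec(n_genes = 30, baseline_mean = 50, seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_count_table(sim, path)
  libs <- read_count_table(path)
  expect_identical(names(libs), names(sim$libraries))
  expect_equal(libs[["SR-salt"]]$counts, sim$libraries[["SR-salt"]]$counts)
  expect_equal(libs[["PR"]]$gene_lengths, sim$libraries[["PR"]]$gene_lengths)
})

test_that("annotation generator plants a detectable term and rejects bad input", {
  expect_error(gen_annotations(100, 5, target_gene_set = character(), seed = 1),
               "non-empty")
  genes <- sprintf("gene_%05d", 1:1000)
  target <- genes[1:50]
  wins <- 0L
  for (s in 1:20) {
    ann <- gen_annotations(1000, 30, target_gene_set = target,
                           odds_ratio = 10, seed = s)
    res <- enrich(target, genes, ann$annotations)
    if (res$term_id[which.min(res$raw_p)] == ann$planted_term) wins <- wins + 1L
  }
  expect_gt(wins, 10)  # majority of seeds
})

test_that("zero terms yields empty annotations and empty enrichment", {
  ann <- gen_annotations(100, 0, target_gene_set = sprintf("gene_%05d", 1:5),
                         seed = 1)
  expect_equal(nrow(ann$annotations), 0)
  res <- enrich(sprintf("gene_%05d", 1:5), sprintf("gene_%05d", 1:100),
                ann$annotations)
  expect_equal(nrow(res), 0)
})

test_that("qPCR generator plants recoverable ratios", {
  planted <- c(geneA = 2, geneB = -1.5, geneC = 0)
  ct <- gen_qpcr_ct(planted, noise_sd = 0, seed = 4)
  est <- qpcr_relative_abundance(ct)
  expect_equal(log2(est[names(planted)]), planted, tolerance = 1e-10,
               ignore_attr = TRUE)
})
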