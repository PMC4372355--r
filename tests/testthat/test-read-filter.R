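adaptor <- "AGATCGGAAGAGC"
policy <- filter_policy(adaptor_sequences = adaptor)

test_that("adaptor detection is exact substring matching", {
  carrier <- paste0("ACGT", adaptor, "TTGC")
  expect_true(has_adaptor(carrier, policy))
  # one mismatch in the adaptor must not match
  mut <- adaptor
  substr(mut, 5, 5) <- ifelse(substr(mut, 5, 5) == "A", "C", "A")
  expect_false(has_adaptor(paste0("ACGT", mut, "TTGC"), policy))
  # empty adaptor list never matches
  expect_false(has_adaptor(carrier, filter_policy()))
})

test_that("N-content rule uses a strict 10 percent boundary", {
  b11 <- paste0(strrep("N", 11), strrep("A", 89))
  b10 <- paste0(strrep("N", 10), strrep("A", 90))
  expect_equal(n_fraction(b11), 0.11)
  expect_equal(n_fraction(b10), 0.10)
  expect_equal(n_fraction(strrep("A", 100)), 0)
  pol <- filter_policy()
  expect_true(n_fraction(b11) > pol$max_n_fraction)
  expect_false(n_fraction(b10) > pol$max_n_fraction)
  expect_error(n_fraction(""), "empty")
})

test_that("low-quality rule uses a strict 50 percent boundary at q <= 5", {
  q51 <- int_to_qual(c(rep(5, 51), rep(40, 49)))
  q50 <- int_to_qual(c(rep(5, 50), rep(40, 50)))
  expect_equal(low_quality_fraction(q51, policy), 0.51)
  expect_equal(low_quality_fraction(q50, policy), 0.50)
  expect_equal(low_quality_fraction(int_to_qual(rep(40, 80)), policy), 0)
  expect_true(low_quality_fraction(q51, policy) > policy$max_low_quality_fraction)
  expect_false(low_quality_fraction(q50, policy) > policy$max_low_quality_fraction)
})

test_that("filter_reads reproduces planted contamination counts", {
  sim <- gen_fastq(fastq_sim_spec(n_reads = 1000, adaptor_fraction = 0.05,
                                  high_n_fraction = 0.03,
                                  low_quality_fraction = 0.07, seed = 2))
  res <- filter_reads(sim$reads, policy)
  expect_equal(res$stats$retained_count, 850)
  expect_equal(res$stats$removed_by_adaptor, 50)
  expect_equal(res$stats$removed_by_n, 30)
  expect_equal(res$stats$removed_by_quality, 70)
  expect_identical(res$rule, sim$truth)
  # conservation
  expect_equal(res$stats$input_count,
               res$stats$retained_count + res$stats$removed_by_adaptor +
                 res$stats$removed_by_n + res$stats$removed_by_quality)
  # retained reads keep input order
  expect_identical(res$clean$read_id,
                   sim$reads$read_id[sim$truth == "clean"])
})

test_that("filtering is idempotent on already-clean reads", {
  sim <- gen_fastq(fastq_sim_spec(n_reads = 400, seed = 6))
  once <- filter_reads(sim$reads, policy)
  twice <- filter_reads(once$clean, policy)
  expect_equal(twice$stats$retained_count, once$stats$retained_count)
  expect_identical(twice$clean, once$clean)
})

test_that("empty input gives all-zero stats", {
  empty <- fastq_reads(character(), character(), character())
  res <- filter_reads(empty, policy)
  expect_true(all(unlist(res$stats) == 0))
})

test_that("a read violating rules 1 and 3 is attributed to rule 1 only", {
  bases <- paste0(adaptor, strrep("A", 27))
  qual <- int_to_qual(rep(2, nchar(bases)))  # also > 50 percent low quality
  reads <- fastq_reads("r1", bases, qual)
  res <- filter_reads(reads, policy)
  expect_equal(res$stats$removed_by_adaptor, 1)
  expect_equal(res$stats$removed_by_quality, 0)
  expect_identical(naive_filter_label(bases, qual, adaptor), "adaptor")
})

test_that("naive per-read oracle reproduces the retained set on random reads", {
  sim <- gen_fastq(fastq_sim_spec(n_reads = 2000, adaptor_fraction = 0.1,
                                  high_n_fraction = 0.1,
                                  low_quality_fraction = 0.1, seed = 13))
  res <- filter_reads(sim$reads, policy)
  oracle <- vapply(seq_len(nrow(sim$reads)), function(i)
    naive_filter_label(sim$reads$bases[i], sim$reads$qual[i], adaptor),
    character(1))
  expect_identical(res$rule, oracle)
  expect_identical(res$clean$read_id, sim$reads$read_id[oracle == "clean"])
})

test_that("mismatched base/quality lengths are rejected", {
  expect_error(fastq_reads("r1", "ACGT", "III"), "quality score per base")
})

test_that("FASTQ round-trips through files, including Phred+64 input", {
  sim <- gen_fastq(fastq_sim_spec(n_reads = 50, seed = 9))
  path <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_equal(back$bases, sim$reads$bases)
  expect_equal(back$qual, sim$reads$qual)
  # same reads re-encoded at +64 decode to the same scores
  p64 <- tempfile(fileext = ".fastq")
  qual64 <- vapply(sim$reads$qual,
                   function(q) intToUtf8(utf8ToInt(q) + 31L), character(1),
                   USE.NAMES = FALSE)
  writeLines(as.vector(rbind(paste0("@", sim$reads$read_id), sim$reads$bases,
                             "+", qual64)), p64)
  back64 <- read_fastq(p64, phred64 = TRUE)
  expect_equal(back64$qual, sim$reads$qual)
})
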