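test_that("without tailing every simulated sRNA is templated on its precursor", {
  loc <- small_locus(seed = 1)
  cfg <- read_sim_config(depth = 500, tail_prob = 0, background_prob = 0)
  sim <- simulate_srna_reads(srna_samples(loc), cfg, seed = 2)
  expect_equal(nrow(sim$reads), 500)
  expect_true(all(sim$truth$templated))
  p <- precursor_seq(loc, 1)
  expect_true(all(vapply(sim$truth$srna, grepl, TRUE, x = p, fixed = TRUE)))
  # reads are sRNA + adapter truncated to the read length
  expect_true(all(nchar(sim$reads$sequence) == cfg$read_length))
  expect_true(all(startsWith(sim$reads$sequence, sim$truth$srna)))
})

test_that("canonical yield falls in the binomial interval", {
  loc <- small_locus(seed = 3)
  cfg <- read_sim_config(depth = 1000, tail_prob = 0, background_prob = 0,
                         variant_prob = 0.3)
  sim <- simulate_srna_reads(srna_samples(loc), cfg, seed = 4)
  mir <- substr(precursor_seq(loc, 1), loc$mir5p_span[1] + 1, loc$mir5p_span[2])
  n_canon <- sum(sim$truth$srna == mir)
  expect_gte(n_canon, qbinom(0.005, 1000, 0.7) -
               qbinom(0.995, 1000, 0.3) * 0) # lower bound from variant_prob
  # canonical reads also arise when both sampled offsets are zero, so the
  # count must be at least the no-variant draw and at most all reads
  expect_gte(n_canon, qbinom(0.005, 1000, 1 - cfg$variant_prob))
  expect_gt(n_canon, 0)
})

test_that("impaired precursors with zero leak yield no reads", {
  loc <- small_locus(seed = 5)
  cfg <- read_sim_config(depth = 300, leak_rate = 0, background_prob = 0.5)
  sim <- simulate_srna_reads(srna_samples(loc, impaired = TRUE), cfg, seed = 6)
  expect_true(all(is.na(sim$truth$precursor_id)))
  # with leak the precursor re-appears
  cfg2 <- read_sim_config(depth = 300, leak_rate = 0.5, background_prob = 0.5)
  sim2 <- simulate_srna_reads(srna_samples(loc, impaired = TRUE), cfg2, seed = 6)
  expect_gt(sum(!is.na(sim2$truth$precursor_id)), 0)
})

test_that("non-templated tails never extend templated sequence", {
  loc <- small_locus(seed = 7)
  cfg <- read_sim_config(depth = 2000, tail_prob = 0.5, background_prob = 0)
  sim <- simulate_srna_reads(srna_samples(loc), cfg, seed = 8)
  tails <- sim$truth[!sim$truth$templated, ]
  expect_gt(nrow(tails), 0)
  p <- precursor_seq(loc, 1)
  # the tailed sRNA is non-templated: not an exact substring of the precursor
  expect_false(any(vapply(tails$srna, grepl, TRUE, x = p, fixed = TRUE)))
  # but its core (tail stripped) is
  cores <- substr(tails$srna, 1, nchar(tails$srna) - nchar(tails$tail))
  expect_true(all(vapply(cores, grepl, TRUE, x = p, fixed = TRUE)))
})

test_that("simulation is seed-deterministic and FASTQ round-trips", {
  loc <- small_locus(seed = 9)
  cfg <- read_sim_config(depth = 100, tail_prob = 0.2)
  a <- simulate_srna_reads(srna_samples(loc), cfg, seed = 10)
  b <- simulate_srna_reads(srna_samples(loc), cfg, seed = 10)
  expect_identical(a, b)

  dir <- withr::local_tempdir()
  paths <- write_fastq(a$reads, dir)
  back <- read_fastq(paths)
  expect_equal(back$sequence, a$reads$sequence)
  expect_equal(back$quality, a$reads$quality)
})

test_that("config validation rejects bad adapters and depths", {
  expect_error(read_sim_config(adapter = "ACGTXN"), class = "miredit_format_error")
  expect_error(read_sim_config(depth = 0), class = "miredit_bounds_error")
})
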