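mk_reads <- function(seqs, quals = NULL, sample = "S1") {
  quals <- quals %||% strrep("I", nchar(seqs)) # phred 40
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                 sample_id = sample, sequence = seqs, quality = quals)
}

ADPT <- "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCACATCACGATCTCGTATGC"

test_that("adapter removal and length filtering follow the rules", {
  mir <- "TGCCTGGCTCCCTGTATGCCA" # 21 nt
  read <- substr(paste0(mir, ADPT), 1, 50)
  out <- preprocess(mk_reads(read), ADPT)
  expect_equal(out$sequence, mir)
  expect_equal(out$count, 1L)

  # phred 19 at cycle 15 truncates to 14 nt -> discarded (< 18)
  q <- paste0(strrep("I", 14), "4", strrep("I", 35)) # "4" = phred 19
  out2 <- preprocess(mk_reads(read, q), ADPT)
  expect_equal(nrow(out2), 0)
  # discard mode drops the whole read too
  out3 <- preprocess(mk_reads(read, q), ADPT, quality_mode = "discard")
  expect_equal(nrow(out3), 0)
})

test_that("collapsed counts equal simulator truth for clean-adapter reads", {
  loc <- small_locus(seed = 1)
  cfg <- read_sim_config(depth = 2000, tail_prob = 0.1, background_prob = 0,
                         qual_mean = 38, qual_sd = 1) # no quality losses
  sim <- simulate_srna_reads(srna_samples(loc), cfg, seed = 2)
  clean <- preprocess(sim$reads, cfg$adapter)
  # sRNAs inside the retained length range survive preprocessing 1:1; end
  # shifts can produce 17-mers, which the 18-30 filter removes by design
  in_range <- nchar(sim$truth$srna) >= 18 & nchar(sim$truth$srna) <= 30
  truth_counts <- table(sim$truth$srna[in_range])
  expect_equal(sum(clean$count), sum(in_range))
  for (s in sample(names(truth_counts), min(20, length(truth_counts)))) {
    expect_equal(clean$count[clean$sequence == s], unname(truth_counts[s]),
                 info = s)
  }
  expect_equal(unname(attr(clean, "library_sizes")["S1"]), sum(in_range))
})

test_that("exact mapping admits no mismatches and records all sources", {
  loc <- small_locus(seed = 3)
  p <- precursor_seq(loc, 1)
  mir <- substr(p, loc$mir5p_span[1] + 1, loc$mir5p_span[2])
  # mutated precursor with a 1-nt insertion inside the miR
  cut <- loc$guides$cut_pos[1] - loc$precursor_span[1]
  pmut <- paste0(substr(p, 1, cut), "T", substr(p, cut + 1, nchar(p)))
  precursors <- tibble::tibble(precursor_id = c("wt", "mut"),
                               sequence = c(p, pmut))

  mismatched <- paste0(substr(mir, 1, 10),
                       chartr("ACGT", "GTAC", substr(mir, 11, 11)),
                       substr(mir, 12, nchar(mir)))
  ins_read <- substr(pmut, cut - 9, cut + 11) # spans the insertion
  clean <- tibble::tibble(sample_id = "S1",
                          sequence = c(mir, mismatched, ins_read),
                          count = c(5L, 3L, 2L))
  m <- map_exact(clean, precursors)
  expect_true("wt" %in% m$sources[[1]])
  expect_equal(m$n_sources[[2]], 0) # one substitution -> unmapped
  expect_equal(m$sources[[3]], "mut") # insertion-spanning read is unique
  expect_true(m$unambiguous[[3]])
  expect_error(map_exact(clean, precursors[0, ]), class = "miredit_value_error")
})

test_that("variant classes, offsets and tails are called correctly", {
  loc <- small_locus(seed = 4)
  p <- precursor_seq(loc, 1)
  ann <- tibble::tibble(precursor_id = "wt", sequence = p,
                        mir5p_start = loc$mir5p_span[1],
                        mir5p_end = loc$mir5p_span[2])
  mir <- substr(p, loc$mir5p_span[1] + 1, loc$mir5p_span[2])
  short3 <- substr(mir, 1, nchar(mir) - 1)
  # non-templated 3' tail: base differing from the precursor continuation
  nxt <- substr(p, loc$mir5p_span[2] + 1, loc$mir5p_span[2] + 1)
  tl <- setdiff(c("A", "C", "G", "T"), nxt)[1]
  tailed <- paste0(mir, tl)

  clean <- tibble::tibble(sample_id = "S1",
                          sequence = c(mir, short3, tailed),
                          count = c(10L, 4L, 2L))
  v <- call_variants(map_exact(clean, ann), ann)
  v <- v[match(c(mir, short3, tailed), v$sequence), ]
  expect_equal(v$class, c("canonical", "templated", "non_templated"))
  expect_equal(v$offset5, c(0, 0, 0))
  expect_equal(v$offset3[1:2], c(0, -1))
  expect_equal(v$tail[3], tl)
  expect_equal(v$tail_end[3], "3p")
  expect_equal(v$cpm, v$count / sum(clean$count) * 1e6)
  expect_true(v$low_abundance[3])
  expect_false(v$low_abundance[1])
})

test_that("templated variants re-verify as substrings of every listed source", {
  loc <- small_locus(seed = 5)
  cfg <- read_sim_config(depth = 3000, tail_prob = 0.2, background_prob = 0.2)
  sim <- simulate_srna_reads(srna_samples(loc), cfg, seed = 6)
  ann <- tibble::tibble(precursor_id = paste0(loc$locus_id, "_p1"),
                        sequence = precursor_seq(loc, 1),
                        mir5p_start = loc$mir5p_span[1],
                        mir5p_end = loc$mir5p_span[2])
  v <- call_variants(map_exact(preprocess(sim$reads, cfg$adapter), ann), ann)
  tmpl <- v[v$class %in% c("canonical", "templated"), ]
  for (i in seq_len(nrow(tmpl))) {
    for (src in strsplit(tmpl$sources[i], ",")[[1]]) {
      expect_true(grepl(tmpl$sequence[i],
                        ann$sequence[ann$precursor_id == src], fixed = TRUE))
    }
  }
})

test_that("the exclusion filter removes anything seen in control samples", {
  v <- tibble::tibble(
    sequence = c("AAA", "AAA", "CCC", "GGG", "GGG"),
    class = "templated", sources = "p", unambiguous = TRUE,
    offset5 = 0, offset3 = 0, tail = NA, tail_end = NA,
    sample_id = c("crA_1", "NT1", "crA_1", "crA_1", "crB_1"),
    count = c(3L, 1L, 2L, 4L, 1L), cpm = 1, low_abundance = FALSE)
  out <- specificity_filter(v, test_group = "crA_1",
                            control_groups = list(c("NT1"), c("crB_1")))
  expect_equal(out$sequence, "CCC") # AAA in NT, GGG in reciprocal lines
  expect_error(specificity_filter(v, "crA_1", list("crA_1")),
               class = "miredit_config_error")
  # exclusion guarantee: reported variants have zero control counts
  ctrl_counts <- v$count[v$sequence %in% out$sequence &
                           v$sample_id %in% c("NT1", "crB_1")]
  expect_equal(sum(ctrl_counts), 0)
})

test_that("cpm arithmetic", {
  expect_equal(cpm(5, 1e6), 5)
  expect_equal(cpm(0, 123), 0)
  expect_equal(cpm(10, 2e6), 5)
  expect_error(cpm(1, 0), class = "miredit_value_error")
})
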