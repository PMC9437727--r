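test_that("MFEI arithmetic matches hand calculation", {
  # |MFE|/L*100 / GC% with GC on the 0-100 scale
  r <- mfei(fake_fold(seq_with_gc(100, 40), -40))
  expect_equal(r$amfe, 40)
  expect_equal(r$mfei, 1)

  r <- mfei(fake_fold(seq_with_gc(108, 54), -45.9))
  expect_equal(r$gc_percent, 50)
  expect_equal(r$mfei, 0.85)

  expect_equal(mfei(fake_fold(seq_with_gc(50, 25), 0))$mfei, 0)
  expect_error(mfei(fake_fold(strrep("A", 20), -1)),
               class = "miredit_mfei_undefined")
})

test_that("a perfect duplex hairpin has zero mismatches and no internal loop", {
  loc <- small_locus(seed = 2, n_star_mismatch = 0)
  f <- fold(precursor_seq(loc, 1))
  d <- locate_duplex(f, loc$mir5p_span)
  expect_equal(d$n_mismatch_positions, 0L)
  expect_equal(d$largest_internal_loop_nt, 0L)
  # star span agrees with the annotated miR-3p arm
  expect_lte(abs(d$mirstar_start - loc$mir3p_span[[1]]), 2)
})

test_that("default wild-type precursors are imperfect but processable", {
  for (sd in 1:5) {
    loc <- small_locus(seed = sd)
    f <- fold(precursor_seq(loc, 1))
    d <- locate_duplex(f, loc$mir5p_span)
    cls <- classify_processing(mfei(f), d)
    expect_false(cls$impaired, info = sd)
    expect_lte(d$largest_internal_loop_nt, 5L)
  }
})

test_that("a constructed symmetric internal loop is measured correctly", {
  # stem of 10 bp, 3x3 interior loop (AAA vs AAA cannot pair), stem of 8 bp,
  # tetraloop; loop size = unpaired nts on both strands summed = 6
  s5a <- "GCGCGCGGGC"; s5b <- "GGCGCGCG"
  s <- paste0(s5a, "AAA", s5b, "GAAA", revcomp_rna(s5b), "AAA", revcomp_rna(s5a))
  f <- fold(s)
  # independent check on the structure string itself
  expect_match(f$dot_bracket, "^\\({10}\\.{3}\\({8}\\.{4}\\){8}\\.{3}\\){10}$")
  d <- locate_duplex(f, c(0, nchar(s5a) + 3 + nchar(s5b)))
  expect_equal(d$largest_internal_loop_nt, 6L)
  expect_equal(d$largest_loop_one_strand_nt, 3L)
})

test_that("an excised or unpaired mature region raises a degenerate duplex", {
  loc <- small_locus(seed = 4)
  f <- fold(precursor_seq(loc, 1))
  expect_error(locate_duplex(f, c(5, 5)), class = "miredit_degenerate_duplex")
  f2 <- fake_fold(strrep("A", 40), 0) # no pairs at all
  expect_error(locate_duplex(f2, c(0, 21)), class = "miredit_degenerate_duplex")
})

test_that("the impaired-processing rule applies strict thresholds", {
  cases <- tidyr::crossing(mfei = c(0.84, 0.85, 0.86), loop = c(5L, 6L))
  for (i in seq_len(nrow(cases))) {
    m <- cases$mfei[i]; l <- cases$loop[i]
    cls <- classify_processing(tibble::tibble(mfei = m),
                               tibble::tibble(largest_internal_loop_nt = l))
    expect_equal(cls$impaired, m < 0.85 || l > 5,
                 info = sprintf("mfei=%g loop=%d", m, l))
    if (m < 0.85) expect_match(cls$reasons, "low_mfei")
    if (l > 5) expect_match(cls$reasons, "internal_loop")
  }
  # excision dominates
  cls <- classify_processing(NULL, NULL, excised = TRUE)
  expect_true(cls$impaired)
  expect_equal(cls$reasons, "precursor_excised")
})

test_that("the classifier is monotone in MFEI and loop size", {
  set.seed(11)
  for (i in 1:50) {
    m <- runif(1, 0.4, 1.3); l <- sample(0:10, 1)
    base <- classify_processing(tibble::tibble(mfei = m),
                                tibble::tibble(largest_internal_loop_nt = l))
    worse <- classify_processing(tibble::tibble(mfei = m - runif(1, 0, 0.5)),
                                 tibble::tibble(largest_internal_loop_nt = l + sample(0:5, 1)))
    expect_false(base$impaired && !worse$impaired)
  }
})

test_that("longer deletions degrade MFEI more than 0-1 nt edits", {
  loc <- make_locus(seed = 9, n_alleles = 1, snp_rate = 0, amplicon_length = 400)
  small_prof <- edit_profile(p_none = 0, p_short_deletion = 0,
                             p_insertion_T = 0.5, p_insertion_G = 0.5,
                             p_inter_guide_excision = 0, p_large_deletion = 0)
  big_prof <- edit_profile(p_none = 0, p_short_deletion = 0,
                           p_insertion_T = 0, p_insertion_G = 0,
                           p_inter_guide_excision = 0, p_large_deletion = 1)
  mfei_of <- function(truth) {
    vapply(seq_len(nrow(truth)), function(i) {
      ops <- tibble::tibble(
        op = ifelse(truth$type[i] == "insertion", "ins", "del"),
        start = truth$span_start[i], end = truth$span_end[i],
        ref = "", alt = ifelse(is.na(truth$inserted_base[i]), "",
                               truth$inserted_base[i]))
      ps <- miredit:::remap_span_ops(loc$precursor_span, ops)
      prec <- substr(truth$edited_seq[i], ps[1] + 1, ps[2])
      mfei(fold(prec))$mfei
    }, 0)
  }
  m_small <- mfei_of(simulate_edits(loc, small_prof, 15, seed = 21))
  m_big <- mfei_of(simulate_edits(loc, big_prof, 15, seed = 22))
  expect_lte(mean(m_big), mean(m_small))
})
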