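MIR <- "UGCCUGGCUCCCUGUAUGCCA" # 21 nt

perfect_site <- function(mir) revcomp_rna(mir)

test_that("a perfect complement scores 0 and is functional", {
  hit <- score_site(MIR, perfect_site(MIR))
  expect_equal(hit$expectation, 0)
  expect_true(hit$functional)
  expect_false(hit$central_block)
})

test_that("a single seed G:U wobble scores 1.0 (0.5 x 2 seed weight)", {
  # make miRNA position 5 a G and put U opposite it (instead of C)
  mir <- MIR
  substr(mir, 5, 5) <- "G"
  site <- strsplit(perfect_site(mir), "")[[1]]
  site[nchar(mir) - 5 + 1] <- "U" # window position facing miRNA position 5
  hit <- score_site(mir, paste(site, collapse = ""))
  expect_equal(hit$expectation, 1.0)
  expect_true(hit$functional)

  # the same wobble outside the seed scores 0.5
  mir2 <- MIR
  substr(mir2, 16, 16) <- "G"
  site2 <- strsplit(perfect_site(mir2), "")[[1]]
  site2[nchar(mir2) - 16 + 1] <- "U"
  expect_equal(score_site(mir2, paste(site2, collapse = ""))$expectation, 0.5)
})

test_that("four seed mismatches score 8 and miss the cutoff", {
  site <- strsplit(perfect_site(MIR), "")[[1]]
  mirc <- strsplit(MIR, "")[[1]]
  for (pos in 3:6) { # all inside the double-weighted 2-13 range
    w <- nchar(MIR) - pos + 1
    site[w] <- mirc[pos] # same base as the miRNA never pairs with it
  }
  hit <- score_site(MIR, paste(site, collapse = ""))
  expect_equal(hit$expectation, 8)
  expect_false(hit$functional)

  tx <- tibble::tibble(transcript_id = "tx1",
                       sequence = paste0(strrep("A", 30),
                                         paste(site, collapse = ""),
                                         strrep("A", 30)))
  expect_equal(nrow(screen_targets(MIR, tx, cutoff = 3)), 0)
})

test_that("three consecutive central mispairings block function", {
  site <- strsplit(perfect_site(MIR), "")[[1]]
  mirc <- strsplit(MIR, "")[[1]]
  for (pos in 12:14) {
    site[nchar(MIR) - pos + 1] <- mirc[pos]
  }
  hit <- score_site(MIR, paste(site, collapse = ""), cutoff = 10)
  expect_true(hit$central_block)
  expect_false(hit$functional)
  expect_match(hit$mismatch_positions, "12,13,14")
})

test_that("expectation is monotone under added mismatches and zero on identity", {
  set.seed(33)
  for (i in 1:20) {
    mir <- random_rna(21)
    expect_equal(score_site(mir, perfect_site(mir))$expectation, 0)
    site <- strsplit(perfect_site(mir), "")[[1]]
    prev <- 0
    for (k in sample(seq_len(21), 4)) {
      site[21 - k + 1] <- substr(mir, k, k)
      e <- score_site(mir, paste(site, collapse = ""))$expectation
      expect_gte(e, prev)
      prev <- e
    }
  }
})

test_that("screening finds embedded sites, tolerates bulges, and is empty-safe", {
  set.seed(44)
  mir <- random_rna(21)
  site <- perfect_site(mir)
  tx <- tibble::tibble(transcript_id = "tx1",
                       sequence = paste0(random_rna(80), site, random_rna(80)))
  hits <- screen_targets(setNames(mir, "v1"), tx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$site_start, 80)
  expect_equal(hits$site_end, 80 + 21)

  # a variant with a 1-nt deletion still binds through a bulged target base
  mirdel <- paste0(substr(mir, 1, 9), substr(mir, 11, 21))
  hitd <- screen_targets(mirdel, tx, cutoff = 5)
  expect_equal(nrow(hitd), 1)
  expect_lte(hitd$expectation, 4) # one 2-weighted gap at worst

  expect_equal(nrow(screen_targets(mir, tx[0, ])), 0)
  expect_error(score_site(random_rna(10), random_rna(10)),
               class = "miredit_value_error")
})

test_that("the fast transcript scan agrees with direct window scoring", {
  set.seed(55)
  for (i in 1:10) {
    mir <- random_rna(21)
    tx <- random_rna(120)
    best <- miredit:::scan_transcript(mir, tx, target_weights())
    if (is.null(best)) next
    det <- score_site(mir, substr(tx, best$start + 1, best$end), cutoff = 99)
    expect_equal(det$expectation, best$expectation)
  }
})
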