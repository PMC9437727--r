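test_that("a 100% no-edit profile leaves sequences untouched", {
  loc <- small_locus(seed = 1)
  prof <- edit_profile(p_none = 1, p_short_deletion = 0, p_insertion_T = 0,
                       p_insertion_G = 0, p_inter_guide_excision = 0,
                       p_large_deletion = 0)
  ev <- simulate_edits(loc, prof, 10, seed = 2)
  expect_true(all(ev$type == "none"))
  expect_identical(ev$edited_seq, loc$allele_seqs[ev$allele_index])
})

test_that("inter-guide excision removes exactly the inter-cut interval", {
  loc <- small_locus(seed = 1)
  prof <- edit_profile(p_none = 0, p_short_deletion = 0, p_insertion_T = 0,
                       p_insertion_G = 0, p_inter_guide_excision = 1,
                       p_large_deletion = 0)
  ev <- simulate_edits(loc, prof, 5, seed = 3)
  cuts <- sort(loc$guides$cut_pos)
  expect_true(all(nchar(ev$edited_seq) ==
                    nchar(loc$allele_seqs[ev$allele_index]) - (cuts[2] - cuts[1])))
  # spans are reported left-normalised; they stay the inter-cut interval up
  # to repeat-shift equivalence
  expect_true(all(ev$span_end - ev$span_start == cuts[2] - cuts[1]))
  expect_true(all(ev$span_start <= cuts[1] & ev$span_start >= cuts[1] - 3))
})

test_that("every edited sequence differs from its source exactly by its call", {
  loc <- small_locus(seed = 4)
  ev <- simulate_edits(loc, edit_profile(), 50, seed = 5)
  for (i in seq_len(nrow(ev))) {
    src <- loc$allele_seqs[[ev$allele_index[i]]]
    rebuilt <- if (ev$type[i] == "none") src
      else if (ev$type[i] == "insertion")
        paste0(substr(src, 1, ev$span_start[i]), ev$inserted_base[i],
               substr(src, ev$span_start[i] + 1, nchar(src)))
      else
        paste0(substr(src, 1, ev$span_start[i]),
               substr(src, ev$span_end[i] + 1, nchar(src)))
    expect_identical(rebuilt, ev$edited_seq[i])
  }
})

test_that("edit class frequencies fall in the exact multinomial 99% interval", {
  loc <- small_locus(seed = 6)
  prof <- edit_profile(p_none = 0, p_short_deletion = 0.6, p_insertion_T = 0.4,
                       p_insertion_G = 0, p_inter_guide_excision = 0,
                       p_large_deletion = 0)
  ev <- simulate_edits(loc, prof, 1000, seed = 7)
  n_del <- sum(ev$type == "short_deletion")
  expect_gte(n_del, qbinom(0.005, 1000, 0.6))
  expect_lte(n_del, qbinom(0.995, 1000, 0.6))
  expect_equal(nrow(ev), n_del + sum(ev$type == "insertion"))
  expect_true(all(ev$inserted_base[ev$type == "insertion"] == "T"))
})

test_that("edits sit within the jitter window of a cut site", {
  loc <- small_locus(seed = 8)
  ev <- simulate_edits(loc, edit_profile(p_none = 0, p_short_deletion = 1,
                                         p_insertion_T = 0, p_insertion_G = 0,
                                         p_inter_guide_excision = 0,
                                         p_large_deletion = 0),
                       200, seed = 9)
  expect_true(all(ev$distance_to_cut <= 4 + 3)) # jitter 4 + half of max length
  expect_error(edit_profile(p_none = 0.5), class = "miredit_config_error")
  expect_error(simulate_edits(loc, edit_profile(), 0), class = "miredit_bounds_error")
})

test_that("clone sampling follows mixture proportions", {
  truth1 <- tibble::tibble(edited_seq = "ACGT", proportion = 1)
  cl <- simulate_amplicon_clones(truth1, 10, seed = 1)
  expect_equal(nrow(cl), 10)
  expect_length(unique(cl$sequence), 1)

  truth2 <- tibble::tibble(edited_seq = c("AAAA", "CCCC"),
                           proportion = c(0.5, 0.5))
  cl2 <- simulate_amplicon_clones(truth2, 10000, seed = 2)
  k <- sum(cl2$sequence == "AAAA")
  expect_gte(k, qbinom(0.005, 10000, 0.5))
  expect_lte(k, qbinom(0.995, 10000, 0.5))

  expect_equal(nrow(simulate_amplicon_clones(truth2, 0, seed = 1)), 0)
  expect_error(simulate_amplicon_clones(truth2[0, ], 5, seed = 1),
               class = "miredit_value_error")
  expect_identical(simulate_amplicon_clones(truth2, 50, seed = 3),
                   simulate_amplicon_clones(truth2, 50, seed = 3))
})
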