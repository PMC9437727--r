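test_that("zero SNP rate yields identical alleles; loci are seed-deterministic", {
  loc <- make_locus(seed = 1, n_alleles = 4, snp_rate = 0)
  expect_length(unique(loc$allele_seqs), 1)
  expect_equal(nrow(loc$snps), 0)
  expect_identical(make_locus(seed = 1, n_alleles = 4, snp_rate = 0.01),
                   make_locus(seed = 1, n_alleles = 4, snp_rate = 0.01))
})

test_that("SNP counts fall in the exact binomial 99% interval", {
  loc <- make_locus(seed = 2, n_alleles = 4, snp_rate = 0.01,
                    amplicon_length = 800)
  lo <- qbinom(0.005, 800, 0.01)
  hi <- qbinom(0.995, 800, 0.01)
  per_allele <- table(factor(loc$snps$allele, levels = 2:4))
  for (k in per_allele) {
    expect_gte(k, lo)
    expect_lte(k, hi)
  }
  # ground truth matches the sequences
  for (i in seq_len(nrow(loc$snps))) {
    sn <- loc$snps[i, ]
    expect_equal(substr(loc$allele_seqs[[sn$allele]], sn$pos + 1, sn$pos + 1),
                 sn$alt)
    expect_equal(substr(loc$allele_seqs[[1]], sn$pos + 1, sn$pos + 1), sn$ref)
  }
})

test_that("guides satisfy the protospacer/PAM/cut-site geometry on allele 1", {
  loc <- make_locus(seed = 3, n_alleles = 2, snp_rate = 0.02)
  a1 <- loc$allele_seqs[[1]]
  g <- loc$guides
  for (i in 1:2) {
    proto <- substr(a1, g$proto_start[i] + 1, g$proto_end[i])
    pam <- substr(a1, g$pam_start[i] + 1, g$pam_end[i])
    if (g$strand[i] == "-") {
      proto <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(proto)))
      pam <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pam)))
    }
    expect_equal(nchar(proto), 20)
    expect_match(pam, "^.GG$")
    # blunt cut between protospacer positions 17|18, i.e. 3 bp 5' of the PAM
    expected <- if (g$strand[i] == "+") g$proto_start[i] + 17 else g$proto_start[i] + 3
    expect_equal(g$cut_pos[i], expected)
  }
  # mature spans nested in the precursor and non-overlapping
  expect_lte(loc$mir5p_span[2], loc$precursor_span[2] - loc$precursor_span[1])
  expect_true(loc$mir3p_span[1] >= loc$mir5p_span[2] ||
                loc$mir3p_span[2] <= loc$mir5p_span[1])
})

test_that("allele counts outside 1..4 and bad templates are rejected", {
  expect_error(make_locus(seed = 1, n_alleles = 0), class = "miredit_bounds_error")
  expect_error(make_locus(seed = 1, n_alleles = 5), class = "miredit_bounds_error")
  expect_error(make_locus(seed = 1, snp_rate = 0.2), class = "miredit_bounds_error")
  # template with no NGG placement near the miR-5p 5' end
  tmpl <- strrep("AT", 200)
  expect_error(
    make_locus(seed = 1, locus_template = tmpl,
               template_precursor_span = c(150, 250),
               template_mir5p_span = c(20, 41)),
    class = "miredit_construction_error")
})

test_that("a user template with valid PAM placements is accepted verbatim", {
  base <- make_locus(seed = 5, n_alleles = 1, snp_rate = 0)
  loc <- make_locus(seed = 6, n_alleles = 3, snp_rate = 0.01,
                    locus_template = base$allele_seqs[[1]],
                    template_precursor_span = base$precursor_span,
                    template_mir5p_span = mir5p_span_amplicon(base))
  expect_identical(loc$allele_seqs[[1]], base$allele_seqs[[1]])
  # guide placement scans for any admissible PAM, so cuts may differ by a few
  # nt from the original design but must stay in the flanking windows
  expect_lte(max(abs(sort(loc$guides$cut_pos) - sort(base$guides$cut_pos))), 5)
})
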