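#' Construct a synthetic tetraploid pre-miRNA locus
#'
#' Builds an amplicon-scale miRNA locus of the kind produced by genotyping
#' PCR in a tetraploid crop: up to four allele sequences differing only by
#' natural SNPs (no natural indels), a stem-loop precursor with annotated
#' mature miR-5p/miR-3p spans, and a dual-guide design flanking the miR-5p
#' coding region. Guide 1 targets the sense strand near the miR-5p 5' end and
#' guide 2 the antisense strand near its 3' end, each a 20-nt protospacer with
#' an NGG PAM and a blunt cut 3 bp 5' of the PAM (between protospacer
#' positions 17 and 18). Both protospacers and PAMs match allele 1 exactly at
#' their recorded coordinates.
#'
#' When `locus_template` is supplied, guides are placed on the template by
#' scanning for NGG (sense) and CCN (antisense) PAM placements whose cut sites
#' fall within 5 nt of the miR-5p boundaries; if no such placement exists the
#' construction fails.
#'
#' @param seed integer seed; the locus is a pure function of the seed and
#'   arguments.
#' @param n_alleles number of alleles, 1--4.
#' @param snp_rate per-base substitution probability for non-reference
#'   alleles, in `[0, 0.05]`.
#' @param locus_template optional DNA string to use as allele 1; must contain
#'   a foldable hairpin. Requires `template_precursor_span` and
#'   `template_mir5p_span` (both 0-based half-open on the template).
#' @param template_precursor_span,template_mir5p_span annotation of the
#'   template (amplicon coordinates).
#' @param amplicon_length length of the synthesised amplicon (default 800 nt,
#'   the scale of a genotyping PCR product).
#' @param mir_length mature miRNA length (default 21 nt).
#' @param n_star_mismatch single-base miRNA/miRNA* duplex mismatches built
#'   into the wild-type stem (default 2; real plant duplexes carry up to 5).
#'   The constructed wild type is always validated to classify as
#'   processing-competent.
#' @param locus_id identifier.
#' @return an object of class `premirna_locus`: `locus_id`, `allele_seqs`
#'   (character vector), `precursor_span` (amplicon coords), `mir5p_span`,
#'   `mir3p_span` (precursor coords), `guides` (tibble with `guide`, `strand`,
#'   `proto_start`, `proto_end`, `pam_start`, `pam_end`, `cut_pos`, all
#'   amplicon coords), `snps` (ground-truth tibble: `allele`, `pos`, `ref`,
#'   `alt`), `seed`.
#' @export
#' @examples
#' loc <- make_locus(seed = 1, n_alleles = 4, snp_rate = 0.01)
#' loc$guides
make_locus <- function(seed, n_alleles = 4L, snp_rate = 0.01,
                       locus_template = NULL,
                       template_precursor_span = NULL,
                       template_mir5p_span = NULL,
                       amplicon_length = 800L, mir_length = 21L,
                       n_star_mismatch = 2L, locus_id = "locus1") {
  if (n_alleles < 1 || n_alleles > 4) {
    abort("n_alleles must be in 1..4", class = "miredit_bounds_error")
  }
  if (snp_rate < 0 || snp_rate > 0.05) {
    abort("snp_rate must be in [0, 0.05]", class = "miredit_bounds_error")
  }
  n_alleles <- as.integer(n_alleles)
  amplicon_length <- as.integer(amplicon_length)
  mir_length <- as.integer(mir_length)

  with_seed(seed, {
    if (is.null(locus_template)) {
      # the wild-type precursor must itself pass the processing classifier;
      # resample until it does (imperfect duplexes occasionally misfold)
      for (attempt in 1:20) {
        built <- build_locus_template(amplicon_length, mir_length,
                                      n_star_mismatch = n_star_mismatch)
        ok <- tryCatch({
          f <- fold(span_substr(built$seq, built$precursor_span))
          d <- locate_duplex(f, built$mir5p_span)
          !classify_processing(mfei(f), d)$impaired
        }, error = function(e) FALSE)
        if (ok) break
      }
      if (!ok) {
        abort("could not construct a processable wild-type precursor",
              class = "miredit_construction_error")
      }
    } else {
      check_dna(locus_template, "locus_template")
      if (is.null(template_precursor_span) || is.null(template_mir5p_span)) {
        abort("a template locus needs template_precursor_span and template_mir5p_span",
              class = "miredit_config_error")
      }
      built <- place_guides_on_template(toupper(locus_template),
                                        template_precursor_span,
                                        template_mir5p_span)
    }

    allele1 <- built$seq
    n <- nchar(allele1)
    alleles <- character(n_alleles)
    alleles[1] <- allele1
    snps <- list()
    if (n_alleles > 1) {
      for (a in 2:n_alleles) {
        hit <- which(runif(n) < snp_rate)
        seq_a <- strsplit(allele1, "")[[1]]
        if (length(hit) > 0) {
          ref <- seq_a[hit]
          alt <- unname(vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), ""))
          seq_a[hit] <- alt
          snps[[length(snps) + 1L]] <-
            tibble(allele = a, pos = hit - 1L, ref = ref, alt = alt)
        }
        alleles[a] <- paste(seq_a, collapse = "")
      }
    }
    snps <- if (length(snps)) bind_rows(snps) else
      tibble(allele = integer(), pos = integer(), ref = character(), alt = character())

    loc <- structure(
      list(locus_id = locus_id,
           allele_seqs = alleles,
           precursor_span = built$precursor_span,
           mir5p_span = built$mir5p_span,
           mir3p_span = built$mir3p_span,
           guides = built$guides,
           snps = snps,
           seed = as.integer(seed)),
      class = "premirna_locus")
    validate_locus(loc)
    loc
  })
}

# Synthesise allele 1 de novo: random flanks around a designed stem-loop whose
# 3' arm is the reverse complement of the 5' arm, with PAM-compatible bases
# fixed inside the miR so both guides validate. Real miRNA/miRNA* duplexes
# are imperfect, so `n_star_mismatch` single-base mismatches are introduced at
# well-separated star positions; the wild type must still classify as
# processable (checked by the caller).
build_locus_template <- function(amplicon_length, mir_length,
                                 n_star_mismatch = 2L) {
  pad5 <- 12L
  loop_len <- 14L
  stem_len <- pad5 + mir_length
  prec_len <- 2L * stem_len + loop_len
  if (amplicon_length < prec_len + 100L) {
    abort("amplicon_length too short for the precursor plus flanks",
          class = "miredit_bounds_error")
  }

  mir <- strsplit(random_dna(mir_length), "")[[1]]
  # guide 1 (sense): PAM GG falls at miR positions 6-7 (cut after miR base 1)
  mir[6:7] <- c("G", "G")
  # guide 2 (antisense): plus-strand CC falls at miR positions 15-16 of a
  # 21-mer (cut before the last miR base)
  mir[(mir_length - 6L):(mir_length - 5L)] <- c("C", "C")
  mir <- paste(mir, collapse = "")

  arm5 <- paste0(random_dna(pad5), mir)
  stem3 <- strsplit(revcomp(arm5), "")[[1]]
  if (n_star_mismatch > 0) {
    # star positions pairing the miR interior (avoid the first 2 star bases,
    # which lie inside guide 2's protospacer footprint)
    mm_pos <- round(seq(6, mir_length - 6L, length.out = n_star_mismatch))
    for (p in mm_pos) {
      stem3[p] <- sample(setdiff(DNA_BASES, stem3[p]), 1)
    }
  }
  stem3 <- paste(stem3, collapse = "")
  precursor <- paste0(arm5, random_dna(loop_len), stem3)

  fl <- (amplicon_length - prec_len) %/% 2L
  seqs <- paste0(random_dna(fl), precursor,
                 random_dna(amplicon_length - fl - prec_len))

  precursor_span <- c(fl, fl + prec_len)
  mir5p_span <- c(pad5, pad5 + mir_length)                    # precursor coords
  mir3p_span <- c(stem_len + loop_len,
                  stem_len + loop_len + mir_length)           # revcomp of miR

  mir_start_abs <- fl + pad5
  mir_end_abs <- mir_start_abs + mir_length
  guides <- make_guides(mir_start_abs, mir_end_abs)

  list(seq = seqs, precursor_span = precursor_span,
       mir5p_span = mir5p_span, mir3p_span = mir3p_span, guides = guides)
}

# Guide geometry used throughout: 20-nt protospacer, NGG PAM, blunt cut
# between protospacer positions 17|18 (3 bp 5' of the PAM).
make_guides <- function(mir_start_abs, mir_end_abs) {
  g1s <- mir_start_abs - 16L    # cut at g1s + 17 = mir_start + 1
  g2s <- mir_end_abs - 4L       # cut at g2s + 3  = mir_end - 1
  tibble(
    guide = c(1L, 2L),
    strand = c("+", "-"),
    proto_start = c(g1s, g2s),
    proto_end = c(g1s + 20L, g2s + 20L),
    pam_start = c(g1s + 20L, g2s - 3L),
    pam_end = c(g1s + 23L, g2s),
    cut_pos = c(g1s + 17L, g2s + 3L)
  )
}

# mir5p_span here is given in template (amplicon) coordinates
place_guides_on_template <- function(seq, precursor_span, mir5p_span) {
  n <- nchar(seq)
  mir_start_abs <- mir5p_span[[1]]
  mir_end_abs <- mir5p_span[[2]]
  chars <- strsplit(seq, "")[[1]]

  find_sense <- function() {
    # cut within [mir_start - 5, mir_start + 5]
    for (cut in (mir_start_abs - 5L):(mir_start_abs + 5L)) {
      g1s <- cut - 17L
      if (g1s < 0 || g1s + 23L > n) next
      if (chars[g1s + 22L] == "G" && chars[g1s + 23L] == "G") return(g1s)
    }
    NA_integer_
  }
  find_antisense <- function() {
    for (cut in (mir_end_abs - 5L):(mir_end_abs + 5L)) {
      g2s <- cut - 3L
      if (g2s - 3L < 0 || g2s + 20L > n) next
      if (chars[g2s - 2L] == "C" && chars[g2s - 1L] == "C") return(g2s)
    }
    NA_integer_
  }
  g1s <- find_sense()
  g2s <- find_antisense()
  if (is.na(g1s) || is.na(g2s)) {
    abort("template lacks a valid NGG PAM placement flanking the miR-5p span",
          class = "miredit_construction_error")
  }
  guides <- tibble(
    guide = c(1L, 2L), strand = c("+", "-"),
    proto_start = c(g1s, g2s), proto_end = c(g1s + 20L, g2s + 20L),
    pam_start = c(g1s + 20L, g2s - 3L), pam_end = c(g1s + 23L, g2s),
    cut_pos = c(g1s + 17L, g2s + 3L)
  )
  # star span unknown on an arbitrary template; annotate via pairing later
  list(seq = seq, precursor_span = precursor_span,
       mir5p_span = c(mir5p_span[[1]] - precursor_span[[1]],
                      mir5p_span[[2]] - precursor_span[[1]]),
       mir3p_span = NULL, guides = guides)
}

validate_locus <- function(loc) {
  a1 <- loc$allele_seqs[[1]]
  n <- nchar(a1)
  stopifnot(all(nchar(loc$allele_seqs) == n))
  ps <- loc$precursor_span
  stopifnot(ps[[1]] >= 0, ps[[2]] <= n)
  m5 <- loc$mir5p_span
  stopifnot(m5[[1]] >= 0, m5[[2]] <= span_width(ps))
  if (!is.null(loc$mir3p_span)) {
    stopifnot(loc$mir3p_span[[2]] <= span_width(ps),
              !spans_overlap(m5, loc$mir3p_span))
  }
  g <- loc$guides
  for (i in seq_len(nrow(g))) {
    proto <- span_substr(a1, c(g$proto_start[i], g$proto_end[i]))
    pam <- span_substr(a1, c(g$pam_start[i], g$pam_end[i]))
    if (g$strand[i] == "-") {
      proto <- revcomp(proto)
      pam <- revcomp(pam)
    }
    stopifnot(nchar(proto) == 20L)
    if (!grepl("^.GG$", pam)) {
      abort(sprintf("guide %d PAM is not NGG on its strand", g$guide[i]),
            class = "miredit_construction_error")
    }
    # cut 3 bp 5' of PAM = after protospacer position 17 on the guide strand
    expected_cut <- if (g$strand[i] == "+") g$proto_start[i] + 17L else g$proto_start[i] + 3L
    stopifnot(g$cut_pos[i] == expected_cut)
  }
  invisible(loc)
}

#' @export
print.premirna_locus <- function(x, ...) {
  cat(sprintf("<premirna_locus %s: %d allele(s), %d nt amplicon>\n",
              x$locus_id, length(x$allele_seqs), nchar(x$allele_seqs[[1]])))
  cat(sprintf("  precursor [%d, %d), miR-5p at precursor [%d, %d)\n",
              x$precursor_span[1], x$precursor_span[2],
              x$mir5p_span[1], x$mir5p_span[2]))
  cat(sprintf("  cuts at %d and %d; %d ground-truth SNP(s)\n",
              x$guides$cut_pos[1], x$guides$cut_pos[2], nrow(x$snps)))
  invisible(x)
}

#' Amplicon-coordinate span of the mature miR-5p
#' @param locus a `premirna_locus`.
#' @return 0-based half-open interval on the amplicon.
#' @export
mir5p_span_amplicon <- function(locus) {
  locus$precursor_span[[1]] + c(locus$mir5p_span[[1]], locus$mir5p_span[[2]])
}

#' Precursor sequence of an allele
#' @param locus a `premirna_locus`.
#' @param allele allele index.
#' @return the precursor DNA string.
#' @export
precursor_seq <- function(locus, allele = 1L) {
  span_substr(locus$allele_seqs[[allele]], locus$precursor_span)
}

#' Write locus alleles as FASTA
#' @param locus a `premirna_locus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(locus, path) {
  x <- Biostrings::DNAStringSet(locus$allele_seqs)
  names(x) <- sprintf("%s_allele%d seed=%d", locus$locus_id,
                      seq_along(locus$allele_seqs), locus$seed)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
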