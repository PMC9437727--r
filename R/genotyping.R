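#' Align amplicon clones to the tetraploid allele set
#'
#' Each clone is globally aligned (affine gaps; match +2, mismatch -3, gap
#' opening 6, gap extension 1 per gap base -- a scoring that favours one long
#' gap for inter-guide excisions over scattered small gaps) against every
#' allele; the best-scoring allele wins, ties going to the lowest allele
#' index. Difference operations (substitutions, deletions, insertions) are
#' reported in amplicon (allele) coordinates, and applying them to the best
#' allele is asserted to reconstruct the clone exactly on every call.
#'
#' `align_clones()` is the vectorised batch form used on whole clone sets;
#' `align_clone()` aligns a single sequence.
#'
#' @param clones character vector of clone sequences (ACGTN), or a tibble with
#'   columns `clone_id` and `sequence`.
#' @param locus a [make_locus()] object.
#' @return a list of `allele_alignment` objects: `clone_id`,
#'   `best_allele_index`, `score`, `ops` (tibble `op` in `sub`/`del`/`ins`,
#'   `start`, `end` 0-based half-open allele coords, `ref`, `alt`).
#' @export
align_clones <- function(clones, locus) {
  stopifnot(inherits(locus, "premirna_locus"))
  if (is.data.frame(clones)) {
    ids <- clones$clone_id
    seqs <- clones$sequence
  } else {
    seqs <- as.character(clones)
    ids <- names(clones) %||% sprintf("clone%03d", seq_along(seqs))
  }
  if (length(seqs) == 0) return(list())
  if (any(!nzchar(seqs))) {
    abort("empty clone sequence", class = "miredit_format_error")
  }
  check_dna(seqs, "clone sequence", allow_n = TRUE)
  seqs <- toupper(seqs)

  mat <- genotyping_submat()
  pat <- Biostrings::DNAStringSet(seqs)

  # pick the best allele by vectorised score-only alignment
  scores <- vapply(locus$allele_seqs, function(a) {
    Biostrings::pairwiseAlignment(pat, Biostrings::DNAString(a),
                                  type = "global", substitutionMatrix = mat,
                                  gapOpening = 6, gapExtension = 1,
                                  scoreOnly = TRUE)
  }, numeric(length(seqs)))
  scores <- matrix(scores, nrow = length(seqs))
  best <- apply(scores, 1, which.max)  # ties -> lowest index

  out <- vector("list", length(seqs))
  for (a in sort(unique(best))) {
    sel <- which(best == a)
    aln <- Biostrings::pairwiseAlignment(pat[sel],
                                         Biostrings::DNAString(locus$allele_seqs[[a]]),
                                         type = "global", substitutionMatrix = mat,
                                         gapOpening = 6, gapExtension = 1)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(sel)) {
      i <- sel[k]
      ops <- canonicalize_ops(alignment_ops(ap[k], as_[k]),
                              locus$allele_seqs[[a]])
      res <- structure(list(clone_id = ids[i],
                            best_allele_index = a,
                            score = scores[i, a],
                            aligned_clone = ap[k],
                            aligned_allele = as_[k],
                            ops = ops),
                       class = "allele_alignment")
      assert_reconstruction(res, locus$allele_seqs[[a]], seqs[i])
      out[[i]] <- res
    }
  }
  out
}

#' @rdname align_clones
#' @param clone a single clone sequence.
#' @export
align_clone <- function(clone, locus) {
  align_clones(clone, locus)[[1]]
}

#' @export
print.allele_alignment <- function(x, ...) {
  cat(sprintf("<allele_alignment %s: best allele %d, score %g, %d difference op(s)>\n",
              x$clone_id, x$best_allele_index, x$score, nrow(x$ops)))
  if (nrow(x$ops)) print(x$ops)
  invisible(x)
}

genotyping_submat <- function() {
  bases <- c(DNA_BASES, "N")
  m <- matrix(-3, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# walk two gapped strings (clone vs allele) and emit difference operations in
# allele coordinates (0-based half-open)
alignment_ops <- function(aligned_clone, aligned_allele) {
  p <- strsplit(aligned_clone, "")[[1]]
  s <- strsplit(aligned_allele, "")[[1]]
  n <- length(p)
  ops <- list()
  spos <- 0L  # allele bases consumed
  i <- 1L
  while (i <= n) {
    if (p[i] != "-" && s[i] != "-") {
      if (p[i] != s[i]) {
        ops[[length(ops) + 1L]] <- tibble(op = "sub", start = spos, end = spos + 1L,
                                          ref = s[i], alt = p[i])
      }
      spos <- spos + 1L
      i <- i + 1L
    } else if (p[i] == "-") {       # deletion from allele
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      len <- j - i
      ops[[length(ops) + 1L]] <- tibble(op = "del", start = spos, end = spos + len,
                                        ref = paste(s[i:(j - 1L)], collapse = ""),
                                        alt = "")
      spos <- spos + len
      i <- j
    } else {                        # insertion into clone
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      ops[[length(ops) + 1L]] <- tibble(op = "ins", start = spos, end = spos,
                                        ref = "",
                                        alt = paste(p[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  if (length(ops)) bind_rows(ops) else
    tibble(op = character(), start = integer(), end = integer(),
           ref = character(), alt = character())
}

# left-normalise deletion spans (see canonical_deletion_span) so that
# alignment gap placement inside repeats matches the simulator's canonical
# ground-truth spans exactly; shifts never cross a preceding operation, and
# if the normalised op set fails to reconstruct the clone the raw ops are
# kept (multi-op edge cases)
canonicalize_ops <- function(ops, allele) {
  if (nrow(ops) == 0 || !any(ops$op == "del")) return(ops)
  raw <- ops
  ops <- arrange(ops, .data$start)
  prev_end <- 0L
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "del") {
      s <- ops$start[i]; e <- ops$end[i]
      while (s > prev_end && substr(allele, s, s) == substr(allele, e, e)) {
        s <- s - 1L
        e <- e - 1L
      }
      ops$start[i] <- s
      ops$end[i] <- e
      ops$ref[i] <- substr(allele, s + 1L, e)
    }
    prev_end <- max(prev_end, ops$end[i])
  }
  if (identical(apply_ops(allele, ops), apply_ops(allele, raw))) ops else raw
}

# reconstruction invariant: ops applied to the allele rebuild the clone
assert_reconstruction <- function(aln, allele, clone) {
  rebuilt <- apply_ops(allele, aln$ops)
  if (!identical(rebuilt, clone)) {
    abort(sprintf("alignment reconstruction failed for %s", aln$clone_id),
          class = "miredit_internal_error")
  }
  invisible(TRUE)
}

#' Apply difference operations to a reference sequence
#' @param ref reference (allele) sequence.
#' @param ops tibble as produced by [align_clones()].
#' @return the reconstructed sequence.
#' @export
apply_ops <- function(ref, ops) {
  if (nrow(ops) == 0) return(ref)
  ops <- arrange(ops, desc(.data$start))  # apply right-to-left
  out <- ref
  for (i in seq_len(nrow(ops))) {
    o <- ops[i, ]
    out <- switch(o$op,
      sub = paste0(substr(out, 1, o$start), o$alt,
                   substr(out, o$start + 2L, nchar(out))),
      del = paste0(substr(out, 1, o$start),
                   substr(out, o$end + 1L, nchar(out))),
      ins = paste0(substr(out, 1, o$start), o$alt,
                   substr(out, o$start + 1L, nchar(out))))
  }
  out
}

#' Build a natural-polymorphism panel from control alignments
#'
#' Collects every substitution (coordinate + alternative base) observed in
#' alignments of unedited control (non-transgenic) clones, plus the
#' ground-truth allelic SNPs of the locus itself when supplied.
#'
#' @param control_alignments list of `allele_alignment` objects from control
#'   clones (may be empty).
#' @param locus optionally a [make_locus()] object whose allele-vs-allele-1
#'   SNPs are added to the panel.
#' @return tibble `pos`, `alt`.
#' @export
snp_panel <- function(control_alignments = list(), locus = NULL) {
  subs <- map(control_alignments, function(a) {
    filter(a$ops, .data$op == "sub") |> transmute(pos = .data$start, alt = .data$alt)
  })
  panel <- bind_rows(subs)
  if (!is.null(locus) && nrow(locus$snps)) {
    panel <- bind_rows(panel, transmute(locus$snps, pos = .data$pos, alt = .data$alt))
    # the reference state at SNP positions is also natural variation
    panel <- bind_rows(panel, transmute(locus$snps, pos = .data$pos, alt = .data$ref))
  }
  distinct(panel)
}

#' Mask natural polymorphism in a clone alignment
#'
#' Substitutions that coincide (same coordinate, same base) with variation
#' seen in the non-transgenic panel are removed from the edit-candidate list;
#' indels are never masked, since natural alleles differ by SNPs only.
#'
#' @param aln an `allele_alignment`.
#' @param panel tibble from [snp_panel()].
#' @return the alignment with `ops` filtered; masked substitutions are kept in
#'   `masked_ops`.
#' @export
mask_polymorphism <- function(aln, panel) {
  stopifnot(inherits(aln, "allele_alignment"))
  if (is.null(panel) || nrow(panel) == 0) {
    warn("empty polymorphism panel: no masking performed")
    aln$masked_ops <- aln$ops[0, ]
    return(aln)
  }
  is_sub <- aln$ops$op == "sub"
  key <- paste(aln$ops$start, aln$ops$alt)
  masked <- is_sub & key %in% paste(panel$pos, panel$alt)
  aln$masked_ops <- aln$ops[masked, ]
  aln$ops <- aln$ops[!masked, ]
  aln
}

#' Classify difference operations into mutation calls
#'
#' Maps the (masked) difference operations of one clone onto the edit classes
#' of the dual-sgRNA repair spectrum. Deletions of 1--6 nt are
#' `short_deletion`; a deletion at least as long as the inter-cut distance
#' minus 4 nt that reaches within 4 nt of both cut sites is
#' `inter_guide_excision`; other deletions longer than 6 nt are
#' `large_deletion`; insertions are typed `insertion` with the inserted base
#' recorded. Substitutions surviving the polymorphism mask are not typed (the
#' Cas9 NHEJ spectrum modelled here contains no substitutions); an empty op
#' set yields a single `none` call.
#'
#' @param ops filtered ops tibble (from [mask_polymorphism()]).
#' @param locus a [make_locus()] object (supplies guides and the miR-5p span).
#' @return tibble of calls: `type`, `span_start`, `span_end`,
#'   `inserted_base`, `distance_to_cut`, `overlaps_mir5p`.
#' @export
classify_mutation <- function(ops, locus) {
  cuts <- sort(locus$guides$cut_pos)
  mir_amp <- mir5p_span_amplicon(locus)
  none_call <- tibble(type = "none", span_start = NA_integer_,
                      span_end = NA_integer_, inserted_base = NA_character_,
                      distance_to_cut = NA_integer_, overlaps_mir5p = FALSE)
  indels <- filter(ops, .data$op %in% c("del", "ins"))
  if (nrow(indels) == 0) return(none_call)

  calls <- map(seq_len(nrow(indels)), function(i) {
    o <- indels[i, ]
    span <- c(o$start, o$end)
    if (o$op == "ins") {
      type <- "insertion"
      base <- o$alt
      omir <- mir_amp[[1]] < o$start && o$start < mir_amp[[2]]
    } else {
      len <- o$end - o$start
      base <- NA_character_
      type <- if (excision_like(c(o$start, o$end), cuts)) "inter_guide_excision"
              else if (len <= 6L) "short_deletion"
              else "large_deletion"
      omir <- spans_overlap(span, mir_amp)
    }
    tibble(type = type, span_start = o$start, span_end = o$end,
           inserted_base = base,
           distance_to_cut = edit_distance_to_cut(span, cuts),
           overlaps_mir5p = omir)
  })
  bind_rows(calls)
}

#' Genotype a set of clones end to end
#'
#' Convenience wrapper: aligns clones, masks natural polymorphism against the
#' panel, classifies mutations, and returns one row per call with clone
#' metadata -- the per-clone calls table consumed by [summarize_line()].
#'
#' @param clones character vector or tibble (`clone_id`, `sequence`).
#' @param locus a [make_locus()] object.
#' @param panel SNP panel from [snp_panel()]; defaults to the locus ground
#'   truth.
#' @return tibble: `clone_id`, `best_allele_index`, plus the
#'   [classify_mutation()] columns.
#' @export
genotype_clones <- function(clones, locus, panel = snp_panel(locus = locus)) {
  alns <- align_clones(clones, locus)
  rows <- map(alns, function(a) {
    a <- if (nrow(panel)) mask_polymorphism(a, panel) else { a$masked_ops <- a$ops[0, ]; a }
    calls <- classify_mutation(a$ops, locus)
    calls$clone_id <- a$clone_id
    calls$best_allele_index <- a$best_allele_index
    calls
  })
  relocate(bind_rows(rows), "clone_id", "best_allele_index")
}

#' Summarise per-clone mutation calls into a line genotype
#'
#' @param calls tibble from [genotype_clones()] (>= 1 clone).
#' @param line_id identifier.
#' @return one-row tibble: `line_id`, `n_clones`, `n_mutated`,
#'   `mutated_fraction`, one count column per mutation type, and
#'   `all_alleles_mutated` (every analysed clone carries an edit).
#' @export
summarize_line <- function(calls, line_id = "line1") {
  stopifnot(nrow(calls) > 0)
  per_clone <- calls |>
    group_by(.data$clone_id) |>
    summarise(mutated = any(.data$type != "none"), .groups = "drop")
  n_clones <- nrow(per_clone)
  n_mut <- sum(per_clone$mutated)
  types <- c("short_deletion", "insertion", "inter_guide_excision", "large_deletion")
  spectrum <- vapply(types, function(t) sum(calls$type == t), 1L)
  tibble(line_id = line_id, n_clones = n_clones, n_mutated = n_mut,
         mutated_fraction = n_mut / n_clones,
         !!!setNames(as.list(spectrum), paste0("n_", types)),
         all_alleles_mutated = n_mut == n_clones)
}
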