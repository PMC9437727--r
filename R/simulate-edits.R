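#' Edit-outcome profile for the Cas9 repair spectrum
#'
#' The repair spectrum observed after dual-sgRNA editing is dominated by short
#' deletions (up to 6 nt) at the cut sites, with 1-nt T or G insertions,
#' occasional excision of the whole inter-guide fragment, and rarer longer
#' deletions. Class probabilities must sum to 1. Edits are positioned at a
#' cut site jittered uniformly within `jitter` nt (default +/-4, covering the
#' 0--5 nt offsets from the cut reported across plant editing studies).
#'
#' @param p_none,p_short_deletion,p_insertion_T,p_insertion_G,
#'   p_inter_guide_excision,p_large_deletion class probabilities.
#' @param jitter maximum absolute positional jitter around the cut (nt).
#' @param mosaicism number of distinct edit outcomes carried by one
#'   regenerated line (primary transformants are frequently mosaic).
#' @return a list of class `edit_profile`.
#' @export
edit_profile <- function(p_none = 0.15, p_short_deletion = 0.45,
                         p_insertion_T = 0.1, p_insertion_G = 0.1,
                         p_inter_guide_excision = 0.1,
                         p_large_deletion = 0.1,
                         jitter = 4L, mosaicism = 3L) {
  p <- c(none = p_none, short_deletion = p_short_deletion,
         insertion_T = p_insertion_T, insertion_G = p_insertion_G,
         inter_guide_excision = p_inter_guide_excision,
         large_deletion = p_large_deletion)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("edit class probabilities must be non-negative and sum to 1",
          class = "miredit_config_error")
  }
  if (jitter < 0 || jitter > 4) {
    abort("positional jitter must be within +/-4 nt of the cut",
          class = "miredit_bounds_error")
  }
  structure(list(probs = p, jitter = as.integer(jitter),
                 mosaicism = as.integer(mosaicism)),
            class = "edit_profile")
}

apply_edit <- function(seq, type, span, inserted_base) {
  switch(type,
    none = seq,
    insertion = paste0(substr(seq, 1, span[[1]]), inserted_base,
                       substr(seq, span[[1]] + 1L, nchar(seq))),
    # all deletion flavours
    paste0(substr(seq, 1, span[[1]]), substr(seq, span[[2]] + 1L, nchar(seq)))
  )
}

# left-normalise a deletion span: the same edited sequence can arise from
# several shift-equivalent spans inside a repeat; sliding to the leftmost
# placement gives every equivalent deletion one canonical span, so simulator
# ground truth and alignment-derived operations compare exactly
canonical_deletion_span <- function(seq, span) {
  s <- span[[1]]; e <- span[[2]]
  while (s > 0 && substr(seq, s, s) == substr(seq, e, e)) {
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

# span-based definition of an inter-guide excision, shared by the simulator's
# ground-truth labels and the mutation classifier: at least as long as the
# inter-cut distance minus 4 nt and reaching within 4 nt of both cut sites
# (jitter-proof against alignment gap sliding)
excision_like <- function(span, cuts) {
  (span[[2]] - span[[1]]) >= (cuts[2] - cuts[1] - 4L) &&
    span[[1]] <= cuts[1] + 4L && span[[2]] >= cuts[2] - 4L
}

edit_distance_to_cut <- function(span, cuts) {
  d <- vapply(cuts, function(cut) {
    if (span[[1]] <= cut && cut <= span[[2]]) 0
    else min(abs(span[[1]] - cut), abs(span[[2]] - cut))
  }, numeric(1))
  as.integer(min(d))
}

#' Simulate CRISPR edit events on a locus
#'
#' Draws `n_events` independent edit outcomes: an allele is picked uniformly,
#' an edit class is drawn from the profile, and the edit is placed at one of
#' the two cut sites with bounded uniform jitter. Short deletions are 1--6 nt,
#' large deletions 7--30 nt (both placed straddling the jittered cut),
#' insertions add one T or G at the jittered cut, and inter-guide excision
#' removes exactly the interval between the two cut positions. The returned
#' table is the machine-readable ground truth used to score genotyping.
#'
#' @param locus a [make_locus()] object.
#' @param profile an [edit_profile()].
#' @param n_events number of outcomes to draw (>= 1).
#' @param seed integer seed.
#' @return tibble with one row per event: `event`, `allele_index`, `type`
#'   (`none`, `short_deletion`, `insertion`, `inter_guide_excision`,
#'   `large_deletion`), `span_start`, `span_end` (0-based half-open, amplicon
#'   coords of the unedited allele; width 0 at the insertion point), `
#'   inserted_base`, `guide`, `distance_to_cut`, `overlaps_mir5p`,
#'   `edited_seq`.
#' @export
simulate_edits <- function(locus, profile, n_events, seed = locus$seed + 1L) {
  stopifnot(inherits(locus, "premirna_locus"))
  if (!inherits(profile, "edit_profile")) {
    abort("profile must be an edit_profile()", class = "miredit_config_error")
  }
  if (n_events < 1) abort("n_events must be >= 1", class = "miredit_bounds_error")
  if (nrow(locus$guides) != 2) {
    abort("locus must carry a guide pair", class = "miredit_config_error")
  }
  cuts <- sort(locus$guides$cut_pos)
  mir_amp <- mir5p_span_amplicon(locus)
  n_all <- length(locus$allele_seqs)

  with_seed(seed, {
    rows <- map(seq_len(n_events), function(ev) {
      allele <- sample.int(n_all, 1)
      src <- locus$allele_seqs[[allele]]
      cls <- sample(names(profile$probs), 1, prob = profile$probs)
      g <- sample(1:2, 1)
      j <- if (profile$jitter > 0) sample(seq(-profile$jitter, profile$jitter), 1) else 0L
      cutj <- cuts[g] + j

      if (cls == "none") {
        type <- "none"; span <- c(NA_integer_, NA_integer_); base <- NA_character_
      } else if (cls == "short_deletion") {
        len <- sample(1:6, 1)
        s <- cutj - as.integer(ceiling(len / 2))
        type <- "short_deletion"; span <- c(s, s + len); base <- NA_character_
      } else if (cls == "large_deletion") {
        len <- sample(7:30, 1)
        s <- cutj - as.integer(ceiling(len / 2))
        span <- c(s, s + len); base <- NA_character_
        # a long deletion spanning both cut neighbourhoods is, by the
        # span-based type rules, an inter-guide excision
        type <- if (excision_like(span, cuts)) "inter_guide_excision"
                else "large_deletion"
      } else if (cls == "inter_guide_excision") {
        type <- "inter_guide_excision"; span <- c(cuts[1], cuts[2]); base <- NA_character_
      } else { # insertion_T / insertion_G
        type <- "insertion"; span <- c(cutj, cutj)
        base <- if (cls == "insertion_T") "T" else "G"
      }

      if (type == "none") {
        edited <- src; dist <- NA_integer_; omir <- FALSE
      } else {
        stopifnot(span[[1]] >= 0, span[[2]] <= nchar(src))
        if (type != "insertion") {
          span <- canonical_deletion_span(src, span)
          if (type != "inter_guide_excision" && excision_like(span, cuts)) {
            type <- "inter_guide_excision"
          }
        }
        edited <- apply_edit(src, if (type == "insertion") "insertion" else "deletion",
                             span, base)
        dist <- edit_distance_to_cut(span, cuts)
        omir <- if (type == "insertion") {
          mir_amp[[1]] < span[[1]] && span[[1]] < mir_amp[[2]]
        } else {
          spans_overlap(span, mir_amp)
        }
      }
      tibble(event = ev, allele_index = allele, type = type,
             span_start = span[[1]], span_end = span[[2]],
             inserted_base = base, guide = if (type %in% c("none")) NA_integer_ else g,
             distance_to_cut = dist, overlaps_mir5p = omir, edited_seq = edited)
    })
    bind_rows(rows)
  })
}

#' Simulate the allele composition of one regenerated transgenic line
#'
#' A line carries `n_alleles` chromosomal alleles; mosaicism means the number
#' of distinct sequence outcomes can exceed the allele count. This helper
#' draws `profile$mosaicism` outcomes via [simulate_edits()] and assigns them
#' equal proportions, yielding the `line truth` consumed by clone, trace and
#' sRNA simulation.
#'
#' @param locus a [make_locus()] object.
#' @param profile an [edit_profile()].
#' @param seed integer seed.
#' @param line_id identifier.
#' @return tibble: one row per outcome with the [simulate_edits()] columns
#'   plus `line_id` and `proportion` (summing to 1).
#' @export
simulate_line <- function(locus, profile, seed, line_id = "line1") {
  k <- max(1L, profile$mosaicism)
  truth <- simulate_edits(locus, profile, n_events = k, seed = seed)
  truth$line_id <- line_id
  truth$proportion <- rep(1 / k, k)
  truth
}

#' Sample amplicon clones from a mosaic line
#'
#' Models the colony-sequencing step of genotyping: individual PCR products
#' are cloned and `n_clones` colonies are sequenced, i.e. outcomes are sampled
#' with replacement according to their proportions in the line.
#'
#' @param line_truth tibble with columns `edited_seq` and `proportion`
#'   (proportions sum to 1), e.g. from [simulate_line()].
#' @param n_clones number of clones to draw (0 gives an empty result).
#' @param seed integer seed.
#' @return tibble: `clone_id`, `source_event` (row index into `line_truth`),
#'   `allele_index` and `type` when present in the truth, and `sequence`.
#' @export
simulate_amplicon_clones <- function(line_truth, n_clones, seed) {
  if (nrow(line_truth) == 0) {
    abort("line_truth is empty", class = "miredit_value_error")
  }
  if (abs(sum(line_truth$proportion) - 1) > 1e-8) {
    abort("line_truth proportions must sum to 1", class = "miredit_value_error")
  }
  if (n_clones == 0) {
    return(tibble(clone_id = character(), source_event = integer(),
                  allele_index = integer(), type = character(),
                  sequence = character()))
  }
  with_seed(seed, {
    idx <- sample.int(nrow(line_truth), n_clones, replace = TRUE,
                      prob = line_truth$proportion)
    tibble(clone_id = sprintf("clone%03d", seq_len(n_clones)),
           source_event = idx,
           allele_index = if ("allele_index" %in% names(line_truth))
             line_truth$allele_index[idx] else NA_integer_,
           type = if ("type" %in% names(line_truth))
             line_truth$type[idx] else NA_character_,
           sequence = line_truth$edited_seq[idx])
  })
}
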