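#' Knock-out score by non-negative least-squares trace deconvolution
#'
#' Estimates the editing rate at a locus from a mixed Sanger trace, in the
#' spirit of trace-deconvolution screening tools: the observed base-proportion
#' matrix over a window spanning the divergence region is approximated as a
#' non-negative mixture of candidate trace profiles (the unedited alleles plus
#' an enumerated indel set around the cut sites), proportions are normalised,
#' and the editing rate is 1 minus the proportion assigned to unedited
#' candidates.
#'
#' Candidates whose profiles are identical over the window are collapsed into
#' one equivalence group (they are mutually indistinguishable); if a group
#' mixes edited and unedited candidates the editing rate is unidentifiable
#' over this window and a widen-window error is raised.
#'
#' @param trace a `trace_matrix` from [simulate_sanger_trace()] or
#'   [read_trace_tsv()].
#' @param locus a [make_locus()] object supplying the unedited alleles and cut
#'   positions.
#' @param candidate_edits optional tibble of extra candidates with columns
#'   `candidate_id`, `sequence`, `edited` (logical); by default the candidate
#'   set is enumerated by [enumerate_edit_candidates()].
#' @return an object of class `knockout_score`: list with `editing_rate`,
#'   `proportions` (tibble `candidate_id`, `edited`, `proportion`; groups of
#'   indistinguishable candidates are reported under their first member with
#'   `n_equivalent`), and `residual` (Euclidean norm of the NNLS residual).
#' @export
ko_score <- function(trace, locus, candidate_edits = NULL) {
  stopifnot(inherits(trace, "trace_matrix"), inherits(locus, "premirna_locus"))
  window <- attr(trace, "window")

  cands <- candidate_edits %||% enumerate_edit_candidates(locus)
  stopifnot(all(c("candidate_id", "sequence", "edited") %in% names(cands)))
  # always include the unedited alleles
  base <- tibble(candidate_id = paste0("allele", seq_along(locus$allele_seqs)),
                 sequence = locus$allele_seqs, edited = FALSE)
  cands <- bind_rows(base, anti_join(cands, base, by = "candidate_id"))

  profiles <- map(cands$sequence, trace_profile, window = window)
  C <- do.call(cbind, map(profiles, as.vector))

  # collapse indistinguishable candidates
  key <- vapply(seq_len(ncol(C)), function(j) paste(C[, j], collapse = ","), "")
  grp <- match(key, unique(key))
  rep_idx <- match(seq_along(unique(key)), grp)
  mixed <- vapply(seq_along(unique(key)), function(g) {
    ed <- cands$edited[grp == g]
    any(ed) && !all(ed)
  }, TRUE)
  if (any(mixed)) {
    abort(paste0("candidate trace profiles are indistinguishable between ",
                 "edited and unedited candidates over this window; widen the ",
                 "trace window to cover more of the divergence region"),
          class = "miredit_widen_window_error")
  }
  Cu <- C[, rep_idx, drop = FALSE]

  d <- as.vector(unclass(trace))
  fit <- pracma::lsqnonneg(Cu, d)
  x <- fit$x
  if (sum(x) <= 0) {
    abort("trace deconvolution returned an all-zero mixture",
          class = "miredit_value_error")
  }
  p <- x / sum(x)
  n_equiv <- as.integer(table(grp)[as.character(seq_along(rep_idx))])

  props <- tibble(candidate_id = cands$candidate_id[rep_idx],
                  edited = cands$edited[rep_idx],
                  proportion = p,
                  n_equivalent = n_equiv) |>
    arrange(desc(.data$proportion))

  structure(list(editing_rate = sum(p[cands$edited[rep_idx]]),
                 proportions = props,
                 residual = sqrt(sum((Cu %*% x - d)^2))),
            class = "knockout_score")
}

#' @export
print.knockout_score <- function(x, ...) {
  cat(sprintf("<knockout_score: editing rate %.3f, residual %.4f>\n",
              x$editing_rate, x$residual))
  print(head(x$proportions, 5))
  invisible(x)
}

#' Enumerate indel candidates for trace deconvolution
#'
#' The candidate grammar covers every edit class the genotyping module can
#' call: deletions of 1--15 nt ending at offsets -4..+4 around each cut,
#' single-base insertions (A/C/G/T) at each cut, and the inter-guide excision
#' -- all applied to allele 1 (allele-specific SNPs are second-order for the
#' trace signal and are represented by the unedited allele candidates).
#'
#' @param locus a [make_locus()] object.
#' @param del_lengths deletion lengths to enumerate.
#' @param offsets cut-site offsets for deletion ends.
#' @return tibble: `candidate_id`, `sequence`, `edited`.
#' @export
enumerate_edit_candidates <- function(locus, del_lengths = 1:15, offsets = -4:4) {
  a1 <- locus$allele_seqs[[1]]
  cuts <- sort(locus$guides$cut_pos)
  out <- list()
  for (g in 1:2) {
    for (len in del_lengths) {
      for (off in offsets) {
        e <- cuts[g] + off
        s <- e - len
        if (s < 0 || e > nchar(a1)) next
        out[[length(out) + 1L]] <- tibble(
          candidate_id = sprintf("del%d_g%d_off%+d", len, g, off),
          sequence = apply_edit(a1, "deletion", c(s, e), NA),
          edited = TRUE)
      }
    }
    for (b in DNA_BASES) {
      out[[length(out) + 1L]] <- tibble(
        candidate_id = sprintf("ins%s_g%d", b, g),
        sequence = apply_edit(a1, "insertion", c(cuts[g], cuts[g]), b),
        edited = TRUE)
    }
  }
  out[[length(out) + 1L]] <- tibble(
    candidate_id = "inter_guide_excision",
    sequence = apply_edit(a1, "deletion", cuts, NA),
    edited = TRUE)
  distinct(bind_rows(out), .data$sequence, .keep_all = TRUE)
}
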