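#' Locate and characterise the miRNA/miRNA* duplex in a folded precursor
#'
#' Given a folded precursor and the mature miR-5p span, infers the miRNA*
#' (star) span from the pairing partners of the miR-5p bases extended by the
#' canonical 2-nt 3' overhang, and measures the duplex features that drive the
#' impaired-processing call: the number of miR-5p mismatch positions (unpaired
#' or paired outside the star span; G:U wobbles count as paired) and the
#' largest internal loop inside the duplex.
#'
#' Loop size is measured as the total number of unpaired nucleotides on both
#' strands of one contiguous interior loop bounded by duplex pairs. Because
#' the field usage is ambiguous on whether loops are measured per strand or
#' summed, the per-strand maximum is also reported
#' (`largest_loop_one_strand_nt`) for sensitivity analysis; only the summed
#' metric feeds [classify_processing()].
#'
#' @param fold a `fold_result` from [fold()].
#' @param mir5p_span 0-based half-open interval of the mature miR-5p on the
#'   folded sequence.
#' @param mir3p_span optional annotated miR-3p span; when supplied it takes
#'   precedence over the inferred star span.
#' @return a one-row tibble of class `duplex_features`: `mir5p_start/end`,
#'   `mirstar_start/end`, `n_mismatch_positions`, `largest_internal_loop_nt`,
#'   `largest_loop_one_strand_nt`, `overhang_3p_nt`.
#' @export
locate_duplex <- function(fold, mir5p_span, mir3p_span = NULL) {
  stopifnot(inherits(fold, "fold_result"))
  n <- nchar(fold$sequence)
  if (mir5p_span[[1]] < 0 || mir5p_span[[2]] > n) {
    abort("mir5p_span lies outside the folded sequence", class = "miredit_bounds_error")
  }
  if (span_width(mir5p_span) <= 0) {
    abort("miR-5p span is empty (precursor excised)",
          class = "miredit_degenerate_duplex")
  }
  partner <- parse_dotbracket(fold$dot_bracket)
  mir_idx <- (mir5p_span[[1]] + 1L):mir5p_span[[2]] # 1-based
  partners <- partner[mir_idx]
  paired <- !is.na(partners)
  if (!any(paired)) {
    abort("no paired bases in the miR-5p span (degenerate duplex)",
          class = "miredit_degenerate_duplex")
  }

  if (!is.null(mir3p_span)) {
    star <- c(mir3p_span[[1]], mir3p_span[[2]])
  } else {
    # star = span of pairing partners, + 2-nt 3' overhang. The star strand
    # runs antiparallel, so its 3' end is the high-coordinate side (the
    # partner of the miR-5p 5' end).
    lo <- min(partners[paired]) - 1L       # 0-based start
    hi <- max(partners[paired])            # 0-based end (half-open)
    overhang <- min(2L, n - hi)
    star <- c(lo, hi + overhang)
  }

  outside <- !paired | partners <= star[[1]] | partners > star[[2]]
  n_mismatch <- sum(outside)

  # interior loops between consecutive duplex pairs (miR position paired into
  # the star span); loop size = unpaired on the miR strand + unpaired on the
  # star strand between the bounding pairs
  in_duplex <- paired & !outside
  loop_both <- 0L
  loop_one <- 0L
  dk <- mir_idx[in_duplex]
  dp <- partners[in_duplex]
  if (length(dk) >= 2) {
    gap_m <- dk[-1] - dk[-length(dk)] - 1L
    gap_s <- dp[-length(dp)] - dp[-1] - 1L
    gap_s <- pmax(gap_s, 0L) # guard against partner order anomalies
    loop_both <- max(gap_m + gap_s)
    loop_one <- max(pmax(gap_m, gap_s))
  }
  # unpaired overhangs of the miR itself at the duplex edges count as
  # mismatches (above), not as internal loops

  out <- tibble(
    mir5p_start = mir5p_span[[1]], mir5p_end = mir5p_span[[2]],
    mirstar_start = star[[1]], mirstar_end = star[[2]],
    n_mismatch_positions = as.integer(n_mismatch),
    largest_internal_loop_nt = as.integer(loop_both),
    largest_loop_one_strand_nt = as.integer(loop_one),
    overhang_3p_nt = if (is.null(mir3p_span)) as.integer(min(2L, n - max(partners[paired]))) else NA_integer_
  )
  class(out) <- c("duplex_features", class(out))
  out
}

#' Classify pre-miRNA processing competence
#'
#' A precursor is called `impaired` when its MFEI falls below 0.85 (strictly),
#' when an internal loop larger than 5 nt (strictly) is present in the
#' miRNA/miRNA* duplex, or when the precursor/mature region has been excised
#' or the duplex is degenerate. `reasons` enumerates every trigger, so the
#' call is monotone: lowering MFEI or enlarging the loop can never flip an
#' impaired call back to processable.
#'
#' @param mfei_rec one-row tibble from [mfei()], or `NULL` when the precursor
#'   was excised.
#' @param duplex one-row tibble from [locate_duplex()], or `NULL`.
#' @param excised set `TRUE` when the mature region was excised or
#'   [locate_duplex()] signalled a degenerate duplex.
#' @param mfei_threshold,loop_threshold classifier thresholds; impaired when
#'   `mfei < mfei_threshold` or `loop > loop_threshold`.
#' @return a one-row tibble: `impaired`, `reasons` (comma-joined subset of
#'   `low_mfei`, `internal_loop`, `precursor_excised`), `mfei`, `loop_nt`.
#' @export
#' @examples
#' f <- fold("GGGGAAAACCCCGGGGAAAACCCC")
#' classify_processing(mfei(f), NULL)
classify_processing <- function(mfei_rec, duplex = NULL, excised = FALSE,
                                mfei_threshold = 0.85, loop_threshold = 5L) {
  reasons <- character(0)
  mfei_val <- if (!is.null(mfei_rec)) mfei_rec$mfei[[1]] else NA_real_
  loop_val <- if (!is.null(duplex)) duplex$largest_internal_loop_nt[[1]] else NA_integer_

  if (isTRUE(excised)) reasons <- c(reasons, "precursor_excised")
  if (!is.na(mfei_val) && mfei_val < mfei_threshold) reasons <- c(reasons, "low_mfei")
  if (!is.na(loop_val) && loop_val > loop_threshold) reasons <- c(reasons, "internal_loop")

  tibble(impaired = length(reasons) > 0,
         reasons = paste(reasons, collapse = ","),
         mfei = mfei_val,
         loop_nt = loop_val)
}

#' Fold, score and classify a set of precursors
#'
#' Convenience wrapper running [fold()], [mfei()], [locate_duplex()] and
#' [classify_processing()] over a table of precursor sequences, the per-locus
#' step of the pipeline. A degenerate or excised duplex is classified
#' impaired with reason `precursor_excised`.
#'
#' @param precursors tibble with columns `precursor_id`, `sequence`,
#'   `mir5p_start`, `mir5p_end` (0-based half-open on the sequence).
#' @param engine folding engine, see [fold()].
#' @param min_mature_nt mature spans shorter than this are treated as excised:
#'   canonical plant miRNAs are 20--24 nt, so a precursor that has lost more
#'   than a few bases of its mature span cannot produce one (default 16).
#' @return the input with columns `length`, `gc_percent`, `mfe_kcal_mol`,
#'   `amfe`, `mfei`, `n_mismatch_positions`, `largest_internal_loop_nt`,
#'   `largest_loop_one_strand_nt`, `dot_bracket`, `impaired`, `reasons`.
#' @export
classify_precursors <- function(precursors, engine = "internal",
                                min_mature_nt = 16L) {
  stopifnot(all(c("precursor_id", "sequence", "mir5p_start", "mir5p_end")
                %in% names(precursors)))
  rows <- map(seq_len(nrow(precursors)), function(i) {
    sq <- precursors$sequence[[i]]
    span <- c(precursors$mir5p_start[[i]], precursors$mir5p_end[[i]])
    if (is.na(sq) || nchar(sq) < 10 || span_width(span) < min_mature_nt) {
      return(tibble(length = nchar(sq %||% ""), gc_percent = NA_real_,
                    mfe_kcal_mol = NA_real_, amfe = NA_real_, mfei = NA_real_,
                    n_mismatch_positions = NA_integer_,
                    largest_internal_loop_nt = NA_integer_,
                    largest_loop_one_strand_nt = NA_integer_,
                    dot_bracket = NA_character_,
                    impaired = TRUE, reasons = "precursor_excised"))
    }
    f <- fold(sq, engine = engine)
    mf <- mfei(f)
    dup <- tryCatch(locate_duplex(f, span),
                    miredit_degenerate_duplex = function(e) NULL)
    cls <- classify_processing(mf, dup, excised = is.null(dup))
    tibble(length = mf$length, gc_percent = mf$gc_percent,
           mfe_kcal_mol = mf$mfe_kcal_mol, amfe = mf$amfe, mfei = mf$mfei,
           n_mismatch_positions = dup$n_mismatch_positions %||% NA_integer_,
           largest_internal_loop_nt = dup$largest_internal_loop_nt %||% NA_integer_,
           largest_loop_one_strand_nt = dup$largest_loop_one_strand_nt %||% NA_integer_,
           dot_bracket = f$dot_bracket,
           impaired = cls$impaired, reasons = cls$reasons)
  })
  bind_cols(precursors, bind_rows(rows))
}
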