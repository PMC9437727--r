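#' Sequence helpers
#'
#' Small utilities shared across the package. All coordinates in this package
#' are 0-based half-open intervals `c(start, end)` over the sequence they
#' refer to, so that Cas9 cut positions (which fall *between* bases) and
#' interval arithmetic on deletions are exact. Conversion to 1-based
#' coordinates happens only in rendered reports.
#'
#' @name miredit-coordinates
NULL

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

dna_to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, toupper(x))
  if (any(bad)) {
    abort(sprintf("%s contains characters outside the %s alphabet",
                  what, if (allow_n) "ACGTN" else "ACGT"),
          class = "miredit_format_error")
  }
  invisible(toupper(x))
}

#' @noRd
span_width <- function(span) span[[2]] - span[[1]]

#' Extract a 0-based half-open span from a string
#' @noRd
span_substr <- function(seq, span) {
  if (span_width(span) <= 0) return("")
  substr(seq, span[[1]] + 1L, span[[2]])
}

span_contains <- function(span, pos) span[[1]] <= pos && pos <= span[[2]]

spans_overlap <- function(a, b) a[[1]] < b[[2]] && b[[1]] < a[[2]]

#' Remap a span through a single edit
#'
#' Maps a 0-based half-open interval on the unedited sequence onto the edited
#' sequence given one difference operation. Deleted positions collapse onto
#' the deletion point, so a span fully inside a deletion maps to a width-0
#' interval.
#'
#' @param span integer pair, 0-based half-open.
#' @param type one of `"none"`, `"deletion"`, `"insertion"`.
#' @param at for deletions, the deleted interval; for insertions, the 0-based
#'   position before which bases were inserted.
#' @param len edit length (deleted or inserted bases).
#' @return remapped integer pair.
#' @noRd
remap_span <- function(span, type, at, len) {
  if (type == "none") return(span)
  map_pos <- function(p) {
    if (type == "deletion") {
      d0 <- at[[1]]; d1 <- at[[2]]
      if (p <= d0) p else if (p >= d1) p - (d1 - d0) else d0
    } else { # insertion before position `at`
      if (p < at) p else p + len
    }
  }
  c(map_pos(span[[1]]), map_pos(span[[2]]))
}

#' Run code with a locally-set RNG seed
#'
#' Every generator in the package is a pure function of its seed: RNG state is
#' restored on exit.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Derive a bounded per-stage seed from a master seed
#' @noRd
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) * 7919L
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}
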