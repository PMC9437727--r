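#' Scoring weights for miRNA target expectation
#'
#' Penalty-based complementarity scoring of a miRNA against a target site
#' (miRNA 5'->3' aligned antiparallel to the site): each mismatch costs 1,
#' each G:U wobble 0.5, each gapped position 2, and positions 2--13 from the
#' miRNA 5' end are double-weighted. The total penalty is the expectation
#' score: 0 for a perfect complement, lower is better, and hits are typically
#' reported up to a cutoff of 3 (strict) to 5. At most one bulge of up to 2 nt
#' is allowed per site, matching the near-perfect complementarity of plant
#' miRNA targets.
#'
#' @param mismatch,wobble,gap per-position penalties.
#' @param seed_weight multiplier for positions `seed_range[1]..seed_range[2]`.
#' @param seed_range double-weighted miRNA positions (1-based from 5').
#' @param central_range central positions whose consecutive mispairing blocks
#'   cleavage guidance (1-based from 5').
#' @param max_bulge maximum bulge size (nt, one bulge per site).
#' @return list of class `target_weights`.
#' @export
target_weights <- function(mismatch = 1, wobble = 0.5, gap = 2,
                           seed_weight = 2, seed_range = c(2L, 13L),
                           central_range = c(12L, 14L), max_bulge = 2L) {
  structure(list(mismatch = mismatch, wobble = wobble, gap = gap,
                 seed_weight = seed_weight, seed_range = seed_range,
                 central_range = central_range, max_bulge = as.integer(max_bulge)),
            class = "target_weights")
}

# pairing classes between a miRNA base and a target base (both given 5'->3'
# in their own strands): 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
pair_class <- function(m, t) {
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, 0L, ifelse(gu, 1L, 2L))
}

#' Score one miRNA : target-site alignment
#'
#' Aligns the miRNA (5'->3') against a candidate site subsequence (antiparallel)
#' and returns the expectation score, the mismatch positions in miRNA
#' coordinates, and whether a central block (>= 3 consecutive mispaired
#' positions intersecting the central range, default 12--14) is present --
#' mispairing there abolishes cleavage guidance, so such hits are flagged
#' non-functional regardless of score. Window lengths may differ from the
#' miRNA by up to `max_bulge` nt; all admissible single-bulge placements are
#' tried and the best-scoring alignment wins.
#'
#' @param mirna miRNA sequence, 18--26 nt (RNA or DNA).
#' @param window target-site subsequence (sense strand of the transcript).
#' @param weights a [target_weights()].
#' @param cutoff expectation cutoff for the `functional` flag.
#' @return one-row tibble: `expectation`, `mismatch_positions` (comma string,
#'   1-based miRNA coords; G:U wobbles are paired, not mismatches),
#'   `central_block`, `functional`, `n_gap`.
#' @export
#' @examples
#' score_site("UGCCUGGCUCCCUGUAUGCCA",
#'            as.character(Biostrings::reverseComplement(
#'              Biostrings::RNAString("UGCCUGGCUCCCUGUAUGCCA"))))
score_site <- function(mirna, window, weights = target_weights(), cutoff = 3) {
  m <- dna_to_rna(mirna)
  w <- dna_to_rna(window)
  mlen <- nchar(m)
  if (mlen < 18 || mlen > 26) {
    abort("miRNA length must be 18..26 nt", class = "miredit_value_error")
  }
  diff <- nchar(w) - mlen
  if (abs(diff) > weights$max_bulge) {
    abort(sprintf("window length differs from the miRNA by %d nt (max bulge %d)",
                  diff, weights$max_bulge), class = "miredit_value_error")
  }
  mc <- strsplit(m, "")[[1]]
  # target read 3'->5' so that position i of the miRNA faces position i
  tc <- rev(strsplit(w, "")[[1]])

  alns <- enumerate_alignments(mlen, nchar(w))
  best <- NULL
  for (al in alns) {
    sc <- score_alignment(mc, tc, al, weights)
    if (is.null(best) || sc$expectation < best$expectation) best <- sc
  }
  best$functional <- best$expectation <= cutoff && !best$central_block
  as_tibble(best[c("expectation", "mismatch_positions", "central_block",
                   "functional", "n_gap")])
}

# admissible alignments between a miRNA of length m and a (reversed) window of
# length wl, with one interior bulge of size |wl - m| on the longer strand;
# an alignment is the vector of window indices faced by miRNA positions 1..m
# (NA = miRNA base bulged out)
enumerate_alignments <- function(m, wl) {
  g <- wl - m
  if (g == 0) return(list(list(tpos = seq_len(m), gap_at = integer(0))))
  out <- list()
  if (g > 0) {
    # extra target nts bulge out between miRNA positions b and b+1
    for (b in 1:(m - 1)) {
      tpos <- c(seq_len(b), seq_len(m - b) + b + g)
      out[[length(out) + 1L]] <- list(tpos = tpos, gap_at = b + 1L, gap_len = g,
                                      gap_strand = "target")
    }
  } else {
    g <- -g
    # miRNA positions b+1..b+g are bulged out (face no target base)
    for (b in 1:(m - g - 1)) {
      tpos <- c(seq_len(b), rep(NA_integer_, g), seq_len(m - b - g) + b)
      out[[length(out) + 1L]] <- list(tpos = tpos, gap_at = (b + 1L):(b + g),
                                      gap_len = g, gap_strand = "mirna")
    }
  }
  out
}

score_alignment <- function(mc, tc, al, weights) {
  m <- length(mc)
  wpos <- seq_len(m)
  wt <- ifelse(wpos >= weights$seed_range[1] & wpos <= weights$seed_range[2],
               weights$seed_weight, 1)
  pen <- numeric(m)
  mism <- logical(m)
  for (i in seq_len(m)) {
    if (is.na(al$tpos[i])) { # miRNA base bulged out
      pen[i] <- weights$gap * wt[i]
      mism[i] <- TRUE
    } else {
      cls <- pair_class(mc[i], tc[al$tpos[i]])
      pen[i] <- switch(cls + 1L, 0, weights$wobble, weights$mismatch) * wt[i]
      mism[i] <- cls == 2L
    }
  }
  total <- sum(pen)
  n_gap <- 0L
  if (length(al$gap_at) > 0 && identical(al$gap_strand, "target")) {
    # bulged target nts: gap penalty weighted at the flanking miRNA position
    gpos <- min(al$gap_at, m)
    total <- total + weights$gap * al$gap_len * wt[gpos]
    n_gap <- al$gap_len
  } else if (length(al$gap_at) > 0) {
    n_gap <- al$gap_len
  }

  central <- has_central_block(mism, weights$central_range)
  list(expectation = total,
       mismatch_positions = paste(which(mism), collapse = ","),
       central_block = central,
       n_gap = n_gap)
}

# >= 3 consecutive mispaired miRNA positions intersecting the central range
has_central_block <- function(mism, central_range) {
  r <- rle(mism)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  any(r$values & r$lengths >= 3L &
        starts <= central_range[2] & ends >= central_range[1])
}

#' Screen miRNA variants against a transcript set
#'
#' Slides each variant along each transcript (all window lengths within one
#' bulge of the miRNA length), keeps the best site per (variant, transcript),
#' and reports hits with expectation <= `cutoff`. A variant `retains target
#' binding` when it has at least one functional hit against the supplied
#' wild-type target transcripts.
#'
#' @param variants character vector of variant sequences (names used as ids),
#'   or a tibble with a `sequence` column.
#' @param transcripts tibble (`transcript_id`, `sequence`), named character
#'   vector, or FASTA path.
#' @param cutoff maximum expectation (default 3, the strict setting).
#' @param weights a [target_weights()].
#' @return tibble: `variant_id`, `sequence`, `transcript_id`, `site_start`
#'   (0-based on transcript), `site_end`, `expectation`,
#'   `mismatch_positions`, `central_block`, `functional`.
#' @export
screen_targets <- function(variants, transcripts, cutoff = 3,
                           weights = target_weights()) {
  if (is.data.frame(variants)) {
    vseq <- unique(variants$sequence)
    vid <- vseq
  } else {
    vseq <- as.character(variants)
    vid <- names(variants) %||% vseq
  }
  scoreable <- nchar(vseq) >= 18 & nchar(vseq) <= 26
  vseq <- vseq[scoreable]
  vid <- vid[scoreable]
  tx <- as_transcript_tbl(transcripts)
  if (nrow(tx) == 0 || length(vseq) == 0) {
    return(tibble(variant_id = character(), sequence = character(),
                  transcript_id = character(), site_start = integer(),
                  site_end = integer(), expectation = numeric(),
                  mismatch_positions = character(), central_block = logical(),
                  functional = logical()))
  }

  hits <- list()
  for (v in seq_along(vseq)) {
    mrna <- dna_to_rna(vseq[v])
    mlen <- nchar(mrna)
    for (t in seq_len(nrow(tx))) {
      best <- scan_transcript(mrna, dna_to_rna(tx$sequence[t]), weights)
      if (is.null(best) || best$expectation > cutoff) next
      det <- score_site(vseq[v],
                        substr(tx$sequence[t], best$start + 1L, best$end),
                        weights = weights, cutoff = cutoff)
      hits[[length(hits) + 1L]] <- tibble(
        variant_id = vid[v], sequence = vseq[v],
        transcript_id = tx$transcript_id[t],
        site_start = best$start, site_end = best$end,
        expectation = det$expectation,
        mismatch_positions = det$mismatch_positions,
        central_block = det$central_block,
        functional = det$functional)
    }
  }
  if (length(hits) == 0) {
    return(tibble(variant_id = character(), sequence = character(),
                  transcript_id = character(), site_start = integer(),
                  site_end = integer(), expectation = numeric(),
                  mismatch_positions = character(), central_block = logical(),
                  functional = logical()))
  }
  bind_rows(hits)
}

as_transcript_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("transcript_id", "sequence") %in% names(x)))
    return(x)
  }
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    return(tibble(transcript_id = sub("\\s.*", "", names(ss)),
                  sequence = as.character(ss)))
  }
  tibble(transcript_id = names(x) %||% paste0("tx", seq_along(x)),
         sequence = unname(x))
}

# fast scan: penalty matrix A[i, s] for miRNA position i against the site
# starting at 0-based s with no-gap register, column-cumsum C, and O(1)
# combination for every single-bulge placement
scan_transcript <- function(mirna, transcript, weights) {
  mc <- strsplit(mirna, "")[[1]]
  tch <- strsplit(transcript, "")[[1]]
  m <- length(mc)
  L <- length(tch)
  if (L < m - weights$max_bulge) return(NULL)
  wt <- ifelse(seq_len(m) >= weights$seed_range[1] & seq_len(m) <= weights$seed_range[2],
               weights$seed_weight, 1)
  BIG <- 1e6

  # A[i, s1] = weighted penalty of miRNA i facing transcript base (s1 + m - i),
  # s1 = 1-based start of an m-long window; extend s1 range by max_bulge so
  # bulged-target prefixes can be looked up
  smax <- L - m + 1L + weights$max_bulge
  if (smax < 1L) return(NULL)
  A <- matrix(BIG, nrow = m, ncol = smax)
  for (i in seq_len(m)) {
    tpos <- seq_len(smax) + m - i  # transcript index faced (1-based)
    valid <- tpos >= 1L & tpos <= L
    cls <- pair_class(mc[i], tch[tpos[valid]])
    A[i, valid] <- switch_pen(cls, weights) * wt[i]
  }
  C <- apply(A, 2, cumsum)
  if (m == 1) C <- matrix(C, nrow = 1)

  best <- list(expectation = Inf)
  consider <- function(score, s, wlen) {
    ok <- which(score < best$expectation)
    if (length(ok)) {
      j <- ok[which.min(score[ok])]
      best <<- list(expectation = score[j], start = s[j] - 1L,
                    end = s[j] - 1L + wlen)
    }
  }

  # no-gap windows
  s <- seq_len(max(0L, L - m + 1L))
  if (length(s)) consider(C[m, s], s, m)

  # target bulge of g nts after miRNA position b: window length m + g
  for (g in seq_len(weights$max_bulge)) {
    smax_g <- L - m - g + 1L
    if (smax_g < 1L) next
    s <- seq_len(smax_g)
    for (b in 1:(m - 1)) {
      gp <- weights$gap * g * wt[min(b + 1L, m)]
      score <- C[b, s + g] + (C[m, s] - C[b, s]) + gp
      consider(score, s, m + g)
    }
  }

  # miRNA bulge of g nts after position b: window length m - g
  for (g in seq_len(weights$max_bulge)) {
    if (m - g < 1L) next
    smax_g <- L - (m - g) + 1L
    if (smax_g < 1L) next
    for (b in 1:(m - g - 1)) {
      gp <- weights$gap * sum(wt[(b + 1L):(b + g)])
      s <- seq.int(g + 1L, smax_g) # need s - g >= 1 for the prefix lookup
      if (length(s) == 0 || s[1] > smax_g) next
      score <- C[b, s - g] + (C[m, s] - C[b + g, s]) + gp
      consider(score, s, m - g)
    }
  }
  if (!is.finite(best$expectation)) return(NULL)
  best
}

switch_pen <- function(cls, weights) {
  ifelse(cls == 0L, 0, ifelse(cls == 1L, weights$wobble, weights$mismatch))
}
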