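#' Preprocess small-RNA reads: adapter trimming, quality filtering, collapsing
#'
#' The 3' adapter is located by its leftmost occurrence whose continuation
#' matches a prefix of the adapter of at least 6 nt (anchor), and removed.
#' Reads are then 3'-truncated at the first base with phred <= `min_phred`
#' (set `quality_mode = "discard"` to drop whole reads instead), so every
#' retained base has phred > `min_phred`. Survivors outside `len_range` are
#' discarded and identical reads are collapsed per sample with counts.
#'
#' @param reads tibble (`sample_id`, `sequence`, `quality`, phred+33) from
#'   [simulate_srna_reads()] / [read_fastq()], or a named character vector of
#'   FASTQ paths.
#' @param adapter 3' adapter sequence.
#' @param min_phred quality threshold; bases must exceed it (default 20).
#' @param len_range retained length range after trimming (default 18--30 nt).
#' @param quality_mode `"truncate"` (default) or `"discard"`.
#' @return tibble `sample_id`, `sequence`, `count`, with attribute
#'   `library_sizes` (named count of clean reads per sample -- the cpm
#'   denominator).
#' @export
preprocess <- function(reads, adapter, min_phred = 20L, len_range = c(18L, 30L),
                       quality_mode = c("truncate", "discard")) {
  quality_mode <- match.arg(quality_mode)
  if (is.character(reads)) reads <- read_fastq(reads)
  stopifnot(all(c("sample_id", "sequence", "quality") %in% names(reads)))
  check_dna(adapter, "adapter")
  if (nchar(adapter) < 6) {
    abort("adapter must be at least 6 nt (anchor length)",
          class = "miredit_config_error")
  }
  if (nrow(reads) == 0) {
    out <- tibble(sample_id = character(), sequence = character(), count = integer())
    attr(out, "library_sizes") <- integer(0)
    return(out)
  }

  seqs <- reads$sequence
  quals <- reads$quality
  if (any(nchar(seqs) != nchar(quals))) {
    abort("sequence/quality length mismatch in FASTQ records",
          class = "miredit_parse_error")
  }

  # ---- adapter position: leftmost anchored prefix match ----
  # fast path: first anchor occurrence, verified against the adapter prefix;
  # rare failures (spurious anchor hits) fall back to scanning all occurrences
  anchor <- substr(adapter, 1, 6)
  L <- nchar(seqs)
  p1 <- as.integer(regexpr(anchor, seqs, fixed = TRUE))
  found <- p1 > 0L
  take <- pmin(L - p1 + 1L, nchar(adapter))
  ok <- found & substr(seqs, p1, p1 + take - 1L) == substr(adapter, 1, take)
  apos <- ifelse(ok, p1, NA_integer_)
  recheck <- which(found & !ok)
  if (length(recheck)) {
    hits <- gregexpr(anchor, seqs[recheck], fixed = TRUE)
    for (k in seq_along(recheck)) {
      i <- recheck[k]
      for (p in hits[[k]]) {
        tk <- min(L[i] - p + 1L, nchar(adapter))
        if (substr(seqs[i], p, p + tk - 1L) == substr(adapter, 1, tk)) {
          apos[i] <- p
          break
        }
      }
    }
  }
  trim_end <- ifelse(is.na(apos), L, apos - 1L)

  # ---- quality truncation: first base with phred <= min_phred ----
  maxl <- max(L)
  padded <- formatC(quals, width = maxl, flag = "-") # right-pad with spaces
  qm <- matrix(utf8ToInt(paste(padded, collapse = "")) - 33L,
               ncol = maxl, byrow = TRUE)
  qm[qm < 0] <- 99L # padding (space = -1) never triggers
  bad <- qm <= min_phred
  has_bad <- rowSums(bad) > 0
  first_bad <- apply_first_true(bad, maxl)
  if (quality_mode == "truncate") {
    trim_end <- pmin(trim_end, first_bad - 1L)
  } else {
    trim_end <- ifelse(has_bad & first_bad <= trim_end, 0L, trim_end)
  }

  clean <- substr(seqs, 1L, trim_end)
  keep <- nchar(clean) >= len_range[1] & nchar(clean) <= len_range[2]

  out <- tibble(sample_id = reads$sample_id[keep], sequence = clean[keep]) |>
    count(.data$sample_id, .data$sequence, name = "count") |>
    arrange(.data$sample_id, desc(.data$count))
  libs <- out |> group_by(.data$sample_id) |> summarise(n = sum(.data$count))
  attr(out, "library_sizes") <- setNames(libs$n, libs$sample_id)
  out
}

# first TRUE per row of a logical matrix, nrow+1-style default = maxl + 1
apply_first_true <- function(m, maxl) {
  idx <- which(m, arr.ind = TRUE)
  first <- rep(maxl + 1L, nrow(m))
  if (nrow(idx)) {
    agg <- tapply(idx[, "col"], idx[, "row"], min)
    first[as.integer(names(agg))] <- as.integer(agg)
  }
  first
}

#' Map clean reads to precursors by exact substring match
#'
#' A read maps to a precursor iff it is an exact substring of the precursor's
#' sense strand -- no mismatches allowed. Every matching precursor is
#' recorded; a read is `unambiguous` when it maps to exactly one.
#'
#' @param clean tibble from [preprocess()].
#' @param precursors tibble (`precursor_id`, `sequence`), a named character
#'   vector, or a FASTA path.
#' @return `clean` plus list-column `sources`, `n_sources`, `unambiguous`.
#' @export
map_exact <- function(clean, precursors) {
  precursors <- as_precursor_tbl(precursors)
  if (nrow(precursors) == 0) {
    abort("precursor set is empty", class = "miredit_value_error")
  }
  uniq <- unique(clean$sequence)
  if (length(uniq) == 0) {
    clean$sources <- list()
    clean$n_sources <- integer(0)
    clean$unambiguous <- logical(0)
    return(clean)
  }
  lens <- range(nchar(uniq))
  idx <- substring_index(precursors, lens[1], lens[2])
  src <- mget(uniq, envir = idx, ifnotfound = list(character(0)))
  clean$sources <- unname(src[clean$sequence])
  clean$n_sources <- lengths(clean$sources)
  clean$unambiguous <- clean$n_sources == 1L
  clean
}

# enumerate every substring of the precursor set in a length range and return
# a hashed lookup (environment): substring -> character vector of precursor
# ids. Exact-substring semantics, index-backed.
substring_index <- function(precursors, min_len, max_len) {
  entries <- map(seq_len(nrow(precursors)), function(i) {
    s <- precursors$sequence[[i]]
    n <- nchar(s)
    if (min_len > n) return(NULL)
    lens <- seq.int(min_len, min(max_len, n))
    subs <- unlist(map(lens, function(l) {
      starts <- seq_len(n - l + 1L)
      unique(substring(s, starts, starts + l - 1L))
    }))
    tibble(sub = unique(subs), precursor_id = precursors$precursor_id[[i]])
  })
  tbl <- bind_rows(entries)
  list2env(split(tbl$precursor_id, tbl$sub), envir = new.env(hash = TRUE))
}

as_precursor_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("precursor_id", "sequence") %in% names(x)))
    return(mutate(x, sequence = toupper(.data$sequence)))
  }
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    return(tibble(precursor_id = sub("\\s.*", "", names(ss)),
                  sequence = as.character(ss)))
  }
  tibble(precursor_id = names(x) %||% paste0("precursor", seq_along(x)),
         sequence = toupper(unname(x)))
}

#' Call miRNA variants from mapped reads
#'
#' Mapped reads that coincide with a canonical mature sequence are
#' `canonical`; mapped reads differing only in their 5'/3' end positions are
#' `templated` with the end offsets recorded. Unmapped reads that become exact
#' substrings after stripping at most 3 terminal nt from one end are
#' `non_templated`, with the stripped tail recorded (the end giving the longer
#' matching core is preferred; ties go to the 3' end). Everything else is
#' discarded. Counts are per sample; cpm uses the per-sample clean-read totals
#' of the input table. Variants with a total count of 1--2 are retained but
#' flagged `low_abundance`.
#'
#' @param mapped tibble from [map_exact()] (all clean reads, mapped or not).
#' @param annotations tibble (`precursor_id`, `sequence`, `mir5p_start`,
#'   `mir5p_end`): canonical mature annotation per precursor, 0-based
#'   half-open.
#' @param library_sizes optional named per-sample clean-read totals; defaults
#'   to the column sums of `mapped`.
#' @return tibble, one row per (variant sequence, sample): `sequence`,
#'   `class`, `sources` (comma-joined), `unambiguous`, `offset5`, `offset3`,
#'   `tail`, `tail_end`, `sample_id`, `count`, `cpm`, `low_abundance`.
#' @export
call_variants <- function(mapped, annotations, library_sizes = NULL) {
  stopifnot(all(c("precursor_id", "sequence", "mir5p_start", "mir5p_end")
                %in% names(annotations)))
  if (is.null(library_sizes)) {
    ls_tbl <- mapped |> group_by(.data$sample_id) |>
      summarise(n = sum(.data$count))
    library_sizes <- setNames(ls_tbl$n, ls_tbl$sample_id)
  }
  canon <- annotations |>
    mutate(canonical = substr(.data$sequence, .data$mir5p_start + 1L,
                              .data$mir5p_end))
  seq_by_id <- setNames(canon$sequence, canon$precursor_id)
  canon_by_id <- setNames(canon$canonical, canon$precursor_id)
  m5_by_id <- setNames(canon$mir5p_start, canon$precursor_id)
  m3_by_id <- setNames(canon$mir5p_end, canon$precursor_id)

  uniq <- mapped |> distinct(.data$sequence, .keep_all = TRUE) |>
    select("sequence", "sources", "n_sources", "unambiguous")

  n_u <- nrow(uniq)
  cls <- rep(NA_character_, n_u)
  core <- uniq$sequence
  tail_seq <- rep(NA_character_, n_u)
  tail_end <- rep(NA_character_, n_u)
  src_list <- uniq$sources

  is_mapped <- uniq$n_sources > 0
  if (any(is_mapped)) {
    i <- which(is_mapped)
    is_canon <- map2_lgl(uniq$sequence[i], uniq$sources[i],
                         function(s, srcs) s %in% canon_by_id[srcs])
    cls[i] <- ifelse(is_canon, "canonical", "templated")
  }

  # non-templated rescue: strip <= 3 terminal nt from one end; the end giving
  # the longer matching core wins (smaller k first), ties prefer the 3' end
  un <- which(!is_mapped)
  if (length(un)) {
    lens <- range(nchar(uniq$sequence[un]))
    core_idx <- substring_index(select(annotations, "precursor_id", "sequence"),
                                max(15L, lens[1] - 3L), lens[2])
    s <- uniq$sequence[un]
    n <- nchar(s)
    open <- rep(TRUE, length(un))
    for (k in 1:3) {
      for (end in c("3p", "5p")) {
        cand <- which(open & n - k >= 15L)
        if (length(cand) == 0) next
        cr <- if (end == "3p") substr(s[cand], 1L, n[cand] - k)
              else substr(s[cand], k + 1L, n[cand])
        hit <- mget(cr, envir = core_idx, ifnotfound = list(character(0)))
        got <- lengths(hit) > 0
        if (any(got)) {
          j <- un[cand[got]]
          cls[j] <- "non_templated"
          core[j] <- cr[got]
          tail_seq[j] <- if (end == "3p") substr(s[cand[got]], n[cand[got]] - k + 1L, n[cand[got]])
                         else substr(s[cand[got]], 1L, k)
          tail_end[j] <- end
          src_list[j] <- unname(hit[got])
          open[cand[got]] <- FALSE
        }
      }
    }
  }

  keep <- !is.na(cls)
  first_src <- map_chr(src_list[keep], 1)
  pos <- stringr::str_locate(unname(seq_by_id[first_src]),
                             stringr::fixed(core[keep]))[, "start"] - 1L
  uniq <- tibble(
    sequence = uniq$sequence[keep],
    class = cls[keep],
    sources = map_chr(src_list[keep], paste, collapse = ","),
    unambiguous = lengths(src_list[keep]) == 1L,
    offset5 = pos - unname(m5_by_id[first_src]),
    offset3 = (pos + nchar(core[keep])) - unname(m3_by_id[first_src]),
    tail = tail_seq[keep],
    tail_end = tail_end[keep])

  out <- mapped |>
    select("sample_id", "sequence", "count") |>
    inner_join(uniq, by = "sequence") |>
    mutate(cpm = cpm(.data$count, unname(library_sizes[.data$sample_id])))
  tot <- out |> group_by(.data$sequence) |>
    summarise(total = sum(.data$count))
  out |>
    left_join(tot, by = "sequence") |>
    mutate(low_abundance = .data$total <= 2L) |>
    select(-"total") |>
    relocate("sequence", "class", "sources", "unambiguous")
}

#' Exclusion-based specificity filter for line-specific variants
#'
#' A variant is reported for the test group iff it has a count of at least 1
#' in at least one test sample and a count of exactly 0 in every control
#' sample (non-transgenic samples and lines edited at the reciprocal locus,
#' where the test locus is unaffected). Groups must be disjoint.
#'
#' @param variants long tibble from [call_variants()].
#' @param test_group character vector of test sample ids.
#' @param control_groups character vector or list of character vectors of
#'   control sample ids.
#' @return the test-sample rows of reported variants.
#' @export
specificity_filter <- function(variants, test_group, control_groups) {
  controls <- unique(unlist(control_groups))
  if (length(intersect(test_group, controls)) > 0) {
    abort("test and control groups overlap", class = "miredit_config_error")
  }
  in_test <- variants$sample_id %in% test_group & variants$count >= 1
  in_ctrl <- variants$sample_id %in% controls & variants$count >= 1
  ok <- setdiff(unique(variants$sequence[in_test]),
                unique(variants$sequence[in_ctrl]))
  filter(variants, .data$sequence %in% ok, .data$sample_id %in% test_group)
}

#' Counts per million
#'
#' @param count raw count(s).
#' @param library_size clean reads in the sample (> 0).
#' @return `count / library_size * 1e6`.
#' @export
#' @examples
#' cpm(5, 1e6)
cpm <- function(count, library_size) {
  if (any(library_size <= 0)) {
    abort("library_size must be > 0", class = "miredit_value_error")
  }
  count / library_size * 1e6
}
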