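#' Configuration for the small-RNA read simulator
#'
#' Models a 50-bp single-end sRNA sequencing run: each read is a mature miRNA
#' or miRNA variant followed by the 3' adapter, truncated to the read length,
#' with per-base phred qualities drawn around a configurable mean (default 30,
#' so the phred > 20 preprocessing filter has work to do). Templated length
#' variants shift the 5'/3' ends within the precursor; non-templated variants
#' carry a 1--3 nt 3' tail whose first base differs from the precursor
#' continuation, so it cannot be templated from its own precursor. Precursors
#' classified as processing-impaired yield reads at `leak_rate` (default 0 --
#' fully blocked processing; set > 0 to model leaky processing).
#'
#' @param read_length read length in nt (default 50).
#' @param depth reads per sample (> 0).
#' @param adapter 3' adapter sequence (ACGT only).
#' @param qual_mean,qual_sd per-base phred quality model.
#' @param variant_prob probability a read is a templated length variant rather
#'   than the canonical mature sequence.
#' @param offset_range maximum absolute 5'/3' end shift of templated variants.
#' @param tail_prob probability of a non-templated 3' tail.
#' @param tail_len_probs length distribution of tails (1..3 nt).
#' @param leak_rate relative read yield of impaired precursors.
#' @param background_prob fraction of the library that is unrelated background
#'   sRNA (random 20--24 nt sequences).
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 50L, depth = 1000L,
                            adapter = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCACATCACGATCTCGTATGC",
                            qual_mean = 30, qual_sd = 3,
                            variant_prob = 0.3, offset_range = 2L,
                            tail_prob = 0, tail_len_probs = c(0.7, 0.2, 0.1),
                            leak_rate = 0, background_prob = 0.3) {
  if (depth <= 0) abort("depth must be > 0", class = "miredit_bounds_error")
  if (!grepl("^[ACGT]+$", adapter)) {
    abort("adapter contains non-ACGT characters", class = "miredit_format_error")
  }
  if (abs(sum(tail_len_probs) - 1) > 1e-8 || length(tail_len_probs) != 3) {
    abort("tail_len_probs must be 3 probabilities summing to 1",
          class = "miredit_config_error")
  }
  structure(list(read_length = as.integer(read_length), depth = as.integer(depth),
                 adapter = adapter, qual_mean = qual_mean, qual_sd = qual_sd,
                 variant_prob = variant_prob, offset_range = as.integer(offset_range),
                 tail_prob = tail_prob, tail_len_probs = tail_len_probs,
                 leak_rate = leak_rate, background_prob = background_prob),
            class = "read_sim_config")
}

#' Simulate small-RNA reads from processed precursors
#'
#' @param samples tibble describing the precursor content of each library, one
#'   row per (sample, precursor): `sample_id`, `precursor_id`, `sequence`
#'   (precursor), `mir5p_start`, `mir5p_end` (0-based half-open on the
#'   precursor; a width-0 span marks an excised mature region), `impaired`
#'   (logical processing call), `weight` (relative transcript abundance).
#' @param cfg a [read_sim_config()].
#' @param seed integer seed.
#' @return list with `reads` (tibble `read_id`, `sample_id`, `sequence`,
#'   `quality`, phred+33) and `truth` (tibble `read_id`, `sample_id`,
#'   `precursor_id`, `srna`, `templated`, `tail`; background reads carry
#'   `precursor_id = NA`).
#' @export
simulate_srna_reads <- function(samples, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "read_sim_config"))
  need <- c("sample_id", "precursor_id", "sequence", "mir5p_start",
            "mir5p_end", "impaired", "weight")
  stopifnot(all(need %in% names(samples)))
  longest <- max(c(0L, samples$mir5p_end - samples$mir5p_start)) +
    2L * cfg$offset_range + 3L
  if (cfg$read_length < longest + 1L) {
    abort("read_length must exceed the longest simulated sRNA",
          class = "miredit_config_error")
  }

  with_seed(seed, {
    out <- map(unique(samples$sample_id), function(sid) {
      simulate_sample_reads(filter(samples, .data$sample_id == sid), sid, cfg)
    })
  })
  list(reads = bind_rows(map(out, "reads")),
       truth = bind_rows(map(out, "truth")))
}

simulate_sample_reads <- function(tbl, sid, cfg) {
  n_bg <- rbinom(1, cfg$depth, cfg$background_prob)
  n_pre <- cfg$depth - n_bg

  # precursors whose mature span has shrunk below a functional miRNA length
  # cannot be processed into sRNAs at all
  yield <- tbl$weight * ifelse(tbl$impaired, cfg$leak_rate, 1) *
    ifelse(tbl$mir5p_end - tbl$mir5p_start >= 16L, 1, 0)
  srna <- character(0); pre_id <- character(0); templated <- logical(0); tail <- character(0)

  if (n_pre > 0 && sum(yield) > 0) {
    pick <- sample.int(nrow(tbl), n_pre, replace = TRUE, prob = yield)
    m0 <- tbl$mir5p_start[pick]
    m1 <- tbl$mir5p_end[pick]
    plen <- nchar(tbl$sequence)[pick]
    is_var <- runif(n_pre) < cfg$variant_prob
    off5 <- ifelse(is_var, sample(seq(-cfg$offset_range, cfg$offset_range),
                                  n_pre, replace = TRUE), 0L)
    off3 <- ifelse(is_var, sample(seq(-cfg$offset_range, cfg$offset_range),
                                  n_pre, replace = TRUE), 0L)
    s0 <- pmax(0L, m0 + off5)
    s1 <- pmin(plen, m1 + off3)
    keep_len <- s1 - s0 >= 15L
    s0 <- ifelse(keep_len, s0, m0)
    s1 <- ifelse(keep_len, s1, m1)
    srna <- substr(tbl$sequence[pick], s0 + 1L, s1)

    # non-templated 3' tails: first tail base differs from the precursor
    # continuation base (or any base at the precursor end)
    tailed <- runif(n_pre) < cfg$tail_prob
    tail <- character(n_pre)
    if (any(tailed)) {
      idx <- which(tailed)
      tlen <- sample(1:3, length(idx), replace = TRUE, prob = cfg$tail_len_probs)
      nxt <- substr(tbl$sequence[pick[idx]], s1[idx] + 1L, s1[idx] + 1L)
      first <- vapply(nxt, function(b) {
        sample(setdiff(DNA_BASES, if (nzchar(b)) b else character(0)), 1)
      }, "")
      rest <- vapply(tlen - 1L, random_dna, "")
      tail[idx] <- paste0(first, rest)
      srna[idx] <- paste0(srna[idx], tail[idx])
    }
    pre_id <- tbl$precursor_id[pick]
    templated <- !tailed
  }

  if (n_bg > 0) {
    bglen <- sample(20:24, n_bg, replace = TRUE)
    bg <- vapply(bglen, random_dna, "")
    srna <- c(srna, bg)
    pre_id <- c(pre_id, rep(NA_character_, n_bg))
    templated <- c(templated, rep(NA, n_bg))
    tail <- c(tail, rep("", n_bg))
  }
  if (length(srna) == 0) {
    return(list(reads = tibble(read_id = character(), sample_id = character(),
                               sequence = character(), quality = character()),
                truth = tibble(read_id = character(), sample_id = character(),
                               precursor_id = character(), srna = character(),
                               templated = logical(), tail = character())))
  }

  # read = sRNA + adapter (+ adapter recycled), truncated to read_length
  filler <- strrep(cfg$adapter, ceiling(cfg$read_length / nchar(cfg$adapter)) + 1L)
  reads <- substr(paste0(srna, filler), 1L, cfg$read_length)

  n <- length(reads)
  q <- pmin(40L, pmax(2L, as.integer(round(rnorm(n * cfg$read_length,
                                                 cfg$qual_mean, cfg$qual_sd)))))
  qall <- intToUtf8(q + 33L)
  starts <- (seq_len(n) - 1L) * cfg$read_length + 1L
  quals <- substring(qall, starts, starts + cfg$read_length - 1L)

  ids <- sprintf("%s_read%07d", sid, seq_len(n))
  list(reads = tibble(read_id = ids, sample_id = sid, sequence = reads,
                      quality = quals),
       truth = tibble(read_id = ids, sample_id = sid, precursor_id = pre_id,
                      srna = srna, templated = templated, tail = tail))
}

#' Write simulated reads as per-sample FASTQ (phred+33)
#'
#' @param reads tibble from [simulate_srna_reads()]`$reads`.
#' @param dir output directory; one `<sample_id>.fastq` per sample.
#' @return named character vector of paths.
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sids <- unique(reads$sample_id)
  paths <- setNames(file.path(dir, paste0(sids, ".fastq")), sids)
  for (sid in sids) {
    r <- filter(reads, .data$sample_id == sid)
    lines <- as.vector(rbind(paste0("@", r$read_id), r$sequence, "+", r$quality))
    writeLines(lines, paths[[sid]])
  }
  paths
}

#' Read FASTQ files into the reads-tibble form
#'
#' @param paths named character vector (names = sample ids) of FASTQ paths.
#' @return tibble `read_id`, `sample_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(paths) {
  if (is.null(names(paths))) names(paths) <- sub("\\.fastq$", "", basename(paths))
  bind_rows(map(names(paths), function(sid) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(paths[[sid]], format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) abort(sprintf("malformed FASTQ %s: %s",
                                        paths[[sid]], conditionMessage(e)),
                                class = "miredit_parse_error"))
    tibble(read_id = names(x), sample_id = sid,
           sequence = unname(as.character(x)),
           quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }))
}
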