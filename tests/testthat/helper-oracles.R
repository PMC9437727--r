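# Independent oracles used across the suite.

# Exhaustively enumerate all secondary structures (min hairpin 3, no
# pseudoknots, Watson-Crick + G:U pairs only) of a short sequence as
# dot-bracket strings. Feasible up to ~14 nt.
enumerate_structures <- function(seq) {
  chars <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  n <- length(chars)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("CG", "GC", "GU", "UG", "AU", "UA")
  }
  # returns list of integer pair matrices (2 x k) for interval [i, j]
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), nrow = 2)))
    out <- rec(i + 1, j)  # i unpaired
    for (k in (i + 4):j) {
      if (!can_pair(chars[i], chars[k])) next
      inner <- rec(i + 1, k - 1)
      outer <- if (k == j) list(matrix(integer(0), nrow = 2)) else rec(k + 1, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- cbind(c(i, k), a, b)
      }
    }
    out
  }
  structs <- rec(1, n)
  vapply(structs, function(m) {
    db <- rep(".", n)
    if (ncol(m)) {
      db[m[1, ]] <- "("
      db[m[2, ]] <- ")"
    }
    paste(db, collapse = "")
  }, "")
}

# brute-force MFE: minimum loop-decomposition energy over all structures
brute_force_mfe <- function(seq) {
  dbs <- enumerate_structures(seq)
  min(vapply(dbs, function(db) structure_energy(seq, db), 0))
}

revcomp_rna <- function(x) {
  chartr("ACGUT", "UGCAA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a small locus (short flanks) for fast alignment tests
small_locus <- function(seed = 1, n_alleles = 4, snp_rate = 0.01,
                        amplicon_length = 300L, ...) {
  make_locus(seed = seed, n_alleles = n_alleles, snp_rate = snp_rate,
             amplicon_length = amplicon_length, ...)
}

# build a fold_result by hand (for arithmetic tests on mfei())
fake_fold <- function(sequence, mfe) {
  structure(list(sequence = gsub("T", "U", toupper(sequence)),
                 dot_bracket = strrep(".", nchar(sequence)),
                 mfe_kcal_mol = mfe, engine_tag = "internal"),
            class = "fold_result")
}

# one-precursor sRNA sample sheet for a locus
srna_samples <- function(loc, impaired = FALSE, id = "S1") {
  tibble::tibble(sample_id = id, precursor_id = paste0(loc$locus_id, "_p1"),
                 sequence = precursor_seq(loc, 1),
                 mir5p_start = loc$mir5p_span[1], mir5p_end = loc$mir5p_span[2],
                 impaired = impaired, weight = 1)
}

# a sequence of given length and GC count (for exact MFEI arithmetic)
seq_with_gc <- function(len, n_gc) {
  paste0(strrep("G", ceiling(n_gc / 2)), strrep("C", floor(n_gc / 2)),
         strrep("A", len - n_gc))
}
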