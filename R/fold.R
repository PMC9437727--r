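#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Predicts the MFE secondary structure of a pre-miRNA (or any RNA) under the
#' package's nearest-neighbour model (see [fold_params()]). The internal
#' engine is a Zuker-style dynamic program over integer decacalories with a
#' deterministic traceback (base pairs are preferred at the leftmost opening
#' position among co-optimal structures). An external validation backend is
#' available through `engine = "vienna"`, which shells out to `RNAfold` if it
#' is installed; internal and external structures may differ in detail and are
#' never silently mixed -- the `engine_tag` field records provenance and both
#' feed [locate_duplex()]/[classify_processing()] through the same interface.
#'
#' @param seq a DNA or RNA string, length >= 10. `T` is converted to `U`.
#' @param engine `"internal"` (default) or `"vienna"` (external validation
#'   backend; requires `RNAfold` on the `PATH`).
#' @param params energy parameter list from [fold_params()] (internal engine
#'   only).
#' @return an object of class `fold_result`: a list with `sequence` (RNA),
#'   `dot_bracket`, `mfe_kcal_mol` (<= 0) and `engine_tag`.
#' @export
#' @examples
#' f <- fold("GGGGAAAACCCC")
#' f$dot_bracket
#' f$mfe_kcal_mol
fold <- function(seq, engine = c("internal", "vienna"), params = fold_params()) {
  engine <- match.arg(engine)
  seq <- as.character(seq)
  if (length(seq) != 1 || is.na(seq)) {
    abort("fold() takes a single sequence", class = "miredit_format_error")
  }
  rna <- dna_to_rna(seq)
  if (nchar(rna) < 10) {
    abort(sprintf("sequence too short to fold (%d nt, need >= 10)", nchar(rna)),
          class = "miredit_too_short_error")
  }
  if (!grepl("^[ACGU]+$", rna)) {
    abort("sequence contains non-nucleotide symbols", class = "miredit_format_error")
  }

  if (engine == "internal") {
    res <- fold_mfe_cpp(rna, params$stack, params$hairpin, params$bulge,
                        params$internal, params$asym_per_nt, params$asym_max,
                        params$ml_init, params$ml_branch, params$ml_unpaired,
                        params$lxc, params$maxloop)
    out <- list(sequence = rna,
                dot_bracket = res$structure,
                mfe_kcal_mol = res$mfe_dcal / 100,
                engine_tag = "internal")
  } else {
    out <- fold_vienna(rna)
  }
  structure(out, class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result: %d nt, MFE %.2f kcal/mol, engine %s>\n",
              nchar(x$sequence), x$mfe_kcal_mol, x$engine_tag))
  cat(x$sequence, "\n")
  cat(sprintf("%s (%.2f)\n", x$dot_bracket, x$mfe_kcal_mol))
  invisible(x)
}

# external validation backend: ViennaRNA's RNAfold CLI
fold_vienna <- function(rna) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    abort("external folding backend requested but RNAfold is not on the PATH",
          class = "miredit_backend_error")
  }
  out <- suppressWarnings(
    system2(exe, args = c("--noPS"), input = rna, stdout = TRUE, stderr = FALSE)
  )
  if (length(out) < 2) {
    abort("RNAfold produced no parsable output", class = "miredit_backend_error")
  }
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3) {
    abort(sprintf("could not parse RNAfold output line: %s", line),
          class = "miredit_backend_error")
  }
  list(sequence = rna, dot_bracket = m[2],
       mfe_kcal_mol = as.numeric(m[3]), engine_tag = "external-validation")
}

#' Minimal folding free energy index (MFEI)
#'
#' Computes the adjusted MFE (`amfe = |MFE| / L * 100`, kcal/mol per 100 nt)
#' and the minimal folding free energy index (`mfei = amfe / GC%`, with GC
#' content on the 0--100 scale). MFEI above 0.85 is the classical criterion
#' separating genuine plant pre-miRNAs from tRNA/rRNA/mRNA (which sit near
#' 0.6), and is the first arm of the impaired-processing rule in
#' [classify_processing()].
#'
#' @param fold a `fold_result` from [fold()].
#' @return a one-row tibble: `length`, `gc_percent`, `mfe_kcal_mol`, `amfe`,
#'   `mfei`.
#' @export
#' @examples
#' mfei(fold("GGGGAAAACCCCGGGGAAAACCCC"))
mfei <- function(fold) {
  stopifnot(inherits(fold, "fold_result"))
  n <- nchar(fold$sequence)
  gc <- sum(strsplit(fold$sequence, "")[[1]] %in% c("G", "C")) / n * 100
  if (gc == 0) {
    abort("MFEI undefined for a sequence with 0% GC", class = "miredit_mfei_undefined")
  }
  amfe <- abs(fold$mfe_kcal_mol) / n * 100
  tibble(length = n, gc_percent = gc, mfe_kcal_mol = fold$mfe_kcal_mol,
         amfe = amfe, mfei = amfe / gc)
}

#' Write fold results in Vienna format
#'
#' One record per fold: a `>` header, the sequence, and the dot-bracket with
#' the energy in parentheses.
#'
#' @param folds a list of `fold_result` objects (or a single one).
#' @param ids header ids; defaults to `fold_1 ... fold_n`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(folds, path, ids = NULL) {
  if (inherits(folds, "fold_result")) folds <- list(folds)
  ids <- ids %||% paste0("fold_", seq_along(folds))
  lines <- unlist(map2(folds, ids, function(f, id) {
    c(paste0(">", id), f$sequence,
      sprintf("%s (%6.2f)", f$dot_bracket, f$mfe_kcal_mol))
  }))
  writeLines(lines, path)
  invisible(path)
}
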