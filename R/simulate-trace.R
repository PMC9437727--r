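#' Simulate a mixed Sanger trace as a base-proportion matrix
#'
#' A direct Sanger read over a mosaic template produces, downstream of the
#' first divergence point, a superposition of the constituent sequences. This
#' simulator represents that mixed signal as a 4 x L base-proportion matrix
#' (rows A, C, G, T; columns sum to 1) over a window of positions shared by
#' all mixture members measured from the common reference start -- the
#' plain-text surrogate for a chromatogram consumed by [ko_score()].
#'
#' At each window position the column is the mixture-proportion-weighted
#' one-hot encoding of the member bases, perturbed by symmetric uniform noise
#' of amplitude `noise` and renormalised. A member shorter than the window
#' contributes a flat 1/4 signal past its end (signal run-off).
#'
#' @param mixture tibble with columns `sequence` and `proportion` (sequences
#'   pre-aligned to a common reference start; proportions sum to 1).
#' @param window 0-based half-open position interval of the trace.
#' @param noise noise amplitude in `[0, 0.2)`.
#' @param seed integer seed.
#' @return a `trace_matrix`: 4 x width numeric matrix with attributes
#'   `window` and `noise`.
#' @export
#' @examples
#' tr <- simulate_sanger_trace(
#'   tibble::tibble(sequence = "ACGTACGTACGT", proportion = 1),
#'   window = c(0, 12), noise = 0, seed = 1)
#' colSums(tr)
simulate_sanger_trace <- function(mixture, window, noise = 0, seed = 1L) {
  stopifnot(all(c("sequence", "proportion") %in% names(mixture)))
  if (abs(sum(mixture$proportion) - 1) > 1e-8) {
    abort("mixture proportions must sum to 1", class = "miredit_value_error")
  }
  if (noise < 0 || noise >= 0.2) {
    abort("noise must be in [0, 0.2)", class = "miredit_bounds_error")
  }
  w0 <- as.integer(window[[1]]); w1 <- as.integer(window[[2]])
  if (w0 < 0 || w1 <= w0) {
    abort("invalid trace window", class = "miredit_bounds_error")
  }
  if (all(nchar(mixture$sequence) <= w0)) {
    abort("trace window lies outside every mixture sequence",
          class = "miredit_bounds_error")
  }
  width <- w1 - w0

  m <- matrix(0, nrow = 4, ncol = width, dimnames = list(DNA_BASES, NULL))
  for (r in seq_len(nrow(mixture))) {
    m <- m + mixture$proportion[r] *
      trace_profile(mixture$sequence[r], c(w0, w1))
  }
  if (noise > 0) {
    with_seed(seed, {
      m <- m + noise * matrix(runif(4 * width), nrow = 4)
    })
  }
  m <- sweep(m, 2, colSums(m), "/")
  structure(m, class = c("trace_matrix", "matrix"),
            window = c(w0, w1), noise = noise)
}

# one-hot (flat 1/4 past the sequence end) profile of a single sequence over
# a 0-based half-open window
trace_profile <- function(seq, window) {
  width <- window[[2]] - window[[1]]
  m <- matrix(0, nrow = 4, ncol = width, dimnames = list(DNA_BASES, NULL))
  chars <- strsplit(toupper(seq), "")[[1]]
  pos <- window[[1]] + seq_len(width)  # 1-based positions into seq
  inside <- pos <= length(chars)
  b <- match(chars[pos[inside]], DNA_BASES)
  m[cbind(b, which(inside))] <- 1
  if (any(!inside)) m[, !inside] <- 0.25
  m
}

#' Write / read a trace matrix as TSV
#'
#' @param trace a `trace_matrix`.
#' @param path file path.
#' @return `path` (write) or a `trace_matrix` (read).
#' @export
write_trace_tsv <- function(trace, path) {
  w <- attr(trace, "window")
  header <- sprintf("# trace_matrix window=%d:%d noise=%g", w[1], w[2],
                    attr(trace, "noise"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(as.data.frame(t(unclass(trace))), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("window=(\\d+):(\\d+) noise=([0-9.eE+-]+)", header))[[1]]
  tab <- read.table(path, sep = "\t", header = TRUE, skip = 1)
  tr <- t(as.matrix(tab))
  rownames(tr) <- DNA_BASES
  structure(tr, class = c("trace_matrix", "matrix"),
            window = c(as.integer(m[2]), as.integer(m[3])),
            noise = as.numeric(m[4]))
}
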