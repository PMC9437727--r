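#' Nearest-neighbour energy parameters for the folding engine
#'
#' The internal minimum-free-energy engine scores secondary structures with a
#' nearest-neighbour model: stacking free energies for Watson-Crick and G:U
#' pairs (Turner 2004 values, 37 degrees C), length-dependent initiation
#' penalties for hairpin, bulge and internal loops with Jacobson-Stockmayer
#' logarithmic extrapolation beyond 30 nt, an internal-loop asymmetry penalty,
#' and an affine multiloop term. Dangling ends, coaxial stacking, special
#' tetraloop bonuses and terminal-AU penalties are deliberately omitted: the
#' model is used to rank perturbed precursor hairpins against each other and
#' against the MFEI threshold, not to byte-match any particular external
#' folding program.
#'
#' All energies are stored as integer decacalories (kcal/mol x 100) so the
#' dynamic programming engine, its traceback, and independent re-scoring of a
#' structure by [structure_energy()] agree exactly.
#'
#' @return a list with components `stack` (6 x 6 integer matrix over pair
#'   types CG, GC, GU, UG, AU, UA; entry `[p1, p2]` is the stack of outer pair
#'   `p1 = (i,j)` on inner pair read 3' to 5', `p2 = (l,k)`), `hairpin`,
#'   `bulge`, `internal` (integer vectors of initiation energies indexed by
#'   loop size 0..30), `asym_per_nt`, `asym_max`, `ml_init`, `ml_branch`,
#'   `ml_unpaired`, `lxc` (extrapolation coefficient, decacal) and `maxloop`.
#' @export
#' @examples
#' p <- fold_params()
#' p$stack["GC", "GC"] / 100  # kcal/mol for a GC on GC stack
fold_params <- function() {
  inf <- 1000000000L
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  stack_kcal <- matrix(c(
    -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
    -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
    -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
    -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
    -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
    -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))

  lxc <- 107.856 # 1.75 * RT at 310.15 K, in decacal

  sizes <- 0:30
  hairpin <- ifelse(sizes < 3, inf,
                    as.integer(floor(540 + ifelse(sizes > 3, lxc * log(sizes / 3), 0) + 0.5)))
  bulge <- ifelse(sizes < 1, inf,
                  as.integer(floor(380 + ifelse(sizes > 1, lxc * log(sizes) , 0) + 0.5)))
  internal <- ifelse(sizes < 2, inf,
                     as.integer(floor(170 + ifelse(sizes > 4, lxc * log(sizes / 4), 0) + 0.5)))

  list(
    stack = matrix(as.integer(round(stack_kcal * 100)), 6, 6,
                   dimnames = list(pairs, pairs)),
    hairpin = as.integer(hairpin),
    bulge = as.integer(bulge),
    internal = as.integer(internal),
    asym_per_nt = 60L,
    asym_max = 300L,
    ml_init = 930L,
    ml_branch = -90L,
    ml_unpaired = 0L,
    lxc = lxc,
    maxloop = 30L
  )
}

PAIR_LEVELS <- c("CG", "GC", "GU", "UG", "AU", "UA")

pair_name <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% PAIR_LEVELS) p else NA_character_
}

#' Parse a dot-bracket string into a partner vector
#'
#' @param db dot-bracket string (only `(`, `)`, `.`).
#' @return integer vector; `partner[i]` is the 1-based partner of position
#'   `i`, or `NA` if unpaired.
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    abort("dot-bracket string contains characters other than '(', ')', '.'",
          class = "miredit_format_error")
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        abort("unbalanced dot-bracket string", class = "miredit_format_error")
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack) > 0) {
    abort("unbalanced dot-bracket string", class = "miredit_format_error")
  }
  partner
}

#' Score a secondary structure by loop decomposition
#'
#' Independent re-scoring of an explicit structure under the same parameter
#' table as the dynamic-programming engine, by decomposing the structure into
#' hairpin, stack/bulge/internal and multibranch loops. This is a separate
#' code path from the engine's recursions and is used both as the
#' self-consistency check on returned structures and as the scoring half of
#' the brute-force enumeration oracle in the test-suite.
#'
#' @param seq RNA sequence (A/C/G/U; T is converted).
#' @param db dot-bracket structure of the same length.
#' @param params energy parameter list from [fold_params()].
#' @return energy in kcal/mol.
#' @export
#' @examples
#' structure_energy("GGGAAAACCC", "(((....)))")
structure_energy <- function(seq, db, params = fold_params()) {
  seq <- dna_to_rna(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (nchar(db) != n) {
    abort("structure and sequence lengths differ", class = "miredit_format_error")
  }
  partner <- parse_dotbracket(db)

  pt <- function(i, j) {
    p <- pair_name(chars[i], chars[j])
    if (is.na(p)) {
      abort(sprintf("position %d:%d (%s:%s) is not a Watson-Crick or G:U pair",
                    i, j, chars[i], chars[j]),
            class = "miredit_invalid_structure")
    }
    p
  }

  extrap <- function(base30, size) {
    base30 + as.integer(floor(params$lxc * log(size / 30) + 0.5))
  }
  hairpin_e <- function(size) {
    if (size < 3) abort("hairpin loop smaller than 3 nt",
                        class = "miredit_invalid_structure")
    if (size <= 30) params$hairpin[size + 1L] else extrap(params$hairpin[31L], size)
  }
  bulge_e <- function(size) {
    if (size <= 30) params$bulge[size + 1L] else extrap(params$bulge[31L], size)
  }
  internal_e <- function(n1, n2) {
    size <- n1 + n2
    init <- if (size <= 30) params$internal[size + 1L] else extrap(params$internal[31L], size)
    init + min(params$asym_max, params$asym_per_nt * abs(n1 - n2))
  }

  # children = helices directly enclosed in the loop closed by (i, j);
  # i = 0 scans the exterior loop
  children_of <- function(i, j) {
    kids <- list()
    k <- i + 1L
    while (k <= j - 1L) {
      if (!is.na(partner[k])) {
        if (partner[k] < k) {
          abort("crossing base pairs (pseudoknot) in structure",
                class = "miredit_invalid_structure")
        }
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    kids
  }

  total <- 0L
  # stack of helices to decompose, seeded from the exterior loop
  todo <- children_of(0L, n + 1L)
  while (length(todo) > 0) {
    pr <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    i <- pr[[1]]; j <- pr[[2]]
    kids <- children_of(i, j)
    if (length(kids) == 0) {
      total <- total + hairpin_e(j - i - 1L)
    } else if (length(kids) == 1) {
      k <- kids[[1]][[1]]; l <- kids[[1]][[2]]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      e <- if (n1 == 0 && n2 == 0) {
        params$stack[pt(i, j), pt(l, k)]
      } else if (n1 == 0 || n2 == 0) {
        bulge_e(n1 + n2)
      } else {
        internal_e(n1, n2)
      }
      total <- total + e
    } else {
      unpaired <- (j - i - 1L) - sum(vapply(kids, function(kk) kk[[2]] - kk[[1]] + 1L, 1L))
      total <- total + params$ml_init +
        params$ml_branch * (length(kids) + 1L) +
        params$ml_unpaired * unpaired
    }
    # validate the closing pair itself and recurse
    pt(i, j)
    todo <- c(todo, kids)
  }
  total / 100
}
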