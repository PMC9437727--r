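#' Plot the per-line mutation spectrum
#'
#' Stacked bar chart of mutation-call counts per line, by edit class.
#'
#' @param genotypes tibble from [summarize_line()] rows (e.g.
#'   `run_pipeline()$genotypes`).
#' @return a ggplot object.
#' @export
plot_mutation_spectrum <- function(genotypes) {
  long <- genotypes |>
    select("line_id", starts_with("n_"), -"n_clones", -"n_mutated") |>
    tidyr::pivot_longer(-"line_id", names_to = "type", values_to = "count") |>
    mutate(type = sub("^n_", "", .data$type))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$line_id, y = .data$count,
                                     fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mutation calls", fill = "edit class") +
    ggplot2::theme_minimal()
}

#' Plot relative miRNA abundance against impaired-precursor count
#'
#' The qualitative relationship the pipeline is built to expose: lines whose
#' genotyped precursors are more often processing-impaired should show lower
#' relative miRNA abundance (and correspondingly de-repressed targets).
#'
#' @param reports tibble from `run_pipeline()$reports`.
#' @return a ggplot object.
#' @export
plot_processing_vs_abundance <- function(reports) {
  ggplot2::ggplot(reports,
                  ggplot2::aes(x = .data$impaired_k / .data$impaired_n,
                               y = .data$rel_mirna_abundance)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$locus_id), size = 3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "fraction of precursor clones with impaired processing",
                  y = "relative miRNA abundance (NT = 1)",
                  colour = "locus") +
    ggplot2::theme_minimal()
}

#' Render a clone alignment as annotated text
#'
#' A plain-text rendering in the style of genotyping figures: the allele and
#' clone rows with gap characters, an annotation row boxing the mature miR-5p
#' span and tagging the guide protospacers and cut sites. Coordinates are
#' converted to 1-based only here, at rendering.
#'
#' @param aln an `allele_alignment` from [align_clones()].
#' @param locus the [make_locus()] object the clone was aligned to.
#' @param flank nt of context shown around the guide region.
#' @return character vector of lines (also printed invisibly-friendly).
#' @export
render_alignment <- function(aln, locus, flank = 20L) {
  g <- locus$guides
  mir <- mir5p_span_amplicon(locus)
  from <- max(0L, min(g$proto_start) - flank)
  to <- min(nchar(locus$allele_seqs[[aln$best_allele_index]]),
            max(g$proto_end, g$pam_end) + flank)

  # map allele coordinates to alignment columns
  s <- strsplit(aln$aligned_allele, "")[[1]]
  acoord <- cumsum(s != "-")          # allele position (1-based) per column
  cols <- which(acoord > from & acoord <= to)

  ann <- rep(" ", length(s))
  mark <- function(span, ch) {
    sel <- acoord > span[1] & acoord <= span[2] & s != "-"
    ann[sel] <<- ch
  }
  mark(c(g$proto_start[1], g$proto_end[1]), "1")
  mark(c(g$proto_start[2], g$proto_end[2]), "2")
  mark(c(g$pam_start[1], g$pam_end[1]), "P")
  mark(c(g$pam_start[2], g$pam_end[2]), "P")
  mark(mir, "=")
  for (cut in g$cut_pos) {
    cc <- which(acoord == cut & s != "-")
    if (length(cc)) ann[cc[1]] <- "v"
  }

  p <- strsplit(aln$aligned_clone, "")[[1]]
  lines <- c(
    sprintf("%s vs allele %d (amplicon %d..%d, 1-based)",
            aln$clone_id, aln$best_allele_index, from + 1L, to),
    paste0("guide/miR: ", paste(ann[cols], collapse = "")),
    paste0("allele   : ", paste(s[cols], collapse = "")),
    paste0("clone    : ", paste(p[cols], collapse = "")),
    paste0("           ",
           paste(ifelse(p[cols] == s[cols], " ", "*"), collapse = ""))
  )
  lines
}
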