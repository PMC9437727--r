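#' Default end-to-end pipeline configuration
#'
#' The defaults emulate the study conditions of a dual-sgRNA miRNA-editing
#' experiment in a tetraploid crop: two independent loci, four alleles with
#' ~1% natural SNPs over an 800-nt genotyping amplicon, mosaic transgenic
#' lines genotyped by 10 cloned PCR products, an edit spectrum dominated by
#' short deletions with 1-nt T/G insertions, inter-guide excisions and longer
#' deletions, 50-bp single-end sRNA libraries, and relative standard-curve
#' qPCR (duplicate wells at 10- and 50-fold dilutions, NT baseline averaged
#' over ten non-transgenic plants).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    loci = list(
      list(locus_id = "MIRa", n_alleles = 4L, snp_rate = 0.01, amplicon_length = 800L),
      list(locus_id = "MIRb", n_alleles = 4L, snp_rate = 0.01, amplicon_length = 800L)
    ),
    lines_per_locus = 4L,
    clones_per_line = 10L,
    nt_clones_per_locus = 10L,
    edit_profile = list(p_none = 0.15, p_short_deletion = 0.45,
                        p_insertion_T = 0.1, p_insertion_G = 0.1,
                        p_inter_guide_excision = 0.1, p_large_deletion = 0.1,
                        jitter = 4L, mosaicism = 4L),
    trace = list(noise = 0.02, pad_upstream = 20L, pad_downstream = 60L),
    srna = list(depth = 20000L, variant_prob = 0.3, tail_prob = 0.1,
                leak_rate = 0, background_prob = 0.3, n_nt_samples = 3L),
    qpcr = list(noise_sd = 0.1, slope = -3.3219, intercept = 35,
                n_nt_samples = 10L, target_coupling = 0.8),
    targets = list(cutoff = 3),
    thresholds = list(mfei = 0.85, loop = 5L)
  )
}

# recursive merge: named sub-lists merge key-wise, everything else (including
# unnamed lists such as `loci`) replaces the default wholesale
merge_config <- function(user, base = default_config()) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    bv <- base[[nm]]
    uv <- user[[nm]]
    if (is.list(bv) && is.list(uv) &&
        !is.null(names(uv)) && all(nzchar(names(uv)))) {
      base[nm] <- list(merge_config(uv, bv))
    } else {
      base[nm] <- list(uv)
    }
  }
  base
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage in dependency order: locus synthesis, line/edit
#' simulation, clone genotyping with polymorphism masking, trace deconvolution
#' (knock-out score), folding + impaired-processing classification of every
#' clone precursor, sRNA simulation + exclusion-based variant discovery,
#' target-retention screening, qPCR simulation + relative quantification, and
#' a per-line report. All randomness flows from the single top-level seed via
#' per-stage derived seeds; rerunning with the same config is idempotent.
#'
#' @param config nested list (see [default_config()]) or path to a YAML file;
#'   partial configs are merged over the defaults.
#' @param out_dir optional directory; when given, every artifact is written as
#'   TSV with a provenance header (seed, config hash, package version).
#' @return list with `loci`, `line_truth`, `genotypes`, `calls`, `ko`,
#'   `structures`, `variants`, `specific_variants`, `target_hits`,
#'   `abundance`, `reports`, `correlations`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(config)
  validate_config(config)
  seed <- as.integer(config$seed)

  profile <- do.call(edit_profile, config$edit_profile)

  ## ---- stage 1: loci ----
  loci <- map(config$loci, function(ls) {
    make_locus(seed = derive_seed(seed, paste0("locus_", ls$locus_id)),
               n_alleles = ls$n_alleles, snp_rate = ls$snp_rate,
               amplicon_length = ls$amplicon_length, locus_id = ls$locus_id)
  })
  names(loci) <- map_chr(config$loci, "locus_id")

  ## ---- stage 2: lines, clones, genotyping, traces, structures ----
  line_truth <- list(); genotypes <- list(); calls_all <- list()
  ko_list <- list(); structures <- list(); line_index <- list()

  for (locus in loci) {
    panel <- nt_panel_for(locus, config, seed)
    for (i in seq_len(config$lines_per_locus)) {
      line_id <- sprintf("%s_line%d", locus$locus_id, i)
      truth <- simulate_line(locus, profile,
                             seed = derive_seed(seed, paste0("line_", line_id)),
                             line_id = line_id)
      clones <- simulate_amplicon_clones(truth, config$clones_per_line,
                                         seed = derive_seed(seed, paste0("clones_", line_id)))

      alns <- align_clones(clones, locus)
      clone_rows <- map(alns, function(a) {
        a <- mask_polymorphism_quiet(a, panel)
        cl <- classify_mutation(a$ops, locus)
        cl$clone_id <- a$clone_id
        cl$best_allele_index <- a$best_allele_index
        cl$line_id <- line_id
        list(calls = cl, aln = a)
      })
      calls <- bind_rows(map(clone_rows, "calls"))
      genotypes[[line_id]] <- summarize_line(calls, line_id)
      calls_all[[line_id]] <- calls

      # knock-out score from the mixed trace over a window spanning the
      # divergence region downstream of the first cut
      cuts <- sort(locus$guides$cut_pos)
      window <- c(max(0L, cuts[1] - config$trace$pad_upstream),
                  cuts[2] + config$trace$pad_downstream)
      tr <- simulate_sanger_trace(tibble(sequence = truth$edited_seq,
                                         proportion = truth$proportion),
                                  window = window, noise = config$trace$noise,
                                  seed = derive_seed(seed, paste0("trace_", line_id)))
      ko_list[[line_id]] <- ko_score(tr, locus)

      # fold and classify the precursor carried by every genotyped clone
      prec <- clone_precursors(clones, alns, locus, line_id)
      prec_cls <- classify_precursors(
        distinct(prec, .data$sequence, .data$mir5p_start, .data$mir5p_end,
                 .keep_all = TRUE) |>
          select("precursor_id", "sequence", "mir5p_start", "mir5p_end"))
      prec <- prec |>
        left_join(select(prec_cls, -"precursor_id"),
                  by = c("sequence", "mir5p_start", "mir5p_end"))
      structures[[line_id]] <- prec
      line_index[[line_id]] <- tibble(line_id = line_id, locus_id = locus$locus_id)
    }
  }
  genotypes <- bind_rows(genotypes)
  calls_all <- bind_rows(calls_all)
  structures <- bind_rows(structures)
  line_index <- bind_rows(line_index)

  impaired_tally <- structures |>
    group_by(.data$line_id) |>
    summarise(impaired_n = n(), impaired_k = sum(.data$impaired), .groups = "drop")

  ## ---- stage 3: sRNA variant discovery ----
  srna <- run_srna_stage(loci, structures, line_index, config, seed)

  ## ---- stage 4: target screening ----
  tx <- synthetic_target_transcripts(loci, seed)
  target_hits <- screen_targets(
    unique(srna$specific_variants$sequence), tx,
    cutoff = config$targets$cutoff)

  ## ---- stage 5: qPCR quantification ----
  quant <- run_qpcr_stage(loci, line_index, impaired_tally, config, seed)

  ## ---- stage 6: per-line report ----
  retained <- srna$specific_variants |>
    distinct(.data$line_group, .data$sequence) |>
    left_join(target_hits |> group_by(.data$sequence) |>
                summarise(retained = any(.data$functional), .groups = "drop"),
              by = "sequence") |>
    mutate(retained = !is.na(.data$retained) & .data$retained)

  n_var <- srna$specific_variants |>
    group_by(line_group = .data$line_group) |>
    summarise(n_variants = n_distinct(.data$sequence), .groups = "drop")
  n_ret <- retained |> group_by(.data$line_group) |>
    summarise(n_variants_retained = sum(.data$retained), .groups = "drop")

  reports <- genotypes |>
    left_join(line_index, by = "line_id") |>
    left_join(impaired_tally, by = "line_id") |>
    mutate(ko_score = map_dbl(.data$line_id, ~ ko_list[[.x]]$editing_rate)) |>
    left_join(quant$mirna, by = "line_id") |>
    left_join(quant$target, by = "line_id") |>
    left_join(n_var, by = c("locus_id" = "line_group")) |>
    left_join(n_ret, by = c("locus_id" = "line_group")) |>
    mutate(n_variants = ifelse(is.na(.data$n_variants), 0L, .data$n_variants),
           n_variants_retained = ifelse(is.na(.data$n_variants_retained), 0L,
                                        .data$n_variants_retained))

  correlations <- if (nrow(reports) >= 3) {
    list(
      impaired_vs_mirna = correlate_abundance(reports$impaired_k,
                                              reports$rel_mirna_abundance),
      mirna_vs_target = correlate_abundance(reports$rel_mirna_abundance,
                                            reports$rel_target_abundance)
    )
  } else {
    NULL
  }

  result <- list(loci = loci, genotypes = genotypes, calls = calls_all,
                 ko = ko_list, structures = structures,
                 variants = srna$variants,
                 specific_variants = srna$specific_variants,
                 target_hits = target_hits,
                 abundance = quant$abundance, reports = reports,
                 correlations = correlations, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

validate_config <- function(config) {
  ok <- is.numeric(config$seed) && length(config$loci) >= 1 &&
    config$lines_per_locus >= 1 && config$clones_per_line >= 1 &&
    all(map_lgl(config$loci, ~ all(c("locus_id", "n_alleles", "snp_rate",
                                     "amplicon_length") %in% names(.x))))
  if (!ok) abort("invalid pipeline configuration", class = "miredit_config_error")
  invisible(TRUE)
}

mask_polymorphism_quiet <- function(a, panel) {
  if (is.null(panel) || nrow(panel) == 0) {
    a$masked_ops <- a$ops[0, ]
    return(a)
  }
  mask_polymorphism(a, panel)
}

# panel from simulated non-transgenic control clones plus the ground-truth
# allelic SNP set
nt_panel_for <- function(locus, config, seed) {
  nt_truth <- tibble(edited_seq = locus$allele_seqs,
                     proportion = rep(1 / length(locus$allele_seqs),
                                      length(locus$allele_seqs)))
  nt_clones <- simulate_amplicon_clones(
    nt_truth, config$nt_clones_per_locus,
    seed = derive_seed(seed, paste0("ntclones_", locus$locus_id)))
  alns <- align_clones(nt_clones, locus)
  snp_panel(alns, locus = locus)
}

# remap the precursor and miR-5p spans of each clone through its called ops
# and cut the clone's precursor sequence out
clone_precursors <- function(clones, alns, locus, line_id) {
  mir_amp <- mir5p_span_amplicon(locus)
  rows <- map(seq_along(alns), function(i) {
    a <- alns[[i]]
    ops <- filter(a$ops, .data$op %in% c("del", "ins"))
    ps <- remap_span_ops(locus$precursor_span, ops)
    ms <- remap_span_ops(mir_amp, ops)
    ms <- c(max(ms[1], ps[1]), min(ms[2], ps[2]))
    tibble(line_id = line_id, clone_id = a$clone_id,
           precursor_id = sprintf("%s_%s", line_id, a$clone_id),
           sequence = span_substr(clones$sequence[[i]], ps),
           mir5p_start = max(0L, ms[1] - ps[1]),
           mir5p_end = max(0L, ms[2] - ps[1]))
  })
  bind_rows(rows)
}

# map a 0-based half-open span through a set of difference ops given in
# reference coordinates
remap_span_ops <- function(span, ops) {
  map_pos <- function(p, is_end) {
    shift <- 0L
    if (nrow(ops)) for (i in seq_len(nrow(ops))) {
      o <- ops[i, ]
      if (o$op == "del") {
        if (o$end <= p) shift <- shift - (o$end - o$start)
        else if (o$start < p) shift <- shift - (p - o$start)
      } else if (o$op == "ins") {
        if (o$start < p || (is_end && o$start == p)) {
          shift <- shift + nchar(o$alt)
        }
      }
    }
    p + shift
  }
  c(map_pos(span[[1]], FALSE), map_pos(span[[2]], TRUE))
}

run_srna_stage <- function(loci, structures, line_index, config, seed) {
  scfg <- config$srna
  cfg <- read_sim_config(depth = scfg$depth, variant_prob = scfg$variant_prob,
                         tail_prob = scfg$tail_prob, leak_rate = scfg$leak_rate,
                         background_prob = scfg$background_prob)

  wt <- bind_rows(map(loci, function(l) {
    tibble(precursor_id = paste0(l$locus_id, "_wt"),
           locus_id = l$locus_id,
           sequence = precursor_seq(l, 1),
           mir5p_start = l$mir5p_span[[1]], mir5p_end = l$mir5p_span[[2]],
           impaired = FALSE)
  }))

  # per-line precursor content: the edited precursors of the line's locus
  # (clone-frequency weighted) plus the wild-type precursor of every other
  # locus, which is untouched in that line
  samples <- list()
  for (i in seq_len(nrow(line_index))) {
    lid <- line_index$line_id[i]; loc <- line_index$locus_id[i]
    own <- structures |>
      filter(.data$line_id == lid) |>
      group_by(.data$precursor_id, .data$sequence, .data$mir5p_start,
               .data$mir5p_end, .data$impaired) |>
      summarise(weight = n(), .groups = "drop")
    other <- wt |> filter(.data$locus_id != loc) |>
      mutate(weight = mean(own$weight) * 1.0) |>
      select(-"locus_id")
    samples[[lid]] <- bind_rows(own, other) |> mutate(sample_id = lid)
  }
  nt <- map(seq_len(scfg$n_nt_samples), function(k) {
    wt |> select(-"locus_id") |> mutate(weight = 1, sample_id = sprintf("NT%d", k))
  })
  samples <- bind_rows(c(samples, nt)) |>
    relocate("sample_id", "precursor_id", "sequence", "mir5p_start",
             "mir5p_end", "impaired", "weight")

  sim <- simulate_srna_reads(samples, cfg, seed = derive_seed(seed, "srna"))
  clean <- preprocess(sim$reads, adapter = cfg$adapter)

  reference <- samples |>
    distinct(.data$precursor_id, .data$sequence, .data$mir5p_start, .data$mir5p_end)
  mapped <- map_exact(clean, reference)
  variants <- call_variants(mapped, reference)

  # reciprocal exclusion per locus: variants of cr-lines at locus A must be
  # absent from NT samples and from lines edited at any other locus
  nt_ids <- sprintf("NT%d", seq_len(scfg$n_nt_samples))
  specific <- map(unique(line_index$locus_id), function(loc) {
    test <- line_index$line_id[line_index$locus_id == loc]
    ctrl <- c(nt_ids, line_index$line_id[line_index$locus_id != loc])
    out <- specificity_filter(variants, test, ctrl)
    # only variants actually arising from the tested locus' precursors
    out <- filter(out, stringr::str_detect(.data$sources, stringr::fixed(loc)))
    mutate(out, line_group = loc)
  })
  list(variants = variants, specific_variants = bind_rows(specific),
       truth = sim$truth, samples = samples, clean = clean)
}

synthetic_target_transcripts <- function(loci, seed) {
  with_seed(derive_seed(seed, "transcripts"), {
    bind_rows(map(loci, function(l) {
      mir <- span_substr(precursor_seq(l, 1),
                         c(l$mir5p_span[[1]], l$mir5p_span[[2]]))
      site <- revcomp(mir)
      tibble(transcript_id = paste0("target_of_", l$locus_id),
             sequence = paste0(random_dna(150), site, random_dna(150)))
    }))
  })
}

run_qpcr_stage <- function(loci, line_index, impaired_tally, config, seed) {
  qcfg <- config$qpcr
  nt_ids <- sprintf("NTq%d", seq_len(qcfg$n_nt_samples))
  leak <- config$srna$leak_rate

  truth <- line_index |>
    left_join(impaired_tally, by = "line_id") |>
    mutate(mirna_truth = (1 - .data$impaired_k / .data$impaired_n) +
             leak * .data$impaired_k / .data$impaired_n,
           mirna_truth = pmax(.data$mirna_truth, 1e-3),
           target_truth = 1 + qcfg$target_coupling * (1 - .data$mirna_truth))

  abundance <- bind_rows(
    map(seq_len(nrow(truth)), function(i) {
      r <- truth[i, ]
      tibble(sample_id = r$line_id,
             assay = c(paste0("mir_", r$locus_id), paste0("target_", r$locus_id),
                       "control"),
             quantity = c(r$mirna_truth, r$target_truth, 1))
    }),
    map(nt_ids, function(s) {
      tibble(sample_id = s,
             assay = c(paste0("mir_", names(loci)), paste0("target_", names(loci)),
                       "control"),
             quantity = 1)
    })
  )

  assays <- unique(abundance$assay)
  curve_spec <- tibble(assay = assays, slope = qcfg$slope, intercept = qcfg$intercept)
  sim <- simulate_qpcr(abundance, curve_spec,
                       seed = derive_seed(seed, "qpcr"),
                       noise_sd = qcfg$noise_sd)
  curves <- map(assays, function(a) {
    fit_curve(filter(sim$dilution_series, .data$assay == a))
  })
  names(curves) <- assays

  rel <- quantify(sim$cq, curves, control_assay = "control", nt_samples = nt_ids)

  mirna <- rel |>
    filter(startsWith(.data$assay, "mir_"),
           .data$sample_id %in% line_index$line_id) |>
    left_join(line_index, by = c("sample_id" = "line_id")) |>
    filter(.data$assay == paste0("mir_", .data$locus_id)) |>
    select(line_id = "sample_id", rel_mirna_abundance = "relative_to_nt")
  target <- rel |>
    filter(startsWith(.data$assay, "target_"),
           .data$sample_id %in% line_index$line_id) |>
    left_join(line_index, by = c("sample_id" = "line_id")) |>
    filter(.data$assay == paste0("target_", .data$locus_id)) |>
    select(line_id = "sample_id", rel_target_abundance = "relative_to_nt")

  list(abundance = rel, mirna = mirna, target = target, truth = truth,
       curves = curves)
}

#' Write a tibble as TSV with a provenance header
#'
#' @param x data frame.
#' @param path output path.
#' @param seed,config_hash provenance fields.
#' @return `path`, invisibly.
#' @export
write_provenance_tsv <- function(x, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# miredit %s seed=%s config=%s",
                     as.character(utils::packageVersion("miredit")),
                     seed, config_hash), con)
  x <- mutate(x, across(where(is.list), ~ map_chr(.x, paste, collapse = ";")))
  write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- rlang::hash(result$config)
  s <- result$config$seed
  w <- function(x, name) write_provenance_tsv(x, file.path(out_dir, name), s, h)
  w(result$genotypes, "genotypes.tsv")
  w(result$calls, "mutation_calls.tsv")
  w(select(result$structures, -"clone_id"), "structures.tsv")
  w(result$variants, "variants.tsv")
  w(result$specific_variants, "specific_variants.tsv")
  w(result$target_hits, "target_hits.tsv")
  w(result$abundance, "abundance.tsv")
  w(result$reports, "line_reports.tsv")
  invisible(out_dir)
}

#' Reproduce the structure analysis over a local precursor deposit
#'
#' Benchmark mode: runs the folding / MFEI / duplex / impaired-processing
#' stage over an externally deposited set of mutated pre-miRNA sequences (a
#' directory of FASTA files, fetched manually by the user -- this function
#' never downloads anything). The external folding backend is used by default
#' because published MFEI values near the 0.85 threshold are sensitive to the
#' energy parameter set.
#'
#' @param deposit_dir directory containing FASTA file(s) of precursor
#'   sequences.
#' @param annotations tibble (`precursor_id`, `mir5p_start`, `mir5p_end`)
#'   covering every FASTA record.
#' @param engine folding engine (`"vienna"` by default; falls back to
#'   `"internal"` only on explicit request).
#' @return the [classify_precursors()] table.
#' @export
benchmark_structures <- function(deposit_dir, annotations, engine = "vienna") {
  if (!dir.exists(deposit_dir)) {
    abort(paste0("precursor deposit not found at '", deposit_dir, "'. ",
                 "Benchmark mode consumes a manually downloaded deposit of ",
                 "mutated pre-miRNA FASTA files; fetch it and pass the ",
                 "directory path (nothing is downloaded automatically)."),
          class = "miredit_data_error")
  }
  fastas <- list.files(deposit_dir, pattern = "\\.(fa|fasta|fna)$",
                       full.names = TRUE, ignore.case = TRUE)
  if (length(fastas) == 0) {
    abort(sprintf("no FASTA files found in '%s'", deposit_dir),
          class = "miredit_data_error")
  }
  seqs <- bind_rows(map(fastas, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    tibble(precursor_id = sub("\\s.*", "", names(ss)), sequence = as.character(ss))
  }))
  missing <- setdiff(seqs$precursor_id, annotations$precursor_id)
  if (length(missing)) {
    abort(sprintf("annotations missing for: %s", paste(missing, collapse = ", ")),
          class = "miredit_data_error")
  }
  tbl <- inner_join(seqs, annotations, by = "precursor_id")
  classify_precursors(tbl, engine = engine)
}
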