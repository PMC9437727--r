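#' Simulate qPCR Cq tables and dilution series
#'
#' Cq values follow the standard-curve model `Cq = intercept + slope *
#' log10(quantity) + noise`. Each sample is measured in duplicate wells at two
#' dilutions (10- and 50-fold by default), and each assay gets a dilution
#' series of `n_points` ten-fold steps -- the layout of a relative
#' standard-curve experiment.
#'
#' @param abundance tibble (`sample_id`, `assay`, `quantity`): true relative
#'   quantities (> 0).
#' @param curve_spec tibble (`assay`, `slope`, `intercept`).
#' @param seed integer seed.
#' @param noise_sd Gaussian Cq noise (cycles).
#' @param base_quantity copies corresponding to `quantity = 1` before
#'   dilution.
#' @param dilutions dilution factors per sample.
#' @param n_points ten-fold points in the dilution series (>= 4).
#' @return list with `cq` (tibble `sample_id`, `assay`, `dilution`, `well`,
#'   `cq`) and `dilution_series` (tibble `assay`, `log10_quantity`, `well`,
#'   `cq`).
#' @export
simulate_qpcr <- function(abundance, curve_spec, seed = 1L, noise_sd = 0.1,
                          base_quantity = 1000, dilutions = c(10, 50),
                          n_points = 5L) {
  stopifnot(all(c("sample_id", "assay", "quantity") %in% names(abundance)),
            all(c("assay", "slope", "intercept") %in% names(curve_spec)))
  if (any(abundance$quantity <= 0)) {
    abort("quantities must be positive", class = "miredit_value_error")
  }
  if (n_points < 4) {
    abort("the dilution series must span at least 4 ten-fold points",
          class = "miredit_bounds_error")
  }
  cq_of <- function(assay, q, noise) {
    cs <- curve_spec[match(assay, curve_spec$assay), ]
    cs$intercept + cs$slope * log10(q) + noise
  }
  with_seed(seed, {
    grid <- tidyr::crossing(abundance, dilution = dilutions, well = 1:2)
    q <- grid$quantity * base_quantity / grid$dilution
    cq <- cq_of(grid$assay, q,
                if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0)
    cq_tbl <- tibble(sample_id = grid$sample_id, assay = grid$assay,
                     dilution = grid$dilution, well = grid$well, cq = cq)

    ser <- tidyr::crossing(assay = unique(curve_spec$assay),
                           log10_quantity = log10(base_quantity) - (seq_len(n_points) - 1),
                           well = 1:2)
    ser$cq <- cq_of(ser$assay, 10^ser$log10_quantity,
                    if (noise_sd > 0) rnorm(nrow(ser), 0, noise_sd) else 0)
    list(cq = cq_tbl, dilution_series = ser)
  })
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 quantity. Amplification efficiency is
#' `10^(-1/slope) - 1`; a slope of -3.3219 corresponds to 100% efficiency
#' (perfect doubling per cycle).
#'
#' @param dilutions tibble with columns `log10_quantity` and `cq` (>= 3 points
#'   spanning >= 2 logs).
#' @return object of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency`, `n`, and the underlying `lm` fit.
#' @export
#' @examples
#' d <- tibble::tibble(log10_quantity = 0:4, cq = 35 - 3.3219 * (0:4))
#' fit_curve(d)
fit_curve <- function(dilutions) {
  stopifnot(all(c("log10_quantity", "cq") %in% names(dilutions)))
  d <- dilutions[complete.cases(dilutions[, c("log10_quantity", "cq")]), ]
  if (nrow(d) < 3 || length(unique(d$log10_quantity)) < 3) {
    abort("standard curve needs at least 3 dilution points",
          class = "miredit_insufficient_data")
  }
  if (diff(range(d$log10_quantity)) < 2) {
    abort("dilution series must span at least 2 log10 units",
          class = "miredit_insufficient_data")
  }
  fit <- lm(cq ~ log10_quantity, data = d)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warn("standard curve has a non-negative slope: assay failure")
  }
  sst <- sum((d$cq - mean(d$cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r2 = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n = nrow(d), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve: slope %.4f, intercept %.2f, R2 %.4f, efficiency %.1f%%>\n",
              x$slope, x$intercept, x$r2, 100 * x$efficiency))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_curve
#' @param x a `standard_curve`.
#' @param ... unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r.squared = x$r2, efficiency = x$efficiency, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' Relative quantification against an endogenous control and the NT baseline
#'
#' Inverts the per-assay standard curve (`quantity = 10^((Cq - intercept) /
#' slope)`, dilution-corrected), averages duplicate wells and dilutions on the
#' quantity scale (wells disagreeing by more than 0.5 Cq within a
#' sample/assay/dilution are flagged), normalises each target assay by the
#' endogenous control, and scales to the mean normalised value of the
#' non-transgenic samples.
#'
#' @param cq_table tibble (`sample_id`, `assay`, `dilution`, `well`, `cq`).
#'   Undetected reactions must be `NA`, never zero.
#' @param curves named list of `standard_curve` objects (one per assay).
#' @param control_assay endogenous-control assay name.
#' @param nt_samples character vector of non-transgenic sample ids.
#' @return tibble: `sample_id`, `assay`, `quantity`, `control_quantity`,
#'   `normalized`, `relative_to_nt`, `outlier_flagged`. Samples lacking a
#'   control Cq are skipped and recorded in `attr(, "skipped")`.
#' @export
quantify <- function(cq_table, curves, control_assay, nt_samples) {
  stopifnot(all(c("sample_id", "assay", "dilution", "well", "cq") %in% names(cq_table)))
  if (!control_assay %in% names(curves)) {
    abort("no standard curve for the control assay", class = "miredit_config_error")
  }

  inv <- function(assay, cq) {
    cv <- curves[[assay]]
    10^((cq - cv$intercept) / cv$slope)
  }
  per_q <- cq_table |>
    filter(!is.na(.data$cq)) |>
    mutate(q = unlist(map2(.data$assay, .data$cq, inv)) * .data$dilution)

  flags <- per_q |>
    group_by(.data$sample_id, .data$assay, .data$dilution) |>
    summarise(delta = if (n() >= 2) max(.data$cq) - min(.data$cq) else 0,
              .groups = "drop") |>
    group_by(.data$sample_id, .data$assay) |>
    summarise(outlier_flagged = any(.data$delta > 0.5), .groups = "drop")

  q_tbl <- per_q |>
    group_by(.data$sample_id, .data$assay) |>
    summarise(quantity = mean(.data$q), .groups = "drop") |>
    left_join(flags, by = c("sample_id", "assay"))

  ctrl <- q_tbl |> filter(.data$assay == control_assay) |>
    select("sample_id", control_quantity = "quantity")
  targets <- q_tbl |> filter(.data$assay != control_assay)

  skipped <- setdiff(unique(targets$sample_id), ctrl$sample_id)
  if (length(skipped)) {
    warn(sprintf("skipping sample(s) without control Cq: %s",
                 paste(skipped, collapse = ", ")))
  }

  out <- targets |>
    inner_join(ctrl, by = "sample_id") |>
    mutate(normalized = .data$quantity / .data$control_quantity) |>
    group_by(.data$assay) |>
    mutate(relative_to_nt = .data$normalized /
             mean(.data$normalized[.data$sample_id %in% nt_samples])) |>
    ungroup() |>
    relocate("sample_id", "assay", "quantity", "control_quantity",
             "normalized", "relative_to_nt", "outlier_flagged")
  attr(out, "skipped") <- skipped
  out
}

#' Correlate two relative-abundance vectors
#'
#' Pearson and Spearman coefficients with a sign summary, used to report the
#' relationship between miRNA abundance and the abundance of its target
#' transcript (expected negative) or between impaired-allele counts and miRNA
#' abundance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return one-row tibble: `n`, `pearson`, `spearman`, `sign`
#'   (`"negative"`/`"positive"`/`"none"`), `undefined` (zero-variance flag).
#' @export
correlate_abundance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("correlate_abundance needs equal-length vectors of length >= 3",
          class = "miredit_value_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    return(tibble(n = length(x), pearson = NA_real_, spearman = NA_real_,
                  sign = "none", undefined = TRUE))
  }
  p <- cor(x, y, method = "pearson")
  s <- cor(x, y, method = "spearman")
  tibble(n = length(x), pearson = p, spearman = s,
         sign = if (s < 0) "negative" else if (s > 0) "positive" else "none",
         undefined = FALSE)
}
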