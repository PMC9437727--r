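test_that("Cq follows the standard-curve model exactly without noise", {
  ab <- tibble::tibble(sample_id = "S", assay = "a", quantity = 1)
  cs <- tibble::tibble(assay = "a", slope = -3.3219, intercept = 35)
  sim <- simulate_qpcr(ab, cs, seed = 1, noise_sd = 0, base_quantity = 1,
                       dilutions = 1)
  expect_equal(unique(sim$cq$cq), 35)

  ab10 <- tibble::tibble(sample_id = "S", assay = "a", quantity = 10)
  sim10 <- simulate_qpcr(ab10, cs, seed = 1, noise_sd = 0, base_quantity = 1,
                         dilutions = 1)
  expect_equal(unique(sim10$cq$cq), 35 - 3.3219)

  expect_identical(simulate_qpcr(ab, cs, seed = 2, noise_sd = 0.2),
                   simulate_qpcr(ab, cs, seed = 2, noise_sd = 0.2))
  expect_error(simulate_qpcr(dplyr::mutate(ab, quantity = 0), cs, 1),
               class = "miredit_value_error")
  expect_error(simulate_qpcr(ab, cs, 1, n_points = 3),
               class = "miredit_bounds_error")
})

test_that("standard-curve fits recover slope, r2 and 100% efficiency", {
  d <- tibble::tibble(log10_quantity = 0:4, cq = 35 - 3.3219 * (0:4))
  cv <- fit_curve(d)
  expect_equal(cv$slope, -3.3219, tolerance = 1e-9)
  expect_equal(cv$r2, 1)
  expect_equal(cv$efficiency, 1, tolerance = 1e-3)
  expect_error(fit_curve(d[1:2, ]), class = "miredit_insufficient_data")
  expect_error(fit_curve(tibble::tibble(log10_quantity = c(0, 0.5, 1),
                                        cq = c(35, 34, 33))),
               class = "miredit_insufficient_data")
  expect_warning(fit_curve(tibble::tibble(log10_quantity = 0:3,
                                          cq = c(30, 31, 32, 33))),
                 "non-negative slope")
  td <- tidy(cv); gl <- glance(cv)
  expect_equal(td$estimate[td$term == "slope"], cv$slope)
  expect_equal(gl$efficiency, cv$efficiency)
})

test_that("quantification recovers relative abundance and the NT baseline", {
  nt <- sprintf("NT%d", 1:4)
  ab <- dplyr::bind_rows(
    tibble::tibble(sample_id = c(nt, "L1", "L2"), assay = "mir",
                   quantity = c(1, 1, 1, 1, 0.5, 0.1)),
    tibble::tibble(sample_id = c(nt, "L1", "L2"), assay = "ctl", quantity = 1))
  cs <- tibble::tibble(assay = c("mir", "ctl"), slope = -3.3219, intercept = 35)
  sim <- simulate_qpcr(ab, cs, seed = 3, noise_sd = 0)
  curves <- list(mir = fit_curve(dplyr::filter(sim$dilution_series, assay == "mir")),
                 ctl = fit_curve(dplyr::filter(sim$dilution_series, assay == "ctl")))
  rel <- quantify(sim$cq, curves, "ctl", nt)
  expect_equal(rel$relative_to_nt[rel$sample_id == "L1"], 0.5, tolerance = 1e-6)
  expect_equal(rel$relative_to_nt[rel$sample_id == "L2"], 0.1, tolerance = 1e-6)
  expect_equal(mean(rel$relative_to_nt[rel$sample_id %in% nt]), 1,
               tolerance = 1e-9)

  # noisy round trip: within 15% at 0.1 Cq noise over duplicate wells and
  # two dilutions
  simn <- simulate_qpcr(ab, cs, seed = 4, noise_sd = 0.1)
  curvesn <- list(mir = fit_curve(dplyr::filter(simn$dilution_series, assay == "mir")),
                  ctl = fit_curve(dplyr::filter(simn$dilution_series, assay == "ctl")))
  reln <- quantify(simn$cq, curvesn, "ctl", nt)
  expect_lte(abs(reln$relative_to_nt[reln$sample_id == "L1"] - 0.5) / 0.5, 0.15)
  expect_lte(abs(reln$relative_to_nt[reln$sample_id == "L2"] - 0.1) / 0.1, 0.15)
})

test_that("missing control Cq skips the sample with a record", {
  nt <- c("NT1", "NT2", "NT3")
  ab <- dplyr::bind_rows(
    tibble::tibble(sample_id = c(nt, "L1"), assay = "mir", quantity = 1),
    tibble::tibble(sample_id = nt, assay = "ctl", quantity = 1))
  cs <- tibble::tibble(assay = c("mir", "ctl"), slope = -3.3219, intercept = 35)
  sim <- simulate_qpcr(ab, cs, seed = 5, noise_sd = 0)
  curves <- list(mir = fit_curve(dplyr::filter(sim$dilution_series, assay == "mir")),
                 ctl = fit_curve(dplyr::filter(sim$dilution_series, assay == "ctl")))
  expect_warning(rel <- quantify(sim$cq, curves, "ctl", nt), "without control Cq")
  expect_false("L1" %in% rel$sample_id)
  expect_equal(attr(rel, "skipped"), "L1")
})

test_that("correlation reporting covers signs, nulls, and degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_abundance(x, -x + 10)$pearson, -1)
  expect_equal(correlate_abundance(x, x)$spearman, 1)
  expect_true(correlate_abundance(x, rep(1, 5))$undefined)
  expect_error(correlate_abundance(1:2, 1:2), class = "miredit_value_error")

  # permuted pairs at large n stay within the empirical null 99% band
  set.seed(77)
  xx <- rnorm(200)
  yy <- sample(xx)
  nulls <- replicate(2000, cor(xx, sample(yy)))
  band <- quantile(nulls, c(0.005, 0.995))
  r <- correlate_abundance(xx, yy)$pearson
  expect_gte(r, band[[1]])
  expect_lte(r, band[[2]])
})
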