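test_that("exclusion filter drops all-zero and doubly-sparse responses", {
  all_zero <- make_sparse_dataset(1, "before.control")
  two_sparse <- make_sparse_dataset(0.95, c("before.impact", "after.control"))
  one_sparse <- make_sparse_dataset(0.95, "after.impact")
  healthy <- make_saturated_dataset()
  res <- apply_exclusion_filter(list(all_zero, two_sparse, one_sparse, healthy))
  expect_length(res$excluded, 2L)
  expect_length(res$retained, 2L)
  expect_identical(res$report$rule[1L], "all_zero_subset")
  expect_identical(res$report$rule[2L], "gt90_zero_subsets")
  expect_true(is.na(res$report$rule[3L]))  # one sparse subset is retained
  expect_true(all(res$report$repeated_measurements))
})

test_that("design subsetting mirrors what each design would have collected", {
  d <- make_saturated_dataset()
  ba <- subset_for_design(d, "BA")
  expect_true(all(ba$records$treatment == "impact"))
  expect_setequal(unique(ba$records$period), c("before", "after"))
  ci <- subset_for_design(d, "CI")
  expect_true(all(ci$records$period == "after"))
  expect_setequal(unique(ci$records$treatment), c("control", "impact"))
  expect_identical(subset_for_design(d, "BACI_DiD")$records, d$records)

  no_ac <- d
  no_ac$records <- d$records[!(d$records$period == "after" &
                               d$records$treatment == "control"), ]
  no_ac <- response_dataset(no_ac$records)
  expect_error(subset_for_design(no_ac, "CI"), class = "EmptySubset")
  expect_error(subset_for_design(no_ac, "CI"), "after.control")
})

test_that("model structure follows measure and sampling-depth rules", {
  big <- response_dataset(make_cell_records(n_sites = 6L, n_sub = 3L))
  spec <- choose_model_structure(big)  # 12 sites, 12 rows/site
  expect_identical(spec$family, "poisson")
  expect_true(spec$mixed)
  expect_match(spec$random_terms, "site/subsample")

  small <- response_dataset(make_cell_records(n_sites = 3L))  # 6 sites
  expect_false(choose_model_structure(small)$mixed)

  dens <- response_dataset(make_cell_records(measure = "density"))
  expect_identical(choose_model_structure(dens)$family, "quasipoisson")
  pct <- response_dataset(make_cell_records(measure = "percentage"))
  expect_identical(choose_model_structure(pct)$family, "quasibinomial")
  siz <- response_dataset(make_cell_records(measure = "size"))
  expect_identical(choose_model_structure(siz)$family, "gaussian")
})

test_that("saturated Poisson fixtures have closed-form log-ratio estimates", {
  # cell means (BC, BI, AC, AI) = (10, 10, 10, 20): every estimator's MLE
  # is an exact ratio of cell means on the log scale
  d <- make_saturated_dataset(bc = 10, bi = 10, ac = 10, ai = 20)
  ba <- suppressWarnings(fit_design_estimate(d, "BA"))
  ci <- suppressWarnings(fit_design_estimate(d, "CI"))
  did <- suppressWarnings(fit_design_estimate(d, "BACI_DiD"))
  expect_equal(ba$point, log(2), tolerance = 1e-4)
  expect_equal(ci$point, log(2), tolerance = 1e-4)
  expect_equal(did$point, log(20 * 10 / (10 * 10)), tolerance = 1e-4)
  # asymmetric fixture: DiD is the log cross-ratio, BA/CI marginal ratios
  d2 <- make_saturated_dataset(bc = 5, bi = 8, ac = 10, ai = 24)
  did2 <- suppressWarnings(fit_design_estimate(d2, "BACI_DiD"))
  expect_equal(did2$point, log((24 / 8) / (10 / 5)), tolerance = 1e-4)
  ba2 <- suppressWarnings(fit_design_estimate(d2, "BA"))
  expect_equal(ba2$point, log(24 / 8), tolerance = 1e-4)
  # estimate invariants
  for (e in list(ba, ci, did)) {
    expect_gt(e$se, 0)
    expect_equal(e$ci_low, e$point - 1.96 * e$se)
    expect_equal(e$ci_high, e$point + 1.96 * e$se)
    expect_equal(e$p_value, 2 * pt(-abs(e$point / e$se), e$df))
  }
})

test_that("covariance adjustment uses the lagged before-period site mean", {
  d <- make_saturated_dataset(bc = 10, bi = 10, ac = 10, ai = 20)
  ca <- suppressWarnings(fit_design_estimate(d, "BACI_CA"))
  expect_equal(ca$point, log(2), tolerance = 1e-4)
  expect_identical(ca$estimator, "BACI_CA")
})

test_that("zero cells raise separation errors rather than infinite estimates", {
  d <- make_saturated_dataset(ai = 0)
  expect_error(fit_design_estimate(d, "BACI_DiD"),
               class = "SeparationOrZeroCell")
  expect_error(fit_design_estimate(d, "BA"), class = "SeparationOrZeroCell")
})

test_that("batch estimation flags failures without aborting", {
  good1 <- make_saturated_dataset()
  good2 <- response_dataset(make_cell_records(bc = 8, bi = 12, ac = 9, ai = 15))
  bad <- make_saturated_dataset()
  bad$records <- bad$records[!(bad$records$period == "after" &
                               bad$records$treatment == "control"), ]
  bad$records$response_id <- "r_bad"
  bad <- response_dataset(bad$records)
  good2$records$response_id <- "r2"
  good2 <- response_dataset(good2$records)

  m <- suppressWarnings(estimate_all(list(good1, good2, bad)))
  expect_s3_class(m, "estimate_matrix")
  expect_identical(nrow(m), 12L)
  expect_false(any(duplicated(m[c("response_id", "estimator")])))
  # the bad response keeps BA (impact rows intact) but fails CI and both BACI
  bad_rows <- m[m$response_id == "r_bad", ]
  expect_true(bad_rows$converged[bad_rows$estimator == "BA"])
  expect_false(bad_rows$converged[bad_rows$estimator == "CI"])
  expect_match(bad_rows$note[bad_rows$estimator == "CI"], "after.control")
  expect_true(all(m$converged[m$response_id != "r_bad"]))
})

test_that("standard errors shrink roughly like one over root replication", {
  pts <- vapply(c(1L, 4L, 16L), function(k) {
    scn <- monitoring_scenario(n_sites_per_arm = 4, n_subsamples = 2,
                               n_times_before = 2L * k, n_times_after = 2L * k,
                               theta = 0.3, site_sd = 0.1, subsample_sd = 0.1,
                               seed = 50 + k)
    sim <- simulate_monitoring_dataset(scn)
    suppressWarnings(fit_design_estimate(sim$dataset, "BACI_DiD")$se)
  }, numeric(1L))
  expect_true(all(diff(pts) < 0))
  expect_lt(pts[3L], pts[1L] / 2)  # 16x the data: expect ~4x smaller se
})

test_that("quasi families and mixed models are dispatched and labelled", {
  scn <- monitoring_scenario(n_sites_per_arm = 6, n_subsamples = 3,
                             measure = "density", dispersion = 4,
                             theta = 0.2, seed = 61)
  sim <- simulate_monitoring_dataset(scn)
  e <- suppressWarnings(suppressMessages(fit_design_estimate(sim$dataset, "CI")))
  expect_identical(e$family, "quasipoisson")
  expect_true(e$mixed)  # 12 sites, >2 measurements per site

  scn2 <- monitoring_scenario(n_sites_per_arm = 4, n_subsamples = 2,
                              measure = "percentage", baseline_mean = 30,
                              theta = 0.3, seed = 62)
  sim2 <- simulate_monitoring_dataset(scn2)
  e2 <- suppressWarnings(fit_design_estimate(sim2$dataset, "BACI_DiD"))
  expect_identical(e2$family, "quasibinomial")
  expect_true(is.finite(e2$point))

  scn3 <- monitoring_scenario(n_sites_per_arm = 4, n_subsamples = 2,
                              measure = "size", baseline_mean = 50,
                              residual_sd = 4, theta = 0.2, seed = 63)
  sim3 <- simulate_monitoring_dataset(scn3)
  e3 <- suppressWarnings(fit_design_estimate(sim3$dataset, "BA"))
  expect_identical(e3$family, "gaussian")
  expect_true(is.finite(e3$point))
})
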