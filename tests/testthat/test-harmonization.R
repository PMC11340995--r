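test_that("design rank reflects the distinct settings", {
  expect_equal(build_design(hcp_settings_grid())$rank, 4)
  expect_equal(build_design(list(acq_setting(1.25, 1000),
                                 acq_setting(2.3, 3000)))$rank, 2)
  expect_equal(build_design(rep(list(acq_setting(1.25, 1000)), 5))$rank, 1)
  expect_error(build_design(list()), "nonempty")
})

test_that("rank-deficient or tiny training cohorts are rejected with the observed settings", {
  sim <- make_2x2_cohort(n_regions = 6, n_subjects = 4, seed = 8)
  two <- cohort_subset(sim$cohort, settings = hcp_settings_grid()[1:2])
  expect_error(fit_harmonization(two), "rank-deficient.*1.25")

  one <- cohort_subset(sim$cohort,
                       subjects = c("sub-001", "sub-002", "sub-003"),
                       settings = hcp_settings_grid()[1])
  expect_error(fit_harmonization(one), "rank-deficient|at least 4")
})

test_that("noiseless generative cohorts are recovered exactly", {
  sim <- make_2x2_cohort(n_regions = 12, n_subjects = 10, noise_sd = 0,
                         subject_sd = 3, integer_counts = FALSE, seed = 19)
  model <- fit_harmonization(sim$cohort)
  expect_lt(max(abs(model$betas[, c("beta1", "beta2", "beta3")] -
                      sim$truth$true_betas)), 1e-8)
  # intercepts absorb group means, reference offsets and mean subject effect
  ref <- sim$truth$config$reference_setting
  expected_b0 <- sim$truth$group_means + colMeans(sim$truth$subject_effects) -
    sim$truth$true_betas[, "beta1"] * ref$res -
    sim$truth$true_betas[, "beta2"] * ref$bval -
    sim$truth$true_betas[, "beta3"] * ref$res * ref$bval
  expect_equal(unname(model$betas[, "beta0"]), expected_b0, tolerance = 1e-7)
})

test_that("a cohort constant across settings fits zero acquisition effects", {
  m <- random_connectome_matrix(7)
  conns <- lapply(hcp_settings_grid(), function(st) connectome(m, "s1", setting = st))
  model <- fit_harmonization(cohort(conns))
  expect_equal(max(abs(model$betas[, c("beta1", "beta2", "beta3")])), 0,
               tolerance = 1e-9)
  expect_equal(unname(model$betas[, "beta0"]), vectorize(m), tolerance = 1e-9)
})

test_that("the correction formula, rounding and clamping apply in order", {
  # single-edge model with beta1 = 4, beta2 = 0.01, beta3 = 0
  idx <- upper_triangle_index(2)
  model <- structure(
    list(betas = matrix(c(0, 4, 0.01, 0), 1,
                        dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3"))),
         edge_index = idx,
         region_labels = c("region_001", "region_002"),
         training_settings = data.frame(res = c(1.25, 1.25, 2.3, 2.3),
                                        bval = c(1000, 3000, 1000, 3000),
                                        count = 1L),
         n_obs = 4L, resid_var = 0, rounding = "half-away-from-zero"),
    class = "harmonization_model")
  src <- acq_setting(2.3, 1000); tgt <- acq_setting(1.25, 3000)
  cn <- conn_from_edges(100, 2, res = 2.3, bval = 1000)
  h <- harmonize(cn, model, tgt)
  # 100 + 4 * (1.25 - 2.3) + 0.01 * 2000 = 115.8 -> 116
  expect_equal(vectorize(h), 116)
  expect_true(h$setting == tgt)
  expect_true(h$provenance$source_setting == src)

  # continuous mode keeps 115.8
  expect_equal(vectorize(harmonize(cn, model, tgt, integer_output = FALSE)),
               115.8, tolerance = 1e-12)

  # a correction of -10 on y = 3 rounds to -7 then clamps to 0
  model2 <- model
  model2$betas[1, ] <- c(0, 0, -10 / 2000, 0)
  expect_equal(vectorize(harmonize(conn_from_edges(3, 2, res = 2.3, bval = 1000),
                                   model2, acq_setting(2.3, 3000))), 0)
})

test_that("harmonizing to the source setting is the identity", {
  set.seed(23)
  sim <- make_2x2_cohort(n_regions = 10, n_subjects = 6, seed = 23)
  model <- fit_harmonization(sim$cohort)
  for (cn in sim$cohort$connectomes[c(1, 7, 20)]) {
    h <- harmonize(cn, model, cn$setting)
    expect_identical(h$matrix, cn$matrix)
  }
})

test_that("predictions are invariant under affine rescaling of the covariates", {
  sim <- make_2x2_cohort(n_regions = 10, n_subjects = 8, seed = 4)
  model <- fit_harmonization(sim$cohort)
  # remap (res, bval) -> (a res + b, c bval + d) everywhere and refit
  a <- 3.7; b <- -1.1; cc <- 0.004; d <- 2.5
  remap <- function(st) acq_setting(a * st$res + b, cc * st$bval + d)
  remapped <- cohort(lapply(unname(sim$cohort$connectomes), function(cn) {
    connectome(cn$matrix, cn$subject_id, cn$session, remap(cn$setting),
               cn$parcellation)
  }))
  model2 <- fit_harmonization(remapped)
  src <- acq_setting(2.3, 1000); tgt <- acq_setting(1.25, 3000)
  cn <- cohort_get(sim$cohort, "sub-002", src)
  cn2 <- cohort_get(remapped, "sub-002", remap(src))
  h1 <- harmonize(cn, model, tgt, integer_output = FALSE)
  h2 <- harmonize(cn2, model2, remap(tgt), integer_output = FALSE)
  expect_equal(vectorize(h1), vectorize(h2), tolerance = 1e-8)
})

test_that("continuous corrections are path-consistent; integer paths differ by at most 1", {
  sim <- make_2x2_cohort(n_regions = 10, n_subjects = 8, seed = 14)
  model <- fit_harmonization(sim$cohort)
  ap1 <- acq_setting(2.3, 1000); ap2 <- acq_setting(1.25, 1000)
  ap3 <- acq_setting(1.25, 3000)
  cn <- cohort_get(sim$cohort, "sub-003", ap1)
  via <- harmonize(harmonize(cn, model, ap2, integer_output = FALSE),
                   model, ap3, integer_output = FALSE)
  direct <- harmonize(cn, model, ap3, integer_output = FALSE)
  expect_equal(vectorize(via), vectorize(direct), tolerance = 1e-10)

  via_int <- harmonize(harmonize(cn, model, ap2), model, ap3)
  direct_int <- harmonize(cn, model, ap3)
  expect_lte(max(abs(vectorize(via_int) - vectorize(direct_int))), 1)
})

test_that("beta estimates are unbiased with RMSE shrinking as observations grow", {
  errs <- sapply(c(6, 24), function(n_subj) {
    per_seed <- sapply(1:25, function(s) {
      sim <- make_2x2_cohort(n_regions = 6, n_subjects = n_subj, noise_sd = 3,
                             subject_sd = 0, integer_counts = FALSE, seed = 100 + s)
      model <- fit_harmonization(sim$cohort)
      model$betas[, "beta2"] - sim$truth$true_betas[, "beta2"]
    })
    c(bias = mean(per_seed), rmse = sqrt(mean(per_seed^2)))
  })
  # bias indistinguishable from zero relative to the error spread
  expect_lt(abs(errs["bias", 1]), errs["rmse", 1])
  # quadrupling observations roughly halves the RMSE (sqrt scaling)
  expect_lt(errs["rmse", 2], errs["rmse", 1] / 1.5)
})

test_that("traveling and single-setting designs agree on noiseless group effects", {
  trav <- make_2x2_cohort(n_regions = 8, n_subjects = 8, noise_sd = 0,
                          subject_sd = 0, integer_counts = FALSE, seed = 55)
  single <- make_2x2_cohort(n_regions = 8, n_subjects = 8, noise_sd = 0,
                            subject_sd = 0, integer_counts = FALSE,
                            design = "single", seed = 55)
  m1 <- fit_harmonization(trav$cohort)
  m2 <- fit_harmonization(single$cohort)
  expect_equal(m1$betas, m2$betas, tolerance = 1e-8)
})

test_that("model files round-trip bit-exactly and reject malformed input", {
  sim <- make_2x2_cohort(n_regions = 4, n_subjects = 5, seed = 99)
  model <- fit_harmonization(sim$cohort)
  path <- withr::local_tempfile(fileext = ".tsv")
  save_model(model, path)

  # 4 regions -> 6 edge rows
  body <- readLines(path)
  expect_equal(sum(!startsWith(body, "#")) - 1L, 6L)

  back <- load_model(path)
  expect_identical(unname(back$betas), unname(model$betas))
  expect_equal(back$training_settings$count, model$training_settings$count)

  # identical predictions on a probe connectome
  probe <- cohort_get(sim$cohort, "sub-002", acq_setting(2.3, 1000))
  tgt <- acq_setting(1.25, 3000)
  expect_identical(harmonize(probe, back, tgt)$matrix,
                   harmonize(probe, model, tgt)$matrix)

  # dropping a beta column must fail
  broken <- gsub("\tbeta3", "", body[grep("^region_i", body)])
  lines <- body
  lines[grep("^region_i", body)] <- broken
  writeLines(lines, path)
  expect_error(load_model(path), "missing column")
})

test_that("targets outside the training hull warn about extrapolation", {
  sim <- make_2x2_cohort(n_regions = 6, n_subjects = 5, seed = 3)
  model <- fit_harmonization(sim$cohort)
  cn <- cohort_get(sim$cohort, "sub-001", acq_setting(2.3, 1000))
  expect_warning(harmonize(cn, model, acq_setting(2.3, 8000)), "extrapolat")
  expect_silent(harmonize(cn, model, acq_setting(2.0, 2000)))  # interior point
  expect_silent(harmonize(cn, model, acq_setting(1.25, 3000)))  # vertex
})
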