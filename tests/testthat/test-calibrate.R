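test_that("noise-free observations recover the generating parameters", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10),
    observation_design(times = c(24, 48, 96, 168, 240), cv = 0))
  fit <- fit_suv(synth$observations,
                 fit_spec(c("sigma_v", "CL_p"),
                          init = c(sigma_v = 0.90, CL_p = 0.08)),
                 s, dose_spec(10))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["sigma_v"]] - 0.97) / 0.97, 0.01)
  expect_lt(abs(fit$estimates[["CL_p"]] - 0.042) / 0.042, 0.01)
  expect_false(any(fit$non_identifiable))
  # the reported objective equals the recomputed weighted SSE
  expect_equal(fit$objective, sum(fit$residuals$weight^2 *
                                    fit$residuals$residual^2),
               tolerance = 1e-10)
})

test_that("a perfect initial guess yields an (almost) zero objective", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10), observation_design(times = c(48, 96), cv = 0))
  fit <- fit_suv(synth$observations,
                 fit_spec(c("sigma_v", "CL_p"),
                          init = c(sigma_v = 0.97, CL_p = 0.042)),
                 s, dose_spec(10))
  expect_lt(fit$objective, 1e-6)
})

test_that("the objective trace never increases across iterations", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10),
    observation_design(times = c(24, 96, 240), cv = 0.2, seed = 11))
  fit <- fit_suv(synth$observations,
                 fit_spec(c("sigma_v", "CL_p"),
                          init = c(sigma_v = 0.85, CL_p = 0.06)),
                 s, dose_spec(10))
  expect_true(all(diff(fit$rsstrace) <= 1e-8 * fit$rsstrace[1]))
})

test_that("node target and transit shape are flat from plasma-only data", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10),
    observation_design(times = c(24, 48, 96, 168, 240),
                       tissues = "plasma", cv = 0.05, seed = 3))
  fit <- fit_suv(synth$observations, fit_spec(c("R01", "R02", "dln")),
                 s, dose_spec(10))
  expect_true(fit$non_identifiable[["R02"]])
  expect_true(fit$non_identifiable[["dln"]])
})

test_that("estimates pinned at a bound are flagged", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10), observation_design(times = c(48, 96, 168), cv = 0))
  # force sigma_v into a box that excludes the truth
  fit <- fit_suv(synth$observations,
                 fit_spec("sigma_v", upper = c(sigma_v = 0.9),
                          init = c(sigma_v = 0.5)),
                 s, dose_spec(10))
  expect_true(fit$at_bounds[["sigma_v"]])
  # widening the box can only improve (or match) the objective
  fit2 <- fit_suv(synth$observations,
                  fit_spec("sigma_v", init = c(sigma_v = 0.5)),
                  s, dose_spec(10))
  expect_lte(fit2$objective, fit$objective + 1e-10)
})

test_that("fit specification is validated", {
  expect_error(fit_spec(character(0)), "no free parameters")
  expect_error(fit_spec("V_isf_pt"), "cannot fit")
  expect_error(fit_spec("sigma_v", lower = c(sigma_v = 2),
                        upper = c(sigma_v = 1)), "bounds")
})

test_that("multistart is deterministic for a fixed seed", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10),
    observation_design(times = c(48, 168), cv = 0.3, seed = 5))
  spec <- fit_spec(c("sigma_v", "CL_p"), n_start = 3, seed = 77)
  f1 <- fit_suv(synth$observations, spec, s, dose_spec(10))
  f2 <- fit_suv(synth$observations, spec, s, dose_spec(10))
  expect_identical(f1$estimates, f2$estimates)
})

test_that("observation CSV round-trips through the documented schema", {
  s <- get_study("bevacizumab_renal")
  synth <- generate_observations(
    s, dose_spec(10), observation_design(times = c(48, 96), cv = 0.1,
                                         seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(synth$observations, path)
  back <- read_observations(path)
  expect_equal(back$suv, synth$observations$suv, tolerance = 1e-12)
  expect_named(back, c("study_id", "tissue", "time_h", "suv", "sd"))
})
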