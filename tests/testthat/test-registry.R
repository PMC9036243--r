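# Snapshot lock of the eleven registered antibody:tumor parameterizations.
.registry_snapshot <- data.frame(
  study_id = c("fresolimumab_gbm", "bevacizumab_nsclc", "bevacizumab_breast",
               "bevacizumab_renal", "trastuzumab_breast",
               "trastuzumab_esophagogastric", "mmot0530a_pancreatic",
               "mmot0530a_ovarian", "atezolizumab_nsclc",
               "atezolizumab_breast", "atezolizumab_bladder"),
  sigma_v = c(0.94, 0.85, 0.95, 0.97, 0.65, 0.95, 0.87, 0.95, 0.80, 0.90,
              0.86),
  L_organ = c(0.05, 0.012, 0.008, 0.082, 0.008, 0.007, 0.004, 0.004,
              0.012, 0.008, 0.001),
  V_isf_pt = c(0.265, 0.175, 0.112, 0.060, 0.112, 0.005, 0.029, 0.001,
               0.175, 0.112, 0.0084),
  V_p = c(5, 5, 5, 5, 5, 7, 5, 5, 5, 5, 5),
  R01 = c(1, 10, 1, 10, 100, 30, 1000, 24, 7, 1, 11),
  R02 = c(1, 10, 1.5, 2.5, 100, 30, 1000, 24, 7, 2.5, 11),
  Kd = c(1.7, 0.058, 0.058, 0.058, 5, 5, 0.5, 0.5, 0.43, 0.43, 0.43),
  Kd_FcRn = c(2400, 2400, 2400, 2400, 774, 774, 2400, 2400, 2400, 2400,
              2400),
  dln = c(19, 21, 20, 21, 61, 63, 21, 24, 21, 20, 24),
  CL_p = c(0.075, 0.07, 0.06, 0.042, 0.063, 0.0288, 0.033, 0.033, 0.0083,
           0.0083, 0.0083),
  stringsAsFactors = FALSE
)

test_that("registry holds exactly the eleven studies with locked values", {
  expect_length(study_ids(), 11)
  tab <- study_table()
  expect_setequal(tab$study_id, .registry_snapshot$study_id)
  m <- match(.registry_snapshot$study_id, tab$study_id)
  for (col in setdiff(names(.registry_snapshot), "study_id")) {
    expect_equal(tab[[col]][m], .registry_snapshot[[col]],
                 info = col, tolerance = 0)
  }
})

test_that("every study carries the shared constants", {
  for (id in study_ids()) {
    s <- get_study(id)
    p <- s$physiology
    expect_identical(p$sigma_l, 0.2)
    expect_identical(p$L_aff, 0.004)
    expect_identical(p$L_eff, 0.004)
    expect_identical(p$V_isf_tdln, 5.84e-5)
    expect_identical(p$sigma_v_tdln, 1)
    expect_identical(s$target$k_deg, 0.01)
    expect_identical(s$target$k_int, 0.01)
    expect_identical(s$transit$FcRn_conc, 40000)
    # with no antibody the baseline target level is a turnover fixed point
    expect_equal(s$target$k_syn_pt, 0.01 * s$target$R01)
    expect_equal(s$target$k_syn_tdln, 0.01 * s$target$R02)
  }
})

test_that("example studies round-trip to their published rows", {
  s <- get_study("bevacizumab_renal")
  expect_equal(get_study_param(s, "sigma_v"), 0.97)
  expect_equal(get_study_param(s, "L_organ"), 0.082)
  expect_equal(s$physiology$V_isf_pt, 0.060)
  expect_equal(get_study_param(s, "R01"), 10)
  expect_equal(get_study_param(s, "R02"), 2.5)
  expect_equal(get_study_param(s, "Kd"), 0.058)
  expect_equal(get_study_param(s, "dln"), 21)
  expect_equal(get_study_param(s, "CL_p"), 0.042)

  s2 <- get_study("trastuzumab_esophagogastric")
  expect_equal(s2$physiology$V_p, 7.0)
  expect_equal(get_study_param(s2, "Kd_FcRn"), 774)
  expect_equal(get_study_param(s2, "dln"), 63)

  s3 <- get_study("atezolizumab_breast")
  expect_equal(get_study_param(s3, "R01"), 1)
  expect_equal(get_study_param(s3, "R02"), 2.5)
  expect_equal(get_study_param(s3, "CL_p"), 0.0083)
})

test_that("unknown ids fail with the list of valid ids", {
  expect_error(get_study("nivolumab_melanoma"), "bevacizumab_renal")
})

test_that("footnote derivation rules reproduce the registered values", {
  expect_equal(derive_lymph_flow(41.0), 0.082)
  expect_equal(derive_lymph_flow(6.0), 0.012)
  expect_error(derive_lymph_flow(0), "range")
  expect_equal(derive_isf_volume(0.000292), 5.84e-5)
  expect_equal(derive_isf_volume(0.30), 0.060)
  expect_equal(derive_isf_volume(1, fraction = 0.5), 0.5)
  expect_error(derive_isf_volume(1, fraction = 1), "range")
})

test_that("study parameter sets survive a JSON round trip", {
  s <- get_study("bevacizumab_renal")
  path <- withr::local_tempfile(fileext = ".json")
  study_to_json(s, path)
  s2 <- study_from_json(path)
  expect_equal(unclass(s2$physiology), unclass(s$physiology))
  expect_equal(unclass(s2$target), unclass(s$target))
  expect_equal(unclass(s2$transit), unclass(s$transit))
  expect_identical(s2$study_id, s$study_id)
})

test_that("set_study_param revalidates and keeps derived rates in step", {
  s <- get_study("bevacizumab_renal")
  s2 <- set_study_param(s, "k_deg", 0.02)
  expect_equal(s2$target$k_syn_pt, 0.02 * 10)
  expect_error(set_study_param(s, "sigma_v", 1.2), "range")
  expect_error(set_study_param(s, "nonsense", 1), "unknown parameter")
})
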