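test_that("surgery zeroes the tumor target and scales local lymph flows", {
  s <- get_study("bevacizumab_renal")
  post <- apply_surgery(s, 0.5)
  expect_equal(get_study_param(post, "R01"), 0)
  expect_equal(get_study_param(post, "L_organ"), 0.041)
  expect_equal(get_study_param(post, "L_aff"), 0.002)
  none <- apply_surgery(s, 0)
  expect_equal(get_study_param(none, "R01"), 0)
  expect_equal(get_study_param(none, "L_organ"), 0.082)
  expect_error(apply_surgery(s, 1), "range")
  expect_error(apply_surgery(s, -0.1), "range")
})

test_that("TDLN exposure decreases with the severity of lymphedema", {
  s <- get_study("bevacizumab_renal")
  aucs <- vapply(c(0, 0.25, 0.5, 0.8, 0.9), function(r) {
    traj <- simulate_model(apply_surgery(s, r), dose_spec(10),
                           seq(0, 336, by = 4))
    summarize_gradient(traj)$auc_tdln
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("metastasis chains share plasma but keep their own parameters", {
  s <- get_study("atezolizumab_bladder")
  # lung metastasis takes the lung row's physiology
  lung <- study_table()[study_table()$study_id == "atezolizumab_nsclc", ]
  met <- lesion_spec("met_lung", R01 = 11, R02 = 11,
                     sigma_v = lung$sigma_v, L_organ = lung$L_organ,
                     V_isf = lung$V_isf_pt)
  net <- build_metastasis_model(s, met)
  expect_length(net$lesions, 2)
  expect_equal(net$lesions[[2]]$sigma_v, 0.80)
  traj <- simulate_model(net, dose_spec(10), seq(0, 168, by = 4))
  expect_setequal(unique(traj$tissue),
                  c("plasma", "PT", "TDLN", "met_lung", "met_lung_TDLN"))
  expect_error(build_metastasis_model(s, lesion_spec("PT", 1, 1)),
               "duplicate")
})

test_that("high metastatic target density starves the metastasis TDLN", {
  s <- get_study("bevacizumab_renal")
  equal <- build_metastasis_model(s, lesion_spec("met", R01 = 2.5,
                                                 R02 = 2.5))
  high <- build_metastasis_model(s, lesion_spec("met", R01 = 25,
                                                R02 = 2.5))
  t_eq <- simulate_model(equal, dose_spec(10), seq(0, 336, by = 4))
  t_hi <- simulate_model(high, dose_spec(10), seq(0, 336, by = 4))
  expect_lt(tissue_auc(t_hi, "met_TDLN"), tissue_auc(t_eq, "met_TDLN"))
})

test_that("two identical lesions produce identical trajectories", {
  s <- get_study("bevacizumab_renal")
  p <- s$physiology
  twin <- lesion_spec("twin", R01 = 10, R02 = 2.5)
  net <- build_metastasis_model(s, twin)
  traj <- simulate_model(net, dose_spec(10), seq(0, 168, by = 4))
  expect_equal(traj$conc_nM[traj$tissue == "twin"],
               traj$conc_nM[traj$tissue == "PT"], tolerance = 1e-10)
  expect_equal(traj$conc_nM[traj$tissue == "twin_TDLN"],
               traj$conc_nM[traj$tissue == "TDLN"], tolerance = 1e-10)
})

test_that("a target-free metastasis behaves as a linear organ compartment", {
  s <- get_study("bevacizumab_renal")
  net <- build_metastasis_model(s, lesion_spec("met", R01 = 0, R02 = 0))
  traj <- simulate_model(net, dose_spec(10), seq(0, 168, by = 4))
  sol <- attr(traj, "state")
  expect_lt(max(abs(sol[, "met.Rtot"])), 1e-12)
  # the met lesion sees the same plasma as PT but binds nothing
  expect_true(all(traj$conc_nM[traj$tissue == "met"] <=
                    traj$conc_nM[traj$tissue == "PT"] + 1e-9))
})

test_that("single-lesion simulation is unchanged by the network detour", {
  s <- get_study("bevacizumab_renal")
  t_study <- simulate_model(s, dose_spec(10), seq(0, 168, by = 4))
  t_net <- simulate_model(as_network(s), dose_spec(10), seq(0, 168, by = 4))
  expect_identical(t_study$conc_nM, t_net$conc_nM)
})

test_that("inflammation routes antibody to peritumoral branches", {
  s <- get_study("bevacizumab_renal")
  net <- apply_inflammation(s, list(
    tdln_branch_spec("TDLN_intra", "intratumoral", "positive"),
    tdln_branch_spec("TDLN_peri", "peritumoral", "positive")))
  traj <- simulate_model(net, dose_spec(10), seq(0, 336, by = 4))
  intra <- traj$conc_nM[traj$tissue == "TDLN_intra"]
  peri <- traj$conc_nM[traj$tissue == "TDLN_peri"]
  expect_true(all(peri[-1] > intra[-1]))
  expect_error(apply_inflammation(s, list(
    tdln_branch_spec("a", "intratumoral", L_aff_mult = 0),
    tdln_branch_spec("b", "intratumoral", L_aff_mult = 0))),
    "no drainage")
  expect_error(apply_inflammation(s, list(tdln_branch_spec("a"))),
               "length")
})

test_that("equal branches are symmetric; node target shifts the species", {
  s <- get_study("bevacizumab_renal")
  net <- apply_inflammation(s, list(
    tdln_branch_spec("b1", "peritumoral", "positive", L_aff_mult = 1),
    tdln_branch_spec("b2", "peritumoral", "positive", L_aff_mult = 1)))
  traj <- simulate_model(net, dose_spec(10), seq(0, 168, by = 4))
  expect_equal(traj$conc_nM[traj$tissue == "b1"],
               traj$conc_nM[traj$tissue == "b2"], tolerance = 1e-10)

  # tumor-positive vs tumor-negative at equal flow: more total antibody
  # held in the positive node, but less of it free
  net2 <- apply_inflammation(s, list(
    tdln_branch_spec("pos", "peritumoral", "positive", L_aff_mult = 1),
    tdln_branch_spec("neg", "peritumoral", "negative", L_aff_mult = 1)))
  traj2 <- simulate_model(net2, dose_spec(10), seq(0, 336, by = 4))
  sol <- attr(traj2, "state")
  Kd <- get_study_param(s, "Kd")
  free_auc <- function(lbl) {
    b <- quasi_equilibrium_bind(pmax(sol[, paste0(lbl, ".Ctot")], 0),
                                pmax(sol[, paste0(lbl, ".Rtot")], 0), Kd)
    sum(diff(sol[, "time"]) * (utils::head(b$Cf, -1) + b$Cf[-1]) / 2)
  }
  expect_gt(tissue_auc(traj2, "pos"), tissue_auc(traj2, "neg"))
  expect_lt(free_auc("pos"), free_auc("neg"))
})

test_that("branch influx splitting conserves total antibody", {
  s <- conservative_variant(get_study("bevacizumab_renal"))
  net <- apply_inflammation(s, list(
    tdln_branch_spec("b1", "peritumoral", "negative", L_aff_mult = 0.5),
    tdln_branch_spec("b2", "peritumoral", "negative", L_aff_mult = 1.5)))
  traj <- simulate_model(net, dose_spec(10), seq(0, 336, by = 12))
  amt <- total_antibody_amount(traj, net)
  expect_lt(max(abs(amt - amt[1])) / amt[1], 1e-6)
})
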