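# Shared oracles and fixtures, built in code at test time.

# Explicit-kinetics (non-quasi-equilibrium) single-chain model: free
# antibody, complex and free target tracked separately with mass-action
# binding at rate k_on, k_off = k_on * Kd. Independent of the package's
# RHS; used to validate the quasi-equilibrium assumption.
simulate_kinetic_oracle <- function(study, dose, times, k_on = 100,
                                    rtol = 1e-8, atol = 1e-10) {
  p <- study$physiology
  tg <- study$target
  surv <- transit_survival(study$transit)
  k_off <- k_on * tg$Kd
  in1 <- p$L_organ * (1 - p$sigma_v_pt)
  out1 <- p$L_aff * (1 - p$sigma_l)
  tin <- p$L_tissue * (1 - p$sigma_v_tissue)
  tout <- p$L_tissue * (1 - p$sigma_l)
  rhs <- function(t, y, parms) {
    Cp <- y[1]; Ct <- y[2]
    Cf1 <- y[3]; Cb1 <- y[4]; Rf1 <- y[5]
    Cf2 <- y[6]; Cb2 <- y[7]; Rf2 <- y[8]
    bind1 <- k_on * Cf1 * Rf1 - k_off * Cb1
    bind2 <- k_on * Cf2 * Rf2 - k_off * Cb2
    c1 <- (-p$CL_p * Cp - in1 * Cp - tin * Cp + p$L_eff * Cf2 +
             tout * Ct) / p$V_p
    c2 <- (tin * Cp - tout * Ct) / p$V_isf_tissue
    list(c(c1, c2,
           (in1 * Cp - out1 * Cf1) / p$V_isf_pt - bind1,
           bind1 - tg$k_int * Cb1,
           tg$k_syn_pt - tg$k_deg * Rf1 - bind1,
           (out1 * surv * Cf1 - p$L_eff * Cf2) / p$V_isf_tdln - bind2,
           bind2 - tg$k_int * Cb2,
           tg$k_syn_tdln - tg$k_deg * Rf2 - bind2))
  }
  y0 <- c(dose_to_conc(dose, p$V_p), 0, 0, 0, tg$R01, 0, 0, tg$R02)
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
  list(times = sol[, 1], C_p = sol[, 2],
       Ctot_pt = sol[, 4] + sol[, 5], Rtot_pt = sol[, 5] + sol[, 6],
       Ctot_tdln = sol[, 7] + sol[, 8])
}

# total antibody amount (nmol) along a simulated trajectory
total_antibody_amount <- function(traj, net) {
  sol <- attr(traj, "state")
  V <- c(net$V_p, net$V_isf_tissue)
  nm <- c("C_p", "C_tissue")
  for (les in net$lesions) {
    V <- c(V, les$V_isf); nm <- c(nm, paste0(les$label, ".Ctot"))
    for (br in les$branches) {
      V <- c(V, br$V_isf); nm <- c(nm, paste0(br$label, ".Ctot"))
    }
  }
  as.numeric(sol[, nm, drop = FALSE] %*% V)
}

# study variant with elimination, targets and transit loss switched off
conservative_variant <- function(study) {
  for (nm in c("CL_p", "k_int", "R01", "R02")) {
    study <- set_study_param(study, nm, 0)
  }
  tr <- unclass(study$transit)
  tr$uptake_prob <- 0
  study$transit <- do.call(transit_params, tr)
  study
}

tissue_auc <- function(traj, tissue, column = "conc_nM") {
  d <- traj[traj$tissue == tissue, ]
  sum(diff(d$time_h) * (utils::head(d[[column]], -1) + d[[column]][-1]) / 2)
}
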