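#' @keywords internal
"_PACKAGE"

# -- validation helpers --------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a single finite number", name)
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("'%s' = %g outside valid range %s%g, %g%s", name, x,
                 if (allow_lower) "[" else "(", lower, upper,
                 if (allow_upper) "]" else ")")
  }
  as.numeric(x)
}

# -- physiology ----------------------------------------------------------

#' Organ and flow physiology for one tumor / TDLN chain
#'
#' Bundles the convective-transport constants of the minimal PBPK network:
#' plasma volume and clearance, the vascular and lymphatic reflection
#' coefficients, organ lymph flow feeding the primary tumor (PT), afferent
#' and efferent lymph flows of the tumor-draining lymph node (TDLN), the
#' interstitial fluid (ISF) volumes, and the lumped non-tumor tissue
#' compartment. Convection across a barrier with reflection coefficient
#' sigma carries solute at the effective clearance `(1 - sigma) * flow`.
#'
#' The TDLN vascular reflection coefficient defaults to 1: high endothelial
#' venules are assumed impermeable to antibody, so the only route into the
#' node is the afferent lymph.
#'
#' @param sigma_v_pt Vascular reflection coefficient of the PT (0-1).
#' @param L_organ Organ lymph flow feeding the PT, L/h.
#' @param V_isf_pt PT interstitial fluid volume, L.
#' @param V_p Plasma volume, L.
#' @param CL_p Plasma clearance, L/h.
#' @param sigma_v_tdln Vascular reflection coefficient of the TDLN; fixed
#'   at 1 in every base configuration.
#' @param sigma_l Lymphatic reflection coefficient (shared), default 0.2.
#' @param L_aff Afferent lymph flow PT to TDLN, L/h; default 0.004. May be
#'   zero (compressed intratumoral lymphatics).
#' @param L_eff Efferent lymph flow TDLN to plasma, L/h; default 0.004.
#' @param V_isf_tdln TDLN interstitial fluid volume, L; default 5.84e-5
#'   (20\% of an average node volume).
#' @param L_tissue Lumped non-tumor tissue lymph flow, L/h.
#' @param sigma_v_tissue Vascular reflection coefficient of lumped tissue.
#' @param V_isf_tissue Lumped tissue ISF volume, L.
#' @return An object of class `physiology_params`.
#' @export
physiology_params <- function(sigma_v_pt, L_organ, V_isf_pt, V_p, CL_p,
                              sigma_v_tdln = 1, sigma_l = 0.2,
                              L_aff = 0.004, L_eff = 0.004,
                              V_isf_tdln = 5.84e-5,
                              L_tissue = 0.12, sigma_v_tissue = 0.95,
                              V_isf_tissue = 8.4) {
  out <- list(
    sigma_v_pt     = check_scalar(sigma_v_pt, "sigma_v_pt", 0, 1),
    sigma_v_tdln   = check_scalar(sigma_v_tdln, "sigma_v_tdln", 0, 1),
    sigma_l        = check_scalar(sigma_l, "sigma_l", 0, 1),
    L_organ        = check_scalar(L_organ, "L_organ", 0, allow_lower = FALSE),
    L_aff          = check_scalar(L_aff, "L_aff", 0),
    L_eff          = check_scalar(L_eff, "L_eff", 0, allow_lower = FALSE),
    V_p            = check_scalar(V_p, "V_p", 0, allow_lower = FALSE),
    V_isf_pt       = check_scalar(V_isf_pt, "V_isf_pt", 0, allow_lower = FALSE),
    V_isf_tdln     = check_scalar(V_isf_tdln, "V_isf_tdln", 0, allow_lower = FALSE),
    L_tissue       = check_scalar(L_tissue, "L_tissue", 0),
    sigma_v_tissue = check_scalar(sigma_v_tissue, "sigma_v_tissue", 0, 1),
    V_isf_tissue   = check_scalar(V_isf_tissue, "V_isf_tissue", 0, allow_lower = FALSE),
    # CL_p = 0 is admitted for diagnostic (mass-balance) configurations
    CL_p           = check_scalar(CL_p, "CL_p", 0)
  )
  structure(out, class = "physiology_params")
}

# -- target --------------------------------------------------------------

#' Target binding and turnover parameters
#'
#' Baseline target concentrations in the primary tumor (`R01`) and TDLN
#' (`R02`), the antibody-target dissociation constant `Kd`, and the
#' first-order turnover constants. Target synthesis rates are derived as
#' `k_syn = k_deg * R0` so that with no antibody the baseline level is a
#' fixed point of the turnover equations.
#'
#' @param R01,R02 Baseline target concentration in PT / TDLN, nM (>= 0).
#' @param Kd Antibody-target dissociation constant, nM (> 0).
#' @param k_deg First-order degradation rate of free target, 1/h.
#' @param k_int Internalization rate of the antibody-target complex, 1/h.
#' @return An object of class `target_params` with derived fields
#'   `k_syn_pt` and `k_syn_tdln` (nM/h).
#' @export
target_params <- function(R01, R02, Kd, k_deg = 0.01, k_int = 0.01) {
  out <- list(
    R01   = check_scalar(R01, "R01", 0),
    R02   = check_scalar(R02, "R02", 0),
    Kd    = check_scalar(Kd, "Kd", 0, allow_lower = FALSE),
    k_deg = check_scalar(k_deg, "k_deg", 0),
    k_int = check_scalar(k_int, "k_int", 0)
  )
  out$k_syn_pt <- out$k_deg * out$R01
  out$k_syn_tdln <- out$k_deg * out$R02
  structure(out, class = "target_params")
}

# -- lymphatic transit ---------------------------------------------------

#' Lymphatic transit and FcRn salvage parameters
#'
#' Antibody trafficking along the lymphatic vessels from the tumor to its
#' draining node is subject to nonspecific pinocytosis by lymphatic
#' endothelial cells; pinocytosed antibody bound by FcRn is salvaged and
#' continues downstream, the rest is degraded. `dln` is an organ-specific
#' shape factor describing the effective length of the lymphatic path:
#' larger `dln` means less cumulative loss in transit.
#'
#' @param dln Dimensionless shape factor (> 0); registry values span 19-63.
#' @param Kd_FcRn Antibody-FcRn dissociation constant, nM (> 0).
#' @param FcRn_conc FcRn concentration in endothelial cells, nM;
#'   default 40000 (40 uM).
#' @param uptake_prob Per-event pinocytosis probability in [0, 1);
#'   default 0.1 (0 disables transit loss entirely).
#' @param n_ref Reference number of transit loss events (> 0); default 100.
#'   The exponent of the survival law is `n_ref / dln`.
#' @param strategy Name of the registered survival strategy;
#'   default `"power_shape"`. See [transit_survival()].
#' @return An object of class `transit_params`.
#' @export
transit_params <- function(dln, Kd_FcRn, FcRn_conc = 40000,
                           uptake_prob = 0.1, n_ref = 100,
                           strategy = "power_shape") {
  if (!is.character(strategy) || length(strategy) != 1L) {
    stop_invalid("'strategy' must be a single string")
  }
  out <- list(
    dln         = check_scalar(dln, "dln", 0, allow_lower = FALSE),
    Kd_FcRn     = check_scalar(Kd_FcRn, "Kd_FcRn", 0, allow_lower = FALSE),
    FcRn_conc   = check_scalar(FcRn_conc, "FcRn_conc", 0, allow_lower = FALSE),
    uptake_prob = check_scalar(uptake_prob, "uptake_prob", 0, 1,
                               allow_upper = FALSE),
    n_ref       = check_scalar(n_ref, "n_ref", 0, allow_lower = FALSE),
    strategy    = strategy
  )
  structure(out, class = "transit_params")
}

# -- study parameter set -------------------------------------------------

#' Assemble a full study parameterization
#'
#' @param study_id Short slug, e.g. `"bevacizumab_renal"`.
#' @param antibody,tumor Human-readable antibody and tumor names.
#' @param physiology A [physiology_params()] object.
#' @param target A [target_params()] object.
#' @param transit A [transit_params()] object.
#' @param source Citation string for the calibration data.
#' @return An object of class `study_params`.
#' @export
study_params <- function(study_id, antibody, tumor, physiology, target,
                         transit, source = "") {
  stopifnot(inherits(physiology, "physiology_params"),
            inherits(target, "target_params"),
            inherits(transit, "transit_params"))
  structure(list(study_id = as.character(study_id),
                 antibody = as.character(antibody),
                 tumor = as.character(tumor),
                 physiology = physiology, target = target,
                 transit = transit, source = as.character(source)),
            class = "study_params")
}

#' @export
print.study_params <- function(x, ...) {
  cat(sprintf("<study_params> %s  (%s in %s)\n", x$study_id, x$antibody,
              x$tumor))
  p <- x$physiology; tg <- x$target; tr <- x$transit
  cat(sprintf("  sigma_v = %.2f | L_organ = %g L/h | V_ISF,PT = %g L | V_p = %g L\n",
              p$sigma_v_pt, p$L_organ, p$V_isf_pt, p$V_p))
  cat(sprintf("  R01 = %g nM | R02 = %g nM | Kd = %g nM | Kd,FcRn = %g nM\n",
              tg$R01, tg$R02, tg$Kd, tr$Kd_FcRn))
  cat(sprintf("  dln = %g | CL_p = %g L/h\n", tr$dln, p$CL_p))
  invisible(x)
}

# named scalar access used by calibration and sensitivity sweeps ---------

.param_slots <- list(
  sigma_v   = c("physiology", "sigma_v_pt"),
  sigma_l   = c("physiology", "sigma_l"),
  L_organ   = c("physiology", "L_organ"),
  L_aff     = c("physiology", "L_aff"),
  L_eff     = c("physiology", "L_eff"),
  CL_p      = c("physiology", "CL_p"),
  V_p       = c("physiology", "V_p"),
  R01       = c("target", "R01"),
  R02       = c("target", "R02"),
  Kd        = c("target", "Kd"),
  k_deg     = c("target", "k_deg"),
  k_int     = c("target", "k_int"),
  dln       = c("transit", "dln"),
  Kd_FcRn   = c("transit", "Kd_FcRn")
)

#' Read a named scalar parameter from a study set
#' @param study A `study_params` object.
#' @param name One of the names listed in `names(tdlnpk:::.param_slots)`,
#'   e.g. `"sigma_v"`, `"CL_p"`, `"R01"`, `"dln"`.
#' @return The numeric value.
#' @export
get_study_param <- function(study, name) {
  slot <- .param_slots[[name]]
  if (is.null(slot)) {
    stop_invalid("unknown parameter '%s'; valid: %s", name,
                 paste(names(.param_slots), collapse = ", "))
  }
  study[[slot[1]]][[slot[2]]]
}

#' Return a copy of a study set with one scalar parameter replaced
#'
#' Re-runs the component constructor so invariants are revalidated and
#' derived quantities (target synthesis rates) stay consistent.
#'
#' @inheritParams get_study_param
#' @param value New numeric value.
#' @return A modified `study_params` object.
#' @export
set_study_param <- function(study, name, value) {
  slot <- .param_slots[[name]]
  if (is.null(slot)) {
    stop_invalid("unknown parameter '%s'; valid: %s", name,
                 paste(names(.param_slots), collapse = ", "))
  }
  comp <- unclass(study[[slot[1]]])
  comp[[slot[2]]] <- value
  study[[slot[1]]] <- switch(slot[1],
    physiology = do.call(physiology_params, comp),
    target = do.call(target_params,
                     comp[c("R01", "R02", "Kd", "k_deg", "k_int")]),
    transit = do.call(transit_params, comp))
  study
}
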