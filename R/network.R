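# The general simulation container: a plasma compartment, a lumped
# non-tumor tissue compartment, and any number of lesion chains. Each
# lesion is a tumor interstitium attached to plasma by convective
# extravasation and drained by one or more TDLN branches; each branch has
# its own afferent flow, transit survival and node target density. The
# single-study case is one lesion ("PT") with one branch ("TDLN").

#' Describe one TDLN branch draining a lesion
#'
#' @param label Branch label (unique within the network).
#' @param L_aff Afferent lymph flow into this branch, L/h (>= 0).
#' @param L_eff Efferent lymph flow back to plasma, L/h (> 0).
#' @param V_isf TDLN interstitial fluid volume, L.
#' @param R02 Baseline target concentration in the node, nM (>= 0).
#' @param transit A [transit_params()] object for this branch's lymphatic
#'   path.
#' @return A `tdln_branch` list.
#' @export
tdln_branch <- function(label, L_aff, L_eff, V_isf, R02, transit) {
  stopifnot(inherits(transit, "transit_params"))
  structure(list(
    label  = as.character(label),
    L_aff  = check_scalar(L_aff, "L_aff", 0),
    L_eff  = check_scalar(L_eff, "L_eff", 0, allow_lower = FALSE),
    V_isf  = check_scalar(V_isf, "V_isf", 0, allow_lower = FALSE),
    R02    = check_scalar(R02, "R02", 0),
    transit = transit
  ), class = "tdln_branch")
}

#' Describe one lesion (primary tumor or metastasis) and its drainage
#'
#' @param label Lesion label (unique within the network).
#' @param sigma_v Vascular reflection coefficient of the lesion.
#' @param L_organ Organ lymph flow feeding the lesion, L/h.
#' @param V_isf Lesion interstitial fluid volume, L.
#' @param R01 Baseline target concentration in the lesion, nM.
#' @param Kd Antibody-target dissociation constant, nM.
#' @param k_deg,k_int Target turnover constants, 1/h.
#' @param branches List of [tdln_branch()] objects (>= 1).
#' @param role `"primary"` or `"metastasis"`.
#' @return A `lesion_node` list.
#' @export
lesion_node <- function(label, sigma_v, L_organ, V_isf, R01, Kd,
                        branches, k_deg = 0.01, k_int = 0.01,
                        role = c("primary", "metastasis")) {
  role <- match.arg(role)
  stopifnot(length(branches) >= 1L,
            all(vapply(branches, inherits, logical(1), "tdln_branch")))
  structure(list(
    label   = as.character(label),
    role    = role,
    sigma_v = check_scalar(sigma_v, "sigma_v", 0, 1),
    L_organ = check_scalar(L_organ, "L_organ", 0, allow_lower = FALSE),
    V_isf   = check_scalar(V_isf, "V_isf", 0, allow_lower = FALSE),
    R01     = check_scalar(R01, "R01", 0),
    Kd      = check_scalar(Kd, "Kd", 0, allow_lower = FALSE),
    k_deg   = check_scalar(k_deg, "k_deg", 0),
    k_int   = check_scalar(k_int, "k_int", 0),
    branches = branches
  ), class = "lesion_node")
}

#' Assemble a PBPK network
#'
#' @param V_p Plasma volume, L.
#' @param CL_p Plasma clearance, L/h.
#' @param sigma_l Lymphatic reflection coefficient shared by all vessels.
#' @param lesions List of [lesion_node()] objects.
#' @param L_tissue,sigma_v_tissue,V_isf_tissue Lumped non-tumor tissue
#'   compartment constants.
#' @param label Network label carried into trajectory output.
#' @return An object of class `pbpk_network`.
#' @export
pbpk_network <- function(V_p, CL_p, sigma_l, lesions,
                         L_tissue = 0.12, sigma_v_tissue = 0.95,
                         V_isf_tissue = 8.4, label = "network") {
  stopifnot(length(lesions) >= 1L,
            all(vapply(lesions, inherits, logical(1), "lesion_node")))
  labels <- c(vapply(lesions, `[[`, character(1), "label"),
              unlist(lapply(lesions, function(l)
                vapply(l$branches, `[[`, character(1), "label"))))
  if (anyDuplicated(labels)) {
    stop_invalid("duplicate compartment labels: %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(
    V_p      = check_scalar(V_p, "V_p", 0, allow_lower = FALSE),
    CL_p     = check_scalar(CL_p, "CL_p", 0),
    sigma_l  = check_scalar(sigma_l, "sigma_l", 0, 1),
    L_tissue = check_scalar(L_tissue, "L_tissue", 0),
    sigma_v_tissue = check_scalar(sigma_v_tissue, "sigma_v_tissue", 0, 1),
    V_isf_tissue   = check_scalar(V_isf_tissue, "V_isf_tissue", 0,
                                  allow_lower = FALSE),
    lesions  = lesions,
    label    = as.character(label)
  ), class = "pbpk_network")
}

#' Convert a study parameter set to its single-lesion network
#'
#' @param x A `study_params` object (or already a `pbpk_network`, returned
#'   unchanged).
#' @param ... Unused.
#' @return A `pbpk_network` with one lesion labelled `"PT"` draining into
#'   one branch labelled `"TDLN"`.
#' @export
as_network <- function(x, ...) UseMethod("as_network")

#' @export
as_network.pbpk_network <- function(x, ...) x

#' @export
as_network.study_params <- function(x, ...) {
  p <- x$physiology; tg <- x$target
  br <- tdln_branch("TDLN", L_aff = p$L_aff, L_eff = p$L_eff,
                    V_isf = p$V_isf_tdln, R02 = tg$R02,
                    transit = x$transit)
  les <- lesion_node("PT", sigma_v = p$sigma_v_pt, L_organ = p$L_organ,
                     V_isf = p$V_isf_pt, R01 = tg$R01, Kd = tg$Kd,
                     branches = list(br), k_deg = tg$k_deg,
                     k_int = tg$k_int, role = "primary")
  pbpk_network(V_p = p$V_p, CL_p = p$CL_p, sigma_l = p$sigma_l,
               lesions = list(les), L_tissue = p$L_tissue,
               sigma_v_tissue = p$sigma_v_tissue,
               V_isf_tissue = p$V_isf_tissue, label = x$study_id)
}

# -- state layout --------------------------------------------------------
# [C_p, C_tissue, then per lesion (Ctot, Rtot), then its branches'
# (Ctot, Rtot) in declaration order]. All entries are concentrations (nM)
# in the respective fluid volume.

network_state_names <- function(net) {
  nm <- c("C_p", "C_tissue")
  for (les in net$lesions) {
    nm <- c(nm, paste0(les$label, c(".Ctot", ".Rtot")))
    for (br in les$branches) {
      nm <- c(nm, paste0(br$label, c(".Ctot", ".Rtot")))
    }
  }
  nm
}

network_initial_state <- function(net, C_p0 = 0) {
  st <- c(C_p0, 0)
  for (les in net$lesions) {
    st <- c(st, 0, les$R01)
    for (br in les$branches) st <- c(st, 0, br$R02)
  }
  names(st) <- network_state_names(net)
  st
}

# Build a fast RHS closure. Transit survival and all composite clearances
# are precomputed; the closure touches only the state vector.
network_rhs <- function(net) {
  n_les <- length(net$lesions)
  # flat per-lesion constants
  les_in   <- numeric(n_les)   # L_organ * (1 - sigma_v), L/h
  les_V    <- numeric(n_les)
  les_Kd   <- numeric(n_les)
  les_kdeg <- numeric(n_les)
  les_kint <- numeric(n_les)
  les_ksyn <- numeric(n_les)
  les_idx  <- integer(n_les)   # index of lesion Ctot in state
  br_les   <- integer(0)       # owning lesion of each branch
  br_out   <- numeric(0)       # L_aff * (1 - sigma_l), L/h (drain from lesion)
  br_in    <- numeric(0)       # same times transit survival (into branch)
  br_eff   <- numeric(0)       # L_eff, L/h
  br_V     <- numeric(0)
  br_kdeg  <- numeric(0)
  br_ksyn  <- numeric(0)
  br_kint  <- numeric(0)
  br_Kd    <- numeric(0)
  br_idx   <- integer(0)
  one_m_sl <- 1 - net$sigma_l
  pos <- 2L
  for (i in seq_len(n_les)) {
    les <- net$lesions[[i]]
    les_in[i]   <- les$L_organ * (1 - les$sigma_v)
    les_V[i]    <- les$V_isf
    les_Kd[i]   <- les$Kd
    les_kdeg[i] <- les$k_deg
    les_kint[i] <- les$k_int
    les_ksyn[i] <- les$k_deg * les$R01
    les_idx[i]  <- pos + 1L
    pos <- pos + 2L
    for (br in les$branches) {
      surv <- transit_survival(br$transit)
      br_les  <- c(br_les, i)
      br_out  <- c(br_out, br$L_aff * one_m_sl)
      br_in   <- c(br_in, br$L_aff * one_m_sl * surv)
      br_eff  <- c(br_eff, br$L_eff)
      br_V    <- c(br_V, br$V_isf)
      br_kdeg <- c(br_kdeg, les$k_deg)
      br_ksyn <- c(br_ksyn, les$k_deg * br$R02)
      br_kint <- c(br_kint, les$k_int)
      br_Kd   <- c(br_Kd, les$Kd)
      br_idx  <- c(br_idx, pos + 1L)
      pos <- pos + 2L
    }
  }
  tis_in  <- net$L_tissue * (1 - net$sigma_v_tissue)
  tis_out <- net$L_tissue * one_m_sl
  V_p <- net$V_p; CL_p <- net$CL_p
  V_tis <- net$V_isf_tissue
  n_state <- pos

  function(t, state, parms) {
    if (any(!is.finite(state))) {
      stop_invalid("integration failure at t = %g: non-finite state [%s]",
                   t, paste(signif(state, 4), collapse = ", "))
    }
    s <- pmax(state, 0)  # clip before the binding solve
    C_p <- s[1L]; C_tis <- s[2L]
    d <- numeric(n_state)

    # lesions
    lC <- s[les_idx]; lR <- s[les_idx + 1L]
    lb <- quasi_equilibrium_bind(lC, lR, les_Kd)
    # branches
    bC <- s[br_idx]; bR <- s[br_idx + 1L]
    bb <- quasi_equilibrium_bind(bC, bR, br_Kd)

    drain <- br_out * lb$Cf[br_les]          # lesion -> vessel, nmol/h
    d[les_idx] <- (les_in * C_p -
                   as.numeric(rowsum(drain, br_les, reorder = TRUE)) -
                   les_kint * lb$Cb * les_V) / les_V
    d[les_idx + 1L] <- les_ksyn - les_kdeg * lb$Rfree - les_kint * lb$Cb

    d[br_idx] <- (br_in * lb$Cf[br_les] - br_eff * bb$Cf -
                  br_kint * bb$Cb * br_V) / br_V
    d[br_idx + 1L] <- br_ksyn - br_kdeg * bb$Rfree - br_kint * bb$Cb

    d[2L] <- (tis_in * C_p - tis_out * C_tis) / V_tis
    d[1L] <- (-CL_p * C_p - sum(les_in) * C_p - tis_in * C_p +
              sum(br_eff * bb$Cf) + tis_out * C_tis) / V_p
    list(d)
  }
}

#' Evaluate the model right-hand side at one state
#'
#' Mainly a testing and inspection hook; [simulate_model()] builds the
#' same derivative function internally.
#'
#' @param net A `pbpk_network` (or `study_params`, converted).
#' @param state Named state vector as produced by the integrator; see
#'   `tdlnpk:::network_state_names`.
#' @param t Time, h (the system is autonomous; default 0).
#' @return Named vector of time derivatives, nM/h.
#' @export
model_rhs <- function(net, state, t = 0) {
  net <- as_network(net)
  f <- network_rhs(net)
  d <- f(t, state, NULL)[[1]]
  names(d) <- network_state_names(net)
  d
}
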