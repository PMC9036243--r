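# Clinical what-if transforms over the base model: additional metastatic
# lesion chains, surgical resection with lymphedema, and
# inflammation-remodeled TDLN drainage networks.

#' Describe a lesion for scenario building
#'
#' A light-weight specification of one tumor lesion and its draining
#' node, turned into a full network chain by [build_metastasis_model()].
#' Unspecified values inherit from the base study the scenario is built
#' on; a metastasis in another organ typically takes that organ's
#' physiology (e.g., a lung metastasis takes the NSCLC row's
#' `sigma_v`, `L_organ`, `V_isf`).
#'
#' @param label Unique lesion label.
#' @param R01 Target concentration in the lesion, nM.
#' @param R02 Target concentration in its TDLN, nM.
#' @param sigma_v,L_organ,V_isf Organ physiology of the lesion site
#'   (`NULL` = inherit from the base study).
#' @param dln Transit shape factor of the lesion's lymphatic path
#'   (`NULL` = inherit).
#' @param L_aff,L_eff,V_isf_tdln TDLN chain constants (`NULL` = inherit).
#' @param role `"metastasis"` (default) or `"primary"`.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(label, R01, R02, sigma_v = NULL, L_organ = NULL,
                        V_isf = NULL, dln = NULL, L_aff = NULL,
                        L_eff = NULL, V_isf_tdln = NULL,
                        role = c("metastasis", "primary")) {
  structure(list(label = as.character(label), R01 = R01, R02 = R02,
                 sigma_v = sigma_v, L_organ = L_organ, V_isf = V_isf,
                 dln = dln, L_aff = L_aff, L_eff = L_eff,
                 V_isf_tdln = V_isf_tdln, role = match.arg(role)),
            class = "lesion_spec")
}

.lesion_from_spec <- function(spec, base) {
  p <- base$physiology; tg <- base$target; tr <- base$transit
  pick <- function(x, default) if (is.null(x)) default else x
  transit <- tr
  if (!is.null(spec$dln)) {
    transit <- do.call(transit_params,
                       utils::modifyList(unclass(tr), list(dln = spec$dln)))
  }
  br <- tdln_branch(paste0(spec$label, "_TDLN"),
                    L_aff = pick(spec$L_aff, p$L_aff),
                    L_eff = pick(spec$L_eff, p$L_eff),
                    V_isf = pick(spec$V_isf_tdln, p$V_isf_tdln),
                    R02 = spec$R02, transit = transit)
  lesion_node(spec$label, sigma_v = pick(spec$sigma_v, p$sigma_v_pt),
              L_organ = pick(spec$L_organ, p$L_organ),
              V_isf = pick(spec$V_isf, p$V_isf_pt),
              R01 = spec$R01, Kd = tg$Kd, branches = list(br),
              k_deg = tg$k_deg, k_int = tg$k_int, role = spec$role)
}

#' Build a multi-lesion network with metastases
#'
#' All lesions share the plasma and lumped-tissue compartments; each
#' lesion-TDLN chain carries its own vascular leakiness, lymph flows,
#' target densities and transit path.
#'
#' @param base A `study_params` object providing plasma, lumped tissue and
#'   the primary-tumor chain (labelled `"PT"` / `"TDLN"`).
#' @param mets A list of [lesion_spec()] objects (>= 1), or a single
#'   `lesion_spec`.
#' @return A `pbpk_network`.
#' @examples
#' met <- lesion_spec("met_lung", R01 = 10, R02 = 2.5,
#'                    sigma_v = 0.85, L_organ = 0.012, V_isf = 0.175)
#' net <- build_metastasis_model(get_study("atezolizumab_bladder"), met)
#' @export
build_metastasis_model <- function(base, mets) {
  stopifnot(inherits(base, "study_params"))
  if (inherits(mets, "lesion_spec")) mets <- list(mets)
  stopifnot(length(mets) >= 1L,
            all(vapply(mets, inherits, logical(1), "lesion_spec")))
  net <- as_network(base)
  extra <- lapply(mets, .lesion_from_spec, base = base)
  labels <- vapply(c(net$lesions, extra), `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_invalid("duplicate lesion labels: %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  net$lesions <- c(net$lesions, extra)
  net$label <- paste0(base$study_id, "+mets")
  # revalidate as a whole
  do.call(pbpk_network,
          net[c("V_p", "CL_p", "sigma_l", "lesions", "L_tissue",
                "sigma_v_tissue", "V_isf_tissue", "label")])
}

#' Apply surgical resection of the primary tumor
#'
#' Resection removes the tumor target (`R01 = 0`; the tumor bed persists
#' as a compartment) and induces lymphedema: local lymph flows `L_organ`
#' and `L_aff` are reduced by the given fraction.
#'
#' @param base A `study_params` object.
#' @param lymph_reduction Fractional reduction of local lymph flows in
#'   \[0, 1); 0.5 and 0.8 represent moderate and severe surgery-induced
#'   lymphedema.
#' @return A modified `study_params` object.
#' @examples
#' post_op <- apply_surgery(get_study("bevacizumab_renal"), 0.5)
#' @export
apply_surgery <- function(base, lymph_reduction) {
  stopifnot(inherits(base, "study_params"))
  check_scalar(lymph_reduction, "lymph_reduction", 0, 1,
               allow_upper = FALSE)
  out <- set_study_param(base, "R01", 0)
  out <- set_study_param(out, "L_organ",
                         base$physiology$L_organ * (1 - lymph_reduction))
  out <- set_study_param(out, "L_aff",
                         base$physiology$L_aff * (1 - lymph_reduction))
  out$study_id <- sprintf("%s+surgery%.0f", base$study_id,
                          100 * lymph_reduction)
  out
}

#' Describe one TDLN branch of an inflamed drainage network
#'
#' @param label Unique branch label.
#' @param position `"intratumoral"` or `"peritumoral"`. Rapid tumor
#'   expansion compresses intratumoral lymphatics (afferent flow driven
#'   toward 0) while inflammation increases peritumoral flow.
#' @param tumor_status `"positive"` (node carries target, `R02 > 0`) or
#'   `"negative"` (`R02 = 0`).
#' @param L_aff_mult Multiplier applied to the base afferent flow
#'   (>= 0). Defaults: 0.01 for intratumoral, 2 for peritumoral.
#' @param R02 Node target concentration, nM; default inherits the base
#'   `R02` when `tumor_status = "positive"`, 0 otherwise.
#' @return A `tdln_branch_spec` list.
#' @export
tdln_branch_spec <- function(label,
                             position = c("peritumoral", "intratumoral"),
                             tumor_status = c("positive", "negative"),
                             L_aff_mult = NULL, R02 = NULL) {
  position <- match.arg(position)
  tumor_status <- match.arg(tumor_status)
  if (is.null(L_aff_mult)) {
    L_aff_mult <- if (position == "intratumoral") 0.01 else 2
  }
  check_scalar(L_aff_mult, "L_aff_mult", 0)
  structure(list(label = as.character(label), position = position,
                 tumor_status = tumor_status, L_aff_mult = L_aff_mult,
                 R02 = R02),
            class = "tdln_branch_spec")
}

#' Build an inflammation-remodeled multi-TDLN network
#'
#' Splits the primary tumor's lymphatic efflux across several TDLN
#' branches in proportion to their afferent flows. Compressed
#' intratumoral branches (multiplier near 0) receive essentially no
#' antibody; peritumoral branches with inflammation-increased flow
#' receive more.
#'
#' @param base A `study_params` object.
#' @param branches List of [tdln_branch_spec()] objects (>= 2).
#' @return A `pbpk_network` with one lesion (`"PT"`) and one TDLN
#'   compartment per branch.
#' @examples
#' net <- apply_inflammation(get_study("bevacizumab_renal"), list(
#'   tdln_branch_spec("TDLN_intra", "intratumoral", "positive"),
#'   tdln_branch_spec("TDLN_peri", "peritumoral", "positive")))
#' @export
apply_inflammation <- function(base, branches) {
  stopifnot(inherits(base, "study_params"))
  stopifnot(length(branches) >= 2L,
            all(vapply(branches, inherits, logical(1), "tdln_branch_spec")))
  mults <- vapply(branches, `[[`, numeric(1), "L_aff_mult")
  if (all(mults == 0)) {
    stop_invalid("all afferent multipliers are 0: no drainage network")
  }
  p <- base$physiology; tg <- base$target
  brs <- lapply(branches, function(b) {
    R02 <- if (!is.null(b$R02)) b$R02
           else if (b$tumor_status == "positive") tg$R02 else 0
    tdln_branch(b$label, L_aff = p$L_aff * b$L_aff_mult, L_eff = p$L_eff,
                V_isf = p$V_isf_tdln, R02 = R02, transit = base$transit)
  })
  les <- lesion_node("PT", sigma_v = p$sigma_v_pt, L_organ = p$L_organ,
                     V_isf = p$V_isf_pt, R01 = tg$R01, Kd = tg$Kd,
                     branches = brs, k_deg = tg$k_deg, k_int = tg$k_int,
                     role = "primary")
  pbpk_network(V_p = p$V_p, CL_p = p$CL_p, sigma_l = p$sigma_l,
               lesions = list(les), L_tissue = p$L_tissue,
               sigma_v_tissue = p$sigma_v_tissue,
               V_isf_tissue = p$V_isf_tissue,
               label = paste0(base$study_id, "+inflammation"))
}
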