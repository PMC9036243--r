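# Registry of the eleven antibody:tumor parameterizations.
#
# Organ-specific rows: sigma_v, L_organ (L/h), V_isf_pt (L), V_p (L).
# Antibody/tumor rows: R01, R02, Kd, Kd_FcRn (nM), dln, CL_p (L/h).
# Shared by every study: sigma_l = 0.2, L_aff = L_eff = 0.004 L/h,
# V_isf_tdln = 5.84e-5 L (20% of an average node), FcRn = 40 uM,
# k_deg = k_int = 0.01 1/h, sigma_v_tdln = 1.

.registry_rows <- list(
  #            antibody            tumor             sV    Lorg   Visf    Vp   R01  R02  Kd    KdFcRn dln CLp
  fresolimumab_gbm = list("fresolimumab", "glioblastoma",
                          0.94, 0.050, 0.265, 5.0, 1,    1,    1.7,   2400, 19, 0.075),
  bevacizumab_nsclc = list("bevacizumab", "non-small-cell lung cancer",
                          0.85, 0.012, 0.175, 5.0, 10,   10,   0.058, 2400, 21, 0.07),
  bevacizumab_breast = list("bevacizumab", "breast cancer",
                          0.95, 0.008, 0.112, 5.0, 1,    1.5,  0.058, 2400, 20, 0.06),
  bevacizumab_renal = list("bevacizumab", "renal cell carcinoma",
                          0.97, 0.082, 0.060, 5.0, 10,   2.5,  0.058, 2400, 21, 0.042),
  trastuzumab_breast = list("trastuzumab", "breast cancer",
                          0.65, 0.008, 0.112, 5.0, 100,  100,  5,     774,  61, 0.063),
  trastuzumab_esophagogastric = list("trastuzumab", "esophagogastric cancer",
                          0.95, 0.007, 0.005, 7.0, 30,   30,   5,     774,  63, 0.0288),
  mmot0530a_pancreatic = list("MMOT0530A", "pancreatic cancer",
                          0.87, 0.004, 0.029, 5.0, 1000, 1000, 0.5,   2400, 21, 0.033),
  mmot0530a_ovarian = list("MMOT0530A", "ovarian cancer",
                          0.95, 0.004, 0.001, 5.0, 24,   24,   0.5,   2400, 24, 0.033),
  atezolizumab_nsclc = list("atezolizumab", "non-small-cell lung cancer",
                          0.80, 0.012, 0.175, 5.0, 7,    7,    0.43,  2400, 21, 0.0083),
  atezolizumab_breast = list("atezolizumab", "breast cancer",
                          0.90, 0.008, 0.112, 5.0, 1,    2.5,  0.43,  2400, 20, 0.0083),
  atezolizumab_bladder = list("atezolizumab", "bladder cancer",
                          0.86, 0.001, 0.0084, 5.0, 11,  11,   0.43,  2400, 24, 0.0083)
)

.build_study <- function(id) {
  r <- .registry_rows[[id]]
  study_params(
    study_id = id, antibody = r[[1]], tumor = r[[2]],
    physiology = physiology_params(sigma_v_pt = r[[3]], L_organ = r[[4]],
                                   V_isf_pt = r[[5]], V_p = r[[6]],
                                   CL_p = r[[12]]),
    target = target_params(R01 = r[[7]], R02 = r[[8]], Kd = r[[9]]),
    transit = transit_params(dln = r[[11]], Kd_FcRn = r[[10]]),
    source = sprintf("immuno-PET study of %s in %s", r[[1]], r[[2]])
  )
}

#' List the registered study identifiers
#' @return Character vector of the 11 study ids.
#' @export
study_ids <- function() names(.registry_rows)

#' Retrieve a registered study parameter set
#'
#' @param study_id One of [study_ids()].
#' @return An immutable `study_params` object.
#' @examples
#' get_study("bevacizumab_renal")
#' @export
get_study <- function(study_id) {
  if (!is.character(study_id) || length(study_id) != 1L ||
      !study_id %in% names(.registry_rows)) {
    stop_invalid("unknown study_id '%s'; valid ids: %s",
                 paste(study_id, collapse = ","),
                 paste(names(.registry_rows), collapse = ", "))
  }
  .build_study(study_id)
}

#' Tabulate the full registry
#' @return Data frame with one row per study and the organ- and
#'   antibody-specific parameter columns.
#' @export
study_table <- function() {
  do.call(rbind, lapply(names(.registry_rows), function(id) {
    r <- .registry_rows[[id]]
    data.frame(study_id = id, antibody = r[[1]], tumor = r[[2]],
               sigma_v = r[[3]], L_organ = r[[4]], V_isf_pt = r[[5]],
               V_p = r[[6]], R01 = r[[7]], R02 = r[[8]], Kd = r[[9]],
               Kd_FcRn = r[[10]], dln = r[[11]], CL_p = r[[12]],
               stringsAsFactors = FALSE)
  }))
}

# -- footnote derivation rules ------------------------------------------

#' Derive organ lymph flow from organ blood flow
#'
#' Organ lymph flow is taken as 0.2\% of organ blood flow.
#'
#' @param organ_blood_flow Blood flow, L/h (> 0).
#' @return Lymph flow, L/h.
#' @examples
#' derive_lymph_flow(41)  # 0.082 L/h, a highly perfused organ
#' @export
derive_lymph_flow <- function(organ_blood_flow) {
  check_scalar(organ_blood_flow, "organ_blood_flow", 0, allow_lower = FALSE)
  0.002 * organ_blood_flow
}

#' Derive interstitial fluid volume from total tissue volume
#'
#' ISF is taken as 20\% of the total organ/tissue volume by default.
#'
#' @param total_volume Total tissue volume, L (> 0).
#' @param fraction ISF fraction in (0, 1); default 0.20.
#' @return ISF volume, L.
#' @examples
#' derive_isf_volume(0.000292)  # average lymph node -> 5.84e-5 L
#' @export
derive_isf_volume <- function(total_volume, fraction = 0.20) {
  check_scalar(total_volume, "total_volume", 0, allow_lower = FALSE)
  check_scalar(fraction, "fraction", 0, 1, allow_lower = FALSE,
               allow_upper = FALSE)
  fraction * total_volume
}

# -- JSON round trip -----------------------------------------------------

#' Write a study parameter set to JSON
#' @param study A `study_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
study_to_json <- function(study, path) {
  stopifnot(inherits(study, "study_params"))
  x <- list(study_id = study$study_id, antibody = study$antibody,
            tumor = study$tumor, source = study$source,
            physiology = unclass(study$physiology),
            target = unclass(study$target)[c("R01", "R02", "Kd", "k_deg",
                                             "k_int")],
            transit = unclass(study$transit))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study parameter set from JSON
#' @param path Path written by [study_to_json()].
#' @return A validated `study_params` object.
#' @export
study_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_params(study_id = x$study_id, antibody = x$antibody,
               tumor = x$tumor, source = x$source,
               physiology = do.call(physiology_params, x$physiology),
               target = do.call(target_params, as.list(x$target)),
               transit = do.call(transit_params, x$transit))
}
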