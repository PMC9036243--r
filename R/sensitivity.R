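# Local one-at-a-time sensitivity analysis over fold-change grids.

#' Default fold-change grid for sensitivity sweeps
#' @return The 11-point grid `c(0.1, 0.3, 0.5, 0.7, 1, 3, 5, 7, 10, 50, 100)`.
#' @export
sensitivity_folds <- function() c(0.1, 0.3, 0.5, 0.7, 1, 3, 5, 7, 10, 50, 100)

.sens_params <- c("R01_R02_ratio", "dln", "Kd", "k_int", "k_deg",
                  "sigma_v", "sigma_l", "CL_p", "L_organ", "L_aff",
                  "Kd_FcRn", "R01", "R02")

#' Local one-at-a-time sensitivity of tumor and TDLN exposure
#'
#' Sweeps one parameter over a grid while all others stay at their
#' calibrated values, simulating the full model at each grid point and
#' reporting tissue exposures. Conventions:
#' \itemize{
#'   \item `R01_R02_ratio` scales `R01` by the fold with `R02` fixed
#'     (the ratio of tumor burden in the PT versus the TDLN).
#'   \item `sigma_v` is swept on an absolute grid (default
#'     `0.01, 0.25, 0.5, 0.75, 0.9, <base>, 1, 1.25`); reflection
#'     coefficients are physically capped at 1, so requested values above
#'     1 are clamped and marked in the `clamped` column.
#'   \item `sigma_l` folds are restricted to 0.1-5 of the base value and
#'     clamped at 1 likewise.
#'   \item any other registered scalar is multiplied by the fold.
#' }
#'
#' @param base A `study_params` object (reference parameterization).
#' @param parameter One of `R01_R02_ratio, dln, Kd, k_int, k_deg, sigma_v,
#'   sigma_l, CL_p, L_organ, L_aff, Kd_FcRn, R01, R02`.
#' @param grid Fold-change grid (absolute values for `sigma_v`). Default:
#'   [sensitivity_folds()] (restricted to 0.1-5 for `sigma_l`).
#' @param dose A [dose_spec()].
#' @param times Output grid, h.
#' @param metric `"conc"` (AUC of total tissue concentration, nM h,
#'   default) or `"suv"` (AUC of the SUV profile).
#' @param insensitivity_threshold Sensitivity score below which the
#'   parameter is reported insensitive; default 0.05.
#' @return A data frame of class `sensitivity_table` with columns
#'   `parameter`, `fold`, `value`, `tissue`, `auc`, `suv_peak`,
#'   `clamped`, plus attributes `score` and `direction` (per tissue;
#'   direction is the sign of the fold-exposure association) and
#'   `insensitive` (logical per tissue).
#' @examples
#' \donttest{
#' local_sensitivity(get_study("bevacizumab_renal"), "k_deg")
#' }
#' @export
local_sensitivity <- function(base, parameter, grid = NULL,
                              dose = dose_spec(),
                              times = seq(0, 336, by = 4),
                              metric = c("conc", "suv"),
                              insensitivity_threshold = 0.05) {
  stopifnot(inherits(base, "study_params"))
  metric <- match.arg(metric)
  parameter <- match.arg(parameter, .sens_params)

  if (parameter == "sigma_v") {
    base_val <- get_study_param(base, "sigma_v")
    if (is.null(grid)) {
      grid <- sort(unique(c(0.01, 0.25, 0.5, 0.75, 0.9, base_val, 1, 1.25)))
    }
    requested <- grid
    folds <- requested / base_val
  } else if (parameter == "sigma_l") {
    if (is.null(grid)) grid <- c(0.1, 0.3, 0.5, 0.7, 1, 3, 5)
    folds <- grid
    if (any(folds < 0.1 | folds > 5)) {
      stop_invalid("sigma_l folds must lie in [0.1, 5]")
    }
    requested <- get_study_param(base, "sigma_l") * folds
  } else {
    if (is.null(grid)) grid <- sensitivity_folds()
    folds <- grid
    slot_name <- if (parameter == "R01_R02_ratio") "R01" else parameter
    requested <- get_study_param(base, slot_name) * folds
  }
  if (!any(abs(folds - 1) < 1e-12)) {
    stop_invalid("grid must contain the reference (fold 1.0)")
  }
  slot_name <- switch(parameter, R01_R02_ratio = "R01",
                      sigma_v = "sigma_v", sigma_l = "sigma_l", parameter)

  clamped <- requested > 1 & slot_name %in% c("sigma_v", "sigma_l")
  values <- ifelse(clamped, 1, requested)
  if (any(clamped)) {
    warning(sprintf("%s values above 1 clamped to 1 (%s)", slot_name,
                    paste(signif(requested[clamped], 3), collapse = ", ")),
            call. = FALSE)
  }

  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    study_i <- set_study_param(base, slot_name, values[i])
    traj <- simulate_model(study_i, dose = dose, times = times,
                           rtol = 1e-8, atol = 1e-10)
    per_tissue <- split(traj, traj$tissue)
    rows[[i]] <- do.call(rbind, lapply(per_tissue, function(d) {
      data.frame(parameter = parameter, fold = folds[i],
                 value = values[i], tissue = d$tissue[1],
                 auc = if (metric == "conc") trapz_auc(d$time_h, d$conc_nM)
                       else trapz_auc(d$time_h, d$suv),
                 suv_peak = max(d$suv), clamped = clamped[i],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  ref <- out[abs(out$fold - 1) < 1e-12, ]
  tissues <- unique(out$tissue)
  score <- vapply(tissues, function(ts) {
    a <- out$auc[out$tissue == ts]
    a_ref <- ref$auc[ref$tissue == ts]
    if (a_ref <= 0) return(NA_real_)
    max(abs(a - a_ref)) / a_ref
  }, numeric(1))
  direction <- vapply(tissues, function(ts) {
    d <- out[out$tissue == ts, ]
    d <- d[order(d$fold), ]
    dif <- diff(d$auc)
    if (all(dif >= -1e-12 * max(abs(d$auc)))) 1
    else if (all(dif <= 1e-12 * max(abs(d$auc)))) -1
    else 0
  }, numeric(1))
  structure(out, score = score, direction = direction,
            insensitive = score < insensitivity_threshold,
            threshold = insensitivity_threshold,
            class = c("sensitivity_table", "data.frame"))
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("<sensitivity_table> parameter '%s', %d grid points\n",
              x$parameter[1], length(unique(x$fold))))
  sc <- attr(x, "score"); dr <- attr(x, "direction")
  for (ts in names(sc)) {
    cat(sprintf("  %-8s score = %.3g  direction = %s%s\n", ts, sc[[ts]],
                c(`-1` = "decreasing", `0` = "non-monotone",
                  `1` = "increasing")[as.character(dr[[ts]])],
                if (isTRUE(attr(x, "insensitive")[[ts]]))
                  " (insensitive)" else ""))
  }
  print(as.data.frame(x), ...)
  invisible(x)
}
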