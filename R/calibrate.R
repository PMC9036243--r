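# Calibration of free model parameters against sparse immuno-PET SUV
# observations by box-constrained (trust-region) nonlinear least squares.

.fittable <- c("sigma_v", "CL_p", "R01", "R02", "dln", "Kd", "k_int",
               "sigma_l", "L_organ", "L_aff", "f_vasc", "suv_scale")

.default_bounds <- list(
  sigma_v   = c(0, 1),
  CL_p      = c(1e-4, 1),
  R01       = c(0, 1e5),
  R02       = c(0, 1e5),
  dln       = c(1, 500),
  Kd        = c(1e-4, 1e4),
  k_int     = c(0, 10),
  sigma_l   = c(0, 1),
  L_organ   = c(1e-6, 10),
  L_aff     = c(0, 1),
  f_vasc    = c(0, 1),
  suv_scale = c(1e-3, 100)
)

#' Specify which parameters to calibrate and how
#'
#' @param free Character vector of parameter names to estimate; subset of
#'   `sigma_v, CL_p, R01, R02, dln, Kd, k_int, sigma_l, L_organ, L_aff,
#'   f_vasc, suv_scale`. The last two act on the SUV conversion rather
#'   than the ODE system.
#' @param lower,upper Named numeric vectors overriding the default
#'   physical bounds for some or all free parameters.
#' @param init Named numeric vector of initial values; defaults to the
#'   base study's registered values (`f_vasc` 0.05, `suv_scale` 1).
#' @param weighting `"inverse_sd"` (default; residuals scaled by 1/SD
#'   where an SD is reported, 1 otherwise), `"unweighted"`, or
#'   `"inverse_prediction"`.
#' @param n_start Number of multistart points (>= 1). The first start is
#'   `init`; the rest are Latin-hypercube (or uniform) draws within the
#'   bounds under `seed`.
#' @param seed Integer seed making the multistart deterministic.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL, init = NULL,
                     weighting = c("inverse_sd", "unweighted",
                                   "inverse_prediction"),
                     n_start = 1, seed = 20220414) {
  weighting <- match.arg(weighting)
  if (length(free) == 0L) stop_invalid("no free parameters to fit")
  bad <- setdiff(free, .fittable)
  if (length(bad)) {
    stop_invalid("cannot fit: %s (fittable: %s)",
                 paste(bad, collapse = ", "),
                 paste(.fittable, collapse = ", "))
  }
  lo <- vapply(free, function(p) .default_bounds[[p]][1], numeric(1))
  hi <- vapply(free, function(p) .default_bounds[[p]][2], numeric(1))
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo >= hi)) stop_invalid("lower bounds must be below upper bounds")
  structure(list(free = free, lower = lo, upper = hi, init = init,
                 weighting = weighting,
                 n_start = max(1L, as.integer(n_start)),
                 seed = as.integer(seed)),
            class = "fit_spec")
}

# apply a named parameter vector (model + SUV parameters) to the base set
.apply_theta <- function(base, theta) {
  sim_args <- list(f_isf = 0.2, f_vasc = 0.05, suv_scale = 1)
  study <- base
  for (nm in names(theta)) {
    if (nm %in% c("f_vasc", "suv_scale")) {
      sim_args[[nm]] <- theta[[nm]]
    } else {
      study <- set_study_param(study, nm, theta[[nm]])
    }
  }
  list(study = study, sim_args = sim_args)
}

# predicted SUV at the observation rows
.predict_obs <- function(base, theta, obs, dose, rtol, atol) {
  ap <- .apply_theta(base, theta)
  times <- sort(unique(obs$time_h))
  grid <- if (times[1] > 0) c(0, times) else times
  if (length(grid) < 2L) grid <- c(0, grid[grid > 0])
  traj <- simulate_model(ap$study, dose = dose, times = grid,
                         f_isf = ap$sim_args$f_isf,
                         f_vasc = ap$sim_args$f_vasc,
                         suv_scale = ap$sim_args$suv_scale,
                         rtol = rtol, atol = atol)
  key_t <- paste(traj$tissue, signif(traj$time_h, 12))
  key_o <- paste(obs$tissue, signif(obs$time_h, 12))
  idx <- match(key_o, key_t)
  if (anyNA(idx)) {
    stop_invalid("observations refer to tissues not in the model: %s",
                 paste(unique(obs$tissue[is.na(idx)]), collapse = ", "))
  }
  traj$suv[idx]
}

.obs_weights <- function(obs, pred, weighting) {
  switch(weighting,
    unweighted = rep(1, nrow(obs)),
    inverse_sd = {
      w <- rep(1, nrow(obs))
      ok <- !is.na(obs$sd) & obs$sd > 0
      w[ok] <- 1 / obs$sd[ok]
      w
    },
    inverse_prediction = 1 / pmax(pred, 1e-6))
}

# run the RNG-dependent part under a local, restored seed
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Calibrate free parameters against SUV observations
#'
#' Box-constrained Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) on SUV residuals, optionally from multiple
#' Latin-hypercube start points. The fit is deterministic for a fixed
#' `fit_spec` seed.
#'
#' @param observations Data frame with columns `study_id`, `tissue`
#'   (`plasma`, `PT`, `TDLN`, or any lesion label present in the model),
#'   `time_h`, `suv`, and optionally `sd`.
#' @param spec A [fit_spec()] object.
#' @param base A `study_params` object supplying every fixed parameter.
#' @param dose A [dose_spec()] object.
#' @param rtol,atol Solver tolerances used inside the objective (looser
#'   than simulation defaults; the objective is smooth at this level).
#' @param flat_tol Relative objective change below which a parameter is
#'   flagged non-identifiable; probed at the optimum with 2-fold
#'   perturbations. Default 0.05.
#' @return A `fit_result` list: `estimates`, `at_bounds`,
#'   `non_identifiable`, `objective` (weighted SSE), `residuals` (data
#'   frame with predictions), `converged`, `info`, `message`, `rsstrace`
#'   (objective trace of the winning start), `n_start`.
#' @export
fit_suv <- function(observations, spec, base, dose = dose_spec(),
                    rtol = 1e-6, atol = 1e-8, flat_tol = 0.05) {
  stopifnot(inherits(spec, "fit_spec"), inherits(base, "study_params"))
  obs <- as.data.frame(observations)
  need <- c("tissue", "time_h", "suv")
  if (!all(need %in% names(obs))) {
    stop_invalid("observations need columns: %s", paste(need, collapse = ", "))
  }
  if (!"sd" %in% names(obs)) obs$sd <- NA_real_
  if (nrow(obs) == 0L) stop_invalid("no observations")
  if (any(obs$suv < 0) || any(obs$time_h < 0)) {
    stop_invalid("SUV and time must be non-negative")
  }

  free <- spec$free
  init <- vapply(free, function(p) {
    if (!is.null(spec$init) && p %in% names(spec$init)) spec$init[[p]]
    else if (p == "f_vasc") 0.05
    else if (p == "suv_scale") 1
    else get_study_param(base, p)
  }, numeric(1))
  init <- pmin(pmax(init, spec$lower), spec$upper)

  resid_fn <- function(theta) {
    names(theta) <- free
    pred <- .predict_obs(base, theta, obs, dose, rtol, atol)
    w <- .obs_weights(obs, pred, spec$weighting)
    w * (pred - obs$suv)
  }

  starts <- list(init)
  if (spec$n_start > 1L) {
    n_extra <- spec$n_start - 1L
    u <- with_local_seed(spec$seed, {
      if (requireNamespace("lhs", quietly = TRUE)) {
        lhs::randomLHS(n_extra, length(free))
      } else {
        matrix(stats::runif(n_extra * length(free)), nrow = n_extra)
      }
    })
    for (i in seq_len(n_extra)) {
      starts[[i + 1L]] <- spec$lower + u[i, ] * (spec$upper - spec$lower)
    }
  }

  best <- NULL
  for (st in starts) {
    res <- try(minpack.lm::nls.lm(
      par = st, lower = spec$lower, upper = spec$upper, fn = resid_fn,
      # epsfcn keeps the forward-difference step well above the ODE
      # solver noise floor (relative step ~sqrt(epsfcn))
      control = minpack.lm::nls.lm.control(maxiter = 200, epsfcn = 1e-6)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop_invalid("all optimization starts failed")

  est <- best$par
  names(est) <- free
  pred <- .predict_obs(base, est, obs, dose, rtol, atol)
  w <- .obs_weights(obs, pred, spec$weighting)
  objective <- sum((w * (pred - obs$suv))^2)

  width <- spec$upper - spec$lower
  at_lower <- est - spec$lower <= 1e-6 * width
  at_upper <- spec$upper - est <= 1e-6 * width

  # identifiability probe: perturb each free parameter at scale (2-fold,
  # or 20% of the bound width when the estimate sits near zero) and flag
  # it when the objective barely responds anywhere in that range
  flat <- vapply(free, function(p) {
    probes <- if (abs(est[[p]]) > 1e-8 * width[[p]]) {
      c(0.5, 2) * est[[p]]
    } else {
      est[[p]] + c(-0.01, 0.01) * width[[p]]
    }
    changes <- vapply(probes, function(v) {
      th <- est
      th[[p]] <- min(max(v, spec$lower[[p]]), spec$upper[[p]])
      if (th[[p]] == est[[p]]) return(0)
      pr <- .predict_obs(base, th, obs, dose, rtol, atol)
      abs(sum((w * (pr - obs$suv))^2) - objective)
    }, numeric(1))
    max(changes) <= flat_tol * max(objective, 1e-12)
  }, logical(1))

  structure(list(
    estimates = est,
    at_bounds = at_lower | at_upper,
    non_identifiable = flat,
    objective = objective,
    residuals = cbind(obs, pred = pred, weight = w,
                      residual = pred - obs$suv),
    converged = best$info %in% 1:4,
    info = best$info, message = best$message,
    rsstrace = best$rsstrace, niter = best$niter,
    n_start = spec$n_start, spec = spec
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else
      sprintf("NOT converged (info %d)", x$info), "\n")
  for (p in names(x$estimates)) {
    cat(sprintf("  %-10s = %.6g%s%s\n", p, x$estimates[[p]],
                if (x$at_bounds[[p]]) "  [at bound]" else "",
                if (x$non_identifiable[[p]]) "  [non-identifiable]" else ""))
  }
  cat(sprintf("  weighted SSE = %.6g over %d observations\n",
              x$objective, nrow(x$residuals)))
  invisible(x)
}

#' Read SUV observations from CSV
#'
#' Expected header: `study_id,tissue,time_h,suv,sd` (`sd` may be empty).
#'
#' @param path CSV path.
#' @return Validated observations data frame.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "tissue", "time_h", "suv")
  if (!all(need %in% names(obs))) {
    stop_invalid("observation CSV needs columns: %s",
                 paste(need, collapse = ", "))
  }
  if (!"sd" %in% names(obs)) obs$sd <- NA_real_
  if (any(obs$suv < 0, na.rm = TRUE) || any(obs$time_h < 0)) {
    stop_invalid("SUV and time must be non-negative")
  }
  obs
}

#' Write SUV observations to CSV
#' @param obs Observations data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs[, c("study_id", "tissue", "time_h", "suv", "sd")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
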