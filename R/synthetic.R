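# Synthetic immuno-PET SUV observation sets with known ground truth,
# emulating the sparse sampling (a few scans over one to two weeks) and
# the large between-subject dispersion typical of clinical antibody
# imaging.

#' Design a synthetic immuno-PET sampling scheme
#'
#' @param times Scan times, h, positive increasing; default
#'   `c(48, 96, 168)` (days 2, 4 and 7).
#' @param tissues Tissues sampled; default `c("plasma", "PT", "TDLN")`.
#' @param n_subjects Number of subjects per time point; default 6.
#' @param cv Between-subject coefficient of variation of the
#'   multiplicative noise (>= 0); default 0.2, reflecting the high
#'   dispersion of clinical SUV data.
#' @param noise `"lognormal"` (default; SUV is positive and clinical SDs
#'   are large) or `"gaussian"` (additive, truncated at 0). Lognormal
#'   noise is mean-preserving: the subject factor is
#'   `exp(N(-s^2/2, s^2))` with `s^2 = log(1 + cv^2)`.
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @return An `observation_design` object.
#' @export
observation_design <- function(times = c(48, 96, 168),
                               tissues = c("plasma", "PT", "TDLN"),
                               n_subjects = 6, cv = 0.2,
                               noise = c("lognormal", "gaussian"),
                               seed = 1L) {
  noise <- match.arg(noise)
  if (length(times) == 0L || length(tissues) == 0L) {
    stop_invalid("empty sampling design")
  }
  if (any(times <= 0) || any(diff(times) <= 0)) {
    stop_invalid("times must be positive and strictly increasing")
  }
  structure(list(times = as.numeric(times),
                 tissues = as.character(tissues),
                 n_subjects = max(1L, as.integer(n_subjects)),
                 cv = check_scalar(cv, "cv", 0), noise = noise,
                 seed = as.integer(seed)),
            class = "observation_design")
}

#' Generate synthetic SUV observations with known truth
#'
#' Simulates the ground-truth parameter set, applies per-subject
#' multiplicative (or additive) noise at each design point, and returns
#' the per-time-point mean and SD in the observation-table schema used by
#' [fit_suv()], together with the generating truth.
#'
#' @param truth A `study_params` object (the generating parameters).
#' @param dose A [dose_spec()].
#' @param design An [observation_design()].
#' @param f_isf,f_vasc SUV signal fractions, as in [simulate_model()].
#' @return A list of class `synthetic_observations`: `observations`
#'   (data frame `study_id, tissue, time_h, suv, sd` of per-time means
#'   and SDs), `subjects` (per-subject draws, long format), `truth`, and
#'   the `design` and `dose` used.
#' @examples
#' synth <- generate_observations(get_study("bevacizumab_renal"),
#'                                dose_spec(10),
#'                                observation_design(cv = 0.2, seed = 7))
#' head(synth$observations)
#' @export
generate_observations <- function(truth, dose = dose_spec(),
                                  design = observation_design(),
                                  f_isf = 0.2, f_vasc = 0.05) {
  stopifnot(inherits(truth, "study_params"),
            inherits(design, "observation_design"))
  grid <- c(0, design$times)
  traj <- simulate_model(truth, dose = dose, times = grid,
                         f_isf = f_isf, f_vasc = f_vasc)
  pred <- traj[traj$tissue %in% design$tissues &
                 traj$time_h %in% design$times, ]
  if (!all(design$tissues %in% pred$tissue)) {
    stop_invalid("design samples tissues absent from the model: %s",
                 paste(setdiff(design$tissues, pred$tissue),
                       collapse = ", "))
  }
  n <- design$n_subjects
  subjects <- with_local_seed(design$seed, {
    do.call(rbind, lapply(seq_len(nrow(pred)), function(i) {
      mu <- pred$suv[i]
      y <- if (design$cv == 0) {
        rep(mu, n)
      } else if (design$noise == "lognormal") {
        s2 <- log(1 + design$cv^2)
        mu * exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
      } else {
        pmax(stats::rnorm(n, mu, design$cv * mu), 0)
      }
      data.frame(study_id = truth$study_id, subject = seq_len(n),
                 tissue = pred$tissue[i], time_h = pred$time_h[i],
                 suv = y, stringsAsFactors = FALSE)
    }))
  })
  key <- interaction(subjects$tissue, subjects$time_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(subjects, key), function(d) {
    data.frame(study_id = d$study_id[1], tissue = d$tissue[1],
               time_h = d$time_h[1], suv = mean(d$suv),
               sd = if (nrow(d) > 1) stats::sd(d$suv) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$tissue, agg$time_h), ]
  rownames(agg) <- NULL
  structure(list(observations = agg, subjects = subjects, truth = truth,
                 design = design, dose = dose),
            class = "synthetic_observations")
}
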