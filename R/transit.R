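# FcRn salvage during lymphatic transit from tumor to draining node.
#
# Antibody carried with afferent lymph passes a chain of lymphatic
# endothelial segments; in each, a fraction is pinocytosed, and of that
# the FcRn-bound share is recycled intact while the rest is degraded.
# The surviving fraction over the whole path is modelled as a per-event
# loss raised to an effective number of events n_ref / dln: the shape
# factor dln summarizes the organ-specific path, with larger dln meaning
# fewer effective loss events and thus higher survival.

#' Equilibrium FcRn-bound fraction of pinocytosed antibody
#'
#' @param Kd_FcRn Antibody-FcRn dissociation constant, nM (> 0).
#' @param FcRn_conc Endothelial FcRn concentration, nM (> 0).
#' @return `FcRn_conc / (FcRn_conc + Kd_FcRn)`, the fraction of
#'   pinocytosed antibody rescued from degradation.
#' @examples
#' fcrn_bound_fraction(2400, 40000)  # ~0.943
#' @export
fcrn_bound_fraction <- function(Kd_FcRn, FcRn_conc) {
  if (!is.numeric(Kd_FcRn) || any(!is.finite(Kd_FcRn)) || any(Kd_FcRn <= 0) ||
      !is.numeric(FcRn_conc) || any(!is.finite(FcRn_conc)) ||
      any(FcRn_conc <= 0)) {
    stop_invalid("Kd_FcRn and FcRn_conc must be finite and > 0")
  }
  FcRn_conc / (FcRn_conc + Kd_FcRn)
}

# strategy registry: a strategy maps transit_params -> survival in (0, 1]
.transit_strategies <- new.env(parent = emptyenv())

#' Register a lymphatic-transit survival strategy
#'
#' The survival law is pluggable so that alternative mechanistic forms can
#' replace the default without touching the ODE core.
#'
#' @param name Strategy name.
#' @param fn Function of one argument (a [transit_params()] object)
#'   returning a survival fraction in (0, 1].
#' @return Invisibly, the registered function.
#' @export
register_transit_strategy <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .transit_strategies)
  invisible(fn)
}

#' Fraction of antibody surviving lymphatic transit to the TDLN
#'
#' Under the default `"power_shape"` strategy the survival is
#' `(1 - uptake_prob * (1 - f_FcRn))^(n_ref / dln)` with
#' `f_FcRn = FcRn_conc / (FcRn_conc + Kd_FcRn)`: survival increases with
#' the shape factor `dln` and with FcRn affinity (decreasing `Kd_FcRn`),
#' and equals 1 when pinocytosis is switched off.
#'
#' @param transit A [transit_params()] object.
#' @return Survival fraction in (0, 1].
#' @examples
#' transit_survival(transit_params(dln = 21, Kd_FcRn = 2400))
#' @export
transit_survival <- function(transit) {
  stopifnot(inherits(transit, "transit_params"))
  fn <- get0(transit$strategy, envir = .transit_strategies)
  if (is.null(fn)) {
    stop_invalid("unknown transit strategy '%s'; registered: %s",
                 transit$strategy,
                 paste(ls(.transit_strategies), collapse = ", "))
  }
  f <- fn(transit)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
    stop_invalid("transit strategy '%s' returned survival %s outside (0, 1]",
                 transit$strategy, format(f))
  }
  f
}

.power_shape_survival <- function(transit) {
  if (transit$uptake_prob == 0) return(1)
  fb <- fcrn_bound_fraction(transit$Kd_FcRn, transit$FcRn_conc)
  per_event <- 1 - transit$uptake_prob * (1 - fb)
  # log-domain evaluation keeps the power accurate for large exponents
  exp((transit$n_ref / transit$dln) * log(per_event))
}

register_transit_strategy("power_shape", .power_shape_survival)
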