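# Quasi-equilibrium target binding.
#
# At each instant the free antibody Cf, free target Rfree and complex Cb
# satisfy mass action Cf * Rfree = Kd * Cb together with the totals
# Cf + Cb = Ctot and Rfree + Cb = Rtot. Eliminating Cf and Rfree gives the
# quadratic Cb^2 - (Ctot + Rtot + Kd) Cb + Ctot Rtot = 0 whose smaller root
# is the physical one. The textbook form (b - sqrt(b^2 - 4ac)) / 2 loses
# precision when Cb << b (weak binding); the equivalent rationalized form
# 2 Ctot Rtot / (b + sqrt(...)) is stable everywhere and is used here.

#' Solve quasi-equilibrium antibody-target binding
#'
#' Partitions total antibody and total target into free and complexed
#' species under the assumption that association/dissociation is fast
#' relative to target turnover and transport, so binding is always at
#' equilibrium.
#'
#' @param Ctot Total antibody concentration, nM (vectorized, >= 0).
#' @param Rtot Total target concentration, nM (vectorized, >= 0).
#' @param Kd Dissociation constant, nM (> 0).
#' @return A list with numeric components `Cf` (free antibody), `Cb`
#'   (complex) and `Rfree` (free target), each the length of the longer
#'   input; `Cf * Rfree = Kd * Cb` holds to floating-point accuracy.
#' @examples
#' quasi_equilibrium_bind(10, 10, 1)  # strong binding, Cb ~ 7.30
#' @export
quasi_equilibrium_bind <- function(Ctot, Rtot, Kd) {
  if (!is.numeric(Ctot) || !is.numeric(Rtot) || any(!is.finite(Ctot)) ||
      any(!is.finite(Rtot)) || any(Ctot < 0) || any(Rtot < 0)) {
    stop_invalid("Ctot and Rtot must be finite and non-negative")
  }
  if (!is.numeric(Kd) || any(!is.finite(Kd)) || any(Kd <= 0)) {
    stop_invalid("Kd must be finite and > 0")
  }
  b <- Ctot + Rtot + Kd
  disc <- b * b - 4 * Ctot * Rtot
  disc[disc < 0] <- 0  # guard rounding; exact disc >= Kd^2 > 0
  Cb <- 2 * Ctot * Rtot / (b + sqrt(disc))
  # clamp to the feasible box against last-ulp excursions
  Cb <- pmin(Cb, Ctot, Rtot)
  list(Cf = Ctot - Cb, Cb = Cb, Rfree = Rtot - Cb)
}
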