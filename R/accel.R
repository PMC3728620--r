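#' Effective endocytic time constant of a burst
#'
#' Composes the two phases of activity dependence: a multiplicative
#' acceleration of the base time constant by the acceleration state at
#' the end of the burst, and an additive linear slowing in the number of
#' APs,
#' `tau_eff = tau1 * (1 - alpha_max * a_end) + slope_m * (n_ap - 1)`.
#' The value is frozen per burst (evaluated at burst end): a decay is
#' fitted with a single time constant, so within-decay modulation is not
#' observable.
#'
#' @param cell a [CellKinetics-class] object.
#' @param n_ap number of APs in the burst.
#' @param a_end acceleration state at the end of the burst, in `[0, 1]`.
#' @return Effective time constant (s), strictly positive.
#' @examples
#' cell <- CellKinetics(tau1 = 6.09, slope_m = 0.058, alpha_max = 0)
#' effectiveTau(cell, n_ap = 100)   # 6.09 + 0.058 * 99
#' @export
effectiveTau <- function(cell, n_ap, a_end = 0) {
  stopifnot(is(cell, "CellKinetics"))
  if (any(!is.finite(c(n_ap, a_end))))
    stop("non-finite parameters in effectiveTau()")
  if (any(a_end < 0 | a_end > 1)) stop("a_end must be in [0, 1]")
  tau <- cell@tau1 * (1 - cell@alpha_max * a_end) + cell@slope_m * (n_ap - 1)
  if (any(tau <= 0)) stop("effective tau must be strictly positive")
  tau
}

# Relaxation survival factor of the acceleration state over an
# inter-event interval dt: exp(-(dt/tau_pers)^pers_shape).
# pers_shape = 1 is a plain exponential decay; the default shape > 1
# makes the loss of acceleration switch-like (retained at ~20 s,
# dissipated by ~30 s). Applied once per inter-event interval.
.accelSurvival <- function(dt, cell) {
  if (any(dt < 0)) stop("negative elapsed time: events must be non-decreasing")
  exp(-(dt / cell@tau_pers)^cell@pers_shape)
}

#' Update the acceleration state
#'
#' Per AP the state is incremented saturatingly,
#' `a <- a + delta_a * (1 - a)`; between events it relaxes by the
#' survival factor `exp(-(dt / tau_pers)^pers_shape)` applied to the
#' full inter-event interval. The state always stays in `[0, 1]`.
#'
#' @param state an [AccelState-class] object.
#' @param cell a [CellKinetics-class] object.
#' @param ap_time time of an AP (s); the state first relaxes over the
#'   interval since `t_last`, then receives the AP increment. Omit to
#'   apply pure relaxation via `elapsed`.
#' @param elapsed elapsed time without an AP (s); mutually exclusive
#'   with `ap_time`.
#' @return The updated [AccelState-class].
#' @examples
#' s <- AccelState()
#' cell <- defaultKinetics("37C")
#' s <- updateAccelState(s, cell, ap_time = 0)
#' updateAccelState(s, cell, elapsed = cell@tau_pers)
#' @export
updateAccelState <- function(state, cell, ap_time = NULL, elapsed = NULL) {
  stopifnot(is(state, "AccelState"), is(cell, "CellKinetics"))
  if (!is.null(ap_time) && !is.null(elapsed))
    stop("give either ap_time or elapsed, not both")
  a <- state@a
  if (!is.null(elapsed)) {
    a <- a * .accelSurvival(elapsed, cell)
    return(new("AccelState", a = a,
               t_last = if (is.finite(state@t_last)) state@t_last + elapsed else state@t_last))
  }
  if (is.null(ap_time)) stop("give ap_time or elapsed")
  if (is.finite(state@t_last)) {
    dt <- ap_time - state@t_last
    if (dt < 0) stop("AP times must be non-decreasing")
    a <- a * .accelSurvival(dt, cell)
  }
  a <- a + cell@delta_a * (1 - a)
  new("AccelState", a = min(max(a, 0), 1), t_last = ap_time)
}

# Acceleration state after an n_ap burst at `freq` Hz starting from a0,
# with the first AP receiving no prior relaxation (a0 is the state just
# before the first AP of the burst).
.accelAfterBurst <- function(a0, n_ap, freq, cell) {
  a <- a0
  surv <- .accelSurvival(1 / freq, cell)
  for (i in seq_len(n_ap)) {
    if (i > 1) a <- a * surv
    a <- a + cell@delta_a * (1 - a)
  }
  a
}

# Per-burst effective time constants for a whole protocol: threads the
# acceleration state through all bursts (relaxing over inter-burst gaps,
# measured last-AP to first-AP) and freezes tau_eff at each burst end.
.burstTaus <- function(cell, protocol) {
  b <- protocol@bursts
  nb <- nrow(b)
  tau <- numeric(nb)
  a_end <- numeric(nb)
  a <- 0
  prev_last <- NA_real_
  for (i in seq_len(nb)) {
    if (i > 1) a <- a * .accelSurvival(b$onset[i] - prev_last, cell)
    a <- .accelAfterBurst(a, b$n_ap[i], b$freq[i], cell)
    prev_last <- b$onset[i] + (b$n_ap[i] - 1) / b$freq[i]
    a_end[i] <- a
    tau[i] <- effectiveTau(cell, b$n_ap[i], a)
  }
  list(tau = tau, a_end = a_end)
}
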