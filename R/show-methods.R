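#' @describeIn StimulusProtocol-class compact display
#' @param object object to display
#' @export
setMethod("show", "StimulusProtocol", function(object) {
  b <- object@bursts
  cat("StimulusProtocol:", nrow(b), "burst(s),",
      paste0(object@temperature, ","), object@ca_mM, "mM Ca2+,",
      object@condition, "\n")
  cat("  bursts:", paste(sprintf("%d AP @ %g Hz (t=%g s)",
      b$n_ap, b$freq, b$onset), collapse = "; "), "\n")
  cat("  duration:", object@trace_duration, "s @",
      object@sample_interval, "s/sample\n")
})

#' @describeIn CellKinetics-class compact display
#' @param object object to display
#' @export
setMethod("show", "CellKinetics", function(object) {
  cat("CellKinetics: tau1 =", signif(object@tau1, 4), "s, slope =",
      signif(object@slope_m, 4), "s/AP\n")
  cat("  acceleration: alpha_max =", signif(object@alpha_max, 4),
      ", delta_a =", signif(object@delta_a, 4),
      ", tau_pers =", signif(object@tau_pers, 4), "s (shape",
      signif(object@pers_shape, 3), ")\n")
  cat("  reacidification:", signif(object@tau_reacid, 4),
      "s; pool:", object@n_vesicles, "vesicles, p_release =",
      object@p_release, "\n")
})

#' @describeIn FluorescenceTrace-class compact display
#' @param object object to display
#' @export
setMethod("show", "FluorescenceTrace", function(object) {
  cat("FluorescenceTrace:", length(object@t), "samples over",
      signif(max(object@t), 4), "s; peak dF =",
      signif(max(object@dF), 4), "\n")
  if (!is.null(object@meta$cell_id))
    cat("  cell:", object@meta$cell_id, "\n")
})

#' @describeIn EndoFit-class compact display
#' @param object object to display
#' @export
setMethod("show", "EndoFit", function(object) {
  if (!object@converged) {
    cat("EndoFit (", object@method, "): not converged\n", sep = "")
    return(invisible(NULL))
  }
  cat(sprintf("EndoFit (%s): tau = %.3f +/- %.3f s, adj R2 = %.4f (n = %d)\n",
      object@method, object@tau, object@tau_se, object@adj_r2,
      as.integer(object@n_points)))
})

#' @describeIn TuningCurveResult-class compact display
#' @param object object to display
#' @export
setMethod("show", "TuningCurveResult", function(object) {
  cat("TuningCurveResult for", object@cell_id, "\n")
  print(object@fits, row.names = FALSE, digits = 4)
  if (is.finite(object@slope))
    cat(sprintf("  slope = %.4f +/- %.4f s/AP; intercept (1 AP) = %.3f +/- %.3f s\n",
        object@slope, object@slope_se, object@intercept,
        object@intercept_se))
})

#' Fitted time constants of a tuning curve
#' @param curve a [TuningCurveResult-class].
#' @return Named numeric vector of tau (s) by AP count.
#' @export
curveTaus <- function(curve) {
  stopifnot(is(curve, "TuningCurveResult"))
  stats::setNames(curve@fits$tau, curve@fits$n_ap)
}

#' Activity-dependence slope of a tuning curve
#' @param curve a [TuningCurveResult-class].
#' @return Numeric: the OLS slope (s/AP).
#' @export
curveSlope <- function(curve) {
  stopifnot(is(curve, "TuningCurveResult"))
  curve@slope
}

#' Predicted 1 AP time constant (regression intercept) of a curve
#' @param curve a [TuningCurveResult-class].
#' @return Numeric: the extrapolated 1 AP time constant (s).
#' @export
curveIntercept <- function(curve) {
  stopifnot(is(curve, "TuningCurveResult"))
  curve@intercept
}
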