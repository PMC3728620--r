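#' Apply a dynamin genotype preset to a cell's kinetics
#'
#' Presets encode the dynamin phospho-regulation phenotypes:
#' * `control`, `dyn1_rescue`: unchanged.
#' * `S774_8A` (phospho-deficient): the acceleration state is locked on;
#'   the base time constant is scaled by `(1 - alpha_max)` and
#'   modulation removed (`alpha_max = 0`, `delta_a` irrelevant) --
#'   endocytosis is constitutively fast across stimuli.
#' * `S774_8D` (phosphomimetic): the acceleration state is locked off
#'   (`alpha_max = 0`, base tau unchanged) -- constitutively slow.
#'   Both serine mutants retain a residual activity-dependent slowing
#'   (`slope_m` scaled by `mutant_slope_factor`), strong enough to show
#'   slowing at very large stimuli (300 AP) but leaving the 10-100 AP
#'   range flat, as the phospho-locked phenotype shows.
#' * `dyn13_DKO`: `tau1` multiplied by `dko_factor` (>= 10-fold slowing)
#'   and all activity-dependent modulation disabled.
#' * `dyn2_rescue`: partial rescue, `tau1` multiplied by
#'   `dyn2_factor` (approximate), modulation disabled.
#'
#' @param cell a [CellKinetics-class].
#' @param genotype one of `"control"`, `"dyn1_rescue"`, `"dyn13_DKO"`,
#'   `"S774_8A"`, `"S774_8D"`, `"dyn2_rescue"`.
#' @param mutant_slope_factor residual slowing-slope multiplier of the
#'   phospho-mutants (default 0.22).
#' @param dko_factor,dyn2_factor slowing multipliers for the knockout
#'   and the dynamin 2 partial rescue.
#' @return The transformed [CellKinetics-class].
#' @examples
#' base <- defaultKinetics("37C")
#' applyGenotype(base, "S774_8A")@tau1 < base@tau1
#' @export
applyGenotype <- function(cell, genotype, mutant_slope_factor = 0.22,
                          dko_factor = 12, dyn2_factor = 3) {
  stopifnot(is(cell, "CellKinetics"))
  if (!genotype %in% .genotypes)
    stop("unknown genotype: ", genotype)
  out <- cell
  switch(genotype,
    control = , dyn1_rescue = NULL,
    S774_8A = {
      out@tau1 <- cell@tau1 * (1 - cell@alpha_max)
      out@alpha_max <- 0
      out@slope_m <- cell@slope_m * mutant_slope_factor
    },
    S774_8D = {
      out@alpha_max <- 0
      out@slope_m <- cell@slope_m * mutant_slope_factor
    },
    dyn13_DKO = {
      out@tau1 <- cell@tau1 * dko_factor
      out@alpha_max <- 0
      out@slope_m <- 0
    },
    dyn2_rescue = {
      out@tau1 <- cell@tau1 * dyn2_factor
      out@alpha_max <- 0
      out@slope_m <- 0
    })
  validObject(out)
  out
}

#' Cortical-neuron kinetics for genotype comparisons
#'
#' The dynamin genotype experiments are carried out in cortical
#' neurons, which differ from hippocampal ones in their tuning curve:
#' the acceleration phase is shifted to larger stimuli and the slowing
#' phase only becomes evident at very large stimuli. This preset
#' recalibrates `delta_a` and `slope_m` of a base cell so that the
#' noise-free model shows the cortical control benchmarks: 21 %
#' acceleration of the time constant from 10 AP to 100 AP and 66 %
#' slowing from 100 AP to 300 AP (10 Hz).
#'
#' @param base a [CellKinetics-class] (default: the 37C defaults).
#' @param accel_10_100 fractional acceleration between 10 and 100 AP.
#' @param slow_100_300 fractional slowing between 100 and 300 AP.
#' @return The recalibrated [CellKinetics-class].
#' @export
corticalKinetics <- function(base = defaultKinetics("37C"),
                             accel_10_100 = 0.21, slow_100_300 = 0.66) {
  stopifnot(is(base, "CellKinetics"))
  mt <- function(cc, n) effectiveTau(cc, n, .accelAfterBurst(0, n, 10, cc))
  resid <- function(p) {
    cc <- base
    cc@delta_a <- p[1]; cc@slope_m <- p[2]
    tv <- vapply(c(10, 100, 300), function(n) mt(cc, n), numeric(1))
    c((tv[1] - tv[2]) / tv[1] - accel_10_100,
      (tv[3] - tv[2]) / tv[2] - slow_100_300)
  }
  sol <- pracma::fsolve(resid, c(base@delta_a / 3, base@slope_m))
  if (sol$x[1] <= 0 || sol$x[1] > 1 || sol$x[2] <= 0)
    stop("cortical calibration found no solution in bounds")
  out <- base
  out@delta_a <- sol$x[1]; out@slope_m <- sol$x[2]
  validObject(out)
  out
}

# Calibrated 4 mM Ca slope multiplier from the shipped 30C config.
.shippedCaSlopeFactor <- function() {
  path <- system.file("extdata", "defaults_30C.yaml", package = "pHendo")
  if (nzchar(path)) {
    cfg <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
    if (!is.null(cfg$condition$ca_slope_factor))
      return(cfg$condition$ca_slope_factor)
  }
  8
}

#' Apply an external-calcium / pharmacology condition preset
#'
#' * 2 mM Ca2+, control: unchanged (the reference condition).
#' * 4 mM Ca2+: the slowing slope is multiplied by `ca_slope_factor`
#'   (default: the shipped calibrated value, chosen so the
#'   fit-protocol-measured population-mean slope increase is the ~700%
#'   benchmark; the generator-level multiplier is slightly larger than
#'   8 because the measured slope is concave in the true slope) while
#'   the extrapolated 1 AP intercept is unchanged; the per-AP
#'   acceleration increment `delta_a`
#'   is doubled (`ca_delta_factor`), reflecting greater Ca2+ influx per
#'   AP, which accelerates the observed single-AP response without
#'   moving the regression intercept.
#' * `EGTA` (slow Ca2+ chelation): activity-dependent slowing is
#'   eliminated (`slope_m = 0`), all time constants are scaled up by
#'   `egta_slow_factor`, and the acceleration amplitude is reduced to a
#'   modest residual (`min(alpha_max, egta_alpha_residual)`), which is
#'   what unmasks a small acceleration phase at low stimuli.
#' * `bafilomycin`: kinetic parameters unchanged; requenching is
#'   disabled at simulation time (see [simulateTrace()]).
#'
#' @param cell a [CellKinetics-class].
#' @param condition `"control"`, `"EGTA"` or `"bafilomycin"`.
#' @param ca_mM external calcium, 2 or 4 mM.
#' @param ca_slope_factor slope multiplier at 4 mM (default: shipped
#'   calibrated value, ~8; falls back to 8 when no config is
#'   installed).
#' @param ca_delta_factor `delta_a` multiplier at 4 mM (default 2).
#' @param egta_slow_factor uniform tau scale-up under EGTA.
#' @param egta_alpha_residual residual acceleration amplitude under EGTA.
#' @return The transformed [CellKinetics-class].
#' @export
applyCondition <- function(cell, condition = "control", ca_mM = 2,
                           ca_slope_factor = .shippedCaSlopeFactor(),
                           ca_delta_factor = 2,
                           egta_slow_factor = 1.3,
                           egta_alpha_residual = 0.15) {
  stopifnot(is(cell, "CellKinetics"))
  if (!condition %in% c("control", "EGTA", "bafilomycin"))
    stop("unsupported condition: ", condition)
  if (!ca_mM %in% c(2, 4))
    stop("unsupported calcium concentration: ", ca_mM, " mM")
  out <- cell
  if (ca_mM == 4) {
    out@slope_m <- cell@slope_m * ca_slope_factor
    out@delta_a <- min(1, cell@delta_a * ca_delta_factor)
  }
  if (condition == "EGTA") {
    out@slope_m <- 0
    out@tau1 <- out@tau1 * egta_slow_factor
    out@tau_reacid <- out@tau_reacid
    out@alpha_max <- min(out@alpha_max, egta_alpha_residual)
  }
  validObject(out)
  out
}
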