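#' Calibrate the default kinetic parameter sets
#'
#' Root-finds the activity-dependence parameters so that the model
#' reproduces the benchmark tuning-curve constraints at physiological
#' temperature:
#' \itemize{
#'   \item acceleration `(tau(5) - tau(25)) / tau(5) = 0.42`,
#'   \item slowing `(tau(100) - tau(25)) / tau(25) = 0.18`,
#'   \item slowing `(tau(300) - tau(100)) / tau(100) = 0.55`
#' }
#' (all at 10 Hz), and the persistence parameters so that a 5 AP burst
#' delivered 20 s after a prior 5 AP burst reaches the continuous-10 AP
#' time constant within 10 %, while at 30 s spacing the residual
#' reduction of tau is 0.3 % -- dissipated, i.e. below what the
#' population protocols can detect.
#'
#' Three calibration levels are available. `"model"` imposes the ratio
#' constraints on the closed-form effective time constants
#' ([effectiveTau()]). `"measured"` imposes them on the time constants
#' *measured by the fitting protocol* applied to noise-free expected
#' traces of the mean cell ([expectedTrace()] + [fitExpOffset()]): the
#' benchmark values are themselves products of the offset-fit protocol,
#' which carries a small systematic compression, so calibrating through
#' the measurement reproduces them where they were observed.
#' `"population"` (the shipped default) additionally averages the
#' per-cell measured quantity over the lognormal cell-to-cell parameter
#' distribution (by Gauss-Hermite quadrature), because the benchmark
#' values are population means of per-cell measurements, which are
#' nonlinear in the drawn parameters.
#'
#' At 30C there is no resolvable average acceleration; `tau1` and
#' `slope_m` are set (at the same level) so the pipeline recovers the
#' benchmark population means: predicted 1 AP time constant 8.31 s and
#' slope 0.058 s/AP over 10-100 AP, with a modest fixed acceleration
#' amplitude (`alpha_max = 0.10`) that stays below noise but is
#' unmasked when slowing is removed (EGTA).
#'
#' @param temperature `"37C"` or `"30C"`.
#' @param level `"population"`, `"measured"` or `"model"`.
#' @param tau1_cv,slope_cv cell-to-cell CVs used by the
#'   `"population"` level (defaults follow the temperature's shipped
#'   population spread).
#' @param tau1_37 base 1 AP time constant fixed at 37C (s).
#' @param accel_5_25,slow_25_100,slow_100_300 the three ratio
#'   constraints.
#' @param pers_20s_tol relative gap allowed between the 20 s-spaced
#'   second burst and the continuous 10 AP time constant.
#' @param pers_30s_resid residual fractional reduction of tau at 30 s
#'   spacing.
#' @return A list with `kinetics` (the calibrated
#'   [CellKinetics-class]), `residuals` (constraint residuals at the
#'   solution), `level` and `temperature`.
#' @examples
#' \donttest{
#' cal <- calibrateDefaults("37C", level = "model")
#' max(abs(cal$residuals))  # < 1e-6
#' }
#' @export
calibrateDefaults <- function(temperature = c("37C", "30C"),
                              level = c("population", "measured", "model"),
                              tau1_cv = if (temperature == "37C") 0.30 else 0.52,
                              slope_cv = if (temperature == "37C") 0.50 else 1.00,
                              tau1_37 = 12,
                              accel_5_25 = 0.42, slow_25_100 = 0.18,
                              slow_100_300 = 0.55,
                              pers_20s_tol = 0.10, pers_30s_resid = 0.003) {
  temperature <- match.arg(temperature)
  level <- match.arg(level)

  base <- CellKinetics(tau1 = tau1_37, slope_m = 0.015, alpha_max = 0.6,
                       delta_a = 0.12, tau_pers = 24.5, pers_shape = 4.1,
                       tau_reacid = 1.6)

  modelTaus <- function(cell, n_aps) {
    vapply(n_aps, function(n) {
      a <- .accelAfterBurst(0, n, 10, cell)
      effectiveTau(cell, n, a)
    }, numeric(1))
  }
  # Deterministic noise-free measurement: expected trace + profiled
  # exponential-offset fit (identical optimum to the pipeline's
  # Levenberg-Marquardt fit on noiseless data, but much cheaper).
  measuredTaus <- function(cell, n_aps) {
    cfg <- FitConfig(temperature)
    vapply(n_aps, function(n) {
      proto <- StimulusProtocol(n, temperature = temperature,
                                post_window = cfg@offset_t0 + cfg@max_window + 5)
      tr <- expectedTrace(cell, proto)
      .fitTauFast(tr, nrow(proto@bursts), cfg)
    }, numeric(1))
  }
  tauFun <- if (level == "model") modelTaus else measuredTaus

  # Gauss-Hermite quadrature over the lognormal (tau1, slope_m)
  # cell-to-cell distribution; fn(cell) must return a numeric vector.
  popAverage <- function(cell, fn, n_nodes = 7) {
    gh <- pracma::gaussHermite(n_nodes)
    z <- gh$x * sqrt(2); w <- gh$w / sqrt(pi)
    s1 <- sqrt(log(1 + tau1_cv^2)); s2 <- sqrt(log(1 + slope_cv^2))
    acc <- NULL; tot <- 0
    for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
      cc <- cell
      cc@tau1 <- cell@tau1 * exp(s1 * z[i] - s1^2 / 2)
      cc@slope_m <- cell@slope_m * exp(s2 * z[j] - s2^2 / 2)
      v <- fn(cc) * (w[i] * w[j])
      acc <- if (is.null(acc)) v else acc + v
      tot <- tot + w[i] * w[j]
    }
    acc / tot
  }

  if (temperature == "37C") {
    cellRatios <- function(cell) {
      tv <- tauFun(cell, c(5, 25, 100, 300))
      c((tv[1] - tv[2]) / tv[1],
        (tv[3] - tv[2]) / tv[2],
        (tv[4] - tv[3]) / tv[3])
    }
    ratioResid <- function(p, cell) {
      cell@alpha_max <- p[1]; cell@delta_a <- p[2]; cell@slope_m <- p[3]
      r <- if (level == "population") popAverage(cell, cellRatios)
        else cellRatios(cell)
      r - c(accel_5_25, slow_25_100, slow_100_300)
    }
    persResid <- function(q, cell) {
      cell@tau_pers <- q[1]; cell@pers_shape <- q[2]
      a5 <- .accelAfterBurst(0, 5, 10, cell)
      t5 <- effectiveTau(cell, 5, a5)
      t10 <- effectiveTau(cell, 10, .accelAfterBurst(0, 10, 10, cell))
      tau2 <- function(gap) {
        a <- .accelAfterBurst(a5 * .accelSurvival(gap, cell), 5, 10, cell)
        effectiveTau(cell, 5, a)
      }
      c(abs(tau2(20) - t10) / t10 - pers_20s_tol,
        (t5 - tau2(30)) / t5 - pers_30s_resid)
    }

    cell <- base
    p <- c(cell@alpha_max, cell@delta_a, cell@slope_m)
    q <- c(cell@tau_pers, cell@pers_shape)
    for (pass in 1:3) {
      sol <- pracma::fsolve(function(pp) ratioResid(pp, cell), p)
      p <- sol$x
      if (p[1] < 0 || p[1] >= 1 || p[2] < 0 || p[2] > 1 || p[3] <= 0)
        stop("calibration found no solution in bounds; residuals: ",
             paste(signif(sol$fval, 3), collapse = ", "))
      cell@alpha_max <- p[1]; cell@delta_a <- p[2]; cell@slope_m <- p[3]
      solq <- pracma::fsolve(function(qq) persResid(qq, cell), q)
      q <- solq$x
      if (any(q <= 0))
        stop("persistence calibration found no solution in bounds")
      cell@tau_pers <- q[1]; cell@pers_shape <- q[2]
    }
    resid <- c(ratioResid(p, cell), persResid(q, cell))
    names(resid) <- c("accel_5_25", "slow_25_100", "slow_100_300",
                      "pers_20s", "pers_30s")
    validObject(cell)
    return(list(kinetics = cell, residuals = resid, level = level,
                temperature = temperature))
  }

  # 30C: carry over the acceleration-state dynamics from the 37C solve,
  # fix a modest alpha_max, and set (tau1, slope_m) so the benchmark
  # population means are recovered at the requested level.
  cal37 <- calibrateDefaults("37C", level = level, tau1_37 = tau1_37,
                             accel_5_25 = accel_5_25,
                             slow_25_100 = slow_25_100,
                             slow_100_300 = slow_100_300,
                             pers_20s_tol = pers_20s_tol,
                             pers_30s_resid = pers_30s_resid)$kinetics
  cell <- cal37
  cell@alpha_max <- 0.10
  cell@tau_reacid <- 3.2
  cell@tau1 <- 8.31
  cell@slope_m <- 0.058
  if (level == "model") {
    resid <- c(intercept = 0, slope = 0)
    validObject(cell)
    return(list(kinetics = cell, residuals = resid, level = level,
                temperature = "30C"))
  }
  cellReg <- function(cc) {
    tv <- measuredTaus(cc, c(10, 25, 50, 100))
    fit <- stats::lm(tv ~ I(c(10, 25, 50, 100) - 1))
    c(stats::coef(fit)[[1]], stats::coef(fit)[[2]])
  }
  target <- function(p) {
    cc <- cell
    cc@tau1 <- p[1]; cc@slope_m <- p[2]
    r <- if (level == "population") popAverage(cc, cellReg) else cellReg(cc)
    r - c(8.31, 0.058)
  }
  sol <- pracma::fsolve(target, c(8.31, 0.058))
  if (sol$x[1] <= 0 || sol$x[2] <= 0)
    stop("30C calibration found no solution in bounds")
  cell@tau1 <- sol$x[1]; cell@slope_m <- sol$x[2]
  resid <- c(intercept = sol$fval[1], slope = sol$fval[2])
  validObject(cell)

  # Calcium preset: the ~700% slope increase is a measured population
  # mean; the generator-level multiplier is calibrated so the measured
  # (fit-protocol) geometric-mean slope ratio equals 8. Nodes whose
  # measured slope is non-positive (a measurement floor at near-zero
  # slopes) are excluded with weight renormalisation.
  ca_factor <- 8
  if (level == "population") {
    cellSlope <- function(cc) {
      tv <- measuredTaus(cc, c(25, 50, 100))
      stats::coef(stats::lm(tv ~ c(25, 50, 100)))[[2]]
    }
    popLogRatio <- function(f) {
      num <- 0; den <- 0
      gh <- pracma::gaussHermite(7)
      z <- gh$x * sqrt(2); w <- gh$w / sqrt(pi)
      s1 <- sqrt(log(1 + tau1_cv^2)); s2 <- sqrt(log(1 + slope_cv^2))
      for (i in 1:7) for (j in 1:7) {
        cc <- cell
        cc@tau1 <- cell@tau1 * exp(s1 * z[i] - s1^2 / 2)
        cc@slope_m <- cell@slope_m * exp(s2 * z[j] - s2^2 / 2)
        g2 <- cellSlope(applyCondition(cc, "control", 2))
        g4 <- cellSlope(applyCondition(cc, "control", 4,
                                       ca_slope_factor = f))
        if (is.finite(g2) && is.finite(g4) && g2 > 0 && g4 > 0) {
          num <- num + w[i] * w[j] * log(g4 / g2)
          den <- den + w[i] * w[j]
        }
      }
      num / den
    }
    ca_factor <- stats::uniroot(function(f) popLogRatio(f) - log(8),
                                c(4, 18), tol = 1e-4)$root
    resid <- c(resid, ca_ratio = exp(popLogRatio(ca_factor)) - 8)
  }
  list(kinetics = cell, residuals = resid, level = level,
       temperature = "30C", ca_slope_factor = ca_factor)
}

#' Load the shipped default kinetics for a temperature
#'
#' Reads the calibrated default configuration shipped with the package
#' (produced by [calibrateDefaults()] at the `"measured"` level).
#'
#' @param temperature `"37C"` or `"30C"`.
#' @return A [CellKinetics-class].
#' @examples
#' defaultKinetics("37C")@alpha_max
#' @export
defaultKinetics <- function(temperature = c("37C", "30C")) {
  temperature <- match.arg(temperature)
  cfg <- readKineticsConfig(system.file("extdata",
    paste0("defaults_", temperature, ".yaml"), package = "pHendo",
    mustWork = TRUE))
  cfg$kinetics
}

#' Default population specification for a temperature
#'
#' Builds a [PopulationSpec-class] from the shipped defaults: the
#' calibrated base kinetics plus the cell-to-cell CVs of the slope and
#' the predicted 1 AP time constant (100 % and 52 % at 30C; smaller
#' spread at 37C).
#'
#' @param n_cells number of cells.
#' @param temperature `"37C"` or `"30C"`.
#' @param genotype genotype preset.
#' @param rng_seed integer master seed.
#' @return A [PopulationSpec-class].
#' @export
defaultPopulation <- function(n_cells, temperature = c("37C", "30C"),
                              genotype = "control", rng_seed = 1L) {
  temperature <- match.arg(temperature)
  cfg <- readKineticsConfig(system.file("extdata",
    paste0("defaults_", temperature, ".yaml"), package = "pHendo",
    mustWork = TRUE))
  PopulationSpec(n_cells, base = cfg$kinetics,
                 tau1_cv = cfg$population$tau1_cv,
                 slope_cv = cfg$population$slope_cv,
                 genotype = genotype, rng_seed = rng_seed)
}

#' Read a kinetics configuration file
#'
#' Structured-text (YAML) configuration with a `kinetics` section (the
#' [CellKinetics-class] fields), an optional `population` section
#' (`tau1_cv`, `slope_cv`) and an optional `fit` section.
#'
#' @param path file path.
#' @return List with elements `kinetics` ([CellKinetics-class]),
#'   `population`, `fit` and any other sections present.
#' @export
readKineticsConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kinetics))
    stop("config is missing the 'kinetics' section: ", path)
  cfg$kinetics <- do.call(CellKinetics, cfg$kinetics)
  cfg
}

#' Write a kinetics configuration file
#'
#' @param kinetics a [CellKinetics-class].
#' @param path output file path.
#' @param population optional list (`tau1_cv`, `slope_cv`).
#' @param fit optional list of fit settings.
#' @param extra optional named list of additional sections.
#' @return `path`, invisibly.
#' @export
writeKineticsConfig <- function(kinetics, path, population = NULL,
                                fit = NULL, extra = NULL) {
  stopifnot(is(kinetics, "CellKinetics"))
  kin <- lapply(slotNames(kinetics), function(s) slot(kinetics, s))
  names(kin) <- slotNames(kinetics)
  cfg <- c(list(kinetics = kin),
           if (!is.null(population)) list(population = population),
           if (!is.null(fit)) list(fit = fit),
           extra)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}
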