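#' @import methods
NULL

#' StimulusProtocol: ordered action-potential bursts driving a recording
#'
#' Describes one stimulation protocol applied to a cell: a set of
#' non-overlapping AP bursts (each with an AP count, frequency and onset
#' time), the recording temperature, the external calcium concentration,
#' an optional pharmacological condition, the total trace duration and
#' the sampling interval. The protocol drives both the simulator and the
#' analysis windows (decay fits start at the end of each burst).
#'
#' @slot bursts data.frame with columns `n_ap` (APs per burst, >= 1),
#'   `freq` (Hz, > 0) and `onset` (s); bursts must be time-ordered and
#'   non-overlapping.
#' @slot temperature `"30C"` or `"37C"`.
#' @slot ca_mM external Ca2+ in mM (2 or 4).
#' @slot condition `"control"`, `"EGTA"` or `"bafilomycin"`.
#' @slot trace_duration total recorded time (s); must cover the end of
#'   the last burst plus a post-stimulus window.
#' @slot sample_interval sampling interval (s).
#'
#' @export
setClass("StimulusProtocol",
  representation(
    bursts = "data.frame",
    temperature = "character",
    ca_mM = "numeric",
    condition = "character",
    trace_duration = "numeric",
    sample_interval = "numeric"
  )
)

setValidity("StimulusProtocol", function(object) {
  b <- object@bursts
  msg <- character()
  if (!all(c("n_ap", "freq", "onset") %in% names(b)))
    msg <- c(msg, "bursts must have columns n_ap, freq, onset")
  else {
    if (any(b$n_ap < 1) || any(b$n_ap != round(b$n_ap)))
      msg <- c(msg, "n_ap must be integer >= 1")
    if (any(b$freq <= 0)) msg <- c(msg, "freq must be > 0")
    if (is.unsorted(b$onset, strictly = TRUE) && nrow(b) > 1)
      msg <- c(msg, "bursts must be time-ordered")
    if (nrow(b) > 1) {
      ends <- b$onset + (b$n_ap - 1) / b$freq
      if (any(ends[-nrow(b)] >= b$onset[-1]))
        msg <- c(msg, "bursts must be non-overlapping")
    }
  }
  if (!object@temperature %in% c("30C", "37C"))
    msg <- c(msg, "temperature must be '30C' or '37C'")
  if (!object@condition %in% c("control", "EGTA", "bafilomycin"))
    msg <- c(msg, "condition must be control, EGTA or bafilomycin")
  if (object@sample_interval <= 0) msg <- c(msg, "sample_interval must be > 0")
  if (nrow(b) > 0) {
    last_end <- max(b$onset + (b$n_ap - 1) / b$freq)
    if (object@trace_duration <= last_end)
      msg <- c(msg, "trace_duration must extend beyond the last burst")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusProtocol
#'
#' @param bursts data.frame with columns `n_ap`, `freq`, `onset`, or a
#'   numeric vector of AP counts (combined with `freq` and `spacing` to
#'   build onsets).
#' @param freq stimulation frequency in Hz (used when `bursts` is a
#'   vector).
#' @param onset onset of the first burst (s).
#' @param spacing inter-burst interval, end of one burst to the start of
#'   the next (s; used when `bursts` is a vector of several counts).
#' @param temperature `"30C"` or `"37C"`.
#' @param ca_mM external Ca2+ (mM).
#' @param condition `"control"`, `"EGTA"` or `"bafilomycin"`.
#' @param post_window recording time retained after the last burst (s).
#' @param sample_interval sampling interval (s).
#'
#' @return A [StimulusProtocol-class] object.
#' @examples
#' StimulusProtocol(100)                       # single 100 AP 10 Hz burst
#' StimulusProtocol(rep(5, 5), spacing = 30)   # 5 x 5 AP, 30 s apart
#' @export
StimulusProtocol <- function(bursts, freq = 10, onset = 10, spacing = 30,
                             temperature = "37C", ca_mM = 2,
                             condition = "control", post_window = 80,
                             sample_interval = 0.5) {
  if (!is.data.frame(bursts)) {
    n_ap <- as.numeric(bursts)
    onsets <- numeric(length(n_ap))
    onsets[1] <- onset
    if (length(n_ap) > 1)
      for (i in 2:length(n_ap))
        onsets[i] <- onsets[i - 1] + (n_ap[i - 1] - 1) / freq + spacing
    bursts <- data.frame(n_ap = n_ap, freq = freq, onset = onsets)
  }
  last_end <- max(bursts$onset + (bursts$n_ap - 1) / bursts$freq)
  new("StimulusProtocol",
    bursts = bursts, temperature = temperature, ca_mM = ca_mM,
    condition = condition,
    trace_duration = last_end + post_window,
    sample_interval = sample_interval)
}

#' CellKinetics: ground-truth kinetic parameters of one simulated cell
#'
#' Kinetic parameters of the per-vesicle recycling model for a single
#' cell (its ensemble of boutons). The endocytic time constant of a
#' burst is
#' `tau_eff = tau1 * (1 - alpha_max * a) + slope_m * (n_ap - 1)`,
#' where `a` in `[0, 1]` is the acceleration state at the end of the
#' burst (see [updateAccelState()]).
#'
#' @slot tau1 base endocytic time constant extrapolated to 1 AP (s).
#' @slot slope_m activity-dependent slowing (s per AP).
#' @slot alpha_max maximal fractional acceleration of tau, in `[0, 1)`.
#' @slot delta_a per-AP increment of the acceleration state, in `[0, 1]`.
#' @slot tau_pers persistence time scale of the acceleration state (s).
#' @slot pers_shape shape of the inter-event relaxation of the
#'   acceleration state (1 = exponential; larger values give a sharper,
#'   more switch-like loss of acceleration).
#' @slot tau_reacid reacidification time constant (s).
#' @slot n_vesicles recycling-pool size of the simulated bouton ensemble.
#' @slot p_release per-AP release probability of an available vesicle.
#' @slot reprime_s repriming delay (s): time after reacidification
#'   before a vesicle rejoins the available pool for re-release.
#' @slot surface_frac baseline fraction of vesicle reporter stranded on
#'   the surface (contributes only a constant removed by baseline
#'   subtraction).
#' @slot noise_sd additive Gaussian noise per sample (a.u.; the unit is
#'   one vesicle's fluorescence).
#' @slot quench_ratio surface/lumen fluorescence ratio used by the
#'   optional pH mode (approximately 20).
#'
#' @export
setClass("CellKinetics",
  representation(
    tau1 = "numeric", slope_m = "numeric", alpha_max = "numeric",
    delta_a = "numeric", tau_pers = "numeric", pers_shape = "numeric",
    tau_reacid = "numeric", n_vesicles = "numeric", p_release = "numeric",
    reprime_s = "numeric", surface_frac = "numeric", noise_sd = "numeric",
    quench_ratio = "numeric"
  )
)

setValidity("CellKinetics", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1 && is.finite(x)
  for (s in slotNames(object))
    if (!num1(slot(object, s))) msg <- c(msg, paste0(s, " must be a finite scalar"))
  if (length(msg)) return(msg)
  if (object@tau1 <= 0) msg <- c(msg, "tau1 must be > 0")
  if (object@tau_pers <= 0) msg <- c(msg, "tau_pers must be > 0")
  if (object@pers_shape <= 0) msg <- c(msg, "pers_shape must be > 0")
  if (object@tau_reacid < 0) msg <- c(msg, "tau_reacid must be >= 0")
  if (object@alpha_max < 0 || object@alpha_max >= 1)
    msg <- c(msg, "alpha_max must be in [0, 1)")
  if (object@delta_a < 0 || object@delta_a > 1)
    msg <- c(msg, "delta_a must be in [0, 1]")
  if (object@p_release <= 0 || object@p_release > 1)
    msg <- c(msg, "p_release must be in (0, 1]")
  if (object@reprime_s < 0) msg <- c(msg, "reprime_s must be >= 0")
  if (object@surface_frac < 0 || object@surface_frac >= 1)
    msg <- c(msg, "surface_frac must be in [0, 1)")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@quench_ratio <= 1) msg <- c(msg, "quench_ratio must be > 1")
  if (object@n_vesicles < 1) msg <- c(msg, "n_vesicles must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CellKinetics object
#'
#' @param tau1,slope_m,alpha_max,delta_a,tau_pers,pers_shape,tau_reacid
#'   kinetic parameters; see [CellKinetics-class].
#' @param n_vesicles,p_release,reprime_s,surface_frac release-model
#'   parameters.
#' @param noise_sd,quench_ratio measurement-model parameters.
#' @return A [CellKinetics-class] object.
#' @examples
#' CellKinetics(tau1 = 8.31, slope_m = 0.058, alpha_max = 0)
#' @export
CellKinetics <- function(tau1 = 8.31, slope_m = 0.058, alpha_max = 0,
                         delta_a = 0.1, tau_pers = 24.5, pers_shape = 4.1,
                         tau_reacid = 3.2, n_vesicles = 1200,
                         p_release = 0.05, reprime_s = 2,
                         surface_frac = 0.02, noise_sd = 16,
                         quench_ratio = 20) {
  new("CellKinetics",
    tau1 = tau1, slope_m = slope_m, alpha_max = alpha_max,
    delta_a = delta_a, tau_pers = tau_pers, pers_shape = pers_shape,
    tau_reacid = tau_reacid, n_vesicles = n_vesicles,
    p_release = p_release, reprime_s = reprime_s,
    surface_frac = surface_frac, noise_sd = noise_sd,
    quench_ratio = quench_ratio)
}

#' PopulationSpec: distribution of kinetic parameters across cells
#'
#' Cells are drawn with lognormal cell-to-cell variability in `tau1` and
#' `slope_m` (parameterised by their means and coefficients of
#' variation), on top of a shared set of base kinetics; a genotype
#' preset is applied to every cell after drawing.
#'
#' @slot n_cells number of cells.
#' @slot tau1_mean,tau1_cv mean and CV (SD/mean) of `tau1` across cells.
#' @slot slope_mean,slope_cv mean and CV of `slope_m` across cells.
#' @slot genotype one of `"control"`, `"dyn1_rescue"`, `"dyn13_DKO"`,
#'   `"S774_8A"`, `"S774_8D"`, `"dyn2_rescue"`.
#' @slot base shared [CellKinetics-class] defaults.
#' @slot rng_seed integer master seed.
#'
#' @export
setClass("PopulationSpec",
  representation(
    n_cells = "numeric", tau1_mean = "numeric", tau1_cv = "numeric",
    slope_mean = "numeric", slope_cv = "numeric", genotype = "character",
    base = "CellKinetics", rng_seed = "numeric"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@n_cells < 1) msg <- c(msg, "n_cells must be >= 1")
  if (object@tau1_cv < 0 || object@slope_cv < 0)
    msg <- c(msg, "CVs must be >= 0")
  if (!all(is.finite(c(object@tau1_mean, object@tau1_cv,
                       object@slope_mean, object@slope_cv))))
    msg <- c(msg, "lognormal parameters must be finite")
  if (!object@genotype %in% .genotypes)
    msg <- c(msg, paste("genotype must be one of:",
                        paste(.genotypes, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

.genotypes <- c("control", "dyn1_rescue", "dyn13_DKO",
                "S774_8A", "S774_8D", "dyn2_rescue")

#' Construct a PopulationSpec
#'
#' @param n_cells number of cells.
#' @param base shared [CellKinetics-class] defaults; its `tau1` and
#'   `slope_m` serve as the population means unless overridden.
#' @param tau1_mean,tau1_cv,slope_mean,slope_cv lognormal mean/CV of the
#'   two cell-varying parameters.
#' @param genotype genotype preset applied to each cell.
#' @param rng_seed integer master seed (required for reproducibility).
#' @return A [PopulationSpec-class] object.
#' @export
PopulationSpec <- function(n_cells, base = defaultKinetics("30C"),
                           tau1_mean = base@tau1, tau1_cv = 0.52,
                           slope_mean = base@slope_m, slope_cv = 1.0,
                           genotype = "control", rng_seed = 1L) {
  new("PopulationSpec",
    n_cells = n_cells, tau1_mean = tau1_mean, tau1_cv = tau1_cv,
    slope_mean = slope_mean, slope_cv = slope_cv, genotype = genotype,
    base = base, rng_seed = as.numeric(rng_seed))
}

#' AccelState: the persistent endocytic acceleration state
#'
#' A dimensionless state `a` in `[0, 1]` that is incremented by each AP
#' (saturating) and relaxes back to zero between events, together with
#' the time of the last event. The state scales down the base endocytic
#' time constant by up to `alpha_max` (see [effectiveTau()]); its
#' relaxation encodes the persistence of endocytic acceleration for tens
#' of seconds after a burst.
#'
#' @slot a acceleration state in `[0, 1]`.
#' @slot t_last time of the most recent event (s).
#' @export
setClass("AccelState",
  representation(a = "numeric", t_last = "numeric"))

setValidity("AccelState", function(object) {
  if (object@a < 0 || object@a > 1) "a must be in [0, 1]" else TRUE
})

#' Construct an AccelState
#' @param a initial state in `[0, 1]`.
#' @param t_last time of the last event (s).
#' @return An [AccelState-class] object.
#' @export
AccelState <- function(a = 0, t_last = -Inf) new("AccelState", a = a, t_last = t_last)

#' FluorescenceTrace: a uniformly sampled, baseline-subtracted dF trace
#'
#' @slot t time vector (s, strictly increasing, uniform).
#' @slot dF baseline-subtracted fluorescence (a.u.; one vesicle = 1).
#' @slot protocol the [StimulusProtocol-class] that generated / annotates
#'   the trace.
#' @slot meta list of provenance fields (`cell_id`, `genotype`, `seed`,
#'   and for simulated traces the per-burst effective time constants
#'   `tau_eff`).
#' @export
setClass("FluorescenceTrace",
  representation(t = "numeric", dF = "numeric",
                 protocol = "StimulusProtocol", meta = "list"))

setValidity("FluorescenceTrace", function(object) {
  msg <- character()
  if (length(object@t) != length(object@dF))
    msg <- c(msg, "t and dF must have equal length")
  if (length(object@t) > 1 && any(diff(object@t) <= 0))
    msg <- c(msg, "t must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' FitConfig: settings of the post-stimulus decay fit
#'
#' @slot offset_t0 fixed temporal offset after the end of stimulation
#'   accounting for reacidification (s); fitting starts at
#'   `t_end + offset_t0`.
#' @slot window_start additional shift of the fit window start relative
#'   to `t_end + offset_t0` (s).
#' @slot window_len fit window length (s).
#' @slot baseline_mode `"fixed_zero"` (baseline-subtracted traces decay
#'   to zero) or `"free"` (baseline fitted).
#' @slot min_points minimum number of samples required in the window.
#' @slot max_window upper cap of the adaptive window (s): after a pilot
#'   fit on `window_len`, the window is widened to 4x the pilot time
#'   constant (never beyond `max_window` or the trace end) so that slow
#'   decays are not truncated. Set `max_window = window_len` for a
#'   constant window (burst-train protocols).
#' @export
setClass("FitConfig",
  representation(offset_t0 = "numeric", window_start = "numeric",
                 window_len = "numeric", baseline_mode = "character",
                 min_points = "numeric", max_window = "numeric"))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (object@offset_t0 < 0) msg <- c(msg, "offset_t0 must be >= 0")
  if (object@window_len <= 0) msg <- c(msg, "window_len must be > 0")
  if (object@min_points < 4) msg <- c(msg, "min_points must be >= 4")
  if (!object@baseline_mode %in% c("fixed_zero", "free"))
    msg <- c(msg, "baseline_mode must be 'fixed_zero' or 'free'")
  if (object@max_window < object@window_len)
    msg <- c(msg, "max_window must be >= window_len")
  if (length(msg)) msg else TRUE
})

#' Construct a FitConfig
#'
#' Default offsets follow the fitting protocol: about 2.5 s at 37C and
#' 5 s at 30C.
#'
#' @param temperature `"37C"` or `"30C"`; sets the default `offset_t0`.
#' @param offset_t0,window_start,window_len,baseline_mode,min_points,max_window
#'   see [FitConfig-class].
#' @return A [FitConfig-class] object.
#' @examples
#' FitConfig("30C")            # 5 s reacidification offset
#' FitConfig(window_len = 12, max_window = 12)  # constant short window
#' @export
FitConfig <- function(temperature = "37C",
                      offset_t0 = if (temperature == "37C") 2.5 else 5.0,
                      window_start = 0, window_len = 60,
                      baseline_mode = "fixed_zero", min_points = 4,
                      max_window = max(window_len, 180)) {
  new("FitConfig", offset_t0 = offset_t0, window_start = window_start,
      window_len = window_len, baseline_mode = baseline_mode,
      min_points = min_points, max_window = max_window)
}

#' EndoFit: result of one decay (or rise) fit
#'
#' @slot tau fitted time constant (s); for the linear method this is the
#'   amplitude-normalised 1/Rate.
#' @slot tau_se asymptotic standard error of `tau` (s).
#' @slot amplitude fitted amplitude (a.u.).
#' @slot baseline fitted or fixed baseline (a.u.).
#' @slot adj_r2 adjusted R-squared of the fit.
#' @slot method `"exp_offset"`, `"linear_rate"`, `"remaining_fraction"`
#'   or `"rising_exp"`.
#' @slot window numeric length-2, the time window used (s).
#' @slot converged logical convergence flag; when `FALSE` the numeric
#'   slots are `NA` and must not be interpreted.
#' @slot n_points number of samples in the window.
#' @export
setClass("EndoFit",
  representation(tau = "numeric", tau_se = "numeric", amplitude = "numeric",
                 baseline = "numeric", adj_r2 = "numeric",
                 method = "character", window = "numeric",
                 converged = "logical", n_points = "numeric"))

setValidity("EndoFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!is.na(object@tau) && object@tau <= 0)
      msg <- c(msg, "tau must be > 0 when converged")
    if (!is.na(object@adj_r2) && object@adj_r2 > 1 + 1e-12)
      msg <- c(msg, "adj_r2 must be <= 1")
    if (!is.na(object@tau_se) && object@tau_se < 0)
      msg <- c(msg, "tau_se must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

.EndoFit <- function(tau = NA_real_, tau_se = NA_real_,
                     amplitude = NA_real_, baseline = 0,
                     adj_r2 = NA_real_, method = "exp_offset",
                     window = c(NA_real_, NA_real_), converged = FALSE,
                     n_points = 0) {
  new("EndoFit", tau = tau, tau_se = tau_se, amplitude = amplitude,
      baseline = baseline, adj_r2 = adj_r2, method = method,
      window = window, converged = converged, n_points = n_points)
}

#' BiexpParams: parameters of the biexponential reporter model
#'
#' Two-compartment scheme: surface reporter is internalised with time
#' constant `tau_e` and requenched by reacidification with `tau_r`.
#'
#' @slot tau_e endocytosis time constant (s).
#' @slot tau_r reacidification time constant (s).
#' @export
setClass("BiexpParams",
  representation(tau_e = "numeric", tau_r = "numeric"))

setValidity("BiexpParams", function(object) {
  msg <- character()
  if (object@tau_e <= 0) msg <- c(msg, "tau_e must be > 0")
  if (object@tau_r < 0) msg <- c(msg, "tau_r must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct BiexpParams
#' @param tau_e endocytosis time constant (s).
#' @param tau_r reacidification time constant (s).
#' @return A [BiexpParams-class] object.
#' @export
BiexpParams <- function(tau_e, tau_r) new("BiexpParams", tau_e = tau_e, tau_r = tau_r)

#' TuningCurveResult: per-cell endocytosis tuning curve
#'
#' Per-stimulus decay fits of one cell plus the derived linear
#' regressions: the activity-dependent slowing slope (tau versus AP
#' number) and the endocytic-load regression (tau versus end-of-stimulus
#' dF).
#'
#' @slot cell_id cell identifier.
#' @slot fits data.frame, one row per stimulus: `n_ap`, `freq`, `tau`,
#'   `tau_se`, `adj_r2`, `converged`, `peak_dF`, `norm_tau` (filled by
#'   [normalizeCurve()]).
#' @slot slope,slope_se OLS slope of tau vs AP number (s/AP) and its SE;
#'   `NA` with fewer than 3 stimulus levels.
#' @slot intercept,intercept_se OLS intercept, the predicted 1 AP time
#'   constant (s); the regression is of tau on `n_ap - 1` so the
#'   intercept is the extrapolated 1 AP value.
#' @slot load_slope,load_slope_se,load_intercept OLS of tau vs
#'   end-of-stimulus dF (s per dF unit).
#' @slot reference reference stimulus (`n_ap`) used for normalisation,
#'   or `NA`.
#' @export
setClass("TuningCurveResult",
  representation(cell_id = "character", fits = "data.frame",
                 slope = "numeric", slope_se = "numeric",
                 intercept = "numeric", intercept_se = "numeric",
                 load_slope = "numeric", load_slope_se = "numeric",
                 load_intercept = "numeric", reference = "numeric"))
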