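#' Run a multi-stimulus protocol suite on one cell
#'
#' Simulates (or receives) repeat traces for each stimulus, averages the
#' repeats sample-by-sample before fitting, fits every post-stimulus
#' decay with [fitExpOffset()], and assembles the cell's endocytosis
#' tuning curve with the activity-dependence regressions.
#'
#' With a [CellKinetics-class] first argument, traces are simulated with
#' the small-stimulus averaging rule (up to 10 repeats); with a list of
#' trace lists (one element per stimulus), the supplied traces are used
#' as-is.
#'
#' @param x a [CellKinetics-class], or a list (one element per stimulus)
#'   of lists of [FluorescenceTrace-class] repeats.
#' @param stimuli numeric vector of AP counts (default
#'   `c(10, 25, 50, 100)`).
#' @param freq stimulation frequency (Hz).
#' @param cfg a [FitConfig-class]; defaults to the temperature's
#'   standard offset.
#' @param temperature used to build protocols when `x` is a
#'   [CellKinetics-class].
#' @param n_rep repeats per stimulus (`NULL`: `min(10, max(1,
#'   round(100/n_ap)))`).
#' @param seed integer seed (required when simulating).
#' @param cell_id identifier stored in the result.
#' @return A [TuningCurveResult-class].
#' @examples
#' cell <- defaultKinetics("37C")
#' tc <- runProtocolSuite(cell, stimuli = c(5, 25, 100), seed = 1)
#' tc@slope
#' @export
runProtocolSuite <- function(x, stimuli = c(10, 25, 50, 100), freq = 10,
                             cfg = NULL, temperature = "37C",
                             n_rep = NULL, seed = NULL,
                             cell_id = "cell") {
  if (is(x, "CellKinetics")) {
    if (is.null(seed)) stop("a seed is required when simulating")
    if (is.null(cfg)) cfg <- FitConfig(temperature)
    if (is.null(n_rep)) n_rep <- pmin(10, pmax(1, round(100 / stimuli)))
    n_rep <- rep_len(n_rep, length(stimuli))
    traces <- lapply(seq_along(stimuli), function(si) {
      proto <- StimulusProtocol(stimuli[si], freq = freq,
        temperature = temperature,
        post_window = cfg@offset_t0 + cfg@window_start + cfg@max_window + 5)
      lapply(seq_len(n_rep[si]), function(ri)
        simulateTrace(x, proto, seed = .deriveSeed(seed, 1, si, ri)))
    })
  } else {
    traces <- x
    if (!length(traces)) stop("no traces supplied")
    first <- traces[[1]][[1]]
    if (is.null(cfg)) cfg <- FitConfig(first@protocol@temperature)
    stimuli <- vapply(traces, function(trs)
      sum(trs[[1]]@protocol@bursts$n_ap), numeric(1))
    freq <- traces[[1]][[1]]@protocol@bursts$freq[1]
  }

  rows <- lapply(seq_along(traces), function(si) {
    avg <- averageTraces(traces[[si]])
    t_end <- .burstEnd(avg@protocol, nrow(avg@protocol@bursts))
    peak <- stats::approx(avg@t, avg@dF, t_end)$y
    f <- fitExpOffset(avg, cfg = cfg)
    data.frame(n_ap = stimuli[si], freq = freq, tau = f@tau,
               tau_se = f@tau_se, adj_r2 = f@adj_r2,
               converged = f@converged, peak_dF = peak,
               norm_tau = NA_real_)
  })
  fits <- do.call(rbind, rows)

  slope <- slope_se <- intercept <- intercept_se <- NA_real_
  ok <- fits$converged
  if (sum(ok) >= 3) {
    reg <- stats::lm(tau ~ I(n_ap - 1), data = fits[ok, ])
    cf <- summary(reg)$coefficients
    intercept <- cf[1, 1]; intercept_se <- cf[1, 2]
    slope <- cf[2, 1]; slope_se <- cf[2, 2]
  }
  load_slope <- load_slope_se <- load_intercept <- NA_real_
  if (sum(ok) >= 3) {
    regl <- stats::lm(tau ~ peak_dF, data = fits[ok, ])
    cfl <- summary(regl)$coefficients
    load_intercept <- cfl[1, 1]
    load_slope <- cfl[2, 1]; load_slope_se <- cfl[2, 2]
  }
  new("TuningCurveResult", cell_id = cell_id, fits = fits,
      slope = slope, slope_se = slope_se, intercept = intercept,
      intercept_se = intercept_se, load_slope = load_slope,
      load_slope_se = load_slope_se, load_intercept = load_intercept,
      reference = NA_real_)
}

#' Normalise a tuning curve to a reference stimulus
#'
#' Each cell is normalised to its own behaviour at a reference stimulus
#' (conventionally 100 AP at 10 Hz): `norm_tau(s) = tau(s) /
#' tau(reference)`.
#'
#' @param curve a [TuningCurveResult-class].
#' @param reference AP count of the reference stimulus.
#' @return The curve with its `norm_tau` column filled; the reference
#'   entry is exactly 1.
#' @export
normalizeCurve <- function(curve, reference = 100) {
  stopifnot(is(curve, "TuningCurveResult"))
  i <- which(curve@fits$n_ap == reference)
  if (!length(i)) stop("reference stimulus ", reference, " AP not present")
  ref_tau <- curve@fits$tau[i[1]]
  if (!is.finite(ref_tau) || ref_tau == 0)
    stop("reference tau is zero or unavailable")
  curve@fits$norm_tau <- curve@fits$tau / ref_tau
  curve@reference <- reference
  curve
}

#' Percent acceleration or slowing between two time constants
#'
#' Acceleration from a smaller to a larger stimulus is referenced to the
#' smaller stimulus: `100 * (tau_a - tau_b) / tau_a` (`tau_a` the
#' smaller-stimulus value). Slowing is referenced to the first argument:
#' `100 * (tau_b - tau_a) / tau_a`.
#'
#' @param tau_a reference time constant (smaller stimulus for `accel`,
#'   baseline stimulus for `slow`).
#' @param tau_b comparison time constant.
#' @param mode `"accel"` or `"slow"`.
#' @return Percent change; 0 when `tau_a == tau_b`.
#' @examples
#' percentChange(10, 5.8, "accel")  # 42
#' percentChange(1.0, 1.55, "slow") # 55
#' @export
percentChange <- function(tau_a, tau_b, mode = c("accel", "slow")) {
  mode <- match.arg(mode)
  if (any(c(tau_a, tau_b) <= 0)) stop("time constants must be positive")
  switch(mode,
    accel = 100 * (tau_a - tau_b) / tau_a,
    slow = 100 * (tau_b - tau_a) / tau_a)
}

#' Burst-train persistence analysis
#'
#' The persistence protocol delivers 5 bursts of 5 AP at 10 Hz with a
#' fixed inter-burst interval, and asks how long the acceleration
#' produced by one burst outlives it. Per cell and burst, the decay is
#' measured with the exponential-offset fit (spacings >= 20 s, where the
#' inter-burst window permits a robust fit) or the amplitude-normalised
#' 1/Rate linear fit (15 s spacing, too compressed for exponential
#' fitting), using constant short windows; values are normalised to the
#' first burst, and each burst is tested against 1 with a two-sided
#' one-sample t-test across cells.
#'
#' @param x a [PopulationSpec-class] (traces are simulated), or a list of
#'   per-cell lists of repeat [FluorescenceTrace-class] of the 5-burst
#'   protocol.
#' @param spacing inter-burst interval (s): 0, 15, 20 or 30 supported
#'   generically.
#' @param n_rep repeat traces averaged per cell (default 6).
#' @param cfg optional [FitConfig-class]; by default the temperature's
#'   offset with a constant 12 s window (10 s for 15 s spacing).
#' @param method `"auto"` picks exponential fits for spacings >= 20 s or
#'   0 s and 1/Rate for 15 s.
#' @return List with `norm` (cells x 5 matrix of normalised measures),
#'   `tests` (data.frame: burst, mean, sem, t, p, n) and `method`.
#' @export
persistenceAnalysis <- function(x, spacing, n_rep = 6, cfg = NULL,
                                method = c("auto", "exp_offset",
                                           "linear_rate")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (spacing > 0 && spacing < 20) "linear_rate" else "exp_offset"

  if (is(x, "PopulationSpec")) {
    proto <- StimulusProtocol(rep(5, 5), spacing = spacing,
      temperature = if (x@base@tau_reacid < 2.5) "37C" else "30C",
      post_window = 40)
    sim <- simulatePopulation(x, list(proto), n_rep = n_rep)
    cells <- lapply(sim, function(ci) ci$traces[[1]])
  } else cells <- x
  if (!length(cells)) stop("no cells supplied")
  nb <- nrow(averageTraces(cells[[1]])@protocol@bursts)
  if (nb < 5) stop("persistence protocol requires 5 bursts")

  temp <- averageTraces(cells[[1]])@protocol@temperature
  if (is.null(cfg)) {
    wl <- if (method == "linear_rate") 10 else 12
    cfg <- FitConfig(temp, window_len = wl, max_window = wl)
  }

  norm <- t(vapply(cells, function(trs) {
    avg <- averageTraces(trs)
    vals <- vapply(seq_len(nb), function(b) {
      f <- if (method == "exp_offset") fitExpOffset(avg, b, cfg)
           else fitLinearRate(avg, b, cfg)
      if (f@converged) f@tau else NA_real_
    }, numeric(1))
    vals / vals[1]
  }, numeric(nb)))

  tests <- do.call(rbind, lapply(seq_len(nb), function(b) {
    v <- norm[, b]
    v <- v[is.finite(v)]
    if (b == 1 || length(v) < 2)
      return(data.frame(burst = b, mean = mean(v), sem = NA_real_,
                        t = NA_real_, p = NA_real_, n = length(v)))
    tt <- stats::t.test(v, mu = 1)
    data.frame(burst = b, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               t = unname(tt$statistic), p = tt$p.value, n = length(v))
  }))
  list(norm = norm, tests = tests, method = method)
}

#' Endocytic-load regression of a tuning curve
#'
#' Regresses the fitted time constants against the endocytic load (the
#' fluorescence at the end of the stimulus) instead of the AP count;
#' used to show that calcium effects on slowing are not mere
#' differences in exocytosis.
#'
#' @param curve a [TuningCurveResult-class] (with at least 3 converged
#'   stimulus levels and recorded `peak_dF`).
#' @return List with `slope`, `slope_se`, `intercept`, `intercept_se`
#'   (s per dF unit / s).
#' @export
tauVsLoad <- function(curve) {
  stopifnot(is(curve, "TuningCurveResult"))
  ok <- curve@fits$converged & is.finite(curve@fits$peak_dF)
  if (sum(ok) < 3) stop("need >= 3 stimulus levels with recorded load")
  d <- curve@fits[ok, ]
  if (stats::var(d$peak_dF) == 0) stop("singular design: constant load")
  reg <- stats::lm(tau ~ peak_dF, data = d)
  cf <- summary(reg)$coefficients
  list(slope = cf[2, 1], slope_se = cf[2, 2],
       intercept = cf[1, 1], intercept_se = cf[1, 2])
}

#' Population summary statistics and hypothesis tests
#'
#' Computes mean, SEM and CV of a per-cell metric with a one-pass
#' `> 3 SD` outlier exclusion, and runs the standard internal
#' comparisons: a two-sided one-sample t-test against `mu` (optionally
#' log-corrected, i.e. performed on `log(values)` against `log(mu)` --
#' appropriate for ratio metrics), a paired t-test against a second
#' sample, and a two-sample Kolmogorov-Smirnov test for between-cell
#' comparisons of time constants.
#'
#' @param values numeric vector of per-cell values.
#' @param mu null value for the one-sample t-test (`NULL` to skip).
#' @param log_correct perform the one-sample test on the log scale.
#' @param paired second sample for a paired t-test (`NULL` to skip).
#' @param ks_with second sample for a KS test (`NULL` to skip).
#' @param outlier_sd exclusion threshold in SDs (one pass; `Inf` to
#'   disable).
#' @return List with `mean`, `sem`, `cv_pct`, `n`, `n_outliers`,
#'   `outliers` (the excluded values) and `tests` (data.frame with
#'   columns test, statistic, p, n).
#' @export
populationSummary <- function(values, mu = NULL, log_correct = FALSE,
                              paired = NULL, ks_with = NULL,
                              outlier_sd = 3) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need n >= 2 values")
  m <- mean(values); s <- stats::sd(values)
  out_idx <- if (is.finite(outlier_sd) && s > 0)
    which(abs(values - m) > outlier_sd * s) else integer(0)
  outliers <- values[out_idx]
  kept <- if (length(out_idx)) values[-out_idx] else values
  if (!is.null(paired)) {
    paired <- paired[is.finite(paired)]
    if (length(paired) != length(values))
      stop("paired sample must match values in length")
    paired_kept <- if (length(out_idx)) paired[-out_idx] else paired
  }
  m <- mean(kept); s <- stats::sd(kept)

  tests <- list()
  if (!is.null(mu)) {
    x <- if (log_correct) log(kept) else kept
    m0 <- if (log_correct) log(mu) else mu
    tt <- stats::t.test(x, mu = m0)
    tests[[length(tests) + 1]] <- data.frame(
      test = if (log_correct) "one_sample_t_log" else "one_sample_t",
      statistic = unname(tt$statistic), p = tt$p.value, n = length(kept))
  }
  if (!is.null(paired)) {
    tt <- stats::t.test(kept, paired_kept, paired = TRUE)
    tests[[length(tests) + 1]] <- data.frame(test = "paired_t",
      statistic = unname(tt$statistic), p = tt$p.value, n = length(kept))
  }
  if (!is.null(ks_with)) {
    ks <- suppressWarnings(stats::ks.test(kept, ks_with[is.finite(ks_with)]))
    tests[[length(tests) + 1]] <- data.frame(test = "ks",
      statistic = unname(ks$statistic), p = ks$p.value, n = length(kept))
  }
  list(mean = m, sem = s / sqrt(length(kept)), cv_pct = 100 * s / m,
       n = length(kept), n_outliers = length(out_idx), outliers = outliers,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
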