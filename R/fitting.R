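#' Adjusted R-squared
#'
#' `1 - (1 - R^2) * (n - 1) / (n - k - 1)` with `R^2` computed from the
#' residuals about the mean of `y`.
#'
#' @param y observed values.
#' @param residuals fit residuals (same length as `y`).
#' @param k number of fitted parameters.
#' @return Adjusted R-squared (<= 1).
#' @export
adjustedR2 <- function(y, residuals, k) {
  n <- length(y)
  if (n <= k + 1) stop("need n > k + 1 for adjusted R-squared")
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("degenerate data: zero variance")
  r2 <- 1 - sum(residuals^2) / tss
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

# End time of a burst: time of its last AP.
.burstEnd <- function(protocol, burst) {
  b <- protocol@bursts
  if (burst < 1 || burst > nrow(b)) stop("burst index out of range")
  b$onset[burst] + (b$n_ap[burst] - 1) / b$freq[burst]
}

# Extract the post-burst fit window. Returns x (time since window
# start), y, and the absolute window.
.decayWindow <- function(trace, burst, cfg) {
  t_end <- .burstEnd(trace@protocol, burst)
  w0 <- t_end + cfg@offset_t0 + cfg@window_start
  w1 <- w0 + cfg@window_len
  keep <- trace@t >= w0 - 1e-9 & trace@t <= w1 + 1e-9
  if (sum(keep) < cfg@min_points)
    stop("too few samples in fit window (", sum(keep), " < ",
         cfg@min_points, ")")
  list(x = trace@t[keep] - w0, y = trace@dF[keep], window = c(w0, w1),
       t_end = t_end)
}

# Adaptive window: a pilot profiled fit on the base window sets the
# final window to 4x the pilot tau (bounded by window_len below and by
# max_window / the trace end above), so slow decays are not truncated.
.adaptiveWindow <- function(trace, burst, cfg, free_baseline) {
  w <- .decayWindow(trace, burst, cfg)
  if (cfg@max_window <= cfg@window_len + 1e-9) return(w)
  prof <- tryCatch(.profiledExpFit(w$x, w$y, free_baseline),
                   error = function(e) NULL)
  if (is.null(prof)) return(w)
  avail <- max(trace@t) - w$window[1]
  target <- min(max(cfg@window_len, 4 * prof$tau), cfg@max_window, avail)
  if (target > cfg@window_len + 1e-9) {
    cfg@window_len <- target
    w <- .decayWindow(trace, burst, cfg)
  }
  w
}

# Fast deterministic tau: adaptive window + profiled fit. Shares its
# window logic and objective with fitExpOffset; used where thousands of
# noiseless fits are needed (calibration).
.fitTauFast <- function(trace, burst, cfg) {
  free_b <- cfg@baseline_mode == "free"
  w <- .adaptiveWindow(trace, burst, cfg, free_b)
  .profiledExpFit(w$x, w$y, free_b)$tau
}

# Profiled SSE of A * exp(-x / tau) (+ C): for fixed tau the amplitude
# (and baseline) are linear, so tau can be optimised in one dimension.
# Used as a robust fallback and for starting values.
.profiledExpFit <- function(x, y, free_baseline, lower = 0.05, upper = 500) {
  sse <- function(tau) {
    b <- exp(-x / tau)
    if (free_baseline) {
      X <- cbind(b, 1)
      cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                     error = function(e) NULL)
      if (is.null(cf)) return(Inf)
      sum((y - X %*% cf)^2)
    } else {
      A <- sum(b * y) / sum(b * b)
      sum((y - A * b)^2)
    }
  }
  grid <- exp(seq(log(lower), log(upper), length.out = 120))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  tau <- opt$minimum
  b <- exp(-x / tau)
  if (free_baseline) {
    X <- cbind(b, 1)
    cf <- solve(crossprod(X), crossprod(X, y))
    list(tau = tau, A = cf[1], C = cf[2], sse = opt$objective)
  } else {
    A <- sum(b * y) / sum(b * b)
    list(tau = tau, A = A, C = 0, sse = opt$objective)
  }
}

#' Fit a single-exponential decay with a reacidification temporal offset
#'
#' Nonlinear least squares of
#' `F(t) = A * exp(-(t - t_end - offset_t0) / tau) + C`
#' on the window `[t_end + offset_t0, t_end + offset_t0 + window_len]`,
#' where `t_end` is the time of the last AP of the chosen burst. `C` is
#' fixed at zero for baseline-subtracted traces (`baseline_mode
#' "fixed_zero"`) or fitted (`"free"`). The window adapts to slow
#' decays: a pilot fit on `window_len` widens the window to 4x the
#' pilot time constant, never beyond `max_window` or the trace end. A
#' Levenberg-Marquardt optimiser is multi-started on `tau` in
#' `{2, 10, 40}` s (plus a profiled grid-search start); the solution
#' with the smallest SSE is kept, ties broken towards smaller `tau`.
#'
#' @param trace a [FluorescenceTrace-class].
#' @param burst burst index whose decay is fitted (default: last burst).
#' @param cfg a [FitConfig-class]; the default offset follows the trace's
#'   protocol temperature.
#' @return An [EndoFit-class]; `converged == FALSE` (all-`NA` values)
#'   when the optimiser fails or `tau` hits the search bounds.
#' @examples
#' tr <- expectedTrace(defaultKinetics("37C"), StimulusProtocol(100))
#' fitExpOffset(tr)@tau
#' @export
fitExpOffset <- function(trace, burst = nrow(trace@protocol@bursts),
                         cfg = FitConfig(trace@protocol@temperature)) {
  stopifnot(is(trace, "FluorescenceTrace"), is(cfg, "FitConfig"))
  free_b <- cfg@baseline_mode == "free"
  w <- .adaptiveWindow(trace, burst, cfg, free_b)
  x <- w$x; y <- w$y
  k <- if (free_b) 3 else 2

  prof <- tryCatch(.profiledExpFit(x, y, free_b), error = function(e) NULL)
  starts <- c(2, 10, 40, if (!is.null(prof)) prof$tau)
  best <- NULL
  for (tau0 in starts) {
    A0 <- max(y[1], max(y) * 0.5, 1e-6)
    fit <- tryCatch({
      if (free_b)
        minpack.lm::nlsLM(y ~ A * exp(-x / tau) + C,
          start = list(A = A0, tau = tau0, C = 0),
          lower = c(A = 0, tau = 1e-3, C = -Inf),
          upper = c(A = Inf, tau = 1e4, C = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ A * exp(-x / tau),
          start = list(A = A0, tau = tau0),
          lower = c(A = 0, tau = 1e-3), upper = c(A = Inf, tau = 1e4),
          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    tau_hat <- stats::coef(fit)[["tau"]]
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && tau_hat < best$tau))
      best <- list(fit = fit, sse = sse, tau = tau_hat)
  }

  if (is.null(best))
    return(.EndoFit(method = "exp_offset", window = w$window,
                    n_points = length(x)))
  cf <- stats::coef(best$fit)
  tau_hat <- cf[["tau"]]
  if (tau_hat <= 1e-3 * (1 + 1e-6) || tau_hat >= 1e4 * (1 - 1e-6))
    return(.EndoFit(method = "exp_offset", window = w$window,
                    n_points = length(x)))
  se <- tryCatch(summary(best$fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  ar2 <- tryCatch(adjustedR2(y, stats::resid(best$fit), k - 1),
                  error = function(e) NA_real_)
  .EndoFit(tau = tau_hat, tau_se = se, amplitude = cf[["A"]],
           baseline = if (free_b) cf[["C"]] else 0, adj_r2 = ar2,
           method = "exp_offset", window = w$window, converged = TRUE,
           n_points = length(x))
}

#' Inverse-rate linear fit of a post-burst decay
#'
#' When inter-burst intervals are too short for a robust exponential
#' fit, endocytic performance is estimated from a linear fit to the
#' decay. The OLS slope on the post-burst window is normalised by the
#' decay amplitude at the window start (`Rate = |slope| / F0`, units
#' 1/s) so that `1/Rate` is a time-constant-like measure in seconds;
#' its SE follows by error propagation from the slope SE.
#'
#' @inheritParams fitExpOffset
#' @return An [EndoFit-class] with `tau = 1/Rate` and
#'   `method = "linear_rate"`; `converged == FALSE` when the trace does
#'   not decay (non-negative slope).
#' @export
fitLinearRate <- function(trace, burst = nrow(trace@protocol@bursts),
                          cfg = FitConfig(trace@protocol@temperature)) {
  stopifnot(is(trace, "FluorescenceTrace"), is(cfg, "FitConfig"))
  w <- .decayWindow(trace, burst, cfg)
  x <- w$x; y <- w$y
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  F0 <- stats::coef(fit)[["(Intercept)"]]
  if (slope >= 0 || F0 <= 0)
    return(.EndoFit(method = "linear_rate", window = w$window,
                    n_points = length(x)))
  rate <- -slope / F0
  inv_rate <- 1 / rate
  se_slope <- summary(fit)$coefficients["x", "Std. Error"]
  se <- se_slope * F0 / slope^2          # d(1/Rate)/d(slope) = F0/slope^2
  ar2 <- adjustedR2(y, stats::resid(fit), 1)
  .EndoFit(tau = inv_rate, tau_se = abs(se), amplitude = F0, baseline = 0,
           adj_r2 = ar2, method = "linear_rate", window = w$window,
           converged = TRUE, n_points = length(x))
}

#' Remaining fluorescence fraction after the end of stimulation
#'
#' `dF(t_end + at_s) / dF(t_end)`, linearly interpolated; a robust
#' endocytosis measure for low signal-to-noise single-AP responses.
#'
#' @param trace a [FluorescenceTrace-class].
#' @param burst burst index.
#' @param at_s time after the end of stimulation at which the remaining
#'   fraction is evaluated (s; 15 by default, 20 in some comparisons).
#' @return The remaining fraction (typically in `[0, 1]`).
#' @export
remainingFraction <- function(trace, burst = nrow(trace@protocol@bursts),
                              at_s = 15) {
  stopifnot(is(trace, "FluorescenceTrace"))
  t_end <- .burstEnd(trace@protocol, burst)
  if (t_end + at_s > max(trace@t))
    stop("trace does not cover t_end + at_s")
  peak <- stats::approx(trace@t, trace@dF, t_end)$y
  if (!is.finite(peak) || abs(peak) < .Machine$double.eps * 100)
    stop("remaining fraction undefined: zero fluorescence at stimulus end")
  stats::approx(trace@t, trace@dF, t_end + at_s)$y / peak
}

#' Rising-exponential fit of a bafilomycin trace
#'
#' Under bafilomycin, requenching is blocked, so fluorescence during a
#' long train reports cumulative exocytosis and saturates at the
#' recycling pool size. Fits `F(t) = P * (1 - exp(-(t - t_on) / tau))`
#' over the stimulation period; `P` estimates the pool and `tau` the
#' exocytic depletion time constant.
#'
#' @param trace a [FluorescenceTrace-class] recorded under bafilomycin.
#' @param burst burst index (default first).
#' @return An [EndoFit-class] with `method = "rising_exp"`, `tau` the
#'   exocytosis time constant and `amplitude` the plateau `P`;
#'   `converged == FALSE` for non-saturating traces.
#' @export
fitRisingExp <- function(trace, burst = 1) {
  stopifnot(is(trace, "FluorescenceTrace"))
  b <- trace@protocol@bursts
  t_on <- b$onset[burst]
  t_end <- .burstEnd(trace@protocol, burst)
  keep <- trace@t >= t_on & trace@t <= t_end
  if (sum(keep) < 5) stop("too few samples during stimulation")
  x <- trace@t[keep] - t_on
  y <- trace@dF[keep]
  win <- c(t_on, t_end)
  P0 <- max(y)
  if (P0 <= 0)
    return(.EndoFit(method = "rising_exp", window = win,
                    n_points = length(x)))
  best <- NULL
  for (tau0 in c(diff(win) / 10, diff(win) / 3, diff(win))) {
    fit <- tryCatch(minpack.lm::nlsLM(y ~ P * (1 - exp(-x / tau)),
      start = list(P = P0, tau = tau0),
      lower = c(P = 0, tau = 1e-3), upper = c(P = Inf, tau = 1e5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    return(.EndoFit(method = "rising_exp", window = win,
                    n_points = length(x)))
  cf <- stats::coef(best$fit)
  # non-saturating: depletion slower than the train itself
  if (cf[["tau"]] > 3 * diff(win))
    return(.EndoFit(method = "rising_exp", window = win,
                    n_points = length(x)))
  ar2 <- tryCatch(adjustedR2(y, stats::resid(best$fit), 1),
                  error = function(e) NA_real_)
  se <- tryCatch(summary(best$fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  .EndoFit(tau = cf[["tau"]], tau_se = se, amplitude = cf[["P"]],
           baseline = 0, adj_r2 = ar2, method = "rising_exp",
           window = win, converged = TRUE, n_points = length(x))
}
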