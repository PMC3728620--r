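# Independent oracles used across the suite. These deliberately avoid
# the package's fitting code paths.

# Dense grid-search least squares for A * exp(-x / tau): the reference
# the nonlinear fitter is checked against.
gridExpOracle <- function(x, y, tau_grid = exp(seq(log(0.2), log(300),
                                                  length.out = 4000))) {
  best <- list(sse = Inf)
  for (tau in tau_grid) {
    b <- exp(-x / tau)
    A <- sum(b * y) / sum(b * b)
    sse <- sum((y - A * b)^2)
    if (sse < best$sse) best <- list(tau = tau, A = A, sse = sse)
  }
  best
}

# Builds a bare trace object around given samples (protocol with one
# burst ending at t_end) so fitting functions can be pointed at
# arbitrary analytic curves.
analyticTrace <- function(t, y, t_end = 0, temperature = "37C") {
  proto <- new("StimulusProtocol",
    bursts = data.frame(n_ap = 1, freq = 10, onset = t_end),
    temperature = temperature, ca_mM = 2, condition = "control",
    trace_duration = max(t), sample_interval = diff(t[1:2]))
  new("FluorescenceTrace", t = t, dF = y, protocol = proto, meta = list())
}

# A no-modulation cell: pure single-exponential endocytosis, no
# reacidification, no noise; handy ground truth.
plainCell <- function(tau1 = 10, n_vesicles = 120, p_release = 0.05,
                      slope_m = 0) {
  CellKinetics(tau1 = tau1, slope_m = slope_m, alpha_max = 0,
               delta_a = 0, tau_reacid = 0, n_vesicles = n_vesicles,
               p_release = p_release, surface_frac = 0, noise_sd = 0)
}
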