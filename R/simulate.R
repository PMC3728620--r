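#' Simulate a vesicle-resolved pHluorin fluorescence trace
#'
#' Stochastic per-vesicle model of a bouton-averaged, baseline-subtracted
#' dF trace. Each AP releases `Binomial(available, p_release)` vesicles;
#' vesicles recycle -- `reprime_s` after reacidification a vesicle
#' rejoins the available pool; each surface vesicle is internalised
#' after an exponential waiting time with the burst's effective time
#' constant (frozen at burst end, see [effectiveTau()]); each
#' internalised vesicle is requenched after an exponential
#' reacidification delay. Under the `"bafilomycin"` condition requenching
#' is disabled, so dF reports cumulative exocytosis. Fluorescence is
#' binary per vesicle (one unit while surface or internalised but not
#' yet reacidified); the optional pH mode instead assigns
#' Henderson-Hasselbalch fractional brightness (pKa 7.1, pH 7.4 outside /
#' 5.6 in the acidified lumen). Additive i.i.d. Gaussian noise of SD
#' `noise_sd` is applied per sample.
#'
#' @param cell a [CellKinetics-class] object.
#' @param protocol a [StimulusProtocol-class] object.
#' @param seed integer seed; required, every trace is a pure function of
#'   `(cell, protocol, seed)`.
#' @param return_states if `TRUE`, attach a per-sample count matrix of
#'   the four vesicle states (`available`, `surface`, `internalized`,
#'   `reacidified`) to `meta$states`; the rows sum to `n_vesicles`.
#' @param ph_mode use Henderson-Hasselbalch fractional quenching instead
#'   of binary fluorescent/quenched.
#' @return A [FluorescenceTrace-class].
#' @examples
#' tr <- simulateTrace(defaultKinetics("37C"), StimulusProtocol(25), seed = 1)
#' @export
simulateTrace <- function(cell, protocol, seed, return_states = FALSE,
                          ph_mode = FALSE) {
  stopifnot(is(cell, "CellKinetics"), is(protocol, "StimulusProtocol"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required: traces must be reproducible")
  validObject(cell); validObject(protocol)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  b <- protocol@bursts
  bt <- .burstTaus(cell, protocol)
  baf <- protocol@condition == "bafilomycin"
  n_surface0 <- round(cell@n_vesicles * cell@surface_frac)
  avail <- cell@n_vesicles - n_surface0

  # Event-driven release with recycling: each AP releases a binomial
  # draw from the currently available pool; vesicles rejoin the pool
  # reprime_s after reacidification (never under bafilomycin).
  rel_l <- list(); int_l <- list(); quench_l <- list()
  pending <- numeric(0)  # future return-to-pool times
  warned <- FALSE
  for (i in seq_len(nrow(b))) {
    ap_times <- b$onset[i] + (0:(b$n_ap[i] - 1)) / b$freq[i]
    for (tap in ap_times) {
      if (length(pending)) {
        back <- pending <= tap
        avail <- avail + sum(back)
        pending <- pending[!back]
      }
      if (avail == 0) {
        if (!warned) {
          warning("recycling pool exhausted; continuing with zero release")
          warned <- TRUE
        }
        next
      }
      k <- stats::rbinom(1, avail, cell@p_release)
      avail <- avail - k
      if (k > 0) {
        e <- tap + stats::rexp(k, rate = 1) * bt$tau[i]
        q <- if (baf) rep(Inf, k)
          else if (cell@tau_reacid <= 0) e
          else e + stats::rexp(k, rate = 1 / cell@tau_reacid)
        rel_l[[length(rel_l) + 1]] <- rep(tap, k)
        int_l[[length(int_l) + 1]] <- e
        quench_l[[length(quench_l) + 1]] <- q
        if (!baf) pending <- c(pending, q + cell@reprime_s)
      }
    }
  }
  rel_t <- unlist(rel_l); int_t <- unlist(int_l); quench_t <- unlist(quench_l)
  if (is.null(rel_t)) rel_t <- int_t <- quench_t <- numeric(0)

  t <- seq(0, protocol@trace_duration, by = protocol@sample_interval)
  cnt <- function(x) findInterval(t, sort(x))
  n_released <- cnt(rel_t)
  n_internal <- cnt(int_t)
  qf <- quench_t[is.finite(quench_t)]
  n_quench <- cnt(qf)
  n_return <- cnt(qf + cell@reprime_s)

  surface <- n_released - n_internal + n_surface0
  internal_unacid <- n_internal - n_quench
  reacid <- n_quench - n_return
  available <- cell@n_vesicles - n_surface0 - n_released + n_return

  if (ph_mode) {
    f_surf <- 1 / (1 + 10^(7.1 - 7.4))
    f_lum <- 1 / (1 + 10^(7.1 - 5.6))
    Fraw <- (surface + internal_unacid) * f_surf +
      (reacid + available) * f_lum
    baseline <- n_surface0 * f_surf + (cell@n_vesicles - n_surface0) * f_lum
    dF <- Fraw - baseline
  } else {
    dF <- (surface + internal_unacid) - n_surface0
  }
  if (cell@noise_sd > 0) dF <- dF + stats::rnorm(length(t), 0, cell@noise_sd)

  meta <- list(cell_id = "cell", genotype = "control",
               seed = as.integer(seed), tau_eff = bt$tau, a_end = bt$a_end)
  if (return_states)
    meta$states <- cbind(available = available, surface = surface,
                         internalized = internal_unacid,
                         reacidified = reacid)
  new("FluorescenceTrace", t = t, dF = dF, protocol = protocol, meta = meta)
}

#' Expected (noise-free, infinite-pool limit) fluorescence trace
#'
#' Deterministic expectation of the stochastic model: per-AP release is
#' the binomial mean with sequential pool depletion and recycling
#' (expected returns are the released cohorts convolved with the
#' endocytosis + reacidification delay distribution, shifted by the
#' repriming time), and every released cohort decays through the
#' closed-form two-compartment response (surface exponential with the
#' burst's effective time constant feeding a first-order
#' reacidification compartment). Because every transition of the
#' vesicle state machine is linear, this is the exact expectation of
#' [simulateTrace()]. Used by the measurement-level calibration and as
#' a law-of-large-numbers reference in tests.
#'
#' @inheritParams simulateTrace
#' @return A [FluorescenceTrace-class] with the expected dF.
#' @export
expectedTrace <- function(cell, protocol) {
  stopifnot(is(cell, "CellKinetics"), is(protocol, "StimulusProtocol"))
  b <- protocol@bursts
  bt <- .burstTaus(cell, protocol)
  t <- seq(0, protocol@trace_duration, by = protocol@sample_interval)

  tr <- cell@tau_reacid
  baf <- protocol@condition == "bafilomycin"

  ap_t <- unlist(lapply(seq_len(nrow(b)), function(i)
    b$onset[i] + (0:(b$n_ap[i] - 1)) / b$freq[i]))
  ap_tau <- rep(bt$tau, b$n_ap)
  n_ap_total <- length(ap_t)
  # P(vesicle released at lag 0 has returned to the pool by lag u):
  # endocytosis + reacidification completed, plus the repriming delay.
  # elementwise over cohorts: u and te are vectors
  returned <- function(u, te) {
    out <- numeric(length(u))
    v <- u - cell@reprime_s
    pos <- v > 0
    # the biexponential survival P(endo + reacid > v); 1 - it is the CDF
    if (any(pos)) {
      vv <- v[pos]; tt <- te[pos]
      surv <- if (tr <= 0) exp(-vv / tt) else
        ifelse(abs(tt - tr) < 1e-9 * tt,
               (1 + vv / tt) * exp(-vv / tt),
               (tt * exp(-vv / tt) - tr * exp(-vv / tr)) / (tt - tr))
      out[pos] <- 1 - surv
    }
    out
  }
  ap_r <- numeric(n_ap_total)
  avail0 <- cell@n_vesicles * (1 - cell@surface_frac)
  for (i in seq_len(n_ap_total)) {
    back <- if (i > 1 && !baf)
      sum(ap_r[1:(i - 1)] *
            returned(ap_t[i] - ap_t[1:(i - 1)], ap_tau[1:(i - 1)]))
      else 0
    avail <- avail0 - sum(ap_r[seq_len(i - 1)]) + back
    ap_r[i] <- avail * cell@p_release
  }
  dF <- numeric(length(t))
  for (j in seq_along(ap_t)) {
    u <- t - ap_t[j]
    live <- u >= 0
    if (!any(live)) next
    uu <- u[live]
    te <- ap_tau[j]
    f <- if (baf) rep(1, length(uu))
      else if (tr <= 0) exp(-uu / te)
      else if (abs(te - tr) < 1e-8 * te) (1 + uu / te) * exp(-uu / te)
      else {
        cc <- tr / (te - tr)
        (1 + cc) * exp(-uu / te) - cc * exp(-uu / tr)
      }
    dF[live] <- dF[live] + ap_r[j] * f
  }
  new("FluorescenceTrace", t = t, dF = dF, protocol = protocol,
      meta = list(cell_id = "expected", genotype = "control", seed = NA,
                  tau_eff = bt$tau, a_end = bt$a_end))
}

# Deterministic per-trace seed derivation; keeps values in [1, 2^31-2].
.deriveSeed <- function(base, cell_i, proto_i, rep_i) {
  m <- 2147483647
  s <- (as.numeric(base) %% m)
  s <- (s * 48271 + cell_i * 1299709) %% m
  s <- (s * 48271 + proto_i * 15485863) %% m
  s <- (s * 48271 + rep_i * 32452843) %% m
  as.integer(s %% (m - 1) + 1)
}

# Lognormal draws parameterised by mean and CV.
.rlnormMeanCV <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Draw per-cell kinetics from a population specification
#'
#' `tau1` and `slope_m` are drawn lognormally with the specified
#' mean/CV; all other parameters are shared from `base`. The genotype
#' preset is applied after drawing.
#'
#' @param spec a [PopulationSpec-class].
#' @return List of [CellKinetics-class], length `n_cells`.
#' @export
drawCellKinetics <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  validObject(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(.deriveSeed(spec@rng_seed, 0, 0, 0))
  tau1 <- .rlnormMeanCV(spec@n_cells, spec@tau1_mean, spec@tau1_cv)
  slope <- .rlnormMeanCV(spec@n_cells, spec@slope_mean, spec@slope_cv)
  lapply(seq_len(spec@n_cells), function(i) {
    cell <- spec@base
    cell@tau1 <- tau1[i]
    cell@slope_m <- slope[i]
    applyGenotype(cell, spec@genotype)
  })
}

#' Simulate a population of cells over a set of protocols
#'
#' Draws per-cell kinetics via [drawCellKinetics()], then simulates
#' `n_rep[p]` repeat traces of every protocol for every cell. All seeds
#' are derived deterministically from `spec@rng_seed`.
#'
#' @param spec a [PopulationSpec-class].
#' @param protocols list of [StimulusProtocol-class] objects.
#' @param n_rep integer vector of repeats per protocol (recycled);
#'   `NULL` applies the small-stimulus averaging rule
#'   `min(10, max(1, round(100 / n_ap)))` used before fitting.
#' @return List with one element per cell: `list(kinetics = CellKinetics,
#'   traces = list over protocols of lists of FluorescenceTrace)`.
#' @export
simulatePopulation <- function(spec, protocols, n_rep = NULL) {
  stopifnot(is(spec, "PopulationSpec"))
  if (is(protocols, "StimulusProtocol")) protocols <- list(protocols)
  if (is.null(n_rep))
    n_rep <- vapply(protocols, function(p)
      min(10, max(1, round(100 / sum(p@bursts$n_ap)))), numeric(1))
  n_rep <- rep_len(n_rep, length(protocols))
  cells <- drawCellKinetics(spec)
  lapply(seq_along(cells), function(ci) {
    traces <- lapply(seq_along(protocols), function(pi) {
      lapply(seq_len(n_rep[pi]), function(ri) {
        tr <- simulateTrace(cells[[ci]], protocols[[pi]],
                            seed = .deriveSeed(spec@rng_seed, ci, pi, ri))
        tr@meta$cell_id <- sprintf("cell%02d", ci)
        tr@meta$genotype <- spec@genotype
        tr@meta$rep <- ri
        tr
      })
    })
    list(kinetics = cells[[ci]], traces = traces)
  })
}

#' Average repeat traces sample-by-sample
#'
#' Repeated runs of the same stimulus are averaged before fitting, which
#' is how small-stimulus signal-to-noise is recovered in practice.
#'
#' @param traces list of [FluorescenceTrace-class] on identical grids.
#' @return A single [FluorescenceTrace-class].
#' @export
averageTraces <- function(traces) {
  if (is(traces, "FluorescenceTrace")) return(traces)
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]@t
  for (tr in traces) stopifnot(length(tr@t) == length(t0))
  dF <- rowMeans(vapply(traces, function(tr) tr@dF, numeric(length(t0))))
  out <- traces[[1]]
  out@dF <- dF
  out@meta$n_averaged <- length(traces)
  out
}
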