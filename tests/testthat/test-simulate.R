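test_that("traces are deterministic given a seed, and a seed is required", {
  cell <- defaultKinetics("37C")
  proto <- StimulusProtocol(25)
  a <- simulateTrace(cell, proto, seed = 7)
  b <- simulateTrace(cell, proto, seed = 7)
  expect_identical(a@dF, b@dF)
  c <- simulateTrace(cell, proto, seed = 8)
  expect_false(identical(a@dF, c@dF))
  expect_error(simulateTrace(cell, proto), "seed")
})

test_that("vesicle counts are conserved across all four states", {
  cell <- defaultKinetics("37C")
  protos <- list(
    StimulusProtocol(100),
    StimulusProtocol(rep(5, 5), spacing = 20),
    StimulusProtocol(300, condition = "bafilomycin", post_window = 30))
  for (p in protos) {
    # long bafilomycin trains legitimately exhaust the pool (no reuse)
    tr <- suppressWarnings(simulateTrace(cell, p, seed = 3,
                                         return_states = TRUE))
    sums <- rowSums(tr@meta$states)
    expect_true(all(sums == cell@n_vesicles))
    expect_true(all(tr@meta$states >= 0))
  }
})

test_that("ensemble post-burst decay converges to the prescribed exponential", {
  # law of large numbers: 1e5 vesicles, all released in one AP, no
  # reacidification -> the fluorescence after the burst is the survival
  # of Exp(tau_eff), compared against the exponential in sup norm
  cell <- plainCell(tau1 = 10, n_vesicles = 1e5, p_release = 1)
  proto <- StimulusProtocol(1, onset = 1, post_window = 50,
                            sample_interval = 0.25)
  tr <- simulateTrace(cell, proto, seed = 42)
  post <- tr@t >= 1
  u <- tr@t[post] - 1
  emp <- tr@dF[post] / tr@dF[which(tr@t == 1)]
  expect_lt(max(abs(emp - exp(-u / 10))), 0.01)
})

test_that("expected trace is the mean of the stochastic model", {
  cell <- defaultKinetics("37C")
  cell@noise_sd <- 0
  proto <- StimulusProtocol(50, post_window = 60)
  et <- expectedTrace(cell, proto)
  sims <- vapply(1:80, function(s) simulateTrace(cell, proto, seed = s)@dF,
                 numeric(length(et@t)))
  m <- rowMeans(sims)
  # Monte-Carlo tolerance: a few percent of peak at n = 80
  expect_lt(max(abs(m - et@dF)) / max(et@dF), 0.05)
})

test_that("bafilomycin blocks requenching: noise-free dF is non-decreasing", {
  cell <- defaultKinetics("37C")
  cell@noise_sd <- 0
  proto <- StimulusProtocol(1000, condition = "bafilomycin",
                            post_window = 30)
  tr <- suppressWarnings(simulateTrace(cell, proto, seed = 5))
  expect_true(all(diff(tr@dF) >= 0))
  # and the plateau is bounded by the recycling pool
  expect_lte(max(tr@dF), cell@n_vesicles)
})

test_that("baseline before the first burst is zero up to noise", {
  cell <- defaultKinetics("37C")
  tr <- simulateTrace(cell, StimulusProtocol(25, onset = 10), seed = 9)
  pre <- tr@dF[tr@t < 10]
  expect_lt(abs(mean(pre)), 4 * cell@noise_sd / sqrt(length(pre)) + 1e-9)
})

test_that("with zero reacidification time the trace is the pure endocytosis model", {
  cell <- plainCell(tau1 = 8, n_vesicles = 5000, p_release = 0.2)
  proto <- StimulusProtocol(10, post_window = 40)
  tr <- simulateTrace(cell, proto, seed = 1, return_states = TRUE)
  # no vesicle ever dwells in the internalised-unacidified state
  expect_true(all(tr@meta$states[, "internalized"] == 0))
})

test_that("population draws honour the lognormal mean/CV parameterisation", {
  base <- defaultKinetics("30C")
  # CV = 0 collapses to identical cells
  spec0 <- PopulationSpec(5, base = base, tau1_cv = 0, slope_cv = 0,
                          rng_seed = 1)
  cells0 <- drawCellKinetics(spec0)
  expect_true(all(vapply(cells0, function(c) c@tau1, numeric(1)) ==
                  base@tau1))
  # moment recovery at n = 1e4: sample mean within 3 SEM of the spec mean
  spec <- PopulationSpec(1e4, base = base, tau1_cv = 0.52, slope_cv = 1,
                         rng_seed = 2)
  cells <- drawCellKinetics(spec)
  sl <- vapply(cells, function(c) c@slope_m, numeric(1))
  sem <- sd(sl) / sqrt(length(sl))
  expect_lt(abs(mean(sl) - spec@slope_mean), 3 * sem)
  t1 <- vapply(cells, function(c) c@tau1, numeric(1))
  expect_lt(abs(mean(t1) - spec@tau1_mean), 3 * sd(t1) / sqrt(length(t1)))
  # draws are reproducible
  expect_identical(vapply(drawCellKinetics(spec), function(c) c@tau1,
                          numeric(1)), t1)
  expect_error(PopulationSpec(5, base = base, tau1_cv = -1), "CV")
})

test_that("a 44-cell population shows the benchmark cell-to-cell spread", {
  spec <- defaultPopulation(44, "30C", rng_seed = 20)
  cells <- drawCellKinetics(spec)
  sl <- vapply(cells, function(c) c@slope_m, numeric(1))
  t1 <- vapply(cells, function(c) c@tau1, numeric(1))
  # sample CVs near 100 % (slope) and 52 % (1 AP time constant);
  # wide bands because a CV estimate from 44 lognormal draws is noisy
  expect_gt(sd(sl) / mean(sl), 0.6); expect_lt(sd(sl) / mean(sl), 1.5)
  expect_gt(sd(t1) / mean(t1), 0.3); expect_lt(sd(t1) / mean(t1), 0.8)
})

test_that("pool exhaustion warns and continues with zero release", {
  cell <- plainCell(tau1 = 1e5, n_vesicles = 10, p_release = 1)
  proto <- StimulusProtocol(5, post_window = 10)
  expect_warning(tr <- simulateTrace(cell, proto, seed = 1), "exhausted")
  expect_lte(max(tr@dF), 10)
})
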