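test_that("effective tau composes acceleration and slowing correctly", {
  cell <- CellKinetics(tau1 = 6.09, slope_m = 0.058, alpha_max = 0)
  # identity: no acceleration state, single AP
  expect_identical(effectiveTau(cell, 1, 0), 6.09)
  # closed-form slowing: tau1 + slope * (n - 1)
  expect_equal(effectiveTau(cell, 100, 0), 6.09 + 0.058 * 99,
               tolerance = 1e-12)
  # acceleration scales the base only
  cell2 <- CellKinetics(tau1 = 10, slope_m = 0.05, alpha_max = 0.5)
  expect_equal(effectiveTau(cell2, 10, 1), 10 * 0.5 + 0.05 * 9,
               tolerance = 1e-12)
  expect_error(effectiveTau(cell, 10, 1.5), "a_end")
  expect_error(effectiveTau(cell, NaN, 0), "non-finite")
})

test_that("acceleration state saturates per AP and relaxes between events", {
  cell <- CellKinetics(delta_a = 0.2, tau_pers = 1e9, pers_shape = 1,
                       alpha_max = 0.5)
  # closed form for n identical increments from 0 (negligible decay):
  # a_n = 1 - (1 - delta)^n, checked against the sequential update
  s <- AccelState()
  for (i in 1:5) s <- updateAccelState(s, cell, ap_time = (i - 1) / 10)
  expect_equal(s@a, 1 - 0.8^5, tolerance = 1e-9)
  # brute-force sequential oracle at another delta
  cellb <- CellKinetics(delta_a = 0.37, tau_pers = 1e9, pers_shape = 1,
                        alpha_max = 0.5)
  a <- 0
  for (i in 1:8) a <- a + 0.37 * (1 - a)
  sb <- AccelState()
  for (i in 1:8) sb <- updateAccelState(sb, cellb, ap_time = (i - 1) / 10)
  expect_equal(sb@a, a, tolerance = 1e-9)

  # relaxation over one persistence time is e^-1 (any shape)
  for (shape in c(1, 2.5, 4.3)) {
    cellc <- CellKinetics(delta_a = 0.2, tau_pers = 20, pers_shape = shape,
                          alpha_max = 0.5)
    s <- new("AccelState", a = 0.5, t_last = 0)
    s2 <- updateAccelState(s, cellc, elapsed = 20)
    expect_equal(s2@a, 0.5 * exp(-1), tolerance = 1e-12)
  }

  # zero state stays zero without APs
  s0 <- updateAccelState(AccelState(), cell, elapsed = 100)
  expect_identical(s0@a, 0)

  # ordering violation
  s <- updateAccelState(AccelState(), cell, ap_time = 5)
  expect_error(updateAccelState(s, cell, ap_time = 4), "non-decreasing")
})

test_that("acceleration state stays in [0, 1] and relaxes monotonically", {
  set.seed(11)
  cell <- defaultKinetics("37C")
  for (rep in 1:20) {
    s <- AccelState()
    t <- 0
    for (k in 1:50) {
      t <- t + stats::runif(1, 0, 5)
      s <- updateAccelState(s, cell, ap_time = t)
      expect_gte(s@a, 0); expect_lte(s@a, 1)
    }
    # pure relaxation is monotone non-increasing
    prev <- s@a
    for (dt in c(1, 2, 5, 10)) {
      s <- updateAccelState(s, cell, elapsed = dt)
      expect_lte(s@a, prev + 1e-12)
      prev <- s@a
    }
  }
})

test_that("calibrated 37C tuning curve has its minimum near 25 AP", {
  cell <- defaultKinetics("37C")
  taus <- vapply(c(5, 10, 15, 25, 50, 100), function(n)
    effectiveTau(cell, n, pHendo:::.accelAfterBurst(0, n, 10, cell)),
    numeric(1))
  names(taus) <- c(5, 10, 15, 25, 50, 100)
  expect_lt(taus[["25"]], taus[["5"]])
  expect_lt(taus[["25"]], taus[["100"]])
  expect_identical(names(which.min(taus)), "25")
  # without acceleration, tau_eff is non-decreasing in n_ap
  flat <- cell; flat@alpha_max <- 0
  taus_flat <- vapply(c(1, 5, 10, 25, 50, 100, 300), function(n)
    effectiveTau(flat, n, pHendo:::.accelAfterBurst(0, n, 10, flat)),
    numeric(1))
  expect_true(all(diff(taus_flat) >= 0))
})
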