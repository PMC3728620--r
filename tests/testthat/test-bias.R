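test_that("biexponential closed form matches its special values and limits", {
  # no reacidification delay: plain exponential
  t <- seq(0, 50, 0.5)
  expect_equal(biexpFluorescence(t, 10, 0), exp(-t / 10),
               tolerance = 1e-12)
  # closed-form arithmetic: (10 e^-1 - 2 e^-5) / 8
  expect_equal(biexpFluorescence(10, 10, 2),
               (10 * exp(-1) - 2 * exp(-5)) / 8, tolerance = 1e-12)
  # F(0) = 1 and monotone non-increasing for any parameters
  set.seed(17)
  for (k in 1:20) {
    te <- stats::runif(1, 0.5, 40); tr <- stats::runif(1, 0, te * 1.5)
    y <- biexpFluorescence(t, te, tr)
    expect_equal(y[1], 1, tolerance = 1e-12)
    expect_true(all(diff(y) <= 1e-12))
  }
  expect_error(biexpFluorescence(-1, 10, 2), "t must be")
  # BiexpParams dispatch
  expect_equal(biexpFluorescence(5, BiexpParams(10, 2)),
               biexpFluorescence(5, 10, 2))
})

test_that("closed form agrees with numerical ODE integration to 1e-8", {
  skip_if_not_installed("deSolve")
  two_compartment <- function(te, tr, times) {
    rhs <- function(t, y, p)
      list(c(-y[1] / p[1], y[1] / p[1] - y[2] / p[2]))
    out <- deSolve::lsoda(c(S = 1, I = 0), c(0, times), rhs, c(te, tr),
                          rtol = 1e-11, atol = 1e-12)
    rowSums(out[-1, c("S", "I"), drop = FALSE])
  }
  set.seed(23)
  for (k in 1:100) {
    te <- stats::runif(1, 0.5, 30)
    tr <- stats::runif(1, 0.05, 20)
    tt <- stats::runif(1, 0.1, 60)
    expect_equal(biexpFluorescence(tt, te, tr),
                 unname(two_compartment(te, tr, tt)), tolerance = 1e-8)
  }
})

test_that("the equal-time-constant limit is continuous", {
  te <- 10
  for (t in c(1, 5, 20)) {
    lim <- (1 + t / te) * exp(-t / te)
    # the true difference is first order in the gap; at a 1e-4 relative
    # gap it is a few 1e-5, and the closed form must not blow it up
    near <- biexpFluorescence(t, te, te * (1 - 1e-4))
    expect_lt(abs(near - lim), 1e-4)
    # just outside the analytic switch the two branches agree to 1e-6
    closer <- biexpFluorescence(t, te, te * (1 - 1e-8))
    expect_lt(abs(closer - lim), 1e-6)
  }
})

test_that("reacidification bias is zero when correctly specified and grows with mis-specification", {
  b_match <- reacidBias(10, 1.6, 1.6)
  expect_lt(abs(as.numeric(b_match)), 1e-9)
  b26 <- as.numeric(reacidBias(10, 2.6, 1.6))
  b36 <- as.numeric(reacidBias(10, 3.6, 1.6))
  expect_gt(b36, b26)
  expect_gt(b26, 0)
  # the raw deviation from truth carries the protocol's intrinsic bias
  expect_gt(attr(reacidBias(10, 2.6, 1.6), "raw_bias"), b26)
  expect_error(reacidBias(-1, 1, 1), "positive")
})

test_that("bias vanishes as reacidification becomes fast relative to endocytosis", {
  # shrink tau_r_true/tau_e with the assumed offset scaled likewise
  biases <- vapply(c(0.4, 0.2, 0.1, 0.05), function(s)
    abs(as.numeric(reacidBias(10, 10 * s * 1.6, 10 * s))), numeric(1))
  expect_true(all(diff(biases) < 0))
  expect_lt(biases[length(biases)], 0.25 * biases[1])
})

test_that("bias scan is deterministic, zero on the diagonal, monotone off it", {
  g <- biasScan(10, c(1.6, 2.6, 3.6), c(1.6, 2.6))
  g2 <- biasScan(10, c(1.6, 2.6, 3.6), c(1.6, 2.6))
  expect_identical(g, g2)
  diag_rows <- g[g$tau_r_true == g$tau_r_assumed, ]
  expect_true(all(abs(diag_rows$bias_pct) < 1e-9))
  # bias increases with |tau_r_true - tau_r_assumed| at fixed tau_e
  sub <- g[g$tau_r_assumed == 1.6, ]
  sub <- sub[order(abs(sub$tau_r_true - sub$tau_r_assumed)), ]
  expect_true(all(diff(abs(sub$bias_pct)) >= -1e-12))
  # single point equals the scalar function
  one <- biasScan(10, 2.6, 1.6)
  expect_equal(one$bias_pct, as.numeric(reacidBias(10, 2.6, 1.6)))
  expect_error(biasScan(numeric(0), 1, 1), "non-empty")
})
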