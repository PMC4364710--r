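# Dual-TR steady-state signal model, its limits, the Bloch fixed-point
# oracle, and the AFI inversion.

p0 <- SequenceParams()  # TR1/TR2 = 4/7 ms, T1 = 1420 ms, T2* = 450 ms, TE = 3 ms

test_that("boundary flip angles give the analytic signal values", {
  z <- steadyStateSignals(0, p0)
  expect_identical(z$s_strong, 0)
  expect_identical(z$s_weak, 0)

  # at 90 degrees the steady state collapses to saturation-recovery signals
  s <- steadyStateSignals(90, p0)
  ete <- exp(-3 / 450)
  expect_equal(s$s1, (1 - exp(-7 / 1420)) * ete, tolerance = 1e-14)
  expect_equal(s$s2, (1 - exp(-4 / 1420)) * ete, tolerance = 1e-14)
  expect_equal(s$s_strong, s$s1)
})

test_that("exchanging the TRs exchanges the positional signals and leaves the derived labels invariant", {
  th <- c(5, 30, 60, 90)
  a <- steadyStateSignals(th, SequenceParams(tr1_ms = 4, tr2_ms = 7))
  b <- steadyStateSignals(th, SequenceParams(tr1_ms = 7, tr2_ms = 4))
  expect_equal(a$s1, b$s2, tolerance = 1e-15)
  expect_equal(a$s2, b$s1, tolerance = 1e-15)
  expect_equal(a$s_strong, b$s_strong, tolerance = 1e-15)
  expect_equal(a$s_weak, b$s_weak, tolerance = 1e-15)
})

test_that("equal TRs reduce the dual-TR model to the Ernst signal", {
  peq <- SequenceParams(tr1_ms = 5.5, tr2_ms = 5.5)
  s <- steadyStateSignals(30, peq)
  ref <- ernstSignal(30, 5.5, peq)
  expect_equal(s$s_strong, ref, tolerance = 1e-13)
  expect_equal(s$s_weak, ref, tolerance = 1e-13)
  b <- blochSteadyState(30, 30, peq)
  expect_equal(b$s1, ref, tolerance = 1e-10)
})

test_that("the general two-angle model reduces correctly", {
  g <- steadyStateSignalsGeneral(40, 40, p0)
  s <- steadyStateSignals(40, p0)
  expect_equal(g, s, tolerance = 1e-15)
  expect_identical(steadyStateSignalsGeneral(0, 55, p0)$s1, 0)
})

test_that("closed form agrees with the Bloch fixed-point oracle to 1e-10 relative", {
  grid <- c(1, seq(5, 90, by = 5))
  worst <- 0
  for (t1 in grid) {
    for (t2 in grid) {
      b <- blochSteadyState(t1, t2, p0)
      g <- steadyStateSignalsGeneral(t1, t2, p0)
      worst <- max(worst,
                   abs(b$s1 - g$s1) / g$s1,
                   abs(b$s2 - g$s2) / g$s2)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("Bloch iteration converges to a fixed point and reports non-convergence", {
  b1 <- blochSteadyState(50, 70, p0, tol = 1e-10)
  b2 <- blochSteadyState(50, 70, p0, tol = 1e-14)
  # tightening the tolerance leaves the converged value essentially unchanged
  expect_equal(b1$s1, b2$s1, tolerance = 1e-9)
  expect_error(blochSteadyState(1, 1, p0, tol = 1e-14, max_cycles = 3L),
               "did not converge")
})

test_that("strong exceeds weak and the relative contrast grows with flip angle", {
  th <- 1:90
  s <- steadyStateSignals(th, p0)
  expect_true(all(s$s_strong > s$s_weak))
  rel <- (s$s_strong - s$s_weak) / s$s_strong
  expect_true(all(diff(rel) >= 0))
})

test_that("Ernst signal peaks at the Ernst angle", {
  th <- seq(0.5, 90, by = 0.5)
  sig <- ernstSignal(th, 11, p0)
  peak <- th[which.max(sig)]
  expect_equal(peak, ernstAngle(11, p0), tolerance = 0.5)
  expect_identical(ernstSignal(0, 11, p0), 0)
})

test_that("AFI inversion recovers the flip angle from simulated signals", {
  for (th in c(10, 30, 60, 90)) {
    s <- steadyStateSignals(th, p0)
    est <- afiFlipAngle(s$s_strong, s$s_weak, 4, 7)
    expect_lt(abs(est - th), 0.5)
  }
  # degenerate inputs have analytic values
  expect_equal(afiFlipAngle(1, 1, 4, 7), 0)
  expect_equal(afiFlipAngle(1, 0, 4, 7), acos(-4 / 7) * 180 / pi,
               tolerance = 1e-12)
})

test_that("AFI inversion rejects invalid preconditions", {
  expect_error(afiFlipAngle(1, 1.1, 4, 7), "exceeds")
  expect_error(afiFlipAngle(0, 0, 4, 7), "positive")
  expect_error(afiFlipAngle(1, 0.5, 7, 4), "tr2_ms")
})

test_that("signal functions reject out-of-range or non-finite angles by name", {
  expect_error(steadyStateSignals(-1, p0), "theta_deg")
  expect_error(steadyStateSignals(200, p0), "theta_deg")
  expect_error(steadyStateSignals(NaN, p0), "theta_deg")
  expect_error(steadyStateSignalsGeneral(30, Inf, p0), "theta2_deg")
})

test_that("SequenceParams validity enforces positivity and TE < min(TR)", {
  expect_error(SequenceParams(te_ms = 5), "te_ms")
  expect_error(SequenceParams(t1_ms = -1), "positive")
})
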