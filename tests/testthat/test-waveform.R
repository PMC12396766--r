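test_that("synthetic waveforms honor peak, trough, and period", {
  wf <- synth_waveform(100, heart_rate_bpm = 450, pulsatility = 0.5, seed = 4)
  expect_equal(attr(wf, "period_s"), 60 / 450)
  expect_equal(max(wf$value), 100, tolerance = 1e-3)
  expect_gte(min(wf$value), 50)      # pulsatility 0.5 -> trough at half peak
  expect_true(all(wf$value > 0))
  flat <- synth_waveform(80, pulsatility = 0)
  expect_equal(unique(flat$value), 80)
  expect_error(synth_waveform(100, pulsatility = 1), "reverse")
  expect_error(synth_waveform(-5), "positive")
})

test_that("waveform synthesis is seed-deterministic and leaves the RNG alone", {
  a <- synth_waveform(100, pulsatility = 0.4, seed = 7)
  set.seed(123); r1 <- rnorm(1)
  b <- synth_waveform(100, pulsatility = 0.4, seed = 7)
  set.seed(123); r2 <- rnorm(1)
  expect_identical(a$value, b$value)
  expect_identical(r1, r2)
  c2 <- synth_waveform(100, pulsatility = 0.4, seed = 8)
  expect_false(identical(a$value, c2$value))
})

test_that("cycle averaging recovers one cycle from identical cycles", {
  wf <- synth_waveform(90, 450, 0.5, seed = 3)
  f <- waveform_fun(wf)
  tt <- seq(0, 3 * attr(wf, "period_s"), by = 5e-5)
  avg <- cycle_average(tt, f(tt), 450)
  expect_equal(avg$value, f(avg$time_s), tolerance = 0.002)
})

test_that("cycle averaging beats any single noisy cycle in RMS", {
  wf <- synth_waveform(90, 450, 0.5, seed = 3)
  f <- waveform_fun(wf)
  period <- attr(wf, "period_s")
  tt <- seq(0, 3 * period, by = 1e-4)
  set.seed(11)
  noisy <- f(tt) + rnorm(length(tt), sd = 4)
  avg <- cycle_average(tt, noisy, 450, n_phase = 100)
  truth <- f(avg$time_s)
  rms_avg <- sqrt(mean((avg$value - truth)^2))
  ns <- round(period / 1e-4)
  rms_single <- vapply(1:3, function(k) {
    idx <- seq.int((k - 1) * ns + 1, length.out = ns)
    y <- approx((tt[idx] - tt[idx[1]]), noisy[idx], xout = avg$time_s,
                rule = 2)$y
    sqrt(mean((y - truth)^2))
  }, numeric(1))
  expect_lt(rms_avg, min(rms_single))
})

test_that("cycle averaging rejects short records and period mismatch", {
  wf <- synth_waveform(90, 450, 0.5, seed = 3)
  f <- waveform_fun(wf)
  period <- attr(wf, "period_s")
  tt <- seq(0, 2 * period - 1e-4, by = 1e-4)
  expect_error(cycle_average(tt, f(tt), 450, n_cycles = 3), "cycles")
  # record oscillating 20% slower than the nominal rate
  tt3 <- seq(0, 3 * period * 1.25, by = 1e-4)
  slow <- f(tt3 / 1.25)
  expect_error(cycle_average(tt3, slow, 450), "mismatch")
})

test_that("flow_waveform validates its sampling invariants", {
  expect_error(flow_waveform(c(0, 0.01, 0.005), c(1, 2, 3), 450), "increasing")
  expect_error(flow_waveform(c(0, 0.2), c(1, 2), 450), "period")
  expect_error(flow_waveform(c(0, 0.05), c(1, NA), 450), "finite")
})
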