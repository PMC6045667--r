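test_that("directional coupler splits losslessly at c = 0.28", {
  u <- signal_trace(rep(1 + 0i, 16), 1e-5)
  sp <- coupler_split(u, directional_coupler(0.28))
  expect_equal(Mod(sp$copy$samples), rep(0.28, 16))
  expect_equal(Mod(sp$main$samples)^2 + Mod(sp$copy$samples)^2, rep(1, 16))

  sp2 <- coupler_split(u, directional_coupler(1e-9))
  expect_true(all(Mod(sp2$copy$samples) < 1e-8))
  expect_error(directional_coupler(1.2), "coupling_factor")
})

test_that("phase shifter covers 280 degrees with saturating slope", {
  sh <- phase_shifter()
  expect_equal(phase_response(sh, 12) - phase_response(sh, 0), 280)
  expect_equal(phase_response(sh, 0), 0)
  d <- 1e-3
  slope_lo <- (phase_response(sh, 1 + d) - phase_response(sh, 1)) / d
  slope_hi <- (phase_response(sh, 11 + d) - phase_response(sh, 11)) / d
  expect_lt(slope_hi, slope_lo)
  # monotone over the full control range
  v <- seq(0, 25, by = 0.05)
  expect_true(all(diff(phase_response(sh, v)) > 0))
  expect_warning(phase_response(sh, 30), "clamped")
})

test_that("attenuator matches the printed anchors and slope", {
  at <- attenuator()
  expect_equal(attenuation_response(at, 6), 1.3)
  expect_equal(attenuation_response(at, 3), 1.3 + 3 * 1.2)
  expect_equal((attenuation_response(at, 3) - attenuation_response(at, 6)) / 3,
               1.2)
  expect_equal(attenuation_response(at, 0), 30)
  v <- seq(0, 6, by = 0.01)
  expect_true(all(diff(attenuation_response(at, v)) < 0))
  expect_warning(attenuation_response(at, 7), "clamped")
})

test_that("canceller path applies the attenuation, insertion loss and phase", {
  u <- signal_trace(rep(1 + 0i, 8), 1e-5)
  out <- apply_canceller(u, canceller_setting(0, 6))
  expect_equal(Mod(out$samples), rep(10^(-(1.3 + 0.8) / 20), 8))
  expect_equal(Arg(out$samples), rep(0, 8))

  z <- apply_canceller(signal_trace(rep(0 + 0i, 8), 1e-5),
                       canceller_setting(5, 3))
  expect_true(all(z$samples == 0))

  # magnitude independent of the phase voltage
  m1 <- Mod(apply_canceller(u, canceller_setting(2, 4))$samples[1])
  m2 <- Mod(apply_canceller(u, canceller_setting(9, 4))$samples[1])
  expect_equal(m1, m2)
})

test_that("coupling channel leaks a scaled, rotated transmit copy", {
  u <- signal_trace(rep(1 + 0i, 8), 1e-5)
  lk <- leak_signal(u, coupling_channel(1, 0, 30))
  expect_equal(Mod(lk$samples), rep(10^(-30 / 20), 8), tolerance = 1e-12)

  # opposite-phase leakage adds, it does not cancel
  lk180 <- leak_signal(u, coupling_channel(1, 180, 0))
  ref <- signal_trace(rep(1 + 0i, 8), 1e-5)
  summed <- signal_trace(ref$samples - lk180$samples, 1e-5)
  expect_equal(Mod(summed$samples), rep(2, 8), tolerance = 1e-12)

  # zero frequency slope leaves an exactly scaled/rotated copy
  p <- make_chirp(1e-3, 16e3, dt = 8e-6)
  lk2 <- leak_signal(as_pulse_trace <- signal_trace(p$samples, p$dt),
                     coupling_channel(1, 45, 20, freq_slope = c(0, 0)), p)
  expect_equal(lk2$samples,
               10^(-1) * exp(1i * pi / 4) * p$samples, tolerance = 1e-12)
})

test_that("power combiner subtracts sample-wise", {
  a <- signal_trace(complex(real = 1:5, imaginary = 5:1), 1e-5)
  expect_true(all(combine_traces(a, a)$samples == 0))
  z <- signal_trace(rep(0 + 0i, 5), 1e-5)
  expect_equal(combine_traces(a, z)$samples, a$samples)
  b <- signal_trace(rep(0 + 0i, 4), 1e-5)
  expect_error(combine_traces(a, b), "length")
})

test_that("pick-up coil monitors the transmit waveform", {
  u <- signal_trace(complex(real = 1:4, imaginary = 0:3), 1e-5)
  expect_equal(pickup_trace(u, pickup_coil(1, 0))$samples, u$samples)
  rot <- pickup_trace(u, pickup_coil(1, 90))$samples
  expect_equal(rot, 1i * u$samples, tolerance = 1e-12)
  tiny <- pickup_trace(u, pickup_coil(1e-12, 0))$samples
  expect_true(all(Mod(tiny) < 1e-11))
})

test_that("isolation metric follows the dB definition", {
  l <- signal_trace(rep(1 + 0i, 10), 1e-5)
  expect_equal(isolation_db(l, l), 0)
  tenth <- signal_trace(rep(0.1 + 0i, 10), 1e-5)
  expect_equal(isolation_db(l, tenth), 20)
  z <- signal_trace(rep(0 + 0i, 10), 1e-5)
  expect_equal(isolation_db(l, z), 200)
  expect_error(isolation_db(z, l), "power")

  # 1% amplitude mismatch at exact phase leaves 40 dB suppression
  resid <- combine_traces(l, signal_trace(rep(0.99 + 0i, 10), 1e-5))
  expect_equal(isolation_db(l, resid), 40, tolerance = 1e-9)
})

test_that("front end is linear in the transmit waveform", {
  p <- make_chirp(1e-3, 16e3, dt = 8e-6)
  fe <- default_frontend()
  ch <- coupling_channel(1.2, 100, 30)
  st <- canceller_setting(5, 2)
  chain <- function(pulse_samples) {
    u <- signal_trace(pulse_samples, p$dt)
    sp <- coupler_split(u, fe$coupler)
    combine_traces(leak_signal(sp$main, ch),
                   apply_canceller(sp$copy, st, fe$shifter, fe$att))$samples
  }
  base <- chain(p$samples)
  scaled <- chain(3.7 * p$samples)
  expect_equal(scaled, 3.7 * base, tolerance = 1e-12)
})

test_that("pure phase error at the amplitude optimum suppresses as -20 log10 |sin dphi|", {
  for (dphi_deg in c(0.5, 2, 10)) {
    l <- signal_trace(rep(1 + 0i, 64), 1e-5)
    # amplitude-optimal reference for a phase-mismatched canceller
    a_opt <- cos(dphi_deg * pi / 180)
    cref <- signal_trace(rep(a_opt * exp(1i * dphi_deg * pi / 180), 64), 1e-5)
    sup <- isolation_db(l, combine_traces(l, cref))
    expect_equal(sup, -20 * log10(abs(sin(dphi_deg * pi / 180))),
                 tolerance = 0.1)
  }
})

test_that("a matching canceller setting exists for channels inside coverage", {
  set.seed(42)
  fe <- default_frontend()
  p <- make_rect(4e-3, 1, 10e-6)
  for (i in 1:5) {
    ch <- random_channel()
    ref <- grid_search_reference(fe, ch, p,
                                 v1_step = 0.05, v_att_step = 0.005)
    opt <- optimal_setting(fe, ch)
    # residual at the analytic optimum is essentially zero
    sp <- coupler_split(p, fe$coupler)
    resid <- combine_traces(leak_signal(sp$main, ch),
                            apply_canceller(sp$copy, opt, fe$shifter, fe$att))
    leak <- leak_signal(sp$main, ch)
    expect_gt(isolation_db(leak, resid), 100)
    # and the dense grid localizes near it
    expect_lt(abs(ref$v1 - opt$v1), 0.1)
    expect_lt(abs(ref$v_att - opt$v_att), 0.01)
  }
})
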