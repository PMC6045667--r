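test_that("FID of a centred isochromat is a real decaying exponential", {
  ph <- phantom(c(0, 0, 0), m0 = 2, t2star = 0.5e-3)
  g <- gradient_waveform(c(1, 0, 0), 4e-3)
  h <- fid_response(ph, g, 1e-5, 64)
  t <- (0:63) * 1e-5
  expect_equal(h$h, complex(real = 2 * exp(-t / 0.5e-3)), tolerance = 1e-12)
})

test_that("off-centre isochromat under constant gradient matches closed form", {
  x <- 0.01
  ph <- phantom(c(x, 0, 0), t2star = 1e-3)
  g <- gradient_waveform(c(1, 0, 0), 2e-3, ramp_time = 0)
  h <- fid_response(ph, g, 4e-6, 128)
  t <- (0:127) * 4e-6
  f <- GAMMA_HZ_PER_T * 2e-3 * x
  expect_equal(h$h, exp(-t / 1e-3) * exp(2i * pi * f * t), tolerance = 1e-10)
})

test_that("FID is additive over isochromats", {
  g <- gradient_waveform(c(0, 1, 0), 3e-3)
  p1 <- phantom(c(0.01, 0.02, 0), t2star = 0.3e-3)
  p2 <- phantom(c(-0.02, 0.01, 0), t2star = 0.8e-3, chem_shift = 200)
  both <- phantom(rbind(c(0.01, 0.02, 0), c(-0.02, 0.01, 0)),
                  t2star = c(0.3e-3, 0.8e-3), chem_shift = c(0, 200))
  h12 <- fid_response(p1, g, 1e-5, 64)$h + fid_response(p2, g, 1e-5, 64)$h
  expect_equal(fid_response(both, g, 1e-5, 64)$h, h12, tolerance = 1e-12)
})

test_that("a delta transmit pulse passes the impulse response through", {
  dt <- 8e-6
  delta <- structure(list(samples = c(1 + 0i, rep(0 + 0i, 63)), dt = dt,
                          duration = 64 * dt, sweep_bandwidth = 0,
                          kind = "rect", center_offset = 0, amplitude = 1),
                     class = "cea_pulse")
  ph <- phantom(c(0.005, 0, 0), t2star = 0.4e-3)
  g <- gradient_waveform(c(1, 0, 0), 4e-3)
  s <- cea_signal(ph, delta, g)
  h <- fid_response(ph, g, dt, 64)
  expect_equal(s$samples, h$h, tolerance = 1e-12)

  empty <- phantom(c(0, 0, 0), m0 = 0, t2star = 1e-3)
  s0 <- cea_signal(empty, make_chirp(0.5e-3, 16e3, dt = dt), g)
  expect_true(all(Mod(s0$samples) < 1e-14))
})

test_that("Bloch oracle reproduces small-tip nutation and M0 linearity", {
  # on-resonance rectangular pulse, no relaxation: |Mxy| = sin(w1 t)
  dt <- 1e-5
  p <- make_rect(1e-3, 1, dt)
  ph <- phantom(c(0, 0, 0), t2star = 1e9)
  g <- gradient_waveform(c(1, 0, 0), 0)
  b1 <- 50                       # Hz per unit amplitude -> 18 deg flip
  s <- bloch_simulate(ph, p, g, b1_scale = b1, t1 = Inf)
  t <- (1:100) * dt
  mxy <- Mod(s$samples) * (2 * pi * b1 * dt)
  expect_equal(mxy, sin(2 * pi * b1 * t), tolerance = 1e-6)

  # zero RF leaves equilibrium magnetization untouched
  z <- bloch_simulate(phantom(c(0, 0, 0)), make_rect(1e-3, 0, dt), g,
                      b1_scale = 1)
  expect_true(all(Mod(z$samples) == 0))

  ph2 <- phantom(c(0, 0, 0), m0 = 2, t2star = 1e9)
  s2 <- bloch_simulate(ph2, p, g, b1_scale = 1e-3)
  s1 <- bloch_simulate(phantom(c(0, 0, 0), t2star = 1e9), p, g,
                       b1_scale = 1e-3)
  expect_equal(s2$samples, 2 * s1$samples, tolerance = 1e-9)

  expect_error(bloch_simulate(ph, make_rect(1e-3, 1, dt), g, b1_scale = 1e4),
               "0.5 rad")
})

test_that("convolution model matches the Bloch oracle at small flip angles", {
  p <- make_chirp(2.048e-3, 16e3, amplitude = 1, dt = 4e-6)
  ph <- phantom(c(0.01, 0, 0), t2star = 0.5e-3)
  g <- gradient_waveform(c(1, 0, 0), 1e-3, ramp_time = 0)
  flip_to_b1 <- function(flip_deg)
    (flip_deg * pi / 180) / (2 * pi * sum(Mod(p$samples)) * p$dt)
  sc <- cea_signal(ph, p, g)
  rel <- vapply(c(60, 30, 15, 7.5, 0.5), function(fl) {
    sb <- bloch_simulate(ph, p, g, b1_scale = flip_to_b1(fl))
    rel_rms(sb$samples, sc$samples)
  }, 1)
  # < 2% at 0.5 degrees, and decreasing with the flip-angle ladder
  expect_lt(rel[5], 0.02)
  expect_true(all(diff(rel[1:4]) < 0))
  expect_lt(rel[4], rel[1])
})

test_that("phantom translation imprints the expected linear spectral phase", {
  g <- gradient_waveform(c(1, 0, 0), 2e-3, ramp_time = 0)
  dx <- 0.004
  h0 <- fid_response(phantom(c(0.01, 0, 0), t2star = 1e-3), g, 4e-6, 96)$h
  h1 <- fid_response(phantom(c(0.01 + dx, 0, 0), t2star = 1e-3), g, 4e-6, 96)$h
  k <- GAMMA_HZ_PER_T * 2e-3 * (0:95) * 4e-6
  expect_equal(h1, h0 * exp(2i * pi * k * dx), tolerance = 1e-10)
})

test_that("FID energy shrinks with shorter T2*", {
  g <- gradient_waveform(c(1, 0, 0), 1e-3)
  e <- vapply(c(2e-3, 1e-3, 0.5e-3, 0.2e-3), function(t2)
    sum(Mod(fid_response(phantom(c(0, 0, 0), t2star = t2), g, 1e-5, 256)$h)),
    1)
  expect_true(all(diff(e) < 0))
  expect_true(all(is.finite(e)))
})

test_that("radial acquisition geometry is consistent", {
  p <- make_chirp(2.048e-3, 16e3, dt = 8e-6)
  prot <- protocol(8, 256, p, grad_amplitude = 4e-3, ramp_time = 0.2e-3,
                   dim = 2, fov = 0.12, matrix_size = 32)
  ph <- phantom(c(0, 0, 0), t2star = 0.4e-3)
  spokes <- acquire_dataset(ph, prot)
  expect_length(spokes, 8)
  # opposite spokes of a centred phantom have identical magnitude
  expect_equal(Mod(spokes[[1]]$s_mr$samples), Mod(spokes[[5]]$s_mr$samples),
               tolerance = 1e-10)
  # trapezoid endpoint of the ramped trajectory
  t_acq <- 256 * p$dt
  expect_equal(spokes[[1]]$k_traj[256],
               GAMMA_HZ_PER_T * 4e-3 * (t_acq - 0.2e-3 / 2), tolerance = 1e-12)
  expect_true(all(diff(spokes[[1]]$k_traj) > 0))
  expect_error(protocol(0, 256, p), "spoke count")

  dirs <- spoke_directions(1000, dim = 3)
  expect_equal(sqrt(rowSums(dirs^2)), rep(1, 1000), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(dirs)^2)), 0.05)
})

test_that("full chain composes leakage, MR signal and noise reproducibly", {
  p <- make_chirp(1.024e-3, 16e3, dt = 8e-6)
  prot <- protocol(4, 128, p, dim = 2, fov = 0.12, matrix_size = 32)
  fe <- default_frontend()
  ch <- coupling_channel(1, 120, 30)
  empty <- phantom(c(0, 0, 0), m0 = 0, t2star = 1e-3)

  # perfect canceller and zero phantom: silence
  opt <- optimal_setting(fe, ch)
  s0 <- full_chain(empty, prot, fe, ch, opt,
                   noise_cfg = list(sigma_rx = 0, tx_noise_frac = 0), seed = 1)
  expect_lt(max(Mod(s0[[1]]$s$samples)),
            1e-9 * max(Mod(leak_signal(p, ch)$samples)))

  # canceller fully attenuated (V_att = 0: ~30 dB extra loss) leaves the
  # leakage visible
  off <- canceller_setting(0, 0)
  s1 <- full_chain(empty, prot, fe, ch, off,
                   noise_cfg = list(sigma_rx = 0, tx_noise_frac = 0), seed = 1)
  sp <- coupler_split(p, fe$coupler)
  lk <- leak_signal(sp$main, ch)$samples[1:128]
  cref <- apply_canceller(sp$copy, off, fe$shifter, fe$att)$samples[1:128]
  expect_equal(s1[[1]]$s$samples, lk - cref, tolerance = 1e-12)

  # fixed seed: bit-identical noisy datasets
  ph <- phantom(c(0.01, 0, 0), t2star = 0.4e-3)
  a <- full_chain(ph, prot, fe, ch, opt,
                  noise_cfg = list(sigma_rx = 0.01, tx_noise_frac = 0.001),
                  seed = 42)
  b <- full_chain(ph, prot, fe, ch, opt,
                  noise_cfg = list(sigma_rx = 0.01, tx_noise_frac = 0.001),
                  seed = 42)
  expect_identical(a[[3]]$s$samples, b[[3]]$s$samples)
})
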