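# Spin-system side of the received signal: FID impulse response of a digital
# phantom under radial frequency encoding, the small-tip convolution model of
# the concurrently acquired signal
#   s_MR[n] = h[0] u_Tx[n] + h[1] u_Tx[n-1] + ...,
# and a Bloch rotation-matrix integrator used as the validation oracle.

#' Gyromagnetic ratio of 1H
#'
#' gamma / 2 pi in Hz/T.
#' @export
GAMMA_HZ_PER_T <- 42.577e6

#' Digital phantom
#'
#' An isochromat ensemble: positions (m), equilibrium densities (a.u.),
#' effective transverse relaxation times T2* (s) and chemical-shift offsets
#' (Hz).
#'
#' @param positions n x 3 matrix of positions (m); a vector of length 3 is
#'   taken as a single isochromat
#' @param m0 densities (a.u.)
#' @param t2star T2* values (s), recycled
#' @param chem_shift chemical shifts (Hz), recycled
#' @param name label
#' @export
phantom <- function(positions, m0 = 1, t2star = 1e-3, chem_shift = 0,
                    name = "phantom") {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  m0 <- rep_len(m0, n); t2star <- rep_len(t2star, n)
  chem_shift <- rep_len(chem_shift, n)
  if (any(t2star <= 0)) stop("phantom: T2* must be positive")
  if (any(!is.finite(positions))) stop("phantom: positions must be finite")
  structure(list(positions = positions, m0 = m0, t2star = t2star,
                 chem_shift = chem_shift, name = name),
            class = "cea_phantom")
}

#' @export
print.cea_phantom <- function(x, ...) {
  cat(sprintf("<cea_phantom '%s': %d isochromats, T2* %.3g-%.3g ms>\n",
              x$name, nrow(x$positions), min(x$t2star) * 1e3,
              max(x$t2star) * 1e3))
  invisible(x)
}

#' Readout gradient waveform
#'
#' Constant-direction gradient with a linear ramp over `ramp_time` followed
#' by a plateau at `amplitude`.
#'
#' @param direction 3-vector, normalized internally
#' @param amplitude plateau strength (T/m; 4 mT/m = `4e-3`)
#' @param ramp_time linear ramp duration (s)
#' @export
gradient_waveform <- function(direction = c(1, 0, 0), amplitude = 4e-3,
                              ramp_time = 0) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("gradient_waveform: direction must be nonzero")
  structure(list(direction = direction / nrm, amplitude = amplitude,
                 ramp_time = ramp_time), class = "cea_gradient")
}

# exact trapezoidal integral of the ramped gradient magnitude from 0 to t
gradient_integral <- function(grad, t) {
  tr <- grad$ramp_time
  if (tr <= 0) return(grad$amplitude * t)
  ifelse(t < tr,
         grad$amplitude * t^2 / (2 * tr),
         grad$amplitude * (t - tr / 2))
}

#' FID impulse response of a phantom under a readout gradient
#'
#' `h[m] = sum_i M0_i exp(-t_m / T2*_i) exp(+2i pi phi_i(t_m))` with
#' `phi_i(t) = gamma (G . r_i) integral_0^t |G| dt' / |G| + chem_i t`;
#' delays are sampled at `t_m = m dt`, `m = 0 .. n-1`, so `h[0]` carries no
#' encoding and sits exactly at the k-space centre. Positive gradient-induced
#' frequency accrues positive phase.
#'
#' @param phant a [phantom()]
#' @param grad a [gradient_waveform()]
#' @param dt sample interval (s)
#' @param n number of response samples
#' @param gamma gyromagnetic ratio (Hz/T)
#' @return a `cea_impulse_response`: `h` (complex), `dt`, `length`
#' @export
fid_response <- function(phant, grad, dt, n, gamma = GAMMA_HZ_PER_T) {
  if (n < 1) stop("fid_response: n must be >= 1")
  t <- (seq_len(n) - 1) * dt
  kint <- gamma * gradient_integral(grad, t)       # cycles/m accumulated
  proj <- drop(phant$positions %*% grad$direction) # m
  # n x n_iso phase/decay matrix
  ph <- outer(kint, proj) + outer(t, phant$chem_shift)
  dec <- exp(-outer(t, 1 / phant$t2star))
  h <- as.vector((dec * exp(2i * pi * ph)) %*% phant$m0)
  structure(list(h = h, dt = dt, length = n), class = "cea_impulse_response")
}

#' Concurrently acquired MR signal (small-tip convolution model)
#'
#' Causal discrete convolution of the phantom's FID response with the pulse
#' samples, truncated to `n` points.
#'
#' @inheritParams fid_response
#' @param pulse transmit pulse sampled at the same `dt`
#' @param n output length (defaults to the pulse length)
#' @export
cea_signal <- function(phant, pulse, grad, n = length(pulse$samples),
                       gamma = GAMMA_HZ_PER_T) {
  h <- fid_response(phant, grad, pulse$dt, n, gamma)
  s <- convolve_causal(pulse$samples, h$h, n)
  signal_trace(s, pulse$dt)
}

# causal convolution sum_{m} h[m] u[k - m], truncated to n points (FFT-based)
convolve_causal <- function(u, h, n) {
  nu <- length(u); nh <- length(h)
  nfft <- stats::nextn(nu + nh - 1, 2)
  full <- stats::fft(stats::fft(c(u, rep(0, nfft - nu))) *
                       stats::fft(c(h, rep(0, nfft - nh))), inverse = TRUE) / nfft
  full[seq_len(n)]
}

#' Bloch-equation integrator (validation oracle)
#'
#' Per-isochromat rotation-matrix integration in the rotating frame: each
#' step rotates the magnetization about the effective field
#' `(-w1x, -w1y, dw)` (so that free precession at positive off-resonance
#' accrues positive transverse phase and an on-resonance real pulse nutates
#' towards +y), then applies T2* decay to the transverse components (and T1
#' recovery if given). The summed transverse magnetization is rescaled by
#' `1 / (i 2 pi b1_scale dt)` to the units of [cea_signal()].
#'
#' @inheritParams cea_signal
#' @param b1_scale nutation frequency per unit pulse amplitude (Hz); stands
#'   in for the unprinted coil efficiency and sets the effective flip angle
#' @param t1 longitudinal relaxation time (s), `Inf` to disable
#' @export
bloch_simulate <- function(phant, pulse, grad, n = length(pulse$samples),
                           b1_scale = 1, gamma = GAMMA_HZ_PER_T, t1 = Inf) {
  dt <- pulse$dt
  u <- pulse$samples[seq_len(n)]
  t <- (seq_len(n) - 1) * dt
  kgrad <- gamma * grad$amplitude *
    (if (grad$ramp_time > 0) pmin(t / grad$ramp_time, 1) else rep(1, n))
  proj <- drop(phant$positions %*% grad$direction)
  w1 <- 2 * pi * b1_scale * u                     # complex nutation (rad/s)
  if (max(Mod(w1)) * dt > 0.5 ||
      max(abs(2 * pi * (max(abs(kgrad)) * max(abs(proj)) +
                          max(abs(phant$chem_shift)))) * dt) > 0.5)
    stop("bloch_simulate: effective rotation per step exceeds 0.5 rad; ",
         "reduce dt")
  niso <- nrow(phant$positions)
  sig <- complex(n)
  e2 <- exp(-dt / phant$t2star)
  e1 <- if (is.finite(t1)) exp(-dt / t1) else 1
  for (i in seq_len(niso)) {
    M <- c(0, 0, phant$m0[i])
    dw <- 2 * pi * (kgrad * proj[i] + phant$chem_shift[i])  # rad/s per step
    acc <- complex(n)
    for (m in seq_len(n)) {
      w <- c(-Re(w1[m]), -Im(w1[m]), dw[m])
      wn <- sqrt(sum(w^2))
      if (wn > 0) {
        ax <- w / wn; th <- wn * dt
        ct <- cos(th); stn <- sin(th)
        M <- M * ct + crossprod3(ax, M) * stn + ax * sum(ax * M) * (1 - ct)
      }
      M[1:2] <- M[1:2] * e2[i]
      if (is.finite(t1)) M[3] <- phant$m0[i] + (M[3] - phant$m0[i]) * e1
      acc[m] <- complex(real = M[1], imaginary = M[2])
    }
    sig <- sig + acc
  }
  signal_trace(sig / (1i * 2 * pi * b1_scale * dt), dt)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Acquisition protocol
#'
#' @param n_spokes number of radial spokes
#' @param n_samples samples per spoke
#' @param pulse transmit pulse
#' @param grad_amplitude readout plateau strength (T/m)
#' @param ramp_time gradient ramp duration (s)
#' @param dim 2 or 3 (spoke geometry)
#' @param fov field of view (m), used by reconstruction
#' @param matrix_size reconstruction matrix
#' @export
protocol <- function(n_spokes, n_samples, pulse, grad_amplitude = 4e-3,
                     ramp_time = 0, dim = 2, fov = 0.2, matrix_size = 64) {
  if (n_spokes < 1) stop("protocol: spoke count must be >= 1")
  structure(list(n_spokes = n_spokes, n_samples = n_samples, pulse = pulse,
                 grad_amplitude = grad_amplitude, ramp_time = ramp_time,
                 dim = dim, fov = fov, matrix_size = matrix_size),
            class = "cea_protocol")
}

#' Radial spoke directions
#'
#' 2D: equal-angle over the full circle (antipodal pairs for even counts).
#' 3D: deterministic spherical spiral, near-uniform on the sphere.
#'
#' @param n_spokes spoke count
#' @param dim 2 or 3
#' @return n x 3 matrix of unit vectors
#' @export
spoke_directions <- function(n_spokes, dim = 2) {
  if (dim == 2) {
    ang <- 2 * pi * (seq_len(n_spokes) - 1) / n_spokes
    cbind(cos(ang), sin(ang), 0)
  } else {
    i <- seq_len(n_spokes)
    z <- (2 * i - 1) / n_spokes - 1
    golden <- pi * (3 - sqrt(5))
    phi <- golden * (i - 1)
    r <- sqrt(pmax(1 - z^2, 0))
    cbind(r * cos(phi), r * sin(phi), z)
  }
}

#' Acquire a radial CEA dataset (MR signal only)
#'
#' One spoke per direction: the concurrently acquired signal from
#' [cea_signal()] and the k-space radius trajectory
#' `k(t) = gamma integral_0^t G dt'` evaluated at `t_m = m dt`,
#' `m = 1 .. n_samples`.
#'
#' @param phant a [phantom()]
#' @param prot a [protocol()]
#' @return list of spokes, each with `direction`, `s_mr` ([signal_trace()]),
#'   `k_traj` (1/m)
#' @export
acquire_dataset <- function(phant, prot) {
  dirs <- spoke_directions(prot$n_spokes, prot$dim)
  dt <- prot$pulse$dt
  tk <- seq_len(prot$n_samples) * dt
  lapply(seq_len(prot$n_spokes), function(i) {
    grad <- gradient_waveform(dirs[i, ], prot$grad_amplitude, prot$ramp_time)
    s <- cea_signal(phant, prot$pulse, grad, prot$n_samples)
    list(direction = dirs[i, ], s_mr = s,
         k_traj = GAMMA_HZ_PER_T * gradient_integral(grad, tk))
  })
}

#' Simulate the full receive chain for every spoke
#'
#' Per spoke: `s = (leakage + s_MR) - canceller reference + receiver noise`,
#' with optional transmit-noise proportional to the pulse amplitude. Seeded
#' and reproducible.
#'
#' @param phant a [phantom()]
#' @param prot a [protocol()]
#' @param fe a [frontend()]
#' @param channel a [coupling_channel()]
#' @param setting the current [canceller_setting()]
#' @param noise_cfg list with `sigma_rx` (complex receiver noise sd, a.u.)
#'   and `tx_noise_frac` (transmit-noise amplitude fraction)
#' @param seed integer seed
#' @return list of spokes as in [acquire_dataset()], each with an extra `s`
#'   (measured trace) and `puc` (pick-up monitor trace)
#' @export
full_chain <- function(phant, prot, fe, channel, setting,
                       noise_cfg = list(sigma_rx = 0, tx_noise_frac = 0),
                       seed = 1) {
  set.seed(seed)
  sp <- coupler_split(prot$pulse, fe$coupler)
  leak <- leak_signal(sp$main, channel, prot$pulse)
  cref <- apply_canceller(sp$copy, setting, fe$shifter, fe$att)
  resid_leak <- combine_traces(leak, cref)$samples[seq_len(prot$n_samples)]
  puc_clean <- pickup_trace(prot$pulse, fe$puc)$samples[seq_len(prot$n_samples)]
  spokes <- acquire_dataset(phant, prot)
  n <- prot$n_samples
  lapply(spokes, function(sp1) {
    noise <- if (noise_cfg$sigma_rx > 0)
      complex(real = stats::rnorm(n, 0, noise_cfg$sigma_rx / sqrt(2)),
              imaginary = stats::rnorm(n, 0, noise_cfg$sigma_rx / sqrt(2)))
    else complex(n)
    txn <- if ((noise_cfg$tx_noise_frac %||% 0) > 0)
      Mod(prot$pulse$samples[seq_len(n)]) * noise_cfg$tx_noise_frac *
        complex(real = stats::rnorm(n, 0, 1 / sqrt(2)),
                imaginary = stats::rnorm(n, 0, 1 / sqrt(2)))
    else complex(n)
    sp1$s <- signal_trace(sp1$s_mr$samples + resid_leak + noise + txn,
                          prot$pulse$dt)
    sp1$puc <- signal_trace(puc_clean, prot$pulse$dt)
    sp1
  })
}
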