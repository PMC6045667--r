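# Transmit-pulse synthesis. All waveforms are complex baseband envelopes at
# the Larmor carrier; the carrier itself is never synthesized. Amplitudes are
# arbitrary voltage-like units.

#' Construct an RF pulse object
#'
#' Internal constructor shared by the pulse generators.
#'
#' @param samples complex envelope samples (a.u.)
#' @param dt sample interval (s)
#' @param sweep_bandwidth total frequency sweep (Hz)
#' @param kind one of `"rect"`, `"chirp"`, `"hs8"`
#' @param center_offset offset of the sweep centre from the carrier (Hz)
#' @param amplitude configured peak amplitude (a.u.)
#' @return an object of class `cea_pulse`
#' @keywords internal
new_pulse <- function(samples, dt, sweep_bandwidth, kind, center_offset = 0,
                      amplitude = max(Mod(samples))) {
  structure(
    list(samples = as.complex(samples), dt = dt,
         duration = length(samples) * dt,
         sweep_bandwidth = sweep_bandwidth, kind = kind,
         center_offset = center_offset, amplitude = amplitude),
    class = "cea_pulse")
}

#' @export
print.cea_pulse <- function(x, ...) {
  cat(sprintf("<cea_pulse %s: %d samples, dt = %.3g us, duration = %.3g ms, sweep = %.3g kHz>\n",
              x$kind, length(x$samples), x$dt * 1e6, x$duration * 1e3,
              x$sweep_bandwidth / 1e3))
  invisible(x)
}

#' Rectangular calibration pulse
#'
#' Constant complex amplitude with zero phase, as used by the calibration
#' acquisitions of the feedback loop (default protocol: 4 ms).
#'
#' @param duration pulse length (s)
#' @param amplitude peak amplitude (a.u.)
#' @param dt sample interval (s)
#' @return a [new_pulse()] object of kind `"rect"`
#' @examples
#' p <- make_rect(4e-3, 1, 10e-6)
#' length(p$samples)  # 400
#' @export
make_rect <- function(duration, amplitude = 1, dt = 10e-6) {
  if (duration <= 0 || dt <= 0 || duration / dt < 2)
    stop("make_rect: duration and dt must be positive with duration/dt >= 2")
  n <- round(duration / dt)
  new_pulse(rep(complex(real = amplitude), n), dt, 0, "rect",
            amplitude = amplitude)
}

# sample times: t_m = (m-1) dt, m = 1..n, so the first sample sits at t = 0
pulse_times <- function(n, dt) (seq_len(n) - 1) * dt

#' Edge-smoothed chirp pulse
#'
#' Linear frequency sweep from -BW/2 to +BW/2 across the duration. The
#' envelope is ramped by a quarter-period sine (0 to 1) over the first
#' `smooth_fraction` of the duration and mirrored over the last, emulating
#' sinusoidal smoothing of the pulse edges that avoids distortions from a
#' sudden signal onset.
#'
#' @inheritParams make_rect
#' @param sweep_bandwidth total sweep (Hz)
#' @param smooth_fraction fraction of the duration ramped at each edge
#'   (in `[0, 0.5]`)
#' @param center_offset sweep-centre offset from the carrier (Hz)
#' @export
make_chirp <- function(duration, sweep_bandwidth, amplitude = 1, dt = NULL,
                       smooth_fraction = 0.1, center_offset = 0) {
  if (duration <= 0 || sweep_bandwidth <= 0)
    stop("make_chirp: duration and sweep_bandwidth must be positive")
  if (smooth_fraction < 0 || smooth_fraction > 0.5)
    stop("make_chirp: smooth_fraction must lie in [0, 0.5]")
  if (is.null(dt)) dt <- 1 / (8 * sweep_bandwidth)  # >= 8x sweep oversampling
  n <- round(duration / dt)
  duration <- n * dt                     # snap to the sample grid
  t <- pulse_times(n, dt)
  # instantaneous frequency f(t) = c0 + BW (t/T - 1/2); phase by exact integral
  phase <- 2 * pi * (center_offset * t +
                       sweep_bandwidth * (t^2 / (2 * duration) - t / 2))
  env <- rep(1, n)
  if (smooth_fraction > 0) {
    te <- smooth_fraction * duration
    ramp_up <- t < te
    env[ramp_up] <- sin(pi / 2 * t[ramp_up] / te)
    ramp_dn <- t > duration - te
    env[ramp_dn] <- sin(pi / 2 * (duration - t[ramp_dn]) / te)
  }
  new_pulse(amplitude * env * exp(1i * phase), dt, sweep_bandwidth, "chirp",
            center_offset, amplitude)
}

#' HS8 hyperbolic-secant frequency-swept pulse
#'
#' Adiabatic HSn family with n = 8: amplitude modulation
#' `AM(tau) = sech(beta tau^8)` on `tau` in `[-1, 1]` and frequency
#' modulation proportional to the running integral of `AM^2`, scaled so the
#' total excursion equals `sweep_bandwidth`. `beta` is fixed by the edge
#' truncation level, `sech(beta) = truncation`.
#'
#' The phase is accumulated by trapezoidal integration of the instantaneous
#' frequency; no closed form exists for the HS8 frequency modulation.
#'
#' @inheritParams make_chirp
#' @param truncation envelope magnitude at the pulse edges, in (0, 1)
#' @export
make_hs8 <- function(duration, sweep_bandwidth, amplitude = 1, dt = NULL,
                     truncation = 0.01, center_offset = 0) {
  if (duration <= 0 || sweep_bandwidth <= 0)
    stop("make_hs8: duration and sweep_bandwidth must be positive")
  if (truncation <= 0 || truncation >= 1)
    stop("make_hs8: truncation must lie in (0, 1)")
  if (is.null(dt)) dt <- 1 / (8 * sweep_bandwidth)
  n <- round(duration / dt)
  duration <- n * dt                     # snap to the sample grid
  t <- pulse_times(n, dt)
  tau <- seq(-1, 1, length.out = n)      # symmetric grid: AM(-1) = AM(1)
  beta <- acosh(1 / truncation)              # sech(beta) = truncation
  am <- 1 / cosh(beta * tau^8)
  # FM ~ cumulative integral of AM^2, centred and scaled to the full sweep
  am2 <- am^2
  cint <- c(0, cumsum((am2[-1] + am2[-n]) / 2)) * dt
  fm <- cint - cint[n] / 2                   # antisymmetric about mid-pulse
  freq <- center_offset + sweep_bandwidth * fm / (cint[n])
  phase <- 2 * pi * c(0, cumsum((freq[-1] + freq[-n]) / 2)) * dt
  new_pulse(amplitude * am * exp(1i * phase), dt, sweep_bandwidth, "hs8",
            center_offset, amplitude)
}

#' Instantaneous frequency of a pulse
#'
#' Finite-difference derivative of the unwrapped sample phase divided by
#' `2 pi dt`; returns one fewer value than there are samples.
#'
#' @param pulse a [new_pulse()] object
#' @return numeric vector of length `n - 1` (Hz)
#' @export
instantaneous_frequency <- function(pulse) {
  n <- length(pulse$samples)
  if (n < 2) stop("instantaneous_frequency: pulse must have >= 2 samples")
  ph <- Arg(pulse$samples)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi         # unwrap increments into (-pi, pi]
  dph / (2 * pi * pulse$dt)
}

#' Serialize / deserialize a pulse definition
#'
#' Structured-config representation used by the YAML experiment files.
#'
#' @param pulse a pulse object
#' @return a plain named list (`pulse_to_config`) or a pulse
#'   (`pulse_from_config`)
#' @export
pulse_to_config <- function(pulse) {
  cfg <- list(kind = pulse$kind, duration_s = pulse$duration,
              bandwidth_hz = pulse$sweep_bandwidth,
              amplitude = pulse$amplitude, dt_s = pulse$dt)
  cfg
}

#' @rdname pulse_to_config
#' @param cfg named list with fields `kind`, `duration_s`, `bandwidth_hz`,
#'   `amplitude`, `dt_s`, and optionally `smooth_fraction` / `truncation`
#' @export
pulse_from_config <- function(cfg) {
  switch(cfg$kind,
    rect = make_rect(cfg$duration_s, cfg$amplitude, cfg$dt_s),
    chirp = make_chirp(cfg$duration_s, cfg$bandwidth_hz, cfg$amplitude,
                       cfg$dt_s, cfg$smooth_fraction %||% 0.1),
    hs8 = make_hs8(cfg$duration_s, cfg$bandwidth_hz, cfg$amplitude,
                   cfg$dt_s, cfg$truncation %||% 0.01),
    stop("pulse_from_config: unknown pulse kind '", cfg$kind, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
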