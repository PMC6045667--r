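# Analog cancellation chain: directional coupler, voltage-controlled phase
# shifter and attenuator, Tx->Rx coupling channel, pick-up coil, and the
# power-combiner subtraction
#   s(t) = s_Rx(t) - A u_Tx(t) e^{j phi},  s_Rx = A_cpl u_Tx e^{j phi_cpl} + s_MR.
# Everything is linear in the transmit waveform; traces carry complex
# voltage-like samples at a common dt.

#' Signal trace
#'
#' A complex sample sequence with its sampling interval; the common currency
#' of the analog chain.
#'
#' @param samples complex vector (a.u. volts)
#' @param dt sample interval (s)
#' @export
signal_trace <- function(samples, dt) {
  samples <- as.complex(samples)
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop("signal_trace: samples must be finite")
  structure(list(samples = samples, dt = dt), class = "cea_trace")
}

as_trace <- function(x, dt = NULL) {
  if (inherits(x, "cea_trace")) return(x)
  if (inherits(x, "cea_pulse")) return(signal_trace(x$samples, x$dt))
  signal_trace(x, dt)
}

#' @export
print.cea_trace <- function(x, ...) {
  cat(sprintf("<cea_trace: %d samples, dt = %.3g us, rms = %.3g>\n",
              length(x$samples), x$dt * 1e6, sqrt(mean(Mod(x$samples)^2))))
  invisible(x)
}

#' Directional coupler
#'
#' Lossless two-way split with amplitude coupling factor `c` (default 0.28):
#' the tapped copy is `c u_Tx`, the main line `sqrt(1 - c^2) u_Tx`.
#'
#' @param coupling_factor amplitude ratio in (0, 1)
#' @export
directional_coupler <- function(coupling_factor = 0.28) {
  if (coupling_factor <= 0 || coupling_factor >= 1)
    stop("directional_coupler: coupling_factor must be in (0, 1)")
  structure(list(coupling_factor = coupling_factor), class = "cea_coupler")
}

#' Split the transmit signal at the directional coupler
#'
#' @param u_tx transmit [signal_trace()] (or pulse)
#' @param coupler a [directional_coupler()]
#' @return list with elements `main` and `copy`, both traces
#' @export
coupler_split <- function(u_tx, coupler = directional_coupler()) {
  u_tx <- as_trace(u_tx)
  c <- coupler$coupling_factor
  list(main = signal_trace(sqrt(1 - c^2) * u_tx$samples, u_tx$dt),
       copy = signal_trace(c * u_tx$samples, u_tx$dt))
}

#' Voltage-controlled phase shifter model
#'
#' Monotone saturating voltage-to-phase map anchored to 280 degrees of
#' coverage between 0 and 12 V:
#' `phi(V) = 280 * atan(V / v0) / atan(12 / v0)` with `v0 = 4` V, so the
#' slope decreases with voltage (varactor-style saturation). A fixed
#' insertion loss (default 0.8 dB) applies to the through path.
#'
#' @param v0 curvature voltage of the arctangent map (V)
#' @param coverage_deg phase span between 0 and 12 V (degrees)
#' @param insertion_loss_db through-path loss (dB)
#' @export
phase_shifter <- function(v0 = 4, coverage_deg = 280, insertion_loss_db = 0.8) {
  structure(list(v_min = 0, v_max = 25, v0 = v0, coverage_deg = coverage_deg,
                 v_anchor = 12, insertion_loss_db = insertion_loss_db),
            class = "cea_phase_shifter")
}

#' Phase response of the shifter at a control voltage
#'
#' @param shifter a [phase_shifter()]
#' @param v1 control voltage (V); values outside `[v_min, v_max]` are clamped
#'   with a warning
#' @return applied phase (degrees), with `phase_response(shifter, 0) == 0`
#' @export
phase_response <- function(shifter, v1) {
  if (any(v1 < shifter$v_min) || any(v1 > shifter$v_max)) {
    warning("phase_response: control voltage clamped to [",
            shifter$v_min, ", ", shifter$v_max, "] V")
    v1 <- pmin(pmax(v1, shifter$v_min), shifter$v_max)
  }
  shifter$coverage_deg * atan(v1 / shifter$v0) /
    atan(shifter$v_anchor / shifter$v0)
}

#' Voltage-controlled attenuator model
#'
#' Piecewise map anchored at the printed transfer-curve values: 1.3 dB
#' minimum attenuation at 6.0 V, linear at `slope_db_per_v` (default
#' 1.2 dB/V) down to 3.0 V, and a quadratic continuation below 3.0 V matched
#' in value and slope that reaches `max_att_db` (default 30 dB) at 0 V.
#'
#' @param min_att_db attenuation at 6.0 V (dB)
#' @param slope_db_per_v linear slope magnitude on 3-6 V (dB/V)
#' @param max_att_db attenuation at 0 V (dB)
#' @export
attenuator <- function(min_att_db = 1.3, slope_db_per_v = 1.2,
                       max_att_db = 30) {
  v_knee <- 3
  a_knee <- min_att_db + slope_db_per_v * (6 - v_knee)
  # quadratic constraints: value max_att_db at 0 V, value a_knee and slope
  # -slope_db_per_v at the knee
  cc <- max_att_db
  a <- (a_knee - cc + slope_db_per_v * v_knee) / (-v_knee^2)
  b <- -slope_db_per_v - 2 * a * v_knee
  structure(list(v_min = 0, v_max = 6, min_att_db = min_att_db,
                 slope_db_per_v = slope_db_per_v, max_att_db = max_att_db,
                 v_knee = v_knee, quad = c(a = a, b = b, c = cc)),
            class = "cea_attenuator")
}

#' Attenuation response at a control voltage
#'
#' @param att an [attenuator()]
#' @param v_att control voltage (V); out-of-range values are clamped with a
#'   warning
#' @return attenuation (dB, positive)
#' @export
attenuation_response <- function(att, v_att) {
  if (any(v_att < att$v_min) || any(v_att > att$v_max)) {
    warning("attenuation_response: control voltage clamped to [",
            att$v_min, ", ", att$v_max, "] V")
    v_att <- pmin(pmax(v_att, att$v_min), att$v_max)
  }
  q <- att$quad
  ifelse(v_att >= att$v_knee,
         att$min_att_db + att$slope_db_per_v * (6 - v_att),
         q["a"] * v_att^2 + q["b"] * v_att + q["c"])
}

#' Canceller control setting
#'
#' @param v1 phase-control voltage (V)
#' @param v_att attenuation-control voltage (V)
#' @export
canceller_setting <- function(v1, v_att) {
  structure(list(v1 = v1, v_att = v_att), class = "cea_setting")
}

#' Tx-to-Rx coupling channel
#'
#' The leakage path from the transmit coil into the receive coil. The total
#' leakage amplitude is `10^(-geometric_isolation_db/20) * a_cpl`; phase
#' `phi_cpl` in degrees. An optional linear off-resonance variation
#' `freq_slope = c(db_per_khz, deg_per_khz)` modulates the leakage per
#' instantaneous-frequency bin.
#'
#' @param a_cpl coupling amplitude ratio (> 0)
#' @param phi_cpl_deg coupling phase (degrees)
#' @param geometric_isolation_db passive isolation from coil orthogonality (dB)
#' @param freq_slope optional `c(db_per_khz, deg_per_khz)`
#' @export
coupling_channel <- function(a_cpl = 1, phi_cpl_deg = 0,
                             geometric_isolation_db = 30, freq_slope = NULL) {
  if (a_cpl <= 0) stop("coupling_channel: a_cpl must be positive")
  structure(list(a_cpl = a_cpl, phi_cpl_deg = phi_cpl_deg,
                 geometric_isolation_db = geometric_isolation_db,
                 freq_slope = freq_slope),
            class = "cea_channel")
}

#' Pick-up coil
#'
#' Small auxiliary coil monitoring the transmitted waveform: a fixed
#' amplitude/phase coupling to the Tx line.
#'
#' @param amplitude coupling amplitude (> 0)
#' @param phase_deg coupling phase (degrees)
#' @export
pickup_coil <- function(amplitude = 0.05, phase_deg = 0) {
  if (amplitude <= 0) stop("pickup_coil: amplitude must be positive")
  structure(list(amplitude = amplitude, phase_deg = phase_deg),
            class = "cea_puc")
}

deg2rad <- function(x) x * pi / 180

#' Apply the canceller (phase shifter + attenuator) to the coupled copy
#'
#' Produces the cancellation reference `A u_Tx e^{j phi}`: the copy scaled by
#' the attenuation plus the shifter insertion loss and rotated by the shifter
#' phase.
#'
#' @param copy tapped transmit copy ([signal_trace()])
#' @param setting a [canceller_setting()]
#' @param shifter a [phase_shifter()]
#' @param att an [attenuator()]
#' @export
apply_canceller <- function(copy, setting, shifter = phase_shifter(),
                            att = attenuator()) {
  g <- canceller_gain(setting, shifter, att)
  signal_trace(g * copy$samples, copy$dt)
}

# complex gain of the canceller path (excluding the coupler tap)
canceller_gain <- function(setting, shifter, att) {
  loss_db <- attenuation_response(att, setting$v_att) + shifter$insertion_loss_db
  10^(-loss_db / 20) * exp(1i * deg2rad(phase_response(shifter, setting$v1)))
}

#' Leakage of the transmit signal into the receive coil
#'
#' `leakage = 10^(-geometric_isolation_db/20) * a_cpl * e^{j phi_cpl} * u_Tx`.
#' With `freq_slope` set, an additional gain linear (in dB and degrees) in
#' the pulse's instantaneous frequency is applied sample-wise.
#'
#' @param u_tx_main main-line transmit trace
#' @param channel a [coupling_channel()]
#' @param pulse optional pulse object, needed only when `freq_slope` is set
#' @export
leak_signal <- function(u_tx_main, channel, pulse = NULL) {
  u_tx_main <- as_trace(u_tx_main)
  amp <- 10^(-channel$geometric_isolation_db / 20) * channel$a_cpl
  g <- amp * exp(1i * deg2rad(channel$phi_cpl_deg))
  s <- g * u_tx_main$samples
  if (!is.null(channel$freq_slope)) {
    if (is.null(pulse))
      stop("leak_signal: pulse required when the channel has a freq_slope")
    f <- c(0, instantaneous_frequency(pulse)) / 1e3    # kHz per sample
    extra <- 10^(channel$freq_slope[1] * f / 20) *
      exp(1i * deg2rad(channel$freq_slope[2] * f))
    s <- s * extra
  }
  signal_trace(s, u_tx_main$dt)
}

#' Power-combiner subtraction
#'
#' Sample-wise difference `s = s_Rx - cancel_ref`.
#'
#' @param s_rx received trace
#' @param cancel_ref cancellation reference trace
#' @export
combine_traces <- function(s_rx, cancel_ref) {
  if (length(s_rx$samples) != length(cancel_ref$samples) ||
      !isTRUE(all.equal(s_rx$dt, cancel_ref$dt)))
    stop("combine_traces: traces must share length and dt")
  signal_trace(s_rx$samples - cancel_ref$samples, s_rx$dt)
}

#' Pick-up coil monitor trace
#'
#' Scaled/rotated copy of the transmit waveform, optionally with complex
#' white receiver noise.
#'
#' @param u_tx transmit trace
#' @param puc a [pickup_coil()]
#' @param noise_sd per-sample complex noise standard deviation (a.u.)
#' @export
pickup_trace <- function(u_tx, puc = pickup_coil(), noise_sd = 0) {
  u_tx <- as_trace(u_tx)
  s <- puc$amplitude * exp(1i * deg2rad(puc$phase_deg)) * u_tx$samples
  if (noise_sd > 0) {
    n <- length(s)
    s <- s + complex(real = stats::rnorm(n, 0, noise_sd / sqrt(2)),
                     imaginary = stats::rnorm(n, 0, noise_sd / sqrt(2)))
  }
  signal_trace(s, u_tx$dt)
}

#' Isolation between a leakage trace and a residual
#'
#' `10 log10(sum |leak|^2 / sum |residual|^2)`, capped at `cap_db` for an
#' exactly zero residual.
#'
#' @param leak uncancelled leakage trace
#' @param residual post-cancellation residual trace
#' @param cap_db ceiling reported for a zero residual (dB)
#' @return isolation (dB)
#' @export
isolation_db <- function(leak, residual, cap_db = 200) {
  pl <- sum(Mod(leak$samples)^2)
  if (length(leak$samples) == 0 || pl == 0)
    stop("isolation_db: leak trace must have nonzero power")
  pr <- sum(Mod(residual$samples)^2)
  if (pr == 0) return(cap_db)
  min(10 * log10(pl / pr), cap_db)
}
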