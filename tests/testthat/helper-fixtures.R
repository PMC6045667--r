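# Shared builders for the test suite. All fixtures are generated in code.

default_frontend <- function() frontend()

# voltages at which the canceller exactly matches a given channel
optimal_setting <- function(fe, ch) {
  v1 <- stats::uniroot(function(v) phase_response(fe$shifter, v) -
                         ch$phi_cpl_deg, c(0, 25), tol = 1e-12)$root
  c <- fe$coupler$coupling_factor
  target_db <- 20 * log10(c / (sqrt(1 - c^2) *
                                 10^(-ch$geometric_isolation_db / 20) *
                                 ch$a_cpl)) - fe$shifter$insertion_loss_db
  v_att <- stats::uniroot(function(v) attenuation_response(fe$att, v) -
                            target_db, c(0, 6), tol = 1e-12)$root
  canceller_setting(v1, v_att)
}

# random coupling channel at the study conditions: 30 dB geometric
# baseline, coupling phase uniform inside the shifter coverage, amplitude
# within +-3 dB of unity
random_channel <- function() {
  coupling_channel(a_cpl = 10^(stats::runif(1, -0.15, 0.15)),
                   phi_cpl_deg = stats::runif(1, 1, 279),
                   geometric_isolation_db = 30)
}

# starting voltages within +-1.5 V of the optimum, clamped to range
initial_near_optimum <- function(fe, ch, spread = 1.5) {
  opt <- optimal_setting(fe, ch)
  canceller_setting(
    min(max(opt$v1 + stats::runif(1, -spread, spread), 0), 12),
    min(max(opt$v_att + stats::runif(1, -spread, spread), 0), 6))
}

run_calibration_ensemble <- function(n_trials, threshold_db, seed,
                                     max_iter = 300) {
  set.seed(seed)
  fe <- default_frontend()
  out <- data.frame(iterations = integer(n_trials),
                    total_db = numeric(n_trials),
                    analog_db = numeric(n_trials),
                    converged = logical(n_trials))
  for (i in seq_len(n_trials)) {
    ch <- random_channel()
    init <- initial_near_optimum(fe, ch)
    r <- calibrate_canceller(
      fe, ch, cfg = controller_config(threshold_isolation_db = threshold_db,
                                      max_iter = max_iter),
      initial = init)
    out$iterations[i] <- r$iterations
    out$total_db[i] <- r$achieved_isolation_db
    out$analog_db[i] <- r$analog_suppression_db
    out$converged[i] <- r$converged
  }
  out
}

rel_rms <- function(x, ref) sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))

# synthetic chirp-leakage trace of exactly the fitted model form
model_form_leak <- function(pulse, puc, scale = 0.02,
                            slope_l = 3e-7, slope_r = -2e-7,
                            phase_poly = c(0.3, 120, -3e4)) {
  n <- length(pulse$samples)
  t <- (seq_len(n) - 1) * pulse$dt
  f <- pulse$sweep_bandwidth * (t / pulse$duration - 0.5)
  amp <- ifelse(f < 0, scale + slope_l * f, scale + slope_r * f)
  puc_unit <- puc$samples / max(Mod(puc$samples))
  qph <- phase_poly[1] + phase_poly[2] * t + phase_poly[3] * t^2
  signal_trace(amp * puc_unit * exp(1i * qph), pulse$dt)
}
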