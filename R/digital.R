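# Digital removal of the residual, frequency-dependent transmit leakage left
# after analog cancellation. Chirp acquisitions use the pick-up coil (PUC)
# monitor: the residual amplitude is modeled piecewise-linearly on each side
# of the sweep centre frequency and the PUC phase is corrected by a quadratic
# polynomial. HS8 acquisitions use a parametric modulation model fitted by
# simulated annealing.

# centred moving average; the window is truncated symmetrically at the ends
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- floor(w / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- (dp + pi) %% (2 * pi) - pi
  c(p[1], p[1] + cumsum(dp))
}

#' Fit and subtract residual chirp leakage using the PUC monitor
#'
#' Model: the residual leakage is the PUC trace, normalized to unit peak and
#' phase-corrected by a quadratic polynomial in time, scaled by a complex
#' amplitude profile linear in instantaneous frequency on each side of the
#' sweep centre (shared complex value at the centre). Complex side
#' coefficients are essential: after analog cancellation at the centre
#' frequency the physical residual crosses zero there and re-emerges with
#' opposite sign, which a non-negative magnitude profile cannot represent.
#' The time-to-frequency map is the pulse's analytic sweep rate. Samples
#' where the pulse envelope is below 10% of peak are excluded from the
#' fits, and the phase fit smooths the phase difference over
#' `smooth_window` samples to avoid chasing MR-signal ripple.
#'
#' @param s measured trace (residual leakage + MR signal)
#' @param puc pick-up coil trace
#' @param pulse the chirp pulse that was transmitted
#' @param smooth_window moving-average window (samples) for the phase fit
#' @param n_iter phase/amplitude refinement passes
#' @return list with `fit` (class `cea_chirp_leak_fit`: complex `scale`,
#'   `amp_left`, `amp_right` slopes, `phase_poly` quadratic coefficients,
#'   `leak_est` trace) and `s_mr_est` (corrected trace)
#' @export
fit_chirp_leakage <- function(s, puc, pulse, smooth_window = 32,
                              n_iter = 2) {
  if (length(s$samples) != length(puc$samples))
    stop("fit_chirp_leakage: s and puc must be aligned and equal length")
  if (!pulse$kind %in% "chirp")
    stop("fit_chirp_leakage: pulse must be a chirp (use the HS8 path or ",
         "PUC-scale subtraction otherwise)")
  n <- length(s$samples)
  t <- (seq_len(n) - 1) * pulse$dt
  # analytic instantaneous frequency of the linear sweep
  f <- pulse$center_offset +
    pulse$sweep_bandwidth * (t / pulse$duration - 0.5)
  fc <- f - pulse$center_offset
  env <- Mod(pulse$samples[seq_len(n)])
  keep <- env >= 0.1 * max(env)

  puc_unit <- puc$samples / max(Mod(puc$samples))
  fl <- fc < 0
  X <- cbind(1, t, t^2)

  # one fit: alternate a complex per-side linear solve with a quadratic
  # refinement of the phase polynomial against the current model
  run_fit <- function(phase_poly) {
    co <- NULL; leak_est <- NULL
    for (it in seq_len(max(n_iter, 1))) {
      ref <- puc_unit * exp(1i * as.vector(X %*% phase_poly))
      B <- cbind(ref, ref * fc * fl, ref * fc * (1 - fl))
      co <- unname(qr.solve(B[keep, , drop = FALSE], s$samples[keep]))
      leak_est <- as.vector(B %*% co)
      if (it == max(n_iter, 1)) break
      dres <- unwrap_phase(Arg(s$samples) - Arg(leak_est))
      upd <- stats::lm.wfit(X, moving_average(dres, smooth_window),
                            w = Mod(leak_est) * keep)$coefficients
      phase_poly <- phase_poly + upd
    }
    list(co = co, phase_poly = phase_poly, leak_est = leak_est,
         rss = sum(Mod(s$samples[keep] - leak_est[keep])^2))
  }

  # two initializations: the smoothed phase difference against the PUC
  # (captures large quadratic drifts), and zero (robust when the residual
  # flips sign at the centre frequency and the raw difference is bimodal)
  dphi <- unwrap_phase(Arg(s$samples) - Arg(puc$samples))
  dphi_s <- moving_average(dphi, smooth_window)
  pw <- Mod(s$samples) * keep
  init_a <- stats::lm.wfit(X, dphi_s, w = pw)$coefficients
  fit_a <- run_fit(init_a)
  fit_b <- run_fit(c(0, 0, 0))
  best <- if (fit_a$rss <= fit_b$rss) fit_a else fit_b

  fit <- structure(
    list(scale = best$co[1], amp_left = best$co[2], amp_right = best$co[3],
         phase_poly = unname(best$phase_poly),
         leak_est = signal_trace(best$leak_est, s$dt)),
    class = "cea_chirp_leak_fit")
  list(fit = fit, s_mr_est = signal_trace(s$samples - best$leak_est, s$dt))
}

#' Fit and subtract residual HS8 leakage by simulated annealing
#'
#' Leakage model: the theoretical pulse waveform multiplied by a
#' superposition of modulations quadratic and linear in time plus a
#' constant, and a phase constant:
#' `lambda(t) = u_Tx(t) (a2 t^2 + a1 t + a0) e^{i theta0}` with complex
#' `a2, a1, a0` (seconds-based units) and `theta0` in `[-pi, pi)`. Simulated
#' annealing (geometric cooling, Gaussian proposals) minimizes the residual
#' power `sum |s - lambda|^2`; the annealed solution is then polished by an
#' exact linear least-squares solve of the (linear-in-coefficients)
#' modulation at the annealed phase constant. Seeded and reproducible.
#'
#' @param s measured trace
#' @param pulse the HS8 pulse that was transmitted
#' @param sa_cfg list: `n_eval` annealing evaluations, `t0` initial
#'   temperature (fraction of initial objective), `cooling` geometric factor,
#'   `prop_scale` proposal scale (fraction of parameter bounds)
#' @param seed integer seed (mandatory for reproducibility)
#' @return list with `fit` (class `cea_hs8_leak_fit`: `a2`, `a1`, `a0`,
#'   `theta0`, `residual_power`, `improved`, `leak_est`) and `s_mr_est`
#' @export
fit_hs8_leakage <- function(s, pulse,
                            sa_cfg = list(n_eval = 2000, t0 = 0.1,
                                          cooling = 0.95, prop_scale = 0.1),
                            seed = 1) {
  if (pulse$kind != "hs8")
    stop("fit_hs8_leakage: pulse must be an HS8 pulse")
  set.seed(seed)
  n <- length(s$samples)
  t <- (seq_len(n) - 1) * pulse$dt
  u <- pulse$samples[seq_len(n)]
  tn <- t / max(t)                          # normalized time for conditioning
  B <- cbind(u * tn^2, u * tn, u)           # model basis (complex n x 3)
  y <- s$samples

  obj <- function(p) {
    a <- complex(real = p[c(1, 3, 5)], imaginary = p[c(2, 4, 6)])
    lam <- as.vector(B %*% a) * exp(1i * p[7])
    sum(Mod(y - lam)^2)
  }

  # bounds from the data scale: modulation coefficients of order |y|/|u|
  scale0 <- max(Mod(y)) / max(Mod(u))
  bounds <- c(rep(scale0 * 4, 6), pi)
  p <- rep(0, 7)
  f <- obj(p)
  f_init <- f
  best_p <- p; best_f <- f
  sa_trace <- numeric(sa_cfg$n_eval)
  temp <- sa_cfg$t0 * max(f, .Machine$double.eps)
  for (it in seq_len(sa_cfg$n_eval)) {
    prop <- p + stats::rnorm(7, 0, sa_cfg$prop_scale * bounds)
    prop[7] <- ((prop[7] + pi) %% (2 * pi)) - pi
    fp <- obj(prop)
    if (fp < f || stats::runif(1) < exp((f - fp) / temp)) {
      p <- prop; f <- fp
      if (f < best_f) { best_f <- f; best_p <- p }
    }
    sa_trace[it] <- best_f
    temp <- temp * sa_cfg$cooling
  }
  improved <- best_f < f_init

  # exact least-squares polish at the annealed phase constant (the model is
  # linear in the complex coefficients)
  th <- best_p[7]
  Bp <- B * exp(1i * th)
  a_ls <- qr.solve(Bp, y)
  lam <- as.vector(Bp %*% a_ls)
  res_p <- sum(Mod(y - lam)^2)
  if (res_p > best_f) {                     # keep whichever is better
    a_ls <- complex(real = best_p[c(1, 3, 5)],
                    imaginary = best_p[c(2, 4, 6)])
    lam <- as.vector(B %*% a_ls) * exp(1i * th)
    res_p <- best_f
  }
  tmax <- max(t)
  fit <- structure(
    list(a2 = a_ls[1] / tmax^2, a1 = a_ls[2] / tmax, a0 = a_ls[3],
         theta0 = th, residual_power = res_p, improved = improved,
         sa_trace = sa_trace, leak_est = signal_trace(lam, s$dt)),
    class = "cea_hs8_leak_fit")
  if (!improved && res_p >= f_init)
    warning("fit_hs8_leakage: annealing budget exhausted without improvement;",
            " returning best-so-far")
  list(fit = fit, s_mr_est = signal_trace(s$samples - lam, s$dt))
}

#' Relative RMS deviation from a reference trace
#'
#' `||x - ref|| / ||ref||` over the samples. Used in tests to compare a
#' corrected signal with a Bloch-computed reference; it plays no part in the
#' correction itself.
#'
#' @param s_mr_est corrected trace
#' @param reference reference trace
#' @export
refine_against_model <- function(s_mr_est, reference) {
  if (length(s_mr_est$samples) != length(reference$samples))
    stop("refine_against_model: traces must have equal length")
  pr <- sum(Mod(reference$samples)^2)
  if (pr == 0) stop("refine_against_model: reference has zero power")
  sqrt(sum(Mod(s_mr_est$samples - reference$samples)^2) / pr)
}
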