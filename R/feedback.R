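# Automated real-time feedback calibration of the analog canceller:
# coordinate descent on (V1, V_att) minimizing the mean received magnitude
# during a rectangular calibration acquisition, with a coarse-to-fine step
# schedule (phase 0.3 -> 0.1 V, attenuator 0.05 -> 0.005 V), optional
# alternating refinement passes with halved steps, threshold stopping, and
# re-triggering on load changes. One "iteration" is one objective evaluation,
# i.e. one simulated calibration acquisition.

#' Front-end bundle
#'
#' Convenience container tying together the coupler, phase shifter,
#' attenuator and pick-up coil models used by the simulator.
#'
#' @param coupler a [directional_coupler()]
#' @param shifter a [phase_shifter()]
#' @param att an [attenuator()]
#' @param puc a [pickup_coil()]
#' @export
frontend <- function(coupler = directional_coupler(),
                     shifter = phase_shifter(), att = attenuator(),
                     puc = pickup_coil()) {
  structure(list(coupler = coupler, shifter = shifter, att = att, puc = puc),
            class = "cea_frontend")
}

#' Feedback controller configuration
#'
#' @param phase_steps coarse-to-fine phase voltage steps (V)
#' @param att_steps coarse-to-fine attenuator voltage steps (V)
#' @param refine_floor smallest voltage step used by the optional alternating
#'   refinement passes, applied to both actuators (V)
#' @param threshold_isolation_db stopping threshold on the total isolation
#'   (geometric baseline plus analog cancellation, dB)
#' @param max_iter maximum number of objective evaluations
#' @param n_samples averaging length N of the objective
#' @export
controller_config <- function(phase_steps = c(0.3, 0.1),
                              att_steps = c(0.05, 0.005),
                              refine_floor = 5e-4,
                              threshold_isolation_db = 89,
                              max_iter = 200, n_samples = 400) {
  if (any(diff(phase_steps) >= 0) || any(diff(att_steps) >= 0))
    stop("controller_config: step schedules must be strictly decreasing")
  if (max_iter < 1) stop("controller_config: max_iter must be >= 1")
  structure(list(phase_steps = phase_steps, att_steps = att_steps,
                 refine_floor = refine_floor,
                 threshold_isolation_db = threshold_isolation_db,
                 max_iter = max_iter, n_samples = n_samples),
            class = "cea_controller_config")
}

#' Mean-magnitude objective of the feedback loop
#'
#' Mean of `|s_Rx|` over the first `n` samples — the quantity the controller
#' minimizes. The magnitude is taken sample-wise; a complex mean could cancel
#' to zero spuriously.
#'
#' @param s_rx received trace
#' @param n averaging length
#' @export
leakage_objective <- function(s_rx, n) {
  if (n <= 0) stop("leakage_objective: n must be positive")
  if (length(s_rx$samples) < n)
    stop("leakage_objective: trace shorter than n")
  mean(Mod(s_rx$samples[seq_len(n)]))
}

# closed-form ingredients of one calibration acquisition with a rect pulse:
# residual(setting) = (L - c * g(setting)) * u_main, with
#   L = 10^(-geom/20) a_cpl e^{j phi_cpl} * sqrt(1-c^2)  (relative to u_Tx)
# Evaluating the objective only needs |L - c g| times the mean |u_main|.
cal_context <- function(fe, channel, pulse, n_samples) {
  sp <- coupler_split(pulse, fe$coupler)
  n <- min(n_samples, length(sp$main$samples))
  mean_main <- mean(Mod(sp$main$samples[seq_len(n)]))
  leak_gain <- 10^(-channel$geometric_isolation_db / 20) * channel$a_cpl *
    exp(1i * deg2rad(channel$phi_cpl_deg))
  list(fe = fe, channel = channel, pulse = pulse, split = sp, n = n,
       mean_main = mean_main, leak_gain = leak_gain,
       # objective of the raw coupled signal with no geometric isolation:
       # reference amplitude for total-isolation thresholds
       obj_uncancelled_total = channel$a_cpl * mean_main,
       tap = fe$coupler$coupling_factor)
}

# objective at a setting: simulate the calibration acquisition through the
# front-end ops (kept op-level so the simulated chain, not a formula, is what
# the controller observes)
cal_objective <- function(ctx, v1, v_att) {
  setting <- canceller_setting(v1, v_att)
  leak <- leak_signal(ctx$split$main, ctx$channel, ctx$pulse)
  cref <- apply_canceller(ctx$split$copy, setting, ctx$fe$shifter, ctx$fe$att)
  s <- combine_traces(leak, cref)
  leakage_objective(s, ctx$n)
}

#' Calibrate the canceller by coordinate descent
#'
#' Runs the automated feedback schedule against a simulated calibration
#' acquisition (rectangular pulse): a phase pass at 0.3 V then 0.1 V steps,
#' an attenuator pass at 0.05 V then 5 mV steps, then — if the threshold is
#' not yet met — alternating phase/attenuation passes with step sizes halved
#' down to `refine_floor`. Each step direction is found by probing plus/minus
#' one step and moving while the objective decreases. Stops as soon as the
#' objective drops below the amplitude corresponding to
#' `threshold_isolation_db`, or when `max_iter` evaluations are spent.
#'
#' @param fe a [frontend()]
#' @param channel the [coupling_channel()] to cancel
#' @param pulse calibration pulse (default 4 ms rectangular)
#' @param cfg a [controller_config()]
#' @param initial starting [canceller_setting()]
#' @return a `cea_calibration` list: `setting`, `iterations`, `objective`,
#'   `achieved_isolation_db` (total), `analog_suppression_db`, `converged`,
#'   and a per-evaluation `trace` data frame
#' @export
calibrate_canceller <- function(fe, channel, pulse = make_rect(4e-3, 1, 10e-6),
                                cfg = controller_config(),
                                initial = canceller_setting(6, 3)) {
  ctx <- cal_context(fe, channel, pulse, cfg$n_samples)
  obj_thresh <- ctx$obj_uncancelled_total *
    10^(-cfg$threshold_isolation_db / 20)

  st <- new.env(parent = emptyenv())
  st$n_eval <- 0L
  st$trace <- vector("list", cfg$max_iter)
  st$best <- Inf
  st$best_v <- c(initial$v1, initial$v_att)
  st$stop <- FALSE

  evaluate <- function(v) {
    if (st$n_eval >= cfg$max_iter) { st$stop <- TRUE; return(NA_real_) }
    o <- cal_objective(ctx, v[1], v[2])
    st$n_eval <- st$n_eval + 1L
    st$trace[[st$n_eval]] <- c(iter = st$n_eval, v1 = v[1], v_att = v[2],
                               objective = o)
    if (o < st$best) { st$best <- o; st$best_v <- v }
    if (o <= obj_thresh) st$stop <- TRUE
    o
  }

  ranges <- rbind(c(fe$shifter$v_min, fe$shifter$v_max),
                  c(fe$att$v_min, fe$att$v_max))
  clamp <- function(v) pmin(pmax(v, ranges[, 1]), ranges[, 2])

  # one descent pass along coordinate `dim` with step `step`;
  # `f0` is the cached objective at `v` (or NA to force evaluation)
  descend <- function(v, f0, dim, step) {
    if (is.na(f0)) f0 <- evaluate(v)
    if (st$stop) return(list(v = st$best_v, f = st$best))
    dirs <- c(1, -1)
    for (d in dirs) {
      vt <- v; vt[dim] <- vt[dim] + d * step; vt <- clamp(vt)
      if (vt[dim] == v[dim]) next
      ft <- evaluate(vt)
      if (st$stop) return(list(v = st$best_v, f = st$best))
      if (ft < f0) {
        # walk in this direction while improving
        repeat {
          v <- vt; f0 <- ft
          vt <- v; vt[dim] <- vt[dim] + d * step; vt <- clamp(vt)
          if (vt[dim] == v[dim]) break
          ft <- evaluate(vt)
          if (st$stop) return(list(v = st$best_v, f = st$best))
          if (ft >= f0) break
        }
        return(list(v = v, f = f0))
      }
    }
    list(v = v, f = f0)
  }

  v <- clamp(c(initial$v1, initial$v_att))
  f <- NA_real_

  # printed schedule: phase coarse/fine, then attenuator coarse/fine
  for (s in cfg$phase_steps) {
    r <- descend(v, f, 1, s); v <- r$v; f <- r$f
    if (st$stop) break
  }
  if (!st$stop) for (s in cfg$att_steps) {
    r <- descend(v, f, 2, s); v <- r$v; f <- r$f
    if (st$stop) break
  }

  # alternating refinement passes with halved steps down to the floor
  if (!st$stop) {
    ps <- utils::tail(cfg$phase_steps, 1)
    as <- utils::tail(cfg$att_steps, 1)
    while (!st$stop && (ps > cfg$refine_floor || as > cfg$refine_floor)) {
      ps <- max(ps / 2, cfg$refine_floor)
      as <- max(as / 2, cfg$refine_floor)
      r <- descend(v, f, 1, ps); v <- r$v; f <- r$f
      if (st$stop) break
      r <- descend(v, f, 2, as); v <- r$v; f <- r$f
    }
  }

  final_v <- st$best_v
  setting <- canceller_setting(final_v[1], final_v[2])
  # measure achieved isolation with the front-end ops
  leak <- leak_signal(ctx$split$main, channel, pulse)
  cref <- apply_canceller(ctx$split$copy, setting, fe$shifter, fe$att)
  resid <- combine_traces(leak, cref)
  analog_db <- isolation_db(leak, resid)
  total_db <- analog_db + channel$geometric_isolation_db
  tr <- do.call(rbind, st$trace[seq_len(st$n_eval)])
  structure(list(setting = setting, iterations = st$n_eval,
                 objective = st$best,
                 achieved_isolation_db = total_db,
                 analog_suppression_db = analog_db,
                 converged = st$best <= obj_thresh,
                 threshold_isolation_db = cfg$threshold_isolation_db,
                 trace = as.data.frame(tr)),
            class = "cea_calibration")
}

#' @export
print.cea_calibration <- function(x, ...) {
  cat(sprintf(paste0("<cea_calibration: %s in %d iterations, total isolation ",
                     "%.1f dB (analog %.1f dB), V1 = %.4f V, V_att = %.4f V>\n"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$achieved_isolation_db, x$analog_suppression_db,
              x$setting$v1, x$setting$v_att))
  invisible(x)
}

#' Monitor a coupling-channel timeline and re-trigger calibration
#'
#' Calibrates at the start of the timeline; after every channel change the
#' objective at the current setting is checked, and if it exceeds the
#' threshold amplitude a re-calibration is run from the current setting.
#'
#' @param fe a [frontend()]
#' @param channel_timeline list of [coupling_channel()] states in order
#' @param cfg a [controller_config()]
#' @param pulse calibration pulse
#' @param initial starting setting for the first calibration
#' @return list of `cea_calibration` results (one per triggered episode)
#' @export
monitor_and_retrigger <- function(fe, channel_timeline,
                                  cfg = controller_config(),
                                  pulse = make_rect(4e-3, 1, 10e-6),
                                  initial = canceller_setting(6, 3)) {
  if (length(channel_timeline) == 0)
    stop("monitor_and_retrigger: timeline must be nonempty")
  results <- list()
  res <- calibrate_canceller(fe, channel_timeline[[1]], pulse, cfg, initial)
  results[[1]] <- res
  setting <- res$setting
  for (ch in channel_timeline[-1]) {
    ctx <- cal_context(fe, ch, pulse, cfg$n_samples)
    obj_now <- cal_objective(ctx, setting$v1, setting$v_att)
    obj_thresh <- ctx$obj_uncancelled_total *
      10^(-cfg$threshold_isolation_db / 20)
    if (obj_now > obj_thresh) {
      res <- calibrate_canceller(fe, ch, pulse, cfg, setting)
      results[[length(results) + 1]] <- res
      setting <- res$setting
    }
  }
  results
}

#' Perturb the coupling channel to emulate a load change
#'
#' Random jump of `(a_cpl, phi_cpl)` such that, at the given canceller
#' setting, the feedback objective increases by `target_leak_increase`
#' (voltage units of the calibration fixture; the hand-motion scenario uses
#' jumps of 0.05 to 0.15). The jump direction in the complex leakage plane is
#' drawn uniformly; its magnitude is solved in closed form.
#'
#' @param channel the channel before the load change
#' @param target_leak_increase desired objective increase (a.u. volts)
#' @param fe a [frontend()]
#' @param setting current [canceller_setting()]
#' @param pulse calibration pulse
#' @param n_samples objective averaging length
#' @return the perturbed [coupling_channel()]
#' @export
perturb_load <- function(channel, target_leak_increase, fe = frontend(),
                         setting = canceller_setting(6, 3),
                         pulse = make_rect(4e-3, 1, 10e-6), n_samples = 400) {
  if (target_leak_increase < 0)
    stop("perturb_load: target must be non-negative")
  if (target_leak_increase == 0) return(channel)
  ctx <- cal_context(fe, channel, pulse, n_samples)
  # residual complex gain at the current setting, relative to u_main
  g_can <- ctx$tap / sqrt(1 - ctx$tap^2) *
    canceller_gain(setting, fe$shifter, fe$att)
  L <- ctx$leak_gain
  r0 <- L - g_can
  obj0 <- Mod(r0) * ctx$mean_main
  target_mod <- (obj0 + target_leak_increase) / ctx$mean_main
  psi <- stats::runif(1, 0, 2 * pi)
  u <- exp(1i * psi)
  # solve |r0 + rho u| = target_mod for rho > 0
  bq <- 2 * Re(Conj(r0) * u)
  cq <- Mod(r0)^2 - target_mod^2
  disc <- bq^2 - 4 * cq
  if (disc < 0) stop("perturb_load: infeasible target")
  rho <- (-bq + sqrt(disc)) / 2
  if (rho < 0) stop("perturb_load: infeasible target")
  Lnew <- L + rho * u
  geom <- channel$geometric_isolation_db
  a_new <- Mod(Lnew) / 10^(-geom / 20)
  coupling_channel(a_new, Arg(Lnew) * 180 / pi, geom, channel$freq_slope)
}

#' Dense-grid brute-force reference for the calibration optimum
#'
#' Independent check of the feedback controller: evaluates the analytic
#' objective on a dense `(V1, V_att)` grid and returns the best grid point.
#' Used by tests as the oracle that the descent does not stall in a bad
#' local minimum.
#'
#' @param fe a [frontend()]
#' @param channel a [coupling_channel()]
#' @param pulse calibration pulse
#' @param v1_range,v_att_range grid extents (V)
#' @param v1_step,v_att_step grid pitches (V)
#' @param n_samples objective averaging length
#' @return list with `v1`, `v_att`, `objective`
#' @export
grid_search_reference <- function(fe, channel,
                                  pulse = make_rect(4e-3, 1, 10e-6),
                                  v1_range = c(0, 12), v_att_range = c(0, 6),
                                  v1_step = 0.01, v_att_step = 0.001,
                                  n_samples = 400) {
  ctx <- cal_context(fe, channel, pulse, n_samples)
  v1 <- seq(v1_range[1], v1_range[2], by = v1_step)
  va <- seq(v_att_range[1], v_att_range[2], by = v_att_step)
  tap_ratio <- ctx$tap / sqrt(1 - ctx$tap^2)
  g_phase <- exp(1i * deg2rad(phase_response(fe$shifter, v1)))
  g_att <- 10^(-(attenuation_response(fe$att, va) +
                   fe$shifter$insertion_loss_db) / 20)
  # |L - tap_ratio * g_att * g_phase| over the outer grid, vectorized
  L <- ctx$leak_gain
  AL <- Mod(L); phL <- Arg(L)
  amp <- tap_ratio * g_att                       # length(va)
  dph <- Arg(g_phase) - phL                      # length(v1)
  r2 <- outer(amp^2, rep(1, length(v1))) -
    2 * AL * outer(amp, cos(dph)) + AL^2
  idx <- arrayInd(which.min(r2), dim(r2))
  list(v1 = v1[idx[2]], v_att = va[idx[1]],
       objective = sqrt(max(r2[idx], 0)) * ctx$mean_main)
}
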