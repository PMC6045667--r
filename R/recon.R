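# Image reconstruction from radial CEA acquisitions: per-spoke recovery of
# the FID impulse response by pseudo-inverse deconvolution of the transmit
# pulse, response-length selection by RMSE elbow, k-space centre-shift
# correction from opposite-spoke cross-correlation, and Kaiser-Bessel
# convolution gridding onto a Cartesian grid followed by inverse FFT and
# deapodization.

#' Lower-triangular Toeplitz convolution operator of a pulse
#'
#' `U[i, k] = u_Tx[i - k]` (0-based) for `0 <= i - k < n`, else 0: `U h`
#' equals the causal convolution of `h` with the pulse truncated to `n`
#' samples.
#'
#' @param pulse transmit pulse
#' @param n number of rows (signal samples)
#' @param L number of columns (impulse-response length)
#' @param lambda Tikhonov regularization weight (>= 0), carried to the solver
#' @return class `cea_convolution_system`: `U`, `lambda`, `pulse`
#' @export
build_convolution_matrix <- function(pulse, n, L, lambda = 0) {
  if (L > n) stop("build_convolution_matrix: L must be <= n")
  u <- pulse$samples
  if (length(u) < n) u <- c(u, complex(n - length(u)))
  U <- matrix(0+0i, n, L)
  for (k in seq_len(L)) U[k:n, k] <- u[seq_len(n - k + 1)]
  structure(list(U = U, lambda = lambda, pulse = pulse),
            class = "cea_convolution_system")
}

#' Recover the FID impulse response by pseudo-inverse deconvolution
#'
#' Solves `h = (U* U + lambda I)^{-1} U* s_MR`. With `lambda = 0` the system
#' is solved through a rank-tolerant pseudo-inverse (singular values below
#' `machine epsilon x largest singular value x max(dim)` are discarded); a
#' rank-deficient system triggers a warning and returns the minimum-norm
#' solution.
#'
#' @param s_mr corrected MR trace (or complex vector)
#' @param pulse transmit pulse
#' @param L impulse-response length
#' @param lambda Tikhonov weight (default 0)
#' @param sys optional precomputed [build_convolution_matrix()] (reused
#'   across spokes)
#' @return a `cea_impulse_response`
#' @export
deconvolve <- function(s_mr, pulse, L, lambda = 0, sys = NULL) {
  y <- if (inherits(s_mr, "cea_trace")) s_mr$samples else as.complex(s_mr)
  n <- length(y)
  if (L > n) stop("deconvolve: L must be <= length(s_mr)")
  if (is.null(sys)) sys <- build_convolution_matrix(pulse, n, L, lambda)
  h <- solve_convolution(sys, y)
  dt <- if (inherits(s_mr, "cea_trace")) s_mr$dt else pulse$dt
  structure(list(h = h, dt = dt, length = L), class = "cea_impulse_response")
}

solve_convolution <- function(sys, y) {
  U <- sys$U
  if (sys$lambda > 0) {
    A <- Conj(t(U)) %*% U + sys$lambda * diag(ncol(U))
    return(as.vector(solve(A, Conj(t(U)) %*% y)))
  }
  sv <- svd(U)
  tol <- max(dim(U)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!all(keep))
    warning("deconvolve: numerically singular system; ",
            "returning the minimum-norm solution")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  as.vector(sv$v %*% (dinv * (Conj(t(sv$u)) %*% y)))
}

#' Select the impulse-response length by RMSE elbow
#'
#' For each candidate length `L` the fit RMSE `||s_MR - U h_L|| / sqrt(n)`
#' is computed; the scan stops at the elbow: the first candidate whose
#' successor improves the RMSE by less than `tol` relative (default 1%).
#'
#' @param s_mr MR trace or complex vector
#' @param pulse transmit pulse
#' @param candidates ascending candidate lengths
#' @param lambda Tikhonov weight passed to the solver
#' @param tol relative-improvement threshold
#' @return the selected length
#' @export
select_length <- function(s_mr, pulse, candidates, lambda = 0, tol = 0.01) {
  if (length(candidates) == 0)
    stop("select_length: candidate list must be nonempty")
  y <- if (inherits(s_mr, "cea_trace")) s_mr$samples else as.complex(s_mr)
  n <- length(y)
  rmse <- function(L) {
    sys <- build_convolution_matrix(pulse, n, L, lambda)
    h <- solve_convolution(sys, y)
    sqrt(sum(Mod(y - as.vector(sys$U %*% h))^2) / n)
  }
  prev <- rmse(candidates[1])
  if (length(candidates) == 1) return(candidates[1])
  for (i in seq_along(candidates)[-1]) {
    cur <- rmse(candidates[i])
    if (cur > (1 - tol) * prev) return(candidates[i - 1])
    prev <- cur
  }
  candidates[length(candidates)]
}

# shift a sequence by a fractional number of samples via a spectral linear
# phase; positive `shift` delays the sequence
fractional_shift <- function(x, shift) {
  n <- length(x)
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  as.vector(stats::fft(stats::fft(x) * exp(-2i * pi * k * shift / n),
                       inverse = TRUE) / n)
}

#' k-space centre-shift correction from opposite-spoke cross-correlation
#'
#' Spokes must be supplied in antipodal pairs `(a, b)`. For each pair the
#' full diameter profile `P = [rev |h_b|, |h_a|]` is cross-correlated with
#' its own reverse; the peak lag (refined by 3-point parabolic
#' interpolation) equals twice the common sub-sample shift of the k-space
#' centre. Half of that estimate is applied to each spoke as a linear phase
#' in the spectral domain, with opposite signs on the two spokes of a pair.
#'
#' @param responses list of `cea_impulse_response` (or complex vectors),
#'   ordered so that elements `2i - 1` and `2i` are antipodal partners
#' @return list with `responses` (corrected, same layout) and `shifts`
#'   (one per pair, samples)
#' @export
center_shift_correction <- function(responses) {
  np <- length(responses)
  if (np %% 2 != 0)
    stop("center_shift_correction: spokes must come in antipodal pairs")
  get_h <- function(r) if (inherits(r, "cea_impulse_response")) r$h else
    as.complex(r)
  shifts <- numeric(np / 2)
  out <- responses
  for (i in seq_len(np / 2)) {
    ha <- get_h(responses[[2 * i - 1]])
    hb <- get_h(responses[[2 * i]])
    P <- c(rev(Mod(hb)), Mod(ha))
    Q <- rev(P)
    # circular cross-correlation via FFT; lag 0 at index 1
    cc <- Re(stats::fft(stats::fft(P) * Conj(stats::fft(Q)),
                        inverse = TRUE)) / length(P)
    lag_idx <- which.max(cc)
    m <- length(P)
    lag <- if (lag_idx - 1 > m / 2) lag_idx - 1 - m else lag_idx - 1
    # parabolic refinement around the peak
    ym <- cc[((lag_idx - 2) %% m) + 1]
    y0 <- cc[lag_idx]
    yp <- cc[(lag_idx %% m) + 1]
    denom <- ym - 2 * y0 + yp
    frac <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
    raw <- lag + frac
    # a k-centre offset of delta samples along the pair axis makes the
    # composite even profile symmetric about N + 1/2 - delta, so the
    # correlation with its own reverse peaks at lag -2 delta
    delta <- -raw / 2
    shifts[i] <- delta
    ca <- fractional_shift(ha, +delta)
    cb <- fractional_shift(hb, -delta)
    out[[2 * i - 1]] <- put_h(responses[[2 * i - 1]], ca)
    out[[2 * i]] <- put_h(responses[[2 * i]], cb)
  }
  list(responses = out, shifts = shifts)
}

put_h <- function(r, h) {
  if (inherits(r, "cea_impulse_response")) { r$h <- h; r } else h
}

# Kaiser-Bessel kernel and its Fourier transform (deapodization)
kb_beta <- function(width, osf) {
  pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width, beta) {
  x <- 2 * u / width
  v <- 1 - x^2
  ifelse(v > 0, besselI(beta * sqrt(pmax(v, 0)), 0) / besselI(beta, 0), 0)
}

# FT of the KB kernel at normalized image position x (cycles per grid unit)
kb_deapod <- function(x, width, beta) {
  arg <- (pi * width * x)^2 - beta^2
  y <- ifelse(arg > 0,
              sin(sqrt(pmax(arg, 1e-30))) / sqrt(pmax(arg, 1e-30)),
              sinh(sqrt(pmax(-arg, 1e-30))) / sqrt(pmax(-arg, 1e-30)))
  y / max(y)
}

fftshift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

#' Grid radial impulse responses into an image (Kaiser-Bessel gridding)
#'
#' Density compensation proportional to `|k|^(d-1)` times the local sample
#' spacing along the (possibly ramped) trajectory, convolution gridding with
#' a Kaiser-Bessel kernel onto an `osf`-oversampled Cartesian grid, inverse
#' FFT, deapodization by the kernel transform, central crop, magnitude.
#'
#' @param responses list of `cea_impulse_response` (or complex vectors), one
#'   per spoke
#' @param directions matrix of unit spoke directions (n_spokes x 3)
#' @param k_radii list (or vector recycled) of per-sample k radii (1/m)
#' @param fov field of view (m)
#' @param matrix_size output matrix (>= 16)
#' @param dim 2 or 3
#' @param osf grid oversampling factor
#' @param kernel_width kernel width in oversampled grid units
#' @return class `cea_image`: `data` (magnitude array), `fov`, `voxel_size`
#' @export
grid_reconstruct <- function(responses, directions, k_radii, fov,
                             matrix_size = 64, dim = 2, osf = 2,
                             kernel_width = 4) {
  if (matrix_size < 16) stop("grid_reconstruct: matrix_size must be >= 16")
  nspokes <- length(responses)
  if (!is.list(k_radii)) k_radii <- rep(list(k_radii), nspokes)
  G <- round(osf * matrix_size)
  beta <- kb_beta(kernel_width, osf)
  dk <- 1 / fov                       # Cartesian grid pitch in k (1/m)
  kmax_grid <- G / 2 * dk / osf * osf # oversampled grid covers osf * kmax

  half_w <- kernel_width / 2
  d <- dim
  grid_dims <- rep(G, d)
  acc_re <- array(0, grid_dims)
  acc_im <- array(0, grid_dims)
  wsum <- 0

  offs <- as.matrix(do.call(expand.grid,
                            rep(list(seq(-ceiling(half_w), ceiling(half_w))),
                                d)))
  clipped <- FALSE
  for (sidx in seq_len(nspokes)) {
    r <- responses[[sidx]]
    h <- if (inherits(r, "cea_impulse_response")) r$h else as.complex(r)
    kr <- k_radii[[sidx]][seq_along(h)]
    u <- directions[sidx, seq_len(d)]
    # density compensation: |k|^(d-1) * local spacing, with a finite centre
    dkr <- c(diff(kr), utils::tail(diff(kr), 1))
    if (length(h) == 1) dkr <- dk
    dens <- pmax(abs(kr), abs(dkr) / 4)^(d - 1) * abs(dkr)
    # grid coordinates (1-based, centre at G/2 + 1)
    kv <- outer(kr, u)                          # n x d (1/m)
    gc <- kv / dk * osf + G / 2 + 1             # oversampled pitch dk/osf
    nyq <- gc < 1 + half_w | gc > G - half_w
    bad <- rowSums(nyq) > 0
    if (any(bad)) { clipped <- TRUE }
    keep <- !bad
    if (!any(keep)) next
    gck <- gc[keep, , drop = FALSE]
    val <- h[keep] * dens[keep]
    base <- round(gck)
    for (oi in seq_len(nrow(offs))) {
      tg <- sweep(base, 2, offs[oi, ], `+`)
      du <- tg - gck
      w <- rep(1, nrow(tg))
      for (j in seq_len(d)) w <- w * kb_kernel(du[, j], kernel_width, beta)
      nz <- w > 0
      if (!any(nz)) next
      flat <- tg[nz, 1]
      if (d >= 2) flat <- flat + (tg[nz, 2] - 1) * G
      if (d == 3) flat <- flat + (tg[nz, 3] - 1) * G^2
      v <- val[nz] * w[nz]
      agg_re <- rowsum(Re(v), flat)
      agg_im <- rowsum(Im(v), flat)
      ii <- as.integer(rownames(agg_re))
      acc_re[ii] <- acc_re[ii] + agg_re[, 1]
      acc_im[ii] <- acc_im[ii] + agg_im[, 1]
    }
  }
  if (clipped)
    warning("grid_reconstruct: trajectory samples beyond the grid Nyquist ",
            "were clipped")

  kgrid <- array(complex(real = acc_re, imaginary = acc_im), grid_dims)
  sh <- fftshift_idx(G)
  # forward DFT: the response phase convention e^{+2 pi i k x} puts a
  # point at +x back at +x in the image
  if (d == 2) {
    kgrid <- kgrid[sh, sh]
    img <- stats::fft(kgrid) / G^2
    img <- img[sh, sh]
  } else {
    kgrid <- kgrid[sh, sh, sh]
    img <- fft3(kgrid) / G^3
    img <- img[sh, sh, sh]
  }
  # deapodization on the oversampled image, then central crop
  x <- (seq_len(G) - (G / 2 + 1)) / G
  dea <- kb_deapod(x, kernel_width, beta)
  if (d == 2) {
    img <- img / outer(dea, dea)
  } else {
    img <- img / outer(outer(dea, dea), dea)
  }
  lo <- G / 2 + 1 - matrix_size / 2
  hi <- lo + matrix_size - 1
  img <- if (d == 2) img[lo:hi, lo:hi] else img[lo:hi, lo:hi, lo:hi]
  structure(list(data = Mod(img), fov = fov,
                 voxel_size = fov / matrix_size, dim = d),
            class = "cea_image")
}

# n-dimensional FFT via repeated application of mvfft along each dimension
fft3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  y <- x
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    y <- aperm(y, perm)
    dims <- dim(y)
    y <- array(stats::mvfft(matrix(y, dims[1]), inverse = inverse), dims)
    y <- aperm(y, order(perm))
  }
  if (inverse) y else y
}

#' @export
print.cea_image <- function(x, ...) {
  cat(sprintf("<cea_image: %s, FOV %.3g m, voxel %.3g mm>\n",
              paste(dim(x$data), collapse = " x "), x$fov,
              x$voxel_size * 1e3))
  invisible(x)
}

#' Reconstruct an image from simulated CEA spokes
#'
#' Convenience pipeline: optional digital leakage correction per spoke,
#' pseudo-inverse deconvolution with a shared convolution system,
#' opposite-spoke centre-shift correction, and Kaiser-Bessel gridding.
#' Spokes must come from a 2D equal-angle protocol (antipodal partner of
#' spoke `i` is `i + n_spokes/2`) or any layout when `pair_offset` is given.
#'
#' @param spokes list of spokes from [acquire_dataset()] or [full_chain()]
#' @param prot the acquisition [protocol()]
#' @param L impulse-response length (samples); `NULL` selects it from the
#'   first spoke via [select_length()]
#' @param correct `"none"`, `"chirp"` (PUC-based fit) or `"hs8"` (annealing)
#' @param joint fit the leakage once on the complex mean across spokes and
#'   subtract the common estimate (default); the residual leakage is
#'   spoke-invariant while the MR signal varies with spoke direction, so the
#'   averaged fit absorbs far less of the MR signal and, crucially, leaves
#'   no spoke-to-spoke inconsistency at the k-space centre
#' @param lambda Tikhonov weight for the deconvolution; `NULL` (default)
#'   sets `lambda = (0.01 sigma_max)^2` from the convolution operator's
#'   largest singular value, suppressing the out-of-band directions a
#'   band-limited sweep cannot encode
#' @param center_shift apply opposite-spoke centre-shift correction
#' @param seed seed forwarded to the HS8 annealer
#' @return a `cea_image`
#' @export
reconstruct_spokes <- function(spokes, prot, L = NULL, correct = "none",
                               joint = TRUE, lambda = NULL,
                               center_shift = TRUE, seed = 1) {
  nsp <- length(spokes)
  n <- prot$n_samples
  field <- if (!is.null(spokes[[1]][["s"]])) "s" else "s_mr"
  traces <- lapply(spokes, function(sp) sp[[field]])
  if (correct %in% c("chirp", "hs8") && joint) {
    # handled in h-space below, after deconvolution
  } else if (correct == "chirp") {
    traces <- lapply(seq_len(nsp), function(i)
      fit_chirp_leakage(traces[[i]], spokes[[i]]$puc, prot$pulse)$s_mr_est)
  } else if (correct == "hs8") {
    traces <- lapply(seq_len(nsp), function(i)
      fit_hs8_leakage(traces[[i]], prot$pulse, seed = seed + i)$s_mr_est)
  }
  if (is.null(L))
    L <- select_length(traces[[1]], prot$pulse,
                       candidates = unique(pmin(c(32, 64, 96, 128, 144), n)))
  if (is.null(lambda)) {
    smax <- svd(build_convolution_matrix(prot$pulse, n, L)$U, nu = 0,
                nv = 0)$d[1]
    lambda <- (0.01 * smax)^2
  }
  sys <- build_convolution_matrix(prot$pulse, n, L, lambda)
  hs <- lapply(traces, function(tr) solve_convolution(sys, tr$samples))
  if (correct %in% c("chirp", "hs8") && joint) {
    puc <- if (correct == "chirp") spokes[[1]]$puc else NULL
    B <- leak_model_basis(correct, prot$pulse, n, puc)
    hs <- conjsym_leak_correct(hs, sys, B)
  }
  if (center_shift && nsp %% 2 == 0 && prot$dim == 2) {
    half <- nsp / 2
    ord <- as.vector(rbind(seq_len(half), seq_len(half) + half))
    cs <- center_shift_correction(hs[ord])
    hs[ord] <- cs$responses
  }
  kr <- c(0, spokes[[1]]$k_traj[seq_len(L - 1)])
  dirs <- do.call(rbind, lapply(spokes, function(sp) sp$direction))
  grid_reconstruct(hs, dirs, rep(list(kr), nsp), prot$fov,
                   prot$matrix_size, dim = prot$dim)
}

#' Leakage-free analytic reference image
#'
#' Grids the analytic per-spoke FID responses of a phantom (no transmit
#' leakage, no noise, no deconvolution) with the same trajectory and
#' gridding settings as [reconstruct_spokes()]; the reference for
#' end-to-end reconstruction-fidelity checks.
#'
#' @param phant a [phantom()]
#' @param prot a [protocol()]
#' @param L impulse-response length (samples)
#' @return a `cea_image`
#' @export
reference_image <- function(phant, prot, L = 160) {
  dirs <- spoke_directions(prot$n_spokes, prot$dim)
  dt <- prot$pulse$dt
  hs <- lapply(seq_len(prot$n_spokes), function(i) {
    g <- gradient_waveform(dirs[i, ], prot$grad_amplitude, prot$ramp_time)
    fid_response(phant, g, dt, L)$h
  })
  g1 <- gradient_waveform(dirs[1, ], prot$grad_amplitude, prot$ramp_time)
  kr <- GAMMA_HZ_PER_T * gradient_integral(g1, (seq_len(L) - 1) * dt)
  grid_reconstruct(hs, dirs, rep(list(kr), prot$n_spokes), prot$fov,
                   prot$matrix_size, dim = prot$dim)
}

#' Normalized RMS difference between two images
#'
#' Both images are scaled to unit maximum; returns
#' `||a - b|| / ||b||` over all voxels.
#'
#' @param img test image (`cea_image`)
#' @param ref reference image (`cea_image`)
#' @export
image_nrmse <- function(img, ref) {
  a <- img$data / max(img$data)
  b <- ref$data / max(ref$data)
  sqrt(sum((a - b)^2) / sum(b^2))
}


# Trace-domain basis of the residual-leakage model: for chirp, the
# unit-peak PUC reference times {1, f-, f+} (complex per-side linear
# amplitude); for HS8, the pulse waveform times {1, t, t^2} modulations.
leak_model_basis <- function(kind, pulse, n, puc = NULL) {
  t <- (seq_len(n) - 1) * pulse$dt
  if (kind == "chirp") {
    ref <- puc$samples[seq_len(n)] / max(Mod(puc$samples))
    fc <- pulse$sweep_bandwidth * (t / pulse$duration - 0.5)
    fl <- as.numeric(fc < 0)
    cbind(ref, ref * fc * fl, ref * fc * (1 - fl))
  } else {
    u <- pulse$samples[seq_len(n)]
    tn <- t / max(t)
    cbind(u, u * tn, u * tn^2)
  }
}

# Joint leakage estimation across spokes from conjugate symmetry: for a
# real object the antipodal-averaged deconvolved response is real, while
# the (spoke-invariant) leakage deconvolves to a complex profile.  The
# complex model coefficients are therefore estimated by least squares on
# the imaginary part of the mean response; the component of the leakage
# whose deconvolution is purely real (essentially a real scale at the
# k-space centre) is unidentifiable from the object's mass and is left in
# place by the minimum-norm solve, where it only shifts the image DC.
conjsym_leak_correct <- function(hs, sys, B) {
  m_h <- Reduce(`+`, hs) / length(hs)
  D <- vapply(seq_len(ncol(B)),
              function(j) solve_convolution(sys, B[, j]),
              complex(length(m_h)))
  A <- cbind(Im(D), Re(D))                 # Im(D c) = Im(D) cr + Re(D) ci
  sv <- svd(A)
  keep <- sv$d > 1e-8 * sv$d[1]
  x <- sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE], Im(m_h)))
  cc <- complex(real = x[seq_len(ncol(B))],
                imaginary = x[ncol(B) + seq_len(ncol(B))])
  d_leak <- as.vector(D %*% cc)
  lapply(hs, function(h) h - d_leak)
}
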