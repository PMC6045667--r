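# Fixtures, file formats, configuration and logging: digital-phantom and
# protocol presets, a versioned JSON raw-data container, NIfTI image export,
# and YAML experiment configs.

RAW_FORMAT_VERSION <- "ceasim-raw-1"

disk_isochromats <- function(center, radius, spacing, m0 = 1, t2star = 1e-3,
                             chem_shift = 0) {
  g <- seq(-radius, radius, by = spacing)
  pts <- expand.grid(x = g, y = g)
  pts <- pts[pts$x^2 + pts$y^2 <= radius^2, ]
  cbind(pts$x + center[1], pts$y + center[2], 0)
}

#' Generate a phantom/protocol fixture from a preset
#'
#' Presets:
#' * `"tubes"` — 8 large disks on a ring plus 2 smaller attached tubes with
#'   distinct (shorter) T2*, emulating a multi-tube structural phantom.
#' * `"fe-series"` — 6 vials whose relaxation rate 1/T2* is linear in the
#'   iron concentrations 0.02, 0.029, 0.038, 0.056, 0.071 and 0.1 M
#'   (relaxivity configurable; the default 2e5 s^-1 M^-1 puts the highest
#'   concentration near 50 us).
#' * `"two-disk"` — two offset disks, the end-to-end reconstruction test
#'   object.
#' * `"point"` — a single isochromat at a configurable offset.
#'
#' @param spec list with `phantom` (preset name), `protocol` (preset name,
#'   `"chirp-2d"` or `"hs8-2d"`), `noise` (receiver noise sd), `seed`, and
#'   optional preset parameters (`relaxivity`, `offset`, `spacing`)
#' @return list with `phantom`, `protocol`, `noise_cfg`, `seed`
#' @export
gen_fixture <- function(spec) {
  presets <- c("tubes", "fe-series", "two-disk", "point")
  if (!spec$phantom %in% presets)
    stop("gen_fixture: unknown phantom preset '", spec$phantom,
         "'; available: ", paste(presets, collapse = ", "))
  seed <- spec$seed %||% 1
  set.seed(seed)
  spacing <- spec$spacing %||% 3e-3
  # all presets stay inside the frequency band swept by the default pulses:
  # 16 kHz at 4 mT/m excites |x| < ~47 mm around the isocentre
  ph <- switch(spec$phantom,
    "tubes" = {
      ring <- 0.034
      ang <- 2 * pi * (0:7) / 8
      pos <- NULL; t2 <- NULL
      for (i in 1:8) {
        pts <- disk_isochromats(c(ring * cos(ang[i]), ring * sin(ang[i])),
                                0.008, spacing)
        pos <- rbind(pos, pts)
        t2 <- c(t2, rep(0.35e-3, nrow(pts)))
      }
      for (j in 1:2) {
        pts <- disk_isochromats(c(0.016 * (2 * j - 3), 0), 0.005, spacing / 2)
        pos <- rbind(pos, pts)
        # two small tubes with distinct, shorter T2* (contrast-doped)
        t2 <- c(t2, rep(c(0.25e-3, 0.15e-3)[j], nrow(pts)))
      }
      phantom(pos, m0 = 1, t2star = t2, name = "tubes")
    },
    "fe-series" = {
      conc <- c(0.02, 0.029, 0.038, 0.056, 0.071, 0.1)
      relax <- spec$relaxivity %||% 2e5        # (s M)^-1
      t2 <- 1 / (relax * conc)
      ang <- 2 * pi * (0:5) / 6
      pos <- NULL; t2v <- NULL
      for (i in 1:6) {
        pts <- disk_isochromats(c(0.034 * cos(ang[i]), 0.034 * sin(ang[i])),
                                0.008, spacing)
        pos <- rbind(pos, pts)
        t2v <- c(t2v, rep(t2[i], nrow(pts)))
      }
      ph <- phantom(pos, m0 = 1, t2star = t2v, name = "fe-series")
      ph$concentrations <- conc
      ph$relaxivity <- relax
      ph
    },
    "two-disk" = {
      p1 <- disk_isochromats(c(-0.028, 0), 0.015, spacing)
      p2 <- disk_isochromats(c(0.03, 0.012), 0.01, spacing)
      phantom(rbind(p1, p2), m0 = 1,
              t2star = c(rep(0.35e-3, nrow(p1)), rep(0.25e-3, nrow(p2))),
              name = "two-disk")
    },
    "point" = {
      off <- spec$offset %||% c(0, 0, 0)
      phantom(matrix(off, 1, 3), m0 = 1, t2star = 1e-3, name = "point")
    })

  prot_name <- spec$protocol %||% "chirp-2d"
  prot <- switch(prot_name,
    # desk-scale analogue of the 3D tube-phantom protocol: 2D radial,
    # edge-smoothed chirp, 16 kHz sweep over a 4.1 ms window, 4 mT/m
    "chirp-2d" = protocol(
      n_spokes = 128, n_samples = 512,
      pulse = make_chirp(4.1e-3, 16e3, amplitude = 1, dt = 4.1e-3 / 512),
      grad_amplitude = 4e-3, ramp_time = 0.2e-3, dim = 2,
      fov = 0.12, matrix_size = 48),
    # desk-scale analogue of the fast swept protocol: HS8, 128 kHz over 1 ms
    "hs8-2d" = protocol(
      n_spokes = 128, n_samples = 512,
      pulse = make_hs8(1e-3, 128e3, amplitude = 1, dt = 1e-3 / 512),
      grad_amplitude = 4e-3, ramp_time = 0.1e-3, dim = 2,
      fov = 0.12, matrix_size = 48),
    stop("gen_fixture: unknown protocol preset '", prot_name,
         "'; available: chirp-2d, hs8-2d"))

  list(phantom = ph, protocol = prot,
       noise_cfg = list(sigma_rx = spec$noise %||% 0, tx_noise_frac = 0),
       seed = seed)
}

# doubles are serialized as decimal strings with 17 significant digits so
# that write/read round trips are bit-exact
num_out <- function(x) sprintf("%.17g", x)
cplx_out <- function(x) list(re = num_out(Re(x)), im = num_out(Im(x)))

#' Write / read the raw-data container
#'
#' A versioned JSON document with groups `pulse` (samples, dt, metadata),
#' `spokes` (per-spoke signal, direction, k-trajectory), `frontend` (channel
#' and canceller state) and `provenance` (seed, config snapshot, stage
#' history). Round trips are lossless (doubles serialized at full
#' precision).
#'
#' @param raw list with fields `pulse`, `spokes`, `frontend`, `provenance`
#' @param path file path
#' @export
write_raw <- function(raw, path) {
  doc <- list(
    version = RAW_FORMAT_VERSION,
    pulse = list(samples = cplx_out(raw$pulse$samples), dt = raw$pulse$dt,
                 kind = raw$pulse$kind,
                 sweep_bandwidth = raw$pulse$sweep_bandwidth,
                 center_offset = raw$pulse$center_offset,
                 amplitude = raw$pulse$amplitude),
    spokes = lapply(raw$spokes, function(sp) {
      out <- list(direction = num_out(sp$direction),
                  k_traj = num_out(sp$k_traj))
      for (f in c("s", "s_mr", "puc"))
        if (!is.null(sp[[f]])) out[[f]] <-
          list(samples = cplx_out(sp[[f]]$samples), dt = sp[[f]]$dt)
      out
    }),
    frontend = raw$frontend,
    provenance = raw$provenance %||% list())
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  if (!file.exists(path)) stop("read_raw: no such file: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("read_raw: truncated or unparsable container: ",
                         conditionMessage(e)))
  if (is.null(doc$version) || !identical(doc$version, RAW_FORMAT_VERSION))
    stop("read_raw: container version mismatch (found '",
         doc$version %||% "<none>", "', expected '", RAW_FORMAT_VERSION, "')")
  num <- function(x) as.numeric(unlist(x))
  cx <- function(x) complex(real = num(x$re), imaginary = num(x$im))
  pulse <- new_pulse(cx(doc$pulse$samples), num(doc$pulse$dt),
                     num(doc$pulse$sweep_bandwidth), doc$pulse$kind,
                     num(doc$pulse$center_offset), num(doc$pulse$amplitude))
  spokes <- lapply(doc$spokes, function(sp) {
    out <- list(direction = num(sp$direction), k_traj = num(sp$k_traj))
    for (f in c("s", "s_mr", "puc"))
      if (!is.null(sp[[f]]))
        out[[f]] <- signal_trace(cx(sp[[f]]$samples), num(sp[[f]]$dt))
    out
  })
  list(pulse = pulse, spokes = spokes,
       frontend = doc$frontend, provenance = doc$provenance)
}

#' Append a provenance entry to a raw container list
#'
#' @param raw raw container list
#' @param stage stage name
#' @param params named list of stage parameters
#' @export
add_provenance <- function(raw, stage, params = list()) {
  entry <- list(stage = stage, time = format(Sys.time(), tz = "UTC"),
                params = params)
  raw$provenance$history <- c(raw$provenance$history %||% list(),
                              list(entry))
  raw
}

#' Write an image volume as NIfTI-1
#'
#' Voxel size is placed in the header; 2D images are stored as single-slice
#' volumes.
#'
#' @param volume a `cea_image` from [grid_reconstruct()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @export
write_image <- function(volume, path) {
  dat <- volume$data
  if (length(dim(dat)) == 2) dat <- array(dat, c(dim(dat), 1))
  vs <- volume$voxel_size * 1e3               # header pixdim in mm
  img <- RNifti::asNifti(dat)
  attr(img, "pixdim") <- rep(vs, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write an experiment configuration (YAML)
#'
#' @param path YAML file
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param cfg configuration list
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a calibration iteration log as tabular text
#'
#' @param result a `cea_calibration`
#' @param path output path (tab-separated)
#' @export
write_calibration_log <- function(result, path) {
  tr <- result$trace
  utils::write.table(tr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
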