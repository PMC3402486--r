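#' Doppler OCT conversion constants
#'
#' Central wavelength, tissue refractive index, and inter-A-scan time of the
#' spectral-domain OCT system; together they set the phase-to-velocity
#' conversion `V_z = lambda0 * dphi / (4 pi n tau)` and its `+/-` detectable
#' range (`dphi = +/- pi`).
#'
#' @param lambda0_nm Central wavelength (nm), default 1310.
#' @param n Tissue refractive index, default 1.3.
#' @param tau_us Time between adjacent A-scans (us), default 21.
#' @return A `doppler_config` list with fields in SI units (`lambda0_m`,
#'   `n`, `tau_s`).
#' @export
doppler_config <- function(lambda0_nm = 1310, n = 1.3, tau_us = 21) {
  stopifnot(lambda0_nm > 0, tau_us > 0, n >= 1, n <= 2)
  structure(list(lambda0_m = lambda0_nm * 1e-9, n = n, tau_s = tau_us * 1e-6),
            class = "doppler_config")
}

#' Convert inter-A-scan phase shift to axial Doppler velocity
#'
#' `V_z = lambda0 * dphi / (4 pi n tau)`, returned in mm/s. At
#' `dphi = +/- pi` this is the system's unambiguous detectable range
#' (about +/-12 mm/s with the defaults).
#'
#' @param dphi Phase shift(s), radians.
#' @param cfg A [doppler_config()].
#' @return Axial velocity (mm/s), same length as `dphi`.
#' @export
phase_to_velocity <- function(dphi, cfg = doppler_config()) {
  stopifnot(all(is.finite(dphi)))
  1000 * cfg$lambda0_m * dphi / (4 * pi * cfg$n * cfg$tau_s)
}

#' Correct an axial velocity for the Doppler angle
#'
#' `V = V_z / cos(theta)`, where `theta` is the angle between the OCT beam
#' and the flow direction. Noise in `V_z` is amplified by the same factor,
#' which is why measurements at large angles (e.g. 84 degrees) are noisy.
#'
#' @param v_z Axial velocity (mm/s).
#' @param theta_deg Doppler angle (degrees), not 90.
#' @return Flow-direction velocity magnitude (mm/s).
#' @export
angle_correct <- function(v_z, theta_deg) {
  c_th <- cos(theta_deg * pi / 180)
  if (any(abs(c_th) < 1e-12)) {
    stop("Doppler angle of 90 degrees: velocity undefined", call. = FALSE)
  }
  v_z / c_th
}

#' Temporal phase unwrapping
#'
#' Removes the 2 pi jumps of a wrapped phase series: whenever a successive
#' difference exceeds pi in magnitude, a multiple of 2 pi is added to the
#' remainder of the series. Doubles the unambiguous velocity range of the
#' wrapped signal.
#'
#' @param dphi Wrapped phase series (radians), uniformly sampled in time.
#' @return Unwrapped phase series.
#' @export
unwrap_phase <- function(dphi) {
  if (length(dphi) < 2) return(dphi)
  d <- diff(dphi)
  corr <- -2 * pi * round(d / (2 * pi))
  dphi + c(0, cumsum(corr))
}

#' Centerline velocity series from an M-phase image
#'
#' Extracts the phase at one spatial sample of an M-phase raster over time,
#' masks the frames in which the lumen is closed (the sample leaves the
#' lumen), unwraps the remaining series in time, and converts it through the
#' phase-velocity relation and the Doppler-angle correction. Samples whose
#' unwrapped phase magnitude reaches the doubled detectable limit are
#' flagged as potential wrap plateaus.
#'
#' @param mphase M-phase matrix (space x time) from [extract_mmode()], or a
#'   numeric phase series.
#' @param row Row of the raster to use (ignored for a vector input).
#' @param cfg A [doppler_config()].
#' @param theta_deg Doppler angle of the plane (degrees).
#' @param open Optional logical vector per frame: `FALSE` marks closed-lumen
#'   frames, reported as `NA` velocity (missing, not zero).
#' @param times_s Optional frame times.
#' @param plateau_frac Fraction of the doubled wrap limit above which a
#'   sample is flagged (default 0.98).
#' @return Tibble with `time_s`, `phase_rad` (raw), `v_mm_s` (angle-corrected
#'   velocity, `NA` when masked), `masked`, and `plateau` flags.
#' @export
centerline_velocity_series <- function(mphase, row = NULL,
                                       cfg = doppler_config(), theta_deg,
                                       open = NULL, times_s = NULL,
                                       plateau_frac = 0.98) {
  ph <- if (is.matrix(mphase)) {
    if (is.null(row)) row <- round(nrow(mphase) / 2)
    mphase[row, ]
  } else {
    as.numeric(mphase)
  }
  nt <- length(ph)
  if (is.null(open)) open <- rep(TRUE, nt)
  if (is.null(times_s)) times_s <- seq_len(nt) - 1
  masked <- !open

  v <- rep(NA_real_, nt)
  plateau <- rep(FALSE, nt)
  # unwrap each contiguous open segment independently
  runs <- rle(open)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  vz_limit <- phase_to_velocity(pi, cfg)
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    idx <- starts[i]:ends[i]
    un <- unwrap_phase(ph[idx])
    vz <- phase_to_velocity(un, cfg)
    v[idx] <- angle_correct(vz, theta_deg)
    plateau[idx] <- abs(vz) >= plateau_frac * 2 * vz_limit
  }
  tibble::tibble(time_s = times_s, phase_rad = ph, v_mm_s = v,
                 masked = masked, plateau = plateau)
}
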