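#' Image sequence container
#'
#' One fixed plane's time-ordered raster stack. Frames are stored as a 3-D
#' array indexed `[frame, row, col]`; rows run along the OCT beam axis
#' (depth). Intensity is in `[0, 1]`; the optional Doppler phase channel is in
#' `(-pi, pi]`.
#'
#' @param intensity 3-D numeric array, `time x rows x cols`, values in [0, 1].
#' @param phase Optional 3-D array of the same shape, values in (-pi, pi].
#' @param pixel_pitch_um Pixel size (um).
#' @param frame_rate_hz Frame rate (frames/s).
#' @param plane_id Integer plane identifier.
#' @return An `image_sequence` object.
#' @export
image_sequence <- function(intensity, phase = NULL, pixel_pitch_um,
                           frame_rate_hz, plane_id = 1L) {
  stopifnot(length(dim(intensity)) == 3)
  if (!is.null(phase)) {
    stopifnot(identical(dim(phase), dim(intensity)))
    if (any(phase <= -pi | phase > pi)) {
      stop("phase values must lie in (-pi, pi]", call. = FALSE)
    }
  }
  structure(
    list(intensity = intensity, phase = phase,
         pixel_pitch_um = pixel_pitch_um, frame_rate_hz = frame_rate_hz,
         plane_id = as.integer(plane_id)),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<image_sequence> plane %d: %d frames of %dx%d px (%g um) at %g fps%s\n",
              x$plane_id, d[1], d[2], d[3], x$pixel_pitch_um, x$frame_rate_hz,
              if (is.null(x$phase)) "" else ", with Doppler phase"))
  invisible(x)
}

n_frames <- function(seq) dim(seq$intensity)[1]

#' Wrap phase angles into (-pi, pi]
#'
#' @param x Phase angles (radians).
#' @return Wrapped angles in (-pi, pi].
#' @export
wrap_phase <- function(x) -(((-x + pi) %% (2 * pi)) - pi)

# Intensity base levels of the phantom's tissue classes. Endocardium and
# lumen share one level: in OCT they are indistinguishable.
phantom_levels <- c(background = 0.05, myocardium = 0.85, jelly = 0.20,
                    lumen = 0.45)

# Static per-plane raster geometry (beam axis = rows = y/depth).
plane_grid <- function(config, z_um) {
  px <- config$img_px
  pitch_mm <- config$pixel_pitch_um / 1000
  ctr <- (px + 1) / 2
  col <- matrix(rep(seq_len(px), each = px), px, px)  # [row, col]
  row <- matrix(rep(seq_len(px), times = px), px, px)
  x <- (col - ctr) * pitch_mm
  y <- (row - ctr) * pitch_mm
  psi <- config$cushion_spiral_rate_deg_um * z_um * pi / 180
  list(
    x = x, y = y, r2 = x^2 + y^2,
    xr = cos(psi) * x + sin(psi) * y,   # along lumen major axis
    yr = -sin(psi) * x + cos(psi) * y,  # along minor axis (cushion direction)
    depth_mm = (row - 1) * pitch_mm,
    pitch_mm = pitch_mm
  )
}

render_frame_intensity <- function(grid, geo, config) {
  lvl <- phantom_levels
  img <- matrix(lvl[["background"]], nrow(grid$x), ncol(grid$x))
  img[grid$r2 <= geo$r_outer_mm^2] <- lvl[["myocardium"]]
  img[grid$r2 <= geo$r_inner_mm^2] <- lvl[["jelly"]]
  in_lumen <- (grid$xr / geo$a_mm)^2 + (grid$yr / geo$b_render_mm)^2 <= 1
  img[in_lumen & grid$r2 <= geo$r_inner_mm^2] <- lvl[["lumen"]]
  img * exp(-config$attenuation_per_mm * grid$depth_mm)
}

apply_speckle <- function(img, contrast) {
  if (contrast <= 0) return(img)
  k <- 1 / contrast^2
  img * matrix(stats::rgamma(length(img), shape = k, scale = 1 / k),
               nrow(img), ncol(img))
}

#' Render a Doppler phase frame from a known in-plane velocity field
#'
#' Converts the axial (beam-projected) velocity of the elliptical-duct profile
#' `u = U0 (1 - x'^2/a^2 - y'^2/b^2)` into an inter-A-scan phase shift
#' `dphi = 4 pi n tau V cos(theta) / lambda0`, wraps it into `(-pi, pi]`, and
#' adds zero-mean Gaussian phase noise. Pixels outside the lumen carry noise
#' only.
#'
#' @param grid Static plane grid (internal) or `NULL` to build from `config`
#'   and `z_um`.
#' @param geo One-row cross-section tibble from [oft_cross_section()].
#' @param u0_mm_s Centerline velocity (mm/s) for this frame.
#' @param theta_deg Doppler angle (degrees).
#' @param config A [phantom_config()].
#' @param dopcfg A [doppler_config()].
#' @param z_um Axial position, used when `grid` is `NULL`.
#' @return Matrix of wrapped phase values in `(-pi, pi]`.
#' @export
render_doppler_phase <- function(grid = NULL, geo, u0_mm_s, theta_deg, config,
                                 dopcfg = doppler_config(), z_um = 0) {
  if (is.null(grid)) grid <- plane_grid(config, z_um)
  ph <- matrix(0, nrow(grid$x), ncol(grid$x))
  if (geo$open && is.finite(u0_mm_s)) {
    shape <- 1 - (grid$xr / geo$a_mm)^2 - (grid$yr / geo$b_mm)^2
    in_lumen <- shape > 0
    v_mm_s <- u0_mm_s * shape * cos(theta_deg * pi / 180)
    # mm/s -> m/s; dphi = 4 pi n tau V / lambda0
    dphi <- 4 * pi * dopcfg$n * dopcfg$tau_s * (v_mm_s / 1000) / dopcfg$lambda0_m
    ph[in_lumen] <- dphi[in_lumen]
  }
  if (config$phase_noise_sd > 0) {
    ph <- ph + matrix(stats::rnorm(length(ph), sd = config$phase_noise_sd),
                      nrow(ph), ncol(ph))
  }
  wrap_phase(ph)
}

#' Render the full phantom: image sequences plus ground truth
#'
#' Generates, for each analysis plane, at least `n_cycles` cardiac cycles of
#' intensity frames (bright myocardium, dark cardiac jelly, mid-level
#' lumen/endocardium, multiplicative speckle, exponential depth attenuation)
#' and wrapped Doppler phase frames from the ground-truth flow. Each plane's
#' sequence starts at an independent uniformly drawn cycle phase; the drawn
#' phases and every geometric/flow quantity used for rendering are recorded
#' in the returned ground truth. Output is bit-identical for a fixed
#' `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param with_phase Render the Doppler phase channel (default `TRUE`).
#' @return A list with elements `sequences` (list of [image_sequence()], one
#'   per plane) and `truth`, itself a list with `start_phase`, `lag_frames`
#'   (true lag of each plane relative to plane 1, in frames, modulo the
#'   period), `period_frames`, `geometry` (tibble of per-plane per-frame
#'   ground-truth geometry and flow), and `pressure` (tibble from
#'   [generate_pressure_traces()]).
#' @export
render_sequences <- function(config, with_phase = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  zp <- plane_positions_um(config)
  nf <- ceiling(config$n_cycles * config$period_s * config$frame_rate_hz)
  tt <- (seq_len(nf) - 1) / config$frame_rate_hz
  period_frames <- config$period_s * config$frame_rate_hz

  start_phase <- stats::runif(config$n_planes)
  # frame lag of plane i relative to plane 1 (circular, in frames)
  lag_frames <- (config$frame_rate_hz *
                   (zp / config$peristaltic_wave_speed_um_s -
                      (start_phase - start_phase[1]) * config$period_s)) %%
    period_frames

  dopcfg <- doppler_config()
  sequences <- vector("list", config$n_planes)
  geom_list <- vector("list", config$n_planes)

  for (p in seq_len(config$n_planes)) {
    grid <- plane_grid(config, zp[p])
    geo <- oft_cross_section(config, zp[p], tt, start_phase[p])
    flw <- true_flow(config, zp[p], tt, start_phase[p])
    geo$q_mm3_s <- flw$q_mm3_s
    geo$u0_mm_s <- flw$u0_mm_s
    geo$plane <- p
    geo$frame <- seq_len(nf)
    geom_list[[p]] <- geo

    px <- config$img_px
    intensity <- array(0, c(nf, px, px))
    phase <- if (with_phase) array(0, c(nf, px, px)) else NULL
    for (f in seq_len(nf)) {
      g1 <- geo[f, ]
      img <- render_frame_intensity(grid, g1, config)
      intensity[f, , ] <- pmin(1, apply_speckle(img, config$speckle_contrast))
      if (with_phase) {
        phase[f, , ] <- render_doppler_phase(grid, g1, g1$u0_mm_s,
                                             config$doppler_angle_deg[p],
                                             config, dopcfg)
      }
    }
    sequences[[p]] <- image_sequence(intensity, phase,
                                     config$pixel_pitch_um,
                                     config$frame_rate_hz, p)
  }

  pressure <- generate_pressure_traces(config)
  list(
    sequences = sequences,
    truth = list(
      start_phase = start_phase,
      lag_frames = lag_frames,
      period_frames = period_frames,
      plane_z_um = zp,
      geometry = dplyr::bind_rows(geom_list),
      pressure = pressure
    )
  )
}

#' Polygon of a ground-truth boundary
#'
#' Builds the closed, counter-clockwise polygon (mm, centered on the plane
#' center) of one tissue boundary from a ground-truth geometry row.
#'
#' @param geo One-row tibble from [oft_cross_section()] (or a row of
#'   `truth$geometry`).
#' @param label One of `"myo_outer"`, `"myo_inner"`, `"endo"`.
#' @param n Number of vertices.
#' @return A tibble with `x_mm`, `y_mm` (open polygon, implicitly closed).
#' @export
truth_contour <- function(geo, label = c("myo_outer", "myo_inner", "endo"),
                          n = 64) {
  label <- match.arg(label)
  s <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (label == "myo_outer") {
    x <- geo$r_outer_mm * cos(s); y <- geo$r_outer_mm * sin(s)
  } else if (label == "myo_inner") {
    x <- geo$r_inner_mm * cos(s); y <- geo$r_inner_mm * sin(s)
  } else {
    ex <- geo$a_mm * cos(s); ey <- geo$b_render_mm * sin(s)
    psi <- geo$orientation_rad
    x <- cos(psi) * ex - sin(psi) * ey
    y <- sin(psi) * ex + cos(psi) * ey
  }
  tibble::tibble(x_mm = x, y_mm = y)
}

#' Generate ventricular and aortic-sac pressure traces
#'
#' Smooth periodic pressure pulses at the cardiac frequency, sampled at
#' 100 Hz: a raised-cosine-cubed systolic pulse over a 15%-of-peak diastolic
#' baseline. The ventricular trace peaks at exactly `p_vent_peak_pa` and the
#' aortic-sac trace at `p_as_peak_pa`; the ventricular peak is never below
#' the aortic-sac peak with the defaults. The phase relationship to wall
#' motion is established downstream by [align_pressure_phase()].
#'
#' @param config A [phantom_config()].
#' @param n_cycles Number of cycles (default 10).
#' @param sampling_hz Sampling rate (default 100 Hz).
#' @return A tibble with `time_s`, `pressure_pa`, `site`
#'   (`"ventricle"`/`"aortic_sac"`).
#' @export
generate_pressure_traces <- function(config, n_cycles = 10, sampling_hz = 100) {
  t <- seq(0, n_cycles * config$period_s, by = 1 / sampling_hz)
  pulse <- function(peak) {
    ph <- (t / config$period_s) %% 1
    base <- 0.15 * peak
    base + (peak - base) * ((1 + cos(2 * pi * ph)) / 2)^3
  }
  dplyr::bind_rows(
    tibble::tibble(time_s = t, pressure_pa = pulse(config$p_vent_peak_pa),
                   site = "ventricle"),
    tibble::tibble(time_s = t, pressure_pa = pulse(config$p_as_peak_pa),
                   site = "aortic_sac")
  )
}
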