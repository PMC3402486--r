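#' Configuration of the outflow-tract digital phantom
#'
#' Parametric description of a beating tubular outflow tract (OFT) used to
#' generate synthetic cross-sectional OCT image sequences with known ground
#' truth. The phantom is a tapered tube (~600 um long) whose wall has three
#' layers: a bright myocardium, a dark cardiac-jelly layer shaped into two
#' diametrically opposed endocardial cushions whose orientation spirals along
#' the tube, and a lumen whose intensity is indistinguishable from the
#' endocardium. The wall contracts peristaltically, closing the lumen
#' proximally to distally, and stays closed for roughly half of each cycle.
#'
#' All lengths are in the stated units; radii are *inner myocardial* radii.
#' Plane radii taper proximal to distal and the expanded radius must be
#' monotonically non-increasing along the tube.
#'
#' @param tube_length_um Tube length (um).
#' @param n_planes Number of fixed analysis planes along the tube.
#' @param frame_rate_hz Acquisition frame rate (frames/s).
#' @param period_s Cardiac period T (s); ~2.5 Hz beat.
#' @param n_cycles Number of cardiac cycles rendered per plane.
#' @param pixel_pitch_um Isotropic pixel size (um).
#' @param img_px Raster width/height in pixels.
#' @param r_inner_max_mm,r_inner_min_mm Per-plane inner myocardial radius at
#'   full expansion / full contraction (mm).
#' @param wall_thickness_mm Per-plane myocardial wall thickness (mm),
#'   decreasing distally.
#' @param cushion_spiral_rate_deg_um Rotation rate of the cushion-pair
#'   orientation along the tube (degrees/um).
#' @param peristaltic_wave_speed_um_s Speed of the contraction wave (um/s);
#'   closure onset at depth z lags the inlet by `z / speed` seconds.
#' @param closure_fraction Target fraction of the cycle during which a plane's
#'   lumen is closed (dimensionless, ~0.5).
#' @param open_phase_center Cycle phase (0..1) of maximal lumen opening at the
#'   inlet; the flow window is centered here.
#' @param lumen_axis_ratio Minor/major axis ratio of the fully open lumen
#'   ellipse (slightly below 1: near-circular when most expanded).
#' @param d_min_mm Minimal cardiac-jelly thickness, along the lumen major axis
#'   (mm); mimics the thin tethered jelly between cushions.
#' @param endo_slit_mm Apparent thickness of the apposed endocardial layers
#'   when the lumen is closed (mm); sets the rendered slit half-width.
#' @param p_vent_peak_pa,p_as_peak_pa Peak ventricular / aortic-sac pressure
#'   (Pa).
#' @param doppler_angle_deg Per-plane Doppler angle between beam and flow
#'   (degrees).
#' @param q_peak_mm3_s Peak inlet volume flow rate (mm^3/s).
#' @param speckle_contrast Speckle contrast (sd/mean) of the multiplicative
#'   gamma speckle; 0 disables intensity noise.
#' @param attenuation_per_mm Exponential depth-attenuation coefficient along
#'   the beam axis (1/mm).
#' @param phase_noise_sd Additive Doppler phase noise sd (radians); 0 disables.
#' @param longitudinal_jelly_modulation If `TRUE`, modulate the cardiac-jelly
#'   cross-sectional area in antiphase with the ~20% longitudinal stretch
#'   (jelly redistributes along the stretched tube); off by default, and wall
#'   planes never move axially.
#' @param seed Integer seed; fixed seed gives bit-identical phantom output.
#'
#' @return An object of class `phantom_config` (a validated named list).
#' @examples
#' cfg <- phantom_config(n_cycles = 2)
#' cfg$period_s
#' @export
phantom_config <- function(tube_length_um = 600,
                           n_planes = 5,
                           frame_rate_hz = 140,
                           period_s = 0.37,
                           n_cycles = 4,
                           pixel_pitch_um = 5,
                           img_px = 120,
                           r_inner_max_mm = c(0.21, 0.20, 0.19, 0.17, 0.15),
                           r_inner_min_mm = c(0.14, 0.13, 0.12, 0.11, 0.12),
                           wall_thickness_mm = c(0.060, 0.054, 0.048, 0.040, 0.030),
                           cushion_spiral_rate_deg_um = 0.15,
                           peristaltic_wave_speed_um_s = 40000,
                           closure_fraction = 0.52,
                           open_phase_center = 0.68,
                           lumen_axis_ratio = 0.92,
                           d_min_mm = 0.010,
                           endo_slit_mm = 0.018,
                           p_vent_peak_pa = 196,
                           p_as_peak_pa = 180,
                           doppler_angle_deg = c(84, 58.4, 58.4, 58.4, 58.4),
                           q_peak_mm3_s = 1.7,
                           speckle_contrast = 0.3,
                           attenuation_per_mm = 1.0,
                           phase_noise_sd = 0.15,
                           longitudinal_jelly_modulation = FALSE,
                           seed = 1L) {
  cfg <- list(
    tube_length_um = tube_length_um, n_planes = as.integer(n_planes),
    frame_rate_hz = frame_rate_hz, period_s = period_s,
    n_cycles = as.integer(n_cycles), pixel_pitch_um = pixel_pitch_um,
    img_px = as.integer(img_px),
    r_inner_max_mm = rep_len(r_inner_max_mm, n_planes),
    r_inner_min_mm = rep_len(r_inner_min_mm, n_planes),
    wall_thickness_mm = rep_len(wall_thickness_mm, n_planes),
    cushion_spiral_rate_deg_um = cushion_spiral_rate_deg_um,
    peristaltic_wave_speed_um_s = peristaltic_wave_speed_um_s,
    closure_fraction = closure_fraction,
    open_phase_center = open_phase_center,
    lumen_axis_ratio = lumen_axis_ratio,
    d_min_mm = d_min_mm, endo_slit_mm = endo_slit_mm,
    p_vent_peak_pa = p_vent_peak_pa, p_as_peak_pa = p_as_peak_pa,
    doppler_angle_deg = rep_len(doppler_angle_deg, n_planes),
    q_peak_mm3_s = q_peak_mm3_s,
    speckle_contrast = speckle_contrast,
    attenuation_per_mm = attenuation_per_mm,
    phase_noise_sd = phase_noise_sd,
    longitudinal_jelly_modulation = isTRUE(longitudinal_jelly_modulation),
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(
    cfg$tube_length_um > 0, cfg$n_planes >= 1, cfg$frame_rate_hz > 0,
    cfg$period_s > 0, cfg$n_cycles >= 1, cfg$pixel_pitch_um > 0,
    cfg$img_px >= 16,
    all(cfg$r_inner_max_mm > 0), all(cfg$r_inner_min_mm > 0),
    all(cfg$wall_thickness_mm > 0),
    cfg$peristaltic_wave_speed_um_s > 0,
    cfg$closure_fraction > 0, cfg$closure_fraction < 1,
    cfg$lumen_axis_ratio > 0, cfg$lumen_axis_ratio <= 1,
    cfg$d_min_mm >= 0, cfg$endo_slit_mm >= 0,
    cfg$speckle_contrast >= 0, cfg$phase_noise_sd >= 0
  )
  if (any(diff(cfg$r_inner_max_mm) > 1e-12)) {
    stop("r_inner_max_mm must be monotonically non-increasing proximal to distal",
         call. = FALSE)
  }
  if (any(cfg$r_inner_min_mm >= cfg$r_inner_max_mm)) {
    stop("r_inner_min_mm must be smaller than r_inner_max_mm at every plane",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  tube %g um, %d planes, T = %g s at %g fps x %d cycles\n",
              x$tube_length_um, x$n_planes, x$period_s, x$frame_rate_hz,
              x$n_cycles))
  cat(sprintf("  inner radius %.2f -> %.2f mm (expanded), wall %.0f -> %.0f um\n",
              x$r_inner_max_mm[1], x$r_inner_max_mm[x$n_planes],
              1000 * x$wall_thickness_mm[1],
              1000 * x$wall_thickness_mm[x$n_planes]))
  cat(sprintf("  closure fraction %.2f, spiral %.2f deg/um, seed %d\n",
              x$closure_fraction, x$cushion_spiral_rate_deg_um, x$seed))
  invisible(x)
}

#' Axial positions of the analysis planes
#'
#' Planes are evenly spaced along the tube, plane 1 at the proximal inlet
#' (z = 0) and the last plane at the distal outlet.
#'
#' @param config A [phantom_config()].
#' @return Numeric vector of z positions (um), length `n_planes`.
#' @export
plane_positions_um <- function(config) {
  seq(0, config$tube_length_um, length.out = config$n_planes)
}
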