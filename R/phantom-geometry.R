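#' @keywords internal
#' Cycle phase at axial position z and time t.
#' The peristaltic wave delays the activation at depth z by z / wave_speed
#' seconds, so closure onset travels proximal -> distal at the wave speed.
phantom_phase <- function(config, z_um, t_s, start_phase = 0) {
  ((t_s - z_um / config$peristaltic_wave_speed_um_s) / config$period_s +
     start_phase) %% 1
}

# Smooth myocardial expansion factor in [0, 1]: raised cosine peaking at the
# open-phase center. The myocardium never fully stops moving (no flat closed
# plateau) -- only the cushions produce the closure plateau.
phantom_expansion <- function(config, phase) {
  (1 + cos(2 * pi * (phase - config$open_phase_center))) / 2
}

# Lumen opening factor in [0, 1]: the raised cosine clipped below the
# cushion-contact level, so the lumen is exactly closed on a contiguous
# interval occupying `closure_fraction` of the cycle.
phantom_opening <- function(config, phase) {
  c0 <- cos(pi * (1 - config$closure_fraction))
  raw <- cos(2 * pi * (phase - config$open_phase_center))
  pmax(0, (raw - c0) / (1 - c0))
}

# Per-plane parameter interpolated to arbitrary z (linear between planes).
plane_interp <- function(config, values, z_um) {
  zp <- plane_positions_um(config)
  if (length(zp) == 1L) return(rep_len(values, length(z_um)))
  stats::approx(zp, values, xout = z_um, rule = 2)$y
}

#' Ground-truth cross-section geometry of the phantom
#'
#' Analytic description of one tube cross-section at axial position `z_um`
#' and time `t_s`: inner/outer myocardial radii, the lumen ellipse left open
#' between the two apposing cardiac-jelly cushions, and the cushion
#' orientation (which spirals along the tube). The lumen ellipse is the inner
#' myocardial circle minus the two opposing jelly lobes: its major semi-axis
#' runs along the inter-cushion direction (`r_inner - d_min`), its minor
#' semi-axis collapses to zero while the cushions are in contact. Closure
#' onset is delayed linearly in z (peristalsis).
#'
#' @param config A [phantom_config()].
#' @param z_um Axial position(s), 0..tube_length (um).
#' @param t_s Time(s) (s). `z_um` and `t_s` are recycled to common length.
#' @param start_phase Cycle phase (0..1) at `t_s = 0`, `z_um = 0`.
#' @return A tibble with one row per (z, t): `z_um`, `t_s`, `phase`,
#'   `r_inner_mm`, `r_outer_mm`, lumen semi-axes `a_mm >= b_mm` (mm; `b_mm` is
#'   0 when closed), rendered endocardial slit semi-axis `b_render_mm`,
#'   cushion `orientation_rad`, lumen area `area_lumen_mm2`, and `open`.
#' @examples
#' geom <- oft_cross_section(phantom_config(), z_um = 0, t_s = 0.25)
#' geom$a_mm / max(geom$b_mm, 1e-9)
#' @export
oft_cross_section <- function(config, z_um, t_s, start_phase = 0) {
  stopifnot(inherits(config, "phantom_config"))
  if (any(z_um < 0 | z_um > config$tube_length_um)) {
    stop("z_um outside [0, tube_length_um]", call. = FALSE)
  }
  n <- max(length(z_um), length(t_s))
  z_um <- rep_len(z_um, n); t_s <- rep_len(t_s, n)

  phase <- phantom_phase(config, z_um, t_s, start_phase)
  e <- phantom_expansion(config, phase)
  w <- phantom_opening(config, phase)

  r_min <- plane_interp(config, config$r_inner_min_mm, z_um)
  r_max <- plane_interp(config, config$r_inner_max_mm, z_um)
  h <- plane_interp(config, config$wall_thickness_mm, z_um)

  r_inner <- r_min + (r_max - r_min) * e
  r_outer <- r_inner + h
  # optional longitudinal-stretch surrogate: the incompressible jelly
  # redistributes along the ~20% stretched tube at full expansion, thinning
  # every jelly layer in cross-section by up to that fraction (in phase
  # with expansion); closure geometry is unaffected (e ~ 0 there)
  mod <- if (config$longitudinal_jelly_modulation) 0.2 * e * w else 0
  a <- r_inner - config$d_min_mm * (1 - mod)
  b_open <- config$lumen_axis_ratio * (r_max - config$d_min_mm)
  b <- b_open * w + mod * (r_inner - b_open * w)
  b <- pmin(b, a)
  b_render <- pmax(b, config$endo_slit_mm / 2)
  orientation <- config$cushion_spiral_rate_deg_um * z_um * pi / 180

  tibble::tibble(
    z_um = z_um, t_s = t_s, phase = phase,
    r_inner_mm = r_inner, r_outer_mm = r_outer,
    a_mm = a, b_mm = b, b_render_mm = b_render,
    orientation_rad = orientation,
    area_lumen_mm2 = pi * a * b,
    open = w > 0
  )
}

#' Lumen closure onset time at an axial position
#'
#' First time (>= 0) within a cycle at which the lumen at `z_um` closes;
#' increases with z by `z / peristaltic_wave_speed`.
#'
#' @inheritParams oft_cross_section
#' @return Closure onset time(s) in seconds.
#' @export
closure_onset_time <- function(config, z_um, start_phase = 0) {
  # closure begins when the opening factor first returns to 0:
  # phase = open_phase_center + (1 - closure_fraction) / 2
  ph_close <- (config$open_phase_center + (1 - config$closure_fraction) / 2) %% 1
  t_inlet <- ((ph_close - start_phase) %% 1) * config$period_s
  t_inlet + z_um / config$peristaltic_wave_speed_um_s
}

#' Ground-truth flow in the phantom lumen
#'
#' Inlet flow is a smooth pulse supported on the inlet's open interval; flow
#' at depth z follows from exact mass conservation with the moving wall,
#' `Q(z,t) = Q0(t) - integral_0^z dA/dt dz'`. While the proximal lumen is
#' closed and the distal part still contracts, the formula automatically
#' yields the peristaltic squeeze-out (closed sections have dA/dt = 0).
#' Centerline velocity assumes the parabolic-type elliptical-duct profile,
#' `U0 = 2 Q / (pi a b)`.
#'
#' @inheritParams oft_cross_section
#' @return A tibble with `z_um`, `t_s`, `q_mm3_s`, `u0_mm_s` (NA when the
#'   lumen is closed), and the lumen semi-axes.
#' @export
true_flow <- function(config, z_um, t_s, start_phase = 0) {
  n <- max(length(z_um), length(t_s))
  z_um <- rep_len(z_um, n); t_s <- rep_len(t_s, n)
  geo <- oft_cross_section(config, z_um, t_s, start_phase)
  q0 <- inlet_flow(config, t_s, start_phase)

  # cumulative wall-motion source: Simpson quadrature of dA/dt over [0, z]
  q <- vapply(seq_len(n), function(i) {
    q0[i] - integrate_dadt(config, z_um[i], t_s[i], start_phase)
  }, numeric(1))
  u0 <- ifelse(geo$open, 2 * q / (pi * geo$a_mm * pmax(geo$b_mm, 1e-9)), NA_real_)
  tibble::tibble(z_um = z_um, t_s = t_s, q_mm3_s = q, u0_mm_s = u0,
                 a_mm = geo$a_mm, b_mm = geo$b_mm)
}

#' Ground-truth inlet volume flow rate
#'
#' A squared-sine pulse over the inlet's open interval (phase
#' `open_phase_center` +/- half the open fraction), peaking at
#' `q_peak_mm3_s`; zero while the inlet lumen is closed.
#'
#' @inheritParams oft_cross_section
#' @return Flow rate(s), mm^3/s.
#' @export
inlet_flow <- function(config, t_s, start_phase = 0) {
  phase <- phantom_phase(config, 0, t_s, start_phase)
  f_open <- 1 - config$closure_fraction
  x <- (phase - (config$open_phase_center - f_open / 2)) / f_open
  ifelse(x > 0 & x < 1, config$q_peak_mm3_s * sin(pi * x)^2, 0)
}

# d(lumen area)/dt at (z, t), central difference (analytic-grade accuracy
# with dt = 1e-4 s against the smooth area function).
phantom_dadt <- function(config, z_um, t_s, start_phase, dt = 1e-4) {
  a2 <- oft_cross_section(config, z_um, t_s + dt, start_phase)$area_lumen_mm2
  a1 <- oft_cross_section(config, z_um, t_s - dt, start_phase)$area_lumen_mm2
  (a2 - a1) / (2 * dt)
}

# Simpson integral of dA/dt over z' in [0, z] (mm^3/s; z in um -> mm factor).
integrate_dadt <- function(config, z_um, t_s, start_phase, n_sub = 50) {
  if (z_um <= 0) return(0)
  zz <- seq(0, z_um, length.out = 2 * n_sub + 1)
  fz <- phantom_dadt(config, zz, t_s, start_phase)
  simpson_composite(fz, zz[2] - zz[1]) * 1e-3 # um -> mm
}

# Composite Simpson rule on a uniform grid with an odd number of points.
simpson_composite <- function(f, h) {
  n <- length(f)
  stopifnot(n >= 3, n %% 2 == 1)
  idx <- seq_len(n)
  w <- ifelse(idx %% 2 == 0, 4, 2)
  w[1] <- 1; w[n] <- 1
  h / 3 * sum(w * f)
}
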