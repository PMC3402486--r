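#' Fit per-phase lumen ellipses from segmented contours
#'
#' Least-squares ellipse per (plane, frame) endocardium contour, with the
#' relative area mismatch between the fitted ellipse (`pi a b`) and the
#' polygon area. Contours whose fitted minor semi-axis falls below
#' `b_floor_mm` are flagged closed and regularized at the floor.
#'
#' @param contours Tidy contour tibble (label `endo`), in mm.
#' @param b_floor_mm Minor-axis floor regularizing closed lumens (mm).
#' @return Tibble with `plane`, `frame`, `a_mm`, `b_mm`, `angle_rad`,
#'   `center_x_mm`, `center_y_mm`, `area_err`, `closed`.
#' @export
fit_ellipse_series <- function(contours, b_floor_mm = 1e-3) {
  endo <- dplyr::filter(contours, .data$label == "endo")
  if (nrow(endo) == 0) endo <- contours
  dplyr::reframe(
    dplyr::group_by(endo, .data$plane, .data$frame),
    {
      ap <- abs(polygon_area(.data$x_mm, .data$y_mm))
      f <- tryCatch(fit_ellipse(.data$x_mm, .data$y_mm), error = function(e) NULL)
      if (is.null(f)) {
        f <- list(a = max(stats::dist(cbind(.data$x_mm, .data$y_mm))) / 2,
                  b = b_floor_mm, center = c(mean(.data$x_mm), mean(.data$y_mm)),
                  angle = 0)
      }
      closed <- f$b <= b_floor_mm
      b <- max(f$b, b_floor_mm)
      tibble::tibble(a_mm = f$a, b_mm = b, angle_rad = f$angle,
                     center_x_mm = f$center[1], center_y_mm = f$center[2],
                     area_err = if (ap > 0) abs(pi * f$a * b - ap) / ap else NA_real_,
                     closed = closed)
    }
  )
}

#' Reduced-order lumen model of the outflow tract
#'
#' The lumen is a tapered elliptical duct: semi-axes `a(z, t) >= b(z, t)`
#' known at the analysis-plane stations and interpolated along z with a
#' shape-preserving piecewise-cubic (monotone where the data are monotone, so
#' interpolation cannot overshoot into negative axes). Time runs over a
#' simulated window of the cycle (default 0.43 T to 0.93 T; flow outside it
#' is negligible because the lumen is closed) discretized in `n_steps`
#' uniform steps. Blood is Newtonian with viscosity `mu`.
#'
#' @param ellipses Tibble with `plane`, `frame`, `a_mm`, `b_mm` (and
#'   optionally `angle_rad`) on a uniform full-cycle phase grid, as from
#'   [fit_ellipse_series()] or ground truth.
#' @param z_stations_mm Axial position of each plane (mm), ascending.
#' @param period_s Cardiac period T (s).
#' @param mu_pa_s Dynamic viscosity (Pa s), default 3e-3.
#' @param window Simulated window as fractions of T (default `c(0.43, 0.93)`).
#' @param n_steps Number of time steps across the window (default 200).
#' @param n_z Number of axial grid points (odd; default 101).
#' @param b_floor_mm Minor-axis regularization floor (mm).
#' @param closed_mm Minor semi-axis below which a section is treated as
#'   closed (mm). Default 0.012: at the scale of the apposed endocardial
#'   layers (~9 um half-width) the walls are in contact and there is no
#'   through-flow, even though the segmented slit has nonzero area.
#' @return An `oft_lumen_model` list with the discretized axes `a`, `b`
#'   (matrices time x z), grids `t_frac`, `z_mm`, the orientation
#'   interpolant, and the physical constants.
#' @export
lumen_model <- function(ellipses, z_stations_mm, period_s = 0.37,
                        mu_pa_s = 3e-3, window = c(0.43, 0.93),
                        n_steps = 200, n_z = 101, b_floor_mm = 1e-3,
                        closed_mm = 0.012) {
  stopifnot(length(window) == 2, window[2] > window[1], n_z %% 2 == 1)
  planes <- sort(unique(ellipses$plane))
  stopifnot(length(planes) == length(z_stations_mm))
  n_phases <- length(unique(ellipses$frame))

  t_frac <- seq(window[1], window[2], length.out = n_steps + 1)
  z_mm <- seq(z_stations_mm[1], z_stations_mm[length(z_stations_mm)],
              length.out = n_z)

  # per-plane periodic interpolation in time (cubic spline over replicated
  # periods, so dA/dt is smooth and the solver's time derivative converges),
  # then monotone cubic along z
  station_at <- function(var, tf) {
    vapply(planes, function(pl) {
      e <- dplyr::arrange(dplyr::filter(ellipses, .data$plane == pl), .data$frame)
      v <- e[[var]]
      phg <- (e$frame - 1) / n_phases
      f <- stats::splinefun(c(phg - 1, phg, phg + 1), rep(v, 3), method = "fmm")
      pmax(f(tf %% 1), 0)
    }, numeric(length(tf)))
  }
  a_st <- station_at("a_mm", t_frac) # (time x station)
  b_st <- station_at("b_mm", t_frac)

  interp_z <- function(vals_row) {
    if (length(z_stations_mm) >= 3) {
      stats::splinefun(z_stations_mm, vals_row, method = "monoH.FC")(z_mm)
    } else {
      stats::approx(z_stations_mm, vals_row, xout = z_mm)$y
    }
  }
  a <- t(apply(a_st, 1, interp_z))
  b <- t(apply(b_st, 1, interp_z))
  b <- pmax(b, 0)

  orientation <- if ("angle_rad" %in% names(ellipses)) {
    med <- dplyr::summarise(dplyr::group_by(ellipses, .data$plane),
                            ang = stats::median(.data$angle_rad),
                            .groups = "drop")
    ang <- unwrap_phase(2 * med$ang) / 2 # axis angles are pi-periodic
    stats::approxfun(z_stations_mm, ang, rule = 2)
  } else {
    function(z) rep(0, length(z))
  }

  structure(
    list(a = a, b = b, t_frac = t_frac, z_mm = z_mm,
         z_stations_mm = z_stations_mm, period_s = period_s,
         mu_pa_s = mu_pa_s, window = window, n_steps = as.integer(n_steps),
         b_floor_mm = b_floor_mm, closed_mm = closed_mm,
         orientation = orientation),
    class = "oft_lumen_model"
  )
}

#' Solve quasi-steady flow in the moving elliptical duct
#'
#' At every time step the volume flow rate satisfies exact mass conservation
#' with the moving wall, `Q(z, t) = Q0(t) - int_0^z dA/dt dz'`, and the inlet
#' flow `Q0(t)` solves the scalar linear equation
#' `dP(t) = int_0^L R_hyd(z, t) Q(z, t) dz` with the elliptical-duct
#' resistance density `R_hyd = 4 mu (a^2 + b^2) / (pi a^3 b^3)`. Inertia is
#' neglected (quasi-steady; the cardiac outflow tract operates at Reynolds
#' number of order 5). Axial integrals use composite Simpson; `dA/dt` uses
#' centered differences on the time grid. Whenever the lumen is closed
#' (b at or below the floor) anywhere along the duct, through-flow at that
#' step is forced to zero (with one warning per solve).
#'
#' @param model An [lumen_model()].
#' @param dp_pa Driving pressure drop inlet minus outlet (Pa): numeric
#'   vector on the model time grid, or a function of `t_frac`.
#' @param inertial_rho Optional blood density (kg/m^3) enabling a
#'   first-order inertial correction: after the quasi-steady pass, the
#'   acceleration pressure `rho dQ0/dt int dz/A` is subtracted from the
#'   driving pressure and the solve repeated once. `NULL` (default)
#'   disables it; at the Reynolds numbers of the embryonic outflow tract
#'   the correction is small.
#' @return An `oft_flow` object: matrices (time x z) `q_mm3_s`, `u0_mm_s`,
#'   `area_mm2`, `dadt_mm2_s`, vectors `t_frac`, `z_mm`, `q0_mm3_s`,
#'   `dp_pa`, `closed` (per step), and the model.
#' @export
solve_flow <- function(model, dp_pa, inertial_rho = NULL) {
  tf <- model$t_frac
  if (is.function(dp_pa)) dp_pa <- dp_pa(tf)
  stopifnot(length(dp_pa) == length(tf))
  nt <- length(tf); nz <- length(model$z_mm)
  dt <- diff(tf[1:2]) * model$period_s
  dz_m <- diff(model$z_mm[1:2]) * 1e-3

  a_m <- model$a * 1e-3; b_m <- model$b * 1e-3
  A_m2 <- pi * a_m * b_m
  # centered dA/dt, one-sided at the window ends
  dadt <- A_m2
  dadt[2:(nt - 1), ] <- (A_m2[3:nt, ] - A_m2[1:(nt - 2), ]) / (2 * dt)
  # second-order one-sided differences at the window ends
  dadt[1, ] <- (-3 * A_m2[1, ] + 4 * A_m2[2, ] - A_m2[3, ]) / (2 * dt)
  dadt[nt, ] <- (3 * A_m2[nt, ] - 4 * A_m2[nt - 1, ] + A_m2[nt - 2, ]) / (2 * dt)

  closed_any <- apply(model$b, 1, function(bb) any(bb <= model$closed_mm))
  if (any(closed_any)) {
    warning(sprintf("lumen closed during %d of %d steps: through-flow forced to zero there",
                    sum(closed_any), nt))
  }

  solve_pass <- function(dp_eff) {
    q <- matrix(0, nt, nz)
    q0 <- numeric(nt)
    for (k in seq_len(nt)) {
      if (closed_any[k]) next
      rh <- 4 * model$mu_pa_s * (a_m[k, ]^2 + b_m[k, ]^2) /
        (pi * a_m[k, ]^3 * b_m[k, ]^3)
      if (any(!is.finite(rh))) stop("non-finite hydraulic resistance", call. = FALSE)
      # cumulative wall-motion source S(z) = int_0^z dA/dt dz' (trapezoid)
      s_src <- c(0, cumsum((dadt[k, -1] + dadt[k, -nz]) / 2 * dz_m))
      denom <- simpson_composite(rh, dz_m)
      numer <- dp_eff[k] + simpson_composite(rh * s_src, dz_m)
      q0[k] <- numer / denom
      q[k, ] <- q0[k] - s_src
    }
    list(q = q, q0 = q0)
  }
  pass <- solve_pass(dp_pa)
  if (!is.null(inertial_rho)) {
    # one Picard iteration: subtract the acceleration pressure of the
    # first-pass flow and re-solve
    dq0dt <- c(0, diff(pass$q0) / dt) # m^3/s^2
    inert <- vapply(seq_len(nt), function(k) {
      if (closed_any[k]) return(0)
      inertial_rho * dq0dt[k] * simpson_composite(1 / A_m2[k, ], dz_m)
    }, numeric(1))
    pass <- solve_pass(dp_pa - inert)
  }
  q <- pass$q; q0 <- pass$q0
  u0 <- 2 * (q / A_m2) # m/s
  structure(
    list(q_mm3_s = q * 1e9, q0_mm3_s = q0 * 1e9, u0_mm_s = u0 * 1e3,
         area_mm2 = A_m2 * 1e6, dadt_mm2_s = dadt * 1e6,
         t_frac = tf, z_mm = model$z_mm, dp_pa = dp_pa,
         closed = closed_any, model = model),
    class = "oft_flow"
  )
}

#' @export
print.oft_flow <- function(x, ...) {
  cat(sprintf("<oft_flow> %d steps x %d axial points, window %.2f-%.2f T\n",
              length(x$t_frac), length(x$z_mm), min(x$t_frac), max(x$t_frac)))
  cat(sprintf("  peak |Q| = %.3g mm^3/s, peak |U0| = %.3g mm/s\n",
              max(abs(x$q_mm3_s)), max(abs(x$u0_mm_s), na.rm = TRUE)))
  invisible(x)
}

#' Discrete mass-conservation residual of a flow solution
#'
#' Maximum over time of the axially integrated magnitude of
#' `dA/dt + dQ/dz`, relative to the peak flow, evaluated with the solver's
#' own discrete operators (trapezoid-consistent flux differences).
#'
#' @param sol An `oft_flow` from [solve_flow()].
#' @return Relative residual (dimensionless).
#' @export
mass_residual <- function(sol) {
  nz <- length(sol$z_mm)
  dz <- diff(sol$z_mm[1:2]) # mm
  qmax <- max(abs(sol$q_mm3_s))
  if (qmax == 0) return(0)
  open <- which(!sol$closed)
  if (length(open) == 0) return(0)
  res <- vapply(open, function(k) {
    dqdz <- diff(sol$q_mm3_s[k, ]) / dz # at midpoints
    dadt_mid <- (sol$dadt_mm2_s[k, -1] + sol$dadt_mm2_s[k, -nz]) / 2
    sum(abs(dadt_mid + dqdz)) * dz
  }, numeric(1))
  max(res) / qmax
}

#' Wall shear stress on the elliptical lumen wall
#'
#' With the elliptical-duct axial profile
#' `u = U0 (1 - x^2/a^2 - y^2/b^2)`, the wall shear stress at boundary
#' parameter `s` (wall point `(a cos s, b sin s)`) is
#' `tau = 2 mu U0 sqrt(cos^2 s / a^2 + sin^2 s / b^2)`: maximal at the minor
#' axis ends (`s = +/- pi/2`), i.e. on the cushion surfaces, and equal to the
#' Poiseuille value `4 mu Q / (pi R^3)` for a circular section.
#'
#' @param sol An `oft_flow`.
#' @param n_s Number of boundary parameter samples (default 36).
#' @param z_index,t_index Optional index subsets to thin the output.
#' @return Tibble with `t_frac`, `z_mm`, `s_rad` (ellipse parameter measured
#'   from the major axis), `angle_global_rad` (s plus the local cushion
#'   orientation), `tau_pa` (`NA` where the lumen is closed).
#' @export
wss_field <- function(sol, n_s = 36, z_index = NULL, t_index = NULL) {
  model <- sol$model
  if (is.null(z_index)) z_index <- seq(1, length(sol$z_mm), length.out = min(21, length(sol$z_mm)))
  if (is.null(t_index)) t_index <- seq_along(sol$t_frac)
  z_index <- unique(round(z_index))
  s <- seq(0, 2 * pi, length.out = n_s + 1)[-(n_s + 1)]
  mu <- model$mu_pa_s
  ori <- model$orientation(sol$z_mm[z_index])

  purrr::map_dfr(t_index, function(k) {
    a_m <- model$a[k, z_index] * 1e-3
    b_m <- model$b[k, z_index] * 1e-3
    u0 <- sol$u0_mm_s[k, z_index] * 1e-3
    open <- !sol$closed[k] & model$b[k, z_index] > model$closed_mm
    tau <- outer(seq_along(z_index), seq_along(s), function(i, j) {
      2 * mu * abs(u0[i]) * sqrt(cos(s[j])^2 / a_m[i]^2 + sin(s[j])^2 / b_m[i]^2)
    })
    tau[!open, ] <- NA_real_
    tibble::tibble(
      t_frac = sol$t_frac[k],
      z_mm = rep(sol$z_mm[z_index], times = length(s)),
      s_rad = rep(s, each = length(z_index)),
      angle_global_rad = rep(s, each = length(z_index)) + rep(ori, times = length(s)),
      tau_pa = as.vector(tau)
    )
  })
}

#' Summary of a flow solution
#'
#' Peak centerline velocity and its (z, t) location, peak wall shear stress
#' and its (z, s, t) location, and the (z, s) map of wall shear stress at
#' the instant of peak flow (which traces the cushion-following spiral when
#' the lumen orientation spirals along the tract).
#'
#' Peak statistics exclude the first and last `trim` fraction of the
#' simulated window: in the quasi-steady reduction the opening and closing
#' transients (lumen barely open, wall-motion squeeze through near-contact
#' sections) are not reliable, so peaks there would reflect the model's
#' regularization rather than the flow.
#'
#' @param sol An `oft_flow`.
#' @param n_s Boundary samples for the WSS map.
#' @param trim Fraction of the window trimmed at each end for the peak
#'   statistics (default 0.1).
#' @return List with `peak_u0_mm_s`, `peak_u0_z_mm`, `peak_u0_t_frac`,
#'   `peak_tau_pa`, `peak_tau_z_mm`, `peak_tau_s_rad`, `peak_tau_t_frac`,
#'   and `wss_map` (tibble at the peak-flow instant).
#' @export
flow_summary <- function(sol, n_s = 36, trim = 0.1) {
  tf <- sol$t_frac
  span <- diff(range(tf))
  keep <- which(tf >= min(tf) + trim * span & tf <= max(tf) - trim * span)
  u_keep <- abs(sol$u0_mm_s[keep, , drop = FALSE])
  iu <- which(u_keep == max(u_keep, na.rm = TRUE), arr.ind = TRUE)[1, ]
  wss <- wss_field(sol, n_s = n_s, t_index = keep)
  it <- which.max(abs(sol$q0_mm3_s))
  wmax <- wss[which.max(wss$tau_pa), ]
  list(
    peak_u0_mm_s = sol$u0_mm_s[keep[iu[1]], iu[2]],
    peak_u0_z_mm = sol$z_mm[iu[2]],
    peak_u0_t_frac = tf[keep[iu[1]]],
    peak_tau_pa = wmax$tau_pa,
    peak_tau_z_mm = wmax$z_mm,
    peak_tau_s_rad = wmax$s_rad,
    peak_tau_t_frac = wmax$t_frac,
    wss_map = wss_field(sol, n_s = n_s, t_index = it)
  )
}

#' Compare modeled centerline velocity with a Doppler series
#'
#' Aligns the model's centerline velocity at one plane with a Doppler
#' velocity series on the cycle-phase axis and reports the relative RMS
#' residual over the open-lumen window, excluding masked and wrap-plateau
#' samples.
#'
#' @param sol An `oft_flow`.
#' @param vel Tibble from [centerline_velocity_series()] with a
#'   `phase_frac` column (cycle phase of each sample).
#' @param z_mm Axial position of the Doppler plane (mm).
#' @return List with `rel_rms` (residual relative to the peak model
#'   velocity), `n_used`, and the aligned tibble.
#' @export
compare_with_doppler <- function(sol, vel, z_mm) {
  iz <- which.min(abs(sol$z_mm - z_mm))
  u_model <- stats::approx(sol$t_frac, sol$u0_mm_s[, iz], xout = vel$phase_frac)$y
  ok <- !vel$masked & !vel$plateau & is.finite(u_model) & is.finite(vel$v_mm_s)
  if (!any(ok)) stop("no overlapping open-lumen samples", call. = FALSE)
  scale <- max(abs(u_model[ok]))
  if (scale < 1e-9) { # numerically zero model flow (mm/s)
    rel <- if (all(abs(vel$v_mm_s[ok]) < 1e-9)) 0 else Inf
  } else {
    rel <- sqrt(mean((vel$v_mm_s[ok] - u_model[ok])^2)) / scale
  }
  list(rel_rms = rel, n_used = sum(ok),
       aligned = tibble::tibble(phase_frac = vel$phase_frac[ok],
                                v_doppler_mm_s = vel$v_mm_s[ok],
                                v_model_mm_s = u_model[ok]))
}
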