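# analytic ellipse series on a uniform phase grid
ellipse_series <- function(n_ph, planes, a_fun, b_fun, ang_fun = function(pl) 0) {
  dplyr::bind_rows(lapply(planes, function(pl) {
    tibble::tibble(plane = pl, frame = seq_len(n_ph),
                   a_mm = a_fun(pl, seq_len(n_ph)),
                   b_mm = b_fun(pl, seq_len(n_ph)),
                   angle_rad = ang_fun(pl))
  }))
}

rigid_model <- function(a, b, n_ph = 8, L = 0.6, planes = 1:3, ...) {
  ell <- ellipse_series(n_ph, planes,
                        function(pl, f) rep(a, length(f)),
                        function(pl, f) rep(b, length(f)))
  lumen_model(ell, seq(0, L, length.out = length(planes)),
              window = c(0.4, 0.9), n_steps = 40, ...)
}

test_that("ellipse-series fitting recovers polygon lumens", {
  s <- seq(0, 2 * pi, length.out = 65)[-65]
  ct <- dplyr::bind_rows(
    contour_tbl(0.2 * cos(s), 0.12 * sin(s), 1, 1, "endo"),
    contour_tbl(0.15 * cos(s), 0.15 * sin(s), 1, 2, "endo")
  )
  es <- fit_ellipse_series(ct)
  expect_equal(es$a_mm[1], 0.2, tolerance = 1e-3)
  expect_equal(es$b_mm[1], 0.12, tolerance = 1e-3)
  expect_equal(es$a_mm[2] / es$b_mm[2], 1, tolerance = 1e-6) # circle
  expect_true(all(es$area_err < 0.005))
  expect_false(any(es$closed))
})

test_that("rigid ducts reproduce the Poiseuille closed forms", {
  mu <- 3e-3; dp <- 10; L <- 0.6e-3 # m
  # circular tube
  R <- 0.15e-3
  m <- rigid_model(0.15, 0.15)
  sol <- solve_flow(m, function(tf) rep(dp, length(tf)))
  q_exact <- pi * R^4 * dp / (8 * mu * L) * 1e9 # mm^3/s
  expect_equal(max(abs(sol$q_mm3_s - q_exact) / q_exact), 0, tolerance = 1e-3)

  # elliptical duct
  a <- 0.2e-3; b <- 0.1e-3
  m2 <- rigid_model(0.2, 0.1)
  sol2 <- solve_flow(m2, function(tf) rep(dp, length(tf)))
  q_ell <- pi * a^3 * b^3 * dp / (4 * mu * (a^2 + b^2) * L) * 1e9
  expect_equal(max(abs(sol2$q_mm3_s - q_ell) / q_ell), 0, tolerance = 1e-3)

  # rigid geometry conserves mass to machine precision
  expect_lt(mass_residual(sol2), 1e-12)
})

test_that("moving walls conserve mass and match a refined re-solve", {
  n_ph <- 48
  breathing <- function(pl, f) {
    0.16 - 0.02 * (pl - 1) + 0.04 * sin(2 * pi * (f - 1) / n_ph)
  }
  ell <- ellipse_series(n_ph, 1:3, breathing,
                        function(pl, f) 0.9 * breathing(pl, f))
  mk <- function(n_steps, n_z) {
    lumen_model(ell, c(0, 0.3, 0.6), window = c(0.1, 0.6),
                n_steps = n_steps, n_z = n_z)
  }
  sol <- solve_flow(mk(60, 101), function(tf) rep(0, length(tf)))
  expect_lt(mass_residual(sol), 1e-6)

  # with dP = 0, the inlet flow balances the resistance-weighted wall
  # source; a dense-grid re-solve (10x axial resolution) agrees
  sol_dense <- solve_flow(mk(60, 1001), function(tf) rep(0, length(tf)))
  scale <- max(abs(sol_dense$q0_mm3_s))
  expect_lt(max(abs(sol$q0_mm3_s - sol_dense$q0_mm3_s)) / scale, 1e-3)

  # grid convergence: halving both steps changes peak velocity < 1%
  # (compared at the coincident grid points, so the statistic measures the
  # solver, not the sampling of the continuous profile)
  sol_half <- solve_flow(mk(120, 201), function(tf) rep(0, length(tf)))
  u1 <- max(abs(sol$u0_mm_s))
  u2 <- max(abs(sol_half$u0_mm_s[seq(1, 121, by = 2), seq(1, 201, by = 2)]))
  expect_lt(abs(u1 - u2) / u2, 0.01)
})

test_that("wall shear stress has the elliptical-duct structure", {
  mu <- 3e-3; dp <- 10
  # circular: uniform WSS equal to 4 mu Q / (pi R^3)
  m <- rigid_model(0.15, 0.15)
  sol <- solve_flow(m, function(tf) rep(dp, length(tf)))
  wss <- wss_field(sol, n_s = 16, t_index = 1)
  q_si <- sol$q_mm3_s[1, 1] * 1e-9
  tau_exact <- 4 * mu * q_si / (pi * (0.15e-3)^3)
  expect_equal(max(abs(wss$tau_pa - tau_exact) / tau_exact), 0, tolerance = 1e-3)

  # a = 2b: minor-end WSS is twice the major-end WSS
  m2 <- rigid_model(0.2, 0.1)
  sol2 <- solve_flow(m2, function(tf) rep(dp, length(tf)))
  wss2 <- wss_field(sol2, n_s = 4, t_index = 1) # s = 0, pi/2, pi, 3pi/2
  z1 <- wss2[wss2$z_mm == wss2$z_mm[1], ]
  tau_major <- z1$tau_pa[z1$s_rad == 0]
  tau_minor <- z1$tau_pa[abs(z1$s_rad - pi / 2) < 1e-9]
  expect_equal(tau_minor / tau_major, 2, tolerance = 1e-9)

  # no flow, no shear
  sol0 <- solve_flow(m2, function(tf) rep(0, length(tf)))
  wss0 <- wss_field(sol0, n_s = 8, t_index = 1)
  expect_equal(max(wss0$tau_pa), 0, tolerance = 1e-12)
})

test_that("WSS maxima sit on the cushion surfaces and trace the spiral", {
  # ground-truth geometry from the phantom, with spiraling orientation
  cfg <- phantom_config()
  n_ph <- 48
  zp <- plane_positions_um(cfg)
  tt <- (seq_len(n_ph) - 1) / n_ph * cfg$period_s
  ell <- dplyr::bind_rows(lapply(seq_along(zp), function(p) {
    g <- oft_cross_section(cfg, zp[p], tt)
    tibble::tibble(plane = p, frame = seq_len(n_ph), a_mm = g$a_mm,
                   b_mm = pmax(g$b_mm, 1e-3),
                   angle_rad = g$orientation_rad[1])
  }))
  model <- lumen_model(ell, zp / 1000, window = c(0.5, 0.88), n_steps = 60)
  dp <- function(tf) 16 * sin(pi * (tf - 0.44) / 0.48)^2
  sol <- solve_flow(model, dp)
  expect_false(any(sol$closed))
  wss <- wss_field(sol, n_s = 72)

  # at every open (z, t): argmax over s at the minor-axis ends (+/- pi/2)
  by_zt <- dplyr::group_by(wss, .data$t_frac, .data$z_mm)
  top <- dplyr::slice_max(by_zt, .data$tau_pa, n = 1, with_ties = FALSE)
  dist_minor <- pmin(abs(top$s_rad - pi / 2), abs(top$s_rad - 3 * pi / 2))
  expect_lt(max(dist_minor), 2 * pi / 72 + 1e-9)

  # the high-WSS ridge in the (z, global angle) map climbs at the spiral rate
  it <- which.min(abs(sol$t_frac - 0.68))
  map1 <- wss_field(sol, n_s = 144, t_index = it,
                    z_index = seq(1, length(sol$z_mm), length.out = 13))
  ridge <- dplyr::slice_max(dplyr::group_by(map1, .data$z_mm), .data$tau_pa,
                            n = 1, with_ties = FALSE)
  # ridge angle = orientation(z) + pi/2; slope in deg/um
  ridge <- dplyr::arrange(ridge, .data$z_mm)
  ang <- unwrap_phase(2 * (ridge$angle_global_rad %% pi)) / 2
  slope <- stats::coef(stats::lm(ang ~ ridge$z_mm))[2] * 180 / pi / 1000
  expect_equal(unname(slope), cfg$cushion_spiral_rate_deg_um, tolerance = 0.15)
})

test_that("model-vs-doppler comparison respects masking and self-consistency", {
  m <- rigid_model(0.18, 0.15)
  sol <- solve_flow(m, function(tf) rep(8, length(tf)))
  iz <- 1
  u <- sol$u0_mm_s[, iz]
  vel <- tibble::tibble(phase_frac = sol$t_frac, v_mm_s = u,
                        masked = FALSE, plateau = FALSE)
  cmp <- compare_with_doppler(sol, vel, sol$z_mm[iz])
  expect_equal(cmp$rel_rms, 0, tolerance = 1e-9)

  # noisy + partially masked: only unflagged samples enter the residual
  vel2 <- vel
  vel2$v_mm_s[1:5] <- 1e6
  vel2$plateau[1:5] <- TRUE
  cmp2 <- compare_with_doppler(sol, vel2, sol$z_mm[iz])
  expect_equal(cmp2$rel_rms, 0, tolerance = 1e-9)
  expect_equal(cmp2$n_used, nrow(vel2) - 5)

  # zero flow on both sides: residual zero
  sol0 <- solve_flow(m, function(tf) rep(0, length(tf)))
  vel0 <- tibble::tibble(phase_frac = sol0$t_frac, v_mm_s = 0,
                         masked = FALSE, plateau = FALSE)
  expect_equal(compare_with_doppler(sol0, vel0, sol0$z_mm[1])$rel_rms, 0)

  # no overlap errors out
  vel_bad <- tibble::tibble(phase_frac = sol$t_frac, v_mm_s = u,
                            masked = TRUE, plateau = FALSE)
  expect_error(compare_with_doppler(sol, vel_bad, sol$z_mm[1]), "open-lumen")
})

test_that("the optional inertial correction is small and mass-conserving", {
  ell <- ellipse_series(24, 1:3,
                        function(pl, f) 0.18 + 0.03 * sin(2 * pi * f / 24),
                        function(pl, f) 0.9 * (0.18 + 0.03 * sin(2 * pi * f / 24)))
  m <- lumen_model(ell, c(0, 0.3, 0.6), window = c(0.1, 0.6), n_steps = 60)
  dp <- function(tf) 10 * sin(pi * (tf - 0.1) / 0.5)^2
  s0 <- solve_flow(m, dp)
  s1 <- solve_flow(m, dp, inertial_rho = 1060)
  # at outflow-tract Reynolds numbers the correction barely moves the flow
  expect_lt(abs(max(abs(s1$q0_mm3_s)) - max(abs(s0$q0_mm3_s))) /
              max(abs(s0$q0_mm3_s)), 0.05)
  expect_false(isTRUE(all.equal(s1$q0_mm3_s, s0$q0_mm3_s)))
  expect_lt(mass_residual(s1), 1e-6)
  # the correction vanishes with the density
  s2 <- solve_flow(m, dp, inertial_rho = 1e-12)
  expect_equal(s2$q0_mm3_s, s0$q0_mm3_s, tolerance = 1e-9)
})

test_that("flow solution tidiers expose the expected quantities", {
  m <- rigid_model(0.15, 0.15)
  sol <- solve_flow(m, function(tf) rep(10, length(tf)))
  td <- tidy(sol)
  expect_equal(nrow(td), length(sol$t_frac) * length(sol$z_mm))
  expect_true(all(c("q_mm3_s", "u0_mm_s", "a_mm") %in% names(td)))
  gl <- glance(sol)
  expect_equal(gl$n_steps, 40)
  expect_lt(gl$mass_residual, 1e-10)
  s <- flow_summary(sol)
  expect_equal(s$peak_u0_mm_s, max(sol$u0_mm_s), tolerance = 1e-9)
})
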