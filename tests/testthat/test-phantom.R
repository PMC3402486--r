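test_that("cross-section geometry honours the phantom's physiology", {
  cfg <- phantom_config()

  # most-expanded lumen is near-circular (shape factor ~ 1)
  geo_open <- oft_cross_section(cfg, 0, cfg$open_phase_center * cfg$period_s)
  expect_true(geo_open$open)
  expect_lt(geo_open$a_mm / geo_open$b_mm, 1.2)
  expect_gte(geo_open$a_mm / geo_open$b_mm, 1)

  # degenerate cushions: lumen equals the inner myocardial circle
  cfg_nojelly <- phantom_config(d_min_mm = 0, lumen_axis_ratio = 1)
  g <- oft_cross_section(cfg_nojelly, 0, cfg$open_phase_center * cfg$period_s)
  expect_equal(g$a_mm, g$r_inner_mm, tolerance = 1e-12)
  expect_equal(g$b_mm, g$r_inner_mm, tolerance = 1e-3)

  # peristalsis: distal closure onset later by tube_length / wave_speed
  dt_expected <- cfg$tube_length_um / cfg$peristaltic_wave_speed_um_s
  expect_equal(closure_onset_time(cfg, 600) - closure_onset_time(cfg, 0),
               dt_expected, tolerance = 1e-12)

  # out-of-range z errors
  expect_error(oft_cross_section(cfg, -1, 0), "z_um")

  # radius taper must be monotone
  expect_error(phantom_config(r_inner_max_mm = c(0.15, 0.21, 0.19, 0.17, 0.15)),
               "non-increasing")
})

test_that("jelly modulation thins the cushions when expanded, preserving closure", {
  cfg_on <- phantom_config(longitudinal_jelly_modulation = TRUE)
  cfg_off <- phantom_config()
  t_open <- cfg_on$open_phase_center * cfg_on$period_s
  g_on <- oft_cross_section(cfg_on, 0, t_open)
  g_off <- oft_cross_section(cfg_off, 0, t_open)
  jelly <- function(g) pi * g$r_inner_mm^2 - pi * g$a_mm * g$b_mm
  expect_lt(jelly(g_on), jelly(g_off)) # thinner jelly at full expansion
  expect_lte(g_on$b_mm, g_on$a_mm)
  # closed interval unchanged
  tt <- seq(0, cfg_on$period_s, length.out = 400)
  expect_equal(oft_cross_section(cfg_on, 0, tt)$open,
               oft_cross_section(cfg_off, 0, tt)$open)
})

test_that("lumen area is periodic and closed for about half the cycle", {
  cfg <- phantom_config()
  tt <- seq(0, cfg$period_s, length.out = 400)
  zp <- plane_positions_um(cfg)
  open_mat <- sapply(zp, function(z) oft_cross_section(cfg, z, tt)$open)
  # per-plane closure near the target, and all-planes-closed fraction within
  # 10% of it
  per_plane <- colMeans(!open_mat)
  expect_true(all(abs(per_plane - cfg$closure_fraction) < 0.02))
  all_closed <- mean(rowSums(open_mat) == 0)
  expect_lt(abs(all_closed - cfg$closure_fraction) / cfg$closure_fraction, 0.1)

  # periodicity
  a1 <- oft_cross_section(cfg, 0, tt)$area_lumen_mm2
  a2 <- oft_cross_section(cfg, 0, tt + cfg$period_s)$area_lumen_mm2
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("rendering is deterministic and honest about its ground truth", {
  cfg <- phantom_config(n_cycles = 1, img_px = 72, n_planes = 2,
                        r_inner_max_mm = c(0.13, 0.12),
                        r_inner_min_mm = c(0.08, 0.07),
                        wall_thickness_mm = c(0.04, 0.03))
  ph1 <- render_sequences(cfg)
  ph2 <- render_sequences(cfg)
  expect_identical(ph1$sequences[[1]]$intensity, ph2$sequences[[1]]$intensity)
  expect_identical(ph1$sequences[[2]]$phase, ph2$sequences[[2]]$phase)
  expect_identical(ph1$truth$start_phase, ph2$truth$start_phase)

  # phase channel strictly within (-pi, pi]
  expect_true(all(ph1$sequences[[1]]$phase > -pi))
  expect_true(all(ph1$sequences[[1]]$phase <= pi))

  # recorded start phases are real: the rendered area signal peaks where the
  # truth says it should
  tr <- dplyr::filter(ph1$truth$geometry, plane == 1)
  arr <- ph1$sequences[[1]]$intensity
  lum <- apply(arr, 1, function(fr) sum(abs(fr - 0.45) < 0.12))
  d_argmax <- abs(which.max(lum) - which.max(tr$area_lumen_mm2))
  expect_lte(min(d_argmax, nrow(tr) - d_argmax), 3)
})

test_that("noiseless rendering puts ground-truth contours on the boundaries", {
  cfg <- noiseless_cfg()
  fr <- phantom_frame(cfg, 0.68)
  # intensity is piecewise constant at the four layer levels
  expect_true(all(fr$img %in% c(0.05, 0.20, 0.45, 0.85)))
  # boundary pixels: sample image just inside/outside the truth circles
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ctr <- (cfg$img_px + 1) / 2
  px <- function(r_mm, th) cbind(ctr + r_mm * 1000 / 5 * cos(th),
                                 ctr + r_mm * 1000 / 5 * sin(th))
  pitch_mm <- 0.005
  inside <- px(fr$geo$r_inner_mm - 1.5 * pitch_mm, th)
  outside <- px(fr$geo$r_inner_mm + 1.5 * pitch_mm, th)
  get <- function(p) fr$img[cbind(round(p[, 2]), round(p[, 1]))]
  expect_true(all(get(outside) == 0.85)) # myocardium just outside
  expect_true(all(get(inside) %in% c(0.20, 0.45))) # jelly/lumen just inside
})

test_that("doppler phase rendering follows the wrap formula", {
  # odd raster so one pixel sits exactly on the duct centerline
  cfg <- phantom_config(phase_noise_sd = 0, img_px = 65, n_planes = 1,
                        r_inner_max_mm = 0.12, r_inner_min_mm = 0.08,
                        wall_thickness_mm = 0.03)
  geo <- oft_cross_section(cfg, 0, cfg$open_phase_center * cfg$period_s)
  dop <- doppler_config()
  # choose U0 so the beam-projected centerline velocity is exactly 12 mm/s:
  # at the wrap limit the rendered phase lands on +/- pi
  v_wrap <- phase_to_velocity(pi, dop)
  th <- 58.4
  u0 <- v_wrap / cos(th * pi / 180)
  ph <- render_doppler_phase(NULL, geo, u0, th, cfg, dop, z_um = 0)
  expect_equal(max(abs(ph)), pi, tolerance = 1e-9)

  # 18 mm/s axial velocity wraps to its equivalent minus 2 pi
  u0_18 <- 18 / v_wrap * u0
  ph18 <- render_doppler_phase(NULL, geo, u0_18, th, cfg, dop, z_um = 0)
  expected_center <- pi * 18 / v_wrap - 2 * pi
  ctr <- (cfg$img_px + 1) / 2
  expect_equal(ph18[ctr, ctr], expected_center, tolerance = 1e-6)

  # zero flow renders (near) zero phase
  ph0 <- render_doppler_phase(NULL, geo, 0, th, cfg, dop, z_um = 0)
  expect_equal(max(abs(ph0)), 0, tolerance = 1e-12)
})

test_that("pressure traces peak at the configured physiological values", {
  cfg <- phantom_config()
  tr <- generate_pressure_traces(cfg)
  vent <- dplyr::filter(tr, site == "ventricle")
  as_ <- dplyr::filter(tr, site == "aortic_sac")
  expect_equal(max(vent$pressure_pa), 196)
  expect_equal(max(as_$pressure_pa), 180)
  expect_gte(max(vent$pressure_pa), max(as_$pressure_pa))
  # 100 Hz sampling
  expect_equal(diff(vent$time_s[1:2]), 0.01)
  # equal peaks -> zero driving pressure at the peak instant
  cfg_eq <- phantom_config(p_as_peak_pa = 196)
  tr_eq <- generate_pressure_traces(cfg_eq)
  dp <- dplyr::filter(tr_eq, site == "ventricle")$pressure_pa -
    dplyr::filter(tr_eq, site == "aortic_sac")$pressure_pa
  expect_equal(max(abs(dp)), 0, tolerance = 1e-12)
})

test_that("true flow conserves mass with the moving wall", {
  cfg <- phantom_config()
  # at a closed section the flow is zero; during the open phase flow at the
  # inlet equals the prescribed pulse
  t_closed <- 0.1 * cfg$period_s
  f <- true_flow(cfg, 0, t_closed)
  expect_equal(f$q_mm3_s, 0, tolerance = 1e-9)
  t_peak <- cfg$open_phase_center * cfg$period_s
  f_peak <- true_flow(cfg, 0, t_peak)
  expect_equal(f_peak$q_mm3_s, inlet_flow(cfg, t_peak), tolerance = 1e-9)
  # independent finite-volume check on a segment [0, z]: d/dt(volume) equals
  # inflow minus outflow
  z <- 400
  dt <- 1e-4
  vol <- function(t) {
    zz <- seq(0, z, length.out = 201)
    a <- oft_cross_section(cfg, zz, t)$area_lumen_mm2
    oftmech:::simpson_composite(a, diff(zz[1:2])) * 1e-3
  }
  dvdt <- (vol(t_peak + dt) - vol(t_peak - dt)) / (2 * dt)
  qin <- true_flow(cfg, 0, t_peak)$q_mm3_s
  qout <- true_flow(cfg, z, t_peak)$q_mm3_s
  expect_equal(dvdt, qin - qout, tolerance = 1e-3 * max(abs(qin), 1))
})
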