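test_that("circumferential strain follows the contraction-positive convention", {
  s <- circumferential_strain(c(10, 8, 10))
  expect_equal(s$strain, c(0, 0.2, 0))
  expect_equal(attr(s, "peak"), 0.2)
  expect_equal(circumferential_strain(rep(3.3, 7))$strain, rep(0, 7))
  expect_error(circumferential_strain(numeric(0)), "empty")
  # dimensionless: invariant to uniform scaling
  C <- c(1.07, 0.9, 0.68, 0.8)
  expect_equal(circumferential_strain(C)$strain,
               circumferential_strain(1000 * C)$strain)
})

test_that("area shortening fraction matches its definition", {
  expect_equal(area_shortening_fraction(c(2, 1.5, 1)), 0.5)
  expect_equal(area_shortening_fraction(c(5, 5, 5)), 0)
  expect_error(area_shortening_fraction(c(0, 0)), "A_max")
  A <- c(0.09, 0.05, 0.017)
  expect_equal(area_shortening_fraction(A), area_shortening_fraction(7 * A))
})

test_that("radial velocity matches the closed form for sinusoidal motion", {
  n <- 196; T <- 0.37; rho <- 0.035
  t <- (seq_len(n) - 1) / n * T
  R <- 0.17 + rho * sin(2 * pi * t / T)
  v <- radial_velocity(R, T / n)
  expect_equal(attr(v, "max_expansion_mm_s"), 2 * pi * rho / T,
               tolerance = 0.01)
  expect_equal(attr(v, "max_contraction_mm_s"), 2 * pi * rho / T,
               tolerance = 0.01)
  # derivative annihilates constants and is exact on the periodic linear ramp
  expect_equal(radial_velocity(rep(1, 10), 0.1)$dRdt_mm_s, rep(0, 10))
  expect_error(radial_velocity(c(1, 2), 0.1), "3")
})

test_that("shape factor is the fitted-ellipse axis ratio", {
  s <- seq(0, 2 * pi, length.out = 65)[-65]
  expect_equal(shape_factor(cos(s), sin(s)), 1, tolerance = 1e-6)
  expect_equal(shape_factor(2 * cos(s), sin(s)), 2, tolerance = 1e-3)
  expect_error(shape_factor(rep(0, 10), rep(0, 10)), "degenerate")
})

test_that("phase timings split the cycle into expansion, contraction, closure", {
  n <- 200
  t <- (seq_len(n) - 1) / n
  # never-closing sinusoid: no closure, symmetric expansion/contraction
  A <- 2 + sin(2 * pi * t)
  pt <- phase_timings(A, eps_closed = 0)
  expect_lte(pt$T_closure, 1 / n) # only the exact minimum sample counts
  expect_equal(pt$T_e, 0.5, tolerance = 0.02)
  expect_equal(pt$T_c, 0.5, tolerance = 0.02)
  expect_equal(pt$T_e + pt$T_c + pt$T_closure, 1)

  # square pulse with a known 30% closed plateau
  A2 <- rep(1, n); A2[t < 0.3] <- 0
  pt2 <- phase_timings(A2)
  expect_equal(pt2$T_closure, 0.30, tolerance = 1 / n + 1e-9)

  expect_warning(pt3 <- phase_timings(rep(2, 50)), "flat")
  expect_equal(pt3$T_closure, 1)
})

test_that("endocardial thickness models convert perimeter and area", {
  # slit: t = 2 A / C; annulus: t = A / C
  expect_equal(endocardial_thickness(0.68, 0.022, "slit")$thickness_um,
               2 * 0.022 / 0.68 * 1000, tolerance = 1e-9)
  expect_equal(endocardial_thickness(0.68, 0.022, "annulus")$thickness_um,
               0.022 / 0.68 * 1000, tolerance = 1e-9)
  expect_equal(round(endocardial_thickness(0.68, 0.022, "slit")$thickness_um, 1),
               64.7)
  expect_equal(round(endocardial_thickness(0.68, 0.022, "annulus")$thickness_um, 1),
               32.4)
  expect_equal(endocardial_thickness(0.68, 0, "slit")$thickness_um, 0)
})

test_that("longitudinal stretch is displacement over length", {
  expect_equal(longitudinal_stretch(140, 600), 140 / 600)
  expect_equal(longitudinal_stretch(0, 600), 0)
  expect_equal(longitudinal_stretch(60, 600), 0.1)
  expect_error(longitudinal_stretch(10, 0))
})

test_that("kinematics table reproduces analytic contour series", {
  # synthetic contour series: circles breathing sinusoidally, lumen ellipse
  n_ph <- 40
  s <- seq(0, 2 * pi, length.out = 33)[-33]
  rows <- list()
  for (f in seq_len(n_ph)) {
    ri <- 0.15 + 0.05 * sin(2 * pi * (f - 1) / n_ph)
    rows[[length(rows) + 1]] <- contour_tbl((ri + 0.05) * cos(s), (ri + 0.05) * sin(s),
                                            1, f, "myo_outer")
    rows[[length(rows) + 1]] <- contour_tbl(ri * cos(s), ri * sin(s), 1, f, "myo_inner")
    rows[[length(rows) + 1]] <- contour_tbl(0.8 * ri * cos(s), 0.6 * ri * sin(s),
                                            1, f, "endo")
  }
  kin <- kinematics_table(dplyr::bind_rows(rows), period_s = 0.4)
  expect_equal(nrow(kin), n_ph)
  # polygonal radius of a 32-gon is slightly under the circumscribed circle
  poly_r <- sqrt(polygon_area(0.2 * cos(s), 0.2 * sin(s)) / pi) / 0.2
  expect_equal(max(kin$R_eff_mm), 0.2 * poly_r, tolerance = 1e-6)
  # jelly area identity holds exactly by construction
  expect_equal(kin$A_jelly_mm2,
               pmax(kin$A_myo_inner_mm2 - kin$A_lumen_mm2, 0))
  # myocardial strain from effective radius: (R_max - R_min) / R_max
  expect_equal(max(kin$eps_myo), (0.2 - 0.1) / 0.2, tolerance = 1e-6)
  # lumen shape factor: 0.8/0.6 ellipse
  expect_equal(stats::median(kin$lambda), 0.8 / 0.6, tolerance = 1e-2)
  # nesting invariant
  expect_true(all(kin$A_myo_outer_mm2 > kin$A_myo_inner_mm2))
  expect_true(all(kin$A_myo_inner_mm2 >= kin$A_lumen_mm2))
  sum_tbl <- summarize_kinematics(kin)
  expect_equal(sum_tbl$ASF_lumen,
               area_shortening_fraction(kin$A_lumen_mm2))
  expect_equal(sum_tbl$T_e + sum_tbl$T_c + sum_tbl$T_closure, 1)
})
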