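test_that("snake segmentation recovers analytic and phantom boundaries", {
  # perfect bright annulus: outer contour lands on the outer radius
  px <- 100
  ctr <- (px + 1) / 2
  rr <- sqrt(outer(seq_len(px), seq_len(px),
                   function(r, c) (r - ctr)^2 + (c - ctr)^2))
  annulus <- 0.08 + 0.75 * (rr >= 18 & rr <= 32)
  ct_out <- segment_frame(annulus, label = "myo_outer", pixel_pitch_um = 5)
  radii <- sqrt(ct_out$x_mm^2 + ct_out$y_mm^2) * 1000 / 5
  expect_equal(mean(radii), 32, tolerance = 0.05)
  expect_lt(stats::sd(radii), 0.4)
  ct_in <- segment_frame(annulus, label = "myo_inner", pixel_pitch_um = 5)
  radii_in <- sqrt(ct_in$x_mm^2 + ct_in$y_mm^2) * 1000 / 5
  expect_equal(mean(radii_in), 18, tolerance = 0.05)

  # noiseless phantom frame: inner myocardial area within 2% of truth
  fr <- phantom_frame(noiseless_cfg(), 0.68)
  ct <- segment_frame(fr$img, label = "myo_inner", pixel_pitch_um = 5)
  a <- abs(polygon_area(ct$x_mm, ct$y_mm))
  expect_lt(abs(a - pi * fr$geo$r_inner_mm^2) / (pi * fr$geo$r_inner_mm^2), 0.02)

  # default-noise phantom, open lumen: Dice overlap with truth >= 0.9
  frn <- phantom_frame(noisy_cfg(), 0.68, seed = 5)
  ctn <- segment_frame(frn$img, label = "endo", pixel_pitch_um = 5)
  tp <- truth_poly(frn$geo, "endo")
  m_seg <- polygon_mask(ctn$x_mm, ctn$y_mm, 120)
  m_tru <- polygon_mask(tp$x_mm, tp$y_mm, 120)
  expect_gte(dice_coefficient(m_seg, m_tru), 0.9)

  # contours are valid: closed-ccw, simple, >= 8 vertices
  expect_gte(nrow(ctn), 8)
  expect_gt(polygon_area(ctn$x_mm, ctn$y_mm), 0)
  expect_true(oftmech:::is_simple_polygon(ctn$x_mm, ctn$y_mm))
})

test_that("propagation tracks a full cycle within tolerance and recovers from corruption", {
  cfg <- noisy_cfg()
  ph <- cached("noisy_1plane", render_sequences(cfg, with_phase = FALSE))
  tr <- dplyr::filter(ph$truth$geometry, plane == 1)
  ct <- cached("noisy_1plane_contours",
               propagate_contours(ph$sequences[[1]], plane = 1))
  m <- measure_contours(ct)

  # per-frame inner-myocardial area error <= 5% across the cycle
  mi <- dplyr::filter(m, label == "myo_inner")
  a_err <- abs(mi$area_mm2 - pi * tr$r_inner_mm^2) / (pi * tr$r_inner_mm^2)
  expect_lt(max(a_err), 0.05)

  # endocardial area error <= 10% while the lumen is wide open
  en <- dplyr::filter(m, label == "endo")
  wide <- tr$area_lumen_mm2 > 0.5 * max(tr$area_lumen_mm2)
  a_tr <- pi * tr$a_mm * tr$b_render_mm
  expect_lt(max(abs(en$area_mm2[wide] - a_tr[wide]) / a_tr[wide]), 0.1)

  # nesting invariant holds every frame
  wide_tbl <- tidyr::pivot_wider(m[, c("frame", "label", "area_mm2")],
                                 names_from = "label", values_from = "area_mm2")
  expect_true(all(wide_tbl$myo_outer > wide_tbl$myo_inner))
  expect_true(all(wide_tbl$myo_inner >= wide_tbl$endo - 1e-9))

  # static sequence: identical contours every frame
  arr <- ph$sequences[[1]]$intensity[c(30, 30, 30), , ]
  ct_static <- propagate_contours(arr, labels = "myo_inner",
                                  pixel_pitch_um = 5)
  a_static <- measure_contours(ct_static)$area_mm2
  expect_lt(diff(range(a_static)) / mean(a_static), 1e-3)

  # corrupted middle frame: downstream frames recover via re-initialization
  arr2 <- ph$sequences[[1]]$intensity[28:33, , ]
  set.seed(99)
  arr2[3, , ] <- matrix(runif(120 * 120), 120, 120)
  ct_corr <- propagate_contours(arr2, labels = "myo_inner", pixel_pitch_um = 5)
  m_corr <- measure_contours(ct_corr)
  good <- pi * tr$r_inner_mm[28:33]^2
  expect_lt(abs(m_corr$area_mm2[5] - good[5]) / good[5], 0.05)
  expect_lt(abs(m_corr$area_mm2[6] - good[6]) / good[6], 0.05)
})

test_that("automatic contours agree with hand-drawn fixtures within 10%", {
  # the hand-drawn reference: truth polygons jittered as a tracing would be
  fr <- phantom_frame(noisy_cfg(), 0.7, seed = 13)
  set.seed(13)
  for (lab in c("myo_inner", "endo")) {
    hand <- truth_poly(fr$geo, lab, n = 48)
    hand$x_mm <- hand$x_mm * (1 + rnorm(48, sd = 0.01))
    hand$y_mm <- hand$y_mm * (1 + rnorm(48, sd = 0.01))
    auto <- segment_frame(fr$img, label = lab, pixel_pitch_um = 5)
    a_hand <- abs(polygon_area(hand$x_mm, hand$y_mm))
    a_auto <- abs(polygon_area(auto$x_mm, auto$y_mm))
    expect_lt(abs(a_auto - a_hand) / a_hand, 0.10)
  }
})

test_that("centerline and cross-section selection follow the tube axis", {
  sp <- small_phantom()
  ph <- sp$phantom
  zp <- plane_positions_um(sp$cfg)
  # contours at the most-constricted phase of each plane (straight phantom:
  # all centroids at the plane center)
  s <- seq(0, 2 * pi, length.out = 33)[-33]
  ct <- dplyr::bind_rows(lapply(1:3, function(p) {
    tr <- dplyr::filter(ph$truth$geometry, plane == p)
    i <- which.min(tr$r_inner_mm)
    contour_tbl(tr$r_inner_mm[i] * cos(s), tr$r_inner_mm[i] * sin(s),
                plane = p, frame = 1, label = "myo_inner")
  }))
  cl <- compute_centerline(ct, zp)
  expect_equal(max(cl$s_mm), sp$cfg$tube_length_um / 1000, tolerance = 0.005)
  expect_lt(max(abs(cl$x_mm)), 1e-9)

  # translating every plane translates the centerline identically
  ct_shift <- dplyr::mutate(ct, x_mm = x_mm + 0.05, y_mm = y_mm - 0.02)
  cl_shift <- compute_centerline(ct_shift, zp)
  expect_equal(cl_shift$x_mm, cl$x_mm + 0.05, tolerance = 1e-9)
  expect_equal(cl_shift$y_mm, cl$y_mm - 0.02, tolerance = 1e-9)

  # a curved-centerline variant: centroids displaced quadratically in z are
  # interpolated with sub-pixel residuals
  ct_curved <- dplyr::mutate(ct, x_mm = x_mm + 0.1 * (zp[plane] / 600)^2)
  cl_curved <- compute_centerline(ct_curved, zp)
  at_planes <- sapply(zp / 1000, function(z) {
    cl_curved$x_mm[which.min(abs(cl_curved$z_mm - z))]
  })
  expect_lt(max(abs(at_planes - 0.1 * (zp / 600)^2)), 0.005)

  # cross-section selection: even spacing, endpoint inclusion, near-axial
  # normals (within 10 degrees of the tube axis)
  cs <- select_cross_sections(cl, 5)
  expect_equal(diff(cs$s_mm), rep(0.15, 4), tolerance = 1e-6)
  cs2 <- select_cross_sections(cl, 2)
  expect_equal(cs2$s_mm, c(0, 0.6), tolerance = 1e-6)
  ang <- acos(pmin(abs(cs$nz), 1)) * 180 / pi
  expect_lt(max(ang), 10)
  expect_error(select_cross_sections(cl, 1), "at least 2")
  expect_error(compute_centerline(dplyr::filter(ct, plane == 1), zp[1]),
               "2 planes")
})
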