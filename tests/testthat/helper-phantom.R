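# Shared fixtures, rendered once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# single-plane noiseless phantom (clean boundaries, no attenuation)
noiseless_cfg <- function() {
  phantom_config(n_cycles = 1, img_px = 120, n_planes = 1,
                 speckle_contrast = 0, phase_noise_sd = 0,
                 attenuation_per_mm = 0)
}

# single-plane default-noise phantom
noisy_cfg <- function() phantom_config(n_cycles = 1, img_px = 120, n_planes = 1)

# render one frame of a config at cycle-phase fraction tf (plane z = 0)
phantom_frame <- function(cfg, tf, seed = 1) {
  set.seed(seed)
  geo <- oft_cross_section(cfg, 0, tf * cfg$period_s)
  grid <- oftmech:::plane_grid(cfg, 0)
  img <- oftmech:::render_frame_intensity(grid, geo, cfg)
  img <- pmin(oftmech:::apply_speckle(img, cfg$speckle_contrast), 1)
  list(img = img, geo = geo)
}

# 3-plane default-noise phantom spanning the full taper, used by several tests
small_phantom <- function() {
  cached("small_phantom", {
    cfg <- phantom_config(
      n_cycles = 4, img_px = 120, n_planes = 3,
      r_inner_max_mm = c(0.21, 0.19, 0.15),
      r_inner_min_mm = c(0.14, 0.12, 0.12),
      wall_thickness_mm = c(0.060, 0.048, 0.030),
      doppler_angle_deg = c(84, 58.4, 58.4)
    )
    list(cfg = cfg, phantom = render_sequences(cfg))
  })
}

# even-odd rasterized polygon mask on the pixel grid of an img_px raster
polygon_mask <- function(x_mm, y_mm, img_px, pitch_um = 5) {
  ctr <- (img_px + 1) / 2
  px <- x_mm * 1000 / pitch_um + ctr
  py <- y_mm * 1000 / pitch_um + ctr
  gx <- rep(seq_len(img_px), each = img_px)   # col
  gy <- rep(seq_len(img_px), times = img_px)  # row
  n <- length(px)
  inside <- rep(FALSE, length(gx))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > gy) != (py[j] > gy)) &
      (gx < (px[j] - px[i]) * (gy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, img_px, img_px)
}

dice_coefficient <- function(mask_a, mask_b) {
  2 * sum(mask_a & mask_b) / (sum(mask_a) + sum(mask_b))
}

# dense polygon of a ground-truth boundary (for perimeter/area references)
truth_poly <- function(geo, label, n = 256) truth_contour(geo, label, n = n)
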