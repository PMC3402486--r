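#' Plot per-plane wall-motion metrics over the cycle
#'
#' Lumen area, effective myocardial radius, and circumferential strains per
#' analysis plane as functions of cycle phase.
#'
#' @param object An `oft_kinematics` tibble.
#' @param metrics Columns to facet (default the four headline series).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oft_kinematics <- function(object,
                                    metrics = c("A_lumen_mm2", "R_eff_mm",
                                                "eps_myo", "eps_endo"), ...) {
  n_phases <- attr(object, "n_phases")
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, phase_frac = (.data$frame - 1) / n_phases),
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$phase_frac, .data$value,
                                     colour = factor(.data$plane))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "t / T", y = NULL, colour = "plane") +
    ggplot2::theme_minimal()
}

#' Plot wall stress per plane over the cycle
#'
#' @param object An `oft_stress` tibble from [stress_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oft_stress <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$phase_frac, .data$sigma_pa,
                                       colour = factor(.data$plane))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t / T", y = "circumferential wall stress (Pa)",
                  colour = "plane") +
    ggplot2::theme_minimal()
}

#' Plot centerline velocity along the tract over the simulated window
#'
#' @param object An `oft_flow` from [solve_flow()].
#' @param n_z Number of axial positions shown (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oft_flow <- function(object, n_z = 5, ...) {
  idx <- unique(round(seq(1, length(object$z_mm), length.out = n_z)))
  df <- purrr::map_dfr(idx, function(i) {
    tibble::tibble(t_frac = object$t_frac, z_mm = object$z_mm[i],
                   u0_mm_s = object$u0_mm_s[, i])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$t_frac, .data$u0_mm_s,
                                   colour = factor(signif(.data$z_mm, 3)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t / T", y = "centerline velocity (mm/s)",
                  colour = "z (mm)") +
    ggplot2::theme_minimal()
}

#' Unrolled wall-shear-stress map
#'
#' Wall shear stress on the lumen wall unrolled in (z, boundary angle); with
#' a spiraling cushion orientation the high-stress ridge (the cushion
#' surfaces, at the ellipse minor axis) traces a diagonal stripe whose slope
#' is the spiral rate.
#'
#' @param wss Tibble from [wss_field()] (typically one instant, e.g.
#'   `flow_summary()$wss_map`).
#' @param global_angle Use the global (spiral-following) wall angle rather
#'   than the ellipse-local parameter.
#' @return A ggplot object.
#' @export
plot_wss_map <- function(wss, global_angle = TRUE) {
  ang <- if (global_angle) "angle_global_rad" else "s_rad"
  ggplot2::ggplot(wss, ggplot2::aes(.data$z_mm, .data[[ang]] %% (2 * pi),
                                    fill = .data$tau_pa)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "z (mm)", y = "wall angle (rad)", fill = "WSS (Pa)") +
    ggplot2::theme_minimal()
}

#' Display an M-mode / M-phase image
#'
#' @param m An `oft_mmode` matrix from [extract_mmode()].
#' @param pixel_pitch_um Pixel pitch for the space axis (um).
#' @param frame_rate_hz Frame rate for the time axis.
#' @return A ggplot object.
#' @export
plot_mmode <- function(m, pixel_pitch_um = 5, frame_rate_hz = 140) {
  df <- tidyr::expand_grid(col = seq_len(ncol(m)), row = seq_len(nrow(m)))
  df$value <- as.vector(unclass(m)) # column-major: row varies fastest
  df$depth_um <- (df$row - 1) * pixel_pitch_um
  df$time_s <- (df$col - 1) / frame_rate_hz
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$depth_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = if (attr(m, "channel") == "phase") "C" else "B") +
    ggplot2::labs(x = "time (s)", y = "depth (um)",
                  fill = attr(m, "channel")) +
    ggplot2::theme_minimal()
}
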