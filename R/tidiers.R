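#' Tidy a flow solution into a long tibble
#'
#' One row per (time step, axial position) with flow rate, centerline
#' velocity, lumen area, and semi-axes.
#'
#' @param x An `oft_flow` from [solve_flow()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oft_flow <- function(x, ...) {
  nt <- length(x$t_frac); nz <- length(x$z_mm)
  tibble::tibble(
    t_frac = rep(x$t_frac, times = nz),
    z_mm = rep(x$z_mm, each = nt),
    q_mm3_s = as.vector(x$q_mm3_s),
    u0_mm_s = as.vector(x$u0_mm_s),
    area_mm2 = as.vector(x$area_mm2),
    a_mm = as.vector(x$model$a),
    b_mm = as.vector(x$model$b)
  )
}

#' One-row summary of a flow solution
#'
#' @inheritParams tidy.oft_flow
#' @return A one-row tibble with peak flow, peak centerline velocity and its
#'   axial position, the discrete mass-conservation residual, and the
#'   simulated window.
#' @export
glance.oft_flow <- function(x, ...) {
  s <- flow_summary(x)
  tibble::tibble(
    peak_q_mm3_s = max(abs(x$q0_mm3_s)),
    peak_u0_mm_s = s$peak_u0_mm_s,
    peak_u0_z_mm = s$peak_u0_z_mm,
    peak_tau_pa = s$peak_tau_pa,
    mass_residual = mass_residual(x),
    window_lo = min(x$t_frac), window_hi = max(x$t_frac),
    n_steps = length(x$t_frac) - 1
  )
}

#' Tidy a synchronization result
#'
#' @param x An `oft_sync` from [synchronize()].
#' @param ... Unused.
#' @return A tibble with one row per plane: estimated lag (frames) and the
#'   shared period.
#' @export
tidy.oft_sync <- function(x, ...) {
  tibble::tibble(plane = seq_along(x$lags), lag_frames = x$lags,
                 period_frames = x$period_frames, n_phases = x$n_phases)
}

#' Tidy a pipeline report into the per-plane summary table
#'
#' @param x An `oft_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-plane summary tibble.
#' @export
tidy.oft_report <- function(x, ...) x$summary

#' One-row overview of a pipeline report
#'
#' @inheritParams tidy.oft_report
#' @return A one-row tibble: period, overall closure fraction, peak stress
#'   plane, peak modeled velocity, elapsed time.
#' @export
glance.oft_report <- function(x, ...) {
  peaks <- attr(x$stress, "peaks")
  tibble::tibble(
    period_frames = x$period_frames,
    closure_fraction = mean(x$summary$T_closure),
    peak_sigma_pa = max(peaks$peak_sigma_pa),
    peak_sigma_plane = peaks$plane[which.max(peaks$peak_sigma_pa)],
    peak_u0_mm_s = if (!is.null(x$flow_summary)) x$flow_summary$peak_u0_mm_s else NA_real_,
    elapsed_s = x$elapsed_s
  )
}
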