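#' Circumferential strain from a perimeter series
#'
#' Contraction-positive circumferential strain referenced to the maximum
#' perimeter over the cardiac cycle: `eps(t) = (C_max - C(t)) / C_max`. The
#' peak contraction strain is `(C_max - C_min) / C_max`.
#'
#' @param C Perimeter series over the cycle (mm), all positive.
#' @return Tibble with `C`, `strain`; attributes `peak` (peak contraction
#'   strain) and `C_max`.
#' @export
circumferential_strain <- function(C) {
  if (length(C) == 0) stop("empty perimeter series", call. = FALSE)
  stopifnot(all(C > 0))
  cmax <- max(C)
  strain <- (cmax - C) / cmax
  structure(tibble::tibble(C = C, strain = strain),
            peak = (cmax - min(C)) / cmax, C_max = cmax)
}

#' Area shortening fraction
#'
#' `ASF = (A_max - A_min) / A_max` over the cardiac cycle.
#'
#' @param A Area series (mm^2), non-negative.
#' @return The ASF (scalar in `[0, 1)`).
#' @export
area_shortening_fraction <- function(A) {
  if (length(A) == 0) stop("empty area series", call. = FALSE)
  stopifnot(all(A >= 0))
  amax <- max(A)
  if (amax == 0) stop("ASF undefined: A_max = 0", call. = FALSE)
  (amax - min(A)) / amax
}

# centered finite differences on a periodic series
periodic_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / (2 * dt)
}

#' Radial velocity of the wall
#'
#' Centered finite differences of the effective-radius series on the uniform
#' periodic phase grid; reports the maximal expansion (positive) and
#' contraction (negative, as magnitude) speeds.
#'
#' @param R Radius series (mm) on a uniform periodic phase grid.
#' @param dt Phase step (s).
#' @return Tibble with `dRdt_mm_s`; attributes `max_expansion_mm_s`,
#'   `max_contraction_mm_s`.
#' @export
radial_velocity <- function(R, dt) {
  d <- periodic_derivative(R, dt)
  structure(tibble::tibble(dRdt_mm_s = d),
            max_expansion_mm_s = max(d),
            max_contraction_mm_s = abs(min(d)))
}

#' Shape factor of a contour
#'
#' Major/minor axis ratio of the least-squares fitted ellipse
#' ([fit_ellipse()]); 1 for a circle.
#'
#' @param x,y Contour vertex coordinates, or a one-contour tidy tibble in
#'   `x` (with `y` missing).
#' @return Shape factor `lambda >= 1`.
#' @export
shape_factor <- function(x, y = NULL) {
  if (is.null(y)) { y <- x$y_mm; x <- x$x_mm }
  if (abs(polygon_area(x, y)) < 1e-14) {
    stop("degenerate (zero-area) contour", call. = FALSE)
  }
  f <- fit_ellipse(x, y)
  max(f$a / f$b, f$b / f$a) # guards rare numerically swapped axes
}

#' Expansion / contraction / closure timing fractions
#'
#' Phases with area within `eps_closed` of the cyclic minimum (relative to
#' the dynamic range) count as closed; among the open phases, those with
#' rising area are expanding and those with falling area contracting. The
#' three fractions sum to 1.
#'
#' @param A Lumen area series on a uniform periodic phase grid.
#' @param eps_closed Closure tolerance as a fraction of `A_max - A_min`
#'   (default 0.05).
#' @return Tibble with `T_e`, `T_c`, `T_closure` (fractions of the cycle).
#' @export
phase_timings <- function(A, eps_closed = 0.05) {
  n <- length(A)
  amax <- max(A); amin <- min(A)
  if (amax - amin < 1e-12 * max(amax, 1)) {
    warning("flat area series: reporting all-closed by convention")
    return(tibble::tibble(T_e = 0, T_c = 0, T_closure = 1))
  }
  closed <- A <= amin + eps_closed * (amax - amin)
  dA <- periodic_derivative(A, 1)
  expanding <- !closed & dA > 0
  contracting <- !closed & dA <= 0
  tibble::tibble(T_e = mean(expanding), T_c = mean(contracting),
                 T_closure = mean(closed))
}

#' Endocardial layer thickness from the closed-lumen contour
#'
#' When the lumen is fully closed the mid-level area enclosed by the
#' endocardium contour is attributed to the endocardial layer itself. Two
#' geometric models convert (perimeter, area) to a thickness: a collapsed
#' slit of length `C/2` (`t = 2 A / C`) or a thin annulus of circumference
#' `C` (`t = A / C`).
#'
#' @param C_min Endocardium perimeter at closure (mm).
#' @param A_min Enclosed area at closure (mm^2).
#' @param model `"slit"` or `"annulus"`.
#' @return Tibble with `thickness_um` and `model`.
#' @export
endocardial_thickness <- function(C_min, A_min, model = c("slit", "annulus")) {
  model <- match.arg(model)
  stopifnot(C_min > 0, A_min >= 0)
  t_mm <- if (model == "slit") 2 * A_min / C_min else A_min / C_min
  tibble::tibble(thickness_um = 1000 * t_mm, model = model)
}

#' Longitudinal stretch from a landmark excursion
#'
#' @param displacement_um Longitudinal landmark displacement over the cycle
#'   (um).
#' @param length_um Tube length (um), positive.
#' @return Longitudinal strain (dimensionless).
#' @export
longitudinal_stretch <- function(displacement_um, length_um) {
  stopifnot(length_um > 0)
  displacement_um / length_um
}

#' Per-plane, per-phase wall-motion metrics from a contour table
#'
#' Computes, for each plane and phase: endocardial perimeter `C_endo` and
#' enclosed (lumen) area, inner-myocardial area and effective radius
#' `R_eff = sqrt(A_MI / pi)`, cardiac-jelly area (inner myocardium minus
#' lumen), lumen shape factor, circumferential strains of the myocardium
#' (from `C = 2 pi R_eff`) and endocardium, and the periodic time derivatives
#' `dR/dt` and `deps/dt`.
#'
#' @param contours Tidy contour tibble with labels `myo_outer`, `myo_inner`,
#'   `endo` on a shared uniform phase grid per plane.
#' @param period_s Cardiac period (s).
#' @return An `oft_kinematics` tibble: one row per (plane, frame) with the
#'   metric columns, plus attributes `period_s` and `n_phases`.
#' @export
kinematics_table <- function(contours, period_s = 0.37) {
  meas <- measure_contours(contours)
  wide <- tidyr::pivot_wider(
    meas[, c("plane", "frame", "label", "perimeter_mm", "area_mm2")],
    names_from = "label", values_from = c("perimeter_mm", "area_mm2")
  )
  lambda <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(contours, .data$label == "endo"),
                    .data$plane, .data$frame),
    lambda = tryCatch(shape_factor(.data$x_mm, .data$y_mm), error = function(e) NA_real_),
    .groups = "drop"
  )
  tab <- dplyr::left_join(wide, lambda, by = c("plane", "frame"))
  n_phases <- length(unique(tab$frame))
  dt <- period_s / n_phases

  tab <- dplyr::arrange(tab, .data$plane, .data$frame)
  out <- dplyr::mutate(
    dplyr::group_by(tab, .data$plane),
    C_endo_mm = .data$perimeter_mm_endo,
    A_lumen_mm2 = .data$area_mm2_endo,
    A_myo_inner_mm2 = .data$area_mm2_myo_inner,
    A_myo_outer_mm2 = .data$area_mm2_myo_outer,
    A_jelly_mm2 = pmax(.data$A_myo_inner_mm2 - .data$A_lumen_mm2, 0),
    R_eff_mm = sqrt(.data$A_myo_inner_mm2 / pi),
    h_mm = sqrt(.data$A_myo_outer_mm2 / pi) - .data$R_eff_mm,
    eps_myo = (max(.data$R_eff_mm) - .data$R_eff_mm) / max(.data$R_eff_mm),
    eps_endo = (max(.data$C_endo_mm) - .data$C_endo_mm) / max(.data$C_endo_mm),
    dRdt_mm_s = periodic_derivative(.data$R_eff_mm, dt),
    depsdt_myo_s = periodic_derivative(.data$eps_myo, dt),
    depsdt_endo_s = periodic_derivative(.data$eps_endo, dt)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::select(out, "plane", "frame", "C_endo_mm", "A_lumen_mm2",
                       "A_myo_inner_mm2", "A_myo_outer_mm2", "A_jelly_mm2",
                       "R_eff_mm", "h_mm", "lambda", "eps_myo", "eps_endo",
                       "dRdt_mm_s", "depsdt_myo_s", "depsdt_endo_s")
  structure(out, period_s = period_s, n_phases = n_phases,
            class = c("oft_kinematics", class(out)))
}

#' Summary table of wall-motion metrics per plane
#'
#' Condenses an [kinematics_table()] result to one row per plane with the
#' cycle extremes and derived scalars: `C_max/C_min`, `R_max/R_min`,
#' `dR`, lumen and jelly `A_max/A_min/dA/ASF`, peak circumferential strains
#' of myocardium and endocardium, shape-factor extremes, peak expansion and
#' contraction radial velocities, and the expansion/contraction/closure time
#' fractions (from [phase_timings()]).
#'
#' @param kin An `oft_kinematics` tibble.
#' @param eps_closed Closure tolerance passed to [phase_timings()].
#' @return Tibble with one row per plane.
#' @export
summarize_kinematics <- function(kin, eps_closed = 0.05) {
  dplyr::summarise(
    dplyr::group_by(kin, .data$plane),
    C_max_mm = max(.data$C_endo_mm), C_min_mm = min(.data$C_endo_mm),
    R_max_mm = max(.data$R_eff_mm), R_min_mm = min(.data$R_eff_mm),
    dR_mm = max(.data$R_eff_mm) - min(.data$R_eff_mm),
    h_mean_mm = mean(.data$h_mm),
    A_lumen_max_mm2 = max(.data$A_lumen_mm2),
    A_lumen_min_mm2 = min(.data$A_lumen_mm2),
    dA_lumen_mm2 = max(.data$A_lumen_mm2) - min(.data$A_lumen_mm2),
    ASF_lumen = area_shortening_fraction(.data$A_lumen_mm2),
    A_jelly_max_mm2 = max(.data$A_jelly_mm2),
    A_jelly_min_mm2 = min(.data$A_jelly_mm2),
    ASF_jelly = tryCatch(area_shortening_fraction(.data$A_jelly_mm2),
                         error = function(e) NA_real_),
    peak_eps_myo = max(.data$eps_myo),
    peak_eps_endo = max(.data$eps_endo),
    lambda_max = max(.data$lambda, na.rm = TRUE),
    lambda_min = min(.data$lambda, na.rm = TRUE),
    max_expansion_mm_s = max(.data$dRdt_mm_s),
    max_contraction_mm_s = abs(min(.data$dRdt_mm_s)),
    T_e = phase_timings(.data$A_lumen_mm2, eps_closed)$T_e,
    T_c = phase_timings(.data$A_lumen_mm2, eps_closed)$T_c,
    T_closure = phase_timings(.data$A_lumen_mm2, eps_closed)$T_closure,
    .groups = "drop"
  )
}
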