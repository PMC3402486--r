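#' Fold a pressure trace onto the kinematic phase grid
#'
#' Folds a periodic pressure trace to one cycle, resamples it to the
#' kinematics phase grid, and circularly shifts it so that (default rule)
#' the peak pressure coincides with the phase of maximal lumen area at
#' plane 1. Pressure and wall motion are measured in different subjects, so
#' their phase relationship must be imposed; the applied shift is recorded.
#'
#' @param trace Tibble with `time_s`, `pressure_pa` (one site).
#' @param kin An [kinematics_table()] result (used for the phase grid and
#'   the alignment rule).
#' @param period_s Cardiac period of the trace (s); defaults to the
#'   kinematics period.
#' @param rule `"peak_area"` (align peak pressure with peak lumen area at
#'   the reference plane) or `"none"` (fold and resample only).
#' @param ref_plane Plane used by the alignment rule (default 1).
#' @return Tibble with `phase` (1..n_phases), `pressure_pa`; attribute
#'   `shift_phases` records the applied circular shift.
#' @export
align_pressure_phase <- function(trace, kin, period_s = NULL,
                                 rule = c("peak_area", "none"),
                                 ref_plane = 1L) {
  rule <- match.arg(rule)
  if (is.null(period_s)) period_s <- attr(kin, "period_s")
  n_phases <- attr(kin, "n_phases")
  if (diff(range(diff(trace$time_s))) > 1e-9) {
    stop("pressure trace must be uniformly sampled", call. = FALSE)
  }
  if (max(trace$time_s) < period_s) {
    stop("pressure trace shorter than one period", call. = FALSE)
  }
  ph <- (trace$time_s / period_s) %% 1
  grid <- (seq_len(n_phases) - 1) / n_phases
  # fold: local mean in each phase bin, then fill by periodic interpolation
  bin <- pmin(floor(ph * n_phases) + 1, n_phases)
  folded <- rep(NA_real_, n_phases)
  agg <- tapply(trace$pressure_pa, bin, mean)
  folded[as.integer(names(agg))] <- agg
  if (anyNA(folded)) {
    known <- which(!is.na(folded))
    folded <- stats::approx(c(known - n_phases, known, known + n_phases),
                            rep(folded[known], 3),
                            xout = seq_len(n_phases))$y
  }

  shift <- 0L
  if (rule == "peak_area") {
    a <- dplyr::filter(kin, .data$plane == ref_plane)
    if (nrow(a) == 0) stop("reference plane absent from kinematics", call. = FALSE)
    target <- which.max(a$A_lumen_mm2)
    src <- which.max(folded)
    shift <- (target - src) %% n_phases
    folded <- folded[((seq_len(n_phases) - 1 - shift) %% n_phases) + 1]
  }
  structure(tibble::tibble(phase = seq_len(n_phases), pressure_pa = folded,
                           phase_frac = grid),
            shift_phases = shift)
}

#' Linear axial interpolation of pressure along the tract
#'
#' `P(s, t) = (1 - s) P_vent(t) + s P_as(t)` for normalized axial position
#' `s` in `[0, 1]` between the ventricular (inlet) and aortic-sac (outlet)
#' measurement sites.
#'
#' @param p_vent,p_as Pressure series on a common phase grid (Pa).
#' @param s Normalized axial position(s) in `[0, 1]`.
#' @return Pressure series (or matrix if `length(s) > 1`, phases x
#'   positions).
#' @export
interpolate_pressure <- function(p_vent, p_as, s) {
  if (any(s < 0 | s > 1)) stop("s outside [0, 1]", call. = FALSE)
  stopifnot(length(p_vent) == length(p_as))
  out <- outer(p_vent, 1 - s) + outer(p_as, s)
  if (length(s) == 1) as.vector(out) else out
}

#' Laplace-law circumferential wall stress
#'
#' Thin-wall estimate `sigma = P R / h` with `P` the intracardiac pressure,
#' `R` the inner myocardial radius and `h` the average myocardial wall
#' thickness.
#'
#' @param P Pressure (Pa).
#' @param R Inner radius (mm).
#' @param h Wall thickness (mm), positive.
#' @return Stress (Pa).
#' @export
laplace_stress <- function(P, R, h) {
  if (any(h <= 0)) stop("wall thickness must be positive", call. = FALSE)
  P * R / h
}

#' Wall-stress series along the outflow tract
#'
#' For each plane: interpolates the aligned ventricular and aortic-sac
#' pressures to the plane's normalized axial position, and applies the
#' Laplace law with the plane's effective inner radius and wall thickness
#' per phase. Wall thickness defaults to the contour-derived per-phase value
#' in `kin` (`h_mm`, the difference of outer and inner effective radii);
#' a per-plane override can be supplied.
#'
#' @param kin An [kinematics_table()] result.
#' @param p_vent,p_as Aligned pressure tibbles from [align_pressure_phase()].
#' @param h_mm Optional per-plane wall thickness override (mm).
#' @param positions Normalized axial position of each plane (default evenly
#'   spaced 0..1).
#' @return An `oft_stress` tibble: `plane`, `frame`, `phase_frac`, `P_pa`,
#'   `R_mm`, `h_mm`, `sigma_pa`; attribute `peaks` holds per-plane peak
#'   stress.
#' @export
stress_profile <- function(kin, p_vent, p_as, h_mm = NULL, positions = NULL) {
  planes <- sort(unique(kin$plane))
  n_phases <- attr(kin, "n_phases")
  if (is.null(positions)) {
    positions <- if (length(planes) > 1) {
      (seq_along(planes) - 1) / (length(planes) - 1)
    } else 0
  }
  if (!is.null(h_mm)) h_mm <- rep_len(h_mm, length(planes))

  res <- purrr::map2_dfr(planes, seq_along(planes), function(pl, i) {
    a <- dplyr::arrange(dplyr::filter(kin, .data$plane == pl), .data$frame)
    h <- if (is.null(h_mm)) a$h_mm else rep(h_mm[i], nrow(a))
    if (any(!is.finite(h)) || any(h <= 0)) {
      stop("missing or non-positive wall thickness for plane ", pl, call. = FALSE)
    }
    P <- interpolate_pressure(p_vent$pressure_pa, p_as$pressure_pa, positions[i])
    stopifnot(length(P) == nrow(a))
    tibble::tibble(plane = pl, frame = a$frame,
                   phase_frac = (a$frame - 1) / n_phases,
                   P_pa = P, R_mm = a$R_eff_mm, h_mm = h,
                   sigma_pa = laplace_stress(P, a$R_eff_mm, h))
  })
  peaks <- dplyr::summarise(dplyr::group_by(res, .data$plane),
                            peak_sigma_pa = max(.data$sigma_pa),
                            .groups = "drop")
  structure(res, peaks = peaks, class = c("oft_stress", class(res)))
}
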