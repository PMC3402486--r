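#' Write / read an image sequence as multi-page TIFF
#'
#' Intensity frames are written as one multi-page 16-bit TIFF; the Doppler
#' phase channel, when present, is written to a parallel stack with values
#' rescaled from `(-pi, pi]` to `[0, 1]` (and rescaled back on read).
#'
#' @param seq An [image_sequence()].
#' @param path Path of the intensity TIFF.
#' @param phase_path Optional path of the phase TIFF.
#' @return `path`, invisibly.
#' @export
write_sequence_tiff <- function(seq, path, phase_path = NULL) {
  frames <- lapply(seq_len(n_frames(seq)), function(f) {
    pmin(pmax(seq$intensity[f, , ], 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  if (!is.null(phase_path) && !is.null(seq$phase)) {
    pframes <- lapply(seq_len(n_frames(seq)), function(f) {
      (seq$phase[f, , ] + pi) / (2 * pi)
    })
    tiff::writeTIFF(pframes, phase_path, bits.per.sample = 16)
  }
  invisible(path)
}

#' @rdname write_sequence_tiff
#' @param pixel_pitch_um,frame_rate_hz,plane_id Metadata restored on read
#'   (TIFF does not carry them).
#' @export
read_sequence_tiff <- function(path, phase_path = NULL, pixel_pitch_um = 5,
                               frame_rate_hz = 140, plane_id = 1L) {
  frames <- tiff::readTIFF(path, all = TRUE)
  nf <- length(frames)
  d <- dim(frames[[1]])
  intensity <- array(0, c(nf, d[1], d[2]))
  for (f in seq_len(nf)) intensity[f, , ] <- frames[[f]]
  phase <- NULL
  if (!is.null(phase_path)) {
    pf <- tiff::readTIFF(phase_path, all = TRUE)
    phase <- array(0, c(nf, d[1], d[2]))
    for (f in seq_len(nf)) phase[f, , ] <- pf[[f]] * 2 * pi - pi
    phase[phase <= -pi] <- pi
    phase[phase > pi] <- pi
  }
  image_sequence(intensity, phase, pixel_pitch_um, frame_rate_hz, plane_id)
}

#' Write / read pressure traces as CSV
#'
#' Columns `time_s`, `pressure_pa`, and optionally `site`.
#'
#' @param traces Tibble from [generate_pressure_traces()] (or one site's).
#' @param path CSV path.
#' @export
write_pressure_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write / read a tidy contour table as CSV
#'
#' @param contours Tidy contour tibble.
#' @param path CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  utils::write.csv(contours, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Read a YAML run configuration
#'
#' A single YAML file with optional blocks `phantom` (arguments of
#' [phantom_config()]), `segmentation` (arguments of [seg_params()]), and
#' `pipeline` (arguments of [run_pipeline()] such as `n_phases` or
#' `with_flow`). Unknown keys raise an error.
#'
#' @param path YAML path.
#' @return List with `phantom`, `segmentation`, `pipeline` ready to pass to
#'   [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("phantom", "segmentation", "pipeline"))
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  check_args <- function(block, fn, name) {
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad)) stop(sprintf("unknown %s keys: %s", name,
                                  paste(bad, collapse = ", ")), call. = FALSE)
    block
  }
  list(
    phantom = do.call(phantom_config,
                      check_args(y$phantom %||% list(), phantom_config, "phantom")),
    segmentation = do.call(seg_params,
                           check_args(y$segmentation %||% list(), seg_params,
                                      "segmentation")),
    pipeline = check_args(y$pipeline %||% list(), run_pipeline, "pipeline")
  )
}
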