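#' Scalar cardiac activity signal of an image sequence
#'
#' Collapses each frame transition to a scalar: the mean absolute
#' frame-to-frame intensity difference (`method = "tempdiff"`, the default;
#' invariant to static intensity offsets), or one minus the Pearson
#' correlation of consecutive frames (`method = "ncc"`). The signal is
#' periodic with the cardiac period and is the basis for period and phase-lag
#' estimation.
#'
#' @param seq An [image_sequence()] (or 3-D array `time x rows x cols`).
#' @param method `"tempdiff"` or `"ncc"`.
#' @return Numeric vector of length `n_frames - 1`.
#' @export
activity_signal <- function(seq, method = c("tempdiff", "ncc")) {
  method <- match.arg(method)
  arr <- if (inherits(seq, "image_sequence")) seq$intensity else seq
  nf <- dim(arr)[1]
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  flat <- matrix(arr, nrow = nf)
  if (method == "tempdiff") {
    rowMeans(abs(flat[-1, , drop = FALSE] - flat[-nf, , drop = FALSE]))
  } else {
    1 - vapply(seq_len(nf - 1), function(f) {
      stats::cor(flat[f, ], flat[f + 1, ])
    }, numeric(1))
  }
}

#' Estimate the cardiac period of an image sequence
#'
#' Autocorrelation of the scalar activity signal: the period is the first
#' dominant autocorrelation peak, refined to sub-frame precision by parabolic
#' interpolation through the peak and its two neighbours. The sequence must
#' span at least two cardiac cycles.
#'
#' @inheritParams activity_signal
#' @param min_peak Minimum autocorrelation (normalized) accepted as periodic
#'   structure; below it an error is raised.
#' @return Period in frames (possibly fractional).
#' @export
estimate_period <- function(seq, method = "tempdiff", min_peak = 0.2) {
  a <- activity_signal(seq, method)
  a <- a - mean(a)
  if (stats::sd(a) < 1e-12) stop("no periodic structure: flat activity signal",
                                 call. = FALSE)
  n <- length(a)
  ac <- stats::acf(a, lag.max = floor(n / 2), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  ac <- ac / ac[1]
  # first local maximum after the initial decay
  lag <- NA_integer_
  for (k in 3:(length(ac) - 1)) {
    if (ac[k] >= ac[k - 1] && ac[k] > ac[k + 1] && ac[k] >= min_peak) {
      lag <- k; break
    }
  }
  if (is.na(lag)) stop("no periodic structure: no autocorrelation peak above threshold",
                       call. = FALSE)
  # parabolic refinement (lags are 0-based: index k is lag k-1)
  y1 <- ac[lag - 1]; y2 <- ac[lag]; y3 <- ac[lag + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  (lag - 1) + delta
}

#' Estimate the phase lag between two planes' sequences
#'
#' Circular cross-correlation of the two planes' activity signals over one
#' period: the lag (in frames, in `[0, period)`) maximizing the correlation,
#' refined by parabolic interpolation. `other` lags `ref` by the returned
#' amount, i.e. `other(f) ~ ref(f - lag)`; for peristaltic motion the lag of
#' a distal plane relative to a proximal one is positive (modulo the period).
#'
#' @param ref,other [image_sequence()] objects sharing a frame rate.
#' @param period_frames Cardiac period in frames.
#' @inheritParams activity_signal
#' @return Lag in frames, in `[0, period_frames)`.
#' @export
estimate_phase_lag <- function(ref, other, period_frames,
                               method = "tempdiff") {
  if (inherits(ref, "image_sequence") && inherits(other, "image_sequence") &&
      !isTRUE(all.equal(ref$frame_rate_hz, other$frame_rate_hz))) {
    stop("sequences must share a frame rate", call. = FALSE)
  }
  a <- activity_signal(ref, method); b <- activity_signal(other, method)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    stop("flat activity signal: cannot estimate lag", call. = FALSE)
  }
  p <- floor(period_frames)
  n <- min(length(a), length(b))
  if (n < p) stop("sequences shorter than one period", call. = FALSE)
  a <- a[seq_len(n)] - mean(a[seq_len(n)])
  b <- b[seq_len(n)] - mean(b[seq_len(n)])
  # circular cross-correlation in phase (fold shifts modulo the period)
  cc <- vapply(0:(p - 1), function(k) {
    sum(b * a[((seq_len(n) - 1 - k) %% n) + 1])
  }, numeric(1))
  k0 <- which.max(cc) - 1
  y1 <- cc[((k0 - 1) %% p) + 1]; y2 <- cc[k0 + 1]; y3 <- cc[((k0 + 1) %% p) + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  (k0 + delta) %% period_frames
}

# fast row-wise median for a small number of columns
row_median_small <- function(m) {
  k <- ncol(m)
  if (k == 1) return(m[, 1])
  if (k == 2) return((m[, 1] + m[, 2]) / 2)
  if (k == 3) return(rowSums(m) - pmax(m[, 1], m[, 2], m[, 3]) -
                       pmin(m[, 1], m[, 2], m[, 3]))
  if (k == 4) {
    return((rowSums(m) - pmax(m[, 1], m[, 2], m[, 3], m[, 4]) -
              pmin(m[, 1], m[, 2], m[, 3], m[, 4])) / 2)
  }
  apply(m, 1, stats::median)
}

#' Synchronize per-plane sequences into one canonical cardiac cycle
#'
#' Circularly shifts each plane by its estimated lag, folds the shifted
#' sequence over the acquired cycles (per-pixel median across cycles at equal
#' phase, with linear interpolation between neighbouring frames), and
#' resamples to `n_phases` uniform phases shared by all planes. The global
#' phase origin is set to the most-constricted state of plane 1 (minimum of
#' its mean-intensity lumen proxy). Doppler phase channels are folded with
#' the same weights through the circular (complex) mean.
#'
#' @param sequences List of [image_sequence()] objects, proximal to distal.
#' @param lags Numeric vector of per-plane lags in frames (relative to
#'   plane 1), as from [estimate_phase_lag()].
#' @param period_frames Cardiac period in frames.
#' @param n_phases Number of uniform phases of the canonical cycle
#'   (default 196).
#' @return An `oft_sync` object: list with `cycle` (per plane, list with
#'   `intensity` and optionally `phase`, arrays `n_phases x rows x cols`),
#'   `period_frames`, `lags`, `n_phases`, `frame_rate_hz`, `pixel_pitch_um`,
#'   `phase_origin` (phase shift applied, in phases).
#' @export
synchronize <- function(sequences, lags, period_frames, n_phases = 196) {
  stopifnot(length(sequences) == length(lags), n_phases >= 2)
  fr <- unique(vapply(sequences, function(s) s$frame_rate_hz, numeric(1)))
  if (length(fr) != 1) stop("inconsistent frame rates", call. = FALSE)

  fold_plane <- function(arr, lag, circular = FALSE) {
    nf <- dim(arr)[1]; npx <- prod(dim(arr)[2:3])
    flat <- matrix(arr, nrow = nf)
    n_cyc <- max(1, floor((nf - 1) / period_frames))
    # sparse linear-interpolation weights: rows = (phase, cycle), cols = frame
    fis <- outer((seq_len(n_phases) - 1) / n_phases,
                 0:(n_cyc - 1), function(p, c) 1 + lag + (p + c) * period_frames)
    fis <- (as.vector(fis) - 1) %% (nf - 1) + 1
    lo <- pmin(floor(fis), nf - 1); w <- fis - lo
    nr <- length(fis)
    W <- matrix(0, nr, nf)
    W[cbind(seq_len(nr), lo)] <- 1 - w
    W[cbind(seq_len(nr), lo + 1)] <- W[cbind(seq_len(nr), lo + 1)] + w
    if (circular) {
      re <- W %*% cos(flat); im <- W %*% sin(flat)
      # circular mean across cycles at equal phase
      re_m <- matrix(0, n_phases, npx); im_m <- matrix(0, n_phases, npx)
      for (c in seq_len(n_cyc)) {
        idx <- (c - 1) * n_phases + seq_len(n_phases)
        re_m <- re_m + re[idx, , drop = FALSE]
        im_m <- im_m + im[idx, , drop = FALSE]
      }
      out <- atan2(im_m, re_m)
    } else {
      interp <- W %*% flat # (n_phases * n_cyc) x npx
      out <- matrix(0, n_phases, npx)
      for (p in seq_len(n_phases)) {
        idx <- p + (0:(n_cyc - 1)) * n_phases
        out[p, ] <- row_median_small(t(interp[idx, , drop = FALSE]))
      }
    }
    array(out, c(n_phases, dim(arr)[2], dim(arr)[3]))
  }

  cycle <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    res <- list(intensity = fold_plane(s$intensity, lags[i]))
    if (!is.null(s$phase)) {
      ph <- fold_plane(s$phase, lags[i], circular = TRUE)
      ph[ph <= -pi] <- pi
      res$phase <- ph
    }
    res
  })

  # global phase origin: most-constricted state of plane 1
  proxy <- rowMeans(matrix(cycle[[1]]$intensity, nrow = n_phases))
  shift <- which.min(proxy) - 1
  roll <- function(a) {
    idx <- ((seq_len(n_phases) - 1 + shift) %% n_phases) + 1
    a[idx, , , drop = FALSE]
  }
  cycle <- lapply(cycle, function(pl) lapply(pl, roll))

  structure(
    list(cycle = cycle, period_frames = period_frames, lags = lags,
         n_phases = as.integer(n_phases), frame_rate_hz = fr,
         pixel_pitch_um = sequences[[1]]$pixel_pitch_um,
         phase_origin = shift),
    class = "oft_sync"
  )
}

#' @export
print.oft_sync <- function(x, ...) {
  cat(sprintf("<oft_sync> %d planes, canonical cycle of %d phases (period %.2f frames)\n",
              length(x$cycle), x$n_phases, x$period_frames))
  cat("  lags (frames):", paste(sprintf("%.2f", x$lags), collapse = ", "), "\n")
  invisible(x)
}

#' Extract an M-mode (or M-phase) image along a line
#'
#' Samples the chosen channel along a fixed pixel line in every frame and
#' stacks the profiles as columns: rows are positions along the line
#' (space), columns are frames (time). With `channel = "phase"` the result
#' is an M-phase image with values in `(-pi, pi]`.
#'
#' @param seq An [image_sequence()], an `oft_sync` plane entry, or a 3-D
#'   array `time x rows x cols`.
#' @param line Either a list with `x0, y0, x1, y1` endpoints in pixel
#'   coordinates (column, row; 1-based) and optional `n` samples, or an
#'   `n x 2` matrix of (col, row) pixel coordinates.
#' @param channel `"intensity"` or `"phase"`.
#' @return A numeric matrix `space x time` of class `oft_mmode`, with the
#'   sampled pixel coordinates in attributes.
#' @export
extract_mmode <- function(seq, line, channel = c("intensity", "phase")) {
  channel <- match.arg(channel)
  arr <- if (is.array(seq)) seq else seq[[channel]]
  if (is.null(arr)) stop("sequence has no ", channel, " channel", call. = FALSE)
  d <- dim(arr)
  if (is.list(line) && !is.matrix(line)) {
    n <- line$n %||% max(2, round(sqrt((line$x1 - line$x0)^2 +
                                         (line$y1 - line$y0)^2)) + 1)
    pts <- cbind(seq(line$x0, line$x1, length.out = n),
                 seq(line$y0, line$y1, length.out = n))
  } else {
    pts <- as.matrix(line)
  }
  if (any(pts[, 1] < 1 | pts[, 1] > d[3] | pts[, 2] < 1 | pts[, 2] > d[2])) {
    stop("line outside image bounds", call. = FALSE)
  }
  out <- matrix(0, nrow(pts), d[1])
  x <- pts[, 1]; y <- pts[, 2]
  x0 <- pmin(floor(x), d[3] - 1); y0 <- pmin(floor(y), d[2] - 1)
  wx <- x - x0; wy <- y - y0
  for (f in seq_len(d[1])) {
    fr <- arr[f, , ]
    out[, f] <- (1 - wx) * (1 - wy) * fr[cbind(y0, x0)] +
      wx * (1 - wy) * fr[cbind(y0, x0 + 1)] +
      (1 - wx) * wy * fr[cbind(y0 + 1, x0)] +
      wx * wy * fr[cbind(y0 + 1, x0 + 1)]
  }
  structure(out, class = c("oft_mmode", "matrix"),
            points = pts, channel = channel)
}
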