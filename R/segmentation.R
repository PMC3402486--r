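#' Active-contour segmentation parameters
#'
#' Tunable parameters of the snake segmentation. `alpha` and `beta` weight
#' the first- and second-derivative smoothness of the contour, `sigma_px` is
#' the Gaussian pre-smoothing scale of the edge map, `gvf_iter`/`gvf_mu`
#' control the gradient-vector-flow-style diffusion of the image force field,
#' and the snake is declared converged when the maximum vertex displacement
#' falls below `tol_px` pixels (or `max_iter` is reached).
#'
#' @param alpha First-derivative (elasticity) weight.
#' @param beta Second-derivative (stiffness) weight.
#' @param sigma_px Gaussian smoothing sigma for the edge map (pixels).
#' @param n_vertices Number of snake vertices.
#' @param gvf_iter Diffusion iterations for the force field.
#' @param gvf_mu Diffusion strength per iteration.
#' @param gamma Implicit time-step weight of the snake update.
#' @param force_scale Step size applied to the sampled image force.
#' @param max_iter Iteration cap.
#' @param tol_px Convergence threshold on vertex displacement (pixels).
#' @return A named list of class `seg_params`.
#' @export
seg_params <- function(alpha = 0.1, beta = 0.05, sigma_px = 1.5,
                       n_vertices = 64, gvf_iter = 40, gvf_mu = 0.2,
                       gamma = 1, force_scale = 3, max_iter = 200,
                       tol_px = 0.1) {
  structure(list(alpha = alpha, beta = beta, sigma_px = sigma_px,
                 n_vertices = as.integer(n_vertices),
                 gvf_iter = as.integer(gvf_iter), gvf_mu = gvf_mu,
                 gamma = gamma, force_scale = force_scale,
                 max_iter = as.integer(max_iter), tol_px = tol_px),
            class = "seg_params")
}

# ---- low-level image helpers (base R; edge-replicated) ----

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci]
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  # separable convolution with edge replication via padding
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(rep(1, r), seq_len(nr), rep(nr, r)), c(rep(1, r), seq_len(nc), rep(nc, r))]
  out <- matrix(0, nr, nc + 2 * r)
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + nr - 1), ]
  res <- matrix(0, nr, nc)
  for (i in seq_along(k)) res <- res + k[i] * out[, i:(i + nc - 1)]
  res
}

grad_x <- function(m) (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2 # d/dcol
grad_y <- function(m) (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / 2 # d/drow
laplacian <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
}

bilinear_sample <- function(m, x, y) {
  # x = column, y = row, 1-based, clamped to the image
  x <- pmin(pmax(x, 1), ncol(m)); y <- pmin(pmax(y, 1), nrow(m))
  x0 <- pmin(floor(x), ncol(m) - 1); y0 <- pmin(floor(y), nrow(m) - 1)
  wx <- x - x0; wy <- y - y0
  (1 - wx) * (1 - wy) * m[cbind(y0, x0)] +
    wx * (1 - wy) * m[cbind(y0, x0 + 1)] +
    (1 - wx) * wy * m[cbind(y0 + 1, x0)] +
    wx * wy * m[cbind(y0 + 1, x0 + 1)]
}

#' Estimate and remove exponential depth attenuation
#'
#' OCT intensity decays along the beam (row) axis. The decay rate is
#' estimated from the log-ratio of mirror-symmetric row means (the phantom
#' and the embryonic tube are approximately symmetric about the section
#' center, so any asymmetry in depth is attributed to attenuation) and the
#' image is rescaled to a flat depth response.
#'
#' @param img Intensity matrix (rows = depth).
#' @param return_rate Return the estimated rate instead of the corrected
#'   image.
#' @return Corrected image (or attenuation rate in 1/rows).
#' @export
correct_depth_attenuation <- function(img, return_rate = FALSE) {
  nr <- nrow(img)
  rm <- rowMeans(img)
  r <- seq_len(nr)
  mirror <- nr + 1 - r
  ok <- rm > 0 & rm[mirror] > 0 & r < mirror
  if (!any(ok)) return(if (return_rate) 0 else img)
  # log(rm[r] / rm[mirror]) = -rate * (r - mirror)
  rate <- stats::median(log(rm[r][ok] / rm[mirror][ok]) /
                          -(r[ok] - mirror[ok]))
  if (!is.finite(rate)) rate <- 0
  if (return_rate) return(rate)
  img * exp(rate * (r - (nr + 1) / 2))
}

# k-means intensity classes, darkest to brightest; centers refined to the
# per-class median so boundary (mixture) pixels do not drag the thresholds
intensity_classes <- function(img, k = 4) {
  v <- as.vector(img)
  q <- stats::quantile(v, seq(0.05, 0.95, length.out = k))
  km <- suppressWarnings(stats::kmeans(v, centers = unique(q), iter.max = 30))
  centers <- sort(as.vector(km$centers))
  for (i in 1:2) {
    thr <- (centers[-1] + centers[-length(centers)]) / 2
    cls_v <- findInterval(v, thr) + 1
    centers <- vapply(seq_along(centers), function(j) {
      if (any(cls_v == j)) stats::median(v[cls_v == j]) else centers[j]
    }, numeric(1))
    centers <- sort(centers)
  }
  thr <- (centers[-1] + centers[-length(centers)]) / 2
  cls <- matrix(findInterval(v, thr) + 1, nrow(img), ncol(img))
  list(centers = centers, class = cls)
}

# circular moving-average smoothing of a radius profile
smooth_circular <- function(r, w = 3) {
  n <- length(r)
  k <- (w - 1) / 2
  out <- numeric(n)
  for (d in -k:k) out <- out + r[((seq_len(n) - 1 + d) %% n) + 1]
  out / w
}

# Radial-ray initialization: for each of n angles from `center` (col,row px),
# find the [inner, outer] radii of the longest run of `mask` along the ray.
radial_init <- function(mask, center, n = 64, r_step = 0.5,
                        mode = c("longest", "first")) {
  mode <- match.arg(mode)
  rmax <- min(nrow(mask), ncol(mask)) / 2 - 1
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rr <- seq(r_step, rmax, by = r_step)
  inner <- outer <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vals <- bilinear_sample(mask * 1, center[1] + rr * cos(ang[i]),
                            center[2] + rr * sin(ang[i])) > 0.5
    runs <- rle(vals)
    if (!any(runs$values)) next
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- which(runs$values)
    best <- if (mode == "first") k[1] else k[which.max(runs$lengths[k])]
    inner[i] <- rr[starts[best]]
    outer[i] <- rr[ends[best]]
  }
  if (mean(is.na(inner)) > 0.25) {
    stop("segmentation error: no stable boundary found from initialization",
         call. = FALSE)
  }
  if (mode == "longest") {
    # a real myocardial band yields a smooth ring; wildly jumping radii mean
    # the mask is incoherent (e.g. a corrupted frame)
    rough <- stats::median(abs(diff(c(outer, outer[1]))), na.rm = TRUE) /
      stats::median(outer, na.rm = TRUE)
    if (!is.finite(rough) || rough > 0.25) {
      stop("segmentation error: incoherent boundary mask", call. = FALSE)
    }
  }
  # fill failed rays from circular neighbours
  for (v in c("inner", "outer")) {
    r <- get(v)
    if (anyNA(r)) {
      idx <- which(is.na(r))
      good <- which(!is.na(r))
      for (j in idx) r[j] <- r[good[which.min(pmin(abs(good - j), length(r) - abs(good - j)))]]
      assign(v, r)
    }
  }
  list(angle = ang, inner = smooth_circular(inner), outer = smooth_circular(outer))
}

# pentadiagonal circulant snake matrix, returns solve(gamma I + A)
snake_inverse <- function(n, alpha, beta, gamma) {
  a <- beta
  b <- -alpha - 4 * beta
  c0 <- 2 * alpha + 6 * beta
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, ((i - 1 + c(-2, -1, 0, 1, 2)) %% n) + 1] <- c(a, b, c0, b, a)
  }
  solve(gamma * diag(n) + A)
}

# gradient-vector-flow-style diffusion of the edge force field
gvf_force <- function(edge, mu, iters) {
  fx <- grad_x(edge); fy <- grad_y(edge)
  g2 <- fx^2 + fy^2
  u <- fx; v <- fy
  for (i in seq_len(iters)) {
    u <- u + mu * laplacian(u) - g2 * (u - fx)
    v <- v + mu * laplacian(v) - g2 * (v - fy)
  }
  list(u = u, v = v)
}

# Sub-pixel edge relocation: move each vertex along its radial direction to
# the crossing of the local mid-level between the plateaus just inside and
# just outside the contour, sampled on a lightly smoothed image. Removes the
# systematic localization bias that heavier smoothing introduces when a thin
# dark layer separates two bright ones; the per-vertex noise this admits is
# zero-mean and averages out of enclosed areas.
edge_relocate <- function(xy, img, max_shift = 2, probe = 3, step = 0.25) {
  c0 <- colMeans(xy)
  dx <- xy[, 1] - c0[1]; dy <- xy[, 2] - c0[2]
  rr <- sqrt(dx^2 + dy^2)
  if (mean(rr) < 2 * probe) return(xy) # too small to probe (collapsed slit)
  ux <- dx / rr; uy <- dy / rr
  rs <- seq(-probe, probe, by = step)
  vals <- vapply(rs, function(r) {
    bilinear_sample(img, xy[, 1] + r * ux, xy[, 2] + r * uy)
  }, numeric(nrow(xy))) # vertices x probes
  inside <- rowMeans(vals[, rs <= -probe / 2, drop = FALSE])
  outside <- rowMeans(vals[, rs >= probe / 2, drop = FALSE])
  thr <- (inside + outside) / 2
  shift <- numeric(nrow(xy))
  for (i in seq_len(nrow(xy))) {
    d <- vals[i, ] - thr[i]
    sc <- which(d[-length(d)] * d[-1] <= 0 & abs(diff(d)) > 0)
    if (length(sc) == 0) next
    r_cross <- rs[sc] + step * abs(d[sc]) / abs(d[sc + 1] - d[sc])
    shift[i] <- r_cross[which.min(abs(r_cross))]
  }
  shift <- pmin(pmax(shift, -max_shift), max_shift)
  cbind(xy[, 1] + shift * ux, xy[, 2] + shift * uy)
}

snake_refine <- function(xy, force, Minv, params) {
  n <- nrow(xy)
  for (it in seq_len(params$max_iter)) {
    fx <- bilinear_sample(force$u, xy[, 1], xy[, 2])
    fy <- bilinear_sample(force$v, xy[, 1], xy[, 2])
    newx <- Minv %*% (params$gamma * xy[, 1] + params$force_scale * fx)
    newy <- Minv %*% (params$gamma * xy[, 2] + params$force_scale * fy)
    disp <- max(abs(newx - xy[, 1]), abs(newy - xy[, 2]))
    xy <- cbind(as.vector(newx), as.vector(newy))
    if (disp < params$tol_px) break
  }
  xy
}

#' Segment one boundary in a single intensity frame
#'
#' A snake (active contour) minimizing internal smoothness energy (weights
#' `alpha`, `beta`) plus an external image force: the negative gradient
#' magnitude of the Gaussian-smoothed image, diffused by a
#' gradient-vector-flow-style iteration so the force reaches the contour from
#' a distance. When no initial contour is supplied, the snake is initialized
#' from intensity classes (k-means): the bright myocardial band for the
#' myocardial labels; the mid-level lumen/endocardium region for `endo`.
#' When the lumen is closed, the `endo` contour returned is the boundary of
#' the residual mid-level slit.
#'
#' @param image Intensity matrix (one frame, rows = depth).
#' @param init Optional initial contour: matrix/data frame with columns
#'   (x, y) in *pixel* coordinates (col, row), or a tidy contour tibble in mm
#'   (converted using `pixel_pitch_um`).
#' @param label `"myo_outer"`, `"myo_inner"`, or `"endo"`.
#' @param params A [seg_params()].
#' @param pixel_pitch_um Pixel pitch used to express the result in mm.
#' @param plane,frame Identifiers stamped on the output rows.
#' @return Tidy contour tibble (counter-clockwise, in mm, origin at the
#'   image center).
#' @param ctx Optional precomputed [frame_context()] for this image (shared
#'   across labels for speed).
#' @export
segment_frame <- function(image, init = NULL,
                          label = c("myo_inner", "myo_outer", "endo"),
                          params = seg_params(), pixel_pitch_um = 5,
                          plane = 1L, frame = 1L, ctx = NULL) {
  label <- match.arg(label)
  if (is.null(ctx)) ctx <- frame_context(image, params)

  if (is.null(init)) {
    xy <- init_boundary(ctx, label, params)
  } else {
    xy <- init_to_px(init, pixel_pitch_um, dim(image))
    xy <- as.matrix(xy)
    rs <- resample_contour(xy[, 1], xy[, 2], params$n_vertices)
    xy <- cbind(rs$x, rs$y)
  }
  xy <- snake_refine(xy, ctx$force[[label]], ctx$Minv, params)
  xy <- edge_relocate(xy, ctx$light)

  ctr <- (dim(image) + 1) / 2
  x_mm <- (xy[, 1] - ctr[2]) * pixel_pitch_um / 1000
  y_mm <- (xy[, 2] - ctr[1]) * pixel_pitch_um / 1000
  p <- ensure_ccw(x_mm, y_mm)
  contour_tbl(p$x, p$y, plane = plane, frame = frame, label = label)
}

#' Shared per-frame segmentation context
#'
#' Precomputes the depth-corrected image, its Gaussian-smoothed version, the
#' tissue-class map, label-specific edge maps and diffused force fields, and
#' the snake system inverse, so several labels can be segmented on one frame
#' without repeating the image work. The external force is label-specific:
#' the myocardial boundaries attach to the edges of the bright (myocardial)
#' intensity class, the endocardium to the edges of the mid-level
#' (lumen/endocardium) class, so the weak lumen-jelly edge is not captured
#' by the much stronger myocardial edge when the cardiac jelly is thin.
#'
#' @param image Intensity matrix.
#' @param params A [seg_params()].
#' @param centers Optional fixed intensity-class centers (ascending), e.g.
#'   estimated once per sequence; estimated from this frame when `NULL`.
#' @return A list with `img`, `sm`, `class`, `centers`, per-label `force`
#'   fields, and `Minv`.
#' @export
frame_context <- function(image, params = seg_params(), centers = NULL) {
  img <- correct_depth_attenuation(image)
  sm <- gaussian_blur(img, params$sigma_px)
  if (is.null(centers)) {
    centers <- intensity_classes(sm, 4)$centers
  }
  cls <- classify_levels(sm, centers)
  k <- length(centers)
  gmag <- sqrt(grad_x(sm)^2 + grad_y(sm)^2)
  # isophote-selective edge map: gradient magnitude gated to the midpoint
  # level between the two tissue classes meeting at the target boundary, so
  # each snake attaches to its own boundary and the crossing is unbiased
  make_force <- function(lo, hi) {
    thr <- (lo + hi) / 2; delta <- (hi - lo) / 4
    edge <- gmag * exp(-(sm - thr)^2 / (2 * delta^2))
    edge <- edge / max(edge, 1e-12)
    gvf_force(edge, params$gvf_mu, params$gvf_iter)
  }
  list(img = img, sm = sm, light = gaussian_blur(img, min(0.75, params$sigma_px)),
       class = cls, centers = centers,
       force = list(myo_inner = make_force(centers[2], centers[k]),
                    myo_outer = make_force(centers[1], centers[k]),
                    endo = make_force(centers[2], centers[k - 1])),
       Minv = snake_inverse(params$n_vertices, params$alpha, params$beta,
                            params$gamma))
}

# nearest-center classification given fixed ascending centers
classify_levels <- function(img, centers) {
  thr <- (centers[-1] + centers[-length(centers)]) / 2
  cls <- matrix(1L, nrow(img), ncol(img))
  for (t in thr) cls <- cls + (img > t)
  cls
}

init_to_px <- function(init, pixel_pitch_um, dims) {
  if (is.data.frame(init) && all(c("x_mm", "y_mm") %in% names(init))) {
    ctr <- (dims + 1) / 2
    cbind(init$x_mm * 1000 / pixel_pitch_um + ctr[2],
          init$y_mm * 1000 / pixel_pitch_um + ctr[1])
  } else {
    as.matrix(init)
  }
}

init_boundary <- function(ctx, label, params) {
  cl <- list(centers = ctx$centers, class = ctx$class)
  k <- length(cl$centers)
  if (label %in% c("myo_inner", "myo_outer")) {
    mask <- cl$class == k # brightest class: myocardium
    # a myocardial ring occupies a limited fraction of the field of view; a
    # mask filling most of it (or almost none) signals a corrupted frame
    if (mean(mask) > 0.45 || mean(mask) < 0.02) {
      stop("segmentation error: implausible myocardial mask", call. = FALSE)
    }
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) < 10) stop("segmentation error: no myocardial band", call. = FALSE)
    center <- c(mean(idx[, 2]), mean(idx[, 1])) # (col, row)
    ri <- radial_init(mask, center, params$n_vertices)
    r <- if (label == "myo_inner") ri$inner else ri$outer
  } else {
    # endo: mid-level lumen class (below myocardium, above jelly), the
    # connected region around the tube center
    mask_my <- cl$class == k
    idx <- which(mask_my, arr.ind = TRUE)
    center <- c(mean(idx[, 2]), mean(idx[, 1]))
    mask <- cl$class == (k - 1)
    # keep only pixels inside the myocardial inner boundary
    ri_my <- radial_init(mask_my, center, params$n_vertices)
    ang_all <- atan2(row(mask) - center[2], col(mask) - center[1])
    rad_all <- sqrt((col(mask) - center[1])^2 + (row(mask) - center[2])^2)
    lim <- stats::approx(c(ri_my$angle - 2 * pi, ri_my$angle, ri_my$angle + 2 * pi),
                         rep(ri_my$inner, 3), xout = as.vector(ang_all))$y
    mask <- mask & (rad_all < matrix(lim, nrow(mask), ncol(mask)))
    if (sum(mask) < 4) stop("segmentation error: no lumen region", call. = FALSE)
    idx <- which(mask, arr.ind = TRUE)
    lcenter <- c(mean(idx[, 2]), mean(idx[, 1]))
    # first run from the lumen centroid: the slit boundary when closed (the
    # blurred jelly-myocardium transition ring also sits at mid level and
    # must not be picked up)
    ri <- radial_init(mask, lcenter, params$n_vertices, mode = "first")
    center <- lcenter
    r <- ri$outer
  }
  cbind(center[1] + r * cos(ri$angle), center[2] + r * sin(ri$angle))
}

#' Segment a boundary through a whole sequence with temporal propagation
#'
#' Frame 1 is segmented from scratch; each subsequent frame is initialized by
#' warping the previous contour with a coarse optical-flow estimate (global
#' translation from a least-squares gradient fit plus an isotropic scale from
#' the bright-band mask area) and then refined by [segment_frame()]. If the
#' enclosed area jumps by more than 50% between consecutive frames, the frame
#' is re-segmented from scratch; a frame whose from-scratch segmentation also
#' fails raises an error naming the frame.
#'
#' @param seq An [image_sequence()], a plane entry of an `oft_sync`, or a
#'   3-D array `time x rows x cols`.
#' @param labels Character vector of boundary labels to track.
#' @param params A [seg_params()].
#' @param pixel_pitch_um Pixel pitch (um); taken from `seq` when available.
#' @param plane Plane identifier stamped on the output.
#' @return Tidy contour tibble across all frames and labels.
#' @export
propagate_contours <- function(seq, labels = c("myo_outer", "myo_inner", "endo"),
                               params = seg_params(), pixel_pitch_um = NULL,
                               plane = 1L) {
  arr <- if (is.array(seq)) seq else seq$intensity
  if (is.null(pixel_pitch_um)) {
    pixel_pitch_um <- if (!is.null(seq$pixel_pitch_um)) seq$pixel_pitch_um else 5
  }
  nf <- dim(arr)[1]
  # class levels estimated once and held fixed across the sequence (stable
  # through lumen closure): componentwise median of per-frame estimates, so
  # a single corrupted frame cannot drag the thresholds
  sub <- unique(round(seq(1, nf, length.out = min(8, nf))))
  per_frame <- vapply(sub, function(f) {
    intensity_classes(gaussian_blur(correct_depth_attenuation(arr[f, , ]),
                                    params$sigma_px), 4)$centers
  }, numeric(4))
  centers <- apply(per_frame, 1, stats::median)
  out <- vector("list", nf * length(labels))
  i <- 0
  prev <- stats::setNames(vector("list", length(labels)), labels)
  prev_area <- stats::setNames(rep(NA_real_, length(labels)), labels)
  carries <- stats::setNames(rep(0L, length(labels)), labels)
  prev_ctx <- NULL
  for (f in seq_len(nf)) {
    img <- arr[f, , ]
    ctx <- frame_context(img, params, centers = centers)
    for (lab in labels) {
      init <- NULL
      # the endocardium collapses to a slit at closure and re-opens with a
      # different topology scale: warm-starting it from the previous frame
      # traps the snake in the collapsed state, so it is re-initialized from
      # the class map every frame
      if (!is.null(prev[[lab]]) && lab != "endo") {
        # after a carried (unsegmentable) frame the optical-flow estimate is
        # meaningless; reuse the carried contour directly
        init <- if (carries[[lab]] > 0L) prev[[lab]] else {
          warp_contour(prev[[lab]], prev_ctx$sm, ctx$sm, pixel_pitch_um)
        }
      }
      ct <- tryCatch(
        segment_frame(img, init = init, label = lab, params = params,
                      pixel_pitch_um = pixel_pitch_um, plane = plane,
                      frame = f, ctx = ctx),
        error = function(e) NULL
      )
      area <- if (is.null(ct)) NA_real_ else abs(polygon_area(ct$x_mm, ct$y_mm))
      # area-jump divergence applies to the warm-started (myocardial)
      # labels; the endocardium legitimately collapses by more than 50%
      # between frames at closure and is scratch-initialized anyway
      jump <- lab != "endo" && !is.null(ct) && is.finite(prev_area[[lab]]) &&
        prev_area[[lab]] > 0 &&
        abs(area - prev_area[[lab]]) / prev_area[[lab]] > 0.5
      if (is.null(ct) || jump) {
        ct <- tryCatch(
          segment_frame(img, init = NULL, label = lab, params = params,
                        pixel_pitch_um = pixel_pitch_um, plane = plane,
                        frame = f, ctx = ctx),
          error = function(e) NULL
        )
        if (is.null(ct)) {
          # unsegmentable frame (e.g. corrupted): carry the last good
          # contour forward so the next frame can recover; persistent
          # failure is an error
          carries[[lab]] <- carries[[lab]] + 1L
          if (carries[[lab]] > 3L || is.null(prev[[lab]])) {
            stop(sprintf("segmentation failed at frame %d (label %s)",
                         f, lab), call. = FALSE)
          }
          ct <- dplyr::mutate(prev[[lab]], frame = f)
          area <- prev_area[[lab]]
        } else {
          carries[[lab]] <- 0L
          area <- abs(polygon_area(ct$x_mm, ct$y_mm))
        }
      } else {
        carries[[lab]] <- 0L
      }
      i <- i + 1
      out[[i]] <- ct
      prev[[lab]] <- ct; prev_area[[lab]] <- area
    }
    prev_ctx <- ctx
  }
  dplyr::bind_rows(out)
}

# coarse optical-flow warp: global translation (least-squares on image
# gradients) + isotropic scaling from bright-mask area ratio, applied about
# the contour centroid; operates on pre-smoothed images
warp_contour <- function(ct, sm1, sm2, pixel_pitch_um) {
  ix <- grad_x(sm1); iy <- grad_y(sm1); it <- sm2 - sm1
  A <- matrix(c(sum(ix * ix), sum(ix * iy), sum(ix * iy), sum(iy * iy)), 2, 2)
  d <- tryCatch(solve(A, -c(sum(ix * it), sum(iy * it))), error = function(e) c(0, 0))
  thr <- (stats::quantile(sm1, 0.9) + stats::median(sm1)) / 2
  a1 <- sum(sm1 > thr); a2 <- sum(sm2 > thr)
  sc <- if (a1 > 0) sqrt(a2 / a1) else 1
  sc <- min(max(sc, 0.8), 1.25)
  cx <- mean(ct$x_mm); cy <- mean(ct$y_mm)
  dx_mm <- d[1] * pixel_pitch_um / 1000; dy_mm <- d[2] * pixel_pitch_um / 1000
  tibble::tibble(x_mm = cx + (ct$x_mm - cx) * sc + dx_mm,
                 y_mm = cy + (ct$y_mm - cy) * sc + dy_mm)
}

#' Compute the outflow-tract centerline from multi-plane contours
#'
#' A smooth curve through the inner-myocardial centroids of the analysis
#' planes, ordered proximal to distal, evaluated at the most-constricted
#' phase (the frame minimizing total inner-myocardial area) unless a frame is
#' given.
#'
#' @param contours Tidy contour tibble covering `myo_inner` on >= 2 planes.
#' @param plane_z_um Axial position (um) of each plane, ascending.
#' @param frame Frame/phase index to use; default: most-constricted frame.
#' @param n_samples Number of points of the returned polyline.
#' @return Tibble polyline with `s_mm` (arc length), `x_mm`, `y_mm`, `z_mm`,
#'   plus attribute `centroids` (per-plane centroids used).
#' @export
compute_centerline <- function(contours, plane_z_um, frame = NULL,
                               n_samples = 200) {
  mi <- dplyr::filter(contours, .data$label == "myo_inner")
  if (length(unique(mi$plane)) < 2) {
    stop("need myo_inner contours on at least 2 planes", call. = FALSE)
  }
  meas <- measure_contours(mi)
  if (is.null(frame)) {
    tot <- dplyr::summarise(dplyr::group_by(meas, .data$frame),
                            a = sum(.data$area_mm2), .groups = "drop")
    frame <- tot$frame[which.min(tot$a)]
  }
  cen <- dplyr::arrange(dplyr::filter(meas, .data$frame == !!frame), .data$plane)
  z_mm <- plane_z_um[cen$plane] / 1000
  interp <- function(v) {
    if (length(z_mm) >= 4) stats::splinefun(z_mm, v, method = "natural")
    else stats::approxfun(z_mm, v, rule = 2)
  }
  fx <- interp(cen$centroid_x_mm); fy <- interp(cen$centroid_y_mm)
  zz <- seq(min(z_mm), max(z_mm), length.out = n_samples)
  xx <- fx(zz); yy <- fy(zz)
  s <- c(0, cumsum(sqrt(diff(xx)^2 + diff(yy)^2 + diff(zz)^2)))
  structure(
    tibble::tibble(s_mm = s, x_mm = xx, y_mm = yy, z_mm = zz),
    centroids = cen, frame = frame
  )
}

#' Select evenly spaced cross-sections along a centerline
#'
#' @param centerline Tibble from [compute_centerline()].
#' @param n Number of cross-sections (>= 2).
#' @return Tibble with the section centers (`x_mm`, `y_mm`, `z_mm`), arc
#'   position `s_mm`, and unit normals (`nx`, `ny`, `nz`) equal to the
#'   centerline tangents.
#' @export
select_cross_sections <- function(centerline, n = 5) {
  if (n < 2) stop("need at least 2 cross-sections", call. = FALSE)
  s_tot <- max(centerline$s_mm)
  if (s_tot <= 0) stop("centerline has zero arc length", call. = FALSE)
  si <- seq(0, s_tot, length.out = n)
  gx <- stats::approxfun(centerline$s_mm, centerline$x_mm)
  gy <- stats::approxfun(centerline$s_mm, centerline$y_mm)
  gz <- stats::approxfun(centerline$s_mm, centerline$z_mm)
  eps <- s_tot / 1000
  tx <- (gx(pmin(si + eps, s_tot)) - gx(pmax(si - eps, 0)))
  ty <- (gy(pmin(si + eps, s_tot)) - gy(pmax(si - eps, 0)))
  tz <- (gz(pmin(si + eps, s_tot)) - gz(pmax(si - eps, 0)))
  nrm <- sqrt(tx^2 + ty^2 + tz^2)
  tibble::tibble(section = seq_len(n), s_mm = si,
                 x_mm = gx(si), y_mm = gy(si), z_mm = gz(si),
                 nx = tx / nrm, ny = ty / nrm, nz = tz / nrm)
}
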