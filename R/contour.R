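#' Contour utilities
#'
#' Contours are closed planar polygons stored tidily: one row per vertex with
#' columns `plane`, `frame`, `label`, `vertex`, `x_mm`, `y_mm`. Vertices are
#' ordered counter-clockwise and the polygon is implicitly closed (the last
#' vertex connects back to the first). These helpers compute the geometric
#' primitives every downstream metric relies on.
#'
#' @name contour-utils
NULL

#' Signed polygon area by the shoelace formula
#'
#' @param x,y Vertex coordinates (closed implicitly).
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon perimeter (summed vertex distances, closed)
#'
#' @inheritParams polygon_area
#' @return Perimeter length.
#' @export
polygon_perimeter <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  j <- c(seq_len(n)[-1], 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' Force counter-clockwise orientation
#'
#' @inheritParams polygon_area
#' @return List with `x`, `y` in counter-clockwise order.
#' @export
ensure_ccw <- function(x, y) {
  if (polygon_area(x, y) < 0) list(x = rev(x), y = rev(y)) else list(x = x, y = y)
}

#' Resample a closed polygon to n equally spaced vertices
#'
#' Arc-length resampling; preserves perimeter and area to high accuracy for
#' well-resolved contours.
#'
#' @inheritParams polygon_area
#' @param n Number of output vertices.
#' @return List with `x`, `y` of length `n`.
#' @export
resample_contour <- function(x, y, n = 64) {
  xs <- c(x, x[1]); ys <- c(y, y[1])
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  s <- c(0, cumsum(seg))
  tot <- s[length(s)]
  if (tot <= 0) stop("degenerate (zero-length) contour", call. = FALSE)
  si <- seq(0, tot, length.out = n + 1)[-(n + 1)]
  list(x = stats::approx(s, xs, xout = si)$y,
       y = stats::approx(s, ys, xout = si)$y)
}

# basic simplicity check: no two non-adjacent edges intersect (O(n^2))
is_simple_polygon <- function(x, y) {
  n <- length(x)
  if (n < 4) return(TRUE)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  seg_int <- function(i, j) {
    d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    a1 <- d(xs[i], ys[i], xs[i + 1], ys[i + 1], xs[j], ys[j])
    a2 <- d(xs[i], ys[i], xs[i + 1], ys[i + 1], xs[j + 1], ys[j + 1])
    a3 <- d(xs[j], ys[j], xs[j + 1], ys[j + 1], xs[i], ys[i])
    a4 <- d(xs[j], ys[j], xs[j + 1], ys[j + 1], xs[i + 1], ys[i + 1])
    (a1 * a2 < 0) && (a3 * a4 < 0)
  }
  for (i in 1:(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(i, j)) return(FALSE)
    }
  }
  TRUE
}

#' Least-squares ellipse fit
#'
#' Direct algebraic least-squares conic fit constrained to an ellipse
#' (Fitzgibbon's method), returning geometric parameters. Falls back to the
#' polygon's equivalent-moment ellipse when the algebraic fit is degenerate
#' (e.g. a collapsed slit).
#'
#' @param x,y Boundary point coordinates.
#' @return List with semi-axes `a >= b`, `center` (length-2), `angle`
#'   (radians, orientation of the major axis), and `method`
#'   (`"algebraic"` or `"moments"`).
#' @export
fit_ellipse <- function(x, y) {
  stopifnot(length(x) >= 5, length(x) == length(y))
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - mx) / sc; ys <- (y - my) / sc

  fit <- tryCatch({
    D1 <- cbind(xs^2, xs * ys, ys^2)
    D2 <- cbind(xs, ys, 1)
    S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
    Tm <- -solve(S3, t(S2))
    M <- S1 + S2 %*% Tm
    # inv(C1) %*% M with C1 = [[0,0,2],[0,-1,0],[2,0,0]]
    M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
    ev <- eigen(M2)
    vecs <- Re(ev$vectors)
    cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
    k <- which(cond > 0)
    if (length(k) == 0) stop("no elliptical solution")
    a1 <- vecs[, k[1]]
    coef <- c(a1, Tm %*% a1) # A B C D E F in scaled frame
    conic_to_geom(coef, mx, my, sc)
  }, error = function(e) NULL)

  if (!is.null(fit) && is.finite(fit$a) && is.finite(fit$b) && fit$b > 0) {
    fit$method <- "algebraic"
    return(fit)
  }
  moment_ellipse(x, y)
}

conic_to_geom <- function(coef, mx, my, sc) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; F <- coef[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  Fc <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F
  M0 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M0, symmetric = TRUE)
  if (any(-Fc / ev$values <= 0)) stop("not an ellipse")
  ax <- sqrt(-Fc / ev$values) # semi-axis per principal direction
  i_major <- which.max(ax)
  a <- ax[i_major]; b <- min(ax)
  ang <- atan2(ev$vectors[2, i_major], ev$vectors[1, i_major])
  list(a = a * sc, b = b * sc,
       center = c(ctr[1] * sc + mx, ctr[2] * sc + my),
       angle = ((ang + pi / 2) %% pi) - pi / 2)
}

# equivalent ellipse from the polygon's area moments (exact for a true
# ellipse): principal per-area second moments mu give semi-axes 2*sqrt(mu)
moment_ellipse <- function(x, y) {
  p <- ensure_ccw(x, y)
  x <- p$x; y <- p$y
  n <- length(x)
  j <- c(seq_len(n)[-1], 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-14) stop("degenerate (zero-area) contour", call. = FALSE)
  cx <- sum((x + x[j]) * cr) / (6 * A)
  cy <- sum((y + y[j]) * cr) / (6 * A)
  u <- x - cx; v <- y - cy
  uj <- u[j]; vj <- v[j]
  crc <- u * vj - uj * v
  Ixx <- sum(crc * (v^2 + v * vj + vj^2)) / 12
  Iyy <- sum(crc * (u^2 + u * uj + uj^2)) / 12
  Ixy <- sum(crc * (u * vj + 2 * u * v + 2 * uj * vj + uj * v)) / 24
  covm <- matrix(c(Iyy, Ixy, Ixy, Ixx), 2, 2) / A
  ev <- eigen(covm, symmetric = TRUE)
  a <- 2 * sqrt(max(ev$values[1], 0))
  b <- 2 * sqrt(max(ev$values[2], 0))
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  list(a = a, b = b, center = c(cx, cy),
       angle = ((ang + pi / 2) %% pi) - pi / 2, method = "moments")
}

#' Assemble a tidy contour table
#'
#' @param x,y Vertex coordinates (mm).
#' @param plane,frame Integer identifiers.
#' @param label Boundary label (`"myo_outer"`, `"myo_inner"`, `"endo"`).
#' @return Tibble with columns `plane, frame, label, vertex, x_mm, y_mm`.
#' @export
contour_tbl <- function(x, y, plane = 1L, frame = 1L, label = "myo_inner") {
  tibble::tibble(plane = as.integer(plane), frame = as.integer(frame),
                 label = label, vertex = seq_along(x), x_mm = x, y_mm = y)
}

#' Per-contour geometric measures of a tidy contour table
#'
#' @param contours Tidy contour tibble (see [contour_tbl()]).
#' @return Tibble with one row per (plane, frame, label): `perimeter_mm`,
#'   `area_mm2` (absolute), `centroid_x_mm`, `centroid_y_mm`.
#' @export
measure_contours <- function(contours) {
  dplyr::summarise(
    dplyr::group_by(contours, .data$plane, .data$frame, .data$label),
    perimeter_mm = polygon_perimeter(.data$x_mm, .data$y_mm),
    area_mm2 = abs(polygon_area(.data$x_mm, .data$y_mm)),
    centroid_x_mm = mean(.data$x_mm),
    centroid_y_mm = mean(.data$y_mm),
    .groups = "drop"
  )
}
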