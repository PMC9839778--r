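# Internal polyline / raster geometry helpers.
#
# Polylines are n x 2 numeric matrices, columns (x, y), in 0-based pixel
# coordinates: (0, 0) is the centre of the top-left pixel, x grows rightward,
# y grows downward. Images are Y x X matrices indexed [y + 1, x + 1].

#' @noRd
as_polyline <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 2L || !is.numeric(p) || anyNA(p)) {
    stop("polyline must be a numeric n x 2 matrix with n >= 2 and no NAs")
  }
  storage.mode(p) <- "double"
  unname(p)
}

# cumulative arc length along a polyline, in the polyline's units
#' @noRd
polyline_arclength <- function(p) {
  d <- sqrt(rowSums(diff(p)^2))
  c(0, cumsum(d))
}

# resample a polyline to k points at equal normalized arc length
#' @noRd
resample_polyline <- function(p, k) {
  stopifnot(k >= 2L)
  s <- polyline_arclength(p)
  total <- s[length(s)]
  if (total <= 0) stop("polyline has zero length")
  target <- seq(0, total, length.out = k)
  x <- stats::approx(s, p[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(s, p[, 2], xout = target, ties = "ordered")$y
  cbind(x, y, deparse.level = 0)
}

# point on polyline at arc position a (same units as coordinates)
#' @noRd
polyline_point_at <- function(p, a) {
  s <- polyline_arclength(p)
  a <- pmin(pmax(a, 0), s[length(s)])
  x <- stats::approx(s, p[, 1], xout = a, ties = "ordered")$y
  y <- stats::approx(s, p[, 2], xout = a, ties = "ordered")$y
  cbind(x, y, deparse.level = 0)
}

# proper segment intersection between segment (p1,p2) and (q1,q2);
# returns parameter t along (p1,p2) or NA
#' @noRd
segment_intersect_t <- function(p1, p2, q1, q2) {
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12) return(NA_real_)
  qp <- q1 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) return(NA_real_)
  t
}

# TRUE when the polyline crosses itself (non-adjacent segment pairs)
#' @noRd
polyline_self_intersects <- function(p) {
  n <- nrow(p) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n &&
          all(abs(p[1, ] - p[n + 1L, ]) < 1e-12)) next  # closed loop endpoint
      t <- segment_intersect_t(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])
      if (!is.na(t)) return(TRUE)
    }
  }
  FALSE
}

# signed parameters s where the infinite line origin + s * dir crosses the
# polyline; dir must be unit length so s is in coordinate units
#' @noRd
line_polyline_intersections <- function(origin, dir, poly) {
  nrm <- c(-dir[2], dir[1])  # normal to the probe line
  d <- (poly[, 1] - origin[1]) * nrm[1] + (poly[, 2] - origin[2]) * nrm[2]
  out <- numeric(0)
  for (i in seq_len(nrow(poly) - 1L)) {
    d1 <- d[i]; d2 <- d[i + 1L]
    if ((d1 > 0 && d2 > 0) || (d1 < 0 && d2 < 0)) next
    if (d1 == d2) next  # collinear with probe line
    f <- d1 / (d1 - d2)
    pt <- poly[i, ] + f * (poly[i + 1L, ] - poly[i, ])
    out <- c(out, (pt[1] - origin[1]) * dir[1] + (pt[2] - origin[2]) * dir[2])
  }
  out
}

# even-odd point-in-polygon test, vectorized over points
#' @noRd
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# bilinear interpolation of a Y x X image at 0-based coords (x, y);
# points outside the grid are clamped to the border
#' @noRd
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
}

# centered moving average with shrinking windows at the ends
#' @noRd
moving_average <- function(x, width = 5L) {
  n <- length(x)
  if (n == 0L || width <= 1L) return(x)
  h <- width %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - h); b <- min(n, i + h)
    out[i] <- mean(x[a:b])
  }
  out
}
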