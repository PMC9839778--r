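#' Trace the heart midline from two wall annotations
#'
#' Builds the midline of the heart tube as the curve at mid-distance from
#' the two traced walls. Within each chamber (the wall sub-polylines split
#' at the AV markers) both walls are resampled to the same number of points
#' by normalized arc length and paired point-by-point; the midline point is
#' the midpoint of each pair. The two chamber midlines are computed
#' independently — the atrium and ventricle curve very differently — and
#' joined at the AV point, the midpoint of the two AV marker vertices.
#' A 5-point moving average smooths each chamber midline; the inflow,
#' AV and outflow junction points are kept fixed.
#'
#' @param annotation a [heart_annotation].
#' @param points_per_chamber number of resampled wall points per chamber.
#' @param smooth_width moving-average window (points) for smoothing.
#' @return An object of class `heart_midline`: a list with `points`
#'   (n x 2 pixel coordinates, inflow first), `chamber` (per-point label
#'   `"atrium"`, `"av_canal_point"` or `"ventricle"`), `arc_position_um`
#'   (cumulative micrometres from the inflow end), `av_index`, and
#'   `pixel_width`.
#' @export
build_midline <- function(annotation, points_per_chamber = 100L,
                          smooth_width = 5L) {
  stopifnot(inherits(annotation, "heart_annotation"))
  split_wall <- function(w, m) {
    if (m < 2L || m > nrow(w) - 1L) stop("geometry error: AV marker position")
    list(atr = w[1:m, , drop = FALSE],
         ven = w[m:nrow(w), , drop = FALSE])
  }
  a <- split_wall(annotation$wall_a, annotation$av_marker_a)
  b <- split_wall(annotation$wall_b, annotation$av_marker_b)
  chamber_mid <- function(wa, wb) {
    if (nrow(wa) < 2L || nrow(wb) < 2L) {
      stop("geometry error: chamber wall section has fewer than 2 vertices")
    }
    ra <- resample_polyline(wa, points_per_chamber)
    rb <- resample_polyline(wb, points_per_chamber)
    mid <- (ra + rb) / 2
    if (smooth_width > 1L && nrow(mid) > 2L) {
      interior <- 2:(nrow(mid) - 1L)
      sx <- moving_average(mid[, 1], smooth_width)
      sy <- moving_average(mid[, 2], smooth_width)
      mid[interior, 1] <- sx[interior]
      mid[interior, 2] <- sy[interior]
    }
    mid
  }
  atr <- chamber_mid(a$atr, b$atr)
  ven <- chamber_mid(a$ven, b$ven)
  # atr ends and ven starts at the AV point (midpoint of the two markers)
  pts <- rbind(atr, ven[-1, , drop = FALSE])
  av_index <- nrow(atr)
  chamber <- c(rep("atrium", av_index - 1L), "av_canal_point",
               rep("ventricle", nrow(ven) - 1L))
  arc <- polyline_arclength(pts) * annotation$pixel_width
  if (any(diff(arc) <= 0)) {
    stop("geometry error: midline arc length is not strictly increasing")
  }
  structure(
    list(points = pts, chamber = chamber, arc_position_um = arc,
         av_index = av_index, pixel_width = annotation$pixel_width),
    class = "heart_midline"
  )
}

#' @export
print.heart_midline <- function(x, ...) {
  cat(sprintf("<heart_midline> %d points, %.1f um long, AV at %.1f um\n",
              nrow(x$points), max(x$arc_position_um),
              x$arc_position_um[x$av_index]))
  invisible(x)
}

# interpolate midline coordinates at arc positions (micrometres)
midline_at <- function(midline, arc_um) {
  arc_um <- pmin(pmax(arc_um, 0), max(midline$arc_position_um))
  x <- stats::approx(midline$arc_position_um, midline$points[, 1],
                     xout = arc_um, ties = "ordered")$y
  y <- stats::approx(midline$arc_position_um, midline$points[, 2],
                     xout = arc_um, ties = "ordered")$y
  cbind(x, y, deparse.level = 0)
}

# unit tangent of the midline at arc positions (micrometres), by symmetric
# finite difference
midline_tangent_at <- function(midline, arc_um, h_um = NULL) {
  total <- max(midline$arc_position_um)
  if (is.null(h_um)) h_um <- total / (nrow(midline$points) * 2)
  p1 <- midline_at(midline, pmax(arc_um - h_um, 0))
  p2 <- midline_at(midline, pmin(arc_um + h_um, total))
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- 1
  d / len
}

#' Partition the midline into segments
#'
#' Divides the midline into `n_segments` segments, allocated to atrium and
#' ventricle proportionally to their midline arc lengths (the chamber split
#' is preserved: no segment straddles the AV point). Segment centres sit at
#' equal arc spacing within each chamber; the tangent at each centre is the
#' symmetric difference of its neighbours along the midline.
#'
#' @param midline a [build_midline] result.
#' @param n_segments number of segments (default 100).
#' @return An object of class `segment_set`: list with `centers` (data frame
#'   of `segment_index` 0-based, `arc_um`, `chamber`, `x`, `y`), `tangents`
#'   (n x 2 unit vectors), `edges_um` (n + 1 segment boundary arc positions)
#'   and the `midline`.
#' @export
resample_segments <- function(midline, n_segments = 100L) {
  stopifnot(inherits(midline, "heart_midline"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop("n_segments must be at least 2")
  total <- max(midline$arc_position_um)
  if (total <= 0) stop("midline has zero arc length")
  l_atr <- midline$arc_position_um[midline$av_index]
  n_atr <- round(n_segments * l_atr / total)
  n_atr <- min(max(n_atr, 1L), n_segments - 1L)
  n_ven <- n_segments - n_atr
  edges <- c(seq(0, l_atr, length.out = n_atr + 1L),
             seq(l_atr, total, length.out = n_ven + 1L)[-1])
  centers_arc <- (edges[-1] + edges[-length(edges)]) / 2
  pts <- midline_at(midline, centers_arc)
  chamber <- ifelse(centers_arc < l_atr, "atrium", "ventricle")
  # tangent by central difference of neighbouring centres
  tan_pts <- rbind(midline_at(midline, edges[1]), pts,
                   midline_at(midline, edges[length(edges)]))
  d <- tan_pts[3:nrow(tan_pts), , drop = FALSE] -
    tan_pts[1:(nrow(tan_pts) - 2L), , drop = FALSE]
  len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
  tangents <- d / len
  structure(
    list(
      centers = data.frame(segment_index = 0:(n_segments - 1L),
                           arc_um = centers_arc, chamber = chamber,
                           x = pts[, 1], y = pts[, 2]),
      tangents = tangents, edges_um = edges, midline = midline
    ),
    class = "segment_set"
  )
}

# endpoints of the chord through `origin` along unit `normal`, clipped to the
# two walls: the intersection nearest the origin on each wall. Returns a list
# with pa, pb (points) or NULL when either wall is missed.
wall_chord <- function(annotation, origin, normal) {
  nearest <- function(wall) {
    s <- line_polyline_intersections(origin, normal, wall)
    if (!length(s)) return(NULL)
    s[which.min(abs(s))]
  }
  sa <- nearest(annotation$wall_a)
  sb <- nearest(annotation$wall_b)
  if (is.null(sa) || is.null(sb)) return(NULL)
  list(pa = origin + sa * normal, pb = origin + sb * normal,
       width_px = abs(sa - sb))
}

#' Per-segment heart diameter
#'
#' For each segment centre, the diameter is the distance between the
#' intersections of the chord normal to the midline with the two walls
#' (nearest intersection to the centre on each wall), in micrometres.
#' Chords that miss a wall (e.g. at an unclosed inflow end) yield `NA`
#' rather than an error.
#'
#' @param annotation a [heart_annotation].
#' @param segments a [resample_segments] result.
#' @return Numeric vector of per-segment diameters (micrometres), `NA`
#'   where the chord misses a wall.
#' @export
measure_diameter <- function(annotation, segments) {
  stopifnot(inherits(annotation, "heart_annotation"),
            inherits(segments, "segment_set"))
  n <- nrow(segments$centers)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    origin <- c(segments$centers$x[i], segments$centers$y[i])
    tang <- segments$tangents[i, ]
    normal <- c(-tang[2], tang[1])
    ch <- wall_chord(annotation, origin, normal)
    if (!is.null(ch)) out[i] <- ch$width_px * annotation$pixel_width
  }
  out
}

#' Per-segment intensity and diameter profile
#'
#' Fills the 100-segment (or `n_segments`) profile table: per segment, the
#' mean pixel intensity inside the quadrilateral bounded by the wall-clipped
#' normal chords at the segment's two boundaries, plus the diameter at the
#' segment centre. Pixels on shared chord boundaries are claimed by the
#' first segment that contains them, so the segment regions partition their
#' union. Degenerate or wall-missing geometry yields `NA` for the affected
#' segment, never an error.
#'
#' @param image a Y x X intensity matrix on the annotation's pixel grid.
#' @param annotation a [heart_annotation].
#' @param segments a [resample_segments] result.
#' @return A data frame (the segment table) with columns `segment_index`
#'   (0-based), `arc_position_um`, `chamber`, `diameter_um`,
#'   `mean_intensity`, `n_pixels`, `center_x`, `center_y`.
#' @export
measure_intensity_profile <- function(image, annotation, segments) {
  stopifnot(is.matrix(image), inherits(annotation, "heart_annotation"),
            inherits(segments, "segment_set"))
  n <- nrow(segments$centers)
  edges <- segments$edges_um
  midline <- segments$midline
  chords <- vector("list", length(edges))
  for (j in seq_along(edges)) {
    origin <- drop(midline_at(midline, edges[j]))
    tang <- drop(midline_tangent_at(midline, edges[j]))
    normal <- c(-tang[2], tang[1])
    chords[j] <- list(wall_chord(annotation, origin, normal))
  }
  claimed <- matrix(FALSE, nrow(image), ncol(image))
  mean_int <- rep(NA_real_, n)
  n_pix <- rep(0L, n)
  for (i in seq_len(n)) {
    c1 <- chords[[i]]; c2 <- chords[[i + 1L]]
    if (is.null(c1) || is.null(c2)) next
    quad <- rbind(c1$pa, c2$pa, c2$pb, c1$pb)
    x0 <- max(0L, floor(min(quad[, 1]))); x1 <- min(ncol(image) - 1L, ceiling(max(quad[, 1])))
    y0 <- max(0L, floor(min(quad[, 2]))); y1 <- min(nrow(image) - 1L, ceiling(max(quad[, 2])))
    if (x1 < x0 || y1 < y0) next
    gx <- rep(x0:x1, each = y1 - y0 + 1L)
    gy <- rep(y0:y1, times = x1 - x0 + 1L)
    inside <- points_in_polygon(gx, gy, quad)
    if (!any(inside)) next
    idx <- cbind(gy[inside] + 1L, gx[inside] + 1L)
    free <- !claimed[idx]
    if (!any(free)) next
    idx <- idx[free, , drop = FALSE]
    claimed[idx] <- TRUE
    mean_int[i] <- mean(image[idx])
    n_pix[i] <- nrow(idx)
  }
  data.frame(
    segment_index = segments$centers$segment_index,
    arc_position_um = segments$centers$arc_um,
    chamber = segments$centers$chamber,
    diameter_um = measure_diameter(annotation, segments),
    mean_intensity = mean_int,
    n_pixels = n_pix,
    center_x = segments$centers$x,
    center_y = segments$centers$y
  )
}

#' Aggregate segment tables across samples
#'
#' Per segment index, the mean and standard error of the mean (SEM,
#' sd / sqrt(n)) of intensity and diameter across samples; missing values
#' are excluded pairwise with `n` adjusted per segment.
#'
#' @param tables a list of segment tables from
#'   [measure_intensity_profile()], all with the same number of rows.
#' @return A data frame with per-segment `mean_intensity`, `sem_intensity`,
#'   `n_intensity`, `mean_diameter`, `sem_diameter`, `n_diameter`.
#' @export
aggregate_profiles <- function(tables) {
  if (!length(tables)) stop("no segment tables to aggregate")
  nseg <- nrow(tables[[1]])
  if (!all(vapply(tables, nrow, 0L) == nseg)) {
    stop("all segment tables must have the same number of rows")
  }
  agg <- function(col) {
    m <- vapply(tables, function(tb) tb[[col]], numeric(nseg))
    m <- matrix(m, nrow = nseg)
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    sdv <- apply(m, 1, function(v) stats::sd(v, na.rm = TRUE))
    sem <- sdv / sqrt(n)
    sem[n < 2] <- NA_real_
    list(mean = mu, sem = sem, n = n)
  }
  ai <- agg("mean_intensity")
  ad <- agg("diameter_um")
  data.frame(
    segment_index = tables[[1]]$segment_index,
    arc_position_um = tables[[1]]$arc_position_um,
    chamber = tables[[1]]$chamber,
    mean_intensity = ai$mean, sem_intensity = ai$sem, n_intensity = ai$n,
    mean_diameter = ad$mean, sem_diameter = ad$sem, n_diameter = ad$n
  )
}
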