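#' Manual heart-wall annotation
#'
#' Holds the two external wall traces of the heart tube, each an ordered
#' polyline running from the inflow (atrial) end to the outflow
#' (ventricular) end, plus the vertex on each wall marking the
#' atrioventricular (AV) canal. This is the manual input every geometric
#' measurement in the package consumes; walls are never detected from raw
#' pixels.
#'
#' Coordinates are continuous 0-based pixel coordinates (x rightward,
#' y downward, origin at the centre of the top-left pixel). Marker indices
#' are 1-based vertex indices into the corresponding wall and must be
#' strictly interior. Lengths are converted to micrometres only at
#' measurement time via `pixel_width`.
#'
#' @param wall_a,wall_b n x 2 matrices of (x, y) vertices, n >= 4, ordered
#'   inflow to outflow, simple (non-self-intersecting).
#' @param av_marker_a,av_marker_b 1-based interior vertex index of the AV
#'   canal on each wall.
#' @param pixel_width micrometres per pixel.
#' @return An object of class `heart_annotation`.
#' @examples
#' ann <- heart_annotation(
#'   wall_a = cbind(0:9, rep(0, 10)),
#'   wall_b = cbind(0:9, rep(10, 10)),
#'   av_marker_a = 6, av_marker_b = 6, pixel_width = 1.92)
#' @export
heart_annotation <- function(wall_a, wall_b, av_marker_a, av_marker_b,
                             pixel_width) {
  wall_a <- as_polyline(wall_a)
  wall_b <- as_polyline(wall_b)
  for (w in list(a = wall_a, b = wall_b)) {
    if (nrow(w) < 4L) stop("validation error: each wall needs >= 4 vertices")
  }
  if (polyline_self_intersects(wall_a) || polyline_self_intersects(wall_b)) {
    stop("validation error: wall polyline crosses itself")
  }
  check_marker <- function(idx, wall, name) {
    if (!is.numeric(idx) || length(idx) != 1L || idx != round(idx)) {
      stop("validation error: ", name, " must be a single integer index")
    }
    if (idx <= 1L || idx >= nrow(wall)) {
      stop("validation error: ", name, " must be strictly interior ",
           "(not the inflow or outflow endpoint)")
    }
    as.integer(idx)
  }
  av_marker_a <- check_marker(av_marker_a, wall_a, "av_marker_a")
  av_marker_b <- check_marker(av_marker_b, wall_b, "av_marker_b")
  if (!is.numeric(pixel_width) || length(pixel_width) != 1L || pixel_width <= 0) {
    stop("validation error: pixel_width must be a single positive number")
  }
  structure(
    list(wall_a = wall_a, wall_b = wall_b,
         av_marker_a = av_marker_a, av_marker_b = av_marker_b,
         pixel_width = pixel_width),
    class = "heart_annotation"
  )
}

#' @export
print.heart_annotation <- function(x, ...) {
  cat(sprintf(
    "<heart_annotation> wall_a %d vtx (AV @ %d), wall_b %d vtx (AV @ %d), %g um/px\n",
    nrow(x$wall_a), x$av_marker_a, nrow(x$wall_b), x$av_marker_b, x$pixel_width))
  invisible(x)
}

#' Reverse the inflow/outflow orientation of an annotation
#'
#' Flips both wall polylines end-to-end and remaps the AV markers, so that
#' the former outflow end becomes the inflow end. Useful for testing the
#' orientation conventions of downstream measurements.
#'
#' @param annotation a [heart_annotation].
#' @return A [heart_annotation] with reversed orientation.
#' @export
reverse_annotation <- function(annotation) {
  stopifnot(inherits(annotation, "heart_annotation"))
  heart_annotation(
    wall_a = annotation$wall_a[rev(seq_len(nrow(annotation$wall_a))), ],
    wall_b = annotation$wall_b[rev(seq_len(nrow(annotation$wall_b))), ],
    av_marker_a = nrow(annotation$wall_a) - annotation$av_marker_a + 1L,
    av_marker_b = nrow(annotation$wall_b) - annotation$av_marker_b + 1L,
    pixel_width = annotation$pixel_width
  )
}

#' Read / write heart annotations as JSON
#'
#' The on-disk schema is plain JSON with fields `wall_a`, `wall_b` (arrays
#' of `[x, y]` pairs in 0-based pixel coordinates, inflow first),
#' `av_marker_a`, `av_marker_b` (0-based vertex indices in the file;
#' converted to 1-based in R) and `pixel_width` (micrometres per pixel).
#' Readers validate and reject rather than repair.
#'
#' @param path JSON file path.
#' @param annotation a [heart_annotation].
#' @return `read_annotation()` returns a [heart_annotation].
#' @export
read_annotation <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("format error reading annotation '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  need <- c("wall_a", "wall_b", "av_marker_a", "av_marker_b", "pixel_width")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("validation error: annotation is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  heart_annotation(
    wall_a = obj$wall_a, wall_b = obj$wall_b,
    av_marker_a = obj$av_marker_a + 1L,
    av_marker_b = obj$av_marker_b + 1L,
    pixel_width = obj$pixel_width
  )
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "heart_annotation"))
  obj <- list(
    wall_a = unname(annotation$wall_a),
    wall_b = unname(annotation$wall_b),
    av_marker_a = annotation$av_marker_a - 1L,
    av_marker_b = annotation$av_marker_b - 1L,
    pixel_width = annotation$pixel_width
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
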