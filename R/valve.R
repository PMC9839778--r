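#' Leaflet trace container
#'
#' Per-plane polylines tracing the superior AV valve leaflet from its wall
#' attachment to its free tip, across the planes of a z-stack covering the
#' AV canal.
#'
#' @param polylines list of n x 2 matrices (pixel coordinates), one per
#'   traced plane, each with >= 2 points.
#' @param plane_indices integer plane index per polyline.
#' @param pixel_width micrometres per pixel.
#' @param z_step micrometres between planes.
#' @return An object of class `leaflet_trace`.
#' @export
leaflet_trace <- function(polylines, plane_indices, pixel_width, z_step) {
  if (length(polylines) != length(plane_indices)) {
    stop("one plane index per polyline is required")
  }
  polylines <- lapply(polylines, as_polyline)
  if (pixel_width <= 0 || z_step <= 0) {
    stop("pixel_width and z_step must be positive")
  }
  structure(list(polylines = polylines,
                 plane_indices = as.integer(plane_indices),
                 pixel_width = pixel_width, z_step = z_step),
            class = "leaflet_trace")
}

#' Leaflet length per plane and its maximum
#'
#' Polyline arc length per traced plane, converted to micrometres, with
#' the maximum over planes — the length the elongation call is made on.
#' An empty trace yields length 0 over no planes.
#'
#' @param trace a [leaflet_trace].
#' @return A list with `per_plane` (data frame `plane`, `length_um`) and
#'   `max_length_um`.
#' @export
leaflet_length <- function(trace) {
  stopifnot(inherits(trace, "leaflet_trace"))
  if (!length(trace$polylines)) {
    return(list(per_plane = data.frame(plane = integer(0),
                                       length_um = numeric(0)),
                max_length_um = 0))
  }
  len <- vapply(trace$polylines,
                function(p) max(polyline_arclength(p)) * trace$pixel_width, 0)
  list(per_plane = data.frame(plane = trace$plane_indices, length_um = len),
       max_length_um = max(len))
}

#' Binary elongation call
#'
#' Scores a superior leaflet as elongated when its maximal per-plane length
#' reaches `threshold_um`. The threshold is a configurable criterion (the
#' original scoring was visual); it is always recorded in the output.
#'
#' @param length_um maximal leaflet length in micrometres.
#' @param threshold_um elongation threshold, micrometres (> 0; default 10).
#' @return An object of class `elongation_call`: `max_leaflet_length_um`,
#'   `elongated` (logical), `threshold_um`.
#' @export
classify_elongated <- function(length_um, threshold_um = 10) {
  if (!is.numeric(threshold_um) || length(threshold_um) != 1L ||
      threshold_um <= 0) {
    stop("parameter error: threshold_um must be a single positive number")
  }
  structure(list(max_leaflet_length_um = length_um,
                 elongated = length_um >= threshold_um,
                 threshold_um = threshold_um),
            class = "elongation_call")
}

#' Nucleus detections in a z-stack
#'
#' @param x,y pixel coordinates of detected nucleus centres.
#' @param plane integer plane index per detection.
#' @param pixel_width micrometres per pixel.
#' @param z_step micrometres between planes.
#' @return An object of class `nucleus_detections` (a data frame with the
#'   physical scale attached).
#' @export
nucleus_detections <- function(x, y, plane, pixel_width, z_step) {
  if (length(x) != length(y) || length(x) != length(plane)) {
    stop("x, y and plane must have equal length")
  }
  if (pixel_width <= 0 || z_step <= 0) {
    stop("pixel_width and z_step must be positive")
  }
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       plane = as.integer(plane)),
            pixel_width = pixel_width, z_step = z_step,
            class = c("nucleus_detections", "data.frame"))
}

#' Count valve cells with plane deduplication
#'
#' Counts cells from per-plane nucleus detections. The same nucleus is
#' detected in several adjacent optical planes, so detections are linked
#' into chains — greedily, nearest neighbour first — whenever their xy
#' distance is at most `link_radius_um` and their plane gap at most
#' `max_plane_gap`; the cell count is the number of chains. With
#' `per_plane_sum = TRUE` the undeduplicated per-plane sum is returned
#' instead.
#'
#' @param detections a [nucleus_detections].
#' @param link_radius_um maximal xy distance (micrometres) to link two
#'   detections of the same nucleus.
#' @param max_plane_gap maximal plane index gap to link across.
#' @param per_plane_sum return the raw number of detections instead of the
#'   deduplicated chain count.
#' @return Integer cell count.
#' @export
count_valve_cells <- function(detections, link_radius_um = 3,
                              max_plane_gap = 1L, per_plane_sum = FALSE) {
  stopifnot(inherits(detections, "nucleus_detections"))
  n <- nrow(detections)
  if (per_plane_sum || n == 0L) return(n)
  pw <- attr(detections, "pixel_width")
  ord <- order(detections$plane, detections$x, detections$y)
  det <- detections[ord, ]
  # open chains: last linked detection per chain
  chain_x <- numeric(0); chain_y <- numeric(0); chain_plane <- integer(0)
  n_chains <- 0L
  for (i in seq_len(n)) {
    gap <- det$plane[i] - chain_plane
    dist_um <- sqrt((det$x[i] - chain_x)^2 + (det$y[i] - chain_y)^2) * pw
    ok <- which(gap >= 1L & gap <= max_plane_gap & dist_um <= link_radius_um)
    if (length(ok)) {
      j <- ok[which.min(dist_um[ok])]
      chain_x[j] <- det$x[i]; chain_y[j] <- det$y[i]
      chain_plane[j] <- det$plane[i]
    } else {
      n_chains <- n_chains + 1L
      chain_x <- c(chain_x, det$x[i]); chain_y <- c(chain_y, det$y[i])
      chain_plane <- c(chain_plane, det$plane[i])
    }
  }
  n_chains
}

#' 2 x 2 elongation contingency table
#'
#' Tabulates elongation calls for two groups into the 2 x 2 count table
#' consumed by [fisher_exact_two_sided()]: rows are groups, columns are
#' elongated / not elongated.
#'
#' @param calls_a,calls_b lists of [classify_elongated()] calls for the two
#'   groups (both non-empty).
#' @return A 2 x 2 integer matrix with dimnames.
#' @export
elongation_table <- function(calls_a, calls_b) {
  if (!length(calls_a) || !length(calls_b)) {
    stop("both groups must be non-empty")
  }
  count <- function(calls) {
    stopifnot(all(vapply(calls, inherits, TRUE, "elongation_call")))
    e <- vapply(calls, function(cl) cl$elongated, TRUE)
    c(sum(e), sum(!e))
  }
  m <- rbind(count(calls_a), count(calls_b))
  dimnames(m) <- list(group = c("group_a", "group_b"),
                      outcome = c("elongated", "not_elongated"))
  storage.mode(m) <- "integer"
  m
}
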