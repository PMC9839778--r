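#' Plane-by-plane calcium imaging series
#'
#' Container for a z-series of single-plane movies of the same beating
#' heart, acquired one plane at a time (ventral-most first) with the
#' optical plane moved by `z_step` micrometres between movies. All planes
#' must share frame count, image size and frame rate.
#'
#' @param planes list of [movie_stack] objects, ventral-most first.
#' @param z_step micrometres between planes.
#' @return An object of class `plane_series`.
#' @export
plane_series <- function(planes, z_step = 4) {
  if (length(planes) < 2L) stop("a plane series needs at least 2 planes")
  stopifnot(all(vapply(planes, inherits, TRUE, "movie_stack")))
  dims <- vapply(planes, function(p) dim(p$pixels), integer(3))
  if (length(unique(apply(dims, 2, paste, collapse = "x"))) != 1L) {
    stop("all planes must share T, Y, X dimensions")
  }
  fr <- vapply(planes, function(p) p$frame_rate, 0)
  if (length(unique(fr)) != 1L) stop("all planes must share the frame rate")
  if (z_step <= 0) stop("z_step must be positive")
  structure(list(planes = planes, z_step = z_step, frame_rate = fr[1],
                 pixel_width = planes[[1]]$pixel_width),
            class = "plane_series")
}

#' @export
print.plane_series <- function(x, ...) {
  d <- dim(x$planes[[1]]$pixels)
  cat(sprintf("<plane_series> %d planes x %d frames, %d x %d px, %g um z-step\n",
              length(x$planes), d[1], d[2], d[3], x$z_step))
  invisible(x)
}

plane_mean_traces <- function(series) {
  vapply(series$planes,
         function(p) apply(p$pixels, 1, mean),
         numeric(dim(series$planes[[1]]$pixels)[1]))
}

#' Common beat period across planes
#'
#' Estimates the beat period per plane from the autocorrelation of its
#' mean-intensity trace and takes the median across planes as the common
#' period (the heart rate is assumed stable over the acquisition). Planes
#' whose own period deviates more than 10% from the median, or that show
#' no periodicity, are flagged rather than corrected.
#'
#' @param series a [plane_series].
#' @return A list with `period_frames` (median, real-valued),
#'   `per_plane_period` and `flagged` (plane indices).
#' @export
estimate_common_period <- function(series) {
  stopifnot(inherits(series, "plane_series"))
  traces <- plane_mean_traces(series)
  periods <- apply(traces, 2, trace_period)
  if (mean(is.na(periods)) > 0.5) {
    stop("NoPeriodicity: more than half of the planes show no periodic ",
         "mean-intensity signal")
  }
  med <- stats::median(periods, na.rm = TRUE)
  flagged <- which(is.na(periods) | abs(periods - med) > 0.1 * med)
  list(period_frames = med, per_plane_period = periods,
       flagged = as.integer(flagged))
}

# fold a trace to one period using n_bins phase bins with linear
# interpolation of each sample between its two neighbouring bins;
# returns a z-scored folded trace
fold_trace <- function(x, period, n_bins = 100L) {
  tt <- length(x)
  x <- x - mean(x)
  phase_bin <- ((seq_len(tt) - 1) / period * n_bins) %% n_bins
  b0 <- floor(phase_bin)
  w1 <- phase_bin - b0
  b0 <- as.integer(b0 %% n_bins) + 1L
  b1 <- as.integer(b0 %% n_bins) + 1L
  acc <- numeric(n_bins); wt <- numeric(n_bins)
  for (i in seq_len(tt)) {
    acc[b0[i]] <- acc[b0[i]] + x[i] * (1 - w1[i])
    wt[b0[i]] <- wt[b0[i]] + (1 - w1[i])
    acc[b1[i]] <- acc[b1[i]] + x[i] * w1[i]
    wt[b1[i]] <- wt[b1[i]] + w1[i]
  }
  f <- acc / pmax(wt, 1e-12)
  s <- stats::sd(f)
  if (s == 0) f else (f - mean(f)) / s
}

# circular cross-correlation: lag (real-valued bins, parabolic refinement)
# maximizing cor(rotate(f, -m), template), plus the peak correlation
circular_best_lag <- function(f, template) {
  n <- length(f)
  cc <- vapply(0:(n - 1L), function(m) {
    g <- f[((seq_len(n) - 1L + m) %% n) + 1L]
    suppressWarnings(stats::cor(g, template))
  }, 0)
  cc[is.na(cc)] <- -1
  j <- which.max(cc)
  jm <- if (j == 1L) n else j - 1L
  jp <- if (j == n) 1L else j + 1L
  delta <- 0
  denom <- cc[jm] - 2 * cc[j] + cc[jp]
  if (denom < 0) delta <- min(max(0.5 * (cc[jm] - cc[jp]) / denom, -0.5), 0.5)
  list(lag = ((j - 1L) + delta) %% n, peak = cc[j])
}

#' Estimate per-plane acquisition phase offsets
#'
#' Retrospective phase alignment: each plane's mean-intensity trace is
#' folded to the common period (`n_bins` phase bins, linear interpolation);
#' the plane's offset is the circular lag maximizing the correlation of its
#' folded trace with a template propagated plane-to-plane from the
#' reference plane (the plane of maximal temporal variance). The template
#' is the running mean of the already-aligned folded traces, so adjacent
#' planes — which share structure — anchor each other. Planes whose peak
#' correlation falls below `min_corr` are flagged unalignable (offset
#' `NA`).
#'
#' @param series a [plane_series].
#' @param period_frames common beat period in frames (see
#'   [estimate_common_period()]).
#' @param n_bins phase bins for folding (default 100).
#' @param min_corr minimum folded-trace correlation (default 0.2).
#' @return An object of class `phase_offsets`: `offset_frames` (per plane,
#'   in `[0, period)`, `NA` when unalignable; 0 for the reference),
#'   `reference_plane`, `period_frames`, `peak_corr`, `flagged`.
#' @export
estimate_phase_offsets <- function(series, period_frames, n_bins = 100L,
                                   min_corr = 0.2) {
  stopifnot(inherits(series, "plane_series"))
  traces <- plane_mean_traces(series)
  n_planes <- ncol(traces)
  folded <- lapply(seq_len(n_planes),
                   function(p) fold_trace(traces[, p], period_frames, n_bins))
  ref <- which.max(apply(traces, 2, stats::var))
  offset_bins <- rep(NA_real_, n_planes)
  peak <- rep(NA_real_, n_planes)
  offset_bins[ref] <- 0
  peak[ref] <- 1
  template <- folded[[ref]]
  n_used <- 1L
  rotate <- function(x, m) {
    n <- length(x)
    mi <- floor(m); frac <- m - mi
    a <- x[((seq_len(n) - 1L + mi) %% n) + 1L]
    b <- x[((seq_len(n) + mi) %% n) + 1L]
    a * (1 - frac) + b * frac
  }
  order_out <- order(abs(seq_len(n_planes) - ref))[-1]
  for (p in order_out) {
    best <- circular_best_lag(folded[[p]], template)
    peak[p] <- best$peak
    if (best$peak < min_corr) next
    # the best lag rotates this plane onto the template, i.e. it equals
    # reference phase minus plane phase; the plane's offset is its negation
    offset_bins[p] <- (n_bins - best$lag) %% n_bins
    aligned <- rotate(folded[[p]], best$lag)
    template <- (template * n_used + aligned) / (n_used + 1L)
    n_used <- n_used + 1L
  }
  structure(
    list(offset_frames = (offset_bins / n_bins * period_frames) %% period_frames,
         reference_plane = ref, period_frames = period_frames,
         peak_corr = peak, flagged = which(is.na(offset_bins))),
    class = "phase_offsets"
  )
}

#' @export
print.phase_offsets <- function(x, ...) {
  cat(sprintf("<phase_offsets> %d planes, reference %d, period %.2f frames, %d flagged\n",
              length(x$offset_frames), x$reference_plane, x$period_frames,
              length(x$flagged)))
  invisible(x)
}

#' Assemble the aligned 4D volume and its maximum z-projection
#'
#' Shifts each plane in time by its rounded phase offset so all planes
#' share the reference plane's beat phase, truncates to the common frame
#' range, stacks the planes into a T x Z x Y x X volume and computes the
#' per-pixel maximum projection over z. Flagged (unalignable) planes are
#' dropped.
#'
#' @param series a [plane_series].
#' @param offsets a [estimate_phase_offsets()] result.
#' @return An object of class `aligned_volume`: `volume` (T x Z x Y x X),
#'   `projection` (T x Y x X), `planes_used`, `shift_frames`,
#'   `reference_plane`, `period_frames`, `frame_rate`, `pixel_width`,
#'   `z_step`.
#' @export
assemble_and_project <- function(series, offsets) {
  stopifnot(inherits(series, "plane_series"),
            inherits(offsets, "phase_offsets"))
  usable <- which(!is.na(offsets$offset_frames))
  if (!length(usable)) stop("all planes flagged unalignable")
  period <- offsets$period_frames
  # a plane that started `o` frames late shows reference phase t at its
  # own frame t + (period - o); shifting forward keeps indices in range
  shift <- as.integer(round((period - offsets$offset_frames[usable]) %% period)) %%
    max(1L, as.integer(round(period)))
  tt <- dim(series$planes[[1]]$pixels)[1]
  t_common <- tt - max(shift)
  if (t_common < 2L) stop("movies too short for the alignment shifts")
  d <- dim(series$planes[[1]]$pixels)
  vol <- array(0, c(t_common, length(usable), d[2], d[3]))
  for (k in seq_along(usable)) {
    p <- usable[k]
    vol[, k, , ] <- series$planes[[p]]$pixels[(1:t_common) + shift[k], , ,
                                              drop = FALSE]
  }
  proj <- array(0, c(t_common, d[2], d[3]))
  for (t in seq_len(t_common)) {
    proj[t, , ] <- apply(vol[t, , , , drop = FALSE], c(3, 4), max)
  }
  structure(
    list(volume = vol, projection = proj, planes_used = usable,
         shift_frames = shift, reference_plane = offsets$reference_plane,
         period_frames = period, frame_rate = series$frame_rate,
         pixel_width = series$pixel_width, z_step = series$z_step),
    class = "aligned_volume"
  )
}

#' @export
print.aligned_volume <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<aligned_volume> %d frames x %d planes x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Select the atrial diastole and systole frames
#'
#' On the maximum projection, measures the per-frame atrial width at the
#' mid-atrium chord (the annotation is static, so chamber area cannot be
#' tracked; the chord width is the per-frame proxy) and returns the frames
#' of maximal (diastole) and minimal (systole) smoothed width.
#'
#' @param aligned an [assemble_and_project()] result.
#' @param annotation a [heart_annotation] drawn on the projection.
#' @return A list with 0-based `diastole_frame` and `systole_frame`.
#' @export
select_cardiac_state <- function(aligned, annotation) {
  stopifnot(inherits(aligned, "aligned_volume"),
            inherits(annotation, "heart_annotation"))
  mv <- movie_stack(aligned$projection, aligned$frame_rate,
                    aligned$pixel_width)
  width <- chord_width_trace(mv, annotation, mode = "fluorescence")
  if (max(width) - min(width) < 1e-9) {
    stop("flat atrial-diameter trace: cannot identify diastole/systole")
  }
  # fit the phase of a cosine at the beat period: uses every frame of the
  # width trace, so the peak placement is sub-frame accurate, then rounds
  # to the nearest acquired frame
  p <- aligned$period_frames
  tt <- length(width)
  theta <- 2 * pi * (0:(tt - 1)) / p
  xc <- width - mean(width)
  phi <- atan2(sum(xc * sin(theta)), sum(xc * cos(theta)))
  dia <- (phi / (2 * pi) * p) %% p
  sys <- (dia + p / 2) %% p
  list(diastole_frame = as.integer(round(dia)) %% tt,
       systole_frame = as.integer(round(sys)) %% tt)
}

#' Per-segment calcium profile at a cardiac state
#'
#' Profiles the maximum projection at the chosen frame along the
#' 100-segment midline (diameter and mean intensity per segment) and adds
#' each segment's intensity normalized by the whole-heart mean, the form
#' in which an AV canal calcium peak is read.
#'
#' @param aligned an [assemble_and_project()] result.
#' @param annotation a [heart_annotation].
#' @param state_frame 0-based frame index (e.g. from
#'   [select_cardiac_state()]).
#' @param n_segments number of midline segments (default 100).
#' @return A segment table (see [measure_intensity_profile()]) with an
#'   added `normalized_intensity` column.
#' @export
calcium_profile <- function(aligned, annotation, state_frame,
                            n_segments = 100L) {
  stopifnot(inherits(aligned, "aligned_volume"))
  tt <- dim(aligned$projection)[1]
  if (state_frame < 0 || state_frame >= tt) stop("state_frame out of range")
  img <- aligned$projection[state_frame + 1L, , ]
  segs <- resample_segments(build_midline(annotation), n_segments)
  tab <- measure_intensity_profile(img, annotation, segs)
  tab$normalized_intensity <-
    tab$mean_intensity / mean(tab$mean_intensity, na.rm = TRUE)
  tab
}
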