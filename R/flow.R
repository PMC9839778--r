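#' Kymograph of the AV canal
#'
#' Samples the movie along the midline within `window_halfwidth_um` of the
#' AV point, one line per frame, averaging across a narrow band normal to
#' the midline. Increasing sample index always runs atrium to ventricle, so
#' stripe slopes read directly as flow direction: content drifting toward
#' higher indices is anterograde.
#'
#' @param movie a [movie_stack].
#' @param annotation a [heart_annotation] on the movie's pixel grid.
#' @param window_halfwidth_um half-width of the sampling window centred on
#'   the AV point, micrometres (default 20).
#' @param band_px width in pixels of the band normal to the midline over
#'   which intensity is averaged (default 3).
#' @return An object of class `kymograph`: `values` (T x S matrix),
#'   `sample_spacing_um`, `frame_rate`, `pixel_width`.
#' @export
extract_kymograph <- function(movie, annotation, window_halfwidth_um = 20,
                              band_px = 3L) {
  stopifnot(inherits(movie, "movie_stack"),
            inherits(annotation, "heart_annotation"))
  midline <- build_midline(annotation)
  arc_av <- midline$arc_position_um[midline$av_index]
  total <- max(midline$arc_position_um)
  if (arc_av - window_halfwidth_um < 0 ||
      arc_av + window_halfwidth_um > total) {
    stop("geometry error: kymograph window extends past a heart end")
  }
  spacing <- annotation$pixel_width / 2
  s_count <- 2L * floor(window_halfwidth_um / spacing) + 1L
  if (s_count < 8L) stop("geometry error: kymograph window too narrow")
  arcs <- seq(arc_av - window_halfwidth_um, arc_av + window_halfwidth_um,
              length.out = s_count)
  spacing <- (arcs[2] - arcs[1])
  pts <- midline_at(midline, arcs)
  tang <- midline_tangent_at(midline, arcs)
  normals <- cbind(-tang[, 2], tang[, 1])
  offs <- seq(-(band_px - 1L) / 2, (band_px - 1L) / 2, length.out = band_px)
  sx <- as.vector(outer(pts[, 1], rep(1, band_px)) +
                    outer(normals[, 1], offs))
  sy <- as.vector(outer(pts[, 2], rep(1, band_px)) +
                    outer(normals[, 2], offs))
  tt <- dim(movie$pixels)[1]
  values <- matrix(0, tt, s_count)
  for (t in seq_len(tt)) {
    samp <- bilinear_sample(movie$pixels[t, , ], sx, sy)
    values[t, ] <- rowMeans(matrix(samp, s_count, band_px))
  }
  structure(
    list(values = values, sample_spacing_um = spacing,
         frame_rate = movie$frame_rate, pixel_width = annotation$pixel_width),
    class = "kymograph"
  )
}

# normalized cross-correlation of two kymograph lines at integer lag k:
# b is compared with a shifted so that content moving by +k samples between
# a and b scores highest at lag k
ncc_at_lag <- function(a, b, k) {
  s <- length(a)
  i0 <- max(1L, 1L + k); i1 <- min(s, s + k)
  if (i1 - i0 < 3L) return(NA_real_)
  bb <- b[i0:i1]
  aa <- a[(i0 - k):(i1 - k)]
  if (stats::sd(bb) == 0 || stats::sd(aa) == 0) return(NA_real_)
  stats::cor(aa, bb)
}

#' Per-frame displacement from a kymograph
#'
#' For each consecutive pair of kymograph lines, the displacement is the
#' lag maximizing the normalized cross-correlation over integer lags within
#' `max_lag_um`, refined to sub-sample precision by parabolic interpolation
#' of the correlation peak and its two neighbours. Positive displacement is
#' atrium-to-ventricle (anterograde). Constant (zero-variance) lines yield
#' displacement 0 with confidence 0.
#'
#' With `remove_static = TRUE` (the default) the temporal median of each
#' kymograph column is subtracted first, so stationary structure — wall
#' edges, shading — cannot pull the correlation peak toward zero lag; only
#' the moving blood speckle contributes. Each line is lightly smoothed
#' (3-sample moving average), which is shift-invariant and therefore does
#' not bias the displacement.
#'
#' @param kymograph a [extract_kymograph] result.
#' @param max_lag_um largest displacement searched per frame, micrometres.
#' @param remove_static subtract the per-column temporal median before
#'   correlating (needs a kymograph spanning several cycles; disable for
#'   short constructed inputs).
#' @param ensemble odd number of consecutive frame pairs whose correlation
#'   curves are averaged before peak picking (ensemble correlation, the
#'   standard particle-velocimetry defence against spurious peaks in noisy
#'   single-pair correlations). 1 disables it; the default 9 spans under
#'   4\% of a beat cycle at 240 frames/s and 2.5 Hz.
#' @return A data frame with `pair_index` (0-based index of the first frame
#'   of the pair), `displacement_um` (micrometres per frame, signed) and
#'   `confidence` (peak correlation, clamped to `[0, 1]`).
#' @export
estimate_frame_displacement <- function(kymograph, max_lag_um = 15,
                                        remove_static = TRUE,
                                        ensemble = 9L) {
  stopifnot(inherits(kymograph, "kymograph"))
  v <- kymograph$values
  if (remove_static && nrow(v) >= 8L) {
    v <- sweep(v, 2, apply(v, 2, stats::median))
  }
  v <- t(apply(v, 1, moving_average, width = 3L))
  spacing <- kymograph$sample_spacing_um
  s <- ncol(v)
  max_l <- floor(max_lag_um / spacing)
  if (max_l < 1L || max_l >= s / 2) {
    stop("max_lag_um must allow at least one sample lag and stay below ",
         "half the kymograph width")
  }
  lags <- (-max_l):max_l
  n_pairs <- nrow(v) - 1L
  cc_all <- matrix(NA_real_, n_pairs, length(lags))
  for (t in seq_len(n_pairs)) {
    a <- v[t, ]; b <- v[t + 1L, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc_all[t, ] <- vapply(lags, function(k) ncc_at_lag(a, b, k), 0)
  }
  h <- (max(1L, as.integer(ensemble)) - 1L) %/% 2L
  disp <- numeric(n_pairs)
  conf <- numeric(n_pairs)
  for (t in seq_len(n_pairs)) {
    win <- max(1L, t - h):min(n_pairs, t + h)
    cc <- colMeans(cc_all[win, , drop = FALSE], na.rm = TRUE)
    if (all(is.nan(cc) | is.na(cc))) next  # zero-variance lines: 0, 0
    cc[is.na(cc) | is.nan(cc)] <- -Inf
    j <- which.max(cc)
    lag <- lags[j]
    delta <- 0
    if (j > 1L && j < length(cc) &&
        is.finite(cc[j - 1L]) && is.finite(cc[j + 1L])) {
      denom <- cc[j - 1L] - 2 * cc[j] + cc[j + 1L]
      if (denom < 0) delta <- 0.5 * (cc[j - 1L] - cc[j + 1L]) / denom
      delta <- min(max(delta, -0.5), 0.5)
    }
    disp[t] <- (lag + delta) * spacing
    conf[t] <- min(max(cc[j], 0), 1)
  }
  data.frame(pair_index = 0:(n_pairs - 1L), displacement_um = disp,
             confidence = conf)
}

#' Classify per-frame flow direction
#'
#' Applies the speed threshold that separates real flow from jitter:
#' displacements slower than `speed_threshold_um_s` (or with correlation
#' confidence below `confidence_floor`, where motion is unmeasurable) are
#' labelled `no_flow`; otherwise the sign gives `anterograde` (positive,
#' atrium to ventricle) or `retrograde`.
#'
#' @param displacements data frame from [estimate_frame_displacement()].
#' @param speed_threshold_um_s no-flow speed threshold, micrometres/second.
#' @param confidence_floor minimum correlation confidence below which a
#'   frame pair is treated as unmeasurable (no_flow).
#' @param frame_rate frames per second, to convert per-frame displacement
#'   to speed.
#' @return The input data frame with an added factor column `label` with
#'   levels `anterograde`, `retrograde`, `no_flow`.
#' @export
classify_flow_frames <- function(displacements, speed_threshold_um_s = 115,
                                 confidence_floor = 0.3, frame_rate) {
  stopifnot(is.data.frame(displacements),
            all(c("displacement_um", "confidence") %in% names(displacements)))
  if (speed_threshold_um_s <= 0) stop("speed_threshold_um_s must be positive")
  speed <- abs(displacements$displacement_um) * frame_rate
  lab <- ifelse(speed < speed_threshold_um_s |
                  displacements$confidence < confidence_floor,
                "no_flow",
                ifelse(displacements$displacement_um > 0,
                       "anterograde", "retrograde"))
  displacements$label <- factor(lab,
                                levels = c("anterograde", "retrograde", "no_flow"))
  displacements
}

# parabolic sub-sample refinement of a local maximum position
peak_refine <- function(r, j) {
  if (j <= 1L || j >= length(r)) return(j)
  denom <- r[j - 1L] - 2 * r[j] + r[j + 1L]
  if (denom >= 0) return(j)
  j + min(max(0.5 * (r[j - 1L] - r[j + 1L]) / denom, -0.5), 0.5)
}

# period of a 1-D signal in samples (real-valued), or NA when no credible
# peak exists. The first credible autocorrelation peak (first local maximum
# after the first zero crossing, within 30% of the strongest) fixes the
# candidate fundamental — taking the global acf maximum instead can lock
# onto a multiple of the period. The estimate is then refined by maximizing
# the periodogram power of the detrended trace around the candidate.
trace_period <- function(x, min_period = 4, min_peak = 0.2) {
  n <- length(x)
  if (n < 3L * min_period || stats::sd(x) == 0) return(NA_real_)
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x))  # detrend
  r <- stats::acf(x, lag.max = floor(n / 2), plot = FALSE,
                  demean = TRUE)$acf[-1]
  neg <- which(r < 0)
  if (!length(neg)) return(NA_real_)
  search <- seq.int(max(neg[1], floor(min_period)), length(r))
  if (length(search) < 3L) return(NA_real_)
  rs <- r[search]
  best <- max(rs)
  if (best < min_peak) return(NA_real_)
  is_max <- c(FALSE, rs[2:(length(rs) - 1)] >= rs[1:(length(rs) - 2)] &
                rs[2:(length(rs) - 1)] >= rs[3:length(rs)], FALSE)
  cand <- which(is_max & rs >= 0.7 * best & rs >= min_peak)
  if (!length(cand)) return(NA_real_)
  p1 <- peak_refine(r, search[cand[1]])
  # periodogram refinement: the power main lobe is ~p^2/n wide in period,
  # so a +-12% bracket around p1 stays on the true peak
  tvec <- seq_len(n)
  power <- function(p) {
    w <- 2 * pi / p
    sum(x * cos(w * tvec))^2 + sum(x * sin(w * tvec))^2
  }
  lo <- max(min_period, p1 * 0.88)
  hi <- min(n / 2, p1 * 1.12)
  if (hi <= lo) return(p1)
  stats::optimize(power, c(lo, hi), maximum = TRUE)$maximum
}

# per-frame chamber width at the mid-atrium chord, in micrometres.
# Brightfield mode locates the dark wall band on each side of the chord as
# the intensity minimum within the wall's plausible radial range (so blood
# speckle inside the lumen cannot capture it); the width is the distance
# between the two minima. Fluorescence mode (for max-projected movies,
# which are speckle-free and filled-bright) takes the extent of the
# contiguous bright run around the chord centre.
chord_width_trace <- function(movie, annotation,
                              mode = c("brightfield", "fluorescence")) {
  mode <- match.arg(mode)
  midline <- build_midline(annotation)
  l_atr <- midline$arc_position_um[midline$av_index]
  arc <- l_atr / 2
  origin <- drop(midline_at(midline, arc))
  tang <- drop(midline_tangent_at(midline, arc))
  normal <- c(-tang[2], tang[1])
  ch <- wall_chord(annotation, origin, normal)
  r0 <- if (!is.null(ch)) ch$width_px / 2 else
    max(dim(movie$pixels)[2:3]) / 6
  half_px <- 1.7 * r0
  step <- 0.5
  offs_px <- seq(-half_px, half_px, by = step)
  # average several parallel chords around the mid-atrium point to damp
  # blood-speckle interference and pixel noise
  arc_offsets_um <- seq(-6, 6, by = 3)
  pts <- midline_at(midline, arc + arc_offsets_um)
  sx <- as.vector(outer(rep(1, length(offs_px)), pts[, 1]) +
                    outer(offs_px * normal[1], rep(1, nrow(pts))))
  sy <- as.vector(outer(rep(1, length(offs_px)), pts[, 2]) +
                    outer(offs_px * normal[2], rep(1, nrow(pts))))
  n_chords <- nrow(pts)
  tt <- dim(movie$pixels)[1]
  k <- length(offs_px)
  c0 <- (k + 1L) %/% 2L
  # wall search windows: the contracting wall stays within these radii
  win_lo <- 0.68 * r0; win_hi <- 1.6 * r0
  left_win <- which(offs_px <= -win_lo & offs_px >= -win_hi)
  right_win <- which(offs_px >= win_lo & offs_px <= win_hi)
  refine <- function(prof, j) {
    if (j <= 1L || j >= length(prof)) return(j)
    denom <- prof[j - 1L] - 2 * prof[j] + prof[j + 1L]
    if (denom <= 0) return(j)
    j + min(max(0.5 * (prof[j - 1L] - prof[j + 1L]) / denom, -0.5), 0.5)
  }
  width <- numeric(tt)
  for (t in seq_len(tt)) {
    prof <- rowMeans(matrix(bilinear_sample(movie$pixels[t, , ], sx, sy),
                            length(offs_px), n_chords))
    prof <- moving_average(prof, 5L)
    if (mode == "brightfield") {
      jl <- left_win[which.min(prof[left_win])]
      jr <- right_win[which.min(prof[right_win])]
      width[t] <- (refine(prof, jr) - refine(prof, jl)) * step *
        annotation$pixel_width
    } else {
      thr <- (min(prof) + max(prof)) / 2
      below <- prof < thr
      left <- which(below[seq_len(c0 - 1L)])
      right <- which(below[(c0 + 1L):k])
      i_left <- if (length(left)) max(left) else 0L
      i_right <- if (length(right)) min(right) + c0 else k + 1L
      width[t] <- (i_right - i_left - 1L) * step * annotation$pixel_width
    }
  }
  width
}

#' Detect cardiac cycles and the beat period
#'
#' Estimates the beat period from the autocorrelation of the detrended
#' atrial-diameter signal (chamber width measured at the mid-atrium chord,
#' per frame) and places cycle boundaries at successive atrial-diastole
#' peaks (local maxima of the smoothed width trace).
#'
#' @param movie a [movie_stack] spanning at least three beats.
#' @param annotation a [heart_annotation].
#' @param mode `"brightfield"` (dark-wall tracking) or `"fluorescence"`
#'   (bright-band extent, for max-projected movies).
#' @return An object of class `cycle_set`: `boundaries` (0-based frame
#'   indices of successive atrial diastoles), `period_frames` (real),
#'   `heart_rate_bpm`, `frame_rate`.
#' @export
detect_cycles <- function(movie, annotation,
                          mode = c("brightfield", "fluorescence")) {
  stopifnot(inherits(movie, "movie_stack"),
            inherits(annotation, "heart_annotation"))
  width <- chord_width_trace(movie, annotation, mode)
  period <- trace_period(width)
  if (is.na(period)) {
    stop("NoPeriodicity: no autocorrelation peak above the noise floor ",
         "in the atrial-diameter signal")
  }
  # place diastole peaks by fitting the phase of a cosine at the detected
  # period: robust against spurious local maxima in the width trace
  tt <- length(width)
  theta <- 2 * pi * (0:(tt - 1)) / period
  xc <- width - mean(width)
  phi <- atan2(sum(xc * sin(theta)), sum(xc * cos(theta)))
  first_peak <- (phi / (2 * pi)) * period
  first_peak <- first_peak %% period
  boundaries <- round(first_peak + (0:floor((tt - 1 - first_peak) / period)) *
                        period)
  boundaries <- as.integer(boundaries[boundaries >= 0 & boundaries <= tt - 1L])
  if (length(boundaries) < 2L) {
    stop("NoPeriodicity: fewer than one complete cycle detected")
  }
  structure(
    list(boundaries = boundaries, period_frames = period,
         heart_rate_bpm = movie$frame_rate / period * 60,
         frame_rate = movie$frame_rate),
    class = "cycle_set"
  )
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d boundaries, period %.2f frames, %.1f bpm\n",
              length(x$boundaries), x$period_frames, x$heart_rate_bpm))
  invisible(x)
}

#' Per-cycle flow percentages and the averaged AV flow profile
#'
#' Computes, for each complete beating cycle, the percentage of frame
#' pairs classified anterograde, retrograde and no-flow, and averages the
#' three percentages over the first `n_cycles` complete cycles, following
#' the convention of averaging over three beating cycles per animal.
#'
#' @param labels data frame from [classify_flow_frames()].
#' @param cycles a [detect_cycles()] result.
#' @param n_cycles number of complete cycles to average (default 3).
#' @return An object of class `flow_profile`: `per_cycle` (n_cycles x 3
#'   matrix of percentages), `averaged` (named length-3 vector summing to
#'   100), `heart_rate_bpm`, `n_cycles_used`.
#' @export
compute_flow_profile <- function(labels, cycles, n_cycles = 3L) {
  stopifnot(is.data.frame(labels), inherits(cycles, "cycle_set"))
  b <- cycles$boundaries
  if (length(b) - 1L < n_cycles) {
    stop("InsufficientCycles: ", length(b) - 1L, " complete cycles found, ",
         n_cycles, " required")
  }
  classes <- c("anterograde", "retrograde", "no_flow")
  per_cycle <- matrix(0, n_cycles, 3,
                      dimnames = list(NULL, classes))
  for (ci in seq_len(n_cycles)) {
    idx <- labels$pair_index >= b[ci] & labels$pair_index < b[ci + 1L]
    if (!any(idx)) stop("cycle ", ci, " contains no frame pairs")
    counts <- table(factor(labels$label[idx], levels = classes))
    per_cycle[ci, ] <- as.numeric(counts) / sum(counts) * 100
  }
  structure(
    list(per_cycle = per_cycle, averaged = colMeans(per_cycle),
         heart_rate_bpm = cycles$heart_rate_bpm,
         n_cycles_used = n_cycles),
    class = "flow_profile"
  )
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf(
    "<flow_profile> anterograde %.1f%% / retrograde %.1f%% / no-flow %.1f%% (%d cycles, %.1f bpm)\n",
    x$averaged[1], x$averaged[2], x$averaged[3], x$n_cycles_used,
    x$heart_rate_bpm))
  invisible(x)
}

#' Run the full AV flow-profile pipeline on one movie
#'
#' Convenience wrapper: kymograph extraction, displacement estimation,
#' classification, cycle detection and cycle-averaged percentages.
#'
#' @param movie a [movie_stack].
#' @param annotation a [heart_annotation].
#' @param window_halfwidth_um,max_lag_um,speed_threshold_um_s,confidence_floor,n_cycles
#'   passed to the stage functions.
#' @return A [compute_flow_profile()] result.
#' @export
flow_profile_pipeline <- function(movie, annotation,
                                  window_halfwidth_um = 20, max_lag_um = 15,
                                  speed_threshold_um_s = 115,
                                  confidence_floor = 0.3, n_cycles = 3L) {
  kym <- extract_kymograph(movie, annotation, window_halfwidth_um)
  disp <- estimate_frame_displacement(kym, max_lag_um)
  labels <- classify_flow_frames(disp, speed_threshold_um_s, confidence_floor,
                                 movie$frame_rate)
  cycles <- detect_cycles(movie, annotation)
  compute_flow_profile(labels, cycles, n_cycles)
}

#' Group summary of flow profiles
#'
#' Per flow class, the five-number summary (min, Q1, median, Q3, max) plus
#' the mean over a group of averaged profiles — the numbers a
#' box-and-whisker plot with a mean marker depicts. Quartiles use the
#' inclusive linear-interpolation convention (R's default `quantile`
#' type 7).
#'
#' @param profiles list of [flow_profile] objects.
#' @return Data frame with one row per class and columns `class`, `min`,
#'   `q1`, `median`, `q3`, `max`, `mean`, `n`.
#' @export
summarize_profiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to summarize")
  stopifnot(all(vapply(profiles, inherits, TRUE, "flow_profile")))
  classes <- c("anterograde", "retrograde", "no_flow")
  rows <- lapply(classes, function(cl) {
    v <- vapply(profiles, function(p) unname(p$averaged[cl]), 0)
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(class = cl, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], mean = mean(v), n = length(v))
  })
  do.call(rbind, rows)
}
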