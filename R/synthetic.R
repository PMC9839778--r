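#' Configuration for the synthetic beating heart
#'
#' Defines the geometry, kinematics and imaging parameters of a simulated
#' two-chambered heart tube: an atrium and a ventricle joined by a narrow
#' AV canal, laid out in ventral view (atrium right, ventricle left) along
#' an S-curved centerline. Walls contract sinusoidally at `beat_frequency`
#' with a peristaltic phase lag along the tube; blood speckle particles are
#' advected through the AV canal following `flow_schedule`; fluorescence
#' mode renders an endocardial shell instead of brightfield contrast.
#'
#' @param image_size `c(Y, X)` image size in pixels.
#' @param pixel_width micrometres per pixel (default 1.92, the spinning-disc
#'   acquisition scale).
#' @param frame_rate frames per second (brightfield flow movies: 240;
#'   calcium plane movies: 50).
#' @param n_frames number of frames per movie.
#' @param beat_frequency beats per second (Hz).
#' @param chamber_radii `c(atrium, ventricle, canal)` rest radii in
#'   micrometres.
#' @param wall_motion_amplitude fractional radius change over the beat, in
#'   `[0, 0.5)`.
#' @param peristalsis_phase_lag contraction phase lag (radians) across the
#'   normalized tube axis.
#' @param flow_schedule list of phases, each
#'   `list(interval = c(from, to), class, speed)` with `interval` a
#'   half-open phase fraction interval, `class` one of `"anterograde"`,
#'   `"retrograde"`, `"no_flow"` and `speed` in micrometres/second
#'   (0 for no_flow). The intervals must partition `[0, 1)`.
#' @param n_particles number of advected blood speckle particles.
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (intensity units; the rendered intensity range is about 0-200).
#' @param fluorescence_mode render endocardial fluorescence instead of
#'   brightfield.
#' @param av_enrichment fold fluorescence elevation at the AV canal
#'   (>= 1; fluorescence mode only).
#' @param seed integer seed; identical config and seed give bit-identical
#'   output.
#' @return A validated object of class `heart_sim_config`.
#' @export
heart_sim_config <- function(image_size = c(96L, 160L),
                             pixel_width = 1.92,
                             frame_rate = 240,
                             n_frames = 480L,
                             beat_frequency = 2.5,
                             chamber_radii = c(atrium = 30, ventricle = 26,
                                               canal = 10),
                             wall_motion_amplitude = 0.22,
                             peristalsis_phase_lag = pi / 2,
                             flow_schedule = list(
                               list(interval = c(0, 0.7),
                                    class = "anterograde", speed = 300),
                               list(interval = c(0.7, 0.9),
                                    class = "retrograde", speed = 300),
                               list(interval = c(0.9, 1),
                                    class = "no_flow", speed = 0)),
                             n_particles = 120L,
                             noise_sd = 4,
                             fluorescence_mode = FALSE,
                             av_enrichment = 1,
                             seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), pixel_width = pixel_width,
              frame_rate = frame_rate, n_frames = as.integer(n_frames),
              beat_frequency = beat_frequency,
              chamber_radii = chamber_radii,
              wall_motion_amplitude = wall_motion_amplitude,
              peristalsis_phase_lag = peristalsis_phase_lag,
              flow_schedule = flow_schedule,
              n_particles = as.integer(n_particles), noise_sd = noise_sd,
              fluorescence_mode = isTRUE(fluorescence_mode),
              av_enrichment = av_enrichment, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "heart_sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 16L)) {
    stop("configuration error: image_size must be c(Y, X), each >= 16")
  }
  if (cfg$pixel_width <= 0) stop("configuration error: pixel_width <= 0")
  if (cfg$frame_rate <= 0 || cfg$beat_frequency <= 0) {
    stop("configuration error: frame_rate and beat_frequency must be > 0")
  }
  if (cfg$frame_rate / cfg$beat_frequency < 4) {
    stop("configuration error: beat period must span at least 4 frames")
  }
  if (length(cfg$chamber_radii) != 3L || any(cfg$chamber_radii <= 0)) {
    stop("configuration error: chamber_radii must be 3 positive values")
  }
  if (cfg$wall_motion_amplitude < 0 || cfg$wall_motion_amplitude >= 0.5) {
    stop("configuration error: wall_motion_amplitude must be in [0, 0.5)")
  }
  if (cfg$av_enrichment < 1) {
    stop("configuration error: av_enrichment must be >= 1")
  }
  sched <- cfg$flow_schedule
  if (!length(sched)) stop("configuration error: empty flow_schedule")
  starts <- vapply(sched, function(s) s$interval[1], 0)
  ends <- vapply(sched, function(s) s$interval[2], 0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (abs(starts[1]) > 1e-9 || abs(ends[length(ends)] - 1) > 1e-9 ||
      any(abs(starts[-1] - ends[-length(ends)]) > 1e-9) ||
      any(ends <= starts)) {
    stop("configuration error: flow_schedule phase intervals must ",
         "partition [0, 1) with no overlap")
  }
  for (s in sched) {
    if (!s$class %in% c("anterograde", "retrograde", "no_flow")) {
      stop("configuration error: unknown flow class '", s$class, "'")
    }
    if (s$class == "no_flow" && s$speed != 0) {
      stop("configuration error: no_flow phases must have speed 0")
    }
    if (s$speed < 0) stop("configuration error: negative flow speed")
  }
  invisible(cfg)
}

# run expr with a private, seeded RNG stream; the global stream is untouched
with_sim_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# --- static geometry -------------------------------------------------------
# The tube centerline is an S-curve in the image plane; the normalized axial
# coordinate u runs 0 (inflow, atrial end) to 1 (outflow, ventricular end).
# Rest radius profile: two Gaussian chamber bulges over a narrow canal floor,
# with the AV canal at u = 0.5 and chamber centres at u = 0.27 / 0.73.
U_ATRIUM <- 0.27
U_VENTRICLE <- 0.73
U_CANAL <- 0.5

sim_rest_radius <- function(u, radii) {
  canal <- radii[[3]]
  canal +
    (radii[[1]] - canal) * exp(-((u - U_ATRIUM) / 0.13)^2) +
    (radii[[2]] - canal) * exp(-((u - U_VENTRICLE) / 0.13)^2)
}

# time modulation: phase 0 = atrial diastole (maximal atrial radius);
# contraction travels along the tube with the configured phase lag
sim_radius_factor <- function(u, phase_frac, cfg) {
  1 + cfg$wall_motion_amplitude *
    cos(2 * pi * phase_frac - cfg$peristalsis_phase_lag * (u - U_ATRIUM))
}

sim_geometry <- function(cfg, n_points = 301L) {
  pw <- cfg$pixel_width
  wy <- cfg$image_size[1] * pw
  wx <- cfg$image_size[2] * pw
  max_r <- max(cfg$chamber_radii) * (1 + cfg$wall_motion_amplitude)
  margin <- max_r + 3 * pw
  if (wx <= 2 * margin) {
    stop("configuration error: image too narrow for the chamber radii")
  }
  tpar <- seq(0, 1, length.out = n_points)
  # gentle ventral-view S-curve; strong bends skew the equal-arc wall
  # pairing the midline tracer uses, which real traces avoid by keeping
  # the view roughly normal to the heart axis
  bend <- max(0, min(wy / 2 - margin, wy * 0.05))
  # atrium right, ventricle left (ventral view); gentle S-curve in y
  x <- (wx - margin) - tpar * (wx - 2 * margin)
  y <- wy / 2 + bend * sin(2 * pi * tpar)
  pts <- cbind(x, y)
  arc <- polyline_arclength(pts)
  total <- arc[length(arc)]
  u <- arc / total
  d <- rbind(pts[2, ] - pts[1, ],
             pts[3:n_points, ] - pts[1:(n_points - 2L), ],
             pts[n_points, ] - pts[n_points - 1L, ])
  len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
  tangents <- d / len
  normals <- cbind(-tangents[, 2], tangents[, 1])
  list(points_um = pts, u = u, arc_um = arc, total_um = total,
       tangents = tangents, normals = normals,
       rest_radius_um = sim_rest_radius(u, cfg$chamber_radii))
}

# per-pixel distance to the centerline and axial coordinate of the nearest
# centerline point (0-based pixel centres, micrometre units)
sim_pixel_field <- function(cfg, geom) {
  pw <- cfg$pixel_width
  px <- rep((seq_len(cfg$image_size[2]) - 1) * pw, each = cfg$image_size[1])
  py <- rep((seq_len(cfg$image_size[1]) - 1) * pw, times = cfg$image_size[2])
  d2 <- outer(px, geom$points_um[, 1], "-")^2 +
    outer(py, geom$points_um[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  list(dist_um = sqrt(d2[cbind(seq_along(nearest), nearest)]),
       u = geom$u[nearest])
}

# The heart tube is tilted along the optical axis: the atrial (inflow) end
# lies ventral-most and the tube climbs dorsally toward the outflow, as in
# the ventral-view anatomy, so a z-series covers substantially more than
# one tube diameter. The tube's axial extent slightly overhangs the
# nominal depth at both ends, so every sampled plane keeps a solid shell
# cross-section throughout the contraction cycle (a plane exactly tangent
# to a chamber cap would lose its signal at systole).
# Anchored at the chamber centres: the atrial bulge sits near the ventral
# face and the ventricular bulge near the dorsal face, each overhanging
# slightly (0.72 r, i.e. below the systolic radius 0.78 r at the default
# contraction amplitude) so the outermost sampled planes keep a solid
# cross-section throughout the cycle. The tapered inflow/outflow tracts
# extend beyond the imaged depth, as the real tracts do.
sim_z_center <- function(cfg, u) {
  r_atr <- cfg$chamber_radii[[1]]; r_ven <- cfg$chamber_radii[[2]]
  z_atr <- 0.72 * r_atr
  z_ven <- sim_heart_depth(cfg) - 0.72 * r_ven
  z_atr + (z_ven - z_atr) * (u - U_ATRIUM) / (U_VENTRICLE - U_ATRIUM)
}

sim_heart_depth <- function(cfg) {
  2 * (cfg$chamber_radii[[1]] + cfg$chamber_radii[[2]])
}

# interpolate centerline position and normal at arc positions (micrometres)
sim_centerline_at <- function(geom, arc_um) {
  x <- stats::approx(geom$arc_um, geom$points_um[, 1], xout = arc_um,
                     ties = "ordered")$y
  y <- stats::approx(geom$arc_um, geom$points_um[, 2], xout = arc_um,
                     ties = "ordered")$y
  nx <- stats::approx(geom$arc_um, geom$normals[, 1], xout = arc_um,
                      ties = "ordered")$y
  ny <- stats::approx(geom$arc_um, geom$normals[, 2], xout = arc_um,
                      ties = "ordered")$y
  nl <- sqrt(nx^2 + ny^2); nl[nl == 0] <- 1
  list(x = x, y = y, nx = nx / nl, ny = ny / nl)
}

# signed flow speed (micrometres/s, anterograde positive) at a phase fraction
schedule_speed <- function(sched, phase_frac) {
  out <- numeric(length(phase_frac))
  for (s in sched) {
    sel <- phase_frac >= s$interval[1] & phase_frac < s$interval[2]
    sgn <- switch(s$class, anterograde = 1, retrograde = -1, no_flow = 0)
    out[sel] <- sgn * s$speed
  }
  out
}

schedule_class <- function(sched, phase_frac) {
  out <- character(length(phase_frac))
  for (s in sched) {
    sel <- phase_frac >= s$interval[1] & phase_frac < s$interval[2]
    out[sel] <- s$class
  }
  out
}

#' Annotation matching a simulated heart
#'
#' Builds the manual-style wall annotation for a simulated heart: the two
#' wall polylines are the centerline offset by the rest radius on either
#' side, sampled inflow to outflow and clipped away from the (nearly
#' closed) tube tips, with the AV markers at the canal constriction.
#'
#' @param config a [heart_sim_config].
#' @param n_vertices vertices per wall.
#' @param u_range axial range covered by the traces (fractions of the tube).
#' @return A [heart_annotation] in pixel coordinates.
#' @export
sim_annotation <- function(config, n_vertices = 61L,
                           u_range = c(0.05, 0.95)) {
  stopifnot(inherits(config, "heart_sim_config"))
  geom <- sim_geometry(config)
  u <- seq(u_range[1], u_range[2], length.out = n_vertices)
  arc <- u * geom$total_um
  cl <- sim_centerline_at(geom, arc)
  r <- sim_rest_radius(u, config$chamber_radii)
  pw <- config$pixel_width
  wall_a <- cbind((cl$x + cl$nx * r) / pw, (cl$y + cl$ny * r) / pw)
  wall_b <- cbind((cl$x - cl$nx * r) / pw, (cl$y - cl$ny * r) / pw)
  av_idx <- which.min(abs(u - U_CANAL))
  heart_annotation(wall_a, wall_b, av_idx, av_idx, pw)
}

# ground truth container shared by the simulators
new_ground_truth <- function(fields) {
  structure(fields, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# true fractions (percent) implied by the schedule
schedule_fractions <- function(sched) {
  out <- c(anterograde = 0, retrograde = 0, no_flow = 0)
  for (s in sched) {
    out[s$class] <- out[s$class] + (s$interval[2] - s$interval[1]) * 100
  }
  out
}

#' Simulate a brightfield flow movie
#'
#' Renders a contracting heart tube in brightfield contrast polarity
#' (bright lumen, darker wall band, grey background) with dark Gaussian
#' blood speckle particles advected along the tube axis according to the
#' flow schedule. Gaussian noise is added last. The ground truth records
#' the per-frame flow class, cycle boundaries, exact schedule fractions,
#' the beat period and the true rest diameter profile.
#'
#' @param config a [heart_sim_config] with `fluorescence_mode = FALSE`.
#' @return A list with elements `movie` (a [movie_stack]), `truth`
#'   (a `ground_truth`) and `annotation` (a matching [heart_annotation]).
#' @export
simulate_brightfield_movie <- function(config) {
  stopifnot(inherits(config, "heart_sim_config"))
  validate_sim_config(config)
  if (config$fluorescence_mode) {
    stop("configuration error: brightfield simulation requires ",
         "fluorescence_mode = FALSE")
  }
  geom <- sim_geometry(config)
  field <- sim_pixel_field(config, geom)
  pw <- config$pixel_width
  tt <- config$n_frames
  period <- config$frame_rate / config$beat_frequency
  i_bg <- 110; i_wall <- 45; i_lumen <- 200
  wall_w <- 4; edge <- 1.5  # micrometres
  ny <- config$image_size[1]; nx <- config$image_size[2]
  rest_r_px <- sim_rest_radius(field$u, config$chamber_radii)

  out <- with_sim_rng(config$seed, {
    # particles: axial position (um along centerline) and fixed radial
    # offset fraction; confined away from the closed tips. Flow conserves
    # volume, so the axial speed scales as (canal radius / local radius)^2
    # — cells accelerate into single file through the constriction and
    # dawdle in the wide chambers — and the steady-state linear density is
    # proportional to the cross-section area; initial positions are drawn
    # from that density. The schedule speed is the speed AT the AV canal,
    # which is where flow is read out.
    u_lo <- 0.06; u_hi <- 0.94
    arc_lo <- u_lo * geom$total_um; arc_hi <- u_hi * geom$total_um
    r_canal <- sim_rest_radius(U_CANAL, config$chamber_radii)
    u_grid <- seq(u_lo, u_hi, length.out = 512L)
    w <- sim_rest_radius(u_grid, config$chamber_radii)^2
    cdf <- cumsum(w) / sum(w)
    part_arc <- stats::approx(c(0, cdf), c(u_lo, u_grid),
                              xout = stats::runif(config$n_particles),
                              ties = "ordered")$y * geom$total_um
    part_rad <- stats::runif(config$n_particles, -0.55, 0.55)
    sigma_px <- 1.5
    patch <- 3L  # +- pixels rendered around each particle centre
    movie <- array(0, c(tt, ny, nx))
    phase <- (config$beat_frequency * (0:(tt - 1)) / config$frame_rate) %% 1
    dt <- 1 / config$frame_rate
    for (t in seq_len(tt)) {
      fac <- sim_radius_factor(field$u, phase[t], config)
      r_t <- rest_r_px * fac
      lum <- pmin(pmax((r_t - field$dist_um) / edge + 0.5, 0), 1)
      wall <- pmin(pmax((r_t + wall_w - field$dist_um) / edge + 0.5, 0), 1) - lum
      img <- i_bg * (1 - lum - wall) + i_wall * wall + i_lumen * lum
      img <- matrix(img, ny, nx)
      # blood cells absorb light: accumulate Gaussian optical density and
      # attenuate multiplicatively, so overlapping cells darken smoothly
      # instead of clipping to black and erasing the speckle texture
      dens <- matrix(0, ny, nx)
      cl <- sim_centerline_at(geom, part_arc)
      u_p <- part_arc / geom$total_um
      r_p <- sim_rest_radius(u_p, config$chamber_radii) *
        sim_radius_factor(u_p, phase[t], config)
      px_x <- (cl$x + cl$nx * part_rad * r_p) / pw
      px_y <- (cl$y + cl$ny * part_rad * r_p) / pw
      for (p in seq_len(config$n_particles)) {
        cx <- px_x[p]; cy <- px_y[p]
        x0 <- max(0L, floor(cx) - patch); x1 <- min(nx - 1L, floor(cx) + patch + 1L)
        y0 <- max(0L, floor(cy) - patch); y1 <- min(ny - 1L, floor(cy) + patch + 1L)
        if (x1 < x0 || y1 < y0) next
        gx <- x0:x1; gy <- y0:y1
        g <- outer(exp(-((gy - cy)^2) / (2 * sigma_px^2)),
                   exp(-((gx - cx)^2) / (2 * sigma_px^2)))
        dens[gy + 1L, gx + 1L] <- dens[gy + 1L, gx + 1L] + g
      }
      img <- img * exp(-0.8 * dens)
      if (config$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(ny * nx, 0, config$noise_sd), ny, nx)
      }
      movie[t, , ] <- pmax(img, 0)
      # advect for the next frame with the continuity-scaled local speed;
      # the rest-radius profile is used so the speed at the canal centre
      # equals the scheduled speed at every phase of the beat; wrap within
      # the tube span
      v_canal <- schedule_speed(config$flow_schedule, phase[t])
      v_p <- v_canal * (r_canal / sim_rest_radius(u_p, config$chamber_radii))^2
      part_arc <- arc_lo + (part_arc + v_p * dt - arc_lo) %% (arc_hi - arc_lo)
    }
    list(movie = movie, phase = phase)
  })

  ann <- sim_annotation(config)
  frac <- ((0:99) + 0.5) / 100
  truth <- new_ground_truth(list(
    per_frame_flow_class = schedule_class(config$flow_schedule, out$phase),
    cycle_boundaries = {
      k <- seq_len(floor((tt - 1) / period))
      as.integer(round(k * period))
    },
    true_fractions = schedule_fractions(config$flow_schedule),
    period_frames = period,
    beat_frequency = config$beat_frequency,
    diastole_frame = as.integer(round(period)) %% tt,
    systole_frame = as.integer(round(period / 2)) %% tt,
    arc_fraction = frac,
    true_diameter_um = 2 * sim_rest_radius(frac, config$chamber_radii)
  ))
  list(movie = movie_stack(out$movie, config$frame_rate, pw,
                           origin_label = "simulated brightfield"),
       truth = truth, annotation = ann)
}

# render one fluorescence frame: endocardial shell of thickness wall_w at
# the lumen surface, axially modulated by the AV enrichment profile and a
# calcium-like beat modulation
render_fluor_frame <- function(cfg, field, phase_frac, z_um, rest_r_px,
                               enrich_px) {
  # The indicator signal fills the tube cross-section (endocardium plus
  # lumen, as a diffraction-limited acquisition renders it) rather than a
  # thin hollow shell: with a hollow shell, planes tangent to the chamber
  # caps brighten at systole while mid-chamber planes brighten at
  # diastole, and no scalar-trace alignment has a well-defined phase
  # ground truth. A solid cross-section modulates every plane in phase.
  edge <- 1.5; i_base <- 150; i_bg <- 10
  r_t <- rest_r_px * sim_radius_factor(field$u, phase_frac, cfg)
  rho <- sqrt(field$dist_um^2 + (z_um - sim_z_center(cfg, field$u))^2)
  solid <- pmin(pmax((r_t - rho) / edge + 0.5, 0), 1)
  # calcium-like beat modulation, in phase with the area modulation
  ca <- 1 + 0.6 * cos(2 * pi * phase_frac -
                        cfg$peristalsis_phase_lag * (field$u - U_ATRIUM))
  i_bg + i_base * enrich_px * ca * solid
}

#' Simulate a plane-by-plane calcium imaging series
#'
#' Emulates the 4D acquisition protocol: the same beating heart is imaged
#' one optical plane at a time, the plane moving by `z_step` micrometres
#' between movies, each movie starting at an unknown (or specified) phase
#' of the beat. Fluorescence is an endocardial shell, elevated
#' `av_enrichment`-fold at the AV canal, with a calcium-like beat
#' modulation. The ground truth records the per-plane phase offsets, the
#' period, and the diastole/systole frames of the zero-offset timeline.
#'
#' @param config a [heart_sim_config] with `fluorescence_mode = TRUE`.
#' @param n_planes number of planes (>= 2), acquired ventral-most first.
#' @param z_step micrometres between planes.
#' @param phase_offsets `"random"`, or a numeric vector of per-plane
#'   acquisition phase offsets in frames.
#' @return A list with `planes` (list of [movie_stack]), `truth`
#'   (a `ground_truth`), `annotation`, `z_step`.
#' @export
simulate_gcamp_plane_series <- function(config, n_planes = 50L, z_step = 4,
                                        phase_offsets = "random") {
  stopifnot(inherits(config, "heart_sim_config"))
  validate_sim_config(config)
  if (!config$fluorescence_mode) {
    stop("configuration error: plane-series simulation requires ",
         "fluorescence_mode = TRUE")
  }
  n_planes <- as.integer(n_planes)
  if (n_planes < 2L) stop("configuration error: n_planes must be >= 2")
  depth <- sim_heart_depth(config)
  if (n_planes * z_step > depth + 1e-9) {
    stop("configuration error: ", n_planes, " planes x ", z_step,
         " um exceed the simulated heart depth (", depth, " um)")
  }
  period <- config$frame_rate / config$beat_frequency
  geom <- sim_geometry(config)
  field <- sim_pixel_field(config, geom)
  rest_r_px <- sim_rest_radius(field$u, config$chamber_radii)
  enrich_px <- 1 + (config$av_enrichment - 1) *
    exp(-((field$u - U_CANAL) / 0.06)^2)
  ny <- config$image_size[1]; nx <- config$image_size[2]
  tt <- config$n_frames

  out <- with_sim_rng(config$seed, {
    offs <- if (identical(phase_offsets, "random")) {
      stats::runif(n_planes, 0, period)
    } else {
      if (length(phase_offsets) != n_planes) {
        stop("configuration error: phase_offsets length must equal n_planes")
      }
      as.numeric(phase_offsets) %% period
    }
    planes <- vector("list", n_planes)
    for (p in seq_len(n_planes)) {
      z <- (p - 1) * z_step  # ventral-most first
      arr <- array(0, c(tt, ny, nx))
      for (t in seq_len(tt)) {
        phase <- (config$beat_frequency * ((t - 1) + offs[p]) /
                    config$frame_rate) %% 1
        img <- render_fluor_frame(config, field, phase, z, rest_r_px,
                                  enrich_px)
        if (config$noise_sd > 0) {
          img <- img + stats::rnorm(ny * nx, 0, config$noise_sd)
        }
        arr[t, , ] <- pmax(matrix(img, ny, nx), 0)
      }
      planes[[p]] <- movie_stack(arr, config$frame_rate, config$pixel_width,
                                 origin_label = sprintf("simulated plane %d", p))
    }
    list(planes = planes, offsets = offs)
  })

  frac <- ((0:99) + 0.5) / 100
  truth <- new_ground_truth(list(
    per_plane_phase_offset = out$offsets,
    period_frames = period,
    beat_frequency = config$beat_frequency,
    covered_depth_um = n_planes * z_step,
    diastole_frame = as.integer(round(period)) %% tt,
    systole_frame = as.integer(round(period / 2)) %% tt,
    arc_fraction = frac,
    true_diameter_um = 2 * sim_rest_radius(frac, config$chamber_radii),
    true_segment_intensity = 1 + (config$av_enrichment - 1) *
      exp(-((frac - U_CANAL) / 0.06)^2)
  ))
  list(planes = out$planes, truth = truth,
       annotation = sim_annotation(config), z_step = z_step)
}

#' Simulate a static expression z-stack
#'
#' Renders a stopped-heart z-stack whose wall fluorescence along the tube
#' follows `profile_shape`, one multiplier per midline segment. Used as
#' ground truth for per-segment intensity profiling of in situ stacks.
#'
#' @param config a [heart_sim_config].
#' @param profile_shape numeric vector of non-negative per-segment
#'   intensity multipliers; its length sets the segment count.
#' @param z_step micrometres between planes (default 4).
#' @return A list with `stack` (a [z_stack]), `truth` (a `ground_truth`)
#'   and `annotation`.
#' @export
simulate_expression_stack <- function(config, profile_shape, z_step = 4) {
  stopifnot(inherits(config, "heart_sim_config"))
  validate_sim_config(config)
  if (any(profile_shape < 0)) {
    stop("configuration error: profile_shape multipliers must be >= 0")
  }
  nseg <- length(profile_shape)
  if (nseg < 2L) stop("configuration error: profile_shape needs >= 2 values")
  geom <- sim_geometry(config)
  field <- sim_pixel_field(config, geom)
  rest_r_px <- sim_rest_radius(field$u, config$chamber_radii)
  seg_of_u <- pmin(pmax(floor(field$u * nseg) + 1L, 1L), nseg)
  mult_px <- profile_shape[seg_of_u]
  depth <- sim_heart_depth(config)
  zs <- seq(0, depth, by = z_step)
  ny <- config$image_size[1]; nx <- config$image_size[2]
  wall_w <- 6; edge <- 1.5; i_base <- 100; i_bg <- 0

  arr <- with_sim_rng(config$seed, {
    a <- array(0, c(length(zs), ny, nx))
    for (zi in seq_along(zs)) {
      rho <- sqrt(field$dist_um^2 +
                    (zs[zi] - sim_z_center(config, field$u))^2)
      shell <- pmin(pmax((rest_r_px - rho) / edge + 0.5, 0), 1) -
        pmin(pmax((rest_r_px - wall_w - rho) / edge + 0.5, 0), 1)
      img <- i_bg + i_base * mult_px * shell
      if (config$noise_sd > 0) {
        img <- img + stats::rnorm(ny * nx, 0, config$noise_sd)
      }
      a[zi, , ] <- pmax(matrix(img, ny, nx), 0)
    }
    a
  })

  truth <- new_ground_truth(list(
    true_segment_intensity = i_base * profile_shape,
    profile_shape = profile_shape,
    arc_fraction = ((seq_len(nseg) - 0.5)) / nseg,
    true_diameter_um = 2 * sim_rest_radius((seq_len(nseg) - 0.5) / nseg,
                                           config$chamber_radii)
  ))
  list(stack = z_stack(arr, z_step, config$pixel_width), truth = truth,
       annotation = sim_annotation(config))
}

#' Write / read ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path JSON file path.
#' @return `read_ground_truth()` returns a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  new_ground_truth(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read a simulator configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [heart_sim_config()] arguments;
#' `flow_schedule` entries are maps with `interval`, `class`, `speed`.
#' Missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return A [heart_sim_config].
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(heart_sim_config))
  bad <- setdiff(names(obj), known)
  if (length(bad)) {
    stop("configuration error: unknown config keys: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(obj$flow_schedule)) {
    obj$flow_schedule <- lapply(obj$flow_schedule, function(s) {
      list(interval = as.numeric(s$interval), class = s$class,
           speed = as.numeric(s$speed))
    })
  }
  if (!is.null(obj$chamber_radii)) {
    obj$chamber_radii <- as.numeric(obj$chamber_radii)
  }
  if (!is.null(obj$image_size)) obj$image_size <- as.integer(obj$image_size)
  do.call(heart_sim_config, obj)
}
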