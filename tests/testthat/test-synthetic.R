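test_that("configuration invariants are enforced", {
  # schedule must partition [0, 1)
  expect_error(heart_sim_config(flow_schedule = list(
    list(interval = c(0, 0.5), class = "anterograde", speed = 300),
    list(interval = c(0.6, 1), class = "no_flow", speed = 0))),
    "partition")
  expect_error(heart_sim_config(flow_schedule = list(
    list(interval = c(0, 0.6), class = "anterograde", speed = 300),
    list(interval = c(0.5, 1), class = "retrograde", speed = 300))),
    "partition")
  # beat period must span at least 4 frames
  expect_error(heart_sim_config(frame_rate = 10, beat_frequency = 3),
               "at least 4 frames")
  # no_flow phases carry no speed
  expect_error(heart_sim_config(flow_schedule = list(
    list(interval = c(0, 1), class = "no_flow", speed = 10))),
    "speed 0")
})

test_that("ground-truth fractions and cycle geometry copy the schedule", {
  cfg <- brightfield_config(seed = 3, a_pct = 70, r_pct = 20, n_frames = 480L)
  sim <- simulate_brightfield_movie(cfg)
  expect_equal(unname(sim$truth$true_fractions), c(70, 20, 10))
  expect_equal(sum(sim$truth$true_fractions), 100)
  # 2.5 Hz at 240 fps: 96-frame cycles
  expect_equal(sim$truth$period_frames, 96)
  expect_true(all(diff(sim$truth$cycle_boundaries) > 0))
  expect_equal(diff(sim$truth$cycle_boundaries)[1], 96)
  # per-frame labels follow the schedule to within one frame per transition
  tab <- table(sim$truth$per_frame_flow_class) / length(sim$truth$per_frame_flow_class)
  expect_equal(as.numeric(tab[c("anterograde", "retrograde", "no_flow")]) * 100,
               c(70, 20, 10), tolerance = 100 / 96)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- brightfield_config(seed = 9, n_frames = 48L)
  a <- simulate_brightfield_movie(cfg)
  b <- simulate_brightfield_movie(cfg)
  expect_identical(a$movie$pixels, b$movie$pixels)
  expect_identical(a$truth$per_frame_flow_class, b$truth$per_frame_flow_class)
  # and the written TIFFs are byte-identical
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_movie(a$movie, p1); write_movie(b$movie, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # a different seed gives different pixels
  c2 <- simulate_brightfield_movie(brightfield_config(seed = 10, n_frames = 48L))
  expect_false(identical(a$movie$pixels, c2$movie$pixels))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_brightfield_movie(brightfield_config(seed = 1,
                                                          n_frames = 48L)))
  expect_identical(.Random.seed, before)
})

test_that("plane series records offsets, metadata and depth checks", {
  cfg <- gcamp_config(seed = 4, n_frames = 24L)
  sim <- simulate_gcamp_plane_series(cfg, n_planes = 10, z_step = 4)
  expect_length(sim$planes, 10)
  expect_equal(sim$truth$covered_depth_um, 40)
  expect_equal(sim$truth$period_frames, 20)
  # seeded offsets reproduce
  sim2 <- simulate_gcamp_plane_series(cfg, n_planes = 10, z_step = 4)
  expect_identical(sim$truth$per_plane_phase_offset,
                   sim2$truth$per_plane_phase_offset)
  # zero offsets give identical beat phase at frame 0: planes that share a
  # z-section of the atrium rise and fall together
  sim0 <- simulate_gcamp_plane_series(cfg, n_planes = 6, z_step = 8,
                                      phase_offsets = rep(0, 6))
  expect_equal(sim0$truth$per_plane_phase_offset, rep(0, 6))
  tr <- sapply(sim0$planes, function(p) apply(p$pixels, 1, mean))
  peaks <- apply(tr, 2, which.max) - 1L
  spread <- max(sapply(peaks, function(p) circ_dist(p, peaks[1], 20)))
  expect_lt(spread, 3)
  # exceeding the simulated heart depth is a configuration error
  expect_error(simulate_gcamp_plane_series(cfg, n_planes = 60, z_step = 4),
               "depth")
  # 50 planes x 4 um = 200 um fit the default protocol geometry exactly
  expect_silent({
    s <- simulate_gcamp_plane_series(gcamp_config(seed = 1, n_frames = 8L),
                                     n_planes = 50, z_step = 4)
  })
  expect_equal(s$truth$covered_depth_um, 200)
})

test_that("expression stacks encode the requested axial profile", {
  shape <- rep(1, 100)
  cfg <- heart_sim_config(image_size = c(48L, 100L), pixel_width = 4,
                          chamber_radii = c(52, 48, 15), noise_sd = 0,
                          seed = 6)
  sim <- simulate_expression_stack(cfg, shape)
  expect_equal(unname(sim$truth$true_segment_intensity), rep(100, 100))
  # a 2x canal profile doubles the truth at the canal only
  shape2 <- shape; shape2[48:52] <- 2
  sim2 <- simulate_expression_stack(cfg, shape2)
  expect_equal(max(sim2$truth$true_segment_intensity) /
                 min(sim2$truth$true_segment_intensity), 2)
  # noiseless wall pixels hit the encoded intensity exactly
  expect_equal(max(sim$stack$pixels), 100, tolerance = 1e-8)
  expect_error(simulate_expression_stack(cfg, c(-1, rep(1, 99))),
               "profile_shape")
})

test_that("simulator annotations pass validation and label the AV canal", {
  cfg <- brightfield_config(seed = 2)
  ann <- sim_annotation(cfg)
  expect_s3_class(ann, "heart_annotation")
  ml <- build_midline(ann)
  # the AV point sits near the middle of the tube
  expect_equal(ml$arc_position_um[ml$av_index] / max(ml$arc_position_um),
               0.5, tolerance = 0.05)
})

test_that("ground truth survives a JSON round trip", {
  sim <- simulate_brightfield_movie(brightfield_config(seed = 5,
                                                       n_frames = 240L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(unlist(back$true_fractions),
               unname(sim$truth$true_fractions))
  expect_equal(back$cycle_boundaries, sim$truth$cycle_boundaries)
  expect_equal(back$period_frames, sim$truth$period_frames)
})

test_that("YAML configs map onto the constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "beat_frequency: 2.0",
    "n_frames: 48",
    "seed: 12",
    "flow_schedule:",
    "  - interval: [0.0, 0.8]",
    "    class: anterograde",
    "    speed: 250",
    "  - interval: [0.8, 1.0]",
    "    class: no_flow",
    "    speed: 0"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$beat_frequency, 2)
  expect_equal(unname(schedule_fractions_for_test <- vapply(
    cfg$flow_schedule, function(s) s$interval[2] - s$interval[1], 0)),
    c(0.8, 0.2))
  expect_error(read_sim_config({
    p2 <- withr::local_tempfile(fileext = ".yaml")
    writeLines("not_a_field: 3", p2); p2
  }), "unknown config keys")
})
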