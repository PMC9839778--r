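make_kymograph <- function(values, spacing = 1, frame_rate = 240) {
  structure(list(values = values, sample_spacing_um = spacing,
                 frame_rate = frame_rate, pixel_width = 1.92),
            class = "kymograph")
}

test_that("a spatially uniform movie gives a constant kymograph", {
  cfg <- brightfield_config(seed = 1, n_frames = 48L)
  ann <- sim_annotation(cfg)
  arr <- array(42, c(8, cfg$image_size[1], cfg$image_size[2]))
  mv <- movie_stack(arr, 240, 1.92)
  kym <- extract_kymograph(mv, ann)
  expect_true(all(abs(kym$values - 42) < 1e-9))
  expect_gte(ncol(kym$values), 8L)
})

test_that("an oversized window raises a geometry error", {
  cfg <- brightfield_config(seed = 1, n_frames = 48L)
  ann <- sim_annotation(cfg)
  arr <- array(0, c(4, cfg$image_size[1], cfg$image_size[2]))
  expect_error(extract_kymograph(movie_stack(arr, 240, 1.92), ann,
                                 window_halfwidth_um = 500),
               "geometry error")
})

test_that("kymograph stripe slopes flip sign at schedule transitions", {
  sim <- simulate_brightfield_movie(brightfield_config(seed = 17,
                                                       n_frames = 240L))
  kym <- extract_kymograph(sim$movie, sim$annotation)
  disp <- estimate_frame_displacement(kym)
  lab <- sim$truth$per_frame_flow_class[seq_len(nrow(disp))]
  # median signed displacement agrees with the scheduled direction
  expect_gt(median(disp$displacement_um[lab == "anterograde"]), 0)
  expect_lt(median(disp$displacement_um[lab == "retrograde"]), 0)
  expect_lt(abs(median(disp$displacement_um[lab == "no_flow"])),
            median(abs(disp$displacement_um[lab == "anterograde"])))
})

test_that("integer-shift lines recover the constructed displacement", {
  set.seed(5)
  base <- runif(64)
  # line 2 equals line 1 circularly shifted by +3 samples (content moves
  # toward higher indices, i.e. anterograde)
  shifted <- c(base[62:64], base[1:61])
  k <- make_kymograph(rbind(base, shifted), spacing = 2)
  d <- estimate_frame_displacement(k, max_lag_um = 20, remove_static = FALSE)
  expect_equal(d$displacement_um, 3 * 2, tolerance = 0.3)
  expect_gt(d$confidence, 0.9)
})

test_that("fractional shifts are recovered to sub-sample precision", {
  set.seed(6)
  x <- seq(0, 8 * pi, length.out = 200)
  base <- sin(x) + 0.4 * sin(2.7 * x + 1)
  shift_lin <- function(v, s) {
    idx <- seq_along(v) - s
    approx(seq_along(v), v, xout = idx, rule = 2)$y
  }
  true_shift <- 1.5
  line2 <- shift_lin(base, true_shift)  # content moves +1.5 samples
  k <- make_kymograph(rbind(base, line2), spacing = 1)
  d <- estimate_frame_displacement(k, max_lag_um = 10, remove_static = FALSE)
  # oracle: exhaustive correlation over fine lags via the same interpolator
  fine <- seq(-4, 4, by = 0.01)
  cc <- vapply(fine, function(s) cor(shift_lin(base, s), line2), 0)
  oracle <- fine[which.max(cc)]
  expect_equal(oracle, true_shift, tolerance = 0.05)
  expect_equal(d$displacement_um, oracle, tolerance = 0.25)
})

test_that("constant lines yield zero displacement with zero confidence", {
  k <- make_kymograph(matrix(3, 2, 32), spacing = 1)
  d <- estimate_frame_displacement(k, max_lag_um = 10, remove_static = FALSE)
  expect_equal(d$displacement_um, 0)
  expect_equal(d$confidence, 0)
})

test_that("classification applies sign, speed and confidence rules", {
  d <- data.frame(pair_index = 0:3,
                  displacement_um = c(1.25, -1.25, 0.2, 1.25),
                  confidence = c(0.9, 0.9, 0.9, 0.1))
  lab <- classify_flow_frames(d, speed_threshold_um_s = 115,
                              confidence_floor = 0.3, frame_rate = 240)
  # 1.25 um/frame at 240 fps = 300 um/s
  expect_equal(as.character(lab$label),
               c("anterograde", "retrograde", "no_flow", "no_flow"))
  expect_error(classify_flow_frames(d, speed_threshold_um_s = 0,
                                    confidence_floor = 0.3, frame_rate = 240),
               "positive")
})

test_that("no-flow fraction is monotone in the speed threshold", {
  sim <- simulate_brightfield_movie(brightfield_config(seed = 19,
                                                       n_frames = 480L))
  kym <- extract_kymograph(sim$movie, sim$annotation)
  disp <- estimate_frame_displacement(kym)
  cyc <- detect_cycles(sim$movie, sim$annotation)
  prev <- -1
  for (thr in c(30, 80, 150, 300, 600)) {
    lab <- classify_flow_frames(disp, thr, 0.3, 240)
    pr <- compute_flow_profile(lab, cyc)
    expect_gte(pr$averaged[["no_flow"]] + 1e-9, prev)
    prev <- pr$averaged[["no_flow"]]
  }
})

test_that("cycle detection recovers the beat period and heart rate", {
  sim <- simulate_brightfield_movie(brightfield_config(seed = 13))
  cyc <- detect_cycles(sim$movie, sim$annotation)
  # 2.5 Hz at 240 fps: 96 frames, 150 beats/min
  expect_equal(cyc$period_frames, 96, tolerance = 0.02 * 96)
  expect_equal(cyc$heart_rate_bpm, 150, tolerance = 0.02 * 150)
  expect_true(all(diff(cyc$boundaries) > 0))
  expect_true(all(abs(diff(cyc$boundaries) - cyc$period_frames) <=
                    0.2 * cyc$period_frames))
  # constant movie: no periodicity
  arr <- array(50, c(300, 48, 80))
  cann <- sim_annotation(brightfield_config(seed = 13))
  expect_error(detect_cycles(movie_stack(arr,
                                         240, 1.92), cann),
               "NoPeriodicity")
})

test_that("per-cycle percentages count frame pairs and average exactly", {
  # constructed labels: one 10-pair cycle split 7/2/1
  lab <- data.frame(
    pair_index = 0:29,
    displacement_um = 0, confidence = 1,
    label = factor(rep(c(rep("anterograde", 7), rep("retrograde", 2),
                         "no_flow"), 3),
                   levels = c("anterograde", "retrograde", "no_flow")))
  cyc <- structure(list(boundaries = c(0L, 10L, 20L, 30L),
                        period_frames = 10, heart_rate_bpm = 60,
                        frame_rate = 10), class = "cycle_set")
  pr <- compute_flow_profile(lab, cyc, n_cycles = 3)
  expect_equal(unname(pr$averaged), c(70, 20, 10))
  expect_equal(sum(pr$averaged), 100, tolerance = 1e-9)
  expect_true(all(abs(rowSums(pr$per_cycle) - 100) < 1e-9))
  # arithmetic mean across unequal cycles
  lab2 <- lab
  lab2$label[1:10] <- factor(c(rep("anterograde", 6), rep("retrograde", 3),
                               "no_flow"),
                             levels = levels(lab$label))
  lab2$label[11:20] <- factor(c(rep("anterograde", 8), "retrograde",
                                "no_flow"),
                              levels = levels(lab$label))
  pr2 <- compute_flow_profile(lab2, cyc, n_cycles = 3)
  expect_equal(unname(pr2$averaged), c(70, 20, 10))
  expect_error(compute_flow_profile(lab, cyc, n_cycles = 5),
               "InsufficientCycles")
})

test_that("group summaries match a direct sort-and-quantile oracle", {
  mk_profile <- function(a, r) {
    structure(list(per_cycle = matrix(c(a, r, 100 - a - r), 1,
                                      dimnames = list(NULL,
                                        c("anterograde", "retrograde",
                                          "no_flow"))),
                   averaged = c(anterograde = a, retrograde = r,
                                no_flow = 100 - a - r),
                   heart_rate_bpm = 150, n_cycles_used = 1L),
              class = "flow_profile")
  }
  profs <- list(mk_profile(60, 30), mk_profile(70, 20), mk_profile(80, 10),
                mk_profile(65, 25), mk_profile(75, 15))
  s <- summarize_profiles(profs)
  a_row <- s[s$class == "anterograde", ]
  v <- sort(c(60, 70, 80, 65, 75))
  expect_equal(a_row$median, v[3])
  expect_equal(a_row$mean, mean(v))
  expect_equal(a_row$q1, unname(quantile(v, 0.25)))
  expect_equal(a_row$q3, unname(quantile(v, 0.75)))
  expect_equal(a_row$min, 60); expect_equal(a_row$max, 80)
  # degenerate single profile: all summary points coincide
  s1 <- summarize_profiles(list(mk_profile(70, 20)))
  r1 <- s1[s1$class == "retrograde", ]
  expect_true(all(unlist(r1[c("min", "q1", "median", "q3", "max", "mean")]) == 20))
  expect_error(summarize_profiles(list()), "no profiles")
})
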