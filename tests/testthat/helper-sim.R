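# shared fixtures and independent oracles for the test suite

# three-phase flow schedule: anterograde a%, retrograde r%, no-flow rest
three_phase_schedule <- function(a_pct, r_pct, speed) {
  list(
    list(interval = c(0, a_pct / 100), class = "anterograde", speed = speed),
    list(interval = c(a_pct / 100, (a_pct + r_pct) / 100),
         class = "retrograde", speed = speed),
    list(interval = c((a_pct + r_pct) / 100, 1), class = "no_flow", speed = 0)
  )
}

# brightfield study configuration (240 fps, 1.92 um/px, 2.5 Hz beat)
brightfield_config <- function(seed, a_pct = 70, r_pct = 20, speed = 300,
                               noise_sd = 4, n_frames = 480L) {
  heart_sim_config(seed = seed, n_frames = n_frames, noise_sd = noise_sd,
                   flow_schedule = three_phase_schedule(a_pct, r_pct, speed))
}

# calcium plane-series study configuration (50 fps, 4 um z-step protocol:
# 50 planes over a 200 um deep heart); synchronous contraction so each
# plane's scalar trace carries the acquisition phase
gcamp_config <- function(seed, noise_sd = 6, av_enrichment = 2,
                         n_frames = 60L) {
  heart_sim_config(image_size = c(48L, 100L), pixel_width = 4,
                   frame_rate = 50, n_frames = n_frames, beat_frequency = 2.5,
                   chamber_radii = c(atrium = 52, ventricle = 48, canal = 15),
                   peristalsis_phase_lag = 0, noise_sd = noise_sd,
                   fluorescence_mode = TRUE, av_enrichment = av_enrichment,
                   seed = seed)
}

# exact point-to-polyline distance (segment-wise projection)
pt_polyline_dist <- function(p, poly) {
  dmin <- Inf
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]; ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    dmin <- min(dmin, sqrt(sum((a + t * ab - p)^2)))
  }
  dmin
}

# circular distance between frame indices modulo the period
circ_dist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# brute-force connected-components count of nucleus detections: two
# detections are adjacent when their xy distance is within the link radius
# and their plane gap within the allowed gap (union-find)
components_count <- function(det, link_radius_um, max_plane_gap,
                             pixel_width) {
  n <- nrow(det)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      gap <- abs(det$plane[i] - det$plane[j])
      dxy <- sqrt((det$x[i] - det$x[j])^2 + (det$y[i] - det$y[j])^2) *
        pixel_width
      if (gap >= 1L && gap <= max_plane_gap && dxy <= link_radius_um) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# random nucleus detection set: centres separated by more than twice the
# link radius (nuclei are solid bodies), each visible in 1-3 adjacent
# planes with sub-radius jitter
random_detections <- function(n_nuclei, link_radius_um = 3, field_px = 100,
                              n_planes = 8, pixel_width = 1) {
  centres <- matrix(numeric(0), 0, 2)
  while (nrow(centres) < n_nuclei) {
    cand <- stats::runif(2, 0, field_px)
    if (!nrow(centres) ||
        min(sqrt(rowSums(sweep(centres, 2, cand)^2))) * pixel_width >
          2.2 * link_radius_um) {
      centres <- rbind(centres, cand)
    }
  }
  xs <- ys <- numeric(0); pl <- integer(0)
  for (i in seq_len(n_nuclei)) {
    span <- sample(1:3, 1)
    p0 <- sample(seq_len(n_planes - span + 1L), 1)
    for (p in p0:(p0 + span - 1L)) {
      xs <- c(xs, centres[i, 1] + stats::runif(1, -0.3, 0.3) * link_radius_um)
      ys <- c(ys, centres[i, 2] + stats::runif(1, -0.3, 0.3) * link_radius_um)
      pl <- c(pl, p)
    }
  }
  nucleus_detections(xs, ys, pl, pixel_width = pixel_width, z_step = 2)
}

# true relative phase offsets (vs the chosen reference plane), mod period
relative_true_offsets <- function(truth, reference_plane) {
  (truth$per_plane_phase_offset -
     truth$per_plane_phase_offset[reference_plane]) %% truth$period_frames
}

# independent oracle: enumerate every table with the observed margins,
# computing each probability from log-binomial coefficients, and sum the
# probabilities not exceeding the observed table's
fisher_enum_oracle <- function(a, b, c2, d) {
  n <- a + b + c2 + d
  r1 <- a + b; c1 <- a + c2
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  p_obs <- exp(logp(a))
  sum(vapply(lo:hi, function(x) {
    p <- exp(logp(x))
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, 0))
}


make_ct <- function(ct_ctrl_gene, ct_test_gene, ct_ref = 18,
                    gene = "klf2a") {
  nc <- length(ct_ctrl_gene); nt <- length(ct_test_gene)
  data.frame(
    sample_id = c(rep(paste0("c", seq_len(nc)), each = 2),
                  rep(paste0("t", seq_len(nt)), each = 2),
                  paste0("c", rep(seq_len(nc), each = 1)),
                  paste0("t", rep(seq_len(nt), each = 1))),
    condition = c(rep("control", nc * 2), rep("test", nt * 2),
                  rep("control", nc), rep("test", nt)),
    biological_replicate = c(rep(seq_len(nc), each = 2),
                             rep(seq_len(nt), each = 2),
                             seq_len(nc), seq_len(nt)),
    technical_replicate = c(rep(1:2, nc + nt), rep(1L, nc + nt)),
    gene = c(rep(gene, (nc + nt) * 2), rep("eef1b2", nc + nt)),
    ct = c(rep(ct_ctrl_gene, each = 2), rep(ct_test_gene, each = 2),
           rep(ct_ref, nc + nt))
  )
}

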