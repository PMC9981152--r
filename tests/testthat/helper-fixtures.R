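# Shared fixtures, built in code at test time.

# A small grid/session for fast rendering tests: 8 x 4 positions, 2
# repeats, 9-degree figure.
small_grid <- function(repeats = 2L) {
  position_grid(n_azimuth = 8, n_elevation = 4, azimuth_span_deg = 21,
                elevation_span_deg = 9, repeats_per_position = repeats)
}

small_conditions <- function() {
  standard_conditions(figure_size_deg = 9, motion = motion_spec())
}

small_session <- function(seed = 1L, repeats = 2L) {
  build_figure_map_session(small_grid(repeats), small_conditions(),
                           seed = seed)
}

# Wrap a frames array as a minimal stimulus movie (full-field stimuli for
# filter tests).
fake_movie <- function(frames, px_per_deg = 1, frame_rate_hz = 14) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  nr <- dim(frames)[1]; nc <- dim(frames)[2]
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         fig_disp_deg = rep(0, dim(frames)[3]),
         bg_disp_deg = rep(0, dim(frames)[3]),
         px_per_deg = px_per_deg,
         azimuth_deg = (seq_len(nc) - (nc + 1) / 2) / px_per_deg,
         elevation_deg = (seq_len(nr) - (nr + 1) / 2) / px_per_deg,
         spec = figure_ground_spec("Cross")),
    class = "stimulus_movie"
  )
}

# Full-field grating frame in [0, 1] on an n x n canvas at 1 px/deg.
grating_frame <- function(n, orientation_deg, freq_cpd, phase = 0) {
  spec <- texture_spec("grating", orientation_deg = orientation_deg,
                       spatial_freq_cpd = freq_cpd, phase = phase,
                       size_px = c(n, n))
  make_texture(spec)
}

# Trial table for a single condition-variant on the canonical grid (the
# zone-count fixture): 16 x 8 positions x `repeats`.
single_variant_trials <- function(grid = position_grid(), condition = "Cross",
                                  variant = 1L) {
  pos <- expand.grid(az_bin = seq_len(grid$n_azimuth),
                     el_bin = seq_len(grid$n_elevation))
  tt <- pos[rep(seq_len(nrow(pos)), each = grid$repeats_per_position), ]
  tt$condition <- condition
  tt$variant <- variant
  tt$trial <- seq_len(nrow(tt))
  tt$onset_s <- (tt$trial - 1) * grid$dwell_ms / 1000
  rownames(tt) <- NULL
  tt
}

# Planted 2D-Gaussian RF cell: response to a sparse-noise event is the
# Gaussian evaluated at the event's grid square (ON to white squares),
# plus optional Gaussian noise.
planted_rf_responses <- function(events, center = c(16, 9), widths = c(2, 2),
                                 amplitude = 10, noise_sd = 0, seed = 1L) {
  g <- amplitude * exp(-((events$col - center[1])^2 / (2 * widths[1]^2) +
                           (events$row - center[2])^2 / (2 * widths[2]^2)))
  r <- pmax(0, g * (events$polarity > 0))
  if (noise_sd > 0) {
    r <- figground:::with_seed(seed, pmax(0, r + rnorm(length(r), 0, noise_sd)))
  }
  r
}
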