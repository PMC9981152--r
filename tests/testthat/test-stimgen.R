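test_that("figure-map sessions enumerate positions, repeats, and block structure", {
  sess <- build_figure_map_session(seed = 5)
  tr <- sess$trials
  expect_equal(nrow(unique(tr[, c("az_bin", "el_bin")])), 128)
  expect_equal(nrow(tr), 6 * 128 * 10)
  # one condition-variant contributes 1280 trials
  expect_equal(sum(tr$condition == "Cross" & tr$variant == 1), 1280)
  # each position appears exactly repeats times per condition-variant
  counts <- table(tr$condition, tr$variant, tr$az_bin, tr$el_bin)
  expect_true(all(counts == 10))
  # condition-variants run in contiguous blocks, variants of a condition
  # presented consecutively
  runs <- rle(paste(tr$condition, tr$variant))
  expect_equal(length(runs$lengths), 6)
  expect_true(all(runs$lengths == 1280))
  cond_runs <- rle(tr$condition)
  expect_equal(cond_runs$lengths, rep(2560, 3))
})

test_that("sessions are reproducible under seed", {
  a <- build_figure_map_session(seed = 9)
  b <- build_figure_map_session(seed = 9)
  expect_identical(a$trials, b$trials)
  c <- build_figure_map_session(seed = 10)
  expect_false(identical(a$trials, c$trials))
})

test_that("rendered movies are bounded, antisymmetric in displacement, deterministic", {
  sess <- small_session()
  for (cond in c("Cross", "Iso", "Nat")) {
    m <- render_stimulus(sess, cond, 1, 4, 2)
    expect_true(all(m$frames >= 0 & m$frames <= 1))
    expect_equal(m$fig_disp_deg + m$bg_disp_deg, rep(0, length(m$fig_disp_deg)))
    m2 <- render_stimulus(sess, cond, 1, 4, 2)
    expect_identical(m$frames, m2$frames)
  }
})

test_that("Nat figures are invisible at zero relative displacement; Cross never are", {
  sess <- small_session()
  spec <- sess$conditions$Nat1
  spec$figure_center_deg <- c(grid_azimuth_deg(sess$grid, 4),
                              grid_elevation_deg(sess$grid, 2))
  cv <- c(40, 25)
  fig <- render_trial_movie(spec, canvas_deg = cv)
  bg <- render_trial_movie(spec, canvas_deg = cv, draw_figure = FALSE)
  # frame 1 has zero displacement for both figure and background
  expect_identical(fig$frames[, , 1], bg$frames[, , 1])
  expect_gt(max(abs(fig$frames[, , 4] - bg$frames[, , 4])), 0)

  spec_x <- sess$conditions$Cross1
  spec_x$figure_center_deg <- spec$figure_center_deg
  fig_x <- render_trial_movie(spec_x, canvas_deg = cv)
  bg_x <- render_trial_movie(spec_x, canvas_deg = cv, draw_figure = FALSE)
  for (k in seq_len(dim(fig_x$frames)[3])) {
    expect_gt(max(abs(fig_x$frames[, , k] - bg_x$frames[, , k])), 0.1)
  }
})

test_that("Cross frames carry an orientation-energy discontinuity at the figure", {
  spec <- figure_ground_spec("Cross", variant = 1, figure_size_deg = 13)
  m <- render_trial_movie(spec, canvas_deg = c(50, 40))
  frame <- m$frames[, , 1]
  # energy in the figure-orientation channel, inside versus outside
  probe <- list(theta = figground:::deg2rad(135), sigma = 4, lambda = 1 / 0.06,
                gamma = 1, omega = 0)
  g_even <- gabor_filter(c(probe[-5], omega = 0))
  g_odd <- gabor_filter(c(probe[-5], omega = pi / 2))
  energy_at <- function(rowc, colc) {
    h <- (nrow(g_even) - 1) / 2
    patch <- frame[(rowc - h):(rowc + h), (colc - h):(colc + h)] - 0.5
    sqrt(sum(patch * g_even)^2 + sum(patch * g_odd)^2)
  }
  ctr <- c(round(nrow(frame) / 2), round(ncol(frame) / 2))
  e_fig <- energy_at(ctr[1], ctr[2])
  e_bg <- energy_at(ctr[1], 13)
  expect_gt(e_fig, 2 * e_bg)
})

test_that("background_static movies only translate the figure", {
  spec <- figure_ground_spec("Nat", figure_size_deg = 9,
                             motion = motion_spec(background_static = TRUE))
  m <- render_trial_movie(spec, canvas_deg = c(40, 25))
  expect_equal(m$bg_disp_deg, rep(0, length(m$bg_disp_deg)))
  expect_gt(max(abs(m$fig_disp_deg)), 3)
  expect_error(motion_spec(counterphase = TRUE, background_static = TRUE),
               "mutually exclusive")
})

test_that("the static control frame maximizes relative displacement", {
  spec <- figure_ground_spec("Cross", figure_size_deg = 9)
  m <- render_trial_movie(spec, canvas_deg = c(40, 25), duration_s = 1,
                          frame_rate_hz = 40)
  sf <- make_static_frame(m)
  # counterphase sine of amplitude A: max relative displacement is 2A
  expect_equal(sf$relative_disp_deg, 2 * spec$motion$amplitude_deg)
  expect_equal(sf$index, 11)  # t = 0.25 s, the sine extremum

  spec0 <- figure_ground_spec("Cross", figure_size_deg = 9,
                              motion = motion_spec(amplitude_deg = 0))
  m0 <- render_trial_movie(spec0, canvas_deg = c(40, 25), duration_s = 1,
                           frame_rate_hz = 40)
  expect_equal(make_static_frame(m0)$index, 1)  # tie-break: earliest frame

  spec_b <- figure_ground_spec(
    "Nat", figure_size_deg = 9,
    motion = motion_spec(background_static = TRUE))
  mb <- render_trial_movie(spec_b, canvas_deg = c(40, 25), duration_s = 1,
                           frame_rate_hz = 40)
  expect_equal(make_static_frame(mb)$index,
               which.max(abs(mb$fig_disp_deg)))

  # quarter-cycle movie: not a full motion cycle
  m_short <- render_trial_movie(spec, canvas_deg = c(40, 25),
                                duration_s = 0.25, frame_rate_hz = 40)
  expect_error(make_static_frame(m_short), "full motion cycle")
})

test_that("figures that would exit the frame are rejected", {
  spec <- figure_ground_spec("Cross", figure_size_deg = 30)
  expect_error(render_trial_movie(spec, canvas_deg = c(32, 32)),
               "exit the frame")
})

test_that("morph stages follow the 10% weighting schedule exactly", {
  g <- texture_spec("grating", orientation_deg = 45, spatial_freq_cpd = 0.1)
  n <- texture_spec("pink_noise", seed = 3)
  m <- lapply(c(1, 3, 4, 5, 10), function(s)
    make_morph_stimulus(s, g, n, placement = "middle", side = "left",
                        canvas_deg = c(40, 25), duration_s = 0.25,
                        frame_rate_hz = 8))
  names(m) <- c("s1", "s3", "s4", "s5", "s10")
  expect_equal(m$s3$morph_weights, c(grating = 0.7, noise = 0.3))
  expect_equal(m$s4$morph_weights[["noise"]] - m$s3$morph_weights[["noise"]],
               0.1)
  # the frames are an affine family in the stage weight:
  # m_s = (1 - s/10) G + (s/10) N, so m3 - m4 = m4 - m5 = (m1 - m10)/9
  d34 <- m$s3$frames - m$s4$frames
  d45 <- m$s4$frames - m$s5$frames
  expect_equal(d34, d45, tolerance = 1e-12)
  expect_equal(d34, (m$s1$frames - m$s10$frames) / 9, tolerance = 1e-12)
  # stage 10 is pure noise: the grating component is irrelevant
  g2 <- texture_spec("grating", orientation_deg = 135, spatial_freq_cpd = 0.2)
  m10b <- make_morph_stimulus(10, g2, n, placement = "middle", side = "left",
                              canvas_deg = c(40, 25), duration_s = 0.25,
                              frame_rate_hz = 8)
  expect_identical(m$s10$frames, m10b$frames)
  expect_error(make_morph_stimulus(0, g, n), "1..10")
  expect_error(make_morph_stimulus(11, g, n), "1..10")
})

test_that("movies and trial tables round-trip through their text exports", {
  skip_if_not_installed("tiff")
  sess <- small_session()
  m <- render_stimulus(sess, "Cross", 1, 4, 2)
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie_tiff(m, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.tif$", ".json", path)))
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_equal(length(pages), dim(m$frames)[3])
  expect_lt(max(abs(pages[[1]] - m$frames[, , 1])), 1 / 255)

  tt_path <- file.path(withr::local_tempdir(), "trials.csv")
  write_trial_table(sess, tt_path)
  back <- utils::read.csv(tt_path, stringsAsFactors = FALSE)
  expect_equal(back, sess$trials)
})
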