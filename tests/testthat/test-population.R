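test_that("population parameters are drawn from the stated uniform ranges", {
  pop <- sample_gabor_population(2000, seed = 3)
  expect_equal(nrow(pop), 2000)
  expect_true(all(pop$theta >= 0 & pop$theta < pi))
  expect_true(all(pop$sigma >= 2 & pop$sigma <= 7))
  expect_true(all(1 / pop$lambda >= 0.05 & 1 / pop$lambda <= 0.3))
  expect_true(all(pop$omega >= 0 & pop$omega < pi))
  expect_true(all(pop$gamma == 1))
  expect_identical(pop, sample_gabor_population(2000, seed = 3))
  expect_false(identical(pop, sample_gabor_population(2000, seed = 4)))
})

test_that("orientation draws are uniform on [0, pi)", {
  pop <- sample_gabor_population(1e5, seed = 11)
  ks <- suppressWarnings(stats::ks.test(pop$theta, "punif", 0, pi))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("the Gabor filter peaks at its center for zero phase", {
  g <- gabor_filter(list(theta = 0.7, sigma = 3, lambda = 8, gamma = 1,
                         omega = 0))
  ctr <- (nrow(g) + 1) / 2
  expect_equal(g[ctr, ctr], 1)   # envelope * cos(0)
  g2 <- gabor_filter(list(theta = 0.7, sigma = 3, lambda = 8, gamma = 1,
                          omega = pi / 3))
  expect_equal(g2[ctr, ctr], cos(pi / 3))
})

test_that("LN responses vanish on uniform gray and peak for the matched grating", {
  p <- data.frame(theta = figground:::deg2rad(45), sigma = 4, lambda = 10,
                  gamma = 1, omega = 0.4, x0 = 0, y0 = 0)
  gray <- fake_movie(matrix(0.5, 41, 41))
  expect_identical(ln_response(p, gray), 0)

  # brute-force sweep: the matched orientation and frequency win once the
  # best stimulus phase is taken for each (orientation, frequency) pair
  respond <- function(orientation, freq, phase) {
    frame <- grating_frame(41, orientation, freq, phase)
    ln_response(p, fake_movie(frame))
  }
  phases <- seq(0, 2 * pi, length.out = 17)[-17]
  best_at <- function(o, f) max(vapply(phases, function(ph) respond(o, f, ph),
                                       numeric(1)))
  matched <- best_at(45, 0.1)
  others <- c()
  for (o in c(0, 45, 90, 135)) {
    for (f in c(0.05, 0.1, 0.2)) {
      if (o == 45 && f == 0.1) next
      others <- c(others, best_at(o, f))
    }
  }
  expect_gt(matched, max(others))
  expect_true(all(others >= 0))
})

test_that("surround modulation follows the divisive formula and rho signs", {
  sp <- surround_params()
  expect_equal(surround_modulate(3, 0, sp), 3)
  expect_equal(surround_modulate(3, 1, sp), 3 / 1.95)
  expect_error(surround_params(beta = 1), "beta")
  expect_error(surround_params(inner_radius_sigma = 5, outer_radius_sigma = 2),
               "inner")

  # a probe whose annulus samples the ground: Iso surround is iso-oriented
  # (rho > 0, suppression), Cross surround orthogonal (rho < 0, facilitation)
  sp_fast <- surround_params(n_cell_types = 24L)
  probe <- sample_gabor_population(1, seed = 1)
  probe$x0 <- 0; probe$y0 <- 0; probe$sigma <- 7
  frame_for <- function(cond) {
    spec <- figure_ground_spec(cond, figure_size_deg = 27, pop_out = TRUE)
    m <- render_trial_movie(spec, canvas_deg = c(80, 60))
    m$frames[, , which.max(abs(m$fig_disp_deg - m$bg_disp_deg))]
  }
  rho_iso <- surround_rho_frame(frame_for("Iso"), probe, sp_fast)$rho
  rho_cross <- surround_rho_frame(frame_for("Cross"), probe, sp_fast)$rho
  expect_gt(rho_iso, 0)
  expect_lt(rho_cross, 0)

  # degenerate input: a uniform frame has zero orientation energy
  degen <- surround_rho_frame(matrix(0.5, 40, 40), probe, sp_fast)
  expect_true(degen$degenerate)
  expect_equal(degen$rho, 0)
  expect_equal(surround_modulate(2.5, degen$rho, sp_fast), 2.5)
})

test_that("the noise model matches its stated law and contracts", {
  R <- matrix(5, 4, 500)
  conds <- rep(c("Cross", "Nat"), each = 250)
  expect_identical(add_noise(R, conds, 0), R)
  noisy <- add_noise(R, conds, 2, seed = 6)
  expect_true(all(noisy >= 0))

  # empirical variance of the added noise ~ noise_factor * popmean (use a
  # large mean so rectification never binds)
  R2 <- matrix(100, 10, 10000)
  conds2 <- rep("Cross", 10000)
  noisy2 <- add_noise(R2, conds2, 2, seed = 7)
  expect_equal(stats::var(as.vector(noisy2 - R2)), 2 * 100, tolerance = 0.05)
  expect_error(add_noise(R, conds, -1), ">= 0")
  expect_error(add_noise(R, conds[1:3], 1), "per trial")
})

test_that("archetype cells follow their geometric response rules", {
  fc <- archetype_spec("figure_cell", rf_center = c(0, 0), rf_radius = 2)
  # figure centered on the RF responds; figure in the far background does not
  expect_equal(figground:::archetype_geometric_response(fc, 0, 0, 4.5), 1)
  expect_equal(figground:::archetype_geometric_response(fc, 20, 0, 4.5), 0)

  # independent pixel-level oracle: rasterize figure square and RF disc
  intersects <- function(fig_az, fig_el, half, rf, r) {
    xs <- seq(-30, 30, by = 0.25)
    grid_x <- rep(xs, times = length(xs))
    grid_y <- rep(xs, each = length(xs))
    in_fig <- abs(grid_x - fig_az) <= half & abs(grid_y - fig_el) <= half
    in_rf <- (grid_x - rf[1])^2 + (grid_y - rf[2])^2 <= r^2
    as.numeric(any(in_fig & in_rf))
  }
  set.seed(21)
  for (i in 1:25) {
    az <- runif(1, -15, 15); el <- runif(1, -10, 10)
    expect_equal(figground:::archetype_geometric_response(fc, az, el, 4.5),
                 intersects(az, el, 4.5, c(0, 0), 2),
                 info = sprintf("figure at (%.2f, %.2f)", az, el))
  }

  # border cell: vertical edges only, preferred side respected
  bc <- archetype_spec("border_cell", rf_center = c(0, 0), rf_radius = 2,
                       preferred_border_orientation = "vertical",
                       preferred_side = "left")
  # figure to the left with its right edge on the RF
  expect_equal(figground:::archetype_geometric_response(bc, -4.5, 0, 4.5), 1)
  # same edge geometry but figure on the right: wrong side
  expect_equal(figground:::archetype_geometric_response(bc, 4.5, 0, 4.5), 0)
  # figure centered on the RF: no edge within reach
  expect_equal(figground:::archetype_geometric_response(bc, 0, 0, 4.5), 0)
})

test_that("a figure cell's map is the dilation square of figure and RF", {
  sess <- small_session(repeats = 1L)
  rf_r <- 1.5
  pop <- archetype_population(list(
    archetype_spec("figure_cell", rf_center = c(0, 0), rf_radius = rf_r)))
  ds <- simulate_session(pop, sess, noise_factor = 0)
  m <- build_figure_map(ds$responses, ds$trials, ds$grid, "Cross", 1)
  # geometric oracle: response 1 iff |figure center - RF| within
  # figure_half + rf_radius in each... i.e. the dilation of the square by
  # the disc, evaluated at position centers
  half <- 4.5
  oracle <- matrix(0, ds$grid$n_elevation, ds$grid$n_azimuth)
  for (a in seq_len(ds$grid$n_azimuth)) {
    for (e in seq_len(ds$grid$n_elevation)) {
      az <- grid_azimuth_deg(ds$grid, a)
      el <- grid_elevation_deg(ds$grid, e)
      d <- sqrt(max(abs(az) - half, 0)^2 + max(abs(el) - half, 0)^2)
      oracle[e, a] <- as.numeric(d <= rf_r)
    }
  }
  expect_equal(unclass(m), oracle, ignore_attr = TRUE)
})

test_that("a vertical border cell's map shows two vertical stripes", {
  sess <- small_session(repeats = 1L)
  pop <- archetype_population(list(
    archetype_spec("border_cell", rf_center = c(0, 0), rf_radius = 1,
                   preferred_border_orientation = "vertical",
                   preferred_side = "left"),
    archetype_spec("border_cell", rf_center = c(0, 0), rf_radius = 1,
                   preferred_border_orientation = "vertical",
                   preferred_side = "right")))
  ds <- simulate_session(pop, sess, noise_factor = 0)
  m_left <- build_figure_map(ds$responses, ds$trials, ds$grid, "Nat", 1,
                             neuron = 1)
  m_right <- build_figure_map(ds$responses, ds$trials, ds$grid, "Nat", 1,
                              neuron = 2)
  # responses concentrate in one or two azimuth columns (a stripe), on
  # opposite sides for the two preferred sides
  act_cols_l <- which(colSums(m_left) > 0)
  act_cols_r <- which(colSums(m_right) > 0)
  expect_true(length(act_cols_l) >= 1 && length(act_cols_r) >= 1)
  expect_true(all(act_cols_l < (sess$grid$n_azimuth + 1) / 2))
  expect_true(all(act_cols_r > (sess$grid$n_azimuth + 1) / 2))
  # stripes span all elevations
  expect_true(all(m_left[, act_cols_l] > 0))
})

test_that("simulated sessions are deterministic and correctly sized", {
  sess <- small_session(repeats = 2L)
  pop <- sample_gabor_population(4, azimuth_range = c(-8, 8),
                                 elevation_range = c(-4, 4), seed = 2)
  ds1 <- simulate_session(pop, sess, noise_factor = 1, seed = 5)
  ds2 <- simulate_session(pop, sess, noise_factor = 1, seed = 5)
  expect_identical(ds1$responses, ds2$responses)
  expect_equal(dim(ds1$responses), c(4, nrow(sess$trials)))
  expect_true(all(ds1$responses >= 0))

  # noiseless: trials sharing both stimulus and motion onset phase give
  # identical responses (repeats at different onset phases legitimately
  # differ: that is the stimulus-driven variability)
  ds0 <- simulate_session(pop, sess, noise_factor = 0, seed = 5)
  tr <- ds0$trials
  window <- floor(((round((tr$onset_s %% 1) * 16)) %% 16) / 4)
  key <- paste(tr$condition, tr$variant, tr$az_bin, tr$el_bin, window)
  dup <- key[duplicated(key)][1]
  expect_false(is.na(dup))
  same <- which(key == dup)
  expect_equal(ds0$responses[, same[1]], ds0$responses[, same[2]])
  diff_phase <- which(paste(tr$condition, tr$variant, tr$az_bin,
                            tr$el_bin) ==
                        paste(tr$condition, tr$variant, tr$az_bin,
                              tr$el_bin)[same[1]] & window != window[same[1]])
  if (length(diff_phase) > 0) {
    expect_false(isTRUE(all.equal(ds0$responses[, same[1]],
                                  ds0$responses[, diff_phase[1]])))
  }
  # normalization: session grand-mean rate is 1
  expect_equal(mean(ds0$responses), 1, tolerance = 1e-10)
})
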