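cfg_fast <- decoding_config(n_iterations = 10, seed = 5)

test_that("one-hot azimuth features decode almost perfectly", {
  set.seed(1)
  labels <- rep(1:16, each = 12)
  X <- matrix(0, 16, length(labels))
  X[cbind(labels, seq_along(labels))] <- 1
  res <- decode_feature_matrix(X, labels, cfg_fast)
  expect_gt(res$variance_explained, 0.99)
  expect_lte(res$variance_explained, 1)
})

test_that("a localized noiseless archetype population is linearly decodable", {
  sess <- small_session(repeats = 4L)
  # two RF sizes tiling azimuth: the bin index is an exact linear readout
  specs <- c(
    lapply(seq(-10.5, 10.5, by = 3), function(az)
      archetype_spec("figure_cell", rf_center = c(az, 0), rf_radius = 1)),
    lapply(seq(-10.5, 10.5, by = 3), function(az)
      archetype_spec("figure_cell", rf_center = c(az, 0), rf_radius = 2.5)))
  pop <- archetype_population(specs)
  ds <- simulate_session(pop, sess, noise_factor = 0)
  sel <- ds$trials$condition == "Cross" & ds$trials$variant == 1
  # noiseless responses: allow the internal CV to reach tiny penalties
  cfg <- decoding_config(n_iterations = 10,
                         penalty_grid = 10^seq(0, -8, length.out = 9),
                         seed = 5)
  res <- fit_position_decoder(ds$responses[, sel], ds$trials$az_bin[sel],
                              cfg)
  expect_gt(res$variance_explained, 0.99)
})

test_that("permuted labels and pure-noise features decode at chance", {
  set.seed(2)
  labels <- rep(1:16, each = 12)
  X <- matrix(0, 16, length(labels))
  X[cbind(labels, seq_along(labels))] <- 1
  res_perm <- fit_position_decoder(X, labels, cfg_fast, permute_labels = TRUE)
  expect_lt(res_perm$variance_explained, 0.02)
  noise <- matrix(rnorm(30 * length(labels)), 30)
  res_noise <- decode_feature_matrix(noise, labels, cfg_fast)
  expect_lt(res_noise$variance_explained, 0.02)
  # constant features: the decoder falls back to the label mean, r^2 ~ 0
  res_const <- decode_feature_matrix(matrix(1, 5, length(labels)), labels,
                                     cfg_fast)
  expect_equal(res_const$variance_explained, 0, tolerance = 0.05)
})

test_that("decode_feature_matrix is the same pipeline as fit_position_decoder", {
  set.seed(3)
  X <- matrix(rnorm(20 * 96), 20)
  labels <- rep(1:8, each = 12)
  a <- fit_position_decoder(X, labels, cfg_fast)
  b <- decode_feature_matrix(X, labels, cfg_fast)
  expect_identical(a$per_iteration, b$per_iteration)
  expect_error(decode_feature_matrix(matrix(c(1, NA), 2, 4), rep(1:2, 2)),
               "finite")
})

test_that("decoder input contracts are enforced", {
  X <- matrix(rnorm(40), 4, 10)
  expect_error(fit_position_decoder(X, rep(1, 10)), "single-valued")
  expect_error(fit_position_decoder(X, 1:5), "per trial")
  expect_error(fit_position_decoder(X, rep(1:2, 5), n_neurons = 10),
               "exceeds")
})

test_that("decoding curves pool variants and grow with neuron count", {
  sess <- small_session(repeats = 3L)
  specs <- lapply(seq(-9, 9, by = 1.5), function(az)
    archetype_spec("figure_cell", rf_center = c(az, 0), rf_radius = 1))
  pop <- archetype_population(specs)
  ds <- simulate_session(pop, sess, noise_factor = 1, seed = 8)
  cfg <- decoding_config(n_iterations = 8, neuron_counts = c(2, 13), seed = 9)
  curve <- decoding_curve(ds, c("Cross", "Iso"), cfg)
  expect_equal(nrow(curve), 4)
  for (cond in c("Cross", "Iso")) {
    sub <- curve[curve$condition == cond, ]
    # monotone non-decreasing within confidence intervals
    expect_gt(sub$r2[sub$n_neurons == 13] + 0.05,
              sub$r2[sub$n_neurons == 2])
  }
  expect_error(decoding_curve(ds, "CrossTex", cfg), "absent")
})

test_that("an LN population generalizes the side report for Cross but not Nat", {
  pop <- sample_gabor_population(80, azimuth_range = c(-18, 18),
                                 elevation_range = c(-8, 8), seed = 3)
  canvas <- c(60, 36)
  respond_movie <- function(spec) {
    m <- render_trial_movie(spec, canvas_deg = canvas, duration_s = 1,
                            frame_rate_hz = 8)
    vapply(seq_len(nrow(pop)), function(i) ln_response(pop[i, ], m),
           numeric(1))
  }
  build_set <- function(cond, patterns, n_rep = 20, seed = 9) {
    R0 <- list(); lab <- c()
    for (p in seq_along(patterns)) {
      for (s in c("left", "right")) {
        ctr <- c(ifelse(s == "left", -12, 12), 0)
        spec <- if (cond == "Cross") {
          figure_ground_spec("Cross", variant = 1, figure_size_deg = 15,
                             grating_orientations = c(patterns[[p]], 0),
                             figure_center_deg = ctr)
        } else {
          figure_ground_spec("Nat", variant = 1, figure_size_deg = 15,
                             nat_seeds = c(patterns[[p]], 999L),
                             figure_center_deg = ctr)
        }
        R0[[length(R0) + 1]] <- respond_movie(spec)
        lab <- c(lab, s)
      }
    }
    R0 <- do.call(cbind, R0)
    R0 <- R0 / mean(R0)
    R <- R0[, rep(seq_len(ncol(R0)), each = n_rep)]
    R <- add_noise(R, rep("x", ncol(R)), 2, seed = seed)
    list(X = R, sides = rep(lab, each = n_rep))
  }
  # train on 2 patterns per side, test on 5 novel patterns per side
  acc <- list()
  for (cond in c("Cross", "Nat")) {
    train_pat <- if (cond == "Cross") list(45, 135) else list(11L, 12L)
    test_pat <- if (cond == "Cross") list(22.5, 67.5, 90, 112.5, 157.5)
                else list(21L, 22L, 23L, 24L, 25L)
    tr <- build_set(cond, train_pat, seed = 9)
    te <- build_set(cond, test_pat, seed = 10)
    acc[[cond]] <- side_generalization_test(tr$X, tr$sides, te$X, te$sides)
    expect_gte(acc[[cond]]$train_accuracy, acc[[cond]]$accuracy)
  }
  expect_gt(acc$Cross$accuracy, 0.6)          # transfers across orientations
  expect_lt(abs(acc$Nat$accuracy - 0.5), 0.15) # chance on novel textures
})

test_that("the side observer memorizes at least as well as it generalizes", {
  set.seed(10)
  n_per <- 40
  make_side_responses <- function(n_patterns, flip = FALSE) {
    sides <- rep(c("left", "right"), each = n_per * n_patterns)
    signal <- ifelse(sides == "right", 1, -1)
    X <- rbind(signal + rnorm(length(sides), 0, 0.8),
               matrix(rnorm(4 * length(sides)), 4))
    list(X = X, sides = sides)
  }
  tr <- make_side_responses(2)
  te <- make_side_responses(5)
  res <- side_generalization_test(tr$X, tr$sides, te$X, te$sides)
  res_mem <- side_generalization_test(tr$X, tr$sides, tr$X, tr$sides)
  expect_gte(res_mem$accuracy, res$accuracy - 0.02)
  expect_gt(res$accuracy, 0.8)
  # side-uninformative responses generalize at chance
  noise_tr <- list(X = matrix(rnorm(5 * 160), 5), sides = tr$sides)
  noise_te <- list(X = matrix(rnorm(5 * 400), 5), sides = te$sides)
  res_null <- side_generalization_test(noise_tr$X, noise_tr$sides,
                                       noise_te$X, noise_te$sides)
  expect_lt(abs(res_null$accuracy - 0.5), 0.12)
})
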