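#' Sample a population of Gabor simple cells
#'
#' Linear-filter parameters are drawn i.i.d. from uniform ranges: orientation
#' theta ~ U(0, pi), envelope sigma ~ U(2, 7) deg, spatial frequency
#' 1/lambda ~ U(0.05, 0.3) cpd, phase omega ~ U(0, pi), aspect ratio gamma
#' fixed at 1. Receptive-field centers are uniform over the stimulus grid
#' extent (the center distribution is a generator choice).
#'
#' @param n_neurons number of model cells.
#' @param azimuth_range,elevation_range RF-center ranges in degrees.
#' @param seed reproducibility seed.
#' @param sigma_range,freq_range_cpd,gamma parameter ranges.
#' @return a data.frame of class `gabor_population` with columns
#'   `theta, sigma, lambda, gamma, omega, x0, y0`.
#' @export
sample_gabor_population <- function(n_neurons,
                                    azimuth_range = c(-22.5, 22.5),
                                    elevation_range = c(-11.5, 11.5),
                                    seed = 1L,
                                    sigma_range = c(2, 7),
                                    freq_range_cpd = c(0.05, 0.3),
                                    gamma = 1) {
  stop_if_not_positive(n_neurons, "n_neurons")
  pop <- with_seed(seed, data.frame(
    theta = stats::runif(n_neurons, 0, pi),
    sigma = stats::runif(n_neurons, sigma_range[1], sigma_range[2]),
    lambda = 1 / stats::runif(n_neurons, freq_range_cpd[1], freq_range_cpd[2]),
    gamma = gamma,
    omega = stats::runif(n_neurons, 0, pi),
    x0 = stats::runif(n_neurons, azimuth_range[1], azimuth_range[2]),
    y0 = stats::runif(n_neurons, elevation_range[1], elevation_range[2])
  ))
  class(pop) <- c("gabor_population", "data.frame")
  pop
}

#' Evaluate a Gabor filter on a pixel grid
#'
#' g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) cos(2 pi x'/lambda + omega)
#' with (x', y') the coordinates rotated by theta. Support is truncated at
#' `support_sigma` envelope SDs (default 3, discarding <1% of envelope mass).
#'
#' @param params one row of a [sample_gabor_population()] data.frame (or any
#'   list with `theta, sigma, lambda, gamma, omega`).
#' @param px_per_deg resolution.
#' @param support_sigma half-width of the support in units of sigma.
#' @return a matrix; the filter is centered on the middle pixel with value
#'   `cos(omega)` there.
#' @export
gabor_filter <- function(params, px_per_deg = 1, support_sigma = 3) {
  half <- max(1L, as.integer(ceiling(params$sigma * support_sigma * px_per_deg)))
  u <- (-half:half) / px_per_deg
  x <- matrix(rep(u, each = length(u)), length(u))   # azimuth along columns
  y <- matrix(rep(u, times = length(u)), length(u))
  xp <- x * cos(params$theta) + y * sin(params$theta)
  yp <- -x * sin(params$theta) + y * cos(params$theta)
  exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * params$sigma^2)) *
    cos(2 * pi * xp / params$lambda + params$omega)
}

#' Linear-nonlinear response of one model cell to a movie
#'
#' Each frame is mean-centered (the 0.5 luminance pedestal removed), the
#' inner product with the cell's Gabor filter at the cell's center is
#' rectified at zero, and rectified per-frame outputs are averaged over
#' frames (set `per_frame = TRUE` for the time course).
#'
#' @param params one population row (needs `x0, y0` as well).
#' @param movie a `stimulus_movie`.
#' @param per_frame return the per-frame rectified responses instead of
#'   their mean.
#' @return nonnegative scalar rate (or a vector of per-frame rates).
#' @export
ln_response <- function(params, movie, per_frame = FALSE) {
  stopifnot(inherits(movie, "stimulus_movie"))
  ppd <- movie$px_per_deg
  g <- gabor_filter(params, px_per_deg = ppd)
  half <- (nrow(g) - 1) / 2
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  c_col <- round((nc + 1) / 2 + params$x0 * ppd)
  c_row <- round((nr + 1) / 2 + params$y0 * ppd)
  rows <- (c_row - half):(c_row + half)
  cols <- (c_col - half):(c_col + half)
  rok <- rows >= 1 & rows <= nr
  cok <- cols >= 1 & cols <= nc
  if (!any(rok) || !any(cok)) {
    stop("filter support lies entirely outside the movie canvas")
  }
  nt <- dim(movie$frames)[3]
  out <- numeric(nt)
  for (k in seq_len(nt)) {
    patch <- movie$frames[rows[rok], cols[cok], k] - 0.5
    out[k] <- max(0, sum(patch * g[rok, cok]))
  }
  if (per_frame) out else mean(out)
}

# Sparse filter-bank matrix: each row is one neuron's Gabor embedded at its
# center in the flattened canvas (column-major over rows then columns).
population_filter_matrix <- function(pop, nr, nc, px_per_deg,
                                     support_sigma = 3) {
  ii <- vector("list", nrow(pop)); jj <- ii; xx <- ii
  for (i in seq_len(nrow(pop))) {
    p <- pop[i, ]
    g <- gabor_filter(p, px_per_deg = px_per_deg,
                      support_sigma = support_sigma)
    half <- (nrow(g) - 1) / 2
    c_col <- round((nc + 1) / 2 + p$x0 * px_per_deg)
    c_row <- round((nr + 1) / 2 + p$y0 * px_per_deg)
    rows <- (c_row - half):(c_row + half)
    cols <- (c_col - half):(c_col + half)
    rok <- which(rows >= 1 & rows <= nr)
    cok <- which(cols >= 1 & cols <= nc)
    sub <- g[rok, cok, drop = FALSE]
    pix <- outer(rows[rok], (cols[cok] - 1) * nr, "+")
    ii[[i]] <- rep.int(i, length(sub))
    jj[[i]] <- as.vector(pix)
    xx[[i]] <- as.vector(sub)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(pop), nr * nc))
}

#' Divisive surround parameters
#'
#' The orientation-tuned surround divides the feedforward rate by
#' `1 + beta * rho`, where rho is the Pearson correlation between the mean
#' orientation-energy vectors (over a bank of `n_cell_types` filter types)
#' inside the receptive field (< `inner_radius_sigma` * sigma) and in the
#' surround annulus (up to `outer_radius_sigma` * sigma). beta = 0.95 keeps
#' the denominator positive for any rho in [-1, 1]. Iso-oriented surrounds
#' give rho > 0 (suppression); orthogonal surrounds give rho < 0
#' (facilitation).
#'
#' @param beta divisive scaling factor in `[0, 1)`.
#' @param inner_radius_sigma,outer_radius_sigma region radii in sigma units.
#' @param n_cell_types number of orientation channels in the energy bank.
#' @param bank_freq_cpd spatial frequency of the bank's filters (matched to
#'   the session's carrier gratings by default).
#' @param bank_sigma_lambda envelope SD of the bank filters as a fraction
#'   of their wavelength (sets orientation bandwidth).
#' @export
surround_params <- function(beta = 0.95, inner_radius_sigma = 2,
                            outer_radius_sigma = 5, n_cell_types = 100L,
                            bank_freq_cpd = 0.06, bank_sigma_lambda = 0.4) {
  if (beta < 0 || beta >= 1) stop("`beta` must be in [0, 1)")
  if (inner_radius_sigma >= outer_radius_sigma) {
    stop("`inner_radius_sigma` must be < `outer_radius_sigma`")
  }
  structure(list(beta = beta, inner_radius_sigma = inner_radius_sigma,
                 outer_radius_sigma = outer_radius_sigma,
                 n_cell_types = as.integer(n_cell_types),
                 bank_freq_cpd = bank_freq_cpd,
                 bank_sigma_lambda = bank_sigma_lambda),
            class = "surround_params")
}

# Orientation-energy bank: quadrature Gabor pairs (even/odd phase) at
# orientations evenly spaced on [0, pi), all at the bank's carrier-matched
# spatial frequency, so the energy vector is a phase-invariant local
# orientation spectrum. Centers are irrelevant: the bank is applied
# convolutionally.
surround_bank <- function(surround, px_per_deg) {
  lambda <- 1 / surround$bank_freq_cpd
  thetas <- seq(0, pi, length.out = surround$n_cell_types + 1)[-(surround$n_cell_types + 1)]
  lapply(thetas, function(th) {
    p <- list(theta = th, sigma = surround$bank_sigma_lambda * lambda,
              lambda = lambda, gamma = 1)
    list(even = gabor_filter(c(p, omega = 0), px_per_deg = px_per_deg),
         odd = gabor_filter(c(p, omega = pi / 2), px_per_deg = px_per_deg))
  })
}

# FFT of a filter embedded in an nr x nc canvas (origin at [1, 1],
# wrapped), for circular convolution.
embed_filter_fft <- function(g, nr, nc) {
  k <- matrix(0, nr, nc)
  half <- (nrow(g) - 1) / 2
  ri <- ((-half:half) %% nr) + 1
  ci <- ((-half:half) %% nc) + 1
  k[ri, ci] <- g
  stats::fft(k)
}

surround_bank_fft <- function(bank, nr, nc) {
  lapply(bank, function(pair) {
    list(even = embed_filter_fft(pair$even, nr, nc),
         odd = embed_filter_fft(pair$odd, nr, nc))
  })
}

# Quadrature orientation-energy maps of one frame: n_types x n_pixels.
orientation_energy_maps <- function(frame, bank_fft) {
  Ff <- stats::fft(frame - mean(frame))
  npix <- length(frame)
  E <- matrix(0, length(bank_fft), npix)
  for (k in seq_along(bank_fft)) {
    ce <- Re(stats::fft(Ff * bank_fft[[k]]$even, inverse = TRUE)) / npix
    co <- Re(stats::fft(Ff * bank_fft[[k]]$odd, inverse = TRUE)) / npix
    E[k, ] <- sqrt(as.vector(ce)^2 + as.vector(co)^2)
  }
  E
}

# Region-mean masks (columns sum to 1) for inside-RF and annulus regions of
# every neuron, on the flattened canvas.
region_masks <- function(pop, nr, nc, px_per_deg, surround) {
  az <- (seq_len(nc) - (nc + 1) / 2) / px_per_deg
  el <- (seq_len(nr) - (nr + 1) / 2) / px_per_deg
  X <- matrix(rep(az, each = nr), nr, nc)
  Y <- matrix(rep(el, times = nc), nr, nc)
  build <- function(select) {
    ii <- vector("list", nrow(pop)); jj <- ii; xx <- ii
    for (i in seq_len(nrow(pop))) {
      d <- sqrt((X - pop$x0[i])^2 + (Y - pop$y0[i])^2)
      pix <- which(select(d, pop$sigma[i]))
      if (length(pix) == 0) next
      ii[[i]] <- pix
      jj[[i]] <- rep.int(i, length(pix))
      xx[[i]] <- rep.int(1 / length(pix), length(pix))
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(nr * nc, nrow(pop)))
  }
  list(
    inner = build(function(d, s) d < surround$inner_radius_sigma * s),
    outer = build(function(d, s) d >= surround$inner_radius_sigma * s &
                    d < surround$outer_radius_sigma * s)
  )
}

#' Center-surround orientation-energy correlation for one frame
#'
#' rho per neuron: Pearson correlation across the bank's cell types between
#' mean orientation energy inside the RF and in the surround annulus.
#' Neurons with a zero-variance energy vector get rho = 0 (no modulation)
#' and are flagged.
#'
#' @param frame a luminance matrix.
#' @param pop a `gabor_population`.
#' @param surround a [surround_params()].
#' @param px_per_deg resolution of `frame`.
#' @return list with `rho` (per neuron) and logical `degenerate` flags.
#' @export
surround_rho_frame <- function(frame, pop, surround, px_per_deg = 1) {
  nr <- nrow(frame); nc <- ncol(frame)
  bank <- surround_bank(surround, px_per_deg)
  bfft <- surround_bank_fft(bank, nr, nc)
  E <- orientation_energy_maps(frame, bfft)
  masks <- region_masks(pop, nr, nc, px_per_deg, surround)
  Vin <- as.matrix(E %*% masks$inner)
  Vout <- as.matrix(E %*% masks$outer)
  r <- colwise_cor(Vin, Vout)
  degen <- !is.finite(r)
  r[degen] <- 0
  list(rho = r, degenerate = degen)
}

#' Apply divisive surround modulation
#'
#' `rate / (1 + beta * rho)`, elementwise. rho = 0 leaves the feedforward
#' rate unchanged.
#'
#' @param feedforward_rate nonnegative rate(s).
#' @param rho center-surround orientation-energy correlation(s) in [-1, 1].
#' @param surround a [surround_params()] (only `beta` is used).
#' @export
surround_modulate <- function(feedforward_rate, rho, surround = surround_params()) {
  feedforward_rate / (1 + surround$beta * rho)
}

#' Mean-scaled Gaussian noise model
#'
#' Zero-mean Gaussian noise with variance `noise_factor * popmean` is added
#' to every trial, where `popmean` is the mean response over all neurons and
#' trials of the trial's condition, followed by rectification at zero.
#' `noise_factor = 0` is the identity.
#'
#' @param responses neurons x trials matrix of nonnegative rates.
#' @param conditions character vector, one condition label per trial
#'   (defines the popmean scope).
#' @param noise_factor multiplier on the condition population mean.
#' @param seed reproducibility seed.
#' @return a matrix of the same shape, nonnegative.
#' @export
add_noise <- function(responses, conditions, noise_factor, seed = 1L) {
  if (noise_factor < 0) stop("`noise_factor` must be >= 0")
  if (noise_factor == 0) return(responses)
  if (length(conditions) != ncol(responses)) {
    stop("`conditions` must have one entry per trial (column)")
  }
  out <- responses
  with_seed(seed, {
    for (cond in unique(conditions)) {
      cols <- which(conditions == cond)
      popmean <- mean(responses[, cols])
      sdv <- sqrt(noise_factor * max(0, popmean))
      out[, cols] <- responses[, cols] +
        stats::rnorm(length(responses[, cols]), 0, sdv)
    }
  })
  pmax(out, 0)
}

#' Ideal-cell archetypes
#'
#' Deterministic response rules for the three schematic cell types used to
#' interpret figure maps: a `figure_cell` fires iff any part of the figure
#' covers its RF disc; a `border_cell` fires iff a figure border of its
#' preferred orientation falls on the RF *and* the figure lies on its
#' preferred side; an `on_simple_cell` is a rectified ON-center kernel
#' (phase-dependent, so its map tracks the carrier texture).
#'
#' @param kind archetype kind.
#' @param rf_center `(azimuth, elevation)` degrees.
#' @param rf_radius RF disc radius in degrees (kernel SD for the ON cell).
#' @param preferred_border_orientation `"vertical"` or `"horizontal"`
#'   (border cells).
#' @param preferred_side `"left"` or `"right"` (border cells): the side of
#'   the RF on which the figure must lie.
#' @return an `archetype_spec`.
#' @export
archetype_spec <- function(kind = c("figure_cell", "border_cell",
                                    "on_simple_cell"),
                           rf_center = c(0, 0), rf_radius = 3,
                           preferred_border_orientation = "vertical",
                           preferred_side = c("left", "right")) {
  kind <- match.arg(kind)
  preferred_side <- match.arg(preferred_side)
  if (!preferred_border_orientation %in% c("vertical", "horizontal")) {
    stop("`preferred_border_orientation` must be 'vertical' or 'horizontal'")
  }
  structure(list(kind = kind, rf_center = rf_center, rf_radius = rf_radius,
                 preferred_border_orientation = preferred_border_orientation,
                 preferred_side = preferred_side),
            class = "archetype_spec")
}

#' @rdname archetype_spec
#' @param specs list of `archetype_spec`s.
#' @export
archetype_population <- function(specs) {
  stopifnot(length(specs) > 0,
            all(vapply(specs, inherits, logical(1), "archetype_spec")))
  structure(list(specs = specs), class = "archetype_population")
}

# Trial-onset phase windows: a session's dwell time tiles the motion
# period, so each trial covers a contiguous window of the cycle's frames.
phase_windows <- function(session, n_frames) {
  period_s <- 1 / min(vapply(session$conditions,
                             function(s) s$motion$temporal_freq_hz,
                             numeric(1)))
  dwell_s <- session$grid$dwell_ms / 1000
  win_len <- min(n_frames, max(1L, round(n_frames * dwell_s / period_s)))
  n_windows <- max(1L, floor(n_frames / win_len))
  mid_frames <- (seq_len(n_windows) - 1L) * win_len + ceiling(win_len / 2)
  list(period_s = period_s, win_len = as.integer(win_len),
       n_windows = as.integer(n_windows), mid_frames = as.integer(mid_frames))
}

# Window index of each trial given its onset time.
trial_phase_window <- function(onset_s, pw, n_frames) {
  start0 <- round((onset_s %% pw$period_s) / pw$period_s * n_frames) %% n_frames
  pmin(pw$n_windows, floor(start0 / pw$win_len) + 1L)
}

# Distance from a point to an axis-aligned rectangle (0 if inside).
point_rect_distance <- function(px, py, cx, cy, half) {
  dx <- pmax(abs(px - cx) - half, 0)
  dy <- pmax(abs(py - cy) - half, 0)
  sqrt(dx^2 + dy^2)
}

# Deterministic archetype response to a figure at (az, el) of given size.
# ON simple cells need the rendered movie instead.
archetype_geometric_response <- function(spec, fig_az, fig_el, fig_half) {
  rf <- spec$rf_center
  r <- spec$rf_radius
  if (spec$kind == "figure_cell") {
    as.numeric(point_rect_distance(rf[1], rf[2], fig_az, fig_el, fig_half) <= r)
  } else if (spec$kind == "border_cell") {
    if (spec$preferred_border_orientation == "vertical") {
      # vertical edges at fig_az +/- fig_half, spanning fig_el +/- fig_half
      dy <- pmax(abs(rf[2] - fig_el) - fig_half, 0)
      d_edges <- sqrt(pmin((rf[1] - (fig_az - fig_half))^2,
                           (rf[1] - (fig_az + fig_half))^2) + dy^2)
      on_border <- d_edges <= r
      side_ok <- if (spec$preferred_side == "left") fig_az < rf[1]
                 else fig_az > rf[1]
      as.numeric(on_border && side_ok)
    } else {
      dx <- pmax(abs(rf[1] - fig_az) - fig_half, 0)
      d_edges <- sqrt(pmin((rf[2] - (fig_el - fig_half))^2,
                           (rf[2] - (fig_el + fig_half))^2) + dx^2)
      on_border <- d_edges <= r
      side_ok <- if (spec$preferred_side == "left") fig_el < rf[2]
                 else fig_el > rf[2]
      as.numeric(on_border && side_ok)
    }
  } else {
    stop("geometric responses are not defined for on_simple_cell")
  }
}

# Zero-mean ON-center Gaussian kernel response, rectified, frame-averaged.
on_cell_response <- function(spec, movie) {
  ppd <- movie$px_per_deg
  half <- max(1L, as.integer(ceiling(3 * spec$rf_radius * ppd)))
  u <- (-half:half) / ppd
  K <- exp(-outer(u^2, u^2, "+") / (2 * spec$rf_radius^2))
  K <- K - mean(K)
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  c_col <- round((nc + 1) / 2 + spec$rf_center[1] * ppd)
  c_row <- round((nr + 1) / 2 + spec$rf_center[2] * ppd)
  rows <- (c_row - half):(c_row + half)
  cols <- (c_col - half):(c_col + half)
  rok <- rows >= 1 & rows <= nr
  cok <- cols >= 1 & cols <= nc
  nt <- dim(movie$frames)[3]
  vals <- vapply(seq_len(nt), function(k) {
    max(0, sum((movie$frames[rows[rok], cols[cok], k] - 0.5) * K[rok, cok]))
  }, numeric(1))
  mean(vals)
}

#' Population responses to every unique stimulus of a session
#'
#' Streams over the session's unique stimuli (conditions x variants x grid
#' positions), rendering each movie once and computing each model cell's
#' rate; optionally also the surround correlation rho evaluated on the
#' frame of maximal relative displacement.
#'
#' @param population a `gabor_population` or `archetype_population`.
#' @param session an `fg_session`.
#' @param surround optional [surround_params()]; if supplied, the returned
#'   list carries a `rho` array (neurons x stimuli x onset-phase windows,
#'   evaluated at each window's middle frame) alongside the feedforward
#'   responses.
#' @param px_per_deg,n_frames rendering options. The `n_frames` frames
#'   sample one full motion cycle uniformly: because the displacement sine
#'   runs continuously during a recording, the repeats of a position land
#'   on all onset phases, and the expected per-position rate is the
#'   full-cycle phase average (repeat-to-repeat phase variability is
#'   carried by the noise model).
#' @return list with `responses` (neurons x stimuli feedforward rates),
#'   `stimuli` (the unique-stimulus table), `trial_stim`, and optionally
#'   `rho`. With `per_frame = TRUE`, also `responses_frames`
#'   (neurons x stimuli x frames).
#' @param per_frame also return per-frame rectified responses.
#' @export
population_responses <- function(population, session, surround = NULL,
                                 px_per_deg = 1, n_frames = 14,
                                 per_frame = FALSE) {
  us <- unique_stimuli(session)
  stim <- us$stimuli
  n_stim <- nrow(stim)
  canvas <- session_canvas_deg(session)
  freq <- min(vapply(session$conditions,
                     function(s) s$motion$temporal_freq_hz, numeric(1)))
  duration_s <- 1 / freq
  frame_rate_hz <- n_frames / duration_s

  is_gabor <- inherits(population, "gabor_population")
  n_neurons <- if (is_gabor) nrow(population) else length(population$specs)

  # geometry probe to size the canvas once
  probe <- render_stimulus(session, stim$condition[1], stim$variant[1],
                           stim$az_bin[1], stim$el_bin[1],
                           px_per_deg = px_per_deg, duration_s = duration_s,
                           frame_rate_hz = frame_rate_hz, canvas_deg = canvas)
  nr <- dim(probe$frames)[1]; nc <- dim(probe$frames)[2]

  Fmat <- if (is_gabor) {
    population_filter_matrix(population, nr, nc, px_per_deg)
  } else NULL
  bank_fft <- masks <- NULL
  # surround rho is evaluated once per trial-onset phase window (at the
  # window's middle frame), matching the phase sampling of trial responses
  pw <- phase_windows(session, n_frames)
  n_windows <- pw$n_windows
  rho_frames <- pw$mid_frames
  if (!is.null(surround)) {
    if (!is_gabor) stop("surround modulation applies to Gabor populations only")
    bank_fft <- surround_bank_fft(surround_bank(surround, px_per_deg), nr, nc)
    masks <- region_masks(population, nr, nc, px_per_deg, surround)
  }

  R <- matrix(0, n_neurons, n_stim)
  Rframes <- if (per_frame) array(0, dim = c(n_neurons, n_stim, n_frames)) else NULL
  rho <- if (!is.null(surround)) array(0, dim = c(n_neurons, n_stim, n_windows)) else NULL

  # archetype bookkeeping
  on_idx <- geo_idx <- integer(0)
  if (!is_gabor) {
    kinds <- vapply(population$specs, function(s) s$kind, character(1))
    on_idx <- which(kinds == "on_simple_cell")
    geo_idx <- which(kinds != "on_simple_cell")
  }

  for (j in seq_len(n_stim)) {
    need_frames <- is_gabor || length(on_idx) > 0 || !is.null(surround)
    movie <- if (need_frames && j == 1) probe else if (need_frames) {
      render_stimulus(session, stim$condition[j], stim$variant[j],
                      stim$az_bin[j], stim$el_bin[j],
                      px_per_deg = px_per_deg, duration_s = duration_s,
                      frame_rate_hz = frame_rate_hz, canvas_deg = canvas)
    } else NULL

    if (is_gabor) {
      X <- matrix(movie$frames - 0.5, nr * nc, n_frames)
      raw <- as.matrix(Fmat %*% X)
      rect <- pmax(raw, 0)
      R[, j] <- rowMeans(rect)
      if (per_frame) Rframes[, j, ] <- rect
      if (!is.null(surround)) {
        for (w in seq_len(n_windows)) {
          E <- orientation_energy_maps(movie$frames[, , rho_frames[w]],
                                       bank_fft)
          Vin <- as.matrix(E %*% masks$inner)
          Vout <- as.matrix(E %*% masks$outer)
          r <- colwise_cor(Vin, Vout)
          r[!is.finite(r)] <- 0
          rho[, j, w] <- r
        }
      }
    } else {
      fig_az <- grid_azimuth_deg(session$grid, stim$az_bin[j])
      fig_el <- grid_elevation_deg(session$grid, stim$el_bin[j])
      nm <- paste0(stim$condition[j], stim$variant[j])
      fig_half <- session$conditions[[nm]]$figure_size_deg / 2
      for (i in geo_idx) {
        R[i, j] <- archetype_geometric_response(population$specs[[i]],
                                                fig_az, fig_el, fig_half)
      }
      for (i in on_idx) {
        R[i, j] <- on_cell_response(population$specs[[i]], movie)
      }
      if (per_frame) Rframes[, j, ] <- R[, j]
    }
  }

  out <- list(responses = R, stimuli = stim, trial_stim = us$trial_stim)
  if (per_frame) out$responses_frames <- Rframes
  if (!is.null(surround)) out$rho <- rho
  out
}

#' Simulate a full recording session
#'
#' Chains stimulus rendering, the encoding model (feedforward LN, optionally
#' with divisive surround), trial expansion, rate normalization, and the
#' mean-scaled Gaussian noise model into a neurons x trials response matrix
#' with ground-truth metadata.
#'
#' Because the displacement sine runs continuously during a recording while
#' trials tile it at the grid's dwell time, each trial's rate is the mean of
#' the per-frame model rates over the cycle window starting at that trial's
#' onset phase (`onset_s` modulo the motion period). Repeats of a position
#' therefore sample different motion phases, carrying the stimulus-driven
#' component of trial-to-trial variability; the Gaussian noise model sits on
#' top of it.
#'
#' Rates are normalized so the session grand-mean response is 1 (arbitrary
#' units) before noise is added; with `noise_factor = 2` the noise variance
#' is then twice the condition-level population mean.
#'
#' @inheritParams population_responses
#' @param noise_factor noise variance per unit condition popmean.
#' @param seed noise seed.
#' @param normalize scale responses to grand mean 1 before noise (skipped
#'   for archetype populations, whose rates are already 0/1 rules).
#' @param precomputed optionally, the result of [population_responses()]
#'   with `per_frame = TRUE` (so several noise/surround settings can reuse
#'   one rendering pass).
#' @param n_frames frames per motion cycle (16 gives whole-frame quarter
#'   cycle windows at the canonical 250 ms dwell / 1 Hz motion).
#' @return An object of class `fg_dataset`: `responses` (neurons x trials),
#'   `trials`, `neurons` (ground-truth parameters), `grid`, `provenance`.
#' @export
simulate_session <- function(population, session, surround = NULL,
                             noise_factor = 0, seed = 1L, px_per_deg = 1,
                             n_frames = 16, normalize = TRUE,
                             precomputed = NULL) {
  is_gabor <- inherits(population, "gabor_population")
  pr <- if (is.null(precomputed)) {
    population_responses(population, session, surround = surround,
                         px_per_deg = px_per_deg, n_frames = n_frames,
                         per_frame = is_gabor)
  } else precomputed
  trials <- session$trials

  if (is_gabor && !is.null(pr$responses_frames)) {
    RF <- pr$responses_frames
    nf <- dim(RF)[3]
    pw <- phase_windows(session, nf)
    start <- (round((trials$onset_s %% pw$period_s) / pw$period_s * nf)) %% nf
    win <- trial_phase_window(trials$onset_s, pw, nf)
    if (!is.null(surround) && is.null(pr$rho)) {
      stop("`precomputed` lacks rho; rerun with surround")
    }
    resp <- matrix(0, dim(RF)[1], nrow(trials))
    for (j in seq_len(nrow(trials))) {
      frames_j <- ((start[j] + seq_len(pw$win_len) - 1L) %% nf) + 1L
      M <- RF[, pr$trial_stim[j], frames_j, drop = FALSE]
      resp[, j] <- rowMeans(matrix(M, dim(RF)[1]))
      if (!is.null(surround)) {
        resp[, j] <- resp[, j] /
          (1 + surround$beta * pr$rho[, pr$trial_stim[j], win[j]])
      }
    }
  } else {
    R <- pr$responses
    if (!is.null(surround)) {
      if (is.null(pr$rho)) stop("`precomputed` lacks rho; rerun with surround")
      rho_mean <- if (length(dim(pr$rho)) == 3) {
        apply(pr$rho, c(1, 2), mean)
      } else pr$rho
      R <- surround_modulate(R, rho_mean, surround)
    }
    resp <- R[, pr$trial_stim, drop = FALSE]
  }

  if (normalize && is_gabor) {
    gm <- mean(resp)
    if (gm > 0) resp <- resp / gm
  }
  resp <- add_noise(resp, trials$condition, noise_factor,
                    seed = derive_seed(seed, 2L))
  neurons <- if (inherits(population, "gabor_population")) {
    cbind(neuron = seq_len(nrow(population)), as.data.frame(population))
  } else {
    data.frame(neuron = seq_along(population$specs),
               kind = vapply(population$specs, function(s) s$kind,
                             character(1)))
  }
  structure(
    list(responses = resp, trials = trials, neurons = neurons,
         grid = session$grid,
         provenance = list(seed = as.integer(seed),
                           noise_factor = noise_factor,
                           surround = if (is.null(surround)) NULL
                                      else unclass(surround),
                           session_seed = session$seed,
                           schema_version = SESSION_SCHEMA_VERSION)),
    class = "fg_dataset"
  )
}

#' @export
print.fg_dataset <- function(x, ...) {
  cat(sprintf("<fg_dataset> %d neurons x %d trials (noise factor %g)\n",
              nrow(x$responses), ncol(x$responses),
              x$provenance$noise_factor))
  invisible(x)
}
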