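#' Opponent-motion specification
#'
#' Figure and background translate horizontally with a sinusoidal
#' displacement of half-range `amplitude_deg` (canonically 3.5 deg, i.e. 14
#' movie pixels) at `temporal_freq_hz` cycles/s. By default the two move in
#' counterphase (180 deg out of phase), producing accretion-deletion at the
#' figure border; `background_static` freezes the background instead (the
#' control in which only the figure translates).
#'
#' @param amplitude_deg half-range of the sinusoidal displacement, degrees.
#' @param temporal_freq_hz temporal frequency in cycles/s.
#' @param counterphase figure and background displacement traces sum to zero.
#' @param background_static background does not move; figure translates.
#' @export
motion_spec <- function(amplitude_deg = 3.5, temporal_freq_hz = 1,
                        counterphase = TRUE, background_static = FALSE) {
  if (amplitude_deg < 0) stop("`amplitude_deg` must be >= 0")
  stop_if_not_positive(temporal_freq_hz, "temporal_freq_hz")
  if (background_static && missing(counterphase)) counterphase <- FALSE
  if (counterphase && background_static) {
    stop("`counterphase` and `background_static` are mutually exclusive")
  }
  structure(list(amplitude_deg = amplitude_deg,
                 temporal_freq_hz = temporal_freq_hz,
                 counterphase = counterphase,
                 background_static = background_static),
            class = "motion_spec")
}

#' Figure-ground stimulus specification
#'
#' Builds the carrier textures for one condition-variant:
#' * `Cross`: figure grating orthogonal to the background grating.
#' * `Iso`: same orientation, figure offset in phase (default half period).
#' * `Nat`: figure and background are the *same* 1/f noise sample, so with
#'   zero relative displacement the figure is invisible and is defined
#'   purely by opponent motion.
#' * `IsoTex` / `CrossTex`: noise-texture variants where the figure patch is
#'   the background crop as-is, or rotated 90 degrees to add orientation
#'   contrast.
#'
#' @param condition one of `"Cross"`, `"Iso"`, `"Nat"`, `"CrossTex"`,
#'   `"IsoTex"`.
#' @param variant 1 or 2, selecting the grating orientation (45 or 135 deg)
#'   or the noise seed.
#' @param figure_center_deg `(azimuth, elevation)` of the figure center.
#' @param figure_size_deg side of the square figure (27 deg for the
#'   recording stimulus).
#' @param motion a [motion_spec()].
#' @param grating_orientations the two variant orientations, degrees.
#' @param spatial_freq_cpd grating frequency (0.06 cpd canonically).
#' @param nat_seeds two fixed noise seeds, one per Nat/Tex variant; a session
#'   reuses the same two texture samples throughout.
#' @param iso_phase_offset figure-background phase offset for Iso, radians
#'   (behavioral stimulus).
#' @param pop_out recording-session variant of Iso: the figure texture is
#'   *identical* to the background (no phase offset) and the figure pops
#'   out only through opponent motion, as in the figure-map stimulus used
#'   for electrophysiology/imaging. Ignored for other conditions.
#' @return An object of class `fg_spec`.
#' @export
figure_ground_spec <- function(condition = c("Cross", "Iso", "Nat",
                                             "CrossTex", "IsoTex"),
                               variant = 1, figure_center_deg = c(0, 0),
                               figure_size_deg = 27, motion = motion_spec(),
                               grating_orientations = c(45, 135),
                               spatial_freq_cpd = 0.06,
                               nat_seeds = c(101L, 202L),
                               iso_phase_offset = pi,
                               pop_out = FALSE) {
  condition <- match.arg(condition)
  if (!variant %in% c(1, 2)) stop("`variant` must be 1 or 2")
  stop_if_not_positive(figure_size_deg, "figure_size_deg")
  stopifnot(inherits(motion, "motion_spec"))
  structure(
    list(condition = condition, variant = as.integer(variant),
         figure_center_deg = figure_center_deg,
         figure_size_deg = figure_size_deg, motion = motion,
         grating_orientations = grating_orientations,
         spatial_freq_cpd = spatial_freq_cpd,
         nat_seeds = as.integer(nat_seeds),
         iso_phase_offset = iso_phase_offset,
         pop_out = isTRUE(pop_out)),
    class = "fg_spec"
  )
}

# Background / figure texture specs implied by a condition-variant. The
# figure texture is sampled at the aperture's home position, so for Nat the
# patch is pixel-identical to the background it covers.
condition_textures <- function(spec, size_px) {
  o <- spec$grating_orientations[spec$variant]
  grating <- function(orientation, phase = 0) {
    texture_spec("grating", orientation_deg = orientation,
                 spatial_freq_cpd = spec$spatial_freq_cpd, phase = phase,
                 size_px = size_px)
  }
  noise <- texture_spec("pink_noise", seed = spec$nat_seeds[spec$variant],
                        size_px = size_px)
  switch(spec$condition,
    Cross = list(background = grating(o), figure = grating(o + 90),
                 rotate_patch = FALSE),
    Iso = if (spec$pop_out) {
      # session stimulus: figure texture identical to the background,
      # defined only by opponent motion
      list(background = grating(o), figure = grating(o),
           rotate_patch = FALSE)
    } else {
      list(background = grating(o),
           figure = grating(o, phase = spec$iso_phase_offset),
           rotate_patch = FALSE)
    },
    Nat = list(background = noise, figure = noise, rotate_patch = FALSE),
    IsoTex = list(background = noise, figure = noise, rotate_patch = FALSE),
    CrossTex = list(background = noise, figure = noise, rotate_patch = TRUE)
  )
}

rotate90 <- function(m) t(m)[, seq_len(nrow(m)), drop = FALSE][, nrow(m):1, drop = FALSE]

#' Render one figure-ground trial movie
#'
#' The background, shifted by its displacement, is drawn first; the figure
#' patch (its texture rigidly attached to the aperture) is pasted over it at
#' the displaced figure location. Background pixels are thereby revealed and
#' hidden at the figure's trailing and leading edges (accretion-deletion).
#' Displacements are quantized to whole pixels at the rendering resolution.
#'
#' @param spec a [figure_ground_spec()].
#' @param canvas_deg `(width, height)` of the rendered canvas in degrees.
#' @param px_per_deg rendering resolution.
#' @param duration_s movie duration.
#' @param frame_rate_hz frame rate (14 frames per 250 ms trial by default).
#' @param draw_figure set `FALSE` to render the moving background alone
#'   (the no-figure control frame, useful for invisibility checks: a Nat
#'   figure at zero relative displacement is pixel-identical to it).
#' @return An object of class `stimulus_movie`: `frames` is an
#'   `nrow x ncol x n_frames` array in `[0, 1]`; `fig_disp_deg` and
#'   `bg_disp_deg` are the per-frame displacement traces.
#' @export
render_trial_movie <- function(spec, canvas_deg = c(60, 40), px_per_deg = 1,
                               duration_s = 0.25, frame_rate_hz = 56,
                               draw_figure = TRUE) {
  stopifnot(inherits(spec, "fg_spec"))
  nc <- round(canvas_deg[1] * px_per_deg) + 1L
  nr <- round(canvas_deg[2] * px_per_deg) + 1L
  nt <- max(1L, round(duration_s * frame_rate_hz))
  t <- (seq_len(nt) - 1) / frame_rate_hz

  mo <- spec$motion
  s_fig <- mo$amplitude_deg * sin(2 * pi * mo$temporal_freq_hz * t)
  s_bg <- if (mo$background_static) rep(0, nt)
          else if (mo$counterphase) -s_fig else s_fig
  sf <- as.integer(round(s_fig * px_per_deg))
  sb <- as.integer(round(s_bg * px_per_deg))

  margin <- as.integer(ceiling(mo$amplitude_deg * px_per_deg)) + 1L
  tex <- condition_textures(spec, size_px = c(nr, nc + 2L * margin))
  bg_tex <- make_texture(tex$background, px_per_deg = px_per_deg)
  fig_tex <- if (identical(tex$figure, tex$background)) bg_tex
             else make_texture(tex$figure, px_per_deg = px_per_deg)

  # aperture home position (integer pixel indices)
  half <- as.integer(round(spec$figure_size_deg * px_per_deg / 2))
  c_col <- as.integer(round((nc + 1) / 2 + spec$figure_center_deg[1] * px_per_deg))
  c_row <- as.integer(round((nr + 1) / 2 + spec$figure_center_deg[2] * px_per_deg))
  rows <- (c_row - half):(c_row + half)
  cols <- (c_col - half):(c_col + half)
  if (min(rows) < 1 || max(rows) > nr ||
      min(cols) + min(sf) < 1 || max(cols) + max(sf) > nc) {
    stop("figure would exit the frame for some displacement; enlarge the canvas")
  }

  patch <- fig_tex[rows, cols + margin, drop = FALSE]
  if (tex$rotate_patch) {
    if (length(rows) != length(cols)) stop("rotated patch requires a square figure")
    patch <- rotate90(patch)
  }

  frames <- array(0, dim = c(nr, nc, nt))
  for (k in seq_len(nt)) {
    fr <- bg_tex[, (1L + margin - sb[k]):(nc + margin - sb[k]), drop = FALSE]
    if (draw_figure) fr[rows, cols + sf[k]] <- patch
    frames[, , k] <- fr
  }

  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         fig_disp_deg = s_fig, bg_disp_deg = s_bg,
         fig_shift_px = sf, bg_shift_px = sb,
         px_per_deg = px_per_deg,
         azimuth_deg = (seq_len(nc) - (nc + 1) / 2) / px_per_deg,
         elevation_deg = (seq_len(nr) - (nr + 1) / 2) / px_per_deg,
         spec = spec),
    class = "stimulus_movie"
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %s v%d: %d x %d px, %d frames @ %g Hz, figure %g deg\n",
              x$spec$condition, x$spec$variant, d[1], d[2], d[3],
              x$frame_rate_hz, x$spec$figure_size_deg))
  invisible(x)
}

#' Static control frame of a movie
#'
#' Returns the frame with the largest absolute difference between figure and
#' background displacement (the frame used for the static versions of the
#' behavioral tasks); ties are broken by the earliest frame. For a
#' counterphase sine of amplitude A this is the frame with relative
#' displacement 2A.
#'
#' @param movie a [render_trial_movie()] result covering at least one full
#'   motion cycle (unless the motion amplitude is zero).
#' @return list with the selected `frame` (matrix) and its `index`.
#' @export
make_static_frame <- function(movie) {
  stopifnot(inherits(movie, "stimulus_movie"))
  nt <- dim(movie$frames)[3]
  if (nt < 1) stop("empty movie")
  mo <- movie$spec$motion
  duration <- nt / movie$frame_rate_hz
  if (mo$amplitude_deg > 0 && duration < 1 / mo$temporal_freq_hz - 1e-9) {
    stop("movie must cover at least one full motion cycle")
  }
  rel <- abs(movie$fig_disp_deg - movie$bg_disp_deg)
  idx <- which.max(rel)   # earliest frame on ties
  list(frame = movie$frames[, , idx], index = idx,
       relative_disp_deg = rel[idx])
}

#' Grating-to-noise morph stimulus
#'
#' Training-schedule stimulus in which both carrier textures are a weighted
#' sum of a grating and a noise texture. At stage s of 10 the noise weight
#' is s/10 (stage 3: 70% grating / 30% noise; stage 10: pure noise). The
#' figure patch is flipped vertically relative to the background and placed
#' at one of three heights to discourage local-cue strategies.
#'
#' @param stage integer 1..10.
#' @param grating,noise [texture_spec()]s for the two components (sizes are
#'   overridden by the canvas).
#' @param placement `"top"`, `"middle"`, or `"down"`.
#' @param side `"left"` or `"right"` figure placement.
#' @param figure_size_deg,motion,canvas_deg,px_per_deg,duration_s,frame_rate_hz
#'   as in [render_trial_movie()].
#' @return a `stimulus_movie` with `morph_weights` attached.
#' @export
make_morph_stimulus <- function(stage, grating, noise,
                                placement = c("middle", "top", "down"),
                                side = c("left", "right"),
                                figure_size_deg = 15,
                                motion = motion_spec(),
                                canvas_deg = c(60, 40), px_per_deg = 1,
                                duration_s = 1, frame_rate_hz = 30) {
  if (!(is.numeric(stage) && length(stage) == 1 && stage %in% 1:10)) {
    stop("`stage` must be an integer in 1..10")
  }
  placement <- match.arg(placement)
  side <- match.arg(side)
  w_noise <- stage / 10
  w_grating <- 1 - w_noise

  nc <- round(canvas_deg[1] * px_per_deg) + 1L
  nr <- round(canvas_deg[2] * px_per_deg) + 1L
  nt <- max(1L, round(duration_s * frame_rate_hz))
  t <- (seq_len(nt) - 1) / frame_rate_hz
  s_fig <- motion$amplitude_deg * sin(2 * pi * motion$temporal_freq_hz * t)
  s_bg <- if (motion$background_static) rep(0, nt)
          else if (motion$counterphase) -s_fig else s_fig
  sf <- as.integer(round(s_fig * px_per_deg))
  sb <- as.integer(round(s_bg * px_per_deg))
  margin <- as.integer(ceiling(motion$amplitude_deg * px_per_deg)) + 1L

  size_px <- c(nr, nc + 2L * margin)
  g <- grating; g$size_px <- as.integer(size_px)
  n <- noise; n$size_px <- as.integer(size_px)
  bg_tex <- w_grating * make_texture(g, px_per_deg = px_per_deg) +
    w_noise * make_texture(n, px_per_deg = px_per_deg)

  half <- as.integer(round(figure_size_deg * px_per_deg / 2))
  el <- switch(placement,
               top = -canvas_deg[2] / 4, middle = 0, down = canvas_deg[2] / 4)
  az <- switch(side, left = -canvas_deg[1] / 4, right = canvas_deg[1] / 4)
  c_col <- as.integer(round((nc + 1) / 2 + az * px_per_deg))
  c_row <- as.integer(round((nr + 1) / 2 + el * px_per_deg))
  rows <- (c_row - half):(c_row + half)
  cols <- (c_col - half):(c_col + half)
  if (min(rows) < 1 || max(rows) > nr ||
      min(cols) + min(sf) < 1 || max(cols) + max(sf) > nc) {
    stop("figure would exit the frame; enlarge the canvas")
  }
  patch <- bg_tex[rev(rows), cols + margin, drop = FALSE]  # vertical flip

  frames <- array(0, dim = c(nr, nc, nt))
  for (k in seq_len(nt)) {
    fr <- bg_tex[, (1L + margin - sb[k]):(nc + margin - sb[k]), drop = FALSE]
    fr[rows, cols + sf[k]] <- patch
    frames[, , k] <- fr
  }

  spec <- figure_ground_spec("Nat", variant = 1,
                             figure_center_deg = c(az, el),
                             figure_size_deg = figure_size_deg,
                             motion = motion)
  out <- structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         fig_disp_deg = s_fig, bg_disp_deg = s_bg,
         fig_shift_px = sf, bg_shift_px = sb, px_per_deg = px_per_deg,
         azimuth_deg = (seq_len(nc) - (nc + 1) / 2) / px_per_deg,
         elevation_deg = (seq_len(nr) - (nr + 1) / 2) / px_per_deg,
         spec = spec),
    class = "stimulus_movie"
  )
  out$morph_weights <- c(grating = w_grating, noise = w_noise)
  out$morph_stage <- as.integer(stage)
  out
}

#' The six standard condition-variants
#'
#' Cross, Iso, and Nat, each with two variants (two grating orientations or
#' two fixed noise textures), as presented in a figure-map session. Session
#' Iso figures use the background texture itself (`pop_out = TRUE`): within
#' Iso and Nat the figure is defined only by opponent motion.
#'
#' @inheritParams figure_ground_spec
#' @return named list of six [figure_ground_spec()]s.
#' @export
standard_conditions <- function(figure_size_deg = 27, motion = motion_spec(),
                                grating_orientations = c(45, 135),
                                spatial_freq_cpd = 0.06,
                                nat_seeds = c(101L, 202L)) {
  specs <- list()
  for (cond in c("Cross", "Iso", "Nat")) {
    for (v in 1:2) {
      specs[[paste0(cond, v)]] <- figure_ground_spec(
        cond, variant = v, figure_size_deg = figure_size_deg,
        motion = motion, grating_orientations = grating_orientations,
        spatial_freq_cpd = spatial_freq_cpd, nat_seeds = nat_seeds,
        pop_out = TRUE)
    }
  }
  specs
}

#' Build a figure-map session
#'
#' Enumerates every grid position `repeats_per_position` times for each
#' condition-variant and orders the trials the way the recordings were run:
#' the conditions (Cross/Iso/Nat) appear in pseudo-random order, the two
#' within-condition variants are presented consecutively (in random order),
#' and positions are shuffled within each condition-variant block.
#'
#' @param grid a [position_grid()].
#' @param conditions list of [figure_ground_spec()]s (default the six
#'   standard condition-variants).
#' @param seed session seed; identical seeds reproduce identical trial
#'   orders.
#' @return An object of class `fg_session`: `$trials` is a data.frame with
#'   columns `trial, condition, variant, az_bin, el_bin, onset_s`.
#' @export
build_figure_map_session <- function(grid = position_grid(),
                                     conditions = standard_conditions(),
                                     seed = 1L) {
  stopifnot(inherits(grid, "position_grid"))
  info <- data.frame(
    condition = vapply(conditions, function(s) s$condition, character(1)),
    variant = vapply(conditions, function(s) s$variant, integer(1)),
    stringsAsFactors = FALSE
  )
  trials <- with_seed(derive_seed(seed, 1L), {
    conds <- sample(unique(info$condition))
    blocks <- list()
    for (cond in conds) {
      idx <- which(info$condition == cond)
      for (i in sample(idx)) {
        pos <- expand.grid(az_bin = seq_len(grid$n_azimuth),
                           el_bin = seq_len(grid$n_elevation))
        pos <- pos[rep(seq_len(nrow(pos)), grid$repeats_per_position), ]
        pos <- pos[sample(nrow(pos)), ]
        pos$condition <- info$condition[i]
        pos$variant <- info$variant[i]
        blocks[[length(blocks) + 1L]] <- pos
      }
    }
    do.call(rbind, blocks)
  })
  rownames(trials) <- NULL
  trials$trial <- seq_len(nrow(trials))
  trials$onset_s <- (trials$trial - 1) * grid$dwell_ms / 1000
  trials <- trials[, c("trial", "condition", "variant", "az_bin", "el_bin",
                       "onset_s")]
  structure(list(trials = trials, grid = grid, conditions = conditions,
                 seed = as.integer(seed)),
            class = "fg_session")
}

#' @export
print.fg_session <- function(x, ...) {
  cat(sprintf("<fg_session> %d trials: %d x %d grid, %d condition-variants, %d repeats, seed %d\n",
              nrow(x$trials), x$grid$n_azimuth, x$grid$n_elevation,
              length(x$conditions), x$grid$repeats_per_position, x$seed))
  invisible(x)
}

#' Unique stimuli of a session
#'
#' One row per distinct (condition, variant, azimuth bin, elevation bin),
#' with a `stim_id` assigned to each and to every trial.
#'
#' @param session an [build_figure_map_session()] result.
#' @return list with `stimuli` (data.frame of unique stimuli) and
#'   `trial_stim` (stim_id per trial).
#' @export
unique_stimuli <- function(session) {
  tr <- session$trials
  key <- paste(tr$condition, tr$variant, tr$az_bin, tr$el_bin, sep = "|")
  ustim <- !duplicated(key)
  stimuli <- tr[ustim, c("condition", "variant", "az_bin", "el_bin")]
  stimuli <- stimuli[order(stimuli$condition, stimuli$variant,
                           stimuli$az_bin, stimuli$el_bin), ]
  rownames(stimuli) <- NULL
  stimuli$stim_id <- seq_len(nrow(stimuli))
  ukey <- paste(stimuli$condition, stimuli$variant, stimuli$az_bin,
                stimuli$el_bin, sep = "|")
  list(stimuli = stimuli, trial_stim = match(key, ukey))
}

# Default canvas for a session: grid span + figure size + motion margin.
session_canvas_deg <- function(session, pad_deg = 6) {
  g <- session$grid
  fs <- max(vapply(session$conditions, function(s) s$figure_size_deg, numeric(1)))
  amp <- max(vapply(session$conditions, function(s) s$motion$amplitude_deg,
                    numeric(1)))
  c(g$azimuth_span_deg + fs + 2 * (amp + pad_deg),
    g$elevation_span_deg + fs + 2 * pad_deg)
}

#' Render a single session stimulus
#'
#' @param session an `fg_session`.
#' @param condition,variant,az_bin,el_bin stimulus coordinates.
#' @param px_per_deg,duration_s,frame_rate_hz,canvas_deg rendering options;
#'   the default canvas covers the grid plus the figure and motion extent.
#' @return a `stimulus_movie`.
#' @export
render_stimulus <- function(session, condition, variant, az_bin, el_bin,
                            px_per_deg = 1, duration_s = 0.25,
                            frame_rate_hz = 56, canvas_deg = NULL) {
  if (is.null(canvas_deg)) canvas_deg <- session_canvas_deg(session)
  nm <- paste0(condition, variant)
  spec <- session$conditions[[nm]]
  if (is.null(spec)) stop("unknown condition-variant: ", nm)
  spec$figure_center_deg <- c(grid_azimuth_deg(session$grid, az_bin),
                              grid_elevation_deg(session$grid, el_bin))
  render_trial_movie(spec, canvas_deg = canvas_deg, px_per_deg = px_per_deg,
                     duration_s = duration_s, frame_rate_hz = frame_rate_hz)
}

#' Export a movie as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame (luminance quantized to 8 bits only here, at
#' export); the sidecar records the stimulus spec and per-frame
#' displacements.
#'
#' @param movie a `stimulus_movie`.
#' @param path output TIFF path (`.json` sidecar written alongside).
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  nt <- dim(movie$frames)[3]
  pages <- lapply(seq_len(nt), function(k) movie$frames[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  meta <- list(spec = movie$spec[setdiff(names(movie$spec), "motion")],
               motion = unclass(movie$spec$motion),
               frame_rate_hz = movie$frame_rate_hz,
               fig_disp_deg = movie$fig_disp_deg,
               bg_disp_deg = movie$bg_disp_deg)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a trial table as CSV
#'
#' @param session an `fg_session`.
#' @param path output CSV path.
#' @export
write_trial_table <- function(session, path) {
  utils::write.csv(session$trials, path, row.names = FALSE)
  invisible(path)
}
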