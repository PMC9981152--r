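#' Texture specification
#'
#' Carrier patterns for figure-ground stimuli: sinusoidal gratings (the Cross
#' and Iso conditions use 0.06 cpd gratings at 45 or 135 degrees) and
#' naturalistic noise with a 1/f amplitude spectrum (the Nat condition).
#'
#' @param kind `"grating"` or `"pink_noise"`.
#' @param orientation_deg grating orientation, direction of spatial
#'   modulation, in `[0, 180)` degrees.
#' @param spatial_freq_cpd grating spatial frequency in cycles/degree.
#' @param phase grating phase in radians.
#' @param seed random seed for noise textures (determinism contract: the
#'   same seed always reproduces the same texture).
#' @param size_px `(rows, cols)` size of the rendered texture.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(kind = c("grating", "pink_noise"),
                         orientation_deg = 45, spatial_freq_cpd = 0.06,
                         phase = 0, seed = 1L, size_px = c(64L, 64L)) {
  kind <- match.arg(kind)
  if (kind == "grating") {
    stop_if_not_positive(spatial_freq_cpd, "spatial_freq_cpd")
    orientation_deg <- orientation_deg %% 180
  }
  if (length(size_px) != 2 || any(size_px <= 0)) {
    stop("`size_px` must be two positive integers (rows, cols)")
  }
  structure(
    list(kind = kind, orientation_deg = orientation_deg,
         spatial_freq_cpd = spatial_freq_cpd, phase = phase,
         seed = as.integer(seed), size_px = as.integer(size_px)),
    class = "texture_spec"
  )
}

#' Render a texture to a luminance image
#'
#' Luminance convention: values in `[0, 1]` with mean ~0.5; 8-bit
#' quantization happens only at file export, so contrast arithmetic stays
#' exact. The pink-noise path filters Gaussian white noise with a radial 1/f
#' amplitude envelope (DC removed), giving a log-log radial amplitude slope
#' of -1 up to Nyquist.
#'
#' @param spec a [texture_spec()].
#' @param px_per_deg rendering resolution (pixels per degree of visual
#'   angle); converts `spatial_freq_cpd` into cycles/pixel.
#' @param contrast_sd for pink noise, the luminance SD the z-scored texture
#'   is mapped to around 0.5 before clamping.
#' @return a numeric matrix in `[0, 1]`.
#' @export
make_texture <- function(spec, px_per_deg = 1, contrast_sd = 0.15) {
  stopifnot(inherits(spec, "texture_spec"))
  stop_if_not_positive(px_per_deg, "px_per_deg")
  nr <- spec$size_px[1]
  nc <- spec$size_px[2]
  if (spec$kind == "grating") {
    f_px <- spec$spatial_freq_cpd / px_per_deg   # cycles per pixel
    o <- deg2rad(spec$orientation_deg)
    x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
    y <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
    u <- x * cos(o) + y * sin(o)
    0.5 + 0.5 * cos(2 * pi * f_px * u + spec$phase)
  } else {
    z <- with_seed(spec$seed, pink_noise_field(nr, nc))
    clamp01(0.5 + contrast_sd * z)
  }
}

# Zero-mean, unit-SD random field with amplitude spectrum proportional to
# 1/f (radial). White Gaussian noise is shaped in the Fourier domain, which
# also makes the field periodic in both dimensions (used by the renderer for
# seam-free translation).
pink_noise_field <- function(nr, nc) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  fy <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1)) / nc
  f <- sqrt(outer(fy^2, fx^2, "+"))
  env <- 1 / f
  env[1, 1] <- 0   # remove DC
  shaped <- Re(stats::fft(stats::fft(white) * env, inverse = TRUE)) / (nr * nc)
  (shaped - mean(shaped)) / stats::sd(shaped)
}

#' Radially averaged amplitude spectrum and its log-log slope
#'
#' Diagnostic for the 1/f property of naturalistic textures: the slope of
#' log radial amplitude against log spatial frequency should be close to -1.
#'
#' @param img a numeric matrix (luminance image).
#' @param n_bins number of radial frequency bins.
#' @return list with `freq`, `amplitude`, and the fitted `slope`.
#' @export
radial_spectrum_slope <- function(img, n_bins = 20) {
  nr <- nrow(img)
  nc <- ncol(img)
  amp <- Mod(stats::fft(img - mean(img)))
  fy <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1)) / nc
  f <- sqrt(outer(fy^2, fx^2, "+"))
  keep <- f > 0 & f <= 0.5
  bins <- cut(log10(f[keep]), breaks = n_bins)
  fr <- tapply(f[keep], bins, mean)
  am <- tapply(amp[keep], bins, mean)
  ok <- is.finite(fr) & is.finite(am) & am > 0
  fit <- stats::lm(log10(am[ok]) ~ log10(fr[ok]))
  list(freq = unname(fr[ok]), amplitude = unname(am[ok]),
       slope = unname(stats::coef(fit)[2]))
}
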