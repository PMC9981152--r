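#' Screen geometry for degree/pixel conversions
#'
#' Describes a physical display and viewing distance. Two canonical
#' geometries are used throughout: the head-fixed recording monitor (a
#' 32-inch panel, 71 x 40 cm, viewed at 18 cm) and the freely-moving
#' touchscreen (24 x 18.5 cm, 800 x 600 px). Pixel pitch is assumed constant
#' across the screen.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_cm,height_cm physical screen size in cm.
#' @param view_distance_cm eye-to-screen distance in cm.
#' @return An object of class `screen_geometry`.
#' @examples
#' touchscreen_geometry()
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            view_distance_cm) {
  for (nm in c("width_px", "height_px", "width_cm", "height_cm",
               "view_distance_cm")) {
    stop_if_not_positive(get(nm), nm)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_cm = width_cm, height_cm = height_cm,
         view_distance_cm = view_distance_cm),
    class = "screen_geometry"
  )
}

#' @rdname screen_geometry
#' @export
recording_geometry <- function(view_distance_cm = 18) {
  screen_geometry(1920, 1080, 71, 40, view_distance_cm)
}

#' @rdname screen_geometry
#' @export
touchscreen_geometry <- function(view_distance_cm = 10) {
  screen_geometry(800, 600, 24, 18.5, view_distance_cm)
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm,
              x$view_distance_cm))
  cat(sprintf("  pixel pitch %.4f cm, ~%.4f deg/px at center\n",
              pixel_pitch_cm(x), deg_per_px(x)))
  invisible(x)
}

#' @rdname screen_geometry
#' @export
pixel_pitch_cm <- function(geometry) geometry$width_cm / geometry$width_px

#' Visual degrees per pixel
#'
#' Small-angle (linear) conversion at the screen center by default, with an
#' exact tangent-corrected variant for wide-field geometry.
#'
#' @param geometry a [screen_geometry()].
#' @param exact use `2*atan(pitch/2/d)` instead of the small-angle linear map.
#' @export
deg_per_px <- function(geometry, exact = FALSE) {
  p <- pixel_pitch_cm(geometry)
  d <- geometry$view_distance_cm
  if (exact) rad2deg(2 * atan(p / 2 / d)) else rad2deg(p / d)
}

#' Visual angle subtended by an on-screen object
#'
#' Converts an object width given in *movie* pixels into degrees of visual
#' angle, mapping the movie onto the full physical screen width and applying
#' the exact arctangent formula (appropriate for a freely moving observer
#' that can be very close to the screen). A 50 px figure in a 200 px wide
#' movie on a 24 cm screen subtends ~15 deg at 23 cm and ~143 deg at 1 cm.
#'
#' @param geometry a [screen_geometry()].
#' @param object_width_px object width in movie pixels.
#' @param movie_width_px width of the movie that is stretched across the
#'   screen (default 200 px, the behavioral movie width).
#' @param distance_cm viewing distance; defaults to the geometry's.
#' @return visual angle in degrees.
#' @export
angular_geometry <- function(geometry, object_width_px, movie_width_px = 200,
                             distance_cm = geometry$view_distance_cm) {
  if (object_width_px < 0) stop("`object_width_px` must be >= 0")
  stop_if_not_positive(movie_width_px, "movie_width_px")
  stop_if_not_positive(distance_cm, "distance_cm")
  physical_cm <- geometry$width_cm * object_width_px / movie_width_px
  rad2deg(2 * atan(physical_cm / 2 / distance_cm))
}

#' Cycles/cm to cycles/degree
#'
#' Spatial frequency of an on-screen grating in cycles per degree of visual
#' angle, using the small-angle cm-per-degree at the given distance.
#'
#' @param cycles_per_cm grating frequency on the screen surface.
#' @inheritParams angular_geometry
#' @export
cpcm_to_cpd <- function(geometry, cycles_per_cm,
                        distance_cm = geometry$view_distance_cm) {
  cm_per_deg <- distance_cm * deg2rad(1)
  cycles_per_cm * cm_per_deg
}

#' Grid of figure positions for figure-map sessions
#'
#' The canonical session flashes the figure at 16 azimuth x 8 elevation
#' positions (128 total) spanning 45 x 23 degrees (~3 deg per step), 10
#' repeats per position, 250 ms dwell.
#'
#' @param n_azimuth,n_elevation number of horizontal/vertical positions.
#' @param azimuth_span_deg,elevation_span_deg span between outermost centers.
#' @param repeats_per_position repeats of each position per condition-variant.
#' @param dwell_ms presentation time per position.
#' @return An object of class `position_grid` with bin-center accessors.
#' @export
position_grid <- function(n_azimuth = 16, n_elevation = 8,
                          azimuth_span_deg = 45, elevation_span_deg = 23,
                          repeats_per_position = 10, dwell_ms = 250) {
  for (nm in c("n_azimuth", "n_elevation", "azimuth_span_deg",
               "elevation_span_deg", "repeats_per_position", "dwell_ms")) {
    stop_if_not_positive(get(nm), nm)
  }
  structure(
    list(n_azimuth = as.integer(n_azimuth),
         n_elevation = as.integer(n_elevation),
         azimuth_span_deg = azimuth_span_deg,
         elevation_span_deg = elevation_span_deg,
         repeats_per_position = as.integer(repeats_per_position),
         dwell_ms = dwell_ms),
    class = "position_grid"
  )
}

#' @rdname position_grid
#' @param grid a `position_grid`.
#' @param az_bin,el_bin 1-based bin indices.
#' @export
grid_azimuth_deg <- function(grid, az_bin) {
  centers <- seq(-grid$azimuth_span_deg / 2, grid$azimuth_span_deg / 2,
                 length.out = grid$n_azimuth)
  centers[az_bin]
}

#' @rdname position_grid
#' @export
grid_elevation_deg <- function(grid, el_bin) {
  centers <- seq(-grid$elevation_span_deg / 2, grid$elevation_span_deg / 2,
                 length.out = grid$n_elevation)
  centers[el_bin]
}

#' @export
print.position_grid <- function(x, ...) {
  cat(sprintf(
    "<position_grid> %d x %d positions (%d total), %g x %g deg span, %d repeats, %g ms dwell\n",
    x$n_azimuth, x$n_elevation, x$n_azimuth * x$n_elevation,
    x$azimuth_span_deg, x$elevation_span_deg, x$repeats_per_position,
    x$dwell_ms))
  invisible(x)
}
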