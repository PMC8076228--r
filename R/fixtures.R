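#' Specification of a synthetic sinusoidal suture image
#'
#' The fixture generator draws a dark band of constant along-x width `w`
#' whose centerline is a sinusoid of amplitude `A` and wavelength `lambda`
#' (phase-centred on the image mid-row), on a bright bone background, with
#' optional seeded Gaussian noise.  Width,
#' amplitude and arc length have closed forms, so every morphometric
#' operation can be tested against exact ground truth without specimen
#' photographs.
#'
#' @param ny,nx Image size in pixels (rows = along the suture).
#' @param center Band center column (pixels).
#' @param width Band width `w` in pixels (>= 1).
#' @param amplitude Sinusoid amplitude `A` in pixels (>= 0).
#' @param wavelength Sinusoid wavelength `lambda` in pixels (> 0).
#' @param level_suture,level_bone Intensity levels (distinct; suture darker
#'   by default).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param pixel_size Physical calibration (e.g. mm/px).
#' @param seed RNG seed for the noise realization.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(ny = 200, nx = 128, center = nx / 2,
                         width = 5, amplitude = 0, wavelength = 64,
                         level_suture = 20, level_bone = 200,
                         noise_sd = 0, pixel_size = 0.05, seed = 1L) {
  fs <- list(ny = as.integer(ny), nx = as.integer(nx), center = center,
             width = width, amplitude = amplitude, wavelength = wavelength,
             level_suture = level_suture, level_bone = level_bone,
             noise_sd = noise_sd, pixel_size = pixel_size, seed = as.integer(seed))
  if (fs$width < 1) stop("width must be >= 1 pixel")
  if (fs$amplitude < 0) stop("amplitude must be >= 0")
  if (fs$wavelength <= 0) stop("wavelength must be > 0")
  if (fs$level_suture == fs$level_bone) stop("intensity levels must be distinct")
  if (fs$center - fs$amplitude - fs$width / 2 < 1 ||
      fs$center + fs$amplitude + fs$width / 2 > fs$nx)
    stop("band exits the image for the given center, amplitude and width")
  class(fs) <- "fixture_spec"
  fs
}

#' Generate a sinusoidal suture image with ground truth
#'
#' @param spec A [fixture_spec()].
#' @return List with `image` (a [specimen_image()], suture along rows) and
#'   `truth`: the exact mask, the programmed width/amplitude/wavelength
#'   (pixels), the centerline per row, and the arc length of the centerline
#'   over the image (pixels) computed by numerical quadrature of
#'   `sqrt(1 + x'(y)^2)`.
#' @export
make_sinusoidal_suture <- function(spec) {
  fs <- spec
  y <- seq_len(fs$ny)
  # phase-centred sinusoid (even about the image mid-row): a straight
  # least-squares reference line through the midpoints is then untilted,
  # so the amplitude ground truth is exact.  With the generic sin(2*pi*y/l)
  # phase the LS line of a few-period window tilts by ~ 2*A*l/ny per row
  # and inflates the measured amplitude at the window ends.
  cx <- fs$center + fs$amplitude *
    cos(2 * pi * (y - (fs$ny + 1) / 2) / fs$wavelength)
  xs <- seq_len(fs$nx)
  mask <- abs(outer(rep(1, fs$ny), xs) - cx) <= fs$width / 2
  img <- matrix(fs$level_bone, fs$ny, fs$nx)
  img[mask] <- fs$level_suture
  if (fs$noise_sd > 0) {
    img <- img + with_preserved_rng({
      set.seed(fs$seed)
      matrix(rnorm(fs$ny * fs$nx, 0, fs$noise_sd), fs$ny, fs$nx)
    })
  }
  dxdy <- function(t) -2 * pi * fs$amplitude / fs$wavelength *
    sin(2 * pi * (t - (fs$ny + 1) / 2) / fs$wavelength)
  arc <- integrate(function(t) sqrt(1 + dxdy(t)^2), 1, fs$ny,
                   subdivisions = 2000L, rel.tol = 1e-8)$value + 1
  list(image = specimen_image(img, fs$pixel_size, "y",
                              label = "synthetic sinusoidal suture"),
       truth = list(mask = mask, width_px = fs$width,
                    amplitude_px = fs$amplitude,
                    wavelength_px = fs$wavelength,
                    centerline_px = cx, arc_length_px = arc))
}
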