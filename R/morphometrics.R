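#' Calibrated grayscale specimen image
#'
#' Container for a 2-D grayscale image with its physical calibration.
#' `suture_axis` names the image axis the suture runs along: `"y"` (rows;
#' each row is then a transect across the suture — the package's canonical
#' orientation) or `"x"` (columns; measurements transpose internally).
#'
#' @param pixels Numeric matrix of intensities (finite).
#' @param pixel_size Physical length per pixel (e.g. mm/px), > 0.
#' @param suture_axis `"y"` or `"x"`.
#' @param label Free-text provenance.
#' @return An object of class `specimen_image`.
#' @export
specimen_image <- function(pixels, pixel_size, suture_axis = c("y", "x"),
                           label = "") {
  suture_axis <- match.arg(suture_axis)
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("pixels must be a numeric matrix")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 suture_axis = suture_axis, label = label),
            class = "specimen_image")
}

#' @export
print.specimen_image <- function(x, ...) {
  cat(sprintf("specimen_image: %d x %d px, %.4g per px, suture axis %s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$suture_axis,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

# orient a matrix so the suture runs along rows (each row = one transect)
canonical_mask <- function(m, suture_axis = "y") {
  if (identical(suture_axis, "x")) t(m) else m
}

#' Binarize a specimen image into a suture mask
#'
#' Default method is Otsu's threshold with the suture as the darker phase
#' (soft tissue photographs darker than bone); a manual threshold can be
#' supplied instead.  Optionally keeps only the largest 8-connected suture
#' component.
#'
#' @param img A [specimen_image()] or bare numeric matrix.
#' @param method `"otsu"` or `"manual"`.
#' @param threshold Manual threshold (suture-side inclusive), required for
#'   `method = "manual"`.
#' @param darker_is_suture If `FALSE`, the brighter phase is the suture.
#' @param largest_component Keep only the largest connected suture component.
#' @return Logical matrix, `TRUE` = suture, same orientation as the input.
#' @export
binarize <- function(img, method = c("otsu", "manual"), threshold = NULL,
                     darker_is_suture = TRUE, largest_component = FALSE) {
  method <- match.arg(method)
  px <- if (inherits(img, "specimen_image")) img$pixels else img
  if (method == "otsu") {
    if (max(px) == min(px))
      stop("constant image: Otsu threshold undefined, supply method='manual' with a threshold")
    threshold <- otsu_threshold(px)
  } else if (is.null(threshold)) stop("method='manual' requires a threshold")
  mask <- if (darker_is_suture) px <= threshold else px > threshold
  if (largest_component && any(mask)) {
    lab <- label_components(mask)
    keep <- which.max(tabulate(lab[lab > 0]))
    mask <- lab == keep
  }
  mask
}

# Otsu's method on a 256-bin histogram of the intensity range
otsu_threshold <- function(px) {
  rng <- range(px)
  brk <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(px, brk, all.inside = TRUE), 256)
  w <- cumsum(h); m <- cumsum(h * seq_len(256))
  wb <- w[-256]; wf <- w[256] - wb
  ok <- wb > 0 & wf > 0
  mb <- m[-256] / wb; mf <- (m[256] - m[-256]) / wf
  between <- wb * wf * (mb - mf)^2
  between[!ok] <- -Inf
  k <- which.max(between)
  (brk[k] + brk[k + 1]) / 2
}

# 8-connected component labelling by flood fill
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (q in cur) {
        i <- (q - 1L) %% ny + 1L
        j <- (q - 1L) %/% ny + 1L
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
          w <- (jj - 1L) * ny + ii
          if (mask[w] && lab[w] == 0L) { lab[w] <- nextlab; queue <- c(queue, w) }
        }
      }
    }
  }
  lab
}

#' Intensity profile across the suture
#'
#' Mean intensity per across-suture position, averaged along the suture
#' within a band of transects: the profile-plot used to visualise suture
#' width from brightness.  Output length equals the across-suture dimension.
#'
#' @param img A [specimen_image()].
#' @param band Integer range of transects (canonical rows) to average over;
#'   default all.
#' @return An object of class `suture_profile`: list with `position`
#'   (physical units), `intensity`, and `pixel_size`.
#' @export
profile_plot <- function(img, band = NULL) {
  px <- canonical_mask(img$pixels, img$suture_axis)
  if (is.null(band)) band <- seq_len(nrow(px))
  if (!length(band) || any(band < 1 | band > nrow(px)))
    stop("empty or out-of-range transect band")
  prof <- colMeans(px[band, , drop = FALSE])
  structure(list(position = (seq_along(prof) - 0.5) * img$pixel_size,
                 intensity = prof, pixel_size = img$pixel_size),
            class = "suture_profile")
}

#' @export
plot.suture_profile <- function(x, ...) {
  graphics::plot(x$position, x$intensity, type = "l",
                 xlab = "position across suture", ylab = "mean intensity", ...)
  invisible(x)
}

#' Transect widths of a suture mask
#'
#' For each transect (canonical row) the width is the count of suture
#' pixels times `pixel_size`; transects without suture pixels are excluded.
#' This is the pixel-counting analogue of measuring the suture gap on a
#' calibrated photograph.
#'
#' @param mask Logical suture mask (canonical orientation, or supply
#'   `suture_axis`).
#' @param pixel_size Physical length per pixel.
#' @param suture_axis Axis the suture runs along (`"y"` rows / `"x"` cols).
#' @return List with `width_per_transect`, `width_mean`, `width_max`,
#'   `n_transects`.
#' @export
suture_width <- function(mask, pixel_size = 1, suture_axis = "y") {
  m <- canonical_mask(mask, suture_axis)
  if (!any(m)) stop("empty suture mask")
  w <- rowSums(m)
  w <- w[w > 0] * pixel_size
  list(width_per_transect = w, width_mean = mean(w), width_max = max(w),
       n_transects = length(w))
}

#' Suture centerline through transect midpoints
#'
#' Midpoint of the leftmost and rightmost suture pixel per transect, plus
#' the least-squares straight line through the midpoints.  The fitted line
#' is the reference axis from which interdigitation amplitude is measured.
#'
#' @inheritParams suture_width
#' @return List with `transect` (row indices with suture pixels),
#'   `midpoint` (pixel column units), `fit` (intercept, slope of the LS
#'   line), `residual_max` (max |midpoint deviation| in pixels).
#' @export
centerline <- function(mask, suture_axis = "y") {
  m <- canonical_mask(mask, suture_axis)
  if (!any(m)) stop("empty suture mask")
  rows <- which(rowSums(m) > 0)
  mid <- vapply(rows, function(i) {
    j <- which(m[i, ]); (min(j) + max(j)) / 2
  }, numeric(1))
  X <- cbind(1, rows)
  fit <- lm.fit(X, mid)
  list(transect = rows, midpoint = mid,
       fit = c(intercept = unname(fit$coefficients[1]),
               slope = unname(fit$coefficients[2])),
       residual_max = max(abs(fit$residuals)))
}

#' Maximum interdigitation amplitude
#'
#' Maximum perpendicular distance from any suture pixel (default) or any
#' skeleton pixel (`from = "skeleton"`) to the straight least-squares
#' centerline, times `pixel_size`.  For a straight band the farthest suture
#' pixel is the band edge, so the amplitude of an unwavy suture is half its
#' width.
#'
#' @inheritParams suture_width
#' @param from `"boundary"` (all suture pixels) or `"skeleton"`.
#' @return Amplitude (physical units).
#' @export
max_amplitude <- function(mask, pixel_size = 1, suture_axis = "y",
                          from = c("boundary", "skeleton")) {
  from <- match.arg(from)
  m <- canonical_mask(mask, suture_axis)
  if (!any(m)) stop("empty suture mask")
  cl <- centerline(m)
  pts <- if (from == "skeleton") which(skeletonize_mask(m), arr.ind = TRUE)
         else which(m, arr.ind = TRUE)
  # distance from (row, col) to line col = a + b*row
  a <- cl$fit["intercept"]; b <- cl$fit["slope"]
  d <- abs(pts[, 2] - (a + b * pts[, 1])) / sqrt(1 + b^2)
  max(d) * pixel_size
}

#' Interdigitation amplitude of the centerline
#'
#' Maximum deviation of the transect midpoints from their least-squares
#' straight fit, times `pixel_size`.  Unlike [max_amplitude()] this excludes
#' the half-width offset, so a straight band of any width has centerline
#' amplitude ~0; used to isolate waviness from width in parameter sweeps.
#'
#' @inheritParams suture_width
#' @return Amplitude (physical units).
#' @export
centerline_amplitude <- function(mask, pixel_size = 1, suture_axis = "y") {
  m <- canonical_mask(mask, suture_axis)
  cl <- centerline(m)
  cl$residual_max * pixel_size
}

# sub-pixel centerline amplitude from a phase field: interface midpoints by
# interpolation, deviation from their straight LS fit
field_centerline_amplitude <- function(u, dx) {
  cv <- extract_interface(u, dx)
  mid <- (cv$left + cv$right)[cv$valid] / 2
  if (length(mid) < 3) return(NA_real_)
  rows <- which(cv$valid)
  fit <- lm.fit(cbind(1, rows), mid)
  max(abs(fit$residuals))
}

#' Skeletonized suture length
#'
#' Thins the mask to a 1-pixel-wide 8-connected skeleton (Zhang-Suen) and
#' measures it two ways: `skeleton_pixel_count`, the raw pixel count (the
#' classical ImageJ-style length proxy), and `skeleton_length`, the
#' geometric arc length of the skeleton (per-transect mean skeleton
#' positions joined as a polyline, plus one pixel of endpoint support)
#' times `pixel_size`.  The pixel count underestimates the length of steep
#' diagonal segments by up to ~30%, which is why the geometric estimate is
#' reported as the length.
#'
#' @inheritParams suture_width
#' @return List with `skeleton_pixel_count`, `skeleton_length`, and the
#'   logical `skeleton` matrix (canonical orientation).
#' @export
skeleton_length <- function(mask, pixel_size = 1, suture_axis = "y") {
  m <- canonical_mask(mask, suture_axis)
  if (!any(m)) stop("empty suture mask")
  sk <- skeletonize_mask(m)
  rows <- which(rowSums(sk) > 0)
  xbar <- vapply(rows, function(i) mean(which(sk[i, ])), numeric(1))
  plen <- if (length(rows) > 1)
    sum(sqrt(diff(rows)^2 + diff(xbar)^2)) + 1 else length(rows)
  list(skeleton_pixel_count = sum(sk),
       skeleton_length = plen * pixel_size,
       skeleton = sk)
}

#' Full morphometric measurement of a suture mask
#'
#' Combines [suture_width()], [max_amplitude()], [centerline_amplitude()]
#' and [skeleton_length()] into one record.
#'
#' @inheritParams suture_width
#' @return An object of class `suture_measurement`.
#' @export
measure_suture <- function(mask, pixel_size = 1, suture_axis = "y") {
  m <- canonical_mask(mask, suture_axis)
  w <- suture_width(m, pixel_size)
  sk <- skeleton_length(m, pixel_size)
  out <- list(width_per_transect = w$width_per_transect,
              width_mean = w$width_mean, width_max = w$width_max,
              max_amplitude = max_amplitude(m, pixel_size),
              centerline_amplitude = centerline_amplitude(m, pixel_size),
              skeleton_pixel_count = sk$skeleton_pixel_count,
              skeleton_length = sk$skeleton_length,
              n_transects = w$n_transects, pixel_size = pixel_size)
  class(out) <- "suture_measurement"
  out
}

#' @export
print.suture_measurement <- function(x, ...) {
  cat("suture_measurement:\n")
  cat(sprintf("  width mean/max: %.3g / %.3g over %d transects\n",
              x$width_mean, x$width_max, x$n_transects))
  cat(sprintf("  max amplitude: %.3g (centerline %.3g)\n",
              x$max_amplitude, x$centerline_amplitude))
  cat(sprintf("  skeleton: %d px, length %.3g\n",
              x$skeleton_pixel_count, x$skeleton_length))
  invisible(x)
}

#' Measure a simulated phase field
#'
#' Thresholds `u < 0.5` into a suture mask and applies [measure_suture()]
#' with `pixel_size = dx`, so simulated and photographed sutures share one
#' measurement path.
#'
#' @param u Phase-field matrix.
#' @param dx Lattice spacing (the pixel size of the simulation).
#' @return A `suture_measurement`.
#' @export
measure_field <- function(u, dx) measure_suture(u < 0.5, pixel_size = dx)
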