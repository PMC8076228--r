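#' Differentiation forcing of the osteogenic front
#'
#' The normal speed contributed by the osteopromoting factor:
#' `f(v) = alpha * (v - v_c)`.  Positive values advance the bone front into
#' mesenchyme (the suture narrows); at `v = v_c` osteogenesis and resorption
#' balance and the contribution vanishes.  The linear form is the minimal
#' law with a single efficacy parameter `alpha`; it is kept in one place so
#' an alternative (e.g. saturating) response can be swapped in.
#'
#' @param v_value Factor concentration (scalar, vector or matrix, >= 0).
#' @param params A [suture_params()].
#' @return Signed front speed(s), same shape as `v_value`.
#' @export
forcing <- function(v_value, params) {
  if (!all(is.finite(v_value))) stop("forcing: non-finite concentration input")
  params$alpha * (v_value - params$v_c)
}

#' Interface curvature of a phase field
#'
#' Curvature `kappa = -div(grad u / |grad u|)` by centered second
#' differences (the direct formula in terms of `u_xx`, `u_yy`, `u_xy`),
#' with reflecting ghosts in `x` and periodic ghosts in `y`.  The sign
#' convention is positive where the bone region (`u ~ 1`) is locally convex,
#' so a `-sigma * kappa` velocity retards bone protrusions.
#'
#' Curvature is only meaningful on the interface band where the gradient is
#' order `1/eps`; outside it (bulk plateaus, the mid-suture gradient flip)
#' the normalised gradient is noise, so `kappa` is set to zero wherever
#' `|grad u| * eps < band_tol`.  A gradient floor prevents 0/0 inside the
#' band.
#'
#' @param u Phase-field matrix (at least 3 sites per axis).
#' @param dx Lattice spacing.
#' @param eps Interface width used for the band mask (length units;
#'   defaults to `4 * dx`, i.e. band masking relative to a `2*dx`-wide
#'   interface profile).
#' @param band_tol Threshold on `|grad u| * eps` below which curvature is
#'   zeroed (the tanh profile has `|grad u| * eps = 0.5` at the interface).
#' @return Matrix of curvatures (1/length), finite everywhere.
#' @export
curvature <- function(u, dx, eps = 4 * dx, band_tol = 0.02) {
  if (nrow(u) < 3 || ncol(u) < 3) stop("curvature needs at least 3 sites per axis")
  ny <- nrow(u); nx <- ncol(u)
  up <- u[c(ny, seq_len(ny - 1)), , drop = FALSE]
  dn <- u[c(seq_len(ny)[-1], 1), , drop = FALSE]
  lf <- u[, c(1, seq_len(nx - 1)), drop = FALSE]
  rt <- u[, c(seq_len(nx)[-1], nx), drop = FALSE]
  ux <- (rt - lf) / (2 * dx)
  uy <- (dn - up) / (2 * dx)
  uxx <- (rt - 2 * u + lf) / dx^2
  uyy <- (dn - 2 * u + up) / dx^2
  ul <- up[, c(1, seq_len(nx - 1)), drop = FALSE]
  ur <- up[, c(seq_len(nx)[-1], nx), drop = FALSE]
  dl <- dn[, c(1, seq_len(nx - 1)), drop = FALSE]
  dr <- dn[, c(seq_len(nx)[-1], nx), drop = FALSE]
  uxy <- (dr - dl - ur + ul) / (4 * dx^2)
  g2 <- ux^2 + uy^2
  k <- -(uxx * uy^2 - 2 * uxy * ux * uy + uyy * ux^2) /
    pmax(g2^1.5, (1e-8 / dx)^3)
  k[sqrt(g2) * eps < band_tol] <- 0
  k
}

#' Locate the bone-mesenchyme interfaces on each transect
#'
#' For each lattice row (a transect across the suture) the crossings of the
#' `u = 0.5` level are found by linear interpolation between adjacent sites.
#' `left` and `right` are the outermost crossings; rows without a crossing
#' are flagged invalid rather than raising an error, so a uniform field
#' returns an all-invalid curve.
#'
#' @param u Phase-field matrix with values in `[0, 1]`.
#' @param dx Lattice spacing.
#' @return An object of class `interface_curve`: list with `left`, `right`
#'   (length-`ny` positions in length units, `NA` on invalid rows), `valid`
#'   (logical), `n_crossings` (integer per row), and `dx`.
#' @export
extract_interface <- function(u, dx) {
  if (min(u) < -1e-9 || max(u) > 1 + 1e-9) stop("u must lie in [0, 1]")
  ny <- nrow(u); nx <- ncol(u)
  xc <- lattice_x(nx, dx)
  left <- right <- rep(NA_real_, ny)
  ncr <- integer(ny)
  s <- u - 0.5
  for (i in seq_len(ny)) {
    r <- s[i, ]
    idx <- which(r[-nx] * r[-1] < 0 | (r[-nx] == 0 & r[-1] != 0))
    if (!length(idx)) {
      # exact-zero plateau or no crossing at all
      z <- which(r == 0)
      if (length(z)) { left[i] <- right[i] <- xc[z[1]]; ncr[i] <- 1L }
      next
    }
    cross <- xc[idx] + dx * (0 - r[idx]) / (r[idx + 1] - r[idx])
    left[i] <- min(cross); right[i] <- max(cross)
    ncr[i] <- length(cross)
  }
  out <- list(left = left, right = right, valid = !is.na(left),
              n_crossings = ncr, dx = dx)
  class(out) <- "interface_curve"
  out
}

#' @export
print.interface_curve <- function(x, ...) {
  cat(sprintf("interface_curve: %d rows, %d valid; mean span %.2f\n",
              length(x$left), sum(x$valid),
              mean(x$right[x$valid] - x$left[x$valid])))
  invisible(x)
}

#' Interpolated suture span per transect
#'
#' `right - left` of an [extract_interface()] curve: the outer envelope
#' width of the mesenchyme band per row (sub-pixel).  For interdigitated
#' sutures this is the envelope, not the soft-tissue pixel count; see
#' [suture_width()] for the pixel-counting measure.
#'
#' @param curve An `interface_curve`.
#' @return Numeric vector (length units), `NA` on invalid rows.
#' @export
interface_span <- function(curve) curve$right - curve$left
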