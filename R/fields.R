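#' Field state of the suture model
#'
#' A snapshot of the two coupled lattices: `u`, the bone differentiation
#' degree (`u ~ 1` bone, `u ~ 0` mesenchyme, diffuse interface in between),
#' and `v`, the concentration of the osteopromoting factor.  Matrices are
#' oriented with rows indexing `y` (along the suture, periodic) and columns
#' indexing `x` (across the suture, reflecting).
#'
#' @param u Numeric matrix in `[0, 1]`.
#' @param v Numeric matrix, same shape as `u`, non-negative.
#' @param t Simulation time of the snapshot.
#' @param inserted_columns Cumulative count of growth column insertions.
#' @param growth_accum Fractional growth accumulator carried between steps
#'   (internal bookkeeping of [grow_domain()]).
#' @return An object of class `field_state`.
#' @export
field_state <- function(u, v, t = 0, inserted_columns = 0L, growth_accum = 0) {
  s <- list(u = u, v = v, t = t,
            inserted_columns = as.integer(inserted_columns),
            growth_accum = growth_accum)
  class(s) <- "field_state"
  validate_state(s)
  s
}

#' Validate a `field_state`
#'
#' @param s A `field_state`.
#' @return `s` invisibly; errors if the invariants are violated
#'   (`0 <= u <= 1`, `v >= 0`, equal shapes, all values finite).
#' @export
validate_state <- function(s) {
  if (!is.matrix(s$u) || !is.matrix(s$v)) stop("u and v must be matrices")
  if (!identical(dim(s$u), dim(s$v))) stop("u and v must have identical shapes")
  if (!all(is.finite(s$u)) || !all(is.finite(s$v))) stop("fields contain non-finite values")
  if (min(s$u) < 0 || max(s$u) > 1) stop("u must lie in [0, 1]")
  if (min(s$v) < -1e-12) stop("v must be non-negative")
  if (s$inserted_columns < 0) stop("inserted_columns must be >= 0")
  invisible(s)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state: %d x %d at t=%g, inserted_columns=%d\n",
              nrow(x$u), ncol(x$u), x$t, x$inserted_columns))
  cat(sprintf("  u in [%.3f, %.3f], v in [%.4f, %.4f], mesenchyme fraction %.3f\n",
              min(x$u), max(x$u), min(x$v), max(x$v), mean(x$u < 0.5)))
  invisible(x)
}

# x coordinates of pixel centers, column j at (j - 1/2) dx
lattice_x <- function(nx, dx) (seq_len(nx) - 0.5) * dx

tanh_profile <- function(xi) (1 + tanh(xi)) / 2

#' Planar-step phase field
#'
#' Builds a `u` field with a single straight interface following the tanh
#' profile `u(x) = (1 + tanh((x - position)/eps)) / 2` replicated over rows
#' (mesenchyme on the left, bone on the right).  Used by the front-speed and
#' curvature oracles.
#'
#' @param nx,ny Lattice size.
#' @param position Interface position in length units (interior).
#' @param eps Interface width (length units).
#' @param dx Lattice spacing.
#' @return A `u` matrix (`ny` rows, `nx` columns).
#' @export
make_step_field <- function(nx, ny, position, eps, dx = 1) {
  if (position <= 0 || position >= nx * dx) stop("position must be interior to the domain")
  xc <- lattice_x(nx, dx)
  matrix(rep(tanh_profile((xc - position) / eps), each = ny), ny, nx)
}

#' Disc-shaped phase field
#'
#' Radially symmetric tanh profile around `center`: either a bone disc in
#' mesenchyme (`phase = "bone_disc"`) or a mesenchyme hole in bone
#' (`phase = "hole"`).  The complement identity
#' `hole = 1 - bone_disc` holds exactly.
#'
#' @param nx,ny Lattice size.
#' @param center Numeric length-2 vector `(x, y)` in length units.
#' @param radius Disc radius (length units); the disc must fit with a
#'   `5 * eps` margin to all boundaries.
#' @param eps Interface width (length units).
#' @param dx Lattice spacing.
#' @param phase `"bone_disc"` or `"hole"`.
#' @return A `u` matrix.
#' @export
make_disc_field <- function(nx, ny, center, radius, eps, dx = 1,
                            phase = c("bone_disc", "hole")) {
  phase <- match.arg(phase)
  margin <- radius + 5 * eps
  if (center[1] - margin < 0 || center[1] + margin > nx * dx ||
      center[2] - margin < 0 || center[2] + margin > ny * dx)
    stop("disc must fit inside the domain with a 5*eps margin")
  xc <- lattice_x(nx, dx); yc <- lattice_x(ny, dx)
  r <- sqrt(outer((yc - center[2])^2, (xc - center[1])^2, `+`))
  if (phase == "bone_disc") tanh_profile((radius - r) / eps)
  else tanh_profile((r - radius) / eps)
}
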