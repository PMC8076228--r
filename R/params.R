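#' Simulation parameters for the suture interface model
#'
#' Bundles the five effective model parameters (`alpha`, `sigma`, `v_c`,
#' `D_v`, `c`), the factor kinetics (`k_p`, `k_d`), and the numerical
#' configuration of the lattice and the time integration.  All quantities are
#' in dimensionless model units: the lattice spacing is `dx = 50` length
#' units and one time unit is the decay time of the factor (`k_d = 1`).
#'
#' @param alpha Efficacy of the osteopromoting factor: the osteogenic front
#'   advances at speed `alpha * (v - v_c)` (length/time per unit
#'   concentration excess).  Must be positive.
#' @param sigma Surface tension: curvature penalty on the front speed
#'   (length^2/time).  Must be positive.
#' @param v_c Critical factor concentration at which osteogenesis and bone
#'   resorption balance and the front is stationary.  Non-negative.
#' @param D_v Diffusion coefficient of the factor (length^2/time).  With
#'   `k_d = 1` the decay length of the factor is `sqrt(D_v)`.
#' @param c Passive soft-tissue expansion speed (length/time, >= 0); one
#'   lattice column is inserted into the mesenchyme per `dx/c` time units.
#' @param k_p Production rate of the factor in mesenchyme (concentration/time).
#' @param k_d First-order decay rate of the factor (1/time).
#' @param nx,ny Lattice size (sites); `x` runs across the suture (reflecting
#'   boundaries), `y` along it (periodic).
#' @param dx Lattice spacing (length units).
#' @param dt Time step.
#' @param t_end Simulation length in model time units.
#' @param eps Diffuse-interface width of the phase field (length units).
#'   Must be at least `2 * dx` so the interface is resolvable.
#' @param seed Integer RNG seed; fixes the initial interface perturbation and
#'   the growth insertion sites.
#' @param noise_amp Standard deviation of the initial per-row interface
#'   perturbation (length units).
#'
#' @return An object of class `suture_params` (a validated named list).
#' @examples
#' p <- suture_params()
#' p$t_end / p$dt   # number of time steps in the default run
#' @export
suture_params <- function(alpha = 4, sigma = 100, v_c = 0.35, D_v = 9e4,
                          c = 0, k_p = 1, k_d = 1,
                          nx = 128L, ny = 128L, dx = 50, dt = 2,
                          t_end = 6000, eps = 2 * dx,
                          seed = 1L, noise_amp = dx) {
  p <- list(alpha = alpha, sigma = sigma, v_c = v_c, D_v = D_v, c = c,
            k_p = k_p, k_d = k_d, nx = as.integer(nx), ny = as.integer(ny),
            dx = dx, dt = dt, t_end = t_end, eps = eps,
            seed = as.integer(seed), noise_amp = noise_amp)
  class(p) <- "suture_params"
  validate_params(p)
  p
}

#' Validate a `suture_params` object
#'
#' Checks positivity of rates and scales and the interface-resolution
#' constraint `eps >= 2*dx`.  No CFL-type constraint applies to `D_v` or
#' `k_d`: diffusion and decay of the factor are solved backward-Euler
#' implicitly, which is unconditionally stable (the default `dt * k_d = 2`
#' is fine).
#'
#' @param p A `suture_params` object (or bare list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  need <- param_field_names()
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter fields: ", paste(miss, collapse = ", "))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in need) if (!num1(p[[f]])) stop("parameter '", f, "' must be a single finite number")
  pos <- c("alpha", "sigma", "D_v", "k_p", "k_d", "dx", "dt", "eps")
  for (f in pos) if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0")
  if (p$c < 0) stop("parameter 'c' must be >= 0")
  if (p$v_c < 0) stop("parameter 'v_c' must be >= 0")
  if (p$t_end < 0) stop("parameter 't_end' must be >= 0")
  if (p$noise_amp < 0) stop("parameter 'noise_amp' must be >= 0")
  if (p$nx < 3 || p$ny < 3) stop("lattice must be at least 3 x 3")
  if (p$eps < 2 * p$dx) stop("eps must be >= 2*dx for the interface to be resolvable on the lattice")
  invisible(p)
}

param_field_names <- function() {
  c("alpha", "sigma", "v_c", "D_v", "c", "k_p", "k_d",
    "nx", "ny", "dx", "dt", "t_end", "eps", "seed", "noise_amp")
}

#' @export
print.suture_params <- function(x, ...) {
  cat("suture_params:\n")
  cat(sprintf("  model:    alpha=%g sigma=%g v_c=%g D_v=%g c=%g k_p=%g k_d=%g\n",
              x$alpha, x$sigma, x$v_c, x$D_v, x$c, x$k_p, x$k_d))
  cat(sprintf("  lattice:  %d x %d, dx=%g, eps=%g\n", x$nx, x$ny, x$dx, x$eps))
  cat(sprintf("  time:     dt=%g, t_end=%g (%d steps), seed=%d, noise_amp=%g\n",
              x$dt, x$t_end, as.integer(round(x$t_end / x$dt)), x$seed, x$noise_amp))
  invisible(x)
}

#' Read / write a flat JSON parameter configuration
#'
#' The configuration is a flat JSON object whose keys are exactly the fields
#' of [suture_params()].  Unknown keys are rejected; missing keys take the
#' package defaults.
#'
#' @param path File path of the JSON configuration.
#' @return `read_config()` returns a `suture_params`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), param_field_names())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(suture_params, cfg)
}

#' @param params A `suture_params` object to serialize.
#' @rdname read_config
#' @export
write_config <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
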