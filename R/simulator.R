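#' Precomputed spectral operators for the semi-implicit solves
#'
#' Fourier multipliers of the backward-Euler Helmholtz operators for the
#' factor solve `(I + dt*k_d - dt*D_v*L) v` and for the phase-field solve
#' `(I - dt_sub*M0*L) u`, on the even-extended (Neumann-x, periodic-y)
#' lattice.  `M0` is the Allen-Cahn pair mobility `clamp(sigma, 100, 300)`
#' scaled by the curvature calibration constant; the surface-tension
#' remainder `sigma - M0` is applied explicitly (subcycled when stiff).
#'
#' @param params A [suture_params()].
#' @return A list with multipliers and the subcycling plan; pass it to
#'   [step_v()] / [step_u()] to avoid recomputation per step.
#' @export
solver_cache <- function(params) {
  p <- params
  kx <- 0:(2 * p$nx - 1); ky <- 0:(p$ny - 1)
  lam <- outer((2 * cos(2 * pi * ky / p$ny) - 2) / p$dx^2,
               (2 * cos(pi * kx / p$nx) - 2) / p$dx^2, `+`)
  M0 <- min(max(p$sigma, .mobility_bounds[1]), .mobility_bounds[2]) * .cal_curv
  rem <- p$sigma - M0 / .cal_curv   # explicit surface-tension remainder
  if (abs(rem) < 1e-9 * max(1, p$sigma)) rem <- 0   # skip the kappa pass entirely
  nsub <- max(1L, as.integer(ceiling(p$dt * abs(rem) / .curv_subcycle_limit)))
  dts <- p$dt / nsub
  list(coef_v = 1 + p$dt * p$k_d - p$dt * p$D_v * lam,
       coef_u = 1 - dts * M0 * lam,
       M0 = M0, rem = rem, nsub = nsub, dts = dts,
       nx = p$nx, ny = p$ny)
}

check_cache <- function(state, params, cache) {
  if (is.null(cache)) cache <- solver_cache(params)
  if (cache$nx != ncol(state$u) || cache$ny != nrow(state$u))
    stop("solver cache does not match field dimensions")
  cache
}

#' Initial condition: two bone plates flanking a perturbed mesenchyme strip
#'
#' `u = 1` outside a central vertical strip of width `w0`, `u = 0` inside,
#' with tanh interface profiles of width `eps`.  Both interfaces are
#' displaced row-wise by seeded zero-mean noise (marginal standard deviation
#' `noise_amp` after circular 3-row smoothing).  `v` is initialised to its
#' steady profile for the frozen `u` by iterating the implicit factor solve
#' to convergence, so the run starts on the slow manifold of the factor
#' field.  Identical seeds give bit-identical states.
#'
#' @param params A [suture_params()].
#' @param w0 Initial strip width (length units, default `10 * dx`).
#' @return A [field_state()] at `t = 0`.
#' @export
initial_condition <- function(params, w0 = 10 * params$dx) {
  p <- params
  if (w0 + 2 * p$noise_amp >= p$nx * p$dx)
    stop("initial strip (w0 + 2*noise_amp) leaves no bone on the lattice")
  state <- with_preserved_rng({
    set.seed(p$seed)
    xc <- lattice_x(p$nx, p$dx)
    ctr <- p$nx * p$dx / 2
    pert <- function() {
      # circular 3-row moving average of N(0, 3*noise_amp^2) has marginal
      # sd = noise_amp; centred to zero mean
      z <- rnorm(p$ny, 0, sqrt(3) * p$noise_amp)
      zs <- (z + z[c(p$ny, seq_len(p$ny - 1))] + z[c(seq_len(p$ny)[-1], 1)]) / 3
      zs - mean(zs)
    }
    xL <- ctr - w0 / 2 + pert()
    xR <- ctr + w0 / 2 + pert()
    u <- matrix(0, p$ny, p$nx)
    for (i in seq_len(p$ny))
      u[i, ] <- 1 - tanh_profile((xc - xL[i]) / p$eps) + tanh_profile((xc - xR[i]) / p$eps)
    u <- pmin(pmax(u, 0), 1)
    st <- field_state(u, matrix(0, p$ny, p$nx), t = 0)
    cache <- solver_cache(p)
    # iterate the implicit factor solve to its fixed point (geometric
    # convergence with per-step factor <= 1/(1 + dt*k_d))
    for (k in seq_len(400)) {
      v_new <- step_v(st, p, cache)
      if (max(abs(v_new - st$v)) < 1e-12 * max(p$k_p / p$k_d, max(v_new))) {
        st$v <- v_new; break
      }
      st$v <- v_new
    }
    st
  })
  state
}

# Evaluate `expr` with the global RNG stream saved and restored, so seeded
# package internals do not perturb the caller's RNG state.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Semi-implicit update of the factor field
#'
#' Backward-Euler screened diffusion with explicit production in mesenchyme:
#' `(I - dt*D_v*L + dt*k_d*I) v_new = v + dt*k_p*(1 - u)`, solved exactly in
#' Fourier space for the discrete 5-point Laplacian `L` (no-flux in `x`,
#' periodic in `y`).  With `u` frozen, repeated application converges to the
#' unique steady state of the discrete elliptic problem.
#'
#' @param state A [field_state()].
#' @param params A [suture_params()].
#' @param cache Optional [solver_cache()].
#' @return The updated `v` matrix (non-negative).
#' @export
step_v <- function(state, params, cache = NULL) {
  cache <- check_cache(state, params, cache)
  rhs <- state$v + params$dt * params$k_p * (1 - state$u)
  v <- helmholtz_solve(rhs, cache$coef_v)
  # the inverse operator is positivity-preserving; clip roundoff only
  v[v < 0] <- 0
  v
}

#' Phase-field update of the bone field
#'
#' One `dt` of the forced Allen-Cahn equation whose sharp-interface limit is
#' the front law `V = f(v) - sigma*kappa`:
#' \deqn{u_t = M_0 (\nabla^2 u - W'(u)/\epsilon^2) +
#'       [f(v) - (\sigma - M_0)\kappa] \, 2u(1-u)/\epsilon}
#' with `W(u) = 2 u^2 (1-u)^2`.  The `2u(1-u)` bump is proportional to the
#' profile derivative, so the planar travelling wave is exact with speed
#' `f(v)`; the Allen-Cahn pair contributes curvature flow `-M0*kappa`
#' intrinsically (solved implicitly) and the remainder is applied through
#' the same bump, subcycled when `|sigma - M0| * dt` is stiff.  `u` is
#' clipped to `[0, 1]` after the solve.
#'
#' @inheritParams step_v
#' @return The updated `u` matrix.
#' @export
step_u <- function(state, params, cache = NULL) {
  cache <- check_cache(state, params, cache)
  p <- params
  u <- state$u
  f <- forcing(state$v, p)
  for (m in seq_len(cache$nsub)) {
    drive <- f
    if (cache$rem != 0)
      drive <- drive - cache$rem * curvature(u, p$dx, eps = p$eps)
    rhs <- u + cache$dts *
      (-cache$M0 * wprime(u) / p$eps^2 + .cal_front * drive * 2 * u * (1 - u) / p$eps)
    u <- helmholtz_solve(rhs, cache$coef_u)
    u <- pmin(pmax(u, 0), 1)
  }
  if (!all(is.finite(u)))
    stop("non-finite u after phase-field update; dt too large for eps/sigma")
  u
}

# double-well derivative, W(u) = 2 u^2 (1-u)^2 so the standing profile is
# (1 + tanh(x/eps))/2
wprime <- function(u) 4 * u * (1 - u) * (1 - 2 * u)

#' Passive soft-tissue expansion by column insertion
#'
#' Maintains a fractional accumulator `a <- a + c*dt/dx`; while `a >= 1` a
#' lattice column is duplicated inside the suture and one outer bone column
#' is deleted, keeping `nx` constant (a frame co-moving with the expanding
#' tissue).  The insertion site is drawn among mesenchyme-containing columns
#' with probability proportional to their soft-tissue content — a uniform
#' dilation of the soft tissue — and the deletion is taken from the wider
#' bone flank so the suture stays centred.  If no mesenchyme column exists
#' (fused suture) the insertion is skipped with a warning.
#'
#' @inheritParams step_v
#' @return The updated [field_state()] (with `inserted_columns` and
#'   `growth_accum` advanced).  With `c = 0` the state is returned unchanged.
#' @export
grow_domain <- function(state, params, cache = NULL) {
  p <- params
  if (p$c == 0) return(state)
  s <- state
  s$growth_accum <- s$growth_accum + p$c * p$dt / p$dx
  while (s$growth_accum >= 1) {
    s$growth_accum <- s$growth_accum - 1
    mmask <- s$u < 0.5
    mcount <- colSums(mmask)
    mes <- which(mcount > 0)
    if (!length(mes)) {
      warning("grow_domain: suture fused, growth insertion skipped")
      next
    }
    j <- if (length(mes) == 1) mes else
      mes[sample.int(length(mes), 1, prob = mcount[mes])]
    dup <- function(m) {
      left <- m[, seq_len(j), drop = FALSE]
      right <- if (j < ncol(m)) m[, (j + 1):ncol(m), drop = FALSE]
      cbind(left, m[, j, drop = FALSE], right)
    }
    ui <- dup(s$u); vi <- dup(s$v)
    n_left <- (min(mes) - 1) + (j < min(mes))
    n_right <- (ncol(s$u) - max(mes)) + (j > max(mes))
    drop_col <- if (n_left >= n_right) 1L else ncol(ui)
    if (any(ui[, drop_col] < 0.5))
      warning("grow_domain: deleted boundary column contained mesenchyme")
    s$u <- ui[, -drop_col, drop = FALSE]
    s$v <- vi[, -drop_col, drop = FALSE]
    s$inserted_columns <- s$inserted_columns + 1L
  }
  s
}

#' Run a full suture simulation
#'
#' Integrates the coupled system with the per-step splitting: factor solve
#' ([step_v()]), phase-field update ([step_u()]), growth ([grow_domain()]).
#' The factor is solved first so the front sees the current-step
#' concentration.  All randomness (initial perturbation, growth insertion
#' sites) derives from `params$seed`, so identical parameters give
#' bit-identical trajectories.
#'
#' @param params A [suture_params()].
#' @param snapshot_times Times at which to store snapshots (values are
#'   rounded to step boundaries; `0` and `t_end` are always included).
#'   Default: every 100 time units.
#' @param w0 Initial strip width passed to [initial_condition()].
#' @return An object of class `suture_trajectory`: list with `snapshots`
#'   (list of [field_state()]), `params`, `seed`, and `width` (mean
#'   mesenchyme width per snapshot, length units).
#' @export
run_simulation <- function(params, snapshot_times = NULL, w0 = 10 * params$dx) {
  p <- params
  nsteps <- as.integer(round(p$t_end / p$dt))
  if (is.null(snapshot_times))
    snapshot_times <- seq(0, p$t_end, by = max(p$dt, 100))
  if (any(snapshot_times < 0 | snapshot_times > p$t_end))
    stop("snapshot_times must lie in [0, t_end]")
  snap_steps <- sort(unique(c(0L, as.integer(round(snapshot_times / p$dt)), nsteps)))
  state <- initial_condition(p, w0 = w0)
  cache <- solver_cache(p)
  snapshots <- vector("list", length(snap_steps))
  take <- 1L
  if (snap_steps[1] == 0L) { snapshots[[1]] <- state; take <- 2L }
  with_preserved_rng({
    set.seed(p$seed + 1L)   # growth stream, distinct from the init stream
    if (nsteps > 0) for (k in seq_len(nsteps)) {
      state <- step_run_one(state, p, cache, k)
      if (take <= length(snap_steps) && k == snap_steps[take]) {
        snapshots[[take]] <- state
        take <- take + 1L
      }
    }
  })
  snapshots <- snapshots[!vapply(snapshots, is.null, logical(1))]
  traj <- list(snapshots = snapshots, params = p, seed = p$seed,
               width = vapply(snapshots, function(s) mean_suture_width(s$u, p$dx),
                              numeric(1)),
               times = vapply(snapshots, function(s) s$t, numeric(1)))
  class(traj) <- "suture_trajectory"
  traj
}

step_run_one <- function(state, p, cache, k) {
  out <- tryCatch({
    state$v <- step_v(state, p, cache)
    state$u <- step_u(state, p, cache)
    state <- grow_domain(state, p, cache)
    state$t <- k * p$dt
    state
  }, error = function(e)
    stop(sprintf("simulation failed at step %d (t = %g): %s", k, k * p$dt,
                 conditionMessage(e)), call. = FALSE))
  out
}

#' @export
print.suture_trajectory <- function(x, ...) {
  cat(sprintf("suture_trajectory: %d snapshots to t=%g, seed=%d\n",
              length(x$snapshots), max(x$times), x$seed))
  cat(sprintf("  final mean width %.1f, inserted columns %d\n",
              x$width[length(x$width)],
              x$snapshots[[length(x$snapshots)]]$inserted_columns))
  invisible(x)
}

#' Mean suture width of a phase field
#'
#' Soft-tissue measure per transect, `sum(1 - u) * dx`, averaged over rows.
#' Counting `1 - u` rather than thresholded pixels makes the measure smooth
#' in time (sub-pixel front motion changes it continuously), which the
#' steady-state detector and growth-balance fits rely on; the two interface
#' tails contribute a constant offset that cancels in differences.
#'
#' @param u Phase-field matrix.
#' @param dx Lattice spacing.
#' @return Mean width (length units).
#' @export
mean_suture_width <- function(u, dx) mean(rowSums(1 - u)) * dx

#' Detect width steady state in a trajectory
#'
#' Earliest snapshot time after which the mean suture width changes by less
#' than `tol` (relative) over every trailing window of length `window`
#' through the end of the trajectory.  The change is measured between the
#' means of the two halves of the trailing window, so the sawtooth that
#' growth insertions impose on the width (a column insertion is a
#' discontinuous `+dx`-scale jump) is averaged out and only secular drift
#' counts.
#'
#' @param trajectory A `suture_trajectory` with at least 3 snapshots.
#' @param window Trailing window length (time units).
#' @param tol Relative width-change tolerance between half-window means.
#' @return The steady-onset time, or `NULL` if the width never stabilises.
#' @export
detect_steady_state <- function(trajectory, window = 1000, tol = 0.02) {
  tt <- trajectory$times; ww <- trajectory$width
  if (length(tt) < 3) stop("need at least 3 snapshots")
  rel_change <- function(i) {
    if (tt[i] < window) return(Inf)       # window not yet available
    lo <- tt >= tt[i] - window & tt < tt[i] - window / 2
    hi <- tt >= tt[i] - window / 2 & tt <= tt[i]
    if (!any(lo) || !any(hi)) return(Inf)
    m1 <- mean(ww[lo]); m2 <- mean(ww[hi])
    abs(m2 - m1) / max(m1, m2, .Machine$double.eps)
  }
  ok <- vapply(seq_along(tt), rel_change, numeric(1)) < tol
  # steady from the first snapshot whose trailing window is quiet and stays so
  from <- which(rev(cumprod(rev(ok))) == 1)
  if (!length(from)) return(NULL)
  tt[min(from)]
}
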