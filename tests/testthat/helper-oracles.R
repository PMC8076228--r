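# Independent oracles and shared fixtures for the test suite.

# Closed-form steady profile of screened diffusion with a piecewise-constant
# source: production k_p on |x| <= a, decay k_d and diffusion D everywhere,
# infinite domain.  Derived by matching value and flux at |x| = a:
#   inside : v(x) = (k_p/k_d) * (1 - exp(-a/l) * cosh(x/l))
#   outside: v(x) = (k_p/k_d) * sinh(a/l) * exp(-|x|/l),   l = sqrt(D/k_d)
strip_profile_exact <- function(x, a, D, k_p = 1, k_d = 1) {
  l <- sqrt(D / k_d)
  ifelse(abs(x) <= a,
         (k_p / k_d) * (1 - exp(-a / l) * cosh(x / l)),
         (k_p / k_d) * sinh(a / l) * exp(-abs(x) / l))
}

# Apply the discrete backward-Euler factor operator directly (5-point
# Laplacian, reflecting x / periodic y) -- independent check of the
# spectral solve.
apply_factor_operator <- function(v, params) {
  p <- params
  ny <- nrow(v); nx <- ncol(v)
  up <- v[c(ny, seq_len(ny - 1)), ]; dn <- v[c(seq_len(ny)[-1], 1), ]
  lf <- v[, c(1, seq_len(nx - 1))]; rt <- v[, c(seq_len(nx)[-1], nx)]
  L <- (up + dn + lf + rt - 4 * v) / p$dx^2
  (1 + p$dt * p$k_d) * v - p$dt * p$D_v * L
}

# Small, fast parameter set for plumbing tests (not physically interesting).
tiny_params <- function(...) {
  args <- utils::modifyList(list(nx = 48, ny = 24, dx = 50, t_end = 200,
                                 noise_amp = 25), list(...))
  do.call(suture_params, args)
}

# A state with given u and its steady v (u frozen), bypassing the standard
# initial-condition geometry.
state_from_u <- function(u, params, v_iters = 120) {
  st <- field_state(u, matrix(0, nrow(u), ncol(u)))
  cache <- solver_cache(params)
  for (k in seq_len(v_iters)) st$v <- step_v(st, params, cache)
  st
}

# Amplitude of the first Fourier mode of a per-row interface position.
mode1_amplitude <- function(pos) {
  n <- length(pos)
  2 * Mod(fft(pos - mean(pos))[2]) / n
}

# Interface positions (left crossing) per row.
left_positions <- function(u, dx) {
  cv <- extract_interface(u, dx)
  cv$left[cv$valid]
}
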