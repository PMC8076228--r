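test_that("initial_condition geometry, determinism and noise statistics", {
  p0 <- suture_params(nx = 64, ny = 32, noise_amp = 0, t_end = 100)
  s <- initial_condition(p0)
  ctr <- p0$nx * p0$dx / 2
  cv <- extract_interface(s$u, p0$dx)
  expect_true(all(cv$valid))
  expect_lt(max(abs((cv$left + cv$right) / 2 - ctr)), 1e-6)   # mirror symmetry
  expect_equal(length(unique(round(cv$left, 9))), 1)          # straight

  p1 <- suture_params(nx = 64, ny = 32, t_end = 100, seed = 11)
  a <- initial_condition(p1); b <- initial_condition(p1)
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)

  expect_error(initial_condition(suture_params(nx = 8, dx = 50), w0 = 350),
               "no bone")

  # aggregated perturbation statistics: mean ~ 0, sd ~ noise_amp
  pn <- suture_params(nx = 32, ny = 256, dx = 10, eps = 20, noise_amp = 10,
                      D_v = 1e4, t_end = 100)
  offs <- unlist(lapply(1:10, function(sd) {
    pp <- pn; pp$seed <- sd
    st <- initial_condition(pp, w0 = 100)
    left_positions(st$u, pp$dx) - (32 * 10 / 2 - 50)
  }))
  expect_lt(abs(mean(offs)), 1)
  expect_lt(abs(sd(offs) - pn$noise_amp) / pn$noise_amp, 0.05)
})

test_that("factor solve: fixed points, decay rate, and operator identity", {
  p <- suture_params(nx = 32, ny = 16, t_end = 100)
  cache <- solver_cache(p)

  # uniform mesenchyme: convergence to k_p/k_d
  st <- field_state(matrix(0, 16, 32), matrix(0.2, 16, 32))
  for (k in 1:80) st$v <- step_v(st, p, cache)
  expect_lt(max(abs(st$v - p$k_p / p$k_d)), 1e-8)

  # uniform bone: pure decay with per-step factor 1/(1 + dt*k_d)
  st2 <- field_state(matrix(1, 16, 32), matrix(0.7, 16, 32))
  v1 <- step_v(st2, p, cache)
  expect_lt(max(abs(v1 - 0.7 / (1 + p$dt * p$k_d))), 1e-12)

  # spectral solve inverts the discrete operator to machine precision
  set.seed(4)
  st3 <- field_state(matrix(runif(16 * 32), 16, 32),
                     matrix(runif(16 * 32), 16, 32))
  v <- step_v(st3, p, cache)
  rhs <- st3$v + p$dt * p$k_p * (1 - st3$u)
  expect_lt(max(abs(apply_factor_operator(v, p) - rhs)), 1e-9)
})

test_that("1-D strip steady state matches the matched cosh closed form", {
  p <- suture_params(nx = 96, ny = 8, t_end = 100)
  w <- 10 * p$dx
  xc <- (seq_len(p$nx) - 0.5) * p$dx
  ctr <- p$nx * p$dx / 2
  u <- matrix(rep(as.numeric(abs(xc - ctr) > w / 2), each = p$ny), p$ny, p$nx)
  st <- state_from_u(u, p, v_iters = 300)
  exact <- strip_profile_exact(xc - ctr, w / 2, p$D_v, p$k_p, p$k_d)
  mid <- which.min(abs(xc - ctr))
  expect_lt(abs(st$v[1, mid] - exact[mid]) / exact[mid], 0.02)
})

test_that("phase-field front: stationary at threshold, conserves bone area", {
  p <- suture_params(nx = 128, ny = 8, t_end = 100)
  cache <- solver_cache(p)
  u <- make_step_field(p$nx, p$ny, 3200, p$eps, p$dx)
  st <- field_state(u, matrix(p$v_c, p$ny, p$nx))
  area0 <- sum(st$u)
  pos0 <- mean(left_positions(st$u, p$dx))
  for (k in 1:500) st$u <- step_u(st, p, cache)
  expect_lt(abs(mean(left_positions(st$u, p$dx)) - pos0), p$dx / 10)
  expect_lt(abs(sum(st$u) - area0) / area0, 0.001)
})

test_that("planar front speed matches alpha*(v - v_c) (quick oracle)", {
  p <- suture_params(nx = 192, ny = 4, t_end = 100)
  cache <- solver_cache(p)
  for (dlt in c(0.05, 0.2)) {
    u <- make_step_field(p$nx, p$ny, 6000, p$eps, p$dx)
    st <- field_state(u, matrix(p$v_c + dlt, p$ny, p$nx))
    tt <- pos <- numeric(0)
    for (k in 1:600) {
      st$u <- step_u(st, p, cache)
      if (k > 100 && k %% 20 == 0) {
        pos <- c(pos, mean(left_positions(st$u, p$dx))); tt <- c(tt, k * p$dt)
      }
    }
    V <- -unname(coef(lm(pos ~ tt))[2])    # bone grows leftward
    expect_lt(abs(V - p$alpha * dlt) / (p$alpha * dlt), 0.05)
  }
})

test_that("growth: identity at c = 0, exact accumulator bookkeeping", {
  p <- tiny_params()
  st <- initial_condition(p)
  expect_identical(grow_domain(st, p), st)

  # c*t_end/dx = 12 exactly -> 12 insertions, nx constant
  p2 <- suture_params(nx = 64, ny = 16, c = 0.3, t_end = 2000, seed = 3)
  traj <- run_simulation(p2)
  fin <- traj$snapshots[[length(traj$snapshots)]]
  expect_equal(fin$inserted_columns, 12L)
  expect_equal(ncol(fin$u), p2$nx)

  # fused suture: growth skipped with a warning
  pf <- suture_params(nx = 24, ny = 8, c = 10, t_end = 100)
  stf <- field_state(matrix(1, 8, 24), matrix(0, 8, 24))
  stf$growth_accum <- 0.8   # + c*dt/dx = 0.4 crosses 1 within this call
  expect_warning(out <- grow_domain(stf, pf), "fused")
  expect_equal(out$inserted_columns, 0L)
  expect_identical(out$u, stf$u)
})

test_that("run_simulation is deterministic and respects t_end", {
  p <- tiny_params(seed = 9)
  t0 <- run_simulation(suture_params(nx = 48, ny = 24, t_end = 0))
  expect_length(t0$snapshots, 1)
  expect_equal(t0$snapshots[[1]]$t, 0)

  a <- run_simulation(p); b <- run_simulation(p)
  expect_identical(a$snapshots[[length(a$snapshots)]]$u,
                   b$snapshots[[length(b$snapshots)]]$u)
  expect_true(all(diff(a$times) > 0))
})

test_that("fields stay in bounds over fuzzed parameter sets", {
  set.seed(100)
  for (rep in 1:20) {
    p <- suture_params(alpha = runif(1, 0.5, 8),
                       sigma = 10^runif(1, 1, 3),
                       v_c = runif(1, 0.1, 0.45),
                       D_v = 10^runif(1, 4, 5.5),
                       c = sample(c(0, runif(1, 0, 0.4)), 1),
                       nx = 48, ny = 24,
                       t_end = 40, seed = rep,
                       noise_amp = runif(1, 0, 50))
    traj <- run_simulation(p, snapshot_times = c(0, 40))
    fin <- traj$snapshots[[length(traj$snapshots)]]
    expect_true(all(fin$u >= 0 & fin$u <= 1))
    expect_true(all(fin$v >= 0))
    expect_true(all(is.finite(fin$u)) && all(is.finite(fin$v)))
  }
})

test_that("steady-state detector: constant fires early, drifting never", {
  mk <- function(widths, times) {
    structure(list(width = widths, times = times,
                   snapshots = vector("list", length(times))),
              class = "suture_trajectory")
  }
  tt <- seq(0, 6000, by = 200)
  expect_equal(detect_steady_state(mk(rep(400, length(tt)), tt),
                                   window = 1000, tol = 1e-3), 1000)
  expect_null(detect_steady_state(mk(500 + 0.1 * tt, tt),
                                  window = 1000, tol = 1e-3))
})

test_that("sinusoidal perturbations amplify at low sigma, decay at high", {
  grow_rate <- function(sigma) {
    p <- suture_params(nx = 128, ny = 32, sigma = sigma, t_end = 100)
    cache <- solver_cache(p)
    xc <- (seq_len(p$nx) - 0.5) * p$dx
    yc <- seq_len(p$ny)
    A0 <- 25                       # half a pixel
    ctr <- p$nx * p$dx / 2; w0 <- 10 * p$dx
    xL <- ctr - w0 / 2 + A0 * sin(2 * pi * yc / p$ny)
    xR <- ctr + w0 / 2 - A0 * sin(2 * pi * yc / p$ny)
    u <- matrix(0, p$ny, p$nx)
    for (i in seq_len(p$ny))
      u[i, ] <- 1 - (1 + tanh((xc - xL[i]) / p$eps)) / 2 +
        (1 + tanh((xc - xR[i]) / p$eps)) / 2
    st <- state_from_u(pmin(pmax(u, 0), 1), p)
    a0 <- mode1_amplitude(left_positions(st$u, p$dx))
    for (k in 1:500) {
      st$v <- step_v(st, p, cache)
      st$u <- step_u(st, p, cache)
    }
    a1 <- mode1_amplitude(left_positions(st$u, p$dx))
    a1 / a0
  }
  expect_gt(grow_rate(10), 1.1)
  expect_lt(grow_rate(1000), 0.9)
})
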