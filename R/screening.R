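#' Specification of a two-parameter screening sweep
#'
#' Defines a grid over two model parameters, a baseline parameter set, and
#' the replication/measurement policy used to build a phase diagram of
#' suture width and interdigitation amplitude (the numerical screening
#' experiment distinguishing wide/wavy from narrow/straight sutures).
#'
#' @param param1,param2 Names of two (distinct) [suture_params()] fields.
#' @param values1,values2 Strictly increasing value vectors for the sweep.
#' @param base Baseline `suture_params` for all non-swept fields.
#' @param n_rep Replicates per cell; replicate `r` runs with seed
#'   `base$seed + r - 1` unless `seeds` is given.
#' @param seeds Optional integer vector of length `n_rep`.
#' @param w0 Initial strip width for each run.
#' @param snapshot_by Snapshot interval (time units) for steadiness
#'   detection.
#' @param steady_window,steady_tol Passed to [detect_steady_state()].
#' @param measure_at `"t_end"` (default: measure the final state, flagging
#'   unsteady cells) or `"steady_onset"` (measure the first steady
#'   snapshot).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(param1, values1, param2, values2,
                       base = suture_params(), n_rep = 3, seeds = NULL,
                       w0 = 10 * base$dx, snapshot_by = 200,
                       steady_window = 1000, steady_tol = 0.02,
                       measure_at = c("t_end", "steady_onset")) {
  measure_at <- match.arg(measure_at)
  ok_names <- setdiff(param_field_names(), c("nx", "ny", "seed"))
  if (!param1 %in% ok_names || !param2 %in% ok_names)
    stop("swept parameters must be model/numerical fields of suture_params")
  if (param1 == param2) stop("the two swept parameters must differ")
  chk <- function(v) length(v) >= 1 && !is.unsorted(v, strictly = TRUE)
  if (!chk(values1) || !chk(values2))
    stop("value lists must be non-empty and strictly increasing")
  if (is.null(seeds)) seeds <- base$seed + seq_len(n_rep) - 1L
  if (length(seeds) != n_rep) stop("seeds must have length n_rep")
  structure(list(param1 = param1, values1 = values1,
                 param2 = param2, values2 = values2,
                 base = base, n_rep = as.integer(n_rep),
                 seeds = as.integer(seeds), w0 = w0,
                 snapshot_by = snapshot_by, steady_window = steady_window,
                 steady_tol = steady_tol, measure_at = measure_at),
            class = "sweep_spec")
}

#' Run a screening sweep into a phase diagram
#'
#' One simulation per (cell, replicate); each final (or steady) `u` field is
#' measured with [measure_field()] plus the sub-pixel centerline amplitude.
#' Cells where the suture fuses (some transect has no mesenchyme) are
#' flagged `"fused"`; cells whose width never stabilises are `"unsteady"`;
#' failed runs are `"error"` (the sweep continues).  Replicate means over
#' successful runs fill the grids.
#'
#' @param spec A [sweep_spec()].
#' @param quiet Suppress progress output.
#' @return An object of class `phase_diagram`: grids `width_mean`,
#'   `width_max`, `max_amplitude`, `centerline_amplitude`,
#'   `skeleton_length` (matrices `length(values1) x length(values2)`),
#'   character grid `flags`, the tidy `records` data frame (one row per
#'   cell x replicate), and the generating `spec`.
#' @export
run_sweep <- function(spec, quiet = TRUE) {
  n1 <- length(spec$values1); n2 <- length(spec$values2)
  meas_names <- c("width_mean", "width_max", "max_amplitude",
                  "centerline_amplitude", "skeleton_length")
  grids <- lapply(meas_names, function(.) matrix(NA_real_, n1, n2))
  names(grids) <- meas_names
  flags <- matrix("steady", n1, n2)
  records <- list()
  for (i1 in seq_len(n1)) for (i2 in seq_len(n2)) {
    cellvals <- matrix(NA_real_, spec$n_rep, length(meas_names))
    cellflag <- character(spec$n_rep)
    for (r in seq_len(spec$n_rep)) {
      p <- spec$base
      p[[spec$param1]] <- spec$values1[i1]
      p[[spec$param2]] <- spec$values2[i2]
      p$seed <- spec$seeds[r]
      p <- do.call(suture_params, p[param_field_names()])
      res <- tryCatch(
        sweep_one_run(p, spec),
        error = function(e) list(flag = "error", m = NULL))
      cellflag[r] <- res$flag
      if (!is.null(res$m)) cellvals[r, ] <- unlist(res$m[meas_names])
      records[[length(records) + 1L]] <- data.frame(
        param1 = spec$param1, value1 = spec$values1[i1],
        param2 = spec$param2, value2 = spec$values2[i2],
        seed = p$seed,
        width_mean = cellvals[r, 1], width_max = cellvals[r, 2],
        max_amplitude = cellvals[r, 3], centerline_amplitude = cellvals[r, 4],
        skeleton_length = cellvals[r, 5], flag = cellflag[r])
      if (!quiet)
        message(sprintf("%s=%g %s=%g seed=%d: %s", spec$param1,
                        spec$values1[i1], spec$param2, spec$values2[i2],
                        p$seed, cellflag[r]))
    }
    ok <- cellflag != "error"
    for (k in seq_along(meas_names))
      grids[[k]][i1, i2] <- if (any(ok)) mean(cellvals[ok, k]) else NA_real_
    flags[i1, i2] <-
      if (all(cellflag == "error")) "error"
      else if (any(cellflag == "fused")) "fused"
      else if (any(cellflag == "unsteady")) "unsteady"
      else "steady"
  }
  out <- c(grids, list(flags = flags,
                       records = do.call(rbind, records), spec = spec))
  class(out) <- "phase_diagram"
  out
}

sweep_one_run <- function(p, spec) {
  traj <- run_simulation(p, snapshot_times = seq(0, p$t_end, by = spec$snapshot_by),
                         w0 = spec$w0)
  steady_t <- detect_steady_state(traj, window = spec$steady_window,
                                  tol = spec$steady_tol)
  state <- if (spec$measure_at == "steady_onset" && !is.null(steady_t))
    traj$snapshots[[which(traj$times >= steady_t)[1]]]
  else traj$snapshots[[length(traj$snapshots)]]
  mask <- state$u < 0.5
  fused <- any(rowSums(mask) == 0)
  if (fused) {
    m <- list(width_mean = 0, width_max = 0, max_amplitude = 0,
              centerline_amplitude = 0, skeleton_length = 0)
    if (any(mask)) {
      mm <- measure_field(state$u, p$dx)
      m <- list(width_mean = mean(c(mm$width_per_transect,
                                    rep(0, nrow(mask) - mm$n_transects))),
                width_max = mm$width_max, max_amplitude = mm$max_amplitude,
                centerline_amplitude = mm$centerline_amplitude,
                skeleton_length = mm$skeleton_length)
    }
    return(list(flag = "fused", m = m))
  }
  mm <- measure_field(state$u, p$dx)
  amp_sub <- field_centerline_amplitude(state$u, p$dx)
  m <- list(width_mean = mm$width_mean, width_max = mm$width_max,
            max_amplitude = mm$max_amplitude,
            centerline_amplitude = if (is.na(amp_sub)) mm$centerline_amplitude else amp_sub,
            skeleton_length = mm$skeleton_length)
  list(flag = if (is.null(steady_t)) "unsteady" else "steady", m = m)
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase_diagram: %s (%d values) x %s (%d values), %d replicates\n",
              x$spec$param1, length(x$spec$values1),
              x$spec$param2, length(x$spec$values2), x$spec$n_rep))
  cat("flags:\n"); print(x$flags)
  cat("width_mean:\n"); print(round(x$width_mean, 1))
  cat("max_amplitude:\n"); print(round(x$max_amplitude, 1))
  invisible(x)
}

#' Trend statistics along one axis of a phase diagram
#'
#' For each line of the grid along the chosen axis, the sign of the
#' Spearman rank correlation between the swept values and the measurement,
#' and whether the line is (weakly) monotone non-decreasing /
#' non-increasing.  Lines with no finite values are excluded and noted.
#'
#' @param diagram A `phase_diagram`.
#' @param axis `"param1"` (trend along `values1`, one line per value2) or
#'   `"param2"`.
#' @param measure Grid name, e.g. `"width_mean"` or `"max_amplitude"`.
#' @return List with per-line data frame `lines`, `fraction_monotone`
#'   (non-decreasing or non-increasing as a whole), and
#'   `fraction_nondecreasing`.
#' @export
monotonicity_report <- function(diagram, axis = c("param1", "param2"),
                                measure = "width_mean") {
  axis <- match.arg(axis)
  g <- diagram[[measure]]
  if (is.null(g)) stop("unknown measure: ", measure)
  vals <- if (axis == "param1") diagram$spec$values1 else diagram$spec$values2
  if (length(vals) < 3) stop("need >= 3 values along the trend axis")
  lines <- if (axis == "param1") lapply(seq_len(ncol(g)), function(j) g[, j])
           else lapply(seq_len(nrow(g)), function(i) g[i, ])
  res <- lapply(seq_along(lines), function(k) {
    y <- lines[[k]]
    if (all(!is.finite(y))) return(data.frame(line = k, rho_sign = NA,
                                              nondecreasing = NA, nonincreasing = NA,
                                              excluded = TRUE))
    keep <- is.finite(y)
    rho <- if (sd(y[keep]) == 0) 0 else
      cor(vals[keep], y[keep], method = "spearman")
    data.frame(line = k, rho_sign = sign(rho),
               nondecreasing = !is.unsorted(y[keep]),
               nonincreasing = !is.unsorted(rev(y[keep])),
               excluded = FALSE)
  })
  res <- do.call(rbind, res)
  inc <- res$nondecreasing[!res$excluded]; dec <- res$nonincreasing[!res$excluded]
  list(lines = res,
       fraction_monotone = mean(inc | dec),
       fraction_nondecreasing = mean(inc))
}

#' Render a phase diagram to CSV and heatmaps
#'
#' Writes the tidy per-replicate records as CSV (flagged runs keep their
#' flag string; no fabricated numbers) and one PNG heatmap per measurement
#' grid.
#'
#' @param diagram A `phase_diagram`.
#' @param out_dir Output directory (created if needed).
#' @param measures Grid names to render as heatmaps.
#' @return Named list of written file paths, invisibly.
#' @export
render_phase_diagram <- function(diagram, out_dir,
                                 measures = c("width_mean", "max_amplitude")) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  csv <- file.path(out_dir, "sweep_records.csv")
  write.csv(diagram$records, csv, row.names = FALSE)
  paths <- list(csv = csv)
  for (m in measures) {
    png_path <- file.path(out_dir, paste0("phase_", m, ".png"))
    ok <- tryCatch({
      grDevices::png(png_path, width = 640, height = 560)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::image(x = seq_along(diagram$spec$values1),
                      y = seq_along(diagram$spec$values2),
                      z = diagram[[m]], xlab = diagram$spec$param1,
                      ylab = diagram$spec$param2, main = m, axes = FALSE)
      graphics::axis(1, at = seq_along(diagram$spec$values1),
                     labels = signif(diagram$spec$values1, 3))
      graphics::axis(2, at = seq_along(diagram$spec$values2),
                     labels = signif(diagram$spec$values2, 3))
      TRUE
    }, error = function(e) { warning("heatmap rendering failed: ",
                                     conditionMessage(e)); FALSE })
    if (ok) paths[[m]] <- png_path
  }
  invisible(paths)
}

#' Rebuild phase-diagram grids from a records CSV
#'
#' Inverse of the CSV side of [render_phase_diagram()]: replicate means over
#' non-error rows per cell, in the same cell order.  Used to verify the
#' round trip diagram -> CSV -> grids.
#'
#' @param path CSV file written by [render_phase_diagram()].
#' @return List of grids (`width_mean`, `max_amplitude`, ...) plus `values1`,
#'   `values2`.
#' @export
diagram_from_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  v1 <- sort(unique(df$value1)); v2 <- sort(unique(df$value2))
  meas <- c("width_mean", "width_max", "max_amplitude",
            "centerline_amplitude", "skeleton_length")
  grids <- lapply(meas, function(m) {
    g <- matrix(NA_real_, length(v1), length(v2))
    for (i in seq_along(v1)) for (j in seq_along(v2)) {
      rows <- df$value1 == v1[i] & df$value2 == v2[j] & df$flag != "error"
      if (any(rows)) g[i, j] <- mean(df[[m]][rows])
    }
    g
  })
  names(grids) <- meas
  c(grids, list(values1 = v1, values2 = v2))
}

#' Default screening grids
#'
#' Five-point grids per screened parameter, centred on the calibrated
#' baseline: multiplicative grids for `D_v` (factor 2), `sigma` (factor
#' sqrt(10)) and `alpha` (factor 2); a factor-1.1 grid for `v_c` (whose
#' feasible band between suture fusion and unbounded widening is narrow);
#' and `c` in `{0, 0.05, 0.1, 0.2, 0.4}`.
#'
#' @return Named list of value vectors.
#' @export
default_screen_values <- function() {
  list(D_v = 9e4 * 2^(-2:2),
       v_c = 0.35 * 1.1^(-2:2),
       sigma = 100 * 10^seq(-1, 1, by = 0.5),
       alpha = 4 * 2^(-2:2),
       c = c(0, 0.05, 0.1, 0.2, 0.4))
}
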