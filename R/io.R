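#' Read and write 16-bit ASCII PGM images
#'
#' Snapshots and fixtures are stored as plain-text portable graymaps
#' (PGM "P2", maxval 65535): a grayscale format readable by ImageJ/Fiji and
#' scikit-image without any binary dependency.
#'
#' @param m Numeric matrix scaled to `[0, 1]` (values are quantised to
#'   16 bits).
#' @param path Output file path.
#' @return `write_pgm()` returns `path` invisibly; `read_pgm()` returns a
#'   numeric matrix rescaled to `[0, 1]`.
#' @export
write_pgm <- function(m, path) {
  q <- round(pmin(pmax(m, 0), 1) * 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "65535"), con)
  write(t(q), file = con, ncolumns = min(ncol(q), 24))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = txt[-1], what = numeric(), quiet = TRUE)
  if (!identical(txt[1], "P2")) stop("not an ASCII PGM (P2) file: ", path)
  nx <- tok[1]; ny <- tok[2]; maxval <- tok[3]
  vals <- tok[-(1:3)]
  if (length(vals) != nx * ny) stop("corrupt PGM: wrong pixel count")
  matrix(vals, ny, nx, byrow = TRUE) / maxval
}

#' Write trajectory snapshots and the run manifest
#'
#' Writes each snapshot's `u` and `v` as 16-bit ASCII PGM
#' (`{field}_{time:08.1f}.pgm`; `v` scaled by `k_p/k_d`, its uniform-source
#' plateau) and a JSON manifest recording the parameters, seed, snapshot
#' times, inserted column count and package version — everything needed to
#' reproduce the run bit-for-bit.
#'
#' @param traj A `suture_trajectory`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_snapshots <- function(traj, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  p <- traj$params
  vscale <- p$k_p / p$k_d
  for (s in traj$snapshots) {
    stamp <- sprintf("%08.1f", s$t)
    write_pgm(s$u, file.path(out_dir, sprintf("u_%s.pgm", stamp)))
    write_pgm(s$v / vscale, file.path(out_dir, sprintf("v_%s.pgm", stamp)))
  }
  manifest_path(traj, out_dir)
}

manifest_path <- function(traj, out_dir) {
  final <- traj$snapshots[[length(traj$snapshots)]]
  manifest <- list(params = unclass(traj$params),
                   seed = traj$seed,
                   snapshot_times = traj$times,
                   inserted_columns = final$inserted_columns,
                   mean_width_final = traj$width[length(traj$width)],
                   package = "suturesim",
                   version = as.character(packageVersion("suturesim")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest JSON (or the directory containing `manifest.json`).
#' @return The manifest as a list; `$params` is a validated
#'   [suture_params()].
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$params <- do.call(suture_params, man$params[param_field_names()])
  man
}
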