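#' Indentation force--displacement curve
#'
#' Paired probe-displacement (mm) / reaction-force (N) samples, either from
#' an experiment or a simulation. Displacement is the scalar advance of the
#' probe along its trajectory, not a 3D position. The first sample's force
#' is the curve's `initial_force` — for experimental records this is the
#' preload present because the probe was already touching the tissue.
#'
#' @param displacement non-decreasing numeric vector, mm.
#' @param force numeric vector, N, same length.
#' @param source `"experimental"` or `"simulated"`.
#' @return `tc_curve` with fields `displacement`, `force`, `source`,
#'   `initial_force`.
#' @export
indentation_curve <- function(displacement, force,
                              source = c("experimental", "simulated")) {
  source <- match.arg(source)
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force) || length(displacement) < 1L)
    tc_stop("displacement and force must be non-empty and equal length",
            "tissuecal_invalid_curve")
  if (any(!is.finite(displacement)) || any(!is.finite(force)))
    tc_stop("curve samples must be finite", "tissuecal_invalid_curve")
  if (is.unsorted(displacement))
    tc_stop("displacement must be non-decreasing", "tissuecal_invalid_curve")
  structure(list(displacement = displacement, force = force,
                 source = source, initial_force = force[1L]),
            class = "tc_curve")
}

#' @export
print.tc_curve <- function(x, ...) {
  cat(sprintf("%s indentation curve: %d samples, d in [%.3g, %.3g] mm, F in [%.3g, %.3g] N (initial %.3g N)\n",
              x$source, length(x$displacement), min(x$displacement),
              max(x$displacement), min(x$force), max(x$force),
              x$initial_force))
  invisible(x)
}

#' @export
as.data.frame.tc_curve <- function(x, ...) {
  data.frame(displacement_mm = x$displacement, force_n = x$force)
}

#' Read an experimental curve from CSV
#'
#' Expects a header with columns `displacement_mm` and `force_n`. Rows are
#' sorted by displacement if necessary (with a warning); rows containing
#' `NA` are rejected, as are negative displacements.
#'
#' @param path CSV file path.
#' @param source source tag for the resulting curve.
#' @return a [indentation_curve()].
#' @export
read_curve_csv <- function(path, source = "experimental") {
  if (!file.exists(path))
    tc_stop(sprintf("curve file '%s' not found", path), "tissuecal_io_error")
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) tc_stop(
                   sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                   "tissuecal_io_error"))
  if (!all(c("displacement_mm", "force_n") %in% names(df)))
    tc_stop("curve CSV must have columns 'displacement_mm,force_n'",
            "tissuecal_io_error")
  if (nrow(df) == 0L)
    tc_stop("curve CSV is empty", "tissuecal_io_error")
  d <- df$displacement_mm; f <- df$force_n
  if (any(is.na(d)) || any(is.na(f)))
    tc_stop("curve CSV contains missing values", "tissuecal_io_error")
  if (any(d < 0))
    tc_stop("negative displacement in curve CSV", "tissuecal_io_error")
  if (is.unsorted(d)) {
    warning("curve displacement not monotone; rows sorted by displacement")
    o <- order(d)
    d <- d[o]; f <- f[o]
  }
  indentation_curve(d, f, source)
}

#' Write a curve to CSV
#'
#' Columns `increment,displacement_mm,force_n`; 12 significant digits so a
#' read/write round trip is lossless at that precision.
#'
#' @param curve a [indentation_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(increment = seq_along(curve$displacement) - 1L,
                   displacement_mm = sprintf("%.12g", curve$displacement),
                   force_n = sprintf("%.12g", curve$force))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Straight-line probe trajectory
#'
#' The probe's motion is reduced to a linear fit from its starting to its
#' ending position, with no rotation; samples are uniformly spaced on the
#' segment.
#'
#' @param start,end 3D points, mm (must differ).
#' @param n_samples number of samples (>= 2).
#' @return `tc_trajectory` with `start`, `end`, `n_samples`, `points`
#'   (`n x 3`), `displacement_axis` (unit), `total_displacement` (mm).
#' @export
build_trajectory <- function(start, end, n_samples = 100) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3L || length(end) != 3L)
    tc_stop("'start' and 'end' must be 3D points", "tissuecal_invalid_probe")
  if (n_samples < 2L)
    tc_stop("'n_samples' must be >= 2", "tissuecal_invalid_probe")
  v <- end - start
  mag <- sqrt(sum(v^2))
  if (mag == 0)
    tc_stop("trajectory endpoints coincide", "tissuecal_invalid_probe")
  t <- seq(0, 1, length.out = n_samples)
  pts <- outer(t, v) + matrix(start, n_samples, 3, byrow = TRUE)
  structure(list(start = start, end = end, n_samples = as.integer(n_samples),
                 points = pts, displacement_axis = v / mag,
                 total_displacement = mag),
            class = "tc_trajectory")
}
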