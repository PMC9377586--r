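#' Zero-intercept least-squares slope
#'
#' Slope of the regression line through the origin,
#' \eqn{s = \sum d_i F_i / \sum d_i^2} (N/mm). Both the experimental and
#' (after crop-and-align re-zeroing) the simulated curves are fitted this
#' way.
#'
#' @param curve a [indentation_curve()] with >= 2 samples.
#' @return slope, N/mm.
#' @export
fit_slope_zero_intercept <- function(curve) {
  d <- curve$displacement; f <- curve$force
  if (length(d) < 2L)
    tc_stop("need at least 2 samples to fit a slope",
            "tissuecal_invalid_curve")
  if (all(d == 0))
    tc_stop("degenerate curve: all displacements zero",
            "tissuecal_invalid_curve")
  sum(d * f) / sum(d * d)
}

#' Crop and align a simulated curve to an experimental window
#'
#' Applies the three-step rule used before slope comparison:
#' \enumerate{
#'   \item drop simulated samples whose force is below the experimental
#'     curve's initial (preload) force;
#'   \item re-zero displacement at the first retained sample;
#'   \item drop samples whose re-zeroed displacement exceeds the
#'     experimental displacement span.
#' }
#'
#' @param sim simulated [indentation_curve()].
#' @param exp experimental [indentation_curve()].
#' @return the cropped, re-zeroed simulated curve.
#' @export
crop_align <- function(sim, exp) {
  keep <- sim$force >= exp$initial_force
  if (!any(keep))
    tc_stop("insufficient simulated displacement: no simulated force reaches the experimental initial force; simulate a larger displacement",
            "tissuecal_insufficient_simulation")
  first <- which(keep)[1L]
  d <- sim$displacement[first:length(sim$displacement)]
  f <- sim$force[first:length(sim$force)]
  d <- d - d[1L]
  span <- max(exp$displacement) - min(exp$displacement)
  inside <- d <= span + 1e-12
  indentation_curve(d[inside], f[inside], source = "simulated")
}

#' Slope-ratio update of the material coefficient
#'
#' The calibration update: divide the current coefficient by the ratio of
#' the simulated to the experimental slope, `c1' = c1 / (s_sim / s_exp)`.
#' Because the displacement-driven forward problem is (near-)linear in
#' `c1`, one update lands (near) the solution.
#'
#' @param c1 current coefficient, MPa (> 0).
#' @param s_sim simulated-curve slope, N/mm (> 0).
#' @param s_exp experimental-curve slope, N/mm (> 0).
#' @return updated coefficient, MPa.
#' @export
update_c1 <- function(c1, s_sim, s_exp) {
  if (any(c(c1, s_sim, s_exp) <= 0) || any(!is.finite(c(c1, s_sim, s_exp))))
    tc_stop("c1 and both slopes must be positive and finite",
            "tissuecal_invalid_input")
  c1 / (s_sim / s_exp)
}

#' Symmetric percent difference
#'
#' `|a - b| / ((a + b)/2) * 100` — the mean-denominator definition.
#'
#' @param a,b scalars with nonzero mean.
#' @return percent difference.
#' @export
percent_difference <- function(a, b) {
  m <- (a + b) / 2
  if (m == 0)
    tc_stop("percent difference undefined for zero mean",
            "tissuecal_invalid_input")
  abs(a - b) / abs(m) * 100
}

new_calibration_state <- function(s_exp, iterations, tol, converged,
                                  max_iter, method, n_forward) {
  structure(list(s_exp = s_exp, iterations = iterations, tol = tol,
                 converged = converged, max_iter = max_iter,
                 method = method, n_forward = n_forward,
                 c1 = if (nrow(iterations)) iterations$c1[nrow(iterations)]
                 else NA_real_),
            class = "tc_calibration")
}

#' @export
print.tc_calibration <- function(x, ...) {
  cat(sprintf("Slope calibration (%s): %s after %d forward evaluation(s)\n",
              x$method,
              if (x$converged) "converged" else "NOT converged",
              x$n_forward))
  cat(sprintf("  experimental slope: %.6g N/mm; tolerance |ratio-1| < %g\n",
              x$s_exp, x$tol))
  df <- x$iterations
  if (nrow(df)) {
    cat("  iteration  c1 (MPa)     K (MPa)     s_sim (N/mm)  ratio\n")
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %9d  %-11.6g %-11.6g %-13.6g %.4f\n", df$iteration[i],
                  df$c1[i], df$k[i], df$s_sim[i], df$ratio[i]))
    cat(sprintf("  final c1 = %.6g MPa (effective E = %.6g MPa at nu = 0.5)\n",
                x$c1, effective_modulus(x$c1)))
  }
  invisible(x)
}

#' Slope-ratio inverse-FEA calibration
#'
#' Fits the Neo-Hookean coefficient to an experimental force--displacement
#' curve: simulate at the current `c1` (with `k = k_ratio * c1`), crop and
#' align the simulated curve to the experimental window, fit zero-intercept
#' slopes to both, and update `c1` by the slope ratio until the simulated
#' slope is within `tol` (default 2.5%) of the experimental slope.
#'
#' @param forward forward-model handle: `function(c1)` returning a simulated
#'   [indentation_curve()] (see [make_fe_forward()], [make_surrogate_forward()]).
#' @param exp experimental [indentation_curve()].
#' @param c1_init initial guess, MPa (default 0.01).
#' @param tol convergence tolerance on `|s_sim/s_exp - 1|` (default 0.025).
#' @param max_iter maximum iterations (forward evaluations).
#' @param k_ratio coupling `k = k_ratio * c1` recorded per iteration.
#' @param sim_zero_intercept fit the simulated curve with a zero intercept
#'   too (default); the crop re-zeroing makes the origin meaningful.
#' @return `tc_calibration`: experimental slope `s_exp`, per-iteration table
#'   `iterations` (`iteration`, `c1`, `k`, `s_sim`, `ratio`), `converged`,
#'   final `c1`, `n_forward`.
#' @export
calibrate <- function(forward, exp, c1_init = 0.01, tol = 0.025,
                      max_iter = 20, k_ratio = 1000,
                      sim_zero_intercept = TRUE) {
  stopifnot(is.function(forward), inherits(exp, "tc_curve"))
  if (c1_init <= 0) tc_stop("'c1_init' must be > 0", "tissuecal_invalid_input")
  s_exp <- fit_slope_zero_intercept(exp)
  c1 <- c1_init
  rows <- list()
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sim <- tryCatch(forward(c1), error = function(e)
      tc_stop(sprintf("forward model failed at iteration %d (c1 = %g): %s",
                      iter, c1, conditionMessage(e)),
              "tissuecal_forward_failure"))
    cropped <- crop_align(sim, exp)
    s_sim <- if (sim_zero_intercept) fit_slope_zero_intercept(cropped)
    else unname(stats::coef(stats::lm(cropped$force ~ cropped$displacement))[2])
    ratio <- s_sim / s_exp
    rows[[iter]] <- data.frame(iteration = iter, c1 = c1, k = k_ratio * c1,
                               s_sim = s_sim, ratio = ratio)
    if (abs(ratio - 1) < tol) { converged <- TRUE; break }
    c1 <- update_c1(c1, s_sim, s_exp)
  }
  new_calibration_state(s_exp, do.call(rbind, rows), tol, converged,
                        max_iter, "slope-ratio", length(rows))
}

#' Brent bracketing baseline calibration
#'
#' Traditional single-parameter inverse FEA: Brent's root finder
#' ([stats::uniroot()]) applied to the slope mismatch
#' `s_sim(c1) - s_exp` over a bracket. Every forward evaluation counts as
#' one iteration; for comparability with [calibrate()], convergence is
#' declared at the first evaluation whose slope ratio satisfies
#' `|s_sim/s_exp - 1| < tol`.
#'
#' @inheritParams calibrate
#' @param bracket `c(lower, upper)` bracket for `c1` (default
#'   `c1_init/20 .. c1_init*20`); must bracket a sign change of the slope
#'   mismatch.
#' @param root_tol absolute `c1` tolerance handed to the root finder.
#' @return `tc_calibration` (method `"brent"`); `iterations` holds one row
#'   per forward evaluation in evaluation order.
#' @export
calibrate_brent <- function(forward, exp, c1_init = 0.01,
                            bracket = c(c1_init / 20, c1_init * 20),
                            tol = 0.025, k_ratio = 1000,
                            sim_zero_intercept = TRUE, root_tol = NULL) {
  stopifnot(is.function(forward), inherits(exp, "tc_curve"))
  if (length(bracket) != 2L || any(bracket <= 0) || bracket[1] >= bracket[2])
    tc_stop("'bracket' must be positive and increasing",
            "tissuecal_invalid_input")
  s_exp <- fit_slope_zero_intercept(exp)
  evals <- new.env(parent = emptyenv())
  evals$rows <- list()
  f <- function(c1) {
    sim <- forward(c1)
    cropped <- crop_align(sim, exp)
    s_sim <- if (sim_zero_intercept) fit_slope_zero_intercept(cropped)
    else unname(stats::coef(stats::lm(cropped$force ~ cropped$displacement))[2])
    k <- length(evals$rows) + 1L
    evals$rows[[k]] <- data.frame(iteration = k, c1 = c1, k = k_ratio * c1,
                                  s_sim = s_sim, ratio = s_sim / s_exp)
    s_sim - s_exp
  }
  if (is.null(root_tol)) root_tol <- 1e-4 * c1_init
  fl <- f(bracket[1]); fu <- f(bracket[2])
  if (sign(fl) == sign(fu))
    tc_stop("bracket does not contain a solution: slope mismatch has the same sign at both ends",
            "tissuecal_invalid_bracket")
  uniroot(f, interval = bracket, f.lower = fl, f.upper = fu, tol = root_tol)
  tab <- do.call(rbind, evals$rows)
  hit <- which(abs(tab$ratio - 1) < tol)
  if (length(hit)) {
    n_forward <- hit[1]
    tab <- tab[seq_len(n_forward), , drop = FALSE]
    converged <- TRUE
  } else {
    n_forward <- nrow(tab)
    converged <- FALSE
  }
  new_calibration_state(s_exp, tab, tol, converged, n_forward, "brent",
                        n_forward)
}

#' Finite-element forward-model handle
#'
#' Wraps [solve_indentation()] into a `function(c1)` for use with
#' [calibrate()] / [calibrate_brent()]. The probe's total displacement is
#' sized as `sim_displacement_factor` times the experimental span (the
#' simulation covers more travel than the experiment; the crop rule trims
#' it back), unless the supplied probe's displacement is kept.
#'
#' @param mesh a [tet_mesh()].
#' @param probe a [probe_spec()]; its `total_displacement` is overridden
#'   when `exp` is given.
#' @param exp optional experimental curve used to size the displacement.
#' @param k_ratio bulk coupling `k = k_ratio * c1`.
#' @param sim_displacement_factor multiple of the experimental span to
#'   simulate (default 1.5).
#' @param ... further arguments for [solve_indentation()]
#'   (`contact_mode`, `penalty_scale`, ...).
#' @return `function(c1)` returning the simulated [indentation_curve()].
#' @export
make_fe_forward <- function(mesh, probe, exp = NULL, k_ratio = 1000,
                            sim_displacement_factor = 1.5, ...) {
  if (!is.null(exp)) {
    span <- max(exp$displacement) - min(exp$displacement)
    probe <- probe_spec(probe$face_center, probe$face_normal,
                        probe$face_half_lengths, probe$displacement_axis,
                        total_displacement = sim_displacement_factor * span,
                        n_increments = probe$n_increments,
                        face_axis1 = probe$t1)
  }
  force(mesh); force(k_ratio)
  dots <- list(...)
  function(c1) {
    mat <- material(c1, k_ratio = k_ratio)
    res <- do.call(solve_indentation,
                   c(list(mesh = mesh, mat = mat, probe = probe,
                          store_fields = "none"), dots))
    if (res$failed)
      tc_stop("forward simulation failed before reaching full displacement",
              "tissuecal_forward_failure")
    res$curve
  }
}
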