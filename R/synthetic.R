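#' Fast surrogate forward model
#'
#' Analytic stand-in for the finite-element forward model:
#' \deqn{F(d) = c_1\, a\, (d + b\, d^2),}
#' exactly linear in `c1` (mirroring the displacement-driven FE property
#' that underpins the slope-ratio update) with a quadratic stiffening term
#' `b` emulating the nonlinearity of indentation curves. The geometry scale
#' `a` (N / (MPa mm)) sets the overall stiffness; the default 300 puts
#' slopes in the N/mm range observed for limb indentation when
#' `c1 ~ 0.005` MPa.
#'
#' @param c1 Neo-Hookean coefficient, MPa (> 0).
#' @param stiffening quadratic coefficient `b`, 1/mm (>= 0).
#' @param d_max maximum displacement, mm (> 0).
#' @param n number of samples (>= 2), uniformly spaced on `[0, d_max]`.
#' @param scale geometry scale `a`.
#' @return a simulated [indentation_curve()].
#' @export
surrogate_forward <- function(c1, stiffening = 0.05, d_max = 10, n = 101,
                              scale = 300) {
  if (c1 <= 0 || d_max <= 0 || n < 2 || stiffening < 0 || scale <= 0)
    tc_stop("surrogate inputs must be positive (stiffening >= 0)",
            "tissuecal_invalid_input")
  d <- seq(0, d_max, length.out = n)
  indentation_curve(d, c1 * scale * (d + stiffening * d^2),
                    source = "simulated")
}

#' Surrogate forward-model handle
#'
#' Convenience closure `function(c1)` over [surrogate_forward()] for use
#' with [calibrate()] and [calibrate_brent()].
#'
#' @inheritParams surrogate_forward
#' @return `function(c1)` returning a simulated curve.
#' @export
make_surrogate_forward <- function(stiffening = 0.05, d_max = 10, n = 101,
                                   scale = 300) {
  function(c1) surrogate_forward(c1, stiffening = stiffening, d_max = d_max,
                                 n = n, scale = scale)
}

#' Generate a synthetic indentation experiment
#'
#' Emulates a freehand probe-indentation record with known ground truth:
#' evaluates the forward model at `true_c1`, discards the pre-contact
#' portion below `preload_force` (the probe is already pressing when
#' recording starts; 0.14 N is a typical starting force), re-zeroes
#' displacement at the first retained sample, and adds i.i.d. Gaussian
#' noise to the forces. Deterministic given `seed`. Displacement is treated
#' as exact (motion-capture precision is not modelled).
#'
#' @param true_c1 ground-truth coefficient, MPa.
#' @param forward forward handle `function(c1)` (default surrogate).
#' @param preload_force initial-contact force offset, N (>= 0).
#' @param noise_sd force noise standard deviation, N (>= 0).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `curve` (experimental [indentation_curve()]) and
#'   `truth` (record of `true_c1`, `preload_force`, `noise_sd`, `seed`).
#' @export
synth_experiment <- function(true_c1, forward = make_surrogate_forward(),
                             preload_force = 0.14, noise_sd = 0, seed) {
  if (missing(seed)) tc_stop("'seed' must be given explicitly",
                             "tissuecal_invalid_input")
  if (noise_sd < 0 || preload_force < 0)
    tc_stop("'noise_sd' and 'preload_force' must be >= 0",
            "tissuecal_invalid_input")
  base <- forward(true_c1)
  if (preload_force > max(base$force))
    tc_stop("preload exceeds the peak forward force",
            "tissuecal_invalid_input")
  keep <- which(base$force >= preload_force)
  d <- base$displacement[keep] - base$displacement[keep[1]]
  f <- base$force[keep]
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + rnorm(length(f), sd = noise_sd)
  }
  list(curve = indentation_curve(d, f, source = "experimental"),
       truth = list(true_c1 = true_c1, preload_force = preload_force,
                    noise_sd = noise_sd, seed = seed))
}
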