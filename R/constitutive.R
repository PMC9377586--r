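#' Uncoupled Neo-Hookean material
#'
#' Creates a material record for the uncoupled Neo-Hookean law
#' \deqn{\Psi = C_1(\bar I_1 - 3) + \tfrac{1}{2} K (\ln J)^2,}
#' where \eqn{C_1} (MPa) is the Neo-Hookean coefficient, \eqn{\bar I_1} the
#' first invariant of the deviatoric right Cauchy--Green tensor, and \eqn{K}
#' (MPa) a bulk-modulus-like parameter that penalises volume change. `K` is
#' coupled to `C1` through a fixed ratio (default 1000) so that the model
#' stays nearly incompressible with a single free coefficient.
#'
#' `nu_effective` is a bookkeeping Poisson's ratio used only in the
#' small-strain modulus conversions ([c1_from_modulus()],
#' [effective_modulus()]); actual compressibility is governed by `k`.
#'
#' @param c1 Neo-Hookean coefficient, MPa (> 0).
#' @param k_ratio dimensionless coupling factor; `k = k_ratio * c1`.
#' @param nu_effective effective Poisson's ratio used in modulus conversions.
#' @param k bulk-like parameter, MPa. Defaults to `k_ratio * c1`; if given
#'   explicitly, `k_ratio` is recomputed as `k / c1`.
#' @return An object of class `tc_material` with fields `c1`, `k`, `k_ratio`,
#'   `nu_effective`.
#' @examples
#' material(0.01)               # K = 10 MPa
#' material(0.005, k_ratio = 100)
#' @export
material <- function(c1, k_ratio = 1000, nu_effective = 0.5, k = NULL) {
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) || c1 <= 0)
    tc_stop("'c1' must be a single positive number (MPa)",
            "tissuecal_invalid_material")
  if (!is.numeric(k_ratio) || k_ratio <= 0)
    tc_stop("'k_ratio' must be positive", "tissuecal_invalid_material")
  if (is.null(k)) {
    k <- k_ratio * c1
  } else {
    if (!is.numeric(k) || k <= 0)
      tc_stop("'k' must be positive (MPa)", "tissuecal_invalid_material")
    k_ratio <- k / c1
  }
  structure(list(c1 = c1, k = k, k_ratio = k_ratio,
                 nu_effective = nu_effective),
            class = "tc_material")
}

#' @export
print.tc_material <- function(x, ...) {
  cat("Uncoupled Neo-Hookean material (MPa/mm/N units)\n")
  cat(sprintf("  C1 = %.6g MPa   K = %.6g MPa   (K/C1 = %.6g)\n",
              x$c1, x$k, x$k_ratio))
  cat(sprintf("  effective E = %.6g MPa at nu = %g\n",
              effective_modulus(x$c1, x$nu_effective), x$nu_effective))
  invisible(x)
}

#' Deformation state from a deformation gradient
#'
#' Wraps a 3x3 deformation gradient `F` together with its determinant `J`
#' and the first invariant of the deviatoric right Cauchy--Green tensor,
#' \eqn{\bar I_1 = J^{-2/3}\,\mathrm{tr}(F^T F)}.
#'
#' @param F 3x3 deformation gradient (dimensionless).
#' @return `tc_deformation` with fields `F`, `J`, `I1_bar`.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!identical(dim(F), c(3L, 3L)) || any(!is.finite(F)))
    tc_stop("'F' must be a finite 3x3 matrix", "tissuecal_invalid_deformation")
  J <- det(F)
  if (J <= 0)
    tc_stop("non-positive J: deformation gradient is inadmissible",
            "tissuecal_invalid_deformation")
  I1_bar <- J^(-2 / 3) * sum(F * F)  # tr(F'F) = sum of squared entries
  structure(list(F = F, J = J, I1_bar = I1_bar), class = "tc_deformation")
}

as_deformation <- function(state) {
  if (inherits(state, "tc_deformation")) state else deformation_state(state)
}

#' Strain-energy density
#'
#' Evaluates \eqn{\Psi = C_1(\bar I_1 - 3) + 0.5 K (\ln J)^2} in MPa.
#'
#' @param state a [deformation_state()] (or a 3x3 gradient, converted).
#' @param mat a [material()].
#' @return energy density, MPa.
#' @examples
#' strain_energy(diag(3), material(0.01))  # 0: undeformed
#' @export
strain_energy <- function(state, mat) {
  s <- as_deformation(state)
  mat$c1 * (s$I1_bar - 3) + 0.5 * mat$k * log(s$J)^2
}

#' Cauchy stress of the uncoupled Neo-Hookean law
#'
#' \deqn{\sigma = (2 C_1 / J)\,\mathrm{dev}(\bar b) + (K \ln J / J) I,}
#' with \eqn{\bar b = J^{-2/3} F F^T}.
#'
#' @inheritParams strain_energy
#' @return symmetric 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress <- function(state, mat) {
  s <- as_deformation(state)
  F <- s$F; J <- s$J
  bbar <- J^(-2 / 3) * (F %*% t(F))
  devb <- bbar - (sum(diag(bbar)) / 3) * diag(3)
  (2 * mat$c1 / J) * devb + (mat$k * log(J) / J) * diag(3)
}

#' Spatial elasticity tensor
#'
#' Fourth-order spatial tangent `c[i,j,k,l]` of the uncoupled Neo-Hookean
#' law, obtained by push-forward of the material tangent
#' \eqn{2\,\partial S/\partial C}. Possesses both minor symmetries and the
#' major symmetry. At `F = I` it reduces to the small-strain isotropic
#' tensor with shear modulus \eqn{\mu = 2 C_1} and bulk-like modulus `K`.
#'
#' @inheritParams strain_energy
#' @return a `3 x 3 x 3 x 3` array, MPa.
#' @export
material_tangent <- function(state, mat) {
  s <- as_deformation(state)
  F <- s$F; J <- s$J
  b <- F %*% t(F)
  Ib <- sum(diag(b))
  mu <- 2 * mat$c1
  K <- mat$k
  lnJ <- log(J)
  d <- diag(3)
  cc <- array(0, c(3, 3, 3, 3))
  ciso <- 2 * mu * J^(-2 / 3) / J
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    Is <- 0.5 * (d[i, k] * d[j, l] + d[i, l] * d[j, k])
    cc[i, j, k, l] <-
      ciso * ((Ib / 3) * Is + (Ib / 9) * d[i, j] * d[k, l] -
                (d[i, j] * b[k, l] + b[i, j] * d[k, l]) / 3) +
      (K / J) * d[i, j] * d[k, l] - (2 * K * lnJ / J) * Is
  }
  cc
}

#' Convert Young's modulus to the Neo-Hookean coefficient
#'
#' Small-strain relationship `C1 = E / (4 (1 + nu))`. At `nu = 0.5` this is
#' `E / 6`, i.e. an effective Young's modulus of 0.060 MPa corresponds to
#' `C1 = 0.01` MPa.
#'
#' @param E Young's modulus, MPa (>= 0).
#' @param nu Poisson's ratio, in (-1, 0.5].
#' @return `c1`, MPa.
#' @export
c1_from_modulus <- function(E, nu = 0.5) {
  if (any(E < 0)) tc_stop("'E' must be >= 0", "tissuecal_invalid_material")
  if (any(nu <= -1 | nu > 0.5))
    tc_stop("'nu' must lie in (-1, 0.5]", "tissuecal_invalid_material")
  E / (4 * (1 + nu))
}

#' Effective Young's modulus implied by a Neo-Hookean coefficient
#'
#' Exact inverse of [c1_from_modulus()]: `E = 4 (1 + nu) * c1` (so `6 * c1`
#' at `nu = 0.5`). A small-strain reporting convenience, not a measured
#' property.
#'
#' @param c1 Neo-Hookean coefficient, MPa (>= 0).
#' @param nu Poisson's ratio.
#' @return `E`, MPa.
#' @export
effective_modulus <- function(c1, nu = 0.5) {
  if (any(c1 < 0)) tc_stop("'c1' must be >= 0", "tissuecal_invalid_material")
  4 * (1 + nu) * c1
}
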