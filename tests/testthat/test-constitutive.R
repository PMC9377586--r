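test_that("strain energy matches hand-computed states", {
  m <- material(0.01)
  # undeformed
  expect_equal(strain_energy(diag(3), m), 0)
  # isochoric uniaxial stretch: I1 = 4 + 1 = 5, J = 1 -> C1*(5-3)
  F <- diag(c(2, 1 / sqrt(2), 1 / sqrt(2)))
  expect_equal(strain_energy(F, m), 0.02, tolerance = 1e-12)
  # volumetric term vanishes regardless of k
  m2 <- material(0.01, k_ratio = 17)
  expect_equal(strain_energy(F, m2), 0.02, tolerance = 1e-12)
  # simple shear gamma = 0.1: I1bar = 3 + gamma^2, J = 1
  Fs <- diag(3); Fs[1, 2] <- 0.1
  expect_equal(strain_energy(Fs, m), 1e-4, tolerance = 1e-12)
})

test_that("inadmissible deformation gradients are rejected", {
  m <- material(0.01)
  expect_error(deformation_state(diag(c(-1, 1, 1))),
               class = "tissuecal_invalid_deformation")
  expect_error(deformation_state(matrix(0, 3, 3)),
               class = "tissuecal_invalid_deformation")
  expect_error(strain_energy(diag(c(1, 1, 0)), m),
               class = "tissuecal_invalid_deformation")
})

test_that("deformation state invariants hold", {
  set.seed(11)
  for (i in 1:50) {
    F <- random_admissible_F()
    s <- deformation_state(F)
    expect_gt(s$J, 0)
    expect_gte(s$I1_bar, 3 - 1e-12)
    expect_equal(s$I1_bar, det(F)^(-2 / 3) * sum(diag(t(F) %*% F)),
                 tolerance = 1e-12)
  }
  # equality iff deviatoric stretch is identity
  expect_equal(deformation_state(1.3 * diag(3))$I1_bar, 3, tolerance = 1e-12)
})

test_that("Cauchy stress: zero at identity, isotropic under dilatation, matches energy gradient", {
  m <- material(0.01, k_ratio = 50)
  expect_equal(cauchy_stress(diag(3), m), matrix(0, 3, 3), tolerance = 1e-14)
  # pure dilatation: deviatoric part exactly zero, pressure K ln(a^3)/a^3
  a <- 1.07
  s <- cauchy_stress(a * diag(3), m)
  expect_equal(s, diag(3) * (m$k * log(a^3) / a^3), tolerance = 1e-12)
  expect_equal(s[1, 2], 0)

  # finite-difference oracle over random admissible states:
  # sigma = (dW/dF) F^T / J
  set.seed(42)
  for (i in 1:100) {
    F <- random_admissible_F()
    sig <- cauchy_stress(deformation_state(F), m)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    W <- function(fv) strain_energy(deformation_state(matrix(fv, 3, 3)), m)
    P <- matrix(num_grad(W, as.vector(F)), 3, 3)
    sig_fd <- P %*% t(F) / det(F)
    expect_equal(sig, sig_fd, tolerance = 1e-5)
  }
})

test_that("material tangent has its symmetries, small-strain limit and FD consistency", {
  m <- material(0.004, k_ratio = 200)
  cc <- material_tangent(diag(3), m)
  mu <- 2 * m$c1
  d <- diag(3)
  # small-strain isotropic tensor: 2*mu*(Is - I x I/3) + K I x I
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    Is <- (d[i, k] * d[j, l] + d[i, l] * d[j, k]) / 2
    ref <- 2 * mu * (Is - d[i, j] * d[k, l] / 3) + m$k * d[i, j] * d[k, l]
    expect_equal(cc[i, j, k, l], ref, tolerance = 1e-12)
  }

  set.seed(3)
  F <- random_admissible_F(0.15)
  cc <- material_tangent(deformation_state(F), m)
  # minor and major symmetries
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    expect_equal(cc[i, j, k, l], cc[j, i, k, l], tolerance = 1e-10)
    expect_equal(cc[i, j, k, l], cc[i, j, l, k], tolerance = 1e-10)
    expect_equal(cc[i, j, k, l], cc[k, l, i, j], tolerance = 1e-10)
  }
  # scaling (c1, k) by s scales the tangent by s exactly
  s <- 3.7
  m2 <- material(s * m$c1, k_ratio = m$k_ratio)
  expect_equal(material_tangent(deformation_state(F), m2), s * cc,
               tolerance = 1e-12)
})

test_that("spatial tangent matches finite differences of the Kirchhoff-stress response", {
  # d(tau)/d(F) eps F^{-1} push-forward check via small perturbation:
  # c : de  ~  J^-1 * [tau(F + dF) - tau(F)] - geometric terms; verify the
  # dominant material part through a symmetric velocity-gradient probe.
  m <- material(0.01, k_ratio = 100)
  set.seed(9)
  F <- random_admissible_F(0.1)
  cc <- material_tangent(deformation_state(F), m)
  h <- 1e-6
  for (rep in 1:5) {
    # symmetric rate-of-deformation probe
    Dp <- matrix(stats::runif(9, -1, 1), 3, 3); Dp <- (Dp + t(Dp)) / 2
    Fp <- (diag(3) + h * Dp) %*% F
    Fm <- (diag(3) - h * Dp) %*% F
    tau_p <- det(Fp) * cauchy_stress(deformation_state(Fp), m)
    tau_m <- det(Fm) * cauchy_stress(deformation_state(Fm), m)
    dtau <- (tau_p - tau_m) / (2 * h)
    tau <- det(F) * cauchy_stress(deformation_state(F), m)
    # Lie-derivative identity: dtau = J c:D + D tau + tau D
    lhs <- dtau - Dp %*% tau - tau %*% Dp
    rhs <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      rhs[i, j] <- det(F) * sum(cc[i, j, , ] * Dp)
    expect_equal(lhs, rhs, tolerance = 1e-4)
  }
})

test_that("modulus conversions reproduce the reference rows and invert exactly", {
  # initial literature guess: E = 0.060 MPa at nu = 0.5 -> C1 = 0.01
  expect_equal(c1_from_modulus(0.060, 0.5), 0.01, tolerance = 1e-12)
  expect_equal(c1_from_modulus(0, 0.5), 0)
  # female upper arm: C1 = 0.00358 <-> E = 0.02148
  expect_equal(c1_from_modulus(0.02148, 0.5), 0.00358, tolerance = 1e-12)
  expect_equal(effective_modulus(0.00358, 0.5), 0.02148, tolerance = 1e-12)
  expect_equal(effective_modulus(0.00779, 0.5), 0.04674, tolerance = 1e-12)
  expect_equal(effective_modulus(0, 0.5), 0)
  # round trip to machine precision across the plausible range
  for (c1 in c(1e-4, 1e-3, 0.01, 0.1, 1)) {
    expect_equal(c1_from_modulus(effective_modulus(c1, 0.5), 0.5), c1,
                 tolerance = 1e-15)
    expect_equal(c1_from_modulus(effective_modulus(c1, 0.3), 0.3), c1,
                 tolerance = 1e-15)
  }
  expect_error(c1_from_modulus(-1), class = "tissuecal_invalid_material")
  expect_error(c1_from_modulus(1, nu = 0.7),
               class = "tissuecal_invalid_material")
})

test_that("energy and stress are homogeneous of degree 1 in (C1, K), and energy nonnegative", {
  set.seed(5)
  m <- material(0.006, k_ratio = 300)
  ms <- material(0.006 * 2.5, k_ratio = 300)
  for (i in 1:40) {
    F <- random_admissible_F()
    s <- deformation_state(F)
    w <- strain_energy(s, m)
    expect_gte(w, 0)
    expect_equal(strain_energy(s, ms), 2.5 * w, tolerance = 1e-12)
    expect_equal(cauchy_stress(s, ms), 2.5 * cauchy_stress(s, m),
                 tolerance = 1e-12)
  }
  # zero energy iff I1bar = 3 and J = 1 (undeformed up to rotation)
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(strain_energy(R, m), 0, tolerance = 1e-14)
  expect_gt(strain_energy(diag(c(1.01, 1, 1)), m), 0)
})

test_that("material constructor enforces the K coupling and defaults", {
  m <- material(0.004)
  expect_equal(m$k_ratio, 1000)
  expect_equal(m$k, 4)
  expect_equal(m$nu_effective, 0.5)
  m2 <- material(0.004, k = 2)
  expect_equal(m2$k_ratio, 500)
  expect_error(material(-1), class = "tissuecal_invalid_material")
  expect_error(material(0.01, k_ratio = 0),
               class = "tissuecal_invalid_material")
})
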