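test_that("assembly: zero and rigid-motion displacements give zero internal force", {
  m <- material(0.01, k_ratio = 100)
  mesh <- single_tet10()
  a0 <- assemble(mesh, m, numeric(30))
  expect_equal(a0$fint, numeric(30))
  expect_equal(a0$J_mean, 1, tolerance = 1e-12)
  # rigid translation: frame indifference
  u <- rep(c(0.3, -0.2, 0.5), 10)
  at <- assemble(mesh, m, u)
  expect_equal(at$fint, numeric(30), tolerance = 1e-12)
  expect_equal(at$energy, 0, tolerance = 1e-14)
})

test_that("internal force is the gradient of the stored energy", {
  m <- material(0.01, k_ratio = 50)
  for (mesh in list(single_tet4(), single_tet10())) {
    set.seed(21)
    nd <- 3 * nrow(mesh$nodes)
    u <- 0.03 * stats::rnorm(nd)
    a <- assemble(mesh, m, u)
    g <- num_grad(function(v) assemble(mesh, m, v, tangent = FALSE)$energy, u)
    expect_equal(a$fint, g, tolerance = 1e-5)
    # consistent tangent: symmetric, matches FD of the force
    K <- as.matrix(a$K)
    expect_equal(K, t(K), tolerance = 1e-10)
    v <- stats::rnorm(nd)
    h <- 1e-6
    fd <- (assemble(mesh, m, u + h * v, tangent = FALSE)$fint -
             assemble(mesh, m, u - h * v, tangent = FALSE)$fint) / (2 * h)
    expect_equal(as.numeric(a$K %*% v), fd, tolerance = 1e-5)
  }
})

test_that("element inversion is signalled, not crashed", {
  m <- material(0.01)
  mesh <- single_tet4()
  u <- numeric(12)
  u[10:12] <- -c(0, 0, 2)  # push apex through the base
  a <- assemble(mesh, m, u)
  expect_false(a$ok)
})

test_that("patch test: affine boundary displacement reproduces the homogeneous state", {
  m <- material(0.008, k_ratio = 200)
  mesh <- make_box_mesh(1, 1, 1, 2, 2, 2, order = 2)
  Fh <- diag(3) + rbind(c(0.02, 0.01, 0), c(0, -0.015, 0.005), c(0, 0, 0.01))
  bnd <- sort(unique(unlist(mesh$node_sets)))
  disp <- mesh$nodes[bnd, ] %*% t(Fh - diag(3))
  bc <- data.frame(node = rep(bnd, each = 3), dof = rep(1:3, length(bnd)),
                   value = as.vector(t(disp)))
  sol <- solve_static(mesh, m, bc, n_increments = 1)
  # interior nodes follow the affine map to solver precision
  interior <- setdiff(seq_len(nrow(mesh$nodes)), bnd)
  expect_equal(sol$u[interior, ],
               mesh$nodes[interior, ] %*% t(Fh - diag(3)),
               tolerance = 1e-8)
  # every element carries the same volume ratio det(Fh)
  expect_equal(sol$J_mean, rep(det(Fh), nrow(mesh$elements)),
               tolerance = 1e-8)
})

test_that("uniaxial compression matches the semi-analytic uncoupled solution", {
  # quadratic mesh, rollers on three faces, top face driven to lambda = 0.9
  m <- material(0.01, k_ratio = 1000)
  mesh <- make_box_mesh(1, 1, 1, 2, 2, 2, order = 2)
  ns <- mesh$node_sets
  bc <- rbind(
    data.frame(node = ns$xmin, dof = 1, value = 0),
    data.frame(node = ns$ymin, dof = 2, value = 0),
    data.frame(node = ns$zmin, dof = 3, value = 0),
    data.frame(node = ns$zmax, dof = 3, value = -0.1))
  sol <- solve_static(mesh, m, bc, n_increments = 5)
  Ffe <- sum(sol$reactions$force_n[sol$reactions$node %in% ns$zmax &
                                     sol$reactions$dof == 3])
  ana <- uniaxial_response(0.9, m)
  expect_equal(Ffe, ana$nominal_axial, tolerance = 1e-6)
  expect_equal(mean(sol$u[ns$xmax, 1]), ana$lambda_lateral - 1,
               tolerance = 1e-6)
})

test_that("zero probe displacement produces zero forces and fields", {
  mesh <- make_slab(nx = 2, ny = 2, nz = 1)
  probe <- probe_spec(face_center = c(10, 10, 10.5), face_normal = c(0, 0, -1),
                      face_half_lengths = c(6, 6), total_displacement = 0,
                      n_increments = 1)
  res <- solve_indentation(mesh, material(0.01), probe)
  expect_equal(res$curve$force, c(0, 0))
  expect_false(res$failed)
  sf <- surface_fields(res, 1)
  expect_equal(max(abs(sf$von_mises)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sf$contact_pressure)), 0)
  expect_equal(max_volume_change(res), 0, tolerance = 1e-8)
})

test_that("prescribed-patch reaction force is exactly linear in c1 with coupled k", {
  mesh <- make_slab(nx = 3, ny = 3, nz = 2)
  probe <- probe_spec(face_center = c(10, 10, 10), face_normal = c(0, 0, -1),
                      face_half_lengths = c(5, 5), total_displacement = 1.5,
                      n_increments = 3)
  r1 <- solve_indentation(mesh, material(0.004), probe,
                          contact_mode = "prescribed_patch",
                          store_fields = "none")
  r2 <- solve_indentation(mesh, material(0.008), probe,
                          contact_mode = "prescribed_patch",
                          store_fields = "none")
  expect_false(r1$failed || r2$failed)
  expect_equal(r2$curve$force, 2 * r1$curve$force, tolerance = 1e-6)
})

test_that("penalty indentation: monotone loading, compressive contact, frictionless resultant", {
  mesh <- small_phantom(edge = 13)
  probe <- phantom_probe(total = 4, n_inc = 5)
  res <- solve_indentation(mesh, material(0.005), probe, store_fields = "all")
  expect_false(res$failed)
  expect_equal(res$converged_increments, 5L)
  # strictly increasing displacement, one sample per increment plus zero
  expect_length(res$curve$displacement, 6L)
  expect_true(all(diff(res$curve$displacement) > 0))
  # reaction force non-decreasing for monotone probe advance
  expect_true(all(diff(res$curve$force) > -1e-9))
  # contact pressure >= 0 everywhere (compression-only)
  sf <- surface_fields(res)
  expect_gte(min(sf$contact_pressure), 0)
  expect_gt(max(sf$contact_pressure), 0)
  # frictionless: total contact force is normal to the probe face, so the
  # bone reaction resultant aligns with the indentation axis
  last <- res$increments[[res$converged_increments]]
  asmb <- assemble(mesh, material(0.005), as.vector(t(last$u)))
  bone <- mesh$node_sets$bone_fixed
  R <- colSums(matrix(asmb$fint, ncol = 3, byrow = TRUE)[bone, ])
  expect_lt(sqrt(R[2]^2 + R[3]^2), 1e-3 * abs(R[1]) + 1e-8)
})

test_that("symmetric indentation gives a symmetric contact pressure map", {
  mesh <- make_slab(lx = 20, ly = 20, lz = 8, nx = 4, ny = 4, nz = 2)
  probe <- probe_spec(face_center = c(10, 10, 8), face_normal = c(0, 0, -1),
                      face_half_lengths = c(4, 4), total_displacement = 1.2,
                      n_increments = 3)
  res <- solve_indentation(mesh, material(0.006), probe)
  sf <- surface_fields(res)
  xy <- mesh$nodes[sf$nodes, 1:2]
  # mirror about x = 10: pressures at mirrored skin nodes agree
  key <- paste(round(xy[, 1] - 10, 6), round(xy[, 2], 6))
  mirror <- paste(round(10 - xy[, 1], 6), round(xy[, 2], 6))
  idx <- match(mirror, key)
  ok <- !is.na(idx)
  expect_gt(sum(ok), 10)
  expect_equal(sf$contact_pressure[idx[ok]], sf$contact_pressure[ok],
               tolerance = 1e-4)
})

test_that("a tilted probe concentrates effective stress on its leading edge", {
  mesh <- make_slab(lx = 20, ly = 20, lz = 8, nx = 4, ny = 4, nz = 2)
  # face normal tilted about y: leading edge at larger x
  nrm <- c(0.25, 0, -1); nrm <- nrm / sqrt(sum(nrm^2))
  probe <- probe_spec(face_center = c(10, 10, 8.8), face_normal = nrm,
                      face_half_lengths = c(4, 4),
                      displacement_axis = c(0, 0, -1),
                      total_displacement = 2.2, n_increments = 4,
                      face_axis1 = c(1, 0, 0))
  res <- solve_indentation(mesh, material(0.006), probe)
  expect_false(res$failed)
  sf <- surface_fields(res)
  # the tilted face touches the x < 10 side of the footprint first, so the
  # effective stress concentrates there
  x <- mesh$nodes[sf$nodes, 1]
  lead <- sf$von_mises[x < 10 & x >= 5]
  trail <- sf$von_mises[x > 10 & x <= 15]
  expect_gt(max(lead), max(trail))
})

test_that("solver reports partial results when the probe is driven too deep", {
  mesh <- small_phantom(edge = 14, length = 24)
  # drive almost through the whole 21 mm tissue: must fail part-way
  probe <- probe_spec(face_center = c(41, 0, 12), face_normal = c(-1, 0, 0),
                      face_half_lengths = c(10, 5), total_displacement = 20,
                      n_increments = 8)
  res <- solve_indentation(mesh, material(0.005), probe,
                           store_fields = "none")
  expect_true(res$failed)
  expect_lt(res$converged_increments, 8L)
  expect_length(res$curve$force, res$converged_increments + 1L)
})
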