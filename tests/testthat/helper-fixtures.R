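# fixtures built in code: tiny meshes and reference states

single_tet4 <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1, 4))
}

single_tet10 <- function() tet4_to_tet10(single_tet4())

# slab with indentation-style node sets: bone at zmin, skin at zmax
make_slab <- function(lx = 20, ly = 20, lz = 10, nx = 4, ny = 4, nz = 2,
                      order = 2) {
  m <- make_box_mesh(lx, ly, lz, nx, ny, nz, order = order)
  tet_mesh(m$nodes, m$elements,
           list(bone_fixed = m$node_sets$zmin,
                skin_surface = m$node_sets$zmax))
}

small_phantom <- function(edge = 12, length = 30, order = 2) {
  make_limb_phantom(phantom_spec(40, 19, length, edge), order = order)
}

phantom_probe <- function(total = 5, n_inc = 6, length = 30) {
  probe_spec(face_center = c(41, 0, length / 2), face_normal = c(-1, 0, 0),
             face_half_lengths = c(12, 5), total_displacement = total,
             n_increments = n_inc)
}

# numeric gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

random_admissible_F <- function(scale = 0.2) {
  repeat {
    F <- diag(3) + scale * matrix(stats::runif(9, -1, 1), 3, 3)
    if (det(F) > 0.2) return(F)
  }
}
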