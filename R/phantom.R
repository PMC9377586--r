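#' Limb phantom specification
#'
#' An annular cylinder of flesh around a rigid bone: the synthetic stand-in
#' geometry for a limb segment. Defaults give a soft-tissue thickness of
#' 21 mm (outer radius 40 mm, bone radius 19 mm), the scale of an adult
#' upper-leg indentation site, so indentation depths up to ~30% of the
#' tissue thickness are exercisable.
#'
#' @param outer_radius skin radius, mm.
#' @param bone_radius bone radius, mm (0 < bone < outer).
#' @param length cylinder length, mm.
#' @param target_edge_length requested element edge length, mm.
#' @return `tc_phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 40, bone_radius = 19, length = 80,
                         target_edge_length = 8) {
  if (!(bone_radius > 0 && bone_radius < outer_radius))
    tc_stop("need 0 < bone_radius < outer_radius", "tissuecal_invalid_phantom")
  if (length <= 0 || target_edge_length <= 0)
    tc_stop("'length' and 'target_edge_length' must be positive",
            "tissuecal_invalid_phantom")
  structure(list(outer_radius = outer_radius, bone_radius = bone_radius,
                 length = length, target_edge_length = target_edge_length),
            class = "tc_phantom_spec")
}

#' Generate an annular-cylinder limb phantom mesh
#'
#' Builds a structured cylindrical grid (radial x circumferential x axial),
#' splits every hexahedral cell into six tetrahedra (Kuhn subdivision, which
#' is conforming on structured grids including the circumferential seam) and
#' optionally promotes to quadratic tet10 elements. Node sets: `bone_fixed`
#' is the inner cylindrical surface, `skin_surface` the outer.
#'
#' @param spec a [phantom_spec()].
#' @param order element order, 1 (tet4) or 2 (tet10).
#' @return a [tet_mesh()].
#' @export
make_limb_phantom <- function(spec = phantom_spec(), order = 2) {
  stopifnot(inherits(spec, "tc_phantom_spec"), order %in% c(1, 2))
  R <- spec$outer_radius; r <- spec$bone_radius
  L <- spec$length; h <- spec$target_edge_length
  nr <- max(2L, as.integer(round((R - r) / h)))
  nt <- max(12L, as.integer(round(2 * pi * (R + r) / 2 / h)))
  nz <- max(2L, as.integer(round(L / h)))
  if ((nr + 1L) * nt * (nz + 1L) > 2e6)
    tc_stop("target_edge_length too small for this phantom",
            "tissuecal_meshing_failure")

  # vertex grid; theta periodic
  vid <- function(ir, it, iz) {           # 1-based grid index
    it <- it %% nt
    1L + ir + (nr + 1L) * (it + nt * iz)
  }
  radii <- r + (R - r) * (0:nr) / nr
  theta <- 2 * pi * (0:(nt - 1)) / nt
  zs <- L * (0:nz) / nz
  nodes <- matrix(0, (nr + 1L) * nt * (nz + 1L), 3L)
  for (iz in 0:nz) for (it in 0:(nt - 1)) for (ir in 0:nr) {
    nodes[vid(ir, it, iz), ] <- c(radii[ir + 1] * cos(theta[it + 1]),
                                  radii[ir + 1] * sin(theta[it + 1]),
                                  zs[iz + 1])
  }

  # six tets per hex, all sharing the v0-v6 diagonal
  kuhn <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
                c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6)) + 1L
  elems <- matrix(0L, 6L * nr * nt * nz, 4L)
  e <- 0L
  for (iz in 0:(nz - 1)) for (it in 0:(nt - 1)) for (ir in 0:(nr - 1)) {
    v <- c(vid(ir, it, iz),     vid(ir + 1, it, iz),
           vid(ir + 1, it + 1, iz), vid(ir, it + 1, iz),
           vid(ir, it, iz + 1), vid(ir + 1, it, iz + 1),
           vid(ir + 1, it + 1, iz + 1), vid(ir, it + 1, iz + 1))
    for (k in 1:6) {
      e <- e + 1L
      elems[e, ] <- v[kuhn[k, ]]
    }
  }
  # enforce positive orientation
  vol <- tet_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  if (any(tet_volumes(nodes, elems) <= 0))
    tc_stop("phantom meshing produced degenerate elements",
            "tissuecal_meshing_failure")

  rad <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  eps <- 1e-9 * R
  sets <- list(bone_fixed = which(rad < r + eps),
               skin_surface = which(rad > R - eps))
  m <- tet_mesh(nodes, elems, sets)
  if (order == 2) m <- tet4_to_tet10(m)
  m
}

#' Structured box mesh
#'
#' Axis-aligned box `[0,lx] x [0,ly] x [0,lz]` meshed with the same Kuhn
#' hex-to-tet subdivision as the phantom. Node sets name the six faces
#' (`xmin`, `xmax`, ..., `zmax`). Used for verification against homogeneous
#' closed-form states (patch tests, uniaxial compression).
#'
#' @param lx,ly,lz box dimensions, mm.
#' @param nx,ny,nz cells per direction.
#' @param order element order, 1 or 2.
#' @return a [tet_mesh()].
#' @export
make_box_mesh <- function(lx = 1, ly = 1, lz = 1, nx = 2, ny = 2, nz = 2,
                          order = 2) {
  stopifnot(order %in% c(1, 2), nx >= 1, ny >= 1, nz >= 1)
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  nodes <- matrix(0, (nx + 1L) * (ny + 1L) * (nz + 1L), 3L)
  for (k in 0:nz) for (j in 0:ny) for (i in 0:nx)
    nodes[vid(i, j, k), ] <- c(lx * i / nx, ly * j / ny, lz * k / nz)
  kuhn <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
                c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6)) + 1L
  elems <- matrix(0L, 6L * nx * ny * nz, 4L)
  e <- 0L
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    v <- c(vid(i, j, k), vid(i + 1, j, k), vid(i + 1, j + 1, k),
           vid(i, j + 1, k), vid(i, j, k + 1), vid(i + 1, j, k + 1),
           vid(i + 1, j + 1, k + 1), vid(i, j + 1, k + 1))
    for (q in 1:6) { e <- e + 1L; elems[e, ] <- v[kuhn[q, ]] }
  }
  vol <- tet_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  eps <- 1e-9 * max(lx, ly, lz)
  sets <- list(xmin = which(nodes[, 1] < eps),
               xmax = which(nodes[, 1] > lx - eps),
               ymin = which(nodes[, 2] < eps),
               ymax = which(nodes[, 2] > ly - eps),
               zmin = which(nodes[, 3] < eps),
               zmax = which(nodes[, 3] > lz - eps))
  m <- tet_mesh(nodes, elems, sets)
  if (order == 2) m <- tet4_to_tet10(m)
  m
}
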