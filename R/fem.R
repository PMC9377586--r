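#' Rigid flat-probe specification
#'
#' The probe is a rigid rectangle (the ultrasound-probe face), displaced
#' along a straight line without rotation. `face_normal` points into the
#' tissue; `face_half_lengths` are the two in-plane half-dimensions of the
#' footprint (defaults 25 x 5 mm, i.e. a 50 x 10 mm face).
#'
#' @param face_center 3D point on the probe face, mm.
#' @param face_normal unit vector into the tissue (normalised here).
#' @param face_half_lengths two in-plane half-dimensions, mm.
#' @param displacement_axis unit vector of probe motion; defaults to
#'   `face_normal`.
#' @param total_displacement total probe advance, mm (> 0).
#' @param n_increments number of displacement increments (default 100, i.e.
#'   advances of 0.01 of the total displacement).
#' @param face_axis1 optional in-plane direction for the first half-length;
#'   a deterministic perpendicular is chosen if omitted.
#' @return `tc_probe`.
#' @export
probe_spec <- function(face_center, face_normal,
                       face_half_lengths = c(25, 5),
                       displacement_axis = NULL,
                       total_displacement, n_increments = 100,
                       face_axis1 = NULL) {
  face_center <- as.numeric(face_center)
  n <- as.numeric(face_normal)
  n <- n / sqrt(sum(n^2))
  if (is.null(displacement_axis)) displacement_axis <- n
  a <- as.numeric(displacement_axis)
  a <- a / sqrt(sum(a^2))
  if (total_displacement < 0)
    tc_stop("'total_displacement' must be >= 0", "tissuecal_invalid_probe")
  if (n_increments < 1L)
    tc_stop("'n_increments' must be >= 1", "tissuecal_invalid_probe")
  if (is.null(face_axis1)) {
    face_axis1 <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  }
  t1 <- face_axis1 - sum(face_axis1 * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  structure(list(face_center = face_center, face_normal = n,
                 face_half_lengths = as.numeric(face_half_lengths),
                 displacement_axis = a,
                 total_displacement = total_displacement,
                 n_increments = as.integer(n_increments),
                 t1 = t1, t2 = t2),
            class = "tc_probe")
}

#' Assemble internal force, tangent stiffness and volume ratios
#'
#' Total-Lagrangian assembly of the uncoupled Neo-Hookean mesh at nodal
#' displacements `u`. The internal force is the gradient of the total
#' stored energy with respect to `u`; the tangent is the consistent
#' (symmetric) stiffness.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [material()].
#' @param u nodal displacement vector, length `3 * n_nodes` (node-major:
#'   `(u1x,u1y,u1z,u2x,...)`), or an `n x 3` matrix.
#' @param tangent assemble the stiffness matrix too?
#' @return list with `fint` (length-3n vector), `K` (sparse `dgCMatrix`, or
#'   `NULL`), `J_mean` and `J_dev` (per-element volume ratio and max
#'   `|J - 1|` over quadrature points), `energy` (total stored energy,
#'   N mm), and `ok` (`FALSE` signals element inversion, for step cutting).
#' @export
assemble <- function(mesh, mat, u, tangent = TRUE) {
  n <- nrow(mesh$nodes)
  if (is.matrix(u)) u <- as.vector(t(u))
  if (length(u) != 3L * n || any(!is.finite(u)))
    tc_stop("'u' must be a finite vector of length 3 * n_nodes",
            "tissuecal_invalid_input")
  res <- tc_assemble_core(mesh$nodes, mesh$elements, u, mat$c1, mat$k,
                          tangent)
  K <- NULL
  if (res$ok && tangent)
    K <- Matrix::sparseMatrix(i = res$k_i, j = res$k_j, x = res$k_x,
                              dims = c(3L * n, 3L * n))
  list(fint = as.numeric(res$fint), K = K, J_mean = as.numeric(res$J_mean),
       J_dev = as.numeric(res$J_dev), energy = res$energy, ok = res$ok)
}

# contact evaluation: probe face advanced by `adv` along the axis.
# Returns active node ids, penetrations and an edge-taper weight that takes
# the penalty force smoothly to zero at the footprint boundary (a hard
# cutoff makes the residual discontinuous when a penetrated node slides
# across the rectangle edge, which defeats Newton).
probe_contact <- function(mesh, probe, u, adv, candidates,
                          edge_margin = 0.1) {
  ctr <- probe$face_center + adv * probe$displacement_axis
  x <- mesh$nodes[candidates, , drop = FALSE] +
    matrix(u, ncol = 3, byrow = TRUE)[candidates, , drop = FALSE]
  rel <- sweep(x, 2, ctr)
  g <- rel %*% probe$face_normal
  s1 <- rel %*% probe$t1
  s2 <- rel %*% probe$t2
  hl <- probe$face_half_lengths
  smooth <- function(s, h) {
    t <- pmin(pmax((h - abs(s)) / (edge_margin * h), 0), 1)
    t * t * (3 - 2 * t)               # cubic smoothstep
  }
  w <- smooth(s1, hl[1]) * smooth(s2, hl[2])
  act <- which(g < 0 & w > 0)
  list(nodes = candidates[act], pen = -g[act], w = w[act])
}

# patch nodes for prescribed_patch mode: skin nodes inside the footprint
patch_nodes <- function(mesh, probe) {
  cand <- mesh$node_sets$skin_surface
  rel <- sweep(mesh$nodes[cand, , drop = FALSE], 2, probe$face_center)
  s1 <- rel %*% probe$t1
  s2 <- rel %*% probe$t2
  cand[abs(s1) <= probe$face_half_lengths[1] &
         abs(s2) <= probe$face_half_lengths[2]]
}

#' Displacement-driven indentation simulation
#'
#' Advances a rigid probe into the mesh in equal increments of the total
#' displacement, solving static equilibrium by Newton's method at each
#' increment (with step halving down to 1/64 of an increment on
#' non-convergence). The bone node set is fixed. Two contact modes:
#' \describe{
#'   \item{`penalty`}{frictionless node-to-rigid-plane penalty contact
#'     against the probe face, active inside the rectangular footprint.
#'     The penalty stiffness is `penalty_scale * c1 * h` (N/mm per node),
#'     `h` the characteristic element length.}
#'   \item{`prescribed_patch`}{skin nodes under the footprint move with the
#'     probe. Constraints are material-independent, so at fixed increments
#'     the reaction force is exactly linear in `c1` when `k = k_ratio*c1`.}
#' }
#' The reaction force is the component of the total contact (or constraint)
#' force along the displacement axis.
#'
#' @param mesh a [tet_mesh()] with `bone_fixed` and `skin_surface` sets.
#' @param mat a [material()].
#' @param probe a [probe_spec()].
#' @param contact_mode `"penalty"` or `"prescribed_patch"`.
#' @param newton_tol relative residual tolerance.
#' @param max_newton Newton iterations per (sub)step.
#' @param penalty_scale dimensionless penalty scaling factor (default 100).
#' @param store_fields `"all"`, `"last"` or `"none"`: which increments keep
#'   full deformation fields.
#' @param verbose print per-increment progress.
#' @return `tc_simulation` with `curve` (simulated [indentation_curve()]
#'   including the zero state), `increments` (list of per-increment records:
#'   `displacement`, `force`, and optionally `u`, `J`, `J_dev`,
#'   `contact_nodes`, `contact_forces`), `converged_increments`, `failed`,
#'   `mesh`, `probe`, `material`, `contact_mode`.
#' @export
solve_indentation <- function(mesh, mat, probe,
                              contact_mode = c("penalty", "prescribed_patch"),
                              newton_tol = 1e-6, max_newton = 50,
                              penalty_scale = 100,
                              store_fields = c("all", "last", "none"),
                              verbose = FALSE) {
  contact_mode <- match.arg(contact_mode)
  store_fields <- match.arg(store_fields)
  if (is.null(mesh$node_sets$bone_fixed) ||
      !length(mesh$node_sets$bone_fixed))
    tc_stop("'bone_fixed' node set is empty", "tissuecal_invalid_mesh")
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  fixed_nodes <- mesh$node_sets$bone_fixed
  fixed_dofs <- as.vector(t(outer(3L * (fixed_nodes - 1L), 1:3, `+`)))
  skin <- mesh$node_sets$skin_surface
  h_char <- characteristic_length(mesh)
  k_pen <- penalty_scale * mat$c1 * h_char
  du_cap <- 0.2 * h_char
  patch <- if (contact_mode == "prescribed_patch") patch_nodes(mesh, probe)
  patch_dofs <- if (contact_mode == "prescribed_patch")
    as.vector(t(outer(3L * (patch - 1L), 1:3, `+`)))

  u <- numeric(ndof)
  increments <- vector("list", probe$n_increments)
  d_target <- probe$total_displacement * seq_len(probe$n_increments) /
    probe$n_increments
  d_cur <- 0
  failed <- FALSE
  n_conv <- 0L

  solve_at <- function(u, adv) {
    # returns list(u, ok, contact=list(nodes, pen)); Newton at advance `adv`
    if (contact_mode == "prescribed_patch") {
      du <- adv * probe$displacement_axis
      u[patch_dofs] <- rep(du, times = length(patch))
    }
    constrained <- if (contact_mode == "prescribed_patch")
      c(fixed_dofs, patch_dofs) else fixed_dofs
    free <- setdiff(seq_len(ndof), constrained)
    # residual (with contact forces) at displacements `uu`
    residual_at <- function(uu, tangent) {
      asm <- assemble(mesh, mat, uu, tangent = tangent)
      if (!asm$ok) return(list(ok = FALSE))
      r <- -asm$fint
      con <- list(nodes = integer(0), pen = numeric(0))
      if (contact_mode == "penalty") {
        con <- probe_contact(mesh, probe, uu, adv, skin)
        if (length(con$nodes)) {
          fdir <- probe$face_normal
          for (ii in seq_along(con$nodes)) {
            dofs <- 3L * (con$nodes[ii] - 1L) + 1:3
            r[dofs] <- r[dofs] + k_pen * con$w[ii] * con$pen[ii] * fdir
          }
        }
      }
      list(ok = TRUE, r = r, rn = sqrt(sum(r[free]^2)), asm = asm, con = con)
    }
    ref_res <- NA_real_
    st <- residual_at(u, tangent = TRUE)
    for (it in seq_len(max_newton)) {
      if (!st$ok) return(list(ok = FALSE))
      if (is.na(ref_res)) ref_res <- max(st$rn, k_pen * 1e-3, 1e-8)
      if (st$rn <= newton_tol * ref_res || st$rn < 1e-12)
        return(list(ok = TRUE, u = u, contact = st$con, fint = st$asm$fint,
                    J_mean = st$asm$J_mean, J_dev = st$asm$J_dev))
      K <- st$asm$K
      if (contact_mode == "penalty" && length(st$con$nodes)) {
        nvec <- probe$face_normal
        blk0 <- k_pen * (nvec %o% nvec)
        ci <- cj <- cx <- numeric(0)
        for (ii in seq_along(st$con$nodes)) {
          dofs <- 3L * (st$con$nodes[ii] - 1L) + 1:3
          ci <- c(ci, rep(dofs, each = 3))
          cj <- c(cj, rep(dofs, times = 3))
          cx <- c(cx, as.vector(st$con$w[ii] * blk0))
        }
        K <- K + Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                                      dims = c(ndof, ndof))
      }
      Kff <- K[free, free, drop = FALSE]
      du_f <- tryCatch(
        as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff), st$r[free])),
        error = function(e) NULL)
      if (is.null(du_f) || any(!is.finite(du_f))) return(list(ok = FALSE))
      mx <- max(abs(du_f))              # trust-region-style step cap
      if (mx > du_cap) du_f <- du_f * (du_cap / mx)
      # backtracking line search on the residual norm
      accepted <- FALSE
      for (s in 2^(0:-5)) {
        u_try <- u
        u_try[free] <- u_try[free] + s * du_f
        st_try <- residual_at(u_try, tangent = TRUE)
        if (st_try$ok && st_try$rn < st$rn) {
          u <- u_try; st <- st_try; accepted <- TRUE
          break
        }
      }
      if (!accepted) return(list(ok = FALSE))
    }
    list(ok = FALSE)
  }

  for (i in seq_len(probe$n_increments)) {
    target <- d_target[i]
    step <- target - d_cur
    min_step <- (probe$total_displacement / probe$n_increments) / 64
    sol <- NULL
    while (d_cur < target - 1e-12) {
      attempt <- min(step, target - d_cur)
      res <- solve_at(u, d_cur + attempt)
      if (res$ok) {
        u <- res$u
        d_cur <- d_cur + attempt
        sol <- res
      } else {
        step <- attempt / 2
        if (step < min_step) { failed <- TRUE; break }
      }
    }
    if (failed) break
    if (probe$total_displacement == 0)
      sol <- solve_at(u, 0)
    # reaction force along the displacement axis
    if (contact_mode == "penalty") {
      force <- if (length(sol$contact$nodes))
        sum(k_pen * sol$contact$w * sol$contact$pen) *
          sum(probe$face_normal * probe$displacement_axis) else 0
      cforce <- k_pen * sol$contact$w * sol$contact$pen
    } else {
      force <- sum(matrix(sol$fint, ncol = 3, byrow = TRUE)[patch, ,
                                                            drop = FALSE] %*%
                     probe$displacement_axis)
      cforce <- as.numeric(
        matrix(sol$fint, ncol = 3, byrow = TRUE)[patch, , drop = FALSE] %*%
          probe$face_normal)
    }
    rec <- list(displacement = d_cur, force = force)
    keep <- store_fields == "all" ||
      (store_fields == "last" && i == probe$n_increments)
    if (keep) {
      rec$u <- matrix(u, ncol = 3, byrow = TRUE)
      rec$J <- sol$J_mean
      rec$J_dev <- sol$J_dev
      rec$contact_nodes <- if (contact_mode == "penalty") sol$contact$nodes
        else patch
      rec$contact_forces <- cforce
    }
    increments[[i]] <- rec
    n_conv <- i
    if (verbose)
      message(sprintf("  increment %d/%d: d = %.4g mm, F = %.5g N",
                      i, probe$n_increments, d_cur, force))
  }

  increments <- increments[seq_len(n_conv)]
  curve <- indentation_curve(
    c(0, vapply(increments, `[[`, numeric(1), "displacement")),
    c(0, vapply(increments, `[[`, numeric(1), "force")),
    source = "simulated")
  structure(list(curve = curve, increments = increments,
                 converged_increments = n_conv,
                 failed = failed, mesh = mesh, probe = probe, material = mat,
                 contact_mode = contact_mode, k_pen = k_pen,
                 store_fields = store_fields),
            class = "tc_simulation")
}

#' @export
print.tc_simulation <- function(x, ...) {
  cat(sprintf("Indentation simulation (%s contact): %d/%d increments%s\n",
              x$contact_mode, x$converged_increments,
              x$probe$n_increments,
              if (x$failed) " [FAILED EARLY]" else ""))
  if (x$converged_increments > 0)
    cat(sprintf("  final: d = %.4g mm, F = %.5g N\n",
                max(x$curve$displacement), x$curve$force[length(x$curve$force)]))
  invisible(x)
}

#' Maximum element volume change
#'
#' Maximum over elements and stored increments of `|J - 1| * 100` (percent),
#' the guardrail used to judge enforcement of near-incompressibility.
#'
#' @param result a `tc_simulation` with stored fields.
#' @return percent volume change (scalar).
#' @export
max_volume_change <- function(result) {
  stopifnot(inherits(result, "tc_simulation"))
  if (result$converged_increments == 0L) return(0)
  devs <- vapply(result$increments, function(r)
    if (!is.null(r$J_dev)) max(r$J_dev) else NA_real_, numeric(1))
  devs <- devs[!is.na(devs)]
  if (!length(devs))
    tc_stop("no stored fields; rerun with store_fields != 'none'",
            "tissuecal_invalid_input")
  100 * max(devs)
}

#' Surface stress and contact pressure maps
#'
#' Von Mises (effective) stress extrapolated to the skin-surface nodes
#' (volume-weighted average of adjacent-element quadrature stresses) and
#' contact pressure (normal contact traction magnitude, zero outside the
#' active contact set; non-negative by construction for frictionless
#' compression-only contact).
#'
#' @param result a `tc_simulation` with stored fields.
#' @param increment increment index (default: last stored).
#' @return list with `nodes` (skin-surface node ids), `von_mises` (MPa) and
#'   `contact_pressure` (MPa) per skin node.
#' @export
surface_fields <- function(result, increment = result$converged_increments) {
  stopifnot(inherits(result, "tc_simulation"))
  if (increment < 1L || increment > result$converged_increments)
    tc_stop("increment not converged or out of range",
            "tissuecal_invalid_input")
  rec <- result$increments[[increment]]
  if (is.null(rec$u))
    tc_stop("fields were not stored for this increment",
            "tissuecal_invalid_input")
  mesh <- result$mesh
  mat <- result$material
  u <- as.vector(t(rec$u))
  st <- tc_element_stress_core(mesh$nodes, mesh$elements, u, mat$c1, mat$k)
  s <- st$stress
  vm_el <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                         (s[, 3] - s[, 1])^2) +
                  3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  vols <- tet_volumes(mesh$nodes, mesh$elements)
  skin <- mesh$node_sets$skin_surface
  # volume-weighted nodal average over adjacent elements
  num <- numeric(nrow(mesh$nodes)); den <- numeric(nrow(mesh$nodes))
  nn <- ncol(mesh$elements)
  for (a in seq_len(nn)) {
    idx <- mesh$elements[, a]
    num_add <- vm_el * vols
    num <- num + unname(tapply_add(idx, num_add, nrow(mesh$nodes)))
    den <- den + unname(tapply_add(idx, vols, nrow(mesh$nodes)))
  }
  vm_node <- ifelse(den > 0, num / den, 0)

  # contact pressure: nodal normal force / tributary surface area
  pressure <- numeric(nrow(mesh$nodes))
  if (length(rec$contact_nodes)) {
    faces <- boundary_faces(mesh)
    on_skin <- matrix(faces %in% skin, nrow = nrow(faces))
    faces <- faces[rowSums(on_skin) == 3L, , drop = FALSE]
    area <- numeric(nrow(mesh$nodes))
    if (nrow(faces)) {
      a <- mesh$nodes[faces[, 1], , drop = FALSE]
      b <- mesh$nodes[faces[, 2], , drop = FALSE]
      c_ <- mesh$nodes[faces[, 3], , drop = FALSE]
      u1 <- b - a; v1 <- c_ - a
      cr <- cbind(u1[, 2] * v1[, 3] - u1[, 3] * v1[, 2],
                  u1[, 3] * v1[, 1] - u1[, 1] * v1[, 3],
                  u1[, 1] * v1[, 2] - u1[, 2] * v1[, 1])
      fa <- 0.5 * sqrt(rowSums(cr^2))
      for (a_ in 1:3)
        area <- area + unname(tapply_add(faces[, a_], fa / 3,
                                         nrow(mesh$nodes)))
    }
    fn <- pmax(rec$contact_forces, 0)
    pressure[rec$contact_nodes] <-
      ifelse(area[rec$contact_nodes] > 0,
             fn / area[rec$contact_nodes], 0)
  }
  list(nodes = skin, von_mises = vm_node[skin],
       contact_pressure = pressure[skin])
}

# sum `vals` into bins `idx` over 1..n (dense scatter-add)
tapply_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Static solve under prescribed nodal displacements
#'
#' Lower-level entry point: incremental Newton solution with component-wise
#' Dirichlet boundary conditions (no contact). Used for verification
#' problems such as homogeneous patch tests and uniaxial compression, where
#' roller (single-component) constraints are required.
#'
#' @param mesh a [tet_mesh()].
#' @param mat a [material()].
#' @param bc data frame with columns `node` (1-based id), `dof` (1, 2 or 3
#'   for x/y/z) and `value` (total prescribed displacement, mm).
#' @param n_increments load increments over which `value` is ramped.
#' @param newton_tol relative residual tolerance.
#' @param max_newton Newton iterations per increment.
#' @return list with `u` (`n x 3` displacements), `reactions` (data frame
#'   `node`, `dof`, `force_n` at the constrained dofs), `J_mean`, `J_dev`,
#'   `converged`.
#' @export
solve_static <- function(mesh, mat, bc, n_increments = 5,
                         newton_tol = 1e-9, max_newton = 200) {
  stopifnot(all(c("node", "dof", "value") %in% names(bc)))
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  cdof <- 3L * (bc$node - 1L) + bc$dof
  if (anyDuplicated(cdof))
    tc_stop("duplicate boundary conditions", "tissuecal_invalid_input")
  free <- setdiff(seq_len(ndof), cdof)
  du_cap <- 0.2 * characteristic_length(mesh)
  u <- numeric(ndof)
  asm <- NULL
  for (inc in seq_len(n_increments)) {
    u[cdof] <- bc$value * inc / n_increments
    conv <- FALSE
    asm <- assemble(mesh, mat, u, tangent = TRUE)
    if (!asm$ok)
      tc_stop("element inversion during static solve",
              "tissuecal_solver_failure")
    rn <- sqrt(sum(asm$fint[free]^2))
    ref <- max(rn, 1e-10)
    for (it in seq_len(max_newton)) {
      if (rn <= newton_tol * ref || rn < 1e-12) { conv <- TRUE; break }
      Kff <- asm$K[free, free, drop = FALSE]
      du <- as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff),
                                     -asm$fint[free]))
      if (any(!is.finite(du)))
        tc_stop("linear solve failed", "tissuecal_solver_failure")
      mx <- max(abs(du))                # trust-region-style step cap
      if (mx > du_cap) du <- du * (du_cap / mx)
      accepted <- FALSE
      for (s in 2^(0:-5)) {          # backtracking on the residual norm
        u_try <- u
        u_try[free] <- u_try[free] + s * du
        asm_try <- assemble(mesh, mat, u_try, tangent = TRUE)
        if (asm_try$ok) {
          rn_try <- sqrt(sum(asm_try$fint[free]^2))
          if (rn_try < rn) {
            u <- u_try; asm <- asm_try; rn <- rn_try; accepted <- TRUE
            break
          }
        }
      }
      if (!accepted)
        tc_stop(sprintf("Newton stalled at increment %d", inc),
                "tissuecal_solver_failure")
    }
    if (!conv)
      tc_stop(sprintf("Newton did not converge at increment %d", inc),
              "tissuecal_solver_failure")
  }
  list(u = matrix(u, ncol = 3, byrow = TRUE),
       reactions = data.frame(node = bc$node, dof = bc$dof,
                              force_n = asm$fint[cdof]),
       J_mean = asm$J_mean, J_dev = asm$J_dev, converged = TRUE)
}
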