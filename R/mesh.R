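#' Tetrahedral mesh container
#'
#' A volume mesh of 4-node (linear) or 10-node (quadratic) tetrahedra with
#' named node sets. At minimum the sets `bone_fixed` (nodes clamped to the
#' rigid bone) and `skin_surface` (candidate contact nodes) are expected for
#' indentation runs; the two must be disjoint.
#'
#' Quadratic connectivity uses the VTK ordering: four vertices followed by
#' the mid-edge nodes of edges (1,2), (2,3), (1,3), (1,4), (2,4), (3,4).
#'
#' @param nodes numeric matrix `n x 3` of coordinates, mm.
#' @param elements integer matrix `ne x 4` or `ne x 10` of 1-based node ids.
#' @param node_sets named list of integer vectors.
#' @param validate check reference Jacobians and node-set sanity.
#' @return object of class `tc_mesh` with fields `nodes`, `elements`,
#'   `node_sets`, `element_order` (1 or 2).
#' @export
tet_mesh <- function(nodes, elements, node_sets = list(), validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L)
    tc_stop("'nodes' must be an n x 3 matrix", "tissuecal_invalid_mesh")
  nn <- ncol(elements)
  if (!nn %in% c(4L, 10L))
    tc_stop("'elements' must have 4 or 10 columns", "tissuecal_invalid_mesh")
  if (validate) {
    if (any(elements < 1L) || any(elements > nrow(nodes)))
      tc_stop("element connectivity references missing nodes",
              "tissuecal_invalid_mesh")
    for (nm in names(node_sets)) {
      ids <- node_sets[[nm]]
      if (any(ids < 1L) || any(ids > nrow(nodes)))
        tc_stop(sprintf("node set '%s' references missing nodes", nm),
                "tissuecal_invalid_mesh")
    }
    if (all(c("bone_fixed", "skin_surface") %in% names(node_sets)) &&
        length(intersect(node_sets$bone_fixed, node_sets$skin_surface)))
      tc_stop("'bone_fixed' and 'skin_surface' sets must be disjoint",
              "tissuecal_invalid_mesh")
    vol <- tet_volumes(nodes, elements)
    if (any(vol <= 0))
      tc_stop("mesh has non-positive reference Jacobians",
              "tissuecal_invalid_mesh")
  }
  structure(list(nodes = nodes, elements = elements,
                 node_sets = lapply(node_sets, function(s) sort(as.integer(s))),
                 element_order = if (nn == 4L) 1L else 2L),
            class = "tc_mesh")
}

#' @export
print.tc_mesh <- function(x, ...) {
  cat(sprintf("Tetrahedral mesh: %d nodes, %d %s elements\n",
              nrow(x$nodes), nrow(x$elements),
              if (x$element_order == 1L) "tet4" else "tet10"))
  for (nm in names(x$node_sets))
    cat(sprintf("  node set '%s': %d nodes\n", nm, length(x$node_sets[[nm]])))
  invisible(x)
}

# signed corner-tet volumes (uses vertex nodes only)
tet_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE]
  c_ <- nodes[elements[, 3], , drop = FALSE]
  d <- nodes[elements[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Total mesh volume
#' @param mesh a [tet_mesh()].
#' @return volume in mm^3 (corner-node geometry).
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh$nodes, mesh$elements))

# characteristic element length: cube root of mean element volume
characteristic_length <- function(mesh) {
  mean(tet_volumes(mesh$nodes, mesh$elements))^(1 / 3)
}

# boundary triangle faces (vertex-node triples) of the tet mesh
boundary_faces <- function(mesh) {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 3, 2)], el[, c(1, 2, 4)],
                 el[, c(2, 3, 4)], el[, c(1, 4, 3)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Promote a linear tet mesh to quadratic
#'
#' Inserts unique mid-edge nodes (VTK tet10 ordering). A mid-edge node joins
#' a node set iff both edge endpoints belong to it, so surface sets stay
#' coherent.
#'
#' @param mesh a `tc_mesh` of 4-node tets.
#' @return a `tc_mesh` of 10-node tets.
#' @export
tet4_to_tet10 <- function(mesh) {
  if (mesh$element_order != 1L)
    tc_stop("mesh is already quadratic", "tissuecal_invalid_mesh")
  el <- mesh$elements
  ne <- nrow(el)
  edge_local <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  n0 <- nrow(mesh$nodes)
  env <- new.env(hash = TRUE, parent = emptyenv())
  new_pts <- list()
  mid_of <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- env[[key]]
    if (is.null(id)) {
      id <- n0 + length(new_pts) + 1L
      new_pts[[length(new_pts) + 1L]] <<- (mesh$nodes[i, ] + mesh$nodes[j, ]) / 2
      env[[key]] <- id
      attr(env[[key]], "ends") <- NULL
    }
    id
  }
  el10 <- matrix(0L, ne, 10L)
  el10[, 1:4] <- el
  ends <- list()
  for (e in seq_len(ne)) {
    for (k in 1:6) {
      i <- el[e, edge_local[k, 1]]; j <- el[e, edge_local[k, 2]]
      id <- mid_of(i, j)
      el10[e, 4L + k] <- id
      ends[[id - n0]] <- c(i, j)
    }
  }
  nodes <- rbind(mesh$nodes, do.call(rbind, new_pts))
  sets <- lapply(mesh$node_sets, function(s) {
    extra <- which(vapply(ends, function(p) all(p %in% s), logical(1)))
    sort(c(s, n0 + extra))
  })
  tet_mesh(nodes, el10, sets)
}
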