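# Mesh readers/writers: Gmsh MSH (v2.2 ASCII read/write, v4.1 ASCII read)
# and legacy VTK ASCII unstructured grids. Node sets travel as physical
# groups of boundary triangles (MSH) or as 0/1 point-data arrays (VTK).

# VTK tet10 -> Gmsh tet10 differs only in the last two mid-edge nodes
vtk_to_gmsh_tet10 <- function(el) el[, c(1:8, 10, 9), drop = FALSE]
gmsh_to_vtk_tet10 <- vtk_to_gmsh_tet10  # involution

# boundary faces including mid-edge nodes for tet10 (rows of 3 or 6 ids)
boundary_faces_full <- function(mesh) {
  el <- mesh$elements
  if (mesh$element_order == 1L) {
    faces <- rbind(el[, c(1, 3, 2)], el[, c(1, 2, 4)],
                   el[, c(2, 3, 4)], el[, c(1, 4, 3)])
  } else {
    faces <- rbind(el[, c(1, 3, 2, 7, 6, 5)], el[, c(1, 2, 4, 5, 9, 8)],
                   el[, c(2, 3, 4, 6, 10, 9)], el[, c(1, 4, 3, 8, 10, 7)])
  }
  key <- apply(faces[, 1:3, drop = FALSE], 1,
               function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Read a tetrahedral mesh
#'
#' Supports Gmsh MSH ASCII (format 2.2 and 4.1) and legacy VTK ASCII
#' unstructured grids. Node sets are recovered from physical groups of
#' surface triangles (MSH) or from integer 0/1 point-data arrays (VTK).
#'
#' @param path file path (`.msh` or `.vtk`).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    tc_stop(sprintf("mesh file '%s' not found", path), "tissuecal_io_error")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = read_msh(path),
         vtk = read_vtk_mesh(path),
         tc_stop(sprintf("unsupported mesh format '.%s'", ext),
                 "tissuecal_io_error"))
}

#' Write a tetrahedral mesh
#'
#' @param mesh a [tet_mesh()].
#' @param path output path; `.msh` writes Gmsh 2.2 ASCII, `.vtk` legacy VTK.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = write_msh(mesh, path),
         vtk = write_vtk_mesh(mesh, path),
         tc_stop(sprintf("unsupported mesh format '.%s'", ext),
                 "tissuecal_io_error"))
  invisible(path)
}

write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sets <- mesh$node_sets
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  phys <- data.frame(dim = integer(), id = integer(), name = character())
  for (i in seq_along(sets))
    phys <- rbind(phys, data.frame(dim = 2L, id = i, name = names(sets)[i]))
  vol_id <- length(sets) + 1L
  phys <- rbind(phys, data.frame(dim = 3L, id = vol_id, name = "flesh"))
  wl("$PhysicalNames", as.character(nrow(phys)),
     sprintf("%d %d \"%s\"", phys$dim, phys$id, phys$name),
     "$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)),
     sprintf("%d %.12g %.12g %.12g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
     "$EndNodes")
  faces <- boundary_faces_full(mesh)
  face_lines <- character(0)
  eid <- 0L
  tri_type <- if (mesh$element_order == 1L) 2L else 9L
  for (i in seq_along(sets)) {
    in_set <- matrix(faces %in% sets[[i]], nrow = nrow(faces))
    sel <- faces[rowSums(in_set) == ncol(faces), , drop = FALSE]
    if (nrow(sel) == 0) next
    for (f in seq_len(nrow(sel))) {
      eid <- eid + 1L
      face_lines <- c(face_lines,
                      paste(c(eid, tri_type, 2L, i, i, sel[f, ]),
                            collapse = " "))
    }
  }
  el <- mesh$elements
  tet_type <- if (mesh$element_order == 1L) 4L else 11L
  if (mesh$element_order == 2L) el <- vtk_to_gmsh_tet10(el)
  tet_lines <- vapply(seq_len(nrow(el)), function(e)
    paste(c(eid + e, tet_type, 2L, vol_id, vol_id, el[e, ]), collapse = " "),
    character(1))
  wl("$Elements", as.character(length(face_lines) + nrow(el)),
     face_lines, tet_lines, "$EndElements")
  invisible(path)
}

msh_section <- function(lines, name) {
  i0 <- match(paste0("$", name), lines)
  i1 <- match(paste0("$End", name), lines)
  if (is.na(i0) || is.na(i1)) return(NULL)
  lines[(i0 + 1):(i1 - 1)]
}

read_msh <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  fmt <- msh_section(lines, "MeshFormat")
  if (is.null(fmt))
    tc_stop("not a Gmsh MSH file (missing $MeshFormat)", "tissuecal_io_error")
  ver <- as.numeric(strsplit(fmt[1], "\\s+")[[1]][1])
  binary <- as.integer(strsplit(fmt[1], "\\s+")[[1]][2]) != 0L
  if (binary)
    tc_stop("binary MSH files are not supported; export ASCII",
            "tissuecal_io_error")
  phys <- msh_section(lines, "PhysicalNames")
  phys_names <- list()
  if (!is.null(phys) && length(phys) > 1) {
    for (l in phys[-1]) {
      tok <- strsplit(l, "\\s+")[[1]]
      nm <- gsub('"', "", paste(tok[-(1:2)], collapse = " "))
      phys_names[[tok[2]]] <- nm
    }
  }
  if (ver < 3) read_msh_v2(lines, phys_names) else read_msh_v4(lines, phys_names)
}

read_msh_v2 <- function(lines, phys_names) {
  nd <- msh_section(lines, "Nodes")
  n <- as.integer(nd[1])
  ntab <- matrix(as.numeric(unlist(strsplit(nd[1 + seq_len(n)], "\\s+"))),
                 ncol = 4, byrow = TRUE)
  id_map <- integer(max(ntab[, 1]))
  id_map[ntab[, 1]] <- seq_len(n)
  nodes <- ntab[, 2:4, drop = FALSE]
  el <- msh_section(lines, "Elements")
  ne <- as.integer(el[1])
  sets <- list()
  tets <- list()
  order <- NA_integer_
  for (l in el[1 + seq_len(ne)]) {
    tok <- as.integer(strsplit(l, "\\s+")[[1]])
    type <- tok[2]; ntags <- tok[3]
    ptag <- if (ntags >= 1) tok[4] else NA_integer_
    conn <- id_map[tok[(4 + ntags):length(tok)]]
    if (type %in% c(2L, 9L)) {                  # tri3 / tri6 -> node set
      nm <- phys_names[[as.character(ptag)]]
      if (!is.null(nm)) sets[[nm]] <- c(sets[[nm]], conn)
    } else if (type %in% c(4L, 11L)) {          # tet4 / tet10
      order <- if (type == 4L) 1L else 2L
      tets[[length(tets) + 1L]] <- conn
    }
  }
  if (!length(tets))
    tc_stop("MSH file contains no tetrahedra", "tissuecal_io_error")
  elems <- do.call(rbind, tets)
  if (order == 2L) elems <- gmsh_to_vtk_tet10(elems)
  sets <- lapply(sets, function(s) sort(unique(s)))
  tet_mesh(nodes, elems, sets)
}

read_msh_v4 <- function(lines, phys_names) {
  # map surface/volume entities to physical tags
  ent <- msh_section(lines, "Entities")
  ent_phys <- list(s = list(), v = list())
  if (!is.null(ent)) {
    tok <- as.numeric(unlist(strsplit(ent, "\\s+")))
    p <- 1
    counts <- tok[p:(p + 3)]; p <- p + 4
    for (i in seq_len(counts[1])) {             # points: tag xyz nphys phys*
      np <- tok[p + 4]; p <- p + 5 + np
    }
    for (kind in c("c", "s", "v")) {
      kcount <- counts[match(kind, c("c", "s", "v")) + 1]
      for (i in seq_len(kcount)) {
        tag <- tok[p]; np <- tok[p + 7]
        ph <- if (np > 0) tok[(p + 8):(p + 7 + np)] else numeric(0)
        p <- p + 8 + np
        nb <- tok[p]; p <- p + 1 + nb
        if (kind %in% c("s", "v") && length(ph))
          ent_phys[[kind]][[as.character(tag)]] <- as.integer(ph[1])
      }
    }
  }
  nd <- msh_section(lines, "Nodes")
  tok <- as.numeric(unlist(strsplit(nd, "\\s+")))
  p <- 1
  nblocks <- tok[p]; ntotal <- tok[p + 1]; p <- p + 4
  ids <- integer(ntotal); coords <- matrix(0, ntotal, 3)
  at <- 0L
  for (b in seq_len(nblocks)) {
    nb <- tok[p + 3]; p <- p + 4
    if (nb > 0) {
      ids[at + seq_len(nb)] <- as.integer(tok[p:(p + nb - 1)]); p <- p + nb
      xyz <- matrix(tok[p:(p + 3 * nb - 1)], ncol = 3, byrow = TRUE)
      coords[at + seq_len(nb), ] <- xyz
      p <- p + 3 * nb
      at <- at + nb
    }
  }
  id_map <- integer(max(ids)); id_map[ids] <- seq_len(ntotal)
  el <- msh_section(lines, "Elements")
  tok <- as.numeric(unlist(strsplit(el, "\\s+")))
  p <- 1
  nblocks <- tok[p]; p <- p + 4
  npe <- c(`1` = 2, `2` = 3, `4` = 4, `9` = 6, `11` = 10, `15` = 1)
  sets <- list(); tets <- list(); order <- NA_integer_
  for (b in seq_len(nblocks)) {
    edim <- tok[p]; etag <- tok[p + 1]; etype <- tok[p + 2]; nb <- tok[p + 3]
    p <- p + 4
    k <- npe[[as.character(etype)]]
    if (is.null(k))
      tc_stop(sprintf("unsupported MSH element type %d", etype),
              "tissuecal_io_error")
    block <- matrix(tok[p:(p + nb * (1 + k) - 1)], ncol = 1 + k, byrow = TRUE)
    p <- p + nb * (1 + k)
    conn <- matrix(id_map[as.integer(block[, -1])], ncol = k)
    if (etype %in% c(2, 9)) {
      ph <- ent_phys$s[[as.character(etag)]]
      nm <- if (!is.null(ph)) phys_names[[as.character(ph)]] else NULL
      if (!is.null(nm)) sets[[nm]] <- c(sets[[nm]], as.integer(conn))
    } else if (etype %in% c(4, 11)) {
      order <- if (etype == 4) 1L else 2L
      tets[[length(tets) + 1L]] <- conn
    }
  }
  if (!length(tets))
    tc_stop("MSH file contains no tetrahedra", "tissuecal_io_error")
  elems <- do.call(rbind, tets)
  if (order == 2L) elems <- gmsh_to_vtk_tet10(elems)
  sets <- lapply(sets, function(s) sort(unique(s)))
  tet_mesh(coords, elems, sets)
}

write_vtk_mesh <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  nn <- ncol(mesh$elements)
  wl("# vtk DataFile Version 3.0", "tissuecal mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n),
     sprintf("%.12g %.12g %.12g", mesh$nodes[, 1], mesh$nodes[, 2],
             mesh$nodes[, 3]))
  wl(sprintf("CELLS %d %d", ne, ne * (nn + 1)),
     apply(cbind(nn, mesh$elements - 1L), 1, paste, collapse = " "))
  wl(sprintf("CELL_TYPES %d", ne),
     as.character(rep(if (nn == 4L) 10L else 24L, ne)))
  sets <- mesh$node_sets
  if (length(sets) || length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(sets)) {
      flag <- integer(n); flag[sets[[nm]]] <- 1L
      wl(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default",
         as.character(flag))
    }
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        wl(sprintf("VECTORS %s double", nm),
           sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
           sprintf("%.9g", v))
      }
    }
  }
  if (length(cell_data)) {
    wl(sprintf("CELL_DATA %d", ne))
    for (nm in names(cell_data))
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
         sprintf("%.9g", cell_data[[nm]]))
  }
  invisible(path)
}

read_vtk_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  up <- toupper(trimws(lines))
  if (any(grepl("^BINARY", up)))
    tc_stop("binary VTK files are not supported; export ASCII",
            "tissuecal_io_error")
  toks_after <- function(i) as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][-1])
  ip <- grep("^POINTS", up)[1]
  if (is.na(ip)) tc_stop("not a VTK unstructured grid", "tissuecal_io_error")
  n <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  vals <- numeric(0); i <- ip
  while (length(vals) < 3 * n) {
    i <- i + 1
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
  }
  nodes <- matrix(vals[1:(3 * n)], ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", up)[1]
  ne <- as.integer(strsplit(trimws(lines[ic]), "\\s+")[[1]][2])
  cell_tok <- as.integer(unlist(strsplit(trimws(lines[(ic + 1):(ic + ne)]),
                                         "\\s+")))
  p <- 1; conn <- vector("list", ne)
  for (e in seq_len(ne)) {
    k <- cell_tok[p]
    conn[[e]] <- cell_tok[(p + 1):(p + k)] + 1L
    p <- p + k + 1
  }
  nn <- unique(lengths(conn))
  if (length(nn) != 1 || !nn %in% c(4L, 10L))
    tc_stop("VTK file must contain only tet4 or tet10 cells",
            "tissuecal_io_error")
  elems <- do.call(rbind, conn)
  sets <- list()
  ipd <- grep("^POINT_DATA", up)[1]
  if (!is.na(ipd)) {
    j <- ipd + 1
    while (j <= length(lines)) {
      if (grepl("^SCALARS", up[j])) {
        nm <- strsplit(trimws(lines[j]), "\\s+")[[1]][2]
        typ <- strsplit(trimws(lines[j]), "\\s+")[[1]][3]
        j <- j + 2  # skip LOOKUP_TABLE
        vals <- numeric(0)
        while (length(vals) < n) {
          vals <- c(vals, as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
          j <- j + 1
        }
        if (tolower(typ) %in% c("int", "long", "short"))
          sets[[nm]] <- which(vals != 0)
      } else if (grepl("^CELL_DATA", up[j])) {
        break
      } else {
        j <- j + 1
      }
    }
  }
  tet_mesh(nodes, elems, sets)
}
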