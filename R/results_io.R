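#' Write simulation results to a directory
#'
#' Writes `curve.csv` (`increment,displacement_mm,force_n`), one legacy-VTK
#' field file per stored increment (`fields_####.vtk`: nodal displacement,
#' surface von Mises stress and contact pressure as point data, per-element
#' volume ratio `J` as cell data) and a JSON run manifest (`manifest.json`)
#' embedding the material, mesh statistics, the resolved configuration and
#' its hash.
#'
#' @param result a `tc_simulation` from [solve_indentation()].
#' @param dir output directory (created if missing).
#' @param config optional `tc_config` echoed into the manifest.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(result, dir, config = NULL) {
  stopifnot(inherits(result, "tc_simulation"))
  if (result$converged_increments == 0L)
    tc_stop("empty result: no converged increments to write",
            "tissuecal_invalid_input")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) tc_stop(sprintf("cannot create '%s'", dir), "tissuecal_io_error")
  files <- character(0)

  curve_path <- file.path(dir, "curve.csv")
  write_curve_csv(result$curve, curve_path)
  files <- c(files, curve_path)

  mesh <- result$mesh
  for (i in seq_along(result$increments)) {
    rec <- result$increments[[i]]
    if (is.null(rec$u)) next
    sf <- surface_fields(result, i)
    vm <- numeric(nrow(mesh$nodes)); vm[sf$nodes] <- sf$von_mises
    cp <- numeric(nrow(mesh$nodes)); cp[sf$nodes] <- sf$contact_pressure
    path <- file.path(dir, sprintf("fields_%04d.vtk", i))
    write_vtk_mesh(mesh, path,
                   point_data = list(displacement = rec$u,
                                     von_mises = vm,
                                     contact_pressure = cp),
                   cell_data = list(J = rec$J))
    files <- c(files, path)
  }

  cfg <- if (is.null(config)) run_config() else config
  cfg_plain <- unclass(cfg)
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    material = unclass(result$material),
    contact_mode = result$contact_mode,
    mesh = list(nodes = nrow(mesh$nodes), elements = nrow(mesh$elements),
                element_order = mesh$element_order,
                volume_mm3 = mesh_volume(mesh)),
    probe = unclass(result$probe),
    converged_increments = result$converged_increments,
    failed = result$failed,
    config = cfg_plain,
    config_md5 = cfg_hash)
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, man_path)
  invisible(files)
}

#' Bundled reference calibration results for eight extremity regions
#'
#' Region-by-region inverse-FEA calibration outcomes for the upper/lower
#' arms and legs of one male and one female donor (cadaver ultrasound
#' indentation): soft-tissue thickness at the indentation site, iterations
#' to convergence, final `C1`, coupled `K = 1000 C1`, and the implied
#' effective Young's modulus `E = 6 C1`.
#'
#' @return data frame with columns `sex`, `region`, `thickness_mm`,
#'   `iterations`, `c1_mpa`, `k_mpa`, `e_mpa`.
#' @export
extremity_regions <- function() {
  path <- system.file("extdata", "extremity_regions.csv",
                      package = "tissuecal", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
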