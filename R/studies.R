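#' Mesh-convergence protocol
#'
#' Runs the identical indentation on an ordered coarse-to-fine family of
#' meshes and reports, for each mesh with at least two finer successors,
#' the average percent change of the final probe reaction force relative to
#' the two next-finer meshes:
#' \deqn{m_i = \mathrm{mean}_{j \in \{i+1, i+2\}} |F_i - F_j| / F_i \times 100.}
#' A mesh is accepted (`converged_index`) when this metric first falls
#' below `threshold` (default 5%). The last two rows carry `NA` since no
#' two finer meshes exist. Published variants of this protocol do not
#' always state the averaging convention; the formula above is the one this
#' package implements and tests.
#'
#' @param meshes list of [tet_mesh()], strictly increasing element counts.
#' @param mat a [material()].
#' @param probe a [probe_spec()].
#' @param threshold acceptance threshold, percent.
#' @param ... passed to [solve_indentation()].
#' @return `tc_convergence`: data frame `rows` with `nodes`, `elements`,
#'   `force_n`, `avg_pct_diff`, `runtime_s`, `failed`; and
#'   `converged_index` (`NA` if none).
#' @export
mesh_convergence <- function(meshes, mat, probe, threshold = 5, ...) {
  if (length(meshes) < 3L)
    tc_stop("need at least 3 meshes", "tissuecal_invalid_input")
  ecount <- vapply(meshes, function(m) nrow(m$elements), integer(1))
  if (any(diff(ecount) <= 0))
    tc_stop("meshes must have strictly increasing element counts",
            "tissuecal_invalid_input")
  n <- length(meshes)
  force_n <- rep(NA_real_, n); runtime <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(solve_indentation(meshes[[i]], mat, probe,
                                      store_fields = "none", ...),
                    error = function(e) NULL)
    runtime[i] <- proc.time()[["elapsed"]] - t0
    if (is.null(res) || res$failed || res$converged_increments == 0L) {
      failed[i] <- TRUE
    } else {
      force_n[i] <- res$curve$force[length(res$curve$force)]
    }
  }
  metric <- convergence_metric(force_n, failed)
  rows <- data.frame(nodes = vapply(meshes, function(m) nrow(m$nodes),
                                    integer(1)),
                     elements = ecount, force_n = force_n,
                     avg_pct_diff = metric, runtime_s = runtime,
                     failed = failed)
  ok <- which(!is.na(metric) & metric < threshold)
  structure(list(rows = rows,
                 converged_index = if (length(ok)) ok[1] else NA_integer_,
                 threshold = threshold),
            class = "tc_convergence")
}

#' @export
print.tc_convergence <- function(x, ...) {
  cat(sprintf("Mesh convergence study (threshold %g%%)\n", x$threshold))
  print(x$rows, row.names = FALSE)
  if (is.na(x$converged_index)) cat("  no mesh met the threshold\n")
  else cat(sprintf("  converged at mesh %d\n", x$converged_index))
  invisible(x)
}

#' Average percent difference to the two next-finer meshes
#'
#' The acceptance metric of [mesh_convergence()]:
#' `m_i = mean_j |F_i - F_j| / F_i * 100` over `j = i+1, i+2`. `NA` where
#' fewer than two finer meshes exist or where a simulation failed.
#'
#' @param forces reaction forces, coarse to fine, N.
#' @param failed logical flags excluding rows from comparison.
#' @return numeric vector of metrics (percent), `NA` where undefined.
#' @export
convergence_metric <- function(forces, failed = rep(FALSE, length(forces))) {
  n <- length(forces)
  metric <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- (i + 1):(i + 2)
    if (max(js) > n || failed[i]) next
    js <- js[!failed[js]]
    if (length(js) < 2L) next
    metric[i] <- mean(abs(forces[i] - forces[js]) / forces[i]) * 100
  }
  metric
}

#' Bulk-ratio (K/C1) sensitivity sweep
#'
#' One indentation per ratio at fixed `c1`; reports the maximum element
#' volume change and the final reaction force. Larger ratios enforce
#' incompressibility more strongly (smaller volume change) and stiffen the
#' response (larger reaction force), at the cost of conditioning.
#'
#' @param mesh a [tet_mesh()].
#' @param c1 Neo-Hookean coefficient, MPa.
#' @param ratios positive K/C1 ratios (default `c(100, 1000, 10000)`).
#' @param probe a [probe_spec()].
#' @param ... passed to [solve_indentation()].
#' @return data frame with `k_ratio`, `max_volume_change_pct`, `force_n`,
#'   `runtime_s`, `failed`.
#' @export
k_ratio_sensitivity <- function(mesh, c1, ratios = c(100, 1000, 10000),
                                probe, ...) {
  if (any(ratios <= 0))
    tc_stop("ratios must be positive", "tissuecal_invalid_input")
  out <- data.frame(k_ratio = ratios, max_volume_change_pct = NA_real_,
                    force_n = NA_real_, runtime_s = NA_real_,
                    failed = FALSE)
  for (i in seq_along(ratios)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(solve_indentation(mesh, material(c1, k_ratio = ratios[i]),
                                      probe, store_fields = "all", ...),
                    error = function(e) NULL)
    out$runtime_s[i] <- proc.time()[["elapsed"]] - t0
    if (is.null(res) || res$failed || res$converged_increments == 0L) {
      out$failed[i] <- TRUE
    } else {
      out$max_volume_change_pct[i] <- max_volume_change(res)
      out$force_n[i] <- res$curve$force[length(res$curve$force)]
    }
  }
  out
}

#' Homogeneous uniaxial response of the uncoupled Neo-Hookean law
#'
#' Semi-analytic uniaxial solution at prescribed axial stretch: solves the
#' one-element homogeneous-deformation problem
#' \eqn{\sigma_{11}(\lambda_{lat}) = \sigma_{22} = 0} for the free lateral
#' stretch by scalar root finding, then reports stresses. Serves as an
#' independent oracle for displacement-driven FE compression tests.
#'
#' @param lambda_axial prescribed axial stretch (> 0).
#' @param mat a [material()].
#' @return list with `lambda_lateral`, `cauchy_axial` (MPa), `nominal_axial`
#'   (first Piola component, MPa = N/mm^2 of reference area), `J`.
#' @export
uniaxial_response <- function(lambda_axial, mat) {
  if (lambda_axial <= 0)
    tc_stop("'lambda_axial' must be > 0", "tissuecal_invalid_input")
  lat_stress <- function(lam) {
    Fm <- diag(c(lam, lam, lambda_axial))
    cauchy_stress(deformation_state(Fm), mat)[1, 1]
  }
  sol <- uniroot(lat_stress, lower = 1e-3, upper = 1e3,
                 tol = .Machine$double.eps^0.75)
  lam <- sol$root
  Fm <- diag(c(lam, lam, lambda_axial))
  sig <- cauchy_stress(deformation_state(Fm), mat)
  J <- det(Fm)
  list(lambda_lateral = lam, cauchy_axial = sig[3, 3],
       nominal_axial = J * sig[3, 3] / lambda_axial, J = J)
}
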