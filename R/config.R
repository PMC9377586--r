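#' Run configuration with workflow defaults
#'
#' The resolved settings controlling a simulation/calibration run:
#' \itemize{
#'   \item material: `c1_init = 0.01` MPa, `k_ratio = 1000`,
#'     `nu_effective = 0.5`;
#'   \item solver: `increments = 100` (0.01-ratio advances of the total
#'     displacement), `newton_tol = 1e-6`, `contact_mode = "penalty"`,
#'     `penalty_scale = 100`;
#'   \item calibration: `tol = 0.025` (2.5% slope criterion),
#'     `max_iter = 20`, `sim_displacement_factor = 1.5`;
#'   \item `seed = 1`.
#' }
#'
#' @param overrides named (possibly nested) list merged over the defaults.
#' @return nested list of class `tc_config`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    material = list(c1_init = 0.01, k_ratio = 1000, nu_effective = 0.5),
    solver = list(increments = 100L, newton_tol = 1e-6,
                  contact_mode = "penalty", penalty_scale = 100),
    calibration = list(tol = 0.025, max_iter = 20L,
                       sim_displacement_factor = 1.5),
    seed = 1L)
  cfg <- merge_config(cfg, overrides)
  if (cfg$material$c1_init <= 0 || cfg$material$k_ratio <= 0 ||
      cfg$solver$increments < 1 || cfg$calibration$tol <= 0)
    tc_stop("invalid configuration values", "tissuecal_invalid_config")
  class(cfg) <- "tc_config"
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a YAML configuration file
#'
#' Values present in the file override the [run_config()] defaults; all
#' other settings keep their defaults. Material keys: `c1_mpa` (alias of
#' `c1_init`), `k_ratio`, `nu_effective`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a `tc_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path))
    tc_stop(sprintf("config file '%s' not found", path), "tissuecal_io_error")
  y <- yaml::read_yaml(path)
  if (!is.null(y$material$c1_mpa)) {
    y$material$c1_init <- y$material$c1_mpa
    y$material$c1_mpa <- NULL
  }
  run_config(y)
}
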