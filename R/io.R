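# Configuration (YAML), trajectory serialization and run orchestration.
# A run directory always receives the effective configuration, the package
# version and the seed, sufficient to reproduce the run exactly.

.config_sections <- c("grid", "params", "solver", "scenario", "output", "seed")

.known_keys <- list(
  grid = c("b_omega", "n_nodes"),
  solver = c("dt", "t_end", "output_times", "theta_implicit", "cfl_safety",
             "picard_iters", "tol"),
  scenario = c("name", "bulk_extent", "shoulder_cells", "p_ratio",
               "porosity_on", "reduced_model", "overrides", "seed", "sweep"),
  output = c("dir", "formats", "snapshot_times"))

.check_keys <- function(section, keys, allowed) {
  bad <- setdiff(keys, allowed)
  if (length(bad))
    stop(sprintf("schema violation in '%s': unknown key '%s'",
                 section, bad[1]))
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with optional sections `grid`, `params`, `solver`,
#' `scenario`, `output` and `seed`; every omitted entry takes its
#' documented default (an empty file yields the full default configuration,
#' 500 grid nodes, snapshots at 0/5/10/15 h). Unknown sections or keys and
#' invalid parameter values are rejected with an error naming the offending
#' key.
#'
#' @param path Path to a YAML file.
#' @return A `gb_config`: list with `grid` ([grid1d()]), `params`
#'   ([model_params()]), `solver` ([solver_config()]), `scenario`
#'   ([scenario_spec()]), `output` (dir, formats, snapshot_times) and
#'   `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  .check_keys("top level", names(raw), .config_sections)
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw A plain list with the same structure as the YAML file.
#' @export
config_from_list <- function(raw = list()) {
  gsec <- raw$grid %||% list()
  .check_keys("grid", names(gsec), .known_keys$grid)
  grid <- grid1d(b_omega = gsec$b_omega %||% 1,
                 n_nodes = gsec$n_nodes %||% 500L)

  psec <- raw$params %||% list()
  allowed_p <- names(formals(model_params))
  .check_keys("params", names(psec), allowed_p)
  params <- do.call(model_params, psec)

  ssec <- raw$solver %||% list()
  .check_keys("solver", names(ssec), .known_keys$solver)
  osec <- raw$output %||% list()
  .check_keys("output", names(osec), .known_keys$output)
  if (!is.null(osec$snapshot_times) && is.null(ssec$output_times))
    ssec$output_times <- osec$snapshot_times
  solver <- do.call(solver_config, ssec)

  scsec <- raw$scenario %||% list()
  .check_keys("scenario", names(scsec), .known_keys$scenario)
  sweep <- scsec$sweep
  scsec$sweep <- NULL
  scenario <- do.call(scenario_spec, scsec)
  scenario$sweep <- sweep

  structure(list(grid = grid, params = params, solver = solver,
                 scenario = scenario,
                 output = list(dir = osec$dir %||% ".",
                               formats = osec$formats %||% "tsv",
                               snapshot_times = solver$output_times),
                 seed = as.integer(raw$seed %||% 1L)),
            class = "gb_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a configuration back to YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config A `gb_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "gb_config"))
  sc <- config$scenario
  raw <- list(
    grid = list(b_omega = config$grid$b_omega,
                n_nodes = config$grid$n_nodes),
    params = unclass(config$params),
    solver = unclass(config$solver),
    scenario = list(name = sc$name, bulk_extent = sc$bulk_extent,
                    shoulder_cells = sc$shoulder_cells,
                    p_ratio = sc$p_ratio, porosity_on = sc$porosity_on,
                    reduced_model = sc$reduced_model,
                    overrides = sc$overrides, seed = sc$seed,
                    sweep = sc$sweep),
    output = config$output,
    seed = config$seed)
  raw$scenario <- Filter(Negate(is.null), raw$scenario)
  if (length(raw$scenario$overrides) == 0) raw$scenario$overrides <- NULL
  writeLines(yaml::as.yaml(raw, precision = 15), path)
  invisible(path)
}

# ---- trajectory serialization -----------------------------------------------

#' Write a trajectory as delimited text
#'
#' Long format, one row per (output time, node): columns `t`, `x`, `N`,
#' `P`, `E`, `A`, `I`. Values are written with shortest round-trip
#' precision, so `read_trajectory()` recovers the fields to full double
#' precision.
#'
#' @param traj A `gb_trajectory`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gb_trajectory"))
  if (length(traj$states) == 0L) stop("empty trajectory")
  blocks <- lapply(traj$states, function(s)
    data.frame(t = s$t, x = s$grid$x, N = s$N, P = s$P, E = s$E,
               A = s$A, I = s$I))
  data.table::fwrite(data.table::rbindlist(blocks), path, sep = "\t")
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns a `gb_trajectory` (states only;
#'   `params` and `solver` are not stored in the text format).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("t", "x", "N", "P", "E", "A", "I")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns t, x, N, P, E, A, I")
  states <- lapply(split(df, df$t), function(b) {
    b <- b[order(b$x), ]
    grid <- grid1d(b_omega = max(b$x), n_nodes = nrow(b))
    new_state(b$t[1], b$N, b$P, b$E, b$A, b$I, grid)
  })
  states <- states[order(vapply(states, `[[`, numeric(1), "t"))]
  structure(list(states = unname(states), params = NULL, solver = NULL,
                 diagnostics = list()),
            class = "gb_trajectory")
}

# ---- run orchestration ------------------------------------------------------

#' Run a configuration end to end
#'
#' Builds the initial state from the configured scenario, simulates, and
#' writes to `out_dir`: the trajectory (`trajectory.tsv`), the front-report
#' table (`metrics.tsv`), and the effective configuration with package
#' version and seed (`effective_config.yaml`, `run_info.yaml`) —
#' everything needed to reproduce the run.
#'
#' @param config A `gb_config` from [load_config()] or
#'   [config_from_list()].
#' @param out_dir Output directory (created if missing).
#' @return The `gb_trajectory`, invisibly.
#' @export
run_config <- function(config, out_dir = config$output$dir) {
  stopifnot(inherits(config, "gb_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  sc <- config$scenario
  if (length(sc$overrides)) {
    bad <- setdiff(names(sc$overrides), names(params))
    if (length(bad))
      stop(sprintf("schema violation in 'scenario': unknown override '%s'",
                   bad[1]))
    params[names(sc$overrides)] <- sc$overrides
    params <- validate_params(params)
  }
  if (sc$porosity_on) params <- porosity_variant(params, sc$reduced_model)
  initial <- baseline_initial(sc, params, config$grid)
  traj <- simulate_front(initial, params, config$solver)
  write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
  data.table::fwrite(front_report_table(traj), sep = "\t",
                     file.path(out_dir, "metrics.tsv"))
  save_config(config, file.path(out_dir, "effective_config.yaml"))
  writeLines(yaml::as.yaml(list(
    package = "gbfront",
    version = as.character(utils::packageVersion("gbfront")),
    seed = config$seed,
    n_steps = traj$diagnostics$n_steps,
    floored_nodes = traj$diagnostics$floored)),
    file.path(out_dir, "run_info.yaml"))
  invisible(traj)
}
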