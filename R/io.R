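#' Load a run configuration
#'
#' Reads a YAML configuration with blocks `model`, `weights`, `initial`,
#' `survival`, `transcription`, plus optional `output_dir`, `seed` and
#' `log_level`. Missing fields take the package's nominal defaults; unknown
#' keys are rejected by name; every block is validated through its
#' constructor. An empty (or absent) file yields the full nominal
#' configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config`: list with `model` (`model_params`), `weights`
#'   (`objective_weights`), `initial` (`tumor_state`), `survival`
#'   (`survival_settings`), `transcription` (`transcription_settings`),
#'   `output_dir`, `seed`, `log_level`, and `provenance` (per-field "file" or
#'   "default").
#' @export
#' @examples
#' cfg <- load_config(NULL)
#' cfg$survival$n_crit
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known_blocks <- c("model", "weights", "initial", "survival",
                    "transcription", "output_dir", "seed", "log_level")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(block, ctor, defaults) {
    given <- raw[[block]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(defaults))
    if (length(bad) > 0)
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    args <- utils::modifyList(defaults, given)
    obj <- tryCatch(do.call(ctor, args), error = function(e)
      stop("invalid '", block, "' block: ", conditionMessage(e), call. = FALSE))
    prov <- setNames(ifelse(names(defaults) %in% names(given),
                            "file", "default"), names(defaults))
    list(obj = obj, prov = prov)
  }
  model <- build("model", model_params,
                 formals_defaults(model_params))
  weights <- build("weights", objective_weights,
                   formals_defaults(objective_weights))
  initial <- build("initial", tumor_state, list(N1 = 280, N2 = 20, K = 650))
  surv <- build("survival", survival_settings,
                formals_defaults(survival_settings))
  trans <- build("transcription", transcription_settings,
                 formals_defaults(transcription_settings))
  structure(list(model = model$obj, weights = weights$obj,
                 initial = initial$obj, survival = surv$obj,
                 transcription = trans$obj,
                 output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 log_level = if (is.null(raw$log_level)) "INFO" else raw$log_level,
                 provenance = list(model = model$prov, weights = weights$prov,
                                   initial = initial$prov, survival = surv$prov,
                                   transcription = trans$prov)),
            class = "run_config")
}

formals_defaults <- function(f) {
  d <- formals(f)
  d <- d[!vapply(d, is.symbol, logical(1))]
  lapply(d, eval, envir = baseenv())
}

#' Export a trajectory as CSV
#'
#' Columns `t,N1,N2,K,u,v` (days, mm^3, dose fractions).
#'
#' @param traj A `tumor_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  n <- length(traj$times)
  df <- data.frame(t = traj$times,
                   N1 = traj$states[, 1], N2 = traj$states[, 2],
                   K = traj$states[, 3],
                   u = if (is.null(traj$u)) rep(NA_real_, n) else traj$u,
                   v = rep(traj$v, n))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a dose heatmap as long-format CSV
#'
#' Columns `u,v,t_s,reached`; never-reached cells carry an empty `t_s` and
#' `reached = FALSE`.
#'
#' @param hm A `dose_heatmap`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_heatmap_csv <- function(hm, path) {
  df <- expand.grid(u = hm$u_grid, v = hm$v_grid)
  df$t_s <- as.vector(t(hm$t_s))
  df$reached <- as.vector(t(hm$reached))
  df$t_s[is.infinite(df$t_s)] <- NA_real_
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export / import a solved schedule as JSON
#'
#' The JSON round-trips losslessly: `read_solution_json(write_solution_json(x))`
#' reproduces the control, grid, objective parts and averages exactly (doubles
#' are serialized at full precision).
#'
#' @param solution An `ocp_solution`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  payload <- list(
    horizon = solution$horizon,
    v = solution$v,
    times = solution$times,
    control = solution$control,
    objective = solution$objective[c("total", "terminal_part",
                                     "running_tumor_part", "resistance_part",
                                     "dose_part")],
    average_dose_pct = solution$average_dose_pct,
    solver_status = solution$solver_status,
    singular = solution$singular)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_solution_json
#' @export
read_solution_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$objective <- structure(c(list(total = x$objective$total),
                             x$objective[c("terminal_part",
                                           "running_tumor_part",
                                           "resistance_part", "dose_part")]),
                           class = "objective_value")
  structure(x, class = "ocp_solution")
}

#' Write a run manifest
#'
#' Drops a small JSON manifest (tool version, seed, configuration echo and a
#' content hash of it) next to a run's outputs so the run can be repeated
#' exactly.
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @param extra Optional named list merged into the manifest.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  echo <- list(model = unclass(config$model),
               weights = unclass(config$weights),
               initial = as.list(unclass(config$initial)),
               survival = unclass(config$survival),
               transcription = unclass(config$transcription),
               seed = config$seed)
  hash <- sum(utf8ToInt(jsonlite::toJSON(echo, auto_unbox = TRUE,
                                         digits = NA))) %% 2^31
  payload <- c(list(tool = "chemosched",
                    version = as.character(utils::packageVersion("chemosched")),
                    seed = config$seed,
                    config_hash = hash,
                    config = echo),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
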