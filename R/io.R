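RUN_FORMAT_VERSION <- 1L

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML dump of the hyperparameters and environment
#' settings; written into saved runs and summaries so every reported
#' number can be traced to its exact configuration.
#'
#' @param preset A preset-style list with `hp` and `env`.
#' @return Hex string.
#' @export
config_hash <- function(preset) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(list(hp = unclass(preset$hp),
                                env = unclass(preset$env))), tmp)
  unname(tools::md5sum(tmp))
}

#' Load and validate a run configuration file
#'
#' Plain-text YAML. A `preset` key selects one of the published
#' configurations ([recollect_preset()]); any key under `hp:` or `env:`
#' overrides the preset value. Unknown keys and out-of-range values are
#' rejected with a descriptive error.
#'
#' Top-level keys: `preset` (required), `hp:`, `env:`, `seeds` (integer
#' vector, default 1), `out_dir` (default `"."`), `n_episodes`,
#' `max_trials`, `eval_episodes`.
#'
#' @param path Path to the YAML file.
#' @return A `recollect_config` list with `task`, `hp`, `env`, `seeds`,
#'   `out_dir`, `n_episodes`, `max_trials`, `eval_episodes`, `hash`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse config ", path, ": ", conditionMessage(e)))
  known_top <- c("preset", "hp", "env", "seeds", "out_dir", "n_episodes",
                 "max_trials", "eval_episodes")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(raw$preset)) stop("config must name a preset")
  preset <- recollect_preset(raw$preset)
  if (!is.null(raw$hp)) {
    bad <- setdiff(names(raw$hp), names(unclass(preset$hp)))
    if (length(bad))
      stop("unknown hp key(s): ", paste(bad, collapse = ", "))
    hp_args <- utils::modifyList(unclass(preset$hp), raw$hp)
    preset$hp <- do.call(hyperparameters, hp_args)
  }
  if (!is.null(raw$env)) {
    env_fields <- setdiff(names(unclass(preset$env)), "n_in")
    bad <- setdiff(names(raw$env), env_fields)
    if (length(bad))
      stop("unknown env key(s): ", paste(bad, collapse = ", "))
    env_args <- utils::modifyList(unclass(preset$env)[env_fields], raw$env)
    ctor <- if (preset$task == "saccade") saccade_config else bandit_config
    preset$env <- do.call(ctor, env_args)
  }
  if (preset$task == "saccade" && preset$env$n_in != preset$hp$n_in)
    stop("hp n_in (", preset$hp$n_in, ") does not match environment (",
         preset$env$n_in, ")")
  cfgobj <- list(
    task = preset$task, hp = preset$hp, env = preset$env,
    seeds = as.integer(raw$seeds %||% 1L),
    out_dir = raw$out_dir %||% ".",
    n_episodes = as.integer(raw$n_episodes %||% 20000L),
    max_trials = as.numeric(raw$max_trials %||% 1e6),
    eval_episodes = as.integer(raw$eval_episodes %||% 300L),
    hash = config_hash(preset))
  class(cfgobj) <- "recollect_config"
  cfgobj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run (agent, plasticity, environment and RNG state)
#'
#' Serialises everything needed to resume a run identically: the agent
#' (parameters, traces/tags, memory), the environment continuation state,
#' the current state of R's random stream, and the configuration hash.
#'
#' @param trained A result of [train_bandit()]/[train_saccade()] (or any
#'   list with an `agent` and optionally `env_state`).
#' @param path Destination file.
#' @param preset The preset/config the run used (for the hash).
#' @return `path`, invisibly.
#' @export
save_run <- function(trained, path, preset = NULL) {
  agent <- if (inherits(trained, "recollect_agent")) trained else
    trained$agent
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(version = RUN_FORMAT_VERSION,
              hash = if (!is.null(preset)) config_hash(preset) else NA,
              hp = unclass(agent$hp),
              params = agent$params, plast = agent$plast,
              state = agent$state,
              env_state = if (is.list(trained)) trained$env_state else NULL,
              rng_state = rng)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a saved run
#'
#' Restores the agent and (optionally) R's random stream so that a
#' resumed run continues exactly as the uninterrupted one would have.
#'
#' @param path File written by [save_run()].
#' @param hp Optional [hyperparameters()] object to validate against; a
#'   mismatch in layer sizes is rejected.
#' @param restore_rng Restore the saved random stream (default `TRUE`).
#' @return List with `agent`, `env_state`, `hash`.
#' @export
load_run <- function(path, hp = NULL, restore_rng = TRUE) {
  obj <- readRDS(path)
  if (!identical(obj$version, RUN_FORMAT_VERSION))
    stop("saved run has format version ", obj$version,
         "; this package reads version ", RUN_FORMAT_VERSION)
  saved_hp <- do.call(hyperparameters, obj$hp)
  if (!is.null(hp)) {
    if (!identical(c(hp$n_in, hp$n_mem, hp$n_out),
                   c(saved_hp$n_in, saved_hp$n_mem, saved_hp$n_out)))
      stop("saved run layer sizes do not match the requested configuration")
  }
  agent <- list(hp = saved_hp, params = obj$params, plast = obj$plast,
                state = obj$state)
  class(agent) <- "recollect_agent"
  if (restore_rng && !is.null(obj$rng_state))
    assign(".Random.seed", obj$rng_state, envir = globalenv())
  list(agent = agent, env_state = obj$env_state, hash = obj$hash)
}
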