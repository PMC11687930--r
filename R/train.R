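#' Train an agent on the pro-/anti-saccade task until convergence
#'
#' Runs the learning rule against the saccade environment until the
#' convergence criterion holds or the trial cap is hit. Convergence
#' requires (1) at least 85% correct over the last `window` trials of each
#' of the four trial types (pro/anti crossed with cue left/right) and
#' (2) perfect completion of all four trial types with weights frozen and
#' exploration disabled. With `curriculum = TRUE` the memory delay is
#' lengthened through the stages of [make_curriculum()] (each stage
#' advanced on the rolling criterion alone) before the final stage is
#' trained to full convergence.
#'
#' @param preset A preset list from [recollect_preset()], or any list with
#'   elements `hp` and `env` (a [saccade_config()]).
#' @param seed Integer seed for the run (weights and task randomness).
#' @param max_trials Trial cap (1e6, as in the published protocol).
#' @param window Trials per type in the rolling criterion (100).
#' @param threshold Required accuracy (0.85).
#' @param curriculum Train through delay stages up to `env$delay_steps`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference loop).
#' @param log_trials Keep the per-trial type/correct transcript.
#' @return List with `trials` (trials to convergence; the cap value if not
#'   converged), `converged`, `agent`, `stage_trials` and, if requested,
#'   `trial_type`/`trial_correct` of the final stage.
#' @export
train_saccade <- function(preset = recollect_preset("saccade"), seed = 1,
                          max_trials = 1e6, window = 100, threshold = 0.85,
                          curriculum = FALSE, engine = c("cpp", "r"),
                          log_trials = FALSE) {
  engine <- match.arg(engine)
  hp <- preset$hp; cfg <- preset$env
  if (cfg$n_in != hp$n_in)
    stop("environment input size does not match the network")
  set.seed(as.integer(seed))
  agent <- new_agent(hp)
  stages <- if (curriculum) make_curriculum(cfg$delay_steps) else
    cfg$delay_steps
  total <- 0L
  stage_trials <- integer(0)
  res <- NULL
  for (i in seq_along(stages)) {
    stage_cfg <- cfg
    stage_cfg$delay_steps <- stages[i]
    final <- i == length(stages)
    budget <- as.integer(max_trials) - total
    if (budget <= 0L) break
    res <- if (engine == "cpp") {
      cpp_saccade_run(agent, unclass(hp), unclass(stage_cfg), budget,
                      as.integer(window), threshold, final,
                      log_trials && final)
    } else {
      run_saccade_r(agent, hp, stage_cfg, budget, window, threshold,
                    require_greedy = final, log_trials = log_trials && final)
    }
    agent <- rebuild_agent(res$agent, hp)
    total <- total + res$trials
    stage_trials <- c(stage_trials, res$trials)
    if (!res$converged) break
  }
  out <- list(trials = total, converged = isTRUE(res$converged),
              agent = agent, stage_trials = stage_trials)
  if (log_trials && !is.null(res$trial_type)) {
    out$trial_type <- res$trial_type
    out$trial_correct <- as.logical(res$trial_correct)
  }
  out
}

# Re-attach class/hp to an agent structure returned by the C++ engine.
rebuild_agent <- function(raw, hp) {
  agent <- list(hp = hp, params = raw$params, plast = raw$plast,
                state = raw$state)
  class(agent) <- "recollect_agent"
  agent
}

#' Train an agent on the reversal bandit
#'
#' Presents `n_episodes` training episodes as one continuing task (memory,
#' traces and tags are never reset between episodes; learning-to-learn
#' depends on this).
#'
#' @param preset A preset list from [recollect_preset()] (`"bandit"`,
#'   `"bandit-no-signal"`, `"random-bandit"` or `"rat-schedule"`), or any
#'   list with `hp` and a [bandit_config()] `env`.
#' @param seed Integer seed for the run.
#' @param n_episodes Training episodes (20,000 in the published protocol).
#' @param engine `"cpp"` or `"r"`.
#' @param record Keep the per-pull training transcript (action, optimal,
#'   rewarded, episode) — needed for serial-reversal error curves.
#' @return List with `agent`, `env_state` (so evaluation continues the
#'   same stream) and, if `record`, a `transcript` data frame.
#' @export
train_bandit <- function(preset = recollect_preset("bandit"), seed = 1,
                         n_episodes = 20000, engine = c("cpp", "r"),
                         record = FALSE) {
  engine <- match.arg(engine)
  hp <- preset$hp; cfg <- preset$env
  set.seed(as.integer(seed))
  agent <- new_agent(hp)
  env <- bandit_reset(cfg)
  run_bandit(agent, cfg, env_state_of(env), n_episodes, learn = TRUE,
             epsilon = hp$epsilon, engine = engine, record = record)
}

env_state_of <- function(env) {
  list(high = env$high, episode_index = env$episode_index,
       prev_action = 0L, prev_reward = 0, eoe_flag = FALSE)
}

episode_lengths_for <- function(cfg, n_episodes, start_index = 1L) {
  idx <- seq.int(start_index, length.out = n_episodes)
  vapply(idx, function(i) bandit_episode_length(cfg, i), integer(1))
}

run_bandit <- function(agent, cfg, env_state, n_episodes, learn, epsilon,
                       engine = "cpp", record = FALSE, record_q = FALSE) {
  lengths <- episode_lengths_for(cfg, n_episodes, env_state$episode_index)
  env_in <- c(unclass(cfg), list(lengths = as.integer(lengths)))
  res <- if (engine == "cpp") {
    cpp_bandit_run(agent, unclass(agent$hp), env_in, env_state,
                   as.integer(n_episodes), learn, epsilon, record, record_q)
  } else {
    run_bandit_r(agent, cfg, env_state, n_episodes, learn, epsilon,
                 record, record_q)
  }
  out <- list(agent = rebuild_agent(res$agent, agent$hp),
              env_state = res$env_state)
  if (record) {
    tr <- data.frame(episode = res$episode, action = res$action,
                     optimal = as.logical(res$optimal),
                     reward = as.numeric(res$rewarded) *
                       cfg$reward_magnitude)
    trial <- stats::ave(seq_along(tr$episode), tr$episode,
                        FUN = seq_along)
    tr$trial <- as.integer(trial)
    if (record_q) { tr$q1 <- res$q1; tr$q2 <- res$q2 }
    out$transcript <- tr
  }
  out
}

#' Greedy evaluation of a trained bandit agent
#'
#' Disables learning and exploration (memory dynamics still run) and
#' continues the task for `n_episodes` evaluation episodes, returning the
#' published performance metrics and the per-pull transcript.
#'
#' @param trained Result of [train_bandit()] (uses its `agent`,
#'   `env_state` and config), or an agent plus explicit `cfg`/`env_state`.
#' @param cfg A [bandit_config()]; defaults to the one in `trained` if
#'   present.
#' @param n_episodes Evaluation episodes (300).
#' @param engine `"cpp"` or `"r"`.
#' @param record_q Also record the two Q-values at every pull.
#' @return List with `metrics` (optimal-pull fraction, suboptimal-pull
#'   count, mean per-episode cumulative regret) and `transcript`.
#' @export
evaluate_bandit <- function(trained, cfg, n_episodes = 300,
                            engine = c("cpp", "r"), record_q = FALSE) {
  engine <- match.arg(engine)
  agent <- if (inherits(trained, "recollect_agent")) trained else
    trained$agent
  env_state <- if (is.list(trained) && !is.null(trained$env_state))
    trained$env_state else env_state_of(bandit_reset(cfg))
  res <- run_bandit(agent, cfg, env_state, n_episodes, learn = FALSE,
                    epsilon = 0, engine = engine, record = TRUE,
                    record_q = record_q)
  tr <- res$transcript
  n_pulls <- nrow(tr)
  n_subopt <- sum(!tr$optimal)
  metrics <- list(
    optimal_fraction = mean(tr$optimal),
    suboptimal_pulls = n_subopt,
    n_pulls = n_pulls,
    mean_episode_regret = cumulative_regret(tr, cfg)$mean_per_episode
  )
  list(metrics = metrics, transcript = tr, agent = res$agent,
       env_state = res$env_state)
}

# ---------------------------------------------------------------------
# Pure-R reference loops: same semantics and random-draw order as the
# compiled engine; used for short runs and the parity tests.

#' Rolling per-type convergence tracker
#'
#' Maintains, for each of the four saccade trial types, the outcomes of
#' the most recent `window` trials and reports whether every type has a
#' full window at or above the accuracy threshold.
#'
#' @param window Trials per type (100).
#' @param threshold Required accuracy (0.85).
#' @return A list of closures: `add(type, correct)` records a completed
#'   trial (type in 1..4); `met()` tests the rolling criterion.
#' @export
convergence_tracker <- function(window = 100, threshold = 0.85) {
  buf <- lapply(1:4, function(i) integer(window))
  idx <- rep(1L, 4); count <- rep(0L, 4); acc <- rep(0L, 4)
  add <- function(type, correct) {
    c_ <- as.integer(correct)
    if (count[type] < window) {
      acc[type] <<- acc[type] + c_
      count[type] <<- count[type] + 1L
    } else {
      acc[type] <<- acc[type] + c_ - buf[[type]][idx[type]]
    }
    buf[[type]][idx[type]] <<- c_
    idx[type] <<- idx[type] %% window + 1L
    invisible(NULL)
  }
  met <- function() {
    all(count == window) && all(acc / window >= threshold - 1e-12)
  }
  list(add = add, met = met)
}

saccade_trial_type <- function(env) {
  (if (env$trial_pro) 0L else 2L) + (if (env$cue_left) 0L else 1L) + 1L
}

run_saccade_r <- function(agent, hp, cfg, max_trials, window = 100,
                          threshold = 0.85, require_greedy = TRUE,
                          log_trials = FALSE) {
  env <- saccade_reset(cfg)
  tracker <- convergence_tracker(window, threshold)
  trials <- 0L
  types <- integer(0); corrects <- logical(0)
  converged <- FALSE
  steps <- 0
  while (trials < max_trials) {
    st <- learn_step(agent, env$obs, env$reward, learn = TRUE,
                     epsilon = hp$epsilon)
    agent <- st$agent
    env <- saccade_step(env, st$action)
    steps <- steps + 1
    if (env$trial_done) {
      trials <- trials + 1L
      type <- saccade_trial_type(env)
      tracker$add(type, env$correct)
      if (log_trials) {
        types <- c(types, type); corrects <- c(corrects, env$correct)
      }
      if (tracker$met() &&
          (!require_greedy || greedy_check_r(agent, cfg))) {
        converged <- TRUE
        break
      }
    }
  }
  out <- list(agent = unclass(agent)[c("params", "plast", "state")],
              trials = trials, converged = converged, steps = steps)
  if (log_trials) { out$trial_type <- types; out$trial_correct <- corrects }
  out
}

#' Run a scripted policy against the saccade task
#'
#' Drives the environment with an arbitrary policy function instead of an
#' agent — useful for validating the environment mechanics and the
#' convergence bookkeeping independently of learning.
#'
#' @param policy `function(obs, env)` returning an action in 1..3; the
#'   environment state is exposed so oracle policies can be scripted.
#' @param cfg A [saccade_config()].
#' @param max_trials Trial cap.
#' @param window,threshold Convergence-criterion settings.
#' @return List with `trials` (trials until the rolling criterion first
#'   held; `max_trials` if never), `converged`, `rewards` (per-trial
#'   total reward).
#' @export
saccade_run_policy <- function(policy, cfg, max_trials = 1000,
                               window = 100, threshold = 0.85) {
  env <- saccade_reset(cfg)
  tracker <- convergence_tracker(window, threshold)
  trials <- 0L
  converged <- FALSE
  rewards <- numeric(0)
  trial_reward <- 0
  while (trials < max_trials) {
    a <- policy(env$obs, env)
    env <- saccade_step(env, a)
    trial_reward <- trial_reward + env$reward
    if (env$trial_done) {
      trials <- trials + 1L
      rewards <- c(rewards, trial_reward)
      trial_reward <- 0
      tracker$add(saccade_trial_type(env), env$correct)
      if (tracker$met()) { converged <- TRUE; break }
    }
  }
  list(trials = trials, converged = converged, rewards = rewards)
}

#' Greedy completion check for the saccade task
#'
#' Runs the four trial types in a fixed order with frozen weights and no
#' exploration on a copy of the agent (the training run is unaffected and
#' no random numbers are consumed). Each scripted trial is preceded by the
#' inter-trial interval, with the end-of-trial bit raised on its first
#' step as in the continuing stream.
#'
#' @param agent A `recollect_agent`.
#' @param cfg A [saccade_config()].
#' @return `TRUE` if all four trial types are completed correctly.
#' @export
greedy_check_r <- function(agent, cfg) {
  for (tt in 1:4) {
    env <- saccade_reset(cfg)
    env$obs <- saccade_obs(cfg, eot = TRUE)
    forced_pro <- tt <= 2
    forced_left <- tt %% 2 == 1
    done_ok <- FALSE
    for (step in 1:1000) {
      st <- learn_step(agent, env$obs, env$reward, learn = FALSE,
                       epsilon = 0)
      agent <- st$agent
      # force the trial type drawn at trial start
      if (env$phase == "iti" && env$step_in_phase >= cfg$iti_steps) {
        env$cfg$type_schedule <- "iid"
        env <- saccade_step_forced(env, st$action, forced_pro, forced_left)
      } else {
        env <- saccade_step(env, st$action)
      }
      if (env$trial_done) { done_ok <- env$correct; break }
    }
    if (!done_ok) return(FALSE)
  }
  TRUE
}

saccade_step_forced <- function(env, action, pro, cue_left) {
  # as saccade_step for the ITI->WAIT transition, but with a preset type
  env$reward <- 0; env$trial_done <- FALSE; env$correct <- NA
  env$trial_pro <- pro; env$cue_left <- cue_left
  env$phase <- "wait"; env$step_in_phase <- 1L
  env$obs <- saccade_obs(env$cfg, marker = if (pro) 1L else 2L)
  env
}

run_bandit_r <- function(agent, cfg, env_state, n_episodes, learn, epsilon,
                         record = FALSE, record_q = FALSE) {
  lengths <- episode_lengths_for(cfg, n_episodes, env_state$episode_index)
  high <- env_state$high
  episode_index <- env_state$episode_index
  prev_action <- env_state$prev_action
  prev_reward <- env_state$prev_reward
  eoe_flag <- env_state$eoe_flag
  r_action <- integer(0); r_optimal <- logical(0)
  r_rewarded <- integer(0); r_episode <- integer(0)
  r_q1 <- numeric(0); r_q2 <- numeric(0)
  for (ep in seq_len(n_episodes)) {
    len <- lengths[ep]
    for (pull in seq_len(len)) {
      x <- numeric(4)
      if (prev_action > 0) x[prev_action] <- 1
      x[3] <- prev_reward / cfg$reward_magnitude
      if (cfg$end_of_episode_signal && eoe_flag) x[4] <- 1
      st <- learn_step(agent, x, prev_reward, learn = learn,
                       epsilon = epsilon)
      agent <- st$agent
      a <- st$action
      p <- if (a == high) cfg$p_high else cfg$p_low
      rewarded <- stats::runif(1) < p
      rew <- if (rewarded) cfg$reward_magnitude else 0
      if (record) {
        r_action <- c(r_action, a)
        r_optimal <- c(r_optimal, a == high)
        r_rewarded <- c(r_rewarded, as.integer(rewarded))
        r_episode <- c(r_episode, episode_index)
        if (record_q) { r_q1 <- c(r_q1, st$state$q[1]); r_q2 <- c(r_q2, st$state$q[2]) }
      }
      boundary <- pull == len
      if (boundary) {
        episode_index <- episode_index + 1L
        high <- if (cfg$mode == "alternating") 3L - high
                else if (stats::runif(1) < 0.5) 1L else 2L
      }
      eoe_flag <- boundary
      prev_action <- a
      prev_reward <- rew
    }
  }
  out <- list(
    agent = unclass(agent)[c("params", "plast", "state")],
    env_state = list(high = high, episode_index = episode_index,
                     prev_action = prev_action, prev_reward = prev_reward,
                     eoe_flag = eoe_flag))
  if (record) {
    out$action <- r_action; out$optimal <- r_optimal
    out$rewarded <- r_rewarded; out$episode <- r_episode
    if (record_q) { out$q1 <- r_q1; out$q2 <- r_q2 }
  }
  out
}
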