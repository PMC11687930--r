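#' Pro-/anti-saccade task configuration
#'
#' A delayed-response task: after an inter-trial interval an empty screen is
#' replaced by a coloured fixation marker (blue = pro-saccade, green =
#' anti-saccade, 50/50). The model must fixate (centre action) within
#' `fixation_timeout` steps, earning `fixation_reward`; a cue then flashes
#' left or right for one step, followed by a memory delay during which
#' fixation must be held. When the marker disappears (go signal) the model
#' must saccade toward the cue (pro) or away from it (anti) within
#' `saccade_timeout` steps to earn `final_reward`. Breaking fixation during
#' cue or delay, a wrong saccade, or a timeout ends the trial unrewarded.
#'
#' Observations are `[blue marker, green marker, cue left, cue right]` plus
#' an optional fifth unit raised for exactly one step (the first ITI step
#' after a trial ends) when `end_of_trial_signal` is `TRUE`. The start-of-
#' trial empty screen is the all-zeros vector.
#'
#' @param iti_steps Inter-trial interval length (1 for the performance
#'   protocol; 3 for unit-analysis runs).
#' @param delay_steps Memory-delay length (2 for the performance protocol;
#'   up to 5 via the curriculum).
#' @param fixation_timeout Steps allowed to acquire fixation (10).
#' @param saccade_timeout Steps allowed to respond after the go signal (8).
#' @param fixation_reward Reward for acquiring fixation (0.2).
#' @param final_reward Reward for a correct saccade (1.5).
#' @param end_of_trial_signal Include the end-of-trial input unit.
#' @param type_schedule `"iid"` draws each trial type independently
#'   (50/50 pro/anti and left/right); `"balanced"` uses permuted blocks of
#'   the four trial types (R engine only).
#' @return A `saccade_config` list. `n_in` is 4, or 5 with the signal.
#' @export
saccade_config <- function(iti_steps = 1, delay_steps = 2,
                           fixation_timeout = 10, saccade_timeout = 8,
                           fixation_reward = 0.2, final_reward = 1.5,
                           end_of_trial_signal = FALSE,
                           type_schedule = c("iid", "balanced")) {
  type_schedule <- match.arg(type_schedule)
  stopifnot(iti_steps >= 1, delay_steps >= 0, fixation_timeout >= 1,
            saccade_timeout >= 1, fixation_reward >= 0, final_reward >= 0)
  structure(list(
    iti_steps = as.integer(iti_steps), delay_steps = as.integer(delay_steps),
    fixation_timeout = as.integer(fixation_timeout),
    saccade_timeout = as.integer(saccade_timeout),
    fixation_reward = fixation_reward, final_reward = final_reward,
    end_of_trial_signal = isTRUE(end_of_trial_signal),
    type_schedule = type_schedule,
    n_in = 4L + isTRUE(end_of_trial_signal)
  ), class = "saccade_config")
}

# Actions: 1 = left, 2 = centre, 3 = right.
SACCADE_LEFT <- 1L
SACCADE_CENTRE <- 2L
SACCADE_RIGHT <- 3L

saccade_obs <- function(cfg, marker = 0L, cue = 0L, eot = FALSE) {
  x <- numeric(cfg$n_in)
  if (marker > 0L) x[marker] <- 1       # 1 = blue/pro, 2 = green/anti
  if (cue > 0L) x[2L + cue] <- 1        # 1 = left, 2 = right
  if (cfg$end_of_trial_signal && eot) x[5L] <- 1
  x
}

#' Initialise (reset) the pro-/anti-saccade environment
#'
#' @param cfg A [saccade_config()].
#' @return Environment state list carrying the observation to present next
#'   (`obs`), the reward delivered with it (`reward`), the current `phase`
#'   and the trial bookkeeping. Uses R's global random stream; seed with
#'   [set.seed()] beforehand.
#' @export
saccade_reset <- function(cfg) {
  list(cfg = cfg, phase = "iti", step_in_phase = 1L,
       trial_pro = NA, cue_left = NA, trial_index = 0L,
       obs = saccade_obs(cfg), reward = 0,
       trial_done = FALSE, correct = NA, block = integer(0))
}

saccade_draw_type <- function(env) {
  cfg <- env$cfg
  if (cfg$type_schedule == "balanced") {
    if (length(env$block) == 0L) {
      # permuted block of the four trial types (pro/anti x left/right)
      blk <- 1:4
      for (i in 4:2) {
        j <- floor(stats::runif(1) * i) + 1
        tmp <- blk[i]; blk[i] <- blk[j]; blk[j] <- tmp
      }
      env$block <- blk
    }
    tt <- env$block[1]; env$block <- env$block[-1]
    env$trial_pro <- tt <= 2
    env$cue_left <- tt %% 2 == 1
  } else {
    env$trial_pro <- stats::runif(1) < 0.5
    env$cue_left <- stats::runif(1) < 0.5
  }
  env
}

saccade_end_trial <- function(env, correct) {
  cfg <- env$cfg
  env$phase <- "iti"
  env$step_in_phase <- 1L
  env$trial_done <- TRUE
  env$correct <- correct
  env$trial_index <- env$trial_index + 1L
  env$obs <- saccade_obs(cfg, eot = TRUE)
  env
}

#' Advance the pro-/anti-saccade task by one timestep
#'
#' Consumes the agent's `action` taken in response to the currently
#' presented observation and returns the updated environment, whose `obs`
#' and `reward` fields are what the agent receives on the next step.
#' `trial_done`/`correct` flag a trial that ended with this transition.
#'
#' @param env Environment state from [saccade_reset()] or a previous step.
#' @param action Integer in 1..3 (left, centre, right).
#' @return Updated environment state.
#' @export
saccade_step <- function(env, action) {
  if (!action %in% 1:3) stop("invalid saccade action")
  cfg <- env$cfg
  env$reward <- 0
  env$trial_done <- FALSE
  env$correct <- NA
  switch(env$phase,
    iti = {
      if (env$step_in_phase < cfg$iti_steps) {
        env$step_in_phase <- env$step_in_phase + 1L
        env$obs <- saccade_obs(cfg)   # eot bit only on the first ITI step
      } else {
        env <- saccade_draw_type(env)
        env$phase <- "wait"
        env$step_in_phase <- 1L
        env$obs <- saccade_obs(cfg, marker = if (env$trial_pro) 1L else 2L)
      }
    },
    wait = {
      if (action == SACCADE_CENTRE) {
        env$reward <- cfg$fixation_reward
        env$phase <- "cue"
        env$step_in_phase <- 1L
        env$obs <- saccade_obs(cfg, marker = if (env$trial_pro) 1L else 2L,
                               cue = if (env$cue_left) 1L else 2L)
      } else if (env$step_in_phase >= cfg$fixation_timeout) {
        env <- saccade_end_trial(env, correct = FALSE)
      } else {
        env$step_in_phase <- env$step_in_phase + 1L
      }
    },
    cue = {
      if (action != SACCADE_CENTRE) {
        env <- saccade_end_trial(env, correct = FALSE)
      } else if (cfg$delay_steps == 0L) {
        env$phase <- "go"
        env$step_in_phase <- 1L
        env$obs <- saccade_obs(cfg)
      } else {
        env$phase <- "delay"
        env$step_in_phase <- 1L
        env$obs <- saccade_obs(cfg, marker = if (env$trial_pro) 1L else 2L)
      }
    },
    delay = {
      if (action != SACCADE_CENTRE) {
        env <- saccade_end_trial(env, correct = FALSE)
      } else if (env$step_in_phase >= cfg$delay_steps) {
        env$phase <- "go"
        env$step_in_phase <- 1L
        env$obs <- saccade_obs(cfg)
      } else {
        env$step_in_phase <- env$step_in_phase + 1L
        env$obs <- saccade_obs(cfg, marker = if (env$trial_pro) 1L else 2L)
      }
    },
    go = {
      if (action == SACCADE_CENTRE) {
        # waiting consumes one of the response steps
        if (env$step_in_phase >= cfg$saccade_timeout) {
          env <- saccade_end_trial(env, correct = FALSE)
        } else {
          env$step_in_phase <- env$step_in_phase + 1L
        }
      } else {
        correct_side <- if (env$trial_pro == env$cue_left) SACCADE_LEFT
                        else SACCADE_RIGHT
        ok <- action == correct_side
        env <- saccade_end_trial(env, correct = ok)
        if (ok) env$reward <- cfg$final_reward
      }
    },
    stop("unknown phase")
  )
  env
}

#' Two-armed reversal-bandit configuration
#'
#' Each pull of one of two levers is rewarded with probability `p_high`
#' (high lever) or `p_low`. Episodes last `episode_length` pulls; at an
#' episode boundary the assignment is deterministically swapped
#' (`mode = "alternating"`) or redrawn uniformly, possibly repeating
#' (`mode = "random"`). Observations are
#' `[previous action one-hot (2), previous reward, end-of-episode bit]`;
#' the first step of a run sees all zeros, and the boundary bit is raised
#' on the first observation of each new episode when
#' `end_of_episode_signal` is `TRUE` (silent otherwise; the unit is kept so
#' layer sizes match the published table in both arms of the ablation).
#'
#' @param p_high,p_low Reward probabilities (0.75/0.25; 1/0 for the
#'   deterministic serial-reversal variant).
#' @param episode_length Pulls per episode (100).
#' @param episode_lengths Optional integer vector of per-episode lengths
#'   (e.g. the 24/16/8 serial-reversal schedule); recycled if shorter than
#'   the run.
#' @param mode Reversal mode at episode boundaries.
#' @param end_of_episode_signal Raise the boundary input unit.
#' @param reward_magnitude Reward size in arbitrary units (1, so reward
#'   rate and optimal-pull fraction coincide).
#' @return A `bandit_config` list; `n_in` is always 4.
#' @export
bandit_config <- function(p_high = 0.75, p_low = 0.25, episode_length = 100,
                          episode_lengths = NULL,
                          mode = c("alternating", "random"),
                          end_of_episode_signal = TRUE,
                          reward_magnitude = 1) {
  mode <- match.arg(mode)
  stopifnot(p_low >= 0, p_high <= 1, p_low <= p_high,
            episode_length >= 1, reward_magnitude > 0)
  if (!is.null(episode_lengths)) {
    episode_lengths <- as.integer(episode_lengths)
    stopifnot(all(episode_lengths >= 1))
  }
  structure(list(
    p_high = p_high, p_low = p_low,
    episode_length = as.integer(episode_length),
    episode_lengths = episode_lengths, mode = mode,
    end_of_episode_signal = isTRUE(end_of_episode_signal),
    reward_magnitude = reward_magnitude, n_in = 4L
  ), class = "bandit_config")
}

bandit_episode_length <- function(cfg, episode_index) {
  if (is.null(cfg$episode_lengths)) return(cfg$episode_length)
  cfg$episode_lengths[(episode_index - 1L) %% length(cfg$episode_lengths) + 1L]
}

bandit_obs <- function(cfg, prev_action, prev_reward, eoe) {
  x <- numeric(4L)
  if (prev_action > 0L) x[prev_action] <- 1
  x[3L] <- prev_reward / cfg$reward_magnitude
  if (cfg$end_of_episode_signal && eoe) x[4L] <- 1
  x
}

#' Initialise (reset) the reversal-bandit environment
#'
#' Draws the initial high lever uniformly. Uses R's global random stream.
#'
#' @param cfg A [bandit_config()].
#' @return Environment state list with the first observation (all zeros).
#' @export
bandit_reset <- function(cfg) {
  high <- if (stats::runif(1) < 0.5) 1L else 2L
  list(cfg = cfg, high = high, pull_in_episode = 0L, episode_index = 1L,
       obs = numeric(4L), reward = 0, episode_done = FALSE, optimal = NA)
}

#' Advance the reversal bandit by one pull
#'
#' Draws the Bernoulli reward for the chosen lever, advances the episode
#' counter and, at an episode boundary, reverses or randomly reassigns the
#' lever probabilities. The returned `obs` carries the action and reward of
#' this pull (i.e. what the agent sees on its next step), with the
#' end-of-episode bit raised on the first observation of a new episode.
#'
#' @param env Environment state from [bandit_reset()] or a previous step.
#' @param action Integer lever index (1 or 2).
#' @return Updated environment state; `episode_done` flags a boundary,
#'   `optimal` whether the pull took the high-probability lever.
#' @export
bandit_step <- function(env, action) {
  if (!action %in% 1:2) stop("invalid lever")
  cfg <- env$cfg
  p <- if (action == env$high) cfg$p_high else cfg$p_low
  rewarded <- stats::runif(1) < p
  env$reward <- if (rewarded) cfg$reward_magnitude else 0
  env$optimal <- action == env$high
  env$pull_in_episode <- env$pull_in_episode + 1L
  boundary <- env$pull_in_episode >=
    bandit_episode_length(cfg, env$episode_index)
  if (boundary) {
    env$episode_index <- env$episode_index + 1L
    env$pull_in_episode <- 0L
    if (cfg$mode == "alternating") {
      env$high <- 3L - env$high
    } else {
      env$high <- if (stats::runif(1) < 0.5) 1L else 2L
    }
  }
  env$episode_done <- boundary
  env$obs <- bandit_obs(cfg, action, env$reward, boundary)
  env
}

#' Curriculum of memory-delay stages
#'
#' Training toward long memory delays proceeds through the stage list
#' `1, 2, 4, 5`, truncated at the target delay; each stage is trained until
#' criterion performance before the delay is lengthened.
#'
#' @param target_delay Final memory delay, in `1..5`.
#' @return Integer vector of delay stages ending at `target_delay`.
#' @examples
#' make_curriculum(5)  # 1 2 4 5
#' make_curriculum(2)  # 1 2
#' @export
make_curriculum <- function(target_delay) {
  stages <- c(1L, 2L, 4L, 5L)
  target_delay <- as.integer(target_delay)
  if (!target_delay %in% 1:5) stop("target delay must be in 1..5")
  out <- stages[stages < target_delay]
  c(out, target_delay)
}
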