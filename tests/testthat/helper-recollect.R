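# Shared fixtures for the test suite. Everything is generated in code.

tiny_hp <- function(n_in = 2, n_mem = 2, n_out = 2, output = "linear", ...) {
  hyperparameters(n_in = n_in, n_mem = n_mem, n_out = n_out,
                  output = output, ...)
}

# Environment state for a saccade trial already in a given phase, with a
# preset trial type (bypasses the random type draw for scripted trials).
scripted_saccade_env <- function(cfg, phase = "wait", pro = TRUE,
                                 cue_left = TRUE) {
  env <- saccade_reset(cfg)
  env$phase <- phase
  env$step_in_phase <- 1L
  env$trial_pro <- pro
  env$cue_left <- cue_left
  marker <- if (pro) 1L else 2L
  env$obs <- switch(phase,
    wait = recollect:::saccade_obs(cfg, marker = marker),
    cue = recollect:::saccade_obs(cfg, marker = marker,
                                  cue = if (cue_left) 1L else 2L),
    delay = recollect:::saccade_obs(cfg, marker = marker),
    go = recollect:::saccade_obs(cfg),
    recollect:::saccade_obs(cfg))
  env
}

# Drive a scripted saccade trial from the wait phase; returns total reward
# and the final environment.
play_saccade <- function(env, actions) {
  total <- 0
  for (a in actions) {
    env <- saccade_step(env, a)
    total <- total + env$reward
    if (env$trial_done) break
  }
  list(reward = total, env = env)
}

# Oracle policy that always completes saccade trials correctly by reading
# the environment state.
always_correct_policy <- function(obs, env) {
  if (env$phase %in% c("iti", "wait", "cue", "delay")) return(2L)
  if (env$trial_pro == env$cue_left) 1L else 3L
}

# A transcript data frame in the evaluate_bandit() layout.
make_transcript <- function(episode, trial, optimal, reward,
                            action = ifelse(optimal, 1L, 2L)) {
  data.frame(episode = episode, trial = trial, action = action,
             optimal = optimal, reward = reward)
}
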