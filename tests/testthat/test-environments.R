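test_that("a correct pro-saccade trial earns 0.2 + 1.5", {
  cfg <- saccade_config()
  env <- scripted_saccade_env(cfg, pro = TRUE, cue_left = TRUE)
  # fixate, hold through cue + 2 delay steps, saccade left at go
  res <- play_saccade(env, c(2, 2, 2, 2, 1))
  expect_equal(res$reward, 1.7)
  expect_true(res$env$trial_done)
  expect_true(res$env$correct)
})

test_that("an anti-saccade with a left cue is rewarded for looking right", {
  cfg <- saccade_config()
  env <- scripted_saccade_env(cfg, pro = FALSE, cue_left = TRUE)
  res <- play_saccade(env, c(2, 2, 2, 2, 3))
  expect_equal(res$reward, 1.7)
  expect_true(res$env$correct)
  # ... and looking at the cue is an error
  env2 <- scripted_saccade_env(cfg, pro = FALSE, cue_left = TRUE)
  res2 <- play_saccade(env2, c(2, 2, 2, 2, 1))
  expect_equal(res2$reward, 0.2)
  expect_false(res2$env$correct)
})

test_that("failing to fixate within 10 steps ends the trial unrewarded", {
  cfg <- saccade_config()
  env <- scripted_saccade_env(cfg)
  res <- play_saccade(env, rep(1, 10))
  expect_true(res$env$trial_done)
  expect_false(res$env$correct)
  expect_equal(res$reward, 0)
  # nine non-centre responses followed by fixation still works
  env2 <- scripted_saccade_env(cfg)
  res2 <- play_saccade(env2, c(rep(1, 9), 2, 2, 2, 2, 1))
  expect_equal(res2$reward, 1.7)
})

test_that("breaking fixation during cue or delay aborts without further reward", {
  cfg <- saccade_config()
  env <- scripted_saccade_env(cfg)
  res <- play_saccade(env, c(2, 1))          # break at cue
  expect_true(res$env$trial_done)
  expect_equal(res$reward, 0.2)
  env2 <- scripted_saccade_env(cfg)
  res2 <- play_saccade(env2, c(2, 2, 2, 3))  # break in delay
  expect_true(res2$env$trial_done)
  expect_equal(res2$reward, 0.2)
})

test_that("waiting at go consumes response steps until the timeout", {
  cfg <- saccade_config()
  env <- scripted_saccade_env(cfg, pro = TRUE, cue_left = FALSE)
  # 7 waits then a correct rightward saccade
  res <- play_saccade(env, c(2, 2, 2, 2, rep(2, 7), 3))
  expect_equal(res$reward, 1.7)
  # 8 waits: timeout
  env2 <- scripted_saccade_env(cfg, pro = TRUE, cue_left = FALSE)
  res2 <- play_saccade(env2, c(2, 2, 2, 2, rep(2, 8)))
  expect_true(res2$env$trial_done)
  expect_equal(res2$reward, 0.2)
})

test_that("the end-of-trial bit is raised for exactly one step per trial", {
  cfg <- saccade_config(end_of_trial_signal = TRUE, iti_steps = 3)
  set.seed(5)
  env <- saccade_reset(cfg)
  eot_steps <- 0; trials <- 0; steps <- 0
  while (trials < 30) {
    a <- sample(1:3, 1)
    env <- saccade_step(env, a)
    steps <- steps + 1
    if (env$obs[5] == 1) {
      eot_steps <- eot_steps + 1
      expect_true(env$trial_done)  # raised only at trial end
    }
    if (env$trial_done) trials <- trials + 1
  }
  expect_equal(eot_steps, trials)
  # without the signal the observation has only 4 units
  expect_equal(saccade_config()$n_in, 4L)
  expect_equal(cfg$n_in, 5L)
})

test_that("trial types are balanced in the long run", {
  cfg <- saccade_config()
  set.seed(11)
  env <- saccade_reset(cfg)
  pro <- 0; left <- 0; trials <- 0
  while (trials < 600) {
    env <- saccade_step(env, 1L)  # never fixate: fast failed trials
    if (env$trial_done) {
      trials <- trials + 1
      pro <- pro + env$trial_pro
      left <- left + env$cue_left
    }
  }
  expect_lt(abs(pro / 600 - 0.5), 3 * sqrt(0.25 / 600))
  expect_lt(abs(left / 600 - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("bandit observations report the previous pull, lagged by one step", {
  cfg <- bandit_config(p_high = 1, p_low = 0, episode_length = 5)
  set.seed(2)
  env <- bandit_reset(cfg)
  expect_equal(env$obs, rep(0, 4))  # first step: nothing to report
  high <- env$high
  env <- bandit_step(env, high)
  expect_equal(env$obs[high], 1)
  expect_equal(env$obs[3], 1)       # rewarded with certainty
  env <- bandit_step(env, 3L - high)
  expect_equal(env$obs[3L - high], 1)
  expect_equal(env$obs[3], 0)       # never rewarded
  expect_error(bandit_step(env, 5), "invalid")
})

test_that("alternating reversals swap the high lever every episode", {
  cfg <- bandit_config(episode_length = 3)
  set.seed(4)
  env <- bandit_reset(cfg)
  firsts <- integer(0)
  for (ep in 1:6) {
    firsts <- c(firsts, env$high)
    for (i in 1:3) env <- bandit_step(env, 1L)
  }
  expect_equal(firsts[c(1, 3, 5)], rep(firsts[1], 3))
  expect_equal(firsts[c(2, 4, 6)], rep(3L - firsts[1], 3))
})

test_that("the end-of-episode bit marks only the first observation of an episode", {
  cfg <- bandit_config(episode_length = 4, end_of_episode_signal = TRUE)
  set.seed(9)
  env <- bandit_reset(cfg)
  bits <- logical(0)
  for (i in 1:20) {
    env <- bandit_step(env, sample(1:2, 1))
    bits <- c(bits, env$obs[4] == 1)
  }
  # raised exactly at pulls 4, 8, 12, 16, 20 (observation for the next step)
  expect_equal(which(bits), c(4L, 8L, 12L, 16L, 20L))
  cfg2 <- bandit_config(episode_length = 4, end_of_episode_signal = FALSE)
  set.seed(9)
  env2 <- bandit_reset(cfg2)
  for (i in 1:20) {
    env2 <- bandit_step(env2, sample(1:2, 1))
    expect_equal(env2$obs[4], 0)
  }
})

test_that("the 75% lever pays at its programmed rate", {
  cfg <- bandit_config(episode_length = 10000, mode = "alternating")
  set.seed(100)
  env <- bandit_reset(cfg)
  high <- env$high
  rew <- 0
  for (i in 1:10000) {
    env <- bandit_step(env, high)
    rew <- rew + env$reward
  }
  expect_lt(abs(rew / 10000 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
})

test_that("the delay curriculum lists the published stages", {
  expect_equal(make_curriculum(5), c(1L, 2L, 4L, 5L))
  expect_equal(make_curriculum(2), c(1L, 2L))
  expect_equal(make_curriculum(1), 1L)
  expect_equal(make_curriculum(4), c(1L, 2L, 4L))
  expect_error(make_curriculum(7), "1..5")
})

test_that("episode-length schedules recycle per episode index", {
  cfg <- bandit_config(episode_lengths = c(24L, 16L, 8L))
  expect_equal(recollect:::bandit_episode_length(cfg, 1), 24L)
  expect_equal(recollect:::bandit_episode_length(cfg, 2), 16L)
  expect_equal(recollect:::bandit_episode_length(cfg, 3), 8L)
  expect_equal(recollect:::bandit_episode_length(cfg, 4), 24L)
})
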