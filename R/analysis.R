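#' Record unit activities on scripted saccade trials
#'
#' Runs a (typically trained) agent with learning and exploration disabled
#' over `n_trials` trials and logs every unit's activity at every
#' timestep, together with the trial factors needed for selectivity
#' analysis. Trial types are presented in permuted blocks so the factors
#' are fully crossed.
#'
#' @param agent A `recollect_agent`.
#' @param cfg A [saccade_config()] (its delay/ITI settings are used).
#' @param n_trials Completed trials to record.
#' @param seed Optional seed for the block permutations.
#' @return Data frame with columns `trial`, `step`, `phase`, `saccade_type`
#'   (`"pro"`/`"anti"`), `cue_side` (`"L"`/`"R"`), `action`, `reward`, and
#'   one column per unit: gate `k1..`, candidate `C1..`, memory `M1..`,
#'   output `q1..`.
#' @export
collect_saccade_activity <- function(agent, cfg, n_trials = 40,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg$type_schedule <- "balanced"
  hp <- agent$hp
  env <- saccade_reset(cfg)
  rows <- list()
  trial <- 1L
  step <- 0L
  while (trial <= n_trials) {
    step <- step + 1L
    phase <- env$phase
    pro <- env$trial_pro; cl <- env$cue_left
    st <- learn_step(agent, env$obs, env$reward, learn = FALSE, epsilon = 0)
    agent <- st$agent
    rows[[length(rows) + 1L]] <- data.frame(
      trial = trial, step = step, phase = phase,
      saccade_type = if (isTRUE(pro)) "pro" else if (isFALSE(pro)) "anti"
        else NA_character_,
      cue_side = if (isTRUE(cl)) "L" else if (isFALSE(cl)) "R"
        else NA_character_,
      action = st$action,
      t(c(stats::setNames(st$state$k, paste0("k", seq_len(hp$n_mem))),
          stats::setNames(st$state$C, paste0("C", seq_len(hp$n_mem))),
          stats::setNames(st$state$M, paste0("M", seq_len(hp$n_mem))),
          stats::setNames(st$state$q, paste0("q", seq_len(hp$n_out))))),
      stringsAsFactors = FALSE)
    env <- saccade_step(env, st$action)
    if (env$trial_done) trial <- trial + 1L
  }
  do.call(rbind, rows)
}

# D'Agostino-Pearson omnibus normality test (K^2 against chi-square 2 df):
# combines transformed sample skewness and kurtosis.
dagostino_omnibus <- function(x) {
  n <- length(x)
  if (n < 20) return(list(statistic = NA_real_, p.value = 1))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) return(list(statistic = NA_real_, p.value = 1))
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p.value = stats::pchisq(K2, df = 2,
                                               lower.tail = FALSE))
}

# Jarque-Bera test on residuals (chi-square 2 df).
jarque_bera <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0 || n < 4) return(list(statistic = NA_real_, p.value = 1))
  S <- mean((x - m)^3) / m2^1.5
  K <- mean((x - m)^4) / m2^2
  JB <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = JB, p.value = stats::pchisq(JB, df = 2,
                                               lower.tail = FALSE))
}

#' Per-unit selectivity regression with diagnostics and robust fallback
#'
#' For every unit, the mean activity per trial within the given task phase
#' is regressed on saccade type, cue side and their interaction. Residual
#' diagnostics — a D'Agostino-Pearson omnibus normality test, the
#' Durbin-Watson test and the Jarque-Bera test, each at alpha 0.05 —
#' decide between the ordinary least-squares fit and a robust fit with
#' Huber's t function ([MASS::rlm]). P-values are Bonferroni-corrected
#' across all tests performed in the call.
#'
#' @param activity A table from [collect_saccade_activity()].
#' @param phase Phase window: `"cue"`, `"delay"` or `"go"`.
#' @param units Unit columns to analyse (default: all `k/C/M/q` columns).
#' @param alpha Significance level (0.05).
#' @return Data frame with one row per unit x effect: `unit`,
#'   `unit_class`, `effect` (`saccade_type`, `cue_side`, `interaction`),
#'   `estimate`, `p_raw`, `p_adj`, `significant`, `model` (`"ols"` or
#'   `"robust"`), `testable`.
#' @export
selectivity_regression <- function(activity, phase = c("cue", "delay", "go"),
                                   units = NULL, alpha = 0.05) {
  phase <- match.arg(phase)
  dat <- activity[activity$phase == phase &
                    !is.na(activity$saccade_type), ]
  if (is.null(units))
    units <- grep("^[kCMq][0-9]+$", names(activity), value = TRUE)
  effects <- c("saccade_type", "cue_side", "interaction")
  out <- list()
  for (u in units) {
    per_trial <- stats::aggregate(
      dat[[u]], by = list(trial = dat$trial,
                          saccade_type = dat$saccade_type,
                          cue_side = dat$cue_side), FUN = mean)
    names(per_trial)[4] <- "y"
    cells <- table(per_trial$saccade_type, per_trial$cue_side)
    testable <- all(dim(cells) == c(2, 2)) && all(cells >= 2) &&
      stats::var(per_trial$y) > 1e-16
    if (!testable) {
      out[[u]] <- data.frame(unit = u, unit_class = substr(u, 1, 1),
                             effect = effects, estimate = NA_real_,
                             p_raw = NA_real_, p_adj = NA_real_,
                             significant = FALSE, model = NA_character_,
                             testable = FALSE, stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm(y ~ saccade_type * cue_side, data = per_trial)
    res <- stats::residuals(fit)
    robust <- dagostino_omnibus(res)$p.value < alpha ||
      lmtest::dwtest(fit)$p.value < alpha ||
      jarque_bera(res)$p.value < alpha
    if (robust) {
      fit <- MASS::rlm(y ~ saccade_type * cue_side, data = per_trial,
                       maxit = 100)
      cf <- summary(fit)$coefficients
      pv <- 2 * stats::pnorm(-abs(cf[, "t value"]))
    } else {
      cf <- summary(fit)$coefficients
      pv <- cf[, 4]
    }
    idx <- 2:4  # main effects and interaction
    out[[u]] <- data.frame(unit = u, unit_class = substr(u, 1, 1),
                           effect = effects,
                           estimate = unname(cf[idx, 1]),
                           p_raw = unname(pv[idx]), p_adj = NA_real_,
                           significant = FALSE,
                           model = if (robust) "robust" else "ols",
                           testable = TRUE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_tests <- sum(!is.na(res$p_raw))
  res$p_adj <- pmin(1, res$p_raw * n_tests)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Record unit activities during bandit evaluation
#'
#' Greedy, plasticity-off evaluation that logs gate, candidate, memory and
#' Q-value activities at every pull, for reversal-aligned averaging.
#'
#' @param trained Result of [train_bandit()].
#' @param cfg The [bandit_config()] of the run.
#' @param n_episodes Evaluation episodes to record.
#' @return Data frame: `episode`, `trial`, `high` (high lever that
#'   episode), `action`, `optimal`, `reward`, and per-unit activity
#'   columns.
#' @export
collect_bandit_activity <- function(trained, cfg, n_episodes = 60) {
  agent <- trained$agent
  hp <- agent$hp
  es <- trained$env_state
  high <- es$high; episode_index <- es$episode_index
  prev_action <- es$prev_action; prev_reward <- es$prev_reward
  eoe_flag <- es$eoe_flag
  rows <- list()
  for (ep in seq_len(n_episodes)) {
    len <- bandit_episode_length(cfg, episode_index)
    for (pull in seq_len(len)) {
      x <- numeric(4)
      if (prev_action > 0) x[prev_action] <- 1
      x[3] <- prev_reward / cfg$reward_magnitude
      if (cfg$end_of_episode_signal && eoe_flag) x[4] <- 1
      st <- learn_step(agent, x, prev_reward, learn = FALSE, epsilon = 0)
      agent <- st$agent
      a <- st$action
      p <- if (a == high) cfg$p_high else cfg$p_low
      rew <- if (stats::runif(1) < p) cfg$reward_magnitude else 0
      rows[[length(rows) + 1L]] <- data.frame(
        episode = episode_index, trial = pull, high = high, action = a,
        optimal = a == high, reward = rew,
        t(c(stats::setNames(st$state$k, paste0("k", seq_len(hp$n_mem))),
            stats::setNames(st$state$C, paste0("C", seq_len(hp$n_mem))),
            stats::setNames(st$state$M, paste0("M", seq_len(hp$n_mem))),
            stats::setNames(st$state$q, paste0("q", seq_len(hp$n_out))))))
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
  do.call(rbind, rows)
}

#' Reversal-aligned average unit activity
#'
#' Aligns activities on episode starts (each start of a non-first episode
#' is a reversal), splits by which lever is high during the episode, and
#' averages within condition; the standard error of the mean quantifies
#' across-episode variability.
#'
#' @param activity Table from [collect_bandit_activity()] (or any data
#'   frame with `episode`, `trial`, `high` and numeric unit columns).
#' @param window Trials from episode start to include.
#' @param units Unit columns (default: all activity columns present).
#' @return Data frame: `high`, `trial`, `unit`, `mean`, `sem`, `n`.
#' @export
reversal_aligned_average <- function(activity, window = 20, units = NULL) {
  if (is.null(units))
    units <- grep("^[kCMq][0-9]+$", names(activity), value = TRUE)
  first_ep <- min(activity$episode)
  dat <- activity[activity$trial <= window & activity$episode > first_ep, ]
  if (length(unique(dat$episode)) < 2)
    stop("need at least two reversal-aligned episodes")
  out <- list()
  for (u in units) {
    ag <- stats::aggregate(dat[[u]],
                           by = list(high = dat$high, trial = dat$trial),
                           FUN = function(z)
                             c(mean = mean(z),
                               sem = stats::sd(z) / sqrt(length(z)),
                               n = length(z)))
    out[[u]] <- data.frame(high = ag$high, trial = ag$trial, unit = u,
                           mean = ag$x[, "mean"], sem = ag$x[, "sem"],
                           n = ag$x[, "n"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Memory-unit persistence across delay lengths
#'
#' Probes a trained agent with scripted trials at each requested memory
#' delay and returns the per-step average memory-unit activity, aligned on
#' trial start. For a unit with persistent delay coding, the span of
#' elevated activity lengthens with the delay and collapses after the
#' end-of-trial signal.
#'
#' @param agent A `recollect_agent` (trained with variable delays).
#' @param cfg Base [saccade_config()].
#' @param delays Delay lengths to probe.
#' @param n_trials Trials per delay.
#' @param seed Optional seed.
#' @return Data frame: `delay`, `phase`, `step_in_trial`, one mean-activity
#'   column per memory unit.
#' @export
delay_persistence_profile <- function(agent, cfg, delays = 1:5,
                                      n_trials = 24, seed = NULL) {
  out <- list()
  for (d in delays) {
    cfg_d <- cfg
    cfg_d$delay_steps <- as.integer(d)
    act <- collect_saccade_activity(agent, cfg_d, n_trials = n_trials,
                                    seed = seed)
    act$step_in_trial <- stats::ave(act$step, act$trial, FUN = seq_along)
    mcols <- grep("^M[0-9]+$", names(act), value = TRUE)
    ag <- stats::aggregate(act[mcols],
                           by = list(step_in_trial = act$step_in_trial),
                           FUN = mean)
    phs <- stats::aggregate(list(phase = act$phase),
                            by = list(step_in_trial = act$step_in_trial),
                            FUN = function(z) names(sort(table(z),
                                                         decreasing = TRUE))[1])
    ag <- merge(phs, ag, by = "step_in_trial")
    ag$delay <- d
    out[[as.character(d)]] <- ag
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
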