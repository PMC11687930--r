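#' Cumulative regret of a bandit transcript
#'
#' Regret accrues whenever the chosen lever deviates from the optimal one
#' and the expected reward of the optimal lever is forfeited: each
#' suboptimal pull contributes `p_high * reward_magnitude`. (This —
#' rather than the expected-reward *difference* between the levers — is
#' the convention under which the published accuracy/regret pairs are
#' internally consistent, here and for the LSTM-based meta-learners used
#' as the comparison basis: 2.8 suboptimal pulls per 100 x 0.75 = 2.1.)
#' Reported per episode and as a total.
#'
#' @param transcript Data frame with columns `episode` and `optimal`
#'   (logical), as produced by [evaluate_bandit()].
#' @param cfg The [bandit_config()] of the run.
#' @return List with `per_episode` (named numeric vector),
#'   `mean_per_episode` and `total`.
#' @export
cumulative_regret <- function(transcript, cfg) {
  if (nrow(transcript) == 0) stop("empty transcript")
  gap <- cfg$p_high * cfg$reward_magnitude
  per_ep <- tapply(!transcript$optimal, transcript$episode,
                   function(z) sum(z) * gap)
  per_ep <- per_ep[order(as.integer(names(per_ep)))]
  list(per_episode = per_ep,
       mean_per_episode = mean(per_ep),
       total = sum(per_ep))
}

#' Reward history preceding correct versus incorrect choices
#'
#' For every pull from the fourth onward within an episode, averages the
#' reward obtained on the preceding three pulls, grouped by whether the
#' current pull took the high-probability lever. Episodes that are
#' entirely correct or entirely incorrect are excluded, as are the first
#' three pulls of each episode (to avoid confounding with the reversal
#' itself). A low preceding reward before errors indicates that runs of
#' omitted rewards are what drives the model to (wrongly) infer a context
#' switch.
#'
#' @param transcript Data frame with columns `episode`, `trial`, `reward`,
#'   `optimal` (see [evaluate_bandit()]).
#' @return List with `before_correct` and `before_incorrect` (mean
#'   preceding rewards) and the contributing counts `n_correct`,
#'   `n_incorrect`.
#' @export
preceding_reward_analysis <- function(transcript) {
  tr <- transcript[order(transcript$episode, transcript$trial), ]
  mixed <- tapply(tr$optimal, tr$episode,
                  function(z) any(z) && !all(z))
  keep_ep <- as.integer(names(mixed))[mixed]
  vals_c <- numeric(0); vals_i <- numeric(0)
  for (ep in keep_ep) {
    e <- tr[tr$episode == ep, ]
    if (nrow(e) < 4) next
    for (t in 4:nrow(e)) {
      m <- mean(e$reward[(t - 3):(t - 1)])
      if (e$optimal[t]) vals_c <- c(vals_c, m) else vals_i <- c(vals_i, m)
    }
  }
  if (length(vals_c) == 0 && length(vals_i) == 0)
    warning("no episodes with mixed outcomes of length >= 4")
  list(before_correct = if (length(vals_c)) mean(vals_c) else NA_real_,
       before_incorrect = if (length(vals_i)) mean(vals_i) else NA_real_,
       n_correct = length(vals_c), n_incorrect = length(vals_i))
}

#' Switch latency after each reversal
#'
#' Number of pulls from the start of each episode (i.e. after a reversal)
#' until the high-probability lever is first chosen. A model exploiting an
#' end-of-episode signal switches within one pull; without it, evidence
#' must be integrated over several pulls.
#'
#' @param transcript Evaluation transcript (see [evaluate_bandit()]).
#' @param drop_first Exclude the first recorded episode (whose start is
#'   not reversal-aligned).
#' @return Integer vector of latencies (one per episode); an episode with
#'   no optimal pull contributes its length + 1.
#' @export
reversal_switch_trials <- function(transcript, drop_first = TRUE) {
  eps <- sort(unique(transcript$episode))
  if (drop_first && length(eps) > 1) eps <- eps[-1]
  vapply(eps, function(ep) {
    z <- transcript$optimal[transcript$episode == ep]
    w <- which(z)
    if (length(w)) w[1] else length(z) + 1L
  }, integer(1))
}

#' Q-value crossover latency after each reversal
#'
#' For each reversal-aligned episode, the first pull at which the Q-value
#' of the newly optimal lever exceeds that of the previously optimal one.
#' With an end-of-episode signal the crossover completes within a single
#' pull; without it the model must integrate omitted rewards over several
#' pulls before its value estimates swap.
#'
#' @param transcript Evaluation transcript recorded with Q-values
#'   (`evaluate_bandit(..., record_q = TRUE)`).
#' @param drop_first Exclude the first recorded episode.
#' @return Integer vector of crossover latencies, one per episode
#'   (episode length + 1 if the values never cross).
#' @export
q_crossover_trials <- function(transcript, drop_first = TRUE) {
  if (is.null(transcript$q1))
    stop("transcript has no recorded Q-values; evaluate with record_q = TRUE")
  high <- ifelse(transcript$optimal, transcript$action,
                 3L - transcript$action)
  eps <- sort(unique(transcript$episode))
  if (drop_first && length(eps) > 1) eps <- eps[-1]
  vapply(eps, function(ep) {
    sel <- transcript$episode == ep
    h <- high[sel]; q1 <- transcript$q1[sel]; q2 <- transcript$q2[sel]
    lead <- ifelse(h == 1L, q1 - q2, q2 - q1)
    w <- which(lead > 0)
    if (length(w)) w[1] else sum(sel) + 1L
  }, integer(1))
}

#' Serial-reversal experiment on the deterministic bandit
#'
#' Reproduces the rodent serial-reversal protocol: one lever is always
#' rewarded and the other never; the first episode lasts 24 trials, the
#' next 16, and all later episodes 8, with deterministic reversals.
#' Training runs online across `n_episodes` episodes for `n_networks`
#' independently initialised networks, and the per-trial error counts
#' (choices of the unrewarded lever, summed over networks) are returned
#' for selected episodes.
#'
#' @param n_networks Number of networks (48 in the published protocol).
#' @param n_episodes Episodes to run (226 reaches the last plotted
#'   reversal).
#' @param plot_episodes Episodes whose per-trial error counts to return.
#' @param seed Base seed; network `i` uses `seed * 1000 + i`.
#' @param engine `"cpp"` or `"r"`.
#' @return List with `errors_by_trial` (named list: episode -> integer
#'   vector of summed errors per trial) and the full `error_matrix`
#'   (episode-major trial index x nothing; a data frame of per-trial
#'   summed errors).
#' @export
rat_schedule_experiment <- function(n_networks = 48, n_episodes = 226,
                                    plot_episodes = c(1, 2, 175, 176, 200,
                                                      201, 225, 226),
                                    seed = 1, engine = "cpp") {
  preset <- recollect_preset("rat-schedule")
  preset$env$episode_lengths <-
    c(24L, 16L, rep(8L, max(0L, n_episodes - 2L)))
  total <- NULL
  for (i in seq_len(n_networks)) {
    res <- train_bandit(preset, seed = seed * 1000 + i,
                        n_episodes = n_episodes, engine = engine,
                        record = TRUE)
    tr <- res$transcript
    err <- as.integer(!tr$optimal)
    if (is.null(total)) {
      total <- data.frame(episode = tr$episode, trial = tr$trial,
                          errors = err)
    } else {
      total$errors <- total$errors + err
    }
  }
  by_ep <- lapply(plot_episodes, function(ep)
    total$errors[total$episode == ep])
  names(by_ep) <- as.character(plot_episodes)
  list(errors_by_trial = by_ep, error_table = total,
       n_networks = n_networks)
}

#' Trials to recover after a reversal, from summed error curves
#'
#' Helper for the learning-to-learn signature: given a per-trial summed
#' error vector for an episode that starts at a reversal, returns the
#' first trial index at which the error count drops to or below
#' `frac * n_networks` (i.e. most networks have switched).
#'
#' @param errors Integer vector of summed errors per trial.
#' @param n_networks Number of networks summed over.
#' @param frac Error fraction defining recovery (0.5).
#' @return Integer trial index (length(errors) + 1 if never reached).
#' @export
trials_to_recover <- function(errors, n_networks, frac = 0.5) {
  w <- which(errors <= frac * n_networks)
  if (length(w)) w[1] else length(errors) + 1L
}
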