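#' Construct and validate a set of network hyperparameters
#'
#' Bundles the learning rates, temporal-difference constants, exploration
#' rate, activation slope and layer sizes of a gated working-memory network.
#'
#' @param beta Learning rate for candidate-memory, output and feedback
#'   weights (and their biases).
#' @param beta_gate Learning rate specific to the gating-unit weights; kept
#'   lower than `beta` because fast gate plasticity destabilises learning.
#' @param gamma Reward discount factor in `[0, 1]`.
#' @param lam Tag decay rate in `[0, 1]`; tags decay by `lam * gamma` per
#'   step, implementing SARSA(lambda).
#' @param epsilon Exploration probability of the epsilon-greedy policy.
#' @param rho Slope of the sigmoid activation (> 0).
#' @param n_in,n_mem,n_out Layer sizes: inputs, light-GRU (memory) units,
#'   output (Q-value) units.
#' @param output Output-unit activation: `"sigmoid"` squashes Q-values into
#'   (0, 1); `"linear"` leaves them unbounded. See the methods vignette for
#'   why the experiment presets use linear outputs.
#' @param init_range Half-width of the uniform weight initialisation
#'   interval `[-init_range, init_range]`.
#' @return An object of class `recollect_hp` (a validated list).
#' @seealso [recollect_preset()] for the published per-task configurations.
#' @export
hyperparameters <- function(beta = 0.1, beta_gate = 0.006, gamma = 0.9,
                            lam = 0.4, epsilon = 0.025, rho = 2,
                            n_in = 4, n_mem = 7, n_out = 3,
                            output = c("sigmoid", "linear"),
                            init_range = 0.25) {
  output <- match.arg(output)
  stopifnot(
    is.numeric(beta), length(beta) == 1, beta > 0,
    is.numeric(beta_gate), length(beta_gate) == 1, beta_gate > 0,
    is.numeric(gamma), gamma >= 0, gamma <= 1,
    is.numeric(lam), lam >= 0, lam <= 1,
    is.numeric(epsilon), epsilon >= 0, epsilon <= 1,
    is.numeric(rho), rho > 0,
    is.numeric(init_range), init_range >= 0
  )
  n_in <- as.integer(n_in); n_mem <- as.integer(n_mem); n_out <- as.integer(n_out)
  if (n_in < 1L || n_mem < 1L || n_out < 1L)
    stop("layer sizes must be >= 1")
  structure(
    list(beta = beta, beta_gate = beta_gate, gamma = gamma, lam = lam,
         epsilon = epsilon, rho = rho, n_in = n_in, n_mem = n_mem,
         n_out = n_out, output = output, init_range = init_range),
    class = "recollect_hp"
  )
}

#' @export
print.recollect_hp <- function(x, ...) {
  cat(sprintf(
    "gated-memory hyperparameters: %d-%d-%d (%s output)\n", x$n_in, x$n_mem,
    x$n_out, x$output))
  cat(sprintf("  beta=%g beta_gate=%g gamma=%g lambda=%g epsilon=%g rho=%g\n",
              x$beta, x$beta_gate, x$gamma, x$lam, x$epsilon, x$rho))
  invisible(x)
}

#' Published per-task hyperparameter presets
#'
#' Returns the full run configuration (hyperparameters plus task settings)
#' for each published experiment variant.
#'
#' \describe{
#'   \item{`saccade`}{Pro-/anti-saccade task, 4 inputs (no end-of-trial
#'     unit), 7 light-GRU units, 3 outputs; beta 0.1, beta_gate 0.006,
#'     gamma 0.9, lambda 0.4, epsilon 0.025.}
#'   \item{`saccade+eot`}{Same, with a fifth input unit carrying the
#'     end-of-trial signal.}
#'   \item{`bandit`}{Alternating reversal bandit, 4 inputs, 4 light-GRU
#'     units, 2 outputs; beta 0.01, beta_gate 0.006, lambda 0.2.}
#'   \item{`bandit-no-signal`}{Alternating reversal bandit with the
#'     end-of-episode input silenced.}
#'   \item{`random-bandit`}{Random reversal bandit, 5 light-GRU units;
#'     beta 0.005, beta_gate 0.0005, lambda 0.1.}
#'   \item{`rat-schedule`}{Deterministic (100%/0%) serial-reversal bandit on
#'     the 24/16/8 episode schedule, 4 light-GRU units with the faster
#'     learning settings (beta 0.1, lambda 0.4) so that adaptation is
#'     possible within the short protocol; no end-of-episode signal.}
#' }
#'
#' @param name Preset name.
#' @return A list with elements `hp` (a [hyperparameters()] object), `task`
#'   (`"saccade"` or `"bandit"`) and `env` (a [saccade_config()] or
#'   [bandit_config()]).
#' @export
recollect_preset <- function(name = c("saccade", "saccade+eot", "bandit",
                                      "bandit-no-signal", "random-bandit",
                                      "rat-schedule")) {
  name <- match.arg(name)
  switch(name,
    "saccade" = list(
      task = "saccade",
      hp = hyperparameters(beta = 0.1, beta_gate = 0.006, gamma = 0.9,
                           lam = 0.4, epsilon = 0.025, rho = 2,
                           n_in = 4, n_mem = 7, n_out = 3, output = "linear"),
      env = saccade_config(end_of_trial_signal = FALSE)
    ),
    "saccade+eot" = list(
      task = "saccade",
      hp = hyperparameters(beta = 0.1, beta_gate = 0.006, gamma = 0.9,
                           lam = 0.4, epsilon = 0.025, rho = 2,
                           n_in = 5, n_mem = 7, n_out = 3, output = "linear"),
      env = saccade_config(end_of_trial_signal = TRUE)
    ),
    "bandit" = list(
      task = "bandit",
      hp = hyperparameters(beta = 0.01, beta_gate = 0.006, gamma = 0.9,
                           lam = 0.2, epsilon = 0.025, rho = 2,
                           n_in = 4, n_mem = 4, n_out = 2, output = "linear"),
      env = bandit_config(end_of_episode_signal = TRUE)
    ),
    "bandit-no-signal" = list(
      task = "bandit",
      hp = hyperparameters(beta = 0.01, beta_gate = 0.006, gamma = 0.9,
                           lam = 0.2, epsilon = 0.025, rho = 2,
                           n_in = 4, n_mem = 4, n_out = 2, output = "linear"),
      env = bandit_config(end_of_episode_signal = FALSE)
    ),
    "random-bandit" = list(
      task = "bandit",
      hp = hyperparameters(beta = 0.005, beta_gate = 0.0005, gamma = 0.9,
                           lam = 0.1, epsilon = 0.025, rho = 2,
                           n_in = 4, n_mem = 5, n_out = 2, output = "linear"),
      env = bandit_config(mode = "random", end_of_episode_signal = TRUE)
    ),
    "rat-schedule" = list(
      task = "bandit",
      hp = hyperparameters(beta = 0.1, beta_gate = 0.006, gamma = 0.9,
                           lam = 0.4, epsilon = 0.025, rho = 2,
                           n_in = 4, n_mem = 4, n_out = 2, output = "linear"),
      env = bandit_config(p_high = 1, p_low = 0,
                          episode_lengths = c(24L, 16L, rep(8L, 224L)),
                          end_of_episode_signal = FALSE)
    )
  )
}
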