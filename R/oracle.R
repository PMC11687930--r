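#' Build a replay history for gradient probing
#'
#' A frozen record of everything needed to differentiate the selected
#' action value with respect to the parameters: the input sequence, the
#' initial memory, a parameter snapshot, and which output unit is probed
#' at which timestep. Replaying is deterministic, so central differences
#' are well defined.
#'
#' @param X Matrix of inputs, one row per timestep (`len x n_in`), values
#'   in `[0, 1]`.
#' @param M0 Initial memory vector.
#' @param params Parameter snapshot (as in [new_agent()]).
#' @param hp A [hyperparameters()] object.
#' @param probe_t Timestep whose output is probed (defaults to the last).
#' @param probe_action Output unit probed (defaults to 1).
#' @return A `replay_history` list.
#' @export
replay_history <- function(X, M0, params, hp, probe_t = nrow(X),
                           probe_action = 1) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == hp$n_in, length(M0) == hp$n_mem,
            probe_t >= 1, probe_t <= nrow(X),
            probe_action >= 1, probe_action <= hp$n_out)
  structure(list(X = X, M0 = M0, params = params, hp = hp,
                 probe_t = as.integer(probe_t),
                 probe_action = as.integer(probe_action)),
            class = "replay_history")
}

#' Random small network and input history for gradient checking
#'
#' Draws a parameter snapshot (feedback weights tied to the transpose of
#' the output weights, the configuration in which the local rule is the
#' exact gradient) and a uniform input sequence.
#'
#' @param n_in,n_mem,n_out Layer sizes.
#' @param len History length.
#' @param seed Optional seed.
#' @param output Output activation (`"linear"` by default: the
#'   configuration the gradient derivation assumes).
#' @return A [replay_history()].
#' @export
random_history <- function(n_in = 3, n_mem = 2, n_out = 2, len = 5,
                           seed = NULL, output = "linear") {
  if (!is.null(seed)) set.seed(seed)
  hp <- hyperparameters(n_in = n_in, n_mem = n_mem, n_out = n_out,
                        output = output)
  agent <- new_agent(hp, tie_feedback = TRUE)
  X <- matrix(stats::runif(len * n_in), len, n_in)
  M0 <- stats::runif(n_mem)
  probe_t <- len
  probe_action <- floor(stats::runif(1) * n_out) + 1
  replay_history(X, M0, agent$params, hp, probe_t, min(probe_action, n_out))
}

#' Replay a history and return the probed action value
#'
#' Runs the forward dynamics from the initial memory over the stored input
#' sequence with the snapshot parameters (optionally overridden) and
#' returns the probed output unit's value at the probed timestep.
#'
#' @param history A [replay_history()].
#' @param params_override Optional replacement parameter list (e.g. a
#'   perturbed copy).
#' @param M0_override Optional replacement initial memory.
#' @return Scalar action value `q_s(probe_t)`.
#' @export
q_of_history <- function(history, params_override = NULL,
                         M0_override = NULL) {
  hp <- history$hp
  params <- if (is.null(params_override)) history$params else params_override
  M <- if (is.null(M0_override)) history$M0 else M0_override
  for (t in seq_len(history$probe_t)) {
    st <- forward(params, history$X[t, ], M, hp)
    M <- st$M
  }
  st$q[history$probe_action]
}

#' Central-difference gradient of the probed action value
#'
#' Perturbs one named parameter coordinate by `+h` and `-h` and returns
#' `(q(+h) - q(-h)) / (2h)`.
#'
#' @param history A [replay_history()].
#' @param param Parameter name (`"W_C"`, `"W_k"`, `"W_q"`, `"b_C"`, ...,
#'   or `"M0"` for the initial memory).
#' @param i,j Coordinate indices (`j` ignored for vectors).
#' @param h Step size (parameters here are O(1), so `1e-5` balances
#'   truncation against rounding).
#' @return Scalar gradient estimate.
#' @export
numerical_gradient <- function(history, param, i, j = NULL, h = 1e-5) {
  stopifnot(h > 0)
  perturb <- function(sign) {
    if (param == "M0") {
      M0 <- history$M0
      M0[i] <- M0[i] + sign * h
      return(q_of_history(history, M0_override = M0))
    }
    p <- history$params
    if (is.matrix(p[[param]])) p[[param]][i, j] <- p[[param]][i, j] + sign * h
    else p[[param]][i] <- p[[param]][i] + sign * h
    q_of_history(history, params_override = p)
  }
  (perturb(1) - perturb(-1)) / (2 * h)
}

# Recompute traces (and gate products) along a history; pure replay of the
# trace recursions, no learning.
replay_traces <- function(history) {
  hp <- history$hp
  params <- history$params
  M <- history$M0
  trace_C <- matrix(0, hp$n_in, hp$n_mem)
  trace_k <- matrix(0, hp$n_in, hp$n_mem)
  trace_bC <- rep(0, hp$n_mem); trace_bk <- rep(0, hp$n_mem)
  kprod <- rep(1, hp$n_mem)
  for (t in seq_len(history$probe_t)) {
    x <- history$X[t, ]
    st <- forward(params, x, M, hp)
    tc <- update_trace_c(trace_C, trace_bC, x, st$k, st$inp_C, hp$rho)
    tk <- update_trace_k(trace_k, trace_bk, x, st$k, M, st$C, st$inp_k,
                         hp$rho)
    trace_C <- tc$trace_C; trace_bC <- tc$trace_bC
    trace_k <- tk$trace_k; trace_bk <- tk$trace_bk
    kprod <- kprod * st$k
    M <- st$M
  }
  list(trace_C = trace_C, trace_k = trace_k, trace_bC = trace_bC,
       trace_bk = trace_bk, kprod = kprod, final = st)
}

#' Verify the trace/tag machinery against finite-difference gradients
#'
#' Recomputes the synaptic traces along a replay history and checks the
#' locality identities: the trace times the attentional feedback weight of
#' the probed action equals the (central-difference) gradient of the
#' probed action value with respect to every candidate-memory and gating
#' weight, and the sensitivity to the initial memory equals the product of
#' the gates times the feedback weight. With sigmoid output units the
#' exact gradient carries one additional shared factor — the slope of the
#' output activation at the probe step — which is included in the local
#' prediction (it is 1 for linear outputs, the configuration the
#' derivation assumes). The identities are structural, not approximate,
#' because the network has no recurrent weights.
#'
#' @param history A [replay_history()] whose snapshot has
#'   `W_FB = t(W_q)` (as produced by [random_history()]).
#' @param h Central-difference step.
#' @param tol Relative tolerance; exceeding it raises an error naming the
#'   offending coordinate.
#' @param stop_on_fail Raise an error on tolerance violation (otherwise
#'   just report).
#' @return Data frame with one row per parameter class (`W_C`, `W_k`,
#'   `b_C`, `b_k`, `M0`): maximum absolute and relative discrepancy and
#'   the number of coordinates checked.
#' @export
verify_trace_gradient <- function(history, h = 1e-5, tol = 1e-4,
                                  stop_on_fail = FALSE) {
  hp <- history$hp
  s <- history$probe_action
  rp <- replay_traces(history)
  w_fb <- history$params$W_FB[s, ]
  # slope of the output activation at the probe step (1 if linear)
  g_out <- if (hp$output == "sigmoid")
    sigmoid_deriv(rp$final$inp_q[s], hp$rho) else 1
  rel <- function(diff, num) abs(diff) / pmax(abs(num), 1e-2)

  check_class <- function(name, local_fun, coords) {
    worst_abs <- 0; worst_rel <- 0; worst_coord <- ""
    for (cc in coords) {
      num <- numerical_gradient(history, name, cc[1],
                                if (length(cc) > 1) cc[2] else NULL, h)
      loc <- local_fun(cc)
      d <- loc - num
      r <- rel(d, num)
      if (r > worst_rel) {
        worst_rel <- r; worst_abs <- abs(d)
        worst_coord <- paste(c(name, cc), collapse = ",")
      }
    }
    if (stop_on_fail && worst_rel > tol)
      stop(sprintf("gradient mismatch at (%s): rel %.3g", worst_coord,
                   worst_rel))
    data.frame(param = name, max_abs = worst_abs, max_rel = worst_rel,
               n = length(coords), worst = worst_coord,
               stringsAsFactors = FALSE)
  }

  mat_coords <- function(n, m)
    unlist(lapply(seq_len(n), function(i) lapply(seq_len(m), function(j)
      c(i, j))), recursive = FALSE)

  out <- rbind(
    check_class("W_C", function(cc)
      rp$trace_C[cc[1], cc[2]] * g_out * w_fb[cc[2]],
      mat_coords(hp$n_in, hp$n_mem)),
    check_class("W_k", function(cc)
      rp$trace_k[cc[1], cc[2]] * g_out * w_fb[cc[2]],
      mat_coords(hp$n_in, hp$n_mem)),
    check_class("b_C", function(cc)
      rp$trace_bC[cc[1]] * g_out * w_fb[cc[1]],
      lapply(seq_len(hp$n_mem), function(i) i)),
    check_class("b_k", function(cc)
      rp$trace_bk[cc[1]] * g_out * w_fb[cc[1]],
      lapply(seq_len(hp$n_mem), function(i) i)),
    check_class("M0", function(cc)
      rp$kprod[cc[1]] * g_out * w_fb[cc[1]],
      lapply(seq_len(hp$n_mem), function(i) i))
  )
  out
}
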