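#' Create a fresh agent
#'
#' Initialises all learnable parameters, the plasticity state (synaptic
#' traces and tags, all zero) and the memory activity (zero). Biases are set
#' to one; weights are drawn i.i.d. uniform on
#' `[-init_range, init_range]`. Feedback weights `W_FB` are drawn
#' independently of `W_q` by default; because both follow the same
#' plasticity rule they become proportional as learning progresses. Set
#' `tie_feedback = TRUE` to initialise `W_FB = t(W_q)`, in which case the
#' two stay exact transposes forever.
#'
#' @param hp A [hyperparameters()] object.
#' @param seed Optional integer seed (calls [set.seed()] before drawing).
#' @param tie_feedback Initialise feedback weights as the transpose of the
#'   output weights.
#' @return An object of class `recollect_agent`: a list with elements
#'   `hp`, `params` (`W_C`, `W_k`, `W_q`, `W_FB`, `b_C`, `b_k`, `b_q`),
#'   `plast` (traces and tags, including bias analogues) and `state`
#'   (`M`, `q_prev`, `has_prev`).
#' @export
new_agent <- function(hp, seed = NULL, tie_feedback = FALSE) {
  stopifnot(inherits(hp, "recollect_hp"))
  if (!is.null(seed)) set.seed(seed)
  r <- hp$init_range
  rw <- function(n, m) matrix(stats::runif(n * m, -r, r), n, m)
  params <- list(
    W_C  = rw(hp$n_in, hp$n_mem),
    W_k  = rw(hp$n_in, hp$n_mem),
    W_q  = rw(hp$n_mem, hp$n_out),
    W_FB = rw(hp$n_out, hp$n_mem),
    b_C  = rep(1, hp$n_mem),
    b_k  = rep(1, hp$n_mem),
    b_q  = rep(1, hp$n_out)
  )
  if (tie_feedback) params$W_FB <- t(params$W_q)
  agent <- list(hp = hp, params = params,
                plast = zero_plasticity(hp),
                state = list(M = rep(0, hp$n_mem), q_prev = 0,
                             has_prev = FALSE))
  class(agent) <- "recollect_agent"
  agent
}

#' Zeroed plasticity state (traces and tags)
#'
#' All traces and tags start at zero; an agent with zero tags performs a
#' zero weight update whatever the reward-prediction error.
#'
#' @param hp A [hyperparameters()] object.
#' @return List of trace/tag matrices and their bias analogues.
#' @export
zero_plasticity <- function(hp) {
  zim <- matrix(0, hp$n_in, hp$n_mem)
  list(
    trace_C = zim, trace_k = zim,
    tag_C = zim, tag_k = zim,
    tag_q = matrix(0, hp$n_mem, hp$n_out),
    tag_FB = matrix(0, hp$n_out, hp$n_mem),
    trace_bC = rep(0, hp$n_mem), trace_bk = rep(0, hp$n_mem),
    tag_bC = rep(0, hp$n_mem), tag_bk = rep(0, hp$n_mem),
    tag_bq = rep(0, hp$n_out)
  )
}

#' @export
print.recollect_agent <- function(x, ...) {
  cat(sprintf("gated-memory agent: %d inputs, %d light-GRU units, %d outputs\n",
              x$hp$n_in, x$hp$n_mem, x$hp$n_out))
  invisible(x)
}

#' Forward pass of the gated memory network
#'
#' Computes candidate activities `C = sigma(x W_C + b_C)`, gate activities
#' `k = sigma(x W_k + b_k)`, the gated memory update
#' `M = k * M_prev + (1 - k) * C` and the action values
#' `q = f(M W_q + b_q)` (`f` sigmoid or identity per `hp$output`).
#' Pre-activation sums are returned so the trace recursions can reuse the
#' activation-function slopes.
#'
#' @param params Parameter list (as in [new_agent()]).
#' @param x Input vector of length `hp$n_in`, values in `[0, 1]`.
#' @param M_prev Memory vector from the previous timestep.
#' @param hp A [hyperparameters()] object.
#' @return List with `C`, `k`, `M`, `q`, `inp_C`, `inp_k`, `inp_q`.
#' @export
forward <- function(params, x, M_prev, hp) {
  if (length(x) != hp$n_in)
    stop(sprintf("input length %d does not match n_in = %d", length(x), hp$n_in))
  if (length(M_prev) != hp$n_mem)
    stop(sprintf("memory length %d does not match n_mem = %d",
                 length(M_prev), hp$n_mem))
  inp_C <- drop(x %*% params$W_C) + params$b_C
  inp_k <- drop(x %*% params$W_k) + params$b_k
  C <- sigmoid(inp_C, hp$rho)
  k <- sigmoid(inp_k, hp$rho)
  M <- k * M_prev + (1 - k) * C
  inp_q <- drop(M %*% params$W_q) + params$b_q
  q <- if (hp$output == "sigmoid") sigmoid(inp_q, hp$rho) else inp_q
  list(C = C, k = k, M = M, q = q, inp_C = inp_C, inp_k = inp_k,
       inp_q = inp_q)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` returns the index of the largest Q-value
#' (ties broken toward the lowest index); otherwise a uniformly random
#' action. Uses R's global random stream. When `epsilon == 0` no random
#' numbers are consumed.
#'
#' @param q Numeric vector of action values.
#' @param epsilon Exploration probability.
#' @return Integer action index in `1..length(q)`.
#' @export
select_action <- function(q, epsilon = 0) {
  if (length(q) < 1) stop("empty action-value vector")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    a <- floor(stats::runif(1) * length(q)) + 1
    return(as.integer(min(a, length(q))))
  }
  which.max(q)  # which.max breaks ties toward the lowest index
}

#' SARSA reward-prediction error
#'
#' `delta = r + gamma * q_sel_now - q_chosen_prev`: the discrepancy between
#' the value predicted for the previous action and the observed reward plus
#' the discounted value of the action just selected. Broadcast to all
#' synapses as a global neuromodulatory factor.
#'
#' @param r Reward received at the current step.
#' @param q_sel_now Q-value of the action selected at the current step.
#' @param q_chosen_prev Q-value (at selection time) of the previous action.
#' @param gamma Discount factor.
#' @return Scalar prediction error.
#' @export
rpe <- function(r, q_sel_now, q_chosen_prev, gamma) {
  r + gamma * q_sel_now - q_chosen_prev
}

#' Update output-weight tags
#'
#' Every tag decays by `lam * gamma`; the column of the chosen action
#' additionally accumulates the presynaptic memory activities `M`. The
#' feedback-tag table follows the identical rule transposed, so feedback
#' and feedforward weights stay proportional.
#'
#' @param tag_q `n_mem x n_out` tag matrix for output weights.
#' @param tag_FB `n_out x n_mem` tag matrix for feedback weights.
#' @param tag_bq Length-`n_out` tag vector for output biases.
#' @param M Memory activity vector.
#' @param chosen Chosen action index.
#' @param lam,gamma Tag decay rate and discount factor.
#' @return List with updated `tag_q`, `tag_FB`, `tag_bq`.
#' @export
update_tags_q <- function(tag_q, tag_FB, tag_bq, M, chosen, lam, gamma) {
  if (chosen < 1 || chosen > ncol(tag_q)) stop("chosen action out of range")
  d <- lam * gamma
  tag_q <- tag_q * d
  tag_q[, chosen] <- tag_q[, chosen] + M
  tag_FB <- tag_FB * d
  tag_FB[chosen, ] <- tag_FB[chosen, ] + M
  tag_bq <- tag_bq * d
  tag_bq[chosen] <- tag_bq[chosen] + 1
  list(tag_q = tag_q, tag_FB = tag_FB, tag_bq = tag_bq)
}

#' Update candidate-memory synaptic traces
#'
#' `trace_C(t) = k * trace_C(t-1) + (1 - k) * outer(x, sigma'(inp_C))`.
#' A closed gate (`k = 1`) freezes the trace with the memory; an open gate
#' (`k = 0`) erases history and leaves only the instantaneous derivative
#' term. The bias trace follows the same recursion with a constant-1 input.
#'
#' @param trace_C `n_in x n_mem` trace matrix.
#' @param trace_bC Length-`n_mem` bias trace.
#' @param x Input vector.
#' @param k Gate activity vector.
#' @param inp_C Candidate pre-activations (for the derivative).
#' @param rho Activation slope.
#' @return List with updated `trace_C`, `trace_bC`.
#' @export
update_trace_c <- function(trace_C, trace_bC, x, k, inp_C, rho) {
  g <- sigmoid_deriv(inp_C, rho)
  new_term <- outer(x, (1 - k) * g)
  trace_C <- sweep(trace_C, 2, k, `*`) + new_term
  trace_bC <- k * trace_bC + (1 - k) * g
  list(trace_C = trace_C, trace_bC = trace_bC)
}

#' Update gating-unit synaptic traces
#'
#' `trace_k(t) = k * trace_k(t-1) + (M_prev - C) * outer(x, sigma'(inp_k))`.
#' The bracketed sensory-prediction term makes the gate's influence vanish
#' when the candidate equals the retained memory. The bias trace uses a
#' constant-1 input.
#'
#' @param trace_k `n_in x n_mem` trace matrix.
#' @param trace_bk Length-`n_mem` bias trace.
#' @param x Input vector.
#' @param k Gate activity vector.
#' @param M_prev Memory activities of the previous timestep.
#' @param C Candidate activities of the current timestep.
#' @param inp_k Gate pre-activations.
#' @param rho Activation slope.
#' @return List with updated `trace_k`, `trace_bk`.
#' @export
update_trace_k <- function(trace_k, trace_bk, x, k, M_prev, C, inp_k, rho) {
  g <- sigmoid_deriv(inp_k, rho)
  coef <- (M_prev - C) * g
  trace_k <- sweep(trace_k, 2, k, `*`) + outer(x, coef)
  trace_bk <- k * trace_bk + coef
  list(trace_k = trace_k, trace_bk = trace_bk)
}

#' Update memory-layer tags from traces and attentional feedback
#'
#' `tag(t) = lam * gamma * tag(t-1) + trace(t) * W_FB[chosen, ]` (the
#' feedback weight broadcast across each memory unit's column). Applied
#' identically to candidate-memory and gating tags and their bias
#' analogues.
#'
#' @param tag `n_in x n_mem` tag matrix (candidate or gate class).
#' @param tag_b Length-`n_mem` bias tag of the same class.
#' @param trace Matching trace matrix.
#' @param trace_b Matching bias trace.
#' @param w_fb_chosen Length-`n_mem` feedback weights of the chosen action.
#' @param lam,gamma Tag decay rate and discount factor.
#' @return List with updated `tag`, `tag_b`.
#' @export
update_tags_mem <- function(tag, tag_b, trace, trace_b, w_fb_chosen,
                            lam, gamma) {
  d <- lam * gamma
  tag <- tag * d + sweep(trace, 2, w_fb_chosen, `*`)
  tag_b <- tag_b * d + trace_b * w_fb_chosen
  list(tag = tag, tag_b = tag_b)
}

#' Apply the neuromodulated weight updates
#'
#' Each weight changes by its learning rate times the global
#' reward-prediction error times its tag: `W <- W + beta * delta * tag`
#' (`beta_gate` for the gating weights and bias). `delta = 0` leaves all
#' parameters unchanged.
#'
#' @param params Parameter list.
#' @param plast Plasticity state list.
#' @param delta Scalar reward-prediction error.
#' @param hp A [hyperparameters()] object.
#' @return Updated parameter list.
#' @export
apply_updates <- function(params, plast, delta, hp) {
  if (!is.finite(delta)) stop("non-finite reward-prediction error")
  bd <- hp$beta * delta
  gd <- hp$beta_gate * delta
  params$W_q  <- params$W_q  + bd * plast$tag_q
  params$W_FB <- params$W_FB + bd * plast$tag_FB
  params$W_C  <- params$W_C  + bd * plast$tag_C
  params$W_k  <- params$W_k  + gd * plast$tag_k
  params$b_q  <- params$b_q  + bd * plast$tag_bq
  params$b_C  <- params$b_C  + bd * plast$tag_bC
  params$b_k  <- params$b_k  + gd * plast$tag_bk
  params
}

#' One learning step of the agent
#'
#' Executes, in order: (1) forward pass on the observation; (2)
#' epsilon-greedy action selection; (3) reward-prediction error against the
#' stored Q-value of the previously chosen action; (4) weight update using
#' the tags accumulated through the previous step; (5) trace update with
#' the current activities; (6) tag decay-and-accumulation keyed to the
#' just-selected action (using the post-update feedback weights); finally
#' stores the selected Q-value for the next step's prediction error. On the
#' very first step of a fresh agent no previous Q-value exists and no
#' weight update is performed (the tags are zero in any case).
#'
#' @param agent A `recollect_agent`.
#' @param x Observation vector.
#' @param reward Reward delivered with this observation (for the transition
#'   that ended here).
#' @param learn Apply plasticity (`FALSE` freezes weights, traces and tags;
#'   memory dynamics still run).
#' @param epsilon Exploration rate override (defaults to `hp$epsilon`;
#'   pass 0 for greedy evaluation).
#' @return List with `agent` (updated), `action`, `delta` (NA on the first
#'   step), and `state` (the forward-pass activities).
#' @export
learn_step <- function(agent, x, reward = 0, learn = TRUE,
                       epsilon = agent$hp$epsilon) {
  hp <- agent$hp
  M_prev <- agent$state$M
  st <- forward(agent$params, x, M_prev, hp)
  a <- select_action(st$q, epsilon)
  delta <- NA_real_
  if (learn) {
    if (agent$state$has_prev) {
      delta <- rpe(reward, st$q[a], agent$state$q_prev, hp$gamma)
      agent$params <- apply_updates(agent$params, agent$plast, delta, hp)
    }
    pl <- agent$plast
    tc <- update_trace_c(pl$trace_C, pl$trace_bC, x, st$k, st$inp_C, hp$rho)
    tk <- update_trace_k(pl$trace_k, pl$trace_bk, x, st$k, M_prev, st$C,
                         st$inp_k, hp$rho)
    pl$trace_C <- tc$trace_C; pl$trace_bC <- tc$trace_bC
    pl$trace_k <- tk$trace_k; pl$trace_bk <- tk$trace_bk
    tq <- update_tags_q(pl$tag_q, pl$tag_FB, pl$tag_bq, st$M, a,
                        hp$lam, hp$gamma)
    pl$tag_q <- tq$tag_q; pl$tag_FB <- tq$tag_FB; pl$tag_bq <- tq$tag_bq
    w_fb <- agent$params$W_FB[a, ]
    tC <- update_tags_mem(pl$tag_C, pl$tag_bC, pl$trace_C, pl$trace_bC,
                          w_fb, hp$lam, hp$gamma)
    tK <- update_tags_mem(pl$tag_k, pl$tag_bk, pl$trace_k, pl$trace_bk,
                          w_fb, hp$lam, hp$gamma)
    pl$tag_C <- tC$tag; pl$tag_bC <- tC$tag_b
    pl$tag_k <- tK$tag; pl$tag_bk <- tK$tag_b
    agent$plast <- pl
  }
  agent$state$M <- st$M
  agent$state$q_prev <- st$q[a]
  agent$state$has_prev <- TRUE
  list(agent = agent, action = a, delta = delta, state = st)
}
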