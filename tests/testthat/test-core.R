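test_that("sigmoid matches its closed form and saturates gracefully", {
  expect_equal(sigmoid(0, rho = 1), 0.5)
  expect_equal(sigmoid(0, rho = 7.3), 0.5)
  expect_equal(sigmoid(1, rho = 2), 1 / (1 + exp(-2)))
  expect_equal(sigmoid(1e4), 1)
  expect_equal(sigmoid(-1e4), 0)
  # slope at zero is rho/4
  expect_equal(sigmoid_deriv(0, rho = 2), 0.5)
  expect_equal(sigmoid_deriv(0, rho = 3), 0.75)
})

test_that("forward pass obeys the gate-limit identities", {
  hp <- tiny_hp(n_in = 3, n_mem = 4, n_out = 2)
  agent <- new_agent(hp, seed = 11)
  x <- c(0.2, 0.8, 0.5)
  M_prev <- c(0.1, 0.9, 0.4, 0.6)

  # closed gate (k = 1): memory untouched
  p1 <- agent$params
  p1$W_k[] <- 0; p1$b_k[] <- 1e4
  st <- forward(p1, x, M_prev, hp)
  expect_equal(st$M, M_prev)

  # open gate (k = 0): memoryless, M = C
  p0 <- agent$params
  p0$W_k[] <- 0; p0$b_k[] <- -1e4
  st0 <- forward(p0, x, M_prev, hp)
  expect_equal(st0$M, st0$C)

  # all weights 0, biases 1, rho = 2: C = k = sigmoid(2) elementwise
  pz <- agent$params
  pz$W_C[] <- 0; pz$W_k[] <- 0
  pz$b_C[] <- 1; pz$b_k[] <- 1
  stz <- forward(pz, x, M_prev, hp)
  expect_equal(stz$C, rep(1 / (1 + exp(-2)), 4))
  expect_equal(stz$k, rep(1 / (1 + exp(-2)), 4))

  expect_error(forward(agent$params, c(1, 2), M_prev, hp), "n_in")
})

test_that("epsilon-greedy selection is greedy, tie-breaks low, explores uniformly", {
  expect_identical(select_action(c(0.2, 0.7, 0.5), epsilon = 0), 2L)
  expect_identical(select_action(c(0.5, 0.5), epsilon = 0), 1L)
  expect_error(select_action(numeric(0)), "empty")
  set.seed(1)
  n <- 10000
  draws <- replicate(n, select_action(c(0, 0, 0.1), epsilon = 1))
  freq <- tabulate(draws, 3) / n
  bound <- 3 * sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < bound))
})

test_that("reward-prediction error follows the SARSA form", {
  expect_equal(rpe(0, 0.5, 0.45, gamma = 0.9), 0)
  expect_equal(rpe(1.5, 0, 1.0, gamma = 0.9), 0.5)
  expect_equal(rpe(1, 0.5, 0.25, gamma = 0), 0.75)
})

test_that("output tags decay by lambda*gamma and accumulate presynaptic memory", {
  tag_q <- matrix(1, 2, 3); tag_FB <- matrix(1, 3, 2); tag_bq <- rep(1, 3)
  M <- c(0.5, 0.25)

  # lambda = 0: non-chosen tags vanish entirely
  r0 <- update_tags_q(tag_q, tag_FB, tag_bq, M, chosen = 2, lam = 0,
                      gamma = 0.9)
  expect_equal(r0$tag_q[, c(1, 3)], matrix(0, 2, 2))
  expect_equal(r0$tag_q[, 2], M)
  expect_equal(r0$tag_FB[2, ], M)
  expect_equal(r0$tag_FB[c(1, 3), ], matrix(0, 2, 2))

  # decay + accumulate arithmetic: 0.4*0.9*1 + 0.5 = 0.86
  r1 <- update_tags_q(tag_q, tag_FB, tag_bq, M, chosen = 1, lam = 0.4,
                      gamma = 0.9)
  expect_equal(r1$tag_q[1, 1], 0.86)
  expect_equal(r1$tag_q[1, 2], 0.36)

  # two steps, same action, same memory: tag = m * (1 + lam*gamma)
  z <- update_tags_q(matrix(0, 2, 3), matrix(0, 3, 2), rep(0, 3), M, 1,
                     0.4, 0.9)
  z <- update_tags_q(z$tag_q, z$tag_FB, z$tag_bq, M, 1, 0.4, 0.9)
  expect_equal(z$tag_q[, 1], M * (1 + 0.4 * 0.9))

  expect_error(update_tags_q(tag_q, tag_FB, tag_bq, M, chosen = 5,
                             lam = 0.4, gamma = 0.9), "range")
})

test_that("candidate trace recursion freezes, erases and decays correctly", {
  trace <- matrix(c(1, 2, 3, 4), 2, 2)
  trace_b <- c(0.5, 0.5)
  x <- c(0.3, 0.7)
  inp_C <- c(0.2, -0.4)

  # closed gate: trace unchanged
  r <- update_trace_c(trace, trace_b, x, k = c(1, 1), inp_C, rho = 2)
  expect_equal(r$trace_C, trace)
  expect_equal(r$trace_bC, trace_b)

  # open gate: history erased, instantaneous term only
  r0 <- update_trace_c(trace, trace_b, x, k = c(0, 0), inp_C, rho = 2)
  expect_equal(r0$trace_C, outer(x, sigmoid_deriv(inp_C, 2)))
  expect_equal(r0$trace_bC, sigmoid_deriv(inp_C, 2))

  # zero input: pure gate decay
  rz <- update_trace_c(trace, trace_b, c(0, 0), k = c(0.6, 0.2), inp_C, 2)
  expect_equal(rz$trace_C, sweep(trace, 2, c(0.6, 0.2), `*`))
})

test_that("gate trace vanishes when candidate equals retained memory", {
  trace <- matrix(0.5, 2, 2); trace_b <- c(0.1, 0.2)
  x <- c(0.4, 0.6); inp_k <- c(0.1, 0.3)
  C <- c(0.3, 0.8)

  # M_prev == C: gate irrelevant, no new contribution
  r <- update_trace_k(trace, trace_b, x, k = c(0.5, 0.5), M_prev = C, C = C,
                      inp_k, rho = 2)
  expect_equal(r$trace_k, 0.5 * trace)

  # zero input: no new contribution either
  rz <- update_trace_k(trace, trace_b, c(0, 0), k = c(1, 1),
                       M_prev = c(0.9, 0.1), C = C, inp_k, rho = 2)
  expect_equal(rz$trace_k, trace)

  # closed gate with M_prev != C: previous trace kept plus bracket term
  M_prev <- c(0.9, 0.1)
  r1 <- update_trace_k(trace, trace_b, x, k = c(1, 1), M_prev, C, inp_k, 2)
  expect_equal(r1$trace_k,
               trace + outer(x, (M_prev - C) * sigmoid_deriv(inp_k, 2)))
})

test_that("memory tags combine traces with attentional feedback", {
  tag <- matrix(0.5, 2, 2); tag_b <- c(0.5, 0.5)
  trace <- matrix(1, 2, 2); trace_b <- c(1, 1)

  # zero feedback: pure decay
  r <- update_tags_mem(tag, tag_b, trace, trace_b, c(0, 0), lam = 0.4,
                       gamma = 0.9)
  expect_equal(r$tag, 0.36 * tag)

  # lambda = 0 reduces to trace scaled by feedback (TD(0))
  r0 <- update_tags_mem(tag, tag_b, trace, trace_b, c(0.2, -0.3), 0, 0.9)
  expect_equal(r0$tag, sweep(trace, 2, c(0.2, -0.3), `*`))

  # decay + accumulate arithmetic: 0.4*0.9*0.5 + 1*0.2 = 0.38
  r1 <- update_tags_mem(tag, tag_b, trace, trace_b, c(0.2, 0.2), 0.4, 0.9)
  expect_equal(r1$tag[1, 1], 0.38)
})

test_that("weight updates scale tags by learning rate and RPE", {
  hp <- tiny_hp(beta = 0.1, beta_gate = 0.006)
  agent <- new_agent(hp, seed = 3)
  pl <- agent$plast
  pl$tag_q[1, 1] <- 0.86
  pl$tag_k[1, 1] <- 1

  expect_equal(apply_updates(agent$params, pl, 0, hp), agent$params)

  up <- apply_updates(agent$params, pl, 0.5, hp)
  expect_equal(up$W_q[1, 1] - agent$params$W_q[1, 1], 0.1 * 0.5 * 0.86)
  # gate weights use the gate-specific learning rate
  expect_equal(up$W_k[1, 1] - agent$params$W_k[1, 1], 0.006 * 0.5 * 1)
  expect_error(apply_updates(agent$params, pl, NaN, hp), "finite")
})

test_that("first step of a fresh agent changes no weights whatever the reward", {
  hp <- tiny_hp()
  agent <- new_agent(hp, seed = 5)
  before <- agent$params
  st <- learn_step(agent, c(1, 0), reward = 10, epsilon = 0)
  expect_equal(st$agent$params, before)
  expect_true(is.na(st$delta))
  # second step does update (tags are now non-zero)
  st2 <- learn_step(st$agent, c(0, 1), reward = 1, epsilon = 0)
  expect_false(isTRUE(all.equal(st2$agent$params$W_q, before$W_q)))
  expect_false(is.na(st2$delta))
})

test_that("greedy behaviour with frozen weights is a pure function of the inputs", {
  hp <- tiny_hp(n_in = 3, n_mem = 3, n_out = 3)
  agent <- new_agent(hp, seed = 9)
  X <- matrix(stats::runif(30), 10, 3)
  run <- function() {
    a <- agent
    sapply(seq_len(nrow(X)), function(t) {
      st <- learn_step(a, X[t, ], 0, learn = FALSE, epsilon = 0)
      a <<- st$agent
      st$action
    })
  }
  expect_identical(run(), run())
})

test_that("two hand-unrolled learning steps match the recursion exactly", {
  # 1-input / 1-memory / 1-output network, linear output: every quantity
  # is scalar and the whole update chain can be written out longhand.
  hp <- hyperparameters(beta = 0.1, beta_gate = 0.05, gamma = 0.9,
                        lam = 0.4, epsilon = 0, rho = 2, n_in = 1,
                        n_mem = 1, n_out = 1, output = "linear")
  agent <- new_agent(hp, seed = 21)
  p <- agent$params
  wC <- p$W_C[1, 1]; wk <- p$W_k[1, 1]; wq <- p$W_q[1, 1]
  wFB <- p$W_FB[1, 1]; bC <- p$b_C[1]; bk <- p$b_k[1]; bq <- p$b_q[1]
  sig <- function(u) 1 / (1 + exp(-2 * u))
  dsig <- function(u) 2 * sig(u) * (1 - sig(u))
  x1 <- 0.7; x2 <- 0.4; r2 <- 1.2

  # --- step 1 (no weight change: tags are zero) -------------------------
  i1C <- wC * x1 + bC; i1k <- wk * x1 + bk
  C1 <- sig(i1C); k1 <- sig(i1k)
  M1 <- k1 * 0 + (1 - k1) * C1
  q1 <- wq * M1 + bq
  trC <- (1 - k1) * x1 * dsig(i1C)
  trbC <- (1 - k1) * dsig(i1C)
  trk <- (0 - C1) * x1 * dsig(i1k)
  trbk <- (0 - C1) * dsig(i1k)
  tagq <- M1; tagbq <- 1; tagFB <- M1
  tagC <- trC * wFB; tagbC <- trbC * wFB
  tagk <- trk * wFB; tagbk <- trbk * wFB

  # --- step 2: TD error against q1, weights move, then traces/tags ------
  i2C <- wC * x2 + bC; i2k <- wk * x2 + bk
  C2 <- sig(i2C); k2 <- sig(i2k)
  M2 <- k2 * M1 + (1 - k2) * C2
  q2 <- wq * M2 + bq
  delta2 <- r2 + 0.9 * q2 - q1
  wq2 <- wq + 0.1 * delta2 * tagq
  wFB2 <- wFB + 0.1 * delta2 * tagFB
  wC2 <- wC + 0.1 * delta2 * tagC
  wk2 <- wk + 0.05 * delta2 * tagk
  bq2 <- bq + 0.1 * delta2 * tagbq
  bC2 <- bC + 0.1 * delta2 * tagbC
  bk2 <- bk + 0.05 * delta2 * tagbk
  trC2 <- k2 * trC + (1 - k2) * x2 * dsig(i2C)
  trk2 <- k2 * trk + (M1 - C2) * x2 * dsig(i2k)
  tagC2 <- 0.36 * tagC + trC2 * wFB2
  tagk2 <- 0.36 * tagk + trk2 * wFB2

  s1 <- learn_step(agent, x1, 0)
  s2 <- learn_step(s1$agent, x2, r2)
  a2 <- s2$agent
  expect_equal(s2$delta, delta2)
  expect_equal(a2$params$W_q[1, 1], wq2)
  expect_equal(a2$params$W_FB[1, 1], wFB2)
  expect_equal(a2$params$W_C[1, 1], wC2)
  expect_equal(a2$params$W_k[1, 1], wk2)
  expect_equal(a2$params$b_q[1], bq2)
  expect_equal(a2$params$b_C[1], bC2)
  expect_equal(a2$params$b_k[1], bk2)
  expect_equal(a2$plast$trace_C[1, 1], trC2)
  expect_equal(a2$plast$trace_k[1, 1], trk2)
  expect_equal(a2$plast$tag_C[1, 1], tagC2)
  expect_equal(a2$plast$tag_k[1, 1], tagk2)
  expect_equal(a2$plast$tag_q[1, 1], 0.36 * tagq + M2)
  expect_equal(a2$state$M, M2)
})

test_that("agent reset gives unit biases, zero plasticity and seeded determinism", {
  hp <- tiny_hp(n_in = 3, n_mem = 4, n_out = 2)
  a1 <- new_agent(hp, seed = 42)
  expect_equal(a1$params$b_C, rep(1, 4))
  expect_equal(a1$params$b_k, rep(1, 4))
  expect_equal(a1$params$b_q, rep(1, 2))
  expect_true(all(vapply(a1$plast, function(z) all(z == 0), logical(1))))
  expect_equal(a1$state$M, rep(0, 4))
  expect_true(all(abs(a1$params$W_C) <= hp$init_range))
  a2 <- new_agent(hp, seed = 42)
  expect_equal(a1, a2)
  tied <- new_agent(hp, seed = 1, tie_feedback = TRUE)
  expect_equal(tied$params$W_FB, t(tied$params$W_q))
})
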