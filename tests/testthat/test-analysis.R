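# Synthetic activity table: n trials per cell of the 2x2 design, several
# steps per phase, unit columns built from known tuning + noise.
make_activity <- function(n_per_cell = 30, noise = 0.02, seed = 1) {
  set.seed(seed)
  design <- expand.grid(saccade_type = c("pro", "anti"),
                        cue_side = c("L", "R"),
                        rep = seq_len(n_per_cell),
                        stringsAsFactors = FALSE)
  design$trial <- seq_len(nrow(design))
  rows <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    data.frame(trial = d$trial, step = 1:6,
               phase = rep(c("cue", "delay", "go"), each = 2),
               saccade_type = d$saccade_type, cue_side = d$cue_side,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  clamp <- function(z) pmin(pmax(z, 1e-4), 1 - 1e-4)
  rows$M1 <- clamp(ifelse(rows$cue_side == "L", 0.9, 0.1) +
                     rnorm(n, 0, noise))          # cue-tuned
  rows$M2 <- 0.5                                   # constant: untestable
  rows$k1 <- clamp(ifelse(rows$saccade_type == "pro", 0.8, 0.3) +
                     rnorm(n, 0, noise))          # type-tuned
  rows$q1 <- clamp(0.5 +
      0.3 * (rows$saccade_type == "pro") * (rows$cue_side == "L") +
      rnorm(n, 0, noise))                          # interaction-tuned
  rows$C1 <- clamp(0.5 + rnorm(n, 0, noise))       # untuned
  rows
}

test_that("selectivity regression recovers the planted tuning pattern", {
  act <- make_activity()
  res <- selectivity_regression(act, phase = "delay")

  sig <- function(u, eff) res$significant[res$unit == u & res$effect == eff]
  expect_true(sig("M1", "cue_side"))
  expect_false(sig("M1", "saccade_type"))
  expect_true(sig("k1", "saccade_type"))
  expect_false(sig("k1", "cue_side"))
  expect_true(sig("q1", "interaction"))
  expect_false(any(res$significant[res$unit == "C1"]))

  # the constant unit is flagged untestable, not silently dropped
  m2 <- res[res$unit == "M2", ]
  expect_true(all(!m2$testable))
  expect_true(all(!m2$significant))
  expect_equal(nrow(res), 5 * 3)
  expect_true(all(res$p_adj >= res$p_raw | is.na(res$p_raw)))
})

test_that("heavy-tailed residuals trigger the robust Huber fit", {
  act <- make_activity(noise = 0.01, seed = 7)
  # contaminate one unit with gross outliers
  idx <- sample(which(act$phase == "delay"), 25)
  act$C1[idx] <- 0.999
  res <- selectivity_regression(act, phase = "delay")
  expect_equal(unique(res$model[res$unit == "C1"]), "robust")
  # clean strongly-tuned unit stays on ordinary least squares or robust
  # depending on its diagnostics, but must remain testable
  expect_true(all(res$testable[res$unit == "M1"]))
})

test_that("normality statistics match an independent implementation", {
  # frozen oracle values (scipy.stats.normaltest / jarque_bera)
  x1 <- sin(1:30)
  d1 <- recollect:::dagostino_omnibus(x1)
  expect_equal(d1$statistic, 18.607759537316372, tolerance = 1e-10)
  expect_equal(d1$p.value, 9.107021380769058e-05, tolerance = 1e-8)
  j1 <- recollect:::jarque_bera(x1)
  expect_equal(j1$statistic, 2.9600204125623133, tolerance = 1e-10)
  expect_equal(j1$p.value, 0.22763536506141946, tolerance = 1e-8)

  x2 <- c((1:24) / 10, 8, -6)
  d2 <- recollect:::dagostino_omnibus(x2)
  expect_equal(d2$statistic, 15.323071049855308, tolerance = 1e-10)
  j2 <- recollect:::jarque_bera(x2)
  expect_equal(j2$statistic, 61.00129752022908, tolerance = 1e-10)
})

test_that("reversal-aligned averages report means and SEM per condition", {
  # identical episodes: SEM must be exactly 0
  n_ep <- 8; len <- 10
  act <- data.frame(episode = rep(1:n_ep, each = len),
                    trial = rep(1:len, n_ep),
                    high = rep(c(1L, 2L), length.out = n_ep * len,
                               each = len),
                    M1 = rep(seq(0.1, 1, length.out = len), n_ep))
  avg <- reversal_aligned_average(act, window = len)
  expect_equal(unique(avg$sem), 0)
  expect_equal(avg$mean[avg$high == 1 & avg$trial == 3],
               seq(0.1, 1, length.out = len)[3])

  # i.i.d. noise: SEM shrinks like 1/sqrt(n_episodes)
  sem_for <- function(n_ep, seed) {
    set.seed(seed)
    a <- data.frame(episode = rep(seq_len(n_ep + 1), each = 5),
                    trial = rep(1:5, n_ep + 1),
                    high = 1L,
                    M1 = rnorm(5 * (n_ep + 1)))
    mean(reversal_aligned_average(a, window = 5)$sem)
  }
  s_small <- mean(sapply(1:20, function(s) sem_for(16, s)))
  s_large <- mean(sapply(1:20, function(s) sem_for(64, s)))
  expect_equal(s_small / s_large, 2, tolerance = 0.15)
  expect_error(reversal_aligned_average(act[act$episode == 1, ]),
               "at least two")
})

test_that("activity collection labels phases and factors consistently", {
  hp <- recollect_preset("saccade")$hp
  agent <- new_agent(hp, seed = 2)
  act <- collect_saccade_activity(agent, saccade_config(), n_trials = 8,
                                  seed = 3)
  expect_true(all(c("phase", "saccade_type", "cue_side", "M1", "k7",
                    "q3") %in% names(act)))
  expect_true(all(act$phase[!is.na(act$saccade_type)] %in%
                    c("iti", "wait", "cue", "delay", "go")))
  # activities are valid unit outputs
  ucols <- grep("^[kCM][0-9]+$", names(act), value = TRUE)
  expect_true(all(act[ucols] > 0 & act[ucols] < 1))
})

test_that("go-phase tuning on a trained network follows the published ordering", {
  # train to the unit-analysis protocol (ITI 3, delay 5 via curriculum,
  # end-of-trial signal); deterministic given the seeds
  pre <- recollect_preset("saccade+eot")
  pre$env$iti_steps <- 3L
  pre$env$delay_steps <- 5L
  res <- train_saccade(pre, seed = 1, curriculum = TRUE)
  expect_true(res$converged)
  act <- collect_saccade_activity(res$agent, pre$env, n_trials = 120,
                                  seed = 2)
  sel <- selectivity_regression(act, phase = "go")
  frac <- vapply(split(sel$significant, sel$unit_class), mean, numeric(1))
  # gating units show almost no tuning at go; most memory and output
  # units are selective
  expect_lt(frac[["k"]], 0.25)
  expect_lt(frac[["k"]], frac[["M"]])
  expect_lt(frac[["k"]], frac[["q"]])
  expect_gte(frac[["M"]], 0.5)
  expect_gte(frac[["q"]], 0.5)
})

test_that("a gate pinned open leaves no delay persistence", {
  hp <- recollect_preset("saccade")$hp
  agent <- new_agent(hp, seed = 4)
  agent$params$W_k[] <- 0
  agent$params$b_k[] <- -1e4   # k -> 0: memoryless
  prof <- delay_persistence_profile(agent, saccade_config(), delays = c(1, 5),
                                    n_trials = 8, seed = 6)
  expect_true(all(c("delay", "phase", "step_in_trial", "M1") %in%
                    names(prof)))
  # memoryless: memory activity equals the (input-driven) candidate at
  # every step, so profiles at different delays coincide step by step
  # during the shared pre-delay epochs
  p1 <- prof[prof$delay == 1, ]
  p5 <- prof[prof$delay == 5, ]
  shared <- seq_len(min(4, nrow(p1), nrow(p5)))
  expect_equal(p1$M1[shared], p5$M1[shared], tolerance = 1e-6)
})
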