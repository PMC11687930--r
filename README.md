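# recollect

Reinforcement learning of working memory with a biologically plausible,
strictly local plasticity rule.

`recollect` implements a gated recurrent working-memory network built from
light-GRU units — each unit has a candidate-memory cell `C_j`, a single
memory gate `k_j` and a memory cell `M_j` — trained with SARSA(λ)
temporal-difference learning in which every weight change uses only
information available at the synapse: a synaptic **trace** (the synapse's
influence on its memory unit, propagated through the gate), a synaptic
**tag** (the trace combined with attentional feedback from the selected
action), and a globally broadcast reward-prediction error. The package is
for computational neuroscientists who want an interpretable, brain-mappable
alternative to backpropagation-through-time (BPTT) for studying working
memory, forgetting and learning-to-learn.

## The model

Forward dynamics (no recurrent weights; σ is a logistic with slope ρ = 2):

    C_j(t) = σ(Σ_i W^C_ij x_i(t) + b^C_j)
    k_j(t) = σ(Σ_i W^k_ij x_i(t) + b^k_j)
    M_j(t) = k_j(t) M_j(t−1) + (1 − k_j(t)) C_j(t)
    q_a(t) = Σ_j W^q_ja M_j(t) + b^q_a

An ε-greedy policy selects action `s`; the SARSA reward-prediction error
δ(t) = r(t) + γ q_s(t) − q_a(t−1) gates all plasticity. Tags and traces:

    Tag^q_js(t)   = λγ Tag^q_js(t−1) + M_j(t)            (selected action only)
    Trace^C_ij(t) = k_j Trace^C_ij(t−1) + (1−k_j) x_i σ'(Inp^C_j)
    Trace^k_ij(t) = k_j Trace^k_ij(t−1) + (M_j(t−1) − C_j) x_i σ'(Inp^k_j)
    Tag^{C,k}_ij(t) = λγ Tag^{C,k}_ij(t−1) + Trace^{C,k}_ij(t) W^FB_sj
    ΔW = β δ(t) Tag     (β_gate for gate weights)

Because the network has no recurrent weights, the traces are *exactly* the
BPTT gradients ∂q_s/∂W — the package ships a finite-difference oracle
(`verify_trace_gradient()`) that checks this identity coordinate by
coordinate on random networks.

Two task families are included: a pro-/anti-saccade delayed-response task
(fixate, memorise a cue, saccade toward or away from it) and two-armed
reversal bandits (75%/25% reward probabilities swapped or reassigned every
100 pulls), plus the deterministic 24/16/8 serial-reversal schedule used
for comparison with rodent behaviour.

## Worked example

Train a network on the alternating reversal bandit and evaluate it
greedily (this is the published protocol at full length; ~20 s compiled):

```r
library(recollect)
pre <- recollect_preset("bandit")       # 4 inputs, 4 light-GRU units, 2 levers
tr  <- train_bandit(pre, seed = 1, n_episodes = 20000)
ev  <- evaluate_bandit(tr, pre$env, n_episodes = 300)
str(ev$metrics)
#> List of 4
#>  $ optimal_fraction   : num 1
#>  $ suboptimal_pulls   : int 0
#>  $ n_pulls            : int 30000
#>  $ mean_episode_regret: num 0
```

`optimal_fraction` is the share of the 30,000 evaluation pulls that took
the 75%-reward lever (this seed switches perfectly at every reversal by
exploiting the end-of-episode signal), and `mean_episode_regret` charges
each deviating pull the optimal lever's expected reward, summed per
100-pull episode. The gradient oracle prints its verdict directly:

```r
h <- random_history(n_in = 3, n_mem = 2, n_out = 2, len = 5, seed = 1)
max(verify_trace_gradient(h)$max_rel)
#> [1] 1.05e-09
```

A thin command-line front end covers the same protocols
(`exec/recollect train-saccade | train-bandit | evaluate | rat-schedule |
regret-report | verify-gradients`), reading a YAML config whose presets
mirror the published hyperparameter table (see `?recollect_preset` and
`?load_config`).

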