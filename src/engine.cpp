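// Compiled engine for long training runs. Semantics mirror the pure-R
// reference implementation (R/agent.R, R/environments.R) step for step,
// including the order in which numbers are drawn from R's random stream,
// so that short runs of the two engines are interchangeable. Parity is
// enforced by tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct HP {
  double beta, beta_gate, gamma, lam, epsilon, rho;
  int n_in, n_mem, n_out;
  bool sigmoid_out;
};

HP hp_from_list(const List& l) {
  HP hp;
  hp.beta = l["beta"]; hp.beta_gate = l["beta_gate"];
  hp.gamma = l["gamma"]; hp.lam = l["lam"]; hp.epsilon = l["epsilon"];
  hp.rho = l["rho"];
  hp.n_in = l["n_in"]; hp.n_mem = l["n_mem"]; hp.n_out = l["n_out"];
  std::string out = as<std::string>(l["output"]);
  hp.sigmoid_out = (out == "sigmoid");
  return hp;
}

struct Agent {
  mat W_C, W_k, W_q, W_FB;
  vec b_C, b_k, b_q;
  mat trace_C, trace_k, tag_C, tag_k, tag_q, tag_FB;
  vec trace_bC, trace_bk, tag_bC, tag_bk, tag_bq;
  vec M;
  double q_prev;
  bool has_prev;
};

Agent agent_from_list(const List& a) {
  Agent A;
  List p = a["params"], pl = a["plast"], st = a["state"];
  A.W_C = as<mat>(p["W_C"]); A.W_k = as<mat>(p["W_k"]);
  A.W_q = as<mat>(p["W_q"]); A.W_FB = as<mat>(p["W_FB"]);
  A.b_C = as<vec>(p["b_C"]); A.b_k = as<vec>(p["b_k"]);
  A.b_q = as<vec>(p["b_q"]);
  A.trace_C = as<mat>(pl["trace_C"]); A.trace_k = as<mat>(pl["trace_k"]);
  A.tag_C = as<mat>(pl["tag_C"]); A.tag_k = as<mat>(pl["tag_k"]);
  A.tag_q = as<mat>(pl["tag_q"]); A.tag_FB = as<mat>(pl["tag_FB"]);
  A.trace_bC = as<vec>(pl["trace_bC"]); A.trace_bk = as<vec>(pl["trace_bk"]);
  A.tag_bC = as<vec>(pl["tag_bC"]); A.tag_bk = as<vec>(pl["tag_bk"]);
  A.tag_bq = as<vec>(pl["tag_bq"]);
  A.M = as<vec>(st["M"]);
  A.q_prev = st["q_prev"];
  A.has_prev = st["has_prev"];
  return A;
}

// arma::vec converts to an n x 1 matrix by default; flatten so the R side
// sees plain numeric vectors, as the reference implementation produces.
NumericVector as_rvec(const vec& v) {
  return NumericVector(v.begin(), v.end());
}

List agent_to_list(const Agent& A) {
  return List::create(
    _["params"] = List::create(
      _["W_C"] = A.W_C, _["W_k"] = A.W_k, _["W_q"] = A.W_q,
      _["W_FB"] = A.W_FB, _["b_C"] = as_rvec(A.b_C),
      _["b_k"] = as_rvec(A.b_k), _["b_q"] = as_rvec(A.b_q)),
    _["plast"] = List::create(
      _["trace_C"] = A.trace_C, _["trace_k"] = A.trace_k,
      _["tag_C"] = A.tag_C, _["tag_k"] = A.tag_k,
      _["tag_q"] = A.tag_q, _["tag_FB"] = A.tag_FB,
      _["trace_bC"] = as_rvec(A.trace_bC),
      _["trace_bk"] = as_rvec(A.trace_bk),
      _["tag_bC"] = as_rvec(A.tag_bC), _["tag_bk"] = as_rvec(A.tag_bk),
      _["tag_bq"] = as_rvec(A.tag_bq)),
    _["state"] = List::create(
      _["M"] = as_rvec(A.M), _["q_prev"] = A.q_prev,
      _["has_prev"] = A.has_prev));
}

inline vec sigm(const vec& u, double rho) {
  return 1.0 / (1.0 + arma::exp(-rho * u));
}

// One agent timestep: forward, select, TD error, weight update with the
// tags carried over from the previous step, then trace and tag updates
// keyed to the selected action. Returns the 0-based action.
int agent_step(Agent& A, const HP& hp, const vec& x, double reward,
               bool learn, double eps, vec* q_out = nullptr) {
  vec M_prev = A.M;
  vec inp_C = A.W_C.t() * x + A.b_C;
  vec inp_k = A.W_k.t() * x + A.b_k;
  vec C = sigm(inp_C, hp.rho);
  vec k = sigm(inp_k, hp.rho);
  vec M = k % M_prev + (1.0 - k) % C;
  vec inp_q = A.W_q.t() * M + A.b_q;
  vec q = hp.sigmoid_out ? vec(sigm(inp_q, hp.rho)) : inp_q;
  if (q_out) *q_out = q;

  bool explore = false;
  if (eps > 0) explore = unif_rand() < eps;
  int a;
  if (explore) {
    a = (int)(unif_rand() * hp.n_out);
    if (a >= hp.n_out) a = hp.n_out - 1;
  } else {
    a = 0;
    for (int j = 1; j < hp.n_out; ++j) if (q(j) > q(a)) a = j;
  }

  if (learn) {
    if (A.has_prev) {
      double delta = reward + hp.gamma * q(a) - A.q_prev;
      double bd = hp.beta * delta, gd = hp.beta_gate * delta;
      A.W_q += bd * A.tag_q;
      A.W_FB += bd * A.tag_FB;
      A.W_C += bd * A.tag_C;
      A.W_k += gd * A.tag_k;
      A.b_q += bd * A.tag_bq;
      A.b_C += bd * A.tag_bC;
      A.b_k += gd * A.tag_bk;
    }
    vec gC = hp.rho * C % (1.0 - C);
    vec gk = hp.rho * k % (1.0 - k);
    vec coefC = (1.0 - k) % gC;
    vec coefK = (M_prev - C) % gk;
    A.trace_C = A.trace_C.each_row() % k.t() + x * coefC.t();
    A.trace_k = A.trace_k.each_row() % k.t() + x * coefK.t();
    A.trace_bC = k % A.trace_bC + coefC;
    A.trace_bk = k % A.trace_bk + coefK;
    double d = hp.lam * hp.gamma;
    A.tag_q *= d;  A.tag_q.col(a) += M;
    A.tag_FB *= d; A.tag_FB.row(a) += M.t();
    A.tag_bq *= d; A.tag_bq(a) += 1.0;
    vec w_fb = A.W_FB.row(a).t();
    A.tag_C = d * A.tag_C + A.trace_C.each_row() % w_fb.t();
    A.tag_k = d * A.tag_k + A.trace_k.each_row() % w_fb.t();
    A.tag_bC = d * A.tag_bC + A.trace_bC % w_fb;
    A.tag_bk = d * A.tag_bk + A.trace_bk % w_fb;
  }
  A.M = M;
  A.q_prev = q(a);
  A.has_prev = true;
  return a;
}

// ---------------------------------------------------------------------
// Pro-/anti-saccade environment (actions 0 = left, 1 = centre, 2 = right)

struct SacCfg {
  int iti, delay, fix_to, sac_to, n_in;
  double fix_r, fin_r;
  bool eot;
};

SacCfg sac_cfg_from_list(const List& l) {
  SacCfg c;
  c.iti = l["iti_steps"]; c.delay = l["delay_steps"];
  c.fix_to = l["fixation_timeout"]; c.sac_to = l["saccade_timeout"];
  c.fix_r = l["fixation_reward"]; c.fin_r = l["final_reward"];
  c.eot = l["end_of_trial_signal"]; c.n_in = l["n_in"];
  return c;
}

enum SacPhase { ITI, WAIT, CUE, DELAY, GO };

struct SacEnv {
  SacCfg cfg;
  int phase, sip;
  bool pro, cue_left;
  vec obs;
  double reward;
  bool done, correct;
  bool forced, f_pro, f_cue_left;

  void make_obs(int marker, int cue, bool eot_bit) {
    obs.zeros(cfg.n_in);
    if (marker > 0) obs(marker - 1) = 1.0;
    if (cue > 0) obs(1 + cue) = 1.0;
    if (cfg.eot && eot_bit) obs(4) = 1.0;
  }
  void reset() {
    phase = ITI; sip = 1; reward = 0; done = false; correct = false;
    forced = false;
    make_obs(0, 0, false);
  }
  void end_trial(bool ok) {
    phase = ITI; sip = 1; done = true; correct = ok;
    make_obs(0, 0, true);
  }
  void step(int action) {
    reward = 0; done = false; correct = false;
    switch (phase) {
    case ITI:
      if (sip < cfg.iti) { sip++; make_obs(0, 0, false); }
      else {
        if (forced) { pro = f_pro; cue_left = f_cue_left; }
        else { pro = unif_rand() < 0.5; cue_left = unif_rand() < 0.5; }
        phase = WAIT; sip = 1;
        make_obs(pro ? 1 : 2, 0, false);
      }
      break;
    case WAIT:
      if (action == 1) {
        reward = cfg.fix_r;
        phase = CUE; sip = 1;
        make_obs(pro ? 1 : 2, cue_left ? 1 : 2, false);
      } else if (sip >= cfg.fix_to) end_trial(false);
      else sip++;
      break;
    case CUE:
      if (action != 1) end_trial(false);
      else if (cfg.delay == 0) { phase = GO; sip = 1; make_obs(0, 0, false); }
      else { phase = DELAY; sip = 1; make_obs(pro ? 1 : 2, 0, false); }
      break;
    case DELAY:
      if (action != 1) end_trial(false);
      else if (sip >= cfg.delay) { phase = GO; sip = 1; make_obs(0, 0, false); }
      else { sip++; make_obs(pro ? 1 : 2, 0, false); }
      break;
    case GO:
      if (action == 1) {
        if (sip >= cfg.sac_to) end_trial(false);
        else sip++;
      } else {
        int correct_side = (pro == cue_left) ? 0 : 2;
        bool ok = (action == correct_side);
        end_trial(ok);
        if (ok) reward = cfg.fin_r;
      }
      break;
    }
  }
};

// Greedy completion check: run the four trial types with frozen weights
// and no exploration on a copy of the agent, each preceded by the
// inter-trial interval (end-of-trial bit raised on its first step as it
// would be in the continuing stream). Consumes no random numbers.
bool greedy_check(const Agent& A0, const HP& hp, const SacCfg& cfg) {
  static const bool types[4][2] = {
    {true, true}, {true, false}, {false, true}, {false, false}};
  Agent A = A0;
  for (int t = 0; t < 4; ++t) {
    SacEnv env;
    env.cfg = cfg;
    env.reset();
    env.forced = true; env.f_pro = types[t][0]; env.f_cue_left = types[t][1];
    // end-of-trial bit as if a trial just ended
    env.make_obs(0, 0, true);
    bool ok = false;
    for (int step = 0; step < 1000; ++step) {
      int a = agent_step(A, hp, env.obs, env.reward, false, 0.0);
      env.step(a);
      if (env.done) { ok = env.correct; break; }
    }
    if (!ok) return false;
  }
  return true;
}

struct Criterion {
  int window;
  double threshold;
  std::vector<std::vector<int>> buf;
  int idx[4], count[4], sum[4];
  Criterion(int w, double th) : window(w), threshold(th) {
    buf.assign(4, std::vector<int>(w, 0));
    for (int t = 0; t < 4; ++t) { idx[t] = 0; count[t] = 0; sum[t] = 0; }
  }
  void add(int type, bool correct) {
    int c = correct ? 1 : 0;
    if (count[type] < window) {
      sum[type] += c; buf[type][idx[type]] = c; count[type]++;
    } else {
      sum[type] += c - buf[type][idx[type]];
      buf[type][idx[type]] = c;
    }
    idx[type] = (idx[type] + 1) % window;
  }
  bool met() const {
    for (int t = 0; t < 4; ++t) {
      if (count[t] < window) return false;
      if ((double)sum[t] / window < threshold - 1e-12) return false;
    }
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_saccade_run(List agent_in, List hp_in, List env_in,
                     int max_trials, int window, double threshold,
                     bool require_greedy, bool log_trials) {
  HP hp = hp_from_list(hp_in);
  Agent A = agent_from_list(agent_in);
  SacCfg cfg = sac_cfg_from_list(env_in);
  if (cfg.n_in != hp.n_in)
    stop("environment input size does not match the network");
  SacEnv env; env.cfg = cfg; env.reset();
  Criterion crit(window, threshold);
  std::vector<int> types; std::vector<int> corrects;
  if (log_trials) { types.reserve(max_trials); corrects.reserve(max_trials); }
  int trials = 0;
  long long steps = 0;
  bool converged = false;
  while (trials < max_trials) {
    int a = agent_step(A, hp, env.obs, env.reward, true, hp.epsilon);
    env.step(a);
    ++steps;
    if (env.done) {
      ++trials;
      int type = (env.pro ? 0 : 2) + (env.cue_left ? 0 : 1);
      crit.add(type, env.correct);
      if (log_trials) {
        types.push_back(type + 1);
        corrects.push_back(env.correct ? 1 : 0);
      }
      if (crit.met() &&
          (!require_greedy || greedy_check(A, hp, cfg))) {
        converged = true;
        break;
      }
    }
  }
  List out = List::create(
    _["agent"] = agent_to_list(A),
    _["trials"] = trials,
    _["converged"] = converged,
    _["steps"] = (double)steps);
  if (log_trials) {
    out["trial_type"] = wrap(types);
    out["trial_correct"] = wrap(corrects);
  }
  return out;
}

// ---------------------------------------------------------------------
// Two-armed reversal bandit (actions 0/1)

// [[Rcpp::export]]
List cpp_bandit_run(List agent_in, List hp_in, List env_in, List env_state,
                    int n_episodes, bool learn, double eps, bool record,
                    bool record_q) {
  HP hp = hp_from_list(hp_in);
  Agent A = agent_from_list(agent_in);
  double p_high = env_in["p_high"], p_low = env_in["p_low"];
  double mag = env_in["reward_magnitude"];
  bool eoe_signal = env_in["end_of_episode_signal"];
  bool alternating = as<std::string>(env_in["mode"]) == "alternating";
  IntegerVector ep_len = env_in["lengths"];  // one entry per episode to run
  if (ep_len.size() < n_episodes) stop("episode length vector too short");

  int high = env_state["high"];              // 1-based lever
  int episode_index = env_state["episode_index"];
  int prev_action = env_state["prev_action"];  // 0 = none yet
  double prev_reward = env_state["prev_reward"];
  bool eoe_flag = env_state["eoe_flag"];

  std::vector<int> r_action, r_episode;
  std::vector<int> r_optimal, r_reward_flag;
  std::vector<double> r_q0, r_q1;
  vec qbuf(hp.n_out);

  for (int ep = 0; ep < n_episodes; ++ep) {
    int len = ep_len[ep];
    for (int pull = 0; pull < len; ++pull) {
      vec x(4, arma::fill::zeros);
      if (prev_action > 0) x(prev_action - 1) = 1.0;
      x(2) = prev_reward / mag;
      if (eoe_signal && eoe_flag) x(3) = 1.0;
      int a = agent_step(A, hp, x, prev_reward, learn, eps,
                         record_q ? &qbuf : nullptr);
      double p = ((a + 1) == high) ? p_high : p_low;
      bool rewarded = unif_rand() < p;
      double rew = rewarded ? mag : 0.0;
      if (record) {
        r_action.push_back(a + 1);
        r_optimal.push_back((a + 1) == high ? 1 : 0);
        r_reward_flag.push_back(rewarded ? 1 : 0);
        r_episode.push_back(episode_index);
        if (record_q) { r_q0.push_back(qbuf(0)); r_q1.push_back(qbuf(1)); }
      }
      bool boundary = (pull + 1 == len);
      if (boundary) {
        episode_index++;
        if (alternating) high = 3 - high;
        else high = (unif_rand() < 0.5) ? 1 : 2;
      }
      eoe_flag = boundary;
      prev_action = a + 1;
      prev_reward = rew;
    }
  }
  List st = List::create(
    _["high"] = high, _["episode_index"] = episode_index,
    _["prev_action"] = prev_action, _["prev_reward"] = prev_reward,
    _["eoe_flag"] = eoe_flag);
  List out = List::create(
    _["agent"] = agent_to_list(A), _["env_state"] = st);
  if (record) {
    out["action"] = wrap(r_action);
    out["optimal"] = wrap(r_optimal);
    out["rewarded"] = wrap(r_reward_flag);
    out["episode"] = wrap(r_episode);
    if (record_q) { out["q1"] = wrap(r_q0); out["q2"] = wrap(r_q1); }
  }
  return out;
}
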