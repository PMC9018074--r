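#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bytecode ops: 0 push0, 1 push1, 2 push node (next: 0-based index),
// 3 NOT, 4 AND, 5 OR.
static inline int eval_code(const std::vector<int> &code,
                            const std::vector<int> &state) {
  int stack[64];
  int sp = 0;
  for (size_t i = 0; i < code.size(); ++i) {
    switch (code[i]) {
    case 0: stack[sp++] = 0; break;
    case 1: stack[sp++] = 1; break;
    case 2: stack[sp++] = state[code[++i]]; break;
    case 3: stack[sp - 1] = 1 - stack[sp - 1]; break;
    case 4: --sp; stack[sp - 1] = stack[sp - 1] & stack[sp]; break;
    case 5: --sp; stack[sp - 1] = stack[sp - 1] | stack[sp]; break;
    }
  }
  return stack[0];
}

// SplitMix64: deterministic per-trajectory substreams from one root
// seed, independent of execution order.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
  }
  // xoroshiro128+
  uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
};

struct Variant {
  std::vector<std::vector<int>> code;
  std::vector<double> kup, kdn, p0;
  // joint initial-condition assignments
  std::vector<std::vector<int>> joint_nodes;           // 0-based indices
  std::vector<std::vector<std::vector<int>>> joint_states;
  std::vector<std::vector<double>> joint_probs;
};

static Variant build_variant(const List &v) {
  Variant out;
  List code = v["code"];
  for (int i = 0; i < code.size(); ++i) {
    IntegerVector ci = code[i];
    out.code.emplace_back(ci.begin(), ci.end());
  }
  NumericVector kup = v["k_up"], kdn = v["k_down"], p0 = v["p0"];
  out.kup.assign(kup.begin(), kup.end());
  out.kdn.assign(kdn.begin(), kdn.end());
  out.p0.assign(p0.begin(), p0.end());
  List joint = v["joint"];
  for (int j = 0; j < joint.size(); ++j) {
    List ja = joint[j];
    IntegerVector idx = ja["idx0"];
    out.joint_nodes.emplace_back(idx.begin(), idx.end());
    List sts = ja["states"];
    std::vector<std::vector<int>> stv;
    for (int k = 0; k < sts.size(); ++k) {
      IntegerVector st = sts[k];
      stv.emplace_back(st.begin(), st.end());
    }
    out.joint_states.push_back(stv);
    NumericVector pr = ja["probs"];
    out.joint_probs.emplace_back(pr.begin(), pr.end());
  }
  return out;
}

static void sample_initial(const Variant &v, Rng &rng,
                           std::vector<int> &state) {
  const int n = (int)v.p0.size();
  for (int i = 0; i < n; ++i) state[i] = (rng.unif() < v.p0[i]) ? 1 : 0;
  for (size_t j = 0; j < v.joint_nodes.size(); ++j) {
    double u = rng.unif(), cum = 0.0;
    size_t pick = v.joint_probs[j].size() - 1;
    for (size_t k = 0; k < v.joint_probs[j].size(); ++k) {
      cum += v.joint_probs[j][k];
      if (u < cum) { pick = k; break; }
    }
    for (size_t m = 0; m < v.joint_nodes[j].size(); ++m)
      state[v.joint_nodes[j][m]] = v.joint_states[j][pick][m];
  }
}

// [[Rcpp::export]]
List sim_ensemble_cpp(List variants, NumericVector variant_probs,
                      int n_nodes, int n_traj, double max_time,
                      double tick, IntegerVector tracked0,
                      double seed, bool want_joint) {
  std::vector<Variant> vars;
  for (int i = 0; i < variants.size(); ++i)
    vars.push_back(build_variant(variants[i]));
  const int n_win = (int)std::ceil(max_time / tick - 1e-9);
  const int n_tr = tracked0.size();
  std::vector<int> tracked(tracked0.begin(), tracked0.end());
  const bool joint_ok = want_joint && n_tr <= 12;
  const int n_js = joint_ok ? (1 << n_tr) : 0;

  std::vector<double> win_w(n_win, tick);
  win_w[n_win - 1] = max_time - tick * (n_win - 1);

  std::vector<double> marg((size_t)n_win * n_tr, 0.0);
  std::vector<double> joint((size_t)n_win * n_js, 0.0);
  std::vector<int> vcount(vars.size(), 0);

  std::vector<int> state(n_nodes);
  std::vector<double> rates(n_nodes);
  // one SplitMix64 stream keyed on the root seed hands every
  // trajectory an independent substream seed
  uint64_t sm = (uint64_t)seed;
  splitmix64(sm);

  for (int tr = 0; tr < n_traj; ++tr) {
    Rng rng(splitmix64(sm));
    // variant choice (drug-mixture semantics)
    int vi = 0;
    if (vars.size() > 1) {
      double u = rng.unif(), cum = 0.0;
      vi = (int)vars.size() - 1;
      for (size_t k = 0; k < vars.size(); ++k) {
        cum += variant_probs[k];
        if (u < cum) { vi = (int)k; break; }
      }
    }
    vcount[vi]++;
    const Variant &V = vars[vi];
    sample_initial(V, rng, state);

    double t = 0.0;
    while (t < max_time) {
      double total = 0.0;
      for (int i = 0; i < n_nodes; ++i) {
        int target = eval_code(V.code[i], state);
        double r = 0.0;
        if (state[i] == 0 && target == 1) r = V.kup[i];
        else if (state[i] == 1 && target == 0) r = V.kdn[i];
        rates[i] = r;
        total += r;
      }
      double t_next = (total > 0.0)
        ? t - std::log(rng.unif_pos()) / total
        : max_time;
      double t_end = std::min(t_next, max_time);
      // accumulate occupancy of [t, t_end)
      int w0 = (int)(t / tick); if (w0 >= n_win) w0 = n_win - 1;
      int w1 = (int)((t_end - 1e-12) / tick); if (w1 >= n_win) w1 = n_win - 1;
      int key = 0;
      if (joint_ok)
        for (int b = 0; b < n_tr; ++b)
          if (state[tracked[b]]) key |= (1 << b);
      for (int w = w0; w <= w1; ++w) {
        double lo = std::max(t, w * tick);
        double hi = std::min(t_end, (w + 1.0) * tick);
        if (w == n_win - 1) hi = std::min(t_end, max_time);
        double d = hi - lo;
        if (d <= 0) continue;
        for (int b = 0; b < n_tr; ++b)
          if (state[tracked[b]]) marg[(size_t)w * n_tr + b] += d;
        if (joint_ok) joint[(size_t)w * n_js + key] += d;
      }
      if (total <= 0.0 || t_next >= max_time) break;
      // pick flipping node proportionally to its rate
      double u = rng.unif() * total, cum = 0.0;
      int pick = n_nodes - 1;
      for (int i = 0; i < n_nodes; ++i) {
        cum += rates[i];
        if (u < cum) { pick = i; break; }
      }
      state[pick] = 1 - state[pick];
      t = t_next;
    }
  }

  NumericMatrix margM(n_win, n_tr);
  for (int w = 0; w < n_win; ++w)
    for (int b = 0; b < n_tr; ++b)
      margM(w, b) = marg[(size_t)w * n_tr + b] / (win_w[w] * n_traj);
  List out = List::create(_["marginal"] = margM,
                          _["variant_counts"] = IntegerVector(vcount.begin(),
                                                              vcount.end()));
  if (joint_ok) {
    NumericMatrix jm(n_win, n_js);
    for (int w = 0; w < n_win; ++w)
      for (int k = 0; k < n_js; ++k)
        jm(w, k) = joint[(size_t)w * n_js + k] / (win_w[w] * n_traj);
    out["joint"] = jm;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame run_trajectory_cpp(List variant, IntegerVector init,
                             double max_time, double seed) {
  Variant V = build_variant(variant);
  const int n = (int)V.p0.size();
  std::vector<int> state(init.begin(), init.end());
  std::vector<double> rates(n);
  uint64_t x = (uint64_t)seed + 1ULL;
  Rng rng(splitmix64(x));
  std::vector<double> ev_t;
  std::vector<int> ev_node, ev_val;
  double t = 0.0;
  while (t < max_time) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      int target = eval_code(V.code[i], state);
      double r = 0.0;
      if (state[i] == 0 && target == 1) r = V.kup[i];
      else if (state[i] == 1 && target == 0) r = V.kdn[i];
      rates[i] = r;
      total += r;
    }
    if (total <= 0.0) break;
    double t_next = t - std::log(rng.unif_pos()) / total;
    if (t_next >= max_time) break;
    double u = rng.unif() * total, cum = 0.0;
    int pick = n - 1;
    for (int i = 0; i < n; ++i) {
      cum += rates[i];
      if (u < cum) { pick = i; break; }
    }
    state[pick] = 1 - state[pick];
    ev_t.push_back(t_next);
    ev_node.push_back(pick + 1);
    ev_val.push_back(state[pick]);
    t = t_next;
  }
  return DataFrame::create(_["time"] = ev_t, _["node"] = ev_node,
                           _["value"] = ev_val);
}
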