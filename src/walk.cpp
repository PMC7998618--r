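#include <Rcpp.h>
using namespace Rcpp;

// General-asynchronous random walk over a probabilistic Boolean system.
//
// Each step draws exactly two uniforms in this order: the free node to
// update, then the acceptance draw against the node's rule probability.
// The pure-R reference implementation in simulate_walk() consumes the
// RNG stream identically, so the two routes are byte-comparable under a
// common seed.
//
// state0      : 0/1 start state (length n)
// reg_idx     : per node, 0-based indices of its regulators
// prob_tab    : per node, table of ON-probabilities (length 2^k),
//               regulator 1 in the least-significant bit
// free_nodes  : 0-based indices of updatable (non-held) nodes
// mod_members : per tracked module, 0-based member node indices
//               (non-source members only)
// start_band  : per module, 0 = low start, 1 = intermediate start
// n_steps     : walk length
// stop_early  : stop once every tracked module has switched
//
// Returns switch times per module (censored at n_steps + 1) and the
// final state.
// [[Rcpp::export]]
List walk_switch_core(IntegerVector state0, List reg_idx, List prob_tab,
                      IntegerVector free_nodes, List mod_members,
                      IntegerVector start_band, int n_steps,
                      bool stop_early) {
  int n = state0.size();
  int n_free = free_nodes.size();
  int n_mod = mod_members.size();
  std::vector<int> state(state0.begin(), state0.end());

  // per-module ON counts and sizes
  std::vector<int> mcount(n_mod, 0), msize(n_mod, 0);
  // node -> modules containing it
  std::vector< std::vector<int> > node_mods(n);
  for (int m = 0; m < n_mod; ++m) {
    IntegerVector mem = mod_members[m];
    msize[m] = mem.size();
    for (int k = 0; k < mem.size(); ++k) {
      mcount[m] += state[mem[k]];
      node_mods[mem[k]].push_back(m);
    }
  }

  IntegerVector switch_time(n_mod, n_steps + 1);
  int unswitched = n_mod;

  for (int step = 1; step <= n_steps; ++step) {
    int j = free_nodes[(int)(unif_rand() * n_free)];
    IntegerVector regs = reg_idx[j];
    int idx = 0;
    for (int k = 0; k < regs.size(); ++k) {
      idx += state[regs[k]] << k;
    }
    NumericVector tab = prob_tab[j];
    double p = tab[idx];
    int newv = (unif_rand() < p) ? 1 : 0;
    if (newv != state[j]) {
      state[j] = newv;
      int delta = newv == 1 ? 1 : -1;
      for (size_t t = 0; t < node_mods[j].size(); ++t) {
        int m = node_mods[j][t];
        mcount[m] += delta;
        if (switch_time[m] > n_steps) {
          double frac = (double)mcount[m] / msize[m];
          int band = frac < 0.25 ? 0 : (frac <= 0.75 ? 1 : 2);
          bool crossed = (start_band[m] == 0) ? (band >= 1) : (band == 0);
          if (crossed) {
            switch_time[m] = step;
            --unswitched;
          }
        }
      }
      if (stop_early && unswitched == 0) break;
    }
  }

  return List::create(_["switch_times"] = switch_time,
                      _["state"] = IntegerVector(state.begin(), state.end()));
}
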