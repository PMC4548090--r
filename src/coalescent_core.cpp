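#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact backward-in-time Wright-Fisher structured coalescent.
//
// Generations are discrete. One step t -> t+1 (backward) is:
//   (i)  migration: each lineage moves with probability m according to the
//        migration mode (1 = sink: lineages outside deme 1 move to deme 1;
//        2 = island: move to a uniformly chosen *other* deme; 0 = none);
//   (ii) parent choice: every lineage in deme d draws a parent uniformly from
//        the deme's gene-copy count at generation t+1; lineages sharing a
//        parent coalesce (multiple and simultaneous mergers allowed).
//
// From generation 0 to t_end the per-deme gene-copy counts follow the
// trajectory matrix exactly, generation by generation. Beyond t_end sizes are
// constant and the simulation switches to a geometric-jump scheme: the
// per-generation probability that *nothing* happens (no migration, all
// parents distinct) is computed, the waiting time to the next eventful
// generation is drawn geometrically, and that generation is realised by
// rejection (re-simulating it until at least one event occurs), which
// preserves the exact Wright-Fisher law while skipping empty generations.
// Large constant-size tails (e.g. N = 50,000) thus stay cheap without
// approximating the process.

struct MergeRec {
  double time;
  int deme;
  std::vector<int> children;
};

struct SimState {
  std::vector<int> deme, node;
  // scratch buffers reused across generations
  std::vector<int> new_deme, order, keep_node, keep_deme;
  std::vector<unsigned long long> key;
};

static inline int draw_parent(double n_copies) {
  int p = (int)std::floor(unif_rand() * n_copies);
  if (p >= (int)n_copies) p = (int)n_copies - 1;
  return p;
}

// One generation: migrate + choose parents. Returns true if any event
// (migration or coalescence) happened; the state is only modified when an
// event occurs (so the same call doubles as a rejection-sampling trial).
static bool step_generation(SimState& st, const std::vector<double>& copies,
                            double m, int mig_mode, double time,
                            std::vector<MergeRec>& merges, int& next_node) {
  const int k = (int)st.deme.size();
  const int D = (int)copies.size();
  st.new_deme.assign(st.deme.begin(), st.deme.end());
  bool any_mig = false;
  if (m > 0 && mig_mode == 1) {
    for (int i = 0; i < k; ++i)
      if (st.deme[i] != 0 && unif_rand() < m) { st.new_deme[i] = 0; any_mig = true; }
  } else if (m > 0 && mig_mode == 2) {
    for (int i = 0; i < k; ++i)
      if (unif_rand() < m) {
        int d = (int)std::floor(unif_rand() * (D - 1));
        if (d >= st.deme[i]) ++d;  // uniform over the D-1 other demes
        st.new_deme[i] = d;
        any_mig = true;
      }
  }

  st.key.resize(k);
  for (int i = 0; i < k; ++i) {
    int d = st.new_deme[i];
    st.key[i] = ((unsigned long long)d << 40) |
                (unsigned long long)draw_parent(copies[d]);
  }
  st.order.resize(k);
  for (int i = 0; i < k; ++i) st.order[i] = i;
  std::sort(st.order.begin(), st.order.end(),
            [&](int a, int b) { return st.key[a] < st.key[b]; });
  bool any_coal = false;
  for (int i = 1; i < k; ++i)
    if (st.key[st.order[i]] == st.key[st.order[i - 1]]) { any_coal = true; break; }
  if (!any_mig && !any_coal) return false;

  st.deme.swap(st.new_deme);
  if (any_coal) {
    st.keep_node.clear();
    st.keep_deme.clear();
    int i = 0;
    while (i < k) {
      int j = i + 1;
      while (j < k && st.key[st.order[j]] == st.key[st.order[i]]) ++j;
      if (j - i == 1) {
        st.keep_node.push_back(st.node[st.order[i]]);
        st.keep_deme.push_back(st.deme[st.order[i]]);
      } else {
        MergeRec mr;
        mr.time = time;
        mr.deme = st.deme[st.order[i]];
        for (int q = i; q < j; ++q) mr.children.push_back(st.node[st.order[q]]);
        merges.push_back(mr);
        st.keep_node.push_back(next_node++);
        st.keep_deme.push_back(mr.deme);
      }
      i = j;
    }
    st.node.swap(st.keep_node);
    st.deme.swap(st.keep_deme);
  }
  return true;
}

// [[Rcpp::export(name = ".sim_coalescent_cpp")]]
List sim_coalescent_cpp(IntegerVector lineage_deme, NumericMatrix traj,
                        NumericVector post_copies, double m, int mig_mode,
                        int t_end, bool absorb_at_tend, double max_gen) {
  const int n = lineage_deme.size();
  const int D = post_copies.size();
  if (traj.ncol() != D) stop("trajectory/deme mismatch");
  if (traj.nrow() < t_end + 1) stop("trajectory shorter than t_end + 1");

  SimState st;
  st.deme.resize(n);
  st.node.resize(n);
  for (int i = 0; i < n; ++i) {
    st.deme[i] = lineage_deme[i] - 1;
    if (st.deme[i] < 0 || st.deme[i] >= D) stop("lineage deme out of range");
    st.node[i] = i + 1;
  }
  int next_node = n + 1;
  std::vector<MergeRec> merges;
  merges.reserve(n);

  // phase 1: generation-by-generation along the size trajectory
  std::vector<double> copies(D);
  for (int g = 0; g < t_end && (int)st.deme.size() > 1; ++g) {
    for (int d = 0; d < D; ++d) copies[d] = traj(g + 1, d);
    step_generation(st, copies, m, mig_mode, (double)(g + 1), merges,
                    next_node);
  }

  // phase 2: constant sizes beyond t_end
  if ((int)st.deme.size() > 1) {
    double t = (double)t_end;
    if (absorb_at_tend)
      std::fill(st.deme.begin(), st.deme.end(), 0);
    for (int d = 0; d < D; ++d) copies[d] = post_copies[d];
    for (size_t i = 0; i < st.deme.size(); ++i)
      if (copies[st.deme[i]] < 1.0) st.deme[i] = 0;  // extinct deme: pull to 1

    std::vector<int> kd(D);
    bool hit_cap = false;
    while ((int)st.deme.size() > 1) {
      const int k = (int)st.deme.size();
      std::fill(kd.begin(), kd.end(), 0);
      for (int i = 0; i < k; ++i) kd[st.deme[i]]++;
      double log_p_none = 0.0;
      int movable = 0;
      if (mig_mode == 1) movable = k - kd[0];
      else if (mig_mode == 2) movable = k;
      if (m > 0 && movable > 0) log_p_none += movable * std::log1p(-m);
      for (int d = 0; d < D; ++d)
        for (int i = 1; i < kd[d]; ++i)
          log_p_none += std::log1p(-(double)i / copies[d]);
      if (log_p_none >= 0.0) {
        return List::create(_["error"] = "deadlock: multiple lineages with no "
                            "possible migration or coalescence");
      }
      if (log_p_none > -0.5) {
        // empty generations are common: jump geometrically to the next
        // eventful one and realise it by rejection (exact conditional draw)
        double skip = std::floor(std::log(unif_rand()) / log_p_none);
        t += skip + 1.0;
        if (t > max_gen) { hit_cap = true; break; }
        while (!step_generation(st, copies, m, mig_mode, t, merges, next_node)) {}
      } else {
        // events are frequent: plain unconditional per-generation stepping
        t += 1.0;
        if (t > max_gen) { hit_cap = true; break; }
        step_generation(st, copies, m, mig_mode, t, merges, next_node);
      }
    }
    if (hit_cap)
      return List::create(_["error"] = "MRCA not reached before generation cap");
  }

  const int n_merge = (int)merges.size();
  int n_edges = 0;
  for (int i = 0; i < n_merge; ++i) n_edges += (int)merges[i].children.size();
  IntegerVector parent(n_edges), child(n_edges);
  NumericVector node_time(next_node - 1);  // tips at 0
  IntegerVector merge_deme(n_merge);
  int e = 0;
  for (int i = 0; i < n_merge; ++i) {
    int pid = n + 1 + i;
    node_time[pid - 1] = merges[i].time;
    merge_deme[i] = merges[i].deme + 1;
    for (size_t j = 0; j < merges[i].children.size(); ++j) {
      parent[e] = pid;
      child[e] = merges[i].children[j];
      ++e;
    }
  }
  return List::create(_["n_tips"] = n, _["parent"] = parent,
                      _["child"] = child, _["node_time"] = node_time,
                      _["merge_deme"] = merge_deme,
                      _["tmrca"] = (n_merge > 0) ? merges[n_merge - 1].time : 0.0);
}
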