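// Greedy maximization of weighted modularity (Q) or modularity density (Qds)
// on a dense weighted adjacency matrix (zero diagonal, symmetric).
//
// Phase 1: agglomerative merging — every node starts as its own community and
// the connected community pair with the largest positive objective gain is
// merged until no merge improves the objective.
// Phase 2: fine-tuning — best-improvement single-node moves to adjacent
// communities or to a fresh singleton (the split mechanism), swept in fixed
// node order; phases alternate until a local optimum.
//
// Phase 3: Kernighan-Lin refinement and community split proposals (below).
//
// Determinism: candidates are scanned in ascending community-slot /node order
// and a candidate replaces the incumbent only on a strictly larger gain, so
// ties resolve to the smallest label pair. Randomness enters only through
// optional restarts: restarts beyond the first pick uniformly among all
// positive-gain merges (randomized greedy, driven by R's RNG) and the best
// local optimum across restarts is kept.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Optimizer {
  int n;
  std::vector<double> A;   // dense n x n, column-major
  double twoW;             // total strength sum_i s_i
  double W;                // total edge weight
  bool density;            // true: Qds, false: Q
  double eps;
  bool stochastic = false; // restarts > 1: randomize merge selection

  std::vector<int> comm;                  // node -> community slot
  std::vector<char> active;               // slot in use
  std::vector<int> csize;                 // community sizes
  std::vector<double> wout;               // external strength per community
  std::vector<std::vector<double> > M;    // M[c][c'] inter weight, M[c][c] internal
  std::vector<int> slots;                 // active slots, ascending (rebuilt on demand)

  double a(int i, int j) const { return A[i + (size_t)n * j]; }

  void init(const NumericMatrix& Ain, bool dens, double eps_) {
    n = Ain.nrow();
    density = dens;
    eps = eps_;
    A.assign(Ain.begin(), Ain.end());
    twoW = 0.0;
    for (double v : A) twoW += v;
    W = twoW / 2.0;
    comm.resize(n);
    active.assign(n, 1);
    csize.assign(n, 1);
    wout.assign(n, 0.0);
    M.assign(n, std::vector<double>(n, 0.0));
    for (int i = 0; i < n; ++i) {
      comm[i] = i;
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j != i) {
          M[i][j] = a(i, j);
          s += a(i, j);
        }
      }
      wout[i] = s;
    }
  }

  // contribution of one community to the objective (pair penalties excluded)
  double own(double win, double wo, int size) const {
    if (!density) {
      double S = 2.0 * win + wo;
      return 2.0 * win / twoW - (S / twoW) * (S / twoW);
    }
    double d = (size > 1) ? 2.0 * win / ((double)size * (size - 1)) : 0.0;
    double t1 = (win / W) * d;
    double t2 = ((2.0 * win + wo) / twoW) * d;
    return t1 - t2 * t2;
  }

  // one direction of the split penalty between two communities
  double pen(double w, int na, int nb) const {
    if (!density || w <= 0.0) return 0.0;
    return (w / twoW) * (w / ((double)na * nb));
  }

  double total_objective() const {
    double q = 0.0;
    for (int c = 0; c < n; ++c) {
      if (!active[c]) continue;
      q += own(M[c][c], wout[c], csize[c]);
      if (density) {
        for (int d = 0; d < n; ++d) {
          if (d != c && active[d]) q -= pen(M[c][d], csize[c], csize[d]);
        }
      }
    }
    return q;
  }

  void rebuild_slots() {
    slots.clear();
    for (int c = 0; c < n; ++c) if (active[c]) slots.push_back(c);
  }

  double merge_delta(int ca, int cb) const {
    double wab = M[ca][cb];
    int ns = csize[ca] + csize[cb];
    double win_new = M[ca][ca] + M[cb][cb] + wab;
    double wout_new = wout[ca] + wout[cb] - 2.0 * wab;
    double delta = own(win_new, wout_new, ns)
      - own(M[ca][ca], wout[ca], csize[ca])
      - own(M[cb][cb], wout[cb], csize[cb]);
    if (density) {
      delta += 2.0 * pen(wab, csize[ca], csize[cb]);
      for (int c : slots) {
        if (c == ca || c == cb) continue;
        double w1 = M[ca][c], w2 = M[cb][c];
        if (w1 == 0.0 && w2 == 0.0) continue;
        delta -= 2.0 * (pen(w1 + w2, ns, csize[c])
                        - pen(w1, csize[ca], csize[c])
                        - pen(w2, csize[cb], csize[c]));
      }
    }
    return delta;
  }

  void apply_merge(int ca, int cb) {  // merge cb into ca
    double wab = M[ca][cb];
    M[ca][ca] += M[cb][cb] + wab;
    wout[ca] += wout[cb] - 2.0 * wab;
    for (int c : slots) {
      if (c == ca || c == cb) continue;
      M[ca][c] += M[cb][c];
      M[c][ca] = M[ca][c];
    }
    M[ca][cb] = M[cb][ca] = 0.0;
    csize[ca] += csize[cb];
    active[cb] = 0;
    csize[cb] = 0;
    for (int i = 0; i < n; ++i) if (comm[i] == cb) comm[i] = ca;
    rebuild_slots();
  }

  // one round of greedy merging; returns true if any merge happened
  bool merge_phase() {
    bool any = false;
    for (;;) {
      rebuild_slots();
      double best = eps;
      int ba = -1, bb = -1;
      std::vector<std::pair<int, int> > positive;
      for (size_t x = 0; x < slots.size(); ++x) {
        for (size_t y = x + 1; y < slots.size(); ++y) {
          int ca = slots[x], cb = slots[y];
          // For Q a zero-weight merge strictly lowers the objective, so only
          // connected pairs are candidates. For Qds merging non-adjacent
          // communities can pay (it dilutes the split penalty), so all pairs
          // are considered.
          if (!density && M[ca][cb] <= 0.0) continue;
          double d = merge_delta(ca, cb);
          if (d > best) { best = d; ba = ca; bb = cb; }
          if (stochastic && d > eps) positive.push_back(std::make_pair(ca, cb));
        }
      }
      if (ba < 0) break;
      if (stochastic && positive.size() > 1) {
        // randomized greedy: any positive-gain merge may be taken, which
        // diversifies the search path across restarts
        size_t pick = (size_t)(unif_rand() * positive.size());
        if (pick >= positive.size()) pick = positive.size() - 1;
        ba = positive[pick].first;
        bb = positive[pick].second;
      }
      apply_merge(ba, bb);
      any = true;
    }
    return any;
  }

  // delta of moving node i from c1 to c2 (c2 == -1: a fresh singleton)
  double move_delta(int i, int c1, int c2,
                    const std::vector<double>& wi, double si) const {
    int n1 = csize[c1];
    double win1 = M[c1][c1], wo1 = wout[c1], w_ic1 = wi[c1];
    int n2 = (c2 >= 0) ? csize[c2] : 0;
    double win2 = (c2 >= 0) ? M[c2][c2] : 0.0;
    double wo2 = (c2 >= 0) ? wout[c2] : 0.0;
    double w_ic2 = (c2 >= 0) ? wi[c2] : 0.0;

    int n1n = n1 - 1, n2n = n2 + 1;
    double win1n = win1 - w_ic1;
    double wo1n = wo1 - si + 2.0 * w_ic1;
    double win2n = win2 + w_ic2;
    double wo2n = wo2 + si - 2.0 * w_ic2;

    double delta = 0.0;
    delta += (n1n > 0 ? own(win1n, wo1n, n1n) : 0.0) - own(win1, wo1, n1);
    delta += own(win2n, wo2n, n2n) - (c2 >= 0 ? own(win2, wo2, n2) : 0.0);
    if (density) {
      double m12 = (c2 >= 0) ? M[c1][c2] : 0.0;
      double m12n = m12 - w_ic2 + w_ic1;
      for (int c : slots) {
        if (c == c1 || c == c2) continue;
        double r1 = M[c1][c], r2 = (c2 >= 0) ? M[c2][c] : 0.0;
        double wic = wi[c];
        if (r1 == 0.0 && r2 == 0.0 && wic == 0.0) continue;
        double oldp = pen(r1, n1, csize[c]) + (c2 >= 0 ? pen(r2, n2, csize[c]) : 0.0);
        double newp = (n1n > 0 ? pen(r1 - wic, n1n, csize[c]) : 0.0)
          + pen(r2 + wic, n2n, csize[c]);
        delta -= 2.0 * (newp - oldp);
      }
      double oldp = (c2 >= 0) ? pen(m12, n1, n2) : 0.0;
      double newp = (n1n > 0) ? pen(m12n, n1n, n2n) : 0.0;
      delta -= 2.0 * (newp - oldp);
    }
    return delta;
  }

  void apply_move(int i, int c1, int c2, const std::vector<double>& wi, double si) {
    if (c2 < 0) {  // fresh singleton: reuse a free slot
      for (int c = 0; c < n; ++c) {
        if (!active[c]) { c2 = c; break; }
      }
      active[c2] = 1;
      csize[c2] = 0;
      M[c2][c2] = 0.0;
      wout[c2] = 0.0;
      for (int c = 0; c < n; ++c) { M[c2][c] = 0.0; M[c][c2] = 0.0; }
      M[c2][c2] = 0.0;
      rebuild_slots();
    }
    double w_ic1 = wi[c1], w_ic2 = wi[c2];
    // remove i from c1
    M[c1][c1] -= w_ic1;
    wout[c1] += -si + 2.0 * w_ic1;
    csize[c1] -= 1;
    // add i to c2
    M[c2][c2] += w_ic2;
    wout[c2] += si - 2.0 * w_ic2;
    csize[c2] += 1;
    for (int c : slots) {
      if (c == c1 || c == c2) continue;
      double wic = wi[c];
      if (wic != 0.0) {
        M[c1][c] -= wic; M[c][c1] = M[c1][c];
        M[c2][c] += wic; M[c][c2] = M[c2][c];
      }
    }
    double m12 = M[c1][c2] - w_ic2 + w_ic1;
    M[c1][c2] = M[c2][c1] = m12;
    comm[i] = c2;
    if (csize[c1] == 0) {
      active[c1] = 0;
      for (int c = 0; c < n; ++c) { M[c1][c] = 0.0; M[c][c1] = 0.0; }
      rebuild_slots();
    }
  }

  // one sweep of single-node moves; returns true if any move happened
  bool move_phase() {
    bool any = false;
    std::vector<double> wi(n, 0.0);
    for (int i = 0; i < n; ++i) {
      rebuild_slots();
      std::fill(wi.begin(), wi.end(), 0.0);
      double si = 0.0;
      for (int j = 0; j < n; ++j) {
        double v = a(i, j);
        if (v != 0.0 && j != i) { wi[comm[j]] += v; si += v; }
      }
      int c1 = comm[i];
      double best = eps;
      int bestc = -2;
      for (int c2 : slots) {
        if (c2 == c1) continue;
        if (!density && wi[c2] <= 0.0) continue;  // never pays for Q
        double d = move_delta(i, c1, c2, wi, si);
        if (d > best) { best = d; bestc = c2; }
      }
      if (csize[c1] > 1) {  // extraction to a fresh singleton
        double d = move_delta(i, c1, -1, wi, si);
        if (d > best) { best = d; bestc = -1; }
      }
      if (bestc != -2) {
        apply_move(i, c1, bestc, wi, si);
        any = true;
      }
    }
    return any;
  }

  void node_weights(int i, std::vector<double>& wi, double& si) const {
    std::fill(wi.begin(), wi.end(), 0.0);
    si = 0.0;
    for (int j = 0; j < n; ++j) {
      double v = a(i, j);
      if (v != 0.0 && j != i) { wi[comm[j]] += v; si += v; }
    }
  }

  // Kernighan-Lin style split proposal for one community: greedily peel
  // members into a fresh community, allowing temporarily negative gains,
  // and keep the best cumulative prefix if it improves the objective.
  bool try_split(int c0) {
    std::vector<int> members;
    for (int i = 0; i < n; ++i) if (comm[i] == c0) members.push_back(i);
    if ((int)members.size() < 3) return false;

    Optimizer trial = *this;
    std::vector<double> wi(n, 0.0);
    double si = 0.0;
    double cum = 0.0, best_cum = eps;
    int best_k = 0;
    std::vector<int> sequence;
    int newslot = -1;
    std::vector<char> moved(n, 0);
    for (size_t k = 0; k + 1 < members.size(); ++k) {
      double best = R_NegInf;
      int pick = -1;
      for (int i : members) {
        if (moved[i]) continue;
        trial.node_weights(i, wi, si);
        double d = trial.move_delta(i, c0, newslot, wi, si);
        if (d > best) { best = d; pick = i; }
      }
      if (pick < 0) break;
      trial.node_weights(pick, wi, si);
      trial.apply_move(pick, c0, newslot, wi, si);
      if (newslot < 0) newslot = trial.comm[pick];
      moved[pick] = 1;
      sequence.push_back(pick);
      cum += best;
      if (cum > best_cum) { best_cum = cum; best_k = (int)(k + 1); }
    }
    if (best_k == 0) return false;
    // replay the winning prefix on the real state
    int slot = -1;
    for (int k = 0; k < best_k; ++k) {
      int i = sequence[k];
      node_weights(i, wi, si);
      apply_move(i, c0, slot, wi, si);
      if (slot < 0) slot = comm[i];
    }
    return true;
  }

  bool split_phase() {
    rebuild_slots();
    std::vector<int> snapshot = slots;
    bool any = false;
    for (int c : snapshot) {
      if (active[c] && try_split(c)) any = true;
    }
    return any;
  }

  // Kernighan-Lin refinement: a chain of single-node relocations, each the
  // best available move (possibly with a negative gain, each node moved at
  // most once); the best-scoring prefix of the chain is kept if it improves
  // the objective. This escapes local optima that no single move or merge
  // can leave.
  bool kl_phase() {
    Optimizer trial = *this;
    std::vector<double> wi(n, 0.0);
    double si = 0.0;
    double cum = 0.0, best_cum = eps;
    int best_k = 0;
    std::vector<char> moved(n, 0);
    std::vector<int> seq_node, seq_rep;  // rep: member of target, -1 = fresh
    for (int step = 0; step < n; ++step) {
      trial.rebuild_slots();
      double best = R_NegInf;
      int bi = -1, btarget = -2;
      for (int i = 0; i < n; ++i) {
        if (moved[i]) continue;
        trial.node_weights(i, wi, si);
        int c1 = trial.comm[i];
        for (int c2 : trial.slots) {
          if (c2 == c1) continue;
          if (!density && wi[c2] <= 0.0) continue;
          double d = trial.move_delta(i, c1, c2, wi, si);
          if (d > best) { best = d; bi = i; btarget = c2; }
        }
        if (trial.csize[c1] > 1) {
          double d = trial.move_delta(i, c1, -1, wi, si);
          if (d > best) { best = d; bi = i; btarget = -1; }
        }
      }
      if (bi < 0) break;
      int rep = -1;
      if (btarget >= 0) {
        for (int j = 0; j < n; ++j) {
          if (j != bi && trial.comm[j] == btarget) { rep = j; break; }
        }
      }
      trial.node_weights(bi, wi, si);
      trial.apply_move(bi, trial.comm[bi], btarget, wi, si);
      moved[bi] = 1;
      seq_node.push_back(bi);
      seq_rep.push_back(rep);
      cum += best;
      if (cum > best_cum) { best_cum = cum; best_k = step + 1; }
    }
    if (best_k == 0) return false;
    for (int k = 0; k < best_k; ++k) {  // replay the winning prefix
      int i = seq_node[k];
      int target = (seq_rep[k] >= 0) ? comm[seq_rep[k]] : -1;
      node_weights(i, wi, si);
      apply_move(i, comm[i], target, wi, si);
    }
    return true;
  }

  double run() {
    rebuild_slots();
    merge_phase();
    for (int iter = 0; iter < 200; ++iter) {
      bool moved = move_phase();
      bool split = split_phase();
      bool merged = merge_phase();
      if (!moved && !split && !merged) {
        if (!kl_phase()) break;
      }
    }
    return total_objective();
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_maximize")]]
List cpp_maximize(NumericMatrix A, bool density, double eps, int n_restarts) {
  int n = A.nrow();
  if (n == 0) stop("empty graph");
  if (A.ncol() != n) stop("adjacency must be square");

  std::vector<int> best_assign;
  double best_obj = R_NegInf;

  for (int r = 0; r < std::max(1, n_restarts); ++r) {
    Optimizer opt;
    opt.init(A, density, eps);
    opt.stochastic = (r > 0);  // the first restart is plain deterministic greedy
    double obj = opt.run();
    if (obj > best_obj + eps) {
      best_obj = obj;
      best_assign.assign(n, 0);
      for (int i = 0; i < n; ++i) best_assign[i] = opt.comm[i];
    }
  }

  // contiguous labels in first-appearance order
  IntegerVector out(n);
  std::vector<int> map(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int c = best_assign[i];
    if (map[c] == 0) map[c] = ++next;
    out[i] = map[c];
  }
  return List::create(_["assignment"] = out, _["objective"] = best_obj);
}
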