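// Optimal Channel Network synthesis on a periodic lattice: random spanning
// drainage forest initialization, metaheuristic minimization of the total
// energy dissipation E = sum_i A_i^gamma over loop-free drainage-direction
// configurations, and elevation reconstruction from the slope-area relation
// (local slope along a flow link proportional to A^(gamma-1)).
#include <Rcpp.h>
using namespace Rcpp;

namespace {

const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
const double LEN[8] = {M_SQRT2, 1.0, M_SQRT2, 1.0, 1.0, M_SQRT2, 1.0, M_SQRT2};

inline int wrap(int x, int n) { return (x % n + n) % n; }

inline int receiver(int cell, int dir, int n) {
  const int r = cell % n, c = cell / n;  // column-major like R matrices
  return wrap(r + DR[dir], n) + wrap(c + DC[dir], n) * n;
}

// walk downstream from `start`; returns true if the walk hits `avoid`
bool reaches(const IntegerVector& dir, int start, int avoid, int n) {
  const int N = n * n;
  int cur = start;
  for (int s = 0; s < N + 1; ++s) {
    if (cur == avoid) return true;
    const int d = dir[cur];
    if (d < 0) return false;  // outlet
    cur = receiver(cur, d, n);
  }
  return true;  // should not happen on a valid configuration
}

}  // namespace

// Randomized-Prim spanning forest toward `outlets` (0-based cell indices,
// column-major). Every non-outlet cell drains to the neighbor from which it
// was attached, so the configuration is loop-free by construction.
// [[Rcpp::export]]
List cpp_init_drainage(int n, IntegerVector outlets) {
  const int N = n * n;
  IntegerVector dir(N, -2);  // -2 unassigned, -1 outlet
  std::vector<std::pair<int, int> > edges;  // (assigned cell, dir toward it from neighbor)
  edges.reserve(8 * N);

  auto push_edges = [&](int cell) {
    for (int d = 0; d < 8; ++d) {
      const int nb = receiver(cell, d, n);
      if (dir[nb] == -2) edges.push_back(std::make_pair(cell, d));
    }
  };

  for (int k = 0; k < outlets.size(); ++k) {
    dir[outlets[k]] = -1;
    push_edges(outlets[k]);
  }
  int assigned = outlets.size();
  std::vector<int> order;  // attachment order (receivers before senders)
  order.reserve(N);
  for (int k = 0; k < outlets.size(); ++k) order.push_back(outlets[k]);

  while (assigned < N && !edges.empty()) {
    const size_t pick = (size_t)(R::unif_rand() * edges.size());
    const std::pair<int, int> ed = edges[std::min(pick, edges.size() - 1)];
    edges[std::min(pick, edges.size() - 1)] = edges.back();
    edges.pop_back();
    // ed.first is assigned; the neighbor in direction ed.second drains INTO it
    const int nb = receiver(ed.first, ed.second, n);
    if (dir[nb] != -2) continue;
    // nb -> ed.first is the opposite direction (7 - d under this ordering)
    dir[nb] = 7 - ed.second;
    ++assigned;
    order.push_back(nb);
    push_edges(nb);
  }

  // accumulate drainage areas leaf-to-outlet (reverse attachment order)
  IntegerVector area(N, 1);
  for (int k = N - 1; k >= 0; --k) {
    const int cell = order[k];
    if (dir[cell] >= 0) area[receiver(cell, dir[cell], n)] += area[cell];
  }
  return List::create(_["flow_dir"] = dir, _["area"] = area);
}

// [[Rcpp::export]]
List cpp_optimize_ocn(IntegerVector flow_dir, IntegerVector area, double gamma,
                      int n_iters, bool annealing, double T0, double alpha,
                      int trace_every) {
  const int N = flow_dir.size();
  const int n = (int)std::round(std::sqrt((double)N));
  IntegerVector dir = clone(flow_dir);
  IntegerVector ar = clone(area);

  double energy = 0.0;
  for (int i = 0; i < N; ++i) energy += std::pow((double)ar[i], gamma);

  std::vector<int> cells;  // perturbable (non-outlet) cells
  cells.reserve(N);
  for (int i = 0; i < N; ++i)
    if (dir[i] >= 0) cells.push_back(i);

  const int n_tr = trace_every > 0 ? n_iters / trace_every : 0;
  NumericVector trace(n_tr);
  int tr_i = 0, n_accept = 0;
  double T = T0;

  for (int it = 1; it <= n_iters; ++it) {
    const int i = cells[std::min((size_t)(R::unif_rand() * cells.size()),
                                 cells.size() - 1)];
    int nd = (int)(R::unif_rand() * 8.0);
    if (nd > 7) nd = 7;
    if (nd != dir[i]) {
      const int j = receiver(i, nd, n);
      // reject proposals that create a loop (new receiver drains through i)
      if (!reaches(dir, j, i, n)) {
        const int A = ar[i];
        const int r_old = receiver(i, dir[i], n);
        double dE = 0.0;
        int cur = r_old;
        for (;;) {
          dE += std::pow((double)(ar[cur] - A), gamma) -
                std::pow((double)ar[cur], gamma);
          ar[cur] -= A;
          if (dir[cur] < 0) break;
          cur = receiver(cur, dir[cur], n);
        }
        cur = j;
        for (;;) {
          dE += std::pow((double)(ar[cur] + A), gamma) -
                std::pow((double)ar[cur], gamma);
          ar[cur] += A;
          if (dir[cur] < 0) break;
          cur = receiver(cur, dir[cur], n);
        }
        bool accept;
        if (dE <= 0) accept = true;
        else if (annealing && T > 1e-300)
          accept = R::unif_rand() < std::exp(-dE / T);
        else accept = false;
        if (accept) {
          dir[i] = nd;
          energy += dE;
          ++n_accept;
        } else {  // revert area updates
          cur = r_old;
          for (;;) {
            ar[cur] += A;
            if (dir[cur] < 0) break;
            cur = receiver(cur, dir[cur], n);
          }
          cur = j;
          for (;;) {
            ar[cur] -= A;
            if (dir[cur] < 0) break;
            cur = receiver(cur, dir[cur], n);
          }
        }
      }
    }
    if (annealing) T *= alpha;
    if (trace_every > 0 && it % trace_every == 0 && tr_i < n_tr)
      trace[tr_i++] = energy;
  }

  return List::create(_["flow_dir"] = dir, _["area"] = ar,
                      _["energy"] = energy, _["energy_trace"] = trace,
                      _["n_accept"] = n_accept);
}

// Elevations by upstream accumulation of slopes from outlet level 0:
// z_i = z_receiver + link_length * A_i^(gamma-1).
// [[Rcpp::export]]
NumericVector cpp_elevations_from_areas(IntegerVector flow_dir,
                                        IntegerVector area, double gamma) {
  const int N = flow_dir.size();
  const int n = (int)std::round(std::sqrt((double)N));
  NumericVector z(N, NA_REAL);
  // children lists via counting sort on receivers
  std::vector<std::vector<int> > children(N);
  std::vector<int> stack;
  for (int i = 0; i < N; ++i) {
    if (flow_dir[i] < 0) {
      z[i] = 0.0;
      stack.push_back(i);
    } else {
      children[receiver(i, flow_dir[i], n)].push_back(i);
    }
  }
  while (!stack.empty()) {
    const int cur = stack.back();
    stack.pop_back();
    for (size_t k = 0; k < children[cur].size(); ++k) {
      const int ch = children[cur][k];
      z[ch] = z[cur] + LEN[flow_dir[ch]] * std::pow((double)area[ch], gamma - 1.0);
      stack.push_back(ch);
    }
  }
  return z;
}

// Validation helper: follow every cell downstream; returns the number of steps
// to an outlet, or -1 if an outlet is not reached within N steps (loop).
// [[Rcpp::export]]
IntegerVector cpp_path_lengths(IntegerVector flow_dir) {
  const int N = flow_dir.size();
  const int n = (int)std::round(std::sqrt((double)N));
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) {
    int cur = i, s = 0;
    while (flow_dir[cur] >= 0 && s <= N) {
      cur = receiver(cur, flow_dir[cur], n);
      ++s;
    }
    out[i] = (s > N) ? -1 : s;
  }
  return out;
}
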