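// Core numerical engine: discrete-time GRN dynamics, fitness, single-edge
// deletion scans, hysteresis sweeps, the multicanonical Monte Carlo chain,
// truncation-selection evolution with lineage replay, and simple-path
// counting.  All randomness goes through R's RNG so set.seed() governs
// every stochastic routine.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double sigm(double x, double beta, double mu) {
  return 1.0 / (1.0 + std::exp(-beta * (x - mu)));
}

// One synchronous update x -> R(I*delta_{i,0} + J x).  Edges are stored as
// parallel arrays (src, tgt, sign); J is never materialised (K << N^2).
static inline void net_step(const std::vector<int>& src,
                            const std::vector<int>& tgt,
                            const std::vector<int>& sgn,
                            const std::vector<double>& x,
                            std::vector<double>& xn,
                            double I, int N, double beta, double mu) {
  std::fill(xn.begin(), xn.end(), 0.0);
  const size_t K = src.size();
  for (size_t e = 0; e < K; ++e) xn[tgt[e]] += sgn[e] * x[src[e]];
  xn[0] += I;
  for (int i = 0; i < N; ++i) xn[i] = sigm(xn[i], beta, mu);
}

struct SteadyRes {
  double out_level;
  bool converged;
  bool cycle;
  int iters;
};

// Fixed-point iteration from `state` (modified in place to the final state).
// Convergence: max per-node change < tol.  If no fixed point, look for a
// limit cycle of period <= 64 by state recurrence (started after a grace
// period since almost all networks converge); on detection the output is
// averaged over one period.  If max_iter is exhausted the output is the
// average of the trailing window.
static SteadyRes steady_solve(const std::vector<int>& src,
                              const std::vector<int>& tgt,
                              const std::vector<int>& sgn,
                              std::vector<double>& state,
                              double I, int N, double beta, double mu,
                              double tol, int max_iter, int out_idx) {
  const int CYCLE_START = 512, PMAX = 64, TAIL = 1000;
  std::vector<double> xn(N);
  std::vector<double> ring;           // last PMAX states (flat, circular)
  std::vector<double> tail_out;       // last TAIL outputs
  tail_out.reserve(TAIL);
  int tail_pos = 0, ring_n = 0, ring_pos = 0;

  for (int iter = 1; iter <= max_iter; ++iter) {
    net_step(src, tgt, sgn, state, xn, I, N, beta, mu);
    double md = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = std::fabs(xn[i] - state[i]);
      if (d > md) md = d;
    }
    state.swap(xn);
    if (md < tol) return {state[out_idx], true, false, iter};

    if ((int)tail_out.size() < TAIL) {
      tail_out.push_back(state[out_idx]);
    } else {
      tail_out[tail_pos] = state[out_idx];
      tail_pos = (tail_pos + 1) % TAIL;
    }

    if (iter >= CYCLE_START) {
      // compare with states at lag 1..min(PMAX, ring_n)
      for (int lag = 1; lag <= ring_n; ++lag) {
        int idx = (ring_pos - lag + PMAX) % PMAX;
        const double* past = &ring[(size_t)idx * N];
        double d = 0.0;
        for (int i = 0; i < N; ++i) {
          double di = std::fabs(state[i] - past[i]);
          if (di > d) d = di;
        }
        if (d < tol) {
          // period-lag cycle: average output over one period
          double s = state[out_idx];
          for (int b = 1; b < lag; ++b) {
            int j = (ring_pos - b + PMAX) % PMAX;
            s += ring[(size_t)j * N + out_idx];
          }
          return {s / lag, false, true, iter};
        }
      }
      if ((int)ring.size() < PMAX * N) ring.resize((size_t)PMAX * N);
      std::copy(state.begin(), state.end(), ring.begin() + (size_t)ring_pos * N);
      ring_pos = (ring_pos + 1) % PMAX;
      if (ring_n < PMAX) ++ring_n;
    }
  }
  double s = 0.0;
  for (double v : tail_out) s += v;
  int n = (int)tail_out.size();
  return {n > 0 ? s / n : state[out_idx], false, false, max_iter};
}

static double fitness_core(const std::vector<int>& src,
                           const std::vector<int>& tgt,
                           const std::vector<int>& sgn,
                           int N, double beta, double mu,
                           double tol, int max_iter, int out_idx) {
  std::vector<double> s0(N, 0.5), s1(N, 0.5);
  SteadyRes a = steady_solve(src, tgt, sgn, s0, 0.0, N, beta, mu, tol, max_iter, out_idx);
  SteadyRes b = steady_solve(src, tgt, sgn, s1, 1.0, N, beta, mu, tol, max_iter, out_idx);
  return std::fabs(a.out_level - b.out_level);
}

static void unpack(const IntegerVector& codes, int N,
                   std::vector<int>& src, std::vector<int>& tgt) {
  const int K = codes.size();
  src.resize(K); tgt.resize(K);
  for (int e = 0; e < K; ++e) { src[e] = codes[e] / N; tgt[e] = codes[e] % N; }
}

// [[Rcpp::export]]
List cpp_steady(IntegerVector codes, IntegerVector signs, int n_nodes,
                double input, double beta, double mu, double tol,
                int max_iter, int out_idx, NumericVector init) {
  std::vector<int> src, tgt, sgn(signs.begin(), signs.end());
  unpack(codes, n_nodes, src, tgt);
  std::vector<double> state(init.begin(), init.end());
  SteadyRes r = steady_solve(src, tgt, sgn, state, input, n_nodes, beta, mu,
                             tol, max_iter, out_idx);
  return List::create(_["output_level"] = r.out_level,
                      _["converged"] = r.converged,
                      _["cycle_detected"] = r.cycle,
                      _["iterations"] = r.iters,
                      _["state"] = NumericVector(state.begin(), state.end()));
}

// [[Rcpp::export]]
double cpp_fitness(IntegerVector codes, IntegerVector signs, int n_nodes,
                   double beta, double mu, double tol, int max_iter,
                   int out_idx) {
  std::vector<int> src, tgt, sgn(signs.begin(), signs.end());
  unpack(codes, n_nodes, src, tgt);
  return fitness_core(src, tgt, sgn, n_nodes, beta, mu, tol, max_iter, out_idx);
}

// Fitness after deleting each edge in turn (no replacement edge).
// [[Rcpp::export]]
NumericVector cpp_deletion_fitness(IntegerVector codes, IntegerVector signs,
                                   int n_nodes, double beta, double mu,
                                   double tol, int max_iter, int out_idx) {
  const int K = codes.size();
  std::vector<int> src, tgt, sgn(signs.begin(), signs.end());
  unpack(codes, n_nodes, src, tgt);
  NumericVector out(K);
  std::vector<int> s2(K - 1), t2(K - 1), g2(K - 1);
  for (int d = 0; d < K; ++d) {
    int j = 0;
    for (int e = 0; e < K; ++e) {
      if (e == d) continue;
      s2[j] = src[e]; t2[j] = tgt[e]; g2[j] = sgn[e]; ++j;
    }
    out[d] = fitness_core(s2, t2, g2, n_nodes, beta, mu, tol, max_iter, out_idx);
  }
  return out;
}

// Hysteresis protocol: up-sweep cold-starts from all-0.5 at I = 0 and
// warm-starts each subsequent grid point from the previous steady state;
// the down-sweep mirrors it from I = 1.
// [[Rcpp::export]]
List cpp_hysteresis(IntegerVector codes, IntegerVector signs, int n_nodes,
                    double delta_I, double beta, double mu, double tol,
                    int max_iter, int out_idx) {
  std::vector<int> src, tgt, sgn(signs.begin(), signs.end());
  unpack(codes, n_nodes, src, tgt);
  int n_grid = (int)std::lround(1.0 / delta_I) + 1;
  NumericVector Igrid(n_grid), up(n_grid), down(n_grid);
  bool all_conv = true;
  std::vector<double> state(n_nodes, 0.5);
  for (int k = 0; k < n_grid; ++k) {
    double I = std::min(1.0, k * delta_I);
    Igrid[k] = I;
    SteadyRes r = steady_solve(src, tgt, sgn, state, I, n_nodes, beta, mu,
                               tol, max_iter, out_idx);
    up[k] = r.out_level;
    if (!r.converged && !r.cycle) all_conv = false;
  }
  std::fill(state.begin(), state.end(), 0.5);
  for (int k = n_grid - 1; k >= 0; --k) {
    SteadyRes r = steady_solve(src, tgt, sgn, state, Igrid[k], n_nodes, beta,
                               mu, tol, max_iter, out_idx);
    down[k] = r.out_level;
    if (!r.converged && !r.cycle) all_conv = false;
  }
  double gap = 0.0;
  for (int k = 0; k < n_grid; ++k)
    gap = std::max(gap, std::fabs(up[k] - down[k]));
  return List::create(_["I"] = Igrid, _["up"] = up, _["down"] = down,
                      _["max_gap"] = gap, _["all_converged"] = all_conv);
}

// Count simple directed paths from -> to by DFS; abort at cap.
static bool dfs_paths(int v, int to, const std::vector<std::vector<int>>& adj,
                      std::vector<char>& vis, long long& count, long long cap) {
  if (v == to) {
    if (++count >= cap) return false;
    return true;
  }
  vis[v] = 1;
  for (int w : adj[v]) {
    if (!vis[w]) {
      if (!dfs_paths(w, to, adj, vis, count, cap)) { vis[v] = 0; return false; }
    }
  }
  vis[v] = 0;
  return true;
}

// [[Rcpp::export]]
List cpp_count_paths(IntegerVector codes, int n_nodes, int from, int to,
                     double cap) {
  std::vector<int> src, tgt;
  unpack(codes, n_nodes, src, tgt);
  std::vector<std::vector<int>> adj(n_nodes);
  for (size_t e = 0; e < src.size(); ++e)
    if (src[e] != tgt[e]) adj[src[e]].push_back(tgt[e]);  // self-loops never on a simple path
  std::vector<char> vis(n_nodes, 0);
  long long count = 0;
  bool ok = true;
  if (from == to) {
    count = 1;  // length-0 path
  } else {
    ok = dfs_paths(from, to, adj, vis, count, (long long)cap);
  }
  return List::create(_["n_path"] = (double)count, _["saturated"] = !ok);
}

static inline int rint_below(int n) {
  int v;
  do { v = (int)(unif_rand() * n); } while (v >= n);
  return v;
}

static inline int bin_index(double f, int nbins) {
  int b = (int)(f * nbins);
  if (b >= nbins) b = nbins - 1;
  if (b < 0) b = 0;
  return b;
}

// Elementary rewire: delete a random edge slot, add an edge at a uniformly
// chosen currently-unlinked ordered pair (the freed pair may be redrawn),
// fresh sign.  Acts on the genotype arrays in place; returns the slot.
static void rewire_inplace(std::vector<int>& codes, std::vector<int>& sgn,
                           int N2, int& slot, int& new_code, int& new_sign) {
  const int K = (int)codes.size();
  slot = rint_below(K);
  int old = codes[slot];
  codes[slot] = -1;  // mark free
  for (;;) {
    int c = rint_below(N2);
    bool linked = false;
    for (int e = 0; e < K; ++e)
      if (codes[e] == c) { linked = true; break; }
    if (!linked) { new_code = c; break; }
  }
  (void)old;
  new_sign = unif_rand() < 0.5 ? 1 : -1;
  codes[slot] = new_code;
  sgn[slot] = new_sign;
}

// Multicanonical chain segment: n_mcs Monte Carlo steps of K Metropolis
// updates each.  With update_weights the Wang-Landau rule log_w[bin] -= ln_f
// is applied to the current bin after every update.  Acceptance uses
// min(1, exp(log_w[new] - log_w[old])) with log_w = -log Omega-hat, so
// never-visited bins (log_w still at its initial maximum) are always
// entered.  With sample_every > 0 the genotype is recorded every
// sample_every MCS.
// [[Rcpp::export]]
List cpp_mc_run(IntegerVector codes_in, IntegerVector signs_in, int n_nodes,
                NumericVector log_w_in, IntegerVector hist_in, int n_mcs,
                bool update_weights, double ln_f, int sample_every,
                double beta, double mu, double tol, int max_iter,
                int out_idx, double f_in) {
  const int K = codes_in.size();
  const int N2 = n_nodes * n_nodes;
  const int nbins = log_w_in.size();
  std::vector<int> codes(codes_in.begin(), codes_in.end());
  std::vector<int> sgn(signs_in.begin(), signs_in.end());
  NumericVector log_w = clone(log_w_in);
  IntegerVector hist = clone(hist_in);
  std::vector<int> src, tgt;

  double f = f_in;
  if (f < 0) {
    unpack(IntegerVector(codes.begin(), codes.end()), n_nodes, src, tgt);
    f = fitness_core(src, tgt, sgn, n_nodes, beta, mu, tol, max_iter, out_idx);
  }
  int b = bin_index(f, nbins);

  std::vector<int> samp_mcs;
  std::vector<double> samp_f;
  std::vector<IntegerMatrix> samp_geno;
  long long n_accept = 0, n_prop = 0;

  std::vector<int> pcodes(K), psgn(K);
  for (int mcs = 1; mcs <= n_mcs; ++mcs) {
    for (int u = 0; u < K; ++u) {
      pcodes = codes; psgn = sgn;
      int slot, nc, ns;
      rewire_inplace(pcodes, psgn, N2, slot, nc, ns);
      unpack(IntegerVector(pcodes.begin(), pcodes.end()), n_nodes, src, tgt);
      double fp = fitness_core(src, tgt, psgn, n_nodes, beta, mu, tol,
                               max_iter, out_idx);
      int bp = bin_index(fp, nbins);
      ++n_prop;
      double la = log_w[bp] - log_w[b];
      if (la >= 0 || unif_rand() < std::exp(la)) {
        codes.swap(pcodes); sgn.swap(psgn);
        f = fp; b = bp;
        ++n_accept;
      }
      hist[b] += 1;
      if (update_weights) log_w[b] -= ln_f;
    }
    if (sample_every > 0 && mcs % sample_every == 0) {
      IntegerMatrix g(K, 2);
      for (int e = 0; e < K; ++e) { g(e, 0) = codes[e]; g(e, 1) = sgn[e]; }
      samp_mcs.push_back(mcs);
      samp_f.push_back(f);
      samp_geno.push_back(g);
    }
    if (mcs % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List samples(samp_geno.size());
  for (size_t i = 0; i < samp_geno.size(); ++i) samples[i] = samp_geno[i];
  return List::create(
      _["codes"] = IntegerVector(codes.begin(), codes.end()),
      _["signs"] = IntegerVector(sgn.begin(), sgn.end()),
      _["fitness"] = f,
      _["log_w"] = log_w,
      _["hist"] = hist,
      _["sample_mcs"] = IntegerVector(samp_mcs.begin(), samp_mcs.end()),
      _["sample_f"] = NumericVector(samp_f.begin(), samp_f.end()),
      _["samples"] = samples,
      _["acceptance_rate"] = n_prop > 0 ? (double)n_accept / n_prop : NA_REAL);
}

// Draw K distinct ordered pairs (codes in 0..N2-1) by partial Fisher-Yates.
static void random_genotype(std::vector<int>& codes, std::vector<int>& sgn,
                            int N2, int K, std::vector<int>& pool) {
  pool.resize(N2);
  for (int i = 0; i < N2; ++i) pool[i] = i;
  for (int e = 0; e < K; ++e) {
    int j = e + rint_below(N2 - e);
    std::swap(pool[e], pool[j]);
    codes[e] = pool[e];
    sgn[e] = unif_rand() < 0.5 ? 1 : -1;
  }
}

// Truncation-selection evolution.  Population layout per generation:
// indices 0..n_keep-1 are the preserved individuals in rank order,
// n_keep..pop-1 the mutated offspring.  Lineage of the final top
// individual is reconstructed by backtracking parent indices and
// replaying the recorded moves from the founding genotype.
// mode: 0 = Evo50 (each of the top n_keep parents one offspring),
//       1 = Evo90 (offspring parents drawn uniformly with replacement
//       from the preserved set).
// fitness_cap <= 0 means no cap.  snapshot_every > 0 records, every that
// many generations, all individuals whose (capped) fitness equals the cap.
// [[Rcpp::export]]
List cpp_evolve(int n_nodes, int n_edges, int pop, int n_keep, int n_off,
                int mode, int generations, double beta, double mu,
                double tol, int max_iter, int out_idx, double fitness_cap,
                int snapshot_every, bool store_lineage_genotypes) {
  const int N2 = n_nodes * n_nodes, K = n_edges, G = generations;
  const bool capped = fitness_cap > 0;

  std::vector<std::vector<int>> codes(pop, std::vector<int>(K));
  std::vector<std::vector<int>> sgn(pop, std::vector<int>(K));
  std::vector<double> fit(pop);
  std::vector<int> pool, src, tgt;

  for (int i = 0; i < pop; ++i) {
    random_genotype(codes[i], sgn[i], N2, K, pool);
    unpack(IntegerVector(codes[i].begin(), codes[i].end()), n_nodes, src, tgt);
    double f = fitness_core(src, tgt, sgn[i], n_nodes, beta, mu, tol,
                            max_iter, out_idx);
    fit[i] = capped ? std::min(f, fitness_cap) : f;
  }

  // founders kept for lineage replay
  std::vector<std::vector<int>> founder_codes = codes, founder_sgn = sgn;

  // history: parent index, move (slot, code, sign; -1 = no move), fitness
  std::vector<std::vector<int>> h_parent(G), h_slot(G), h_code(G), h_sign(G);
  std::vector<std::vector<double>> h_fit(G + 1);
  h_fit[0] = fit;

  NumericVector mean_f(G + 1), max_f(G + 1);
  IntegerVector ord_buf(pop);
  int first_all_capped = -1;

  List snapshots;
  std::vector<int> snapshot_gens;

  auto summarise = [&](int g) {
    double s = 0.0, m = fit[0];
    for (int i = 0; i < pop; ++i) { s += fit[i]; if (fit[i] > m) m = fit[i]; }
    mean_f[g] = s / pop; max_f[g] = m;
  };
  summarise(0);

  std::vector<std::vector<int>> ncodes(pop, std::vector<int>(K));
  std::vector<std::vector<int>> nsgn(pop, std::vector<int>(K));
  std::vector<double> nfit(pop);

  for (int g = 1; g <= G; ++g) {
    // stable rank by fitness, descending; index tie-break
    std::vector<int> ord(pop);
    for (int i = 0; i < pop; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int bb) { return fit[a] > fit[bb]; });

    h_parent[g - 1].assign(pop, -1);
    h_slot[g - 1].assign(pop, -1);
    h_code[g - 1].assign(pop, -1);
    h_sign[g - 1].assign(pop, 0);

    for (int r = 0; r < n_keep; ++r) {
      int p = ord[r];
      ncodes[r] = codes[p]; nsgn[r] = sgn[p]; nfit[r] = fit[p];
      h_parent[g - 1][r] = p;
    }
    if (capped && first_all_capped < 0) {
      bool all = true;
      for (int r = 0; r < n_keep; ++r)
        if (nfit[r] < fitness_cap) { all = false; break; }
      if (all) first_all_capped = g;
    }
    for (int j = 0; j < n_off; ++j) {
      int p = (mode == 0) ? ord[j] : ord[rint_below(n_keep)];
      int i = n_keep + j;
      ncodes[i] = codes[p]; nsgn[i] = sgn[p];
      int slot, nc, ns;
      rewire_inplace(ncodes[i], nsgn[i], N2, slot, nc, ns);
      unpack(IntegerVector(ncodes[i].begin(), ncodes[i].end()), n_nodes, src, tgt);
      double f = fitness_core(src, tgt, nsgn[i], n_nodes, beta, mu, tol,
                              max_iter, out_idx);
      nfit[i] = capped ? std::min(f, fitness_cap) : f;
      h_parent[g - 1][i] = p;
      h_slot[g - 1][i] = slot;
      h_code[g - 1][i] = nc;
      h_sign[g - 1][i] = ns;
    }
    codes.swap(ncodes); sgn.swap(nsgn); fit.swap(nfit);
    h_fit[g] = fit;
    summarise(g);

    if (snapshot_every > 0 && g % snapshot_every == 0 && capped) {
      std::vector<int> idx;
      for (int i = 0; i < pop; ++i)
        if (fit[i] >= fitness_cap) idx.push_back(i);
      List snap(idx.size());
      NumericVector snap_f(idx.size());
      for (size_t q = 0; q < idx.size(); ++q) {
        IntegerMatrix m(K, 2);
        for (int e = 0; e < K; ++e) {
          m(e, 0) = codes[idx[q]][e];
          m(e, 1) = sgn[idx[q]][e];
        }
        snap[q] = m;
        snap_f[q] = fit[idx[q]];
      }
      snapshots.push_back(List::create(_["generation"] = g,
                                       _["fitness"] = snap_f,
                                       _["genotypes"] = snap));
      snapshot_gens.push_back(g);
    }
    Rcpp::checkUserInterrupt();
  }

  // final top individual (stable: first max)
  int best = 0;
  for (int i = 1; i < pop; ++i)
    if (fit[i] > fit[best]) best = i;

  // backtrack ancestors
  std::vector<int> chain(G + 1);
  chain[G] = best;
  for (int g = G; g >= 1; --g)
    chain[g - 1] = h_parent[g - 1][chain[g]];

  NumericVector lin_f(G + 1);
  for (int g = 0; g <= G; ++g) lin_f[g] = h_fit[g][chain[g]];

  List lin_geno;
  if (store_lineage_genotypes) {
    std::vector<int> c = founder_codes[chain[0]], s = founder_sgn[chain[0]];
    lin_geno = List(G + 1);
    auto pack = [&](const std::vector<int>& cc, const std::vector<int>& ss) {
      IntegerMatrix m(K, 2);
      for (int e = 0; e < K; ++e) { m(e, 0) = cc[e]; m(e, 1) = ss[e]; }
      return m;
    };
    lin_geno[0] = pack(c, s);
    for (int g = 1; g <= G; ++g) {
      int i = chain[g];
      if (h_slot[g - 1][i] >= 0) {
        c[h_slot[g - 1][i]] = h_code[g - 1][i];
        s[h_slot[g - 1][i]] = h_sign[g - 1][i];
      }
      lin_geno[g] = pack(c, s);
    }
  }

  return List::create(
      _["lineage_fitness"] = lin_f,
      _["lineage_genotypes"] = lin_geno,
      _["mean_fitness"] = mean_f,
      _["max_fitness"] = max_f,
      _["first_all_capped"] = first_all_capped,
      _["snapshots"] = snapshots);
}
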