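// Exact stochastic simulation (Gillespie direct method) of mass-action
// reaction networks, one independent realization per cell, sampled on a
// fixed time grid. Each cell owns an RNG stream keyed by (seed, cell) so
// that enlarging the ensemble leaves earlier cells unchanged.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <cmath>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// reactants/products: L x 2 integer matrices of 0-based species indices,
// -1 for an unused slot. x0: n_cells x N matrix of initial counts.
// Returns a list of T integer matrices (n_cells x N), one per grid time.
// [[Rcpp::export]]
List ssa_simulate_cpp(IntegerMatrix reactants, IntegerMatrix products,
                      NumericVector rates, IntegerMatrix x0,
                      NumericVector t_grid, int seed) {
  const int L = reactants.nrow();
  const int N = x0.ncol();
  const int C = x0.nrow();
  const int T = t_grid.size();

  std::vector<IntegerMatrix> out;
  out.reserve(T);
  for (int t = 0; t < T; ++t) out.push_back(IntegerMatrix(C, N));

  std::vector<double> x(N);
  std::vector<double> a(L);

  for (int c = 0; c < C; ++c) {
    uint64_t key = splitmix64((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL
                              + (uint64_t)(c + 1));
    std::mt19937_64 rng(key);
    auto unif = [&rng]() {
      // strictly in (0, 1)
      return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    };

    for (int i = 0; i < N; ++i) x[i] = x0(c, i);
    double t = t_grid[0] < 0 ? t_grid[0] : 0.0;
    if (t_grid[0] < 0) stop("time grid must be nonnegative");
    int ti = 0;

    while (ti < T) {
      double a0 = 0.0;
      for (int l = 0; l < L; ++l) {
        int ra = reactants(l, 0), rb = reactants(l, 1);
        double g;
        if (ra < 0) g = 1.0;
        else if (rb < 0) g = x[ra];
        else if (ra == rb) g = x[ra] * (x[ra] - 1.0);
        else g = x[ra] * x[rb];
        a[l] = rates[l] * (g > 0 ? g : 0.0);
        a0 += a[l];
      }
      if (a0 <= 0.0) {
        for (; ti < T; ++ti)
          for (int i = 0; i < N; ++i) out[ti](c, i) = (int)x[i];
        break;
      }
      double tau = -std::log(unif()) / a0;
      double t_next = t + tau;
      while (ti < T && t_grid[ti] <= t_next) {
        for (int i = 0; i < N; ++i) out[ti](c, i) = (int)x[i];
        ++ti;
      }
      if (ti >= T) break;
      t = t_next;
      double u = unif() * a0, cum = 0.0;
      int l = 0;
      for (; l < L - 1; ++l) { cum += a[l]; if (u <= cum) break; }
      int ra = reactants(l, 0), rb = reactants(l, 1);
      if (ra >= 0) x[ra] -= 1.0;
      if (rb >= 0) x[rb] -= 1.0;
      int pa = products(l, 0), pb = products(l, 1);
      if (pa >= 0) x[pa] += 1.0;
      if (pb >= 0) x[pb] += 1.0;
    }
  }

  List res(T);
  for (int t = 0; t < T; ++t) res[t] = out[t];
  return res;
}
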