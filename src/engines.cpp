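// Compiled simulation engines for the well-mixed and lattice models.
//
// Replicates run on private mt19937_64 streams seeded by a splitmix64 hash
// of (seed, replicate), so sweeps are reproducible, replicate-order
// independent, and platform-stable (no std::*_distribution, whose output is
// implementation-defined; all sampling is hand-rolled inverse-CDF).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline std::mt19937_64 make_rng(double seed, int rep) {
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t x = mix64(s + 0x9E3779B97F4A7C15ULL * (uint64_t)(rep + 1));
  return std::mt19937_64(x);
}

// Uniform on (0, 1): 53-bit mantissa, offset to exclude the endpoints.
static inline double runif01(std::mt19937_64& g) {
  return ((g() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Binomial(m, p) by inverse-CDF; cheap when m * p is small, exact always.
static int rbinom_inv(int m, double p, double u) {
  if (m <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return m;
  const double s = p / (1.0 - p);
  double f = std::pow(1.0 - p, m);
  double cdf = f;
  int j = 0;
  while (u > cdf && j < m) {
    ++j;
    f *= s * (double)(m - j + 1) / (double)j;
    cdf += f;
  }
  return j;
}

// Binomial(m, p) conditioned on >= 1 success, by inverse-CDF.
static int rbinom_pos(int m, double p, double u) {
  if (m <= 0) return 0;
  if (p >= 1.0) return m;
  const double s = p / (1.0 - p);
  const double denom = -std::expm1((double)m * std::log1p(-p));
  double f = (double)m * p * std::pow(1.0 - p, m - 1);
  double cdf = f / denom;
  int j = 1;
  while (u > cdf && j < m) {
    ++j;
    f *= s * (double)(m - j + 1) / (double)j;
    cdf += f / denom;
  }
  return j;
}

// One Moran division/elimination step on the damaged-cell count.
static inline int moran_step(int k, int n, const double* c,
                             std::mt19937_64& g) {
  const double fk = (c[0] * (n - k - 1) + c[1] * k) / (double)(n - 1);
  const double gk = (c[2] * (n - k) + c[3] * (k - 1)) / (double)(n - 1);
  const double w_int = (n - k) * fk;
  const double w_dam = k * gk;
  const double tot = w_int + w_dam;
  const double up = ((double)k / n) * w_int / tot;
  const double down = ((double)(n - k) / n) * w_dam / tot;
  const double u = runif01(g);
  if (u < up) return k + 1;
  if (u < up + down) return k - 1;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_wellmixed_absorption(int n, double lam, NumericVector costs,
                                       double max_steps, double seed,
                                       int reps) {
  const double c[4] = {costs[0], costs[1], costs[2], costs[3]};
  const double p = -std::expm1(-lam / n);
  const double log_q_all = -lam;  // log((1-p)^n) = -lam exactly
  NumericVector out(reps);

  for (int r = 0; r < reps; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    std::mt19937_64 g = make_rng(seed, r);
    int k = 0;
    double steps = 0.0;
    bool censored = false;
    while (k < n) {
      if (steps >= max_steps) { censored = true; break; }
      if (k == 0) {
        // All intact: division/elimination changes nothing, so jump
        // straight to the elementary step carrying the first hit.
        const double gsteps =
            std::floor(std::log(runif01(g)) / log_q_all) + 1.0;
        if (steps + gsteps > max_steps) { censored = true; break; }
        steps += gsteps - 1.0;
        k = rbinom_pos(n, p, runif01(g));
      } else {
        k += rbinom_inv(n - k, p, runif01(g));
      }
      if (k > 0 && k < n) k = moran_step(k, n, c, g);
      steps += 1.0;
    }
    out[r] = censored ? NA_REAL : steps / n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lattice engine: periodic L x L torus, Moore neighborhoods.

struct Lattice {
  int L, N, nd;               // side, sites, damaged count
  double c[4];
  std::vector<int> type;      // 0 intact, 1 damaged
  std::vector<int> ndam;      // damaged cells among the 8 neighbors
  std::vector<double> phi;    // per-site interaction cost
  std::vector<int> nbr;       // N x 8 neighbor indices

  void build(int L_, const double* costs) {
    L = L_;
    N = L * L;
    for (int i = 0; i < 4; ++i) c[i] = costs[i];
    type.assign(N, 0);
    ndam.assign(N, 0);
    phi.assign(N, 0.0);
    nbr.assign(N * 8, 0);
    nd = 0;
    for (int row = 0; row < L; ++row) {
      for (int col = 0; col < L; ++col) {
        int i = row * L + col, m = 0;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            nbr[i * 8 + m++] =
                ((row + dr + L) % L) * L + ((col + dc + L) % L);
          }
        }
      }
    }
    for (int i = 0; i < N; ++i) phi[i] = calc_phi(i);
  }

  double calc_phi(int i) const {
    const int l = ndam[i];
    return type[i] ? (c[2] * (8 - l) + c[3] * l) / 8.0
                   : (c[0] * (8 - l) + c[1] * l) / 8.0;
  }

  // Flip a site's type, updating neighbor counts and costs incrementally.
  void set_type(int i, int t) {
    if (type[i] == t) return;
    const int d = t ? 1 : -1;
    type[i] = t;
    nd += d;
    phi[i] = calc_phi(i);
    for (int j = 0; j < 8; ++j) {
      const int b = nbr[i * 8 + j];
      ndam[b] += d;
      phi[b] = calc_phi(b);
    }
  }
};

// Cost-weighted elimination followed by uniform replacement from the
// 9-candidate set {removed cell itself, its 8 Moore neighbors}.
static void competition_step(Lattice& lat, std::mt19937_64& g,
                             std::vector<double>& cum) {
  double tot = 0.0;
  for (int i = 0; i < lat.N; ++i) {
    tot += lat.phi[i];
    cum[i] = tot;
  }
  const double u = runif01(g) * tot;
  int site = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (site >= lat.N) site = lat.N - 1;
  int cand = (int)(runif01(g) * 9.0);
  if (cand > 8) cand = 8;
  const int t = (cand == 8) ? lat.type[site] : lat.type[lat.nbr[site * 8 + cand]];
  lat.set_type(site, t);
}

// Flip j distinct uniformly chosen intact sites to damaged.
static void flip_random_intact(Lattice& lat, int j, std::mt19937_64& g,
                               std::vector<int>& scratch) {
  if (j <= 0) return;
  scratch.clear();
  for (int i = 0; i < lat.N; ++i) {
    if (lat.type[i] == 0) scratch.push_back(i);
  }
  const int m = (int)scratch.size();
  for (int a = 0; a < j && a < m; ++a) {
    int pick = a + (int)(runif01(g) * (m - a));
    if (pick >= m) pick = m - 1;
    std::swap(scratch[a], scratch[pick]);
    lat.set_type(scratch[a], 1);
  }
}

static void radiation_step(Lattice& lat, double p, std::mt19937_64& g,
                           std::vector<int>& scratch) {
  const int m = lat.N - lat.nd;
  if (m == 0 || p <= 0.0) return;
  const int j = rbinom_inv(m, p, runif01(g));
  if (j > 0) flip_random_intact(lat, j, g, scratch);
}

// [[Rcpp::export]]
NumericVector cpp_lattice_absorption(int side, double lam, NumericVector costs,
                                     double max_steps, double seed, int reps) {
  const double c[4] = {costs[0], costs[1], costs[2], costs[3]};
  NumericVector out(reps);
  Lattice lat;
  std::vector<double> cum;
  std::vector<int> scratch;

  for (int r = 0; r < reps; ++r) {
    Rcpp::checkUserInterrupt();
    std::mt19937_64 g = make_rng(seed, r);
    lat.build(side, c);
    cum.assign(lat.N, 0.0);
    const int N = lat.N;
    const double p = -std::expm1(-lam / N);
    const double log_q_all = -lam;
    double steps = 0.0;
    bool censored = false;
    while (lat.nd < N) {
      if (steps >= max_steps) { censored = true; break; }
      if (lat.nd == 0) {
        // Uniform all-intact grid: competition changes nothing; skip to
        // the step carrying the first hit (same law as stepping through).
        const double gsteps =
            std::floor(std::log(runif01(g)) / log_q_all) + 1.0;
        if (steps + gsteps > max_steps) { censored = true; break; }
        steps += gsteps - 1.0;
        flip_random_intact(lat, rbinom_pos(N, p, runif01(g)), g, scratch);
      } else {
        radiation_step(lat, p, g, scratch);
      }
      if (lat.nd > 0 && lat.nd < N) competition_step(lat, g, cum);
      steps += 1.0;
    }
    out[r] = censored ? NA_REAL : steps / N;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_lattice_fixation(int side, NumericVector costs, double seed,
                                   int reps, double max_steps) {
  const double c[4] = {costs[0], costs[1], costs[2], costs[3]};
  IntegerVector out(reps);
  Lattice lat;
  std::vector<double> cum;

  for (int r = 0; r < reps; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    std::mt19937_64 g = make_rng(seed, r);
    lat.build(side, c);
    cum.assign(lat.N, 0.0);
    int start = (int)(runif01(g) * lat.N);
    if (start >= lat.N) start = lat.N - 1;
    lat.set_type(start, 1);
    double steps = 0.0;
    while (lat.nd > 0 && lat.nd < lat.N && steps < max_steps) {
      competition_step(lat, g, cum);
      steps += 1.0;
    }
    out[r] = (lat.nd == lat.N) ? 1 : (lat.nd == 0 ? 0 : NA_INTEGER);
  }
  return out;
}

// Debug/verification entry: run a fixed number of (radiation, competition)
// steps from a given grid and expose the internally maintained per-site
// costs so the incremental updates can be checked against a full recompute.
// [[Rcpp::export]]
List cpp_lattice_run(IntegerMatrix grid, NumericVector costs, double lam,
                     int nsteps, double seed) {
  const int side = grid.nrow();
  const double c[4] = {costs[0], costs[1], costs[2], costs[3]};
  Lattice lat;
  lat.build(side, c);
  // R matrices are column-major: grid(row, col) -> site row * L + col.
  for (int row = 0; row < side; ++row) {
    for (int col = 0; col < side; ++col) {
      if (grid(row, col) != 0) lat.set_type(row * side + col, 1);
    }
  }
  std::mt19937_64 g = make_rng(seed, 0);
  std::vector<double> cum(lat.N, 0.0);
  std::vector<int> scratch;
  const double p = lam > 0 ? -std::expm1(-lam / lat.N) : 0.0;
  IntegerVector nd_trace(nsteps);
  for (int s = 0; s < nsteps; ++s) {
    if (lam > 0) radiation_step(lat, p, g, scratch);
    if (lat.nd > 0 && lat.nd < lat.N) competition_step(lat, g, cum);
    nd_trace[s] = lat.nd;
  }
  IntegerMatrix out_grid(side, side);
  NumericMatrix out_phi(side, side);
  for (int row = 0; row < side; ++row) {
    for (int col = 0; col < side; ++col) {
      out_grid(row, col) = lat.type[row * side + col];
      out_phi(row, col) = lat.phi[row * side + col];
    }
  }
  return List::create(_["grid"] = out_grid, _["phi"] = out_phi,
                      _["nd_trace"] = nd_trace);
}

// ---------------------------------------------------------------------------
// Tridiagonal hitting-probability solve in extended precision.
//
// The first-step system for fixation probabilities of a birth-death chain is
// an M-matrix, so the Thomas algorithm needs no pivoting; strongly selected
// matrices make it ill-conditioned in double, hence long double throughout
// plus extra-precision iterative refinement.

// [[Rcpp::export]]
double cpp_hitting_probability(NumericVector up, NumericVector down) {
  const int m = up.size();
  std::vector<long double> dia(m), low(m), upp(m), b(m, 0.0L), x(m);
  for (int i = 0; i < m; ++i) {
    dia[i] = (long double)up[i] + (long double)down[i];
    low[i] = -(long double)down[i];  // sub-diagonal (row i, col i-1)
    upp[i] = -(long double)up[i];    // super-diagonal (row i, col i+1)
  }
  b[m - 1] = (long double)up[m - 1];

  std::vector<long double> cp(m), dp(m);
  auto thomas = [&](const std::vector<long double>& rhs,
                    std::vector<long double>& out) {
    cp[0] = upp[0] / dia[0];
    dp[0] = rhs[0] / dia[0];
    for (int i = 1; i < m; ++i) {
      const long double denom = dia[i] - low[i] * cp[i - 1];
      cp[i] = (i < m - 1) ? upp[i] / denom : 0.0L;
      dp[i] = (rhs[i] - low[i] * dp[i - 1]) / denom;
    }
    out[m - 1] = dp[m - 1];
    for (int i = m - 2; i >= 0; --i) out[i] = dp[i] - cp[i] * out[i + 1];
  };

  thomas(b, x);
  std::vector<long double> r(m), dx(m);
  for (int it = 0; it < 2; ++it) {
    for (int i = 0; i < m; ++i) {
      long double ax = dia[i] * x[i];
      if (i > 0) ax += low[i] * x[i - 1];
      if (i < m - 1) ax += upp[i] * x[i + 1];
      r[i] = b[i] - ax;
    }
    thomas(r, dx);
    for (int i = 0; i < m; ++i) x[i] += dx[i];
  }
  return (double)x[0];
}
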