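#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mutual information from integer bin indices
// ---------------------------------------------------------------------------

// MI (nats) of each feature column with the label vector.
// bins: N x n matrix of 0-based bin indices; labels: 0-based classes.
// [[Rcpp::export]]
NumericVector cpp_importance(const IntegerMatrix& bins,
                             const IntegerVector& labels,
                             int n_bins, int n_classes) {
  const int N = bins.nrow(), n = bins.ncol();
  if (labels.size() != N) stop("labels length must match bins rows");
  NumericVector out(n);
  std::vector<double> cnt((size_t)n_bins * n_classes);
  std::vector<double> rb(n_bins), ry(n_classes);
  for (int y = 0; y < n_classes; ++y) ry[y] = 0.0;
  for (int i = 0; i < N; ++i) {
    int y = labels[i];
    if (y < 0 || y >= n_classes) stop("label out of range");
    ry[y] += 1.0;
  }
  for (int j = 0; j < n; ++j) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(rb.begin(), rb.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int b = bins(i, j);
      if (b < 0 || b >= n_bins) stop("bin index out of range");
      cnt[(size_t)b * n_classes + labels[i]] += 1.0;
      rb[b] += 1.0;
    }
    double mi = 0.0;
    for (int b = 0; b < n_bins; ++b) {
      if (rb[b] == 0.0) continue;
      for (int y = 0; y < n_classes; ++y) {
        double c = cnt[(size_t)b * n_classes + y];
        if (c > 0.0)
          mi += (c / N) * std::log(c * N / (rb[b] * ry[y]));
      }
    }
    out[j] = mi;
  }
  return out;
}

// Pairwise MI (nats) for requested feature pairs (0-based column indices).
// [[Rcpp::export]]
NumericVector cpp_pairwise_mi(const IntegerMatrix& bins,
                              const IntegerVector& pi,
                              const IntegerVector& pj,
                              int n_bins) {
  const int N = bins.nrow(), n = bins.ncol(), m = pi.size();
  if (pj.size() != m) stop("pair index vectors differ in length");
  NumericVector out(m);
  std::vector<double> cnt((size_t)n_bins * n_bins);
  std::vector<double> ri(n_bins), rj(n_bins);
  for (int p = 0; p < m; ++p) {
    int a = pi[p], b = pj[p];
    if (a < 0 || a >= n || b < 0 || b >= n) stop("pair index out of range");
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(ri.begin(), ri.end(), 0.0);
    std::fill(rj.begin(), rj.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int ba = bins(i, a), bb = bins(i, b);
      cnt[(size_t)ba * n_bins + bb] += 1.0;
      ri[ba] += 1.0;
      rj[bb] += 1.0;
    }
    double mi = 0.0;
    for (int ba = 0; ba < n_bins; ++ba) {
      if (ri[ba] == 0.0) continue;
      for (int bb = 0; bb < n_bins; ++bb) {
        double c = cnt[(size_t)ba * n_bins + bb];
        if (c > 0.0)
          mi += (c / N) * std::log(c * N / (ri[ba] * rj[bb]));
      }
    }
    out[p] = mi;
  }
  return out;
}

// ---------------------------------------------------------------------------
// QUBO solvers
// ---------------------------------------------------------------------------

namespace {

struct Adjacency {
  // CSR over both directions of the i<j coupling list
  std::vector<int> ptr, nbr;
  std::vector<double> w;
  Adjacency(int n, const IntegerVector& qi, const IntegerVector& qj,
            const NumericVector& qv) {
    const int m = qi.size();
    std::vector<int> deg(n, 0);
    for (int e = 0; e < m; ++e) { ++deg[qi[e]]; ++deg[qj[e]]; }
    ptr.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
    nbr.resize(ptr[n]); w.resize(ptr[n]);
    std::vector<int> at(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < m; ++e) {
      int a = qi[e], b = qj[e]; double v = qv[e];
      nbr[at[a]] = b; w[at[a]++] = v;
      nbr[at[b]] = a; w[at[b]++] = v;
    }
  }
  // energy delta of flipping bit b from state x (0/1 per entry)
  inline double flip_delta(const std::vector<uint8_t>& x, int b,
                           const NumericVector& lin) const {
    double d = lin[b];
    for (int t = ptr[b]; t < ptr[b + 1]; ++t)
      if (x[nbr[t]]) d += w[t];
    return x[b] ? -d : d;
  }
};

double full_energy(const std::vector<uint8_t>& x, const NumericVector& lin,
                   const IntegerVector& qi, const IntegerVector& qj,
                   const NumericVector& qv) {
  double e = 0.0;
  for (int i = 0; i < (int)x.size(); ++i) if (x[i]) e += lin[i];
  for (int t = 0; t < qi.size(); ++t)
    if (x[qi[t]] && x[qj[t]]) e += qv[t];
  return e;
}

bool lex_smaller(const std::vector<uint8_t>& a, const std::vector<uint8_t>& b) {
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) return a[i] < b[i];
  return false;
}

// splitmix64 for seed mixing, xorshift64* for the stream
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

} // namespace

// Exhaustive minimizer by Gray-code enumeration; ties -> lexicographically
// smallest mask. Indices in qi/qj are 0-based with qi < qj.
// [[Rcpp::export]]
List cpp_solve_exhaustive(int n, const NumericVector& lin,
                          const IntegerVector& qi, const IntegerVector& qj,
                          const NumericVector& qv, double offset) {
  if (n < 1 || n > 30) stop("exhaustive solver requires 1 <= n <= 30");
  Adjacency adj(n, qi, qj, qv);
  std::vector<uint8_t> x(n, 0), best(n, 0);
  double e = 0.0, bestE = 0.0;
  const uint64_t total = (uint64_t)1 << n;
  for (uint64_t t = 1; t < total; ++t) {
    // bit to flip = count of trailing zeros of t
    int b = 0;
    uint64_t tt = t;
    while (!(tt & 1)) { tt >>= 1; ++b; }
    e += adj.flip_delta(x, b, lin);
    x[b] ^= 1;
    if (e < bestE) {
      bestE = full_energy(x, lin, qi, qj, qv); // re-derive: no drift
      e = bestE;
      best = x;
    } else if (e == bestE && lex_smaller(x, best)) {
      best = x;
    }
  }
  IntegerVector mask(n);
  for (int i = 0; i < n; ++i) mask[i] = best[i];
  return List::create(_["mask"] = mask, _["energy"] = bestE + offset);
}

// Multi-restart single-spin-flip simulated annealing with geometric cooling.
// Returns the best state visited over all reads plus per-read best energies.
// [[Rcpp::export]]
List cpp_solve_sa(int n, const NumericVector& lin,
                  const IntegerVector& qi, const IntegerVector& qj,
                  const NumericVector& qv, double offset,
                  int n_reads, int sweeps, double t_hot, double t_cold,
                  double seed) {
  if (n < 1) stop("empty problem");
  if (n_reads < 1) stop("n_reads must be >= 1");
  if (sweeps > 0 && !(t_hot > t_cold && t_cold > 0))
    stop("need t_hot > t_cold > 0");
  Adjacency adj(n, qi, qj, qv);
  std::vector<uint8_t> x(n), readBest(n), best(n, 0);
  double bestE = R_PosInf;
  bool haveBest = false;
  NumericVector readE(n_reads);
  const double ratio = (sweeps > 1) ? std::pow(t_cold / t_hot,
                                               1.0 / (sweeps - 1)) : 1.0;
  for (int r = 0; r < n_reads; ++r) {
    Rng rng((uint64_t)seed * 0x100000001B3ULL + (uint64_t)r);
    for (int i = 0; i < n; ++i) x[i] = rng.unif() < 0.5 ? 1 : 0;
    double e = full_energy(x, lin, qi, qj, qv);
    readBest = x;
    double rbE = e;
    double T = t_hot;
    for (int s = 0; s < sweeps; ++s) {
      const double reject_cut = 27.6 * T;  // exp(-27.6) ~ 1e-12
      for (int b = 0; b < n; ++b) {
        double d = adj.flip_delta(x, b, lin);
        if (d > reject_cut) continue;  // deterministic fast reject
        if (d <= 0.0 || rng.unif() < std::exp(-d / T)) {
          x[b] ^= 1;
          e += d;
          if (e < rbE) { rbE = e; readBest = x; }
        }
      }
      T *= ratio;
    }
    // guard against float drift in the incremental energy
    rbE = full_energy(readBest, lin, qi, qj, qv);
    readE[r] = rbE + offset;
    if (!haveBest || rbE < bestE ||
        (rbE == bestE && lex_smaller(readBest, best))) {
      bestE = rbE; best = readBest; haveBest = true;
    }
  }
  IntegerVector mask(n);
  for (int i = 0; i < n; ++i) mask[i] = best[i];
  return List::create(_["mask"] = mask, _["energy"] = bestE + offset,
                      _["read_energies"] = readE);
}

// ---------------------------------------------------------------------------
// CRC32 (ISO 3309 / zip) for the stored-zip NPZ writer
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_crc32(const RawVector& bytes) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < bytes.size(); ++i)
    c = table[(c ^ bytes[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}
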