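#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Small counter-free PRNG (xoshiro256++) seeded via splitmix64. Each walk gets
// its own stream from an R-supplied seed, so reproducibility is governed
// entirely by R-side seed management and is independent of R's global RNG.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".walk_positions_cpp")]]
NumericVector walk_positions_cpp(double n_steps, double delta, double x0,
                                 double lo, double hi, int thin, double seed) {
  const R_xlen_t n = (R_xlen_t)n_steps;
  if (thin < 1) stop("thin must be >= 1");
  const R_xlen_t n_out = n / thin;
  NumericVector out(n_out);
  Xoshiro rng((uint64_t)seed);
  double x = x0;
  const bool has_lo = R_finite(lo), has_hi = R_finite(hi);
  uint64_t bits = 0;
  int avail = 0;
  R_xlen_t k = 0;
  for (R_xlen_t i = 1; i <= n; ++i) {
    if (avail == 0) { bits = rng.next(); avail = 64; }
    x += (bits & 1ULL) ? delta : -delta;
    bits >>= 1; --avail;
    if (has_lo && x < lo) x = 2.0 * lo - x;
    if (has_hi && x > hi) x = 2.0 * hi - x;
    if (i % thin == 0) out[k++] = x;
  }
  return out;
}

//' Fused lattice walk + frame-averaged FRET efficiencies.
//'
//' The register coordinate lives on the lattice {0, 1, ..., n_sites-1} (site i
//' at physical offset i * step_size). Per micro-step the walker moves +/-1 site
//' with equal probability and reflects off the ends; the per-site FRET
//' efficiencies (one column per acceptor) are accumulated and averaged per
//' camera frame.
//' @noRd
// [[Rcpp::export(name = ".slide_frames_cpp")]]
List slide_frames_cpp(int n_frames, double steps_per_frame, int start_index,
                      NumericMatrix e_table, double seed) {
  const int n_sites = e_table.nrow();
  const int k_ch = e_table.ncol();
  if (n_sites < 1) stop("empty efficiency table");
  if (start_index < 0 || start_index >= n_sites) stop("start index out of range");
  NumericMatrix mean_e(n_frames, k_ch);
  Xoshiro rng((uint64_t)seed);
  int idx = start_index;
  const R_xlen_t spf = (R_xlen_t)steps_per_frame;
  const double *tab = &e_table(0, 0);          // column-major, n_sites rows
  const int last = n_sites - 1;
  uint64_t bits = 0;
  int avail = 0;
  std::vector<double> acc(k_ch);
  for (int f = 0; f < n_frames; ++f) {
    if (spf == 0) {
      // D = 0: static trace, efficiency of the current site
      for (int c = 0; c < k_ch; ++c) mean_e(f, c) = tab[c * n_sites + idx];
      continue;
    }
    if (k_ch == 1) {                           // two-color hot path
      double a0 = 0.0;
      for (R_xlen_t s = 0; s < spf; ++s) {
        if (avail == 0) { bits = rng.next(); avail = 64; }
        idx += (bits & 1ULL) ? 1 : -1;
        bits >>= 1; --avail;
        if (idx < 0) idx = last > 0 ? 1 : 0;
        else if (idx > last) idx = last > 0 ? last - 1 : 0;
        a0 += tab[idx];
      }
      mean_e(f, 0) = a0 / (double)spf;
    } else if (k_ch == 2) {                    // three-color hot path
      const double *tab2 = tab + n_sites;
      double a0 = 0.0, a1 = 0.0;
      for (R_xlen_t s = 0; s < spf; ++s) {
        if (avail == 0) { bits = rng.next(); avail = 64; }
        idx += (bits & 1ULL) ? 1 : -1;
        bits >>= 1; --avail;
        if (idx < 0) idx = last > 0 ? 1 : 0;
        else if (idx > last) idx = last > 0 ? last - 1 : 0;
        a0 += tab[idx];
        a1 += tab2[idx];
      }
      mean_e(f, 0) = a0 / (double)spf;
      mean_e(f, 1) = a1 / (double)spf;
    } else {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (R_xlen_t s = 0; s < spf; ++s) {
        if (avail == 0) { bits = rng.next(); avail = 64; }
        idx += (bits & 1ULL) ? 1 : -1;
        bits >>= 1; --avail;
        if (idx < 0) idx = last > 0 ? 1 : 0;
        else if (idx > last) idx = last > 0 ? last - 1 : 0;
        for (int c = 0; c < k_ch; ++c) acc[c] += tab[c * n_sites + idx];
      }
      for (int c = 0; c < k_ch; ++c) mean_e(f, c) = acc[c] / (double)spf;
    }
  }
  return List::create(_["mean_e"] = mean_e, _["end_index"] = idx);
}
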