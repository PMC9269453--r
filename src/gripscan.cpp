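#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Zero-phase IIR filtering with odd-reflection padding.
// ---------------------------------------------------------------------------

// Direct form II transposed; a[0] must be 1 (normalised by caller wrapper).
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  const int nb = (int)b.size(), na = (int)a.size();
  const int ns = std::max(na, nb) - 1;
  std::vector<double> z(ns, 0.0);
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (ns > 0 ? z[0] : 0.0);
    for (int j = 0; j < ns; ++j) {
      const double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
      const double aj = (j + 1 < na) ? a[j + 1] : 0.0;
      z[j] = bj * xi - aj * yi + ((j + 1 < ns) ? z[j + 1] : 0.0);
    }
    x[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector filtfilt_pad_cpp(NumericVector b, NumericVector a,
                               NumericVector x, int pad) {
  const int n = x.size();
  if (n < 2) return clone(x);
  if (pad > n - 1) pad = n - 1;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const double a0 = aa[0];
  for (double& v : bb) v /= a0;
  for (double& v : aa) v /= a0;

  std::vector<double> xp(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xp[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  iir_pass(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());
  iir_pass(bb, aa, xp);
  std::reverse(xp.begin(), xp.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[pad + i];
  return out;
}

// ---------------------------------------------------------------------------
// Threshold-free cluster enhancement (1-D).
// enhanced(t) = sum over h = dh, 2dh, ..., <= f(t) of extent(t,h)^E * h^H * dh
// where extent(t,h) is the length of the contiguous suprathreshold run
// (f >= h) containing t.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector f, double E, double H, double dh) {
  const int T = f.size();
  NumericVector out(T);
  if (T == 0 || dh <= 0) return out;
  double fmax = 0.0;
  for (int t = 0; t < T; ++t) if (f[t] > fmax) fmax = f[t];
  const long mmax = (long)std::floor(fmax / dh + 1e-9);
  for (long m = 1; m <= mmax; ++m) {
    const double h = m * dh;
    const double hH = std::pow(h, H) * dh;
    int t = 0;
    while (t < T) {
      if (f[t] >= h - 1e-12 * dh) {
        int s = t;
        while (t < T && f[t] >= h - 1e-12 * dh) ++t;
        const double add = std::pow((double)(t - s), E) * hH;
        for (int u = s; u < t; ++u) out[u] += add;
      } else {
        ++t;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pointwise two-way repeated-measures ANOVA (2 x 3 within design) and the
// within-participant permutation max-TFCE engine.
//
// Data layout: M is a (6*n) x T matrix; row = i*6 + c for participant i
// (0-based) and cell c = hand*3 + side (hand 0/1, side 0/1/2). Each column
// is one timepoint.
// ---------------------------------------------------------------------------

struct FScanWork {
  int n, T;
  std::vector<double> mi;    // participant means, n x T (t-major: mi[t*n+i])
  std::vector<double> g;     // grand mean per t
  std::vector<double> sstw;  // total within-participant SS per t
};

static void fscan_precompute(const NumericMatrix& M, int n, FScanWork& w) {
  const int T = M.ncol();
  w.n = n; w.T = T;
  w.mi.assign((size_t)n * T, 0.0);
  w.g.assign(T, 0.0);
  w.sstw.assign(T, 0.0);
  for (int t = 0; t < T; ++t) {
    double gt = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < 6; ++c) s += M(i * 6 + c, t);
      w.mi[(size_t)t * n + i] = s / 6.0;
      gt += s;
    }
    w.g[t] = gt / (6.0 * n);
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double m = w.mi[(size_t)t * n + i];
      for (int c = 0; c < 6; ++c) {
        const double d = M(i * 6 + c, t) - m;
        ss += d * d;
      }
    }
    w.sstw[t] = ss;
  }
}

// Compute F statistics at one timepoint for a given per-row cell labelling.
// labels: length 6n, values 0..5. fout[0]=hand, fout[1]=side, fout[2]=int.
static inline void f_at_t(const NumericMatrix& M, const FScanWork& w,
                          const int* labels, int t, double* fout,
                          std::vector<double>& sij, std::vector<double>& sik,
                          double* sjk) {
  const int n = w.n;
  std::fill(sij.begin(), sij.end(), 0.0);
  std::fill(sik.begin(), sik.end(), 0.0);
  for (int c = 0; c < 6; ++c) sjk[c] = 0.0;
  for (int i = 0; i < n; ++i) {
    const int base = i * 6;
    for (int c0 = 0; c0 < 6; ++c0) {
      const int c = labels[base + c0];
      const double v = M(base + c0, t);
      sij[i * 2 + (c / 3)] += v;
      sik[i * 3 + (c % 3)] += v;
      sjk[c] += v;
    }
  }
  const double g = w.g[t];
  double mj[2], mk[3], mjk[6];
  for (int j = 0; j < 2; ++j)
    mj[j] = (sjk[j * 3] + sjk[j * 3 + 1] + sjk[j * 3 + 2]) / (3.0 * n);
  for (int k = 0; k < 3; ++k) mk[k] = (sjk[k] + sjk[3 + k]) / (2.0 * n);
  for (int c = 0; c < 6; ++c) mjk[c] = sjk[c] / n;

  double ssA = 0.0, ssB = 0.0, ssAB = 0.0, ssAS = 0.0, ssBS = 0.0;
  for (int j = 0; j < 2; ++j) { const double d = mj[j] - g; ssA += d * d; }
  ssA *= 3.0 * n;
  for (int k = 0; k < 3; ++k) { const double d = mk[k] - g; ssB += d * d; }
  ssB *= 2.0 * n;
  for (int j = 0; j < 2; ++j)
    for (int k = 0; k < 3; ++k) {
      const double d = mjk[j * 3 + k] - mj[j] - mk[k] + g;
      ssAB += d * d;
    }
  ssAB *= n;
  for (int i = 0; i < n; ++i) {
    const double m = w.mi[(size_t)t * n + i];
    for (int j = 0; j < 2; ++j) {
      const double d = sij[i * 2 + j] / 3.0 - m - mj[j] + g;
      ssAS += d * d;
    }
    for (int k = 0; k < 3; ++k) {
      const double d = sik[i * 3 + k] / 2.0 - m - mk[k] + g;
      ssBS += d * d;
    }
  }
  ssAS *= 3.0;
  ssBS *= 2.0;
  double ssABS = w.sstw[t] - ssA - ssB - ssAB - ssAS - ssBS;
  if (ssABS < 0.0) ssABS = 0.0;

  const double dfe = (double)(n - 1);
  const double eps = 1e-12;
  const double msAS = ssAS / dfe, msBS = ssBS / (2.0 * dfe),
               msABS = ssABS / (2.0 * dfe);
  fout[0] = (msAS > eps) ? ssA / msAS : 0.0;
  fout[1] = (msBS > eps) ? (ssB / 2.0) / msBS : 0.0;
  fout[2] = (msABS > eps) ? (ssAB / 2.0) / msABS : 0.0;
}

// [[Rcpp::export]]
NumericMatrix fscan_cpp(NumericMatrix M, int n) {
  const int T = M.ncol();
  FScanWork w;
  fscan_precompute(M, n, w);
  std::vector<int> id(6 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 6; ++c) id[i * 6 + c] = c;
  std::vector<double> sij(2 * n), sik(3 * n);
  double sjk[6], fout[3];
  NumericMatrix out(3, T);
  for (int t = 0; t < T; ++t) {
    f_at_t(M, w, id.data(), t, fout, sij, sik, sjk);
    out(0, t) = fout[0]; out(1, t) = fout[1]; out(2, t) = fout[2];
  }
  return out;
}

// perms: n_perm x (6*n) matrix of cell labels 0..5 (within-participant
// permutations). effect: 0 hand, 1 side, 2 interaction. Returns the max
// over time of the TFCE-enhanced F scan for each permutation.
// [[Rcpp::export]]
NumericVector perm_max_tfce_cpp(NumericMatrix M, int n, IntegerMatrix perms,
                                int effect, double E, double H, double dh) {
  const int T = M.ncol();
  const int np = perms.nrow();
  FScanWork w;
  fscan_precompute(M, n, w);
  std::vector<double> sij(2 * n), sik(3 * n), fvec(T);
  double sjk[6], fout[3];
  std::vector<int> labels(6 * n);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    for (int r = 0; r < 6 * n; ++r) labels[r] = perms(p, r);
    for (int t = 0; t < T; ++t) {
      f_at_t(M, w, labels.data(), t, fout, sij, sik, sjk);
      fvec[t] = fout[effect];
    }
    NumericVector enh = tfce_cpp(wrap(fvec), E, H, dh);
    double mx = 0.0;
    for (int t = 0; t < T; ++t) if (enh[t] > mx) mx = enh[t];
    out[p] = mx;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Portable noise stream for the synthetic generator: xoshiro256++ seeded via
// splitmix64, Box-Muller normals. Returns an n x 2 matrix of
// coupled white noise plus independent random-walk drift (left, right).
// The random walk advances every `drift_every` samples and is linearly
// interpolated in between.
// ---------------------------------------------------------------------------

static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  bool have_cached;
  double cached;
  explicit Xoshiro(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  uint64_t next() {
    const uint64_t r = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return r;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_cached) { have_cached = false; return cached; }
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double th = 6.283185307179586 * u2;
    cached = r * std::sin(th);
    have_cached = true;
    return r * std::cos(th);
  }
};

// [[Rcpp::export]]
NumericMatrix sim_noise_cpp(int n, double white_sd, double coupling,
                            double drift_step_sd, int drift_every,
                            double seed) {
  NumericMatrix out(n, 2);
  Xoshiro rng((uint64_t)seed);
  // bivariate construction: corr(left, right) = coupling exactly
  const double cc = coupling, ci = std::sqrt(1.0 - coupling * coupling);
  double dl0 = 0.0, dr0 = 0.0, dl1 = 0.0, dr1 = 0.0;
  int phase = drift_every;  // force knot draw at first sample
  for (int i = 0; i < n; ++i) {
    if (phase >= drift_every) {
      dl0 = dl1; dr0 = dr1;
      dl1 = dl0 + drift_step_sd * rng.norm();
      dr1 = dr0 + drift_step_sd * rng.norm();
      phase = 0;
    }
    const double fr = (double)phase / drift_every;
    const double z1 = rng.norm(), z2 = rng.norm();
    out(i, 0) = white_sd * z1 + dl0 + fr * (dl1 - dl0);
    out(i, 1) = white_sd * (cc * z1 + ci * z2) + dr0 + fr * (dr1 - dr0);
    ++phase;
  }
  return out;
}

// Per-column maximum absolute value (trials are columns).
// [[Rcpp::export]]
NumericVector col_absmax_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  for (int j = 0; j < nc; ++j) {
    double m = 0.0;
    const double* col = &x(0, j);
    for (int i = 0; i < nr; ++i) {
      const double v = std::fabs(col[i]);
      if (v > m) m = v;
    }
    out[j] = m;
  }
  return out;
}
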