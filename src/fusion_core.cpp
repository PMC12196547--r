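// Batched forward/backward core of the dual-stream fusion network.
//
// Activations are stored as flat (T*B x d) matrices, row index t + T*b, so
// that all shared-weight projections are single BLAS calls; only the T x T
// sequence-mixing products (attention scores, semiseparable state-space
// matrix) are evaluated per batch slice. The state-space block materializes
// its T x T mixing matrix densely (T = 50), which is numerically identical
// to the chunked evaluation and keeps the backward pass simple.

#include "gaitscreen_types.h"

#include <RcppArmadillo.h>
#include <chrono>
#include <cstdint>
#include <cstdlib>
#include <cstring>
#include <map>
#include <random>
#include <vector>

// ---------------------------------------------------------------------------
// caching pool allocator (see gaitscreen_types.h)

namespace {
struct BlockHeader {
  std::uint64_t magic;
  std::size_t bytes;
};
const std::uint64_t kPoolMagic = 0x67616974706f6f6cULL; // "gaitpool"
const std::size_t kHeader = 64; // keep returned pointers 64-byte aligned
const std::size_t kMinCached = 1 << 12;
const std::size_t kMaxPoolBytes = std::size_t(3) << 30;
std::multimap<std::size_t, void*> pool_cache;
std::size_t pool_bytes = 0;
std::size_t pool_hits = 0, pool_misses = 0;
} // namespace

void* gaitscreen_pool_alloc(std::size_t n_bytes) {
  if (n_bytes >= kMinCached) {
    std::multimap<std::size_t, void*>::iterator it = pool_cache.find(n_bytes);
    if (it != pool_cache.end()) {
      void* raw = it->second;
      pool_cache.erase(it);
      pool_bytes -= n_bytes;
      ++pool_hits;
      return static_cast<char*>(raw) + kHeader;
    }
  }
  ++pool_misses;
  void* raw = std::malloc(n_bytes + kHeader);
  if (!raw) return 0;
  BlockHeader* h = static_cast<BlockHeader*>(raw);
  h->magic = kPoolMagic;
  h->bytes = n_bytes;
  return static_cast<char*>(raw) + kHeader;
}

void gaitscreen_pool_free(void* ptr) {
  if (!ptr) return;
  char* raw = static_cast<char*>(ptr) - kHeader;
  BlockHeader* h = reinterpret_cast<BlockHeader*>(raw);
  if (h->magic != kPoolMagic) {
    // not ours (allocated before the pool was linked in); free directly
    std::free(ptr);
    return;
  }
  if (h->bytes >= kMinCached && pool_bytes + h->bytes <= kMaxPoolBytes) {
    pool_cache.insert(std::make_pair(h->bytes, static_cast<void*>(raw)));
    pool_bytes += h->bytes;
  } else {
    std::free(raw);
  }
}

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb, const float* beta,
            float* c, const int* ldc);
}

namespace {

// direct single-precision GEMM on raw (possibly strided) column-major
// blocks; avoids submatrix temporaries for the many small per-slice
// products
inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct Config {
  int T, d, heads, ffn, N, depth, B;
  double dropout;
};

// lightweight phase profiler (inspect with .fusion_profile_report())
static std::map<std::string, double> prof_acc;
struct ProfTimer {
  std::chrono::high_resolution_clock::time_point t0;
  ProfTimer() : t0(std::chrono::high_resolution_clock::now()) {}
  void lap(const char* name) {
    auto t1 = std::chrono::high_resolution_clock::now();
    prof_acc[name] += std::chrono::duration<double>(t1 - t0).count();
    t0 = t1;
  }
};

typedef std::map<std::string, fmat> ParamMap;

ParamMap read_params(const Rcpp::List& plist) {
  ParamMap out;
  Rcpp::CharacterVector nms = plist.names();
  for (int i = 0; i < plist.size(); ++i) {
    std::string key = Rcpp::as<std::string>(nms[i]);
    Rcpp::NumericVector v(plist[i]);
    int nr = v.size(), nc = 1;
    if (v.hasAttribute("dim")) {
      Rcpp::IntegerVector dm = v.attr("dim");
      nr = dm[0];
      nc = dm[1];
    }
    mat tmp(v.begin(), nr, nc, false);
    out[key] = conv_to<fmat>::from(tmp);
  }
  return out;
}

const fmat& P(const ParamMap& p, const std::string& key) {
  ParamMap::const_iterator it = p.find(key);
  if (it == p.end()) Rcpp::stop("missing parameter: " + key);
  return it->second;
}

inline frowvec as_row(const fmat& m) { return m.as_row(); }

// contiguous column-wise implementations of the per-feature bias/gain
// operations (arma's each_row walks the matrix in row order, which is a
// strided access pattern on column-major storage)
inline void add_bias(fmat& X, const fmat& b) {
  const float* bp = b.memptr();
  const uword nr = X.n_rows;
  for (uword j = 0; j < X.n_cols; ++j) {
    float* __restrict__ cj = X.colptr(j);
    const float bj = bp[j];
    for (uword i = 0; i < nr; ++i) cj[i] += bj;
  }
}

inline void scale_bias_cols(fmat& X, const fmat& g, const fmat& b) {
  const float* gp = g.memptr();
  const float* bp = b.memptr();
  const uword nr = X.n_rows;
  for (uword j = 0; j < X.n_cols; ++j) {
    float* __restrict__ cj = X.colptr(j);
    const float gj = gp[j], bj = bp[j];
    for (uword i = 0; i < nr; ++i) cj[i] = cj[i] * gj + bj;
  }
}

inline void scale_cols(fmat& X, const fmat& g) {
  const float* gp = g.memptr();
  const uword nr = X.n_rows;
  for (uword j = 0; j < X.n_cols; ++j) {
    float* __restrict__ cj = X.colptr(j);
    const float gj = gp[j];
    for (uword i = 0; i < nr; ++i) cj[i] *= gj;
  }
}


// branch-free exp approximation (rel. error ~2e-7), written so the
// compiler can vectorize the elementwise loops below
inline float fast_expf(float x) {
  x = std::max(-87.0f, std::min(88.0f, x));
  float t = x * 1.44269504f;
  float fi = std::floor(t);
  float f = t - fi;
  float p = 1.0f +
      f * (0.69314718f +
           f * (0.24022651f +
                f * (0.05550411f + f * (0.00961813f + f * 0.00133336f))));
  std::int32_t i = (std::int32_t)fi;
  std::uint32_t u = (std::uint32_t)(i + 127) << 23;
  float r;
  std::memcpy(&r, &u, 4);
  return p * r;
}

#ifdef __AVX2__
#include <immintrin.h>
// 8-lane version of fast_expf (same polynomial)
inline __m256 fast_exp8(__m256 x) {
  const __m256 lo = _mm256_set1_ps(-87.0f), hi = _mm256_set1_ps(88.0f);
  x = _mm256_min_ps(_mm256_max_ps(x, lo), hi);
  __m256 t = _mm256_mul_ps(x, _mm256_set1_ps(1.44269504f));
  __m256 fi = _mm256_floor_ps(t);
  __m256 f = _mm256_sub_ps(t, fi);
  __m256 p = _mm256_set1_ps(0.00133336f);
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(0.00961813f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(0.05550411f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(0.24022651f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(0.69314718f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(1.0f));
  __m256i i = _mm256_cvtps_epi32(fi);
  i = _mm256_add_epi32(i, _mm256_set1_epi32(127));
  i = _mm256_slli_epi32(i, 23);
  return _mm256_mul_ps(p, _mm256_castsi256_ps(i));
}

inline void exp_span(float* __restrict__ o, const float* __restrict__ x,
                     std::size_t n) {
  std::size_t i = 0;
  for (; i + 8 <= n; i += 8)
    _mm256_storeu_ps(o + i, fast_exp8(_mm256_loadu_ps(x + i)));
  for (; i < n; ++i) o[i] = fast_expf(x[i]);
}
#else
inline void exp_span(float* __restrict__ o, const float* __restrict__ x,
                     std::size_t n) {
  for (std::size_t i = 0; i < n; ++i) o[i] = fast_expf(x[i]);
}
#endif

inline fmat silu(const fmat& x) {
  fmat out(size(x));
  const float* xi = x.memptr();
  float* oi = out.memptr();
  const uword n = x.n_elem;
  // oi <- exp(-x), then combine
  for (uword i = 0; i < n; ++i) oi[i] = -xi[i];
  exp_span(oi, oi, n);
  for (uword i = 0; i < n; ++i) oi[i] = xi[i] / (1.0f + oi[i]);
  return out;
}

inline fmat silu_deriv(const fmat& x) {
  fmat out(size(x));
  const float* xi = x.memptr();
  float* oi = out.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) oi[i] = -xi[i];
  exp_span(oi, oi, n);
  for (uword i = 0; i < n; ++i) {
    float s = 1.0f / (1.0f + oi[i]);
    oi[i] = s * (1.0f + xi[i] * (1.0f - s));
  }
  return out;
}

// C (T x dh, column stride ldc) = alpha * A (T x T) * B (T x dh, stride ldb)
// axpy formulation over contiguous columns; beats library sgemm at these
// tiny widths
inline void kern_NN(int T, int dh, float alpha, const float* __restrict__ A,
                    const float* __restrict__ B, int ldb,
                    float* __restrict__ C, int ldc) {
  for (int j = 0; j < dh; ++j) {
    float* __restrict__ cj = C + (std::size_t)j * ldc;
    for (int i = 0; i < T; ++i) cj[i] = 0.0f;
    const float* __restrict__ bj = B + (std::size_t)j * ldb;
    for (int k = 0; k < T; ++k) {
      const float s = alpha * bj[k];
      const float* __restrict__ ak = A + (std::size_t)k * T;
      for (int i = 0; i < T; ++i) cj[i] += ak[i] * s;
    }
  }
}

// C (T x dh, stride ldc) = alpha * A^T (A is T x T) * B (T x dh, stride ldb)
// dot formulation over contiguous columns
inline void kern_TN(int T, int dh, float alpha, const float* __restrict__ A,
                    const float* __restrict__ B, int ldb,
                    float* __restrict__ C, int ldc) {
  for (int j = 0; j < dh; ++j) {
    const float* __restrict__ bj = B + (std::size_t)j * ldb;
    float* __restrict__ cj = C + (std::size_t)j * ldc;
    for (int i = 0; i < T; ++i) {
      const float* __restrict__ ai = A + (std::size_t)i * T;
      float acc = 0.0f;
      for (int k = 0; k < T; ++k) acc += ai[k] * bj[k];
      cj[i] = alpha * acc;
    }
  }
}

// row-wise softmax of a T x T column-major matrix, vectorized across the
// contiguous row index
inline void softmax_rows_inplace(int T, float* __restrict__ S) {
  float mx[64], sm[64];
  for (int i = 0; i < T; ++i) mx[i] = S[i];
  for (int j = 1; j < T; ++j) {
    const float* __restrict__ sj = S + (std::size_t)j * T;
    for (int i = 0; i < T; ++i) mx[i] = std::max(mx[i], sj[i]);
  }
  for (int i = 0; i < T; ++i) sm[i] = 0.0f;
  for (int j = 0; j < T; ++j) {
    float* __restrict__ sj = S + (std::size_t)j * T;
    for (int i = 0; i < T; ++i) sj[i] -= mx[i];
    exp_span(sj, sj, T);
    for (int i = 0; i < T; ++i) sm[i] += sj[i];
  }
  for (int i = 0; i < T; ++i) sm[i] = 1.0f / sm[i];
  for (int j = 0; j < T; ++j) {
    float* __restrict__ sj = S + (std::size_t)j * T;
    for (int i = 0; i < T; ++i) sj[i] *= sm[i];
  }
}

// in-place softmax backward: dP <- (dP - rowsum(dP % P)) % P, both T x T
inline void softmax_bwd_inplace(int T, float* __restrict__ dP,
                                const float* __restrict__ Pm) {
  float rs[64];
  for (int i = 0; i < T; ++i) rs[i] = 0.0f;
  for (int j = 0; j < T; ++j) {
    const float* __restrict__ pj = Pm + (std::size_t)j * T;
    float* __restrict__ dj = dP + (std::size_t)j * T;
    for (int i = 0; i < T; ++i) rs[i] += dj[i] * pj[i];
  }
  for (int j = 0; j < T; ++j) {
    const float* __restrict__ pj = Pm + (std::size_t)j * T;
    float* __restrict__ dj = dP + (std::size_t)j * T;
    for (int i = 0; i < T; ++i) dj[i] = (dj[i] - rs[i]) * pj[i];
  }
}

inline double softplus(double x) {
  return x > 30 ? x : std::log1p(std::exp(x));
}

// ---------------------------------------------------------------------------
// layer norm (row-wise, population variance, eps 1e-5)

struct LnCache {
  fmat xhat;
  fvec istd;
};

fmat ln_forward(const fmat& X, const fmat& g, const fmat& b, LnCache* c) {
  fvec mu = mean(X, 1);
  fmat xc = X.each_col() - mu;
  fvec v = mean(xc % xc, 1);
  fvec istd = 1.0 / sqrt(v + 1e-5);
  fmat xhat = xc.each_col() % istd;
  fmat y = xhat;
  scale_bias_cols(y, g, b);
  if (c) { c->xhat = xhat; c->istd = istd; }
  return y;
}

fmat ln_backward(const fmat& dY, const LnCache& c, const fmat& g,
                fmat& dg, fmat& db) {
  fmat dyh = dY;
  scale_cols(dyh, g);
  dg += sum(dY % c.xhat, 0).t();
  db += sum(dY, 0).t();
  fvec m1 = mean(dyh, 1);
  fvec m2 = mean(dyh % c.xhat, 1);
  fmat dx = dyh;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.istd;
  return dx;
}

// ---------------------------------------------------------------------------
// dropout

fmat make_mask(int nr, int nc, double p, std::mt19937& rng) {
  fmat m(nr, nc);
  if (p <= 0) { m.ones(); return m; }
  const std::uint32_t thresh = (std::uint32_t)(p * 4294967296.0);
  const float scale = (float)(1.0 / (1.0 - p));
  float* mi = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i) mi[i] = rng() < thresh ? 0.0f : scale;
  return m;
}

// ---------------------------------------------------------------------------
// attention block (MHA + residual + LN + FFN + residual + LN)

struct AttnCache {
  fmat Xq, Xkv, Q, K, V, Ocat, maskA, U, Z1, H, maskF;
  fcube Pc; // T x T x (B*heads)
  LnCache ln1, ln2;
  bool self_attn;
};

fmat attn_forward(const fmat& Xq, const fmat& Xkv, const ParamMap& p,
                 const std::string& pre, const Config& cfg,
                 std::mt19937& rng, AttnCache* c) {
  ProfTimer pt;
  const int T = cfg.T, B = cfg.B, H = cfg.heads;
  const int dh = cfg.d / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  fmat Q = Xq * P(p, pre + "Wq"); add_bias(Q, P(p, pre + "bq"));
  fmat K = Xkv * P(p, pre + "Wk"); add_bias(K, P(p, pre + "bk"));
  fmat V = Xkv * P(p, pre + "Wv"); add_bias(V, P(p, pre + "bv"));
  pt.lap("attn.proj");
  fmat Ocat(Q.n_rows, cfg.d);
  fcube Pc(T, T, B * H);
  pt.lap("attn.alloc");
  const int TB = Q.n_rows;
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dh;
      float* S = Pc.slice_memptr(b * H + h);
      const float* q = Q.memptr() + c0 * TB + r0;
      const float* k = K.memptr() + c0 * TB + r0;
      const float* v = V.memptr() + c0 * TB + r0;
      sgemm('N', 'T', T, T, dh, (float)sc, q, TB, k, TB, 0.0f, S, T);
      softmax_rows_inplace(T, S);
      kern_NN(T, dh, 1.0f, S, v, TB, Ocat.memptr() + c0 * TB + r0, TB);
    }
  }
  pt.lap("attn.scores");
  fmat A = Ocat * P(p, pre + "Wo"); add_bias(A, P(p, pre + "bo"));
  fmat maskA;
  if (cfg.dropout > 0) {
    maskA = make_mask(A.n_rows, A.n_cols, cfg.dropout, rng);
    A %= maskA;
  }
  LnCache* l1 = c ? &c->ln1 : 0;
  LnCache* l2 = c ? &c->ln2 : 0;
  fmat U = ln_forward(Xq + A, P(p, pre + "ln1g"), P(p, pre + "ln1b"), l1);
  fmat Z1 = U * P(p, pre + "Wf1"); add_bias(Z1, P(p, pre + "bf1"));
  fmat Hh = silu(Z1);
  fmat F = Hh * P(p, pre + "Wf2"); add_bias(F, P(p, pre + "bf2"));
  fmat maskF;
  if (cfg.dropout > 0) {
    maskF = make_mask(F.n_rows, F.n_cols, cfg.dropout, rng);
    F %= maskF;
  }
  fmat Y = ln_forward(U + F, P(p, pre + "ln2g"), P(p, pre + "ln2b"), l2);
  pt.lap("attn.ffn_ln");
  if (c) {
    c->Xq = Xq; c->Xkv = Xkv; c->Q = std::move(Q); c->K = std::move(K);
    c->V = std::move(V); c->Ocat = std::move(Ocat);
    c->maskA = std::move(maskA); c->U = std::move(U); c->Z1 = std::move(Z1);
    c->H = std::move(Hh); c->maskF = std::move(maskF); c->Pc = std::move(Pc);
  }
  pt.lap("attn.cache");
  return Y;
}

// Accumulates input grads into dXq / dXkv (dXkv may alias dXq for
// self-attention: caller passes the same matrix).
void attn_backward(const fmat& dY, AttnCache& c, const ParamMap& p,
                   const std::string& pre, const Config& cfg, ParamMap& g,
                   fmat& dXq, fmat& dXkv, bool self_attn) {
  const int T = cfg.T, B = cfg.B, H = cfg.heads;
  const int dh = cfg.d / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  ProfTimer pt;
  fmat dR2 = ln_backward(dY, c.ln2, P(p, pre + "ln2g"),
                        g[pre + "ln2g"], g[pre + "ln2b"]);
  fmat dU = dR2;
  fmat dF = dR2;
  if (cfg.dropout > 0) dF %= c.maskF;
  g[pre + "Wf2"] += c.H.t() * dF;
  g[pre + "bf2"] += sum(dF, 0).t();
  fmat dH = dF * P(p, pre + "Wf2").t();
  fmat dZ1 = dH % silu_deriv(c.Z1);
  g[pre + "Wf1"] += c.U.t() * dZ1;
  g[pre + "bf1"] += sum(dZ1, 0).t();
  dU += dZ1 * P(p, pre + "Wf1").t();
  fmat dR1 = ln_backward(dU, c.ln1, P(p, pre + "ln1g"),
                        g[pre + "ln1g"], g[pre + "ln1b"]);
  pt.lap("bwd.ffn_ln");
  dXq += dR1;
  fmat dA = dR1;
  if (cfg.dropout > 0) dA %= c.maskA;
  g[pre + "Wo"] += c.Ocat.t() * dA;
  g[pre + "bo"] += sum(dA, 0).t();
  fmat dOcat = dA * P(p, pre + "Wo").t();
  pt.lap("bwd.wo");
  fmat dQ(size(c.Q), fill::none), dK(size(c.K), fill::none),
      dV(size(c.V), fill::none);
  const int TB = c.Q.n_rows;
  fmat dP(T, T);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dh;
      const float* Pm = c.Pc.slice_memptr(b * H + h);
      const float* dO = dOcat.memptr() + c0 * TB + r0;
      const float* v = c.V.memptr() + c0 * TB + r0;
      const float* q = c.Q.memptr() + c0 * TB + r0;
      const float* k = c.K.memptr() + c0 * TB + r0;
      kern_TN(T, dh, 1.0f, Pm, dO, TB, dV.memptr() + c0 * TB + r0, TB);
      float* dPp = dP.memptr();
      sgemm('N', 'T', T, T, dh, 1.0f, dO, TB, v, TB, 0.0f, dPp, T);
      softmax_bwd_inplace(T, dPp, Pm);
      kern_NN(T, dh, (float)sc, dPp, k, TB, dQ.memptr() + c0 * TB + r0, TB);
      kern_TN(T, dh, (float)sc, dPp, q, TB, dK.memptr() + c0 * TB + r0, TB);
    }
  }
  pt.lap("bwd.scores");
  g[pre + "Wq"] += c.Xq.t() * dQ;
  g[pre + "bq"] += sum(dQ, 0).t();
  g[pre + "Wk"] += c.Xkv.t() * dK;
  g[pre + "bk"] += sum(dK, 0).t();
  g[pre + "Wv"] += c.Xkv.t() * dV;
  g[pre + "bv"] += sum(dV, 0).t();
  dXq += dQ * P(p, pre + "Wq").t();
  pt.lap("bwd.proj_grads_pre");
  if (self_attn) {
    dXq += dK * P(p, pre + "Wk").t() + dV * P(p, pre + "Wv").t();
  } else {
    dXkv += dK * P(p, pre + "Wk").t() + dV * P(p, pre + "Wv").t();
  }
  pt.lap("bwd.proj_grads");
}

// ---------------------------------------------------------------------------
// state-space (Mamba-2 style) block, dense semiseparable-matrix route

struct MambaCache {
  fmat X, u0, uc, u, z, gz, delta_raw, delta, Bm, Cm, Yss, o, maskM;
  fvec loga;
  fcube Lc, Gc, Mc; // T x T x B
};

fmat mamba_forward(const fmat& X, const ParamMap& p, const std::string& pre,
                  const Config& cfg, std::mt19937& rng, MambaCache* c) {
  ProfTimer pt;
  const int T = cfg.T, B = cfg.B, d = cfg.d;
  fmat P0 = X * P(p, pre + "Win"); add_bias(P0, P(p, pre + "bin"));
  fmat u0 = P0.cols(0, d - 1);
  fmat z = P0.cols(d, 2 * d - 1);
  fmat uc = u0;
  scale_cols(uc, P(p, pre + "wcv"));
  add_bias(uc, P(p, pre + "bcv"));
  fmat u = silu(uc);
  fmat delta_raw = u * P(p, pre + "Wd");
  delta_raw += P(p, pre + "bd")(0, 0);
  fmat delta = delta_raw;
  delta.transform([](double x) { return softplus(x); });
  const double abar = softplus(P(p, pre + "abase")(0, 0));
  fvec loga = -abar * delta.col(0);
  fmat Bm = u * P(p, pre + "WB"); add_bias(Bm, P(p, pre + "bB"));
  fmat Cm = u * P(p, pre + "WC"); add_bias(Cm, P(p, pre + "bC"));
  pt.lap("mamba.proj");
  fmat Yss(size(u), fill::zeros);
  fcube Lc(T, T, B), Gc(T, T, B), Mc(T, T, B);
  fvec ones_T(T, fill::ones);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    fvec s = cumsum(loga.subvec(r0, r1));
    fmat L(T, T);
    const float* sp = s.memptr();
    float* Lp = L.memptr();
    for (int i = 0; i < T; ++i) { // column i: L(j, i) = exp(s_j - s_i), j >= i
      const float si = sp[i];
      float* Li = Lp + (std::size_t)i * T;
      for (int j = 0; j < i; ++j) Li[j] = 0.0f;
      for (int j = i; j < T; ++j) Li[j] = sp[j] - si;
      exp_span(Li + i, Li + i, T - i);
    }
    fmat G = Cm.rows(r0, r1) * Bm.rows(r0, r1).t();
    fmat M = trimatl(G % L);
    Yss.rows(r0, r1) = M * u.rows(r0, r1);
    Lc.slice(b) = L; Gc.slice(b) = G; Mc.slice(b) = M;
  }
  pt.lap("mamba.ssm");
  fmat gz = silu(z);
  fmat o = Yss % gz;
  fmat out = o * P(p, pre + "Wout"); add_bias(out, P(p, pre + "bout"));
  fmat maskM;
  if (cfg.dropout > 0) {
    maskM = make_mask(out.n_rows, out.n_cols, cfg.dropout, rng);
    out %= maskM;
  }
  fmat Y = X + out;
  pt.lap("mamba.gate_out");
  if (c) {
    c->X = X; c->u0 = std::move(u0); c->uc = std::move(uc);
    c->u = std::move(u); c->z = std::move(z); c->gz = std::move(gz);
    c->delta_raw = std::move(delta_raw); c->delta = std::move(delta);
    c->Bm = std::move(Bm); c->Cm = std::move(Cm); c->Yss = std::move(Yss);
    c->o = std::move(o); c->maskM = std::move(maskM);
    c->loga = std::move(loga); c->Lc = std::move(Lc);
    c->Gc = std::move(Gc); c->Mc = std::move(Mc);
  }
  pt.lap("mamba.cache");
  return Y;
}

void mamba_backward(const fmat& dY, MambaCache& c, const ParamMap& p,
                    const std::string& pre, const Config& cfg, ParamMap& g,
                    fmat& dX) {
  const int T = cfg.T, B = cfg.B, d = cfg.d;
  ProfTimer pt;
  dX += dY;
  fmat dout = dY;
  if (cfg.dropout > 0) dout %= c.maskM;
  g[pre + "Wout"] += c.o.t() * dout;
  g[pre + "bout"] += sum(dout, 0).t();
  fmat do_ = dout * P(p, pre + "Wout").t();
  fmat dYss = do_ % c.gz;
  fmat dgz = do_ % c.Yss;
  fmat dz = dgz % silu_deriv(c.z);
  pt.lap("mbwd.out");
  fmat du(size(c.u), fill::zeros);
  fmat dBm(size(c.Bm), fill::zeros), dCm(size(c.Cm), fill::zeros);
  fvec dloga(c.loga.n_elem, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    fmat dYs = dYss.rows(r0, r1);
    const fmat& L = c.Lc.slice(b);
    const fmat& G = c.Gc.slice(b);
    const fmat& M = c.Mc.slice(b);
    fmat dM = trimatl(dYs * c.u.rows(r0, r1).t());
    du.rows(r0, r1) += M.t() * dYs;
    fmat dG = dM % L;
    fmat dL = dM % G;
    dCm.rows(r0, r1) = dG * c.Bm.rows(r0, r1);
    dBm.rows(r0, r1) = dG.t() * c.Cm.rows(r0, r1);
    fmat Pm = dL % L;
    fvec ds = sum(Pm, 1) - sum(Pm, 0).t();
    dloga.subvec(r0, r1) = reverse(cumsum(reverse(ds)));
  }
  pt.lap("mbwd.slices");
  const double abase = P(p, pre + "abase")(0, 0);
  const double abar = softplus(abase);
  fvec ddelta = -abar * dloga;
  double dabar = -dot(c.delta.col(0), dloga);
  g[pre + "abase"] += dabar / (1.0 + std::exp(-abase));
  fmat ddraw = ddelta % (1.0 / (1.0 + exp(-c.delta_raw.col(0))));
  g[pre + "Wd"] += c.u.t() * ddraw;
  g[pre + "bd"] += accu(ddraw);
  du += ddraw * P(p, pre + "Wd").t();
  g[pre + "WB"] += c.u.t() * dBm;
  g[pre + "bB"] += sum(dBm, 0).t();
  g[pre + "WC"] += c.u.t() * dCm;
  g[pre + "bC"] += sum(dCm, 0).t();
  du += dBm * P(p, pre + "WB").t() + dCm * P(p, pre + "WC").t();
  fmat duc = du % silu_deriv(c.uc);
  g[pre + "wcv"] += sum(duc % c.u0, 0).t();
  g[pre + "bcv"] += sum(duc, 0).t();
  fmat du0 = duc;
  scale_cols(du0, P(p, pre + "wcv"));
  fmat dP0 = join_rows(du0, dz);
  g[pre + "Win"] += c.X.t() * dP0;
  g[pre + "bin"] += sum(dP0, 0).t();
  dX += dP0 * P(p, pre + "Win").t();
  pt.lap("mbwd.proj");
}

// ---------------------------------------------------------------------------
// full network

struct LayerCache {
  AttnCache tf, tl; // used when layer is attention
  MambaCache mf, ml; // used when layer is mamba
  AttnCache cf, cl;
};

struct ForwardOut {
  fmat probs; // B x 2
  std::vector<fmat> feats_f, feats_l; // flat (TB x d), post-exchange
  fmat pooled; // B x 2d
  std::vector<LayerCache>* caches;
};

std::string key(const char* stream, int layer, const char* block) {
  std::ostringstream os;
  os << stream << "." << layer << "." << block << ".";
  return os.str();
}

// flush subnormal gradients to zero: scores backward otherwise spends most
// of its time in the hardware's denormal slow path once gradients shrink
struct ScopedFlushZero {
#ifdef __SSE2__
  unsigned int saved;
  ScopedFlushZero() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~ScopedFlushZero() { _mm_setcsr(saved); }
#endif
};

ForwardOut network_forward(const ParamMap& p, const Config& cfg,
                           const fmat& Xf, const fmat& Xl, std::mt19937& rng,
                           std::vector<LayerCache>* caches) {
  ForwardOut out;
  fmat hf = Xf, hl = Xl;
  if (caches) caches->resize(cfg.depth);
  for (int layer = 1; layer <= cfg.depth; ++layer) {
    LayerCache* lc = caches ? &(*caches)[layer - 1] : 0;
    fmat tf, tl;
    if (layer % 2 == 1) {
      tf = attn_forward(hf, hf, p, key("f", layer, "attn"), cfg, rng,
                        lc ? &lc->tf : 0);
      tl = attn_forward(hl, hl, p, key("l", layer, "attn"), cfg, rng,
                        lc ? &lc->tl : 0);
    } else {
      tf = mamba_forward(hf, p, key("f", layer, "mamba"), cfg, rng,
                         lc ? &lc->mf : 0);
      tl = mamba_forward(hl, p, key("l", layer, "mamba"), cfg, rng,
                         lc ? &lc->ml : 0);
    }
    fmat cf = attn_forward(tf, tl, p, key("f", layer, "cross"), cfg, rng,
                          lc ? &lc->cf : 0);
    fmat cl = attn_forward(tl, tf, p, key("l", layer, "cross"), cfg, rng,
                          lc ? &lc->cl : 0);
    hf = tf + cf;
    hl = tl + cl;
    out.feats_f.push_back(hf);
    out.feats_l.push_back(hl);
  }
  // temporal mean pooling per slice, then concat and classify
  const int T = cfg.T, B = cfg.B, d = cfg.d;
  fmat pooled(B, 2 * d);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    pooled.submat(b, 0, b, d - 1) = mean(hf.rows(r0, r1), 0);
    pooled.submat(b, d, b, 2 * d - 1) = mean(hl.rows(r0, r1), 0);
  }
  fmat logits = pooled * P(p, "cls.W");
  logits.each_row() += as_row(P(p, "cls.b"));
  fmat probs = logits;
  probs.each_col() -= max(probs, 1);
  probs = exp(probs);
  probs.each_col() /= sum(probs, 1);
  out.probs = probs;
  out.pooled = pooled;
  out.caches = caches;
  return out;
}

Config read_config(const Rcpp::List& cfg, int B) {
  Config c;
  c.T = Rcpp::as<int>(cfg["seq_len"]);
  c.d = Rcpp::as<int>(cfg["embed_dim"]);
  c.heads = Rcpp::as<int>(cfg["heads"]);
  c.ffn = Rcpp::as<int>(cfg["ffn_dim"]);
  c.N = Rcpp::as<int>(cfg["state_dim"]);
  c.depth = Rcpp::as<int>(cfg["depth"]);
  c.dropout = 0.0;
  c.B = B;
  if (c.T > 64 || c.d / c.heads > 64)
    Rcpp::stop("compiled path supports seq_len <= 64 and head dim <= 64");
  return c;
}

fmat flatten_cube(const fcube& X) {
  // (T, d, B) fcube -> (T*B x d) flat matrix
  const uword T = X.n_rows, d = X.n_cols, B = X.n_slices;
  fmat out(T * B, d);
  for (uword b = 0; b < B; ++b) out.rows(b * T, b * T + T - 1) = X.slice(b);
  return out;
}

fcube unflatten(const fmat& X, int T, int B) {
  fcube out(T, X.n_cols, B);
  for (int b = 0; b < B; ++b)
    out.slice(b) = X.rows((uword)b * T, (uword)b * T + T - 1);
  return out;
}

// ---------------------------------------------------------------------------
// MMD (Gaussian kernel, unbiased estimator, median-heuristic bandwidth)

double mmd_pair(const fmat& Fx, const fmat& Fy, fmat* dFx, fmat* dFy) {
  const int n = Fx.n_rows, m = Fy.n_rows;
  fmat Z = join_cols(Fx, Fy);
  fvec sq = sum(Z % Z, 1);
  fmat D2 = -2.0 * Z * Z.t();
  D2.each_col() += sq;
  D2.each_row() += sq.t();
  D2.transform([](double x) { return x < 0 ? 0.0 : x; });
  // median of pairwise distances (i < j)
  std::vector<double> dists;
  dists.reserve((n + m) * (n + m - 1) / 2);
  for (int i = 0; i < n + m; ++i)
    for (int j = i + 1; j < n + m; ++j) dists.push_back(std::sqrt(D2(i, j)));
  std::sort(dists.begin(), dists.end());
  double med;
  size_t q = dists.size();
  med = (q % 2 == 1) ? dists[q / 2] : 0.5 * (dists[q / 2 - 1] + dists[q / 2]);
  double gamma = med > 0 ? 1.0 / (med * med) : 1.0;
  fmat Km = exp(-gamma * D2);
  fmat Kxx = Km.submat(0, 0, n - 1, n - 1);
  fmat Kyy = Km.submat(n, n, n + m - 1, n + m - 1);
  fmat Kxy = Km.submat(0, n, n - 1, n + m - 1);
  double sxx = (accu(Kxx) - n) / ((double)n * (n - 1));
  double syy = (accu(Kyy) - m) / ((double)m * (m - 1));
  double sxy = accu(Kxy) / ((double)n * m);
  double d2 = sxx + syy - 2.0 * sxy;
  if (dFx && d2 > 0) {
    // gradients with gamma treated as a constant
    double cxx = 1.0 / ((double)n * (n - 1));
    double cyy = 1.0 / ((double)m * (m - 1));
    double cxy = 2.0 / ((double)n * m);
    fmat Wxx = cxx * Kxx; Wxx.diag().zeros();
    fmat Wyy = cyy * Kyy; Wyy.diag().zeros();
    // within-X term: d/dx_a = -4 gamma [x_a rowsum(Wxx)_a - (Wxx Fx)_a]
    fvec rx = sum(Wxx, 1);
    *dFx = -4.0 * gamma * (Fx.each_col() % rx - Wxx * Fx);
    fvec ry = sum(Wyy, 1);
    *dFy = -4.0 * gamma * (Fy.each_col() % ry - Wyy * Fy);
    // cross term (enters with -cxy): d/dx_a = +2 cxy gamma [x_a rs - Kxy Fy]_a
    fvec rkx = sum(Kxy, 1);
    *dFx += 2.0 * cxy * gamma * (Fx.each_col() % rkx - Kxy * Fy);
    fvec rky = sum(Kxy, 0).t();
    *dFy += 2.0 * cxy * gamma * (Fy.each_col() % rky - Kxy.t() * Fx);
  } else if (dFx) {
    dFx->zeros(n, Fx.n_cols);
    dFy->zeros(m, Fy.n_cols);
  }
  return d2;
}

fmat sample_features(const fmat& flat, const uvec& idx, int T) {
  // rows = selected samples, flattened (column-major over T x d slice)
  fmat out(idx.n_elem, (uword)T * flat.n_cols);
  for (uword a = 0; a < idx.n_elem; ++a) {
    fmat sl = flat.rows(idx(a) * T, idx(a) * T + T - 1);
    out.row(a) = vectorise(sl).t();
  }
  return out;
}

} // namespace

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export(name = ".fusion_profile_report")]]
Rcpp::List fusion_profile_report(bool reset = true) {
  Rcpp::List out;
  for (std::map<std::string, double>::iterator it = prof_acc.begin();
       it != prof_acc.end(); ++it)
    out[it->first] = it->second;
  out["pool_hits"] = (double)pool_hits;
  out["pool_misses"] = (double)pool_misses;
  out["pool_bytes"] = (double)pool_bytes;
  if (reset) prof_acc.clear();
  return out;
}

// [[Rcpp::export(name = ".fusion_forward_cpp")]]
Rcpp::List fusion_forward_cpp(Rcpp::List params, Rcpp::List config,
                            arma::fcube Xf, arma::fcube Xl,
                            bool return_feats = false) {
  ParamMap p = read_params(params);
  Config cfg = read_config(config, Xf.n_slices);
  ScopedFlushZero fz;
  std::mt19937 rng(1u);
  fmat xf = flatten_cube(Xf), xl = flatten_cube(Xl);
  ForwardOut out = network_forward(p, cfg, xf, xl, rng, 0);
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("probs") = out.probs);
  if (return_feats) {
    Rcpp::List ff(cfg.depth), fl(cfg.depth);
    for (int i = 0; i < cfg.depth; ++i) {
      ff[i] = unflatten(out.feats_f[i], cfg.T, cfg.B);
      fl[i] = unflatten(out.feats_l[i], cfg.T, cfg.B);
    }
    res["feats_frontal"] = ff;
    res["feats_lateral"] = fl;
  }
  return res;
}

// [[Rcpp::export(name = ".fusion_train_step_cpp")]]
Rcpp::List fusion_train_step_cpp(Rcpp::List params, Rcpp::List config,
                               arma::fcube Xf, arma::fcube Xl,
                               arma::ivec y, double w1, double w2,
                               double lambda1, arma::uvec mmd_idx,
                               double dropout, int seed) {
  ParamMap p = read_params(params);
  Config cfg = read_config(config, Xf.n_slices);
  ScopedFlushZero fz;
  cfg.dropout = dropout;
  std::mt19937 rng((unsigned)seed);
  const int T = cfg.T, B = cfg.B, d = cfg.d;
  fmat xf = flatten_cube(Xf), xl = flatten_cube(Xl);
  std::vector<LayerCache> caches;
  ForwardOut out = network_forward(p, cfg, xf, xl, rng, &caches);

  // weighted cross-entropy (column 0 = HC, 1 = PD; PD is positive, y = 1)
  const double eps = 1e-7;
  double loss_w = 0.0;
  fmat dlogits(B, 2, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double p_pd = std::min(std::max((double)out.probs(b, 1), eps), 1.0 - eps);
    if (y(b) == 1) {
      loss_w += -w1 * std::log(p_pd);
      dlogits(b, 0) = w1 * out.probs(b, 0);
      dlogits(b, 1) = w1 * (out.probs(b, 1) - 1.0);
    } else {
      loss_w += -w2 * std::log(1.0 - p_pd);
      dlogits(b, 0) = w2 * (out.probs(b, 0) - 1.0);
      dlogits(b, 1) = w2 * out.probs(b, 1);
    }
  }
  loss_w /= B;
  dlogits /= B;

  ParamMap g;
  for (ParamMap::const_iterator it = p.begin(); it != p.end(); ++it)
    g[it->first] = fmat(size(it->second), fill::zeros);

  g["cls.W"] += out.pooled.t() * dlogits;
  g["cls.b"] += sum(dlogits, 0).t();
  fmat dpooled = dlogits * p["cls.W"].t();

  // per-layer MMD between the two streams' flattened features
  fvec Dvec(cfg.depth, fill::zeros);
  std::vector<fmat> dfeat_f(cfg.depth), dfeat_l(cfg.depth);
  for (int i = 0; i < cfg.depth; ++i) {
    dfeat_f[i] = fmat(xf.n_rows, d, fill::zeros);
    dfeat_l[i] = fmat(xf.n_rows, d, fill::zeros);
  }
  if (mmd_idx.n_elem >= 2) {
    const double coef = lambda1 / cfg.depth;
    for (int i = 0; i < cfg.depth; ++i) {
      fmat Fx = sample_features(out.feats_f[i], mmd_idx, T);
      fmat Fy = sample_features(out.feats_l[i], mmd_idx, T);
      fmat dFx, dFy;
      double d2 = mmd_pair(Fx, Fy, lambda1 > 0 ? &dFx : 0,
                           lambda1 > 0 ? &dFy : 0);
      Dvec(i) = d2 > 0 ? d2 : 0.0;
      if (lambda1 > 0 && d2 > 0) {
        for (uword a = 0; a < mmd_idx.n_elem; ++a) {
          uword r0 = mmd_idx(a) * T;
          dfeat_f[i].rows(r0, r0 + T - 1) +=
              coef * reshape(dFx.row(a).t(), T, d);
          dfeat_l[i].rows(r0, r0 + T - 1) +=
              coef * reshape(dFy.row(a).t(), T, d);
        }
      }
    }
  }

  // classifier pooling gradient into the last layer's features
  fmat dhf = dfeat_f[cfg.depth - 1], dhl = dfeat_l[cfg.depth - 1];
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    dhf.rows(r0, r1).each_row() += dpooled.submat(b, 0, b, d - 1) / T;
    dhl.rows(r0, r1).each_row() += dpooled.submat(b, d, b, 2 * d - 1) / T;
  }

  for (int layer = cfg.depth; layer >= 1; --layer) {
    LayerCache& lc = caches[layer - 1];
    // h = t + c(t): split incoming grad
    fmat dtf = dhf, dtl = dhl;
    attn_backward(dhf, lc.cf, p, key("f", layer, "cross"), cfg, g, dtf, dtl,
                  false);
    attn_backward(dhl, lc.cl, p, key("l", layer, "cross"), cfg, g, dtl, dtf,
                  false);
    fmat dprev_f(size(dtf), fill::zeros), dprev_l(size(dtl), fill::zeros);
    if (layer % 2 == 1) {
      attn_backward(dtf, lc.tf, p, key("f", layer, "attn"), cfg, g, dprev_f,
                    dprev_f, true);
      attn_backward(dtl, lc.tl, p, key("l", layer, "attn"), cfg, g, dprev_l,
                    dprev_l, true);
    } else {
      mamba_backward(dtf, lc.mf, p, key("f", layer, "mamba"), cfg, g, dprev_f);
      mamba_backward(dtl, lc.ml, p, key("l", layer, "mamba"), cfg, g, dprev_l);
    }
    dhf = dprev_f;
    dhl = dprev_l;
    if (layer > 1) {
      dhf += dfeat_f[layer - 2];
      dhl += dfeat_l[layer - 2];
    }
    caches[layer - 1] = LayerCache(); // release memory as we go
  }

  Rcpp::List gl(g.size());
  Rcpp::CharacterVector gnames(g.size());
  int i = 0;
  for (ParamMap::iterator it = g.begin(); it != g.end(); ++it, ++i) {
    gnames[i] = it->first;
    gl[i] = Rcpp::wrap(it->second);
  }
  gl.names() = gnames;
  return Rcpp::List::create(
      Rcpp::Named("probs") = out.probs, Rcpp::Named("loss_w") = loss_w,
      Rcpp::Named("per_layer_D") = Dvec,
      Rcpp::Named("ld") = mean(Dvec), Rcpp::Named("grads") = gl);
}
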