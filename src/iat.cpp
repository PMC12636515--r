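// Interpretable attention transformer (IAT) core: slice/conv token
// embedding, pre-norm multi-head self-attention encoder, CLS classification
// head, and the exact analytic backward pass used for training.
// Parameters travel as one flat vector; traverse() defines the single
// canonical layout used by init, unpack and gradient packing.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct IATCfg {
  int L, S, T, T1, D, H, dh, nlayer, M, K, K2, C, Cw, Cl, ncls;
  double pdrop;
  bool adrop;
};

IATCfg make_cfg(const Rcpp::List& cfg, int input_len) {
  IATCfg c;
  c.L = input_len;
  c.S = Rcpp::as<int>(cfg["slice_len"]);
  c.D = Rcpp::as<int>(cfg["embed_dim"]);
  c.H = Rcpp::as<int>(cfg["n_heads"]);
  c.nlayer = Rcpp::as<int>(cfg["n_layers"]);
  c.M = Rcpp::as<int>(cfg["mlp_dim"]);
  c.K = Rcpp::as<int>(cfg["conv_kernel"]);
  c.K2 = Rcpp::as<int>(cfg["conv_kernel_local"]);
  c.C = Rcpp::as<int>(cfg["conv_channels"]);
  c.ncls = Rcpp::as<int>(cfg["n_classes"]);
  c.pdrop = Rcpp::as<double>(cfg["dropout"]);
  c.adrop = cfg.containsElementNamed("attn_dropout") ?
    Rcpp::as<bool>(cfg["attn_dropout"]) : false;
  if (c.S <= 0 || c.L < c.S) Rcpp::stop("window shorter than one slice");
  if (c.D % c.H != 0) Rcpp::stop("embed_dim must be divisible by n_heads");
  if (c.K % 2 == 0 || c.K2 % 2 == 0) Rcpp::stop("conv kernels must be odd");
  if (c.C % 2 != 0) Rcpp::stop("conv_channels must be even (two scales)");
  c.Cw = c.C / 2;
  c.Cl = c.C - c.Cw;
  c.T = c.L / c.S;
  c.T1 = c.T + 1;
  c.dh = c.D / c.H;
  return c;
}

struct Layer {
  vec ln1g, ln1b, bq, bk, bv, bo, ln2g, ln2b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct Params {
  mat convW, convWl, We, pos, Wc;
  vec convB, be, cls, lnfg, lnfb, bc;
  std::vector<Layer> layers;
};

// Kind tags: 0 = weight matrix/vector, 1 = layernorm gain, 2 = bias.
template <typename F>
void traverse(Params& P, const IATCfg& c, F& f) {
  P.layers.resize(c.nlayer);
  f.m(P.convW, c.Cw, c.K, 0); f.m(P.convWl, c.Cl, c.K2, 0);
  f.v(P.convB, c.C, 2);
  f.m(P.We, c.D, c.S * c.C, 0); f.v(P.be, c.D, 2);
  f.m(P.pos, c.T, c.D, 0); f.v(P.cls, c.D, 0);
  for (int l = 0; l < c.nlayer; ++l) {
    Layer& ly = P.layers[l];
    f.v(ly.ln1g, c.D, 1); f.v(ly.ln1b, c.D, 2);
    f.m(ly.Wq, c.D, c.D, 0); f.v(ly.bq, c.D, 2);
    f.m(ly.Wk, c.D, c.D, 0); f.v(ly.bk, c.D, 2);
    f.m(ly.Wv, c.D, c.D, 0); f.v(ly.bv, c.D, 2);
    f.m(ly.Wo, c.D, c.D, 0); f.v(ly.bo, c.D, 2);
    f.v(ly.ln2g, c.D, 1); f.v(ly.ln2b, c.D, 2);
    f.m(ly.W1, c.M, c.D, 0); f.v(ly.b1, c.M, 2);
    f.m(ly.W2, c.D, c.M, 0); f.v(ly.b2, c.D, 2);
  }
  f.v(P.lnfg, c.D, 1); f.v(P.lnfb, c.D, 2);
  f.m(P.Wc, c.ncls, c.D, 0); f.v(P.bc, c.ncls, 2);
}

struct Counter {
  size_t o = 0;
  void m(mat&, int r, int c2, int) { o += (size_t)r * c2; }
  void v(vec&, int n, int) { o += n; }
};

struct Reader {
  const double* p; size_t o = 0;
  void m(mat& x, int r, int c2, int) { x = mat(p + o, r, c2); o += (size_t)r * c2; }
  void v(vec& x, int n, int) { x = vec(p + o, n); o += n; }
};

struct WriterOut {
  double* p; size_t o = 0;
  void m(mat& x, int r, int c2, int) {
    std::memcpy(p + o, x.memptr(), sizeof(double) * (size_t)r * c2);
    o += (size_t)r * c2;
  }
  void v(vec& x, int n, int) {
    std::memcpy(p + o, x.memptr(), sizeof(double) * n);
    o += n;
  }
};

struct Zeroer {
  void m(mat& x, int r, int c2, int) { x.zeros(r, c2); }
  void v(vec& x, int n, int) { x.zeros(n); }
};

size_t n_params(const IATCfg& c) {
  Params P;
  Counter cnt;
  traverse(P, const_cast<IATCfg&>(c), cnt);
  return cnt.o;
}

Params unpack(const double* p, const IATCfg& c, size_t expect) {
  Params P;
  Reader rd{p};
  traverse(P, c, rd);
  if (rd.o != expect) Rcpp::stop("parameter vector has wrong length");
  return P;
}

// splitmix64 counter RNG: deterministic dropout masks and initialization
struct RNG {
  uint64_t s;
  bool have_spare = false;
  double spare = 0;
  explicit RNG(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {  // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = std::max(unif(), 1e-300), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct Initializer {
  RNG rng;
  double wsd;
  explicit Initializer(uint64_t seed, double sd) : rng(seed), wsd(sd) {}
  void m(mat& x, int r, int c2, int kind) { fill(x, r, c2, kind); }
  void v(vec& x, int n, int kind) {
    x.set_size(n);
    mat tmp(x.memptr(), n, 1, false, true);
    fill2(tmp, kind);
  }
  void fill(mat& x, int r, int c2, int kind) { x.set_size(r, c2); fill2(x, kind); }
  void fill2(mat& x, int kind) {
    if (kind == 1) x.fill(1.0);
    else if (kind == 2) x.fill(0.0);
    else for (uword i = 0; i < x.n_elem; ++i) x(i) = wsd * rng.gauss();
  }
};

mat dropout_mask(int r, int cc2, double p, RNG* rng) {
  mat m(r, cc2);
  double q = 1.0 - p;
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (rng->unif() < q) ? 1.0 / q : 0.0;
  return m;
}

const double LN_EPS = 1e-5;

void ln_forward(const mat& X, const vec& g, const vec& b,
                mat& Xn, vec& mu, vec& istd) {
  int n = X.n_rows;
  Xn.set_size(n, X.n_cols);
  mu.set_size(n); istd.set_size(n);
  for (int i = 0; i < n; ++i) {
    rowvec x = X.row(i);
    double m = mean(x);
    double v = mean(square(x - m));
    double is = 1.0 / std::sqrt(v + LN_EPS);
    mu(i) = m; istd(i) = is;
    Xn.row(i) = ((x - m) * is) % g.t() + b.t();
  }
}

mat ln_backward(const mat& X, const vec& g, const mat& dY,
                const vec& mu, const vec& istd, vec& dg, vec& db) {
  mat dX(X.n_rows, X.n_cols);
  for (uword i = 0; i < X.n_rows; ++i) {
    rowvec xhat = (X.row(i) - mu(i)) * istd(i);
    rowvec dy = dY.row(i);
    dg += (dy % xhat).t();
    db += dy.t();
    rowvec dxh = dy % g.t();
    double m1 = mean(dxh);
    double m2 = mean(dxh % xhat);
    dX.row(i) = istd(i) * (dxh - m1 - xhat * m2);
  }
  return dX;
}

inline double gelu(double x) { return 0.5 * x * (1.0 + std::erf(x / 1.4142135623730951)); }
inline double dgelu(double x) {
  return 0.5 * (1.0 + std::erf(x / 1.4142135623730951)) +
    x * std::exp(-0.5 * x * x) * 0.3989422804014327;
}

struct LayerCache {
  mat Xin, Xn1, Q, K, V, O, att, drop1, Xmid, Xn2, H1, G, F, drop2;
  vec mu1, is1, mu2, is2;
  std::vector<mat> A, Amask;  // pre-dropout attention + dropout masks
};

struct WinCache {
  mat Xim, Xim2, conv_pre, conv_out, Eflat, X0, Xf_pre, Xnf;
  vec muf, isf, logits, probs;
  std::vector<LayerCache> layers;
};

void softmax_vec(vec& v) {
  v -= v.max();
  v = exp(v);
  v /= accu(v);
}

// Token embedding: conv over the raw window, per-slice flatten, linear
// projection, positional encoding, CLS prepended.
// im2col: row t holds the kernel-sized neighbourhood of sample t
static void im2col(const double* x, int L, int K, mat& out) {
  int pad = K / 2;
  out.zeros(L, K);
  for (int k = 0; k < K; ++k) {
    int lo = std::max(0, pad - k), hi = std::min(L, L + pad - k);
    for (int t = lo; t < hi; ++t) out(t, k) = x[t + k - pad];
  }
}

// Two-scale convolution: wide channels capture beat-to-beat (rhythm)
// context across about half a second, narrow channels keep waveform
// morphology local to the deflection it belongs to.
void tokenize_core(const Params& P, const IATCfg& c, const double* x, WinCache& W) {
  im2col(x, c.L, c.K, W.Xim);
  im2col(x, c.L, c.K2, W.Xim2);
  W.conv_pre = join_rows(W.Xim * P.convW.t(), W.Xim2 * P.convWl.t());
  W.conv_pre.each_row() += P.convB.t();
  W.conv_out = clamp(W.conv_pre, 0.0, datum::inf);
  W.Eflat.set_size(c.T, c.S * c.C);
  for (int t = 0; t < c.T; ++t)
    for (int ch = 0; ch < c.C; ++ch)
      for (int s = 0; s < c.S; ++s)
        W.Eflat(t, ch * c.S + s) = W.conv_out(t * c.S + s, ch);
  mat tok = W.Eflat * P.We.t();
  tok.each_row() += P.be.t();
  tok += P.pos;
  W.X0.set_size(c.T1, c.D);
  W.X0.row(0) = P.cls.t();
  W.X0.rows(1, c.T) = tok;
}

// Encoder + classification head from a prepared token matrix X0.
void encode_core(const Params& P, const IATCfg& c, WinCache& W, RNG* rng) {
  double scale = 1.0 / std::sqrt((double)c.dh);
  mat X = W.X0;
  W.layers.clear();
  W.layers.resize(c.nlayer);
  for (int l = 0; l < c.nlayer; ++l) {
    LayerCache& L = W.layers[l];
    const Layer& ly = P.layers[l];
    L.Xin = X;
    ln_forward(X, ly.ln1g, ly.ln1b, L.Xn1, L.mu1, L.is1);
    L.Q = L.Xn1 * ly.Wq.t(); L.Q.each_row() += ly.bq.t();
    L.K = L.Xn1 * ly.Wk.t(); L.K.each_row() += ly.bk.t();
    L.V = L.Xn1 * ly.Wv.t(); L.V.each_row() += ly.bv.t();
    L.O.set_size(c.T1, c.D);
    L.A.assign(c.H, mat());
    L.Amask.assign(c.H, mat());
    for (int h = 0; h < c.H; ++h) {
      span cs(h * c.dh, (h + 1) * c.dh - 1);
      mat Sc = L.Q.cols(cs) * L.K.cols(cs).t() * scale;
      for (uword i = 0; i < Sc.n_rows; ++i) {
        rowvec r = Sc.row(i);
        r -= r.max();
        r = exp(r);
        Sc.row(i) = r / accu(r);
      }
      L.A[h] = Sc;
      if (rng && c.adrop && c.pdrop > 0) {
        // optional dropout on the attention probabilities (spreads
        // attention mass across redundant tokens)
        L.Amask[h] = dropout_mask(c.T1, c.T1, c.pdrop, rng);
        Sc %= L.Amask[h];
      }
      L.O.cols(cs) = Sc * L.V.cols(cs);
    }
    L.att = L.O * ly.Wo.t(); L.att.each_row() += ly.bo.t();
    if (rng && c.pdrop > 0) {
      L.drop1 = dropout_mask(c.T1, c.D, c.pdrop, rng);
      L.att %= L.drop1;
    } else L.drop1.reset();
    L.Xmid = X + L.att;
    ln_forward(L.Xmid, ly.ln2g, ly.ln2b, L.Xn2, L.mu2, L.is2);
    L.H1 = L.Xn2 * ly.W1.t(); L.H1.each_row() += ly.b1.t();
    L.G.set_size(c.T1, c.M);
    for (uword j = 0; j < L.G.n_cols; ++j)
      for (uword i = 0; i < L.G.n_rows; ++i)
        L.G(i, j) = gelu(L.H1(i, j));
    L.F = L.G * ly.W2.t(); L.F.each_row() += ly.b2.t();
    if (rng && c.pdrop > 0) {
      L.drop2 = dropout_mask(c.T1, c.D, c.pdrop, rng);
      L.F %= L.drop2;
    } else L.drop2.reset();
    X = L.Xmid + L.F;
  }
  W.Xf_pre = X;
  ln_forward(X, P.lnfg, P.lnfb, W.Xnf, W.muf, W.isf);
  W.logits = P.Wc * W.Xnf.row(0).t() + P.bc;
  W.probs = W.logits;
  softmax_vec(W.probs);
}

void forward_core(const Params& P, const IATCfg& c, const double* x,
                  WinCache& W, RNG* rng) {
  tokenize_core(P, c, x, W);
  encode_core(P, c, W, rng);
}

// Backward through one window, accumulating into G.
void backward_core(const Params& P, Params& G, const IATCfg& c,
                   const double* x, const WinCache& W, const vec& dlogits) {
  double scale = 1.0 / std::sqrt((double)c.dh);
  G.Wc += dlogits * W.Xnf.row(0);
  G.bc += dlogits;
  mat dXnf(c.T1, c.D, fill::zeros);
  dXnf.row(0) = (P.Wc.t() * dlogits).t();
  mat dX = ln_backward(W.Xf_pre, P.lnfg, dXnf, W.muf, W.isf, G.lnfg, G.lnfb);
  for (int l = c.nlayer - 1; l >= 0; --l) {
    const LayerCache& L = W.layers[l];
    const Layer& ly = P.layers[l];
    Layer& gl = G.layers[l];
    mat dF = dX;
    if (L.drop2.n_elem) dF %= L.drop2;
    gl.W2 += dF.t() * L.G;
    gl.b2 += sum(dF, 0).t();
    mat dG = dF * ly.W2;
    mat dH1(c.T1, c.M);
    for (uword j = 0; j < dH1.n_cols; ++j)
      for (uword i = 0; i < dH1.n_rows; ++i)
        dH1(i, j) = dG(i, j) * dgelu(L.H1(i, j));
    gl.W1 += dH1.t() * L.Xn2;
    gl.b1 += sum(dH1, 0).t();
    mat dXn2 = dH1 * ly.W1;
    mat dXmid = dX + ln_backward(L.Xmid, ly.ln2g, dXn2, L.mu2, L.is2,
                                 gl.ln2g, gl.ln2b);
    mat datt = dXmid;
    if (L.drop1.n_elem) datt %= L.drop1;
    gl.Wo += datt.t() * L.O;
    gl.bo += sum(datt, 0).t();
    mat dO = datt * ly.Wo;
    mat dQ(c.T1, c.D, fill::zeros), dK(c.T1, c.D, fill::zeros), dV(c.T1, c.D, fill::zeros);
    for (int h = 0; h < c.H; ++h) {
      span cs(h * c.dh, (h + 1) * c.dh - 1);
      const mat& A = L.A[h];
      mat dOh = dO.cols(cs);
      mat dA = dOh * L.V.cols(cs).t();
      if (L.Amask[h].n_elem) {
        dV.cols(cs) = (A % L.Amask[h]).t() * dOh;
        dA %= L.Amask[h];
      } else {
        dV.cols(cs) = A.t() * dOh;
      }
      vec rs = sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rs);
      dQ.cols(cs) = dS * L.K.cols(cs) * scale;
      dK.cols(cs) = dS.t() * L.Q.cols(cs) * scale;
    }
    gl.Wq += dQ.t() * L.Xn1; gl.bq += sum(dQ, 0).t();
    gl.Wk += dK.t() * L.Xn1; gl.bk += sum(dK, 0).t();
    gl.Wv += dV.t() * L.Xn1; gl.bv += sum(dV, 0).t();
    mat dXn1 = dQ * ly.Wq + dK * ly.Wk + dV * ly.Wv;
    dX = dXmid + ln_backward(L.Xin, ly.ln1g, dXn1, L.mu1, L.is1,
                             gl.ln1g, gl.ln1b);
  }
  G.cls += dX.row(0).t();
  mat dtok = dX.rows(1, c.T);
  G.pos += dtok;
  G.We += dtok.t() * W.Eflat;
  G.be += sum(dtok, 0).t();
  mat dEflat = dtok * P.We;
  mat dconv(c.L, c.C, fill::zeros);
  for (int t = 0; t < c.T; ++t)
    for (int ch = 0; ch < c.C; ++ch)
      for (int s = 0; s < c.S; ++s)
        dconv(t * c.S + s, ch) = dEflat(t, ch * c.S + s);
  dconv %= conv_to<mat>::from(W.conv_pre > 0);
  G.convB += sum(dconv, 0).t();
  G.convW += dconv.cols(0, c.Cw - 1).t() * W.Xim;
  G.convWl += dconv.cols(c.Cw, c.C - 1).t() * W.Xim2;
}

}  // namespace

// [[Rcpp::export]]
int cpp_iat_nparams(Rcpp::List cfg, int input_len) {
  return (int)n_params(make_cfg(cfg, input_len));
}

// Deterministic parameter initialization: weights N(0, sd^2), biases 0,
// layer-norm gains 1.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_iat_init(Rcpp::List cfg, int input_len, int seed,
                                 double sd = 0.02) {
  IATCfg c = make_cfg(cfg, input_len);
  Params P;
  Initializer init((uint64_t)seed * 747796405ULL + 1ULL, sd);
  traverse(P, c, init);
  Rcpp::NumericVector out((int)n_params(c));
  WriterOut wr{REAL(out)};
  traverse(P, c, wr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_iat_forward(Rcpp::NumericVector params, Rcpp::List cfg,
                           Rcpp::NumericMatrix X, bool want_attention = false,
                           bool want_tokens = false, bool want_reps = false) {
  IATCfg c = make_cfg(cfg, X.ncol());
  Params P = unpack(REAL(params), c, params.size());
  int n = X.nrow();
  mat probs(n, c.ncls);
  Rcpp::List attn(want_attention ? n : 0);
  Rcpp::List toks(want_tokens ? n : 0);
  Rcpp::List reps(want_reps ? n : 0);
  std::vector<double> buf(c.L);
  WinCache W;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < c.L; ++j) buf[j] = X(i, j);
    forward_core(P, c, buf.data(), W, nullptr);
    probs.row(i) = W.probs.t();
    if (want_attention) {
      cube A(c.T1, c.T1, c.nlayer * c.H);
      for (int l = 0; l < c.nlayer; ++l)
        for (int h = 0; h < c.H; ++h)
          A.slice(l * c.H + h) = W.layers[l].A[h];
      attn[i] = A;
    }
    if (want_tokens) toks[i] = W.X0;
    if (want_reps) reps[i] = W.Xnf;
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("attention") = attn,
                            Rcpp::Named("tokens") = toks,
                            Rcpp::Named("reps") = reps);
}

// Encoder applied to an explicit token matrix (T1 x D); used to test
// structural properties such as permutation equivariance.
// [[Rcpp::export]]
Rcpp::List cpp_iat_encode(Rcpp::NumericVector params, Rcpp::List cfg,
                          Rcpp::NumericMatrix tokens, int input_len) {
  IATCfg c = make_cfg(cfg, input_len);
  if ((int)tokens.nrow() != c.T1 || (int)tokens.ncol() != c.D)
    Rcpp::stop("token matrix must be (T+1) x embed_dim");
  Params P = unpack(REAL(params), c, params.size());
  WinCache W;
  W.X0 = mat(REAL(tokens), c.T1, c.D);
  encode_core(P, c, W, nullptr);
  cube A(c.T1, c.T1, c.nlayer * c.H);
  for (int l = 0; l < c.nlayer; ++l)
    for (int h = 0; h < c.H; ++h)
      A.slice(l * c.H + h) = W.layers[l].A[h];
  return Rcpp::List::create(Rcpp::Named("reps") = W.Xnf,
                            Rcpp::Named("attention") = A,
                            Rcpp::Named("probs") = W.probs);
}

// Mean cross-entropy and its gradient over a batch. dropout_seed <= 0
// disables dropout (evaluation-mode gradients, used for gradient checks).
// [[Rcpp::export]]
Rcpp::List cpp_iat_grad(Rcpp::NumericVector params, Rcpp::List cfg,
                        Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                        double dropout_seed = 0) {
  IATCfg c = make_cfg(cfg, X.ncol());
  Params P = unpack(REAL(params), c, params.size());
  int n = X.nrow();
  if ((int)y.size() != n) Rcpp::stop("y length must match rows of X");
  Params G;
  Zeroer z;
  traverse(G, c, z);
  std::vector<double> buf(c.L);
  double loss = 0;
  WinCache W;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < c.L; ++j) buf[j] = X(i, j);
    RNG rng((uint64_t)(dropout_seed) * 2654435761ULL + 17ULL * (i + 1));
    RNG* rp = (dropout_seed > 0 && c.pdrop > 0) ? &rng : nullptr;
    forward_core(P, c, buf.data(), W, rp);
    int yi = y[i];
    if (yi < 0 || yi >= c.ncls) Rcpp::stop("label out of range");
    loss += -std::log(std::max(W.probs(yi), 1e-12));
    vec dlogits = W.probs;
    dlogits(yi) -= 1.0;
    dlogits /= (double)n;
    backward_core(P, G, c, buf.data(), W, dlogits);
  }
  Rcpp::NumericVector grad((int)n_params(c));
  WriterOut wr{REAL(grad)};
  traverse(G, c, wr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = grad);
}
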