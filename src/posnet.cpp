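// Wear-position network core: per-frame fully connected embedding, 1-D
// convolution over the frame sequence, GRU summarization, a 3-class
// orientation head, and a discriminator that scores the summary against the
// encoded standard-position reference. Includes the analytic backward pass
// (classification cross-entropy + adversarial discriminator loss).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct PosCfg {
  int L, fr, T, fc, cc, k, gh, dh, ncls;
};

PosCfg make_cfg(const Rcpp::List& cfg, int input_len) {
  PosCfg c;
  c.L = input_len;
  c.fr = Rcpp::as<int>(cfg["frame_len"]);
  c.fc = Rcpp::as<int>(cfg["fc_dim"]);
  c.cc = Rcpp::as<int>(cfg["conv_channels"]);
  c.k = Rcpp::as<int>(cfg["conv_kernel"]);
  c.gh = Rcpp::as<int>(cfg["gru_hidden"]);
  c.dh = Rcpp::as<int>(cfg["disc_hidden"]);
  c.ncls = 3;
  if (c.fr <= 0 || c.L < c.fr) Rcpp::stop("window shorter than one frame");
  if (c.k % 2 == 0) Rcpp::stop("conv_kernel must be odd");
  c.T = c.L / c.fr;
  return c;
}

struct Params {
  mat Wf, Wcv, Wz, Uz, Wr, Ur, Wn, Un, Wcls, Wd1;
  vec bf, bcv, bz, br, bn, bcls, bd1, wd2;
  double bd2;
};

template <typename F>
void traverse(Params& P, const PosCfg& c, F& f) {
  f.m(P.Wf, c.fc, c.fr, 0); f.v(P.bf, c.fc, 2);
  f.m(P.Wcv, c.cc, c.fc * c.k, 0); f.v(P.bcv, c.cc, 2);
  f.m(P.Wz, c.gh, c.cc, 0); f.m(P.Uz, c.gh, c.gh, 0); f.v(P.bz, c.gh, 2);
  f.m(P.Wr, c.gh, c.cc, 0); f.m(P.Ur, c.gh, c.gh, 0); f.v(P.br, c.gh, 2);
  f.m(P.Wn, c.gh, c.cc, 0); f.m(P.Un, c.gh, c.gh, 0); f.v(P.bn, c.gh, 2);
  f.m(P.Wcls, c.ncls, c.gh, 0); f.v(P.bcls, c.ncls, 2);
  f.m(P.Wd1, c.dh, 2 * c.gh, 0); f.v(P.bd1, c.dh, 2);
  f.v(P.wd2, c.dh, 0); f.s(P.bd2);
}

struct Counter {
  size_t o = 0;
  void m(mat&, int r, int c2, int) { o += (size_t)r * c2; }
  void v(vec&, int n, int) { o += n; }
  void s(double&) { o += 1; }
};
struct Reader {
  const double* p; size_t o = 0;
  void m(mat& x, int r, int c2, int) { x = mat(p + o, r, c2); o += (size_t)r * c2; }
  void v(vec& x, int n, int) { x = vec(p + o, n); o += n; }
  void s(double& x) { x = p[o]; o += 1; }
};
struct WriterOut {
  double* p; size_t o = 0;
  void m(mat& x, int r, int c2, int) {
    std::memcpy(p + o, x.memptr(), sizeof(double) * (size_t)r * c2);
    o += (size_t)r * c2;
  }
  void v(vec& x, int n, int) {
    std::memcpy(p + o, x.memptr(), sizeof(double) * n); o += n;
  }
  void s(double& x) { p[o] = x; o += 1; }
};
struct Zeroer {
  void m(mat& x, int r, int c2, int) { x.zeros(r, c2); }
  void v(vec& x, int n, int) { x.zeros(n); }
  void s(double& x) { x = 0; }
};

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
  double gauss() {
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
  void m(mat& x, int r, int c2, int kind) {
    x.set_size(r, c2);
    if (kind == 2) x.zeros();
    else for (uword i = 0; i < x.n_elem; ++i) x(i) = wsd * rng.gauss();
  }
  void v(vec& x, int n, int kind) {
    x.set_size(n);
    if (kind == 2) x.zeros();
    else for (int i = 0; i < n; ++i) x(i) = wsd * rng.gauss();
  }
  void s(double& x) { x = 0; }
};

size_t n_params(const PosCfg& c) {
  Params P; Counter cnt; traverse(P, c, cnt); return cnt.o;
}

Params unpack(const double* p, const PosCfg& c, size_t expect) {
  Params P; Reader rd{p}; traverse(P, c, rd);
  if (rd.o != expect) Rcpp::stop("parameter vector has wrong length");
  return P;
}

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  mat Fm;        // T x fr raw frames
  mat Epre, E;   // T x fc
  mat Z;         // T x fc*k im2col
  mat Cpre, Cv;  // T x cc
  mat Hs;        // (T+1) x gh hidden states, row 0 = h0 = 0
  mat Zg, Rg, Ng, UnH;  // T x gh gate caches
  vec h;         // summary
  vec cls_probs;
  vec u, d1pre, d1;
  double score;
};

void forward_one(const Params& P, const PosCfg& c, const double* x,
                 const vec& ref, Cache& K) {
  K.Fm.set_size(c.T, c.fr);
  for (int t = 0; t < c.T; ++t)
    for (int j = 0; j < c.fr; ++j)
      K.Fm(t, j) = x[t * c.fr + j];
  K.Epre = K.Fm * P.Wf.t();
  K.Epre.each_row() += P.bf.t();
  K.E = clamp(K.Epre, 0.0, datum::inf);
  int pad = c.k / 2;
  K.Z.zeros(c.T, c.fc * c.k);
  for (int t = 0; t < c.T; ++t)
    for (int kk = 0; kk < c.k; ++kk) {
      int ti = t + kk - pad;
      if (ti >= 0 && ti < c.T)
        for (int ch = 0; ch < c.fc; ++ch)
          K.Z(t, kk * c.fc + ch) = K.E(ti, ch);
    }
  K.Cpre = K.Z * P.Wcv.t();
  K.Cpre.each_row() += P.bcv.t();
  K.Cv = clamp(K.Cpre, 0.0, datum::inf);
  K.Hs.zeros(c.T + 1, c.gh);
  K.Zg.set_size(c.T, c.gh); K.Rg.set_size(c.T, c.gh);
  K.Ng.set_size(c.T, c.gh); K.UnH.set_size(c.T, c.gh);
  vec h(c.gh, fill::zeros);
  for (int t = 0; t < c.T; ++t) {
    vec xt = K.Cv.row(t).t();
    vec z = sigmoid(P.Wz * xt + P.Uz * h + P.bz);
    vec r = sigmoid(P.Wr * xt + P.Ur * h + P.br);
    vec unh = P.Un * h;
    vec nn = tanh(P.Wn * xt + r % unh + P.bn);
    h = (1.0 - z) % nn + z % h;
    K.Zg.row(t) = z.t(); K.Rg.row(t) = r.t();
    K.Ng.row(t) = nn.t(); K.UnH.row(t) = unh.t();
    K.Hs.row(t + 1) = h.t();
  }
  K.h = h;
  vec logits = P.Wcls * h + P.bcls;
  logits -= logits.max();
  logits = exp(logits);
  K.cls_probs = logits / accu(logits);
  K.u = join_cols(h, h - ref);
  K.d1pre = P.Wd1 * K.u + P.bd1;
  K.d1 = clamp(K.d1pre, 0.0, datum::inf);
  K.score = 1.0 / (1.0 + std::exp(-(dot(P.wd2, K.d1) + P.bd2)));
}

// Backward from classification gradient dlogits and discriminator
// pre-sigmoid gradient dsc; accumulates into G.
void backward_one(const Params& P, Params& G, const PosCfg& c,
                  const Cache& K, const vec& dlogits, double dsc) {
  G.Wcls += dlogits * K.h.t();
  G.bcls += dlogits;
  vec dh = P.Wcls.t() * dlogits;
  if (dsc != 0) {
    G.wd2 += dsc * K.d1;
    G.bd2 += dsc;
    vec dd1 = dsc * P.wd2;
    for (int i = 0; i < c.dh; ++i) if (K.d1pre(i) <= 0) dd1(i) = 0;
    G.Wd1 += dd1 * K.u.t();
    G.bd1 += dd1;
    vec du = P.Wd1.t() * dd1;
    dh += du.head(c.gh) + du.tail(c.gh);
  }
  mat dCv(c.T, c.cc, fill::zeros);
  for (int t = c.T - 1; t >= 0; --t) {
    vec z = K.Zg.row(t).t(), r = K.Rg.row(t).t(), nn = K.Ng.row(t).t();
    vec unh = K.UnH.row(t).t();
    vec hprev = K.Hs.row(t).t();
    vec xt = K.Cv.row(t).t();
    vec dz = dh % (hprev - nn);
    vec dnn = dh % (1.0 - z);
    vec dhprev = dh % z;
    vec da = dnn % (1.0 - nn % nn);
    G.Wn += da * xt.t(); G.bn += da;
    vec dxt = P.Wn.t() * da;
    vec dr = da % unh;
    vec dunh = da % r;
    G.Un += dunh * hprev.t();
    dhprev += P.Un.t() * dunh;
    vec daz = dz % z % (1.0 - z);
    G.Wz += daz * xt.t(); G.Uz += daz * hprev.t(); G.bz += daz;
    dxt += P.Wz.t() * daz; dhprev += P.Uz.t() * daz;
    vec dar = dr % r % (1.0 - r);
    G.Wr += dar * xt.t(); G.Ur += dar * hprev.t(); G.br += dar;
    dxt += P.Wr.t() * dar; dhprev += P.Ur.t() * dar;
    dCv.row(t) = dxt.t();
    dh = dhprev;
  }
  mat dCpre = dCv % conv_to<mat>::from(K.Cpre > 0);
  G.Wcv += dCpre.t() * K.Z;
  G.bcv += sum(dCpre, 0).t();
  mat dZ = dCpre * P.Wcv;
  mat dE(c.T, c.fc, fill::zeros);
  int pad = c.k / 2;
  for (int t = 0; t < c.T; ++t)
    for (int kk = 0; kk < c.k; ++kk) {
      int ti = t + kk - pad;
      if (ti >= 0 && ti < c.T)
        for (int ch = 0; ch < c.fc; ++ch)
          dE(ti, ch) += dZ(t, kk * c.fc + ch);
    }
  mat dEpre = dE % conv_to<mat>::from(K.Epre > 0);
  G.Wf += dEpre.t() * K.Fm;
  G.bf += sum(dEpre, 0).t();
}

}  // namespace

// [[Rcpp::export]]
int cpp_pos_nparams(Rcpp::List cfg, int input_len) {
  return (int)n_params(make_cfg(cfg, input_len));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_pos_init(Rcpp::List cfg, int input_len, int seed,
                                 double sd = 0.05) {
  PosCfg c = make_cfg(cfg, input_len);
  Params P;
  Initializer init((uint64_t)seed * 747796405ULL + 3ULL, sd);
  traverse(P, c, init);
  Rcpp::NumericVector out((int)n_params(c));
  WriterOut wr{REAL(out)};
  traverse(P, c, wr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_pos_forward(Rcpp::NumericVector params, Rcpp::List cfg,
                           Rcpp::NumericMatrix X, Rcpp::NumericVector ref,
                           bool want_intermediate = false) {
  PosCfg c = make_cfg(cfg, X.ncol());
  Params P = unpack(REAL(params), c, params.size());
  vec refv(REAL(ref), ref.size());
  if ((int)refv.n_elem != c.gh) Rcpp::stop("reference must have gru_hidden length");
  int n = X.nrow();
  mat probs(n, c.ncls), summaries(n, c.gh);
  vec scores(n);
  Rcpp::List inter(want_intermediate ? n : 0);
  std::vector<double> buf(c.L);
  Cache K;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < c.L; ++j) buf[j] = X(i, j);
    forward_one(P, c, buf.data(), refv, K);
    probs.row(i) = K.cls_probs.t();
    summaries.row(i) = K.h.t();
    scores(i) = K.score;
    if (want_intermediate) {
      inter[i] = Rcpp::List::create(Rcpp::Named("embedding") = K.E,
                                    Rcpp::Named("conv") = K.Cv,
                                    Rcpp::Named("hidden") = K.Hs);
    }
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("summaries") = summaries,
                            Rcpp::Named("scores") = scores,
                            Rcpp::Named("intermediate") = inter);
}

// Joint objective: orientation cross-entropy plus lambda * discriminator
// binary cross-entropy (real = standard position O0, label 0).
// [[Rcpp::export]]
Rcpp::List cpp_pos_grad(Rcpp::NumericVector params, Rcpp::List cfg,
                        Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                        Rcpp::NumericVector ref, double lambda = 1.0) {
  PosCfg c = make_cfg(cfg, X.ncol());
  Params P = unpack(REAL(params), c, params.size());
  vec refv(REAL(ref), ref.size());
  int n = X.nrow();
  if ((int)y.size() != n) Rcpp::stop("y length must match rows of X");
  Params G; Zeroer z; traverse(G, c, z);
  std::vector<double> buf(c.L);
  double loss = 0;
  vec o0_sum(c.gh, fill::zeros);
  int n_o0 = 0;
  Cache K;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < c.L; ++j) buf[j] = X(i, j);
    forward_one(P, c, buf.data(), refv, K);
    int yi = y[i];
    if (yi < 0 || yi >= c.ncls) Rcpp::stop("label out of range");
    double target = (yi == 0) ? 1.0 : 0.0;
    loss += -std::log(std::max(K.cls_probs(yi), 1e-12));
    loss += -lambda * (target * std::log(std::max(K.score, 1e-12)) +
                       (1.0 - target) * std::log(std::max(1.0 - K.score, 1e-12)));
    vec dlogits = K.cls_probs;
    dlogits(yi) -= 1.0;
    dlogits /= (double)n;
    double dsc = lambda * (K.score - target) / (double)n;
    backward_one(P, G, c, K, dlogits, dsc);
    if (yi == 0) { o0_sum += K.h; ++n_o0; }
  }
  Rcpp::NumericVector grad((int)n_params(c));
  WriterOut wr{REAL(grad)};
  traverse(G, c, wr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("o0_sum") = o0_sum,
                            Rcpp::Named("n_o0") = n_o0);
}
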