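// Compiled forward/backward engine for the dual-channel reasoning network.
//
// One call processes a single query (head, relation) on one graph: the
// query-conditioned initialization, the base local-only GNN layers, the
// stacked dual-channel layers (kernelized linear global attention in
// parallel with attentive relational message passing, fused per node by an
// attention softmax over the self/global/local branches), the relation
// updates between layers, the MLP triple scorer, and — for training — the
// negative-sampling loss with hand-derived reverse-mode gradients for every
// parameter block.  The block order of the flat parameter vector matches
// R/params.R exactly.
//
// All indices arriving from R are 0-based.  Single-threaded, no RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;
using arma::uword;

namespace {

struct Cfg {
  int d, k, L, n_base, fusion, m_aug;
  bool normalize, ablate_global, ablate_local, layer_independent;
  double slope;
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.d = as<int>(cfg["d"]);
  c.k = as<int>(cfg["k"]);
  c.L = as<int>(cfg["L"]);
  c.n_base = as<int>(cfg["n_base"]);
  c.fusion = as<int>(cfg["fusion"]);   // 0 attention, 1 sum, 2 concat
  c.m_aug = as<int>(cfg["m_aug"]);
  c.normalize = as<bool>(cfg["normalize"]);
  c.ablate_global = as<bool>(cfg["ablate_global"]);
  c.ablate_local = as<bool>(cfg["ablate_local"]);
  c.layer_independent = as<bool>(cfg["layer_independent"]);
  c.slope = as<double>(cfg["slope"]);
  if (c.d % c.k != 0) stop("embedding width not divisible by head count");
  return c;
}

struct LayerP {
  mat Wq, Wk, Wv, Wm, Wphi;
  vec a, w;
  mat rel;   // Wrel (d x d) or free relation table (m_aug x d)
  mat Wc;    // concat fusion projection, 3d x d (empty otherwise)
};

struct Params {
  mat rel0;
  std::vector<LayerP> layers;
  mat W1;        // 3d x 64
  vec b1, w2;    // 64
  double b2;
};

const int HID = 64;

struct Reader {
  const double* p;
  uword off = 0;
  explicit Reader(const NumericVector& v) : p(v.begin()) {}
  mat get(uword r, uword c) {
    mat m(p + off, r, c);  // copies
    off += r * c;
    return m;
  }
  vec getv(uword n) {
    vec v(p + off, n);
    off += n;
    return v;
  }
};

Params unpack(const NumericVector& par, const Cfg& c) {
  Params P;
  Reader rd(par);
  uword d = c.d, m = c.m_aug;
  P.rel0 = rd.get(m, d);
  P.layers.resize(c.L);
  for (int l = 0; l < c.L; ++l) {
    LayerP& lp = P.layers[l];
    lp.Wq = rd.get(d, d); lp.Wk = rd.get(d, d); lp.Wv = rd.get(d, d);
    lp.Wm = rd.get(d, d); lp.Wphi = rd.get(d, d);
    lp.a = rd.getv(d); lp.w = rd.getv(d);
    lp.rel = c.layer_independent ? rd.get(m, d) : rd.get(d, d);
    if (c.fusion == 2) lp.Wc = rd.get(3 * d, d);
  }
  P.W1 = rd.get(3 * d, HID);
  P.b1 = rd.getv(HID);
  P.w2 = rd.getv(HID);
  P.b2 = rd.getv(1)(0);
  if ((int)rd.off != (int)par.size()) stop("parameter vector length mismatch");
  return P;
}

struct Grads {
  mat rel0;
  std::vector<LayerP> layers;
  mat W1;
  vec b1, w2;
  double b2 = 0.0;
};

Grads zero_grads(const Params& P) {
  Grads G;
  G.rel0 = arma::zeros<mat>(P.rel0.n_rows, P.rel0.n_cols);
  G.layers.resize(P.layers.size());
  for (size_t l = 0; l < P.layers.size(); ++l) {
    const LayerP& s = P.layers[l];
    LayerP& g = G.layers[l];
    g.Wq = arma::zeros<mat>(s.Wq.n_rows, s.Wq.n_cols);
    g.Wk = arma::zeros<mat>(s.Wk.n_rows, s.Wk.n_cols);
    g.Wv = arma::zeros<mat>(s.Wv.n_rows, s.Wv.n_cols);
    g.Wm = arma::zeros<mat>(s.Wm.n_rows, s.Wm.n_cols);
    g.Wphi = arma::zeros<mat>(s.Wphi.n_rows, s.Wphi.n_cols);
    g.a = arma::zeros<vec>(s.a.n_elem);
    g.w = arma::zeros<vec>(s.w.n_elem);
    g.rel = arma::zeros<mat>(s.rel.n_rows, s.rel.n_cols);
    if (s.Wc.n_elem) g.Wc = arma::zeros<mat>(s.Wc.n_rows, s.Wc.n_cols);
  }
  G.W1 = arma::zeros<mat>(P.W1.n_rows, P.W1.n_cols);
  G.b1 = arma::zeros<vec>(P.b1.n_elem);
  G.w2 = arma::zeros<vec>(P.w2.n_elem);
  return G;
}

NumericVector flatten(const Grads& G, const Cfg& c, int total) {
  NumericVector out(total);
  double* p = out.begin();
  uword off = 0;
  auto put = [&](const mat& m) { std::copy(m.begin(), m.end(), p + off); off += m.n_elem; };
  auto putv = [&](const vec& v) { std::copy(v.begin(), v.end(), p + off); off += v.n_elem; };
  put(G.rel0);
  for (size_t l = 0; l < G.layers.size(); ++l) {
    const LayerP& g = G.layers[l];
    put(g.Wq); put(g.Wk); put(g.Wv); put(g.Wm); put(g.Wphi);
    putv(g.a); putv(g.w); put(g.rel);
    if (c.fusion == 2) put(g.Wc);
  }
  put(G.W1); putv(G.b1); putv(G.w2);
  p[off++] = G.b2;
  if ((int)off != total) stop("gradient length mismatch");
  return out;
}

inline mat phi(const mat& x) {
  mat out = x;
  out.for_each([](double& v) { v = (v > 0.0) ? v + 1.0 : std::exp(v); });
  return out;
}

inline mat phi_grad(const mat& x) {
  mat out = x;
  out.for_each([](double& v) { v = (v > 0.0) ? 1.0 : std::exp(v); });
  return out;
}

inline double lrelu(double x, double s) { return x > 0.0 ? x : s * x; }
inline double lrelu_grad(double x, double s) { return x > 0.0 ? 1.0 : s; }

// Per-layer caches required by the backward pass.
struct HeadCache {
  mat Qraw, Kraw, P, S, V, C, Unorm;  // Unorm only when normalized
  vec z, svec;
};

struct LayerCache {
  mat E_in;           // states entering the layer
  mat msum, M;        // local channel
  vec gam_raw, beta;
  mat El;
  std::vector<HeadCache> heads;  // global channel (full layers only)
  mat G, Eg;
  mat T, alpha;       // fusion (attention mode): raw scores, weights
  mat X;              // concat fusion input
  bool is_base = false;
  bool skipped = false;
};

struct Forward {
  std::vector<LayerCache> layers;
  std::vector<mat> Rs;   // Rs[i] = relation states consumed by layer i
  mat E_final;
  const mat* R_final;
};

class Engine {
 public:
  Engine(const IntegerVector& dst, const IntegerVector& rel,
         const IntegerVector& src, int n_entities,
         const NumericVector& par, const Cfg& cfg)
      : c(cfg), n(n_entities), P(unpack(par, cfg)), total_len(par.size()) {
    ne = dst.size();
    edst = arma::conv_to<uvec>::from(as<arma::ivec>(dst));
    erel = arma::conv_to<uvec>::from(as<arma::ivec>(rel));
    esrc = arma::conv_to<uvec>::from(as<arma::ivec>(src));
    // CSR row pointers over destination-sorted edges
    row_ptr.assign(n + 1, 0);
    for (uword e = 0; e < ne; ++e) row_ptr[edst(e) + 1]++;
    for (int i = 0; i < n; ++i) row_ptr[i + 1] += row_ptr[i];
    for (uword e = 1; e < ne; ++e)
      if (edst(e) < edst(e - 1)) stop("message edges must be sorted by destination");
  }

  Forward forward(int head, int qrel) {
    Forward F;
    F.Rs.resize(c.L);
    F.Rs[0] = P.rel0;
    for (int i = 1; i < c.L; ++i) {
      F.Rs[i] = c.layer_independent ? P.layers[i - 1].rel
                                    : mat(F.Rs[i - 1] * P.layers[i - 1].rel);
    }
    mat E = arma::zeros<mat>(n, c.d);
    if (head < 0 || head >= n) stop("query head out of range");
    if (qrel < 0 || qrel >= (int)P.rel0.n_rows) stop("query relation out of range");
    E.row(head) = F.Rs[0].row(qrel);

    F.layers.resize(c.L);
    for (int l = 0; l < c.L; ++l) {
      LayerCache& LC = F.layers[l];
      LC.E_in = E;
      LC.is_base = (l < c.n_base);
      if (LC.is_base && c.ablate_local) {
        // the base GNN is the local channel; with that channel ablated the
        // base stage has nothing to compute and passes states through
        LC.skipped = true;
        continue;
      }
      local_forward(E, F.Rs[l], P.layers[l], LC);
      if (LC.is_base) {
        E = LC.El;
      } else {
        if (!c.ablate_global) global_forward(E, P.layers[l], LC);
        else LC.Eg = arma::zeros<mat>(n, c.d);
        mat El_use = c.ablate_local ? arma::zeros<mat>(n, c.d) : LC.El;
        E = fuse_forward(LC.E_in, LC.Eg, El_use, P.layers[l], LC);
      }
      if (!E.is_finite())
        stop("non-finite node states after layer %d", l + 1);
    }
    F.E_final = E;
    F.R_final = &F.Rs[c.L - 1];
    return F;
  }

  // MLP scores for candidate tails (0-based), all conditioned on (head, qrel)
  vec score(const Forward& F, int head, int qrel, const uvec& tails,
            std::vector<vec>* h1_cache = nullptr,
            std::vector<vec>* x_cache = nullptr) const {
    vec out(tails.n_elem);
    arma::rowvec eh = F.E_final.row(head);
    arma::rowvec rq = F.R_final->row(qrel);
    for (uword i = 0; i < tails.n_elem; ++i) {
      arma::rowvec x(3 * c.d);
      x.cols(0, c.d - 1) = eh;
      x.cols(c.d, 2 * c.d - 1) = rq;
      x.cols(2 * c.d, 3 * c.d - 1) = F.E_final.row(tails(i));
      vec z1 = P.W1.t() * x.t() + P.b1;
      vec h1 = arma::clamp(z1, 0.0, arma::datum::inf);
      double logit = arma::dot(h1, P.w2) + P.b2;
      out(i) = 1.0 / (1.0 + std::exp(-logit));
      if (h1_cache) h1_cache->push_back(h1);
      if (x_cache) x_cache->push_back(x.t());
    }
    return out;
  }

  // Training step: loss and full parameter gradient for one positive with
  // its negatives.  loss = softplus(-z_pos) + mean(softplus(z_neg)), the
  // numerically stable form of -log p+ - mean(log(1 - p-)).
  List step(int head, int qrel, int pos_tail, const uvec& neg_tails) {
    Forward F = forward(head, qrel);
    uvec tails(neg_tails.n_elem + 1);
    tails(0) = pos_tail;
    for (uword i = 0; i < neg_tails.n_elem; ++i) tails(i + 1) = neg_tails(i);
    std::vector<vec> h1s, xs;
    vec p = score(F, head, qrel, tails, &h1s, &xs);

    auto softplus = [](double x) {
      return std::log1p(std::exp(-std::fabs(x))) + std::max(x, 0.0);
    };
    double nneg = (double)neg_tails.n_elem;
    // recover logits from cached h1 (p can saturate)
    vec logits(tails.n_elem);
    for (uword i = 0; i < tails.n_elem; ++i)
      logits(i) = arma::dot(h1s[i], P.w2) + P.b2;
    double loss = softplus(-logits(0));
    for (uword i = 1; i < tails.n_elem; ++i)
      loss += softplus(logits(i)) / nneg;
    if (!std::isfinite(loss)) stop("non-finite loss");

    Grads G = zero_grads(P);
    mat dE = arma::zeros<mat>(n, c.d);
    mat dR_cur = arma::zeros<mat>(c.m_aug, c.d);

    for (uword i = 0; i < tails.n_elem; ++i) {
      double dlogit = (i == 0) ? (p(0) - 1.0) : p(i) / nneg;
      const vec& h1 = h1s[i];
      const vec& x = xs[i];
      vec dh1 = dlogit * P.w2;
      for (int j = 0; j < HID; ++j) if (h1(j) <= 0.0) dh1(j) = 0.0;
      G.w2 += dlogit * h1;
      G.b2 += dlogit;
      G.W1 += x * dh1.t();
      G.b1 += dh1;
      vec dx = P.W1 * dh1;
      dE.row(head) += dx.subvec(0, c.d - 1).t();
      dR_cur.row(qrel) += dx.subvec(c.d, 2 * c.d - 1).t();
      dE.row(tails(i)) += dx.subvec(2 * c.d, 3 * c.d - 1).t();
    }

    for (int l = c.L - 1; l >= 0; --l) {
      if (!F.layers[l].skipped) {
        mat dE_prev = arma::zeros<mat>(n, c.d);
        layer_backward(F.layers[l], P.layers[l], G.layers[l], dE, dE_prev,
                       dR_cur);
        dE = dE_prev;
      }
      if (l > 0) {
        // cross the relation update between layer l-1 and l
        if (c.layer_independent) {
          G.layers[l - 1].rel += dR_cur;
          dR_cur.zeros();
        } else {
          G.layers[l - 1].rel += F.Rs[l - 1].t() * dR_cur;
          dR_cur = dR_cur * P.layers[l - 1].rel.t();
        }
      }
    }
    G.rel0 += dR_cur;
    G.rel0.row(qrel) += dE.row(head);   // query-conditioned initialization

    return List::create(
      _["loss"] = loss,
      _["grad"] = flatten(G, c, total_len),
      _["p_pos"] = p(0),
      _["p_neg"] = NumericVector(p.begin() + 1, p.end()));
  }

  const Cfg c;
  const int n;

 private:
  Params P;
  int total_len;
  uword ne;
  uvec edst, erel, esrc;
  std::vector<uword> row_ptr;

  void local_forward(const mat& E, const mat& R, const LayerP& lp,
                     LayerCache& LC) const {
    LC.El = arma::zeros<mat>(n, c.d);
    if (ne == 0) return;
    LC.msum = E.rows(esrc) + R.rows(erel);
    LC.M = LC.msum * lp.Wphi;
    LC.gam_raw = LC.M * lp.a;
    LC.beta.set_size(ne);
    for (int u = 0; u < n; ++u) {
      uword r0 = row_ptr[u], r1 = row_ptr[u + 1];
      if (r0 == r1) continue;
      double mx = -arma::datum::inf;
      for (uword e = r0; e < r1; ++e)
        mx = std::max(mx, lrelu(LC.gam_raw(e), c.slope));
      double den = 0.0;
      for (uword e = r0; e < r1; ++e) {
        LC.beta(e) = std::exp(lrelu(LC.gam_raw(e), c.slope) - mx);
        den += LC.beta(e);
      }
      for (uword e = r0; e < r1; ++e) {
        LC.beta(e) /= den;
        LC.El.row(u) += LC.beta(e) * LC.M.row(e);
      }
    }
  }

  void global_forward(const mat& E, const LayerP& lp, LayerCache& LC) const {
    int dh = c.d / c.k;
    LC.G.set_size(n, c.d);
    LC.heads.resize(c.k);
    for (int h = 0; h < c.k; ++h) {
      HeadCache& HC = LC.heads[h];
      arma::span sp(h * dh, (h + 1) * dh - 1);
      HC.Qraw = E * lp.Wq.cols(sp);
      HC.Kraw = E * lp.Wk.cols(sp);
      HC.P = phi(HC.Qraw);
      HC.S = phi(HC.Kraw);
      HC.V = E * lp.Wv.cols(sp);
      HC.C = HC.S.t() * HC.V;
      mat U = HC.P * HC.C;
      if (!U.is_finite()) stop("non-finite values in global attention head %d", h + 1);
      if (c.normalize) {
        HC.svec = arma::sum(HC.S, 0).t();
        HC.z = arma::clamp(HC.P * HC.svec, 1e-12, arma::datum::inf);
        U.each_col() /= HC.z;
        HC.Unorm = U;
      }
      LC.G.cols(sp) = U;
    }
    LC.Eg = LC.G * lp.Wm;
  }

  mat fuse_forward(const mat& Es, const mat& Eg, const mat& El,
                   const LayerP& lp, LayerCache& LC) const {
    if (c.fusion == 1) {  // sum
      return Es + Eg + El;
    }
    if (c.fusion == 2) {  // concat
      LC.X.set_size(n, 3 * c.d);
      LC.X.cols(0, c.d - 1) = Es;
      LC.X.cols(c.d, 2 * c.d - 1) = Eg;
      LC.X.cols(2 * c.d, 3 * c.d - 1) = El;
      return LC.X * lp.Wc;
    }
    // attention fusion
    LC.T.set_size(n, 3);
    LC.T.col(0) = Es * lp.w;
    LC.T.col(1) = Eg * lp.w;
    LC.T.col(2) = El * lp.w;
    LC.alpha = arma::zeros<mat>(n, 3);
    bool act[3] = {true, !c.ablate_global, !c.ablate_local};
    mat out(n, c.d);
    for (int i = 0; i < n; ++i) {
      double mx = -arma::datum::inf;
      for (int b = 0; b < 3; ++b)
        if (act[b]) mx = std::max(mx, lrelu(LC.T(i, b), c.slope));
      double den = 0.0;
      for (int b = 0; b < 3; ++b) {
        if (!act[b]) continue;
        LC.alpha(i, b) = std::exp(lrelu(LC.T(i, b), c.slope) - mx);
        den += LC.alpha(i, b);
      }
      for (int b = 0; b < 3; ++b) LC.alpha(i, b) /= den;
      out.row(i) = LC.alpha(i, 0) * Es.row(i) + LC.alpha(i, 1) * Eg.row(i) +
                   LC.alpha(i, 2) * El.row(i);
    }
    return out;
  }

  void local_backward(const LayerCache& LC, const LayerP& lp, LayerP& g,
                      const mat& dEl, mat& dE_prev, mat& dR) const {
    if (ne == 0) return;
    mat dM = arma::zeros<mat>(ne, c.d);
    vec dgam(ne, arma::fill::zeros);
    for (int u = 0; u < n; ++u) {
      uword r0 = row_ptr[u], r1 = row_ptr[u + 1];
      if (r0 == r1) continue;
      double sg = 0.0;
      for (uword e = r0; e < r1; ++e) {
        double db = arma::dot(dEl.row(u), LC.M.row(e));
        dM.row(e) += LC.beta(e) * dEl.row(u);
        dgam(e) = db;
        sg += LC.beta(e) * db;
      }
      for (uword e = r0; e < r1; ++e)
        dgam(e) = LC.beta(e) * (dgam(e) - sg) * lrelu_grad(LC.gam_raw(e), c.slope);
    }
    g.a += LC.M.t() * dgam;
    dM += dgam * lp.a.t();
    g.Wphi += LC.msum.t() * dM;
    mat dmsum = dM * lp.Wphi.t();
    for (uword e = 0; e < ne; ++e) {
      dE_prev.row(esrc(e)) += dmsum.row(e);
      dR.row(erel(e)) += dmsum.row(e);
    }
  }

  void global_backward(const LayerCache& LC, const LayerP& lp, LayerP& g,
                       const mat& dEg, mat& dE_prev) const {
    int dh = c.d / c.k;
    mat dG = dEg * lp.Wm.t();
    g.Wm += LC.G.t() * dEg;
    for (int h = 0; h < c.k; ++h) {
      const HeadCache& HC = LC.heads[h];
      arma::span sp(h * dh, (h + 1) * dh - 1);
      mat dU = dG.cols(sp);
      mat dP(arma::size(HC.P), arma::fill::zeros);
      mat dS(arma::size(HC.S), arma::fill::zeros);
      if (c.normalize) {
        vec dz(n);
        for (int i = 0; i < n; ++i)
          dz(i) = -arma::dot(dU.row(i), HC.Unorm.row(i)) / HC.z(i);
        dU.each_col() /= HC.z;
        dP += dz * HC.svec.t();
        vec dsvec = HC.P.t() * dz;
        dS.each_row() += dsvec.t();
      }
      dP += dU * HC.C.t();
      mat dC = HC.P.t() * dU;
      dS += HC.V * dC.t();
      mat dV = HC.S * dC;
      mat dQ = dP % phi_grad(HC.Qraw);
      mat dK = dS % phi_grad(HC.Kraw);
      const mat& E = LC.E_in;
      g.Wq.cols(sp) += E.t() * dQ;
      g.Wk.cols(sp) += E.t() * dK;
      g.Wv.cols(sp) += E.t() * dV;
      dE_prev += dQ * lp.Wq.cols(sp).t();
      dE_prev += dK * lp.Wk.cols(sp).t();
      dE_prev += dV * lp.Wv.cols(sp).t();
    }
  }

  void layer_backward(const LayerCache& LC, const LayerP& lp, LayerP& g,
                      const mat& dOut, mat& dE_prev, mat& dR) const {
    if (LC.is_base) {
      local_backward(LC, lp, g, dOut, dE_prev, dR);
      return;
    }
    mat dEs, dEg, dEl;
    const mat& Es = LC.E_in;
    mat El_used = c.ablate_local ? arma::zeros<mat>(n, c.d) : LC.El;
    if (c.fusion == 1) {
      dEs = dOut;
      dEg = c.ablate_global ? arma::zeros<mat>(n, c.d) : dOut;
      dEl = c.ablate_local ? arma::zeros<mat>(n, c.d) : dOut;
    } else if (c.fusion == 2) {
      g.Wc += LC.X.t() * dOut;
      mat dX = dOut * lp.Wc.t();
      dEs = dX.cols(0, c.d - 1);
      dEg = c.ablate_global ? arma::zeros<mat>(n, c.d)
                            : mat(dX.cols(c.d, 2 * c.d - 1));
      dEl = c.ablate_local ? arma::zeros<mat>(n, c.d)
                           : mat(dX.cols(2 * c.d, 3 * c.d - 1));
    } else {
      dEs = arma::zeros<mat>(n, c.d);
      dEg = arma::zeros<mat>(n, c.d);
      dEl = arma::zeros<mat>(n, c.d);
      bool act[3] = {true, !c.ablate_global, !c.ablate_local};
      for (int i = 0; i < n; ++i) {
        double dal[3], ds[3];
        dal[0] = arma::dot(dOut.row(i), Es.row(i));
        dal[1] = arma::dot(dOut.row(i), LC.Eg.row(i));
        dal[2] = arma::dot(dOut.row(i), El_used.row(i));
        double sm = 0.0;
        for (int b = 0; b < 3; ++b) sm += LC.alpha(i, b) * dal[b];
        for (int b = 0; b < 3; ++b)
          ds[b] = act[b] ? LC.alpha(i, b) * (dal[b] - sm) : 0.0;
        for (int b = 0; b < 3; ++b)
          ds[b] *= lrelu_grad(LC.T(i, b), c.slope);
        dEs.row(i) = LC.alpha(i, 0) * dOut.row(i) + ds[0] * lp.w.t();
        dEg.row(i) = LC.alpha(i, 1) * dOut.row(i) + ds[1] * lp.w.t();
        dEl.row(i) = LC.alpha(i, 2) * dOut.row(i) + ds[2] * lp.w.t();
        g.w += ds[0] * Es.row(i).t() + ds[1] * LC.Eg.row(i).t() +
               ds[2] * El_used.row(i).t();
      }
    }
    dE_prev += dEs;
    if (!c.ablate_global) global_backward(LC, lp, g, dEg, dE_prev);
    if (!c.ablate_local) local_backward(LC, lp, g, dEl, dE_prev, dR);
  }
};

uvec to_uvec(const IntegerVector& v) {
  uvec out(v.size());
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] < 0) stop("negative index");
    out(i) = (uword)v[i];
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List engine_forward(IntegerVector dst, IntegerVector rel, IntegerVector src,
                    int n_entities, NumericVector par, List cfg,
                    int head, int qrel) {
  Engine eng(dst, rel, src, n_entities, par, read_cfg(cfg));
  Forward F = eng.forward(head, qrel);
  return List::create(_["nodes"] = F.E_final, _["relations"] = *F.R_final);
}

// [[Rcpp::export]]
List engine_step(IntegerVector dst, IntegerVector rel, IntegerVector src,
                 int n_entities, NumericVector par, List cfg,
                 int head, int qrel, int pos_tail, IntegerVector neg_tails) {
  Engine eng(dst, rel, src, n_entities, par, read_cfg(cfg));
  return eng.step(head, qrel, pos_tail, to_uvec(neg_tails));
}

// [[Rcpp::export]]
NumericVector engine_score_tails(IntegerVector dst, IntegerVector rel,
                                 IntegerVector src, int n_entities,
                                 NumericVector par, List cfg, int head,
                                 int qrel, IntegerVector tails) {
  Engine eng(dst, rel, src, n_entities, par, read_cfg(cfg));
  Forward F = eng.forward(head, qrel);
  vec s = eng.score(F, head, qrel, to_uvec(tails));
  return NumericVector(s.begin(), s.end());
}
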