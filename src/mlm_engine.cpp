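// Transformer encoder trained by masked-node prediction, with per-epoch
// random-walk-with-restart propagation of the embedding table.
//
// Layout conventions (all 0-based here; the R wrappers translate):
//   token ids: 0..M-1 node tokens, M = [CLS], M+1 = [MASK], M+2 = [PAD]
//   a batch of B sequences of length L is flattened row-wise into a
//   (B*L) x d matrix, row b*L + l = position l of sequence b.
// Post-norm blocks: H <- LN(H + MHA(H)); H <- LN(H + FFN(H)); layer norm
// carries no learnable affine. Heads are concatenated with no output
// projection; the decoder is an untied linear map onto the M node classes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

namespace {

struct Block {
  mat Wq, Wk, Wv;  // d x d
  mat W1, W2;      // d x f, f x d
  rowvec b1, b2;   // f, d
};

struct Model {
  mat X;                     // (M + 3) x e embedding table
  std::vector<Block> blocks;
  mat Wd;                    // d x M decoder
  rowvec bd;                 // M
};

struct Cfg {
  int e, d, heads, dk, M, clsId, maskId, padId;
  bool concat;
  double dropout, lnEps;
};

struct Grads {
  mat X;
  std::vector<Block> blocks;
  mat Wd;
  rowvec bd;
};

// Deterministic RNG independent of R's stream (the master seed is passed in
// from R); mt19937_64 output mapped to [0,1) doubles.
struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t s) : g(s) {}
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(g() % static_cast<uint64_t>(n)); }
};

struct BlockCache {
  mat Hin, Q, K, V;          // BL x d
  std::vector<mat> P;        // B*heads softmax matrices, each L x L
  mat attnDrop, ffnDrop;     // dropout masks (already 1/keep scaled), empty if unused
  mat xhat1, xhat2;          // layer-norm outputs
  vec invstd1, invstd2;
  mat Zb, Arelu;             // BL x f
};

struct Cache {
  imat tokens;               // B x L
  umat pad;                  // B x L
  std::vector<BlockCache> blocks;
  mat Hfinal;                // BL x d
};

Cfg cfgFromList(const List& cfgR) {
  Cfg c;
  c.e = as<int>(cfgR["e"]);
  c.heads = as<int>(cfgR["heads"]);
  c.concat = as<bool>(cfgR["concat"]);
  c.d = c.concat ? 2 * c.e : c.e;
  if (c.d % c.heads != 0) stop("model width not divisible by number of heads");
  c.dk = c.d / c.heads;
  c.M = as<int>(cfgR["M"]);
  c.clsId = c.M;
  c.maskId = c.M + 1;
  c.padId = c.M + 2;
  c.dropout = as<double>(cfgR["dropout"]);
  c.lnEps = 1e-5;
  return c;
}

Model modelFromList(const List& m) {
  Model mo;
  mo.X = as<mat>(m["X"]);
  List bl = m["blocks"];
  for (int i = 0; i < bl.size(); ++i) {
    List b = bl[i];
    Block blk;
    blk.Wq = as<mat>(b["Wq"]);
    blk.Wk = as<mat>(b["Wk"]);
    blk.Wv = as<mat>(b["Wv"]);
    blk.W1 = as<mat>(b["W1"]);
    blk.b1 = as<rowvec>(b["b1"]);
    blk.W2 = as<mat>(b["W2"]);
    blk.b2 = as<rowvec>(b["b2"]);
    mo.blocks.push_back(blk);
  }
  mo.Wd = as<mat>(m["Wd"]);
  mo.bd = as<rowvec>(m["bd"]);
  return mo;
}

List modelToList(const Model& mo) {
  List bl(mo.blocks.size());
  for (size_t i = 0; i < mo.blocks.size(); ++i) {
    const Block& b = mo.blocks[i];
    bl[i] = List::create(_["Wq"] = b.Wq, _["Wk"] = b.Wk, _["Wv"] = b.Wv,
                         _["W1"] = b.W1, _["b1"] = b.b1, _["W2"] = b.W2,
                         _["b2"] = b.b2);
  }
  return List::create(_["X"] = mo.X, _["blocks"] = bl, _["Wd"] = mo.Wd,
                      _["bd"] = mo.bd);
}

Grads zeroGrads(const Model& mo) {
  Grads g;
  g.X = zeros<mat>(mo.X.n_rows, mo.X.n_cols);
  for (const Block& b : mo.blocks) {
    Block z;
    z.Wq = zeros<mat>(size(b.Wq));
    z.Wk = zeros<mat>(size(b.Wk));
    z.Wv = zeros<mat>(size(b.Wv));
    z.W1 = zeros<mat>(size(b.W1));
    z.W2 = zeros<mat>(size(b.W2));
    z.b1 = zeros<rowvec>(b.b1.n_elem);
    z.b2 = zeros<rowvec>(b.b2.n_elem);
    g.blocks.push_back(z);
  }
  g.Wd = zeros<mat>(size(mo.Wd));
  g.bd = zeros<rowvec>(mo.bd.n_elem);
  return g;
}

void layerNormFwd(const mat& Xin, double eps, mat& xhat, vec& invstd) {
  const uword n = Xin.n_rows, d = Xin.n_cols;
  xhat.set_size(n, d);
  invstd.set_size(n);
  for (uword i = 0; i < n; ++i) {
    rowvec c = Xin.row(i) - mean(Xin.row(i));
    double v = dot(c, c) / d;
    double is = 1.0 / std::sqrt(v + eps);
    invstd(i) = is;
    xhat.row(i) = c * is;
  }
}

void layerNormBwd(const mat& xhat, const vec& invstd, const mat& dy, mat& dx) {
  const uword n = xhat.n_rows;
  dx.set_size(size(xhat));
  for (uword i = 0; i < n; ++i) {
    const rowvec g = dy.row(i);
    double m1 = mean(g);
    double m2 = mean(g % xhat.row(i));
    dx.row(i) = (g - m1 - xhat.row(i) * m2) * invstd(i);
  }
}

mat dropMask(uword r, uword c, double p, Rng& rng) {
  mat m(r, c);
  double keep = 1.0 - p;
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i)
      m(i, j) = (rng.unif() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// Forward pass; PE is an L x e positional-encoding matrix computed in R so
// that one definition serves both the exported R operation and the engine.
void forwardPass(const Model& mo, const Cfg& cfg, const imat& tokens,
                 const mat& PE, bool training, Rng* rng, Cache& C) {
  const int B = tokens.n_rows, L = tokens.n_cols, d = cfg.d, e = cfg.e;
  const int BL = B * L;
  if ((int)PE.n_rows < L || (int)PE.n_cols != e)
    stop("positional-encoding matrix does not cover the sequence length");
  C.tokens = tokens;
  C.pad.set_size(B, L);
  mat H(BL, d);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      int t = tokens(b, l);
      if (t < 0 || t >= (int)mo.X.n_rows) stop("token id out of range");
      C.pad(b, l) = (t == cfg.padId) ? 1u : 0u;
      int r = b * L + l;
      if (cfg.concat) {
        H(r, span(0, e - 1)) = mo.X.row(t);
        H(r, span(e, d - 1)) = PE.row(l);
      } else {
        H.row(r) = mo.X.row(t) + PE.row(l);
      }
    }
  }
  const double sdk = std::sqrt((double)cfg.dk);
  const bool useDrop = training && cfg.dropout > 0.0;
  C.blocks.assign(mo.blocks.size(), BlockCache());
  for (size_t bi = 0; bi < mo.blocks.size(); ++bi) {
    const Block& W = mo.blocks[bi];
    BlockCache& bc = C.blocks[bi];
    bc.Hin = H;
    bc.Q = H * W.Wq;
    bc.K = H * W.Wk;
    bc.V = H * W.Wv;
    mat attn(BL, d, fill::zeros);
    bc.P.assign((size_t)B * cfg.heads, mat());
    for (int b = 0; b < B; ++b) {
      span rows(b * L, b * L + L - 1);
      for (int h = 0; h < cfg.heads; ++h) {
        span cols(h * cfg.dk, (h + 1) * cfg.dk - 1);
        mat S = bc.Q(rows, cols) * bc.K(rows, cols).t() / sdk;
        for (int j = 0; j < L; ++j)
          if (C.pad(b, j)) S.col(j).fill(-1e30);
        for (int i = 0; i < L; ++i) {
          rowvec r = S.row(i);
          r -= r.max();
          r = exp(r);
          S.row(i) = r / accu(r);
        }
        bc.P[(size_t)b * cfg.heads + h] = S;
        attn(rows, cols) = S * bc.V(rows, cols);
      }
    }
    if (useDrop) {
      bc.attnDrop = dropMask(BL, d, cfg.dropout, *rng);
      attn %= bc.attnDrop;
    }
    layerNormFwd(bc.Hin + attn, cfg.lnEps, bc.xhat1, bc.invstd1);
    bc.Zb = bc.xhat1 * W.W1;
    bc.Zb.each_row() += W.b1;
    bc.Arelu = bc.Zb;
    bc.Arelu.transform([](double x) { return x > 0.0 ? x : 0.0; });
    mat F = bc.Arelu * W.W2;
    F.each_row() += W.b2;
    if (useDrop) {
      bc.ffnDrop = dropMask(BL, d, cfg.dropout, *rng);
      F %= bc.ffnDrop;
    }
    layerNormFwd(bc.xhat1 + F, cfg.lnEps, bc.xhat2, bc.invstd2);
    H = bc.xhat2;
  }
  C.Hfinal = H;
}

// Cross-entropy over masked positions + full backward pass. mrows are row
// indices into the flattened (B*L) matrix; mtg the original node ids.
// meanReduce divides loss and gradients by the mask count.
double lossAndBackward(const Model& mo, const Cfg& cfg, const Cache& C,
                       const std::vector<int>& mrows,
                       const std::vector<int>& mtg, bool meanReduce,
                       Grads& G) {
  const int BL = C.Hfinal.n_rows, d = cfg.d, e = cfg.e;
  const int B = C.tokens.n_rows, L = C.tokens.n_cols;
  const int nm = (int)mrows.size();
  if (nm == 0) stop("batch contains no masked positions");
  uvec mr(nm);
  for (int i = 0; i < nm; ++i) mr(i) = (uword)mrows[i];
  mat Hm = C.Hfinal.rows(mr);              // nm x d
  mat logits = Hm * mo.Wd;                 // nm x M
  logits.each_row() += mo.bd;
  double loss = 0.0;
  mat dL(nm, cfg.M);
  for (int i = 0; i < nm; ++i) {
    rowvec r = logits.row(i);
    double mx = r.max();
    rowvec ex = exp(r - mx);
    double Z = accu(ex);
    rowvec p = ex / Z;
    loss += -(r(mtg[i]) - mx - std::log(Z));
    dL.row(i) = p;
    dL(i, mtg[i]) -= 1.0;
  }
  const double scale = meanReduce ? 1.0 / nm : 1.0;
  if (meanReduce) loss /= nm;
  dL *= scale;
  G.Wd += Hm.t() * dL;
  G.bd += sum(dL, 0);
  mat dH(BL, d, fill::zeros);
  dH.rows(mr) = dL * mo.Wd.t();
  const double sdk = std::sqrt((double)cfg.dk);
  for (int bi = (int)mo.blocks.size() - 1; bi >= 0; --bi) {
    const Block& W = mo.blocks[bi];
    const BlockCache& bc = C.blocks[bi];
    Block& g = G.blocks[bi];
    // LN2
    mat dR2;
    layerNormBwd(bc.xhat2, bc.invstd2, dH, dR2);
    mat dHn1 = dR2;                        // residual branch
    mat dF = dR2;
    if (bc.ffnDrop.n_elem) dF %= bc.ffnDrop;
    // FFN
    g.W2 += bc.Arelu.t() * dF;
    g.b2 += sum(dF, 0);
    mat dZ = dF * W.W2.t();
    dZ.elem(find(bc.Zb <= 0.0)).zeros();
    g.W1 += bc.xhat1.t() * dZ;
    g.b1 += sum(dZ, 0);
    dHn1 += dZ * W.W1.t();
    // LN1
    mat dR1;
    layerNormBwd(bc.xhat1, bc.invstd1, dHn1, dR1);
    mat dHin = dR1;
    mat dAttn = dR1;
    if (bc.attnDrop.n_elem) dAttn %= bc.attnDrop;
    // attention
    mat dQ(BL, d, fill::zeros), dK(BL, d, fill::zeros), dV(BL, d, fill::zeros);
    for (int b = 0; b < B; ++b) {
      span rows(b * L, b * L + L - 1);
      for (int h = 0; h < cfg.heads; ++h) {
        span cols(h * cfg.dk, (h + 1) * cfg.dk - 1);
        const mat& P = bc.P[(size_t)b * cfg.heads + h];
        mat dA = dAttn(rows, cols);
        mat dP = dA * bc.V(rows, cols).t();
        dV(rows, cols) = P.t() * dA;
        mat dS = P % (dP.each_col() - sum(dP % P, 1));
        dQ(rows, cols) = dS * bc.K(rows, cols) / sdk;
        dK(rows, cols) = dS.t() * bc.Q(rows, cols) / sdk;
      }
    }
    g.Wq += bc.Hin.t() * dQ;
    g.Wk += bc.Hin.t() * dK;
    g.Wv += bc.Hin.t() * dV;
    dHin += dQ * W.Wq.t() + dK * W.Wk.t() + dV * W.Wv.t();
    dH = dHin;
  }
  // into the embedding table
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      int t = C.tokens(b, l);
      int r = b * L + l;
      if (cfg.concat)
        G.X.row(t) += dH(r, span(0, e - 1));
      else
        G.X.row(t) += dH.row(r);
    }
  }
  return loss;
}

struct AdamState {
  Grads m, v;
  long t = 0;
};

void adamOne(mat& th, const mat& g, mat& m, mat& v, double lr, double c1,
             double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  th -= lr * (m / c1) / (sqrt(v / c2) + 1e-8);
}

void adamOne(rowvec& th, const rowvec& g, rowvec& m, rowvec& v, double lr,
             double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  th -= lr * (m / c1) / (sqrt(v / c2) + 1e-8);
}

void adamStep(Model& mo, const Grads& g, AdamState& st, double lr) {
  st.t += 1;
  double c1 = 1.0 - std::pow(0.9, (double)st.t);
  double c2 = 1.0 - std::pow(0.999, (double)st.t);
  adamOne(mo.X, g.X, st.m.X, st.v.X, lr, c1, c2);
  for (size_t i = 0; i < mo.blocks.size(); ++i) {
    Block& b = mo.blocks[i];
    const Block& gb = g.blocks[i];
    Block& mb = st.m.blocks[i];
    Block& vb = st.v.blocks[i];
    adamOne(b.Wq, gb.Wq, mb.Wq, vb.Wq, lr, c1, c2);
    adamOne(b.Wk, gb.Wk, mb.Wk, vb.Wk, lr, c1, c2);
    adamOne(b.Wv, gb.Wv, mb.Wv, vb.Wv, lr, c1, c2);
    adamOne(b.W1, gb.W1, mb.W1, vb.W1, lr, c1, c2);
    adamOne(b.b1, gb.b1, mb.b1, vb.b1, lr, c1, c2);
    adamOne(b.W2, gb.W2, mb.W2, vb.W2, lr, c1, c2);
    adamOne(b.b2, gb.b2, mb.b2, vb.b2, lr, c1, c2);
  }
  adamOne(mo.Wd, g.Wd, st.m.Wd, st.v.Wd, lr, c1, c2);
  adamOne(mo.bd, g.bd, st.m.bd, st.v.bd, lr, c1, c2);
}

int roundHalfUp(double x) { return (int)std::floor(x + 0.5); }

}  // namespace

// Full training loop. tokens: S x L matrix of 0-based token ids with the
// [CLS] id in column 0 and [PAD] padding. WList: per-network symmetric
// normalised adjacencies (n x n sparse); presentList: per-network 0-based
// indices of nodes with positive degree (the rows propagation touches).
// [[Rcpp::export(name = ".cppTrain")]]
List cppTrain(IntegerMatrix tokensR, List WList, List presentList,
              List modelR, List cfgR, NumericMatrix PER, int epochs,
              int batchSize, double maskRate, double alpha, double lr,
              bool propagate, bool meanReduce, int seed) {
  Model mo = modelFromList(modelR);
  Cfg cfg = cfgFromList(cfgR);
  mat PE = as<mat>(PER);
  imat tokens(tokensR.nrow(), tokensR.ncol());
  for (int i = 0; i < tokensR.nrow(); ++i)
    for (int j = 0; j < tokensR.ncol(); ++j) tokens(i, j) = tokensR(i, j);
  const int S = tokens.n_rows, L = tokens.n_cols;
  const int T = WList.size();
  std::vector<sp_mat> Ws;
  std::vector<uvec> present;
  for (int t = 0; t < T; ++t) {
    Ws.push_back(as<sp_mat>(WList[t]));
    present.push_back(as<uvec>(presentList[t]));
  }
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  AdamState st;
  st.m = zeroGrads(mo);
  st.v = zeroGrads(mo);
  std::vector<double> trace;
  std::vector<int> perm(S);
  for (int i = 0; i < S; ++i) perm[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    if (propagate && T > 0 && alpha < 1.0) {
      const sp_mat& W = Ws[ep % T];
      const uvec& pr = present[ep % T];
      mat Xn = mo.X.rows(0, cfg.M - 1);
      mat WX = W * Xn;
      for (uword i = 0; i < pr.n_elem; ++i) {
        uword r = pr(i);
        mo.X.row(r) = (1.0 - alpha) * WX.row(r) + alpha * Xn.row(r);
      }
    }
    // Fisher-Yates shuffle of the corpus
    for (int i = S - 1; i > 0; --i) std::swap(perm[i], perm[rng.below(i + 1)]);
    double lossSum = 0.0;
    long nmTot = 0;
    for (int off = 0; off < S; off += batchSize) {
      int B = std::min(batchSize, S - off);
      imat bt(B, L);
      std::vector<int> mrows, mtg;
      std::vector<int> maskable;
      for (int b = 0; b < B; ++b) {
        int sidx = perm[off + b];
        maskable.clear();
        for (int l = 0; l < L; ++l) {
          int tk = tokens(sidx, l);
          bt(b, l) = tk;
          if (l > 0 && tk != cfg.padId) maskable.push_back(l);
        }
        int m = (int)maskable.size();
        if (m == 0) continue;
        int k = std::max(1, roundHalfUp(maskRate * m));
        for (int i = 0; i < k; ++i) {  // partial Fisher-Yates for k picks
          int j = i + rng.below(m - i);
          std::swap(maskable[i], maskable[j]);
        }
        for (int i = 0; i < k; ++i) {
          int l = maskable[i];
          mrows.push_back(b * L + l);
          mtg.push_back(bt(b, l));
          bt(b, l) = cfg.maskId;
        }
      }
      if (mrows.empty()) continue;
      Cache C;
      forwardPass(mo, cfg, bt, PE, true, &rng, C);
      Grads g = zeroGrads(mo);
      double loss = lossAndBackward(mo, cfg, C, mrows, mtg, meanReduce, g);
      if (!std::isfinite(loss)) stop("training diverged: non-finite loss at epoch %d", ep + 1);
      adamStep(mo, g, st, lr);
      lossSum += meanReduce ? loss * mrows.size() : loss;
      nmTot += mrows.size();
    }
    trace.push_back(nmTot > 0 ? lossSum / nmTot : NA_REAL);
  }
  return List::create(_["model"] = modelToList(mo),
                      _["lossTrace"] = NumericVector(trace.begin(), trace.end()));
}

// Inference pass: returns the final hidden states as a (B*L) x d matrix
// (row b*L + l) plus decoder logits. Dropout is inactive.
// [[Rcpp::export(name = ".cppForward")]]
List cppForward(List modelR, List cfgR, IntegerMatrix tokensR,
                NumericMatrix PER, bool logits) {
  Model mo = modelFromList(modelR);
  Cfg cfg = cfgFromList(cfgR);
  mat PE = as<mat>(PER);
  imat tokens(tokensR.nrow(), tokensR.ncol());
  for (int i = 0; i < tokensR.nrow(); ++i)
    for (int j = 0; j < tokensR.ncol(); ++j) tokens(i, j) = tokensR(i, j);
  Cache C;
  forwardPass(mo, cfg, tokens, PE, false, nullptr, C);
  List out = List::create(_["H"] = C.Hfinal, _["B"] = (int)tokens.n_rows,
                          _["L"] = (int)tokens.n_cols);
  if (logits) {
    mat lg = C.Hfinal * mo.Wd;
    lg.each_row() += mo.bd;
    out["logits"] = lg;
  }
  return out;
}

// Loss and analytic gradients for an explicitly masked batch (tokens already
// contain [MASK]; maskFlag marks those cells and targets holds the original
// ids there). Used by the finite-difference gradient checks.
// [[Rcpp::export(name = ".cppLossGrad")]]
List cppLossGrad(List modelR, List cfgR, IntegerMatrix tokensR,
                 IntegerMatrix maskFlagR, IntegerMatrix targetsR,
                 NumericMatrix PER, bool meanReduce) {
  Model mo = modelFromList(modelR);
  Cfg cfg = cfgFromList(cfgR);
  mat PE = as<mat>(PER);
  const int B = tokensR.nrow(), L = tokensR.ncol();
  imat tokens(B, L);
  std::vector<int> mrows, mtg;
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      tokens(b, l) = tokensR(b, l);
      if (maskFlagR(b, l)) {
        mrows.push_back(b * L + l);
        mtg.push_back(targetsR(b, l));
      }
    }
  }
  Cache C;
  forwardPass(mo, cfg, tokens, PE, false, nullptr, C);
  Grads g = zeroGrads(mo);
  double loss = lossAndBackward(mo, cfg, C, mrows, mtg, meanReduce, g);
  List bl(g.blocks.size());
  for (size_t i = 0; i < g.blocks.size(); ++i) {
    const Block& b = g.blocks[i];
    bl[i] = List::create(_["Wq"] = b.Wq, _["Wk"] = b.Wk, _["Wv"] = b.Wv,
                         _["W1"] = b.W1, _["b1"] = b.b1, _["W2"] = b.W2,
                         _["b2"] = b.b2);
  }
  return List::create(_["loss"] = loss, _["X"] = g.X, _["blocks"] = bl,
                      _["Wd"] = g.Wd, _["bd"] = g.bd);
}
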