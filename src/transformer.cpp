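// Small pre-LayerNorm self-attention encoder over k-mer token ids with a
// two-class softmax head on the [CLS] position, trained from random
// initialization with AdamW under linear warmup / linear decay.
// Single-precision throughout; all randomness comes from one mt19937_64
// stream seeded from the training config, so runs are reproducible on a
// single worker.
//
// Token ids arrive 1-based from R ([PAD]=1, [UNK]=2, [CLS]=3, [SEP]=4,
// [MASK]=5, k-mers follow) and are shifted to 0-based row indices here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;

static const float LN_EPS = 1e-5f;

struct Cfg {
  int V, d, H, L, maxLen, ff, dh;
  float dropout;
};

static Cfg cfgFromList(const List& cl) {
  Cfg c;
  c.V = Rcpp::as<int>(cl["vocabSize"]);
  c.d = Rcpp::as<int>(cl["hiddenDim"]);
  c.H = Rcpp::as<int>(cl["nHeads"]);
  c.L = Rcpp::as<int>(cl["nLayers"]);
  c.maxLen = Rcpp::as<int>(cl["maxSeqLength"]);
  c.dropout = Rcpp::as<double>(cl["dropout"]);
  c.ff = 4 * c.d;
  c.dh = c.d / c.H;
  if (c.d % c.H != 0) Rcpp::stop("hiddenDim must be divisible by nHeads");
  return c;
}

struct Layer {
  fmat ln1g, ln1b, Wq, bq, Wk, bk, Wv, bv, Wo, bo;
  fmat ln2g, ln2b, W1, b1, W2, b2;
};

struct Model {
  fmat E, P;
  std::vector<Layer> layers;
  fmat lnfg, lnfb, Wc, bc;
};

// Fixed parameter order shared by list I/O, the optimizer and grads.
static void collectParams(Model& m, std::vector<fmat*>& ps,
                          std::vector<bool>& decay,
                          std::vector<std::string>& names) {
  ps.clear(); decay.clear(); names.clear();
  auto add = [&](fmat& w, bool dec, const std::string& nm) {
    ps.push_back(&w); decay.push_back(dec); names.push_back(nm);
  };
  add(m.E, true, "tok_emb");
  add(m.P, true, "pos_emb");
  for (size_t i = 0; i < m.layers.size(); ++i) {
    Layer& l = m.layers[i];
    std::string p = "L" + std::to_string(i) + ".";
    add(l.ln1g, false, p + "ln1_g"); add(l.ln1b, false, p + "ln1_b");
    add(l.Wq, true, p + "Wq"); add(l.bq, false, p + "bq");
    add(l.Wk, true, p + "Wk"); add(l.bk, false, p + "bk");
    add(l.Wv, true, p + "Wv"); add(l.bv, false, p + "bv");
    add(l.Wo, true, p + "Wo"); add(l.bo, false, p + "bo");
    add(l.ln2g, false, p + "ln2_g"); add(l.ln2b, false, p + "ln2_b");
    add(l.W1, true, p + "W1"); add(l.b1, false, p + "b1");
    add(l.W2, true, p + "W2"); add(l.b2, false, p + "b2");
  }
  add(m.lnfg, false, "lnf_g"); add(m.lnfb, false, "lnf_b");
  add(m.Wc, true, "cls_W"); add(m.bc, false, "cls_b");
}

static Model emptyModel(const Cfg& c) {
  Model m;
  m.E.set_size(c.V, c.d);
  m.P.set_size(c.maxLen, c.d);
  m.layers.resize(c.L);
  for (auto& l : m.layers) {
    l.ln1g.set_size(1, c.d); l.ln1b.set_size(1, c.d);
    l.Wq.set_size(c.d, c.d); l.bq.set_size(1, c.d);
    l.Wk.set_size(c.d, c.d); l.bk.set_size(1, c.d);
    l.Wv.set_size(c.d, c.d); l.bv.set_size(1, c.d);
    l.Wo.set_size(c.d, c.d); l.bo.set_size(1, c.d);
    l.ln2g.set_size(1, c.d); l.ln2b.set_size(1, c.d);
    l.W1.set_size(c.d, c.ff); l.b1.set_size(1, c.ff);
    l.W2.set_size(c.ff, c.d); l.b2.set_size(1, c.d);
  }
  m.lnfg.set_size(1, c.d); m.lnfb.set_size(1, c.d);
  m.Wc.set_size(c.d, 2); m.bc.set_size(1, 2);
  return m;
}

static Model zerosModel(const Cfg& c) {
  Model m = emptyModel(c);
  std::vector<fmat*> ps; std::vector<bool> dec;
  std::vector<std::string> nm;
  collectParams(m, ps, dec, nm);
  for (auto* w : ps) w->zeros();
  return m;
}

static Model initModel(const Cfg& c, std::mt19937_64& rng) {
  Model m = emptyModel(c);
  std::normal_distribution<float> nd(0.0f, 0.02f);
  std::vector<fmat*> ps; std::vector<bool> dec;
  std::vector<std::string> nm;
  collectParams(m, ps, dec, nm);
  for (size_t i = 0; i < ps.size(); ++i) {
    if (dec[i]) {
      for (uword j = 0; j < ps[i]->n_elem; ++j) (*ps[i])(j) = nd(rng);
    } else if (nm[i].find("ln") != std::string::npos &&
               nm[i].find("_g") != std::string::npos) {
      ps[i]->ones();
    } else {
      ps[i]->zeros();
    }
  }
  return m;
}

static Model modelFromList(const List& wl, const Cfg& c) {
  Model m = emptyModel(c);
  std::vector<fmat*> ps; std::vector<bool> dec;
  std::vector<std::string> nm;
  collectParams(m, ps, dec, nm);
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericMatrix w = Rcpp::as<NumericMatrix>(wl[nm[i]]);
    if ((uword)w.nrow() != ps[i]->n_rows || (uword)w.ncol() != ps[i]->n_cols)
      Rcpp::stop("weight '%s' has shape %dx%d, expected %dx%d", nm[i],
                 w.nrow(), w.ncol(), (int)ps[i]->n_rows,
                 (int)ps[i]->n_cols);
    for (uword col = 0; col < ps[i]->n_cols; ++col)
      for (uword row = 0; row < ps[i]->n_rows; ++row)
        (*ps[i])(row, col) = (float)w(row, col);
  }
  return m;
}

static List modelToList(Model& m) {
  std::vector<fmat*> ps; std::vector<bool> dec;
  std::vector<std::string> nm;
  collectParams(m, ps, dec, nm);
  List out(ps.size());
  Rcpp::CharacterVector names(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericMatrix w(ps[i]->n_rows, ps[i]->n_cols);
    for (uword col = 0; col < ps[i]->n_cols; ++col)
      for (uword row = 0; row < ps[i]->n_rows; ++row)
        w(row, col) = (*ps[i])(row, col);
    out[i] = w;
    names[i] = nm[i];
  }
  out.attr("names") = names;
  return out;
}

// ---------------------------------------------------------------------
// forward / backward

struct LnCache { fmat xhat; fvec rstd; };

struct LayerCache {
  fmat X, Y1, Q, K, V, O, attnOut, attnMask, Xmid, Y2, Hff, Aff, ffMask;
  LnCache ln1, ln2;
  std::vector<fmat> A; // per-head softmax attention, n x n
};

struct FwdCache {
  fmat X0, embMask;
  std::vector<LayerCache> lc;
  fmat Xf, Hf;
  LnCache lnf;
  fvec probs;
  fvec logits;
};

static fmat lnFwd(const fmat& X, const fmat& g, const fmat& b,
                  LnCache& cache) {
  fvec mu = mean(X, 1);
  fmat Xc = X.each_col() - mu;
  fvec var = mean(square(Xc), 1);
  cache.rstd = 1.0f / sqrt(var + LN_EPS);
  cache.xhat = Xc.each_col() % cache.rstd;
  fmat out = cache.xhat.each_row() % g.row(0);
  out.each_row() += b.row(0);
  return out;
}

static fmat lnBwd(const fmat& dY, const LnCache& cache, const fmat& g,
                  fmat& dg, fmat& db) {
  dg.row(0) += sum(dY % cache.xhat, 0);
  db.row(0) += sum(dY, 0);
  fmat dxhat = dY.each_row() % g.row(0);
  fvec m1 = mean(dxhat, 1);
  fvec m2 = mean(dxhat % cache.xhat, 1);
  fmat dX = dxhat;
  dX.each_col() -= m1;
  fmat xm = cache.xhat;
  xm.each_col() %= m2;
  dX -= xm;
  dX.each_col() %= cache.rstd;
  return dX;
}

static fmat geluFwd(const fmat& x) {
  fmat a = 0.7978845608f * (x + 0.044715f * (x % x % x));
  return 0.5f * (x % (1.0f + tanh(a)));
}

static fmat geluBwd(const fmat& x, const fmat& dY) {
  fmat x2 = x % x;
  fmat a = 0.7978845608f * (x + 0.044715f * (x % x2));
  fmat t = tanh(a);
  fmat da = 0.7978845608f * (1.0f + 0.134145f * x2);
  return dY % (0.5f * (1.0f + t) + 0.5f * (x % (1.0f - t % t) % da));
}

static void softmaxRows(fmat& S) {
  fvec mx = max(S, 1);
  S.each_col() -= mx;
  S = exp(S);
  fvec sm = sum(S, 1);
  S.each_col() /= sm;
}

static fmat dropMask(uword r, uword c, float p, std::mt19937_64& rng) {
  fmat m(r, c);
  std::uniform_real_distribution<float> ud(0.0f, 1.0f);
  float keep = 1.0f - p;
  for (uword j = 0; j < m.n_elem; ++j)
    m(j) = (ud(rng) < keep) ? 1.0f / keep : 0.0f;
  return m;
}

// Forward pass over one sequence of 0-based token ids. When `train` is
// true, inverted-dropout masks are drawn from rng and kept in the cache.
static fvec forwardSeq(const Model& M, const Cfg& c, const ivec& toks,
                       bool train, std::mt19937_64* rng, FwdCache* cache) {
  const int n = toks.n_elem;
  const float scale = 1.0f / std::sqrt((float)c.dh);
  const bool drop = train && c.dropout > 0.0f;

  fmat X(n, c.d);
  for (int i = 0; i < n; ++i)
    X.row(i) = M.E.row(toks(i)) + M.P.row(i);
  if (drop) {
    fmat msk = dropMask(n, c.d, c.dropout, *rng);
    X %= msk;
    if (cache) cache->embMask = std::move(msk);
  }
  if (cache) { cache->X0 = X; cache->lc.resize(c.L); }

  for (int li = 0; li < c.L; ++li) {
    const Layer& l = M.layers[li];
    LayerCache tmp;
    LayerCache& lc = cache ? cache->lc[li] : tmp;
    lc.X = X;
    lc.Y1 = lnFwd(X, l.ln1g, l.ln1b, lc.ln1);
    lc.Q = lc.Y1 * l.Wq; lc.Q.each_row() += l.bq.row(0);
    lc.K = lc.Y1 * l.Wk; lc.K.each_row() += l.bk.row(0);
    lc.V = lc.Y1 * l.Wv; lc.V.each_row() += l.bv.row(0);
    lc.O.set_size(n, c.d);
    lc.A.resize(c.H);
    for (int h = 0; h < c.H; ++h) {
      const uword c0 = h * c.dh, c1 = (h + 1) * c.dh - 1;
      fmat S = lc.Q.cols(c0, c1) * lc.K.cols(c0, c1).t() * scale;
      softmaxRows(S);
      lc.O.cols(c0, c1) = S * lc.V.cols(c0, c1);
      lc.A[h] = std::move(S);
    }
    lc.attnOut = lc.O * l.Wo;
    lc.attnOut.each_row() += l.bo.row(0);
    if (drop) {
      lc.attnMask = dropMask(n, c.d, c.dropout, *rng);
      lc.attnOut %= lc.attnMask;
    }
    lc.Xmid = X + lc.attnOut;
    lc.Y2 = lnFwd(lc.Xmid, l.ln2g, l.ln2b, lc.ln2);
    lc.Hff = lc.Y2 * l.W1; lc.Hff.each_row() += l.b1.row(0);
    lc.Aff = geluFwd(lc.Hff);
    fmat F = lc.Aff * l.W2; F.each_row() += l.b2.row(0);
    if (drop) {
      lc.ffMask = dropMask(n, c.d, c.dropout, *rng);
      F %= lc.ffMask;
    }
    X = lc.Xmid + F;
  }

  LnCache tmpLn;
  LnCache& lnf = cache ? cache->lnf : tmpLn;
  if (cache) cache->Xf = X;
  fmat Hf = lnFwd(X, M.lnfg, M.lnfb, lnf);
  if (cache) cache->Hf = Hf;
  frowvec logits = Hf.row(0) * M.Wc + M.bc.row(0);
  float mx = logits.max();
  frowvec ex = exp(logits - mx);
  fvec probs = (ex / accu(ex)).t();
  if (cache) { cache->probs = probs; cache->logits = logits.t(); }
  return probs;
}

// Backward through one cached forward. `dlogits` is the gradient at the
// two logits; accumulates parameter gradients into G and returns the
// gradient at the (post-dropout) input embeddings.
static fmat backwardSeq(const Model& M, const Cfg& c, const ivec& toks,
                        const FwdCache& cache, fvec dlogits, Model& G,
                        bool wantInputGrad) {
  const int n = toks.n_elem;
  const float scale = 1.0f / std::sqrt((float)c.dh);
  const bool drop = cache.embMask.n_elem > 0;

  // classifier head
  G.Wc += cache.Hf.row(0).t() * dlogits.t();
  G.bc.row(0) += dlogits.t();
  fmat dHf(n, c.d, fill::zeros);
  dHf.row(0) = dlogits.t() * M.Wc.t();
  fmat dX = lnBwd(dHf, cache.lnf, M.lnfg, G.lnfg, G.lnfb);

  for (int li = c.L - 1; li >= 0; --li) {
    const Layer& l = M.layers[li];
    const LayerCache& lc = cache.lc[li];
    Layer& g = G.layers[li];

    // FFN branch
    fmat dF = dX;
    if (drop) dF %= lc.ffMask;
    g.W2 += lc.Aff.t() * dF;
    g.b2.row(0) += sum(dF, 0);
    fmat dAff = dF * l.W2.t();
    fmat dHffm = geluBwd(lc.Hff, dAff);
    g.W1 += lc.Y2.t() * dHffm;
    g.b1.row(0) += sum(dHffm, 0);
    fmat dY2 = dHffm * l.W1.t();
    fmat dXmid = dX + lnBwd(dY2, lc.ln2, l.ln2g, g.ln2g, g.ln2b);

    // attention branch
    fmat dAttn = dXmid;
    if (drop) dAttn %= lc.attnMask;
    g.Wo += lc.O.t() * dAttn;
    g.bo.row(0) += sum(dAttn, 0);
    fmat dO = dAttn * l.Wo.t();
    fmat dQ(n, c.d), dK(n, c.d), dV(n, c.d);
    for (int h = 0; h < c.H; ++h) {
      const uword c0 = h * c.dh, c1 = (h + 1) * c.dh - 1;
      const fmat& A = lc.A[h];
      fmat dOh = dO.cols(c0, c1);
      fmat dA = dOh * lc.V.cols(c0, c1).t();
      dV.cols(c0, c1) = A.t() * dOh;
      fvec rowdot = sum(dA % A, 1);
      dA.each_col() -= rowdot;
      fmat dS = A % dA;
      dQ.cols(c0, c1) = dS * lc.K.cols(c0, c1) * scale;
      dK.cols(c0, c1) = dS.t() * lc.Q.cols(c0, c1) * scale;
    }
    g.Wq += lc.Y1.t() * dQ; g.bq.row(0) += sum(dQ, 0);
    g.Wk += lc.Y1.t() * dK; g.bk.row(0) += sum(dK, 0);
    g.Wv += lc.Y1.t() * dV; g.bv.row(0) += sum(dV, 0);
    fmat dY1 = dQ * l.Wq.t() + dK * l.Wk.t() + dV * l.Wv.t();
    dX = dXmid + lnBwd(dY1, lc.ln1, l.ln1g, g.ln1g, g.ln1b);
  }

  fmat dX0 = dX;
  if (drop) dX %= cache.embMask;
  for (int i = 0; i < n; ++i) {
    G.E.row(toks(i)) += dX.row(i);
    G.P.row(i) += dX.row(i);
  }
  return wantInputGrad ? dX0 : fmat();
}

static ivec toksFromR(const IntegerVector& tv, const Cfg& c) {
  ivec t(tv.size());
  for (int i = 0; i < tv.size(); ++i) {
    int id = tv[i] - 1;
    if (id < 0 || id >= c.V) Rcpp::stop("token id out of range");
    t(i) = id;
  }
  if ((int)t.n_elem > c.maxLen)
    Rcpp::stop("sequence longer than maxSeqLength after encoding");
  if (t.n_elem < 1) Rcpp::stop("empty token sequence");
  return t;
}

// ---------------------------------------------------------------------
// entry points

// [[Rcpp::export(name = ".cpp_init_weights")]]
List cppInitWeights(List cfgList, int seed) {
  Cfg c = cfgFromList(cfgList);
  std::mt19937_64 rng((uint64_t)seed);
  Model m = initModel(c, rng);
  return modelToList(m);
}

// [[Rcpp::export(name = ".cpp_predict")]]
NumericMatrix cppPredict(List weights, List cfgList, List tokensList) {
  Cfg c = cfgFromList(cfgList);
  Model m = modelFromList(weights, c);
  NumericMatrix out(tokensList.size(), 2);
  for (int i = 0; i < tokensList.size(); ++i) {
    ivec t = toksFromR(tokensList[i], c);
    fvec p = forwardSeq(m, c, t, false, nullptr, nullptr);
    out(i, 0) = p(0); out(i, 1) = p(1);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_train")]]
List cppTrain(List tokensList, IntegerVector labels, List evalTokensList,
              IntegerVector evalLabels, List cfgList, double lr,
              double epochs, int batchSize, double warmupFraction,
              double weightDecay, int loggingSteps, int seed) {
  Cfg c = cfgFromList(cfgList);
  const int n = tokensList.size();
  if (n == 0) Rcpp::stop("empty training set");
  std::vector<ivec> toks(n);
  for (int i = 0; i < n; ++i)
    toks[i] = toksFromR(tokensList[i], c);
  const int nEval = evalTokensList.size();
  std::vector<ivec> etoks(nEval);
  for (int i = 0; i < nEval; ++i)
    etoks[i] = toksFromR(evalTokensList[i], c);

  std::mt19937_64 rng((uint64_t)seed);
  Model m = initModel(c, rng);
  Model grad = zerosModel(c), adamM = zerosModel(c), adamV = zerosModel(c);
  std::vector<fmat*> pw, pg, pm, pv;
  std::vector<bool> dec, dum;
  std::vector<std::string> nm;
  collectParams(m, pw, dec, nm);
  collectParams(grad, pg, dum, nm);
  collectParams(adamM, pm, dum, nm);
  collectParams(adamV, pv, dum, nm);

  const int stepsPerEpoch = (n + batchSize - 1) / batchSize;
  const int totalSteps = (int)std::ceil(epochs * stepsPerEpoch);
  const int warmupSteps = (int)std::lround(warmupFraction * totalSteps);
  const float b1 = 0.9f, b2 = 0.999f, adamEps = 1e-8f;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  int ptr = 0;

  std::vector<int> logStep;
  std::vector<double> logLr, logLoss, logEvalLoss, logEvalAcc;
  double lossAccum = 0.0;
  int lossCount = 0;

  auto evalPass = [&](double& evLoss, double& evAcc) {
    if (nEval == 0) { evLoss = NA_REAL; evAcc = NA_REAL; return; }
    double s = 0.0; int correct = 0;
    for (int i = 0; i < nEval; ++i) {
      fvec p = forwardSeq(m, c, etoks[i], false, nullptr, nullptr);
      int y = evalLabels[i];
      s += -std::log(std::max(p(y), 1e-12f));
      if ((p(1) >= 0.5f ? 1 : 0) == y) ++correct;
    }
    evLoss = s / nEval;
    evAcc = (double)correct / nEval;
  };

  for (int step = 0; step < totalSteps; ++step) {
    for (auto* g : pg) g->zeros();
    int used = 0;
    double stepLoss = 0.0;
    for (int bi = 0; bi < batchSize; ++bi) {
      if (ptr >= n) {
        std::shuffle(order.begin(), order.end(), rng);
        ptr = 0;
      }
      int idx = order[ptr++];
      FwdCache cache;
      fvec p = forwardSeq(m, c, toks[idx], true, &rng, &cache);
      int y = labels[idx];
      stepLoss += -std::log(std::max(p(y), 1e-12f));
      fvec dlog = p;
      dlog(y) -= 1.0f;
      backwardSeq(m, c, toks[idx], cache, dlog, grad, false);
      ++used;
    }
    stepLoss /= used;
    lossAccum += stepLoss; ++lossCount;

    float lrT;
    if (totalSteps <= 1) lrT = (float)lr;
    else if (step < warmupSteps)
      lrT = (float)lr * (float)(step + 1) / std::max(1, warmupSteps);
    else
      lrT = (float)lr *
        (float)(totalSteps - step) /
        std::max(1, totalSteps - warmupSteps);

    const float bc1 = 1.0f - std::pow(b1, (float)(step + 1));
    const float bc2 = 1.0f - std::pow(b2, (float)(step + 1));
    for (size_t i = 0; i < pw.size(); ++i) {
      fmat g = *pg[i] / (float)used;
      *pm[i] = b1 * (*pm[i]) + (1.0f - b1) * g;
      *pv[i] = b2 * (*pv[i]) + (1.0f - b2) * (g % g);
      fmat upd = (*pm[i] / bc1) / (sqrt(*pv[i] / bc2) + adamEps);
      if (dec[i] && weightDecay > 0)
        upd += (float)weightDecay * (*pw[i]);
      *pw[i] -= lrT * upd;
    }

    if ((step + 1) % loggingSteps == 0 || step + 1 == totalSteps) {
      double evLoss, evAcc;
      evalPass(evLoss, evAcc);
      logStep.push_back(step + 1);
      logLr.push_back(lrT);
      logLoss.push_back(lossAccum / lossCount);
      logEvalLoss.push_back(evLoss);
      logEvalAcc.push_back(evAcc);
      lossAccum = 0.0; lossCount = 0;
    }
  }

  List logDf = List::create(
    Rcpp::Named("step") = logStep,
    Rcpp::Named("lr") = logLr,
    Rcpp::Named("train_loss") = logLoss,
    Rcpp::Named("eval_loss") = logEvalLoss,
    Rcpp::Named("eval_accuracy") = logEvalAcc);
  return List::create(Rcpp::Named("weights") = modelToList(m),
                      Rcpp::Named("log") = logDf,
                      Rcpp::Named("total_steps") = totalSteps);
}

// Occlusion attribution: for each content token (CLS and SEP excluded),
// score = p_lncRNA(full) - p_lncRNA(token replaced by [MASK]).
// [[Rcpp::export(name = ".cpp_occlusion")]]
NumericVector cppOcclusion(List weights, List cfgList, IntegerVector tokens,
                           int maskId) {
  Cfg c = cfgFromList(cfgList);
  Model m = modelFromList(weights, c);
  ivec t = toksFromR(tokens, c);
  const int n = t.n_elem;
  if (n < 3) return NumericVector(0);
  fvec pFull = forwardSeq(m, c, t, false, nullptr, nullptr);
  NumericVector out(n - 2);
  ivec tm = t;
  for (int i = 1; i < n - 1; ++i) {
    sword keep = tm(i);
    tm(i) = maskId - 1;
    fvec p = forwardSeq(m, c, tm, false, nullptr, nullptr);
    out[i - 1] = (double)pFull(1) - (double)p(1);
    tm(i) = keep;
  }
  return out;
}

// Gradient-times-input attribution: gradient of the logit margin
// (lncRNA minus non-lncRNA) at the input embeddings, dotted with the
// embeddings, per content token.
// [[Rcpp::export(name = ".cpp_grad_input")]]
NumericVector cppGradInput(List weights, List cfgList,
                           IntegerVector tokens) {
  Cfg c = cfgFromList(cfgList);
  Model m = modelFromList(weights, c);
  ivec t = toksFromR(tokens, c);
  const int n = t.n_elem;
  if (n < 3) return NumericVector(0);
  FwdCache cache;
  forwardSeq(m, c, t, false, nullptr, &cache);
  Model g = zerosModel(c);
  fvec dlog = {-1.0f, 1.0f};
  fmat dX0 = backwardSeq(m, c, t, cache, dlog, g, true);
  NumericVector out(n - 2);
  for (int i = 1; i < n - 1; ++i)
    out[i - 1] = dot(dX0.row(i), cache.X0.row(i));
  return out;
}

// Loss and full parameter gradients for one example; used by the
// finite-difference gradient check in the test suite.
// [[Rcpp::export(name = ".cpp_loss_grads")]]
List cppLossGrads(List weights, List cfgList, IntegerVector tokens,
                  int label) {
  Cfg c = cfgFromList(cfgList);
  Model m = modelFromList(weights, c);
  ivec t = toksFromR(tokens, c);
  FwdCache cache;
  fvec p = forwardSeq(m, c, t, false, nullptr, &cache);
  double loss = -std::log(std::max(p(label), 1e-12f));
  Model g = zerosModel(c);
  fvec dlog = p;
  dlog(label) -= 1.0f;
  backwardSeq(m, c, t, cache, dlog, g, false);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = modelToList(g));
}

// [[Rcpp::export(name = ".cpp_loss")]]
double cppLoss(List weights, List cfgList, IntegerVector tokens,
               int label) {
  Cfg c = cfgFromList(cfgList);
  Model m = modelFromList(weights, c);
  ivec t = toksFromR(tokens, c);
  fvec p = forwardSeq(m, c, t, false, nullptr, nullptr);
  return -std::log(std::max(p(label), 1e-12f));
}
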