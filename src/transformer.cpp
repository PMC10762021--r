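// Per-exon transformer kernels: forward, backward (parameter gradients) and
// gradient-weighted attention relevance. Sequences are stored rows = tokens
// (row 0 = chromosome classification token), cols = embedding dimensions, so
// linear layers right-multiply. Padded positions are never materialised: the
// classification head reads only the token row and padded keys are excluded
// from attention, so dropping padded columns is exactly equivalent to running
// the full padded sequence with a key-padding mask.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LN_EPS = 1e-5;
static const double INV_SQRT2 = 0.70710678118654752440;
static const double INV_SQRT2PI = 0.39894228040143267794;

struct BlockParams {
  vec ln1_g, ln1_b, bq, bk, bv, bo, ln2_g, ln2_b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct Params {
  int H, L, heads, mlp_hidden;
  vec embed_w, embed_b;
  mat C;
  std::vector<BlockParams> blocks;
  mat hW1, hW2;
  vec hb1, hb2;
};

static Params unpack(const Rcpp::List& par, const Rcpp::List& cfg) {
  Params p;
  p.H = Rcpp::as<int>(cfg["H"]);
  p.L = Rcpp::as<int>(cfg["L"]);
  p.heads = Rcpp::as<int>(cfg["heads"]);
  p.mlp_hidden = Rcpp::as<int>(cfg["mlp_hidden"]);
  p.embed_w = Rcpp::as<vec>(par["embed_w"]);
  p.embed_b = Rcpp::as<vec>(par["embed_b"]);
  p.C = Rcpp::as<mat>(par["C"]);
  Rcpp::List blocks = par["blocks"];
  for (int l = 0; l < p.L; ++l) {
    Rcpp::List b = blocks[l];
    BlockParams bp;
    bp.ln1_g = Rcpp::as<vec>(b["ln1_g"]); bp.ln1_b = Rcpp::as<vec>(b["ln1_b"]);
    bp.Wq = Rcpp::as<mat>(b["Wq"]); bp.bq = Rcpp::as<vec>(b["bq"]);
    bp.Wk = Rcpp::as<mat>(b["Wk"]); bp.bk = Rcpp::as<vec>(b["bk"]);
    bp.Wv = Rcpp::as<mat>(b["Wv"]); bp.bv = Rcpp::as<vec>(b["bv"]);
    bp.Wo = Rcpp::as<mat>(b["Wo"]); bp.bo = Rcpp::as<vec>(b["bo"]);
    bp.ln2_g = Rcpp::as<vec>(b["ln2_g"]); bp.ln2_b = Rcpp::as<vec>(b["ln2_b"]);
    bp.W1 = Rcpp::as<mat>(b["W1"]); bp.b1 = Rcpp::as<vec>(b["b1"]);
    bp.W2 = Rcpp::as<mat>(b["W2"]); bp.b2 = Rcpp::as<vec>(b["b2"]);
    p.blocks.push_back(bp);
  }
  Rcpp::List head = par["head"];
  p.hW1 = Rcpp::as<mat>(head["W1"]); p.hb1 = Rcpp::as<vec>(head["b1"]);
  p.hW2 = Rcpp::as<mat>(head["W2"]); p.hb2 = Rcpp::as<vec>(head["b2"]);
  return p;
}

// ---- gradient accumulators, mirroring Params ---------------------------------
struct BlockGrads {
  vec ln1_g, ln1_b, bq, bk, bv, bo, ln2_g, ln2_b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct Grads {
  vec embed_w, embed_b;
  mat C;
  std::vector<BlockGrads> blocks;
  mat hW1, hW2;
  vec hb1, hb2;
  void init(const Params& p) {
    embed_w.zeros(p.H); embed_b.zeros(p.H); C.zeros(p.H, p.C.n_cols);
    blocks.resize(p.L);
    for (int l = 0; l < p.L; ++l) {
      BlockGrads& g = blocks[l];
      g.ln1_g.zeros(p.H); g.ln1_b.zeros(p.H);
      g.Wq.zeros(p.H, p.H); g.bq.zeros(p.H);
      g.Wk.zeros(p.H, p.H); g.bk.zeros(p.H);
      g.Wv.zeros(p.H, p.H); g.bv.zeros(p.H);
      g.Wo.zeros(p.H, p.H); g.bo.zeros(p.H);
      g.ln2_g.zeros(p.H); g.ln2_b.zeros(p.H);
      g.W1.zeros(p.H, p.mlp_hidden); g.b1.zeros(p.mlp_hidden);
      g.W2.zeros(p.mlp_hidden, p.H); g.b2.zeros(p.H);
    }
    hW1.zeros(p.H, p.mlp_hidden); hb1.zeros(p.mlp_hidden);
    hW2.zeros(p.mlp_hidden, 3); hb2.zeros(3);
  }
};

static Rcpp::List grads_to_list(const Grads& g, const Params& p) {
  Rcpp::List blocks(p.L);
  for (int l = 0; l < p.L; ++l) {
    const BlockGrads& b = g.blocks[l];
    blocks[l] = Rcpp::List::create(
      Rcpp::Named("ln1_g") = b.ln1_g, Rcpp::Named("ln1_b") = b.ln1_b,
      Rcpp::Named("Wq") = b.Wq, Rcpp::Named("bq") = b.bq,
      Rcpp::Named("Wk") = b.Wk, Rcpp::Named("bk") = b.bk,
      Rcpp::Named("Wv") = b.Wv, Rcpp::Named("bv") = b.bv,
      Rcpp::Named("Wo") = b.Wo, Rcpp::Named("bo") = b.bo,
      Rcpp::Named("ln2_g") = b.ln2_g, Rcpp::Named("ln2_b") = b.ln2_b,
      Rcpp::Named("W1") = b.W1, Rcpp::Named("b1") = b.b1,
      Rcpp::Named("W2") = b.W2, Rcpp::Named("b2") = b.b2);
  }
  return Rcpp::List::create(
    Rcpp::Named("embed_w") = g.embed_w, Rcpp::Named("embed_b") = g.embed_b,
    Rcpp::Named("C") = g.C, Rcpp::Named("blocks") = blocks,
    Rcpp::Named("head") = Rcpp::List::create(
      Rcpp::Named("W1") = g.hW1, Rcpp::Named("b1") = g.hb1,
      Rcpp::Named("W2") = g.hW2, Rcpp::Named("b2") = g.hb2));
}

// ---- nonlinearities ----------------------------------------------------------
static mat gelu(const mat& x) {
  mat phi = x * INV_SQRT2;
  phi.transform([](double v) { return 0.5 * (1.0 + std::erf(v)); });
  return x % phi;
}
static mat gelu_grad(const mat& x) {
  mat cdf = x * INV_SQRT2;
  cdf.transform([](double v) { return 0.5 * (1.0 + std::erf(v)); });
  mat pdf = exp(-0.5 * square(x)) * INV_SQRT2PI;
  return cdf + x % pdf;
}

// Row-wise layer norm; returns y, stores xhat and inverse sd.
static mat layernorm(const mat& x, const vec& g, const vec& b,
                     mat& xhat, vec& inv_sd) {
  vec mu = mean(x, 1);
  mat cent = x.each_col() - mu;
  vec v = mean(square(cent), 1);
  inv_sd = 1.0 / sqrt(v + LN_EPS);
  xhat = cent.each_col() % inv_sd;
  mat y = xhat.each_row() % g.t();
  y.each_row() += b.t();
  return y;
}

// Backward through layer norm. dY -> dX; accumulates dg, db.
static mat layernorm_bwd(const mat& dY, const mat& xhat, const vec& inv_sd,
                         const vec& g, vec& dg, vec& db) {
  dg += sum(dY % xhat, 0).t();
  db += sum(dY, 0).t();
  mat dxhat = dY.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv_sd;
  return dX;
}

// ---- forward cache -----------------------------------------------------------
struct BlockCache {
  mat X_in;              // O_{l-1}
  mat xhat1; vec inv1;   // LN before attention
  mat Q, K, V;           // projected (n x H)
  std::vector<mat> S;    // per-head attention maps (n x n)
  mat att;               // concatenated head outputs, pre-Wo
  mat O_mid;             // after attention residual
  mat xhat2; vec inv2;   // LN before MLP
  mat H1;                // MLP pre-activation (n x M)
  mat G1;                // gelu(H1)
};

struct Cache {
  std::vector<BlockCache> blocks;
  mat O_final;
  rowvec tok, h1, g1;    // head intermediates
  vec probs, logits;
};

// Builds O_0 = [token; per-base embedding] + positional encoding.
static mat input_matrix(const Params& p, const vec& x, const vec& loc,
                        int chrom) {
  int n = x.n_elem;
  mat X(n + 1, p.H);
  X.row(0) = p.C.col(chrom - 1).t();
  X.rows(1, n) = x * p.embed_w.t();
  X.rows(1, n).each_row() += p.embed_b.t();
  vec full_loc(n + 1);
  full_loc(0) = 0.0;
  full_loc.subvec(1, n) = loc;
  for (int j = 0; j < p.H / 2; ++j) {
    double denom = std::pow(10.0, 9.0 * 2.0 * j / p.H);
    X.col(2 * j) += sin(full_loc / denom);
    X.col(2 * j + 1) += cos(full_loc / denom);
  }
  return X;
}

static vec forward_exon(const Params& p, const vec& x, const vec& loc,
                        int chrom, Cache& cache) {
  int n = x.n_elem;
  int d = p.H / p.heads;
  double scale = 1.0 / std::sqrt((double)d);
  mat O = input_matrix(p, x, loc, chrom);
  cache.blocks.resize(p.L);
  for (int l = 0; l < p.L; ++l) {
    const BlockParams& bp = p.blocks[l];
    BlockCache& bc = cache.blocks[l];
    bc.X_in = O;
    mat A = layernorm(O, bp.ln1_g, bp.ln1_b, bc.xhat1, bc.inv1);
    bc.Q = A * bp.Wq; bc.Q.each_row() += bp.bq.t();
    bc.K = A * bp.Wk; bc.K.each_row() += bp.bk.t();
    bc.V = A * bp.Wv; bc.V.each_row() += bp.bv.t();
    bc.att.set_size(n + 1, p.H);
    bc.S.resize(p.heads);
    for (int h = 0; h < p.heads; ++h) {
      int c0 = h * d, c1 = (h + 1) * d - 1;
      mat Z = bc.Q.cols(c0, c1) * bc.K.cols(c0, c1).t() * scale;
      Z.each_col() -= max(Z, 1);
      mat S = exp(Z);
      S.each_col() /= sum(S, 1);
      bc.S[h] = S;
      bc.att.cols(c0, c1) = S * bc.V.cols(c0, c1);
    }
    mat att_out = bc.att * bp.Wo;
    att_out.each_row() += bp.bo.t();
    bc.O_mid = O + att_out;
    mat B = layernorm(bc.O_mid, bp.ln2_g, bp.ln2_b, bc.xhat2, bc.inv2);
    bc.H1 = B * bp.W1; bc.H1.each_row() += bp.b1.t();
    bc.G1 = gelu(bc.H1);
    mat mlp_out = bc.G1 * bp.W2;
    mlp_out.each_row() += bp.b2.t();
    O = bc.O_mid + mlp_out;
  }
  cache.O_final = O;
  cache.tok = O.row(0);
  cache.h1 = cache.tok * p.hW1 + p.hb1.t();
  rowvec g1cdf = cache.h1 * INV_SQRT2;
  g1cdf.transform([](double v) { return 0.5 * (1.0 + std::erf(v)); });
  cache.g1 = cache.h1 % g1cdf;
  rowvec lg = cache.g1 * p.hW2 + p.hb2.t();
  cache.logits = lg.t();
  vec e = exp(cache.logits - cache.logits.max());
  cache.probs = e / accu(e);
  if (!cache.probs.is_finite())
    Rcpp::stop("non-finite activations in classification head");
  return cache.probs;
}

// Backward from dlogits. Accumulates parameter gradients into g and returns
// the gradient at O_0 through dO_out; if attn_grads is non-null, stores
// per-block per-head dL/dA (gradient w.r.t. the post-softmax attention map)
// for relevance propagation.
static void backward_exon(const Params& p, const Cache& cache, vec dlogits,
                          Grads& g, mat& dO_out,
                          std::vector<std::vector<mat> >* attn_grads) {
  int n1 = cache.O_final.n_rows;           // n + 1 tokens
  int n = n1 - 1;
  int d = p.H / p.heads;
  double scale = 1.0 / std::sqrt((double)d);

  // head
  g.hW2 += cache.g1.t() * dlogits.t();
  g.hb2 += dlogits;
  rowvec dg1 = dlogits.t() * p.hW2.t();
  mat h1m(cache.h1);
  rowvec dh1 = dg1 % conv_to<rowvec>::from(gelu_grad(h1m));
  g.hW1 += cache.tok.t() * dh1;
  g.hb1 += dh1.t();
  rowvec dtok = dh1 * p.hW1.t();
  mat dO(n1, p.H, fill::zeros);
  dO.row(0) = dtok;

  if (attn_grads) attn_grads->resize(p.L);

  for (int l = p.L - 1; l >= 0; --l) {
    const BlockParams& bp = p.blocks[l];
    const BlockCache& bc = cache.blocks[l];
    BlockGrads& bg = g.blocks[l];
    // MLP branch
    g.blocks[l].W2 += bc.G1.t() * dO;
    bg.b2 += sum(dO, 0).t();
    mat dG1 = dO * bp.W2.t();
    mat dH1 = dG1 % gelu_grad(bc.H1);
    mat B = bc.xhat2.each_row() % bp.ln2_g.t();   // reconstruct LN2 output
    B.each_row() += bp.ln2_b.t();
    bg.W1 += B.t() * dH1;
    bg.b1 += sum(dH1, 0).t();
    mat dB = dH1 * bp.W1.t();
    mat dO_mid = dO + layernorm_bwd(dB, bc.xhat2, bc.inv2, bp.ln2_g,
                                    bg.ln2_g, bg.ln2_b);
    // attention branch
    bg.Wo += bc.att.t() * dO_mid;
    bg.bo += sum(dO_mid, 0).t();
    mat datt = dO_mid * bp.Wo.t();
    mat dQ(n1, p.H, fill::zeros), dK(n1, p.H, fill::zeros),
        dV(n1, p.H, fill::zeros);
    if (attn_grads) (*attn_grads)[l].resize(p.heads);
    for (int h = 0; h < p.heads; ++h) {
      int c0 = h * d, c1 = (h + 1) * d - 1;
      const mat& S = bc.S[h];
      dV.cols(c0, c1) = S.t() * datt.cols(c0, c1);
      mat dS = datt.cols(c0, c1) * bc.V.cols(c0, c1).t();
      if (attn_grads) (*attn_grads)[l][h] = dS;
      mat dZ = S % (dS.each_col() - sum(dS % S, 1));
      dZ *= scale;
      dQ.cols(c0, c1) = dZ * bc.K.cols(c0, c1);
      dK.cols(c0, c1) = dZ.t() * bc.Q.cols(c0, c1);
    }
    mat A = bc.xhat1.each_row() % bp.ln1_g.t();   // reconstruct LN1 output
    A.each_row() += bp.ln1_b.t();
    bg.Wq += A.t() * dQ; bg.bq += sum(dQ, 0).t();
    bg.Wk += A.t() * dK; bg.bk += sum(dK, 0).t();
    bg.Wv += A.t() * dV; bg.bv += sum(dV, 0).t();
    mat dA = dQ * bp.Wq.t() + dK * bp.Wk.t() + dV * bp.Wv.t();
    dO = dO_mid + layernorm_bwd(dA, bc.xhat1, bc.inv1, bp.ln1_g,
                                bg.ln1_g, bg.ln1_b);
  }

  g.embed_b += sum(dO.rows(1, n), 0).t();
  dO_out = dO;
}

static void accumulate_input_grads(Grads& g, const mat& dO, const vec& x,
                                   int chrom) {
  int n = x.n_elem;
  g.C.col(chrom - 1) += dO.row(0).t();
  g.embed_w += dO.rows(1, n).t() * x;
  // embed_b accumulated inside backward_exon
}

// ---- exported entry points ---------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_input_matrix(Rcpp::List params, Rcpp::List cfg,
                           arma::vec x, arma::vec loc, int chrom) {
  Params p = unpack(params, cfg);
  return input_matrix(p, x, loc, chrom);
}

// [[Rcpp::export]]
arma::mat cpp_forward_batch(Rcpp::List params, Rcpp::List cfg,
                            Rcpp::List xs, Rcpp::List locs,
                            Rcpp::IntegerVector chroms) {
  Params p = unpack(params, cfg);
  int m = xs.size();
  mat out(m, 3);
  for (int i = 0; i < m; ++i) {
    vec x = Rcpp::as<vec>(xs[i]);
    vec loc = Rcpp::as<vec>(locs[i]);
    Cache cache;
    out.row(i) = forward_exon(p, x, loc, chroms[i], cache).t();
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Sum of weighted cross-entropy loss and parameter gradients over a batch.
// ys: 1=DEL, 2=DUP, 3=NOCALL. cls_w: per-class loss weights.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad_batch(Rcpp::List params, Rcpp::List cfg,
                               Rcpp::List xs, Rcpp::List locs,
                               Rcpp::IntegerVector chroms,
                               Rcpp::IntegerVector ys,
                               arma::vec cls_w) {
  Params p = unpack(params, cfg);
  Grads g; g.init(p);
  int m = xs.size();
  double loss = 0.0;
  for (int i = 0; i < m; ++i) {
    vec x = Rcpp::as<vec>(xs[i]);
    vec loc = Rcpp::as<vec>(locs[i]);
    int y = ys[i];
    Cache cache;
    vec probs = forward_exon(p, x, loc, chroms[i], cache);
    double w = cls_w(y - 1);
    double pl = std::max(probs(y - 1), 1e-12);
    loss += -w * std::log(pl);
    vec onehot(3, fill::zeros); onehot(y - 1) = 1.0;
    vec dlogits = w * (probs - onehot);
    mat dO0;
    backward_exon(p, cache, dlogits, g, dO0, nullptr);
    accumulate_input_grads(g, dO0, x, chroms[i]);
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads_to_list(g, p),
                            Rcpp::Named("n") = m);
}

// Gradient-weighted attention relevance (generic attention explainability for
// softmax attention): R = I, then R <- R + mean_h[(dA ⊙ A)^+] R per block,
// front to back; relevance of the depth positions is the token row of R.
// [[Rcpp::export]]
arma::vec cpp_relevance(Rcpp::List params, Rcpp::List cfg,
                        arma::vec x, arma::vec loc, int chrom,
                        int target_class, int from_block) {
  Params p = unpack(params, cfg);
  Cache cache;
  forward_exon(p, x, loc, chrom, cache);
  Grads g; g.init(p);
  vec dlogits(3, fill::zeros);
  dlogits(target_class - 1) = 1.0;   // gradient of the target-class score
  std::vector<std::vector<mat> > attn_grads;
  mat dO0;
  backward_exon(p, cache, dlogits, g, dO0, &attn_grads);
  int n1 = x.n_elem + 1;
  mat R = eye(n1, n1);
  for (int l = std::max(0, from_block - 1); l < p.L; ++l) {
    mat Ebar(n1, n1, fill::zeros);
    for (int h = 0; h < p.heads; ++h) {
      mat w = attn_grads[l][h] % cache.blocks[l].S[h];
      w.transform([](double v) { return v > 0.0 ? v : 0.0; });
      Ebar += w;
    }
    Ebar /= (double)p.heads;
    R = R + Ebar * R;
  }
  return R.row(0).subvec(1, n1 - 1).t();
}
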