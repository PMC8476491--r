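// Autoregressive sequence model: embedding -> dilated causal convolution
// blocks (residual) -> optional causally masked self-attention -> linear
// softmax output. Forward, exact backward, and an Adam training loop with
// the two-rate learning schedule and optional teacher distillation term.
//
// Row layout for activations: row r = b*L + t (sample-major), so a causal
// shift by d within each sample is a block copy.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

struct Cfg {
  int K, Kin, L, De, C, kernel, heads, Da, nb, bos;
  std::vector<int> dil;
};

static Cfg parseCfg(const List& cfg) {
  Cfg c;
  c.K = as<int>(cfg["K"]);
  c.Kin = as<int>(cfg["Kin"]);
  c.L = as<int>(cfg["L"]);
  c.De = as<int>(cfg["De"]);
  c.C = as<int>(cfg["C"]);
  c.kernel = as<int>(cfg["kernel"]);
  IntegerVector d = cfg["dil"];
  c.dil = std::vector<int>(d.begin(), d.end());
  c.nb = (int)c.dil.size();
  c.heads = as<int>(cfg["heads"]);
  c.Da = as<int>(cfg["Da"]);
  c.bos = c.Kin - 1;  // begin-of-sequence code is the last embedding row
  return c;
}

// fixed parameter ordering shared with the R constructor
struct PIdx {
  int emb, pos, W_in, b_in, convBase, attBase, W_out, b_out, n;
  int kernel;
  explicit PIdx(const Cfg& c) {
    kernel = c.kernel;
    emb = 0; pos = 1; W_in = 2; b_in = 3; convBase = 4;
    attBase = convBase + c.nb * (c.kernel + 1);
    int a = (c.heads > 0) ? 5 : 0;
    W_out = attBase + a;
    b_out = W_out + 1;
    n = b_out + 1;
  }
  int Wc(int b, int j) const { return convBase + b * (kernel + 1) + j; }
  int bc(int b) const { return convBase + b * (kernel + 1) + kernel; }
};

static std::vector<mat> paramsFromList(const List& p) {
  std::vector<mat> P;
  P.reserve(p.size());
  for (int i = 0; i < p.size(); i++) P.push_back(as<mat>(p[i]));
  return P;
}

static List paramsToList(const std::vector<mat>& P, const List& proto) {
  List out(proto.size());
  out.attr("names") = proto.attr("names");
  for (size_t i = 0; i < P.size(); i++) out[i] = wrap(P[i]);
  return out;
}

// causal shift by d positions within each sample (zero padding)
static mat shiftRows(const mat& H, int d, int B, int L) {
  if (d == 0) return H;
  mat out(H.n_rows, H.n_cols, fill::zeros);
  if (d >= L) return out;
  for (int b = 0; b < B; b++) {
    int base = b * L;
    out.rows(base + d, base + L - 1) = H.rows(base, base + L - 1 - d);
  }
  return out;
}

static void unshiftAdd(mat& acc, const mat& G, int d, int B, int L) {
  if (d == 0) { acc += G; return; }
  if (d >= L) return;
  for (int b = 0; b < B; b++) {
    int base = b * L;
    acc.rows(base, base + L - 1 - d) += G.rows(base + d, base + L - 1);
  }
}

struct Cache {
  int B;
  Mat<int> Xin;                 // shifted input codes, B x L
  mat H0, A0, Hin;
  std::vector<mat> Hpre, Zb;    // per conv block
  mat Hconv, Q, Km, V, Concat;
  std::vector<mat> S;           // per sample per head, L x L softmaxed
  mat Hatt, logits, logp;
};

static void softmaxRowsInplace(mat& M) {
  vec mx = max(M, 1);
  M.each_col() -= mx;
  M = exp(M);
  vec s = sum(M, 1);
  M.each_col() /= s;
}

static void logSoftmaxRowsInplace(mat& M) {
  vec mx = max(M, 1);
  M.each_col() -= mx;
  vec lse = log(sum(exp(M), 1));
  M.each_col() -= lse;
}

static void forwardPass(const std::vector<mat>& P, const Cfg& c, const PIdx& ix,
                        const Mat<int>& X, Cache& ca, bool wantLogp) {
  int B = X.n_rows, L = c.L, BL = B * L;
  ca.B = B;
  ca.Xin.set_size(B, L);
  for (int b = 0; b < B; b++) {
    ca.Xin(b, 0) = c.bos;
    for (int t = 1; t < L; t++) ca.Xin(b, t) = X(b, t - 1);
  }
  uvec embIdx(BL);
  for (int b = 0; b < B; b++)
    for (int t = 0; t < L; t++)
      embIdx[b * L + t] = (uword)ca.Xin(b, t);
  ca.H0 = P[ix.emb].rows(embIdx);
  for (int b = 0; b < B; b++)   // learned positional embedding, additive
    ca.H0.rows(b * L, b * L + L - 1) += P[ix.pos];
  ca.A0 = ca.H0 * P[ix.W_in];
  ca.A0.each_row() += P[ix.b_in].row(0);
  ca.Hin = clamp(ca.A0, 0.0, datum::inf);
  mat H = ca.Hin;
  ca.Hpre.clear(); ca.Zb.clear();
  for (int b = 0; b < c.nb; b++) {
    ca.Hpre.push_back(H);
    mat Z(BL, c.C, fill::zeros);
    Z.each_row() += P[ix.bc(b)].row(0);
    for (int j = 0; j < c.kernel; j++)
      Z += shiftRows(H, j * c.dil[b], B, L) * P[ix.Wc(b, j)];
    ca.Zb.push_back(Z);
    H += clamp(Z, 0.0, datum::inf);
  }
  ca.Hconv = H;
  if (c.heads > 0) {
    ca.Q = H * P[ix.attBase + 0];
    ca.Km = H * P[ix.attBase + 1];
    ca.V = H * P[ix.attBase + 2];
    int dh = c.Da / c.heads;
    double sc = 1.0 / std::sqrt((double)dh);
    ca.Concat.set_size(BL, c.Da);
    ca.S.assign((size_t)B * c.heads, mat());
    for (int b = 0; b < B; b++) {
      int base = b * L;
      for (int h = 0; h < c.heads; h++) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        mat Qh = ca.Q.submat(base, c0, base + L - 1, c1);
        mat Kh = ca.Km.submat(base, c0, base + L - 1, c1);
        mat Vh = ca.V.submat(base, c0, base + L - 1, c1);
        mat Sc = Qh * Kh.t() * sc;
        for (int i = 0; i < L; i++)
          for (int j = i + 1; j < L; j++) Sc(i, j) = -datum::inf;
        softmaxRowsInplace(Sc);
        ca.S[(size_t)b * c.heads + h] = Sc;
        ca.Concat.submat(base, c0, base + L - 1, c1) = Sc * Vh;
      }
    }
    ca.Hatt = H + ca.Concat * P[ix.attBase + 3];
    ca.Hatt.each_row() += P[ix.attBase + 4].row(0);
  } else {
    ca.Hatt = H;
  }
  ca.logits = ca.Hatt * P[ix.W_out];
  ca.logits.each_row() += P[ix.b_out].row(0);
  if (wantLogp) {
    ca.logp = ca.logits;
    logSoftmaxRowsInplace(ca.logp);
  }
}

static void backwardPass(const std::vector<mat>& P, const Cfg& c, const PIdx& ix,
                         const Cache& ca, const mat& Glogits,
                         std::vector<mat>& G) {
  int B = ca.B, L = c.L;
  G.resize(P.size());
  for (size_t i = 0; i < P.size(); i++)
    G[i] = mat(P[i].n_rows, P[i].n_cols, fill::zeros);
  G[ix.W_out] = ca.Hatt.t() * Glogits;
  G[ix.b_out].row(0) = sum(Glogits, 0);
  mat dH = Glogits * P[ix.W_out].t();
  if (c.heads > 0) {
    G[ix.attBase + 4].row(0) = sum(dH, 0);
    G[ix.attBase + 3] = ca.Concat.t() * dH;
    mat dConcat = dH * P[ix.attBase + 3].t();
    int dh = c.Da / c.heads;
    double sc = 1.0 / std::sqrt((double)dh);
    mat dQ(dH.n_rows, c.Da, fill::zeros), dK(dH.n_rows, c.Da, fill::zeros),
        dV(dH.n_rows, c.Da, fill::zeros);
    for (int b = 0; b < B; b++) {
      int base = b * L;
      for (int h = 0; h < c.heads; h++) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        const mat& S = ca.S[(size_t)b * c.heads + h];
        mat dA = dConcat.submat(base, c0, base + L - 1, c1);
        mat Vh = ca.V.submat(base, c0, base + L - 1, c1);
        mat Qh = ca.Q.submat(base, c0, base + L - 1, c1);
        mat Kh = ca.Km.submat(base, c0, base + L - 1, c1);
        mat dS = dA * Vh.t();
        dV.submat(base, c0, base + L - 1, c1) = S.t() * dA;
        vec rs = sum(dS % S, 1);
        mat tmp = dS;
        tmp.each_col() -= rs;
        mat dsc = (S % tmp) * sc;
        dQ.submat(base, c0, base + L - 1, c1) = dsc * Kh;
        dK.submat(base, c0, base + L - 1, c1) = dsc.t() * Qh;
      }
    }
    dH += dQ * P[ix.attBase + 0].t() + dK * P[ix.attBase + 1].t() +
          dV * P[ix.attBase + 2].t();
    G[ix.attBase + 0] = ca.Hconv.t() * dQ;
    G[ix.attBase + 1] = ca.Hconv.t() * dK;
    G[ix.attBase + 2] = ca.Hconv.t() * dV;
  }
  for (int b = c.nb - 1; b >= 0; b--) {
    mat dZ = dH;
    dZ.elem(find(ca.Zb[b] <= 0)).zeros();
    G[ix.bc(b)].row(0) = sum(dZ, 0);
    mat dHprev = dH;  // residual path
    for (int j = 0; j < c.kernel; j++) {
      int d = j * c.dil[b];
      mat Hs = shiftRows(ca.Hpre[b], d, B, L);
      G[ix.Wc(b, j)] = Hs.t() * dZ;
      unshiftAdd(dHprev, dZ * P[ix.Wc(b, j)].t(), d, B, L);
    }
    dH = dHprev;
  }
  mat dA0 = dH;
  dA0.elem(find(ca.A0 <= 0)).zeros();
  G[ix.b_in].row(0) = sum(dA0, 0);
  G[ix.W_in] = ca.H0.t() * dA0;
  mat dH0 = dA0 * P[ix.W_in].t();
  for (int b = 0; b < B; b++) {
    G[ix.pos] += dH0.rows(b * L, b * L + L - 1);
    for (int t = 0; t < L; t++)
      G[ix.emb].row(ca.Xin(b, t)) += dH0.row(b * L + t);
  }
}

// cross-entropy of targets under the model; targets with code >= K
// (the input-only unknown code) are dropped from the mean
static double labelLossGrad(const Cache& ca, const Mat<int>& X, int K,
                            mat& Glogits) {
  int B = X.n_rows, L = X.n_cols;
  int nvalid = 0;
  for (int b = 0; b < B; b++)
    for (int t = 0; t < L; t++)
      if (X(b, t) < K) nvalid++;
  Glogits = exp(ca.logp);
  double ll = 0;
  for (int b = 0; b < B; b++)
    for (int t = 0; t < L; t++) {
      int r = b * L + t, y = X(b, t);
      if (y < K) {
        ll -= ca.logp(r, y);
        Glogits(r, y) -= 1.0;
      } else {
        Glogits.row(r).zeros();
      }
    }
  if (nvalid == 0) { Glogits.zeros(); return 0.0; }
  Glogits /= (double)nvalid;
  return ll / (double)nvalid;
}

// distillation term: cross-entropy of the (optionally softened) student
// distribution against the temperature-softened teacher distribution,
// averaged over all positions
static double teacherLossGrad(const mat& studentLogits, const mat& teacherLogits,
                              double T, bool distillStudent, mat& Gadd) {
  double Ts = distillStudent ? T : 1.0;
  mat pt = teacherLogits / T;
  softmaxRowsInplace(pt);
  mat logq = studentLogits / Ts;
  logSoftmaxRowsInplace(logq);
  double n = (double)studentLogits.n_rows;
  double loss = -accu(pt % logq) / n;
  Gadd = (exp(logq) - pt) / (Ts * n);
  return loss;
}

static Mat<int> toArmaInt0(const IntegerMatrix& X) {
  Mat<int> M(X.nrow(), X.ncol());
  for (int i = 0; i < X.nrow(); i++)
    for (int j = 0; j < X.ncol(); j++)
      M(i, j) = X(i, j) - 1;  // to 0-based codes
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_logp(List params, List cfgList, IntegerMatrix X) {
  Cfg c = parseCfg(cfgList);
  PIdx ix(c);
  std::vector<mat> P = paramsFromList(params);
  Mat<int> Xa = toArmaInt0(X);
  Cache ca;
  forwardPass(P, c, ix, Xa, ca, true);
  return wrap(ca.logp);  // (B*L) x K, row r = b*L + t
}

// [[Rcpp::export]]
List cpp_loss_grad(List params, List cfgList, IntegerMatrix X,
                   Nullable<List> teacherParams, double temperature,
                   bool distillStudent) {
  Cfg c = parseCfg(cfgList);
  PIdx ix(c);
  std::vector<mat> P = paramsFromList(params);
  Mat<int> Xa = toArmaInt0(X);
  Cache ca;
  forwardPass(P, c, ix, Xa, ca, true);
  mat Glogits;
  double ll = labelLossGrad(ca, Xa, c.K, Glogits);
  double tl = NA_REAL;
  if (teacherParams.isNotNull()) {
    std::vector<mat> TP = paramsFromList(teacherParams.get());
    Cache tca;
    forwardPass(TP, c, ix, Xa, tca, false);
    mat Gt;
    tl = teacherLossGrad(ca.logits, tca.logits, temperature, distillStudent, Gt);
    Glogits += Gt;
  }
  std::vector<mat> G;
  backwardPass(P, c, ix, ca, Glogits, G);
  return List::create(_["label_loss"] = ll, _["teacher_loss"] = tl,
                      _["grads"] = paramsToList(G, params));
}

// [[Rcpp::export]]
List cpp_train(List params, List cfgList, IntegerMatrix data,
               IntegerMatrix batches, List tcfg, Nullable<List> teacherParams,
               double temperature, bool distillStudent) {
  Cfg c = parseCfg(cfgList);
  PIdx ix(c);
  std::vector<mat> P = paramsFromList(params);
  bool hasTeacher = teacherParams.isNotNull();
  std::vector<mat> TP;
  if (hasTeacher) TP = paramsFromList(teacherParams.get());

  Mat<int> D = toArmaInt0(data);
  int iters = batches.nrow(), B = batches.ncol();
  double lrHigh = as<double>(tcfg["lrHigh"]), lrLow = as<double>(tcfg["lrLow"]);
  int lrSwitch = as<int>(tcfg["lrSwitch"]), logEvery = as<int>(tcfg["logEvery"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::vector<mat> M(P.size()), V(P.size());
  for (size_t i = 0; i < P.size(); i++) {
    M[i] = mat(P[i].n_rows, P[i].n_cols, fill::zeros);
    V[i] = mat(P[i].n_rows, P[i].n_cols, fill::zeros);
  }

  std::vector<int> logIt;
  std::vector<double> logLr, logLabel, logTeacher;
  Mat<int> X(B, c.L);
  Cache ca, tca;
  for (int it = 1; it <= iters; it++) {
    for (int bi = 0; bi < B; bi++) {
      int row = batches(it - 1, bi) - 1;
      X.row(bi) = D.row(row);
    }
    double lr = (it < lrSwitch) ? lrHigh : lrLow;
    forwardPass(P, c, ix, X, ca, true);
    mat Glogits;
    double ll = labelLossGrad(ca, X, c.K, Glogits);
    double tl = NA_REAL;
    if (hasTeacher) {
      forwardPass(TP, c, ix, X, tca, false);
      mat Gt;
      tl = teacherLossGrad(ca.logits, tca.logits, temperature, distillStudent, Gt);
      Glogits += Gt;
    }
    std::vector<mat> G;
    backwardPass(P, c, ix, ca, Glogits, G);
    if (!std::isfinite(ll) || (hasTeacher && !std::isfinite(tl)))
      stop("training diverged (non-finite loss) at iteration %d", it);
    double bc1 = 1.0 - std::pow(b1, (double)it);
    double bc2 = 1.0 - std::pow(b2, (double)it);
    for (size_t i = 0; i < P.size(); i++) {
      M[i] = b1 * M[i] + (1.0 - b1) * G[i];
      V[i] = b2 * V[i] + (1.0 - b2) * square(G[i]);
      P[i] -= lr * (M[i] / bc1) / (sqrt(V[i] / bc2) + eps);
    }
    if (it == 1 || it % logEvery == 0 || it == iters) {
      logIt.push_back(it);
      logLr.push_back(lr);
      logLabel.push_back(ll);
      logTeacher.push_back(tl);
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  DataFrame log = DataFrame::create(
      _["iteration"] = logIt, _["lr"] = logLr, _["label_loss"] = logLabel,
      _["teacher_loss"] = logTeacher);
  return List::create(_["params"] = paramsToList(P, params), _["log"] = log);
}

// neighbourhood sizes for inverse-redundancy sequence weights:
// count, for each row, the rows (itself included) with pairwise
// identity >= threshold over the encoded columns
// [[Rcpp::export]]
NumericVector cpp_neighbour_counts(IntegerMatrix m, double thr) {
  int N = m.nrow(), L = m.ncol();
  std::vector<std::vector<int> > rows(N, std::vector<int>(L));
  for (int i = 0; i < N; i++)
    for (int j = 0; j < L; j++) rows[i][j] = m(i, j);
  NumericVector cnt(N, 1.0);  // self always within threshold
  for (int i = 0; i < N; i++) {
    for (int j = i + 1; j < N; j++) {
      int eq = 0;
      for (int l = 0; l < L; l++)
        if (rows[i][l] == rows[j][l]) eq++;
      if ((double)eq / (double)L >= thr - 1e-12) {
        cnt[i] += 1.0;
        cnt[j] += 1.0;
      }
    }
  }
  return cnt;
}
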