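// Linear-chain CRF inference kernels: log-space forward/backward, Viterbi
// decoding and likelihood gradients.  Sequences arrive as lists of integer
// vectors of active feature-atom ids (1-based; 0/absent ids are ignored so
// unseen predict-time atoms drop out).  State weights are passed TRANSPOSED
// (labels x atoms) so the per-atom label loop walks contiguous memory; the
// R wrappers own that layout conversion.  Label ids are 1-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (double x : v) if (x > m) m = x;
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// State log-potentials for one sequence: T x L, entry (t,y) = sum of
// state weights of the token's active atoms for label y.
static std::vector<std::vector<double>> state_scores(const List& atoms,
                                                     const NumericMatrix& WsT) {
  int T = atoms.size(), L = WsT.nrow(), nA = WsT.ncol();
  const double* w = WsT.begin();
  std::vector<std::vector<double>> S(T, std::vector<double>(L, 0.0));
  for (int t = 0; t < T; ++t) {
    IntegerVector a = atoms[t];
    double* st = S[t].data();
    for (int j = 0; j < a.size(); ++j) {
      int id = a[j];
      if (id < 1 || id > nA) continue;
      const double* col = w + (size_t)(id - 1) * L;
      for (int y = 0; y < L; ++y) st[y] += col[y];
    }
  }
  return S;
}

// [[Rcpp::export]]
double crf_logZ_cpp(List atoms, NumericMatrix WsT, NumericMatrix Wt) {
  int T = atoms.size(), L = WsT.nrow();
  if (T == 0) stop("empty sequence");
  auto S = state_scores(atoms, WsT);
  std::vector<double> alpha(S[0]), tmp(L);
  for (int t = 1; t < T; ++t) {
    std::vector<double> nxt(L);
    for (int y = 0; y < L; ++y) {
      for (int yp = 0; yp < L; ++yp) tmp[yp] = alpha[yp] + Wt(yp, y);
      nxt[y] = S[t][y] + logsumexp(tmp);
    }
    alpha = nxt;
  }
  return logsumexp(alpha);
}

// Viterbi with the tie-break "earliest label in alphabet order at the
// latest differing position": strict improvement while scanning previous
// labels in alphabet order keeps the smallest argmax everywhere.
// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(List atoms, NumericMatrix WsT, NumericMatrix Wt) {
  int T = atoms.size(), L = WsT.nrow();
  if (T == 0) stop("empty sequence");
  auto S = state_scores(atoms, WsT);
  std::vector<std::vector<double>> delta(T, std::vector<double>(L));
  std::vector<std::vector<int>> bp(T, std::vector<int>(L, 0));
  delta[0] = S[0];
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < L; ++y) {
      double best = R_NegInf; int arg = 0;
      for (int yp = 0; yp < L; ++yp) {
        double v = delta[t - 1][yp] + Wt(yp, y);
        if (v > best) { best = v; arg = yp; }
      }
      delta[t][y] = S[t][y] + best;
      bp[t][y] = arg;
    }
  }
  int last = 0; double best = delta[T - 1][0];
  for (int y = 1; y < L; ++y)
    if (delta[T - 1][y] > best) { best = delta[T - 1][y]; last = y; }
  IntegerVector path(T);
  path[T - 1] = last + 1;
  for (int t = T - 1; t > 0; --t) {
    last = bp[t][last];
    path[t - 1] = last + 1;
  }
  return path;
}

// Unregularised log-likelihood and its gradient (observed minus expected
// feature counts) over a set of sequences, via forward-backward marginals.
// The state gradient comes back in the same transposed L x nA layout.
// [[Rcpp::export]]
List crf_loglik_grad_cpp(List seq_atoms, List seq_labels,
                         NumericMatrix WsT, NumericMatrix Wt) {
  int L = WsT.nrow(), nA = WsT.ncol();
  NumericMatrix gWsT(L, nA), gWt(L, L);
  double* gw = gWsT.begin();
  double ll = 0.0;
  std::vector<double> tmp(L), p(L);
  for (int s = 0; s < seq_atoms.size(); ++s) {
    List atoms = seq_atoms[s];
    IntegerVector lab = seq_labels[s];
    int T = atoms.size();
    if (T == 0) continue;
    auto S = state_scores(atoms, WsT);

    std::vector<std::vector<double>> alpha(T, std::vector<double>(L));
    std::vector<std::vector<double>> beta(T, std::vector<double>(L, 0.0));
    alpha[0] = S[0];
    for (int t = 1; t < T; ++t)
      for (int y = 0; y < L; ++y) {
        for (int yp = 0; yp < L; ++yp) tmp[yp] = alpha[t - 1][yp] + Wt(yp, y);
        alpha[t][y] = S[t][y] + logsumexp(tmp);
      }
    double logZ = logsumexp(alpha[T - 1]);
    for (int t = T - 2; t >= 0; --t)
      for (int y = 0; y < L; ++y) {
        for (int yn = 0; yn < L; ++yn)
          tmp[yn] = Wt(y, yn) + S[t + 1][yn] + beta[t + 1][yn];
        beta[t][y] = logsumexp(tmp);
      }

    // observed score
    double obs = 0.0;
    for (int t = 0; t < T; ++t) {
      obs += S[t][lab[t] - 1];
      if (t > 0) obs += Wt(lab[t - 1] - 1, lab[t] - 1);
    }
    ll += obs - logZ;

    // node marginals -> state gradient; gold counts added as observed
    for (int t = 0; t < T; ++t) {
      IntegerVector a = atoms[t];
      for (int y = 0; y < L; ++y)
        p[y] = std::exp(alpha[t][y] + beta[t][y] - logZ);
      int gold = lab[t] - 1;
      for (int j = 0; j < a.size(); ++j) {
        int id = a[j];
        if (id < 1 || id > nA) continue;
        double* col = gw + (size_t)(id - 1) * L;
        col[gold] += 1.0;
        for (int y = 0; y < L; ++y) col[y] -= p[y];
      }
    }
    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      gWt(lab[t - 1] - 1, lab[t] - 1) += 1.0;
      for (int yp = 0; yp < L; ++yp)
        for (int y = 0; y < L; ++y)
          gWt(yp, y) -= std::exp(alpha[t - 1][yp] + Wt(yp, y) +
                                 S[t][y] + beta[t][y] - logZ);
    }
  }
  return List::create(_["loglik"] = ll, _["grad_state_t"] = gWsT,
                      _["grad_trans"] = gWt);
}
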