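#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// TN93/HKY transition-probability matrix, mean rate normalised to one
// substitution per site per unit branch length. kappa1 = A<->G rate
// multiplier relative to transversions, kappa2 = C<->T; HKY has
// kappa1 == kappa2.
static void tn93_pmat(double t, const double* pi, double kappa1,
                      double kappa2, double P[4][4]) {
  const double piA = pi[0], piC = pi[1], piG = pi[2], piT = pi[3];
  const double piR = piA + piG, piY = piC + piT;
  const double beta =
      1.0 / (2.0 * (kappa1 * piA * piG + kappa2 * piC * piT + piR * piY));
  const double a1 = kappa1 * beta, a2 = kappa2 * beta;
  const double e2 = std::exp(-beta * t);
  const double e3 = std::exp(-(piR * a1 + piY * beta) * t);
  const double e4 = std::exp(-(piY * a2 + piR * beta) * t);
  // order A, C, G, T
  P[0][0] = piA + piA * piY / piR * e2 + piG / piR * e3;
  P[0][2] = piG + piG * piY / piR * e2 - piG / piR * e3;
  P[2][0] = piA + piA * piY / piR * e2 - piA / piR * e3;
  P[2][2] = piG + piG * piY / piR * e2 + piA / piR * e3;
  P[1][1] = piC + piC * piR / piY * e2 + piT / piY * e4;
  P[1][3] = piT + piT * piR / piY * e2 - piT / piY * e4;
  P[3][1] = piC + piC * piR / piY * e2 - piC / piY * e4;
  P[3][3] = piT + piT * piR / piY * e2 + piC / piY * e4;
  P[0][1] = piC * (1.0 - e2); P[0][3] = piT * (1.0 - e2);
  P[2][1] = piC * (1.0 - e2); P[2][3] = piT * (1.0 - e2);
  P[1][0] = piA * (1.0 - e2); P[1][2] = piG * (1.0 - e2);
  P[3][0] = piA * (1.0 - e2); P[3][2] = piG * (1.0 - e2);
}

// [[Rcpp::export(name = ".tn93_pmat_cpp")]]
NumericMatrix tn93_pmat_cpp(double t, NumericVector pi, double kappa1,
                            double kappa2) {
  double P[4][4];
  tn93_pmat(t, pi.begin(), kappa1, kappa2, P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i][j];
  return out;
}

// Felsenstein pruning log-likelihood under HKY on compressed site patterns.
//
// edge_child/edge_parent: 1-based node indices, tips 1..n, internals
// n+1..2n-1, listed so every child edge precedes the edge where that
// node is itself the child's parent (postorder). edge_len in expected
// substitutions/site. tip_states: n x P integer matrix, 0..3 or
// negative for ambiguous. weights: pattern multiplicities.
// [[Rcpp::export(name = ".hky_loglik_cpp")]]
double hky_loglik_cpp(IntegerVector edge_child, IntegerVector edge_parent,
                      NumericVector edge_len, const IntegerMatrix& tip_states,
                      NumericVector weights, NumericVector pi, double kappa) {
  const int ntip = tip_states.nrow(), P = tip_states.ncol();
  const int nnode = 2 * ntip - 1, nedge = edge_child.size();
  std::vector<double> part(static_cast<size_t>(nnode) * P * 4);
  std::vector<double> logscale(static_cast<size_t>(nnode) * P, 0.0);
  std::vector<char> init(nnode, 0);

  // tip partials
  for (int i = 0; i < ntip; ++i) {
    double* p = &part[static_cast<size_t>(i) * P * 4];
    for (int s = 0; s < P; ++s) {
      const int st = tip_states(i, s);
      for (int k = 0; k < 4; ++k) p[s * 4 + k] = (st < 0 || st == k) ? 1.0 : 0.0;
    }
    init[i] = 1;
  }

  double Pm[4][4];
  for (int e = 0; e < nedge; ++e) {
    const int ch = edge_child[e] - 1, pa = edge_parent[e] - 1;
    tn93_pmat(edge_len[e], pi.begin(), kappa, kappa, Pm);
    double* ppa = &part[static_cast<size_t>(pa) * P * 4];
    const double* pch = &part[static_cast<size_t>(ch) * P * 4];
    double* lpa = &logscale[static_cast<size_t>(pa) * P];
    const double* lch = &logscale[static_cast<size_t>(ch) * P];
    if (!init[pa]) {
      for (int s = 0; s < P * 4; ++s) ppa[s] = 1.0;
      for (int s = 0; s < P; ++s) lpa[s] = 0.0;
      init[pa] = 1;
    }
    for (int s = 0; s < P; ++s) {
      double mx = 0.0;
      double tmp[4];
      for (int i = 0; i < 4; ++i) {
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) acc += Pm[i][j] * pch[s * 4 + j];
        tmp[i] = acc;
        if (acc > mx) mx = acc;
      }
      if (mx <= 0.0) return R_NegInf;
      // rescale only when underflow threatens; log() is the hot path
      if (mx < 1e-100) {
        for (int i = 0; i < 4; ++i) ppa[s * 4 + i] *= tmp[i] / mx;
        lpa[s] += lch[s] + std::log(mx);
      } else {
        for (int i = 0; i < 4; ++i) ppa[s * 4 + i] *= tmp[i];
        lpa[s] += lch[s];
      }
    }
  }

  const int root = edge_parent[nedge - 1] - 1;
  const double* pr = &part[static_cast<size_t>(root) * P * 4];
  const double* lr = &logscale[static_cast<size_t>(root) * P];
  double ll = 0.0;
  for (int s = 0; s < P; ++s) {
    double acc = 0.0;
    for (int k = 0; k < 4; ++k) acc += pi[k] * pr[s * 4 + k];
    if (acc <= 0.0) return R_NegInf;
    ll += weights[s] * (std::log(acc) + lr[s]);
  }
  return ll;
}
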