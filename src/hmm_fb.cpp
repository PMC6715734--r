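#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward posteriors for the 3-state background-ancestry HMM.
// States: 0 = BB (homozygous B6), 1 = BC (heterozygous), 2 = CC.
// Calls: 0 = homB6, 1 = het, 2 = homCAST, NA = missing.
// Emission: 1 - eps for the concordant call, eps/2 for each discordant
// call, flat for missing. Transition over a gap of d bp:
// P(i -> j) = (1 - exp(-r d)) * T[i][j] for i != j, with direct
// BB <-> CC moves disallowed (T[0][2] = T[2][0] = 0); diagonal takes
// the remainder.
//
// [[Rcpp::export]]
NumericMatrix hmm_fb_cpp(IntegerVector call, NumericVector pos,
                         double eps, double r) {
  const int n = call.size();
  NumericMatrix post(n, 3);
  if (n == 0) return post;

  static const double T[3][3] = {
    {0.0, 1.0, 0.0},
    {0.5, 0.0, 0.5},
    {0.0, 1.0, 0.0}
  };

  std::vector<double> em(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 3; ++s) {
      if (call[i] == NA_INTEGER) em[3 * i + s] = 1.0;
      else em[3 * i + s] = (call[i] == s) ? (1.0 - eps) : (eps / 2.0);
    }
  }

  std::vector<double> alpha(3 * n), beta(3 * n), scale(n);
  // uniform initial distribution
  double s0 = 0.0;
  for (int s = 0; s < 3; ++s) {
    alpha[s] = (1.0 / 3.0) * em[s];
    s0 += alpha[s];
  }
  scale[0] = s0;
  for (int s = 0; s < 3; ++s) alpha[s] /= s0;

  for (int i = 1; i < n; ++i) {
    double q = 1.0 - std::exp(-r * (pos[i] - pos[i - 1]));
    double A[3][3];
    for (int a = 0; a < 3; ++a) {
      double off = 0.0;
      for (int b = 0; b < 3; ++b)
        if (a != b) { A[a][b] = q * T[a][b]; off += A[a][b]; }
      A[a][a] = 1.0 - off;
    }
    double si = 0.0;
    for (int b = 0; b < 3; ++b) {
      double acc = 0.0;
      for (int a = 0; a < 3; ++a) acc += alpha[3 * (i - 1) + a] * A[a][b];
      alpha[3 * i + b] = acc * em[3 * i + b];
      si += alpha[3 * i + b];
    }
    scale[i] = si;
    for (int b = 0; b < 3; ++b) alpha[3 * i + b] /= si;
  }

  for (int s = 0; s < 3; ++s) beta[3 * (n - 1) + s] = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    double q = 1.0 - std::exp(-r * (pos[i + 1] - pos[i]));
    double A[3][3];
    for (int a = 0; a < 3; ++a) {
      double off = 0.0;
      for (int b = 0; b < 3; ++b)
        if (a != b) { A[a][b] = q * T[a][b]; off += A[a][b]; }
      A[a][a] = 1.0 - off;
    }
    for (int a = 0; a < 3; ++a) {
      double acc = 0.0;
      for (int b = 0; b < 3; ++b)
        acc += A[a][b] * em[3 * (i + 1) + b] * beta[3 * (i + 1) + b];
      beta[3 * i + a] = acc / scale[i + 1];
    }
  }

  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int s = 0; s < 3; ++s) {
      post(i, s) = alpha[3 * i + s] * beta[3 * i + s];
      tot += post(i, s);
    }
    for (int s = 0; s < 3; ++s) post(i, s) /= tot;
  }
  return post;
}
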