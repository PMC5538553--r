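#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Equilibrium base-pair probabilities for a single ungapped sequence under a
// pair-additive Boltzmann model: every pseudoknot-free structure S gets weight
// prod_{(i,j) in S} W[s_i][s_j], pairs must span > h positions.  Inside
// recursion over segment partition functions Z and paired partition functions
// Zb, then an outside pass conditioning on the closest enclosing pair.
// Exterior pass is O(n^4/24) in the worst case; fine for the desk-scale
// sequence lengths (<= a few hundred nt) this toolkit targets.
//
// s is 0-based encoded (A=0, C=1, G=2, U=3); W is the 4x4 matrix of pair
// Boltzmann weights (0 for non-pairing combinations).
// [[Rcpp::export]]
NumericMatrix bpp_matrix_cpp(IntegerVector s, NumericMatrix W, int h) {
  int n = s.size();
  NumericMatrix P(n, n);
  if (n < h + 2) return P;

  // Z[i][j] on 1-based closed [i..j]; empty segments (j < i) have Z = 1,
  // which the all-ones initialisation provides.
  std::vector< std::vector<double> > Z(n + 2, std::vector<double>(n + 2, 1.0));
  std::vector< std::vector<double> > Zb(n + 2, std::vector<double>(n + 2, 0.0));

  for (int len = 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double w = W(s[i - 1], s[j - 1]);
      if (j - i > h && w > 0.0) Zb[i][j] = w * Z[i + 1][j - 1];
      double z = Z[i][j - 1];  // j unpaired
      for (int k = i; k <= j - h - 1; ++k) {
        if (Zb[k][j] > 0.0) z += (k > i ? Z[i][k - 1] : 1.0) * Zb[k][j];
      }
      Z[i][j] = z;
    }
  }
  double Ztot = Z[1][n];

  // Outside: Pb(i,j) = Zb(i,j)/Z * Zhat(i,j) with Zhat accumulated over the
  // closest enclosing pair (k,l); longest spans first so Pb(k,l) is ready.
  std::vector< std::vector<double> > Pb(n + 2, std::vector<double>(n + 2, 0.0));
  for (int len = n; len >= h + 2; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (Zb[i][j] <= 0.0) continue;
      double ext = (i > 1 ? Z[1][i - 1] : 1.0) * (j < n ? Z[j + 1][n] : 1.0) / Ztot;
      double enc = 0.0;
      for (int k = 1; k < i; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          if (Pb[k][l] > 0.0) {
            double w = W(s[k - 1], s[l - 1]);
            enc += Pb[k][l] / Zb[k][l] * w * Z[k + 1][i - 1] * Z[j + 1][l - 1];
          }
        }
      }
      double p = Zb[i][j] * (ext + enc);
      Pb[i][j] = p;
      P(i - 1, j - 1) = p;
    }
  }
  return P;
}
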