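#include <Rcpp.h>
#include <limits>
#include <string>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Needleman-Wunsch / Gotoh).
// A gap of length k costs open + (k - 1) * extend (both positive costs).
// Traceback ties are broken deterministically: diagonal, then up (gap in
// reference), then left (gap in query).

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string q, std::string r, NumericMatrix sub,
                     double gap_open, double gap_extend) {
  const int n = q.size(), m = r.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // residue -> row index lookup from the substitution matrix dimnames
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(sub);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> qi(n), ri(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = lut[(unsigned char)q[i]];
    if (qi[i] < 0) stop("residue '%s' absent from substitution matrix",
                        std::string(1, q[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    ri[j] = lut[(unsigned char)r[j]];
    if (ri[j] < 0) stop("residue '%s' absent from substitution matrix",
                        std::string(1, r[j]).c_str());
  }

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + (i - 1) * gap_extend);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + (j - 1) * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = best + sub(qi[i - 1], ri[j - 1]);

      double x = M[u] - gap_open;
      if (X[u] - gap_extend > x) x = X[u] - gap_extend;
      if (Y[u] - gap_open > x) x = Y[u] - gap_open;
      X[c] = x;

      double y = M[l] - gap_open;
      if (Y[l] - gap_extend > y) y = Y[l] - gap_extend;
      if (X[l] - gap_open > y) y = X[l] - gap_open;
      Y[c] = y;
    }
  }

  const int end = n * W + m;
  // state preference on ties: 0 = M (diagonal), 1 = X (up), 2 = Y (left)
  int state = 0;
  double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // pick the predecessor state exactly as the forward pass scored it:
  // argmax over candidate scores with fixed preference M > X > Y on ties
  auto argmax3 = [](double a, double b, double c) {
    if (a >= b && a >= c) return 0;
    if (b >= c) return 1;
    return 2;
  };

  std::string aq, ar;
  aq.reserve(n + m);
  ar.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const int d = (i - 1) * W + (j - 1);
      aq.push_back(q[i - 1]);
      ar.push_back(r[j - 1]);
      state = argmax3(M[d], X[d], Y[d]);
      --i; --j;
    } else if (state == 1) {
      const int u = (i - 1) * W + j;
      aq.push_back(q[i - 1]);
      ar.push_back('-');
      state = argmax3(M[u] - gap_open, X[u] - gap_extend, Y[u] - gap_open);
      --i;
    } else {
      const int l = i * W + (j - 1);
      aq.push_back('-');
      ar.push_back(r[j - 1]);
      const int k = argmax3(M[l] - gap_open, Y[l] - gap_extend, X[l] - gap_open);
      state = (k == 0) ? 0 : (k == 1 ? 2 : 1);
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());

  return List::create(_["score"] = score, _["aligned_query"] = aq,
                      _["aligned_ref"] = ar);
}
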