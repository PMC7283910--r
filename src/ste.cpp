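#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All-pairs symbolic transfer entropy over embedded word sequences.
// words: channels x n_words integer matrix with values in 1..S.
// Entry (i, j) of the result is TE from channel i (source) to channel j
// (target), in bits, with k = l = 1:
//   TE = sum_{x+,x,y} p(x+,x,y) * log2( p(x+,x,y) p(x) / (p(x+,x) p(x,y)) )
// Zero-probability terms contribute 0; tiny negative round-off is clamped.
// [[Rcpp::export]]
NumericMatrix cpp_ste_matrix(IntegerMatrix words, int S) {
  const int C = words.nrow();
  const int W = words.ncol();
  const int n = W - 1;  // transitions
  if (n < 1) stop("cpp_ste_matrix: need at least 2 words per channel");

  NumericMatrix te(C, C);
  const double ln2 = std::log(2.0);

  // per-channel current/next word (0-based)
  std::vector<std::vector<int> > now(C, std::vector<int>(n));
  std::vector<std::vector<int> > nxt(C, std::vector<int>(n));
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < n; ++t) {
      now[c][t] = words(c, t) - 1;
      nxt[c][t] = words(c, t + 1) - 1;
    }
  }

  // per-target marginals: c_x over S, c_xx over S*S
  std::vector<std::vector<int> > cx(C, std::vector<int>(S, 0));
  std::vector<std::vector<int> > cxx(C, std::vector<int>(S * S, 0));
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < n; ++t) {
      cx[c][now[c][t]]++;
      cxx[c][nxt[c][t] * S + now[c][t]]++;
    }
  }

  std::vector<int> c3(static_cast<size_t>(S) * S * S);
  std::vector<int> cxy(static_cast<size_t>(S) * S);
  std::vector<int> used3;
  std::vector<int> used2;
  used3.reserve(n);
  used2.reserve(n);

  for (int j = 0; j < C; ++j) {        // target
    const std::vector<int>& xj = now[j];
    const std::vector<int>& xjn = nxt[j];
    for (int i = 0; i < C; ++i) {      // source
      if (i == j) continue;
      const std::vector<int>& yi = now[i];
      used3.clear();
      used2.clear();
      for (int t = 0; t < n; ++t) {
        int i3 = (xjn[t] * S + xj[t]) * S + yi[t];
        int i2 = xj[t] * S + yi[t];
        if (c3[i3]++ == 0) used3.push_back(i3);
        if (cxy[i2]++ == 0) used2.push_back(i2);
      }
      double sum = 0.0;
      for (size_t u = 0; u < used3.size(); ++u) {
        int i3 = used3[u];
        int y = i3 % S;
        int rest = i3 / S;           // xjn * S + xj
        int x = rest % S;
        double num = static_cast<double>(c3[i3]) * cx[j][x];
        double den = static_cast<double>(cxx[j][rest]) * cxy[x * S + y];
        sum += c3[i3] * std::log(num / den);
      }
      double val = sum / (n * ln2);
      if (val < 0.0) val = 0.0;      // round-off guard (plug-in TE >= 0)
      te(i, j) = val;
      for (size_t u = 0; u < used3.size(); ++u) c3[used3[u]] = 0;
      for (size_t u = 0; u < used2.size(); ++u) cxy[used2[u]] = 0;
    }
  }
  return te;
}
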