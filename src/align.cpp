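#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). A gap of length L costs
// gap_open + (L - 1) * gap_extend. Local mode is Smith-Waterman
// (traceback from the best cell, stopping at score 0); global mode is
// Needleman-Wunsch with end gaps charged like any other gap.
// Traceback ties are resolved deterministically: diagonal, then up
// (consume a query residue against a gap), then left.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix S,
                    double gap_open, double gap_extend, bool local) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  // score lookup by character, built from the matrix dimnames
  double lut[128][128];
  bool known[128];
  for (int i = 0; i < 128; ++i) known[i] = false;
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) lut[i][j] = NEG_INF;
  CharacterVector rn = rownames(S), cn = colnames(S);
  std::vector<int> rc(rn.size()), cc(cn.size());
  for (int i = 0; i < rn.size(); ++i) rc[i] = (int) as<std::string>(rn[i])[0];
  for (int j = 0; j < cn.size(); ++j) cc[j] = (int) as<std::string>(cn[j])[0];
  for (int i = 0; i < rn.size(); ++i) {
    known[rc[i]] = true;
    for (int j = 0; j < cn.size(); ++j) lut[rc[i]][cc[j]] = S(i, j);
  }
  for (int j = 0; j < cn.size(); ++j) known[cc[j]] = true;
  for (int i = 0; i < m; ++i)
    if (!known[(unsigned char) a[i] & 127])
      stop("character '%s' at position %d of the first sequence is not in the scoring matrix",
           std::string(1, a[i]).c_str(), i + 1);
  for (int j = 0; j < n; ++j)
    if (!known[(unsigned char) b[j] & 127])
      stop("character '%s' at position %d of the second sequence is not in the scoring matrix",
           std::string(1, b[j]).c_str(), j + 1);

  const size_t W = n + 1;
  std::vector<double> H((m + 1) * W), E((m + 1) * W), F((m + 1) * W);
  // E: alignment ends with b[j-1] against a gap ("left")
  // F: alignment ends with a[i-1] against a gap ("up")
  H[0] = 0.0; E[0] = F[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    H[j] = local ? 0.0 : -(gap_open + (j - 1) * gap_extend);
    E[j] = local ? NEG_INF : H[j];
    F[j] = NEG_INF;
  }
  for (int i = 1; i <= m; ++i) {
    H[i * W] = local ? 0.0 : -(gap_open + (i - 1) * gap_extend);
    F[i * W] = local ? NEG_INF : H[i * W];
    E[i * W] = NEG_INF;
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ca = (unsigned char) a[i - 1] & 127;
    for (int j = 1; j <= n; ++j) {
      const size_t k = i * W + j;
      double e = std::max(H[k - 1] - gap_open, E[k - 1] - gap_extend);
      double f = std::max(H[k - W] - gap_open, F[k - W] - gap_extend);
      double d = H[k - W - 1] + lut[ca][(unsigned char) b[j - 1] & 127];
      double h = std::max(d, std::max(e, f));
      if (local && h < 0.0) h = 0.0;
      E[k] = e; F[k] = f; H[k] = h;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (!local) { best = H[m * W + n]; bi = m; bj = n; }

  // traceback
  std::string ra, rb;
  int i = bi, j = bj;
  if (local && best <= 0.0) { i = 0; j = 0; bi = 0; bj = 0; }
  int state = 0; // 0 = H, 1 = F (up), 2 = E (left)
  while (i > 0 || j > 0) {
    const size_t k = i * W + j;
    if (state == 0) {
      if (local && H[k] == 0.0) break;
      if (!local && i == 0) { state = 2; continue; }
      if (!local && j == 0) { state = 1; continue; }
      double d = H[k - W - 1] + lut[(unsigned char) a[i - 1] & 127]
                                   [(unsigned char) b[j - 1] & 127];
      if (i > 0 && j > 0 && H[k] == d) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
      } else if (i > 0 && H[k] == F[k]) {
        state = 1;
      } else if (j > 0 && H[k] == E[k]) {
        state = 2;
      } else {
        stop("traceback failure (H)"); // should be unreachable
      }
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      // prefer closing the gap (back to H) when both traces are optimal
      bool close = (H[(i - 1) * W + j] - gap_open == F[i * W + j]);
      --i;
      state = close ? 0 : 1;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      bool close = (H[i * W + (j - 1)] - gap_open == E[i * W + j]);
      --j;
      state = close ? 0 : 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(
    _["score"] = best <= 0.0 && local ? 0.0 : best,
    _["a_start"] = i,  // 0-based half-open span on a
    _["a_end"] = (local && best <= 0.0) ? i : bi,
    _["b_start"] = j,
    _["b_end"] = (local && best <= 0.0) ? j : bj,
    _["aligned_a"] = (local && best <= 0.0) ? std::string() : ra,
    _["aligned_b"] = (local && best <= 0.0) ? std::string() : rb);
}
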