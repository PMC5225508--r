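#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) over an arbitrary alphabet.
// Gap of length k costs gap_open + k * gap_extend.
// Traceback is deterministic: on ties prefer diagonal, then up (gap in b),
// then left (gap in a); in local mode the maximum cell is the first one in
// row-major order and traceback stops at score 0.

static std::vector<int> encode_seq(const std::string& s, const std::string& alphabet) {
  int idx[256];
  for (int k = 0; k < 256; ++k) idx[k] = -1;
  for (size_t k = 0; k < alphabet.size(); ++k) idx[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int v = idx[(unsigned char)s[i]];
    if (v < 0) stop("symbol '" + std::string(1, s[i]) + "' not in alignment alphabet");
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_affine_align(std::string a, std::string b, std::string alphabet,
                      IntegerMatrix submat, double gap_open, double gap_extend,
                      bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  const int K = (int)alphabet.size();
  if (submat.nrow() != K || submat.ncol() != K)
    stop("substitution matrix does not match alphabet size");
  std::vector<int> ea = encode_seq(a, alphabet), eb = encode_seq(b, alphabet);

  const double NEG = -1e18;
  const size_t W = (size_t)m + 1;
  std::vector<double> H((size_t)(n + 1) * W), E((size_t)(n + 1) * W), F((size_t)(n + 1) * W);
  // pointers: pH 0=stop/origin 1=diag 2=fromE 3=fromF ; pE/pF 0=open-from-H 1=extend
  std::vector<unsigned char> pH((size_t)(n + 1) * W), pE((size_t)(n + 1) * W), pF((size_t)(n + 1) * W);

  H[0] = 0.0; E[0] = NEG; F[0] = NEG; pH[0] = 0;
  for (int j = 1; j <= m; ++j) {
    size_t c = (size_t)j;
    E[c] = NEG;
    F[c] = local ? NEG : -(gap_open + j * gap_extend);
    pF[c] = (j == 1) ? 0 : 1;
    H[c] = local ? 0.0 : F[c];
    pH[c] = local ? 0 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W;
    F[r] = NEG;
    E[r] = local ? NEG : -(gap_open + i * gap_extend);
    pE[r] = (i == 1) ? 0 : 1;
    H[r] = local ? 0.0 : E[r];
    pH[r] = local ? 0 : 2;
  }

  double best = 0.0; int bi = 0, bj = 0; bool any = false;
  for (int i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W, ru = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      // E: gap in b (consume a_i), move up
      double e_open = H[ru + j] - gap_open - gap_extend;
      double e_ext  = E[ru + j] - gap_extend;
      if (e_open >= e_ext) { E[r + j] = e_open; pE[r + j] = 0; }
      else                 { E[r + j] = e_ext;  pE[r + j] = 1; }
      // F: gap in a (consume b_j), move left
      double f_open = H[r + j - 1] - gap_open - gap_extend;
      double f_ext  = F[r + j - 1] - gap_extend;
      if (f_open >= f_ext) { F[r + j] = f_open; pF[r + j] = 0; }
      else                 { F[r + j] = f_ext;  pF[r + j] = 1; }

      double diag = H[ru + j - 1] + submat(ea[i - 1], eb[j - 1]);
      double h = diag; unsigned char p = 1;
      if (E[r + j] > h) { h = E[r + j]; p = 2; }
      if (F[r + j] > h) { h = F[r + j]; p = 3; }
      if (local && h <= 0.0) { h = 0.0; p = 0; }
      H[r + j] = h; pH[r + j] = p;
      if (local) {
        if (h > best) { best = h; bi = i; bj = j; any = true; }
      }
    }
  }

  int ei, ej; double score;
  if (local) {
    if (!any || best <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0,
                          _["a_aln"] = "", _["b_aln"] = "");
    }
    ei = bi; ej = bj; score = best;
  } else {
    ei = n; ej = m; score = H[(size_t)n * W + m];
  }

  // traceback
  std::string aa, bb;
  int i = ei, j = ej, state = 0; // 0=H 1=E 2=F
  while (true) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      unsigned char p = pH[c];
      if (p == 0) break;                       // local stop or origin
      if (p == 1) {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        --i; --j;
        if (!local && i == 0 && j == 0) break;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {                   // E: consume a_i, gap in b
      unsigned char p = pE[c];
      aa.push_back(a[i - 1]); bb.push_back('-');
      --i;
      if (p == 0) state = 0;
      if (i == 0 && j == 0) break;
    } else {                                   // F: consume b_j, gap in a
      unsigned char p = pF[c];
      aa.push_back('-'); bb.push_back(b[j - 1]);
      --j;
      if (p == 0) state = 0;
      if (i == 0 && j == 0) break;
    }
    if (i == 0 && j == 0 && state == 0) break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["score"] = score,
                      _["a_start"] = i, _["a_end"] = ei,
                      _["b_start"] = j, _["b_end"] = ej,
                      _["a_aln"] = aa, _["b_aln"] = bb);
}

// Hamming-style windowed identity used by boundary refinement; compares two
// equal-length strings and returns the number of matching positions ('N'
// never matches).
// [[Rcpp::export]]
int cpp_match_count(std::string a, std::string b) {
  if (a.size() != b.size()) stop("length mismatch");
  int n = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] == b[i] && a[i] != 'N') ++n;
  return n;
}
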