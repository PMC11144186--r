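#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with full three-state traceback.
// A gap of length k costs open + k * extend. Masked positions are
// unusable (large negative substitution score), which lets repeated
// scans extract secondary HSPs after masking the residues of
// previously reported ones.

namespace {

struct AlnResult {
  int score;
  int a_start, a_end, b_start, b_end;  // 1-based inclusive; 0 if empty
  int matches, aln_length, mismatches, gapopens;
};

const int NEG = -1000000000;

enum { TB_NONE = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

AlnResult sw_once(const std::string& a, const std::string& b,
                  const std::vector<int>& lut, int nsym,
                  const std::vector<int>& code_a,
                  const std::vector<int>& code_b,
                  const std::vector<char>& mask_a,
                  const std::vector<char>& mask_b,
                  int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> Hprev(m + 1, 0), H(m + 1, 0);
  std::vector<int> E(m + 1, NEG), F(m + 1, NEG);
  const size_t W = (size_t)m + 1;
  std::vector<unsigned char> tbH((size_t)(n + 1) * W, TB_NONE);
  std::vector<unsigned char> tbE((size_t)(n + 1) * W, 0);  // 1 = extend
  std::vector<unsigned char> tbF((size_t)(n + 1) * W, 0);  // 1 = extend
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    H[0] = 0;
    E[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int sub = (mask_a[i - 1] || mask_b[j - 1])
                    ? NEG
                    : lut[code_a[i - 1] * nsym + code_b[j - 1]];
      int e_open = H[j - 1] - gap_open - gap_extend;
      int e_ext = E[j - 1] - gap_extend;
      if (e_ext > e_open) {
        E[j] = e_ext;
        tbE[i * W + j] = 1;
      } else {
        E[j] = e_open;
        tbE[i * W + j] = 0;
      }
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext = F[j] - gap_extend;
      if (f_ext > f_open) {
        F[j] = f_ext;
        tbF[i * W + j] = 1;
      } else {
        F[j] = f_open;
        tbF[i * W + j] = 0;
      }
      int diag = Hprev[j - 1] + sub;
      int h = 0;
      unsigned char dir = TB_NONE;
      if (diag > h) { h = diag; dir = TB_DIAG; }
      if (F[j] > h) { h = F[j]; dir = TB_UP; }
      if (E[j] > h) { h = E[j]; dir = TB_LEFT; }
      H[j] = h;
      tbH[i * W + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, H);
  }
  AlnResult res{best, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best <= 0) return res;
  int i = bi, j = bj;
  res.a_end = bi;
  res.b_end = bj;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char dir = tbH[i * W + j];
      if (dir == TB_NONE) break;
      if (dir == TB_DIAG) {
        res.aln_length++;
        if (a[i - 1] == b[j - 1]) res.matches++; else res.mismatches++;
        --i; --j;
      } else if (dir == TB_LEFT) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // consuming b (gap in a)
      res.aln_length++;
      bool ext = tbE[i * W + j] != 0;
      --j;
      if (!ext) { res.gapopens++; state = 0; }
    } else {  // consuming a (gap in b)
      res.aln_length++;
      bool ext = tbF[i * W + j] != 0;
      --i;
      if (!ext) { res.gapopens++; state = 0; }
    }
  }
  res.a_start = i + 1;
  res.b_start = j + 1;
  return res;
}

void build_codes(const std::string& s, const std::string& alphabet,
                 std::vector<int>& codes) {
  int map[256];
  for (int k = 0; k < 256; ++k) map[k] = -1;
  for (size_t k = 0; k < alphabet.size(); ++k) {
    map[(unsigned char)alphabet[k]] = (int)k;
  }
  int unk = map[(unsigned char)'X'];
  if (unk < 0) unk = 0;
  codes.resize(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    int c = map[(unsigned char)s[k]];
    codes[k] = c < 0 ? unk : c;
  }
}

List result_to_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["a_start"] = r.a_start,
      _["a_end"] = r.a_end, _["b_start"] = r.b_start,
      _["b_end"] = r.b_end, _["matches"] = r.matches,
      _["aln_length"] = r.aln_length, _["mismatches"] = r.mismatches,
      _["gapopens"] = r.gapopens);
}

}  // namespace

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix sub,
                  std::string alphabet, int gap_open, int gap_extend) {
  int nsym = alphabet.size();
  std::vector<int> lut(nsym * nsym);
  for (int i = 0; i < nsym; ++i)
    for (int j = 0; j < nsym; ++j) lut[i * nsym + j] = sub(i, j);
  std::vector<int> ca, cb;
  build_codes(a, alphabet, ca);
  build_codes(b, alphabet, cb);
  std::vector<char> ma(a.size(), 0), mb(b.size(), 0);
  AlnResult r =
      sw_once(a, b, lut, nsym, ca, cb, ma, mb, gap_open, gap_extend);
  return result_to_list(r);
}

// [[Rcpp::export]]
List sw_hsps_cpp(std::string a, std::string b, IntegerMatrix sub,
                 std::string alphabet, int gap_open, int gap_extend,
                 int score_min, int max_hsps) {
  int nsym = alphabet.size();
  std::vector<int> lut(nsym * nsym);
  for (int i = 0; i < nsym; ++i)
    for (int j = 0; j < nsym; ++j) lut[i * nsym + j] = sub(i, j);
  std::vector<int> ca, cb;
  build_codes(a, alphabet, ca);
  build_codes(b, alphabet, cb);
  std::vector<char> ma(a.size(), 0), mb(b.size(), 0);
  List out;
  for (int h = 0; h < max_hsps; ++h) {
    AlnResult r =
        sw_once(a, b, lut, nsym, ca, cb, ma, mb, gap_open, gap_extend);
    if (r.score < score_min || r.score <= 0) break;
    out.push_back(result_to_list(r));
    for (int i = r.a_start; i <= r.a_end; ++i) ma[i - 1] = 1;
    for (int j = r.b_start; j <= r.b_end; ++j) mb[j - 1] = 1;
  }
  return out;
}

// Best ungapped sliding identity between two sequences: max over all
// offsets of (matching residues) / (length of the shorter sequence).
// [[Rcpp::export]]
double sliding_identity_cpp(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  int best = 0;
  for (int off = -(m - 1); off <= n - 1; ++off) {
    int matches = 0;
    int i0 = off > 0 ? off : 0;
    int j0 = off > 0 ? 0 : -off;
    int len = std::min(n - i0, m - j0);
    for (int k = 0; k < len; ++k) {
      if (a[i0 + k] == b[j0 + k]) ++matches;
    }
    if (matches > best) best = matches;
  }
  return (double)best / (double)std::min(n, m);
}
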