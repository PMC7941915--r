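#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Pairing class between a small RNA base and a target base, both given on
// the sense strand 5'->3' in DNA letters: 2 = Watson-Crick, 1 = G:U wobble
// (G:T / T:G in DNA letters), 0 = mismatch.
static inline int pair_class(char s, char t) {
  switch (s) {
    case 'A': return t == 'T' ? 2 : 0;
    case 'C': return t == 'G' ? 2 : 0;
    case 'G': return t == 'C' ? 2 : (t == 'T' ? 1 : 0);
    case 'T': return t == 'A' ? 2 : (t == 'G' ? 1 : 0);
  }
  return 0;
}

static inline double pair_score(int cls) {
  return cls == 2 ? 1.0 : (cls == 1 ? 0.5 : 0.0);
}

// [[Rcpp::export(name = ".mott_trim_cpp")]]
IntegerMatrix mott_trim_cpp(CharacterVector quals, double limit) {
  // Maximal-scoring segment under the running-sum rule
  // score += (limit - P_error(base)); returns 1-based [start, end] per read
  // (start 0 / end -1 when the whole read is discarded). Leftmost maximal
  // segment wins ties.
  int n = quals.size();
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    std::string q = as<std::string>(quals[r]);
    int len = q.size();
    double best = 0.0, cur = 0.0;
    int bs = 0, be = -1, cs = 0;
    for (int i = 0; i < len; ++i) {
      double perr = std::pow(10.0, -((double)(q[i] - 33)) / 10.0);
      double w = limit - perr;
      if (cur + w > w) { cur += w; } else { cur = w; cs = i; }
      if (cur > best + 1e-12) { best = cur; bs = cs; be = i; }
    }
    if (be < 0) { out(r, 0) = 0; out(r, 1) = -1; }
    else { out(r, 0) = bs + 1; out(r, 1) = be + 1; }
  }
  return out;
}

// [[Rcpp::export(name = ".adapter_find_cpp")]]
IntegerVector adapter_find_cpp(CharacterVector seqs, std::string adapter,
                               int min_overlap) {
  // Leftmost start of a 3' adapter occurrence: the adapter prefix is
  // matched against the read suffix starting at each position, allowing
  // one mismatch per 10 aligned bases. Returns the 0-based insert length
  // (= adapter start); read length when no adapter is found.
  int n = seqs.size();
  int alen = adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int len = s.size();
    int found = len;
    for (int st = 0; st <= len - min_overlap; ++st) {
      int ov = std::min(len - st, alen);
      int allowed = ov / 10;
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (s[st + k] != adapter[k]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) { found = st; break; }
    }
    out[r] = found;
  }
  return out;
}

struct Cand {
  int site_start, site_end;
  double score;
  std::vector<int> spos, tpos, pcls;
};

// Global Needleman-Wunsch of the sRNA against the reverse of a transcript
// window: match +1, G:U +0.5, mismatch 0, gap -2 (end gaps included).
// Ties broken diagonal > gap-in-window > gap-in-sRNA, so alignments are
// deterministic.
static Cand align_window(const std::string& s, const std::string& tx,
                         int a, int L) {
  int m = s.size();
  // reversed window characters: w[k] = tx[a + L - 1 - k] (0-based a)
  std::vector<double> dp((m + 1) * (L + 1));
  std::vector<char> tb((m + 1) * (L + 1));
  const double G = -2.0;
  for (int j = 0; j <= L; ++j) { dp[j] = G * j; tb[j] = 'l'; }
  for (int i = 1; i <= m; ++i) {
    dp[i * (L + 1)] = G * i;
    tb[i * (L + 1)] = 'u';
    for (int j = 1; j <= L; ++j) {
      char tc = tx[a + L - j];  // reversed window char j (1-based)
      double diag = dp[(i - 1) * (L + 1) + (j - 1)] +
                    pair_score(pair_class(s[i - 1], tc));
      double left = dp[i * (L + 1) + (j - 1)] + G;
      double up = dp[(i - 1) * (L + 1) + j] + G;
      double best = diag; char mv = 'd';
      if (left > best + 1e-12) { best = left; mv = 'l'; }
      if (up > best + 1e-12) { best = up; mv = 'u'; }
      dp[i * (L + 1) + j] = best;
      tb[i * (L + 1) + j] = mv;
    }
  }
  Cand c;
  c.site_start = a + 1;          // back to 1-based transcript coords
  c.site_end = a + L;
  c.score = dp[m * (L + 1) + L];
  int i = m, j = L;
  while (i > 0 || j > 0) {
    char mv = tb[i * (L + 1) + j];
    if (i > 0 && j > 0 && mv == 'd') {
      char tc = tx[a + L - j];
      c.spos.push_back(i);
      c.tpos.push_back(a + L - j + 1);  // 1-based transcript position
      c.pcls.push_back(pair_class(s[i - 1], tc));
      --i; --j;
    } else if (j > 0 && (mv == 'l' || i == 0)) {
      --j;
    } else {
      --i;
    }
  }
  std::reverse(c.spos.begin(), c.spos.end());
  std::reverse(c.tpos.begin(), c.tpos.end());
  std::reverse(c.pcls.begin(), c.pcls.end());
  return c;
}

// [[Rcpp::export(name = ".duplex_scan_cpp")]]
List duplex_scan_cpp(std::string srna, std::string tx, int max_bulge,
                     double min_score) {
  // Scan every window of length len(srna)-max_bulge .. len(srna)+max_bulge,
  // keeping, per window start, the best-scoring alignment when it reaches
  // min_score.
  int m = srna.size();
  int n = tx.size();
  List out;
  if (n < m) return out;
  for (int a = 0; a < n; ++a) {
    bool have = false;
    Cand best;
    for (int L = std::max(1, m - max_bulge);
         L <= std::min(m + max_bulge, n - a); ++L) {
      Cand c = align_window(srna, tx, a, L);
      if (!have || c.score > best.score + 1e-12) { best = c; have = true; }
    }
    if (have && best.score >= min_score - 1e-12) {
      out.push_back(List::create(
        _["site_start"] = best.site_start, _["site_end"] = best.site_end,
        _["pair_score"] = best.score,
        _["srna_pos"] = IntegerVector(best.spos.begin(), best.spos.end()),
        _["target_pos"] = IntegerVector(best.tpos.begin(), best.tpos.end()),
        _["pair_class"] = IntegerVector(best.pcls.begin(), best.pcls.end())));
    }
  }
  return out;
}
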