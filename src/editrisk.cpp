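// Core string machinery: suffix automata for shortest-unique-substring
// (SUS) statistics, banded-free ("fitting") semiglobal alignment, and the
// tandem-arm longest-homology scan. Everything here must agree with the
// brute-force definitions exercised in the test suite.
#include <Rcpp.h>
#include <array>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

struct Sam {
  std::vector<std::array<int, 4>> nxt;
  std::vector<int> len, lnk;
  std::vector<long long> cnt;
  int last;

  explicit Sam(size_t cap) {
    nxt.reserve(2 * cap + 4);
    len.reserve(2 * cap + 4);
    lnk.reserve(2 * cap + 4);
    cnt.reserve(2 * cap + 4);
    nxt.push_back({{-1, -1, -1, -1}});
    len.push_back(0);
    lnk.push_back(-1);
    cnt.push_back(0);
    last = 0;
  }

  int add_node(int l, int link, const std::array<int, 4>& tr, long long c) {
    nxt.push_back(tr);
    len.push_back(l);
    lnk.push_back(link);
    cnt.push_back(c);
    return (int)len.size() - 1;
  }

  // Classic single-string extension; cnt marks primary (non-clone) states.
  void extend(int c) {
    int cur = add_node(len[last] + 1, -1, {{-1, -1, -1, -1}}, 1);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) { nxt[p][c] = cur; p = lnk[p]; }
    if (p == -1) {
      lnk[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        lnk[cur] = q;
      } else {
        int clone = add_node(len[p] + 1, lnk[q], nxt[q], 0);
        while (p != -1 && nxt[p][c] == q) { nxt[p][c] = clone; p = lnk[p]; }
        lnk[q] = clone;
        lnk[cur] = clone;
      }
    }
    last = cur;
  }

  // Generalized extension (multi-string corpus); occurrence counts unused.
  int gen_extend(int from, int c) {
    if (nxt[from][c] != -1) {
      int q = nxt[from][c];
      if (len[q] == len[from] + 1) return q;
      int clone = add_node(len[from] + 1, lnk[q], nxt[q], 0);
      int p = from;
      while (p != -1 && nxt[p][c] == q) { nxt[p][c] = clone; p = lnk[p]; }
      lnk[q] = clone;
      return clone;
    }
    int cur = add_node(len[from] + 1, -1, {{-1, -1, -1, -1}}, 0);
    int p = from;
    while (p != -1 && nxt[p][c] == -1) { nxt[p][c] = cur; p = lnk[p]; }
    if (p == -1) {
      lnk[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        lnk[cur] = q;
      } else {
        int clone = add_node(len[p] + 1, lnk[q], nxt[q], 0);
        while (p != -1 && nxt[p][c] == q) { nxt[p][c] = clone; p = lnk[p]; }
        lnk[q] = clone;
        lnk[cur] = clone;
      }
    }
    return cur;
  }

  // Propagate endpos occurrence counts along suffix links (len-sorted).
  void propagate_counts() {
    int n = (int)len.size();
    int maxlen = 0;
    for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, len[i]);
    std::vector<int> bucket(maxlen + 2, 0), order(n);
    for (int i = 0; i < n; ++i) bucket[len[i] + 1]++;
    for (int l = 1; l <= maxlen + 1; ++l) bucket[l] += bucket[l - 1];
    for (int i = 0; i < n; ++i) order[bucket[len[i]]++] = i;
    for (int k = n - 1; k >= 1; --k) {
      int v = order[k];
      if (lnk[v] >= 0) cnt[lnk[v]] += cnt[v];
    }
  }
};

// Matching statistics ending at each query position, restricted to factors
// with >= min_cnt occurrences (min_cnt <= 0 means "exists in automaton").
static std::vector<int> ms_end(const Sam& sam, const std::vector<int>& q,
                               long long min_cnt) {
  int n = (int)q.size();
  std::vector<int> res(n, 0);
  int v = 0, l = 0;
  for (int i = 0; i < n; ++i) {
    int c = q[i];
    if (c < 0) { v = 0; l = 0; res[i] = 0; continue; }
    while (v != 0 && sam.nxt[v][c] == -1) { v = sam.lnk[v]; l = sam.len[v]; }
    if (sam.nxt[v][c] != -1) { v = sam.nxt[v][c]; ++l; } else { l = 0; }
    if (min_cnt > 0) {
      while (v != 0 && sam.cnt[v] < min_cnt) { v = sam.lnk[v]; l = sam.len[v]; }
    }
    res[i] = l;
  }
  return res;
}

// Convert end-anchored matching statistics to start-anchored ones using the
// monotonicity of match start positions.
static std::vector<int> ms_start(const std::vector<int>& mse) {
  int n = (int)mse.size();
  std::vector<int> res(n, 0);
  int J = -1;
  for (int i = 0; i < n; ++i) {
    if (J < i - 1) J = i - 1;
    while (J + 1 < n && (J + 1) - mse[J + 1] + 1 <= i) ++J;
    res[i] = (J >= i) ? (J - i + 1) : 0;
  }
  return res;
}

// Per-position shortest-unique-substring lengths within `seq`.
// Element i is 1 + (longest prefix of seq[i..] occurring >= 2 times in seq);
// when the full suffix repeats this equals the sentinel (suffix length + 1).
// [[Rcpp::export]]
IntegerVector cpp_sus_local(std::string seq) {
  std::vector<int> q = encode(seq);
  Sam sam(q.size());
  for (int c : q) {
    if (c < 0) stop("sequence must contain only A/C/G/T");
    sam.extend(c);
  }
  sam.propagate_counts();
  std::vector<int> L2 = ms_start(ms_end(sam, q, 2));
  IntegerVector out((int)q.size());
  for (size_t i = 0; i < q.size(); ++i) out[i] = L2[i] + 1;
  return out;
}

// For each query and each start position, the longest prefix of the query
// suffix occurring as a substring of any corpus string. Non-ACGT characters
// break matches.
// [[Rcpp::export]]
List cpp_match_prefix(CharacterVector queries, CharacterVector corpus) {
  size_t total = 0;
  for (int i = 0; i < corpus.size(); ++i) total += std::string(corpus[i]).size();
  Sam sam(total);
  for (int i = 0; i < corpus.size(); ++i) {
    std::string s = as<std::string>(corpus[i]);
    int st = 0;
    for (char ch : s) {
      int c = base_code(ch);
      if (c < 0) { st = 0; continue; }
      st = sam.gen_extend(st, c);
    }
  }
  List out(queries.size());
  for (int i = 0; i < queries.size(); ++i) {
    std::vector<int> q = encode(as<std::string>(queries[i]));
    std::vector<int> L = ms_start(ms_end(sam, q, 0));
    out[i] = IntegerVector(L.begin(), L.end());
  }
  return out;
}

// Longest same-strand ungapped homology between two arms allowing at most
// `max_mismatch` substitutions: maximum over all alignment offsets of the
// longest window with <= max_mismatch mismatches.
// [[Rcpp::export]]
int cpp_tandem_len(std::string left, std::string right, int max_mismatch) {
  int nl = (int)left.size(), nr = (int)right.size();
  if (nl == 0 || nr == 0) return 0;
  int best = 0;
  if (max_mismatch == 1) {
    // match-run decomposition: the best window around each mismatch is
    // (run before) + 1 + (run after); cheap on mismatch-dense diagonals
    for (int s = -(nl - 1); s <= nr - 1; ++s) {
      int i0 = std::max(0, -s);
      int i1 = std::min(nl, nr - s);  // exclusive
      if (i1 - i0 <= best) continue;
      const char* R_ = right.c_str() + s;
      int prev = -1, cur = 0;
      for (int i = i0; i < i1; ++i) {
        if (left[i] == R_[i]) {
          ++cur;
        } else {
          if (prev + 1 + cur > best) best = prev + 1 + cur;
          prev = cur;
          cur = 0;
        }
      }
      int tail = (prev == -1) ? cur : prev + 1 + cur;
      if (tail > best) best = tail;
    }
    return best;
  }
  const int cap = std::max(1, max_mismatch);
  std::vector<int> ring(cap);
  for (int s = -(nl - 1); s <= nr - 1; ++s) {
    int i0 = std::max(0, -s);
    int i1 = std::min(nl, nr - s);  // exclusive
    if (i1 - i0 <= best) continue;
    int lo = i0, head = 0, cnt = 0;
    const char* R_ = right.c_str() + s;
    for (int i = i0; i < i1; ++i) {
      if (left[i] != R_[i]) {
        if (max_mismatch == 0) {
          lo = i + 1;
        } else {
          if (cnt == max_mismatch) {  // evict oldest mismatch
            lo = ring[head] + 1;
            head = (head + 1) % cap;
            --cnt;
          }
          ring[(head + cnt) % cap] = i;
          ++cnt;
        }
      }
      if (i - lo + 1 > best) best = i - lo + 1;
    }
  }
  return best;
}

// Fitting ("semiglobal") alignment of a short guide inside a longer window:
// the window's flanks are free, the full guide must be consumed, internal
// gaps and substitutions cost 1. Returns the minimum edit distance, the
// 0-based window start/end of the aligned segment, and the substitution
// count along one optimal (diagonal-preferring) path.
// [[Rcpp::export]]
List cpp_semiglobal(std::string guide, std::string window) {
  int g = (int)guide.size(), w = (int)window.size();
  if (w < g) stop("window shorter than guide");
  std::vector<std::vector<int>> dp(g + 1, std::vector<int>(w + 1));
  for (int j = 0; j <= w; ++j) dp[0][j] = 0;
  for (int i = 1; i <= g; ++i) {
    dp[i][0] = i;
    for (int j = 1; j <= w; ++j) {
      int sub = dp[i - 1][j - 1] + (guide[i - 1] == window[j - 1] ? 0 : 1);
      int del = dp[i - 1][j] + 1;  // guide base unmatched (gap in window row)
      int ins = dp[i][j - 1] + 1;  // extra window base inside alignment
      dp[i][j] = std::min(sub, std::min(del, ins));
    }
  }
  int bestj = 0, bestd = dp[g][0];
  for (int j = 1; j <= w; ++j)
    if (dp[g][j] < bestd) { bestd = dp[g][j]; bestj = j; }
  // traceback, preferring diagonal moves
  int i = g, j = bestj, mism = 0;
  while (i > 0) {
    if (j > 0 && dp[i][j] == dp[i - 1][j - 1] +
                     (guide[i - 1] == window[j - 1] ? 0 : 1)) {
      if (guide[i - 1] != window[j - 1]) ++mism;
      --i; --j;
    } else if (dp[i][j] == dp[i - 1][j] + 1) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["distance"] = bestd, _["start"] = j,
                      _["end"] = bestj, _["mismatches"] = mism);
}

// Reverse complement (upper case); non-ACGT maps to N.
// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.size(), 'N');
  static const char comp[] = "TGCA";
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[s.size() - 1 - i]);
    if (c >= 0) out[i] = comp[c];
  }
  return out;
}

// Fisher-Yates shuffle driven by R's RNG (deterministic under set.seed).
static void shuffle_codes(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

static double mean_sus_local(const std::vector<int>& q) {
  Sam sam(q.size());
  for (int c : q) sam.extend(c);
  sam.propagate_counts();
  std::vector<int> L2 = ms_start(ms_end(sam, q, 2));
  double s = 0;
  for (int v : L2) s += v + 1;
  return s / (double)q.size();
}

// Mean local SUS length of `seq` and of n_shuffles composition-preserving
// shuffles (observed value first).
// [[Rcpp::export]]
NumericVector cpp_sus_mean_local(std::string seq, int n_shuffles) {
  std::vector<int> q = encode(seq);
  for (int c : q)
    if (c < 0) stop("sequence must contain only A/C/G/T");
  NumericVector out(n_shuffles + 1);
  out[0] = mean_sus_local(q);
  for (int k = 1; k <= n_shuffles; ++k) {
    shuffle_codes(q);
    out[k] = mean_sus_local(q);
  }
  return out;
}

// Mean global SUS length (against a fixed corpus) of `window` and of
// n_shuffles shuffles of the window (observed value first).
// [[Rcpp::export]]
NumericVector cpp_sus_mean_global(std::string window, CharacterVector corpus,
                                  int n_shuffles) {
  size_t total = 0;
  for (int i = 0; i < corpus.size(); ++i) total += std::string(corpus[i]).size();
  Sam sam(total);
  for (int i = 0; i < corpus.size(); ++i) {
    std::string s = as<std::string>(corpus[i]);
    int st = 0;
    for (char ch : s) {
      int c = base_code(ch);
      if (c < 0) { st = 0; continue; }
      st = sam.gen_extend(st, c);
    }
  }
  std::vector<int> q = encode(window);
  NumericVector out(n_shuffles + 1);
  for (int k = 0; k <= n_shuffles; ++k) {
    if (k > 0) shuffle_codes(q);
    std::vector<int> L = ms_start(ms_end(sam, q, 0));
    double s = 0;
    for (int v : L) s += v + 1;
    out[k] = s / (double)q.size();
  }
  return out;
}

static Sam* build_gen_sam(CharacterVector corpus) {
  size_t total = 0;
  for (int i = 0; i < corpus.size(); ++i) total += std::string(corpus[i]).size();
  Sam* sam = new Sam(total);
  for (int i = 0; i < corpus.size(); ++i) {
    std::string s = as<std::string>(corpus[i]);
    int st = 0;
    for (char ch : s) {
      int c = base_code(ch);
      if (c < 0) { st = 0; continue; }
      st = sam->gen_extend(st, c);
    }
  }
  return sam;
}

// Persistent generalized suffix automaton over a fixed corpus, reusable
// across many query windows.
// [[Rcpp::export]]
SEXP cpp_sam_xptr(CharacterVector corpus) {
  XPtr<Sam> p(build_gen_sam(corpus), true);
  return p;
}

// Mean global SUS of `window` (+ shuffles) against the union of a fixed
// corpus automaton and an additional small corpus built per call.
// [[Rcpp::export]]
NumericVector cpp_sus_mean_global_x(std::string window, SEXP big_sam,
                                    CharacterVector extra_corpus,
                                    int n_shuffles) {
  XPtr<Sam> big(big_sam);
  Sam* extra = NULL;
  if (extra_corpus.size() > 0) extra = build_gen_sam(extra_corpus);
  std::vector<int> q = encode(window);
  NumericVector out(n_shuffles + 1);
  for (int k = 0; k <= n_shuffles; ++k) {
    if (k > 0) shuffle_codes(q);
    std::vector<int> L = ms_start(ms_end(*big, q, 0));
    if (extra) {
      std::vector<int> L2 = ms_start(ms_end(*extra, q, 0));
      for (size_t i = 0; i < L.size(); ++i) L[i] = std::max(L[i], L2[i]);
    }
    double s = 0;
    for (int v : L) s += v + 1;
    out[k] = s / (double)q.size();
  }
  if (extra) delete extra;
  return out;
}

// Hamming distances between a spacer and a set of equal-length strings.
// [[Rcpp::export]]
IntegerVector cpp_hamming(std::string spacer, CharacterVector others) {
  int n = others.size();
  IntegerVector out(n);
  int L = (int)spacer.size();
  for (int k = 0; k < n; ++k) {
    const char* o = CHAR(STRING_ELT(others, k));
    int d = 0;
    for (int i = 0; i < L; ++i) d += (spacer[i] != o[i]);
    out[k] = d;
  }
  return out;
}
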