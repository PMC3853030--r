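// Core dynamic programming and search loops for Sequence-Levenshtein barcodes.
// Words are encoded over the quaternary alphabet A,C,G,T = 0,1,2,3.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

typedef std::vector<uint8_t> Word;

static const int METRIC_HAMMING = 0;
static const int METRIC_LEV = 1;
static const int METRIC_SEQLEV = 2;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char BASES[5] = "ACGT";

static Word encode_word(const std::string& s) {
  Word w(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) stop("non-ACGT character '%s' in word '%s'", std::string(1, s[i]).c_str(), s.c_str());
    w[i] = (uint8_t) b;
  }
  return w;
}

static std::string decode_word(const Word& w) {
  std::string s(w.size(), 'A');
  for (size_t i = 0; i < w.size(); ++i) s[i] = BASES[w[i]];
  return s;
}

static std::vector<Word> encode_all(const CharacterVector& x) {
  std::vector<Word> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = encode_word(as<std::string>(x[i]));
  return out;
}

// ---- distances ------------------------------------------------------------

static int hamming(const Word& a, const Word& b) {
  if (a.size() != b.size())
    stop("hamming distance requires words of equal length (%d vs %d)",
         (int) a.size(), (int) b.size());
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) d += (a[i] != b[i]);
  return d;
}

// Wagner-Fischer with two rows; returns the classic Levenshtein distance.
static int lev(const Word& a, const Word& b, std::vector<int>& prev, std::vector<int>& cur) {
  const int la = (int) a.size(), lb = (int) b.size();
  prev.resize(lb + 1); cur.resize(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    const uint8_t ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int d = prev[j - 1] + (ai != b[j - 1]);
      int e = prev[j] + 1;
      if (e < d) d = e;
      int f = cur[j - 1] + 1;
      if (f < d) d = f;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Sequence-Levenshtein distance: minimum over the last row and last column of
// the Levenshtein DP matrix (free final truncation/elongation).
static int seqlev(const Word& a, const Word& b, std::vector<int>& prev, std::vector<int>& cur) {
  const int la = (int) a.size(), lb = (int) b.size();
  prev.resize(lb + 1); cur.resize(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  int best = prev[lb];  // cell (0, lb) of the last column
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    const uint8_t ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int d = prev[j - 1] + (ai != b[j - 1]);
      int e = prev[j] + 1;
      if (e < d) d = e;
      int f = cur[j - 1] + 1;
      if (f < d) d = f;
      cur[j] = d;
    }
    if (cur[lb] < best) best = cur[lb];  // last column
    std::swap(prev, cur);
  }
  for (int j = 0; j <= lb; ++j)          // last row
    if (prev[j] < best) best = prev[j];
  return best;
}

static int dist_by_metric(int metric, const Word& a, const Word& b,
                          std::vector<int>& prev, std::vector<int>& cur) {
  switch (metric) {
    case METRIC_HAMMING: return hamming(a, b);
    case METRIC_LEV:     return lev(a, b, prev, cur);
    default:             return seqlev(a, b, prev, cur);
  }
}

// [[Rcpp::export]]
IntegerVector c_pair_distance(CharacterVector a, CharacterVector b, int metric) {
  if (a.size() != b.size()) stop("'a' and 'b' must have the same length");
  std::vector<Word> wa = encode_all(a), wb = encode_all(b);
  std::vector<int> prev, cur;
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = dist_by_metric(metric, wa[i], wb[i], prev, cur);
  return out;
}

// Full (|a|+1) x (|b|+1) Levenshtein DP matrix.
// [[Rcpp::export]]
IntegerMatrix c_lev_matrix(std::string a, std::string b) {
  Word wa = encode_word(a), wb = encode_word(b);
  const int la = (int) wa.size(), lb = (int) wb.size();
  IntegerMatrix m(la + 1, lb + 1);
  for (int j = 0; j <= lb; ++j) m(0, j) = j;
  for (int i = 1; i <= la; ++i) {
    m(i, 0) = i;
    for (int j = 1; j <= lb; ++j) {
      int d = m(i - 1, j - 1) + (wa[i - 1] != wb[j - 1]);
      int e = m(i - 1, j) + 1;
      if (e < d) d = e;
      int f = m(i, j - 1) + 1;
      if (f < d) d = f;
      m(i, j) = d;
    }
  }
  return m;
}

// Optimal Sequence-Levenshtein boundary cell for word a vs word b.
// Tie-break: prefer a last-row cell over a last-column cell; among last-row
// cells prefer column j with |j - |a|| minimal, then larger j (net indel
// balance closest to zero, then fewest net deletions).
// Returns (distance, row, col) of the selected boundary cell.
static void seqlev_boundary_cell(const Word& a, const Word& b,
                                 int& dist, int& row, int& col) {
  const int la = (int) a.size(), lb = (int) b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  int bestcol_val = prev[lb], bestcol_row = 0;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    const uint8_t ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int d = prev[j - 1] + (ai != b[j - 1]);
      int e = prev[j] + 1;
      if (e < d) d = e;
      int f = cur[j - 1] + 1;
      if (f < d) d = f;
      cur[j] = d;
    }
    if (cur[lb] < bestcol_val) { bestcol_val = cur[lb]; bestcol_row = i; }
    std::swap(prev, cur);
  }
  // last row is in prev
  int bestrow_val = prev[0], bestrow_col = 0;
  for (int j = 1; j <= lb; ++j) {
    if (prev[j] < bestrow_val) { bestrow_val = prev[j]; bestrow_col = j; }
    else if (prev[j] == bestrow_val) {
      int dnew = std::abs(j - la), dold = std::abs(bestrow_col - la);
      if (dnew < dold || (dnew == dold && j > bestrow_col)) bestrow_col = j;
    }
  }
  if (bestrow_val <= bestcol_val) { dist = bestrow_val; row = la; col = bestrow_col; }
  else                            { dist = bestcol_val; row = bestcol_row; col = lb; }
}

// [[Rcpp::export]]
IntegerVector c_seqlev_boundary(std::string a, std::string b) {
  Word wa = encode_word(a), wb = encode_word(b);
  int d, r, c;
  seqlev_boundary_cell(wa, wb, d, r, c);
  return IntegerVector::create(_["distance"] = d, _["row"] = r, _["col"] = c);
}

// Threshold test: is dist(a, b) >= dmin? Uses a banded DP (Ukkonen) with
// threshold t = dmin - 1: any cell with |i - j| > t already exceeds t, so
// only the diagonal band is computed. Exact distances use the full matrix;
// this is the hot path of the greedy closure only.
static bool dist_ge(int metric, const Word& a, const Word& b, int dmin,
                    std::vector<int>& prev, std::vector<int>& cur) {
  if (dmin <= 0) return true;
  const int t = dmin - 1;
  if (metric == METRIC_HAMMING) {
    if (a.size() != b.size())
      stop("hamming distance requires words of equal length");
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i)
      if (a[i] != b[i] && ++d >= dmin) return true;
    return false;
  }
  const int la = (int) a.size(), lb = (int) b.size();
  if (metric == METRIC_LEV && std::abs(la - lb) > t) return true;
  const int INF = 1 << 28;
  prev.assign(lb + 1, INF);
  cur.assign(lb + 1, INF);
  for (int j = 0; j <= std::min(lb, t); ++j) prev[j] = j;
  int best = INF;                       // seqlev: min over last col/row in band
  if (lb <= t) best = prev[lb];
  bool completed = (la == 0);
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(0, i - t), jhi = std::min(lb, i + t);
    if (jlo > jhi) break;               // band left the matrix
    if (jlo > 0) cur[jlo - 1] = INF;
    const uint8_t ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      if (j == 0) { cur[0] = i; continue; }
      int d = INF;
      if (prev[j - 1] < INF) d = prev[j - 1] + (ai != b[j - 1]);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      cur[j] = d;
    }
    if (jhi < lb) cur[jhi + 1] = INF;
    if (jhi == lb && cur[lb] < best) best = cur[lb];
    std::swap(prev, cur);
    if (i == la) completed = true;
  }
  if (metric == METRIC_LEV) {
    return !completed || prev[lb] > t;
  }
  if (completed) {                      // last row contribution (in prev)
    for (int j = std::max(0, la - t); j <= std::min(lb, la + t); ++j)
      if (prev[j] < best) best = prev[j];
  }
  return best > t;
}

// [[Rcpp::export]]
LogicalVector c_pair_dist_ge(CharacterVector a, CharacterVector b,
                             int dmin, int metric) {
  if (a.size() != b.size()) stop("'a' and 'b' must have the same length");
  std::vector<Word> wa = encode_all(a), wb = encode_all(b);
  std::vector<int> prev, cur;
  LogicalVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = dist_ge(metric, wa[i], wb[i], dmin, prev, cur);
  return out;
}

// ---- candidate enumeration -------------------------------------------------

static inline bool word_passes(const Word& w, double gc_min, double gc_max,
                               int max_run, bool reject_self_rc) {
  const int n = (int) w.size();
  int gc = 0, run = 1, maxrun = 1;
  for (int i = 0; i < n; ++i) {
    if (w[i] == 1 || w[i] == 2) ++gc;
    if (i > 0) {
      run = (w[i] == w[i - 1]) ? run + 1 : 1;
      if (run > maxrun) maxrun = run;
    }
  }
  double frac = (double) gc / n;
  if (frac < gc_min - 1e-9 || frac > gc_max + 1e-9) return false;
  if (maxrun > max_run) return false;
  if (reject_self_rc) {
    bool self_rc = true;
    for (int i = 0; i < n; ++i)
      if (w[i] != 3 - w[n - 1 - i]) { self_rc = false; break; }
    if (self_rc) return false;
  }
  return true;
}

// All length-n words over ACGT passing the filter policy, in lexicographic
// order (A < C < G < T).
// [[Rcpp::export]]
CharacterVector c_enumerate_candidates(int n, double gc_min, double gc_max,
                                       int max_run, bool reject_self_rc) {
  if (n < 1) stop("barcode length must be >= 1");
  if (n > 14) stop("candidate enumeration limited to n <= 14 (4^n words)");
  Word w(n, 0);
  std::vector<std::string> keep;
  for (;;) {
    if (word_passes(w, gc_min, gc_max, max_run, reject_self_rc))
      keep.push_back(decode_word(w));
    // odometer increment
    int i = n - 1;
    while (i >= 0 && w[i] == 3) { w[i] = 0; --i; }
    if (i < 0) break;
    ++w[i];
  }
  return wrap(keep);
}

// ---- greedy closure --------------------------------------------------------

// Scan candidates in the given (lexicographic) order, accepting each whose
// distance to every already-accepted barcode is >= dmin. The seed is accepted
// first and must itself satisfy the pairwise constraint.
// [[Rcpp::export]]
CharacterVector c_greedy_closure(CharacterVector seed, CharacterVector candidates,
                                 int dmin, int metric, int max_size) {
  std::vector<Word> acc = encode_all(seed);
  std::vector<int> prev, cur;
  for (size_t i = 0; i < acc.size(); ++i)
    for (size_t j = i + 1; j < acc.size(); ++j)
      if (dist_by_metric(metric, acc[i], acc[j], prev, cur) < dmin)
        stop("invalid seed: barcodes %d and %d are at distance < dmin",
             (int) i + 1, (int) j + 1);
  std::vector<Word> cand = encode_all(candidates);
  std::vector<std::string> out;
  out.reserve(acc.size() + 64);
  for (size_t i = 0; i < acc.size(); ++i) out.push_back(decode_word(acc[i]));
  for (size_t c = 0; c < cand.size(); ++c) {
    bool ok = true;
    // newest-first: lexicographic neighbours reject candidates fastest
    for (size_t j = acc.size(); j-- > 0; ) {
      if (!dist_ge(metric, cand[c], acc[j], dmin, prev, cur)) { ok = false; break; }
    }
    if (ok) {
      acc.push_back(cand[c]);
      out.push_back(decode_word(cand[c]));
      if (max_size > 0 && (int) acc.size() >= max_size) break;
    }
  }
  return wrap(out);
}

// All violating pairs (distance < dmin) in a set; rows of (i, j, distance).
// [[Rcpp::export]]
IntegerMatrix c_violating_pairs(CharacterVector barcodes, int dmin, int metric) {
  std::vector<Word> w = encode_all(barcodes);
  std::vector<int> prev, cur;
  std::vector<int> ii, jj, dd;
  for (size_t i = 0; i < w.size(); ++i)
    for (size_t j = i + 1; j < w.size(); ++j) {
      int d = dist_by_metric(metric, w[i], w[j], prev, cur);
      if (d < dmin) { ii.push_back((int) i + 1); jj.push_back((int) j + 1); dd.push_back(d); }
    }
  IntegerMatrix out((int) ii.size(), 3);
  for (size_t r = 0; r < ii.size(); ++r) {
    out(r, 0) = ii[r]; out(r, 1) = jj[r]; out(r, 2) = dd[r];
  }
  colnames(out) = CharacterVector::create("i", "j", "distance");
  return out;
}

// ---- decoding --------------------------------------------------------------

// Sequence-Levenshtein decoding of reads against a code. window > 0 limits the
// comparison to the read prefix of that length. max_distance < 0 means
// best-effort (accept any unique minimum). ties_random resolves minimum-
// distance ties uniformly at random (R's RNG) instead of reporting them.
// Status: 1 unique, 2 ambiguous (randomly resolved if ties_random),
// 3 rejected.
// [[Rcpp::export]]
List c_sl_decode_batch(CharacterVector reads, CharacterVector codewords,
                       int window, int max_distance, bool ties_random) {
  std::vector<Word> code = encode_all(codewords);
  const int m = (int) code.size();
  std::vector<int> prev, cur;
  R_xlen_t nr = reads.size();
  IntegerVector idx(nr), dist(nr), boundary(nr), status(nr);
  for (R_xlen_t r = 0; r < nr; ++r) {
    Word w = encode_word(as<std::string>(reads[r]));
    if (window > 0 && (int) w.size() > window) w.resize(window);
    int best = INT_MAX, besti = -1, ties = 0;
    for (int c = 0; c < m; ++c) {
      int d = seqlev(code[c], w, prev, cur);
      if (d < best) { best = d; besti = c; ties = 1; }
      else if (d == best) ++ties;
    }
    dist[r] = best;
    if (max_distance >= 0 && best > max_distance) {
      idx[r] = NA_INTEGER; boundary[r] = NA_INTEGER; status[r] = 3;
      continue;
    }
    if (ties > 1 && !ties_random) {
      idx[r] = NA_INTEGER; boundary[r] = NA_INTEGER; status[r] = 2;
      continue;
    }
    if (ties > 1) {  // random resolution among the tied codewords
      int pick = (int) (unif_rand() * ties) % ties;
      for (int c = 0, seen = 0; c < m; ++c) {
        int d = seqlev(code[c], w, prev, cur);
        if (d == best && seen++ == pick) { besti = c; break; }
      }
    }
    int d2, row, col;
    seqlev_boundary_cell(code[besti], w, d2, row, col);
    idx[r] = besti + 1;
    boundary[r] = col;
    status[r] = (ties > 1) ? 2 : 1;
  }
  return List::create(_["index"] = idx, _["distance"] = dist,
                      _["boundary"] = boundary, _["status"] = status);
}

// Fixed-length classic Levenshtein decoding. The received barcode length is
// unknown, so the presumed word length cascades outwards from n: first the
// window of length n is tried, accepting a codeword iff it is the only one
// within distance k; on failure the windows n-s and n+s are tried for
// s = 1..k (an s-indel imbalance shifts the boundary by s). Remaining
// ambiguity is resolved uniformly at random with R's RNG.
// Status: 1 resolved uniquely, 2 resolved by random tie-break.
// [[Rcpp::export]]
List c_classic_decode_batch(CharacterVector reads, CharacterVector codewords,
                            int n, int k) {
  std::vector<Word> code = encode_all(codewords);
  const int m = (int) code.size();
  const int nwin = 2 * k + 1;  // window order: n, n-1, n+1, ..., n-k, n+k
  std::vector<int> wlen(nwin);
  wlen[0] = n;
  for (int s = 1; s <= k; ++s) { wlen[2 * s - 1] = n - s; wlen[2 * s] = n + s; }
  std::vector<int> prev, cur;
  R_xlen_t nr = reads.size();
  IntegerVector idx(nr), dist(nr), window_used(nr), status(nr);
  std::vector<std::vector<int> > d(nwin, std::vector<int>(m));
  for (R_xlen_t r = 0; r < nr; ++r) {
    Word w = encode_word(as<std::string>(reads[r]));
    if ((int) w.size() < n + k)
      stop("read %d is shorter than n + k = %d", (int) r + 1, n + k);
    int resolved = -1, resolved_win = -1, tried = 0;
    for (int s = 0; s <= k && resolved < 0; ++s) {
      // windows with boundary shift s (one window for s = 0, two otherwise)
      int from = (s == 0) ? 0 : 2 * s - 1, to = (s == 0) ? 0 : 2 * s;
      for (int wi = from; wi <= to; ++wi) {
        if (wlen[wi] < 0) { d[wi].assign(m, INT_MAX); continue; }
        Word ww(w.begin(), w.begin() + wlen[wi]);
        for (int c = 0; c < m; ++c) d[wi][c] = lev(code[c], ww, prev, cur);
      }
      tried = to;
      int within = 0, hit = -1;
      for (int c = 0; c < m; ++c) {
        for (int wi = from; wi <= to; ++wi) {
          if (d[wi][c] <= k) { ++within; hit = c; break; }
        }
      }
      if (within == 1) {
        resolved = hit;
        resolved_win = from;
        for (int wi = from + 1; wi <= to; ++wi)
          if (d[wi][hit] < d[resolved_win][hit]) resolved_win = wi;
      } else if (within > 1) {
        break;  // ambiguous: go straight to the random tie-break
      }
    }
    if (resolved >= 0) {
      idx[r] = resolved + 1;
      dist[r] = d[resolved_win][resolved];
      window_used[r] = wlen[resolved_win];
      status[r] = 1;
      continue;
    }
    // random among codewords within k at any tried window, else among those
    // achieving the global minimum over the tried windows
    std::vector<int> pool;
    std::vector<int> mind(m, INT_MAX);
    for (int c = 0; c < m; ++c)
      for (int wi = 0; wi <= tried; ++wi)
        if (d[wi][c] < mind[c]) mind[c] = d[wi][c];
    for (int c = 0; c < m; ++c)
      if (mind[c] <= k) pool.push_back(c);
    if (pool.empty()) {
      int gmin = INT_MAX;
      for (int c = 0; c < m; ++c) gmin = std::min(gmin, mind[c]);
      for (int c = 0; c < m; ++c)
        if (mind[c] == gmin) pool.push_back(c);
    }
    int pick = pool[(int) (unif_rand() * pool.size()) % pool.size()];
    int bestwin = 0;
    for (int wi = 0; wi <= tried; ++wi)
      if (d[wi][pick] == mind[pick]) { bestwin = wi; break; }
    idx[r] = pick + 1; dist[r] = mind[pick];
    window_used[r] = wlen[bestwin];
    status[r] = 2;
  }
  return List::create(_["index"] = idx, _["distance"] = dist,
                      _["window_used"] = window_used, _["status"] = status);
}

// Nearest-codeword Hamming decoding on the read prefix of length n.
// [[Rcpp::export]]
List c_hamming_decode_batch(CharacterVector reads, CharacterVector codewords,
                            int n, int max_distance, bool ties_random) {
  std::vector<Word> code = encode_all(codewords);
  const int m = (int) code.size();
  R_xlen_t nr = reads.size();
  IntegerVector idx(nr), dist(nr), status(nr);
  for (R_xlen_t r = 0; r < nr; ++r) {
    Word w = encode_word(as<std::string>(reads[r]));
    if ((int) w.size() < n) stop("read %d is shorter than n = %d", (int) r + 1, n);
    w.resize(n);
    int best = INT_MAX, besti = -1, ties = 0;
    for (int c = 0; c < m; ++c) {
      int d = hamming(code[c], w);
      if (d < best) { best = d; besti = c; ties = 1; }
      else if (d == best) ++ties;
    }
    dist[r] = best;
    if (max_distance >= 0 && best > max_distance) {
      idx[r] = NA_INTEGER; status[r] = 3;
      continue;
    }
    if (ties > 1 && !ties_random) { idx[r] = NA_INTEGER; status[r] = 2; continue; }
    if (ties > 1) {
      int pick = (int) (unif_rand() * ties) % ties;
      for (int c = 0, seen = 0; c < m; ++c) {
        if (hamming(code[c], w) == best && seen++ == pick) { besti = c; break; }
      }
    }
    idx[r] = besti + 1;
    status[r] = (ties > 1) ? 2 : 1;
  }
  return List::create(_["index"] = idx, _["distance"] = dist, _["status"] = status);
}

// ---- mutation models -------------------------------------------------------

static inline int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int i = (int) (unif_rand() * n);
  return (i >= n) ? n - 1 : i;
}

// e sequential random edits per word. Type weights (w_sub, w_ins, w_del) need
// not be normalized. Substitutions always change the base; inserted bases are
// uniform over ACGT; positions are uniform on the current word (insertions
// have len+1 slots). A zero-length word can only be extended by insertion.
// [[Rcpp::export]]
List c_mutate_exact_batch(CharacterVector words, int e,
                          double w_sub, double w_ins, double w_del) {
  R_xlen_t nw = words.size();
  CharacterVector out(nw);
  IntegerVector nsub(nw), nins(nw), ndel(nw);
  double tot = w_sub + w_ins + w_del;
  if (tot <= 0) stop("at least one mutation type must have positive weight");
  for (R_xlen_t i = 0; i < nw; ++i) {
    Word w = encode_word(as<std::string>(words[i]));
    int cs = 0, ci = 0, cd = 0;
    for (int t = 0; t < e; ++t) {
      double u = unif_rand() * tot;
      int type = (u < w_sub) ? 0 : (u < w_sub + w_ins ? 1 : 2);
      if (w.empty() && type != 1) {
        if (w_ins <= 0) stop("cannot mutate an empty word without insertions");
        type = 1;
      }
      if (type == 0) {          // substitution: one of the 3 other bases
        int pos = runif_int((int) w.size());
        int nb = runif_int(3);
        if (nb >= w[pos]) ++nb;
        w[pos] = (uint8_t) nb;
        ++cs;
      } else if (type == 1) {   // insertion: len+1 slots, uniform base
        int pos = runif_int((int) w.size() + 1);
        int nb = runif_int(4);
        w.insert(w.begin() + pos, (uint8_t) nb);
        ++ci;
      } else {                  // deletion
        int pos = runif_int((int) w.size());
        w.erase(w.begin() + pos);
        ++cd;
      }
    }
    out[i] = decode_word(w);
    nsub[i] = cs; nins[i] = ci; ndel[i] = cd;
  }
  return List::create(_["word"] = out, _["n_sub"] = nsub,
                      _["n_ins"] = nins, _["n_del"] = ndel);
}

// Per-base mutation: each original base independently mutates with probability
// p; a mutating base is substituted (uniform over the other 3), deleted, or
// kept with a uniform base inserted before it (each type probability 1/3).
// Inserted bases are not re-mutated, so the expected edit count is p * length.
// [[Rcpp::export]]
List c_mutate_per_base_batch(CharacterVector words, double p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]");
  R_xlen_t nw = words.size();
  CharacterVector out(nw);
  IntegerVector nsub(nw), nins(nw), ndel(nw);
  for (R_xlen_t i = 0; i < nw; ++i) {
    Word w = encode_word(as<std::string>(words[i]));
    Word res;
    res.reserve(w.size() + 4);
    int cs = 0, ci = 0, cd = 0;
    for (size_t pos = 0; pos < w.size(); ++pos) {
      if (unif_rand() < p) {
        int type = runif_int(3);
        if (type == 0) {        // substitution
          int nb = runif_int(3);
          if (nb >= w[pos]) ++nb;
          res.push_back((uint8_t) nb);
          ++cs;
        } else if (type == 1) { // insertion before this base
          res.push_back((uint8_t) runif_int(4));
          res.push_back(w[pos]);
          ++ci;
        } else {                // deletion
          ++cd;
        }
      } else {
        res.push_back(w[pos]);
      }
    }
    out[i] = decode_word(res);
    nsub[i] = cs; nins[i] = ci; ndel[i] = cd;
  }
  return List::create(_["word"] = out, _["n_sub"] = nsub,
                      _["n_ins"] = nins, _["n_del"] = ndel);
}

// Uniform random ACGT words via R's RNG.
// [[Rcpp::export]]
CharacterVector c_random_words(int n_words, int len) {
  CharacterVector out(n_words);
  for (int i = 0; i < n_words; ++i) {
    std::string s(len, 'A');
    for (int j = 0; j < len; ++j) s[j] = BASES[runif_int(4)];
    out[i] = s;
  }
  return out;
}
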