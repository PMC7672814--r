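#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Internal text encoding: residues are mapped to (unsigned char) + 2 so the
// two sentinels (codes 1 and 2, with $1 < $2 < every residue) can never
// collide with sequence content.  Each sentinel occurs exactly once, so no
// common prefix between two distinct suffixes ever crosses a sentinel.
static const int SENT1 = 1;
static const int SENT2 = 2;

static std::vector<int> encode_text(const std::string &x, const std::string &y,
                                    int &boundary) {
  std::vector<int> t;
  t.reserve(x.size() + y.size() + 2);
  for (char c : x) t.push_back(static_cast<int>(static_cast<unsigned char>(c)) + 2);
  boundary = static_cast<int>(t.size());
  t.push_back(SENT1);
  for (char c : y) t.push_back(static_cast<int>(static_cast<unsigned char>(c)) + 2);
  t.push_back(SENT2);
  return t;
}

// Suffix array by prefix doubling (O(n log^2 n)); adequate for the pair
// sizes this package targets, and free of external dependencies.
static std::vector<int> build_sa(const std::vector<int> &t) {
  const int n = static_cast<int>(t.size());
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = t[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = (a + len < n) ? rnk[a + len] : -1;
      int rb = (b + len < n) ? rnk[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's algorithm: lcp[r] = |LCP| of suffixes ranked r-1 and r.
static std::vector<int> build_lcp(const std::vector<int> &t,
                                  const std::vector<int> &sa,
                                  std::vector<int> &rank_) {
  const int n = static_cast<int>(t.size());
  rank_.assign(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  std::vector<int> lcp(n, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && t[i + h] == t[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// Sparse table for range-minimum queries over the LCP array.
static std::vector<std::vector<int> > build_sparse(const std::vector<int> &lcp) {
  const int n = static_cast<int>(lcp.size());
  int levels = 1;
  while ((1 << levels) <= n) ++levels;
  std::vector<std::vector<int> > sp(levels, std::vector<int>(n));
  sp[0] = lcp;
  for (int j = 1; j < levels; ++j) {
    int span = 1 << j;
    for (int i = 0; i + span <= n; ++i)
      sp[j][i] = std::min(sp[j - 1][i], sp[j - 1][i + span / 2]);
  }
  return sp;
}

static int rmq_min(const std::vector<std::vector<int> > &sp, int lo, int hi) {
  // min over lcp[lo..hi], inclusive; requires lo <= hi
  int j = 0;
  while ((1 << (j + 1)) <= hi - lo + 1) ++j;
  return std::min(sp[j][lo], sp[j][hi - (1 << j) + 1]);
}

// ---------------------------------------------------------------------------
// Bundled index for one sequence pair: suffix array, LCP, RMQ, and exact
// matching statistics of X against Y (lambda with all tie positions).
// ---------------------------------------------------------------------------

struct PairIndex {
  std::string x, y;
  int nx, ny, boundary, n;
  std::vector<int> text, sa, rank_, lcp;
  std::vector<std::vector<int> > sparse;

  PairIndex(const std::string &xs, const std::string &ys) : x(xs), y(ys) {
    nx = static_cast<int>(x.size());
    ny = static_cast<int>(y.size());
    text = encode_text(x, y, boundary);
    n = static_cast<int>(text.size());
    sa = build_sa(text);
    lcp = build_lcp(text, sa, rank_);
    sparse = build_sparse(lcp);
  }

  bool is_y_suffix(int pos) const {
    return pos > boundary && pos < n - 1;  // skips $1 suffix and the $2 suffix
  }
  int y_pos(int text_pos) const { return text_pos - boundary - 1; }

  int lcp_pair(int a, int b) const {
    if (a == b) return n - a;
    int ra = rank_[a], rb = rank_[b];
    if (ra > rb) std::swap(ra, rb);
    return rmq_min(sparse, ra + 1, rb);
  }
};

struct MatchStats {
  std::vector<int> lambda;              // per X position, exact lambda_0
  std::vector<std::vector<int> > ties;  // all j in Y attaining lambda (ascending)
  double z;                             // mean multiplicity over lambda>0 positions
};

static MatchStats matching_stats(const PairIndex &ix, int anchor_limit) {
  const int n = ix.n;
  MatchStats ms;
  ms.lambda.assign(ix.nx, 0);

  // nearest-Y sweep in rank order, both directions
  std::vector<int> up(n, 0), down(n, 0);
  long cur = -1;
  for (int r = 0; r < n; ++r) {
    if (cur >= 0 && r > 0) cur = std::min(cur, static_cast<long>(ix.lcp[r]));
    if (ix.is_y_suffix(ix.sa[r])) cur = LONG_MAX;
    else if (cur > 0) up[r] = static_cast<int>(cur);
  }
  cur = -1;
  for (int r = n - 1; r >= 0; --r) {
    if (cur >= 0 && r + 1 < n) cur = std::min(cur, static_cast<long>(ix.lcp[r + 1]));
    if (ix.is_y_suffix(ix.sa[r])) cur = LONG_MAX;
    else if (cur > 0) down[r] = static_cast<int>(cur);
  }
  for (int i = 0; i < ix.nx; ++i) {
    int r = ix.rank_[i];
    ms.lambda[i] = std::max(up[r], down[r]);
  }

  // enumerate every Y position attaining lambda(i) (SA-contiguous block)
  ms.ties.assign(ix.nx, std::vector<int>());
  double zsum = 0.0;
  int zcount = 0;
  for (int i = 0; i < ix.nx; ++i) {
    int lam = ms.lambda[i];
    if (lam == 0) continue;
    std::vector<int> &js = ms.ties[i];
    int r = ix.rank_[i];
    long run = LONG_MAX;
    for (int r2 = r; r2 >= 1; --r2) {
      run = std::min(run, static_cast<long>(ix.lcp[r2]));
      if (run < lam) break;
      int p = ix.sa[r2 - 1];
      if (ix.is_y_suffix(p)) js.push_back(ix.y_pos(p));
    }
    run = LONG_MAX;
    for (int r2 = r; r2 + 1 < ix.n; ++r2) {
      run = std::min(run, static_cast<long>(ix.lcp[r2 + 1]));
      if (run < lam) break;
      int p = ix.sa[r2 + 1];
      if (ix.is_y_suffix(p)) js.push_back(ix.y_pos(p));
    }
    std::sort(js.begin(), js.end());
    zsum += static_cast<double>(js.size());
    ++zcount;
    if (anchor_limit > 0 && static_cast<int>(js.size()) > anchor_limit)
      js.resize(anchor_limit);
  }
  ms.z = (zcount > 0) ? zsum / zcount : 0.0;
  return ms;
}

// ---------------------------------------------------------------------------
// Greedy walks on the raw strings.  A k-mismatch LCP computed by walking is
// identical to a chain of k+1 exact LCP queries separated by skipped
// mismatches, so all chain arithmetic below uses walks.
// ---------------------------------------------------------------------------

// length of the maximal <=k-mismatch common prefix of X_i and Y_j (0-based)
static int walk_k(const std::string &x, const std::string &y, int i, int j,
                  int k, long long *counter = nullptr) {
  const int nx = static_cast<int>(x.size()), ny = static_cast<int>(y.size());
  int mis = 0, l = 0;
  while (i + l < nx && j + l < ny) {
    if (counter) ++(*counter);
    if (x[i + l] != y[j + l]) {
      if (mis == k) break;
      ++mis;
    }
    ++l;
  }
  return l;
}

// forward chain: L[m] = <=m-mismatch greedy extension length from (i, j)
static std::vector<int> fchain(const std::string &x, const std::string &y,
                               int i, int j, int k) {
  const int nx = static_cast<int>(x.size()), ny = static_cast<int>(y.size());
  std::vector<int> L(k + 1);
  int off = 0;
  while (i + off < nx && j + off < ny && x[i + off] == y[j + off]) ++off;
  L[0] = off;
  for (int m = 1; m <= k; ++m) {
    if (i + off < nx && j + off < ny) {
      ++off;  // consume the mismatch
      while (i + off < nx && j + off < ny && x[i + off] == y[j + off]) ++off;
    }
    L[m] = off;
  }
  return L;
}

// backward chain: characters strictly before (i, j), walking leftwards
static std::vector<int> bchain(const std::string &x, const std::string &y,
                               int i, int j, int k) {
  std::vector<int> L(k + 1);
  int d = 0;
  while (i - 1 - d >= 0 && j - 1 - d >= 0 && x[i - 1 - d] == y[j - 1 - d]) ++d;
  L[0] = d;
  for (int m = 1; m <= k; ++m) {
    if (i - 1 - d >= 0 && j - 1 - d >= 0) {
      ++d;
      while (i - 1 - d >= 0 && j - 1 - d >= 0 && x[i - 1 - d] == y[j - 1 - d]) ++d;
    }
    L[m] = d;
  }
  return L;
}

// ---------------------------------------------------------------------------
// Exported: index construction and queries
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_index(std::string x, std::string y) {
  PairIndex ix(x, y);
  int levels = static_cast<int>(ix.sparse.size());
  IntegerMatrix sp(levels, ix.n);
  for (int j = 0; j < levels; ++j)
    for (int i = 0; i < ix.n; ++i) sp(j, i) = ix.sparse[j][i];
  return List::create(_["text"] = IntegerVector(ix.text.begin(), ix.text.end()),
                      _["boundary"] = ix.boundary,
                      _["suffix_array"] = IntegerVector(ix.sa.begin(), ix.sa.end()),
                      _["inverse_array"] = IntegerVector(ix.rank_.begin(), ix.rank_.end()),
                      _["lcp_array"] = IntegerVector(ix.lcp.begin(), ix.lcp.end()),
                      _["rmq"] = sp);
}

// a, b: 0-based text positions; policy: 0 = walk, 1 = rmq, 2 = walk with rmq
// fallback past `threshold` characters.  All policies return the same value.
// [[Rcpp::export]]
int cpp_lcp_query(IntegerVector text, IntegerVector inverse_array,
                  IntegerVector lcp_array, IntegerMatrix rmq, int a, int b,
                  int policy, int threshold) {
  const int n = text.size();
  if (a < 0 || b < 0 || a >= n || b >= n) stop("text position out of range");
  if (a == b) return n - a;
  auto by_rmq = [&]() {
    int ra = inverse_array[a], rb = inverse_array[b];
    if (ra > rb) std::swap(ra, rb);
    int lo = ra + 1, hi = rb;
    int j = 0;
    while ((1 << (j + 1)) <= hi - lo + 1) ++j;
    return std::min(rmq(j, lo), rmq(j, hi - (1 << j) + 1));
  };
  if (policy == 1) return by_rmq();
  int l = 0;
  while (a + l < n && b + l < n && text[a + l] == text[b + l]) {
    ++l;
    if (policy == 2 && l > threshold) return by_rmq();
  }
  return l;
}

// [[Rcpp::export]]
List cpp_matching_statistics(std::string x, std::string y, int anchor_limit) {
  PairIndex ix(x, y);
  MatchStats ms = matching_stats(ix, anchor_limit);
  List ties(ix.nx);
  IntegerVector mu(ix.nx);
  for (int i = 0; i < ix.nx; ++i) {
    ties[i] = IntegerVector(ms.ties[i].begin(), ms.ties[i].end());
    mu[i] = ms.ties[i].empty() ? NA_INTEGER : ms.ties[i][0];
  }
  return List::create(_["lambda"] = IntegerVector(ms.lambda.begin(), ms.lambda.end()),
                      _["mu"] = mu, _["match_positions"] = ties, _["z"] = ms.z);
}

// ---------------------------------------------------------------------------
// Exported: exact oracle
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_lcp_k_walk(std::string x, std::string y, int i, int j, int k) {
  if (i < 0 || i >= static_cast<int>(x.size())) stop("position i out of range");
  if (j < 0 || j >= static_cast<int>(y.size())) stop("position j out of range");
  if (k < 0) stop("k must be >= 0");
  return walk_k(x, y, i, j, k);
}

// [[Rcpp::export]]
List cpp_exact_lambda(std::string x, std::string y, int k, double cap) {
  const int nx = static_cast<int>(x.size()), ny = static_cast<int>(y.size());
  long long counter = 0;
  const long long capl = (cap <= 0) ? LLONG_MAX : static_cast<long long>(cap);
  IntegerVector values(nx), witness(nx);
  for (int i = 0; i < nx; ++i) {
    int best = 0, bj = NA_INTEGER;
    for (int j = 0; j < ny; ++j) {
      int l = walk_k(x, y, i, j, k, &counter);
      if (l > best) { best = l; bj = j; }
    }
    if (counter > capl)
      stop("exact oracle cap of %.0f character comparisons exceeded; "
           "use the adyar or kmacs heuristics for inputs of this size",
           static_cast<double>(capl));
    values[i] = best;
    witness[i] = bj;
  }
  return List::create(_["values"] = values, _["witness"] = witness,
                      _["comparisons"] = static_cast<double>(counter));
}

// ---------------------------------------------------------------------------
// Exported: chains and heuristics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_forward_chain(std::string x, std::string y, int i, int j, int k) {
  std::vector<int> L = fchain(x, y, i, j, k);
  return IntegerVector(L.begin(), L.end());
}

// [[Rcpp::export]]
IntegerVector cpp_backward_chain(std::string x, std::string y, int i, int j, int k) {
  std::vector<int> L = bchain(x, y, i, j, k);
  return IntegerVector(L.begin(), L.end());
}

// kmacs greedy: anchor at each exact-LCP match position, forward chain only.
// [[Rcpp::export]]
List cpp_kmacs(std::string x, std::string y, int k, bool ties_all,
               int anchor_limit, bool fallback) {
  PairIndex ix(x, y);
  MatchStats ms = matching_stats(ix, anchor_limit);
  const int nx = ix.nx;
  IntegerVector values(nx, 0), witness(nx, NA_INTEGER);
  for (int i = 0; i < nx; ++i) {
    if (ms.lambda[i] == 0) continue;
    int best = -1, bj = NA_INTEGER;
    size_t limit = ties_all ? ms.ties[i].size() : 1;
    for (size_t a = 0; a < limit; ++a) {
      int j = ms.ties[i][a];
      std::vector<int> L = fchain(x, y, i, j, k);
      if (L[k] > best) { best = L[k]; bj = j; }
    }
    values[i] = best;
    witness[i] = bj;
  }
  if (fallback) {
    for (int i = nx - 2; i >= 0; --i)
      if (ms.lambda[i] == 0) { values[i] = values[i + 1]; witness[i] = NA_INTEGER; }
  }
  return List::create(_["values"] = values, _["witness"] = witness, _["z"] = ms.z);
}

// Two-phase forward/backward extension heuristic.
// Phase 1: every maximal exact anchor (i, j) is extended forward and
// backward with mismatch budgets t + (k - t) = k; the candidate of length
// L_r[t] + L_f[k-t] is credited to start position i - L_r[t].
// Phase 2: left-to-right pass values[i] = max(values[i], values[i-1] - 1)
// (optionally guarded on the dropped character not being a mismatch).
// Fallback: right-to-left copy over positions whose exact anchor LCP is 0.
// [[Rcpp::export]]
List cpp_adyar(std::string x, std::string y, int k, bool ties_all,
               int anchor_limit, bool fallback, bool guard, bool run_phase2) {
  PairIndex ix(x, y);
  MatchStats ms = matching_stats(ix, anchor_limit);
  const int nx = ix.nx, ny = ix.ny;
  IntegerVector values(nx, 0), witness(nx, NA_INTEGER);
  for (int i = 0; i < nx; ++i) {
    if (ms.lambda[i] == 0) continue;
    size_t limit = ties_all ? ms.ties[i].size() : 1;
    for (size_t a = 0; a < limit; ++a) {
      int j = ms.ties[i][a];
      std::vector<int> Lf = fchain(x, y, i, j, k);
      std::vector<int> Lr = bchain(x, y, i, j, k);
      for (int t = 0; t <= k; ++t) {
        int s = i - Lr[t];
        int cand = Lr[t] + Lf[k - t];
        if (cand > values[s]) { values[s] = cand; witness[s] = j - Lr[t]; }
      }
    }
  }
  if (run_phase2) {
    for (int i = 1; i < nx; ++i) {
      if (guard) {
        // skip when position i is one of the mismatch characters of the
        // preceding entry's match
        int w = witness[i - 1];
        if (w == NA_INTEGER || w + 1 >= ny || x[i] != y[w + 1]) continue;
      }
      if (values[i - 1] - 1 > values[i]) {
        values[i] = values[i - 1] - 1;
        witness[i] = (witness[i - 1] == NA_INTEGER) ? NA_INTEGER : witness[i - 1] + 1;
      }
    }
  }
  if (fallback) {
    for (int i = nx - 2; i >= 0; --i)
      if (ms.lambda[i] == 0) { values[i] = values[i + 1]; witness[i] = NA_INTEGER; }
  }
  return List::create(_["values"] = values, _["witness"] = witness, _["z"] = ms.z);
}

// ALFRED-G: 1-mismatch anchor (from the exact oracle) plus a (k-2)-budget
// greedy forward extension after one skipped mismatch.
// [[Rcpp::export]]
List cpp_alfredg(std::string x, std::string y, int k, double cap) {
  if (k < 2) stop("ALFRED-G requires k >= 2");
  const int nx = static_cast<int>(x.size()), ny = static_cast<int>(y.size());
  List l1 = cpp_exact_lambda(x, y, 1, cap);
  IntegerVector lam1 = l1["values"], mu1 = l1["witness"];
  IntegerVector values(nx), witness(nx);
  for (int i = 0; i < nx; ++i) {
    int L = lam1[i];
    int j = mu1[i];
    if (j == NA_INTEGER) { values[i] = 0; witness[i] = NA_INTEGER; continue; }
    int v = L;
    if (i + L < nx && j + L < ny) {
      v = L + 1;
      if (i + L + 1 < nx && j + L + 1 < ny)
        v += walk_k(x, y, i + L + 1, j + L + 1, k - 2);
    }
    values[i] = v;
    witness[i] = j;
  }
  return List::create(_["values"] = values, _["witness"] = witness);
}
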