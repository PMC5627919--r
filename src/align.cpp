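#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh recurrences.
// Scoring fixed package-wide: match +1, mismatch -1, first gap base -2,
// each further gap base -1. Identity is computed over aligned columns after
// stripping terminal gap columns, so it is alphabet-agnostic (used for both
// nucleotide and amino-acid sequences; characters compare by exact equality).

static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP_OPEN = -2;   // cost of the first base of a gap
static const int GAP_EXT = -1;

static const int NEG = std::numeric_limits<int>::min() / 4;

struct Aln {
  int score;
  std::string a_aln;
  std::string b_aln;
};

static Aln gotoh(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  Aln out;
  if (n == 0 && m == 0) { out.score = 0; return out; }
  if (n == 0) {
    out.score = GAP_OPEN + (m - 1) * GAP_EXT;
    out.a_aln.assign(m, '-'); out.b_aln = b; return out;
  }
  if (m == 0) {
    out.score = GAP_OPEN + (n - 1) * GAP_EXT;
    out.a_aln = a; out.b_aln.assign(n, '-'); return out;
  }

  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<int> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // traceback pointers: which state the cell came from (0=M, 1=X, 2=Y)
  std::vector<signed char> tM(sz, -1), tX(sz, -1), tY(sz, -1);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  M[idx(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = GAP_OPEN + (i - 1) * GAP_EXT;
    tX[idx(i, 0)] = (signed char)(i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = GAP_OPEN + (j - 1) * GAP_EXT;
    tY[idx(0, j)] = (signed char)(j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = idx(i, j), d = idx(i - 1, j - 1),
                   u = idx(i - 1, j), l = idx(i, j - 1);
      const int s = (ai == b[j - 1]) ? MATCH : MISMATCH;
      // M: diagonal from the best of the three states (prefer M on ties)
      int best = M[d]; signed char st = 0;
      if (X[d] > best) { best = X[d]; st = 1; }
      if (Y[d] > best) { best = Y[d]; st = 2; }
      if (best > NEG) { M[c] = best + s; tM[c] = st; }
      // X: gap in b (consume a); open from M or extend X
      int xo = (M[u] > NEG) ? M[u] + GAP_OPEN : NEG;
      int xe = (X[u] > NEG) ? X[u] + GAP_EXT : NEG;
      if (xo >= xe) { X[c] = xo; tX[c] = 0; } else { X[c] = xe; tX[c] = 1; }
      // Y: gap in a (consume b); open from M or extend Y
      int yo = (M[l] > NEG) ? M[l] + GAP_OPEN : NEG;
      int ye = (Y[l] > NEG) ? Y[l] + GAP_EXT : NEG;
      if (yo >= ye) { Y[c] = yo; tY[c] = 0; } else { Y[c] = ye; tY[c] = 2; }
    }
  }

  const size_t e = idx(n, m);
  int state = 0, score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      int prev = tY[idx(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  out.score = score; out.a_aln = ra; out.b_aln = rb;
  return out;
}

// matches / columns over the alignment with terminal gap columns stripped
static void aln_stats(const Aln &al, int &matches, int &columns) {
  const std::string &x = al.a_aln, &y = al.b_aln;
  int L = (int)x.size();
  int lo = 0, hi = L - 1;
  while (lo <= hi && (x[lo] == '-' || y[lo] == '-')) ++lo;
  while (hi >= lo && (x[hi] == '-' || y[hi] == '-')) --hi;
  matches = 0; columns = 0;
  for (int k = lo; k <= hi; ++k) {
    ++columns;
    if (x[k] == y[k]) ++matches;
  }
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, bool keep_alignment = false) {
  Aln al = gotoh(a, b);
  int matches, columns;
  aln_stats(al, matches, columns);
  double ident = columns > 0 ? 100.0 * matches / columns : 0.0;
  List out = List::create(
    _["score"] = al.score, _["matches"] = matches,
    _["columns"] = columns, _["identity"] = ident);
  if (keep_alignment) {
    out["a_aln"] = al.a_aln;
    out["b_aln"] = al.b_aln;
  }
  return out;
}

// [[Rcpp::export(name = ".nw_batch_cpp")]]
NumericMatrix nw_batch_cpp(CharacterVector a, std::string b) {
  const int n = a.size();
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("identity", "matches", "columns", "score");
  for (int k = 0; k < n; ++k) {
    Aln al = gotoh(as<std::string>(a[k]), b);
    int matches, columns;
    aln_stats(al, matches, columns);
    out(k, 0) = columns > 0 ? 100.0 * matches / columns : 0.0;
    out(k, 1) = matches; out(k, 2) = columns; out(k, 3) = al.score;
  }
  return out;
}

// Per-position match profile of `parent` against `query`, in query
// coordinates: profile[i] = 1 iff query base i is aligned to an identical
// parent base. Used by the chimera detector for unequal-length pairs.
// [[Rcpp::export(name = ".nw_profile_cpp")]]
IntegerVector nw_profile_cpp(std::string query, std::string parent) {
  Aln al = gotoh(query, parent);
  IntegerVector prof((int)query.size());
  int qi = 0;
  for (size_t k = 0; k < al.a_aln.size(); ++k) {
    if (al.a_aln[k] != '-') {
      prof[qi] = (al.a_aln[k] == al.b_aln[k]) ? 1 : 0;
      ++qi;
    }
  }
  return prof;
}

// Ungapped (Hamming) identity for equal-length sequences: the identity of
// the gap-free alignment, which is the score-optimal global alignment
// whenever the two sequences are highly similar. Used as a fast accept
// path before the full DP.
// [[Rcpp::export(name = ".hamming_identity_cpp")]]
double hamming_identity_cpp(std::string a, std::string b) {
  if (a.size() != b.size() || a.empty()) return -1.0;
  size_t match = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] == b[i]) ++match;
  return 100.0 * match / a.size();
}

// Equal-length two-parent chimera scan: for each query, the best single
// parent match count, the best constrained single-crossover two-parent
// match count with its (1-based) parent pair, and the midpoint of the
// optimal crossover plateau. Caller guarantees all strings share one length.
// [[Rcpp::export(name = ".chimera_scan_cpp")]]
NumericMatrix chimera_scan_cpp(CharacterVector queries, CharacterVector parents,
                               int min_segment) {
  const int nq = queries.size(), np = parents.size();
  std::vector<std::string> ps(np);
  for (int p = 0; p < np; ++p) ps[p] = as<std::string>(parents[p]);
  const int L = (int)ps[0].size();
  NumericMatrix out(nq, 5);
  colnames(out) = CharacterVector::create("single", "two", "parent_a",
                                          "parent_b", "crossover");
  std::vector<std::vector<int> > cum(np, std::vector<int>(L + 1, 0));
  for (int qi = 0; qi < nq; ++qi) {
    const std::string q = as<std::string>(queries[qi]);
    int single = 0;
    for (int p = 0; p < np; ++p) {
      const std::string &pp = ps[p];
      int acc = 0;
      for (int i = 0; i < L; ++i) {
        acc += (q[i] == pp[i]);
        cum[p][i + 1] = acc;
      }
      if (acc > single) single = acc;
    }
    int best = -1, ba = -1, bb = -1, klo = 0, khi = 0;
    for (int a = 0; a < np; ++a) {
      for (int b = 0; b < np; ++b) {
        if (a == b) continue;
        const int totb = cum[b][L];
        for (int k = 0; k <= L; ++k) {
          const int ca = cum[a][k], sb = totb - cum[b][k];
          if (ca < min_segment || sb < min_segment) continue;
          const int v = ca + sb;
          if (v > best) { best = v; ba = a; bb = b; klo = khi = k; }
          else if (v == best && a == ba && b == bb) khi = k;
        }
      }
    }
    out(qi, 0) = single;
    out(qi, 1) = best;
    out(qi, 2) = ba + 1;
    out(qi, 3) = bb + 1;
    out(qi, 4) = best >= 0 ? std::floor((klo + khi) / 2.0 + 0.5) : NA_REAL;
  }
  return out;
}
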