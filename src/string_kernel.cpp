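#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// 'N' (or any non-ACGT character) never matches anything, itself included.
static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static int levenshtein(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Hamming distance with the N rule: positions where base_match fails.
static int hamming(const std::string &a, const std::string &b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (!base_match(a[i], b[i])) ++d;
  return d;
}

// Hamming with early exit once the budget is blown (for scanning).
static int hamming_capped(const char *a, const char *b, int L, int cap) {
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (!base_match(a[i], b[i]) && ++d > cap) return d;
  }
  return d;
}

static char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// [[Rcpp::export(name = ".lev_cpp")]]
IntegerVector lev_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = levenshtein(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// [[Rcpp::export(name = ".hamming_cpp")]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    if (sa.size() != sb.size())
      stop("hamming_distance: unequal lengths at pair %d (%d vs %d)",
           (int)(i + 1), (int)sa.size(), (int)sb.size());
    out[i] = hamming(sa, sb);
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// Pairwise Levenshtein matrix; symmetric fast path when X is Y.
// [[Rcpp::export(name = ".edit_matrix_cpp")]]
IntegerMatrix edit_matrix_cpp(CharacterVector X, CharacterVector Y,
                              bool symmetric) {
  R_xlen_t n = X.size(), m = Y.size();
  std::vector<std::string> xs(n), ys(m);
  for (R_xlen_t i = 0; i < n; ++i) xs[i] = as<std::string>(X[i]);
  for (R_xlen_t j = 0; j < m; ++j) ys[j] = as<std::string>(Y[j]);
  IntegerMatrix out(n, m);
  if (symmetric) {
    for (R_xlen_t i = 0; i < n; ++i) {
      for (R_xlen_t j = i + 1; j < m; ++j) {
        int d = levenshtein(xs[i], ys[j]);
        out(i, j) = d;
        out(j, i) = d;
      }
      Rcpp::checkUserInterrupt();
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      for (R_xlen_t j = 0; j < m; ++j)
        out(i, j) = levenshtein(xs[i], ys[j]);
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}

// [[Rcpp::export(name = ".hamming_matrix_cpp")]]
IntegerMatrix hamming_matrix_cpp(CharacterVector X, CharacterVector Y,
                                 bool symmetric) {
  R_xlen_t n = X.size(), m = Y.size();
  std::vector<std::string> xs(n), ys(m);
  for (R_xlen_t i = 0; i < n; ++i) xs[i] = as<std::string>(X[i]);
  for (R_xlen_t j = 0; j < m; ++j) ys[j] = as<std::string>(Y[j]);
  IntegerMatrix out(n, m);
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t j0 = symmetric ? i + 1 : 0;
    for (R_xlen_t j = j0; j < m; ++j) {
      if (xs[i].size() != ys[j].size())
        stop("hamming matrix: unequal lengths");
      int d = hamming(xs[i], ys[j]);
      out(i, j) = d;
      if (symmetric) out(j, i) = d;
    }
  }
  return out;
}

// Greedy clustering in input order: a sequence joins the first
// representative with identity (= matching positions / length, N never
// matches, best orientation when both_strands) strictly above the
// threshold, else founds a new cluster. Returns 1-based index of each
// sequence's representative in the input vector.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold,
                                 bool both_strands) {
  R_xlen_t n = seqs.size();
  IntegerVector rep(n);
  if (n == 0) return rep;
  std::vector<std::string> fwd(n), rc(n);
  size_t L = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    if (i == 0) L = fwd[i].size();
    else if (fwd[i].size() != L) stop("redundancy_filter: mixed lengths");
    if (both_strands) rc[i] = revcomp(fwd[i]);
  }
  std::vector<int> reps;  // 0-based indices of representatives
  for (R_xlen_t i = 0; i < n; ++i) {
    int assigned = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      const std::string &s = fwd[reps[r]];
      double ident = (double)(L - hamming(fwd[i], s)) / (double)L;
      if (both_strands) {
        double ident_rc = (double)(L - hamming(rc[i], s)) / (double)L;
        if (ident_rc > ident) ident = ident_rc;
      }
      if (ident > threshold) { assigned = reps[r]; break; }
    }
    if (assigned < 0) { reps.push_back((int)i); assigned = (int)i; }
    rep[i] = assigned + 1;
  }
  return rep;
}

// For each member of A, is there any member of B with identity > threshold?
// [[Rcpp::export(name = ".cross_similar_cpp")]]
LogicalVector cross_similar_cpp(CharacterVector A, CharacterVector B,
                                double threshold, bool both_strands) {
  R_xlen_t n = A.size(), m = B.size();
  LogicalVector out(n);
  std::vector<std::string> bs(m);
  size_t L = 0;
  for (R_xlen_t j = 0; j < m; ++j) {
    bs[j] = as<std::string>(B[j]);
    if (j == 0) L = bs[j].size();
    else if (bs[j].size() != L) stop("cross_set_similarity: mixed lengths");
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(A[i]);
    if (m > 0 && a.size() != L) stop("cross_set_similarity: mixed lengths");
    std::string arc = both_strands ? revcomp(a) : std::string();
    bool hit = false;
    for (R_xlen_t j = 0; j < m && !hit; ++j) {
      double ident = (double)(L - hamming(a, bs[j])) / (double)L;
      if (both_strands) {
        double irc = (double)(L - hamming(arc, bs[j])) / (double)L;
        if (irc > ident) ident = irc;
      }
      hit = ident > threshold;
    }
    out[i] = hit;
  }
  return out;
}

// Enumerate adenine-centered candidate windows: every forward 'A' yields a
// '+' candidate, every forward 'T' a '-' candidate (context is the reverse
// complement). Windows clipped by the contig edge are skipped and counted.
// [[Rcpp::export(name = ".enumerate_candidates_cpp")]]
List enumerate_candidates_cpp(std::string seq, int L1) {
  int flank = (L1 - 1) / 2;
  int n = (int)seq.size();
  std::vector<int> pos;
  std::vector<int> strand;  // 1 = '+', -1 = '-'
  std::vector<std::string> ctx;
  int skipped = 0;
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'T') continue;
    if (i - flank < 0 || i + flank >= n) { ++skipped; continue; }
    std::string w = seq.substr(i - flank, L1);
    if (c == 'A') {
      pos.push_back(i + 1); strand.push_back(1); ctx.push_back(w);
    } else {
      pos.push_back(i + 1); strand.push_back(-1); ctx.push_back(revcomp(w));
    }
  }
  return List::create(_["pos"] = wrap(pos), _["strand"] = wrap(strand),
                      _["context"] = wrap(ctx), _["skipped"] = skipped);
}

// Mismatch-tolerant seed scan over one contig. Seeds are adenine-centered
// L-mers. A forward window w matches seed s on '+' when the center of w is
// 'A' and hamming(flanks) <= max_mm; on '-' when the center is 'T' and
// revcomp(w) is within budget of s (equivalently w vs revcomp(s)).
// Overlapping hits at one (pos, strand) are merged keeping the
// lowest-mismatch seed (ties -> first seed in input order).
// [[Rcpp::export(name = ".seed_scan_cpp")]]
List seed_scan_cpp(std::string seq, CharacterVector seeds, int max_mm) {
  R_xlen_t k = seeds.size();
  if (k == 0)
    return List::create(_["pos"] = IntegerVector(0),
                        _["strand"] = IntegerVector(0),
                        _["seed_id"] = IntegerVector(0),
                        _["mismatches"] = IntegerVector(0));
  std::vector<std::string> fwd(k), rc(k);
  size_t L = as<std::string>(seeds[0]).size();
  for (R_xlen_t j = 0; j < k; ++j) {
    fwd[j] = as<std::string>(seeds[j]);
    if (fwd[j].size() != L) stop("seed_match: seeds of unequal length");
    rc[j] = revcomp(fwd[j]);
  }
  int Li = (int)L, flank = (Li - 1) / 2, n = (int)seq.size();
  // Exact-match fast path: hash the seeds (and their reverse complements).
  std::unordered_map<std::string, int> exact_fwd, exact_rc;
  if (max_mm == 0) {
    for (R_xlen_t j = (R_xlen_t)k - 1; j >= 0; --j) {
      exact_fwd[fwd[j]] = (int)j;
      exact_rc[rc[j]] = (int)j;
    }
  }
  std::vector<int> pos, strand, seed_id, mism;
  for (int i = flank; i + flank < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'T') continue;
    const char *w = seq.c_str() + (i - flank);
    int best = max_mm + 1, best_seed = -1;
    if (max_mm == 0) {
      std::string ws(w, L);
      const std::unordered_map<std::string, int> &idx =
        (c == 'A') ? exact_fwd : exact_rc;
      std::unordered_map<std::string, int>::const_iterator it = idx.find(ws);
      if (it != idx.end()) { best = 0; best_seed = it->second; }
    } else {
      const std::vector<std::string> &bank = (c == 'A') ? fwd : rc;
      for (R_xlen_t j = 0; j < k; ++j) {
        int d = hamming_capped(w, bank[j].c_str(), Li, best - 1);
        if (d < best) { best = d; best_seed = (int)j; }
        if (best == 0) break;
      }
    }
    if (best_seed >= 0 && best <= max_mm) {
      pos.push_back(i + 1);
      strand.push_back(c == 'A' ? 1 : -1);
      seed_id.push_back(best_seed + 1);
      mism.push_back(best);
    }
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["pos"] = wrap(pos), _["strand"] = wrap(strand),
                      _["seed_id"] = wrap(seed_id),
                      _["mismatches"] = wrap(mism));
}
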