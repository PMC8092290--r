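// Ungapped alignment kernels: local protospacer search, best-offset
// identity, and greedy identity clustering. Coordinates are 0-based
// half-open on the forward genome strand; callers convert to R's 1-based
// views at the boundary.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

// N never matches anything, including another N (conservative handling of
// ambiguous bases).
static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

// vectorised reverse complement with full IUPAC support
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  auto comp = [](char c) -> char {
    switch (c) {
      case 'A': return 'T'; case 'C': return 'G';
      case 'G': return 'C'; case 'T': return 'A';
      case 'U': return 'A';
      case 'R': return 'Y'; case 'Y': return 'R';
      case 'S': return 'S'; case 'W': return 'W';
      case 'K': return 'M'; case 'M': return 'K';
      case 'B': return 'V'; case 'V': return 'B';
      case 'D': return 'H'; case 'H': return 'D';
      case 'N': return 'N';
      case 'a': return 't'; case 'c': return 'g';
      case 'g': return 'c'; case 't': return 'a';
      default: return 'N';
    }
  };
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp(c);
    out[i] = r;
  }
  return out;
}

struct LocalHit {
  double score = R_NegInf;
  int mismatches = 0;
  int start = 0;   // genome, 0-based
  int end = 0;     // half-open
  int strand = 0;  // 0 = '+', 1 = '-'
  bool found = false;
};

// true if a is strictly better under (score desc, mismatches asc,
// start asc, '+' before '-')
static inline bool better(const LocalHit& a, const LocalHit& b) {
  if (!b.found) return a.found;
  if (a.score != b.score) return a.score > b.score;
  if (a.mismatches != b.mismatches) return a.mismatches < b.mismatches;
  if (a.start != b.start) return a.start < b.start;
  return a.strand < b.strand;
}

// Best soft-clipped ungapped alignment of `pat` on one genome strand.
// For every diagonal d (genome coordinate of pattern index 0) a Kadane
// scan finds the maximum-score contiguous sub-span; the reset condition
// (running score <= 0) also drops zero-score prefixes so that among
// equal-score windows ending at a given position the one with fewest
// mismatches is kept, matching the declared tie-break order.
static void scan_strand(const std::string& pat, const std::string& g,
                        double match, double mismatch, int strand,
                        LocalHit& best) {
  const int L = (int)pat.size(), G = (int)g.size();
  for (int d = -(L - 1); d < G; ++d) {
    int i0 = std::max(0, -d);
    int i1 = std::min(L - 1, G - 1 - d);
    double cur = 0.0;
    int cur_start = i0, cur_mm = 0;
    for (int i = i0; i <= i1; ++i) {
      bool m = base_match(pat[(size_t)i], g[(size_t)(d + i)]);
      cur += m ? match : -mismatch;
      if (!m) ++cur_mm;
      if (cur <= 0.0) {
        cur = 0.0;
        cur_start = i + 1;
        cur_mm = 0;
      } else {
        LocalHit cand;
        cand.score = cur;
        cand.mismatches = cur_mm;
        cand.start = d + cur_start;
        cand.end = d + i + 1;
        cand.strand = strand;
        cand.found = true;
        if (better(cand, best)) best = cand;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_best_local_hit(std::string spacer, std::string genome,
                        double match, double mismatch) {
  LocalHit best;
  scan_strand(spacer, genome, match, mismatch, 0, best);
  std::string rc = revcomp(spacer);
  scan_strand(rc, genome, match, mismatch, 1, best);
  return List::create(
      _["found"] = best.found, _["score"] = best.score,
      _["start"] = best.start, _["end"] = best.end,
      _["strand"] = best.strand == 0 ? "+" : "-",
      _["mismatches"] = best.mismatches);
}

// Best-offset ungapped identity: matches in the best overlap over all
// relative offsets, divided by the shorter sequence length.
// [[Rcpp::export]]
double cpp_identity(std::string a, std::string b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) stop("sequences must be non-empty");
  int best = 0;
  for (int s = -(la - 1); s < lb; ++s) {
    int i0 = std::max(0, -s), i1 = std::min(la - 1, lb - 1 - s);
    int m = 0;
    for (int i = i0; i <= i1; ++i)
      if (base_match(a[(size_t)i], b[(size_t)(i + s)])) ++m;
    if (m > best) best = m;
  }
  return (double)best / (double)std::min(la, lb);
}

// Does identity(a, b) reach `thr`? Only offsets whose overlap can still
// deliver the required match count are scanned, with early bailout once
// the remaining bases cannot recover the deficit.
static bool identity_ge(const std::string& a, const std::string& b,
                        double thr) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int shorter = std::min(la, lb);
  const int req = (int)std::ceil(thr * shorter - 1e-9);
  if (req <= 0) return true;
  for (int s = -(la - 1); s < lb; ++s) {
    int i0 = std::max(0, -s), i1 = std::min(la - 1, lb - 1 - s);
    int overlap = i1 - i0 + 1;
    if (overlap < req) continue;
    int allowed_mm = overlap - req;
    int m = 0, mm = 0;
    for (int i = i0; i <= i1; ++i) {
      if (base_match(a[(size_t)i], b[(size_t)(i + s)])) ++m;
      else if (++mm > allowed_mm) break;
    }
    if (m >= req) return true;
  }
  return false;
}

// 2-bit word codes for exact k-mers (words containing N are skipped),
// sorted for O(n) intersection.
static std::vector<uint64_t> word_codes(const std::string& s, int w) {
  std::vector<uint64_t> out;
  const int n = (int)s.size();
  for (int i = 0; i + w <= n; ++i) {
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int v;
      switch (s[(size_t)(i + j)]) {
        case 'A': v = 0; break;
        case 'C': v = 1; break;
        case 'G': v = 2; break;
        case 'T': v = 3; break;
        default: v = -1;
      }
      if (v < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)v;
    }
    if (ok) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static bool share_word(const std::vector<uint64_t>& a,
                       const std::vector<uint64_t>& b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return true;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return false;
}

// Greedy CD-HIT-style clustering. `seqs` must already be in the
// deterministic processing order; each sequence joins the first existing
// representative sharing >= 1 word of `word_size` with identity >= `thr`,
// else founds a cluster. Returns the 1-based index (into `seqs`) of each
// sequence's representative.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double thr,
                                 int word_size) {
  const int n = seqs.size();
  IntegerVector rep(n);
  std::vector<std::string> ss(n);
  std::vector<std::vector<uint64_t>> words(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    words[i] = word_codes(ss[i], word_size);
  }
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    int assigned = 0;
    for (int r : reps) {
      if (share_word(words[i], words[r]) && identity_ge(ss[i], ss[r], thr)) {
        assigned = r + 1;
        break;
      }
    }
    if (assigned == 0) {
      reps.push_back(i);
      assigned = i + 1;
    }
    rep[i] = assigned;
  }
  return rep;
}

// For each query, 1-based index of the first reference reaching identity
// `thr`, or NA. Drives cross-pool matching and the Monte-Carlo overlap
// null, so it is the hot path.
// [[Rcpp::export]]
IntegerVector cpp_cross_match(CharacterVector query, CharacterVector ref,
                              double thr) {
  const int nq = query.size(), nr = ref.size();
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(ref[j]);
  IntegerVector out(nq, NA_INTEGER);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(query[i]);
    for (int j = 0; j < nr; ++j) {
      if (identity_ge(q, rs[j], thr)) {
        out[i] = j + 1;
        break;
      }
    }
  }
  return out;
}
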