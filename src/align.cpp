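#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Approximate occurrence search (semi-global edit-distance DP).
//
// Finds all occurrences of `pattern` in `text` with edit distance <= max_edits
// (unit-cost substitutions and indels).  Qualifying end positions form runs
// (an exact match also qualifies at +/-1 with one edit); each maximal run is
// collapsed to its best (lowest-distance, then leftmost) end, and the start is
// recovered by traceback.  Coordinates are 0-based half-open.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_approx_find(std::string text, std::string pattern, int max_edits) {
  const int n = (int) text.size();
  const int m = (int) pattern.size();
  std::vector<int> starts, ends, dists;
  if (n == 0 || m == 0) {
    return DataFrame::create(_["start"] = starts, _["end"] = ends,
                             _["edits"] = dists);
  }
  // full DP matrix (m small: a primer), row-major (m+1) x (n+1)
  std::vector<int> D((size_t)(m + 1) * (n + 1));
  for (int i = 0; i <= m; ++i) D[(size_t)i * (n + 1)] = i;
  for (int j = 0; j <= n; ++j) D[j] = 0;           // free start in text
  for (int i = 1; i <= m; ++i) {
    const char pc = pattern[i - 1];
    size_t row = (size_t)i * (n + 1), prow = (size_t)(i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int sub = D[prow + j - 1] + (text[j - 1] == pc ? 0 : 1);
      int del = D[prow + j] + 1;      // consume pattern char
      int ins = D[row + j - 1] + 1;   // consume text char
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      D[row + j] = v;
    }
  }
  const size_t last = (size_t)m * (n + 1);
  int j = 1;
  while (j <= n) {
    if (D[last + j] > max_edits) { ++j; continue; }
    int runEnd = j, best = j;
    while (runEnd + 1 <= n && D[last + runEnd + 1] <= max_edits) {
      ++runEnd;
      if (D[last + runEnd] < D[last + best]) best = runEnd;
    }
    // traceback from (m, best) to row 0 to get the start
    int ii = m, jj = best;
    while (ii > 0) {
      int cur = D[(size_t)ii * (n + 1) + jj];
      if (jj > 0 &&
          D[(size_t)(ii - 1) * (n + 1) + jj - 1] +
              (text[jj - 1] == pattern[ii - 1] ? 0 : 1) == cur) {
        --ii; --jj;
      } else if (D[(size_t)(ii - 1) * (n + 1) + jj] + 1 == cur) {
        --ii;
      } else {
        --jj;
      }
    }
    starts.push_back(jj);
    ends.push_back(best);
    dists.push_back(D[last + best]);
    j = runEnd + 1;
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["edits"] = dists);
}

// ---------------------------------------------------------------------------
// Banded global alignment with affine gap costs (Gotoh), returning a
// run-length CIGAR over ops {=, X, I, D}.  I = base present in query but not
// target; D = target base missing from query.  Affine costs (match 0,
// mismatch 4, gap open 4, gap extend 1) keep each indel tract contiguous and
// favour gap over mismatch-run representations inside tandem repeats, so
// one mutational event maps to one CIGAR run.  The band covers diagonals
// (j - i) in [min(0, n-m) - pad, max(0, n-m) + pad].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_banded_global(std::string q, std::string t, int pad) {
  const int m = (int) q.size();   // query rows
  const int n = (int) t.size();   // target cols
  const int lo = std::min(0, n - m) - pad;
  const int hi = std::max(0, n - m) + pad;
  const int w = hi - lo + 1;
  const int INF = 1 << 28;
  const int MIS = 4, OPEN = 4, EXT = 1;
  // states: 0 = M (diagonal), 1 = D (target gap run), 2 = I (query gap run)
  std::vector<int> M((size_t)(m + 1) * w, INF), Dm = M, Im = M;
  std::vector<unsigned char> tb((size_t)(m + 1) * w, 0xFF);
  // tb packs predecessor state per state: bits 0-1 for M, 2-3 for D, 4-5 for I
  auto idx = [&](int i, int d) { return (size_t)i * w + (d - lo); };
  if (0 >= lo && 0 <= hi) M[idx(0, 0)] = 0;
  for (int jj = 1; jj <= n; ++jj) {
    int d = jj;                       // i = 0
    if (d < lo || d > hi) break;
    Dm[idx(0, d)] = OPEN + jj * EXT;
    tb[idx(0, d)] &= (unsigned char) ~(3 << 2);
    tb[idx(0, d)] |= (unsigned char) ((jj == 1 ? 0 : 1) << 2);
  }
  for (int i = 1; i <= m; ++i) {
    const char qc = q[i - 1];
    int jlo = std::max(0, i + lo), jhi = std::min(n, i + hi);
    for (int jj = jlo; jj <= jhi; ++jj) {
      int d = jj - i;
      size_t here = idx(i, d);
      unsigned char trace = 0;
      // M: from (i-1, jj-1), same diagonal index
      int bm = INF; int pm = 0;
      if (jj > 0) {
        size_t prev = idx(i - 1, d);
        int vm = M[prev], vd = Dm[prev], vi = Im[prev];
        bm = vm; pm = 0;
        if (vd < bm) { bm = vd; pm = 1; }
        if (vi < bm) { bm = vi; pm = 2; }
        if (bm < INF) bm += (t[jj - 1] == qc ? 0 : MIS);
      }
      M[here] = bm; trace |= (unsigned char) pm;
      // D: from (i, jj-1) = diagonal d-1
      int bd = INF; int pd = 0;
      if (jj > 0 && d - 1 >= lo) {
        size_t prev = idx(i, d - 1);
        int vm = (M[prev] < INF) ? M[prev] + OPEN + EXT : INF;
        int vd = (Dm[prev] < INF) ? Dm[prev] + EXT : INF;
        int vi = (Im[prev] < INF) ? Im[prev] + OPEN + EXT : INF;
        bd = vm; pd = 0;
        if (vd < bd) { bd = vd; pd = 1; }
        if (vi < bd) { bd = vi; pd = 2; }
      }
      Dm[here] = bd; trace |= (unsigned char) (pd << 2);
      // I: from (i-1, jj) = diagonal d+1
      int bi = INF; int pi = 0;
      if (d + 1 <= hi) {
        size_t prev = idx(i - 1, d + 1);
        int vm = (M[prev] < INF) ? M[prev] + OPEN + EXT : INF;
        int vd = (Dm[prev] < INF) ? Dm[prev] + OPEN + EXT : INF;
        int vi = (Im[prev] < INF) ? Im[prev] + EXT : INF;
        bi = vm; pi = 0;
        if (vd < bi) { bi = vd; pi = 1; }
        if (vi < bi) { bi = vi; pi = 2; }
      }
      Im[here] = bi; trace |= (unsigned char) (pi << 4);
      tb[here] = trace;
    }
  }
  if (n - m < lo || n - m > hi) return List::create(_["ok"] = false);
  size_t endc = idx(m, n - m);
  int state = 0, best = M[endc];
  if (Dm[endc] < best) { best = Dm[endc]; state = 1; }
  if (Im[endc] < best) { best = Im[endc]; state = 2; }
  if (best >= INF) return List::create(_["ok"] = false);
  // traceback (collects ops back-to-front)
  std::vector<char> ops; std::vector<int> lens;
  auto push = [&](char op) {
    if (!ops.empty() && ops.back() == op) { ++lens.back(); }
    else { ops.push_back(op); lens.push_back(1); }
  };
  int i = m, jj = n;
  int nmatch = 0, nmis = 0, ins_len = 0, del_len = 0;
  while (i > 0 || jj > 0) {
    unsigned char trace = tb[idx(i, jj - i)];
    if (state == 0) {
      bool eq = (t[jj - 1] == q[i - 1]);
      push(eq ? '=' : 'X');
      if (eq) ++nmatch; else ++nmis;
      state = trace & 3; --i; --jj;
    } else if (state == 1) {
      push('D'); ++del_len;
      state = (trace >> 2) & 3; --jj;
    } else {
      push('I'); ++ins_len;
      state = (trace >> 4) & 3; --i;
    }
  }
  std::string cigar;
  int nins = 0, ndel = 0;
  for (int kk = (int) ops.size() - 1; kk >= 0; --kk) {
    cigar += std::to_string(lens[kk]);
    cigar += ops[kk];
    if (ops[kk] == 'I') ++nins;
    if (ops[kk] == 'D') ++ndel;
  }
  return List::create(_["ok"] = true, _["cigar"] = cigar,
                      _["cost"] = best,
                      _["nmatch"] = nmatch, _["nmismatch"] = nmis,
                      _["ins_events"] = nins, _["del_events"] = ndel,
                      _["ins_len"] = ins_len, _["del_len"] = del_len);
}

// ---------------------------------------------------------------------------
// Exact k-mer index over a set of contigs (forward strand, 2-bit encoding).
// K-mers occurring more than max_occ times are masked (repeat control).
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int32_t>> map;  // global positions
  std::vector<int64_t> offsets;                            // contig start in global coords
};

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k, int max_occ) {
  KmerIndex *ix = new KmerIndex();
  ix->k = k;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int64_t off = 0;
  for (int s = 0; s < seqs.size(); ++s) {
    ix->offsets.push_back(off);
    std::string seq = as<std::string>(seqs[s]);
    const int n = (int) seq.size();
    uint64_t kmer = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2(seq[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) ix->map[kmer].push_back((int32_t)(off + i - k + 1));
    }
    off += n;
  }
  if (max_occ > 0) {
    for (auto it = ix->map.begin(); it != ix->map.end();) {
      if ((int) it->second.size() > max_occ) it = ix->map.erase(it);
      else ++it;
    }
  }
  XPtr<KmerIndex> p(ix, true);
  return p;
}

// [[Rcpp::export]]
DataFrame cpp_find_seeds(SEXP idx_ptr, std::string query, int stride) {
  XPtr<KmerIndex> ix(idx_ptr);
  const int k = ix->k;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<int> qpos, tpos;
  const int n = (int) query.size();
  uint64_t kmer = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2(query[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int q0 = i - k + 1;
      if (stride > 1 && (q0 % stride) != 0) continue;
      auto it = ix->map.find(kmer);
      if (it != ix->map.end()) {
        for (int32_t t : it->second) { qpos.push_back(q0); tpos.push_back(t); }
      }
    }
  }
  return DataFrame::create(_["q"] = qpos, _["t"] = tpos);
}

// [[Rcpp::export]]
NumericVector cpp_index_offsets(SEXP idx_ptr) {
  XPtr<KmerIndex> ix(idx_ptr);
  NumericVector out(ix->offsets.size());
  for (size_t i = 0; i < ix->offsets.size(); ++i) out[i] = (double) ix->offsets[i];
  return out;
}

// common prefix length of two strings
// [[Rcpp::export]]
int cpp_common_prefix(std::string a, std::string b) {
  const size_t n = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < n && a[i] == b[i]) ++i;
  return (int) i;
}
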