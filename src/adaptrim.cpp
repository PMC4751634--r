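#include <Rcpp.h>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Best ungapped overlap between two sequences. Offsets are shifts of b
// relative to a; every offset with >= 1 overlapping position is scanned.
struct Aln {
  int offset, overlap, matches, mismatches, ambiguous, score;
  bool valid;
  Aln()
      : offset(0), overlap(0), matches(0), mismatches(0), ambiguous(0),
        score(0), valid(false) {}
};

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (std::string::size_type i = 0; i < out.size(); ++i)
    out[i] = comp_base(out[i]);
  return out;
}

void score_offset(const char *a, int la, const char *b, int lb, int off,
                  Aln &out) {
  const int astart = off > 0 ? off : 0;
  const int aend = (la < off + lb) ? la : off + lb;
  int m = 0, mm = 0, amb = 0;
  for (int i = astart; i < aend; ++i) {
    const char ca = a[i], cb = b[i - off];
    if (ca == 'N' || cb == 'N')
      ++amb;
    else if (ca == cb)
      ++m;
    else
      ++mm;
  }
  out.offset = off;
  out.overlap = aend - astart;
  out.matches = m;
  out.mismatches = mm;
  out.ambiguous = amb;
  out.score = m - mm;
  out.valid = out.overlap >= 1;
}

// Tie-breaking: higher score, then longer overlap, then smaller offset.
inline bool better(const Aln &cand, const Aln &best) {
  if (!cand.valid) return false;
  if (!best.valid) return true;
  if (cand.score != best.score) return cand.score > best.score;
  if (cand.overlap != best.overlap) return cand.overlap > best.overlap;
  return cand.offset < best.offset;
}

Aln best_alignment(const std::string &a, const std::string &b,
                   int min_offset) {
  const int la = (int)a.size(), lb = (int)b.size();
  Aln best, cur;
  int lo = min_offset;
  if (lo < 1 - lb) lo = 1 - lb; // need at least one overlapping position
  for (int off = lo; off <= la - 1; ++off) {
    score_offset(a.c_str(), la, b.c_str(), lb, off, cur);
    if (better(cur, best)) best = cur;
  }
  return best;
}

inline int max_mm_allowed(int eff, double mm) {
  const double rate = (mm > 1.0) ? 1.0 / mm : mm;
  return (int)std::floor(eff * rate + 1e-9);
}

// Short alignments carry little evidence, so the rate-derived mismatch
// budget is capped: below 6 unambiguously called bases no mismatch is
// tolerated, below 10 at most one.
inline bool acceptable(const Aln &a, double mm, int min_score,
                       int min_overlap) {
  if (!a.valid) return false;
  if (a.score < min_score) return false;
  if (a.overlap < min_overlap) return false;
  const int called = a.matches + a.mismatches;
  int threshold = max_mm_allowed(called, mm);
  if (called < 6)
    threshold = 0;
  else if (called < 10 && threshold > 1)
    threshold = 1;
  return a.mismatches <= threshold;
}

} // namespace

// [[Rcpp::export]]
List cpp_align_overlap(std::string a, std::string b, int min_offset) {
  Aln best = best_alignment(a, b, min_offset);
  return List::create(
      _["offset"] = best.offset, _["overlap"] = best.overlap,
      _["matches"] = best.matches, _["mismatches"] = best.mismatches,
      _["ambiguous"] = best.ambiguous, _["score"] = best.score,
      _["valid"] = best.valid);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(seqs[i]));
  }
  return out;
}

// Single-end trimming: adapter aligned against the read at offsets >= 0
// (the adapter may run past the 3' end of the read). Per read, the best
// alignment across all adapters is selected first and the acceptance rule
// is applied to that single candidate.
// Returns a matrix with columns: trimmed length, adapter index (1-based,
// 0 = none), score of the selected alignment (NA if no overlap existed).
// [[Rcpp::export]]
IntegerMatrix cpp_trim_se(CharacterVector seqs, CharacterVector adapters,
                          double mm, int min_score, int min_adapter_overlap) {
  const int n = seqs.size(), k = adapters.size();
  std::vector<std::string> ads(k);
  for (int j = 0; j < k; ++j) ads[j] = as<std::string>(adapters[j]);
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    Aln best;
    int best_ad = 0;
    for (int j = 0; j < k; ++j) {
      Aln a = best_alignment(s, ads[j], 0);
      if (better(a, best)) { best = a; best_ad = j + 1; }
    }
    if (acceptable(best, mm, min_score, min_adapter_overlap)) {
      out(i, 0) = best.offset;
      out(i, 1) = best_ad;
      out(i, 2) = best.score;
    } else {
      out(i, 0) = (int)s.size();
      out(i, 1) = 0;
      out(i, 2) = best.valid ? best.score : NA_INTEGER;
    }
  }
  return out;
}

// Paired-end alignment of the aggregate sequences
//   A = revcomp(adapter2) + seq1,  B = revcomp(seq2) + adapter1
// over offsets >= -(len(adapter2) + max_shift). The inferred insert length
// is offset - len(adapter2) + len(seq2). Best alignment across all adapter
// pairs is selected, then tested for acceptability.
// [[Rcpp::export]]
List cpp_trim_pe(CharacterVector seq1, CharacterVector seq2,
                 CharacterVector adapter1, CharacterVector adapter2,
                 double mm, int min_score, int min_overlap, int max_shift) {
  const int n = seq1.size(), k = adapter1.size();
  std::vector<std::string> a1(k), rc_a2(k);
  for (int j = 0; j < k; ++j) {
    a1[j] = as<std::string>(adapter1[j]);
    rc_a2[j] = revcomp(as<std::string>(adapter2[j]));
  }
  IntegerVector insert_len(n), adapter_idx(n), score(n), overlap(n);
  for (int i = 0; i < n; ++i) {
    const std::string s1 = as<std::string>(seq1[i]);
    const std::string s2 = as<std::string>(seq2[i]);
    const std::string rc_s2 = revcomp(s2);
    const int r2 = (int)s2.size();
    Aln best;
    int best_ad = 0, best_la2 = 0;
    for (int j = 0; j < k; ++j) {
      const std::string A = rc_a2[j] + s1;
      const std::string B = rc_s2 + a1[j];
      const int la2 = (int)rc_a2[j].size();
      Aln a = best_alignment(A, B, -(la2 + max_shift));
      if (better(a, best)) { best = a; best_ad = j + 1; best_la2 = la2; }
    }
    if (acceptable(best, mm, min_score, min_overlap)) {
      int L = best.offset - best_la2 + r2;
      if (L < 0) L = 0;
      insert_len[i] = L;
      adapter_idx[i] = best_ad;
      score[i] = best.score;
      overlap[i] = best.overlap;
    } else {
      insert_len[i] = NA_INTEGER;
      adapter_idx[i] = 0;
      score[i] = best.valid ? best.score : NA_INTEGER;
      overlap[i] = best.valid ? best.overlap : NA_INTEGER;
    }
  }
  return List::create(_["insert"] = insert_len, _["adapter"] = adapter_idx,
                      _["score"] = score, _["overlap"] = overlap);
}

// Collapse mate pairs into the inferred insert. Double-covered positions
// combine the two observations with the position-specific scoring rule:
// agreement sums the Phred scores (capped), disagreement keeps the higher
// quality base at the score difference, exact ties emit N at quality 0, and
// an N observation contributes nothing.
// [[Rcpp::export]]
List cpp_merge(CharacterVector seq1, CharacterVector qual1,
               CharacterVector seq2, CharacterVector qual2,
               IntegerVector insert_len, IntegerVector aln_overlap,
               int min_overlap, int quality_cap) {
  const int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  IntegerVector src_overlap(n);
  for (int i = 0; i < n; ++i) {
    merged[i] = false;
    mseq[i] = NA_STRING;
    mqual[i] = NA_STRING;
    src_overlap[i] = NA_INTEGER;
    if (IntegerVector::is_na(insert_len[i])) continue;
    const int L = insert_len[i];
    if (L < 1) continue;
    const std::string s1 = as<std::string>(seq1[i]);
    const std::string q1 = as<std::string>(qual1[i]);
    const std::string s2 = as<std::string>(seq2[i]);
    const std::string q2 = as<std::string>(qual2[i]);
    const int r1 = (int)s1.size(), r2 = (int)s2.size();
    const int m1 = r1 < L ? r1 : L;
    const int m2 = r2 < L ? r2 : L;
    const int ov = m1 + m2 - L;
    src_overlap[i] = ov > 0 ? ov : 0;
    if (IntegerVector::is_na(aln_overlap[i]) || aln_overlap[i] < min_overlap)
      continue;
    if (m1 + m2 < L) continue; // inferred insert not fully covered
    std::string os(L, 'N'), oq(L, '!');
    for (int p = 0; p < L; ++p) {
      const bool c1 = p < m1;
      const bool c2 = p >= L - m2;
      char b1 = 'N', b2 = 'N';
      int Q1 = 0, Q2 = 0;
      if (c1) { b1 = s1[p]; Q1 = (int)q1[p] - 33; }
      if (c2) {
        const int orig = L - p - 1; // 0-based index into the raw mate 2 read
        b2 = comp_base(s2[orig]);
        Q2 = (int)q2[orig] - 33;
      }
      char ob;
      int oqv;
      if (c1 && c2) {
        const bool n1 = (b1 == 'N'), n2 = (b2 == 'N');
        if (n1 && n2)       { ob = 'N'; oqv = 0; }
        else if (n1)        { ob = b2;  oqv = Q2; }
        else if (n2)        { ob = b1;  oqv = Q1; }
        else if (b1 == b2)  { ob = b1;  oqv = Q1 + Q2; }
        else if (Q1 > Q2)   { ob = b1;  oqv = Q1 - Q2; }
        else if (Q2 > Q1)   { ob = b2;  oqv = Q2 - Q1; }
        else                { ob = 'N'; oqv = 0; }
      } else if (c1) {
        ob = b1; oqv = Q1;
      } else {
        ob = b2; oqv = Q2;
      }
      if (oqv > quality_cap) oqv = quality_cap;
      if (oqv < 0) oqv = 0;
      os[p] = ob;
      oq[p] = (char)(oqv + 33);
    }
    merged[i] = true;
    mseq[i] = os;
    mqual[i] = oq;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["merged"] = merged, _["overlap"] = src_overlap);
}

// Inject substitution errors using R's RNG stream; p gives the per-position
// substitution probability. N bases are left untouched.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, NumericVector p) {
  const int n = seqs.size(), np = p.size();
  const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int len = (int)s.size();
    for (int j = 0; j < len; ++j) {
      if (s[j] == 'N') continue;
      const double pp = j < np ? p[j] : p[np - 1];
      if (unif_rand() < pp) {
        int k = (int)(unif_rand() * 3.0);
        if (k > 2) k = 2;
        int bi = 0;
        for (int t = 0; t < 4; ++t)
          if (bases[t] == s[j]) { bi = t; break; }
        s[j] = bases[k < bi ? k : k + 1];
      }
    }
    out[i] = s;
  }
  return out;
}
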