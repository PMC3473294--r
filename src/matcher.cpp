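#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Seed-and-extend local matcher over (optionally circular) nucleotide
// sequences. One call handles ONE orientation: the caller passes the
// reverse complement of s2 for the inverted strand and maps coordinates
// back. Circularity is handled by doubling each circular sequence; seed
// start positions stay within the first copy, extensions may run into the
// second, and residual duplicates (origin-truncated representations of the
// same physical match) are removed by a containment pass in modular
// coordinates.

static inline uint8_t enc_base(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N or anything else: never matches, stops extension
  }
}

struct RawFrag {
  long a, b, len, matches;
};

static std::vector<uint8_t> encode_doubled(const std::string& s, bool circ) {
  size_t L = s.size();
  std::vector<uint8_t> e;
  e.reserve(circ ? 2 * L : L);
  for (size_t i = 0; i < L; ++i) e.push_back(enc_base(s[i]));
  if (circ)
    for (size_t i = 0; i < L; ++i) e.push_back(e[i]);
  return e;
}

static inline long posmod(long x, long m) { return ((x % m) + m) % m; }

// [[Rcpp::export]]
DataFrame cpp_scan_matches(std::string s1, std::string s2, bool circ1,
                           bool circ2, int k, double min_len,
                           double min_identity, int xdrop, bool skip_diag0,
                           int mismatch_penalty) {
  const long L1 = (long)s1.size(), L2 = (long)s2.size();
  std::vector<RawFrag> out;
  if (L1 >= k && L2 >= k) {
    std::vector<uint8_t> e1 = encode_doubled(s1, circ1);
    std::vector<uint8_t> e2 = encode_doubled(s2, circ2);
    const long n1 = (long)e1.size(), n2 = (long)e2.size();
    const long cap = std::min(L1, L2);
    const uint64_t mask =
        (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

    // index of k-mers of e2 with start position in [0, L2)
    std::vector<std::pair<uint64_t, long> > idx;
    {
      uint64_t km = 0;
      int bad = 0;
      for (long j = 0; j < n2; ++j) {
        uint8_t c = e2[j];
        km = ((km << 2) | (uint64_t)(c & 3)) & mask;
        if (c > 3) bad = k;
        else if (bad > 0) --bad;
        if (j >= k - 1) {
          long start = j - k + 1;
          if (start >= L2) break;
          if (bad == 0) idx.push_back(std::make_pair(km, start));
        }
      }
      std::sort(idx.begin(), idx.end());
    }

    std::unordered_map<long, long> cov;  // diagonal -> rightmost covered i
    uint64_t km = 0;
    int bad = 0;
    for (long p = 0; p < n1; ++p) {
      uint8_t c = e1[p];
      km = ((km << 2) | (uint64_t)(c & 3)) & mask;
      if (c > 3) bad = k;
      else if (bad > 0) --bad;
      if (p < k - 1) continue;
      long i = p - k + 1;
      if (i >= L1) break;
      if (bad != 0) continue;
      std::pair<uint64_t, long> key(km, -1L);
      std::vector<std::pair<uint64_t, long> >::const_iterator it =
          std::lower_bound(idx.begin(), idx.end(), key);
      for (; it != idx.end() && it->first == km; ++it) {
        long j = it->second;
        if (skip_diag0 && posmod(i - j, L1) == 0) continue;
        long diag = i - j;
        std::unordered_map<long, long>::iterator cit = cov.find(diag);
        if (cit != cov.end() && i < cit->second) continue;

        // extend left of the seed
        long bestl = 0, bestlm = 0;
        {
          long score = 0, best = 0, curm = 0, t = 1;
          while (i - t >= 0 && j - t >= 0) {
            uint8_t c1 = e1[i - t], c2 = e2[j - t];
            if (c1 > 3 || c2 > 3) break;
            bool m = (c1 == c2);
            score += m ? 1 : -mismatch_penalty;
            if (m) ++curm;
            if (score > best) { best = score; bestl = t; bestlm = curm; }
            if (best - score > xdrop) break;
            if (k + t >= cap) break;
            ++t;
          }
        }
        // extend right of the seed
        long bestr = 0, bestrm = 0;
        {
          long score = 0, best = 0, curm = 0, t = 0;
          long rmax = cap - (k + bestl);
          while (i + k + t < n1 && j + k + t < n2 && t < rmax) {
            uint8_t c1 = e1[i + k + t], c2 = e2[j + k + t];
            if (c1 > 3 || c2 > 3) break;
            bool m = (c1 == c2);
            score += m ? 1 : -mismatch_penalty;
            if (m) ++curm;
            if (score > best) { best = score; bestr = t + 1; bestrm = curm; }
            if (best - score > xdrop) break;
            ++t;
          }
        }

        long covend = i + k + bestr;
        long& ce = cov[diag];
        if (covend > ce) ce = covend;

        long len = bestl + k + bestr;
        long matches = bestlm + k + bestrm;
        if ((double)len >= min_len &&
            (double)matches / (double)len >= min_identity) {
          RawFrag f;
          f.a = i - bestl;
          f.b = j - bestl;
          f.len = len;
          f.matches = matches;
          out.push_back(f);
        }
      }
    }

    // containment / duplicate removal in modular coordinates
    std::sort(out.begin(), out.end(),
              [](const RawFrag& x, const RawFrag& y) {
                if (x.len != y.len) return x.len > y.len;
                if (x.a != y.a) return x.a < y.a;
                return x.b < y.b;
              });
    std::vector<RawFrag> kept;
    for (size_t f = 0; f < out.size(); ++f) {
      bool contained = false;
      for (size_t g = 0; g < kept.size(); ++g) {
        long t = out[f].a - kept[g].a;
        if (circ1) t = posmod(t, L1);
        if (t < 0 || t + out[f].len > kept[g].len) continue;
        long gb = kept[g].b + t;
        bool same_b = circ2 ? (posmod(gb - out[f].b, L2) == 0)
                            : (gb == out[f].b);
        if (same_b) { contained = true; break; }
      }
      if (!contained) kept.push_back(out[f]);
    }
    std::sort(kept.begin(), kept.end(), [](const RawFrag& x, const RawFrag& y) {
      if (x.a != y.a) return x.a < y.a;
      return x.b < y.b;
    });
    out.swap(kept);
  }

  size_t n = out.size();
  NumericVector a(n), b(n), len(n), matches(n);
  for (size_t f = 0; f < n; ++f) {
    a[f] = (double)out[f].a;
    b[f] = (double)out[f].b;
    len[f] = (double)out[f].len;
    matches[f] = (double)out[f].matches;
  }
  return DataFrame::create(Named("a_start") = a, Named("b_start") = b,
                           Named("len") = len, Named("matches") = matches);
}

// Hamming-distance motif scan over a (possibly circular) sequence, one
// strand. Returns 0-based start offsets and mismatch counts.
// [[Rcpp::export]]
DataFrame cpp_motif_scan(std::string seq, std::string motif, bool circular,
                         int max_mismatch) {
  const long L = (long)seq.size(), m = (long)motif.size();
  std::vector<long> starts;
  std::vector<int> mism;
  if (m <= L && m > 0) {
    std::vector<uint8_t> e = encode_doubled(seq, circular);
    std::vector<uint8_t> mo;
    for (long t = 0; t < m; ++t) mo.push_back(enc_base(motif[t]));
    long nstart = circular ? L : (L - m + 1);
    for (long i = 0; i < nstart; ++i) {
      int d = 0;
      for (long t = 0; t < m; ++t) {
        uint8_t c1 = e[i + t], c2 = mo[t];
        if (c1 > 3 || c2 > 3 || c1 != c2) ++d;
        if (d > max_mismatch) break;
      }
      if (d <= max_mismatch) {
        starts.push_back(i);
        mism.push_back(d);
      }
    }
  }
  return DataFrame::create(Named("start") = wrap(starts),
                           Named("mismatches") = wrap(mism));
}
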