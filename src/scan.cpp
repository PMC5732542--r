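#include <Rcpp.h>

#include <cstdint>
#include <cstring>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// 2-bit base code; -1 for any ambiguity code (never matches under "strict")
inline int base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default:  return -1;
  }
}

// IUPAC nucleotide -> 4-bit mask (A=1, C=2, G=4, T=8); 0 for non-IUPAC
inline int iupac_mask(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 4;
  case 'T': case 't': case 'U': case 'u': return 8;
  case 'R': case 'r': return 1 | 4;
  case 'Y': case 'y': return 2 | 8;
  case 'S': case 's': return 2 | 4;
  case 'W': case 'w': return 1 | 8;
  case 'K': case 'k': return 4 | 8;
  case 'M': case 'm': return 1 | 2;
  case 'B': case 'b': return 2 | 4 | 8;
  case 'D': case 'd': return 1 | 4 | 8;
  case 'H': case 'h': return 1 | 2 | 8;
  case 'V': case 'v': return 1 | 2 | 4;
  case 'N': case 'n': return 15;
  default:  return 0;
  }
}

struct HitSink {
  std::vector<int> win, subj, pos, mm, seed;
  void add(int w, int s, int p, int m, bool seed_ok) {
    win.push_back(w + 1);
    subj.push_back(s + 1);
    pos.push_back(p);
    mm.push_back(m);
    seed.push_back(seed_ok ? 1 : 0);
  }
  List as_list() const {
    return List::create(_["window"] = win, _["subject"] = subj,
                        _["position"] = pos, _["mismatches"] = mm,
                        _["seed_perfect"] = seed);
  }
};

}  // namespace

// Exhaustive Hamming scan of equal-length windows against subject sequences,
// strict ambiguity policy (a position holding any non-ACGT base is a
// mismatch, even when the two characters are equal). Pigeonhole filter: an
// alignment with <= max_mm mismatches over L positions has at least one of
// max_mm+1 contiguous near-equal parts matching exactly, so part keys (2 bits
// per base) are hashed and only key-sharing (window, position) pairs are
// verified in full. A candidate is accepted only from its first exact part,
// so each pair is reported exactly once. seed_perfect marks alignments with
// no mismatch at window positions 2-8 (1-based); reported FALSE when the
// window is shorter than 8 nt.
// [[Rcpp::export]]
List scan_windows_strict(CharacterVector windows, CharacterVector subjects,
                         int max_mm) {
  HitSink out;
  const int nw = windows.size();
  const int ns = subjects.size();
  if (nw == 0 || ns == 0) return out.as_list();
  if (max_mm < 0) stop("max_mm must be >= 0");

  const int L = (int)std::strlen(CHAR(STRING_ELT(windows, 0)));
  if (L < 1) stop("windows must be non-empty");
  std::vector<int8_t> wc((size_t)nw * L);
  for (int w = 0; w < nw; ++w) {
    const char *s = CHAR(STRING_ELT(windows, w));
    if ((int)std::strlen(s) != L) stop("all windows must have equal length");
    for (int i = 0; i < L; ++i) wc[(size_t)w * L + i] = (int8_t)base2(s[i]);
  }

  int np = max_mm + 1;
  if (np > L) np = L;
  std::vector<int> pstart(np + 1);
  for (int p = 0; p <= np; ++p)
    pstart[p] = (int)(((long long)p * L) / np);
  if (pstart[1] - pstart[0] > 31) stop("part length exceeds 31 nt; raise max_mm or shorten windows");

  std::vector<std::unordered_map<uint64_t, std::vector<int> > > index(np);
  for (int p = 0; p < np; ++p) {
    for (int w = 0; w < nw; ++w) {
      uint64_t key = 0;
      bool ok = true;
      for (int i = pstart[p]; i < pstart[p + 1]; ++i) {
        int c = wc[(size_t)w * L + i];
        if (c < 0) { ok = false; break; }  // part with ambiguity: never exact
        key = (key << 2) | (uint64_t)c;
      }
      if (ok) index[p][key].push_back(w);
    }
  }

  const bool has_seed = L >= 8;
  std::vector<int8_t> sc;
  for (int s = 0; s < ns; ++s) {
    const char *str = CHAR(STRING_ELT(subjects, s));
    const int slen = (int)std::strlen(str);
    if (slen < L) continue;
    sc.assign(slen, 0);
    for (int i = 0; i < slen; ++i) sc[i] = (int8_t)base2(str[i]);

    for (int pos = 0; pos + L <= slen; ++pos) {
      for (int p = 0; p < np; ++p) {
        uint64_t key = 0;
        bool ok = true;
        for (int i = pstart[p]; i < pstart[p + 1]; ++i) {
          int c = sc[pos + i];
          if (c < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            index[p].find(key);
        if (it == index[p].end()) continue;
        for (size_t ci = 0; ci < it->second.size(); ++ci) {
          const int w = it->second[ci];
          int mm_total = 0, first_exact = -1;
          for (int q = 0; q < np && mm_total <= max_mm; ++q) {
            int mmq = 0;
            for (int i = pstart[q]; i < pstart[q + 1]; ++i) {
              const int a = wc[(size_t)w * L + i], b = sc[pos + i];
              if (a < 0 || b < 0 || a != b) ++mmq;
            }
            if (mmq == 0 && first_exact < 0) first_exact = q;
            mm_total += mmq;
          }
          if (mm_total > max_mm || first_exact != p) continue;
          bool seed_ok = has_seed;
          if (seed_ok) {
            for (int i = 1; i <= 7; ++i) {
              const int a = wc[(size_t)w * L + i], b = sc[pos + i];
              if (a < 0 || b < 0 || a != b) { seed_ok = false; break; }
            }
          }
          out.add(w, s, pos, mm_total, seed_ok);
        }
      }
    }
  }
  return out.as_list();
}

// Naive scan under the IUPAC ambiguity policy: two bases match when their
// IUPAC sets intersect. No hash filter (N intersects everything, so exact
// part keys are unsound); intended for small inputs / non-default use.
// [[Rcpp::export]]
List scan_windows_iupac(CharacterVector windows, CharacterVector subjects,
                        int max_mm) {
  HitSink out;
  const int nw = windows.size();
  const int ns = subjects.size();
  if (nw == 0 || ns == 0) return out.as_list();
  if (max_mm < 0) stop("max_mm must be >= 0");

  const int L = (int)std::strlen(CHAR(STRING_ELT(windows, 0)));
  if (L < 1) stop("windows must be non-empty");
  std::vector<int8_t> wc((size_t)nw * L);
  for (int w = 0; w < nw; ++w) {
    const char *s = CHAR(STRING_ELT(windows, w));
    if ((int)std::strlen(s) != L) stop("all windows must have equal length");
    for (int i = 0; i < L; ++i) wc[(size_t)w * L + i] = (int8_t)iupac_mask(s[i]);
  }

  const bool has_seed = L >= 8;
  std::vector<int8_t> sc;
  for (int s = 0; s < ns; ++s) {
    const char *str = CHAR(STRING_ELT(subjects, s));
    const int slen = (int)std::strlen(str);
    if (slen < L) continue;
    sc.assign(slen, 0);
    for (int i = 0; i < slen; ++i) sc[i] = (int8_t)iupac_mask(str[i]);

    for (int pos = 0; pos + L <= slen; ++pos) {
      for (int w = 0; w < nw; ++w) {
        int mm_total = 0;
        for (int i = 0; i < L && mm_total <= max_mm; ++i)
          if ((wc[(size_t)w * L + i] & sc[pos + i]) == 0) ++mm_total;
        if (mm_total > max_mm) continue;
        bool seed_ok = has_seed;
        if (seed_ok) {
          for (int i = 1; i <= 7; ++i)
            if ((wc[(size_t)w * L + i] & sc[pos + i]) == 0) { seed_ok = false; break; }
        }
        out.add(w, s, pos, mm_total, seed_ok);
      }
    }
  }
  return out.as_list();
}
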