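// Core sequence kernels: k-mer seed index, unique-best ungapped mapper,
// non-overlapping motif counter, and the read-error model.  These are the
// hot loops of the pipeline; everything else lives in R.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char upBase(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

static inline char compBase(char c) {
  switch (upBase(c)) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

struct SeedIndexCpp {
  int k;
  int maxOcc;
  std::string ref;                       // contigs concatenated, 'N'-separated
  std::vector<long long> cstart;         // global start of each contig
  std::vector<long long> cend;           // exclusive global end
  // canonical k-mer -> encoded positions ((gpos << 1) | flip); flip = 1 when
  // the forward reference k-mer at gpos is the reverse complement of canonical
  std::unordered_map<uint64_t, std::vector<uint64_t> > pos;
  long long mappable;                    // non-N reference bases
  long long nPositions;                  // indexed seed positions kept
};

// [[Rcpp::export(name = ".buildIndexCpp")]]
SEXP buildIndexCpp(CharacterVector contigs, int k, int maxOcc) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  SeedIndexCpp *idx = new SeedIndexCpp();
  idx->k = k;
  idx->maxOcc = maxOcc;
  long long total = 0;
  for (int i = 0; i < contigs.size(); ++i) total += LENGTH(STRING_ELT(contigs, i)) + 1;
  idx->ref.reserve(total);
  for (int i = 0; i < contigs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(contigs, i));
    idx->cstart.push_back((long long)idx->ref.size());
    for (const char *p = s; *p; ++p) idx->ref.push_back(upBase(*p));
    idx->cend.push_back((long long)idx->ref.size());
    idx->ref.push_back('N');             // separator: no k-mer spans contigs
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  long long mappable = 0;
  const std::string &R = idx->ref;
  for (long long i = 0; i < (long long)R.size(); ++i) {
    int c = baseCode(R[i]);
    if (c < 0) { run = 0; fwd = rev = 0; continue; }
    ++mappable;
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      long long gpos = i - k + 1;
      uint64_t canon = std::min(fwd, rev);
      uint64_t flip = (fwd == canon) ? 0ULL : 1ULL;
      idx->pos[canon].push_back(((uint64_t)gpos << 1) | flip);
    }
  }
  idx->mappable = mappable;
  long long kept = 0;
  for (auto it = idx->pos.begin(); it != idx->pos.end();) {
    if ((int)it->second.size() > maxOcc) it = idx->pos.erase(it);
    else { kept += (long long)it->second.size(); ++it; }
  }
  idx->nPositions = kept;
  XPtr<SeedIndexCpp> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".indexStatsCpp")]]
List indexStatsCpp(SEXP xp) {
  XPtr<SeedIndexCpp> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["maxOcc"] = idx->maxOcc,
                      _["nKmers"] = (double)idx->pos.size(),
                      _["nPositions"] = (double)idx->nPositions,
                      _["mappable"] = (double)idx->mappable);
}

// Every stored position must regenerate its canonical k-mer.
// [[Rcpp::export(name = ".verifyIndexCpp")]]
bool verifyIndexCpp(SEXP xp) {
  XPtr<SeedIndexCpp> idx(xp);
  const int k = idx->k;
  for (auto const &kv : idx->pos) {
    for (uint64_t enc : kv.second) {
      long long gpos = (long long)(enc >> 1);
      uint64_t fwd = 0, rev = 0;
      for (int j = 0; j < k; ++j) {
        int c = baseCode(idx->ref[gpos + j]);
        if (c < 0) return false;
        fwd = (fwd << 2) | (uint64_t)c;
        rev |= (uint64_t)(3 - c) << (2 * j);
      }
      if (std::min(fwd, rev) != kv.first) return false;
    }
  }
  return true;
}

static inline int countMismFwd(const std::string &R, long long s,
                               const char *q, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (upBase(q[i]) != R[s + i]) { if (++mm > cap) return mm; }
  }
  return mm;
}

static inline int countMismRev(const std::string &R, long long s,
                               const char *q, int len, int cap) {
  // reverse complement of q compared against R[s .. s+len)
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (compBase(q[len - 1 - i]) != R[s + i]) { if (++mm > cap) return mm; }
  }
  return mm;
}

// Map reads against the index.  Seeds are the non-overlapping k-mers of the
// read plus the terminal k-mer; candidate diagonals from both strands are
// scored by full-length ungapped comparison.  uniqueBest: ties are discarded;
// otherwise one of the best-scoring placements is drawn uniformly (R RNG).
// [[Rcpp::export(name = ".mapReadsCpp")]]
List mapReadsCpp(SEXP xp, CharacterVector reads, double maxMismatchFrac,
                 bool uniqueBest) {
  XPtr<SeedIndexCpp> idx(xp);
  const int k = idx->k;
  const std::string &R = idx->ref;
  const int n = reads.size();
  IntegerVector outContig(n, NA_INTEGER);
  NumericVector outStart(n, NA_REAL);   // 0-based within contig
  IntegerVector outStrand(n, NA_INTEGER);
  IntegerVector outMism(n, NA_INTEGER);
  std::vector<std::pair<long long, int> > cand;   // (global start, strand)
  std::vector<long long> bestS;
  std::vector<int> bestStr, bestMm;
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    if (len < k) continue;
    int cap = (int)std::floor(maxMismatchFrac * len);
    cand.clear();
    // seed offsets: the non-overlapping k-mers plus the terminal k-mer
    std::vector<int> offs;
    for (int o = 0; o + k <= len; o += k) offs.push_back(o);
    if ((len - k) % k != 0) offs.push_back(len - k);
    for (size_t oi = 0; oi < offs.size(); ++oi) {
      int o = offs[oi];
      uint64_t fwd = 0, rev = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int c = baseCode(q[o + j]);
        if (c < 0) { ok = false; break; }
        fwd = (fwd << 2) | (uint64_t)c;
        rev |= (uint64_t)(3 - c) << (2 * j);
      }
      if (ok) {
        uint64_t canon = std::min(fwd, rev);
        uint64_t qflip = (fwd == canon) ? 0ULL : 1ULL;
        auto it = idx->pos.find(canon);
        if (it != idx->pos.end()) {
          for (uint64_t enc : it->second) {
            long long p = (long long)(enc >> 1);
            uint64_t rflip = enc & 1ULL;
            if (rflip == qflip) {
              cand.push_back(std::make_pair(p - o, 1));           // forward
            } else {
              cand.push_back(std::make_pair(p - (len - k - o), -1)); // reverse
            }
          }
        }
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    int bestScore = -2 * len;
    bestS.clear(); bestStr.clear(); bestMm.clear();
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      long long s = cand[ci].first;
      if (s < 0 || s + len > (long long)R.size()) continue;
      // must lie inside a single contig
      size_t lo = std::upper_bound(idx->cstart.begin(), idx->cstart.end(), s)
        - idx->cstart.begin();
      if (lo == 0) continue;
      size_t ct = lo - 1;
      if (s + len > idx->cend[ct]) continue;
      int mm = (cand[ci].second > 0)
        ? countMismFwd(R, s, q, len, cap)
        : countMismRev(R, s, q, len, cap);
      if (mm > cap) continue;
      int score = len - 2 * mm;          // matches - mismatches
      if (score > bestScore) {
        bestScore = score;
        bestS.clear(); bestStr.clear(); bestMm.clear();
      }
      if (score == bestScore) {
        bestS.push_back(s);
        bestStr.push_back(cand[ci].second);
        bestMm.push_back(mm);
      }
    }
    if (bestS.empty()) continue;
    size_t pick = 0;
    if (bestS.size() > 1) {
      if (uniqueBest) continue;          // ambiguous: no hit
      pick = (size_t)(unif_rand() * (double)bestS.size());
      if (pick >= bestS.size()) pick = bestS.size() - 1;
    }
    long long s = bestS[pick];
    size_t ct = (size_t)(std::upper_bound(idx->cstart.begin(), idx->cstart.end(), s)
                         - idx->cstart.begin()) - 1;
    outContig[r] = (int)ct + 1;
    outStart[r] = (double)(s - idx->cstart[ct]);
    outStrand[r] = bestStr[pick];
    outMism[r] = bestMm[pick];
  }
  return List::create(_["contig"] = outContig, _["start"] = outStart,
                      _["strand"] = outStrand, _["mismatches"] = outMism);
}

// Non-overlapping, case-insensitive, left-to-right greedy motif count.
// [[Rcpp::export(name = ".countMotifCpp")]]
IntegerVector countMotifCpp(CharacterVector seqs, std::string motif) {
  int m = (int)motif.size();
  if (m == 0) stop("motif must be non-empty");
  for (int j = 0; j < m; ++j) motif[j] = upBase(motif[j]);
  int n = seqs.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    if (seqs[r] == NA_STRING) { out[r] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    int cnt = 0, i = 0;
    while (i + m <= len) {
      int j = 0;
      while (j < m && upBase(s[i + j]) == motif[j]) ++j;
      if (j == m) { ++cnt; i += m; } else { ++i; }
    }
    out[r] = cnt;
  }
  return out;
}

// Independent per-base substitutions at the given rate, drawn from R's RNG
// stream so results are reproducible under set.seed().
// [[Rcpp::export(name = ".addSubstitutionsCpp")]]
CharacterVector addSubstitutionsCpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    buf.assign(s, (size_t)len);
    for (int i = 0; i < len; ++i) {
      if (unif_rand() < rate) {
        char cur = upBase(buf[i]);
        char nb;
        do {
          nb = bases[(int)(unif_rand() * 4.0) & 3];
        } while (nb == cur);
        buf[i] = nb;
      }
    }
    out[r] = buf;
  }
  return out;
}
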