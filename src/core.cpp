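#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// 2-bit encode; -1 for anything not ACGT (upper case expected)
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  // kmer -> packed (chrom << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
};

static inline uint64_t pack_hit(int chrom, int pos) {
  return (uint64_t(chrom) << 32) | uint64_t(uint32_t(pos));
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  for (int i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->names.push_back(as<std::string>(names[i]));
  }
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string &s = idx->seqs[c];
    if ((int)s.size() < k) continue;
    uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0; // valid bases accumulated
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | uint64_t(b)) & mask;
      if (++run >= k) idx->map[kmer].push_back(pack_hit((int)c, (int)(i - k + 1)));
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = (int)idx->seqs[i].size();
  return List::create(_["k"] = idx->k,
                      _["names"] = wrap(idx->names),
                      _["lengths"] = lens,
                      _["n_kmers"] = (double)idx->map.size());
}

// exact-occurrence lookup of one k-length string (forward strand)
// [[Rcpp::export]]
DataFrame cpp_lookup_kmer(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  std::vector<int> chrom, pos;
  if ((int)kmer.size() == idx->k) {
    uint64_t key = 0; bool ok = true;
    for (char c : kmer) { int b = base2bit(c); if (b < 0) { ok = false; break; } key = (key << 2) | uint64_t(b); }
    if (ok) {
      auto it = idx->map.find(key);
      if (it != idx->map.end())
        for (uint64_t h : it->second) { chrom.push_back(int(h >> 32) + 1); pos.push_back(int(uint32_t(h))); }
    }
  }
  return DataFrame::create(_["chrom_id"] = wrap(chrom), _["pos"] = wrap(pos));
}

// count mismatches between read and ref at start p (0-based), early exit
static inline int mm_count(const std::string &ref, const std::string &read, int p, int cap) {
  int L = (int)read.size();
  if (p < 0 || p + L > (int)ref.size()) return cap + 1;
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    if (ref[p + i] != read[i] && ++mm > cap) return mm;
  }
  return mm;
}

struct Placement {
  int chrom, pos; // 0-based
  bool fwd;
  int mm;
};

// collect candidate placements of one oriented read sequence
static void candidates(const SeedIndex &idx, const std::string &read, bool fwd, int max_mm,
                       std::vector<Placement> &out, std::vector<uint64_t> &scratch) {
  int k = idx.k, L = (int)read.size();
  if (L < k) return;
  scratch.clear();
  int nseed = std::max(1, L / k);
  for (int s = 0; s <= nseed; ++s) {
    int off = (s == nseed) ? (L - k) : s * k;
    if (s == nseed && off % k == 0 && off / k < nseed) break; // already done
    uint64_t key = 0; bool ok = true;
    for (int i = 0; i < k; ++i) { int b = base2bit(read[off + i]); if (b < 0) { ok = false; break; } key = (key << 2) | uint64_t(b); }
    if (!ok) continue;
    auto it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    for (uint64_t h : it->second) {
      int chrom = int(h >> 32), pos = int(uint32_t(h));
      int start = pos - off;
      if (start < 0) continue;
      scratch.push_back(pack_hit(chrom, start));
    }
  }
  std::sort(scratch.begin(), scratch.end());
  scratch.erase(std::unique(scratch.begin(), scratch.end()), scratch.end());
  for (uint64_t h : scratch) {
    int chrom = int(h >> 32), start = int(uint32_t(h));
    int mm = mm_count(idx.seqs[chrom], read, start, max_mm);
    if (mm <= max_mm) out.push_back({chrom, start, fwd, mm});
  }
}

// best placement of a read on either strand; returns mm = -1 when unmapped
struct BestHit { int chrom, pos, mm; bool fwd; int nties; bool mapped; };

static BestHit best_hit(const SeedIndex &idx, const std::string &read, int max_mm,
                        std::vector<Placement> &cands, std::vector<uint64_t> &scratch) {
  cands.clear();
  candidates(idx, read, true, max_mm, cands, scratch);
  std::string rc = revcomp(read);
  candidates(idx, rc, false, max_mm, cands, scratch);
  BestHit bh; bh.mapped = false; bh.nties = 0; bh.mm = max_mm + 1;
  for (const Placement &p : cands) {
    if (p.mm < bh.mm) {
      bh.mm = p.mm; bh.chrom = p.chrom; bh.pos = p.pos; bh.fwd = p.fwd;
      bh.mapped = true; bh.nties = 1;
    } else if (p.mm == bh.mm && bh.mapped) {
      bh.nties++;
      // deterministic leftmost tie-break for reporting
      if (p.chrom < bh.chrom || (p.chrom == bh.chrom && (p.pos < bh.pos ||
          (p.pos == bh.pos && p.fwd && !bh.fwd)))) {
        bh.chrom = p.chrom; bh.pos = p.pos; bh.fwd = p.fwd;
      }
    }
  }
  return bh;
}

// single-end alignment of many reads: best hit each, tie count reported
// [[Rcpp::export]]
DataFrame cpp_align_se(SEXP xp, CharacterVector reads, int max_mm) {
  XPtr<SeedIndex> idx(xp);
  int n = reads.size();
  IntegerVector chrom(n), pos(n), mm(n), nties(n);
  LogicalVector fwd(n), mapped(n);
  std::vector<Placement> cands; std::vector<uint64_t> scratch;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    BestHit bh = best_hit(*idx, r, max_mm, cands, scratch);
    mapped[i] = bh.mapped;
    if (bh.mapped) { chrom[i] = bh.chrom + 1; pos[i] = bh.pos; fwd[i] = bh.fwd; mm[i] = bh.mm; nties[i] = bh.nties; }
    else { chrom[i] = NA_INTEGER; pos[i] = NA_INTEGER; fwd[i] = NA_LOGICAL; mm[i] = NA_INTEGER; nties[i] = 0; }
  }
  return DataFrame::create(_["mapped"] = mapped, _["chrom_id"] = chrom, _["pos"] = pos,
                           _["fwd"] = fwd, _["mm"] = mm, _["nties"] = nties);
}

// paired alignment: each mate best-hit; tie on either mate -> ambiguous
// [[Rcpp::export]]
DataFrame cpp_align_pe(SEXP xp, CharacterVector reads1, CharacterVector reads2, int max_mm) {
  XPtr<SeedIndex> idx(xp);
  int n = reads1.size();
  IntegerVector c1(n), p1(n), m1(n), c2(n), p2(n), m2(n);
  LogicalVector f1(n), f2(n), mapped(n), unique_(n);
  std::vector<Placement> cands; std::vector<uint64_t> scratch;
  for (int i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(reads1[i]);
    std::string r2 = as<std::string>(reads2[i]);
    BestHit b1 = best_hit(*idx, r1, max_mm, cands, scratch);
    BestHit b2 = best_hit(*idx, r2, max_mm, cands, scratch);
    bool ok = b1.mapped && b2.mapped;
    mapped[i] = ok;
    unique_[i] = ok && b1.nties == 1 && b2.nties == 1;
    if (ok) {
      c1[i] = b1.chrom + 1; p1[i] = b1.pos; f1[i] = b1.fwd; m1[i] = b1.mm;
      c2[i] = b2.chrom + 1; p2[i] = b2.pos; f2[i] = b2.fwd; m2[i] = b2.mm;
    } else {
      c1[i] = NA_INTEGER; p1[i] = NA_INTEGER; f1[i] = NA_LOGICAL; m1[i] = NA_INTEGER;
      c2[i] = NA_INTEGER; p2[i] = NA_INTEGER; f2[i] = NA_LOGICAL; m2[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["mapped"] = mapped, _["unique"] = unique_,
                           _["chrom1"] = c1, _["pos1"] = p1, _["fwd1"] = f1, _["mm1"] = m1,
                           _["chrom2"] = c2, _["pos2"] = p2, _["fwd2"] = f2, _["mm2"] = m2);
}

struct GapHit {
  int chrom, pos;       // alignment start, 0-based
  bool fwd;
  int mm;
  int gap_type;         // 1 = deletion from read (ref bases absent in read, CIGAR D)
                        // 2 = insertion in read (extra read bases, CIGAR I)
  int gap_len;
  int split;            // read offset where gap opens (bases consumed before gap)
  bool valid;
};

// best single-gap placement of oriented read at candidate start p
static void eval_gapped(const std::string &ref, const std::string &read, int p,
                        int max_mm, int max_gap, bool fwd, int chrom, GapHit &best, int &nbest) {
  int L = (int)read.size();
  if (p < 0) return;
  // deletion of g ref bases after read offset i
  for (int g = 1; g <= max_gap; ++g) {
    if (p + L + g > (int)ref.size()) continue;
    // prefix mismatches
    int pre = 0;
    std::vector<int> prefix(L + 1, 0);
    for (int i = 0; i < L; ++i) { if (ref[p + i] != read[i]) ++pre; prefix[i + 1] = pre; }
    // suffix mismatches for split i: read[i..L) vs ref[p+g+i ..)
    std::vector<int> suffix(L + 1, 0);
    for (int i = L - 1; i >= 0; --i)
      suffix[i] = suffix[i + 1] + (ref[p + g + i] != read[i] ? 1 : 0);
    for (int i = 1; i <= L - 1; ++i) {
      int mm = prefix[i] + suffix[i];
      if (mm > max_mm) continue;
      GapHit h = {chrom, p, fwd, mm, 1, g, i, true};
      if (!best.valid || h.mm < best.mm) { best = h; nbest = 1; }
      else if (h.mm == best.mm) {
        // same-locus shifted representations of one gap are not counted as ties;
        // left-most split wins (left-aligned gap)
        if (h.chrom == best.chrom && h.pos == best.pos && h.gap_type == best.gap_type && h.gap_len == best.gap_len) {
          if (h.split < best.split) best = h;
        } else ++nbest;
      }
    }
  }
  // insertion of g read bases after read offset i (ref skips nothing)
  for (int g = 1; g <= max_gap; ++g) {
    if (p + L - g > (int)ref.size()) continue;
    if (L - g < 2) continue;
    int pre = 0;
    std::vector<int> prefix(L + 1, 0);
    for (int i = 0; i < L; ++i) {
      if (p + i < (int)ref.size() && ref[p + i] != read[i]) ++pre;
      else if (p + i >= (int)ref.size()) ++pre;
      prefix[i + 1] = pre;
    }
    std::vector<int> suffix(L + 1, 0); // read[j..L) vs ref[p + j - g ..)
    for (int j = L - 1; j >= g; --j) {
      int rpos = p + j - g;
      suffix[j] = suffix[j + 1] + ((rpos < (int)ref.size() && ref[rpos] == read[j]) ? 0 : 1);
    }
    for (int i = 1; i <= L - g - 1; ++i) {
      int mm = prefix[i] + suffix[i + g];
      if (mm > max_mm) continue;
      GapHit h = {chrom, p, fwd, mm, 2, g, i, true};
      if (!best.valid || h.mm < best.mm) { best = h; nbest = 1; }
      else if (h.mm == best.mm) {
        if (h.chrom == best.chrom && h.pos == best.pos && h.gap_type == best.gap_type && h.gap_len == best.gap_len) {
          if (h.split < best.split) best = h;
        } else ++nbest;
      }
    }
  }
}

static void gapped_candidate_starts(const SeedIndex &idx, const std::string &read, int max_gap,
                                    std::vector<uint64_t> &starts) {
  int k = idx.k, L = (int)read.size();
  int nseed = std::max(1, L / k);
  for (int s = 0; s <= nseed; ++s) {
    int off = (s == nseed) ? (L - k) : s * k;
    if (s == nseed && off % k == 0 && off / k < nseed) break;
    uint64_t key = 0; bool ok = true;
    for (int i = 0; i < k; ++i) { int b = base2bit(read[off + i]); if (b < 0) { ok = false; break; } key = (key << 2) | uint64_t(b); }
    if (!ok) continue;
    auto it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    for (uint64_t h : it->second) {
      int chrom = int(h >> 32), pos = int(uint32_t(h));
      for (int d = -max_gap; d <= max_gap; ++d) {
        int start = pos - off + d;
        if (start >= 0) starts.push_back(pack_hit(chrom, start));
      }
    }
  }
  std::sort(starts.begin(), starts.end());
  starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
}

// single-gap rescue alignment (one 1..max_gap bp indel plus <= max_mm mismatches)
// [[Rcpp::export]]
DataFrame cpp_realign_gapped(SEXP xp, CharacterVector reads, int max_mm, int max_gap) {
  XPtr<SeedIndex> idx(xp);
  int n = reads.size();
  IntegerVector chrom(n), pos(n), mm(n), gtype(n), glen(n), gpos(n), nties(n);
  LogicalVector fwd(n), mapped(n);
  CharacterVector gseq(n);
  std::vector<uint64_t> starts;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    std::string rc = revcomp(r);
    GapHit best; best.valid = false; best.mm = max_mm + 1;
    int nbest = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &rd = strand == 0 ? r : rc;
      starts.clear();
      gapped_candidate_starts(*idx, rd, max_gap, starts);
      for (uint64_t h : starts) {
        int c = int(h >> 32), p0 = int(uint32_t(h));
        eval_gapped(idx->seqs[c], rd, p0, max_mm, max_gap, strand == 0, c, best, nbest);
      }
    }
    if (best.valid && nbest == 1) {
      mapped[i] = true;
      chrom[i] = best.chrom + 1; pos[i] = best.pos; fwd[i] = best.fwd; mm[i] = best.mm;
      gtype[i] = best.gap_type; glen[i] = best.gap_len; nties[i] = 1;
      const std::string &rd = best.fwd ? r : rc;
      // left-align the gap against the reference
      int split = best.split, refgap = best.pos + best.split; // 0-based ref coord where gap opens
      if (best.gap_type == 1) {
        const std::string &rs = idx->seqs[best.chrom];
        // deleted bases rs[refgap .. refgap+g); shift left while preceding base equals last deleted base
        while (refgap > best.pos && split > 0 &&
               rs[refgap - 1] == rs[refgap + best.gap_len - 1] &&
               rd[split - 1] == rs[refgap - 1]) { --refgap; --split; }
        gpos[i] = refgap;
        gseq[i] = idx->seqs[best.chrom].substr(refgap, best.gap_len);
      } else {
        const std::string &rs = idx->seqs[best.chrom];
        // inserted bases rd[split .. split+g); shift left while preceding read base equals last inserted base
        while (split > 0 && refgap > best.pos &&
               rd[split - 1] == rd[split + best.gap_len - 1] &&
               rs[refgap - 1] == rd[split - 1]) { --refgap; --split; }
        gpos[i] = refgap;
        gseq[i] = rd.substr(split, best.gap_len);
      }
    } else {
      mapped[i] = false; nties[i] = nbest;
      chrom[i] = NA_INTEGER; pos[i] = NA_INTEGER; fwd[i] = NA_LOGICAL; mm[i] = NA_INTEGER;
      gtype[i] = NA_INTEGER; glen[i] = NA_INTEGER; gpos[i] = NA_INTEGER; gseq[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["mapped"] = mapped, _["chrom_id"] = chrom, _["pos"] = pos,
                           _["fwd"] = fwd, _["mm"] = mm, _["gap_type"] = gtype,
                           _["gap_len"] = glen, _["gap_pos"] = gpos, _["gap_seq"] = gseq,
                           _["nties"] = nties);
}

// stranded base pileup: 8 x len matrix per chromosome (A,C,G,T fwd then A,C,G,T rev)
// [[Rcpp::export]]
List cpp_pileup(CharacterVector ref_seqs, IntegerVector chrom_id, IntegerVector pos,
                LogicalVector fwd, CharacterVector read_seqs) {
  int nchrom = ref_seqs.size();
  std::vector<int> lens(nchrom);
  List out(nchrom);
  std::vector<IntegerMatrix> mats;
  for (int c = 0; c < nchrom; ++c) {
    lens[c] = (int)std::string(ref_seqs[c]).size();
    IntegerMatrix m(8, lens[c]);
    mats.push_back(m);
  }
  int n = chrom_id.size();
  for (int i = 0; i < n; ++i) {
    if (chrom_id[i] == NA_INTEGER) continue;
    int c = chrom_id[i] - 1, p = pos[i];
    bool f = fwd[i];
    std::string rd = as<std::string>(read_seqs[i]);
    if (!f) rd = revcomp(rd);
    IntegerMatrix &m = mats[c];
    int L = (int)rd.size();
    for (int j = 0; j < L; ++j) {
      int b = base2bit(rd[j]);
      if (b < 0) continue;
      int q = p + j;
      if (q < 0 || q >= lens[c]) continue;
      m(b + (f ? 0 : 4), q)++;
    }
  }
  for (int c = 0; c < nchrom; ++c) out[c] = mats[c];
  return out;
}

// per-target fraction of positions covered by any k-mer shared with db
// [[Rcpp::export]]
NumericVector cpp_kmer_coverage(CharacterVector targets, CharacterVector db, int k) {
  std::unordered_set<uint64_t> kmers;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int d = 0; d < db.size(); ++d) {
    std::string s = as<std::string>(db[d]);
    for (int strand = 0; strand < 2; ++strand) {
      if (strand == 1) s = revcomp(s);
      uint64_t kmer = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | uint64_t(b)) & mask;
        if (++run >= k) kmers.insert(kmer);
      }
    }
  }
  int n = targets.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    std::string s = as<std::string>(targets[t]);
    int L = (int)s.size();
    if (L < k) { out[t] = 0.0; continue; }
    long covered = 0;
    int cov_until = -1; // highest position (exclusive) already counted
    uint64_t kmer = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | uint64_t(b)) & mask;
      if (++run >= k && kmers.count(kmer)) {
        int lo = i - k + 1, hi = i + 1;
        if (lo < cov_until) lo = cov_until;
        if (hi > lo) covered += hi - lo;
        if (hi > cov_until) cov_until = hi;
      }
    }
    out[t] = L > 0 ? (double)covered / (double)L : 0.0;
  }
  return out;
}

// substitution error injection at fixed positions (1-based), deterministic given inputs
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector reads, IntegerVector read_idx,
                                 IntegerVector pos, IntegerVector offset) {
  // offset in 1..3 selects replacement among the 3 non-matching bases
  std::vector<std::string> rs(reads.size());
  for (int i = 0; i < reads.size(); ++i) rs[i] = as<std::string>(reads[i]);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int e = 0; e < read_idx.size(); ++e) {
    int ri = read_idx[e] - 1, p = pos[e] - 1;
    if (ri < 0 || ri >= (int)rs.size()) continue;
    std::string &r = rs[ri];
    if (p < 0 || p >= (int)r.size()) continue;
    int cur = base2bit(r[p]);
    if (cur < 0) cur = 0;
    r[p] = bases[(cur + offset[e]) % 4];
  }
  return wrap(rs);
}
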