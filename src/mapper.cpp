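// Seed-and-extend paired-end mapper core.
//
// Semantics: exact k-mer seeds on both strands, candidates extended by a
// free-end-in-reference / global-on-read ("glocal") alignment under the
// score scheme (match +1, mismatch -2, indel -3).  All co-optimal
// placements are enumerated; records failing the length-fraction or
// similarity-fraction filters are discarded.  References are circular:
// k-mers spanning the origin are indexed via a k-1 base wraparound and
// extension windows are fetched with modular arithmetic.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

struct RefIndex {
  std::vector<std::string> names;
  std::vector<std::string> seqs;   // forward strand, length L each
  int k;
  // packed 2-bit k-mer -> packed (replicon << 40 | pos) occurrence list
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// encode k-mer starting at i in s (s must have >= i + k chars); false if non-ACGT
static bool encode_kmer(const std::string& s, size_t i, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int c = base2code(s[i + j]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  RefIndex* idx = new RefIndex();
  idx->k = k;
  for (int r = 0; r < names.size(); ++r) {
    std::string nm = as<std::string>(names[r]);
    std::string sq = as<std::string>(seqs[r]);
    idx->names.push_back(nm);
    idx->seqs.push_back(sq);
    size_t L = sq.size();
    if ((int)L < k) continue;  // caller warns
    // circular: append first k-1 bases so origin-spanning k-mers are indexed
    std::string ext = sq + sq.substr(0, (size_t)(k - 1));
    for (size_t p = 0; p < L; ++p) {
      uint64_t code;
      if (!encode_kmer(ext, p, k, code)) continue;
      idx->table[code].push_back(((uint64_t)r << 40) | (uint64_t)p);
    }
  }
  XPtr<RefIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<RefIndex> idx(xp);
  size_t total = 0;
  std::vector<double> per(idx->names.size(), 0.0);
  for (auto& kv : idx->table) {
    total += kv.second.size();
    for (uint64_t e : kv.second) per[(size_t)(e >> 40)] += 1.0;
  }
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = (double)idx->table.size(),
                      _["n_positions"] = (double)total,
                      _["positions_per_replicon"] = wrap(per),
                      _["replicon"] = wrap(idx->names));
}

// [[Rcpp::export(name = ".cpp_kmer_positions")]]
DataFrame cpp_kmer_positions(SEXP xp, std::string kmer) {
  XPtr<RefIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
  uint64_t code;
  std::vector<int> reps; std::vector<double> poss;
  if (encode_kmer(kmer, 0, idx->k, code)) {
    auto it = idx->table.find(code);
    if (it != idx->table.end()) {
      for (uint64_t e : it->second) {
        reps.push_back((int)(e >> 40) + 1);
        poss.push_back((double)(e & 0xFFFFFFFFFFull));
      }
    }
  }
  return DataFrame::create(_["replicon_index"] = reps, _["pos"] = poss);
}

struct Placement {
  int rep;        // replicon index
  char strand;    // '+' or '-'
  long start;     // 0-based on forward strand, in [0, L)
  long end;       // start + ref span (may exceed L when wrapping)
  int score;
  int matches;
  int cols;       // aligned columns (M + I + D)
  std::string cigar;  // on forward reference strand
};

// glocal alignment: read must align end-to-end, reference window has free
// ends.  Returns all co-optimal placements within the window (deduped by
// start offset).  win is the reference window on the forward strand;
// rd is the read already oriented to the forward reference strand.
static void align_window(const std::string& rd, const std::string& win,
                         int match, int mism, int indel,
                         std::vector<int>& opt_start, std::vector<int>& opt_end,
                         std::vector<int>& opt_matches, std::vector<int>& opt_cols,
                         std::vector<std::string>& opt_cigar, int& best_score) {
  const int m = (int)rd.size(), w = (int)win.size();
  // dp[(i)*(w+1)+j]; moves: 1=diag, 2=up (gap in ref, consumes read), 3=left
  std::vector<int> dp((size_t)(m + 1) * (w + 1));
  std::vector<uint8_t> mv((size_t)(m + 1) * (w + 1), 0);
  const int NEG = -1000000000;
  for (int j = 0; j <= w; ++j) dp[j] = 0;           // free ref start
  for (int i = 1; i <= m; ++i) {
    dp[(size_t)i * (w + 1)] = -indel * i;           // read overhangs window start
    mv[(size_t)i * (w + 1)] = 2;
    for (int j = 1; j <= w; ++j) {
      int cr = base2code(rd[i - 1]), cw = base2code(win[j - 1]);
      bool is_m = (cr >= 0 && cr == cw);
      int sdiag = dp[(size_t)(i - 1) * (w + 1) + (j - 1)] + (is_m ? match : -mism);
      int sup   = dp[(size_t)(i - 1) * (w + 1) + j] - indel;
      int sleft = dp[(size_t)i * (w + 1) + (j - 1)] - indel;
      int best = sdiag; uint8_t bm = 1;
      if (sup > best)   { best = sup;   bm = 2; }
      if (sleft > best) { best = sleft; bm = 3; }
      if (best < NEG) best = NEG;
      dp[(size_t)i * (w + 1) + j] = best;
      mv[(size_t)i * (w + 1) + j] = bm;
    }
  }
  best_score = NEG;
  for (int j = 0; j <= w; ++j)
    best_score = std::max(best_score, dp[(size_t)m * (w + 1) + j]);
  opt_start.clear(); opt_end.clear(); opt_matches.clear(); opt_cols.clear(); opt_cigar.clear();
  for (int j = 0; j <= w; ++j) {
    if (dp[(size_t)m * (w + 1) + j] != best_score) continue;
    // traceback
    int i = m, jj = j, matches = 0, cols = 0;
    std::string ops;  // reversed op chars
    while (i > 0) {
      uint8_t bm = mv[(size_t)i * (w + 1) + jj];
      if (bm == 1) {
        int cr = base2code(rd[i - 1]), cw = base2code(win[jj - 1]);
        if (cr >= 0 && cr == cw) ++matches;
        ops.push_back('M'); --i; --jj; ++cols;
      } else if (bm == 2) {
        ops.push_back('I'); --i; ++cols;
      } else if (bm == 3 && jj > 0) {
        // a leading run of left moves at i==0 would be free ref, but i>0 here
        ops.push_back('D'); --jj; ++cols;
      } else {
        break;
      }
    }
    int jstart = jj;                       // window offset where alignment begins
    // run-length encode CIGAR (ops is reversed -> reverse first)
    std::reverse(ops.begin(), ops.end());
    std::string cig;
    for (size_t t = 0; t < ops.size();) {
      size_t u = t;
      while (u < ops.size() && ops[u] == ops[t]) ++u;
      cig += std::to_string(u - t); cig.push_back(ops[t]);
      t = u;
    }
    // dedupe by start offset
    bool seen = false;
    for (size_t q = 0; q < opt_start.size(); ++q)
      if (opt_start[q] == jstart && opt_end[q] == j) { seen = true; break; }
    if (seen) continue;
    opt_start.push_back(jstart); opt_end.push_back(j);
    opt_matches.push_back(matches); opt_cols.push_back(cols);
    opt_cigar.push_back(cig);
  }
}

// map a single read; results appended to vectors
static void map_one(const RefIndex& idx, const std::string& read,
                    int match, int mism, int indel,
                    double length_fraction, double similarity_fraction,
                    int max_hits, int band,
                    std::vector<Placement>& out, int& n_cooptimal) {
  const int k = idx.k;
  const int m = (int)read.size();
  n_cooptimal = 0;
  if (m < k) return;
  std::string rc = revcomp(read);
  // candidate anchor starts: (rep, strand, start mod L)
  struct Cand { int rep; char strand; long start; };
  std::vector<Cand> cands;
  auto collect = [&](const std::string& s, char strand) {
    for (int q = 0; q + k <= m; ++q) {
      uint64_t code;
      if (!encode_kmer(s, (size_t)q, k, code)) continue;
      auto it = idx.table.find(code);
      if (it == idx.table.end()) continue;
      for (uint64_t e : it->second) {
        int rep = (int)(e >> 40);
        long p = (long)(e & 0xFFFFFFFFFFull);
        long L = (long)idx.seqs[rep].size();
        if (L < m) continue;
        long st = ((p - q) % L + L) % L;
        cands.push_back({rep, strand, st});
      }
    }
  };
  collect(read, '+');
  collect(rc, '-');
  // dedupe candidates
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.rep != b.rep) return a.rep < b.rep;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.start < b.start;
  });
  cands.erase(std::unique(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    return a.rep == b.rep && a.strand == b.strand && a.start == b.start;
  }), cands.end());
  // merge near-identical anchors (within band): keep representative per group
  std::vector<Cand> merged;
  for (const auto& c : cands) {
    if (!merged.empty() && merged.back().rep == c.rep &&
        merged.back().strand == c.strand &&
        c.start - merged.back().start <= band / 2) continue;
    merged.push_back(c);
  }
  if (merged.size() > 512) merged.resize(512);  // safety cap at desk scale

  std::vector<Placement> placements;
  int global_best = -1000000000;
  for (const auto& c : merged) {
    const std::string& ref = idx.seqs[c.rep];
    long L = (long)ref.size();
    long w = (long)m + 2L * band;
    long off = c.start - band;
    std::string win((size_t)w, 'N');
    for (long t = 0; t < w; ++t)
      win[(size_t)t] = ref[(size_t)(((off + t) % L + L) % L)];
    const std::string& rd = (c.strand == '+') ? read : rc;
    std::vector<int> js, je, mt, cl; std::vector<std::string> cg; int sc;
    align_window(rd, win, match, mism, indel, js, je, mt, cl, cg, sc);
    for (size_t q = 0; q < js.size(); ++q) {
      Placement pl;
      pl.rep = c.rep; pl.strand = c.strand;
      long gstart = ((off + js[q]) % L + L) % L;
      pl.start = gstart;
      pl.end = gstart + (je[q] - js[q]);
      pl.score = sc; pl.matches = mt[q]; pl.cols = cl[q]; pl.cigar = cg[q];
      placements.push_back(pl);
    }
    if (sc > global_best) global_best = sc;
  }
  // co-optimal set, deduped by (rep, strand, start, end)
  std::vector<Placement> co;
  for (const auto& pl : placements) {
    if (pl.score != global_best) continue;
    bool seen = false;
    for (const auto& x : co)
      if (x.rep == pl.rep && x.strand == pl.strand && x.start == pl.start && x.end == pl.end) {
        seen = true; break;
      }
    if (!seen) co.push_back(pl);
  }
  // filters
  std::vector<Placement> kept;
  for (const auto& pl : co) {
    double af = 1.0;  // end-to-end on the read
    double id = pl.cols > 0 ? (double)pl.matches / pl.cols : 0.0;
    if (af < length_fraction) continue;
    if (id < similarity_fraction) continue;
    kept.push_back(pl);
  }
  n_cooptimal = (int)kept.size();
  std::sort(kept.begin(), kept.end(), [](const Placement& a, const Placement& b) {
    if (a.rep != b.rep) return a.rep < b.rep;
    if (a.start != b.start) return a.start < b.start;
    return a.strand < b.strand;
  });
  if ((int)kept.size() > max_hits) kept.resize(max_hits);
  for (auto& pl : kept) out.push_back(pl);
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
List cpp_map_reads(SEXP xp, CharacterVector reads,
                   int match, int mismatch_cost, int indel_cost,
                   double length_fraction, double similarity_fraction,
                   int max_hits, int band) {
  XPtr<RefIndex> idx(xp);
  std::vector<int> read_idx, rep, score, matches, cols, n_hits;
  std::vector<double> start, end;
  std::vector<std::string> strand, cigar;
  for (int i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<Placement> out;
    int nco = 0;
    map_one(*idx, rd, match, mismatch_cost, indel_cost,
            length_fraction, similarity_fraction, max_hits, band, out, nco);
    for (const auto& pl : out) {
      read_idx.push_back(i + 1);
      rep.push_back(pl.rep + 1);
      start.push_back((double)pl.start);
      end.push_back((double)pl.end);
      strand.push_back(std::string(1, pl.strand));
      score.push_back(pl.score);
      matches.push_back(pl.matches);
      cols.push_back(pl.cols);
      cigar.push_back(pl.cigar);
      n_hits.push_back(nco);
    }
  }
  return List::create(
    _["read_index"] = wrap(read_idx), _["replicon_index"] = wrap(rep),
    _["start"] = wrap(start), _["end"] = wrap(end), _["strand"] = wrap(strand),
    _["score"] = wrap(score), _["matches"] = wrap(matches),
    _["aligned_cols"] = wrap(cols), _["cigar"] = wrap(cigar),
    _["n_hits"] = wrap(n_hits));
}
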