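#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
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

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// canonical form: lexicographic min of k-mer and its reverse complement
static inline std::string canonical(const std::string& kmer) {
  std::string rc = revcomp_str(kmer);
  return (rc < kmer) ? rc : kmer;
}

static void collect_canonical(const std::string& seq, int k,
                              std::unordered_set<std::string>& out) {
  int n = (int)seq.size();
  for (int i = 0; i + k <= n; ++i) {
    bool ok = true;
    for (int j = i; j < i + k; ++j) {
      char c = seq[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (!ok) continue;
    out.insert(canonical(seq.substr(i, k)));
  }
}

// [[Rcpp::export]]
CharacterVector canonical_kmers_cpp(std::string seq, int k,
                                    bool unique_only = true) {
  if (unique_only) {
    std::unordered_set<std::string> set;
    collect_canonical(seq, k, set);
    std::vector<std::string> v(set.begin(), set.end());
    std::sort(v.begin(), v.end());
    return wrap(v);
  }
  std::vector<std::string> v;
  int n = (int)seq.size();
  for (int i = 0; i + k <= n; ++i) {
    std::string kmer = seq.substr(i, k);
    if (kmer.find_first_not_of("ACGT") != std::string::npos) continue;
    v.push_back(canonical(kmer));
  }
  return wrap(v);
}

// longest run (bp) of alternating A/T (AT-dinucleotide tandem repeat)
// [[Rcpp::export]]
int longest_at_run_cpp(std::string seq) {
  int best = 0, cur = 0;
  char prev = 0;
  for (char c : seq) {
    bool at = (c == 'A' || c == 'T');
    if (at && (cur == 0 || c != prev)) {
      ++cur;
    } else if (at) {          // same base twice: restart run at this base
      cur = 1;
    } else {
      cur = 0;
    }
    prev = at ? c : 0;
    if (cur > best) best = cur;
  }
  return best;
}

// Per-pair shared canonical k-mer counts against an indexed marker set.
// keys/key_markers flatten a kmer_index; counts are distinct shared keys.
// [[Rcpp::export]]
IntegerMatrix enrich_counts_cpp(CharacterVector seq1, CharacterVector seq2,
                                CharacterVector keys, List key_markers,
                                int n_markers, int k) {
  int nk = keys.size();
  std::unordered_map<std::string, int> lut;
  lut.reserve(nk * 2);
  std::vector<std::vector<int>> km(nk);
  for (int i = 0; i < nk; ++i) {
    lut[as<std::string>(keys[i])] = i;
    IntegerVector m = key_markers[i];
    km[i] = std::vector<int>(m.begin(), m.end());
  }
  int n = seq1.size();
  IntegerMatrix counts(n, n_markers);
  std::unordered_set<std::string> pair_kmers;
  for (int i = 0; i < n; ++i) {
    pair_kmers.clear();
    collect_canonical(as<std::string>(seq1[i]), k, pair_kmers);
    collect_canonical(as<std::string>(seq2[i]), k, pair_kmers);
    for (const auto& kmer : pair_kmers) {
      auto it = lut.find(kmer);
      if (it == lut.end()) continue;
      for (int m : km[it->second]) counts(i, m - 1) += 1;  // 1-based from R
    }
  }
  return counts;
}

// 3' trim: number of leading bases to keep so that the trailing run of
// bases with quality < min_q (Phred+33) is removed
// [[Rcpp::export]]
IntegerVector quality_keep_length_cpp(CharacterVector qual, int min_q) {
  int n = qual.size();
  IntegerVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(qual[i]);
    int end = (int)q.size();
    while (end > 0 && (int)q[end - 1] - 33 < min_q) --end;
    keep[i] = end;
  }
  return keep;
}

// substitution errors at a fixed per-base rate; uses the R RNG
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& c : s) {
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') continue;
      if (unif_rand() < rate) {
        char nb;
        do { nb = bases[(int)(unif_rand() * 4.0) & 3]; } while (nb == c);
        c = nb;
      }
    }
    out[i] = s;
  }
  return out;
}

// approximate AT-dinucleotide tandem repeat detector: TRUE when some window
// of `run_len` bp contains at most `max_defects` defects, where a defect is
// a non-A/T base or a broken alternation. Robust to sequencing errors
// inside the repeat (an exact-run test is not).
// [[Rcpp::export]]
bool has_at_repeat_cpp(std::string seq, int run_len, int max_defects) {
  int n = (int)seq.size();
  if (n < run_len) return false;
  std::vector<int> defect(n, 0);
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'T') { defect[i] = 1; continue; }
    if (i > 0 && seq[i - 1] == c) defect[i] = 1;  // AA / TT breaks phase
  }
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    cur += defect[i];
    if (i >= run_len) cur -= defect[i - run_len];
    if (i >= run_len - 1 && cur <= max_defects) return true;
  }
  return false;
}

// Banded global alignment (match +1, mismatch -1, linear gap -2) of a
// candidate against each parent; returns, per parent, the match indicator
// over candidate positions (candidate-gap columns skipped). Used by the
// chimera screen, where parents are same-locus sequences of similar length.
// [[Rcpp::export]]
List chimera_match_profiles_cpp(std::string cand, CharacterVector parents) {
  const double MATCH = 1.0, MISMATCH = -1.0, GAP = -2.0;
  int m = (int)cand.size();
  List out(parents.size());
  for (int pi = 0; pi < parents.size(); ++pi) {
    std::string par = as<std::string>(parents[pi]);
    int n = (int)par.size();
    int band = std::max(32, std::abs(m - n) + 16);
    const double NEG = -1e9;
    // dp[i][j] over band: j in [i - band, i + band]
    int W = 2 * band + 1;
    std::vector<double> prev(W, NEG), cur(W, NEG);
    std::vector<std::vector<signed char>> bt(m + 1,
        std::vector<signed char>(W, 0)); // 0 diag, 1 up(cand gap? ), 2 left
    // row 0
    for (int j = 0; j <= std::min(n, band); ++j) {
      prev[j - 0 + band] = GAP * j;
      // bt[0][j + band] = 2;
    }
    for (int i = 1; i <= m; ++i) {
      std::fill(cur.begin(), cur.end(), NEG);
      int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
      for (int j = jlo; j <= jhi; ++j) {
        int o = j - i + band;
        double best = NEG; signed char dir = 0;
        if (j > 0 && prev[o] > NEG / 2) {          // diag (i-1, j-1)
          double d = prev[o] +
            (cand[i - 1] == par[j - 1] ? MATCH : MISMATCH);
          if (d > best) { best = d; dir = 0; }
        }
        if (o + 1 < W && prev[o + 1] > NEG / 2) {  // up (i-1, j): cand vs gap
          double d = prev[o + 1] + GAP;
          if (d > best) { best = d; dir = 1; }
        }
        if (j > 0 && o - 1 >= 0 && cur[o - 1] > NEG / 2) {  // left (i, j-1)
          double d = cur[o - 1] + GAP;
          if (d > best) { best = d; dir = 2; }
        }
        cur[o] = best; bt[i][o] = dir;
      }
      std::swap(prev, cur);
    }
    // traceback from (m, n)
    LogicalVector prof(m);
    int i = m, j = n;
    while (i > 0 || j > 0) {
      int o = j - i + band;
      signed char dir = (o >= 0 && o < W) ? bt[i][o] : (i > 0 ? 1 : 2);
      if (i > 0 && j > 0 && dir == 0) {
        prof[i - 1] = (cand[i - 1] == par[j - 1]);
        --i; --j;
      } else if (i > 0 && (dir == 1 || j == 0)) {
        prof[i - 1] = false;
        --i;
      } else {
        --j;
      }
    }
    out[pi] = prof;
  }
  return out;
}

// best PWM hit: lo is a 4 x w log-odds matrix (rows A,C,G,T); returns
// c(score, start) with 1-based start, or c(-Inf, NA) when seq shorter than w
// [[Rcpp::export]]
NumericVector pwm_best_hit_cpp(std::string seq, NumericMatrix lo) {
  int w = lo.ncol(), L = (int)seq.size();
  if (L < w)
    return NumericVector::create(R_NegInf, NA_REAL);
  auto row_of = [](char c) {
    switch (c) {
      case 'A': return 0;
      case 'C': return 1;
      case 'G': return 2;
      case 'T': return 3;
      default:  return -1;
    }
  };
  double best = R_NegInf; int at = 1;
  for (int s = 0; s + w <= L; ++s) {
    double sc = 0;
    for (int j = 0; j < w; ++j) {
      int r = row_of(seq[s + j]);
      if (r >= 0) sc += lo(r, j);
    }
    if (sc > best) { best = sc; at = s + 1; }
  }
  return NumericVector::create(best, (double)at);
}

// containment flags for exact de-duplication: seqs must be sorted by
// descending length (ties broken upstream); out[i] = TRUE when seqs[i] is an
// exact substring (either strand) of an earlier kept sequence
// [[Rcpp::export]]
LogicalVector contained_in_earlier_cpp(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  LogicalVector contained(n);
  std::vector<int> kept;
  for (int i = 0; i < n; ++i) {
    std::string rcs = revcomp_str(s[i]);
    bool hit = false;
    for (int k : kept) {
      if (s[k].find(s[i]) != std::string::npos ||
          s[k].find(rcs) != std::string::npos) { hit = true; break; }
    }
    contained[i] = hit;
    if (!hit) kept.push_back(i);
  }
  return contained;
}

// ---------------------------------------------------------------------------
// seed-and-extend ungapped read mapping against short representatives
// ---------------------------------------------------------------------------

struct Hit { int ref; int start; int len; int mm; };

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector refs, int seed_k,
                   int max_mismatch, bool mode_all, int min_aligned) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  for (int r = 0; r < nref; ++r) {
    R[r] = as<std::string>(refs[r]);
    int L = (int)R[r].size();
    for (int p = 0; p + seed_k <= L; ++p)
      idx[R[r].substr(p, seed_k)].push_back({r, p});
  }
  std::vector<std::vector<int>> depth(nref);
  for (int r = 0; r < nref; ++r) depth[r].assign(R[r].size(), 0);

  int n = reads.size();
  LogicalVector mapped(n);
  List assigned(n);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rc = revcomp_str(fwd);
    int L = (int)fwd.size();
    int best_mm = max_mismatch + 1;
    std::vector<Hit> best;            // best hits, at most one per ref
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rd = ori ? rc : fwd;
      if (L < seed_k) break;
      int offs[3] = {0, (L - seed_k) / 2, L - seed_k};
      std::unordered_set<long long> seen;  // (ref, diag) pairs already scored
      for (int oi = 0; oi < 3; ++oi) {
        auto it = idx.find(rd.substr(offs[oi], seed_k));
        if (it == idx.end()) continue;
        for (auto& cand : it->second) {
          int ref = cand.first;
          int diag = cand.second - offs[oi];  // ref position of read base 0
          long long key = ((long long)ref << 32) ^ (long long)(diag + 100000) ^
                          ((long long)ori << 60);
          if (!seen.insert(key).second) continue;
          int rl = (int)R[ref].size();
          int a = std::max(0, -diag);          // read coords
          int b = std::min(L, rl - diag);
          if (b - a < min_aligned) continue;
          int mm = 0;
          for (int p = a; p < b && mm <= max_mismatch; ++p)
            if (rd[p] != R[ref][p + diag]) ++mm;
          if (mm > max_mismatch) continue;
          Hit h = {ref, a + diag, b - a, mm};
          if (mm < best_mm) { best_mm = mm; best.clear(); best.push_back(h); }
          else if (mm == best_mm) {
            bool dup = false;
            for (auto& e : best)
              if (e.ref == ref) { dup = true; if (h.len > e.len) e = h; }
            if (!dup) best.push_back(h);
          }
        }
      }
    }
    if (best.empty()) { assigned[i] = IntegerVector(0); continue; }
    mapped[i] = true;
    std::vector<Hit> placed;
    if (mode_all || best.size() == 1) {
      placed = best;
    } else {
      int pick = (int)(unif_rand() * best.size());
      if (pick >= (int)best.size()) pick = (int)best.size() - 1;
      placed.push_back(best[pick]);
    }
    IntegerVector arefs(placed.size());
    for (size_t j = 0; j < placed.size(); ++j) {
      arefs[j] = placed[j].ref + 1;
      for (int p = placed[j].start; p < placed[j].start + placed[j].len; ++p)
        depth[placed[j].ref][p] += 1;
    }
    assigned[i] = arefs;
  }

  List dl(nref);
  for (int r = 0; r < nref; ++r) dl[r] = wrap(depth[r]);
  return List::create(_["depth"] = dl, _["mapped"] = mapped,
                      _["assigned"] = assigned);
}
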