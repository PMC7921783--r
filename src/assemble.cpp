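#include <Rcpp.h>
#include <unordered_map>
#include <array>
using namespace Rcpp;

// shared helpers (defined in core.cpp)
int longest_at_run_cpp(std::string seq);
bool has_at_repeat_cpp(std::string seq, int run_len, int max_defects);

static inline char cbase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}
static inline std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = cbase(c);
  return r;
}

struct Placement { int read; int orient; int start; };
struct RAnchor { int read; int orient; int off; };

// Greedy overlap-layout-consensus assembly of short barcode loci.
//
// Reads must arrive sorted lexicographically by id (the deterministic
// seeding order). Extension joins the unused read with the longest prefix
// overlap (>= min_overlap, mismatch rate <= max_mm_rate), anchored on exact
// anchor_w-mers; after each extension pass the supporting reads are
// re-recruited and the contig replaced by the per-column majority
// consensus, which repairs single-coverage errors at the growing tip and
// lets extension continue (iterated to a fixed point). Reads containing an
// alternating-AT tandem run of >= at_abort bp are withheld entirely, and
// overlaps that consist almost entirely of AT-dinucleotide repeat are
// rejected (their placement is ambiguous), so contigs cannot extend across
// such repeats. Consensus ties resolve to the earliest supporting read.
// [[Rcpp::export]]
List assemble_greedy_cpp(CharacterVector reads, int min_overlap,
                         double max_mm_rate, int anchor_w, int min_len,
                         int min_support, int at_abort, int max_contig_len) {
  int n = reads.size();
  std::vector<std::string> fwd(n), rc(n);
  std::vector<bool> used(n, false), excluded(n, false);
  int max_rl = 0;
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads[i]);
    rc[i] = rc_str(fwd[i]);
    if ((int)fwd[i].size() > max_rl) max_rl = (int)fwd[i].size();
    if (at_abort > 0 && has_at_repeat_cpp(fwd[i], at_abort, 2))
      excluded[i] = true;
  }

  // prefix anchors (first anchor_w bases of each oriented read) drive
  // extension; recruit anchors (w-mers at offsets 0, w, 2w) drive pileup
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> pref;
  std::unordered_map<std::string, std::vector<RAnchor>> recruit;
  for (int i = 0; i < n; ++i) {
    if (excluded[i]) continue;
    if ((int)fwd[i].size() < anchor_w) continue;
    pref[fwd[i].substr(0, anchor_w)].push_back({i, 0});
    pref[rc[i].substr(0, anchor_w)].push_back({i, 1});
    for (int orient = 0; orient < 2; ++orient) {
      const std::string& rd = orient ? rc[i] : fwd[i];
      for (int off = 0; off <= 2 * anchor_w && off + anchor_w <= (int)rd.size();
           off += anchor_w)
        recruit[rd.substr(off, anchor_w)].push_back({i, orient, off});
    }
  }

  std::vector<int> mine_gen(n, -1);  // contig currently owning each read
  int gen = -1;

  auto mismatches_le = [&](const std::string& a, int ap, const std::string& b,
                           int bp, int len, int cap) {
    int mm = 0;
    for (int j = 0; j < len; ++j) {
      if (a[ap + j] != b[bp + j] && ++mm > cap) return -1;
    }
    return mm;
  };

  auto extend_right = [&](std::string& contig) {
    bool grew = false;
    for (;;) {
      int L = (int)contig.size();
      if (L >= max_contig_len) break;
      bool step = false;
      int p0 = std::max(0, L - max_rl);
      for (int p = p0; p <= L - min_overlap && !step; ++p) {
        if (p + anchor_w > L) break;
        auto it = pref.find(contig.substr(p, anchor_w));
        if (it == pref.end()) continue;
        int ov = L - p;
        for (auto& cand : it->second) {
          int i = cand.first;
          if (used[i]) continue;
          const std::string& rd = cand.second ? rc[i] : fwd[i];
          if ((int)rd.size() <= ov) continue;  // must extend past the end
          int cap = (int)std::floor(max_mm_rate * ov);
          if (mismatches_le(contig, p, rd, 0, ov, cap) < 0) continue;
          if (at_abort > 0 &&
              longest_at_run_cpp(contig.substr(p, ov)) >= ov - 5)
            continue;  // overlap ambiguous inside an AT repeat
          contig += rd.substr(ov);
          used[i] = true;
          mine_gen[i] = gen;
          step = true;
          grew = true;
          break;
        }
      }
      if (!step) break;
    }
    return grew;
  };

  // place every available read that fits inside the contig
  auto place_reads = [&](const std::string& contig,
                         std::vector<Placement>& placed) {
    placed.clear();
    int L = (int)contig.size();
    std::unordered_map<int, char> seen;
    for (int p = 0; p + anchor_w <= L; ++p) {
      auto it = recruit.find(contig.substr(p, anchor_w));
      if (it == recruit.end()) continue;
      for (auto& ra : it->second) {
        int i = ra.read;
        if (excluded[i]) continue;
        if (used[i] && mine_gen[i] != gen) continue;
        if (seen.count(i)) continue;
        int rl = (int)fwd[i].size();
        int start = p - ra.off;
        if (start < 0 || start + rl > L) continue;
        const std::string& rd = ra.orient ? rc[i] : fwd[i];
        int cap = (int)std::floor(max_mm_rate * rl);
        if (mismatches_le(contig, start, rd, 0, rl, cap) < 0) continue;
        seen[i] = 1;
        placed.push_back({i, ra.orient, start});
      }
    }
    std::sort(placed.begin(), placed.end(),
              [](const Placement& a, const Placement& b) {
                return a.read < b.read;
              });
  };

  static const std::string alph = "ACGTN";
  int n_variant = 0;
  auto consensus_of = [&](const std::string& contig,
                          const std::vector<Placement>& placed) {
    int L = (int)contig.size();
    std::vector<std::array<int, 5>> counts(L, {0, 0, 0, 0, 0});
    for (auto& pl : placed) {
      const std::string& rd = pl.orient ? rc[pl.read] : fwd[pl.read];
      for (int j = 0; j < (int)rd.size(); ++j) {
        size_t b = alph.find(rd[j]);
        counts[pl.start + j][b == std::string::npos ? 4 : b] += 1;
      }
    }
    std::string cons(contig);
    n_variant = 0;
    for (int p = 0; p < L; ++p) {
      int tot = 0, mx = 0;
      for (int b = 0; b < 5; ++b) {
        tot += counts[p][b];
        if (counts[p][b] > mx) mx = counts[p][b];
      }
      if (tot == 0) continue;
      int ties = 0;
      for (int b = 0; b < 5; ++b) if (counts[p][b] == mx) ++ties;
      if (ties == 1) {
        for (int b = 0; b < 5; ++b) if (counts[p][b] == mx) cons[p] = alph[b];
      } else {
        for (auto& pl : placed) {
          const std::string& rd = pl.orient ? rc[pl.read] : fwd[pl.read];
          if (pl.start <= p && p < pl.start + (int)rd.size()) {
            size_t b = alph.find(rd[p - pl.start]);
            if (b != std::string::npos && counts[p][b] == mx) {
              cons[p] = rd[p - pl.start];
              break;
            }
          }
        }
      }
      if (tot >= 4 && (tot - mx) >= 0.3 * tot) ++n_variant;
    }
    return cons;
  };

  List out_seq, out_members;
  std::vector<int> out_support, out_variant;
  std::vector<bool> out_collapse;

  for (int seed = 0; seed < n; ++seed) {
    if (used[seed] || excluded[seed]) continue;
    ++gen;
    used[seed] = true;
    mine_gen[seed] = gen;
    std::string contig = fwd[seed];
    std::vector<Placement> placed;
    for (int iter = 0; iter < 40; ++iter) {
      bool g1 = extend_right(contig);
      contig = rc_str(contig);
      bool g2 = extend_right(contig);
      contig = rc_str(contig);
      place_reads(contig, placed);
      for (auto& pl : placed)
        if (!used[pl.read]) { used[pl.read] = true; mine_gen[pl.read] = gen; }
      std::string cons = consensus_of(contig, placed);
      bool changed = (cons != contig);
      contig = cons;
      if (!g1 && !g2 && !changed) break;
    }
    int L = (int)contig.size();
    if (L < min_len) continue;
    place_reads(contig, placed);
    std::string cons = consensus_of(contig, placed);
    if ((int)placed.size() < min_support) continue;

    IntegerVector members(placed.size());
    for (size_t j = 0; j < placed.size(); ++j) members[j] = placed[j].read + 1;
    out_seq.push_back(cons);
    out_members.push_back(members);
    out_support.push_back((int)placed.size());
    out_variant.push_back(n_variant);
    out_collapse.push_back(n_variant >= 2);
  }

  return List::create(_["sequence"] = out_seq, _["n_reads"] = wrap(out_support),
                      _["n_variant_cols"] = wrap(out_variant),
                      _["collapse_warning"] = wrap(out_collapse),
                      _["members"] = out_members);
}
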