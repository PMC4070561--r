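// Compiled kernels: banded affine local alignment (Gotoh) with traceback,
// exhaustive Smith-Waterman oracle, k-mer seeding and containment, the
// paired-read simulator and the vector/insert junction scanner.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <set>
#include <tuple>

using namespace Rcpp;

namespace {

const int NEG_INF = -1000000000;

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct AlnResult {
  int score = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;  // 1-based, 0 when empty
  int matches = 0, mismatches = 0, gap_openings = 0, columns = 0;
};

// Affine-gap local alignment restricted to diagonals d = j - i in [dlo, dhi].
// With dlo = -m, dhi = n this is full Smith-Waterman. A gap of length g costs
// gap_open + g * gap_ext (penalties passed as positive numbers).
AlnResult band_align(const std::string& q, const std::string& s,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int dlo, int dhi) {
  AlnResult res;
  const int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) return res;
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  if (dlo > dhi) return res;
  const int W = dhi - dlo + 1;

  std::vector<int> Hprev((size_t)W, 0), Hcur((size_t)W, NEG_INF);
  std::vector<int> Fprev((size_t)W, NEG_INF), Fcur((size_t)W, NEG_INF);
  std::vector<uint8_t> tb((size_t)m * W, 0);

  int best = 0, bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    const int jmin = std::max(1, i + dlo), jmax = std::min(n, i + dhi);
    const int qc = base_code(q[i - 1]);
    int Eval = NEG_INF;
    for (int j = jmin; j <= jmax; ++j) {
      const int off = j - (i + dlo);
      // E: gap consuming subject, same row
      int hleft;
      if (j - 1 == 0) hleft = 0;
      else if (off - 1 >= 0) hleft = Hcur[off - 1];
      else hleft = NEG_INF;
      const int Eopen = (hleft <= NEG_INF / 2) ? NEG_INF : hleft - gap_open - gap_ext;
      const int Eext  = (Eval  <= NEG_INF / 2) ? NEG_INF : Eval - gap_ext;
      int E; int ebit;
      if (Eext > Eopen) { E = Eext; ebit = 1; } else { E = Eopen; ebit = 0; }
      Eval = E;
      // F: gap consuming query, previous row same column
      int hup, fup;
      if (i - 1 == 0) { hup = 0; fup = NEG_INF; }
      else if (off + 1 < W) { hup = Hprev[off + 1]; fup = Fprev[off + 1]; }
      else { hup = NEG_INF; fup = NEG_INF; }
      const int Fopen = (hup <= NEG_INF / 2) ? NEG_INF : hup - gap_open - gap_ext;
      const int Fext  = (fup <= NEG_INF / 2) ? NEG_INF : fup - gap_ext;
      int F; int fbit;
      if (Fext > Fopen) { F = Fext; fbit = 1; } else { F = Fopen; fbit = 0; }
      Fcur[off] = F;
      // H
      int hd;
      if (j - 1 == 0 || i - 1 == 0) hd = 0;
      else hd = Hprev[off];
      const int sc = (qc >= 0 && qc == base_code(s[j - 1])) ? match : mismatch;
      const int diagv = (hd <= NEG_INF / 2) ? NEG_INF : hd + sc;
      int H = 0, origin = 0;
      if (diagv > H) { H = diagv; origin = 1; }
      if (E > H) { H = E; origin = 2; }
      if (F > H) { H = F; origin = 3; }
      Hcur[off] = H;
      tb[(size_t)(i - 1) * W + off] = (uint8_t)(origin | (ebit << 2) | (fbit << 3));
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0) return res;
  res.score = best;
  int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
  res.qend = bi; res.send = bj; res.qstart = bi; res.sstart = bj;
  while (i >= 1 && j >= 1) {
    const uint8_t t = tb[(size_t)(i - 1) * W + (j - (i + dlo))];
    if (state == 0) {
      const int origin = t & 3;
      if (origin == 0) break;
      if (origin == 1) {
        const int a = base_code(q[i - 1]), b = base_code(s[j - 1]);
        if (a >= 0 && a == b) res.matches++; else res.mismatches++;
        res.columns++;
        res.qstart = i; res.sstart = j;
        --i; --j;
      } else if (origin == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap column consuming subject base j
      res.columns++;
      res.sstart = j;
      const int ext = (t >> 2) & 1;
      --j;
      if (!ext) { res.gap_openings++; state = 0; }
    } else {  // gap column consuming query base i
      res.columns++;
      res.qstart = i;
      const int ext = (t >> 3) & 1;
      --i;
      if (!ext) { res.gap_openings++; state = 0; }
    }
  }
  return res;
}

inline List aln_to_list(const AlnResult& r) {
  return List::create(
    _["score"] = r.score, _["qstart"] = r.qstart, _["qend"] = r.qend,
    _["sstart"] = r.sstart, _["send"] = r.send,
    _["matches"] = r.matches, _["mismatches"] = r.mismatches,
    _["gap_openings"] = r.gap_openings, _["columns"] = r.columns,
    _["identity"] = r.columns > 0 ? 100.0 * r.matches / r.columns : NA_REAL);
}

struct KmerEntry { uint64_t code; int32_t sidx; int32_t pos; };

// Rolling 2-bit encoder; calls f(pos, code) for every valid k-mer start.
template <typename F>
void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int valid = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    const int c = base_code(s[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= k) f(i - k + 1, code);
  }
}

// Canonical (strand-symmetric) variant: f(pos, min(code, revcomp code)).
template <typename F>
void for_each_canonical_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0, rc = 0;
  const int shift = 2 * (k - 1);
  int valid = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    const int c = base_code(s[i]);
    if (c < 0) { valid = 0; code = 0; rc = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(i - k + 1, std::min(code, rc));
  }
}

}  // namespace

// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s, int match, int mismatch,
                  int gap_open, int gap_ext) {
  AlnResult r = band_align(q, s, match, mismatch, gap_open, gap_ext,
                           -(int)q.size(), (int)s.size());
  return aln_to_list(r);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export]]
std::string random_dna_cpp(int n) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(n, 'A');
  for (int i = 0; i < n; ++i) s[i] = bases[(int)(unif_rand() * 4) & 3];
  return s;
}

// Per-base substitution at `rate` using geometric skipping; substituted bases
// become a uniformly chosen different base.
// [[Rcpp::export]]
List mutate_seq_cpp(std::string seq, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n_sub = 0;
  std::vector<int> pos;
  if (rate > 0 && !seq.empty()) {
    const double log1mp = std::log1p(-rate);
    long i = -1;
    const long n = (long)seq.size();
    while (true) {
      const double u = unif_rand();
      i += (long)std::floor(std::log(u) / log1mp) + 1;
      if (i >= n) break;
      const int c = base_code(seq[i]);
      if (c >= 0) {
        int r = (int)(unif_rand() * 3);
        if (r > 2) r = 2;
        seq[i] = bases[(c + 1 + r) & 3];
        ++n_sub;
        pos.push_back((int)i + 1);
      }
    }
  }
  return List::create(_["seq"] = seq, _["n_sub"] = n_sub,
                      _["positions"] = wrap(pos));
}

// [[Rcpp::export]]
NumericVector kmer_index_cpp(CharacterVector seqs, int k) {
  std::vector<uint64_t> codes;
  for (int i = 0; i < seqs.size(); ++i) {
    const std::string s = as<std::string>(seqs[i]);
    for_each_canonical_kmer(s, k, [&](int, uint64_t code) { codes.push_back(code); });
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  NumericVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = (double)codes[i];
  return out;
}

// [[Rcpp::export]]
NumericVector kmer_containment_cpp(CharacterVector seqs, NumericVector index, int k) {
  std::vector<uint64_t> idx(index.size());
  for (int i = 0; i < index.size(); ++i) idx[i] = (uint64_t)index[i];
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    long total = 0, present = 0;
    for_each_canonical_kmer(s, k, [&](int, uint64_t code) {
      ++total;
      if (std::binary_search(idx.begin(), idx.end(), code)) ++present;
    });
    out[i] = total > 0 ? (double)present / (double)total : NA_REAL;
  }
  return out;
}

// Seed-and-extend local aligner. Exact k-mer seeds on both strands, seeds
// grouped per subject into diagonal bands (gap <= band_merge), chained along
// the query (gap <= chain_gap), and each cluster extended by banded DP in a
// window reaching `margin` bases past the outermost seeds with `band_pad`
// diagonals around the seed diagonals. Coordinates are reported 1-based;
// sstart > send encodes a minus-strand hit.
// [[Rcpp::export]]
DataFrame local_align_cpp(CharacterVector queries, CharacterVector subjects,
                          int k, double min_identity, int min_length,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int band_pad, int band_merge, int chain_gap,
                          int margin, int max_kmer_hits) {
  // subject k-mer index
  std::vector<KmerEntry> entries;
  std::vector<std::string> subj(subjects.size());
  for (int si = 0; si < subjects.size(); ++si) {
    subj[si] = as<std::string>(subjects[si]);
    for_each_kmer(subj[si], k, [&](int pos, uint64_t code) {
      entries.push_back(KmerEntry{code, si, pos});
    });
  }
  std::sort(entries.begin(), entries.end(),
            [](const KmerEntry& a, const KmerEntry& b) {
              return std::tie(a.code, a.sidx, a.pos) < std::tie(b.code, b.sidx, b.pos);
            });

  struct Hit {
    int qi, sidx, strand;
    double pident;
    int length, mismatches, gapopen;
    int qstart, qend, sstart, send, score, matches;
  };
  std::vector<Hit> hits;
  std::set<std::tuple<int,int,int,int,int,int,int>> seen;

  struct Seed { int sidx, d, qpos, spos; };

  for (int qi = 0; qi < queries.size(); ++qi) {
    const std::string qfwd = as<std::string>(queries[qi]);
    const int qlen = (int)qfwd.size();
    if (qlen < k) continue;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string qs = strand == 0 ? qfwd : revcomp_str(qfwd);
      std::vector<Seed> seeds;
      for_each_kmer(qs, k, [&](int qpos, uint64_t code) {
        KmerEntry key{code, 0, 0};
        auto lo = std::lower_bound(entries.begin(), entries.end(), key,
          [](const KmerEntry& a, const KmerEntry& b) { return a.code < b.code; });
        auto hi = std::upper_bound(entries.begin(), entries.end(), key,
          [](const KmerEntry& a, const KmerEntry& b) { return a.code < b.code; });
        if (hi - lo > max_kmer_hits) return;  // repetitive seed, skip
        for (auto it = lo; it != hi; ++it)
          seeds.push_back(Seed{it->sidx, it->pos - qpos, qpos, it->pos});
      });
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
        return std::tie(a.sidx, a.d, a.qpos) < std::tie(b.sidx, b.d, b.qpos);
      });
      size_t g0 = 0;
      while (g0 < seeds.size()) {
        size_t g1 = g0 + 1;
        while (g1 < seeds.size() && seeds[g1].sidx == seeds[g0].sidx &&
               seeds[g1].d - seeds[g1 - 1].d <= band_merge) ++g1;
        // diagonal band group [g0, g1); chain along query
        std::vector<Seed> grp(seeds.begin() + g0, seeds.begin() + g1);
        std::sort(grp.begin(), grp.end(), [](const Seed& a, const Seed& b) {
          return std::tie(a.qpos, a.d) < std::tie(b.qpos, b.d);
        });
        size_t c0 = 0;
        while (c0 < grp.size()) {
          size_t c1 = c0 + 1;
          while (c1 < grp.size() && grp[c1].qpos - grp[c1 - 1].qpos <= chain_gap) ++c1;
          int dmin = grp[c0].d, dmax = grp[c0].d;
          int qmin = grp[c0].qpos, qmax = grp[c0].qpos;
          int smin = grp[c0].spos, smax = grp[c0].spos;
          for (size_t t = c0; t < c1; ++t) {
            dmin = std::min(dmin, grp[t].d); dmax = std::max(dmax, grp[t].d);
            qmin = std::min(qmin, grp[t].qpos); qmax = std::max(qmax, grp[t].qpos);
            smin = std::min(smin, grp[t].spos); smax = std::max(smax, grp[t].spos);
          }
          const int sidx = grp[c0].sidx;
          const std::string& ss = subj[sidx];
          const int slen = (int)ss.size();
          const int q0 = std::max(0, qmin - margin);
          const int q1 = std::min(qlen, qmax + k + margin);
          const int s0 = std::max(0, smin - margin);
          const int s1 = std::min(slen, smax + k + margin);
          const int shiftd = s0 - q0;
          int dlo = dmin - band_pad - shiftd;
          int dhi = dmax + band_pad - shiftd;
          AlnResult r = band_align(qs.substr(q0, q1 - q0), ss.substr(s0, s1 - s0),
                                   match, mismatch, gap_open, gap_ext, dlo, dhi);
          c0 = c1;
          if (r.score <= 0 || r.columns < min_length) continue;
          const double pid = 100.0 * r.matches / r.columns;
          if (pid < min_identity) continue;
          int aq0 = q0 + r.qstart, aq1 = q0 + r.qend;       // on qs, 1-based
          const int as0 = s0 + r.sstart, as1 = s0 + r.send; // subject, 1-based
          int rq0, rq1, rs0, rs1;
          if (strand == 0) { rq0 = aq0; rq1 = aq1; rs0 = as0; rs1 = as1; }
          else { rq0 = qlen - aq1 + 1; rq1 = qlen - aq0 + 1; rs0 = as1; rs1 = as0; }
          auto key = std::make_tuple(qi, sidx, strand, rq0, rq1, rs0, rs1);
          if (!seen.insert(key).second) continue;
          hits.push_back(Hit{qi, sidx, strand, pid, r.columns, r.mismatches,
                             r.gap_openings, rq0, rq1, rs0, rs1, r.score, r.matches});
        }
        g0 = g1;
      }
    }
  }

  std::stable_sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    const int amin = std::min(a.sstart, a.send), bmin = std::min(b.sstart, b.send);
    return std::tie(a.qi, a.sidx, amin, a.qstart) <
           std::tie(b.qi, b.sidx, bmin, b.qstart);
  });

  const int nh = (int)hits.size();
  IntegerVector qidx(nh), sidx(nh), length(nh), mism(nh), gapo(nh),
      qstart(nh), qend(nh), sstart(nh), send(nh), score(nh), matches(nh);
  NumericVector pident(nh);
  for (int i = 0; i < nh; ++i) {
    const Hit& h = hits[i];
    qidx[i] = h.qi + 1; sidx[i] = h.sidx + 1; pident[i] = h.pident;
    length[i] = h.length; mism[i] = h.mismatches; gapo[i] = h.gapopen;
    qstart[i] = h.qstart; qend[i] = h.qend; sstart[i] = h.sstart;
    send[i] = h.send; score[i] = h.score; matches[i] = h.matches;
  }
  return DataFrame::create(
    _["qidx"] = qidx, _["sidx"] = sidx, _["pident"] = pident,
    _["length"] = length, _["mismatch"] = mism, _["gapopen"] = gapo,
    _["qstart"] = qstart, _["qend"] = qend, _["sstart"] = sstart,
    _["send"] = send, _["score"] = score, _["matches"] = matches,
    _["stringsAsFactors"] = false);
}

// Paired-read simulator. Fragments are drawn from `templates` with
// probability proportional to length; `circular` templates wrap. Uses the R
// RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List sim_reads_cpp(CharacterVector templates, bool circular, int n_pairs,
                   int read_len, double frag_mean, double frag_sd,
                   double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int nt = templates.size();
  std::vector<std::string> tpl(nt);
  std::vector<double> cum(nt);
  double total = 0;
  for (int i = 0; i < nt; ++i) {
    tpl[i] = as<std::string>(templates[i]);
    total += (double)tpl[i].size();
    cum[i] = total;
  }
  CharacterVector read1(n_pairs), read2(n_pairs);
  IntegerVector tidx(n_pairs), frag_start(n_pairs), frag_len(n_pairs);
  const double log1mp = error_rate > 0 ? std::log1p(-error_rate) : 0.0;
  std::string r1, r2;
  for (int p = 0; p < n_pairs; ++p) {
    const double u = unif_rand() * total;
    int ti = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (ti >= nt) ti = nt - 1;
    const std::string& t = tpl[ti];
    const int len = (int)t.size();
    int fl = (int)std::lround(frag_mean + frag_sd * norm_rand());
    if (fl < read_len) fl = read_len;
    if (fl > len) fl = len;
    int start;
    if (circular) {
      start = (int)(unif_rand() * len);
      if (start >= len) start = len - 1;
    } else {
      start = (int)(unif_rand() * (len - fl + 1));
      if (start > len - fl) start = len - fl;
    }
    r1.resize(read_len); r2.resize(read_len);
    for (int i = 0; i < read_len; ++i) {
      int pos = start + i;
      if (pos >= len) pos -= len;
      r1[i] = t[pos];
    }
    const int m2 = start + fl - read_len;
    for (int i = 0; i < read_len; ++i) {
      int pos = m2 + read_len - 1 - i;
      while (pos >= len) pos -= len;
      r2[i] = comp_base(t[pos]);
    }
    if (error_rate > 0) {
      for (std::string* rp : {&r1, &r2}) {
        long i = -1;
        while (true) {
          const double uu = unif_rand();
          i += (long)std::floor(std::log(uu) / log1mp) + 1;
          if (i >= read_len) break;
          const int c = base_code((*rp)[i]);
          if (c >= 0) {
            int rr = (int)(unif_rand() * 3);
            if (rr > 2) rr = 2;
            (*rp)[i] = bases[(c + 1 + rr) & 3];
          }
        }
      }
    }
    read1[p] = r1; read2[p] = r2;
    tidx[p] = ti + 1; frag_start[p] = start; frag_len[p] = fl;
  }
  return List::create(_["read1"] = read1, _["read2"] = read2,
                      _["tidx"] = tidx, _["frag_start"] = frag_start,
                      _["frag_len"] = frag_len);
}

namespace {

inline bool approx_match(const char* a, const char* b, int len, int max_mm) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (a[i] != b[i] && ++mm > max_mm) return false;
  }
  return true;
}

// does `win` (length wl) occur anywhere in `vec` with <= max_mm mismatches?
bool window_in_vector(const std::string& win, const std::string& vec, int max_mm) {
  const int wl = (int)win.size(), vl = (int)vec.size();
  for (int p = 0; p + wl <= vl; ++p)
    if (approx_match(win.c_str(), vec.c_str() + p, wl, max_mm)) return true;
  return false;
}

}  // namespace

// Vector/insert junction scanner. A read is a junction read when a
// read-terminal vector segment of >= m bases ends exactly at a vector
// terminus inside the read, adjacent to an insert-side flank of f bases.
// A read crossing the START junction carries insert | vector[0..] running to
// the read's 3' edge; a read crossing the END junction carries
// vector[..L] | insert from its 5' edge. Both read orientations are scanned
// (the reverse-complemented read is tested against the same two layouts).
// Up to `max_mm` mismatches are tolerated over the whole vector-side
// segment; flanks are reported orientation-normalised (along the vector's
// own strand). Candidates whose flank+segment window occurs inside the
// vector are rejected (vector-internal near-repeats, not junctions).
// [[Rcpp::export]]
DataFrame junction_scan_cpp(CharacterVector reads, std::string vec,
                            int m, int f, int max_mm) {
  const int L = (int)vec.size();
  const std::string rcvec = revcomp_str(vec);
  std::vector<int> out_read;
  std::vector<std::string> out_term, out_flank;

  // Junction layouts on the forward read r (n = read length), V in
  // {vec, rcvec} (rcvec handles reads sequenced in reverse orientation):
  //  START layout: r[c..n) == V[0..n-c)   (segment >= m, flank r[c-f..c))
  //  END   layout: r[0..c) == V[L-c..L)   (segment >= m, flank r[c..c+f))
  // Seeds: the pl = min(15, m) vector bases adjacent to the terminus occur
  // in a junction read with <= max_mm mismatches, so with max_mm <= 1 one of
  // the two seed halves matches exactly (pigeonhole); rolling 2-bit codes
  // prune verification to a handful of candidate cuts per read.
  const int pl = std::min(15, m);
  const int h1 = pl / 2, h2 = pl - h1;

  struct Layout {
    const std::string* V;
    bool is_start;
    const char* term;
    bool rc_flank;
    uint32_t codeA, codeB;
  };
  auto encode = [&](const char* s, int len) -> uint32_t {
    uint32_t code = 0;
    for (int i = 0; i < len; ++i) code = (code << 2) | (uint32_t)base_code(s[i]);
    return code;
  };
  Layout layouts[4] = {
    {&vec,   true,  "START", false, 0, 0},
    {&vec,   false, "END",   false, 0, 0},
    {&rcvec, false, "START", true,  0, 0},
    {&rcvec, true,  "END",   true,  0, 0}};
  for (auto& ly : layouts) {
    const char* pat = ly.is_start ? ly.V->c_str() : ly.V->c_str() + (L - pl);
    ly.codeA = encode(pat, h1);
    ly.codeB = encode(pat + h1, h2);
  }

  auto context_ok = [&](const std::string& win) {
    return !window_in_vector(win, vec, max_mm + 1) &&
           !window_in_vector(win, rcvec, max_mm + 1);
  };

  std::vector<uint32_t> codes;
  std::vector<int> valid;
  const uint32_t maskA = (1u << (2 * h1)) - 1;
  const uint32_t maskB = (1u << (2 * h2)) - 1;
  for (int ri = 0; ri < reads.size(); ++ri) {
    const std::string r = as<std::string>(reads[ri]);
    const int n = (int)r.size();
    if (n < m + f) continue;
    // codes[i]: 2-bit rolling code ending at i; valid[i]: ACGT run length
    codes.assign(n, 0u);
    valid.assign(n, 0);
    {
      uint32_t roll = 0; int run = 0;
      for (int i = 0; i < n; ++i) {
        const int c = base_code(r[i]);
        if (c < 0) { run = 0; roll = 0; } else { roll = (roll << 2) | (uint32_t)c; ++run; }
        codes[i] = roll; valid[i] = run;
      }
    }
    bool gotS = false, gotE = false;
    for (const auto& ly : layouts) {
      bool& got = (ly.term[0] == 'S') ? gotS : gotE;
      if (got) continue;
      const std::string& V = *ly.V;
      for (int p = 0; p + pl <= n && !got; ++p) {
        const bool hitA = valid[p + h1 - 1] >= h1 &&
                          (codes[p + h1 - 1] & maskA) == ly.codeA;
        const bool hitB = !hitA && valid[p + pl - 1] >= h2 &&
                          (codes[p + pl - 1] & maskB) == ly.codeB;
        if (!hitA && !hitB) continue;
        const int c = ly.is_start ? p : p + pl;  // candidate cut
        if (ly.is_start) {
          if (c < f || n - c < m || n - c > L) continue;
          if (!approx_match(r.c_str() + c, V.c_str(), n - c, max_mm)) continue;
          if (!context_ok(r.substr(c - f, f + std::min(m, n - c)))) continue;
          got = true;
          out_read.push_back(ri + 1);
          out_term.push_back(ly.term);
          const std::string fl = r.substr(c - f, f);
          out_flank.push_back(ly.rc_flank ? revcomp_str(fl) : fl);
        } else {
          if (c < m || c > n - f || c > L) continue;
          if (!approx_match(r.c_str(), V.c_str() + (L - c), c, max_mm)) continue;
          if (!context_ok(r.substr(std::max(0, c - m), std::min(m, c) + f))) continue;
          got = true;
          out_read.push_back(ri + 1);
          out_term.push_back(ly.term);
          const std::string fl = r.substr(c, f);
          out_flank.push_back(ly.rc_flank ? revcomp_str(fl) : fl);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = wrap(out_read),
                           _["terminus"] = wrap(out_term),
                           _["flank"] = wrap(out_flank),
                           _["stringsAsFactors"] = false);
}
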