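// Core sequence kernels: minimizer-seeded all-vs-all dovetail overlap
// detection with gapless per-diagonal verification, query-vs-target block
// mapping, quality-weighted consensus, capped union-find, and FASTQ QC
// helpers. Alignment model is substitution-aware and gapless: short-read
// overlaps are verified along the seed diagonal, so indel-containing
// overlaps are not chained (documented package-level assumption).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <array>
#include <functional>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
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
  for (auto& c : r) c = comp_base(c);
  return r;
}

// invertible 64-bit mix (minimizer hashing)
static inline uint64_t hash64(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

struct Seed {
  uint64_t hash;
  uint32_t id;
  uint32_t pos;    // start of k-mer on forward strand
  uint8_t strand;  // 0: canonical == forward k-mer, 1: canonical == rc
};

// minimizers of one sequence (minimap2-style, canonical k-mers)
static void collect_minimizers(const std::string& s, uint32_t id, int k, int w,
                               std::vector<Seed>& out) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t kf = 0, kr = 0;
  int span = 0;
  std::vector<Seed> win;  // ring of last w k-mer seeds
  win.reserve(n);
  std::vector<Seed> all;
  all.reserve(n);
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { span = 0; kf = 0; kr = 0; continue; }
    kf = ((kf << 2) | (uint64_t)b) & mask;
    kr = (kr >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++span < k) continue;
    Seed sd;
    sd.id = id;
    sd.pos = (uint32_t)(i - k + 1);
    if (kf < kr) { sd.strand = 0; sd.hash = hash64(kf, mask); }
    else if (kr < kf) { sd.strand = 1; sd.hash = hash64(kr, mask); }
    else continue;  // palindromic k-mer: strand ambiguous
    all.push_back(sd);
  }
  // sliding window minimum over hash; emit each window's minimizer once
  const int m = (int)all.size();
  if (m == 0) return;
  int last_emitted = -1;
  for (int i = 0; i + 1 <= m; ++i) {
    int lo = std::max(0, i - w + 1);
    if (i < w - 1 && i != m - 1) continue;  // wait for first full window
    int start = (i == m - 1 && m < w) ? 0 : lo;
    int best = start;
    for (int j = start + 1; j <= i; ++j)
      if (all[j].hash < all[best].hash) best = j;
    if (best != last_emitted) { out.push_back(all[best]); last_emitted = best; }
  }
}

struct DiagVotes {
  int32_t d1; uint32_t c1;
  int32_t d2; uint32_t c2;
  DiagVotes() : d1(0), c1(0), d2(0), c2(0) {}
  void add(int32_t d) {
    if (c1 && d1 == d) { ++c1; return; }
    if (c2 && d2 == d) { ++c2; if (c2 > c1) { std::swap(d1, d2); std::swap(c1, c2); } return; }
    if (!c1) { d1 = d; c1 = 1; return; }
    if (!c2) { d2 = d; c2 = 1; return; }
    // replace the weaker secondary candidate
    if (c2 == 1) { d2 = d; }
  }
};

struct Cand { uint32_t a, b; uint8_t strand; int32_t d1, d2; uint32_t c1, c2; };

// gapless column comparison of a[astart, aend) vs oriented-b at offset d.
// Returns matches; N counts as mismatch.
static inline int count_matches(const std::string& a, const std::string& bo,
                                int d, int astart, int aend) {
  int m = 0;
  for (int j = astart; j < aend; ++j) {
    char x = a[j], y = bo[j - d];
    if (x == y && x != 'N' && x != 'n') ++m;
  }
  return m;
}

static std::string gapless_cigar(const std::string& a, const std::string& bo,
                                 int d, int astart, int aend) {
  std::string cig;
  int run = 0; char op = 0;
  for (int j = astart; j < aend; ++j) {
    char x = a[j], y = bo[j - d];
    char cur = (x == y && x != 'N' && x != 'n') ? '=' : 'X';
    if (cur == op) ++run;
    else {
      if (run) cig += std::to_string(run) + op;
      op = cur; run = 1;
    }
  }
  if (run) cig += std::to_string(run) + op;
  return cig;
}

// [[Rcpp::export]]
DataFrame cpp_find_overlaps(CharacterVector seqs, int k, int w, int min_ovlen,
                            double min_identity, int max_occ, bool keep_cigar,
                            bool targets_only = false, int n_targets = 0) {
  const int n = seqs.size();
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) S[i] = as<std::string>(seqs[i]);
  std::vector<int> L(n);
  for (int i = 0; i < n; ++i) L[i] = (int)S[i].size();

  std::vector<Seed> seeds;
  seeds.reserve((size_t)n * 8);
  for (int i = 0; i < n; ++i) collect_minimizers(S[i], (uint32_t)i, k, w, seeds);
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    if (x.hash != y.hash) return x.hash < y.hash;
    if (x.id != y.id) return x.id < y.id;
    return x.pos < y.pos;
  });

  // vote per (a<b, relative strand) for the implied layout diagonal
  std::unordered_map<uint64_t, DiagVotes> votes;
  votes.reserve(1 << 16);
  size_t i = 0, m = seeds.size();
  while (i < m) {
    size_t j = i;
    while (j < m && seeds[j].hash == seeds[i].hash) ++j;
    size_t c = j - i;
    if ((int)c <= max_occ) {
      for (size_t p = i; p < j; ++p) {
        for (size_t q = p + 1; q < j; ++q) {
          const Seed &sp = seeds[p], &sq = seeds[q];
          if (sp.id == sq.id) continue;
          const Seed &sa = (sp.id < sq.id) ? sp : sq;
          const Seed &sb = (sp.id < sq.id) ? sq : sp;
          if (targets_only) {
            // query-vs-target mode: exactly one of the pair must be a target
            bool at = (int)sa.id < n_targets, bt = (int)sb.id < n_targets;
            if (at == bt) continue;
          }
          uint8_t rel = sa.strand ^ sb.strand;
          int32_t d;
          if (rel == 0) d = (int32_t)sa.pos - (int32_t)sb.pos;
          else d = (int32_t)sa.pos - (L[sb.id] - k - (int32_t)sb.pos);
          uint64_t key = ((((uint64_t)sa.id << 24) | sb.id) << 1) | rel;
          votes[key].add(d);
        }
      }
    }
    i = j;
  }

  std::vector<Cand> cands;
  cands.reserve(votes.size());
  for (auto& kv : votes) {
    Cand c;
    c.strand = (uint8_t)(kv.first & 1);
    uint64_t ab = kv.first >> 1;
    c.b = (uint32_t)(ab & 0xFFFFFF);
    c.a = (uint32_t)(ab >> 24);
    c.d1 = kv.second.d1; c.c1 = kv.second.c1;
    c.d2 = kv.second.d2; c.c2 = kv.second.c2;
    cands.push_back(c);
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
    if (x.a != y.a) return x.a < y.a;
    if (x.b != y.b) return x.b < y.b;
    return x.strand < y.strand;
  });

  std::vector<int> out_a, out_b, out_strand, out_d, out_o, out_nm;
  std::vector<int> out_type;
  std::vector<std::string> out_cig;
  int rc_cache_id = -1;
  std::string rc_cache;

  for (auto& c : cands) {
    const std::string& a = S[c.a];
    const std::string* bo;
    if (c.strand == 0) bo = &S[c.b];
    else {
      if (rc_cache_id != (int)c.b) { rc_cache = revcomp(S[c.b]); rc_cache_id = (int)c.b; }
      bo = &rc_cache;
    }
    int la = L[c.a], lb = L[c.b];
    int best_d = 0, best_m = -1, best_o = 0;
    int try_d[2] = { c.d1, c.d2 };
    int ntry = (c.c2 > 0 && c.d2 != c.d1) ? 2 : 1;
    for (int t = 0; t < ntry; ++t) {
      int d = try_d[t];
      int astart = std::max(0, d), aend = std::min(la, d + lb);
      int o = aend - astart;
      if (o < min_ovlen) continue;
      int mm = count_matches(a, *bo, d, astart, aend);
      if ((double)mm / o < min_identity) continue;
      if (mm > best_m || (mm == best_m && d < best_d)) { best_m = mm; best_d = d; best_o = o; }
    }
    if (best_m < 0) continue;
    int d = best_d;
    int astart = std::max(0, d), aend = std::min(la, d + lb);
    int type;  // 0 dovetail a->b, 1 dovetail b->a, 2 b in a, 3 a in b
    if (d >= 0 && d + lb <= la) type = 2;
    else if (d <= 0 && d + lb >= la) type = 3;
    else if (d > 0) type = 0;
    else type = 1;
    out_a.push_back((int)c.a + 1);
    out_b.push_back((int)c.b + 1);
    out_strand.push_back(c.strand);
    out_d.push_back(d);
    out_o.push_back(best_o);
    out_nm.push_back(best_m);
    out_type.push_back(type);
    if (keep_cigar) out_cig.push_back(gapless_cigar(a, *bo, d, astart, aend));
  }

  if (keep_cigar)
    return DataFrame::create(_["a"] = out_a, _["b"] = out_b,
                             _["strand"] = out_strand, _["offset"] = out_d,
                             _["o"] = out_o, _["n_match"] = out_nm,
                             _["type"] = out_type, _["cigar"] = out_cig,
                             _["stringsAsFactors"] = false);
  return DataFrame::create(_["a"] = out_a, _["b"] = out_b,
                           _["strand"] = out_strand, _["offset"] = out_d,
                           _["o"] = out_o, _["n_match"] = out_nm,
                           _["type"] = out_type,
                           _["stringsAsFactors"] = false);
}

// Best local gapless segment (Kadane) per seeded placement of query on
// target. Used for contig-to-truth alignment and read-to-junction support.
// [[Rcpp::export]]
DataFrame cpp_map_blocks(CharacterVector queries, CharacterVector targets,
                         int k, int w, int max_occ, int min_votes,
                         int mismatch_penalty) {
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::string> S(nt + nq);
  for (int i = 0; i < nt; ++i) S[i] = as<std::string>(targets[i]);
  for (int i = 0; i < nq; ++i) S[nt + i] = as<std::string>(queries[i]);
  std::vector<int> L(nt + nq);
  for (size_t i = 0; i < S.size(); ++i) L[i] = (int)S[i].size();

  std::vector<Seed> seeds;
  for (int i = 0; i < nt + nq; ++i) collect_minimizers(S[i], (uint32_t)i, k, w, seeds);
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    if (x.hash != y.hash) return x.hash < y.hash;
    if (x.id != y.id) return x.id < y.id;
    return x.pos < y.pos;
  });

  // key: (query, target, strand); diag = offset of oriented query on target
  std::unordered_map<uint64_t, std::unordered_map<int32_t, uint32_t> > votes;
  size_t i = 0, m = seeds.size();
  while (i < m) {
    size_t j = i;
    while (j < m && seeds[j].hash == seeds[i].hash) ++j;
    size_t c = j - i;
    if ((int)c <= max_occ) {
      for (size_t p = i; p < j; ++p) {
        for (size_t q = p + 1; q < j; ++q) {
          const Seed* st;
          const Seed* sq2;
          if ((int)seeds[p].id < nt && (int)seeds[q].id >= nt) { st = &seeds[p]; sq2 = &seeds[q]; }
          else if ((int)seeds[q].id < nt && (int)seeds[p].id >= nt) { st = &seeds[q]; sq2 = &seeds[p]; }
          else continue;
          uint8_t rel = st->strand ^ sq2->strand;
          int lq = L[sq2->id];
          int32_t d;  // start of oriented query on target
          if (rel == 0) d = (int32_t)st->pos - (int32_t)sq2->pos;
          else d = (int32_t)st->pos - (lq - k - (int32_t)sq2->pos);
          uint64_t key = ((((uint64_t)(sq2->id - nt) << 20) | st->id) << 1) | rel;
          votes[key][d]++;
        }
      }
    }
    i = j;
  }

  std::vector<uint64_t> keys;
  keys.reserve(votes.size());
  for (auto& kv : votes) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::vector<int> o_q, o_t, o_strand, o_qs, o_qe, o_ts, o_te, o_nm, o_len;
  std::string rc_cache; int rc_cache_id = -1;

  for (uint64_t key : keys) {
    int rel = (int)(key & 1);
    uint64_t qt = key >> 1;
    int t_id = (int)(qt & 0xFFFFF);
    int q_id = (int)(qt >> 20);
    const std::string& T = S[t_id];
    const std::string* Q;
    if (rel == 0) Q = &S[nt + q_id];
    else {
      if (rc_cache_id != q_id) { rc_cache = revcomp(S[nt + q_id]); rc_cache_id = q_id; }
      Q = &rc_cache;
    }
    int lt = L[t_id], lq = L[nt + q_id];
    std::vector<std::pair<int32_t, uint32_t> > dv(votes[key].begin(), votes[key].end());
    std::sort(dv.begin(), dv.end());
    for (auto& pr : dv) {
      if ((int)pr.second < min_votes) continue;
      int d = pr.first;
      int qs0 = std::max(0, -d), qe0 = std::min(lq, lt - d);
      if (qe0 - qs0 < k) continue;
      // Kadane over +1 match / -penalty mismatch
      long cur = 0, best = 0;
      int cur_s = qs0, best_s = qs0, best_e = qs0;
      for (int x = qs0; x < qe0; ++x) {
        char qc = (*Q)[x], tc = T[d + x];
        long sc = (qc == tc && qc != 'N' && qc != 'n') ? 1 : -(long)mismatch_penalty;
        if (cur <= 0) { cur = sc; cur_s = x; }
        else cur += sc;
        if (cur > best) { best = cur; best_s = cur_s; best_e = x + 1; }
      }
      if (best_e - best_s < k) continue;
      int nm = count_matches(T, *Q, d, d + best_s, d + best_e);
      int qs = best_s, qe = best_e;
      int qs_f = qs, qe_f = qe;
      if (rel == 1) { qs_f = lq - qe; qe_f = lq - qs; }
      o_q.push_back(q_id + 1);
      o_t.push_back(t_id + 1);
      o_strand.push_back(rel);
      o_qs.push_back(qs_f);
      o_qe.push_back(qe_f);
      o_ts.push_back(d + qs);
      o_te.push_back(d + qe);
      o_nm.push_back(nm);
      o_len.push_back(qe - qs);
    }
  }
  return DataFrame::create(_["query"] = o_q, _["target"] = o_t,
                           _["strand"] = o_strand,
                           _["q_start"] = o_qs, _["q_end"] = o_qe,
                           _["t_start"] = o_ts, _["t_end"] = o_te,
                           _["n_match"] = o_nm, _["aln_len"] = o_len,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, CharacterVector quals,
                   IntegerVector offsets, IntegerVector strands) {
  const int n = seqs.size();
  int total = 0;
  std::vector<std::string> S(n), Q(n);
  for (int i = 0; i < n; ++i) {
    S[i] = as<std::string>(seqs[i]);
    if (strands[i] == 1) S[i] = revcomp(S[i]);
    if (quals[i] == NA_STRING) Q[i] = std::string(S[i].size(), 'I');
    else {
      Q[i] = as<std::string>(quals[i]);
      if (strands[i] == 1) std::reverse(Q[i].begin(), Q[i].end());
    }
    total = std::max(total, offsets[i] + (int)S[i].size());
  }
  std::vector<std::array<long, 4> > wt(total, std::array<long, 4>{0, 0, 0, 0});
  std::vector<std::array<int, 4> > maxq(total, std::array<int, 4>{-1, -1, -1, -1});
  std::vector<int> depth(total, 0);
  for (int i = 0; i < n; ++i) {
    int off = offsets[i];
    for (size_t p = 0; p < S[i].size(); ++p) {
      int b = base2bit(S[i][p]);
      depth[off + p]++;
      if (b < 0) continue;
      int q = (int)Q[i][p] - 33;
      wt[off + p][b] += q;
      if (q > maxq[off + p][b]) maxq[off + p][b] = q;
    }
  }
  std::string cons(total, 'N');
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  for (int p = 0; p < total; ++p) {
    long bw = -1; int bb = -1;
    for (int b = 0; b < 4; ++b) {
      if (wt[p][b] > bw) { bw = wt[p][b]; bb = b; }
      else if (wt[p][b] == bw && bb >= 0 && bw > 0) {
        // tie: toward the base seen at highest single quality, then A<C<G<T
        if (maxq[p][b] > maxq[p][bb]) bb = b;
      }
    }
    if (bb >= 0 && bw > 0) cons[p] = BASES[bb];
  }
  return List::create(_["seq"] = cons, _["depth"] = IntegerVector(depth.begin(), depth.end()));
}

// One-pass size-capped single-linkage union-find over pre-sorted edges.
// max_size <= 0 means no cap. Returns 1-based dense cluster id per element,
// densified by first appearance in element order.
// [[Rcpp::export]]
IntegerVector cpp_union_find(int n, IntegerVector ia, IntegerVector ib, int max_size) {
  std::vector<int> parent(n), sz(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const int m = ia.size();
  for (int e = 0; e < m; ++e) {
    int ra = find(ia[e] - 1), rb = find(ib[e] - 1);
    if (ra == rb) continue;
    if (max_size > 0 && sz[ra] + sz[rb] > max_size) continue;
    if (sz[ra] < sz[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    sz[ra] += sz[rb];
  }
  IntegerVector out(n);
  std::unordered_map<int, int> dense;
  int next = 1;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = dense.find(r);
    if (it == dense.end()) { dense[r] = next; out[i] = next; ++next; }
    else out[i] = it->second;
  }
  return out;
}

// End-trim bounds: longest retained run after removing terminal bases with
// Phred < cut from both ends. Returns 0-based half-open [start, end).
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int phred_cut) {
  const int n = quals.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    int s = 0, e = (int)q.size();
    while (s < e && (int)q[s] - 33 < phred_cut) ++s;
    while (e > s && (int)q[e - 1] - 33 < phred_cut) --e;
    out(i, 0) = s;
    out(i, 1) = e;
  }
  return out;
}

// Paired-end self-overlap base correction: detect the overlap of r1 with
// rc(r2) by exhaustive gapless offset scan, then at disagreeing columns
// replace the lower-quality base by the higher-quality one when the Phred
// difference is at least `margin`.
// [[Rcpp::export]]
List cpp_mate_correct(std::string s1, std::string q1, std::string s2, std::string q2,
                      int min_ov, double min_identity, int margin) {
  std::string s2r = revcomp(s2);
  std::string q2r(q2.rbegin(), q2.rend());
  const int l1 = (int)s1.size(), l2 = (int)s2r.size();
  int best_d = 0, best_m = -1, best_o = 0;
  // d = start of s2r on s1
  for (int d = -(l2 - min_ov); d <= l1 - min_ov; ++d) {
    int a0 = std::max(0, d), a1 = std::min(l1, d + l2);
    int o = a1 - a0;
    if (o < min_ov) continue;
    int mm = count_matches(s1, s2r, d, a0, a1);
    if ((double)mm / o < min_identity) continue;
    if (mm > best_m) { best_m = mm; best_d = d; best_o = o; }
  }
  int ncorr = 0;
  if (best_m >= 0) {
    int d = best_d;
    int a0 = std::max(0, d), a1 = std::min(l1, d + l2);
    for (int j = a0; j < a1; ++j) {
      int p2 = j - d;
      if (s1[j] == s2r[p2]) continue;
      int qa = (int)q1[j] - 33, qb = (int)q2r[p2] - 33;
      if (qa - qb >= margin) { s2r[p2] = s1[j]; q2r[p2] = q1[j]; ++ncorr; }
      else if (qb - qa >= margin) { s1[j] = s2r[p2]; q1[j] = q2r[p2]; ++ncorr; }
    }
  }
  std::string s2o = revcomp(s2r);
  std::string q2o(q2r.rbegin(), q2r.rend());
  return List::create(_["seq1"] = s1, _["qual1"] = q1,
                      _["seq2"] = s2o, _["qual2"] = q2o,
                      _["n_corrected"] = ncorr,
                      _["overlap_len"] = (best_m >= 0 ? best_o : 0));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// i.i.d. substitution errors at rate p using R's RNG (respects set.seed)
// [[Rcpp::export]]
List cpp_add_subst_errors(CharacterVector seqs, double p) {
  RNGScope scope;
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  std::vector<int> n_err(seqs.size(), 0);
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (R::unif_rand() < p) {
        int b = base2bit(s[j]);
        if (b < 0) continue;
        int nb = (b + 1 + (int)(R::unif_rand() * 3)) & 3;
        if (nb == b) nb = (b + 1) & 3;
        s[j] = BASES[nb];
        n_err[i]++;
      }
    }
    out[i] = s;
  }
  return List::create(_["seqs"] = out,
                      _["n_errors"] = IntegerVector(n_err.begin(), n_err.end()));
}

// gapless identity of a vs oriented b at a fixed offset (test/debug hook)
// [[Rcpp::export]]
List cpp_verify_pair(std::string a, std::string b, int strand, int offset) {
  std::string bo = strand == 1 ? revcomp(b) : b;
  int la = (int)a.size(), lb = (int)bo.size();
  int a0 = std::max(0, offset), a1 = std::min(la, offset + lb);
  if (a1 <= a0) return List::create(_["o"] = 0, _["n_match"] = 0);
  int mm = count_matches(a, bo, offset, a0, a1);
  return List::create(_["o"] = a1 - a0, _["n_match"] = mm,
                      _["cigar"] = gapless_cigar(a, bo, offset, a0, a1));
}
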