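// Core routines for the seed-and-vote aligner: 2-bit k-mer encoding with
// modular-prime hashing, stride-indexed hash table construction, per-read
// vote collection, affine-gap Smith-Waterman with traceback, and the
// batch mapping loop.  Coordinates are global 0-based over the virtual
// concatenation of the reference sequences.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// decimal-string -> uint64 (values are produced by this package, so no
// overflow handling beyond digit validation)
static uint64_t parse_u64(const std::string& s) {
  uint64_t v = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9') stop("invalid decimal value '%s'", s);
    v = v * 10u + (uint64_t)(s[i] - '0');
  }
  return v;
}

// [[Rcpp::export]]
std::string C_encode_kmer(std::string seq) {
  if (seq.size() < 1 || seq.size() > 32)
    stop("k-mer length must be in [1, 32]");
  uint64_t v = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) stop("ambiguous base '%s' in k-mer", std::string(1, seq[i]));
    v = (v << 2) | (uint64_t)b;
  }
  return std::to_string(v);
}

// [[Rcpp::export]]
std::string C_decode_kmer(std::string value, int len) {
  if (len < 1 || len > 32) stop("k-mer length must be in [1, 32]");
  uint64_t v = parse_u64(value);
  std::string s(len, 'A');
  for (int i = len - 1; i >= 0; --i) {
    s[i] = BITS2BASE[v & 3u];
    v >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
double C_key_from_value(std::string value, double M) {
  uint64_t v = parse_u64(value);
  uint64_t m = (uint64_t)M;
  return (double)(v % m);
}

// key of an sl-mer starting at `start` (0-based) of `seq`; -1 if any
// non-ACGT base falls inside the window.
static inline long long key_at(const char* seq, int start, int sl, uint64_t M) {
  uint64_t r = 0;
  for (int i = 0; i < sl; ++i) {
    int b = base2bit(seq[start + i]);
    if (b < 0) return -1;
    r = (r * 4u + (uint64_t)b) % M;
  }
  return (long long)r;
}

// [[Rcpp::export]]
double C_key_from_seq(std::string seq, double M) {
  long long k = key_at(seq.c_str(), 0, (int)seq.size(), (uint64_t)M);
  return (double)k;  // -1 signals an ambiguous base
}

// [[Rcpp::export]]
std::string C_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default: break;  // N and friends are their own complement here
    }
  }
  return r;
}

// Build the key -> coordinate-vector table.  Windows are enumerated per
// sequence at local offsets 0, w, 2w, ... with start + sl <= length; any
// window containing a non-ACGT character is dropped without key
// calculation.  Output is CSR over keys sorted ascending; coordinate
// vectors preserve ascending genome order.
// [[Rcpp::export]]
List C_build_index(std::string genome, IntegerVector seq_start,
                   IntegerVector seq_len, int sl, int w, double Md) {
  uint64_t M = (uint64_t)Md;
  const char* g = genome.c_str();
  std::unordered_map<uint64_t, std::vector<int> > table;
  long n_windows = 0, n_dropped = 0;
  for (int s = 0; s < seq_start.size(); ++s) {
    int s0 = seq_start[s], L = seq_len[s];
    for (int loc = 0; loc + sl <= L; loc += w) {
      long long k = key_at(g, s0 + loc, sl, M);
      if (k < 0) { ++n_dropped; continue; }
      table[(uint64_t)k].push_back(s0 + loc);
      ++n_windows;
    }
  }
  std::vector<uint64_t> ks;
  ks.reserve(table.size());
  for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = table.begin();
       it != table.end(); ++it)
    ks.push_back(it->first);
  std::sort(ks.begin(), ks.end());
  NumericVector keys(ks.size());
  IntegerVector cs(ks.size() + 1);
  cs[0] = 0;
  long total = 0;
  for (size_t i = 0; i < ks.size(); ++i) {
    keys[i] = (double)ks[i];
    total += (long)table[ks[i]].size();
    cs[i + 1] = (int)total;
  }
  IntegerVector coords(total);
  for (size_t i = 0; i < ks.size(); ++i) {
    std::vector<int>& v = table[ks[i]];
    std::sort(v.begin(), v.end());
    std::copy(v.begin(), v.end(), coords.begin() + cs[i]);
  }
  return List::create(_["keys"] = keys, _["cs"] = cs, _["coords"] = coords,
                      _["n_windows"] = (double)n_windows,
                      _["n_dropped"] = (double)n_dropped);
}

static inline int key_pos(const double* keys, int nk, double key) {
  const double* e = keys + nk;
  const double* p = std::lower_bound(keys, e, key);
  if (p == e || *p != key) return -1;
  return (int)(p - keys);
}

// [[Rcpp::export]]
IntegerVector C_lookup(NumericVector keys, IntegerVector cs,
                       IntegerVector coords, double key) {
  int i = key_pos(REAL(keys), keys.size(), key);
  if (i < 0) return IntegerVector(0);
  return IntegerVector(coords.begin() + cs[i], coords.begin() + cs[i + 1]);
}

// index of the sequence containing global coordinate c
static inline int seq_of(const int* starts, int ns, int c) {
  const int* p = std::upper_bound(starts, starts + ns, c);
  return (int)(p - starts) - 1;
}

struct Cand { int block; int strand; int votes; };

// Optional post-tally clustering: blocks closer than merge_window are
// collapsed, votes summed, the member with most votes (leftmost on ties)
// representing the cluster.  merge_window = 0 leaves the tally as-is.
static void merge_tally(std::unordered_map<int, int>& tally, int merge_window) {
  if (merge_window <= 0 || tally.size() < 2) return;
  std::vector<std::pair<int, int> > v(tally.begin(), tally.end());
  std::sort(v.begin(), v.end());
  std::unordered_map<int, int> out;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    int rep = v[i].first, rep_votes = v[i].second, total = v[i].second;
    while (j + 1 < v.size() && v[j + 1].first - v[j].first <= merge_window) {
      ++j;
      total += v[j].second;
      if (v[j].second > rep_votes) { rep = v[j].first; rep_votes = v[j].second; }
    }
    out[rep] = total;
    i = j + 1;
  }
  tally.swap(out);
}

// Tally votes for one oriented read sequence.  Each seed (every read
// offset) is hashed and looked up; seeds whose coordinate vector exceeds
// max_occ are skipped; with verify on, a hit only counts when the
// reference sl-mer equals the seed text (killing mod-M collisions).
// Votes accrue to block = coordinate - read_offset; blocks that leave
// the hit's sequence are discarded.
static void tally_strand(const char* g, const int* sstart, const int* slen,
                         int ns, const double* keys, int nk, const int* cs,
                         const int* coords, const std::string& read, int sl,
                         uint64_t M, int max_occ, bool verify,
                         std::unordered_map<int, int>& tally) {
  int n = (int)read.size();
  const char* r = read.c_str();
  for (int off = 0; off + sl <= n; ++off) {
    long long k = key_at(r, off, sl, M);
    if (k < 0) continue;
    int ki = key_pos(keys, nk, (double)k);
    if (ki < 0) continue;
    int lo = cs[ki], hi = cs[ki + 1];
    if (hi - lo > max_occ) continue;  // unrepresentative seed
    for (int j = lo; j < hi; ++j) {
      int c = coords[j];
      if (verify && memcmp(g + c, r + off, (size_t)sl) != 0) continue;
      int b = c - off;
      int si = seq_of(sstart, ns, c);
      if (b < sstart[si] || b + n > sstart[si] + slen[si]) continue;
      ++tally[b];
    }
  }
}

// [[Rcpp::export]]
List C_collect_votes(std::string genome, IntegerVector seq_start,
                     IntegerVector seq_len, NumericVector keys,
                     IntegerVector cs, IntegerVector coords, std::string read,
                     int sl, double Md, int max_occ, bool verify,
                     int merge_window) {
  std::unordered_map<int, int> tally;
  tally_strand(genome.c_str(), INTEGER(seq_start), INTEGER(seq_len),
               seq_start.size(), REAL(keys), keys.size(), INTEGER(cs),
               INTEGER(coords), read, sl, (uint64_t)Md, max_occ, verify,
               tally);
  merge_tally(tally, merge_window);
  std::vector<std::pair<int, int> > v(tally.begin(), tally.end());
  std::sort(v.begin(), v.end());
  IntegerVector block(v.size()), votes(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    block[i] = v[i].first;
    votes[i] = v[i].second;
  }
  return List::create(_["block_start"] = block, _["votes"] = votes);
}

// [[Rcpp::export]]
int C_count_mismatches(std::string genome, int block, std::string read) {
  if (block < 0 || block + (int)read.size() > (int)genome.size())
    stop("block outside reference");
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i)
    if (genome[block + i] != read[i]) ++mm;  // N in reference mismatches
  return mm;
}

// ---- Smith-Waterman, affine gaps, full DP with traceback ----------------
// Gap of length L costs gap_open + L * gap_extend (both negative).
// Traceback ties resolve diagonal > up (I, consumes read) > left (D).

struct SWresult {
  int score, read_start, read_end, ref_start, ref_end, edit;
  std::string cigar;  // includes soft clips for unaligned read ends
  bool ok;
};

static const int NEG = -(1 << 28);

static SWresult sw_align(const std::string& a, const std::string& b, int match,
                         int mismatch, int go, int ge) {
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> H((m + 1) * (n + 1), 0), I((m + 1) * (n + 1), NEG),
      D((m + 1) * (n + 1), NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int idx = i * (n + 1) + j;
      int up = idx - (n + 1), left = idx - 1, diag = up - 1;
      int iv = std::max(H[up] + go + ge, I[up] + ge);
      int dv = std::max(H[left] + go + ge, D[left] + ge);
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int hv = H[diag] + s;
      int h = std::max(std::max(hv, iv), std::max(dv, 0));
      I[idx] = iv;
      D[idx] = dv;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SWresult res;
  res.score = best;
  if (best <= 0) { res.ok = false; return res; }
  res.ok = true;
  // traceback
  std::vector<std::pair<char, int> > ops;  // reversed runs
  int i = bi, j = bj;
  char state = 'H';
  int edit = 0;
  while (true) {
    int idx = i * (n + 1) + j;
    if (state == 'H') {
      if (H[idx] == 0) break;
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && H[idx] == H[idx - (n + 1) - 1] + s) {
        if (a[i - 1] != b[j - 1]) ++edit;
        if (!ops.empty() && ops.back().first == 'M') ++ops.back().second;
        else ops.push_back(std::make_pair('M', 1));
        --i; --j;
      } else if (H[idx] == I[idx]) {
        state = 'I';
      } else if (H[idx] == D[idx]) {
        state = 'D';
      } else break;  // defensive
    } else if (state == 'I') {
      ++edit;
      if (!ops.empty() && ops.back().first == 'I') ++ops.back().second;
      else ops.push_back(std::make_pair('I', 1));
      bool opened = (H[idx - (n + 1)] + go + ge == I[idx]);
      --i;
      state = opened ? 'H' : 'I';
    } else {  // 'D'
      ++edit;
      if (!ops.empty() && ops.back().first == 'D') ++ops.back().second;
      else ops.push_back(std::make_pair('D', 1));
      bool opened = (H[idx - 1] + go + ge == D[idx]);
      --j;
      state = opened ? 'H' : 'D';
    }
  }
  res.read_start = i;
  res.read_end = bi;
  res.ref_start = j;
  res.ref_end = bj;
  res.edit = edit;
  std::string cig;
  if (i > 0) cig += std::to_string(i) + "S";
  for (int k = (int)ops.size() - 1; k >= 0; --k)
    cig += std::to_string(ops[k].second) + std::string(1, ops[k].first);
  if (m - bi > 0) cig += std::to_string(m - bi) + "S";
  res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
List C_smith_waterman(std::string read, std::string segment, int match,
                      int mismatch, int gap_open, int gap_extend) {
  SWresult r = sw_align(read, segment, match, mismatch, gap_open, gap_extend);
  if (!r.ok)
    return List::create(_["score"] = r.score, _["ok"] = false);
  return List::create(
      _["score"] = r.score, _["ok"] = true, _["cigar"] = r.cigar,
      _["read_start"] = r.read_start, _["read_end"] = r.read_end,
      _["ref_start"] = r.ref_start, _["ref_end"] = r.ref_end,
      _["edit_distance"] = r.edit);
}

struct BlockAln {
  bool ok, rescued;
  int pos, nm, score;  // pos global 0-based leftmost
  std::string cigar;
};

// Ungapped check against the selected block; Smith-Waterman rescue on the
// +/- pad extended block when more than mm_thresh mismatches.
static BlockAln align_to_block(const char* g, int glen, const int* sstart,
                               const int* slen, int ns,
                               const std::string& seq, int block, int match,
                               int mismatch, int go, int ge, int pad,
                               int mm_thresh) {
  BlockAln out;
  int n = (int)seq.size();
  int mm = 0;
  for (int i = 0; i < n; ++i)
    if (g[block + i] != seq[i]) ++mm;
  if (mm <= mm_thresh) {
    out.ok = true;
    out.rescued = false;
    out.pos = block;
    out.nm = mm;
    out.score = (n - mm) * match + mm * mismatch;
    out.cigar = std::to_string(n) + "M";
    return out;
  }
  int si = seq_of(sstart, ns, block);
  int lo = std::max(block - pad, sstart[si]);
  int hi = std::min(block + n + pad, sstart[si] + slen[si]);
  std::string segment(g + lo, g + hi);
  SWresult r = sw_align(seq, segment, match, mismatch, go, ge);
  if (!r.ok || r.score <= 0) {
    out.ok = false;
    out.rescued = true;
    out.pos = -1; out.nm = 0; out.score = r.score; out.cigar = "*";
    return out;
  }
  out.ok = true;
  out.rescued = true;
  out.pos = lo + r.ref_start;
  out.nm = r.edit;
  out.score = r.score;
  out.cigar = r.cigar;
  return out;
}

// [[Rcpp::export]]
List C_align_to_block(std::string genome, IntegerVector seq_start,
                      IntegerVector seq_len, std::string seq, int block,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int pad, int mm_thresh) {
  BlockAln a = align_to_block(genome.c_str(), (int)genome.size(),
                              INTEGER(seq_start), INTEGER(seq_len),
                              seq_start.size(), seq, block, match, mismatch,
                              gap_open, gap_extend, pad, mm_thresh);
  return List::create(_["ok"] = a.ok, _["rescued"] = a.rescued,
                      _["pos"] = a.pos, _["cigar"] = a.cigar,
                      _["nm"] = a.nm, _["score"] = a.score);
}

// Full per-read pipeline over a batch of reads: vote on both strands,
// merge the candidate pools, pick the winner (random tie-break via R's
// RNG), score mapq from the vote difference, then ungapped check or
// Smith-Waterman rescue.  Tied-optimal candidate sets are returned so a
// paired-end caller can prefer a concordant combination.
// [[Rcpp::export]]
List C_map_batch(std::string genome, IntegerVector seq_start,
                 IntegerVector seq_len, NumericVector keys, IntegerVector cs,
                 IntegerVector coords, CharacterVector reads, int sl,
                 double Md, int max_occ, bool verify, int min_votes,
                 int match, int mismatch, int gap_open, int gap_extend,
                 int pad, int mm_thresh, int mapq_scale, int mapq_cap,
                 int merge_window) {
  int nr = reads.size();
  const char* g = genome.c_str();
  const int* sstart = INTEGER(seq_start);
  const int* slen = INTEGER(seq_len);
  int ns = seq_start.size();
  const double* kp = REAL(keys);
  int nk = keys.size();
  const int* csp = INTEGER(cs);
  const int* cop = INTEGER(coords);
  uint64_t M = (uint64_t)Md;

  LogicalVector mapped(nr), tie(nr), rescued(nr);
  IntegerVector block(nr), pos(nr), optimal(nr), suboptimal(nr), mapq(nr),
      nm(nr);
  CharacterVector strand(nr), cigar(nr);
  List tied_blocks(nr), tied_strands(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    mapped[r] = false; tie[r] = false; rescued[r] = false;
    block[r] = NA_INTEGER; pos[r] = NA_INTEGER; mapq[r] = 0; nm[r] = NA_INTEGER;
    strand[r] = NA_STRING; cigar[r] = NA_STRING;
    optimal[r] = 0; suboptimal[r] = 0;
    int n = (int)fwd.size();
    if (n < sl) continue;
    std::string rev = C_revcomp(fwd);
    std::unordered_map<int, int> tf, tr;
    tally_strand(g, sstart, slen, ns, kp, nk, csp, cop, fwd, sl, M, max_occ,
                 verify, tf);
    tally_strand(g, sstart, slen, ns, kp, nk, csp, cop, rev, sl, M, max_occ,
                 verify, tr);
    merge_tally(tf, merge_window);
    merge_tally(tr, merge_window);
    std::vector<Cand> pool;
    pool.reserve(tf.size() + tr.size());
    for (std::unordered_map<int, int>::iterator it = tf.begin(); it != tf.end(); ++it) {
      Cand c; c.block = it->first; c.strand = 0; c.votes = it->second;
      pool.push_back(c);
    }
    for (std::unordered_map<int, int>::iterator it = tr.begin(); it != tr.end(); ++it) {
      Cand c; c.block = it->first; c.strand = 1; c.votes = it->second;
      pool.push_back(c);
    }
    if (pool.empty()) continue;
    int opt = 0;
    for (size_t i = 0; i < pool.size(); ++i) opt = std::max(opt, pool[i].votes);
    if (opt < min_votes) { optimal[r] = opt; continue; }
    std::vector<int> arg;
    int sub = 0;
    for (size_t i = 0; i < pool.size(); ++i) {
      if (pool[i].votes == opt) arg.push_back((int)i);
      else sub = std::max(sub, pool[i].votes);
    }
    bool is_tie = arg.size() > 1;
    if (is_tie) sub = opt;  // second-best block shares the top count
    // deterministic candidate order for reproducible tie-breaks
    std::sort(arg.begin(), arg.end(),
              [&pool](int x, int y) {
                if (pool[x].block != pool[y].block)
                  return pool[x].block < pool[y].block;
                return pool[x].strand < pool[y].strand;
              });
    int pick = 0;
    if (is_tie) {
      pick = (int)(unif_rand() * (double)arg.size());
      if (pick >= (int)arg.size()) pick = (int)arg.size() - 1;
    }
    Cand sel = pool[arg[pick]];
    int q = is_tie ? 0 : (opt - sub) * mapq_scale;
    if (q > mapq_cap) q = mapq_cap;
    const std::string& seq = sel.strand ? rev : fwd;
    BlockAln a = align_to_block(g, (int)genome.size(), sstart, slen, ns, seq,
                                sel.block, match, mismatch, gap_open,
                                gap_extend, pad, mm_thresh);
    optimal[r] = opt;
    suboptimal[r] = sub;
    tie[r] = is_tie;
    block[r] = sel.block;
    strand[r] = sel.strand ? "-" : "+";
    IntegerVector tb(arg.size()), ts(arg.size());
    for (size_t i = 0; i < arg.size(); ++i) {
      tb[i] = pool[arg[i]].block;
      ts[i] = pool[arg[i]].strand;
    }
    tied_blocks[r] = tb;
    tied_strands[r] = ts;
    if (!a.ok) continue;  // rescue produced nothing alignable
    mapped[r] = true;
    rescued[r] = a.rescued;
    pos[r] = a.pos;
    mapq[r] = q;
    nm[r] = a.nm;
    cigar[r] = a.cigar;
  }
  return List::create(
      _["mapped"] = mapped, _["tie"] = tie, _["strand"] = strand,
      _["block_start"] = block, _["pos"] = pos, _["optimal"] = optimal,
      _["suboptimal"] = suboptimal, _["mapq"] = mapq, _["cigar"] = cigar,
      _["nm"] = nm, _["rescued"] = rescued, _["tied_blocks"] = tied_blocks,
      _["tied_strands"] = tied_strands);
}
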