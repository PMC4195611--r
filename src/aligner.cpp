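// k-mer seeded banded local alignment of long amplicon reads against a
// short-exon library, with the thresholds of a BLAT-style search
// (tile 8, step 5, one mismatch allowed per tile, min score 20,
// min identity 70). Scoring: match +1, mismatch -1, gap open -2,
// gap extend -1 (a length-L gap costs 2 + L). Coordinates are 0-based
// half-open on the original read strand.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG = -1000000;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

struct AlnParams {
  int tile, step, min_score, min_seed_support, diag_window, band_slack;
  int match, mismatch, gap_open, gap_ext, prescreen;
  double min_identity;
  bool one_off;
};

struct ExonHit {
  int exon;        // 0-based exon index
  int score;
  double identity; // percent
  int rstart, rend, estart, eend; // 0-based half-open, aligned strand
  bool found;
};

// posting: exon index (high 16 bits) | tile position (low 16 bits)
typedef std::vector<std::vector<uint32_t> > TileIndex;

static void build_index(const std::vector<std::vector<uint8_t> > &exons,
                        const AlnParams &p, TileIndex &table) {
  table.assign(1 << (2 * p.tile), std::vector<uint32_t>());
  for (size_t e = 0; e < exons.size(); ++e) {
    const std::vector<uint8_t> &s = exons[e];
    if ((int)s.size() < p.tile) continue;
    for (int pos = 0; pos + p.tile <= (int)s.size(); pos += p.step) {
      bool ok = true;
      uint32_t key = 0;
      for (int k = 0; k < p.tile; ++k) {
        if (s[pos + k] > 3) { ok = false; break; }
        key = (key << 2) | s[pos + k];
      }
      if (!ok) continue;
      uint32_t val = ((uint32_t)e << 16) | (uint32_t)pos;
      table[key].push_back(val);
      if (p.one_off) {
        for (int k = 0; k < p.tile; ++k) {
          uint32_t shift = 2 * (p.tile - 1 - k);
          uint32_t cur = (key >> shift) & 3u;
          for (uint32_t b = 0; b < 4; ++b) {
            if (b == cur) continue;
            uint32_t nk = (key & ~(3u << shift)) | (b << shift);
            table[nk].push_back(val);
          }
        }
      }
    }
  }
}

static void encode(const std::string &s, std::vector<uint8_t> &out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (uint8_t)base_code(s[i]);
}

static void revcomp(const std::vector<uint8_t> &in,
                    std::vector<uint8_t> &out) {
  out.resize(in.size());
  for (size_t i = 0; i < in.size(); ++i) {
    uint8_t c = in[in.size() - 1 - i];
    out[i] = (c > 3) ? 4 : (uint8_t)(3 - c);
  }
}

// count index postings touched by a read (orientation selection heuristic)
static long count_postings(const std::vector<uint8_t> &read,
                           const TileIndex &table, const AlnParams &p) {
  long n = 0;
  int L = (int)read.size();
  if (L < p.tile) return 0;
  uint32_t key = 0, mask = (1u << (2 * p.tile)) - 1u;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    if (read[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | read[i]) & mask;
    if (++run >= p.tile) n += (long)table[key].size();
  }
  return n;
}

// gather (exon, diagonal) seeds for one read orientation
static void gather_seeds(const std::vector<uint8_t> &read,
                         const TileIndex &table, const AlnParams &p,
                         std::vector<std::vector<int> > &diags) {
  int L = (int)read.size();
  if (L < p.tile) return;
  uint32_t key = 0, mask = (1u << (2 * p.tile)) - 1u;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    if (read[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | read[i]) & mask;
    if (++run < p.tile) continue;
    const std::vector<uint32_t> &bucket = table[key];
    int kstart = i - p.tile + 1;
    for (size_t b = 0; b < bucket.size(); ++b) {
      int e = (int)(bucket[b] >> 16);
      int pos = (int)(bucket[b] & 0xFFFFu);
      diags[e].push_back(kstart - pos);
    }
  }
}

// best ungapped local score along one diagonal (Kadane on +match/-mismatch)
static int ungapped_best(const std::vector<uint8_t> &exon,
                         const std::vector<uint8_t> &read, int diag,
                         const AlnParams &p) {
  int m = (int)exon.size(), L = (int)read.size();
  int jlo = std::max(0, -diag), jhi = std::min(m, L - diag);
  int best = 0, run = 0;
  for (int j = jlo; j < jhi; ++j) {
    int i = j + diag;
    bool match = exon[j] <= 3 && exon[j] == read[i];
    run += match ? p.match : p.mismatch;
    if (run < 0) run = 0;
    if (run > best) best = run;
  }
  return best;
}

// banded affine-gap (Gotoh) local alignment; STORE=false runs a cheap
// score-only pass, STORE=true additionally records traceback directions
template <bool STORE>
static ExonHit banded_align(const std::vector<uint8_t> &exon,
                            const std::vector<uint8_t> &read,
                            int dlo, int dhi, const AlnParams &p,
                            std::vector<int> &Hprev, std::vector<int> &Hcur,
                            std::vector<int> &Fprev, std::vector<int> &Fcur,
                            std::vector<int> &Ecur,
                            std::vector<uint8_t> &DH, std::vector<uint8_t> &DE,
                            std::vector<uint8_t> &DF) {
  ExonHit hit; hit.found = false;
  int m = (int)exon.size(), L = (int)read.size();
  int W = dhi - dlo + 1;
  if (W <= 0 || m == 0 || L == 0) return hit;
  int open_cost = p.gap_open + p.gap_ext; // first gap character
  Hprev.assign(W, NEG); Hcur.assign(W, NEG);
  Fprev.assign(W, NEG); Fcur.assign(W, NEG);
  Ecur.assign(W, NEG);
  if (STORE) {
    DH.assign((size_t)m * W, 0); DE.assign((size_t)m * W, 0);
    DF.assign((size_t)m * W, 0);
  }

  // virtual row j = -1: starting anywhere with 0 on valid read positions
  for (int d = 0; d < W; ++d) { Hprev[d] = 0; Fprev[d] = NEG; }

  int best = 0, bj = -1, bd = -1;
  for (int j = 0; j < m; ++j) {
    size_t rowoff = (size_t)j * W;
    for (int d = 0; d < W; ++d) {
      int i = j + dlo + d;
      if (i < 0 || i >= L) {
        Hcur[d] = NEG; Ecur[d] = NEG; Fcur[d] = NEG;
        continue;
      }
      // E: gap consuming read base (left neighbour, same row)
      int e_open = (d > 0 ? Hcur[d - 1] : NEG) - open_cost;
      int e_ext  = (d > 0 ? Ecur[d - 1] : NEG) - p.gap_ext;
      int E = std::max(e_open, e_ext);
      Ecur[d] = E;
      if (STORE) DE[rowoff + d] = (uint8_t)(e_open >= e_ext ? 1 : 0);
      // F: gap consuming exon base (upper neighbour, previous row, d+1)
      int f_open = (d + 1 < W ? Hprev[d + 1] : NEG) - open_cost;
      int f_ext  = (d + 1 < W ? Fprev[d + 1] : NEG) - p.gap_ext;
      int F = std::max(f_open, f_ext);
      Fcur[d] = F;
      if (STORE) DF[rowoff + d] = (uint8_t)(f_open >= f_ext ? 1 : 0);
      // H
      bool mm = exon[j] <= 3 && read[i] <= 3 && exon[j] == read[i];
      int diag_from = (Hprev[d] <= NEG / 2) ? NEG
                      : Hprev[d] + (mm ? p.match : p.mismatch);
      int H = 0; uint8_t dir = 0;
      if (diag_from > H) { H = diag_from; dir = 1; }
      if (E > H) { H = E; dir = 2; }
      if (F > H) { H = F; dir = 3; }
      Hcur[d] = H;
      if (STORE) DH[rowoff + d] = dir;
      if (H > best) { best = H; bj = j; bd = d; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    // next row's virtual previous values must not allow restarts outside
    // valid cells; restart value 0 is encoded through dir = 0 cells above.
    for (int d = 0; d < W; ++d) {
      int i = (j + 1) + dlo + d - 1; // diag move source validity handled above
      (void)i;
      if (Hprev[d] <= NEG / 2) Hprev[d] = NEG;
    }
  }
  // rows use Hprev of the *previous* j with 0-start semantics: a dir==1 cell
  // whose predecessor had dir==0 starts the alignment there. The virtual
  // row held 0 for all valid d, so alignments may start at any row-0 cell.

  if (best < p.min_score || bj < 0) return hit;
  if (!STORE) { hit.found = true; hit.score = best; return hit; }

  // traceback
  int j = bj, d = bd, state = 0; // 0=H, 1=E, 2=F
  int matches = 0, cols = 0;
  int rmin = 1 << 30, rmax = -1, emin = 1 << 30, emax = -1;
  while (j >= 0) {
    size_t off = (size_t)j * W + d;
    int i = j + dlo + d;
    if (state == 0) {
      uint8_t dir = DH[off];
      if (dir == 0) break;
      if (dir == 1) {
        ++cols;
        if (exon[j] <= 3 && exon[j] == read[i]) ++matches;
        rmin = std::min(rmin, i); rmax = std::max(rmax, i);
        emin = std::min(emin, j); emax = std::max(emax, j);
        --j; // d unchanged (i and j both decrement)
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: consumes read base i
      ++cols;
      rmin = std::min(rmin, i); rmax = std::max(rmax, i);
      state = DE[off] ? 0 : 1;
      --d; // i decrements, j fixed
      if (d < 0) break;
    } else { // F: consumes exon base j
      ++cols;
      emin = std::min(emin, j); emax = std::max(emax, j);
      state = DF[off] ? 0 : 2;
      --j; ++d; // j decrements, i fixed
      if (d >= W) break;
    }
  }
  if (cols == 0) return hit;
  double identity = 100.0 * matches / cols;
  if (identity < p.min_identity) return hit;
  hit.found = true;
  hit.score = best;
  hit.identity = identity;
  hit.rstart = rmin; hit.rend = rmax + 1;
  hit.estart = emin; hit.eend = emax + 1;
  return hit;
}

static AlnParams parse_params(List params) {
  AlnParams p;
  p.tile = as<int>(params["tile_size"]);
  p.step = as<int>(params["step"]);
  p.one_off = as<bool>(params["one_off"]);
  p.min_score = as<int>(params["min_score"]);
  p.min_identity = as<double>(params["min_identity"]);
  p.min_seed_support = as<int>(params["min_seed_support"]);
  p.diag_window = as<int>(params["diag_window"]);
  p.band_slack = as<int>(params["band_slack"]);
  p.match = as<int>(params["match"]);
  p.mismatch = as<int>(params["mismatch"]);
  p.gap_open = as<int>(params["gap_open"]);
  p.gap_ext = as<int>(params["gap_ext"]);
  p.prescreen = as<int>(params["prescreen"]);
  if (p.tile < 4 || p.tile > 12) stop("tile_size must be in [4, 12]");
  return p;
}

// [[Rcpp::export]]
List mx_align_batch(CharacterVector reads, CharacterVector exons,
                    IntegerVector exon_group, List params,
                    bool return_hits) {
  AlnParams p = parse_params(params);
  int n_exon = exons.size();
  std::vector<std::vector<uint8_t> > exon_codes(n_exon);
  for (int e = 0; e < n_exon; ++e)
    encode(as<std::string>(exons[e]), exon_codes[e]);
  TileIndex table;
  build_index(exon_codes, p, table);

  int n_groups = 0;
  for (int e = 0; e < n_exon; ++e)
    n_groups = std::max(n_groups, exon_group[e]);

  // hit collection (hits mode)
  std::vector<int> h_read, h_exon, h_score, h_rs, h_re, h_es, h_ee, h_strand;
  std::vector<double> h_ident;
  // compact mode output
  int n_reads = reads.size();
  IntegerMatrix best_exon(n_reads, n_groups), second_exon(n_reads, n_groups);
  IntegerMatrix best_score(n_reads, n_groups), second_score(n_reads, n_groups);
  IntegerMatrix n_pass(n_reads, n_groups);
  IntegerVector strand_used(n_reads);

  std::vector<uint8_t> fwd, rc;
  std::vector<std::vector<int> > diags(n_exon);
  std::vector<int> Hp, Hc, Fp, Fc, Ec;
  std::vector<uint8_t> DH, DE, DF;

  for (int r = 0; r < n_reads; ++r) {
    encode(as<std::string>(reads[r]), fwd);
    revcomp(fwd, rc);
    long nf = count_postings(fwd, table, p);
    long nr = count_postings(rc, table, p);
    bool use_rc = nr > nf;
    const std::vector<uint8_t> &read = use_rc ? rc : fwd;
    int L = (int)read.size();
    strand_used[r] = use_rc ? -1 : 1;

    for (int e = 0; e < n_exon; ++e) diags[e].clear();
    gather_seeds(read, table, p, diags);

    // per-group top-2 bookkeeping
    std::vector<int> g_best(n_groups, NEG), g_second(n_groups, NEG);
    std::vector<int> g_beste(n_groups, NA_INTEGER),
                     g_seconde(n_groups, NA_INTEGER);
    std::vector<int> g_npass(n_groups, 0);

    for (int e = 0; e < n_exon; ++e) {
      std::vector<int> &dv = diags[e];
      if ((int)dv.size() < p.min_seed_support) continue;
      std::sort(dv.begin(), dv.end());
      // densest window of width diag_window
      int bestcount = 0, wlo = 0, whi = 0;
      size_t a = 0;
      for (size_t b = 0; b < dv.size(); ++b) {
        while (dv[b] - dv[a] > p.diag_window) ++a;
        int cnt = (int)(b - a + 1);
        if (cnt > bestcount) { bestcount = cnt; wlo = dv[a]; whi = dv[b]; }
      }
      if (bestcount < p.min_seed_support) continue;
      // ungapped prescreen over the seeded diagonals in the window
      int pre = 0, lastd = INT32_MIN;
      for (size_t q = 0; q < dv.size(); ++q) {
        int dgl = dv[q];
        if (dgl < wlo || dgl > whi || dgl == lastd) continue;
        lastd = dgl;
        pre = std::max(pre, ungapped_best(exon_codes[e], read, dgl, p));
        if (pre >= p.prescreen) break;
      }
      if (pre < p.prescreen) continue;
      int dlo = wlo - p.band_slack, dhi = whi + p.band_slack;
      ExonHit hit = banded_align<true>(exon_codes[e], read, dlo, dhi, p,
                                       Hp, Hc, Fp, Fc, Ec, DH, DE, DF);
      if (!hit.found) continue;
      if (return_hits) {
        int rs = hit.rstart, re = hit.rend;
        if (use_rc) { rs = L - hit.rend; re = L - hit.rstart; }
        h_read.push_back(r + 1);
        h_exon.push_back(e + 1);
        h_score.push_back(hit.score);
        h_ident.push_back(hit.identity);
        h_rs.push_back(rs); h_re.push_back(re);
        h_es.push_back(hit.estart); h_ee.push_back(hit.eend);
        h_strand.push_back(use_rc ? -1 : 1);
      }
      int g = exon_group[e];
      if (g >= 1) {
        int gi = g - 1;
        ++g_npass[gi];
        if (hit.score > g_best[gi]) {
          g_second[gi] = g_best[gi]; g_seconde[gi] = g_beste[gi];
          g_best[gi] = hit.score; g_beste[gi] = e + 1;
        } else if (hit.score > g_second[gi]) {
          g_second[gi] = hit.score; g_seconde[gi] = e + 1;
        }
      }
    }
    for (int g = 0; g < n_groups; ++g) {
      best_exon(r, g) = g_beste[g];
      second_exon(r, g) = g_seconde[g];
      best_score(r, g) = g_best[g] <= NEG / 2 ? NA_INTEGER : g_best[g];
      second_score(r, g) = g_second[g] <= NEG / 2 ? NA_INTEGER : g_second[g];
      n_pass(r, g) = g_npass[g];
    }
  }

  if (return_hits) {
    return List::create(
      _["read"] = wrap(h_read), _["exon"] = wrap(h_exon),
      _["score"] = wrap(h_score), _["identity"] = wrap(h_ident),
      _["read_start"] = wrap(h_rs), _["read_end"] = wrap(h_re),
      _["exon_start"] = wrap(h_es), _["exon_end"] = wrap(h_ee),
      _["strand"] = wrap(h_strand));
  }
  return List::create(
    _["best_exon"] = best_exon, _["best_score"] = best_score,
    _["second_exon"] = second_exon, _["second_score"] = second_score,
    _["n_pass"] = n_pass, _["strand"] = strand_used);
}

// Apply i.i.d. per-base substitution / insertion / deletion errors.
// Insertions are placed before each template base; deletions drop the
// base; substitutions replace it with a uniformly chosen different base.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List mx_mutate_reads(CharacterVector seqs, double sub_rate,
                     double ins_rate, double del_rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  IntegerVector n_sub(n), n_ins(n), n_del(n);
  std::string buf;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    buf.clear();
    buf.reserve(s.size() + 16);
    int cs = 0, ci = 0, cd = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      if (ins_rate > 0 && unif_rand() < ins_rate) {
        buf.push_back(BASES[(int)(unif_rand() * 4) & 3]);
        ++ci;
      }
      if (del_rate > 0 && unif_rand() < del_rate) { ++cd; continue; }
      char c = s[i];
      if (sub_rate > 0 && unif_rand() < sub_rate) {
        int code = base_code(c);
        int nb = (code + 1 + (int)(unif_rand() * 3)) & 3;
        if (code > 3) nb = (int)(unif_rand() * 4) & 3;
        c = BASES[nb];
        ++cs;
      }
      buf.push_back(c);
    }
    out[r] = buf;
    n_sub[r] = cs; n_ins[r] = ci; n_del[r] = cd;
  }
  return List::create(_["sequence"] = out, _["n_sub"] = n_sub,
                      _["n_ins"] = n_ins, _["n_del"] = n_del);
}
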