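#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Phred+33 quality trimming with Trimmomatic step semantics:
// LEADING -> TRAILING -> SLIDINGWINDOW -> MINLEN.
// Returns an n x 2 matrix of 1-based (start, end) into the original read;
// (0, 0) marks a dropped read.
// [[Rcpp::export]]
IntegerMatrix trim_reads_cpp(CharacterVector seqs, CharacterVector quals,
                             int leading, int trailing,
                             int window_size, double window_quality,
                             int min_length) {
  int n = seqs.size();
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(quals, r));
    int len = (int) std::strlen(q);
    int s = 0, e = len;                       // kept region [s, e)
    while (s < e && (q[s] - 33) < leading) ++s;
    while (e > s && (q[e - 1] - 33) < trailing) --e;
    // scan 5'->3'; cut at the start of the first window whose mean < threshold;
    // windows truncated at the read end use the available bases
    for (int i = s; i < e; ++i) {
      int wend = std::min(i + window_size, e);
      double sum = 0.0;
      for (int j = i; j < wend; ++j) sum += q[j] - 33;
      if (sum / (wend - i) < window_quality) { e = i; break; }
    }
    if (e - s < min_length) { out(r, 0) = 0; out(r, 1) = 0; }
    else { out(r, 0) = s + 1; out(r, 1) = e; }
  }
  return out;
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Banded, affine-gap, glocal alignment (global in the read, local in the
// reference) against a small amplicon panel.  Candidate amplicon and band
// centre are chosen by shared-k-mer voting; the first gap base costs
// gap_open + gap_ext, further gap bases gap_ext (Gotoh).
// [[Rcpp::export]]
List align_reads_cpp(CharacterVector seqs, CharacterVector refs,
                     int k = 15, int band = 10,
                     int match = 1, int mismatch = -2,
                     int gap_open = -4, int gap_ext = -1,
                     double min_identity = 0.8) {
  const int NEG = -1000000;
  int n_reads = seqs.size(), n_refs = refs.size();

  // k-mer index over the panel: 2-bit encoded k-mers (k <= 15)
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > index;
  std::vector<std::string> refstr(n_refs);
  for (int r = 0; r < n_refs; ++r) {
    refstr[r] = as<std::string>(refs[r]);
    const std::string &rs = refstr[r];
    uint32_t key = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
    int run = 0;
    for (int i = 0; i < (int) rs.size(); ++i) {
      int b = base2bits(rs[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | b) & mask;
      if (++run >= k) index[key].push_back(std::make_pair(r, i - k + 1));
    }
  }

  IntegerVector out_ref(n_reads), out_start(n_reads), out_nm(n_reads),
      out_score(n_reads), out_nmatch(n_reads);
  CharacterVector out_cigar(n_reads), out_strand(n_reads);

  int W = 2 * band + 1;
  std::vector<int> H, E, F;  // (m+1) x W, resized per read

  // shared-k-mer votes for one oriented read; returns total votes of the
  // best reference (0 when none)
  auto vote = [&](const std::string &read,
                  std::unordered_map<int64_t, int> &votes, int &best_ref) {
    votes.clear();
    best_ref = -1;
    int m = (int) read.size();
    uint32_t key = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
    int run = 0;
    for (int i = 0; i < m; ++i) {
      int b = base2bits(read[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | b) & mask;
      if (++run >= k) {
        std::unordered_map<uint32_t,
            std::vector<std::pair<int, int> > >::iterator it = index.find(key);
        if (it != index.end())
          for (size_t h = 0; h < it->second.size(); ++h) {
            int rf = it->second[h].first;
            int diag = it->second[h].second - (i - k + 1);
            votes[((int64_t) rf << 32) | (uint32_t)(diag + 1000000)] += 1;
          }
      }
    }
    if (votes.empty()) return 0;
    std::vector<int> per_ref(n_refs, 0);
    for (std::unordered_map<int64_t, int>::iterator it = votes.begin();
         it != votes.end(); ++it)
      per_ref[(int)(it->first >> 32)] += it->second;
    best_ref = (int)(std::max_element(per_ref.begin(), per_ref.end())
                     - per_ref.begin());
    return per_ref[best_ref];
  };

  for (int rd = 0; rd < n_reads; ++rd) {
    out_ref[rd] = 0;
    std::string read = as<std::string>(seqs[rd]);
    int m = (int) read.size();
    if (m < k) continue;

    // try both orientations; keep the one with more shared k-mers
    std::string rc(read.rbegin(), read.rend());
    for (size_t i = 0; i < rc.size(); ++i) {
      switch (rc[i]) {
        case 'A': rc[i] = 'T'; break; case 'T': rc[i] = 'A'; break;
        case 'C': rc[i] = 'G'; break; case 'G': rc[i] = 'C'; break;
      }
    }
    std::unordered_map<int64_t, int> votes, votes_rc;
    int ref_f = -1, ref_r = -1;
    int vf = vote(read, votes, ref_f);
    int vr = vote(rc, votes_rc, ref_r);
    bool minus = vr > vf;
    if (minus) { read = rc; votes = votes_rc; }
    int best_ref = minus ? ref_r : ref_f;
    if (votes.empty() || best_ref < 0) continue;

    // best diagonal window (votes within +/- band of the centre diagonal)
    std::vector<std::pair<int, int> > diags;  // (diag, votes) for best_ref
    for (std::unordered_map<int64_t, int>::iterator it = votes.begin();
         it != votes.end(); ++it)
      if ((int)(it->first >> 32) == best_ref)
        diags.push_back(std::make_pair((int)(it->first & 0xFFFFFFFF) - 1000000,
                                       it->second));
    int best_diag = 0, best_dv = -1;
    for (size_t a = 0; a < diags.size(); ++a) {
      int acc = 0;
      for (size_t b2 = 0; b2 < diags.size(); ++b2)
        if (std::abs(diags[b2].first - diags[a].first) <= band)
          acc += diags[b2].second;
      if (acc > best_dv) { best_dv = acc; best_diag = diags[a].first; }
    }

    const std::string &ref = refstr[best_ref];
    int nr = (int) ref.size();

    // banded Gotoh; row i = read pos (1-based), ref j in i+diag +/- band
    H.assign((size_t)(m + 1) * W, NEG);
    E.assign((size_t)(m + 1) * W, NEG);
    F.assign((size_t)(m + 1) * W, NEG);
    // row 0: free start anywhere in the reference
    for (int c = 0; c < W; ++c) {
      int j = 0 + best_diag + (c - band);
      if (j >= 0 && j <= nr) H[c] = 0;
    }
    for (int i = 1; i <= m; ++i) {
      int jlo = std::max(1, i + best_diag - band);
      int jhi = std::min(nr, i + best_diag + band);
      for (int j = jlo; j <= jhi; ++j) {
        int c = j - (i + best_diag) + band;
        size_t id = (size_t) i * W + c;
        // diagonal from (i-1, j-1): same column offset
        size_t idd = (size_t)(i - 1) * W + c;
        int best_prev = std::max(H[idd], std::max(E[idd], F[idd]));
        if (best_prev > NEG / 2) {
          int sc = (read[i - 1] == ref[j - 1]) ? match : mismatch;
          H[id] = best_prev + sc;
        }
        // E: gap in the read (consumes ref) from (i, j-1): column c-1
        if (c - 1 >= 0) {
          size_t idl = (size_t) i * W + (c - 1);
          int a = (H[idl] > NEG / 2) ? H[idl] + gap_open + gap_ext : NEG;
          int b = (E[idl] > NEG / 2) ? E[idl] + gap_ext : NEG;
          if (i > 0 && std::max(a, b) > NEG) E[id] = std::max(a, b);
        }
        // F: gap in the reference (consumes read) from (i-1, j): column c+1
        if (c + 1 < W) {
          size_t idu = (size_t)(i - 1) * W + (c + 1);
          int a = (H[idu] > NEG / 2) ? H[idu] + gap_open + gap_ext : NEG;
          int b = (F[idu] > NEG / 2) ? F[idu] + gap_ext : NEG;
          if (std::max(a, b) > NEG) F[id] = std::max(a, b);
        }
      }
    }

    // best end: read fully consumed, reference end free
    int best_sc = NEG, best_c = -1, best_state = 0;  // 0=H, 2=F
    for (int c = 0; c < W; ++c) {
      int j = m + best_diag + (c - band);
      if (j < 0 || j > nr) continue;
      size_t id = (size_t) m * W + c;
      if (H[id] > best_sc) { best_sc = H[id]; best_c = c; best_state = 0; }
      if (F[id] > best_sc) { best_sc = F[id]; best_c = c; best_state = 2; }
    }
    if (best_c < 0 || best_sc <= NEG / 2) continue;

    // traceback
    std::string ops;
    int i = m, c = best_c, state = best_state, nmatch = 0, nmm = 0, ngap = 0;
    int first_ref = -1, last_ref = -1;
    while (i > 0) {
      int j = i + best_diag + (c - band);
      size_t id = (size_t) i * W + c;
      if (state == 0) {  // H: i-1,j-1
        ops.push_back('M');
        if (read[i - 1] == ref[j - 1]) ++nmatch; else ++nmm;
        first_ref = j; if (last_ref < 0) last_ref = j;
        int sc = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        size_t idd = (size_t)(i - 1) * W + c;
        int target = H[id] - sc;
        if (H[idd] == target) state = 0;
        else if (E[idd] == target) state = 1;
        else state = 2;
        --i;
      } else if (state == 1) {  // E: gap in read, consumes ref (D op)
        ops.push_back('D');
        ++ngap;
        first_ref = j; if (last_ref < 0) last_ref = j;
        size_t idl = (size_t) i * W + (c - 1);
        if (E[id] == ((E[idl] > NEG / 2) ? E[idl] + gap_ext : NEG)) state = 1;
        else state = 0;
        c -= 1;
      } else {  // F: gap in ref, consumes read (I op)
        ops.push_back('I');
        ++ngap;
        size_t idu = (size_t)(i - 1) * W + (c + 1);
        if (F[id] == ((F[idu] > NEG / 2) ? F[idu] + gap_ext : NEG)) state = 2;
        else state = 0;
        --i; c += 1;
      }
    }
    if (first_ref < 0) continue;           // no reference base aligned
    if ((double) nmatch / m < min_identity) continue;

    std::reverse(ops.begin(), ops.end());
    // run-length encode into a CIGAR
    std::string cigar;
    for (size_t p = 0; p < ops.size();) {
      size_t q2 = p;
      while (q2 < ops.size() && ops[q2] == ops[p]) ++q2;
      cigar += std::to_string(q2 - p);
      cigar.push_back(ops[p]);
      p = q2;
    }
    out_ref[rd] = best_ref + 1;
    out_start[rd] = first_ref;
    out_cigar[rd] = cigar;
    out_nm[rd] = nmm + ngap;
    out_score[rd] = best_sc;
    out_nmatch[rd] = nmatch;
    out_strand[rd] = minus ? "-" : "+";
  }
  return List::create(_["ref"] = out_ref, _["start"] = out_start,
                      _["cigar"] = out_cigar, _["nm"] = out_nm,
                      _["score"] = out_score, _["nmatch"] = out_nmatch,
                      _["strand"] = out_strand);
}

struct PileEntry { int ref; int pos; char base; int qual; bool shadow; };

// Per-sample pileup over the panel.  Reads must be sorted by pair id;
// overlapping mate bases at one position are counted once (higher base
// quality wins), bases within gap_pad of an alignment gap are excluded,
// and a base passes only when its phred quality is strictly greater than
// min_bq.  Returns, per amplicon, a 5 x L matrix (A, C, G, T, filtered).
// [[Rcpp::export]]
List pileup_cpp(IntegerVector ref_idx, IntegerVector ref_start,
                CharacterVector cigars, CharacterVector seqs,
                CharacterVector quals, IntegerVector pair_id,
                IntegerVector ref_lens, int min_bq = 30, int gap_pad = 3) {
  int n_refs = ref_lens.size();
  std::vector<IntegerMatrix> mats;
  for (int r = 0; r < n_refs; ++r) mats.push_back(IntegerMatrix(5, ref_lens[r]));

  int n = ref_idx.size();
  std::vector<PileEntry> pair_buf;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && pair_id[j] == pair_id[i]) ++j;
    pair_buf.clear();
    for (int r = i; r < j; ++r) {
      if (ref_idx[r] == 0) continue;
      const char *sq = CHAR(STRING_ELT(seqs, r));
      const char *ql = CHAR(STRING_ELT(quals, r));
      std::string cg = as<std::string>(cigars[r]);
      int rp = ref_start[r];  // 1-based
      int qp = 0;             // 0-based read offset
      size_t first_entry = pair_buf.size();
      std::vector<std::pair<int, int> > gap_spans;  // ref intervals near gaps
      size_t p = 0;
      while (p < cg.size()) {
        int len = 0;
        while (p < cg.size() && isdigit(cg[p])) len = len * 10 + (cg[p++] - '0');
        char op = cg[p++];
        if (op == 'M') {
          for (int t = 0; t < len; ++t) {
            PileEntry e;
            e.ref = ref_idx[r] - 1; e.pos = rp + t;
            e.base = sq[qp + t]; e.qual = ql[qp + t] - 33; e.shadow = false;
            pair_buf.push_back(e);
          }
          rp += len; qp += len;
        } else if (op == 'D') {
          gap_spans.push_back(std::make_pair(rp - gap_pad, rp + len - 1 + gap_pad));
          rp += len;
        } else {  // 'I'
          gap_spans.push_back(std::make_pair(rp - gap_pad, rp - 1 + gap_pad));
          qp += len;
        }
      }
      for (size_t g = 0; g < gap_spans.size(); ++g)
        for (size_t e2 = first_entry; e2 < pair_buf.size(); ++e2)
          if (pair_buf[e2].pos >= gap_spans[g].first &&
              pair_buf[e2].pos <= gap_spans[g].second)
            pair_buf[e2].shadow = true;
    }
    // de-duplicate overlapping mate positions: higher quality wins
    std::sort(pair_buf.begin(), pair_buf.end(),
              [](const PileEntry &a, const PileEntry &b) {
                if (a.ref != b.ref) return a.ref < b.ref;
                if (a.pos != b.pos) return a.pos < b.pos;
                return a.qual > b.qual;
              });
    for (size_t e2 = 0; e2 < pair_buf.size(); ++e2) {
      if (e2 > 0 && pair_buf[e2].ref == pair_buf[e2 - 1].ref &&
          pair_buf[e2].pos == pair_buf[e2 - 1].pos)
        continue;  // lower-quality duplicate of an overlapping mate base
      const PileEntry &e = pair_buf[e2];
      IntegerMatrix &M = mats[e.ref];
      if (e.pos < 1 || e.pos > M.ncol()) continue;
      int b = base2bits(e.base);
      if (!e.shadow && e.qual > min_bq && b >= 0) M(b, e.pos - 1) += 1;
      else M(4, e.pos - 1) += 1;
    }
    i = j;
  }
  List out(n_refs);
  for (int r = 0; r < n_refs; ++r) out[r] = mats[r];
  return out;
}

// i.i.d. substitution errors at the given per-base rate (uses the R RNG)
// [[Rcpp::export]]
CharacterVector add_errors_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    if (rate > 0) {
      for (size_t i = 0; i < s.size(); ++i) {
        if (unif_rand() < rate) {
          int cur = base2bits(s[i]);
          int sub = (int)(unif_rand() * 3);
          if (sub > 2) sub = 2;
          int nb = (cur + 1 + sub) % 4;  // any base but the current one
          s[i] = bases[nb];
        }
      }
    }
    out[r] = s;
  }
  return out;
}

// Phred+33 quality strings: N(mean - decay * position, sd), clamped to [2, 41]
// [[Rcpp::export]]
CharacterVector sim_quals_cpp(int n, int len, double mean, double sd,
                              double decay) {
  CharacterVector out(n);
  std::string s(len, '!');
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < len; ++i) {
      double q = mean - decay * i + ((sd > 0) ? norm_rand() * sd : 0.0);
      int qi = (int) std::lround(q);
      if (qi < 2) qi = 2;
      if (qi > 41) qi = 41;
      s[i] = (char)(33 + qi);
    }
    out[r] = s;
  }
  return out;
}

// Hamming distances from each observed barcode to each barcode in a set
// (equal lengths assumed)
// [[Rcpp::export]]
IntegerMatrix hamming_to_set_cpp(CharacterVector obs, CharacterVector set) {
  int n = obs.size(), K = set.size();
  std::vector<std::string> ss(K);
  for (int k = 0; k < K; ++k) ss[k] = as<std::string>(set[k]);
  IntegerMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    const char *o = CHAR(STRING_ELT(obs, i));
    int lo = (int) std::strlen(o);
    for (int k = 0; k < K; ++k) {
      int d = 0, lk = (int) ss[k].size();
      int l = std::min(lo, lk);
      for (int p = 0; p < l; ++p) d += (o[p] != ss[k][p]);
      d += std::abs(lo - lk);
      out(i, k) = d;
    }
  }
  return out;
}
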