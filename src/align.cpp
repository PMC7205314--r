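#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Word-seeded local alignment in transcript space.  Scoring follows blastn-like
// conventions (match +2, mismatch -3, affine gaps) with ungapped Karlin-Altschul
// E-values computed from (lambda, K) supplied by the caller.

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
  }
  return -1;
}

struct Aln {
  int score = 0;
  int qs = 0, qe = 0, ss = 0, se = 0;  // 0-based half-open
  int matches = 0, mism = 0, gaps = 0;
  bool found = false;
};

// Smith-Waterman with Gotoh affine gaps and traceback.
static Aln sw_pair(const char *q, int n, const char *s, int m,
                   int ma, int mi, int go, int ge) {
  const int NEG = -1000000;
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);  // 0 stop,1 diag,2 up(E),3 left(F)
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int up = idx - (m + 1), left = idx - 1, diag = up - 1;
      E[idx] = std::max(H[up] - go - ge, E[up] - ge);
      F[idx] = std::max(H[left] - go - ge, F[left] - ge);
      int sc = (q[i - 1] == s[j - 1]) ? ma : mi;
      int d = H[diag] + sc;
      int h = 0; unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tb[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  Aln a;
  if (best <= 0) return a;
  a.found = true; a.score = best; a.qe = bi; a.se = bj;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in subject), 2 = F
  while (i > 0 && j > 0) {
    int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tb[idx];
      if (t == 0) break;
      if (t == 1) {
        if (q[i - 1] == s[j - 1]) a.matches++; else a.mism++;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      a.gaps++;
      if (E[idx] == H[idx - (m + 1)] - go - ge) state = 0;
      --i;
    } else {
      a.gaps++;
      if (F[idx] == H[idx - 1] - go - ge) state = 0;
      --j;
    }
    if (state == 0) {
      int id2 = i * (m + 1) + j;
      if (tb[id2] == 0) break;
    }
  }
  a.qs = i; a.ss = j;
  return a;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > WordIndex;

static void index_words(const char *s, int len, int k, int id, WordIndex &idx,
                        size_t max_hits) {
  if (len < k) return;
  uint64_t w = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int p = 0; p < len; ++p) {
    int b = base2(s[p]);
    if (b < 0) { run = 0; w = 0; continue; }
    w = ((w << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      std::vector<std::pair<int, int> > &v = idx[w];
      if (v.size() < max_hits) v.push_back(std::make_pair(id, p - k + 1));
    }
  }
}

// Best local alignment of each read against a set of mature miRNAs sharing at
// least one word of `word_size`.  Ties broken by higher identity, longer
// alignment, then lower miRNA index (callers pass miRNAs sorted by id).
// [[Rcpp::export]]
DataFrame cpp_mirna_scan(CharacterVector reads, CharacterVector mirnas,
                         int word_size, int match, int mismatch, int gap_open,
                         int gap_extend, double lambda, double K, double db_len,
                         double evalue_max) {
  int nm = mirnas.size();
  WordIndex widx;
  std::vector<std::string> mseq(nm);
  for (int i = 0; i < nm; ++i) {
    mseq[i] = as<std::string>(mirnas[i]);
    index_words(mseq[i].c_str(), mseq[i].size(), word_size, i, widx, 1000000);
  }
  int nr = reads.size();
  std::vector<int> r_out, m_out, qs, qe, ss, se, mat, mis, gp, sc;
  std::vector<double> ev;
  std::vector<int> stamp(nm, -1);
  for (int r = 0; r < nr; ++r) {
    const char *seq = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    if (len < word_size) continue;
    // candidate miRNAs via shared words
    std::vector<int> cand;
    uint64_t w = 0, mask = (1ULL << (2 * word_size)) - 1;
    int run = 0;
    for (int p = 0; p < len; ++p) {
      int b = base2(seq[p]);
      if (b < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mask;
      if (++run >= word_size) {
        WordIndex::const_iterator it = widx.find(w);
        if (it != widx.end())
          for (size_t h = 0; h < it->second.size(); ++h) {
            int id = it->second[h].first;
            if (stamp[id] != r) { stamp[id] = r; cand.push_back(id); }
          }
      }
    }
    if (cand.empty()) continue;
    Aln best; int best_id = -1;
    for (size_t c = 0; c < cand.size(); ++c) {
      int id = cand[c];
      Aln a = sw_pair(seq, len, mseq[id].c_str(), mseq[id].size(), match,
                      mismatch, gap_open, gap_extend);
      if (!a.found) continue;
      bool take = false;
      if (best_id < 0 || a.score > best.score) take = true;
      else if (a.score == best.score) {
        int alen_a = a.matches + a.mism + a.gaps;
        int alen_b = best.matches + best.mism + best.gaps;
        double id_a = alen_a ? (double)a.matches / alen_a : 0.0;
        double id_b = alen_b ? (double)best.matches / alen_b : 0.0;
        if (id_a > id_b + 1e-12) take = true;
        else if (std::abs(id_a - id_b) <= 1e-12) {
          if (alen_a > alen_b) take = true;
          else if (alen_a == alen_b && id < best_id) take = true;
        }
      }
      if (take) { best = a; best_id = id; }
    }
    if (best_id < 0) continue;
    // E-value as for a miRNA query against the read database (m = miRNA
    // length, n = total read nucleotides), matching the screen's semantics.
    double e = K * (double)mseq[best_id].size() * db_len *
               std::exp(-lambda * best.score);
    if (e >= evalue_max) continue;
    r_out.push_back(r + 1); m_out.push_back(best_id + 1);
    qs.push_back(best.qs); qe.push_back(best.qe);
    ss.push_back(best.ss); se.push_back(best.se);
    mat.push_back(best.matches); mis.push_back(best.mism); gp.push_back(best.gaps);
    sc.push_back(best.score); ev.push_back(e);
  }
  return DataFrame::create(
      _["read"] = r_out, _["mirna"] = m_out, _["q_start"] = qs, _["q_end"] = qe,
      _["s_start"] = ss, _["s_end"] = se, _["matches"] = mat,
      _["mismatches"] = mis, _["gaps"] = gp, _["score"] = sc, _["evalue"] = ev);
}

// Map query segments to a transcriptome by k-mer seeding + banded local
// alignment around each seed diagonal.  Reports the best hit per segment, the
// number of distinct loci attaining the best score (n_best > 1 => multimapped)
// and the second-best score.
// [[Rcpp::export]]
DataFrame cpp_target_map(CharacterVector segments, CharacterVector transcripts,
                         int k, int match, int mismatch, int gap_open,
                         int gap_extend, int band, double lambda, double K,
                         double db_len, double evalue_max) {
  int nt = transcripts.size();
  WordIndex widx;
  std::vector<std::string> tseq(nt);
  for (int i = 0; i < nt; ++i) {
    tseq[i] = as<std::string>(transcripts[i]);
    index_words(tseq[i].c_str(), tseq[i].size(), k, i, widx, 200);
  }
  int ns = segments.size();
  IntegerVector seg_out(ns), t_out(ns), ts(ns), te(ns), qs(ns), qe(ns),
      mat(ns), mis(ns), gp(ns), sc(ns), nbest(ns), sc2(ns);
  NumericVector ev(ns);
  for (int s = 0; s < ns; ++s) {
    seg_out[s] = s + 1; t_out[s] = NA_INTEGER; ev[s] = NA_REAL;
    const char *seq = CHAR(STRING_ELT(segments, s));
    int len = LENGTH(STRING_ELT(segments, s));
    if (len < k) continue;
    // candidate windows keyed by (transcript, diagonal bucket)
    std::vector<std::pair<int, int> > wins;  // (transcript, window start)
    {
      std::unordered_map<uint64_t, bool> seen;
      uint64_t w = 0, mask = (1ULL << (2 * k)) - 1;
      int run = 0;
      for (int p = 0; p < len; ++p) {
        int b = base2(seq[p]);
        if (b < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          WordIndex::const_iterator it = widx.find(w);
          if (it == widx.end()) continue;
          for (size_t h = 0; h < it->second.size(); ++h) {
            int tid = it->second[h].first;
            int diag = it->second[h].second - (p - k + 1);
            int bucket = (diag + 1000000) / (band + 1);
            uint64_t key = ((uint64_t)tid << 32) | (uint64_t)bucket;
            if (!seen.count(key)) {
              seen[key] = true;
              wins.push_back(std::make_pair(tid, diag - band));
            }
            if (wins.size() > 64) break;
          }
        }
        if (wins.size() > 64) break;
      }
    }
    if (wins.empty()) continue;
    // align within each window; keep all hits to resolve multimapping
    struct Hit { int tid, ts, te, qs, qe, matches, mism, gaps, score; };
    std::vector<Hit> hits;
    for (size_t wI = 0; wI < wins.size(); ++wI) {
      int tid = wins[wI].first;
      int ws = std::max(0, wins[wI].second);
      int wlen = std::min((int)tseq[tid].size() - ws, len + 2 * band);
      if (wlen < k) continue;
      Aln a = sw_pair(seq, len, tseq[tid].c_str() + ws, wlen, match, mismatch,
                      gap_open, gap_extend);
      if (!a.found) continue;
      Hit h;
      h.tid = tid; h.ts = ws + a.ss; h.te = ws + a.se; h.qs = a.qs; h.qe = a.qe;
      h.matches = a.matches; h.mism = a.mism; h.gaps = a.gaps; h.score = a.score;
      hits.push_back(h);
    }
    if (hits.empty()) continue;
    int bi = 0;
    for (size_t h = 1; h < hits.size(); ++h)
      if (hits[h].score > hits[bi].score ||
          (hits[h].score == hits[bi].score &&
           (hits[h].tid < hits[bi].tid ||
            (hits[h].tid == hits[bi].tid && hits[h].ts < hits[bi].ts))))
        bi = (int)h;
    const Hit &b = hits[bi];
    double e = K * (double)len * db_len * std::exp(-lambda * b.score);
    if (e >= evalue_max) continue;
    int nb = 0, second = 0;
    for (size_t h = 0; h < hits.size(); ++h) {
      bool same_locus = (hits[h].tid == b.tid) &&
                        (hits[h].ts < b.te + band) && (hits[h].te > b.ts - band);
      if (hits[h].score == b.score && (!same_locus || (int)h == bi)) {
        if ((int)h == bi || !same_locus) nb++;
      }
      if ((int)h != bi && !same_locus && hits[h].score > second)
        second = hits[h].score;
    }
    t_out[s] = b.tid + 1; ts[s] = b.ts; te[s] = b.te; qs[s] = b.qs; qe[s] = b.qe;
    mat[s] = b.matches; mis[s] = b.mism; gp[s] = b.gaps; sc[s] = b.score;
    ev[s] = e; nbest[s] = nb; sc2[s] = second;
  }
  return DataFrame::create(
      _["segment"] = seg_out, _["transcript"] = t_out, _["t_start"] = ts,
      _["t_end"] = te, _["q_start"] = qs, _["q_end"] = qe, _["matches"] = mat,
      _["mismatches"] = mis, _["gaps"] = gp, _["score"] = sc,
      _["evalue"] = ev, _["n_best"] = nbest, _["second_score"] = sc2);
}
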