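#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Semi-global alignment of each read against every reference: the read is
// aligned end-to-end, reference overhangs are free (the usual model for a
// short read contained in a longer reference).  Linear gap penalty.
//
// Returns, per read, the index of the best-scoring reference, the best and
// second-best scores, the covered reference span for the best alignment,
// and the mutation events (mismatch, deletion, insertion) of the best
// alignment.  Ties and score thresholds are resolved by the R caller.

static inline int score_pair(const std::string& read, const std::string& ref,
                             int match, int mismatch, int gap,
                             std::vector<int>& row) {
  const int m = (int)read.size(), n = (int)ref.size();
  row.assign(n + 1, 0);                 // H[0][j] = 0: free ref prefix
  int best_last = INT32_MIN;
  for (int i = 1; i <= m; ++i) {
    int diag = row[0];                  // H[i-1][0]
    row[0] = i * gap;                   // read prefix gaps are penalized
    for (int j = 1; j <= n; ++j) {
      int up = row[j];                  // H[i-1][j]
      int sub = diag + (read[i - 1] == ref[j - 1] ? match : mismatch);
      int del = row[j - 1] + gap;       // gap in read (ref consumed)
      int ins = up + gap;               // gap in ref (read consumed)
      int h = sub >= del ? sub : del;
      if (ins > h) h = ins;
      diag = up;
      row[j] = h;
    }
  }
  for (int j = 0; j <= n; ++j)          // free ref suffix
    if (row[j] > best_last) best_last = row[j];
  return best_last;
}

// Full DP with traceback against one reference; fills events.
static void traceback_pair(const std::string& read, const std::string& ref,
                           int match, int mismatch, int gap,
                           int& ref_start, int& ref_end,
                           std::vector<int>& ev_pos,
                           std::vector<int>& ev_type) {
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<int> H((m + 1) * (n + 1));
  std::vector<unsigned char> D((m + 1) * (n + 1)); // 0 stop,1 diag,2 up,3 left
  for (int j = 0; j <= n; ++j) { H[j] = 0; D[j] = 0; }
  for (int i = 1; i <= m; ++i) {
    H[i * (n + 1)] = i * gap;
    D[i * (n + 1)] = 2;
    for (int j = 1; j <= n; ++j) {
      int sub = H[(i - 1) * (n + 1) + j - 1] +
                (read[i - 1] == ref[j - 1] ? match : mismatch);
      int del = H[i * (n + 1) + j - 1] + gap;
      int ins = H[(i - 1) * (n + 1) + j] + gap;
      int h = sub; unsigned char d = 1;
      if (del > h) { h = del; d = 3; }
      if (ins > h) { h = ins; d = 2; }
      H[i * (n + 1) + j] = h;
      D[i * (n + 1) + j] = d;
    }
  }
  int jbest = n;
  for (int j = n; j >= 0; --j)
    if (H[m * (n + 1) + j] > H[m * (n + 1) + jbest]) jbest = j;
  ref_end = jbest;                       // 1-based inclusive (0 = none)
  int i = m, j = jbest;
  while (i > 0) {
    unsigned char d = D[i * (n + 1) + j];
    if (d == 1) {
      if (read[i - 1] != ref[j - 1]) { ev_pos.push_back(j); ev_type.push_back(1); }
      --i; --j;
    } else if (d == 3) {                 // deletion: ref base unmatched
      ev_pos.push_back(j); ev_type.push_back(2);
      --j;
    } else {                             // insertion after ref position j
      ev_pos.push_back(j); ev_type.push_back(3);
      --i;
    }
  }
  ref_start = j + 1;
}

// [[Rcpp::export(name = ".alignBatch")]]
List alignBatch(CharacterVector reads, CharacterVector refs,
                int match, int mismatch, int gap,
                IntegerVector precomputed) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nr), F(nf);
  for (int i = 0; i < nr; ++i) R[i] = as<std::string>(reads[i]);
  for (int k = 0; k < nf; ++k) F[k] = as<std::string>(refs[k]);

  IntegerVector best(nr), bestScore(nr), secondScore(nr),
      refStart(nr), refEnd(nr);
  std::vector<int> evRead, evPos, evType;
  std::vector<int> row;

  for (int i = 0; i < nr; ++i) {
    int b = -1, bs = INT32_MIN, ss = INT32_MIN;
    if (precomputed[i] > 0) {
      // caller already established an exact full-length match
      b = precomputed[i] - 1;
      bs = (int)R[i].size() * match;
      ss = INT32_MIN;
    } else {
      for (int k = 0; k < nf; ++k) {
        int s = score_pair(R[i], F[k], match, mismatch, gap, row);
        if (s > bs) { ss = bs; bs = s; b = k; }
        else if (s > ss) ss = s;
      }
    }
    best[i] = b + 1;
    bestScore[i] = bs;
    secondScore[i] = (ss == INT32_MIN) ? NA_INTEGER : ss;
    if (precomputed[i] > 0) {
      refStart[i] = 1;
      refEnd[i] = (int)F[b].size();
    } else {
      std::vector<int> ep, et;
      int rs = 0, re = 0;
      traceback_pair(R[i], F[b], match, mismatch, gap, rs, re, ep, et);
      refStart[i] = rs; refEnd[i] = re;
      for (size_t q = 0; q < ep.size(); ++q) {
        evRead.push_back(i + 1);
        evPos.push_back(ep[q]);
        evType.push_back(et[q]);
      }
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["best"] = best, _["bestScore"] = bestScore,
                      _["secondScore"] = secondScore,
                      _["refStart"] = refStart, _["refEnd"] = refEnd,
                      _["evRead"] = wrap(evRead), _["evPos"] = wrap(evPos),
                      _["evType"] = wrap(evType));
}
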