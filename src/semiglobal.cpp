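#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap semi-global DP: the read is aligned end to end, reference
// overhangs on either side are free. Three-state (M/X/Y) recurrence with
// byte backpointers for a fully deterministic traceback.
//
// States: M = read base against ref base (match or mismatch)
//         X = gap in the read (deletion, consumes reference)
//         Y = gap in the reference (insertion, consumes read)
// A gap of length L costs gap_open + gap_extend * L.
// Alignments never start or end in X: leading/trailing unaligned reference
// is an (unpenalized) overhang, not a deletion.
// Tie-breaking: M over X over Y at every cell; among equal-scoring end
// columns the leftmost (smallest reference span) wins.

static const int NEG = std::numeric_limits<int>::min() / 4;

// backpointer codes: previous state at each cell, per state
// 0 = start, 1 = from M, 2 = from X, 3 = from Y

// [[Rcpp::export(name = ".semiglobal_core")]]
List semiglobal_core(std::string read, std::string ref,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  const int W = n + 1;

  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  std::vector<unsigned char> bM((m + 1) * W, 0), bX((m + 1) * W, 0), bY((m + 1) * W, 0);

  for (int j = 0; j <= n; ++j) M[j] = 0;  // free leading reference overhang

  const int gin = gap_open + gap_extend;  // cost of opening a length-1 gap

  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    for (int j = 0; j <= n; ++j) {
      const int idx = i * W + j;
      // Y: consumes read base i, stays at ref j
      {
        const int up = (i - 1) * W + j;
        int best = NEG; unsigned char bp = 0;
        if (M[up] > NEG && M[up] - gin > best) { best = M[up] - gin; bp = 1; }
        if (X[up] > NEG && X[up] - gin > best) { best = X[up] - gin; bp = 2; }
        if (Y[up] > NEG && Y[up] - gap_extend > best) { best = Y[up] - gap_extend; bp = 3; }
        Y[idx] = best; bY[idx] = bp;
      }
      if (j == 0) continue;
      const char fc = ref[j - 1];
      // M: diagonal
      {
        const int di = (i - 1) * W + (j - 1);
        const bool is_match = (rc == fc) && rc != 'N';  // N never matches
        const int s = is_match ? match : -mismatch;
        int best = NEG; unsigned char bp = 0;
        if (M[di] > NEG && M[di] + s > best) { best = M[di] + s; bp = (i == 1) ? 0 : 1; }
        if (X[di] > NEG && X[di] + s > best) { best = X[di] + s; bp = 2; }
        if (Y[di] > NEG && Y[di] + s > best) { best = Y[di] + s; bp = 3; }
        M[idx] = best; bM[idx] = bp;
      }
      // X: consumes ref base j, stays at read i
      {
        const int le = i * W + (j - 1);
        int best = NEG; unsigned char bp = 0;
        if (M[le] > NEG && M[le] - gin > best) { best = M[le] - gin; bp = 1; }
        if (Y[le] > NEG && Y[le] - gin > best) { best = Y[le] - gin; bp = 3; }
        if (X[le] > NEG && X[le] - gap_extend > best) { best = X[le] - gap_extend; bp = 2; }
        X[idx] = best; bX[idx] = bp;
      }
    }
  }

  // end: best over columns j of M[m][j] or Y[m][j]; leftmost j wins ties,
  // M preferred over Y at equal score
  int best_score = NEG, best_j = 0; unsigned char best_state = 1;
  for (int j = 0; j <= n; ++j) {
    const int idx = m * W + j;
    if (M[idx] > best_score) { best_score = M[idx]; best_j = j; best_state = 1; }
    if (Y[idx] > best_score) { best_score = Y[idx]; best_j = j; best_state = 3; }
  }

  // traceback: emit per-column op codes then run-length merge in R caller
  // op codes: 1 match, 2 mismatch, 3 insertion, 4 deletion
  std::vector<int> op_code, op_ref;  // op and 0-based ref position (start for M/X, inter-base for Y)
  int i = m, j = best_j; unsigned char st = best_state;
  while (i > 0) {
    const int idx = i * W + j;
    if (st == 1) {
      const bool is_match = (read[i - 1] == ref[j - 1]) && read[i - 1] != 'N';
      op_code.push_back(is_match ? 1 : 2);
      op_ref.push_back(j - 1);
      st = bM[idx] == 0 ? 0 : bM[idx];
      --i; --j;
      if (st == 0) break;
    } else if (st == 2) {
      op_code.push_back(4);
      op_ref.push_back(j - 1);
      st = bX[idx];
      --j;
    } else {
      op_code.push_back(3);
      op_ref.push_back(j);
      st = bY[idx];
      --i;
    }
  }
  std::reverse(op_code.begin(), op_code.end());
  std::reverse(op_ref.begin(), op_ref.end());

  return List::create(_["score"] = best_score,
                      _["op"] = wrap(op_code),
                      _["ref_pos"] = wrap(op_ref));
}
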