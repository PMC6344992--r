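// CYK-style inside-max scorer for single-exemplar profile SCFGs.
//
// Nodes arrive in post-order (children before parents; the last node is the
// root). Spans are encoded as (i, jj): the subsequence seq[i .. jj-1], with
// jj == i the empty span. For each node three layers are computed:
//   CORE - emit/delete transitions from the child matrices
//   IL   - an affine run of left insertions before the node's emission
//   IR   - an affine run of right insertions
// and M = max(CORE, IL, IR). End nodes absorb any remaining bases as an
// affine insertion run; the root score is maximized over all spans, giving
// free end insertions (glocal alignment).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
double cmScoreCpp(IntegerVector nodeType, IntegerVector child1,
                  IntegerVector child2, NumericMatrix pairEmit,
                  NumericMatrix singleEmit, NumericVector delCost,
                  double gapOpen, double gapExtend, IntegerVector seqIdx) {
  const int nN = nodeType.size();
  const int L = seqIdx.size();
  const int W = L + 1;  // span index range for i and jj

  std::vector<std::vector<double>> M(nN);

  auto pairScore = [&](int v, int x, int y) -> double {
    if (x >= 4 || y >= 4) return 0.0;  // N: null-neutral
    return pairEmit(v, 4 * x + y);
  };
  auto singleScore = [&](int v, int x) -> double {
    if (x >= 4) return 0.0;
    return singleEmit(v, x);
  };
  auto insRun = [&](int len) -> double {
    if (len <= 0) return 0.0;
    return -(gapOpen + (len - 1) * gapExtend);
  };

  std::vector<double> CORE((size_t)W * W), IL((size_t)W * W),
      IR((size_t)W * W);

  for (int v = 0; v < nN; ++v) {
    M[v].assign((size_t)W * W, NEG_INF);
    const int type = nodeType[v];
    if (type == 4) {  // END: empty span or an insertion run
      for (int i = 0; i <= L; ++i)
        for (int jj = i; jj <= L; ++jj)
          M[v][(size_t)i * W + jj] = (jj == i) ? 0.0 : insRun(jj - i);
      continue;
    }
    if (type == 3) {  // BIF
      const std::vector<double>& ml = M[child1[v] - 1];
      const std::vector<double>& mr = M[child2[v] - 1];
      for (int i = 0; i <= L; ++i)
        for (int jj = i; jj <= L; ++jj) {
          double best = NEG_INF;
          for (int k = i; k <= jj; ++k) {
            double a = ml[(size_t)i * W + k];
            double b = mr[(size_t)k * W + jj];
            if (a > NEG_INF && b > NEG_INF && a + b > best) best = a + b;
          }
          M[v][(size_t)i * W + jj] = best;
        }
      // children consumed by exactly one parent; free them
      std::vector<double>().swap(M[child1[v] - 1]);
      std::vector<double>().swap(M[child2[v] - 1]);
      continue;
    }
    // PAIR (0), LEFT (1), RIGHT (2): CORE then insert channels
    const std::vector<double>& mc = M[child1[v] - 1];
    for (int i = 0; i <= L; ++i) {
      for (int jj = i; jj <= L; ++jj) {
        double best = NEG_INF;
        double del = mc[(size_t)i * W + jj];
        if (del > NEG_INF) best = del - delCost[v];
        if (type == 0 && jj - i >= 2) {
          double inner = mc[(size_t)(i + 1) * W + (jj - 1)];
          if (inner > NEG_INF) {
            double s = inner + pairScore(v, seqIdx[i], seqIdx[jj - 1]);
            if (s > best) best = s;
          }
        } else if (type == 1 && jj - i >= 1) {
          double inner = mc[(size_t)(i + 1) * W + jj];
          if (inner > NEG_INF) {
            double s = inner + singleScore(v, seqIdx[i]);
            if (s > best) best = s;
          }
        } else if (type == 2 && jj - i >= 1) {
          double inner = mc[(size_t)i * W + (jj - 1)];
          if (inner > NEG_INF) {
            double s = inner + singleScore(v, seqIdx[jj - 1]);
            if (s > best) best = s;
          }
        }
        CORE[(size_t)i * W + jj] = best;
      }
    }
    // IL: seq[i] inserted left of node v; fill with i descending
    for (int jj = 0; jj <= L; ++jj) {
      IL[(size_t)jj * W + jj] = NEG_INF;  // empty span holds no insertion
      for (int i = jj - 1; i >= 0; --i) {
        double best = NEG_INF;
        double fromCore = CORE[(size_t)(i + 1) * W + jj];
        if (fromCore > NEG_INF) best = fromCore - gapOpen;
        double fromIL = IL[(size_t)(i + 1) * W + jj];
        if (fromIL > NEG_INF && fromIL - gapExtend > best)
          best = fromIL - gapExtend;
        IL[(size_t)i * W + jj] = best;
      }
    }
    // IR: seq[jj-1] inserted right of node v; fill with jj ascending
    for (int i = 0; i <= L; ++i) {
      IR[(size_t)i * W + i] = NEG_INF;
      for (int jj = i + 1; jj <= L; ++jj) {
        double best = NEG_INF;
        double fromCore = CORE[(size_t)i * W + (jj - 1)];
        if (fromCore > NEG_INF) best = fromCore - gapOpen;
        double fromIR = IR[(size_t)i * W + (jj - 1)];
        if (fromIR > NEG_INF && fromIR - gapExtend > best)
          best = fromIR - gapExtend;
        IR[(size_t)i * W + jj] = best;
      }
    }
    for (int i = 0; i <= L; ++i)
      for (int jj = i; jj <= L; ++jj) {
        double best = CORE[(size_t)i * W + jj];
        double a = IL[(size_t)i * W + jj];
        double b = IR[(size_t)i * W + jj];
        if (a > best) best = a;
        if (b > best) best = b;
        M[v][(size_t)i * W + jj] = best;
      }
    std::vector<double>().swap(M[child1[v] - 1]);
  }

  const std::vector<double>& root = M[nN - 1];
  double best = NEG_INF;
  for (int i = 0; i <= L; ++i)
    for (int jj = i; jj <= L; ++jj)
      if (root[(size_t)i * W + jj] > best) best = root[(size_t)i * W + jj];
  return best;
}
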