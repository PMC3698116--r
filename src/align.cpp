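#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Banded global alignment of a received bit vector against a reference
// watermark vector w.  Indels are interpreted on the received side only:
// a "gap in received" leaves a w position with no received bit, a "gap in w"
// is forbidden conceptually, so an unmatched received bit is simply skipped.
// Costs: mismatch << indel (defaults 0.15 vs 1.0), so that a spurious
// insertion-deletion pair would have to save more than 2/mismatch matched
// positions to beat the identity path; ties resolve toward the diagonal.  Returns, for each w
// position, the aligned received bit, falling back to w's own value where a
// received bit is missing.
// [[Rcpp::export]]
IntegerVector align_to_watermark(IntegerVector w, IntegerVector received,
                                 int band, double mismatch = 0.15,
                                 double indel = 1.0) {
  const int L = w.size();
  const int R = received.size();
  const double INF = std::numeric_limits<double>::infinity();
  const double MISMATCH = mismatch, INDEL = indel;
  const int W = 2 * band + 1;

  // cost[i][j] stored banded: j in [i - band, i + band]
  std::vector<double> cost((size_t)(L + 1) * W, INF);
  std::vector<signed char> move((size_t)(L + 1) * W, 0); // 1 diag, 2 up (skip w), 3 left (skip r)
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i + band); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= R && j >= i - band && j <= i + band;
  };

  cost[idx(0, 0)] = 0.0;
  for (int j = 1; j <= R && j <= band; ++j) {
    cost[idx(0, j)] = j * INDEL;
    move[idx(0, j)] = 3;
  }
  for (int i = 1; i <= L; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(R, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double best = INF;
      signed char mv = 0;
      if (j >= 1 && inband(i - 1, j - 1) && cost[idx(i - 1, j - 1)] < INF) {
        double c = cost[idx(i - 1, j - 1)] +
                   (w[i - 1] == received[j - 1] ? 0.0 : MISMATCH);
        if (c < best) { best = c; mv = 1; } // diagonal preferred on ties
      }
      if (inband(i - 1, j) && cost[idx(i - 1, j)] < INF) {
        double c = cost[idx(i - 1, j)] + INDEL;
        if (c < best) { best = c; mv = 2; }
      }
      if (j >= 1 && inband(i, j - 1) && cost[idx(i, j - 1)] < INF) {
        double c = cost[idx(i, j - 1)] + INDEL;
        if (c < best) { best = c; mv = 3; }
      }
      cost[idx(i, j)] = best;
      move[idx(i, j)] = mv;
    }
  }

  IntegerVector out(L);
  int i = L, j = R;
  if (!inband(L, R) || cost[idx(L, R)] == INF) {
    stop("alignment band too narrow for the received drift");
  }
  while (i > 0 || j > 0) {
    signed char mv = move[idx(i, j)];
    if (mv == 1) {
      out[i - 1] = received[j - 1]; // keep the received value at mismatches
      --i; --j;
    } else if (mv == 2) {
      out[i - 1] = w[i - 1]; // received bit missing at this w position
      --i;
    } else if (mv == 3) {
      --j; // surplus received bit, dropped
    } else {
      stop("alignment traceback failed");
    }
  }
  return out;
}
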