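#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed similarity
// matrix sim (n x m): sim(i,j) is the score of pairing column i+1 of
// profile A with column j+1 of profile B.  A gap run of length L costs
// open + (L - 1) * ext.  Deterministic traceback: diagonal preferred,
// then a gap in A (B column against gap... see below), then a gap in B.
//
// States: M = columns paired; GA = A column against a gap ("gap in b");
// GB = B column against a gap ("gap in a").  Preference order for ties
// is M > GB > GA, i.e. match/mismatch first, then gap-in-a.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix sim, double open, double ext) {
  int n = sim.nrow(), m = sim.ncol();
  // DP tables, (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GA((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GB((n + 1) * (m + 1), NEG_INF);
#define IDX(i, j) ((i) * (m + 1) + (j))
  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) GA[IDX(i, 0)] = -(open + (i - 1) * ext);
  for (int j = 1; j <= m; ++j) GB[IDX(0, j)] = -(open + (j - 1) * ext);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dM = M[IDX(i - 1, j - 1)], dGB = GB[IDX(i - 1, j - 1)],
             dGA = GA[IDX(i - 1, j - 1)];
      double best = dM;
      if (dGB > best) best = dGB;
      if (dGA > best) best = dGA;
      if (best > NEG_INF / 2) M[IDX(i, j)] = best + sim(i - 1, j - 1);
      // GA: A column i against gap (move down)
      double a1 = M[IDX(i - 1, j)] - open;
      double a2 = GA[IDX(i - 1, j)] - ext;
      double a3 = GB[IDX(i - 1, j)] - open;
      GA[IDX(i, j)] = std::max(a1, std::max(a2, a3));
      // GB: B column j against gap (move right)
      double b1 = M[IDX(i, j - 1)] - open;
      double b2 = GB[IDX(i, j - 1)] - ext;
      double b3 = GA[IDX(i, j - 1)] - open;
      GB[IDX(i, j)] = std::max(b1, std::max(b2, b3));
    }
  }
  // final state: prefer M, then GB (gap in a), then GA
  double sM = M[IDX(n, m)], sGB = GB[IDX(n, m)], sGA = GA[IDX(n, m)];
  int state;  // 0 = M, 1 = GB, 2 = GA
  double score;
  if (sM >= sGB && sM >= sGA) { state = 0; score = sM; }
  else if (sGB >= sGA) { state = 1; score = sGB; }
  else { state = 2; score = sGA; }

  std::vector<int> ai, bi;  // 1-based column indices, 0 for gap
  int i = n, j = m;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) break;  // cannot happen for valid M
      double need = M[IDX(i, j)] - sim(i - 1, j - 1);
      ai.push_back(i); bi.push_back(j);
      double dM = M[IDX(i - 1, j - 1)], dGB = GB[IDX(i - 1, j - 1)],
             dGA = GA[IDX(i - 1, j - 1)];
      if (std::abs(dM - need) < tol) state = 0;
      else if (std::abs(dGB - need) < tol) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {  // GB: B column j against gap
      ai.push_back(0); bi.push_back(j);
      double cur = GB[IDX(i, j)];
      double fromM = M[IDX(i, j - 1)] - open;
      double fromGB = GB[IDX(i, j - 1)] - ext;
      if (std::abs(fromM - cur) < tol) state = 0;
      else if (std::abs(fromGB - cur) < tol) state = 1;
      else state = 2;
      --j;
    } else {  // GA: A column i against gap
      ai.push_back(i); bi.push_back(0);
      double cur = GA[IDX(i, j)];
      double fromM = M[IDX(i - 1, j)] - open;
      double fromGA = GA[IDX(i - 1, j)] - ext;
      if (std::abs(fromM - cur) < tol) state = 0;
      else if (std::abs(fromGA - cur) < tol) state = 2;
      else state = 1;
      --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
#undef IDX
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
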