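#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment with affine gaps. A gap of length k costs
// gap_open + k * gap_ext (BLAST convention). Sequences arrive as 0-based
// integer indices into the substitution matrix. Traceback ties are broken
// diagonal > up (gap in target) > left (gap in query); among equal-scoring
// end cells the first in row-major order wins, so output is deterministic.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int n = q.size(), m = t.size();
  if (n == 0 || m == 0)
    stop("smith_waterman: empty peptide");
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, INT_MIN / 4),
      F((n + 1) * W, INT_MIN / 4);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      E[idx] = std::max(H[idx - 1] - gap_open - gap_ext, E[idx - 1] - gap_ext);
      F[idx] = std::max(H[idx - W] - gap_open - gap_ext, F[idx - W] - gap_ext);
      int d = H[idx - W - 1] + sub(q[i - 1], t[j - 1]);
      int h = d;
      if (F[idx] > h) h = F[idx];
      if (E[idx] > h) h = E[idx];
      if (h < 0) h = 0;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // Traceback from the best cell in match state.
  std::vector<int> qa, ta;  // 0-based indices, -1 for gap
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (best > 0 && (i > 0 || j > 0)) {
    const int idx = i * W + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      const int d = H[idx - W - 1] + sub(q[i - 1], t[j - 1]);
      if (H[idx] == d) {
        qa.push_back(i - 1); ta.push_back(j - 1); --i; --j;
      } else if (H[idx] == F[idx]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      qa.push_back(i - 1); ta.push_back(-1);
      if (F[idx] == H[idx - W] - gap_open - gap_ext) state = 0;
      --i;
    } else {
      qa.push_back(-1); ta.push_back(j - 1);
      if (E[idx] == H[idx - 1] - gap_open - gap_ext) state = 0;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());

  int identical = 0, mismatches = 0, gapopens = 0;
  bool in_gap_q = false, in_gap_t = false;
  for (size_t k = 0; k < qa.size(); ++k) {
    if (qa[k] >= 0 && ta[k] >= 0) {
      in_gap_q = in_gap_t = false;
      if (q[qa[k]] == t[ta[k]]) ++identical; else ++mismatches;
    } else if (qa[k] < 0) {
      if (!in_gap_q) { ++gapopens; in_gap_q = true; }
      in_gap_t = false;
    } else {
      if (!in_gap_t) { ++gapopens; in_gap_t = true; }
      in_gap_q = false;
    }
  }
  // first/last consumed positions (1-based)
  int qs = 0, qe = -1, ts = 0, te = -1;
  for (size_t k = 0; k < qa.size(); ++k) if (qa[k] >= 0) { qs = qa[k] + 1; break; }
  for (size_t k = qa.size(); k > 0; --k) if (qa[k - 1] >= 0) { qe = qa[k - 1] + 1; break; }
  for (size_t k = 0; k < ta.size(); ++k) if (ta[k] >= 0) { ts = ta[k] + 1; break; }
  for (size_t k = ta.size(); k > 0; --k) if (ta[k - 1] >= 0) { te = ta[k - 1] + 1; break; }

  return List::create(
      _["score"] = best, _["qstart"] = qs, _["qend"] = qe, _["tstart"] = ts,
      _["tend"] = te, _["qa"] = wrap(qa), _["ta"] = wrap(ta),
      _["identical"] = identical, _["mismatches"] = mismatches,
      _["gapopens"] = gapopens, _["length"] = (int)qa.size());
}

// Exhaustive reference enumerator for the optimal local alignment score.
// Recurses over every gapped alignment path (affine gap state carried
// explicitly, no DP table), so it is an independent check of the Gotoh
// kernel. Exponential: intended for peptides of length <= 8.
static double naive_best(const IntegerVector& q, const IntegerVector& t,
                         const IntegerMatrix& sub, int open, int ext,
                         int i, int j, int gapstate) {
  double best = 0.0;  // stop here
  const int n = q.size(), m = t.size();
  if (i < n && j < m) {
    double s = sub(q[i], t[j]) +
               naive_best(q, t, sub, open, ext, i + 1, j + 1, 0);
    if (s > best) best = s;
  }
  if (i < n) {
    double s = -(gapstate == 1 ? ext : open + ext) +
               naive_best(q, t, sub, open, ext, i + 1, j, 1);
    if (s > best) best = s;
  }
  if (j < m) {
    double s = -(gapstate == 2 ? ext : open + ext) +
               naive_best(q, t, sub, open, ext, i, j + 1, 2);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export(name = ".sw_naive_cpp")]]
double sw_naive_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                    int gap_open, int gap_ext) {
  const int n = q.size(), m = t.size();
  if (n > 12 || m > 12)
    stop("naive enumerator is exponential; use peptides of length <= 12");
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      // an optimal local alignment starts (and ends) on an aligned pair
      double s = sub(q[i], t[j]) +
                 naive_best(q, t, sub, gap_open, gap_ext, i + 1, j + 1, 0);
      if (s > best) best = s;
    }
  return best;
}
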