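#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Chebyshev (max-norm) recurrence test between delay vectors i and j of the
// series x with embedding (m, tau); i, j are 0-based template starts.
static inline bool rec_pt(const double* x, int i, int j, int m, int tau,
                          double eps) {
  for (int k = 0; k < m; ++k) {
    double d = std::fabs(x[i + k * tau] - x[j + k * tau]);
    if (d > eps) return false;
  }
  return true;
}

// Sample entropy template counts: B = pairs of length-m templates within
// tolerance r (max norm, self-matches excluded), A = same for length m+1.
// Templates run over the first n-m starting positions for both lengths
// (Richman & Moorman convention).
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;
  if (N < 2) stop("series too short for template length m");
  const double* xp = x.begin();
  double A = 0, B = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (rec_pt(xp, i, j, m, 1, r)) {
        B += 1;
        if (std::fabs(xp[i + m] - xp[j + m]) <= r) A += 1;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

struct RqaAcc {
  std::vector<double> dhist;  // diagonal line histogram (upper triangle)
  std::vector<double> vhist;  // vertical line histogram (all columns)
  double rec_upper;           // recurrent cells strictly above the diagonal
  long long np;
};

static NumericVector rqa_finalize(const RqaAcc& acc, int lmin, int vmin) {
  long long np = acc.np;
  double off_cells = (double)np * (np - 1);
  double rr = off_cells > 0 ? 2.0 * acc.rec_upper / off_cells : 0.0;

  double d_all = 0, d_sel = 0, d_cnt = 0, lmax = 0;
  for (size_t l = 1; l < acc.dhist.size(); ++l) {
    double h = acc.dhist[l];
    if (h <= 0) continue;
    d_all += l * h;
    if ((int)l >= lmin) { d_sel += l * h; d_cnt += h; }
    if ((double)l > lmax) lmax = (double)l;
  }
  double det = d_all > 0 ? d_sel / d_all : 0.0;
  double lmean = d_cnt > 0 ? d_sel / d_cnt : 0.0;
  double lentr = 0.0;
  if (d_cnt > 0) {
    for (size_t l = lmin; l < acc.dhist.size(); ++l) {
      double h = acc.dhist[l];
      if (h > 0) {
        double p = h / d_cnt;
        lentr -= p * std::log(p);
      }
    }
  }

  double v_all = 0, v_sel = 0, v_cnt = 0;
  for (size_t v = 1; v < acc.vhist.size(); ++v) {
    double h = acc.vhist[v];
    if (h <= 0) continue;
    v_all += v * h;
    if ((int)v >= vmin) { v_sel += v * h; v_cnt += h; }
  }
  double lam = v_all > 0 ? v_sel / v_all : 0.0;
  double tt = v_cnt > 0 ? v_sel / v_cnt : 0.0;

  NumericVector out = NumericVector::create(
    _["RR"] = rr, _["DET"] = det, _["LAM"] = lam, _["L_max"] = lmax,
    _["L_entr"] = lentr, _["L_mean"] = lmean, _["TT"] = tt);
  out.attr("degenerate") = (d_cnt == 0 && v_cnt == 0);
  return out;
}

// RQA statistics straight from a series: the recurrence matrix (max-norm,
// threshold eps, line of identity excluded) is streamed diagonal-by-diagonal
// and column-by-column without being materialized, so full-length band
// series are feasible.
// [[Rcpp::export]]
NumericVector rqa_series_cpp(NumericVector x, int m, int tau, double eps,
                             int lmin, int vmin) {
  int n = x.size();
  int np = n - (m - 1) * tau;
  if (np < 2) stop("series too short for embedding");
  const double* xp = x.begin();
  RqaAcc acc;
  acc.np = np;
  acc.dhist.assign(np + 1, 0.0);
  acc.vhist.assign(np + 1, 0.0);
  acc.rec_upper = 0;

  for (int d = 1; d < np; ++d) {
    int run = 0;
    for (int i = 0; i + d < np; ++i) {
      if (rec_pt(xp, i, i + d, m, tau, eps)) {
        ++run;
        acc.rec_upper += 1;
      } else if (run > 0) {
        acc.dhist[run] += 1;
        run = 0;
      }
    }
    if (run > 0) acc.dhist[run] += 1;
  }
  for (int j = 0; j < np; ++j) {
    int run = 0;
    for (int i = 0; i < np; ++i) {
      bool r = (i != j) && rec_pt(xp, i, j, m, tau, eps);
      if (r) ++run;
      else if (run > 0) { acc.vhist[run] += 1; run = 0; }
    }
    if (run > 0) acc.vhist[run] += 1;
  }
  return rqa_finalize(acc, lmin, vmin);
}

// Same statistics from an explicit binary recurrence matrix.
// [[Rcpp::export]]
NumericVector rqa_matrix_cpp(LogicalMatrix rp, int lmin, int vmin,
                             bool loi_excluded) {
  int np = rp.nrow();
  if (rp.ncol() != np) stop("recurrence matrix must be square");
  RqaAcc acc;
  acc.np = np;
  acc.dhist.assign(np + 1, 0.0);
  acc.vhist.assign(np + 1, 0.0);
  acc.rec_upper = 0;

  for (int d = 1; d < np; ++d) {
    int run = 0;
    for (int i = 0; i + d < np; ++i) {
      if (rp(i, i + d)) {
        ++run;
        acc.rec_upper += 1;
      } else if (run > 0) { acc.dhist[run] += 1; run = 0; }
    }
    if (run > 0) acc.dhist[run] += 1;
  }
  for (int j = 0; j < np; ++j) {
    int run = 0;
    for (int i = 0; i < np; ++i) {
      bool r = rp(i, j) && !(loi_excluded && i == j);
      if (r) ++run;
      else if (run > 0) { acc.vhist[run] += 1; run = 0; }
    }
    if (run > 0) acc.vhist[run] += 1;
  }
  return rqa_finalize(acc, lmin, vmin);
}
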