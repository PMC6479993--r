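// Correlation optimized warping (COW): dynamic programming over segment
// boundary positions. The reference is cut into N segments of roughly
// `seg` points with fixed boundaries; the matching sample boundaries may
// move by at most `slack` points per segment. Each candidate sample
// segment is linearly interpolated onto the reference segment length and
// scored by its Pearson correlation with the reference segment; the DP
// maximises the sum of segment correlations, with both endpoints fixed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pearson correlation between the linear interpolation of x[q..p] onto
// `len` points and a pre-centered reference segment refc (sum(refc) == 0,
// nrm = sqrt(sum(refc^2))). Segments whose variance is negligible against
// the whole signal (var_floor, per point) are degenerate and score 0:
// their "correlation" would be numerical noise and must not steer the warp.
static double seg_corr(const double* x, int q, int p,
                       const std::vector<double>& refc, double nrm,
                       int len, double x_var_floor) {
  if (nrm <= 0.0) return 0.0;
  const double step = (double)(p - q) / (double)(len - 1);
  double sum = 0.0, sumsq = 0.0, cross = 0.0;
  for (int k = 0; k < len; ++k) {
    double pos = q + step * k;
    int i0 = (int)std::floor(pos);
    if (i0 >= p) i0 = p - 1;
    double fr = pos - i0;
    double v = x[i0] * (1.0 - fr) + x[i0 + 1] * fr;
    sum += v;
    sumsq += v * v;
    cross += v * refc[k];
  }
  double mean = sum / len;
  double ss = sumsq - (double)len * mean * mean;
  if (ss <= x_var_floor * len) return 0.0;
  return cross / (std::sqrt(ss) * nrm);  // sum(refc)==0 makes cross centered
}

// Per-point variance of a signal, used to scale the degeneracy floor.
static double point_var(const double* x, int n) {
  double s = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) { s += x[i]; ss += x[i] * x[i]; }
  double m = s / n;
  return std::max(ss / n - m * m, 0.0);
}

static void interp_segment(const double* x, int q, int p, double* out,
                           int len) {
  const double step = (double)(p - q) / (double)(len - 1);
  for (int k = 0; k < len; ++k) {
    double pos = q + step * k;
    int i0 = (int)std::floor(pos);
    if (i0 >= p) i0 = p - 1;
    double fr = pos - i0;
    out[k] = x[i0] * (1.0 - fr) + x[i0 + 1] * fr;
  }
}

// [[Rcpp::export]]
List cow_dp_cpp(NumericVector x, NumericVector ref, int seg, int slack) {
  const int Lx = x.size(), Lr = ref.size();
  if (Lx < 4 || Lr < 4) stop("signals too short to warp");
  if (seg < 2) stop("`segment_length` must be >= 2");
  if (slack < 0) stop("`slack` must be >= 0");

  const int N = std::max(1, (int)std::floor((double)(Lr - 1) / seg + 0.5));
  std::vector<int> v(N + 1), u(N + 1);
  for (int i = 0; i <= N; ++i) {
    v[i] = (int)std::floor((double)i * (Lr - 1) / N + 0.5);
    u[i] = (int)std::floor((double)i * (Lx - 1) / N + 0.5);
  }

  // Feasible sample-boundary ranges from forward/backward slack budgets;
  // every sample segment keeps at least 2 points.
  std::vector<int> lof(N + 1), hif(N + 1), lob(N + 1), hib(N + 1);
  std::vector<int> lo(N + 1), hi(N + 1);
  lof[0] = hif[0] = 0;
  for (int i = 1; i <= N; ++i) {
    int d = u[i] - u[i - 1];
    lof[i] = lof[i - 1] + std::max(2, d - slack);
    hif[i] = hif[i - 1] + d + slack;
  }
  lob[N] = hib[N] = Lx - 1;
  for (int i = N - 1; i >= 0; --i) {
    int d = u[i + 1] - u[i];
    lob[i] = lob[i + 1] - (d + slack);
    hib[i] = hib[i + 1] - std::max(2, d - slack);
  }
  for (int i = 0; i <= N; ++i) {
    lo[i] = std::max(lof[i], lob[i]);
    hi[i] = std::min(hif[i], hib[i]);
    if (lo[i] > hi[i]) {
      stop("infeasible warp: this segment/slack combination cannot map the "
           "signal onto the reference");
    }
  }

  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<std::vector<double> > F(N + 1);
  std::vector<std::vector<int> > pred(N + 1);
  F[0].assign(1, 0.0);
  pred[0].assign(1, -1);

  const double* xp = REAL(x);
  const double* rp = REAL(ref);

  // Degeneracy floors: a segment with variance below 1e-10 of the signal's
  // per-point variance carries no usable shape information.
  const double x_var_floor = 1e-10 * point_var(xp, Lx);
  const double r_var_floor = 1e-10 * point_var(rp, Lr);
  // Tiny quadratic penalty on boundary displacement: breaks the ties left
  // by degenerate segments toward the unwarped (nominal) boundaries, far
  // below the scale of any real correlation difference.
  const double disp_pen = 1e-6 / ((double)(slack + 1) * (slack + 1));

  for (int i = 1; i <= N; ++i) {
    const int len = v[i] - v[i - 1] + 1;
    std::vector<double> refc(len);
    double rs = 0.0;
    for (int k = 0; k < len; ++k) rs += rp[v[i - 1] + k];
    rs /= len;
    double nrm = 0.0;
    for (int k = 0; k < len; ++k) {
      refc[k] = rp[v[i - 1] + k] - rs;
      nrm += refc[k] * refc[k];
    }
    if (nrm <= r_var_floor * len) nrm = 0.0;
    nrm = std::sqrt(nrm);

    const int d = u[i] - u[i - 1];
    const int dmin = std::max(2, d - slack), dmax = d + slack;
    F[i].assign(hi[i] - lo[i] + 1, NEG);
    pred[i].assign(hi[i] - lo[i] + 1, -1);
    for (int p = lo[i]; p <= hi[i]; ++p) {
      const int qlo = std::max(lo[i - 1], p - dmax);
      const int qhi = std::min(hi[i - 1], p - dmin);
      double best = NEG;
      int bq = -1;
      const double dp_here = (double)(p - u[i]);
      for (int q = qlo; q <= qhi; ++q) {
        double fprev = F[i - 1][q - lo[i - 1]];
        if (fprev == NEG) continue;
        double sc = fprev + seg_corr(xp, q, p, refc, nrm, len, x_var_floor)
          - disp_pen * dp_here * dp_here;
        if (sc > best) { best = sc; bq = q; }
      }
      F[i][p - lo[i]] = best;
      pred[i][p - lo[i]] = bq;
    }
  }

  if (F[N][0] == NEG) stop("infeasible warp: no boundary path found");

  // Backtrack (boundary N is the single fixed endpoint Lx-1).
  std::vector<int> b(N + 1);
  b[N] = Lx - 1;
  for (int i = N; i >= 1; --i) b[i - 1] = pred[i][b[i] - lo[i]];

  NumericVector warped(Lr);
  for (int i = 1; i <= N; ++i) {
    const int len = v[i] - v[i - 1] + 1;
    std::vector<double> outv(len);
    interp_segment(xp, b[i - 1], b[i], outv.data(), len);
    for (int k = 0; k < len; ++k) warped[v[i - 1] + k] = outv[k];
  }

  IntegerVector src(N + 1), tgt(N + 1);
  for (int i = 0; i <= N; ++i) { src[i] = b[i] + 1; tgt[i] = v[i] + 1; }

  return List::create(_["warped"] = warped,
                      _["source"] = src,
                      _["target"] = tgt,
                      _["score"] = F[N][0],
                      _["n_segments"] = N);
}
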