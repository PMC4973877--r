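#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed point of the three self-consistent Information Bottleneck equations
//   P(m|x) = P(m)/Z(x,beta) * exp(-beta * KL[P(y|x) || P(y|m)])
//   P(m)   = sum_x P(x) P(m|x)
//   P(y|m) = sum_x P(y|x) P(x|m)
// on a discrete alphabet.  Convergence: largest per-row total-variation
// change of the encoder under one update falls below `tol`.
//
// The plain update map converges geometrically but suffers critical slowing
// near cluster-split transitions, so the driver wraps it in SQUAREM-style
// extrapolation (Varadhan & Roland 2008): two map evaluations give a
// steplength, the extrapolated point is projected back onto the row
// simplices, and a safeguarded map evaluation keeps every accepted iterate a
// genuine map image.  Everything is deterministic.
//
// pyx:  K x Y conditional P(y|x), rows sum to 1, entries may be 0
// px:   length-K marginal P(x)
// enc0: K x M initial encoder, rows sum to 1
// KL divergences use natural logs; bit conversions happen in the R wrapper.

namespace {

struct IBProblem {
  int K, Y, M;
  const double *pyx; // K x Y, column-major
  const double *px;
  std::vector<double> hrow; // sum_y p log p per input row
};

// one application of the self-consistent update; returns the largest
// per-row total-variation change
double ib_step(const IBProblem &pb, const std::vector<double> &enc,
               std::vector<double> &out, double beta) {
  const int K = pb.K, Y = pb.Y, M = pb.M;
  std::vector<double> pm(M), dec(M * Y), ldec(M * Y), lg(M);
  const double NEG_BIG = -745.0;
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += pb.px[k] * enc[m * K + k];
    pm[m] = s;
    for (int y = 0; y < Y; ++y) {
      double sy = 0.0;
      for (int k = 0; k < K; ++k)
        sy += pb.pyx[y * K + k] * pb.px[k] * enc[m * K + k];
      double d = (s > 0) ? sy / s : 1.0 / Y;
      dec[m * Y + y] = d;
      ldec[m * Y + y] = (d > 0) ? std::log(d) : NEG_BIG;
    }
  }
  double resid = 0.0;
  for (int k = 0; k < K; ++k) {
    double mx = -HUGE_VAL;
    for (int m = 0; m < M; ++m) {
      if (pm[m] <= 0) { lg[m] = -HUGE_VAL; continue; }
      double cross = 0.0;
      for (int y = 0; y < Y; ++y) cross += pb.pyx[y * K + k] * ldec[m * Y + y];
      lg[m] = std::log(pm[m]) - beta * (pb.hrow[k] - cross);
      if (lg[m] > mx) mx = lg[m];
    }
    double z = 0.0;
    for (int m = 0; m < M; ++m) {
      lg[m] = (lg[m] > -HUGE_VAL) ? std::exp(lg[m] - mx) : 0.0;
      z += lg[m];
    }
    double tv = 0.0;
    for (int m = 0; m < M; ++m) {
      double nv = lg[m] / z;
      tv += std::fabs(nv - enc[m * K + k]);
      out[m * K + k] = nv;
    }
    if (0.5 * tv > resid) resid = 0.5 * tv;
  }
  return resid;
}

// clip tiny negatives from extrapolation and renormalise each row
void project_rows(std::vector<double> &enc, int K, int M) {
  for (int k = 0; k < K; ++k) {
    double z = 0.0;
    for (int m = 0; m < M; ++m) {
      double v = enc[m * K + k];
      if (v < 1e-300 || !std::isfinite(v)) v = 1e-300;
      enc[m * K + k] = v;
      z += v;
    }
    for (int m = 0; m < M; ++m) enc[m * K + k] /= z;
  }
}

} // namespace

// [[Rcpp::export(name = ".ib_core")]]
List ib_core(NumericMatrix pyx, NumericVector px, double beta,
             NumericMatrix enc0, double tol, int max_iter) {
  const int K = pyx.nrow(), Y = pyx.ncol(), M = enc0.ncol();
  IBProblem pb{K, Y, M, pyx.begin(), px.begin(), {}};
  pb.hrow.assign(K, 0.0);
  for (int k = 0; k < K; ++k)
    for (int y = 0; y < Y; ++y)
      if (pyx(k, y) > 0) pb.hrow[k] += pyx(k, y) * std::log(pyx(k, y));

  const size_t n = (size_t)K * M;
  std::vector<double> e0(enc0.begin(), enc0.end());
  std::vector<double> e1(n), e2(n), ex(n), e3(n);
  double resid = R_PosInf;
  int evals = 0;
  bool converged = false;

  while (evals < max_iter && !converged) {
    double r1 = ib_step(pb, e0, e1, beta); ++evals;
    if (r1 < tol) { e0 = e1; resid = r1; converged = true; break; }
    if (evals >= max_iter) { e0 = e1; resid = r1; break; }
    double r2 = ib_step(pb, e1, e2, beta); ++evals;
    if (r2 < tol) { e0 = e2; resid = r2; converged = true; break; }
    if (evals >= max_iter) { e0 = e2; resid = r2; break; }
    // SQUAREM S3 steplength
    double rr = 0.0, vv = 0.0;
    for (size_t i = 0; i < n; ++i) {
      double r = e1[i] - e0[i];
      double v = (e2[i] - e1[i]) - r;
      rr += r * r;
      vv += v * v;
    }
    if (vv <= 1e-30) { e0 = e2; resid = r2; continue; }
    double alpha = -std::sqrt(rr / vv);
    if (alpha > -1.0) alpha = -1.0; // never shorter than a plain double step
    for (size_t i = 0; i < n; ++i) {
      double r = e1[i] - e0[i];
      double v = (e2[i] - e1[i]) - r;
      ex[i] = e0[i] - 2.0 * alpha * r + alpha * alpha * v;
    }
    project_rows(ex, K, M);
    double r3 = ib_step(pb, ex, e3, beta); ++evals;
    if (r3 <= r2) { e0 = e3; resid = r3; } // accept accelerated step
    else          { e0 = e2; resid = r2; } // safeguard: keep plain iterate
    if (resid < tol) converged = true;
  }

  NumericMatrix enc(K, M);
  std::copy(e0.begin(), e0.end(), enc.begin());
  NumericVector pm_out(M);
  NumericMatrix dec_out(M, Y);
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += px[k] * enc(k, m);
    pm_out[m] = s;
    for (int y = 0; y < Y; ++y) {
      double sy = 0.0;
      for (int k = 0; k < K; ++k) sy += pyx(k, y) * px[k] * enc(k, m);
      dec_out(m, y) = (s > 0) ? sy / s : 1.0 / Y;
    }
  }
  return List::create(_["encoder"] = enc, _["marginal"] = pm_out,
                      _["decoder"] = dec_out, _["iterations"] = evals,
                      _["residual"] = resid, _["converged"] = converged);
}
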