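#include <Rcpp.h>
using namespace Rcpp;

// Penalized objective and gradient for beads-on-a-string reconstruction.
//
// x           : coordinates, length 3N (bead-major: x1,y1,z1,x2,...)
// ti, tj      : 0-based bead indices of target distance entries
// delta       : target distances (nm)
// chrom       : 0-based chromosome index per bead (adjacency = same chrom,
//               consecutive index)
// r_nucleus   : nucleus radius (nm)
// adj_bound   : maximal distance between adjacent beads (nm)
// min_sep     : minimal distance between non-adjacent beads (nm)
// w_*         : penalty weights
//
// Returns list(value, sse, grad). `sse` is the bare sum of squared
// target errors; `value` adds the constraint penalties.
// [[Rcpp::export]]
List obj_grad_cpp(NumericVector x, IntegerVector ti, IntegerVector tj,
                  NumericVector delta, IntegerVector chrom,
                  double r_nucleus, double adj_bound, double min_sep,
                  double w_nucleus, double w_adj, double w_sep) {
  const int N = chrom.size();
  NumericVector grad(3 * N);
  double sse = 0.0, pen = 0.0;
  const double eps = 1e-12;

  // target terms: (||pi - pj|| - delta)^2
  for (int t = 0; t < ti.size(); ++t) {
    int a = ti[t], b = tj[t];
    double dx = x[3*a] - x[3*b];
    double dy = x[3*a+1] - x[3*b+1];
    double dz = x[3*a+2] - x[3*b+2];
    double d = sqrt(dx*dx + dy*dy + dz*dz);
    double e = d - delta[t];
    sse += e * e;
    double c = 2.0 * e / (d + eps);
    grad[3*a]   += c * dx; grad[3*a+1] += c * dy; grad[3*a+2] += c * dz;
    grad[3*b]   -= c * dx; grad[3*b+1] -= c * dy; grad[3*b+2] -= c * dz;
  }

  // nucleus confinement: max(0, r - R)^2
  for (int k = 0; k < N; ++k) {
    double r = sqrt(x[3*k]*x[3*k] + x[3*k+1]*x[3*k+1] + x[3*k+2]*x[3*k+2]);
    double v = r - r_nucleus;
    if (v > 0) {
      pen += w_nucleus * v * v;
      double c = 2.0 * w_nucleus * v / (r + eps);
      grad[3*k] += c * x[3*k]; grad[3*k+1] += c * x[3*k+1];
      grad[3*k+2] += c * x[3*k+2];
    }
  }

  // adjacency elasticity: max(0, d - bound)^2 for consecutive beads
  for (int k = 0; k + 1 < N; ++k) {
    if (chrom[k] != chrom[k + 1]) continue;
    double dx = x[3*k] - x[3*(k+1)];
    double dy = x[3*k+1] - x[3*(k+1)+1];
    double dz = x[3*k+2] - x[3*(k+1)+2];
    double d = sqrt(dx*dx + dy*dy + dz*dz);
    double v = d - adj_bound;
    if (v > 0) {
      pen += w_adj * v * v;
      double c = 2.0 * w_adj * v / (d + eps);
      grad[3*k]   += c * dx; grad[3*k+1] += c * dy; grad[3*k+2] += c * dz;
      grad[3*(k+1)]   -= c * dx; grad[3*(k+1)+1] -= c * dy;
      grad[3*(k+1)+2] -= c * dz;
    }
  }

  // short-range repulsion: max(0, s - d)^2 for non-adjacent pairs
  if (min_sep > 0) {
    for (int a = 0; a < N; ++a) {
      for (int b = a + 1; b < N; ++b) {
        if (chrom[a] == chrom[b] && b - a == 1) continue;
        double dx = x[3*a] - x[3*b];
        if (fabs(dx) >= min_sep) continue;
        double dy = x[3*a+1] - x[3*b+1];
        if (fabs(dy) >= min_sep) continue;
        double dz = x[3*a+2] - x[3*b+2];
        if (fabs(dz) >= min_sep) continue;
        double d = sqrt(dx*dx + dy*dy + dz*dz);
        double v = min_sep - d;
        if (v > 0) {
          pen += w_sep * v * v;
          double c = -2.0 * w_sep * v / (d + eps);
          grad[3*a]   += c * dx; grad[3*a+1] += c * dy; grad[3*a+2] += c * dz;
          grad[3*b]   -= c * dx; grad[3*b+1] -= c * dy; grad[3*b+2] -= c * dz;
        }
      }
    }
  }

  return List::create(_["value"] = sse + pen, _["sse"] = sse,
                      _["grad"] = grad);
}

// Maximum constraint violation (nm) of a configuration.
// Returns c(nucleus, adjacency, separation) max violations.
// [[Rcpp::export]]
NumericVector violations_cpp(NumericVector x, IntegerVector chrom,
                             double r_nucleus, double adj_bound,
                             double min_sep) {
  const int N = chrom.size();
  double vn = 0.0, va = 0.0, vs = 0.0;
  for (int k = 0; k < N; ++k) {
    double r = sqrt(x[3*k]*x[3*k] + x[3*k+1]*x[3*k+1] + x[3*k+2]*x[3*k+2]);
    if (r - r_nucleus > vn) vn = r - r_nucleus;
  }
  for (int k = 0; k + 1 < N; ++k) {
    if (chrom[k] != chrom[k + 1]) continue;
    double dx = x[3*k] - x[3*(k+1)];
    double dy = x[3*k+1] - x[3*(k+1)+1];
    double dz = x[3*k+2] - x[3*(k+1)+2];
    double d = sqrt(dx*dx + dy*dy + dz*dz);
    if (d - adj_bound > va) va = d - adj_bound;
  }
  if (min_sep > 0) {
    for (int a = 0; a < N; ++a) {
      for (int b = a + 1; b < N; ++b) {
        if (chrom[a] == chrom[b] && b - a == 1) continue;
        double dx = x[3*a] - x[3*b];
        if (fabs(dx) >= min_sep) continue;
        double dy = x[3*a+1] - x[3*b+1];
        if (fabs(dy) >= min_sep) continue;
        double dz = x[3*a+2] - x[3*b+2];
        if (fabs(dz) >= min_sep) continue;
        double d = sqrt(dx*dx + dy*dy + dz*dz);
        if (min_sep - d > vs) vs = min_sep - d;
      }
    }
  }
  return NumericVector::create(vn, va, vs);
}
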