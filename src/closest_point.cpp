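#include <Rcpp.h>
using namespace Rcpp;

// Closest point on a single triangle (a, b, c) to point p.
// Standard region-partition method (project onto plane, clamp to edges).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export(name = ".cpp_closest_on_mesh")]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int n = P.nrow(), nf = F.nrow();
  NumericMatrix cp(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n);

  // column-major copies flattened to row-triples for cache locality
  std::vector<double> pv(3 * n), vv(3 * V.nrow());
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) pv[3 * i + j] = P(i, j);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vv[3 * i + j] = V(i, j);

  for (int i = 0; i < n; ++i) {
    const double *p = &pv[3 * i];
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int besttri = 0;
    double out[3];
    for (int f = 0; f < nf; ++f) {
      const double *a = &vv[3 * (F(f, 0) - 1)];
      const double *b = &vv[3 * (F(f, 1) - 1)];
      const double *c = &vv[3 * (F(f, 2) - 1)];
      closest_on_tri(p, a, b, c, out);
      double dx = out[0] - p[0], dy = out[1] - p[1], dz = out[2] - p[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestpt[0] = out[0]; bestpt[1] = out[1]; bestpt[2] = out[2];
        besttri = f + 1;
      }
    }
    cp(i, 0) = bestpt[0]; cp(i, 1) = bestpt[1]; cp(i, 2) = bestpt[2];
    dist[i] = std::sqrt(best);
    tri[i] = besttri;
  }
  return List::create(_["points"] = cp, _["dist"] = dist, _["tri"] = tri);
}
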