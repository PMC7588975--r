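#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compiled fast path of the flashlight-searching (FS) point-to-surface
// distance for the two parametric families (ellipse conic, cashew quartic).
// The generic R implementation in R/fs.R is the reference; this engine is
// algorithmically equivalent but refines probe-ray roots by Newton's method
// started at the probe point, which lands on the surface arc nearest the
// current iterate.

struct Surface {
  int family; // 1 = ellipse, 2 = cashew
  int dim;
  double par[11];
  double M[9]; // rotation, row-major (cashew only)

  double value(const double* x) const {
    if (family == 1) {
      return par[0]*x[0]*x[0] + 2.0*par[1]*x[0]*x[1] + par[2]*x[1]*x[1]
           + par[3]*x[0] + par[4]*x[1] + par[5];
    }
    const double a = par[0], b = par[1], c = par[2], d = par[3], s = par[4];
    double w[3] = {x[0]-par[5], x[1]-par[6], x[2]-par[7]};
    double u0 = s*(M[0]*w[0] + M[1]*w[1] + M[2]*w[2]);
    double u1 = s*(M[3]*w[0] + M[4]*w[1] + M[5]*w[2]);
    double u2 = s*(M[6]*w[0] + M[7]*w[1] + M[8]*w[2]);
    double q = 1.5*u0*u0 + u1*u1 + u2*u2 + a*a - b*b;
    return q*q - 4.0*a*a*((u0-c)*(u0-c) + (u1-d)*(u1-d));
  }

  void gradient(const double* x, double* g) const {
    if (family == 1) {
      g[0] = 2.0*par[0]*x[0] + 2.0*par[1]*x[1] + par[3];
      g[1] = 2.0*par[1]*x[0] + 2.0*par[2]*x[1] + par[4];
      return;
    }
    const double a = par[0], b = par[1], c = par[2], d = par[3], s = par[4];
    double w[3] = {x[0]-par[5], x[1]-par[6], x[2]-par[7]};
    double u0 = s*(M[0]*w[0] + M[1]*w[1] + M[2]*w[2]);
    double u1 = s*(M[3]*w[0] + M[4]*w[1] + M[5]*w[2]);
    double u2 = s*(M[6]*w[0] + M[7]*w[1] + M[8]*w[2]);
    double q = 1.5*u0*u0 + u1*u1 + u2*u2 + a*a - b*b;
    double gu0 = 6.0*q*u0 - 8.0*a*a*(u0-c);
    double gu1 = 4.0*q*u1 - 8.0*a*a*(u1-d);
    double gu2 = 4.0*q*u2;
    g[0] = s*(M[0]*gu0 + M[3]*gu1 + M[6]*gu2);
    g[1] = s*(M[1]*gu0 + M[4]*gu1 + M[7]*gu2);
    g[2] = s*(M[2]*gu0 + M[5]*gu1 + M[8]*gu2);
  }
};

static double norm_d(const double* v, int d) {
  double s = 0; for (int i = 0; i < d; ++i) s += v[i]*v[i];
  return std::sqrt(s);
}

// Smallest-|c| root of Psi(p + c*dir) on [-L, L]: grid scan + bisection.
// Returns NaN when no sign change is found.
static double nearest_ray_root(const Surface& S, const double* p,
                               const double* dir, double L, int n_scan) {
  int d = S.dim;
  double best = NA_REAL, bestabs = 1e300;
  double x[3];
  std::vector<double> vals(2*n_scan + 1);
  double h = L / n_scan;
  for (int j = -n_scan; j <= n_scan; ++j) {
    for (int k = 0; k < d; ++k) x[k] = p[k] + dir[k]*(j*h);
    vals[j + n_scan] = S.value(x);
  }
  for (int j = -n_scan; j < n_scan; ++j) {
    double f0 = vals[j + n_scan], f1 = vals[j + 1 + n_scan];
    if (f0 == 0.0) {
      if (std::fabs(j*h) < bestabs) { best = j*h; bestabs = std::fabs(j*h); }
      continue;
    }
    if (f0 * f1 < 0) {
      double lo = j*h, hi = (j+1)*h, flo = f0;
      for (int b = 0; b < 80; ++b) {
        double mid = 0.5*(lo + hi);
        for (int k = 0; k < d; ++k) x[k] = p[k] + dir[k]*mid;
        double fm = S.value(x);
        if (flo * fm <= 0) hi = mid; else { lo = mid; flo = fm; }
      }
      double c = 0.5*(lo + hi);
      if (std::fabs(c) < bestabs) { best = c; bestabs = std::fabs(c); }
    }
  }
  return best;
}

// Root of Psi(p + c*u) near c = 1 (u = probe - p): Newton with scan
// fallback on c in [0, 2].
static double probe_ray_root(const Surface& S, const double* p,
                             const double* u, double psi_scale) {
  int d = S.dim;
  double c = 1.0, x[3], g[3];
  for (int it = 0; it < 30; ++it) {
    for (int k = 0; k < d; ++k) x[k] = p[k] + u[k]*c;
    double f = S.value(x);
    if (std::fabs(f) < 1e-13 * psi_scale) return c;
    S.gradient(x, g);
    double fp = 0; for (int k = 0; k < d; ++k) fp += g[k]*u[k];
    if (std::fabs(fp) < 1e-300) break;
    double step = f / fp;
    if (!std::isfinite(step) || std::fabs(step) > 0.5) break;
    c -= step;
    if (c < -1.0 || c > 3.0) break;
  }
  // fallback: bracket scan around c = 1
  const int ns = 64;
  double prev = NA_REAL, prevc = 0;
  double lo = NA_REAL, hi = NA_REAL, flo = 0;
  double bestd = 1e300, bestlo = NA_REAL, besthi = NA_REAL, bestflo = 0;
  for (int j = 0; j <= ns; ++j) {
    double cj = 2.0 * j / ns;
    for (int k = 0; k < d; ++k) x[k] = p[k] + u[k]*cj;
    double f = S.value(x);
    if (j > 0 && prev * f < 0) {
      double mid = 0.5*(prevc + cj);
      if (std::fabs(mid - 1.0) < bestd) {
        bestd = std::fabs(mid - 1.0);
        bestlo = prevc; besthi = cj; bestflo = prev;
      }
    }
    prev = f; prevc = cj;
  }
  if (!std::isfinite(bestlo)) return NA_REAL;
  lo = bestlo; hi = besthi; flo = bestflo;
  for (int b = 0; b < 80; ++b) {
    double mid = 0.5*(lo + hi);
    for (int k = 0; k < d; ++k) x[k] = p[k] + u[k]*mid;
    double fm = S.value(x);
    if (flo * fm <= 0) hi = mid; else { lo = mid; flo = fm; }
  }
  return 0.5*(lo + hi);
}

struct FSOut {
  double dist;
  double foot[3];
  int iters;
  double align;
  bool ok;
};

// Tangent-probe descent from an on-surface start point x0.
static FSOut fs_descend(const Surface& S, const double* p, const double* x0,
                        double delta0, int kprobe, double tau, int max_iter,
                        double shrink, double psi_scale) {
  FSOut out; out.dist = NA_REAL; out.iters = 0; out.align = 0; out.ok = false;
  int d = S.dim;
  double x[3], g[3], vx[3];
  for (int k = 0; k < d; ++k) x[k] = x0[k];
  for (int k = 0; k < d; ++k) vx[k] = p[k] - x[k];
  double dist = norm_d(vx, d);
  double delta = delta0;
  double align = 0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    S.gradient(x, g);
    double gn = norm_d(g, d);
    if (gn < 1e-300) break;
    for (int k = 0; k < d; ++k) vx[k] = p[k] - x[k];
    double vn = norm_d(vx, d);
    if (vn < 1e-300) { align = 1.0; break; } // p on surface
    double dot = 0; for (int k = 0; k < d; ++k) dot += vx[k]*g[k];
    align = std::fabs(dot) / (vn * gn);
    if (1.0 - align < tau) break;

    // tangent directions at x
    double t1[3], t2[3];
    double nx[3]; for (int k = 0; k < d; ++k) nx[k] = g[k]/gn;
    if (d == 2) {
      t1[0] = -nx[1]; t1[1] = nx[0];
    } else {
      double e[3] = {1, 0, 0};
      if (std::fabs(nx[0]) > 0.9) { e[0] = 0; e[1] = 1; }
      double en = e[0]*nx[0] + e[1]*nx[1] + e[2]*nx[2];
      for (int k = 0; k < 3; ++k) t1[k] = e[k] - en*nx[k];
      double t1n = norm_d(t1, 3);
      for (int k = 0; k < 3; ++k) t1[k] /= t1n;
      t2[0] = nx[1]*t1[2] - nx[2]*t1[1];
      t2[1] = nx[2]*t1[0] - nx[0]*t1[2];
      t2[2] = nx[0]*t1[1] - nx[1]*t1[0];
    }
    int kk = (d == 2) ? 2 : kprobe;
    double bestd = dist, besty[3] = {0, 0, 0};
    bool moved = false;
    for (int j = 0; j < kk; ++j) {
      double q[3];
      if (d == 2) {
        double sgn = (j == 0) ? 1.0 : -1.0;
        for (int k = 0; k < 2; ++k) q[k] = x[k] + sgn*delta*t1[k];
      } else {
        double ang = 2.0*M_PI*j/kk;
        for (int k = 0; k < 3; ++k)
          q[k] = x[k] + delta*(std::cos(ang)*t1[k] + std::sin(ang)*t2[k]);
      }
      double u[3]; for (int k = 0; k < d; ++k) u[k] = q[k] - p[k];
      double c = probe_ray_root(S, p, u, psi_scale);
      if (!std::isfinite(c)) continue;
      double y[3]; for (int k = 0; k < d; ++k) y[k] = p[k] + c*u[k];
      double dy[3]; for (int k = 0; k < d; ++k) dy[k] = p[k] - y[k];
      double dn = norm_d(dy, d);
      if (dn < bestd) { bestd = dn; for (int k = 0; k < d; ++k) besty[k] = y[k]; moved = true; }
    }
    if (moved) {
      for (int k = 0; k < d; ++k) x[k] = besty[k];
      dist = bestd;
    } else {
      delta *= shrink;
      if (delta < 1e-14 * delta0) break;
    }
  }
  // final alignment
  S.gradient(x, g);
  double gn = norm_d(g, d);
  for (int k = 0; k < d; ++k) vx[k] = p[k] - x[k];
  double vn = norm_d(vx, d);
  if (gn > 0 && vn > 0) {
    double dot = 0; for (int k = 0; k < d; ++k) dot += vx[k]*g[k];
    align = std::fabs(dot) / (vn * gn);
  }
  out.dist = dist;
  for (int k = 0; k < d; ++k) out.foot[k] = x[k];
  out.iters = it;
  out.align = align;
  out.ok = true;
  return out;
}

// Full FS run for one query point. The descent is started from up to four
// well-separated candidate directions (ranked by |Psi| on the search ball)
// and the shortest converged distance wins; this guards against locally
// optimal feet on strongly non-convex surfaces.
static FSOut fs_one(const Surface& S, const double* p,
                    const NumericMatrix& grid, // unit directions, ngrid x dim
                    double r0, double delta0, int kprobe, double tau,
                    int max_iter, double shrink, double L, int n_scan,
                    const double* interior) {
  FSOut out; out.dist = NA_REAL; out.iters = 0; out.align = 0; out.ok = false;
  int d = S.dim;
  double psi_p = S.value(p);
  double psi_scale = std::max(1.0, std::fabs(psi_p));

  // Step 1: shrink r until Psi keeps constant sign on the ball grid, then
  // point the initial ray at the boundary point minimising |Psi| (falling
  // back to the next-best directions when a ray misses the surface). The
  // first-order distance |Psi|/|grad Psi| caps the starting radius so that
  // near-surface points need few shrink rounds.
  double gp[3]; S.gradient(p, gp);
  double gpn = norm_d(gp, d);
  double r = r0;
  if (gpn > 0) {
    double d1 = std::fabs(psi_p) / gpn;
    if (d1 < r) r = std::max(d1, 1e-3 * r0);
  }
  int ng = grid.nrow();
  std::vector<double> absv(ng);
  bool found_ball = false;
  for (int attempt = 0; attempt < 45 && !found_ball; ++attempt) {
    bool pos = false, neg = false;
    double x[3];
    for (int i = 0; i < ng; ++i) {
      for (int k = 0; k < d; ++k) x[k] = p[k] + r * grid(i, k);
      double v = S.value(x);
      if (v > 0) pos = true; else if (v < 0) neg = true;
      absv[i] = std::fabs(v);
    }
    bool center_ok = (psi_p > 0 && !neg) || (psi_p < 0 && !pos);
    if (center_ok) {
      found_ball = true;
    } else {
      r *= 0.5;
      if (r < 1e-12 * r0) break;
    }
  }
  if (!found_ball) return out;

  std::vector<int> order(ng);
  for (int i = 0; i < ng; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int i, int j) { return absv[i] < absv[j]; });

  // collect up to 4 start points: best-|Psi| directions separated by at
  // least ~35 degrees, each contributing its nearest ray root
  const int max_starts = 6;
  double starts[6][3];
  double sdirs[6][3];
  int n_starts = 0;
  int ntry = std::min(ng, 96);
  // at most two starts come from the local ball cue; far queries add up
  // to two more from the global scan below
  for (int t = 0; t < ntry && n_starts < 2; ++t) {
    double dir[3];
    for (int k = 0; k < d; ++k) dir[k] = grid(order[t], k);
    bool sep = true;
    for (int sdx = 0; sdx < n_starts; ++sdx) {
      double dot = 0;
      for (int k = 0; k < d; ++k) dot += dir[k]*sdirs[sdx][k];
      if (dot > 0.82) { sep = false; break; }
    }
    if (!sep) continue;
    double c = nearest_ray_root(S, p, dir, L, n_scan);
    if (!std::isfinite(c)) continue;
    for (int k = 0; k < d; ++k) {
      sdirs[n_starts][k] = dir[k];
      starts[n_starts][k] = p[k] + dir[k]*c;
    }
    ++n_starts;
  }
  // Far queries can have feet on several sheets that the local |Psi| cue
  // cannot rank. Scan rays from the surface's interior reference point
  // (every sheet is visible from there), collect all crossings, and add
  // the candidates closest to p as extra descent starts.
  double d1_est = (gpn > 0) ? std::fabs(psi_p) / gpn : 1e300;
  if (d1_est > 0.25 * r0 && ng >= 8 && std::isfinite(interior[0])) {
    int m = std::min(256, ng);
    int step = std::max(1, ng / m);
    const int ns2 = 192;
    std::vector<double> cand_dist;
    std::vector<std::array<double, 3> > cand_pt;
    double x[3];
    for (int i = 0; i < ng; i += step) {
      double dir[3];
      for (int k = 0; k < d; ++k) dir[k] = grid(i, k);
      double prev = NA_REAL, prevc = 0;
      for (int j = 1; j <= ns2; ++j) {
        double cj = L * j / ns2;
        for (int k = 0; k < d; ++k) x[k] = interior[k] + dir[k]*cj;
        double f = S.value(x);
        if (j > 1 && prev * f < 0) {
          double lo = prevc, hi = cj, flo = prev;
          for (int b = 0; b < 50; ++b) {
            double mid = 0.5*(lo + hi);
            for (int k = 0; k < d; ++k) x[k] = interior[k] + dir[k]*mid;
            double fm = S.value(x);
            if (flo * fm <= 0) hi = mid; else { lo = mid; flo = fm; }
          }
          double cr = 0.5*(lo + hi);
          std::array<double, 3> pt = {0, 0, 0};
          double dd = 0;
          for (int k = 0; k < d; ++k) {
            pt[k] = interior[k] + dir[k]*cr;
            dd += (p[k] - pt[k])*(p[k] - pt[k]);
          }
          cand_dist.push_back(std::sqrt(dd));
          cand_pt.push_back(pt);
        }
        prev = f; prevc = cj;
      }
    }
    std::vector<int> ord2(cand_dist.size());
    for (size_t i = 0; i < ord2.size(); ++i) ord2[i] = (int)i;
    std::sort(ord2.begin(), ord2.end(),
              [&](int i, int j) { return cand_dist[i] < cand_dist[j]; });
    for (size_t t = 0; t < ord2.size() && n_starts < max_starts; ++t) {
      const std::array<double, 3>& pt = cand_pt[ord2[t]];
      double dref = std::max(cand_dist[ord2[t]], 1e-12);
      bool sep = true;
      for (int sdx = 0; sdx < n_starts; ++sdx) {
        double dd = 0;
        for (int k = 0; k < d; ++k)
          dd += (pt[k] - starts[sdx][k])*(pt[k] - starts[sdx][k]);
        if (std::sqrt(dd) < 0.2 * dref) { sep = false; break; }
      }
      if (!sep) continue;
      for (int k = 0; k < d; ++k) {
        starts[n_starts][k] = pt[k];
        sdirs[n_starts][k] = 0; // unused for interior-scan starts
      }
      ++n_starts;
    }
  }
  if (n_starts == 0 && gpn > 0) {
    // last resort: aim straight down the gradient (steepest descent of |Psi|)
    double dir[3];
    double sgn = (psi_p > 0) ? -1.0 : 1.0;
    for (int k = 0; k < d; ++k) dir[k] = sgn * gp[k] / gpn;
    double c = nearest_ray_root(S, p, dir, L, n_scan);
    if (std::isfinite(c)) {
      for (int k = 0; k < d; ++k) {
        sdirs[0][k] = dir[k];
        starts[0][k] = p[k] + dir[k]*c;
      }
      n_starts = 1;
    }
  }
  if (n_starts == 0) return out;

  for (int sdx = 0; sdx < n_starts; ++sdx) {
    FSOut o = fs_descend(S, p, starts[sdx], delta0, kprobe, tau, max_iter,
                         shrink, psi_scale);
    if (!o.ok) continue;
    if (!out.ok || o.dist < out.dist) {
      FSOut merged = o;
      merged.iters = out.ok ? std::max(out.iters, o.iters) : o.iters;
      out = merged;
    } else if (o.iters > out.iters) {
      out.iters = o.iters;
    }
  }
  return out;
}

static Surface make_surface(int family, NumericVector par) {
  Surface S;
  S.family = family;
  S.dim = (family == 1) ? 2 : 3;
  for (int i = 0; i < par.size() && i < 11; ++i) S.par[i] = par[i];
  if (family == 2) {
    double cx = std::cos(par[8]), sx = std::sin(par[8]);
    double cy = std::cos(par[9]), sy = std::sin(par[9]);
    double cz = std::cos(par[10]), sz = std::sin(par[10]);
    // M = Rx * Ry * Rz, row-major
    S.M[0] = cy*cz;            S.M[1] = cy*sz;            S.M[2] = -sy;
    S.M[3] = sx*sy*cz - cx*sz; S.M[4] = cx*cz + sx*sy*sz; S.M[5] = sx*cy;
    S.M[6] = cx*sy*cz + sx*sz; S.M[7] = cx*sy*sz - sx*cz; S.M[8] = cx*cy;
  }
  return S;
}

// [[Rcpp::export(name = ".fs_batch_cpp")]]
List fs_batch_cpp(int family, NumericVector par, NumericMatrix P,
                  NumericMatrix grid, double r0, double delta0, int kprobe,
                  double tau, int max_iter, double shrink, double L,
                  int n_scan, double on_surface_tol,
                  NumericVector interior) {
  Surface S = make_surface(family, par);
  double interior_pt[3] = {NA_REAL, NA_REAL, NA_REAL};
  for (int k = 0; k < std::min(3, (int)interior.size()); ++k)
    interior_pt[k] = interior[k];
  int n = P.nrow(), d = S.dim;
  NumericVector dist(n), align(n);
  IntegerVector iters(n);
  NumericMatrix feet(n, d);
  LogicalVector ok(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) p[k] = P(i, k);
    double psi = S.value(p);
    double g[3]; S.gradient(p, g);
    double gn = norm_d(g, d);
    if (gn > 0 && std::fabs(psi)/gn < on_surface_tol) {
      dist[i] = 0.0; align[i] = 1.0; iters[i] = 0; ok[i] = true;
      for (int k = 0; k < d; ++k) feet(i, k) = p[k];
      continue;
    }
    FSOut o = fs_one(S, p, grid, r0, delta0, kprobe, tau, max_iter,
                     shrink, L, n_scan, interior_pt);
    dist[i] = o.dist; align[i] = o.align; iters[i] = o.iters; ok[i] = o.ok;
    for (int k = 0; k < d; ++k) feet(i, k) = o.ok ? o.foot[k] : NA_REAL;
  }
  return List::create(_["distance"] = dist, _["foot"] = feet,
                      _["iterations"] = iters, _["alignment"] = align,
                      _["ok"] = ok);
}

// Random surface root along each ray from p0 (uniform among the sign-change
// brackets found on a regular scan of (0, L]); used by the brute-force
// sampling oracle. Uses R's RNG so results are seed-reproducible.
// [[Rcpp::export(name = ".ray_random_root_cpp")]]
NumericVector ray_random_root_cpp(int family, NumericVector par,
                                  NumericVector p0, NumericMatrix dirs,
                                  double L, int n_scan) {
  Surface S = make_surface(family, par);
  int m = dirs.nrow(), d = S.dim;
  NumericVector out(m, NA_REAL);
  double h = L / n_scan;
  std::vector<double> cs(n_scan + 1);
  cs[0] = L / (100.0 * n_scan);
  for (int j = 1; j <= n_scan; ++j) cs[j] = j * h;
  std::vector<double> vals(n_scan + 1);
  std::vector<int> brak(n_scan);
  double x[3];
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= n_scan; ++j) {
      for (int k = 0; k < d; ++k) x[k] = p0[k] + dirs(i, k) * cs[j];
      vals[j] = S.value(x);
    }
    int nb = 0;
    for (int j = 0; j < n_scan; ++j)
      if (vals[j] * vals[j + 1] < 0) brak[nb++] = j;
    if (!nb) continue;
    int pick = brak[std::min(nb - 1, (int)(unif_rand() * nb))];
    double lo = cs[pick], hi = cs[pick + 1], flo = vals[pick];
    for (int b = 0; b < 80; ++b) {
      double mid = 0.5 * (lo + hi);
      for (int k = 0; k < d; ++k) x[k] = p0[k] + dirs(i, k) * mid;
      double fm = S.value(x);
      if (flo * fm <= 0) hi = mid; else { lo = mid; flo = fm; }
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}

// [[Rcpp::export(name = ".surface_value_cpp")]]
NumericVector surface_value_cpp(int family, NumericVector par,
                                NumericMatrix P) {
  Surface S = make_surface(family, par);
  int n = P.nrow();
  NumericVector out(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < S.dim; ++k) p[k] = P(i, k);
    out[i] = S.value(p);
  }
  return out;
}
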