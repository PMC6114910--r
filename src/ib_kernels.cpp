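#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 4-point immersed-boundary kernel (grid units)
static inline double phi4(double r) {
  double a = std::fabs(r);
  if (a >= 2.0) return 0.0;
  if (a <= 1.0) {
    double s = 1.0 + 4.0 * a - 4.0 * a * a;
    return (3.0 - 2.0 * a + std::sqrt(s > 0 ? s : 0)) / 8.0;
  }
  double s = -7.0 + 12.0 * a - 4.0 * a * a;
  return (5.0 - 2.0 * a - std::sqrt(s > 0 ? s : 0)) / 8.0;
}

// scatter-add v into a length-n accumulator at 1-based indices
// [[Rcpp::export]]
NumericVector accum_cpp(IntegerVector idx, NumericVector v, int n) {
  NumericVector out(n);
  int m = idx.size();
  for (int i = 0; i < m; ++i) out[idx[i] - 1] += v[i];
  return out;
}

// Spread nodal values f (already weighted by ds/h^2) onto an nx x ny periodic
// face grid whose index coordinates of the nodes are (rx, ry).
// [[Rcpp::export]]
NumericMatrix ib_spread_cpp(NumericVector rx, NumericVector ry,
                            NumericVector f, int nx, int ny) {
  NumericMatrix out(nx, ny);
  int n = rx.size();
  for (int p = 0; p < n; ++p) {
    int bx = (int)std::floor(rx[p]);
    int by = (int)std::floor(ry[p]);
    double wx[4], wy[4];
    int ix[4], iy[4];
    for (int a = 0; a < 4; ++a) {
      int gx = bx - 1 + a;
      int gy = by - 1 + a;
      wx[a] = phi4(rx[p] - gx);
      wy[a] = phi4(ry[p] - gy);
      ix[a] = ((gx - 1) % nx + nx) % nx;
      iy[a] = ((gy - 1) % ny + ny) % ny;
    }
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        out(ix[a], iy[b]) += f[p] * wx[a] * wy[b];
  }
  return out;
}

// Interpolate a periodic face-grid field at node index coordinates (rx, ry).
// [[Rcpp::export]]
NumericVector ib_interp_cpp(NumericVector rx, NumericVector ry,
                            NumericMatrix g, int nx, int ny) {
  int n = rx.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    int bx = (int)std::floor(rx[p]);
    int by = (int)std::floor(ry[p]);
    double wx[4], wy[4];
    int ix[4], iy[4];
    for (int a = 0; a < 4; ++a) {
      int gx = bx - 1 + a;
      int gy = by - 1 + a;
      wx[a] = phi4(rx[p] - gx);
      wy[a] = phi4(ry[p] - gy);
      ix[a] = ((gx - 1) % nx + nx) % nx;
      iy[a] = ((gy - 1) % ny + ny) % ny;
    }
    double s = 0.0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        s += g(ix[a], iy[b]) * wx[a] * wy[b];
    out[p] = s;
  }
  return out;
}

// Hookean link forces: for each link, force k*(|d|-l0) along the unit vector,
// accumulated with opposite signs at its two endpoint nodes (1-based indices).
// Returns an n x 2 force matrix. Errors on a zero-length element.
// beta > 0 adds stiffness-proportional (Rayleigh) damping along each link:
// an extra tension beta * k * d|l|/dt computed from the node velocities V.
// Used as a numerical stabilizer for the fast sub-grid constraint modes in
// reduced-scale runs (negligible at the swimming frequencies of interest).
// [[Rcpp::export]]
NumericMatrix link_forces_cpp(NumericMatrix X, IntegerVector from,
                              IntegerVector to, NumericVector k,
                              NumericVector l0, int n,
                              Nullable<NumericMatrix> V = R_NilValue,
                              double beta = 0.0) {
  NumericMatrix F(n, 2);
  bool damped = beta > 0.0 && V.isNotNull();
  NumericMatrix Vm = damped ? NumericMatrix(V) : NumericMatrix(0, 0);
  int m = from.size();
  for (int i = 0; i < m; ++i) {
    int a = from[i] - 1, b = to[i] - 1;
    double dx = X(b, 0) - X(a, 0);
    double dy = X(b, 1) - X(a, 1);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l == 0.0) stop("zero-length elastic element at link %d", i + 1);
    double tension = k[i] * (l - l0[i]);
    if (damped) {
      double dvx = Vm(b, 0) - Vm(a, 0);
      double dvy = Vm(b, 1) - Vm(a, 1);
      tension += beta * k[i] * (dvx * dx + dvy * dy) / l;
    }
    double fm = tension / l;
    F(a, 0) += fm * dx; F(a, 1) += fm * dy;
    F(b, 0) -= fm * dx; F(b, 1) -= fm * dy;
  }
  return F;
}

// Tension forces of the lateral muscle/skin elements along one side:
// tension = P + k_skin * max(0, ext) + k_skin_comp * min(0, ext)
//           + k_cb * Cb * ext,   ext = l - l0,
// applied as an equal-and-opposite pair along the element axis (in place).
// k_skin_comp = 0 is the tension-only skin of the full-scale model.
// [[Rcpp::export]]
NumericMatrix lateral_forces_cpp(NumericMatrix F, NumericMatrix X,
                                 IntegerVector from, IntegerVector to,
                                 NumericVector P, NumericVector Cb,
                                 NumericVector l0, double k_skin,
                                 double k_cb, double k_skin_comp = 0.0) {
  int m = from.size();
  for (int i = 0; i < m; ++i) {
    int a = from[i] - 1, b = to[i] - 1;
    double dx = X(b, 0) - X(a, 0);
    double dy = X(b, 1) - X(a, 1);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l == 0.0) stop("zero-length muscle segment at element %d", i + 1);
    double ext = l - l0[i];
    double tension = (P[i] > 0 ? P[i] : 0) + k_cb * Cb[i] * ext;
    tension += (ext > 0 ? k_skin : k_skin_comp) * ext;
    double fm = tension / l;
    F(a, 0) += fm * dx; F(a, 1) += fm * dy;
    F(b, 0) -= fm * dx; F(b, 1) -= fm * dy;
  }
  return F;
}


// Triplets of the spring-network force Jacobian dF/dX (2n x 2n, ordering
// x1..xn, y1..yn). For a link (a, b) with unit vector u and length l the 2x2
// stiffness block is K = k[(1 - l0/l) I + (l0/l) u u^T]; dF_a/dX_b = +K,
// dF_a/dX_a = -K (and symmetrically for b). Used by the semi-implicit
// overdamped body solver.
// [[Rcpp::export]]
List spring_jacobian_cpp(NumericMatrix X, IntegerVector from,
                         IntegerVector to, NumericVector k,
                         NumericVector l0, int n) {
  int m = from.size();
  IntegerVector I(16 * m), J(16 * m);
  NumericVector V(16 * m);
  int q = 0;
  for (int e = 0; e < m; ++e) {
    int a = from[e] - 1, b = to[e] - 1;
    double dx = X(b, 0) - X(a, 0);
    double dy = X(b, 1) - X(a, 1);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l == 0.0) stop("zero-length elastic element at link %d", e + 1);
    double ux = dx / l, uy = dy / l;
    double c1 = k[e] * (1.0 - l0[e] / l);
    double c2 = k[e] * (l0[e] / l);
    double Kv[4] = {c1 + c2 * ux * ux, c2 * ux * uy,
                    c2 * ux * uy, c1 + c2 * uy * uy};
    int na[2] = {a + 1, a + 1 + n};   // 1-based rows of node a (x, y)
    int nb[2] = {b + 1, b + 1 + n};
    for (int r = 0; r < 2; ++r) {
      for (int c = 0; c < 2; ++c) {
        double v = Kv[2 * r + c];
        I[q] = na[r]; J[q] = nb[c]; V[q] = v;  ++q;   // dF_a/dX_b
        I[q] = nb[r]; J[q] = na[c]; V[q] = v;  ++q;   // dF_b/dX_a
        I[q] = na[r]; J[q] = na[c]; V[q] = -v; ++q;   // dF_a/dX_a
        I[q] = nb[r]; J[q] = nb[c]; V[q] = -v; ++q;   // dF_b/dX_b
      }
    }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = V);
}

// Jacobian triplets of general axial elements: stiffness block
// K = k_ax u u^T + (T/l)(I - u u^T) for an element with axial stiffness k_ax
// (d tension / d length) and current tension T. Covers the muscle/skin
// lateral elements, whose tension is not a simple Hookean law.
// [[Rcpp::export]]
List element_jacobian_cpp(NumericMatrix X, IntegerVector from,
                          IntegerVector to, NumericVector k_ax,
                          NumericVector T, int n) {
  int m = from.size();
  IntegerVector I(16 * m), J(16 * m);
  NumericVector V(16 * m);
  int q = 0;
  for (int e = 0; e < m; ++e) {
    int a = from[e] - 1, b = to[e] - 1;
    double dx = X(b, 0) - X(a, 0);
    double dy = X(b, 1) - X(a, 1);
    double l = std::sqrt(dx * dx + dy * dy);
    if (l == 0.0) stop("zero-length element at %d", e + 1);
    double ux = dx / l, uy = dy / l;
    double c1 = T[e] / l;                 // transverse (geometric) stiffness
    double c2 = k_ax[e] - c1;             // remaining axial part
    double Kv[4] = {c1 + c2 * ux * ux, c2 * ux * uy,
                    c2 * ux * uy, c1 + c2 * uy * uy};
    int na[2] = {a + 1, a + 1 + n};
    int nb[2] = {b + 1, b + 1 + n};
    for (int r = 0; r < 2; ++r) {
      for (int c = 0; c < 2; ++c) {
        double v = Kv[2 * r + c];
        I[q] = na[r]; J[q] = nb[c]; V[q] = v;  ++q;
        I[q] = nb[r]; J[q] = na[c]; V[q] = v;  ++q;
        I[q] = na[r]; J[q] = na[c]; V[q] = -v; ++q;
        I[q] = nb[r]; J[q] = nb[c]; V[q] = -v; ++q;
      }
    }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = V);
}

// Discrete-beam bending of the midline chain: at each interior node i the
// turning angle phi_i = atan2(cross(e1, e2), dot(e1, e2)) of the adjacent
// segments carries elastic energy B_i phi_i^2 / (2 lbar_i) and muscle work
// -M_i phi_i (M_i: net bending moment from the lateral muscle tensions).
// Returns the node forces -dE/dX and the Gauss-Newton Hessian triplets
// (B_i/lbar_i) g_i g_i^T of the elastic part (the stiff part, for the
// implicit overdamped solve). Ordering of dofs: x1..xn, y1..yn.
// [[Rcpp::export]]
List bend_forces_cpp(NumericMatrix X, NumericVector B_over_l,
                     NumericVector M, bool want_jac) {
  int n = X.nrow();
  NumericMatrix F(n, 2);
  int nint = n - 2;
  IntegerVector I(want_jac ? 36 * nint : 0);
  IntegerVector J(want_jac ? 36 * nint : 0);
  NumericVector V(want_jac ? 36 * nint : 0);
  int q = 0;
  for (int i = 1; i < n - 1; ++i) {
    double e1x = X(i, 0) - X(i - 1, 0), e1y = X(i, 1) - X(i - 1, 1);
    double e2x = X(i + 1, 0) - X(i, 0), e2y = X(i + 1, 1) - X(i, 1);
    double l1s = e1x * e1x + e1y * e1y, l2s = e2x * e2x + e2y * e2y;
    if (l1s == 0.0 || l2s == 0.0) stop("degenerate midline segment at %d", i);
    double cr = e1x * e2y - e1y * e2x;
    double dt = e1x * e2x + e1y * e2y;
    double phi = std::atan2(cr, dt);
    // phi = angle(e2) - angle(e1); d angle(v)/dv = perp(v)/|v|^2
    double g[6]; // (x_{i-1}, x_i, x_{i+1}, y_{i-1}, y_i, y_{i+1})
    double p1x = -e1y / l1s, p1y = e1x / l1s;   // perp(e1)/|e1|^2
    double p2x = -e2y / l2s, p2y = e2x / l2s;
    g[0] = p1x;          g[3] = p1y;
    g[1] = -p1x - p2x;   g[4] = -p1y - p2y;
    g[2] = p2x;          g[5] = p2y;
    double coef = B_over_l[i - 1] * phi - M[i - 1]; // dE/dphi
    int idx[6] = {i - 1, i, i + 1, i - 1 + n, i + n, i + 1 + n};
    F(i - 1, 0) -= coef * g[0]; F(i, 0) -= coef * g[1];
    F(i + 1, 0) -= coef * g[2];
    F(i - 1, 1) -= coef * g[3]; F(i, 1) -= coef * g[4];
    F(i + 1, 1) -= coef * g[5];
    if (want_jac) {
      double w = B_over_l[i - 1];
      for (int r = 0; r < 6; ++r) {
        for (int c = 0; c < 6; ++c) {
          I[q] = idx[r] + 1; J[q] = idx[c] + 1;
          V[q] = -w * g[r] * g[c];  // Jacobian of force = -Hessian of energy
          ++q;
        }
      }
    }
  }
  return List::create(_["F"] = F, _["i"] = I, _["j"] = J, _["x"] = V);
}
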