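#include <Rcpp.h>
using namespace Rcpp;

// Signed (shoelace) areas of polygonal cells stored as CSR vertex cycles.
// cell_ptr: 0-based offsets of length n_cells+1 into cell_idx (0-based vertex ids).
static void cell_areas_impl(const double* x, const double* y,
                            const int* cell_ptr, const int* cell_idx,
                            int n_cells, double* area) {
  for (int c = 0; c < n_cells; ++c) {
    double a = 0.0;
    int s = cell_ptr[c], e = cell_ptr[c + 1];
    for (int k = s; k < e; ++k) {
      int i = cell_idx[k];
      int j = cell_idx[(k + 1 < e) ? (k + 1) : s];
      a += x[i] * y[j] - x[j] * y[i];
    }
    area[c] = 0.5 * a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_cell_areas(NumericMatrix pos, IntegerVector cell_ptr,
                             IntegerVector cell_idx) {
  int n_cells = cell_ptr.size() - 1;
  NumericVector area(n_cells);
  std::vector<double> x(pos.nrow()), y(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  cell_areas_impl(x.data(), y.data(), cell_ptr.begin(), cell_idx.begin(),
                  n_cells, area.begin());
  return area;
}

// Total force on every vertex: wall elasticity k_S(l - l_0) along the wall
// axis (restoring toward rest length) plus turgor pressure k_P/V per
// adjacent cell, perpendicular to the wall, outward from the pressing cell,
// the full magnitude applied to both endpoint vertices.
static void forces_impl(const double* x, const double* y, int n_vert,
                        const int* wv1, const int* wv2, int n_walls,
                        const int* cell_ptr, const int* cell_idx, int n_cells,
                        double kS, double l0, double kP,
                        double* fx, double* fy, double* area_buf) {
  std::fill(fx, fx + n_vert, 0.0);
  std::fill(fy, fy + n_vert, 0.0);

  for (int w = 0; w < n_walls; ++w) {
    int a = wv1[w], b = wv2[w];
    double dx = x[b] - x[a], dy = y[b] - y[a];
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-14) continue;  // degenerate wall: no defined axis
    double mag = kS * (len - l0);
    double ux = dx / len, uy = dy / len;
    // len > l0: contraction, endpoint a pulled toward b and vice versa
    fx[a] += mag * ux;  fy[a] += mag * uy;
    fx[b] -= mag * ux;  fy[b] -= mag * uy;
  }

  cell_areas_impl(x, y, cell_ptr, cell_idx, n_cells, area_buf);

  // Pressure: walk each cell's CCW cycle; outward normal of edge (a -> b)
  // is (dy, -dx)/len for a counter-clockwise polygon.
  for (int c = 0; c < n_cells; ++c) {
    double V = area_buf[c];
    if (V <= 1e-14) continue;
    double p = kP / V;
    int s = cell_ptr[c], e = cell_ptr[c + 1];
    for (int k = s; k < e; ++k) {
      int a = cell_idx[k];
      int b = cell_idx[(k + 1 < e) ? (k + 1) : s];
      double dx = x[b] - x[a], dy = y[b] - y[a];
      double len = std::sqrt(dx * dx + dy * dy);
      if (len < 1e-14) continue;
      double nx = dy / len, ny = -dx / len;
      fx[a] += p * nx;  fy[a] += p * ny;
      fx[b] += p * nx;  fy[b] += p * ny;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_vertex_forces(NumericMatrix pos,
                                IntegerVector wv1, IntegerVector wv2,
                                IntegerVector cell_ptr, IntegerVector cell_idx,
                                double kS, double l0, double kP) {
  int n = pos.nrow(), n_cells = cell_ptr.size() - 1;
  std::vector<double> x(n), y(n), fx(n), fy(n), area(n_cells);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  forces_impl(x.data(), y.data(), n, wv1.begin(), wv2.begin(), wv1.size(),
              cell_ptr.begin(), cell_idx.begin(), n_cells, kS, l0, kP,
              fx.data(), fy.data(), area.data());
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// Overdamped vertex dynamics du_i/dt = k_T F_i, explicit Euler, stopping when
// the largest per-step displacement falls below tol.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, IntegerVector wv1, IntegerVector wv2,
               IntegerVector cell_ptr, IntegerVector cell_idx,
               double kT, double kS, double l0, double kP,
               double dt, double tol, int max_iter) {
  int n = pos.nrow(), n_cells = cell_ptr.size() - 1;
  std::vector<double> x(n), y(n), fx(n), fy(n), area(n_cells);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }

  int iter = 0;
  bool converged = false;
  double max_disp = R_PosInf;
  while (iter < max_iter) {
    forces_impl(x.data(), y.data(), n, wv1.begin(), wv2.begin(), wv1.size(),
                cell_ptr.begin(), cell_idx.begin(), n_cells, kS, l0, kP,
                fx.data(), fy.data(), area.data());
    max_disp = 0.0;
    for (int i = 0; i < n; ++i) {
      double sx = kT * fx[i] * dt, sy = kT * fy[i] * dt;
      x[i] += sx; y[i] += sy;
      double d = std::sqrt(sx * sx + sy * sy);
      if (d > max_disp) max_disp = d;
    }
    ++iter;
    if (max_disp < tol) { converged = true; break; }
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return List::create(_["pos"] = out, _["iterations"] = iter,
                      _["converged"] = converged, _["max_step"] = max_disp);
}

// Forward-Euler integration of the activator-inhibitor dynamics on the cell
// adjacency graph (CSR).  phi clamps activator synthesis to [0, alpha_d*u_max];
// psi adds alpha_m to the activator decay rate in marginal cells.  After each
// step u is clipped to [0, u_max] and v to [0, Inf).
// [[Rcpp::export]]
List cpp_rd_run(NumericVector u_in, NumericVector v_in,
                IntegerVector adj_ptr, IntegerVector adj_idx,
                LogicalVector marginal,
                double alpha_s, double alpha_d, double alpha_m,
                double beta, double gamma, double delta, double epsilon,
                double Du, double Dv, double u_max, double dt, int n_steps) {
  int n = u_in.size();
  std::vector<double> u(u_in.begin(), u_in.end());
  std::vector<double> v(v_in.begin(), v_in.end());
  std::vector<double> un(n), vn(n);
  const int* ap = adj_ptr.begin();
  const int* ai = adj_idx.begin();
  const double phimax = alpha_d * u_max;

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double lap_u = 0.0, lap_v = 0.0;
      int deg = ap[i + 1] - ap[i];
      for (int k = ap[i]; k < ap[i + 1]; ++k) {
        lap_u += u[ai[k]];
        lap_v += v[ai[k]];
      }
      lap_u -= deg * u[i];
      lap_v -= deg * v[i];
      double arg = epsilon + alpha_s * u[i] - beta * v[i];
      double phi = (arg < 0.0) ? 0.0 : ((arg > phimax) ? phimax : arg);
      double decay = alpha_d + (marginal[i] ? alpha_m : 0.0);
      double du = phi - decay * u[i] + Du * lap_u;
      double dv = gamma * u[i] - delta * v[i] + Dv * lap_v;
      double uu = u[i] + dt * du;
      double vv = v[i] + dt * dv;
      un[i] = (uu < 0.0) ? 0.0 : ((uu > u_max) ? u_max : uu);
      vn[i] = (vv < 0.0) ? 0.0 : vv;
    }
    u.swap(un);
    v.swap(vn);
  }
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()));
}
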