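#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One explicit FTCS update of the growth-factor field (column-major N x N,
// mirror/no-flux boundaries): g <- g + dt*(D lap g + rho*c - delta*g).
// Missing neighbours contribute zero to the Laplacian; pointing the
// neighbour-column pointer at the centre column realises exactly that.
// Returns the maximum of the updated field.  Values are floored at zero (the
// floor is only reachable when dt*(4D/d^2 + delta) > 1).
static double field_update(const double* g, double* out, const int* occ,
                           int N, double D, double rho, double delta,
                           double inv_d2, double dt) {
  double gmax = 0.0;
  for (int j = 0; j < N; ++j) {
    const double* gc = g + (size_t)j * N;
    const double* gl = (j > 0)     ? gc - N : gc;
    const double* gr = (j < N - 1) ? gc + N : gc;
    const int* oc = occ + (size_t)j * N;
    double* o = out + (size_t)j * N;
    for (int i = 0; i < N; ++i) {
      double up = gc[i > 0 ? i - 1 : 0];
      double dn = gc[i < N - 1 ? i + 1 : N - 1];
      double lap = up + dn + gl[i] + gr[i] - 4.0 * gc[i];
      double val = gc[i] + dt * (D * lap * inv_d2 + rho * oc[i] - delta * gc[i]);
      if (val < 0.0) val = 0.0;
      o[i] = val;
      if (val > gmax) gmax = val;
    }
  }
  return gmax;
}

// [[Rcpp::export]]
NumericMatrix gf_step_cpp(NumericMatrix g, IntegerMatrix occ,
                          double D, double rho, double delta,
                          double d, double dt, int n_sub) {
  int N = g.nrow();
  NumericMatrix cur(clone(g));
  NumericMatrix nxt(N, N);
  double inv_d2 = 1.0 / (d * d);
  for (int s = 0; s < n_sub; ++s) {
    field_update(REAL(cur), REAL(nxt), INTEGER(occ), N, D, rho, delta,
                 inv_d2, dt);
    std::swap(cur, nxt);
  }
  return cur;
}

// Operator-split fixed-step individual-based simulation.  Within a cell step
// of length dt (chosen so that the largest per-cell total event probability
// stays below `cap`) each cell, visited in random order, draws at most one
// event: division at rate alpha*(1+g), death at rate mu, migration at rate
// nu.  The field is then advanced by dt with positivity-safe sub-steps.
// Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export]]
List ib_simulate_cpp(IntegerMatrix occ0, NumericMatrix g0,
                     double alpha, double mu, double nu, int long_range,
                     double D, double rho, double delta, double d,
                     double T, double record_every, double cap) {
  int N = occ0.nrow();
  IntegerMatrix occ(clone(occ0));
  NumericMatrix g(clone(g0));
  NumericMatrix gtmp(N, N);
  int n2 = N * N;
  int n_cells = 0;
  for (int k = 0; k < n2; ++k) n_cells += occ[k] ? 1 : 0;

  std::vector<double> rec_t, rec_n;
  rec_t.push_back(0.0);
  rec_n.push_back((double)n_cells / n2);
  double t = 0.0, next_rec = record_every;

  double inv_d2 = 1.0 / (d * d);
  double dt_pos = 1.0 / (4.0 * D * inv_d2 + delta + 1e-300);
  bool has_field = (D > 0.0 || rho > 0.0 || delta > 0.0);
  double gmax = 0.0;
  for (int k = 0; k < n2; ++k) if (g[k] > gmax) gmax = g[k];

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  std::vector<int> order;
  order.reserve(n2);
  std::vector<char> fresh(n2, 0); // arrived (born or moved) during this step

  while (t < T - 1e-9) {
    double rate_max = alpha * (1.0 + gmax) + mu + nu;
    double dt = (rate_max > 0.0) ? cap / rate_max : (next_rec - t);
    if (dt > next_rec - t) dt = next_rec - t;
    if (dt > T - t) dt = T - t;

    if (n_cells > 0 && rate_max > 0.0) {
      order.clear();
      for (int k = 0; k < n2; ++k) {
        if (occ[k]) { order.push_back(k); fresh[k] = 0; }
      }
      for (int k = (int)order.size() - 1; k > 0; --k) {
        int m = (int)(unif_rand() * (k + 1));
        if (m > k) m = k;
        std::swap(order[k], order[m]);
      }
      for (size_t idx = 0; idx < order.size(); ++idx) {
        int s = order[idx];
        if (!occ[s] || fresh[s]) continue;
        int i = s % N, j = s / N;
        double u = unif_rand();
        double p_div = alpha * (1.0 + g[s]) * dt;
        double p_die = p_div + mu * dt;
        double p_mig = p_die + nu * dt;
        if (u < p_div) {
          int tgt = -1;
          if (long_range) {
            int w = (int)(unif_rand() * n2);
            if (w >= n2) w = n2 - 1;
            if (!occ[w]) tgt = w;
          } else {
            int dir = (int)(unif_rand() * 4);
            if (dir > 3) dir = 3;
            int ii = i + di[dir], jj = j + dj[dir];
            if (ii >= 0 && ii < N && jj >= 0 && jj < N) {
              int w = jj * N + ii;
              if (!occ[w]) tgt = w;
            }
          }
          if (tgt >= 0) {
            occ[tgt] = 1;
            fresh[tgt] = 1;
            ++n_cells;
          }
        } else if (u < p_die) {
          occ[s] = 0;
          --n_cells;
        } else if (u < p_mig) {
          int dir = (int)(unif_rand() * 4);
          if (dir > 3) dir = 3;
          int ii = i + di[dir], jj = j + dj[dir];
          if (ii >= 0 && ii < N && jj >= 0 && jj < N) {
            int w = jj * N + ii;
            if (!occ[w]) {
              occ[w] = 1;
              occ[s] = 0;
              fresh[w] = 1;
            }
          }
        }
      }
    }

    // advance the field; nothing to do while it is identically zero with no
    // occupied sources
    if (has_field && (gmax > 0.0 || (rho > 0.0 && n_cells > 0))) {
      int n_sub = (int)std::ceil(dt / dt_pos - 1e-12);
      if (n_sub < 1) n_sub = 1;
      double dts = dt / n_sub;
      for (int s = 0; s < n_sub; ++s) {
        gmax = field_update(REAL(g), REAL(gtmp), INTEGER(occ), N, D, rho,
                            delta, inv_d2, dts);
        std::swap(g, gtmp);
      }
    }

    t += dt;
    while (next_rec <= T + 1e-9 && t >= next_rec - 1e-9) {
      rec_t.push_back(next_rec);
      rec_n.push_back((double)n_cells / n2);
      next_rec += record_every;
    }
    if (n_cells == 0) { // absorbing: no spontaneous birth
      while (next_rec <= T + 1e-9) {
        rec_t.push_back(next_rec);
        rec_n.push_back(0.0);
        next_rec += record_every;
      }
      break;
    }
  }

  return List::create(_["time"] = rec_t, _["density"] = rec_n,
                      _["occupancy"] = occ, _["g"] = g,
                      _["n_cells"] = n_cells);
}

// Forward-Euler integration of dn/dt = (A + B n) n (1 - n) - mu n, clipped to
// [0, 1] after every step.
// [[Rcpp::export]]
NumericVector euler_growth_cpp(double A, double B, double mu,
                               double n0, double dt, int n_steps) {
  NumericVector out(n_steps + 1);
  double n = n0;
  if (n < 0.0) n = 0.0;
  if (n > 1.0) n = 1.0;
  out[0] = n;
  for (int i = 1; i <= n_steps; ++i) {
    n += dt * ((A + B * n) * n * (1.0 - n) - mu * n);
    if (n < 0.0) n = 0.0;
    if (n > 1.0) n = 1.0;
    out[i] = n;
  }
  return out;
}

// Multi-curve least-squares error: for each curve, integrate from the curve's
// first retained observation and accumulate (1/k) * sum of squared
// residuals, with model values linearly interpolated off the Euler grid.
// [[Rcpp::export]]
double growth_objective_cpp(double A, double B, double mu,
                            List times, List dens, double dt) {
  double E = 0.0;
  int M = times.size();
  for (int m = 0; m < M; ++m) {
    NumericVector t = times[m], y = dens[m];
    int k = t.size();
    double t0 = t[0];
    double tmax = t[k - 1] - t0;
    int n_steps = (int)std::ceil(tmax / dt - 1e-12);
    if (n_steps < 0) n_steps = 0;
    std::vector<double> traj(n_steps + 1);
    double n = y[0];
    if (n < 0.0) n = 0.0;
    if (n > 1.0) n = 1.0;
    traj[0] = n;
    for (int i = 1; i <= n_steps; ++i) {
      n += dt * ((A + B * n) * n * (1.0 - n) - mu * n);
      if (n < 0.0) n = 0.0;
      if (n > 1.0) n = 1.0;
      traj[i] = n;
    }
    double ss = 0.0;
    for (int i = 0; i < k; ++i) {
      double pos = (t[i] - t0) / dt;
      int lo = (int)std::floor(pos);
      if (lo >= n_steps) { lo = n_steps; pos = n_steps; }
      if (lo < 0) { lo = 0; pos = 0; }
      double frac = pos - lo;
      double pred = (lo < n_steps)
        ? traj[lo] * (1.0 - frac) + traj[lo + 1] * frac
        : traj[lo];
      double r = pred - y[i];
      ss += r * r;
    }
    E += ss / k;
  }
  return E;
}
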