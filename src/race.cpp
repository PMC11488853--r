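#include <Rcpp.h>
using namespace Rcpp;

// Anticorrelated race: two accumulators start at 0 and integrate bivariate
// Normal increments (means +/- m*dt, variance dt each, correlation rho) until
// one reaches its positive, linearly collapsing bound B(t) = max(B0 - a*t,
// floor). Discrete time, Euler steps of dt seconds.

// [[Rcpp::export]]
List cpp_simulate_race(NumericVector mu, double dt, double rho,
                       double B0, double alpha, double bound_floor,
                       double t_max, int path_steps, int path_thin) {
  const int n = mu.size();
  const int n_steps = (int) std::lround(t_max / dt);
  const double sdt = std::sqrt(dt);
  const double rc = std::sqrt(1.0 - rho * rho);
  const bool keep = path_steps > 0;
  const int n_keep = keep ? path_steps : 0;

  IntegerVector choice(n);          // 0 = left, 1 = right
  NumericVector dec_time(n);
  LogicalVector undecided(n);
  NumericMatrix dvL(n_keep, keep ? n : 0), dvR(n_keep, keep ? n : 0),
                ev(n_keep, keep ? n : 0);

  for (int i = 0; i < n; ++i) {
    double x = 0.0, y = 0.0, e = 0.0; // left, right, unfrozen left path
    const double m = mu[i];
    bool done = false;
    int ch = 0; double td = t_max;
    const int last = keep ? (n_keep * path_thin) : 0;
    for (int s = 1; s <= n_steps; ++s) {
      const double z1 = norm_rand();
      const double z2 = rho * z1 + rc * norm_rand();
      const double dx = m * dt + sdt * z1;
      const double dy = -m * dt + sdt * z2;
      e += dx;
      if (!done) {
        x += dx; y += dy;
        const double t = s * dt;
        double B = B0 - alpha * t;
        if (B < bound_floor) B = bound_floor;
        if (x >= B || y >= B) {
          done = true; td = t;
          if (x >= B && y >= B) ch = (x - B >= y - B) ? 0 : 1;
          else ch = (x >= B) ? 0 : 1;
        }
      }
      if (keep && s % path_thin == 0) {
        const int k = s / path_thin - 1;
        if (k < n_keep) { dvL(k, i) = x; dvR(k, i) = y; ev(k, i) = e; }
      }
      if (done && (!keep || s >= last)) break;
    }
    if (!done) { // resolve by proximity to bound at t_max
      double B = std::max(B0 - alpha * t_max, bound_floor);
      ch = (B - x <= B - y) ? 0 : 1;
      undecided[i] = true;
    }
    choice[i] = ch;
    dec_time[i] = td;
  }
  List out = List::create(_["choice"] = choice, _["decision_time"] = dec_time,
                          _["undecided"] = undecided);
  if (keep) { out["dv_left"] = dvL; out["dv_right"] = dvR; out["ev_left"] = ev; }
  return out;
}

// Discrete Gaussian kernel over cell-integrated probabilities, with moment
// matching: the discretisation adds ~h^2/12 of variance, which is subtracted
// from the target variance before integration.
static std::vector<double> gauss_kernel(double mean, double var, double h,
                                        int &offset) {
  double v = var - h * h / 12.0;
  if (v < 1e-12) v = var; // too narrow to correct; keep raw variance
  const double sd = std::sqrt(v);
  const int lo = (int) std::floor((mean - 5.0 * sd) / h) - 1;
  const int hi = (int) std::ceil((mean + 5.0 * sd) / h) + 1;
  std::vector<double> k(hi - lo + 1);
  double sum = 0.0;
  for (int j = lo; j <= hi; ++j) {
    const double a = ((j - 0.5) * h - mean) / sd;
    const double b = ((j + 0.5) * h - mean) / sd;
    k[j - lo] = R::pnorm(b, 0.0, 1.0, 1, 0) - R::pnorm(a, 0.0, 1.0, 1, 0);
    sum += k[j - lo];
  }
  for (auto &w : k) w /= sum;
  offset = lo;
  return k;
}

// Joint density propagation in rotated coordinates u = x + y, v = x - y, in
// which the correlated increments become independent:
//   du ~ N(0, 2(1+rho)dt),  dv ~ N(2 m dt, 2(1-rho)dt).
// Absorption: left wins where x = (u+v)/2 >= B(t), right where y = (u-v)/2 >=
// B(t). bound_shift implements a continuity correction (subtracted from B).
// [[Rcpp::export]]
List cpp_fpt_propagate(double mu, double dt, double rho,
                       double B0, double alpha, double bound_floor,
                       double t_max, double h, double bound_shift,
                       double u_lo, double v_abs) {
  const int n_steps = (int) std::lround(t_max / dt);
  const double var_u = 2.0 * (1.0 + rho) * dt;
  const double var_v = 2.0 * (1.0 - rho) * dt;
  const double drift_v = 2.0 * mu * dt;

  const int iu0 = (int) std::ceil(u_lo / h);       // grid: u = i*h
  const int iu1 = (int) std::floor((2.0 * B0 + 0.5) / h);
  const int iv1 = (int) std::ceil(v_abs / h);
  const int Nu = iu1 - iu0 + 1, Nv = 2 * iv1 + 1;

  int off_u, off_v;
  std::vector<double> ku = gauss_kernel(0.0, var_u, h, off_u);
  std::vector<double> kv = gauss_kernel(drift_v, var_v, h, off_v);
  const int Ku = ku.size(), Kv = kv.size();

  std::vector<double> P(Nu * Nv, 0.0), Q(Nu * Nv, 0.0);
  // initial delta at u = v = 0
  P[(0 - iu0) * Nv + (0 + iv1)] = 1.0;

  NumericVector fL(n_steps), fR(n_steps);
  double edge_loss = 0.0;

  for (int s = 1; s <= n_steps; ++s) {
    // u-pass (scatter with edge clamp, conserves mass exactly):
    // Q(clamp(iu + j + off_u), iv) += ku[j] * P(iu, iv)
    std::fill(Q.begin(), Q.end(), 0.0);
    for (int iu = 0; iu < Nu; ++iu) {
      const double *p = &P[iu * Nv];
      for (int j = 0; j < Ku; ++j) {
        const double w = ku[j];
        if (w < 1e-16) continue;
        int tgt = iu + j + off_u;
        if (tgt < 0) tgt = 0; else if (tgt >= Nu) tgt = Nu - 1;
        double *q = &Q[tgt * Nv];
        for (int iv = 0; iv < Nv; ++iv) q[iv] += w * p[iv];
      }
    }
    // v-pass: P(iu, clamp(iv + j + off_v)) += kv[j] * Q(iu, iv)
    std::fill(P.begin(), P.end(), 0.0);
    for (int iu = 0; iu < Nu; ++iu) {
      const double *q = &Q[iu * Nv];
      double *p = &P[iu * Nv];
      for (int j = 0; j < Kv; ++j) {
        const double w = kv[j];
        if (w < 1e-16) continue;
        const int o = j + off_v;
        for (int iv = 0; iv < Nv; ++iv) {
          int tgt = iv + o;
          if (tgt < 0) tgt = 0; else if (tgt >= Nv) tgt = Nv - 1;
          p[tgt] += w * q[iv];
        }
      }
    }
    // absorption at the (shifted) collapsing bounds
    const double t = s * dt;
    double B = std::max(B0 - alpha * t, bound_floor) - bound_shift;
    double aL = 0.0, aR = 0.0;
    for (int iv = 0; iv < Nv; ++iv) {
      const double v = (iv - iv1) * h;
      // x >= B  <=>  u >= 2B - v ; y >= B  <=>  u >= 2B + v.
      // Cells straddling a bound are absorbed fractionally (uniform
      // within-cell density), which removes the O(h) absorption bias.
      const double tL = (2.0 * B - v) / h, tR = (2.0 * B + v) / h;
      const int first = std::max((int) std::floor(std::min(tL, tR) - 0.5) , iu0);
      for (int iu = first; iu <= iu1; ++iu) {
        double &m = P[(iu - iu0) * Nv + iv];
        if (m == 0.0) continue;
        // fraction of the cell [iu-0.5, iu+0.5] above each threshold
        double fL = iu + 0.5 - tL, fR = iu + 0.5 - tR;
        fL = fL < 0.0 ? 0.0 : (fL > 1.0 ? 1.0 : fL);
        fR = fR < 0.0 ? 0.0 : (fR > 1.0 ? 1.0 : fR);
        double tot = fL + fR;
        if (tot <= 0.0) continue;
        if (tot > 1.0) { fL /= tot; fR /= tot; tot = 1.0; }
        aL += fL * m; aR += fR * m;
        m *= (1.0 - tot);
      }
    }
    fL[s - 1] = aL; fR[s - 1] = aR;
  }
  double rem = 0.0;
  for (double m : P) rem += m;
  return List::create(_["f_left"] = fL, _["f_right"] = fR,
                      _["p_undecided"] = rem, _["edge_loss"] = edge_loss,
                      _["dt"] = dt, _["n_steps"] = n_steps);
}
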