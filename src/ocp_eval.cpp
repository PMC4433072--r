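// Compiled evaluator for the enzyme-program optimal control problem.
//
// The decision vector is [e_i(0) for each enzyme | per-interval slopes
// (enzyme-major) | free initial intermediate levels].  Controls are
// piecewise linear on a uniform mesh of `rho` intervals over [0, t_f].
// The objective (protein cost + regulatory effort) is closed-form in the
// controls; the metabolite trajectory only enters through path-constraint
// penalties, evaluated on a dense grid.
//
// Integrator: second-order modified Patankar-Runge-Kutta (MPRK22).
// Production/destruction splitting keeps metabolite concentrations
// positive and remains stable when a Michaelis constant is small relative
// to the step (stiff consumption), and it preserves steady states exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct OcpSpec {
  int n_enz, n_met, n_inh, n_free, n_drain, rho, n_dense, n_sub, n_seg;
  std::vector<int> sub, prod;           // per reaction, metabolite index
  std::vector<double> kcat, km;
  std::vector<int> inh_met, inh_enz;    // inhibition edges
  std::vector<double> inh_kr;
  std::vector<int> drain_idx;           // drained metabolite indices
  std::vector<int> free_idx;            // metabolites with free x(0)
  std::vector<int> is_buffered;         // per metabolite
  std::vector<int> is_drained;          // per metabolite (0/1)
  std::vector<int> drain_row;           // per metabolite, row in dil values
  std::vector<double> x_fixed;          // baseline initial state
  std::vector<double> dil_breaks;       // n_seg + 1
  std::vector<double> dil_values;       // n_drain x n_seg, column-major
  double sigma, t_f, p_lo, p_hi, x_max, e_max;
  int drain_mode;    // 0 = prescribed demand flux nu(t); 1 = dilution nu*p
  int steady_start;  // enforce d/dt = 0 at t = 0 as an equality penalty

  void parse(const List& spec) {
    n_enz = as<int>(spec["n_enz"]);
    n_met = as<int>(spec["n_met"]);
    rho = as<int>(spec["rho"]);
    n_dense = as<int>(spec["n_dense"]);
    n_sub = as<int>(spec["n_sub"]);
    sub = as<std::vector<int> >(spec["sub"]);
    prod = as<std::vector<int> >(spec["prod"]);
    kcat = as<std::vector<double> >(spec["kcat"]);
    km = as<std::vector<double> >(spec["km"]);
    inh_met = as<std::vector<int> >(spec["inh_met"]);
    inh_enz = as<std::vector<int> >(spec["inh_enz"]);
    inh_kr = as<std::vector<double> >(spec["inh_kr"]);
    n_inh = (int) inh_met.size();
    drain_idx = as<std::vector<int> >(spec["drain_idx"]);
    n_drain = (int) drain_idx.size();
    free_idx = as<std::vector<int> >(spec["free_idx"]);
    n_free = (int) free_idx.size();
    is_buffered = as<std::vector<int> >(spec["is_buffered"]);
    x_fixed = as<std::vector<double> >(spec["x_fixed"]);
    dil_breaks = as<std::vector<double> >(spec["dil_breaks"]);
    dil_values = as<std::vector<double> >(spec["dil_values"]);
    n_seg = (int) dil_breaks.size() - 1;
    sigma = as<double>(spec["sigma"]);
    t_f = as<double>(spec["t_f"]);
    p_lo = as<double>(spec["p_lo"]);
    p_hi = as<double>(spec["p_hi"]);
    x_max = as<double>(spec["x_max"]);
    e_max = as<double>(spec["e_max"]);
    drain_mode = as<int>(spec["drain_mode"]);
    steady_start = as<int>(spec["steady_start"]);
    is_drained.assign(n_met, 0);
    drain_row.assign(n_met, -1);
    for (int k = 0; k < n_drain; ++k) {
      is_drained[drain_idx[k]] = 1;
      drain_row[drain_idx[k]] = k;
    }
  }

  double dil_rate(int met, double t) const {
    int seg = 0;
    while (seg < n_seg - 1 && t >= dil_breaks[seg + 1]) ++seg;
    return dil_values[drain_row[met] + n_drain * seg];
  }
};

// piecewise-linear control evaluation; nodes precomputed from u0 + slopes
struct Controls {
  int n_enz, rho;
  double dt;
  std::vector<double> nodes;   // (rho+1) x n_enz, node-major per enzyme
  std::vector<double> slopes;  // rho x n_enz

  void build(const OcpSpec& sp, const double* x) {
    n_enz = sp.n_enz;
    rho = sp.rho;
    dt = sp.t_f / rho;
    nodes.assign((rho + 1) * n_enz, 0.0);
    slopes.assign(rho * n_enz, 0.0);
    for (int i = 0; i < n_enz; ++i) {
      double u = x[i];
      nodes[i * (rho + 1)] = u;
      for (int k = 0; k < rho; ++k) {
        double s = x[n_enz + i * rho + k];
        slopes[i * rho + k] = s;
        u += s * dt;
        nodes[i * (rho + 1) + k + 1] = u;
      }
    }
  }

  // enzyme value at time t (clamped at 0 for the dynamics)
  double value(int i, double t) const {
    int k = (int) (t / dt);
    if (k >= rho) k = rho - 1;
    double e = nodes[i * (rho + 1) + k] + slopes[i * rho + k] * (t - k * dt);
    return e > 0.0 ? e : 0.0;
  }
};

// production terms and destruction rates (D/x) at one time point
void pd_terms(const OcpSpec& sp, const Controls& ctl, double t,
              const std::vector<double>& x,
              std::vector<double>& P, std::vector<double>& d) {
  P.assign(sp.n_met, 0.0);
  d.assign(sp.n_met, 0.0);
  for (int j = 0; j < sp.n_enz; ++j) {
    double km_eff = sp.km[j];
    for (int q = 0; q < sp.n_inh; ++q) {
      if (sp.inh_enz[q] == j) {
        double p = x[sp.inh_met[q]];
        km_eff += sp.km[j] * (p > 0.0 ? p : 0.0) / sp.inh_kr[q];
      }
    }
    double e = ctl.value(j, t);
    int s = sp.sub[j];
    double xs = x[s] > 0.0 ? x[s] : 0.0;
    double over_x = sp.kcat[j] * e / (xs + km_eff);  // v_j / x_s
    P[sp.prod[j]] += over_x * xs;
    d[s] += over_x;
  }
  for (int m = 0; m < sp.n_met; ++m) {
    if (sp.is_drained[m]) {
      double nu = sp.dil_rate(m, t);
      if (sp.drain_mode == 1) {
        d[m] += nu;  // first-order dilution: outflow nu * p
      } else {
        // prescribed demand flux: outflow nu, saturating as p -> 0
        double xs = x[m] > 1e-12 ? x[m] : 1e-12;
        d[m] += nu / xs;
      }
    }
  }
}

struct EvalResult {
  double J, J_cost, J_reg, penalty, max_violation;
  std::vector<double> cost, reg;
  std::vector<double> traj;      // (n_dense+1) x n_met, column-major
  std::vector<double> enz_traj;  // (n_dense+1) x n_enz
  std::vector<double> times;
};

void evaluate(const OcpSpec& sp, const double* x, bool want_traj,
              EvalResult& out) {
  Controls ctl;
  ctl.build(sp, x);

  // closed-form objective
  out.cost.assign(sp.n_enz, 0.0);
  out.reg.assign(sp.n_enz, 0.0);
  double dtc = ctl.dt;
  for (int i = 0; i < sp.n_enz; ++i) {
    double u0 = x[i];
    out.cost[i] = u0 * sp.t_f;
    double r = 0.0;
    for (int k = 0; k < sp.rho; ++k) {
      double a = ctl.nodes[i * (sp.rho + 1) + k] - u0;
      double b = ctl.slopes[i * sp.rho + k];
      r += dtc * (a * a + a * b * dtc + b * b * dtc * dtc / 3.0);
    }
    out.reg[i] = r;
  }
  out.J_cost = 0.0;
  out.J_reg = 0.0;
  for (int i = 0; i < sp.n_enz; ++i) {
    out.J_cost += out.cost[i];
    out.J_reg += out.reg[i];
  }
  out.J = sp.sigma * out.J_cost + out.J_reg;

  // node-bound violations (enzyme non-negativity and cap)
  double pen = 0.0, maxviol = 0.0;
  for (int i = 0; i < sp.n_enz; ++i) {
    for (int k = 0; k <= sp.rho; ++k) {
      double u = ctl.nodes[i * (sp.rho + 1) + k];
      double v1 = u < 0.0 ? -u : 0.0;
      double v2 = u > sp.e_max ? u - sp.e_max : 0.0;
      pen += v1 * v1 + v2 * v2;
      if (v1 > maxviol) maxviol = v1;
      if (v2 > maxviol) maxviol = v2;
    }
  }

  // integrate and accumulate path-constraint penalties on the dense grid
  std::vector<double> xs(sp.x_fixed);
  for (int q = 0; q < sp.n_free; ++q) xs[sp.free_idx[q]] = x[sp.n_enz * (1 + sp.rho) + q];

  int n_steps = sp.n_dense * sp.n_sub;
  double h = sp.t_f / n_steps;
  double dt_dense = sp.t_f / sp.n_dense;

  if (want_traj) {
    out.traj.assign((sp.n_dense + 1) * sp.n_met, 0.0);
    out.enz_traj.assign((sp.n_dense + 1) * sp.n_enz, 0.0);
    out.times.assign(sp.n_dense + 1, 0.0);
  }

  std::vector<double> P0, d0, P1, d1, x1(sp.n_met);
  auto record = [&](int g, double t) {
    // path-constraint violations at a dense node
    for (int m = 0; m < sp.n_met; ++m) {
      if (sp.is_buffered[m]) continue;
      double v = 0.0;
      if (sp.is_drained[m]) {
        if (xs[m] < sp.p_lo) v = sp.p_lo - xs[m];
        else if (xs[m] > sp.p_hi) v = xs[m] - sp.p_hi;
      } else {
        if (xs[m] > sp.x_max) v = xs[m] - sp.x_max;
        else if (xs[m] < 0.0) v = -xs[m];
      }
      pen += v * v * dt_dense;
      if (v > maxviol) maxviol = v;
    }
    if (want_traj) {
      out.times[g] = t;
      for (int m = 0; m < sp.n_met; ++m) out.traj[g + (sp.n_dense + 1) * m] = xs[m];
      for (int i = 0; i < sp.n_enz; ++i) {
        double e = ctl.value(i, t);
        out.enz_traj[g + (sp.n_dense + 1) * i] = e;
      }
    }
  };

  record(0, 0.0);
  for (int step = 0; step < n_steps; ++step) {
    double t = step * h;
    pd_terms(sp, ctl, t, xs, P0, d0);
    if (sp.steady_start && step == 0) {
      // equality penalty: the initial state is a steady state of the
      // first demand segment
      // weighted strongly relative to the path terms so the equality
      // converges well below the feasibility tolerance
      for (int m = 0; m < sp.n_met; ++m) {
        if (sp.is_buffered[m]) continue;
        double r = P0[m] - d0[m] * xs[m];
        pen += 100.0 * r * r;
        double ar = std::fabs(r);
        if (ar > maxviol) maxviol = ar;
      }
    }
    for (int m = 0; m < sp.n_met; ++m) {
      if (sp.is_buffered[m]) { x1[m] = xs[m]; continue; }
      x1[m] = (xs[m] + h * P0[m]) / (1.0 + h * d0[m]);
    }
    pd_terms(sp, ctl, t + h, x1, P1, d1);
    for (int m = 0; m < sp.n_met; ++m) {
      if (sp.is_buffered[m]) continue;
      xs[m] = (xs[m] + 0.5 * h * (P0[m] + P1[m])) /
              (1.0 + 0.5 * h * (d0[m] + d1[m]));
    }
    if ((step + 1) % sp.n_sub == 0) {
      int g = (step + 1) / sp.n_sub;
      record(g, (step + 1) * h);
    }
  }

  out.penalty = pen;
  out.max_violation = maxviol;
}

} // namespace

// ---------------------------------------------------------------------------
// Discrete adjoint of the penalized objective.
//
// The closed-form protein-cost/regulatory terms are differentiated
// analytically; the path-constraint penalty is differentiated by running
// the MPRK22 integration forward with full state storage and propagating
// the adjoint backwards through both Patankar stages.  Clamps (negative
// states or control values truncated at zero in the dynamics) carry zero
// derivative, matching the forward evaluation.

namespace {

struct AdjWork {
  // per step storage
  std::vector<double> s0, x1, P0, d0, P1, d1;  // n_steps * n_met
};

// accumulate d(pen)/dx for one recorded state into lam (weight dt_dense)
inline void pen_grad(const OcpSpec& sp, const double* xs, double dt_dense,
                     std::vector<double>& lam) {
  for (int m = 0; m < sp.n_met; ++m) {
    if (sp.is_buffered[m]) continue;
    double g = 0.0;
    if (sp.is_drained[m]) {
      if (xs[m] < sp.p_lo) g = -2.0 * (sp.p_lo - xs[m]);
      else if (xs[m] > sp.p_hi) g = 2.0 * (xs[m] - sp.p_hi);
    } else {
      if (xs[m] > sp.x_max) g = 2.0 * (xs[m] - sp.x_max);
      else if (xs[m] < 0.0) g = 2.0 * xs[m];
    }
    lam[m] += g * dt_dense;
  }
}

// backprop through P/d evaluation at (state, controls(t)): given gP, gd,
// accumulate into gx (state adjoint) and the control gradient at time t
inline void pd_backprop(const OcpSpec& sp, const Controls& ctl, double t,
                        const double* x, const std::vector<double>& gP,
                        const std::vector<double>& gd,
                        std::vector<double>& gx,
                        std::vector<double>& gu0,
                        std::vector<double>& gslope) {
  int rho = sp.rho;
  double dtc = ctl.dt;
  for (int j = 0; j < sp.n_enz; ++j) {
    double km_eff = sp.km[j];
    for (int q = 0; q < sp.n_inh; ++q) {
      if (sp.inh_enz[q] == j) {
        double p = x[sp.inh_met[q]];
        km_eff += sp.km[j] * (p > 0.0 ? p : 0.0) / sp.inh_kr[q];
      }
    }
    int sidx = sp.sub[j];
    double xs_raw = x[sidx];
    double xs = xs_raw > 0.0 ? xs_raw : 0.0;
    double den = xs + km_eff;
    double e = ctl.value(j, t);  // already clamped at 0
    double gr_ = gP[sp.prod[j]];
    double gq_ = gd[sidx];
    double kc = sp.kcat[j];
    // control derivative (zero through the clamp)
    double ge = gr_ * kc * xs / den + gq_ * kc / den;
    {
      int k = (int)(t / dtc);
      if (k >= rho) k = rho - 1;
      double raw = ctl.nodes[j * (rho + 1) + k] +
                   ctl.slopes[j * rho + k] * (t - k * dtc);
      if (raw > 0.0 && ge != 0.0) {
        gu0[j] += ge;
        for (int l = 0; l < k; ++l) gslope[j * rho + l] += ge * dtc;
        gslope[j * rho + k] += ge * (t - k * dtc);
      }
    }
    double den2 = den * den;
    if (xs_raw > 0.0) {
      gx[sidx] += gr_ * kc * e * km_eff / den2 - gq_ * kc * e / den2;
    }
    if (sp.n_inh > 0) {
      double gkm = -(gr_ * kc * e * xs + gq_ * kc * e) / den2;
      for (int q = 0; q < sp.n_inh; ++q) {
        if (sp.inh_enz[q] == j && x[sp.inh_met[q]] > 0.0) {
          gx[sp.inh_met[q]] += gkm * sp.km[j] / sp.inh_kr[q];
        }
      }
    }
  }
  // prescribed-demand drain: d[m] = nu / x[m] depends on the state
  if (sp.drain_mode == 0) {
    for (int k = 0; k < sp.n_drain; ++k) {
      int m = sp.drain_idx[k];
      if (gd[m] != 0.0 && x[m] > 1e-12) {
        gx[m] -= gd[m] * sp.dil_rate(m, t) / (x[m] * x[m]);
      }
    }
  }
}

} // namespace

// Exact gradient of J + w * penalty via the discrete adjoint.
// [[Rcpp::export]]
NumericVector ocp_penalized_agrad_cpp(NumericVector x, List spec, double w) {
  OcpSpec sp;
  sp.parse(spec);
  Controls ctl;
  ctl.build(sp, x.begin());
  int n_enz = sp.n_enz, rho = sp.rho, n_met = sp.n_met;
  int n_dim = n_enz * (1 + rho) + sp.n_free;
  double dtc = ctl.dt;

  NumericVector grad(n_dim);
  std::vector<double> gu0(n_enz, 0.0), gslope(n_enz * rho, 0.0);

  // closed-form part: d(sigma * J_cost)/du0 and d(J_reg)/dslopes
  for (int i = 0; i < n_enz; ++i) {
    gu0[i] += sp.sigma * sp.t_f;
    // reg_i depends only on slopes: a_k = dtc * sum_{j<k} s_j, b_k = s_k
    double a = 0.0;
    std::vector<double> acc(rho, 0.0);
    for (int k = 0; k < rho; ++k) {
      double b = ctl.slopes[i * rho + k];
      // d reg / d b_k (k term)
      acc[k] += dtc * (a * dtc + 2.0 * b * dtc * dtc / 3.0);
      // d reg / d a_k spread to slopes j<k
      double da = dtc * (2.0 * a + b * dtc);
      for (int l = 0; l < k; ++l) acc[l] += da * dtc;
      a += b * dtc;
    }
    for (int k = 0; k < rho; ++k) gslope[i * rho + k] += acc[k];
  }

  // node-bound penalty gradient
  for (int i = 0; i < n_enz; ++i) {
    for (int k = 0; k <= rho; ++k) {
      double u = ctl.nodes[i * (rho + 1) + k];
      double g = 0.0;
      if (u < 0.0) g = 2.0 * u;
      else if (u > sp.e_max) g = 2.0 * (u - sp.e_max);
      if (g != 0.0) {
        g *= w;
        gu0[i] += g;
        for (int l = 0; l < k; ++l) gslope[i * rho + l] += g * dtc;
      }
    }
  }

  // forward pass with storage
  int n_steps = sp.n_dense * sp.n_sub;
  double h = sp.t_f / n_steps;
  double dt_dense = sp.t_f / sp.n_dense;
  AdjWork ws;
  ws.s0.resize((size_t)n_steps * n_met);
  ws.x1.resize((size_t)n_steps * n_met);
  ws.P0.resize((size_t)n_steps * n_met);
  ws.d0.resize((size_t)n_steps * n_met);
  ws.P1.resize((size_t)n_steps * n_met);
  ws.d1.resize((size_t)n_steps * n_met);

  std::vector<double> xs(sp.x_fixed);
  for (int q = 0; q < sp.n_free; ++q) {
    xs[sp.free_idx[q]] = x[n_enz * (1 + rho) + q];
  }
  std::vector<double> P0v, d0v, P1v, d1v, x1v(n_met);
  std::vector<double> x_final(n_met);
  for (int s = 0; s < n_steps; ++s) {
    double t = s * h;
    pd_terms(sp, ctl, t, xs, P0v, d0v);
    for (int m = 0; m < n_met; ++m) {
      x1v[m] = sp.is_buffered[m] ? xs[m]
        : (xs[m] + h * P0v[m]) / (1.0 + h * d0v[m]);
    }
    pd_terms(sp, ctl, t + h, x1v, P1v, d1v);
    size_t off = (size_t)s * n_met;
    for (int m = 0; m < n_met; ++m) {
      ws.s0[off + m] = xs[m];
      ws.x1[off + m] = x1v[m];
      ws.P0[off + m] = P0v[m];
      ws.d0[off + m] = d0v[m];
      ws.P1[off + m] = P1v[m];
      ws.d1[off + m] = d1v[m];
      if (!sp.is_buffered[m]) {
        xs[m] = (xs[m] + 0.5 * h * (P0v[m] + P1v[m])) /
                (1.0 + 0.5 * h * (d0v[m] + d1v[m]));
      }
    }
  }
  x_final = xs;

  // backward pass
  std::vector<double> lam(n_met, 0.0);
  std::vector<double> gP0(n_met), gd0(n_met), gP1(n_met), gd1(n_met),
      lam1(n_met), gs0(n_met);
  // terminal dense node
  pen_grad(sp, x_final.data(), w * dt_dense, lam);
  for (int s = n_steps - 1; s >= 0; --s) {
    size_t off = (size_t)s * n_met;
    const double* s0p = &ws.s0[off];
    const double* x1p = &ws.x1[off];
    double t = s * h;
    // reconstruct the post-step state for this step
    std::fill(gP0.begin(), gP0.end(), 0.0);
    std::fill(gd0.begin(), gd0.end(), 0.0);
    std::fill(gP1.begin(), gP1.end(), 0.0);
    std::fill(gd1.begin(), gd1.end(), 0.0);
    std::fill(lam1.begin(), lam1.end(), 0.0);
    std::fill(gs0.begin(), gs0.end(), 0.0);
    for (int m = 0; m < n_met; ++m) {
      if (lam[m] == 0.0) continue;
      if (sp.is_buffered[m]) { gs0[m] += lam[m]; continue; }
      double B = 1.0 + 0.5 * h * (ws.d0[off + m] + ws.d1[off + m]);
      double x2 = (s0p[m] + 0.5 * h * (ws.P0[off + m] + ws.P1[off + m])) / B;
      double gA = lam[m] / B;
      gs0[m] += gA;
      gP0[m] += 0.5 * h * gA;
      gP1[m] += 0.5 * h * gA;
      double gB = -lam[m] * x2 / B;
      gd0[m] += 0.5 * h * gB;
      gd1[m] += 0.5 * h * gB;
    }
    pd_backprop(sp, ctl, t + h, x1p, gP1, gd1, lam1, gu0, gslope);
    for (int m = 0; m < n_met; ++m) {
      if (lam1[m] == 0.0) continue;
      if (sp.is_buffered[m]) { gs0[m] += lam1[m]; continue; }
      double Bp = 1.0 + h * ws.d0[off + m];
      double gA = lam1[m] / Bp;
      gs0[m] += gA;
      gP0[m] += h * gA;
      gd0[m] += -lam1[m] * x1p[m] * h / Bp;
    }
    if (sp.steady_start && s == 0) {
      for (int m = 0; m < n_met; ++m) {
        if (sp.is_buffered[m]) continue;
        double r = ws.P0[off + m] - ws.d0[off + m] * s0p[m];
        double wss = 100.0 * w;
        gP0[m] += wss * 2.0 * r;
        gd0[m] += -wss * 2.0 * r * s0p[m];
        gs0[m] += -wss * 2.0 * r * ws.d0[off + m];
      }
    }
    pd_backprop(sp, ctl, t, s0p, gP0, gd0, gs0, gu0, gslope);
    lam = gs0;
    // dense-node penalty at the state BEFORE this step (node s/n_sub)
    if (s % sp.n_sub == 0) {
      pen_grad(sp, s0p, w * dt_dense, lam);
    }
  }

  for (int i = 0; i < n_enz; ++i) grad[i] = gu0[i];
  for (int i = 0; i < n_enz * rho; ++i) grad[n_enz + i] = gslope[i];
  for (int q = 0; q < sp.n_free; ++q) {
    grad[n_enz * (1 + rho) + q] = lam[sp.free_idx[q]];
  }
  return grad;
}

// [[Rcpp::export]]
List ocp_eval_cpp(NumericVector x, List spec, bool want_traj = false) {
  OcpSpec sp;
  sp.parse(spec);
  EvalResult res;
  evaluate(sp, x.begin(), want_traj, res);
  List out = List::create(
    _["J"] = res.J, _["J_cost"] = res.J_cost, _["J_reg"] = res.J_reg,
    _["cost"] = wrap(res.cost), _["reg"] = wrap(res.reg),
    _["penalty"] = res.penalty, _["max_violation"] = res.max_violation);
  if (want_traj) {
    NumericMatrix traj(sp.n_dense + 1, sp.n_met);
    std::copy(res.traj.begin(), res.traj.end(), traj.begin());
    NumericMatrix enz(sp.n_dense + 1, sp.n_enz);
    std::copy(res.enz_traj.begin(), res.enz_traj.end(), enz.begin());
    out["times"] = wrap(res.times);
    out["states"] = traj;
    out["enzymes"] = enz;
  }
  return out;
}

// [[Rcpp::export]]
double ocp_penalized_cpp(NumericVector x, List spec, double w) {
  OcpSpec sp;
  sp.parse(spec);
  EvalResult res;
  evaluate(sp, x.begin(), false, res);
  return res.J + w * res.penalty;
}

// Forward-difference gradient of the penalized objective, one call.
// [[Rcpp::export]]
NumericVector ocp_penalized_grad_cpp(NumericVector x, List spec, double w,
                                     double h = 1e-6) {
  OcpSpec sp;
  sp.parse(spec);
  EvalResult res;
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  evaluate(sp, xv.data(), false, res);
  double f0 = res.J + w * res.penalty;
  NumericVector g(n);
  for (int i = 0; i < n; ++i) {
    double hi = h * (std::fabs(xv[i]) > 1.0 ? std::fabs(xv[i]) : 1.0);
    double save = xv[i];
    xv[i] = save + hi;
    evaluate(sp, xv.data(), false, res);
    g[i] = (res.J + w * res.penalty - f0) / hi;
    xv[i] = save;
  }
  return g;
}

// Penalized objective over the rows of a matrix (brute-force grids).
// [[Rcpp::export]]
NumericVector ocp_penalized_batch_cpp(NumericMatrix X, List spec, double w) {
  OcpSpec sp;
  sp.parse(spec);
  EvalResult res;
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < p; ++c) row[c] = X(r, c);
    evaluate(sp, row.data(), false, res);
    out[r] = res.J + w * res.penalty;
  }
  return out;
}
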