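#include <Rcpp.h>
using namespace Rcpp;

// Tridiagonal solve (Thomas algorithm). lo[i] multiplies x[i-1], up[i] multiplies x[i+1].
static void thomas(const std::vector<double>& lo, const std::vector<double>& di,
                   const std::vector<double>& up, std::vector<double>& rhs,
                   std::vector<double>& cp, std::vector<double>& dp) {
  const int n = (int)di.size();
  cp[0] = up[0] / di[0];
  dp[0] = rhs[0] / di[0];
  for (int i = 1; i < n; ++i) {
    double m = di[i] - lo[i] * cp[i - 1];
    cp[i] = up[i] / m;
    dp[i] = (rhs[i] - lo[i] * dp[i - 1]) / m;
  }
  rhs[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) rhs[i] = dp[i] - cp[i] * rhs[i + 1];
}

// One- or two-species transport in a tapered 1D duct, finite volume on station
// centers, Crank-Nicolson (two backward-Euler startup steps) or explicit Euler.
//
// Units: x mm, A mm2, V mm3, D mm2/min, rates 1/min, conductances h = ug/min
// per ug/mL i.e. mL/min * 1e-3 scale folded in by the caller (the caller
// passes h such that J[ug/min] = h * C[ug/mL]).
//
// Species 1 may convert into species 2 at rate khyd (mass 1:1).
// [[Rcpp::export(name = ".cn_solve")]]
List cn_solve(NumericVector x, NumericVector A,
              NumericVector D, NumericVector kel,
              double khyd,
              NumericVector h_in, NumericVector h_out,
              NumericVector Cme0, double kme,
              double Q_aq,
              NumericMatrix C_init,            // n x ns
              double dt, int n_steps,
              IntegerVector out_steps,          // sorted, values in 0..n_steps (0 = initial)
              bool implicit_scheme,
              int trace_every) {
  const int n = x.size();
  const int ns = D.size();
  if (n < 2) stop("geometry must have at least 2 stations");

  // cell widths and volumes
  std::vector<double> dx(n), V(n);
  for (int i = 0; i < n; ++i) {
    double xl = (i == 0) ? x[0] - 0.5 * (x[1] - x[0]) : 0.5 * (x[i - 1] + x[i]);
    double xr = (i == n - 1) ? x[n - 1] + 0.5 * (x[n - 1] - x[n - 2]) : 0.5 * (x[i] + x[i + 1]);
    dx[i] = xr - xl;
    V[i] = A[i] * dx[i];
  }
  double Vtot = 0.0; for (int i = 0; i < n; ++i) Vtot += V[i];

  // face diffusive conductances g[i] between cell i and i+1 (harmonic-mean area)
  std::vector<double> gface(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    double Af = 2.0 * A[i] * A[i + 1] / (A[i] + A[i + 1]);
    gface[i] = Af / (x[i + 1] - x[i]);   // multiply by D per species
  }

  // aqueduct advection: flow entering at base face with zero concentration,
  // distributed withdrawal q_i = Q * V_i / Vtot, face flow decreasing apically
  std::vector<double> Qface(n - 1), qout(n);
  double cum = 0.0;
  for (int i = 0; i < n; ++i) { qout[i] = Q_aq * V[i] / Vtot; }
  for (int i = 0; i < n - 1; ++i) { cum += V[i]; Qface[i] = Q_aq * (1.0 - cum / Vtot); }

  // rate matrix per species: dC/dt = M C + b(t)
  // row i: lo*C[i-1] + di*C[i] + up*C[i+1]
  std::vector< std::vector<double> > Mlo(ns), Mdi(ns), Mup(ns);
  for (int s = 0; s < ns; ++s) {
    Mlo[s].assign(n, 0.0); Mdi[s].assign(n, 0.0); Mup[s].assign(n, 0.0);
    double keff = kel[s] + ((s == 0 && ns == 2) ? khyd : 0.0);
    for (int i = 0; i < n; ++i) {
      double gl = (i > 0) ? D[s] * gface[i - 1] : 0.0;
      double gr = (i < n - 1) ? D[s] * gface[i] : 0.0;
      double advl = (i > 0) ? Qface[i - 1] : 0.0;          // upwind inflow from i-1
      double advr = (i < n - 1) ? Qface[i] : 0.0;          // upwind outflow to i+1
      Mlo[s][i] = (gl + advl) / V[i];
      Mup[s][i] = gr / V[i];
      Mdi[s][i] = -(gl + gr + advr + qout[i]) / V[i] - keff;
      if (i == 0) Mdi[s][i] -= h_out[s] / V[i];
    }
  }

  const int n_out = out_steps.size();
  // output fields: list of n x n_out matrices per species
  List fields(ns);
  std::vector<NumericMatrix> Fm(ns);
  for (int s = 0; s < ns; ++s) { Fm[s] = NumericMatrix(n, n_out); fields[s] = Fm[s]; }

  int n_tr = n_steps / trace_every + 1;
  NumericVector tr_t(n_tr), tr_cme(n_tr);
  NumericMatrix tr_base(n_tr, ns), tr_apex(n_tr, ns);

  // state
  std::vector< std::vector<double> > C(ns);
  for (int s = 0; s < ns; ++s) {
    C[s].assign(n, 0.0);
    for (int i = 0; i < n; ++i) C[s][i] = C_init(i, s);
  }
  std::vector<double> influx(ns, 0.0), outflux(ns, 0.0), elim(ns, 0.0),
                      washout(ns, 0.0), hyd(ns, 0.0), mass0(ns, 0.0);
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < n; ++i) mass0[s] += V[i] * C[s][i];

  std::vector<double> rhs(n), cp(n), dp(n), lo(n), di(n), up(n);
  std::vector< std::vector<double> > Cold(ns);

  int out_ptr = 0, tr_ptr = 0;
  auto record_field = [&](int step) {
    while (out_ptr < n_out && out_steps[out_ptr] == step) {
      for (int s = 0; s < ns; ++s)
        for (int i = 0; i < n; ++i) Fm[s](i, out_ptr) = C[s][i];
      ++out_ptr;
    }
  };
  auto record_trace = [&](int step, double t) {
    if (step % trace_every == 0 && tr_ptr < n_tr) {
      tr_t[tr_ptr] = t; tr_cme[tr_ptr] = Cme0[0] * std::exp(-kme * t);
      for (int s = 0; s < ns; ++s) { tr_base(tr_ptr, s) = C[s][0]; tr_apex(tr_ptr, s) = C[s][n - 1]; }
      ++tr_ptr;
    }
  };
  record_field(0); record_trace(0, 0.0);

  for (int step = 1; step <= n_steps; ++step) {
    double t0 = (step - 1) * dt, t1 = step * dt;
    bool be = implicit_scheme && step <= 2;   // damped (L-stable) startup
    for (int s = 0; s < ns; ++s) Cold[s] = C[s];

    for (int s = 0; s < ns; ++s) {
      double cme_a = Cme0[s] * std::exp(-kme * t0);
      double cme_b = Cme0[s] * std::exp(-kme * t1);
      if (implicit_scheme) {
        double th = be ? 1.0 : 0.5;           // implicitness weight
        for (int i = 0; i < n; ++i) {
          lo[i] = -dt * th * Mlo[s][i];
          di[i] = 1.0 - dt * th * Mdi[s][i];
          up[i] = -dt * th * Mup[s][i];
          double expl = 0.0;
          if (!be) {
            expl = Mdi[s][i] * Cold[s][i];
            if (i > 0) expl += Mlo[s][i] * Cold[s][i - 1];
            if (i < n - 1) expl += Mup[s][i] * Cold[s][i + 1];
          }
          rhs[i] = Cold[s][i] + dt * (1.0 - th) * expl;
          if (s == 1 && khyd > 0.0) {
            // product source, parent already advanced this step
            double src = be ? khyd * C[0][i]
                            : 0.5 * khyd * (Cold[0][i] + C[0][i]);
            rhs[i] += dt * src;
          }
        }
        rhs[0] += dt * (be ? h_in[s] * cme_b : 0.5 * h_in[s] * (cme_a + cme_b)) / V[0];
        thomas(lo, di, up, rhs, cp, dp);
        C[s] = rhs;
      } else {
        for (int i = 0; i < n; ++i) {
          double r = Mdi[s][i] * Cold[s][i];
          if (i > 0) r += Mlo[s][i] * Cold[s][i - 1];
          if (i < n - 1) r += Mup[s][i] * Cold[s][i + 1];
          if (s == 1 && khyd > 0.0) r += khyd * Cold[0][i];
          if (i == 0) r += h_in[s] * cme_a / V[0];
          rhs[i] = Cold[s][i] + dt * r;
        }
        C[s] = rhs;
      }

      // audit with the same quadrature as the scheme
      double w_new = (implicit_scheme ? (be ? 1.0 : 0.5) : 0.0);
      double w_old = 1.0 - w_new;
      influx[s] += dt * h_in[s] * (w_old * cme_a + w_new * cme_b);
      outflux[s] += dt * h_out[s] * (w_old * Cold[s][0] + w_new * C[s][0]);
      double eo = 0.0, en = 0.0, wo = 0.0, wn = 0.0;
      for (int i = 0; i < n; ++i) {
        eo += V[i] * Cold[s][i]; en += V[i] * C[s][i];
        wo += qout[i] * Cold[s][i]; wn += qout[i] * C[s][i];
      }
      elim[s] += dt * kel[s] * (w_old * eo + w_new * en);
      washout[s] += dt * (w_old * wo + w_new * wn);
      if (ns == 2 && khyd > 0.0 && s == 0) {
        // parent loss and product gain share one quadrature (see product rhs)
        double h0 = 0.0, h1 = 0.0;
        for (int i = 0; i < n; ++i) { h0 += V[i] * Cold[0][i]; h1 += V[i] * C[0][i]; }
        double amt = dt * khyd * (w_old * h0 + w_new * h1);
        hyd[0] += amt; hyd[1] += amt;
      }
    }

    record_field(step); record_trace(step, t1);
  }

  NumericMatrix Cend(n, ns);
  NumericVector massend(ns);
  for (int s = 0; s < ns; ++s) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) { Cend(i, s) = C[s][i]; m += V[i] * C[s][i]; }
    massend[s] = m;
  }

  return List::create(
    _["fields"] = fields,
    _["C_end"] = Cend,
    _["V"] = NumericVector(V.begin(), V.end()),
    _["dx"] = NumericVector(dx.begin(), dx.end()),
    _["trace_t"] = tr_t, _["trace_cme"] = tr_cme,
    _["trace_base"] = tr_base, _["trace_apex"] = tr_apex,
    _["influx"] = NumericVector(influx.begin(), influx.end()),
    _["outflux"] = NumericVector(outflux.begin(), outflux.end()),
    _["eliminated"] = NumericVector(elim.begin(), elim.end()),
    _["washout"] = NumericVector(washout.begin(), washout.end()),
    _["hydrolysed"] = NumericVector(hyd.begin(), hyd.end()),
    _["mass0"] = NumericVector(mass0.begin(), mass0.end()),
    _["mass_end"] = massend);
}
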