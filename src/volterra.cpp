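// Time-stepping solver for the coupled Volterra integral system of the
// large-population limit.  Unknowns per group: the new-infection flux
// x(t) = I(t,0), the new-susceptible flux y(t) = S(t,0), and the force of
// infection L(t).  The scheme is a uniform grid with product-trapezoidal
// convolutions and per-step Picard iteration; the exposure-conditioning
// term E[sigma(a) exp(-int L sigma)] is maintained per birth cohort, either
// for a panel of gridded susceptibility curves or, for step curves
// sigma = 1(a >= T_R), by an amortized threshold-crossing representation
// that needs O(1) work per cohort per step.
//
// All exposure weights are kept relative to the running cumulative force
// C(t) = int_0^t Ltilde, so no exponential ever overflows.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grp {
  double p;
  std::vector<double> fTV, STV;
  std::vector<int> ibI, ibS;
  std::vector<double> wI, wS;
  // outputs
  std::vector<double> x, y, L, Lt, C, prev, smass, sbar;
  // step-sigma cohort state (born cohorts indexed by birth step m,
  // initial cohorts by their index)
  std::vector<double> Wb, Wi;
  std::vector<int> pb, pi_;
  // curve-sigma cohort state: exposure integrals, ncoh * K
  std::vector<double> Qb, Qi;
  std::vector<char> ab, ai; // active flags
};

inline double cinterp(const std::vector<double>& C, double tau, double dt,
                      int nmax) {
  if (tau <= 0.0) return C[0];
  double u = tau / dt;
  int i = (int)std::floor(u);
  if (i >= nmax) return C[nmax];
  double f = u - i;
  return C[i] * (1.0 - f) + C[i + 1] * f;
}

} // namespace

// [[Rcpp::export]]
List cpp_solve_volterra(double dt, int nt, int nj,
                        NumericVector ml, NumericVector fTI,
                        NumericVector STI, int naI, int naL,
                        List groups, NumericMatrix contact,
                        int sigma_type, NumericMatrix sigma_curves,
                        NumericVector sigma_thr,
                        double picard_tol, int picard_max,
                        IntegerVector density_steps) {
  const int G = groups.size();
  const int K = (sigma_type == 0) ? sigma_curves.nrow()
                                  : (int)sigma_thr.size();
  const double Kd = (double)K;

  // mean susceptibility curve on the grid (curves type)
  std::vector<double> msig;
  if (sigma_type == 0) {
    msig.assign(nj + 1, 0.0);
    for (int j = 0; j <= nj; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += sigma_curves(k, j);
      msig[j] = s / Kd;
    }
  }
  double sig0count = 0.0; // #{T_R thresholds <= 0}, sigma at age 0 (step)
  if (sigma_type == 1) {
    for (int k = 0; k < K; ++k) if (sigma_thr[k] <= 0.0) sig0count += 1.0;
  }
  const double sig_at0 =
      (sigma_type == 0) ? msig[0] : sig0count / Kd;

  std::vector<Grp> gr(G);
  for (int g = 0; g < G; ++g) {
    List gl = groups[g];
    Grp& G_ = gr[g];
    G_.p = as<double>(gl["p"]);
    G_.fTV = as<std::vector<double>>(gl["fTV"]);
    G_.STV = as<std::vector<double>>(gl["STV"]);
    G_.ibI = as<std::vector<int>>(gl["ibI"]);
    G_.wI  = as<std::vector<double>>(gl["wI"]);
    G_.ibS = as<std::vector<int>>(gl["ibS"]);
    G_.wS  = as<std::vector<double>>(gl["wS"]);
    G_.x.assign(nt + 1, 0.0); G_.y.assign(nt + 1, 0.0);
    G_.L.assign(nt + 1, 0.0); G_.Lt.assign(nt + 1, 0.0);
    G_.C.assign(nt + 1, 0.0);
    G_.prev.assign(nt + 1, 0.0); G_.smass.assign(nt + 1, 0.0);
    G_.sbar.assign(nt + 1, 0.0);
    const int nbS = (int)G_.ibS.size();
    if (sigma_type == 1) {
      G_.Wb.assign(nt + 1, 0.0); G_.pb.assign(nt + 1, 0);
      G_.Wi.assign(nbS, 0.0);    G_.pi_.assign(nbS, 0);
    } else {
      G_.Qb.assign((size_t)(nt + 1) * K, 0.0);
      G_.Qi.assign((size_t)nbS * K, 0.0);
    }
    G_.ab.assign(nt + 1, 1); G_.ai.assign(nbS, 1);
  }

  // ---- helpers -----------------------------------------------------------

  // Step-sigma evaluation of E[e^{-Q}] and E[sigma e^{-Q}] for a cohort
  // born at time s, at the (trial) cumulative force Ctrial for step n.
  // Crossings already committed live in (W, ptr); crossings falling inside
  // the current step are peeked at so that the infection flux and the mass
  // bookkeeping stay consistent (otherwise conservation drifts at O(dt)).
  auto step_eval = [&](const Grp& G_, double W, int ptr, double s,
                       double Ctrial, double dfac, int n,
                       double& Ee, double& Ese) {
    const double tn = n * dt;
    double extra = 0.0;
    int cnt = 0;
    for (int k = ptr; k < K && s + sigma_thr[k] <= tn; ++k) {
      double tau0 = std::max(s + sigma_thr[k], 0.0);
      double Cv;
      if (n >= 1 && tau0 >= (n - 1) * dt) {
        double f = (tau0 - (n - 1) * dt) / dt;
        Cv = G_.C[n - 1] * (1.0 - f) + Ctrial * f;
      } else {
        Cv = cinterp(G_.C, tau0, dt, std::max(n - 1, 0));
      }
      extra += std::exp(Cv - Ctrial);
      ++cnt;
    }
    double w = W * dfac;
    Ee = ((Kd - ptr - cnt) + w + extra) / Kd;
    Ese = (w + extra) / Kd;
  };

  // E[e^{-Q}] and E[sigma e^{-Q}] for a born cohort of age index j at the
  // trial force; dfac rescales step-type weights to the trial C(t_n).
  // lt_prev/lt_cur are the group's coupled force at t_{n-1} and (trial) t_n.
  auto eval_born = [&](Grp& G_, int m, int j, double dfac, double lt_prev,
                       double lt_cur, double Ctrial, int n,
                       double& Ee, double& Ese) {
    if (j == 0) { Ee = 1.0; Ese = sig_at0; return; }
    if (!G_.ab[m]) { Ee = 0.0; Ese = 0.0; return; }
    if (sigma_type == 1) {
      step_eval(G_, G_.Wb[m], G_.pb[m], m * dt, Ctrial, dfac, n, Ee, Ese);
    } else {
      double se = 0.0, ss = 0.0;
      const double* q = &G_.Qb[(size_t)m * K];
      for (int k = 0; k < K; ++k) {
        double inc = 0.5 * dt * (lt_prev * sigma_curves(k, j - 1) +
                                 lt_cur * sigma_curves(k, j));
        double e = std::exp(-(q[k] + inc));
        se += e;
        ss += sigma_curves(k, j) * e;
      }
      Ee = se / Kd; Ese = ss / Kd;
    }
  };

  auto eval_init = [&](Grp& G_, int i, int jb, double dfac, double lt_prev,
                       double lt_cur, double Ctrial, int n,
                       double& Ee, double& Ese) {
    if (!G_.ai[i]) { Ee = 0.0; Ese = 0.0; return; }
    if (sigma_type == 1) {
      step_eval(G_, G_.Wi[i], G_.pi_[i], -(G_.ibS[i] * dt), Ctrial, dfac, n,
                Ee, Ese);
    } else {
      double se = 0.0, ss = 0.0;
      const double* q = &G_.Qi[(size_t)i * K];
      for (int k = 0; k < K; ++k) {
        double inc = (n == 0) ? 0.0
          : 0.5 * dt * (lt_prev * sigma_curves(k, jb - 1) +
                        lt_cur * sigma_curves(k, jb));
        double e = std::exp(-(q[k] + inc));
        se += e;
        ss += sigma_curves(k, jb) * e;
      }
      Ee = se / Kd; Ese = ss / Kd;
    }
  };

  auto conv = [&](const NumericVector& ker, const std::vector<double>& v,
                  int n, int trunc) -> double {
    if (n == 0) return 0.0;
    int jm = std::min(n, trunc);
    double s = 0.0;
    for (int j = 0; j <= jm; ++j) {
      double w = (j == 0 || j == n) ? 0.5 : 1.0;
      s += w * ker[j] * v[n - j];
    }
    return s;
  };

  // density dump bookkeeping
  std::vector<int> dsteps(density_steps.begin(), density_steps.end());
  List dens_out(dsteps.size());
  int next_dump = 0;

  // ---- time stepping -----------------------------------------------------
  for (int n = 0; n <= nt; ++n) {
    const double tn = n * dt;

    if (n == 0) {
      // commit the initial cohort state first (C == 0 everywhere)
      for (int g = 0; g < G; ++g) {
        Grp& G_ = gr[g];
        if (sigma_type == 1) {
          G_.Wb[0] = 0.0; G_.pb[0] = 0;
          while (G_.pb[0] < K && sigma_thr[G_.pb[0]] <= 0.0) {
            G_.Wb[0] += 1.0; G_.pb[0]++;
          }
          for (size_t i = 0; i < G_.ibS.size(); ++i) {
            double b = G_.ibS[i] * dt;
            while (G_.pi_[i] < K && sigma_thr[G_.pi_[i]] - b <= 0.0) {
              G_.Wi[i] += 1.0; G_.pi_[i]++;
            }
          }
        }
      }
    }

    // initial-infected contributions at this step
    std::vector<double> LinitN(G, 0.0), yIinitN(G, 0.0), prevIN(G, 0.0);
    for (int g = 0; g < G; ++g) {
      Grp& G_ = gr[g];
      for (size_t c = 0; c < G_.ibI.size(); ++c) {
        int j = G_.ibI[c] + n;
        LinitN[g] += G_.wI[c] * ml[j];
        yIinitN[g] += G_.wI[c] * fTI[j];
        prevIN[g] += G_.wI[c] * STI[j];
      }
    }

    // Picard iteration for (x, y, L) at step n
    if (n > 0) {
      for (int g = 0; g < G; ++g) {
        gr[g].x[n] = gr[g].x[n - 1];
        gr[g].y[n] = gr[g].y[n - 1];
      }
    }
    std::vector<double> lastA(G, 0.0);
    int iter = 0;
    for (; iter < picard_max; ++iter) {
      for (int g = 0; g < G; ++g) {
        gr[g].L[n] = LinitN[g] + dt * conv(ml, gr[g].x, n, naL);
      }
      for (int g = 0; g < G; ++g) {
        double s = 0.0;
        for (int g2 = 0; g2 < G; ++g2) s += contact(g2, g) * gr[g2].L[n];
        gr[g].Lt[n] = s;
      }
      double maxdiff = 0.0;
      for (int g = 0; g < G; ++g) {
        Grp& G_ = gr[g];
        const double lt_prev = (n > 0) ? G_.Lt[n - 1] : G_.Lt[0];
        const double lt_cur = G_.Lt[n];
        double dfac = 1.0;
        double Ctrial = (n > 0)
          ? G_.C[n - 1] + 0.5 * dt * (lt_prev + lt_cur) : 0.0;
        if (sigma_type == 1 && n > 0) {
          dfac = std::exp(-(Ctrial - G_.C[n - 1]));
        }
        double A = 0.0, B = 0.0, Ee, Ese;
        for (int m = n; m >= 0; --m) {
          int j = n - m;
          if (n > 0 || j == 0) {
            eval_born(G_, m, j, dfac, lt_prev, lt_cur, Ctrial, n, Ee, Ese);
            double w = (j == 0 || j == n) ? 0.5 : 1.0;
            if (n == 0) w = 0.0; // zero-length age integral at t = 0
            A += w * G_.STV[j] * Ese * G_.y[m];
            B += w * G_.fTV[j] * Ee * G_.y[m];
          }
        }
        A *= dt; B *= dt;
        if (sigma_type == 1 && n >= 1) {
          // trapezoid correction for the sigma staircase: the integrand of
          // the infection flux jumps by STV * y / K at every threshold age
          // (the exposure factor is exactly 1 at the crossing age), and the
          // plain rule mislocates each jump within its cell
          double corr = 0.0;
          for (int k = 0; k < K; ++k) {
            double rk = sigma_thr[k];
            if (!(rk > 0.0)) continue;
            if (rk >= n * dt) break; // sorted: the rest lie beyond t
            double u = rk / dt;
            int jc = (int)std::ceil(u);
            double f2 = jc - u; // in [0, 1); 0 when the jump sits on a node
            double stv = G_.STV[jc] * (1.0 - f2) + G_.STV[jc - 1] * f2;
            double ys = G_.y[n - jc] * (1.0 - f2) +
              ((n - jc + 1 <= n) ? G_.y[n - jc + 1] : 0.0) * f2;
            corr += (f2 - 0.5) * stv * ys;
          }
          A += dt * corr / Kd;
        }
        for (size_t i = 0; i < G_.ibS.size(); ++i) {
          int jb = G_.ibS[i] + n;
          eval_init(G_, (int)i, jb, dfac, lt_prev, lt_cur, Ctrial, n,
                    Ee, Ese);
          A += G_.wS[i] * G_.STV[jb] * Ese;
          B += G_.wS[i] * G_.fTV[jb] * Ee;
        }
        double newx = G_.Lt[n] * A;
        double newy = yIinitN[g] + dt * conv(fTI, G_.x, n, naI) + B;
        maxdiff = std::max(maxdiff, std::fabs(newx - G_.x[n]));
        maxdiff = std::max(maxdiff, std::fabs(newy - G_.y[n]));
        G_.x[n] = newx; G_.y[n] = newy; lastA[g] = A;
      }
      if (maxdiff < picard_tol) break;
    }
    if (iter >= picard_max) {
      stop("Picard iteration did not converge at t = %g; use a smaller dt",
           tn);
    }

    // commit: cumulative force, cohort exposures, new cohort, outputs
    for (int g = 0; g < G; ++g) {
      Grp& G_ = gr[g];
      if (n > 0) {
        G_.C[n] = G_.C[n - 1] + 0.5 * dt * (G_.Lt[n - 1] + G_.Lt[n]);
        if (sigma_type == 1) {
          double dfac = std::exp(-(G_.C[n] - G_.C[n - 1]));
          for (int m = 0; m < n; ++m) {
            if (!G_.ab[m]) continue;
            G_.Wb[m] *= dfac;
            double s = m * dt;
            while (G_.pb[m] < K && s + sigma_thr[G_.pb[m]] <= tn) {
              double tau0 = std::max(s + sigma_thr[G_.pb[m]], 0.0);
              G_.Wb[m] += std::exp(cinterp(G_.C, tau0, dt, n) - G_.C[n]);
              G_.pb[m]++;
            }
          }
          G_.Wb[n] = 0.0; G_.pb[n] = 0;
          while (G_.pb[n] < K && sigma_thr[G_.pb[n]] <= 0.0) {
            G_.Wb[n] += 1.0; G_.pb[n]++;
          }
          for (size_t i = 0; i < G_.ibS.size(); ++i) {
            if (!G_.ai[i]) continue;
            G_.Wi[i] *= dfac;
            double b = G_.ibS[i] * dt;
            while (G_.pi_[i] < K && sigma_thr[G_.pi_[i]] - b <= tn) {
              double tau0 = std::max(sigma_thr[G_.pi_[i]] - b, 0.0);
              G_.Wi[i] += std::exp(cinterp(G_.C, tau0, dt, n) - G_.C[n]);
              G_.pi_[i]++;
            }
          }
        } else {
          const double lt_prev = G_.Lt[n - 1], lt_cur = G_.Lt[n];
          for (int m = 0; m < n; ++m) {
            if (!G_.ab[m]) continue;
            int j = n - m;
            double* q = &G_.Qb[(size_t)m * K];
            for (int k = 0; k < K; ++k) {
              q[k] += 0.5 * dt * (lt_prev * sigma_curves(k, j - 1) +
                                  lt_cur * sigma_curves(k, j));
            }
          }
          for (size_t i = 0; i < G_.ibS.size(); ++i) {
            if (!G_.ai[i]) continue;
            int jb = G_.ibS[i] + n;
            double* q = &G_.Qi[(size_t)i * K];
            for (int k = 0; k < K; ++k) {
              q[k] += 0.5 * dt * (lt_prev * sigma_curves(k, jb - 1) +
                                  lt_cur * sigma_curves(k, jb));
            }
          }
        }
      }

      // committed outputs: prevalence, susceptible mass, mean susceptibility
      double sm = 0.0, Ee, Ese;
      for (int m = n; m >= 0; --m) {
        int j = n - m;
        eval_born(G_, m, j, 1.0, 0.0, 0.0, G_.C[n], n, Ee, Ese);
        double w = (j == 0 || j == n) ? 0.5 : 1.0;
        if (n == 0) w = 0.0;
        sm += w * G_.STV[j] * Ee * G_.y[m];
      }
      sm *= dt;
      for (size_t i = 0; i < G_.ibS.size(); ++i) {
        int jb = G_.ibS[i] + n;
        eval_init(G_, (int)i, jb, 1.0, 0.0, 0.0, G_.C[n], n, Ee, Ese);
        sm += G_.wS[i] * G_.STV[jb] * Ee;
        // prune once both the vaccination survival and the exposure factor
        // can no longer contribute
        if (G_.ai[i] && G_.STV[jb] < 1e-14 && G_.fTV[jb] < 1e-14) {
          G_.ai[i] = 0;
        }
      }
      G_.prev[n] = dt * conv(STI, G_.x, n, naI) + prevIN[g];
      G_.smass[n] = sm;
      G_.sbar[n] = lastA[g];

      // prune born cohorts whose age left the vaccination support
      if (n >= 1) {
        for (int m = 0; m <= n; ++m) {
          if (!G_.ab[m]) continue;
          int j = n - m;
          if (G_.STV[j] < 1e-14 && G_.fTV[j] < 1e-14) G_.ab[m] = 0;
        }
      }
    }

    // requested age-density dumps
    if (next_dump < (int)dsteps.size() && dsteps[next_dump] == n) {
      List per_group(G);
      for (int g = 0; g < G; ++g) {
        Grp& G_ = gr[g];
        NumericVector dI(nj + 1), dS(nj + 1);
        double Ee, Ese;
        for (int j = 0; j <= std::min(n, nj); ++j) {
          int m = n - j;
          dI[j] = STI[j] * G_.x[m];
          eval_born(G_, m, j, 1.0, 0.0, 0.0, G_.C[n], n, Ee, Ese);
          dS[j] = G_.STV[j] * Ee * G_.y[m];
        }
        for (size_t c = 0; c < G_.ibI.size(); ++c) {
          int j = G_.ibI[c] + n;
          if (j <= nj) dI[j] += G_.wI[c] * STI[j] / dt;
        }
        for (size_t i = 0; i < G_.ibS.size(); ++i) {
          int jb = G_.ibS[i] + n;
          eval_init(G_, (int)i, jb, 1.0, 0.0, 0.0, G_.C[n], n, Ee, Ese);
          if (jb <= nj) dS[jb] += G_.wS[i] * G_.STV[jb] * Ee / dt;
        }
        per_group[g] = List::create(_["I"] = dI, _["S"] = dS);
      }
      dens_out[next_dump] = per_group;
      next_dump++;
    }

    if (n % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List out(G);
  for (int g = 0; g < G; ++g) {
    Grp& G_ = gr[g];
    out[g] = List::create(
      _["x"] = G_.x, _["y"] = G_.y, _["L"] = G_.L, _["Lt"] = G_.Lt,
      _["prevalence"] = G_.prev, _["smass"] = G_.smass,
      _["sigma_bar"] = G_.sbar, _["C"] = G_.C);
  }
  return List::create(_["groups"] = out, _["densities"] = dens_out);
}
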