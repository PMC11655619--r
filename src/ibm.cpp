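// Exact event-driven simulation of the finite-population model.
// Recoveries and vaccinations happen at pre-scheduled times (kept in a
// priority queue with deterministic tie-breaking: recovery < vaccination <
// infection, then individual index).  Infections are generated by thinning
// an inhomogeneous Poisson process: candidate times at a bounding rate that
// is piecewise constant between events, accepted with probability
// sigma_i(t) * Lambda(t) / bound.  With constant per-infection
// transmission rates the force of infection is itself piecewise constant
// and the bound is exact; for profiled curves the bound is
// lambda_max * (#I / N).
//
// All randomness comes from R's RNG stream, so runs are reproducible from
// set.seed().

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Law {
  int fam; // 1 exp(rate), 2 gamma(shape, scale), 3 unif(a, b), 4 point, 5 inf
  double p1, p2, shift;
  double sample() const {
    double v;
    switch (fam) {
      case 1: v = R::rexp(1.0 / p1); break;
      case 2: v = R::rgamma(p1, p2); break;
      case 3: v = R::runif(p1, p2); break;
      case 4: v = p1; break;
      default: return R_PosInf;
    }
    return v + shift;
  }
};

Law parse_law(const NumericVector& enc) {
  Law l;
  l.fam = (int)enc[0]; l.p1 = enc[1]; l.p2 = enc[2]; l.shift = enc[3];
  return l;
}

struct Ev {
  double t;
  int kind; // 0 recovery, 1 vaccination
  int idx, version;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    return a.idx > b.idx;
  }
};

inline double grid_at(const NumericVector& g, double dx, double a) {
  if (a <= 0) return g[0];
  double u = a / dx;
  int i = (int)std::floor(u);
  int m = g.size() - 1;
  if (i >= m) return g[m];
  double f = u - i;
  return g[i] * (1 - f) + g[i + 1] * f;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate_ibm(IntegerVector state_, NumericVector tau_,
                      NumericVector sched_, NumericVector lam_val_,
                      NumericVector wane_t_, IntegerVector sig_idx_,
                      int lam_type, double lam_rate,
                      NumericVector lam_grid, double lam_dx,
                      double lam_max,
                      int sig_type, NumericMatrix sig_curves, double sig_dx,
                      NumericVector law_TI, NumericVector law_TV,
                      NumericVector law_TR, int sig_npanel,
                      double t0, double tmax, NumericVector out_times,
                      bool keep_log, double incidence0) {
  // work on copies: callers' vectors may be shared (even bytecode
  // constants), so in-place mutation of the inputs is never safe
  IntegerVector state = clone(state_), sig_idx = clone(sig_idx_);
  NumericVector tau = clone(tau_), sched = clone(sched_),
                lam_val = clone(lam_val_), wane_t = clone(wane_t_);
  const int N = state.size();
  Law TI = parse_law(law_TI), TV = parse_law(law_TV), TR = parse_law(law_TR);
  RNGScope rng;

  // membership lists with O(1) swap-removal
  std::vector<int> Ilist, Slist, pos(N);
  for (int i = 0; i < N; ++i) {
    if (state[i] == 1) { pos[i] = Ilist.size(); Ilist.push_back(i); }
    else { pos[i] = Slist.size(); Slist.push_back(i); }
  }
  auto move_to = [&](int i, std::vector<int>& from, std::vector<int>& to) {
    int p = pos[i];
    int last = from.back();
    from[p] = last; pos[last] = p; from.pop_back();
    pos[i] = to.size(); to.push_back(i);
  };

  std::vector<int> version(N, 0);
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
  for (int i = 0; i < N; ++i) {
    if (R_FINITE(sched[i])) {
      pq.push({sched[i], state[i] == 1 ? 0 : 1, i, 0});
    }
  }

  double sumLam = 0.0; // sum of constant rates of infected (lam_type 0)
  if (lam_type == 0) for (int i : Ilist) sumLam += lam_val[i];

  auto Lambda_at = [&](double t) -> double {
    if (lam_type == 0) return sumLam / N;
    double s = 0.0;
    for (int i : Ilist) {
      double a = t - tau[i];
      if (t < sched[i]) s += grid_at(lam_grid, lam_dx, a);
    }
    return s / N;
  };
  auto bound_rate = [&]() -> double {
    double lb = (lam_type == 0) ? sumLam / N
                                : lam_max * (double)Ilist.size() / N;
    return lb * (double)Slist.size();
  };
  auto sigma_at = [&](int i, double t) -> double {
    if (sig_type == 1) return (t >= wane_t[i]) ? 1.0 : 0.0;
    double a = t - tau[i];
    int k = sig_idx[i];
    int M = sig_curves.ncol() - 1;
    double u = a / sig_dx;
    int j = (int)std::floor(u);
    if (j >= M) return sig_curves(k, M);
    double f = u - j;
    return sig_curves(k, j) * (1 - f) + sig_curves(k, j + 1) * f;
  };
  auto reset_sigma = [&](int i, double t) {
    if (sig_type == 1) {
      wane_t[i] = t + TR.sample();
    } else if (sig_npanel > 1) {
      sig_idx[i] = (int)std::floor(R::runif(0.0, 1.0) * sig_npanel);
      if (sig_idx[i] >= sig_npanel) sig_idx[i] = sig_npanel - 1;
    }
  };

  double t = t0;
  double incidence = incidence0;
  double cand = R_PosInf;
  auto redraw_candidate = [&](double now) {
    double B = bound_rate();
    cand = (B > 0) ? now + R::rexp(1.0 / B) : R_PosInf;
  };
  redraw_candidate(t);

  const int nout = out_times.size();
  NumericVector o_prev(nout), o_lam(nout), o_inc(nout);
  int kout = 0;
  auto flush_outputs = [&](double upto) {
    while (kout < nout && out_times[kout] <= upto) {
      o_prev[kout] = (double)Ilist.size() / N;
      o_lam[kout] = Lambda_at(out_times[kout]);
      o_inc[kout] = incidence;
      ++kout;
    }
  };

  std::vector<double> log_t;
  std::vector<int> log_id, log_kind;

  int guard = 0;
  while (t < tmax) {
    if (++guard % 16384 == 0) Rcpp::checkUserInterrupt();
    // next valid scheduled event
    while (!pq.empty() && pq.top().version != version[pq.top().idx]) pq.pop();
    double te = pq.empty() ? R_PosInf : pq.top().t;
    double tn = std::min(te, cand);
    if (tn > tmax) { flush_outputs(tmax); t = tmax; break; }
    flush_outputs(std::nextafter(tn, -1.0));
    t = tn;

    if (te <= cand) {
      Ev ev = pq.top(); pq.pop();
      int i = ev.idx;
      version[i]++;
      if (ev.kind == 0) { // recovery: I -> S
        if (lam_type == 0) sumLam -= lam_val[i];
        move_to(i, Ilist, Slist);
        state[i] = 0; tau[i] = t;
        reset_sigma(i, t);
        double tv = TV.sample();
        sched[i] = t + tv;
        if (R_FINITE(sched[i])) pq.push({sched[i], 1, i, version[i]});
        if (keep_log) {
          log_t.push_back(t); log_id.push_back(i + 1); log_kind.push_back(1);
        }
      } else { // vaccination: susceptibility reset, next dose drawn
        tau[i] = t;
        reset_sigma(i, t);
        double tv = TV.sample();
        sched[i] = t + tv;
        if (R_FINITE(sched[i])) pq.push({sched[i], 1, i, version[i]});
        if (keep_log) {
          log_t.push_back(t); log_id.push_back(i + 1); log_kind.push_back(2);
        }
      }
      redraw_candidate(t);
    } else {
      // infection candidate: uniform target among susceptibles, thinning
      int nS = Slist.size();
      if (nS > 0) {
        int u = (int)std::floor(R::runif(0.0, 1.0) * nS);
        if (u >= nS) u = nS - 1;
        int i = Slist[u];
        double lb = (lam_type == 0) ? sumLam / N
                                    : lam_max * (double)Ilist.size() / N;
        double acc = 0.0;
        if (lb > 0) {
          acc = sigma_at(i, t) * Lambda_at(t) / lb;
          if (acc > 1.0 + 1e-12) {
            stop("thinning acceptance probability exceeded 1");
          }
        }
        if (R::runif(0.0, 1.0) < acc) {
          version[i]++;
          move_to(i, Slist, Ilist);
          state[i] = 1; tau[i] = t;
          double ti = TI.sample();
          if (!R_FINITE(ti)) ti = 1e12;
          sched[i] = t + ti;
          pq.push({sched[i], 0, i, version[i]});
          if (lam_type == 0) { lam_val[i] = lam_rate; sumLam += lam_rate; }
          incidence += 1.0 / N;
          if (keep_log) {
            log_t.push_back(t); log_id.push_back(i + 1); log_kind.push_back(0);
          }
        }
      }
      redraw_candidate(t);
    }
  }
  flush_outputs(tmax);

  return List::create(
    _["times"] = out_times, _["prevalence"] = o_prev,
    _["Lambda"] = o_lam, _["incidence"] = o_inc,
    _["state"] = state, _["tau"] = tau, _["sched"] = sched,
    _["wane_t"] = wane_t, _["sig_idx"] = sig_idx, _["lam_val"] = lam_val,
    _["t_end"] = t, _["final_incidence"] = incidence,
    _["log_t"] = wrap(log_t), _["log_id"] = wrap(log_id),
    _["log_kind"] = wrap(log_kind));
}
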