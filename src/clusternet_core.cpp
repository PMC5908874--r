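#include <Rcpp.h>
using namespace Rcpp;

// Upper Gaussian tail H(z); degenerate s = 0 handled by the caller.
static inline double gainH(double z) {
  return 0.5 * std::erfc(z * M_SQRT1_2);
}

// Explicit Euler integration of the population rate dynamics
//   tau_a dm_a/dt = -m_a + H(-mu_a / s_a),
// mu = Jbar m + Jx mX - theta, s2 = Jbar2 m. Populations with fixed[a]
// TRUE are clamped at their initial rate (effective-response slaves).
// [[Rcpp::export]]
List mf_euler_cpp(NumericMatrix Jbar, NumericMatrix Jbar2,
                  NumericVector theta, NumericVector Jx, double mX,
                  NumericVector tau, NumericVector m0, double dt,
                  int nsteps, LogicalVector fixed, int record_every) {
  const int P = m0.size();
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> mu(P), s2(P), target(P);
  int nrec = (record_every > 0) ? nsteps / record_every + 1 : 1;
  NumericMatrix traj(record_every > 0 ? nrec : 1, P);
  NumericVector tout(record_every > 0 ? nrec : 1);
  int ri = 0;
  if (record_every > 0) {
    for (int a = 0; a < P; ++a) traj(0, a) = m[a];
    tout[0] = 0.0;
    ri = 1;
  }
  for (int step = 1; step <= nsteps; ++step) {
    for (int a = 0; a < P; ++a) {
      double acc = 0.0, v = 0.0;
      for (int b = 0; b < P; ++b) {
        acc += Jbar(a, b) * m[b];
        v += Jbar2(a, b) * m[b];
      }
      mu[a] = acc + Jx[a] * mX - theta[a];
      s2[a] = v;
    }
    for (int a = 0; a < P; ++a) {
      if (fixed[a]) continue;
      double tgt;
      if (s2[a] > 0.0) tgt = gainH(-mu[a] / std::sqrt(s2[a]));
      else tgt = (mu[a] > 0.0) ? 1.0 : (mu[a] < 0.0 ? 0.0 : 0.5);
      m[a] += dt * (tgt - m[a]) / tau[a];
      if (m[a] < 0.0) m[a] = 0.0;
      if (m[a] > 1.0) m[a] = 1.0;
    }
    if (record_every > 0 && (step % record_every == 0) && ri < nrec) {
      for (int a = 0; a < P; ++a) traj(ri, a) = m[a];
      tout[ri] = step * dt;
      ++ri;
    }
  }
  NumericVector finalm(P);
  for (int a = 0; a < P; ++a) finalm[a] = m[a];
  if (record_every > 0 && ri < nrec) {
    // trim unreached rows (nsteps not divisible by record_every)
    traj = traj(Range(0, ri - 1), _);
    tout = tout[Range(0, ri - 1)];
  }
  return List::create(_["t"] = tout, _["m"] = traj, _["final"] = finalm);
}

// Event-driven simulation of a network of asynchronously updated binary
// units. Each unit of population alpha has an independent exponential
// update clock with mean interval tau_alpha, realized as a Gillespie
// scheme: total event rate Lambda = N_E/tau_E + N_I/tau_I, population
// chosen proportionally to its rate, unit uniformly within the
// population, time advanced by Exp(1/Lambda). At an update the unit's
// new state is Theta(sum_j J_ij sigma_j - theta_i + J_X m_X). The
// recurrent input h_i = sum_j J_ij sigma_j is maintained incrementally:
// it changes only when a presynaptic unit flips, costing one sparse
// column traversal. Uses the R RNG, so results are reproducible via
// set.seed().
//
// The sparse matrix is passed in compressed sparse column form
// (colptr/rowind 0-based, values w). Only state flips are recorded:
// together with sigma0 they determine the full state trajectory.
// [[Rcpp::export]]
List simulate_binary_cpp(int N_E, int N_I,
                         IntegerVector colptr, IntegerVector rowind,
                         NumericVector w,
                         double theta_E, double theta_I,
                         double Jx_E, double Jx_I, double mX,
                         double tau_E, double tau_I,
                         double duration, LogicalVector sigma0,
                         double discard, bool record_updates) {
  const int N = N_E + N_I;
  if (sigma0.size() != N) stop("sigma0 length mismatch");
  std::vector<int> sigma(N);
  std::vector<double> h(N, 0.0);
  for (int j = 0; j < N; ++j) sigma[j] = sigma0[j] ? 1 : 0;
  for (int j = 0; j < N; ++j) {
    if (!sigma[j]) continue;
    for (int k = colptr[j]; k < colptr[j + 1]; ++k) h[rowind[k]] += w[k];
  }
  const double rate_E = N_E / tau_E, rate_I = N_I / tau_I;
  const double Lambda = rate_E + rate_I, pE = rate_E / Lambda;

  std::vector<double> flip_t; std::vector<int> flip_unit, flip_state;
  std::vector<double> upd_t; std::vector<int> upd_unit, upd_state;
  flip_t.reserve(1 << 16);

  // exact time-averaged activity per population over [discard, duration]
  double accE = 0.0, accI = 0.0, t_last = 0.0;
  int sumE = 0, sumI = 0;
  for (int j = 0; j < N_E; ++j) sumE += sigma[j];
  for (int j = N_E; j < N; ++j) sumI += sigma[j];
  long n_updates = 0, n_flips = 0;

  double t = 0.0;
  while (true) {
    t += R::exp_rand() / Lambda;
    if (t > duration) t = duration;
    double lo = std::max(t_last, discard), hi = std::min(t, duration);
    if (hi > lo) { accE += sumE * (hi - lo); accI += sumI * (hi - lo); }
    t_last = t;
    if (t >= duration) break;

    int unit;
    double inp;
    if (unif_rand() < pE) {
      unit = (int)(unif_rand() * N_E);
      if (unit >= N_E) unit = N_E - 1;
      inp = h[unit] - theta_E + Jx_E * mX;
    } else {
      unit = N_E + (int)(unif_rand() * N_I);
      if (unit >= N) unit = N - 1;
      inp = h[unit] - theta_I + Jx_I * mX;
    }
    if (!std::isfinite(inp)) stop("non-finite input at t=%f", t);
    int news = inp > 0.0 ? 1 : 0;
    ++n_updates;
    if (record_updates) {
      upd_t.push_back(t); upd_unit.push_back(unit + 1);
      upd_state.push_back(news);
    }
    if (news != sigma[unit]) {
      ++n_flips;
      double d = news ? 1.0 : -1.0;
      sigma[unit] = news;
      for (int k = colptr[unit]; k < colptr[unit + 1]; ++k)
        h[rowind[k]] += d * w[k];
      if (unit < N_E) sumE += news ? 1 : -1; else sumI += news ? 1 : -1;
      flip_t.push_back(t); flip_unit.push_back(unit + 1);
      flip_state.push_back(news);
    }
  }
  double span = duration - discard;
  List out = List::create(
    _["flip_t"] = NumericVector(flip_t.begin(), flip_t.end()),
    _["flip_unit"] = IntegerVector(flip_unit.begin(), flip_unit.end()),
    _["flip_state"] = IntegerVector(flip_state.begin(), flip_state.end()),
    _["mean_m_E"] = span > 0 ? accE / (span * N_E) : NA_REAL,
    _["mean_m_I"] = span > 0 ? accI / (span * N_I) : NA_REAL,
    _["n_updates"] = (double)n_updates,
    _["n_flips"] = (double)n_flips,
    _["sigma_final"] = IntegerVector(sigma.begin(), sigma.end()));
  if (record_updates) {
    out["update_t"] = NumericVector(upd_t.begin(), upd_t.end());
    out["update_unit"] = IntegerVector(upd_unit.begin(), upd_unit.end());
    out["update_state"] = IntegerVector(upd_state.begin(), upd_state.end());
  }
  return out;
}
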