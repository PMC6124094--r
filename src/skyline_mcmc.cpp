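// Change-point skyline MCMC conditioned on a point genealogy.
//
// State: log-size values v at knots (knot 0 at time 0, knots 1..m at the
// genealogy's coalescent event times) and binary indicators on knots 1..m.
// The trajectory is linear in Ne between active knots and constant beyond
// the oldest active knot. Priors: Poisson(log 2) on the number of active
// indicators spread uniformly over configurations of that count, and
// log-uniform sizes on [ne_lo, ne_hi]. Reversible-jump flips redraw the
// incoming knot value from a normal proposal centred on the current
// interpolated trajectory, with the matching Hastings correction.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  std::vector<double> times;  // knot times, times[0] = 0, then event times
  int n_tips;
  double gf;                  // g * f
  double lv_lo, lv_hi;        // bounds on v = log Ne
  double pois_mean;
  bool prior_only;
};

// Ne at every knot time given the active-knot structure.
void traj_at_knots(const Model& M, const std::vector<int>& act,
                   const std::vector<double>& v, std::vector<double>& ne) {
  const int m1 = M.times.size();
  const int na = act.size();
  ne.resize(m1);
  int seg = 0;
  for (int i = 0; i < m1; ++i) {
    const double t = M.times[i];
    while (seg + 1 < na && M.times[act[seg + 1]] <= t) ++seg;
    if (seg + 1 >= na) {
      ne[i] = std::exp(v[act[na - 1]]);          // constant beyond last active
    } else {
      const double ta = M.times[act[seg]], tb = M.times[act[seg + 1]];
      const double Na = std::exp(v[act[seg]]), Nb = std::exp(v[act[seg + 1]]);
      ne[i] = (t <= ta) ? Na : Na + (Nb - Na) * (t - ta) / (tb - ta);
    }
  }
}

// Interpolated Ne at knot j's time if knot j were NOT active.
double interp_without(const Model& M, const std::vector<int>& act,
                      const std::vector<double>& v, int j) {
  const int na = act.size();
  const double t = M.times[j];
  int lo = -1, hi = -1;
  for (int s = 0; s < na; ++s) {
    if (act[s] == j) continue;
    if (M.times[act[s]] <= t) lo = act[s];
    else { hi = act[s]; break; }
  }
  if (lo < 0) return std::exp(v[hi]);   // t below every active knot time
  if (hi < 0) return std::exp(v[lo]);
  const double ta = M.times[lo], tb = M.times[hi];
  const double Na = std::exp(v[lo]), Nb = std::exp(v[hi]);
  return Na + (Nb - Na) * (t - ta) / (tb - ta);
}

double seg_integral(double dt, double Na, double Nb) {
  if (dt <= 0) return 0.0;
  const double dN = Nb - Na;
  if (std::fabs(dN) < 1e-9 * std::max(Na, Nb)) return dt * 2.0 / (Na + Nb);
  return dt * std::log(Nb / Na) / dN;
}

// Coalescent log-likelihood given Ne at every knot (trajectory linear
// between consecutive knot times).
double loglik(const Model& M, const std::vector<double>& ne) {
  if (M.prior_only) return 0.0;
  const int m = M.times.size() - 1;   // number of events
  double ll = 0.0;
  int k = M.n_tips;
  for (int i = 1; i <= m; ++i, --k) {
    const double lam =
        seg_integral(M.times[i] - M.times[i - 1], ne[i - 1], ne[i]) / M.gf;
    ll -= 0.5 * k * (k - 1) * lam;
    ll -= std::log(M.gf * ne[i]);
  }
  return ll;
}

double log_prior_ind(const Model& M, int K, int m) {
  // Poisson(pois_mean) on K, uniform over the choose(m, K) configurations
  return R::dpois(K, M.pois_mean, 1) - R::lchoose(m, K);
}

// Two-scale mixture proposal for reversible-jump value redraws: a narrow
// component for refining near the interpolated trajectory and a wide one
// for jumping to genuinely different sizes.
double flip_draw(double mu, double sd) {
  const double s = (unif_rand() < 0.7) ? sd : 3.5 * sd;
  return norm_rand() * s + mu;
}

double flip_logdens(double x, double mu, double sd) {
  return std::log(0.7 * R::dnorm(x, mu, sd, 0) +
                  0.3 * R::dnorm(x, mu, 3.5 * sd, 0));
}

std::vector<int> active_set(const std::vector<int>& ind) {
  std::vector<int> act;
  act.push_back(0);
  for (size_t j = 1; j < ind.size(); ++j)
    if (ind[j]) act.push_back(j);
  return act;
}

}  // namespace

// [[Rcpp::export(name = ".skyline_mcmc_cpp")]]
List skyline_mcmc_cpp(NumericVector event_times, int n_tips, double g, double f,
                      double chain_length, int thin,
                      double ne_lo, double ne_hi, double pois_mean,
                      bool prior_only,
                      double w_flip, double w_scale, double w_swap, double w_all,
                      double flip_sd, double scale_width, double all_width,
                      NumericVector v_init) {
  const int m = event_times.size();
  Model M;
  M.times.resize(m + 1);
  M.times[0] = 0.0;
  for (int i = 0; i < m; ++i) M.times[i + 1] = event_times[i];
  M.n_tips = n_tips;
  M.gf = g * f;
  M.lv_lo = std::log(ne_lo);
  M.lv_hi = std::log(ne_hi);
  M.pois_mean = pois_mean;
  M.prior_only = prior_only;

  std::vector<double> v(m + 1);
  for (int i = 0; i <= m; ++i) v[i] = v_init[i];
  std::vector<int> ind(m + 1, 0);  // ind[0] unused; knot 0 always active
  std::vector<int> act = active_set(ind);
  std::vector<double> ne, ne_prop;
  traj_at_knots(M, act, v, ne);
  double ll = loglik(M, ne);
  int K = 0;

  const double wtot = w_flip + w_scale + w_swap + w_all;
  const double c_flip = w_flip / wtot;
  const double c_scale = c_flip + w_scale / wtot;
  const double c_swap = c_scale + w_swap / wtot;
  const double lpv = -std::log(M.lv_hi - M.lv_lo);  // log-uniform density in v

  const long n_iter = (long)chain_length;
  const int n_samp = (int)(n_iter / thin);
  NumericMatrix traj_out(n_samp, m + 1);
  NumericVector ll_out(n_samp), lp_out(n_samp);
  IntegerVector k_out(n_samp), state_out(n_samp);
  NumericVector att(4), acc(4);

  RNGScope scope;
  int isamp = 0;
  for (long it = 1; it <= n_iter; ++it) {
    const double u = unif_rand();
    if (u < c_flip) {
      // reversible-jump indicator flip with value redraw
      att[0] += 1;
      const int j = 1 + (int)(unif_rand() * m);
      if (ind[j] == 0) {
        const double mu = std::log(interp_without(M, act, v, j));
        const double vp = flip_draw(mu, flip_sd);
        if (vp >= M.lv_lo && vp <= M.lv_hi) {
          std::vector<int> ind2 = ind; ind2[j] = 1;
          std::vector<double> v2 = v; v2[j] = vp;
          std::vector<int> act2 = active_set(ind2);
          traj_at_knots(M, act2, v2, ne_prop);
          const double ll2 = loglik(M, ne_prop);
          const double lq = flip_logdens(vp, mu, flip_sd);
          const double lA = (ll2 - ll) +
              (log_prior_ind(M, K + 1, m) - log_prior_ind(M, K, m)) +
              lpv - lq;
          if (std::log(unif_rand()) < lA) {
            ind = ind2; v = v2; act = act2; ne = ne_prop; ll = ll2; ++K;
            acc[0] += 1;
          }
        }
      } else {
        std::vector<int> ind2 = ind; ind2[j] = 0;
        std::vector<int> act2 = active_set(ind2);
        traj_at_knots(M, act2, v, ne_prop);
        const double ll2 = loglik(M, ne_prop);
        const double mu = std::log(interp_without(M, act, v, j));
        const double lq = flip_logdens(v[j], mu, flip_sd);
        const double lA = (ll2 - ll) +
            (log_prior_ind(M, K - 1, m) - log_prior_ind(M, K, m)) +
            lq - lpv;
        if (std::log(unif_rand()) < lA) {
          ind = ind2; act = act2; ne = ne_prop; ll = ll2; --K;
          acc[0] += 1;
        }
      }
    } else if (u < c_scale) {
      // random-walk move on one active knot's log size
      att[1] += 1;
      const int j = act[(int)(unif_rand() * act.size())];
      const double vp = v[j] + (unif_rand() * 2.0 - 1.0) * scale_width;
      if (vp >= M.lv_lo && vp <= M.lv_hi) {
        std::vector<double> v2 = v; v2[j] = vp;
        traj_at_knots(M, act, v2, ne_prop);
        const double ll2 = loglik(M, ne_prop);
        if (std::log(unif_rand()) < ll2 - ll) {
          v = v2; ne = ne_prop; ll = ll2;
          acc[1] += 1;
        }
      }
    } else if (u < c_swap) {
      // move an active indicator: half the attempts slide it to an adjacent
      // event, half relocate it to a uniformly chosen inactive event
      // (both symmetric: the inactive-slot count is unchanged)
      att[2] += 1;
      if (K > 0) {
        const int pick = 1 + (int)(unif_rand() * K);
        const int j = act[pick];  // act[0] is knot 0
        int jj;
        if (unif_rand() < 0.5) {
          jj = j + ((unif_rand() < 0.5) ? -1 : 1);
        } else {
          jj = 1 + (int)(unif_rand() * m);
        }
        if (jj >= 1 && jj <= m && ind[jj] == 0) {
          std::vector<int> ind2 = ind; ind2[j] = 0; ind2[jj] = 1;
          std::vector<double> v2 = v; v2[jj] = v[j];
          std::vector<int> act2 = active_set(ind2);
          traj_at_knots(M, act2, v2, ne_prop);
          const double ll2 = loglik(M, ne_prop);
          if (std::log(unif_rand()) < ll2 - ll) {
            ind = ind2; v = v2; act = act2; ne = ne_prop; ll = ll2;
            acc[2] += 1;
          }
        }
      }
    } else {
      // shift all active log sizes by a common offset
      att[3] += 1;
      const double off = (unif_rand() * 2.0 - 1.0) * all_width;
      bool ok = true;
      std::vector<double> v2 = v;
      for (size_t s = 0; s < act.size(); ++s) {
        v2[act[s]] += off;
        if (v2[act[s]] < M.lv_lo || v2[act[s]] > M.lv_hi) { ok = false; break; }
      }
      if (ok) {
        traj_at_knots(M, act, v2, ne_prop);
        const double ll2 = loglik(M, ne_prop);
        if (std::log(unif_rand()) < ll2 - ll) {
          v = v2; ne = ne_prop; ll = ll2;
          acc[3] += 1;
        }
      }
    }

    if (it % thin == 0 && isamp < n_samp) {
      for (int i = 0; i <= m; ++i) traj_out(isamp, i) = ne[i];
      ll_out[isamp] = ll;
      lp_out[isamp] = log_prior_ind(M, K, m) + (K + 1) * lpv;
      k_out[isamp] = K;
      state_out[isamp] = (int)it;
      ++isamp;
    }
  }

  NumericVector rate(4);
  for (int i = 0; i < 4; ++i) rate[i] = att[i] > 0 ? acc[i] / att[i] : NA_REAL;
  rate.names() = CharacterVector::create("flip", "scale", "swap", "shift_all");
  return List::create(_["traj"] = traj_out, _["loglik"] = ll_out,
                      _["logprior"] = lp_out, _["n_changes"] = k_out,
                      _["state"] = state_out, _["acceptance"] = rate);
}
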