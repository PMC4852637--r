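#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact event-driven simulation of the immigration-death process.
// Arrivals at constant rate alpha, per-capita departures at rate beta.
// States are recorded at `output_times` by carry-forward of the state
// immediately before the first event strictly after that time.
// Uses R's global RNG, so set.seed() on the R side gives reproducibility.
// [[Rcpp::export]]
IntegerVector box_gillespie_cpp(double alpha, double beta, int x0,
                                NumericVector output_times,
                                double max_events) {
  int M = output_times.size();
  IntegerVector out(M);
  double t = 0.0;
  double x = x0;
  int j = 0;
  double n_events = 0.0;
  while (j < M) {
    double total = alpha + beta * x;
    double t_next;
    if (total <= 0.0 || n_events >= max_events) {
      t_next = R_PosInf;  // absorbed (or event budget spent): state frozen
    } else {
      t_next = t + R::rexp(1.0 / total);
    }
    while (j < M && output_times[j] < t_next) {
      out[j] = (int)x;
      ++j;
    }
    if (!R_finite(t_next)) break;
    t = t_next;
    if (R::unif_rand() * total < alpha) {
      x += 1.0;
    } else {
      x -= 1.0;
    }
    n_events += 1.0;
  }
  return out;
}

static inline bool in_window(double hour, double w0, double w1) {
  // half-open [w0, w1) on the 24 h clock
  return hour >= w0 && hour < w1;
}

static inline double mod24(double x) {
  // hour-of-day without std::fmod (keeps the object free of recent
  // versioned libm symbols that older loaders cannot resolve)
  return x - 24.0 * std::floor(x / 24.0);
}

static inline double draw_batch(double mu, double sigma, double cap) {
  double raw = std::exp(R::rnorm(mu, sigma));
  double b = std::floor(raw + 0.5);  // round half away from zero (raw > 0)
  if (b < 1.0) b = 1.0;
  if (b > cap) b = cap;
  return b;
}

// WHIRS shopper/worker compartment model, exact simulation.
// State (S, I, R, H, W, C); rates are piecewise constant between events
// because the time-of-day windows only switch on integer hours, so a
// candidate waiting time that crosses the next hour boundary is discarded
// and redrawn from the boundary (valid by memorylessness). Scheduled
// actions at boundaries: record + reset C each hour; R -> S at midnight.
// Event codes in the log: 1 shopper arrival (S->I), 2 shopper departure
// (I->R), 3 worker to work (H->W), 4 worker to home (W->H).
// [[Rcpp::export]]
List whirs_gillespie_cpp(NumericVector state0, double t0, double t_end,
                         double N, double Nw,
                         double eps, double alpha, double beta,
                         double gamma_minus, double delta_minus,
                         double gamma_plus, double delta_plus,
                         double mu, double sigma,
                         NumericVector shop_win,
                         NumericVector work_in_win,
                         NumericVector work_out_win,
                         double max_events,
                         bool record_events) {
  double S = state0[0], I = state0[1], R = state0[2];
  double H = state0[3], W = state0[4], C = state0[5];
  double t = t0;
  double n_events = 0.0;

  int n_hours = (int)std::floor(t_end - t0 + 1e-9);
  NumericVector hourly(n_hours);
  NumericMatrix hourly_state(n_hours, 6);  // state just after each boundary
  NumericVector hour_start(n_hours);
  int hour_idx = 0;

  std::vector<double> ev_t, ev_type, ev_size;

  bool budget_hit = false;
  while (t < t_end - 1e-9) {
    double hh = mod24(std::floor(t + 1e-9));
    double next_boundary = std::floor(t + 1e-9) + 1.0;
    if (next_boundary > t_end) next_boundary = t_end;

    double ra = (S > 0.0 && in_window(hh, shop_win[0], shop_win[1]))
                    ? eps + alpha * S * (I + W) / N : 0.0;
    double rd = (I > 0.0) ? beta * I : 0.0;
    double rw = (H > 0.0 && in_window(hh, work_in_win[0], work_in_win[1]))
                    ? gamma_minus + delta_minus * W : 0.0;
    double rh = (W > 0.0 && in_window(hh, work_out_win[0], work_out_win[1]))
                    ? gamma_plus + delta_plus * W : 0.0;
    double total = ra + rd + rw + rh;

    double t_cand = (total > 0.0 && !budget_hit)
                        ? t + R::rexp(1.0 / total) : R_PosInf;

    if (t_cand >= next_boundary) {
      // scheduled boundary actions fire; candidate discarded (memoryless)
      t = next_boundary;
      if (std::fabs(t - std::floor(t + 1e-9)) < 1e-9 && hour_idx < n_hours) {
        hour_start[hour_idx] = t - 1.0;
        hourly[hour_idx] = C;
        C = 0.0;
        if (mod24(std::floor(t + 1e-9)) == 0.0) {
          S += R;  // midnight: everyone returned home becomes susceptible
          R = 0.0;
        }
        hourly_state(hour_idx, 0) = S; hourly_state(hour_idx, 1) = I;
        hourly_state(hour_idx, 2) = R; hourly_state(hour_idx, 3) = H;
        hourly_state(hour_idx, 4) = W; hourly_state(hour_idx, 5) = C;
        ++hour_idx;
      }
      continue;
    }

    t = t_cand;
    double u = R::unif_rand() * total;
    double size = 0.0, type = 0.0;
    if (u < ra) {
      size = draw_batch(mu, sigma, S);
      S -= size; I += size; C += size;
      type = 1.0;
    } else if (u < ra + rd) {
      size = draw_batch(mu, sigma, I);
      I -= size; R += size; C += size;
      type = 2.0;
    } else if (u < ra + rd + rw) {
      H -= 1.0; W += 1.0; C += 1.0;
      size = 1.0; type = 3.0;
    } else {
      W -= 1.0; H += 1.0; C += 1.0;
      size = 1.0; type = 4.0;
    }
    if (S < 0.0 || I < 0.0 || R < 0.0 || H < 0.0 || W < 0.0)
      stop("internal error: negative compartment after event");
    n_events += 1.0;
    if (record_events) {
      ev_t.push_back(t);
      ev_type.push_back(type);
      ev_size.push_back(size);
    }
    if (n_events >= max_events) budget_hit = true;
  }

  NumericVector final_state = NumericVector::create(
      _["S"] = S, _["I"] = I, _["R"] = R, _["H_home"] = H, _["W"] = W,
      _["C"] = C);

  SEXP events = R_NilValue;
  if (record_events) {
    int ne = (int)ev_t.size();
    NumericMatrix em(ne, 3);
    for (int i = 0; i < ne; ++i) {
      em(i, 0) = ev_t[i];
      em(i, 1) = ev_type[i];
      em(i, 2) = ev_size[i];
    }
    colnames(em) = CharacterVector::create("time", "type", "size");
    events = em;
  }

  colnames(hourly_state) =
      CharacterVector::create("S", "I", "R", "H_home", "W", "C");
  return List::create(_["hour_start"] = hour_start,
                      _["hourly_counts"] = hourly,
                      _["hourly_state"] = hourly_state,
                      _["final_state"] = final_state,
                      _["final_time"] = t,
                      _["n_events"] = n_events,
                      _["event_budget_hit"] = budget_hit,
                      _["events"] = events);
}
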