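#include <Rcpp.h>
using namespace Rcpp;

// Inverse piecewise-linear CDF draw. `cdf` is strictly increasing with
// matching `grid`; both are pre-reduced on the R side.
static double draw_inv_cdf(const NumericVector &cdf, const NumericVector &grid) {
  double u = R::runif(0.0, 1.0);
  int lo = 0, hi = cdf.size() - 1;
  if (u <= cdf[0]) return grid[0];
  if (u >= cdf[hi]) return grid[hi];
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid; else hi = mid;
  }
  double w = (u - cdf[lo]) / (cdf[hi] - cdf[lo]);
  return grid[lo] + w * (grid[hi] - grid[lo]);
}

// Sample an interval pair (Tb, Td) with Tb > Td enforced by rejection.
static void sample_cycle(const NumericVector &b_cdf, const NumericVector &b_grid,
                         const NumericVector &d_cdf, const NumericVector &d_grid,
                         double &Tb, double &Td) {
  for (int tries = 0; tries < 100000; ++tries) {
    Tb = draw_inv_cdf(b_cdf, b_grid);
    Td = draw_inv_cdf(d_cdf, d_grid);
    if (Tb > Td) return;
  }
  stop("Could not sample Tb > Td: flash-length support exceeds interval support.");
}

// Stochastic pulse-coupled integrate-and-fire swarm.
//
// Per timestep, synchronously for all agents:
//  (1) threshold updates: a charging agent with V >= 1 starts flashing
//      (eps -> 0) and resamples its next cycle (Tb, Td, Ts = Tb - Td) so
//      the coming start-to-start interval is exactly the sampled Tb; a
//      flashing agent with V <= 0 stops (eps -> 1);
//  (2) agents with eps == 0 are flashing during this step;
//  (3) Euler voltage update using the post-threshold eps snapshot:
//      charging agents gain dt/Ts plus a pulse donation gain*beta/N per
//      visible flash ONSET this step; flashing agents lose dt/Td; V is
//      clamped to [0, 1]. Flashing agents receive no donations, so a
//      collective burst cannot re-trigger agents that already flashed.
//
// Uses R's RNG, so set.seed() on the R side makes runs bit-identical.
// [[Rcpp::export(name = ".swarm_run")]]
List swarm_run(int N, double beta, double gain, double dt, int n_steps,
               Nullable<NumericMatrix> adjacency,
               NumericVector b_cdf, NumericVector b_grid,
               NumericVector d_cdf, NumericVector d_grid) {
  bool all_to_all = adjacency.isNull();
  NumericMatrix adj;
  if (!all_to_all) adj = NumericMatrix(adjacency);

  std::vector<double> V(N), Ts(N), Td(N);
  std::vector<int> eps(N, 1);
  std::vector<double> pending(N, -1.0);

  for (int i = 0; i < N; ++i) {
    V[i] = R::runif(0.0, 1.0);
    double tb, td;
    sample_cycle(b_cdf, b_grid, d_cdf, d_grid, tb, td);
    Ts[i] = tb - td;
    Td[i] = td;
  }

  std::vector<int> ev_agent;
  std::vector<double> ev_start, ev_end;
  std::vector<int> eps0(N), onset(N);
  double couple = (N > 0) ? gain * beta / N : 0.0;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    for (int i = 0; i < N; ++i) onset[i] = 0;
    for (int i = 0; i < N; ++i) {
      if (eps[i] == 1 && V[i] >= 1.0) {
        eps[i] = 0;
        onset[i] = 1;
        pending[i] = t;
        // resample the full cycle at flash onset so the discharge (Td) and
        // the following charge (Ts = Tb - Td) come from the same draw:
        // the next start-to-start interval is exactly the sampled Tb
        double tb, td;
        sample_cycle(b_cdf, b_grid, d_cdf, d_grid, tb, td);
        Ts[i] = tb - td;
        Td[i] = td;
      } else if (eps[i] == 0 && V[i] <= 0.0) {
        eps[i] = 1;
        ev_agent.push_back(i + 1);
        ev_start.push_back(pending[i]);
        ev_end.push_back(t);
        pending[i] = -1.0;
      }
    }

    for (int i = 0; i < N; ++i) eps0[i] = eps[i];
    // pulse coupling: an onsetting neighbor donates gain*beta/N voltage
    double kick_pool = 0.0;
    if (all_to_all) {
      for (int j = 0; j < N; ++j) kick_pool += onset[j];
    }

    for (int i = 0; i < N; ++i) {
      if (eps0[i] == 1) {
        double kicks;
        if (all_to_all) {
          kicks = kick_pool;  // onset[i] == 1 implies eps0[i] == 0
        } else {
          kicks = 0.0;
          for (int j = 0; j < N; ++j) kicks += adj(i, j) * onset[j];
        }
        V[i] += dt / Ts[i] + couple * kicks;
      } else {
        V[i] -= dt / Td[i];
      }
      if (V[i] > 1.0) V[i] = 1.0;
      if (V[i] < 0.0) V[i] = 0.0;
    }
  }

  return List::create(
    _["agent_id"] = wrap(ev_agent),
    _["t_start"] = wrap(ev_start),
    _["t_end"] = wrap(ev_end)
  );
}
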