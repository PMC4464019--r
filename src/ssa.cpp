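#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Combinatorial mass-action propensity for one reaction:
//   a_j(x) = c_j * prod_i choose(x_i, r_ij)
// where r_ij is the reactant multiplicity. All built-in models use r <= 1,
// for which this reduces to c * prod x_i^{r_i}.
static inline double propensity(const std::vector<int>& x,
                                const IntegerMatrix& reactants,
                                const NumericVector& rates, int j) {
  double a = rates[j];
  const int n = reactants.ncol();
  for (int i = 0; i < n && a > 0.0; ++i) {
    const int r = reactants(j, i);
    if (r == 0) continue;
    double h = 1.0;
    for (int k = 0; k < r; ++k) h *= (double)(x[i] - k) / (double)(k + 1);
    if (h < 0.0) h = 0.0;  // fewer molecules than needed
    a *= h;
  }
  return a;
}

// Gillespie direct method for mass-action reaction networks.
//
// x0:        initial copy numbers (length n_species)
// nu:        n_react x n_species state-change matrix
// reactants: n_react x n_species reactant multiplicities
// rates:     stochastic rate constants c_j
// t_max:     stop time (> 0)
// max_events: hard cap on the number of reaction events
//
// Records the state after every event plus the initial row at t = 0; stops
// at t_max, at max_events, or when the total propensity reaches zero.
// When the stop is due to t_max (the next event would overshoot it), a
// closing row at exactly t_max repeats the final state, so the recorded
// domain covers the whole simulated interval. Absorbing or event-capped
// stops do not get a closing row.
// Draws from R's RNG stream, so results are reproducible via set.seed().
// [[Rcpp::export]]
List ssa_direct_cpp(IntegerVector x0, IntegerMatrix nu, IntegerMatrix reactants,
                    NumericVector rates, double t_max, int max_events) {
  const int n_species = x0.size();
  const int n_react = rates.size();
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> times;
  std::vector<int> states;  // row-major: event-major blocks of n_species
  times.reserve(1024);
  states.reserve(1024 * n_species);

  double t = 0.0;
  times.push_back(t);
  for (int i = 0; i < n_species; ++i) states.push_back(x[i]);

  std::vector<double> a(n_react);
  int n_events = 0;
  bool hit_tmax = false;
  while (n_events < max_events) {
    double a0 = 0.0;
    for (int j = 0; j < n_react; ++j) {
      a[j] = propensity(x, reactants, rates, j);
      if (a[j] < 0.0) stop("negative propensity encountered in reaction %d", j + 1);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;  // absorbing state

    t += R::rexp(1.0 / a0);
    if (t > t_max) { hit_tmax = true; break; }

    double u = unif_rand() * a0, cum = 0.0;
    int j = n_react - 1;
    for (int k = 0; k < n_react; ++k) {
      cum += a[k];
      if (u <= cum) { j = k; break; }
    }
    for (int i = 0; i < n_species; ++i) x[i] += nu(j, i);

    times.push_back(t);
    for (int i = 0; i < n_species; ++i) states.push_back(x[i]);
    ++n_events;
  }

  if (hit_tmax && times.back() < t_max) {
    times.push_back(t_max);
    for (int i = 0; i < n_species; ++i) states.push_back(x[i]);
  }

  const int n_rows = (int)times.size();
  IntegerMatrix values(n_rows, n_species);
  for (int r = 0; r < n_rows; ++r)
    for (int i = 0; i < n_species; ++i)
      values(r, i) = states[(size_t)r * n_species + i];

  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["values"] = values,
                      _["n_events"] = n_events);
}
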