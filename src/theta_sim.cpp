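#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the theta-neuron network.
//
// State: theta for the n network cells plus the pacemaker (index n), and
// one gating variable per synapse group (synapses sharing a presynaptic
// cell and a decay time). All derivatives are evaluated from the state at
// time t before any component is advanced.
//
// W        : G x n signed weight matrix (alpha_j * g_jk), fanned out per group
// pre      : 1-based presynaptic index of each group (n+1 = pacemaker)
// tau_d    : decay time per group (ms)
// b        : applied current per network cell
// b_pace   : constant pacemaker current
// noise    : n_steps x n precomputed summed noise EPSP series
// theta0   : initial phases, length n + 1 (pacemaker last)
//
// Returns theta trace (n_steps x (n+1)) and gating trace (n_steps x G),
// both recorded at the start of each step (row i = state at t = i*dt).
// [[Rcpp::export]]
List sim_theta_core(NumericMatrix W, IntegerVector pre, NumericVector tau_d,
                    double tau_R, double eta, NumericVector b, double b_pace,
                    NumericMatrix noise, NumericVector theta0,
                    double dt, int n_steps) {
  const int G = W.nrow();
  const int n = W.ncol();
  const double two_pi = 2.0 * M_PI;

  if (theta0.size() != n + 1) stop("theta0 must have length n_cells + 1");
  if (noise.nrow() < n_steps || noise.ncol() != n)
    stop("noise matrix must be n_steps x n_cells");

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> s(G, 0.0);
  std::vector<double> cth(n + 1), S(n);

  NumericMatrix th_tr(n_steps, n + 1);
  NumericMatrix s_tr(n_steps, G);

  for (int i = 0; i < n_steps; ++i) {
    for (int j = 0; j <= n; ++j) th_tr(i, j) = theta[j];
    for (int g = 0; g < G; ++g) s_tr(i, g) = s[g];

    for (int j = 0; j <= n; ++j) cth[j] = std::cos(theta[j]);

    // synaptic input from gating state at t
    std::fill(S.begin(), S.end(), 0.0);
    for (int k = 0; k < n; ++k) {
      double acc = 0.0;
      for (int g = 0; g < G; ++g) acc += W(g, k) * s[g];
      S[k] = acc;
    }

    // gating update from presynaptic phase at t
    for (int g = 0; g < G; ++g) {
      double act = std::exp(-eta * (1.0 + cth[pre[g] - 1]));
      double sn = s[g] + dt * (-s[g] / tau_d[g] + act * (1.0 - s[g]) / tau_R);
      if (!(sn >= -1e-12 && sn <= 1.0 + 1e-12))
        stop("gating variable left [0,1] at step %d (dt too large)", i + 1);
      s[g] = sn;
    }

    // phase update
    for (int j = 0; j <= n; ++j) {
      double inp = (j < n) ? b[j] + S[j] + noise(i, j) : b_pace;
      double th = theta[j] + dt * (1.0 - cth[j] + inp * (1.0 + cth[j]));
      if (!std::isfinite(th))
        stop("non-finite phase at step %d (numerical blow-up)", i + 1);
      if (th >= two_pi) th -= two_pi;
      else if (th < 0.0) th += two_pi;
      theta[j] = th;
    }
  }

  return List::create(_["theta"] = th_tr, _["s"] = s_tr);
}
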