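#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoid scaling f(x) = 2/(1 + exp(-a*x)) - 1, exponent clamped to +-700
// (defensive: |a*x| stays far below that for the parameter ranges used).
static inline double sigmoid_scale1(double x, double a) {
  double e = -a * x;
  if (e > 700.0) e = 700.0;
  if (e < -700.0) e = -700.0;
  return 2.0 / (1.0 + std::exp(e)) - 1.0;
}

// [[Rcpp::export(name = ".sigmoid_scale_cpp")]]
NumericVector sigmoid_scale_cpp(NumericVector x, double a) {
  int m = x.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = sigmoid_scale1(x[i], a);
  return out;
}

// Squared-difference distance D(X, Y) = sum((x_i - y_i)^2) / (4n), in [0, 1]
// for vectors with elements in [-1, 1].
static inline double state_distance1(const double* x, const double* y, int n) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - y[i];
    acc += d * d;
  }
  return acc / (4.0 * n);
}

// phi over a full window of (tau + 1) states held in `win` (row-major,
// (tau+1) x n): mean state elementwise, then (1/tau) * sum of distances of
// each window member to the mean.
static double phi_window(const std::vector<double>& win, int tau, int n,
                         std::vector<double>& mean_buf) {
  int m = tau + 1;
  for (int j = 0; j < n; ++j) mean_buf[j] = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) mean_buf[j] += win[i * n + j];
  for (int j = 0; j < n; ++j) mean_buf[j] /= m;
  double acc = 0.0;
  for (int i = 0; i < m; ++i)
    acc += state_distance1(&win[i * n], &mean_buf[0], n);
  return acc / tau;
}

// Sample variance of the elements of a state (denominator n - 1); 0 for n < 2.
static double state_variance(const std::vector<double>& s) {
  int n = (int)s.size();
  if (n < 2) return 0.0;
  double m = 0.0;
  for (int j = 0; j < n; ++j) m += s[j];
  m /= n;
  double acc = 0.0;
  for (int j = 0; j < n; ++j) acc += (s[j] - m) * (s[j] - m);
  return acc / (n - 1);
}

// Develop-to-stability loop. States S_0..S_t are kept in a ring buffer of
// tau + 1 slots; phi is first evaluated at step index t = tau (the earliest
// index with a full window S_{t-tau}..S_t) and the run converges at the
// first t with phi < sigma; reaching l_max without that means no
// convergence. The individual is viable when it converges AND the variance
// of its stable expression levels is at least min_var (min_var = 0 reduces
// viability to bare convergence).
// [[Rcpp::export(name = ".develop_cpp")]]
List develop_cpp(NumericMatrix w, NumericVector s0, double a, int tau,
                 double sigma, int l_max, double min_var = 0.1,
                 bool keep_phi = false) {
  int n = w.nrow();
  std::vector<double> ring((tau + 1) * (size_t)n);
  std::vector<double> win((tau + 1) * (size_t)n);
  std::vector<double> mean_buf(n);
  std::vector<double> s(n), s_new(n);
  for (int j = 0; j < n; ++j) {
    s[j] = s0[j];
    ring[j] = s0[j];
  }
  std::vector<double> phis;
  if (keep_phi) phis.reserve(l_max);

  bool converged = false;
  int path = l_max;
  for (int t = 1; t <= l_max; ++t) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += w(i, j) * s[j];
      s_new[i] = sigmoid_scale1(acc, a);
    }
    s = s_new;
    int slot = t % (tau + 1);
    for (int j = 0; j < n; ++j) ring[slot * (size_t)n + j] = s[j];

    if (t >= tau) {
      // copy window in chronological order (order is irrelevant to phi, but
      // keeps the buffer contents well-defined)
      for (int k = 0; k <= tau; ++k) {
        int src = (t - tau + k) % (tau + 1);
        for (int j = 0; j < n; ++j)
          win[k * (size_t)n + j] = ring[src * (size_t)n + j];
      }
      double ph = phi_window(win, tau, n, mean_buf);
      if (keep_phi) phis.push_back(ph);
      if (ph < sigma) {
        converged = true;
        path = t;
        break;
      }
    }
  }

  bool viable = converged &&
    (min_var <= 0.0 || state_variance(s) >= min_var);
  NumericVector final_state(n);
  for (int j = 0; j < n; ++j) final_state[j] = s[j];
  List out = List::create(_["viable"] = viable,
                          _["converged"] = converged,
                          _["final_state"] = final_state,
                          _["path_length"] = path);
  if (keep_phi) out["phi_history"] = NumericVector(phis.begin(), phis.end());
  return out;
}

// Batched viability for Monte-Carlo sweeps: networks and initial vectors are
// drawn with R's RNG (uniform on [-1, 1]) so results are reproducible under
// set.seed(). Returns the number of viable draws out of `reps` at size n.
// [[Rcpp::export(name = ".random_viability_cpp")]]
int random_viability_cpp(int n, int reps, double a, int tau, double sigma,
                         int l_max, double min_var = 0.1) {
  RNGScope scope;
  NumericMatrix w(n, n);
  NumericVector s0(n);
  int viable = 0;
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) w(i, j) = R::runif(-1.0, 1.0);
    for (int j = 0; j < n; ++j) s0[j] = R::runif(-1.0, 1.0);
    List res = develop_cpp(w, s0, a, tau, sigma, l_max, min_var, false);
    if (as<bool>(res["viable"])) ++viable;
  }
  return viable;
}
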