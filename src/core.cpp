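#include <Rcpp.h>
using namespace Rcpp;

// Time-varying two-pole resonator (digital formant filter).
// Coefficients are recomputed per sample from the instantaneous center
// frequency f[t] (Hz) and bandwidth bw[t] (Hz).
// [[Rcpp::export]]
NumericVector cpp_resonator(NumericVector x, NumericVector f,
                            NumericVector bw, double fs) {
  int n = x.size();
  if (f.size() != n || bw.size() != n)
    stop("trajectory length mismatch");
  NumericVector y(n);
  double y1 = 0.0, y2 = 0.0;
  const double twopi = 2.0 * M_PI;
  for (int t = 0; t < n; ++t) {
    double r  = std::exp(-M_PI * bw[t] / fs);
    double a1 = 2.0 * r * std::cos(twopi * f[t] / fs);
    double a2 = -r * r;
    double b0 = 1.0 - r; // approximate unity gain at resonance
    double yt = b0 * x[t] + a1 * y1 + a2 * y2;
    y2 = y1;
    y1 = yt;
    y[t] = yt;
  }
  return y;
}

// Sum of peak-normalized alpha-function PSPs h(s) = (s/tau) exp(1 - s/tau)
// evaluated at the exact (continuous) spike-time offsets on a dt grid.
// spike_times and dt share units; n is the grid length; span is the kernel
// support in multiples of tau.
// [[Rcpp::export]]
NumericVector cpp_alpha_drive(NumericVector spike_times, double tau,
                              double dt, int n, double span = 8.0) {
  NumericVector out(n);
  int klen = (int)std::ceil(span * tau / dt);
  for (int s = 0; s < spike_times.size(); ++s) {
    double ts = spike_times[s];
    int k0 = (int)std::ceil(ts / dt);
    if (k0 < 0) k0 = 0;
    int k1 = std::min(n - 1, k0 + klen);
    for (int k = k0; k <= k1; ++k) {
      double u = k * dt - ts;
      if (u <= 0.0) continue;
      double v = u / tau;
      out[k] += v * std::exp(1.0 - v);
    }
  }
  return out;
}

// Causal direct convolution y[t] = sum_j k[j] x[t - j], same length as x.
// [[Rcpp::export]]
NumericVector cpp_conv_causal(NumericVector x, NumericVector kern) {
  int n = x.size(), m = kern.size();
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    int jmax = std::min(m - 1, t);
    double acc = 0.0;
    for (int j = 0; j <= jmax; ++j) acc += kern[j] * x[t - j];
    y[t] = acc;
  }
  return y;
}

// Leaky integrate-and-fire with exact exponential integrator:
//   V[t] = a V[t-1] + b I[t]
// (V relative to rest). Spike when V >= theta; reset to 0 and hold for
// refrac_steps samples. Returns spike step indices (1-based) and final trace.
// [[Rcpp::export]]
List cpp_lif(NumericVector I, double a, double b, double theta,
             int refrac_steps, bool keep_voltage = false) {
  int n = I.size();
  std::vector<int> spikes;
  NumericVector V;
  if (keep_voltage) V = NumericVector(n);
  double v = 0.0;
  int hold = 0;
  for (int t = 0; t < n; ++t) {
    if (hold > 0) {
      --hold;
      v = 0.0;
    } else {
      v = a * v + b * I[t];
      if (v >= theta) {
        spikes.push_back(t + 1);
        v = 0.0;
        hold = refrac_steps;
      }
    }
    if (keep_voltage) V[t] = v;
  }
  return List::create(_["spikes"] = wrap(spikes), _["voltage"] = V);
}

// Spike-triggered average of a (time x channel) envelope matrix.
// w: per-frame spike counts (length T). Returns (n_lag+1) x K matrix of
// sums over t of w[t] * env[t - lag, k]; caller normalizes by spike count.
// [[Rcpp::export]]
NumericMatrix cpp_sta(NumericMatrix env, NumericVector w, int n_lag) {
  int T = env.nrow(), K = env.ncol();
  NumericMatrix out(n_lag + 1, K);
  for (int t = 0; t < T; ++t) {
    double wt = w[t];
    if (wt == 0.0) continue;
    int lmax = std::min(n_lag, t);
    for (int lag = 0; lag <= lmax; ++lag) {
      int src = t - lag;
      for (int k = 0; k < K; ++k) out(lag, k) += wt * env(src, k);
    }
  }
  return out;
}
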