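// Event-driven, exact simulators for the shot-noise LIF neuron and for
// sparse inhibitory networks.  Between synaptic events the membrane relaxes
// analytically, v(t + d) = mu + (v - mu) e^{-d/tau}; deterministic threshold
// crossings are resolved in closed form, so no discretization parameter
// exists anywhere.  All randomness comes from the R random stream.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Amplitude draw.  code: 0 delta(p1); 1 exponential(mean p1, sign of p1);
// 2 uniform(p1, p2); 3 truncated Gaussian (peak p1, width p2, support <= 0,
// rejection sampling).
static inline double draw_amp(int code, double p1, double p2) {
  switch (code) {
  case 0: return p1;
  case 1: return p1 >= 0 ? R::rexp(p1) : -R::rexp(-p1);
  case 2: return R::runif(p1, p2);
  default: {
    double x;
    do { x = R::rnorm(p1, p2); } while (x > 0.0);
    return x;
  }
  }
}

// [[Rcpp::export]]
NumericVector cpp_simulate_lif(double tau, double vth, double vre,
                               double mu0, double Re, double ae,
                               double Ri, int icode, double ip1, double ip2,
                               int n_spikes, int burn_spikes,
                               double max_events) {
  RNGScope scope;
  std::vector<double> spikes;
  spikes.reserve(n_spikes);
  const double Rtot = Re + Ri;
  const double pe = Rtot > 0 ? Re / Rtot : 0.0;
  double v = vre, t = 0.0;
  long long events = 0;
  int collected = 0, burned = 0;

  double t0 = 0.0;   // end of the burn-in epoch; output times are t - t0
  auto emit = [&](double ts) {
    if (burned < burn_spikes) { ++burned; t0 = ts; return; }
    spikes.push_back(ts - t0); ++collected;
  };

  while (collected < n_spikes) {
    double dt = Rtot > 0 ? R::rexp(1.0 / Rtot) : R_PosInf;
    // deterministic crossings before the next synaptic event
    if (mu0 > vth) {
      double ts = v < vth ? tau * std::log((mu0 - v) / (mu0 - vth)) : 0.0;
      while (ts < dt) {
        t += ts; dt -= ts;
        emit(t);
        if (collected >= n_spikes) return NumericVector(spikes.begin(), spikes.end());
        v = vre;
        ts = tau * std::log((mu0 - v) / (mu0 - vth));
      }
    } else if (Rtot == 0.0) {
      stop("silent configuration: no noise and mu0 <= v_th");
    }
    if (!R_FINITE(dt)) stop("no events and no tonic firing: neuron silent");
    // relax to the event time, apply the kick
    t += dt;
    v = mu0 + (v - mu0) * std::exp(-dt / tau);
    bool exc = pe > 0 && R::unif_rand() < pe;
    v += exc ? R::rexp(ae) : draw_amp(icode, ip1, ip2);
    if (v >= vth) {        // crossing by excitatory overshoot
      emit(t);
      v = vre;
    }
    if (++events > max_events && collected + burned == 0)
      stop("no spikes within the event budget: configuration appears silent");
  }
  return NumericVector(spikes.begin(), spikes.end());
}

// Indexed binary min-heap over neuron crossing times.
struct Heap {
  std::vector<double> key;
  std::vector<int> heap, pos;   // heap of neuron ids; pos[id] = index in heap
  Heap(int n) : key(n, R_PosInf), heap(n), pos(n) {
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  void swap_(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a; pos[heap[b]] = b;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (key[heap[i]] < key[heap[p]]) { swap_(i, p); i = p; } else break;
    }
  }
  void down(int i) {
    int n = heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && key[heap[l]] < key[heap[m]]) m = l;
      if (r < n && key[heap[r]] < key[heap[m]]) m = r;
      if (m == i) break;
      swap_(i, m); i = m;
    }
  }
  void update(int id, double k) {
    double old = key[id]; key[id] = k;
    if (k < old) up(pos[id]); else down(pos[id]);
  }
  int top() const { return heap[0]; }
  double top_key() const { return key[heap[0]]; }
};

// [[Rcpp::export]]
List cpp_simulate_network(double tau, double vth, double vre,
                          NumericVector mu, IntegerMatrix pre,
                          NumericVector a_of_pre,
                          int n_spikes, int burn_spikes) {
  const int N = mu.size();
  const int K = pre.nrow();        // pre(k, j): k-th presynaptic neuron of j
  // postsynaptic adjacency
  std::vector< std::vector<int> > targets(N);
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < K; ++k)
      targets[pre(k, j) - 1].push_back(j);

  std::vector<double> v(N, vre), tl(N, 0.0);
  Heap hp(N);
  auto crossing = [&](int j, double now) -> double {
    if (mu[j] <= vth) return R_PosInf;   // sub-threshold: never crosses
    return now + tau * std::log((mu[j] - v[j]) / (mu[j] - vth));
  };
  for (int j = 0; j < N; ++j) hp.update(j, crossing(j, 0.0));

  std::vector<double> sp_t; std::vector<int> sp_id;
  sp_t.reserve(n_spikes); sp_id.reserve(n_spikes);
  int collected = 0, burned = 0;
  double t = 0.0;

  while (collected < n_spikes) {
    int k = hp.top();
    t = hp.top_key();
    if (!R_FINITE(t)) break;      // network went silent
    // neuron k fires
    if (burned < burn_spikes) ++burned;
    else { sp_t.push_back(t); sp_id.push_back(k + 1); ++collected; }
    v[k] = vre; tl[k] = t;
    hp.update(k, crossing(k, t));
    const double a = a_of_pre[k];
    for (int idx : targets[k]) {
      v[idx] = mu[idx] + (v[idx] - mu[idx]) * std::exp(-(t - tl[idx]) / tau);
      tl[idx] = t;
      v[idx] += a;               // inhibitory kick, a < 0
      hp.update(idx, crossing(idx, t));
    }
  }
  return List::create(_["t"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["id"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["t_end"] = t);
}
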