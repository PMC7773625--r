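#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Explicit operator-split monodomain time stepping with a two-variable
// excitable membrane (normalised voltage in [0,1], recovery gate h).
// The diffusion (+ interlayer coupling) operator L is passed in CSC form:
// dV/dt = L V + I_ion(V,h) + I_stim.
//
// Lp: column pointers (length n+1), Li: row indices, Lx: values.
// stim_nodes: list of 0-based index vectors; stim_on/stim_off: ms windows,
// repeated every stim_cycle[s] ms for stim_count[s] repeats; stim_amp: 1/ms.
// Recording: frames at times t0 + k*dt with k % rec_stride == 0 and
// t >= rec_start (first frame at the first such step).
// [[Rcpp::export]]
List cpp_monodomain(IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                    NumericVector V0, NumericVector h0,
                    double t0, double dt, int nsteps,
                    double tau_in, double tau_out, double tau_open,
                    double tau_close, double v_gate, double excit,
                    List stim_nodes, NumericVector stim_on,
                    NumericVector stim_dur, NumericVector stim_cycle,
                    IntegerVector stim_count, NumericVector stim_amp,
                    double rec_start, int rec_stride) {
  const int n = V0.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> dV(n, 0.0);

  // precount recorded frames
  std::vector<int> rec_steps;
  for (int k = 1; k <= nsteps; ++k) {
    double t = t0 + k * dt;
    if (t >= rec_start - 1e-9 && (k % rec_stride) == 0) rec_steps.push_back(k);
  }
  NumericMatrix Vrec(n, (int)rec_steps.size());
  NumericVector trec(rec_steps.size());
  size_t rptr = 0;

  const int nstim = stim_on.size();
  std::vector<std::vector<int> > snodes(nstim);
  for (int s = 0; s < nstim; ++s) {
    IntegerVector iv = stim_nodes[s];
    snodes[s].assign(iv.begin(), iv.end());
  }

  bool aborted = false;
  int k = 1;
  for (; k <= nsteps; ++k) {
    double t = t0 + (k - 1) * dt;
    // diffusion: dV = L V (CSC: iterate columns)
    std::fill(dV.begin(), dV.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double xj = V[j];
      if (xj == 0.0) continue;
      for (int p = Lp[j]; p < Lp[j + 1]; ++p) dV[Li[p]] += Lx[p] * xj;
    }
    // reaction + stimulus, forward Euler
    for (int i = 0; i < n; ++i) {
      double v = V[i], hh = h[i];
      double ion = excit * hh * v * v * (1.0 - v) / tau_in - v / tau_out;
      V[i] = v + dt * (dV[i] + ion);
      h[i] = hh + dt * (v < v_gate ? (1.0 - hh) / tau_open
                                   : -hh / tau_close);
    }
    for (int s = 0; s < nstim; ++s) {
      double rel = t - stim_on[s];
      if (rel < 0) continue;
      double cyc = stim_cycle[s];
      int beat = (cyc > 0) ? (int)std::floor(rel / cyc) : 0;
      if (beat >= stim_count[s]) continue;
      double ph = rel - beat * ((cyc > 0) ? cyc : 0.0);
      if (ph < stim_dur[s]) {
        double add = dt * stim_amp[s];
        for (size_t q = 0; q < snodes[s].size(); ++q)
          V[snodes[s][q]] += add;
      }
    }
    // stability guard
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = std::fabs(V[i]);
      if (a > vmax) vmax = a;
    }
    if (!std::isfinite(vmax) || vmax > 10.0) { aborted = true; break; }
    if (rptr < rec_steps.size() && k == rec_steps[rptr]) {
      for (int i = 0; i < n; ++i) Vrec(i, (int)rptr) = V[i];
      trec[rptr] = t0 + k * dt;
      ++rptr;
    }
    if ((k % 50000) == 0) Rcpp::checkUserInterrupt();
  }
  if (aborted) {
    // truncate recordings to frames actually written
    Vrec = Vrec(_, Range(0, std::max(0, (int)rptr - 1)));
    trec = trec[Range(0, std::max(0, (int)rptr - 1))];
  }
  return List::create(_["t"] = trec, _["V"] = Vrec,
                      _["v_end"] = NumericVector(V.begin(), V.end()),
                      _["h_end"] = NumericVector(h.begin(), h.end()),
                      _["aborted"] = aborted,
                      _["t_end"] = t0 + (aborted ? k : nsteps) * dt);
}

// Single-cell (0D) run of the same membrane, used for stimulus-threshold
// calibration and action-potential templates.
// [[Rcpp::export]]
List cpp_membrane0d(double v0, double h0, double t0, double dt, int nsteps,
                    double tau_in, double tau_out, double tau_open,
                    double tau_close, double v_gate, double excit,
                    NumericVector stim_on, NumericVector stim_dur,
                    NumericVector stim_amp) {
  NumericVector V(nsteps + 1), H(nsteps + 1), T(nsteps + 1);
  double v = v0, h = h0;
  V[0] = v; H[0] = h; T[0] = t0;
  for (int k = 1; k <= nsteps; ++k) {
    double t = t0 + (k - 1) * dt;
    double ion = excit * h * v * v * (1.0 - v) / tau_in - v / tau_out;
    double st = 0.0;
    for (int s = 0; s < stim_on.size(); ++s)
      if (t >= stim_on[s] && t < stim_on[s] + stim_dur[s]) st += stim_amp[s];
    double vn = v + dt * (ion + st);
    double hn = h + dt * (v < v_gate ? (1.0 - h) / tau_open : -h / tau_close);
    v = vn; h = hn;
    V[k] = v; H[k] = h; T[k] = t0 + k * dt;
  }
  return List::create(_["t"] = T, _["v"] = V, _["h"] = H);
}
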