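#include <Rcpp.h>
using namespace Rcpp;

// Explicit forward update of a compartment network over n_steps of size dt.
// Same arithmetic as the R reference step (circulation_step); kept in C++
// because a 60 s run is 60,000 sequential steps.
//
// kind: 0 = compliant vessel, 1 = elastance chamber, 2 = pressure source.
// up/dn: 1-based compartment indices per connector; dn == 0 drains to an
// external zero-pressure sink.
// act: activation per step-in-cycle (rows) and compartment (cols);
// ecg: waveform per step-in-cycle. step0 is the current 0-based position
// within the cycle; both tables wrap modulo their length.
//
// Recorded rows (pre-update state): t, volumes, pressures, flows, ecg.
// [[Rcpp::export]]
List simulate_chunk(NumericVector V0, int gstep0, int step0,
                    IntegerVector kind,
                    NumericVector e_min, NumericVector e_max_eff,
                    NumericVector v0,
                    NumericVector compliance, NumericVector v_unstressed,
                    NumericVector p_fixed,
                    IntegerVector up, IntegerVector dn,
                    NumericVector resistance, LogicalVector is_valve,
                    NumericMatrix act, NumericVector ecg,
                    double dt, int n_steps, int record_every, bool record) {
  const int n = V0.size();
  const int m = up.size();
  const int spc = act.nrow();

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> P(n), Q(m);

  int n_rec = record ? (n_steps + record_every - 1) / record_every + 1 : 0;
  NumericMatrix rec(n_rec, record ? (1 + n + n + m + 1) : 0);
  int rec_row = 0;

  int err_comp = -1;
  int k = 0;
  for (; k < n_steps; ++k) {
    int s = (step0 + k) % spc;

    // pressures from current volumes
    for (int i = 0; i < n; ++i) {
      if (kind[i] == 1) {
        double e = e_min[i] + act(s, i) * (e_max_eff[i] - e_min[i]);
        double dv = V[i] - v0[i];
        P[i] = e * (dv > 0 ? dv : 0);
      } else if (kind[i] == 0) {
        double p = (V[i] - v_unstressed[i]) / compliance[i];
        P[i] = p > 0 ? p : 0;
      } else {
        P[i] = p_fixed[i];
      }
    }

    // flows from current pressures
    for (int j = 0; j < m; ++j) {
      double pu = P[up[j] - 1];
      double pd = dn[j] > 0 ? P[dn[j] - 1] : 0.0;
      double q = (pu - pd) / resistance[j];
      if (is_valve[j] && q < 0) q = 0;
      Q[j] = q;
    }

    if (record && (gstep0 + k) % record_every == 0) {
      rec(rec_row, 0) = (gstep0 + k) * dt;
      for (int i = 0; i < n; ++i) rec(rec_row, 1 + i) = V[i];
      for (int i = 0; i < n; ++i) rec(rec_row, 1 + n + i) = P[i];
      for (int j = 0; j < m; ++j) rec(rec_row, 1 + 2 * n + j) = Q[j];
      rec(rec_row, 1 + 2 * n + m) = ecg[s];
      ++rec_row;
    }

    // volume update; sources are unbounded reservoirs and store nothing
    for (int j = 0; j < m; ++j) {
      double dv = dt * Q[j];
      if (kind[up[j] - 1] != 2) V[up[j] - 1] -= dv;
      if (dn[j] > 0 && kind[dn[j] - 1] != 2) V[dn[j] - 1] += dv;
    }
    for (int i = 0; i < n; ++i) {
      if (kind[i] != 2 && V[i] < 0) { err_comp = i; break; }
    }
    if (err_comp >= 0) { ++k; break; }
  }

  return List::create(
    _["V"] = NumericVector(V.begin(), V.end()),
    _["gstep"] = gstep0 + k,
    _["t"] = (gstep0 + k) * dt,
    _["steps_done"] = k,
    _["step_in_cycle"] = (step0 + k) % spc,
    _["rec"] = rec,
    _["rec_rows"] = rec_row,
    _["err_comp"] = err_comp + 1  // 0 = no error (1-based index otherwise)
  );
}
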