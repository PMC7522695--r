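#include <Rcpp.h>
using namespace Rcpp;

// Forward propagation of the cohort for one strategy arm.
//
// Line states are expanded by time-in-state (tunnel cells) so each line's
// progression clock runs from entry into that line, while the death
// probability is indexed by model time and applies to every alive state.
//
// prog:  n_lines x n_cycles progression-only probabilities, column s is
//        the probability for a cell that has spent s cycles in the line.
// death: length n_cycles per-cycle death probabilities on model time.
//
// Returns the aggregate occupancy matrix (cycles+1 x lines+BSC+DEAD) and
// per-cycle progression and death flows.
// [[Rcpp::export(name = ".cohort_kernel")]]
List cohort_kernel(NumericMatrix prog, NumericVector death, int n_cycles) {
  const int nl = prog.nrow();
  if (death.size() < n_cycles) stop("death schedule shorter than horizon");
  if (prog.ncol() < n_cycles) stop("progression schedule shorter than horizon");

  std::vector< std::vector<double> > occ(nl, std::vector<double>(n_cycles + 1, 0.0));
  occ[0][0] = 1.0;
  double bsc = 0.0, dead = 0.0;

  NumericMatrix M(n_cycles + 1, nl + 2);
  M(0, 0) = 1.0;
  NumericVector prog_flow(n_cycles), death_flow(n_cycles);
  std::vector<double> flows(nl);

  for (int t = 0; t < n_cycles; ++t) {
    const double pd = death[t];
    double alive = bsc;
    double total_flow = 0.0;

    for (int j = 0; j < nl; ++j) {
      double f = 0.0;
      for (int s = 0; s <= t; ++s) {
        const double v = occ[j][s];
        if (v > 0.0) {
          const double pp = prog(j, s);
          if (pp + pd > 1.0 + 1e-12)
            stop("schedule error: progression + death probability exceeds 1 in cycle %d",
                 t + 1);
          f += v * pp;
          alive += v;
        }
      }
      flows[j] = f;
      total_flow += f;
    }

    for (int j = 0; j < nl; ++j) {
      for (int s = t; s >= 0; --s) {
        const double v = occ[j][s];
        occ[j][s + 1] = (v > 0.0) ? v * (1.0 - prog(j, s) - pd) : 0.0;
      }
      occ[j][0] = (j > 0) ? flows[j - 1] : 0.0;
    }

    bsc = bsc * (1.0 - pd) + flows[nl - 1];
    dead += pd * alive;
    prog_flow[t] = total_flow;
    death_flow[t] = pd * alive;

    for (int j = 0; j < nl; ++j) {
      double tot = 0.0;
      for (int s = 0; s <= t + 1; ++s) tot += occ[j][s];
      M(t + 1, j) = tot;
    }
    M(t + 1, nl) = bsc;
    M(t + 1, nl + 1) = dead;
  }

  return List::create(_["occupancy"] = M,
                      _["prog_flow"] = prog_flow,
                      _["death_flow"] = death_flow);
}
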