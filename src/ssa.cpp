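// Gillespie direct method for mass-action reaction networks.
//
// Propensity of reaction j: c_j * prod over its rate factors of the falling
// factorial n (n-1) ... (n-m+1) of the current count (environment-held
// species included as factors; their counts never change because their rows
// of the net-change matrix are zero).  Uses R's RNG so that set.seed()
// yields bit-identical trajectories.

#include <Rcpp.h>
using namespace Rcpp;

// flat CSR-style layout of the network for a tight inner loop
struct Net {
  int nsp, nrx;
  std::vector<double> cconst;            // rate constants
  std::vector<int> foff, fsp, fmul;      // rate factors per reaction
  std::vector<int> doff, dsp, dval;      // state updates per reaction
  std::vector<int> goff, gdep;           // reactions whose propensity a
                                         // firing of j can change
};

static Net build_net(const NumericVector& rate_const, const List& factor_species,
                     const List& factor_mult, const IntegerMatrix& net) {
  Net w;
  w.nsp = net.nrow();
  w.nrx = net.ncol();
  w.cconst.assign(rate_const.begin(), rate_const.end());
  w.foff.push_back(0);
  w.doff.push_back(0);
  for (int j = 0; j < w.nrx; ++j) {
    IntegerVector fs = factor_species[j], fm = factor_mult[j];
    for (int q = 0; q < fs.size(); ++q) {
      w.fsp.push_back(fs[q]);
      w.fmul.push_back(fm[q]);
    }
    w.foff.push_back((int) w.fsp.size());
    for (int i = 0; i < w.nsp; ++i)
      if (net(i, j) != 0) { w.dsp.push_back(i); w.dval.push_back(net(i, j)); }
    w.doff.push_back((int) w.dsp.size());
  }
  // dependency graph: firing j changes species in dsp[j]; any reaction with
  // a rate factor on one of those species must have its propensity redone
  w.goff.push_back(0);
  for (int j = 0; j < w.nrx; ++j) {
    for (int q = 0; q < w.nrx; ++q) {
      bool hit = false;
      for (int d = w.doff[j]; d < w.doff[j + 1] && !hit; ++d)
        for (int f = w.foff[q]; f < w.foff[q + 1] && !hit; ++f)
          if (w.fsp[f] == w.dsp[d]) hit = true;
      if (hit) w.gdep.push_back(q);
    }
    w.goff.push_back((int) w.gdep.size());
  }
  return w;
}

static inline double propensity(const Net& w, int j, const double* x) {
  double a = w.cconst[j];
  for (int q = w.foff[j]; q < w.foff[j + 1]; ++q) {
    double n = x[w.fsp[q]];
    for (int i = 0; i < w.fmul[q]; ++i) a *= (n - i);
    if (a <= 0.0) return 0.0;
  }
  return a;
}

// advance one realization to t_end (or deadlock); returns final time,
// sets *dead; optionally records onto grid by last-value-carried-forward
static double run_one(const Net& w, std::vector<double>& x, double t_end,
                      const double* grid, int ng, double* rec,
                      bool* dead, double* nev) {
  std::vector<double> a(w.nrx);
  double t = 0.0;
  int g = 0;
  *dead = false;
  for (int j = 0; j < w.nrx; ++j) a[j] = propensity(w, j, x.data());
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < w.nrx; ++j) a0 += a[j];
    if (a0 <= 0.0) { *dead = true; break; }
    double tnext = t + exp_rand() / a0;
    while (g < ng && grid[g] < tnext) {
      for (int i = 0; i < w.nsp; ++i) rec[g + (R_xlen_t) ng * i] = x[i];
      ++g;
    }
    if (tnext > t_end) { t = t_end; break; }
    double u = unif_rand() * a0, cum = 0.0;
    int j = w.nrx - 1;
    for (int q = 0; q < w.nrx; ++q) {
      cum += a[q];
      if (u <= cum) { j = q; break; }
    }
    for (int q = w.doff[j]; q < w.doff[j + 1]; ++q)
      x[w.dsp[q]] += w.dval[q];
    for (int q = w.goff[j]; q < w.goff[j + 1]; ++q)
      a[w.gdep[q]] = propensity(w, w.gdep[q], x.data());
    t = tnext;
    *nev += 1.0;
  }
  while (g < ng) {               // remaining grid points hold the final state
    for (int i = 0; i < w.nsp; ++i) rec[g + (R_xlen_t) ng * i] = x[i];
    ++g;
  }
  return t;
}

// One realization recorded onto `grid` by last-value-carried-forward.
// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector init, NumericVector rate_const,
                 List factor_species, List factor_mult,
                 IntegerMatrix net, NumericVector grid, double t_end) {
  Net w = build_net(rate_const, factor_species, factor_mult, net);
  std::vector<double> x(init.begin(), init.end());
  const int ng = grid.size();
  NumericMatrix rec(ng, w.nsp);
  bool dead = false;
  double nev = 0.0;
  RNGScope scope;
  double t = run_one(w, x, t_end, REAL(grid), ng, REAL(rec), &dead, &nev);
  IntegerVector fin(w.nsp);
  for (int i = 0; i < w.nsp; ++i) fin[i] = (int) x[i];
  return List::create(_["series"] = rec, _["extinct"] = dead,
                      _["t_extinct"] = dead ? t : NA_REAL,
                      _["final_counts"] = fin, _["n_events"] = nev);
}

// Batch of replicates from one RNG stream: final state and extinction
// status per replicate (used for distribution checks and sweeps).
// [[Rcpp::export]]
List ssa_finals_cpp(IntegerVector init, NumericVector rate_const,
                    List factor_species, List factor_mult,
                    IntegerMatrix net, double t_end, int n_reps) {
  Net w = build_net(rate_const, factor_species, factor_mult, net);
  IntegerMatrix fin(n_reps, w.nsp);
  LogicalVector ext(n_reps);
  NumericVector text(n_reps);
  RNGScope scope;
  for (int r = 0; r < n_reps; ++r) {
    std::vector<double> x(init.begin(), init.end());
    bool dead = false;
    double nev = 0.0;
    double t = run_one(w, x, t_end, NULL, 0, NULL, &dead, &nev);
    for (int i = 0; i < w.nsp; ++i) fin(r, i) = (int) x[i];
    ext[r] = dead;
    text[r] = dead ? t : NA_REAL;
  }
  return List::create(_["final_counts"] = fin, _["extinct"] = ext,
                      _["t_extinct"] = text);
}
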